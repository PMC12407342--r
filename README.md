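# kranzC4

Downstream analysis of single-nucleus expression and chromatin-accessibility
data from plants with environmentally plastic C3–C4 photosynthesis — sedges
whose culms develop a C4-like Kranz anatomy on land and revert to C3-like
tissue when submerged. The package targets the questions such a study asks
once counts, cell labels and peak-to-gene links are in hand:

* **Which cell types express the C4 enzymes, and from which subgenome?**
  In an allotetraploid, each enzyme family is encoded by homeologous A/B
  gene pairs. For a gene *g* and two cell types (inner mesophyll IMC and
  Kranz cell KC), the expression differential is

  ```
  D(g) = | Exp_imc(g) − Exp_kc(g) |
  ```

  and the subgenome weight of a homeolog set is

  ```
  Weight_B/AB = Σ D_B / (Σ D_A + Σ D_B)
  ```

  A weight above 0.5 means subgenome B carries the larger share of the
  cell-type differential (B dominance); below 0.5, subgenome A.

* **Which genes mark a cell type or condition?** A self-contained two-sided
  Wilcoxon rank-sum screen (exact small-sample mode plus a tie- and
  continuity-corrected normal mode) with Bonferroni or Benjamini–Hochberg
  adjustment, retaining genes with fold change > 1.5 and adjusted p < 0.05.

* **Which transcription-factor motif families act where?** Accessible
  cis-regulatory elements linked to genes are tabulated per motif family
  and group; each group column is normalised to sum to 1. Per group the
  predominant family is called, and a family is *environment-triggered*
  when its rate is high under one condition (≥ 0.10) and low under the
  other (≤ 0.05). An IUPAC consensus scanner measures intrinsic promoter
  composition (overlapping matches, both strands, `N` never matches).

* **Which cell-specialised genes are conserved across C4 species?**
  Reciprocal-best-hit orthology (e-value ≤ 1e-10) plus a screen for genes
  highly expressed exclusively in the C4 forms of both species within the
  same cell class (IMC↔mesophyll, KC↔bundle sheath).

* **When did the subgenomes diverge?** The molecular-clock conversions
  T = K/(2r) and r = K/(2T) on mean synonymous substitution values.

A fully deterministic synthetic-data generator emulates the study design —
three growth conditions (terrestrial, submerged, submerged + ABA), eight
cell types, ~1232 UMIs per cell, homeolog families planted at known
subgenome weights, planted motif rates and promoter motifs — so every
stage is testable with known ground truth and no sequencing data.

## Worked example

```r
library(kranzC4)

ex  <- simulateExpression(simConfig(seed = 1))
sce <- normalizeCP10K(qcFilter(ex$sce))          # UMIs > 500, genes > 200
prof <- cellTypeProfile(sce)                     # mean cp10k per group

dv <- computeDvalues(prof, "IMC", "KC", "terrestrial",
                     genes = homeologGeneIds(simConfig()))
dominanceReport(subgenomeWeights(dv, ex$homeologs))
```

```
DataFrame with 5 rows and 7 columns
       set_id   sum_D_A   sum_D_B weight_B_AB   n_pairs    n_zero        call
  <character> <numeric> <numeric>   <numeric> <integer> <integer> <character>
1         bCA   80.1835  126.2910    0.611654         4         0  B-dominant
2      NAD-ME  301.9180  151.3109    0.333851         4         0  A-dominant
3        PEPC  147.4862  230.0401    0.609335         4         0  B-dominant
4        PPDK   27.8003   53.4543    0.657862         2         0  B-dominant
5 RuBisCO-SSU  727.4252  277.3644    0.276042         4         0  A-dominant
```

The default simulation plants weights 0.63, 0.56, 0.67, 0.31 and 0.29 for
the five families; with 60 cells per group the estimates fluctuate around
the planted values (here 0.61/0.61/0.66/0.33/0.28) while the dominance
direction of every family is called correctly. `sum_D_A`/`sum_D_B` are the
summed per-gene differentials in cp10k units; `n_zero` counts pairs with
no differential at all.

The whole pipeline, from simulation (or Matrix-Market + TSV inputs) to a
summary JSON, runs as:

```r
runPipeline(list(simulate = list(seed = 1)), out_dir = "out")
```

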