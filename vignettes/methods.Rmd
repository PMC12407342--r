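---
title: "Models and methods in kranzC4"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in kranzC4}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

kranzC4 analyses single-nucleus expression and chromatin-accessibility data
from plants whose photosynthetic mode is environmentally plastic: culms
grown on land develop C4-like Kranz anatomy (an inner mesophyll layer, IMC,
cooperating with Kranz cells, KC), while submerged culms stay C3-like. The
package starts from processed inputs — a genes × cells UMI count matrix,
cell-type/condition labels, a homeolog pair table, a peak-to-gene link
table with motif-family assignments, promoter sequences, and cross-species
similarity scores — and implements the downstream statistics: cell-type
expression profiles, a differential-expression screen, the subgenome
dominance weight, motif-family frequency profiles and calls, promoter
consensus scanning, reciprocal-best-hit orthology with a conserved-gene
screen, and Ks-based divergence timing. Upstream steps (alignment,
counting, clustering, annotation, peak calling, peak-to-gene linking)
are deliberately out of scope; their outputs are inputs here.

# Normalisation and expression profiles

Cells are first filtered by the study's retention rule — strictly more
than 500 UMIs and strictly more than 200 detected genes — implemented in
`qcFilter()` with configurable thresholds. Counts are then scaled to
10,000 per cell (`cp10k`) with a `log1p` companion layer.

The original analysis used a variance-stabilising regression fit for
normalisation; this package instead uses counts-per-10k because it is
fully specified, exactly deterministic and sufficient for the two places
normalisation matters here: linear group means (profiles, fold changes,
D-values) and rank-based testing (ranks are invariant to monotone
per-cell scaling). The layer used by each downstream statistic is
configurable.

`cellTypeProfile()` computes the arithmetic mean of the chosen layer over
every (cell type, condition) group. The scale on which the dominance
statistic lives is not dictated by its definition; linear cp10k means are
the default, with the layer as a parameter.

# The subgenome dominance statistic

For gene *g*, `D(g) = |Exp_imc(g) − Exp_kc(g)|` under one condition, and
for a set of A/B homeolog pairs

`Weight_B/AB = Σ D_B / (Σ D_A + Σ D_B)`.

Weights are computed per enzyme family by default (`subgenomeWeights()`),
matching how per-family values are reported for the C4 enzymes, and for
arbitrary pooled sets via `subgenomeWeight()`. Properties the
implementation guarantees and the tests verify: the weight is invariant
to multiplying all expression values by a constant, complementary under
exchanging the A/B labels (`w → 1 − w`), and equal to the brute-force
ratio of sums to 1e-12. A set whose D-values are all zero raises an
error instead of reporting 0.5: a weight of one half would assert
balance without evidence. Whether the published weights were computed on
all homeolog pairs or only on pairs differentially expressed between the
two cell types is not stated; the pipeline computes them on all pairs by
default, and a marker-restricted variant is obtained by subsetting the
`HomeologPairs` table to pairs whose members pass `findMarkerGenes()`
before calling `subgenomeWeight()`.

`dominanceReport()` classifies `weight > 0.5 + margin` as B-dominant and
`weight < 0.5 − margin` as A-dominant, with `margin = 0` by default so
that reported weights such as 0.63 and 0.29 map to B- and A-dominance
respectively.

# The marker screen

`findMarkerGenes()` re-implements the conventional single-cell marker
test rather than calling an existing toolkit, because the screen's exact
behaviour is part of what the package specifies. Per gene:

* fold change = (mean cp10k in group 1 + 0.1) / (mean cp10k in group 2 +
  0.1); the pseudocount (configurable) stabilises zero means, and
  "fold change > 1.5" is applied two-sidedly via `max(fc, 1/fc)`, since
  both up- and down-regulated sets are of interest;
* a two-sided Wilcoxon rank-sum p-value on the `log1p` layer;
* adjustment over all tested genes, Bonferroni by default (the default of
  the widely used screening tool) with Benjamini–Hochberg available — the
  adjustment behind the published "adjusted p" is not stated, so both are
  provided;
* retention at adjusted p < 0.05.

`rankSumTest()` has two modes. When both groups have at most 8
observations and there are no ties, the exact null distribution of the
rank sum is enumerated by dynamic programming and the smaller tail is
doubled (capped at 1) — identical to the exhaustive permutation two-sided
p-value for tie-free data. Otherwise a normal approximation with tie
correction and continuity correction is used. On tiny tied samples (both
groups ≤ 6) the approximation typically stays within 0.15 of the
exhaustive permutation p (about 90% of random tied cases) but can
deviate by up to ~0.5 when the data are nearly degenerate, e.g. one
group constant; it converges rapidly with group size and the screen is
intended for groups of tens to hundreds of cells. Bonferroni and BH are
implemented directly from their formulas and cross-checked against the
reference implementations in the tests.

# Motif-family frequency profiles and calls

`countElements()` restricts a peak-to-gene link table to a gene set and
tabulates motif families per group. The counting unit is ambiguous in
frequency-of-elements summaries — one accessible element can be linked
several times — so both modes exist: `element` (distinct element–family
pairs; default) and `occurrence` (rows). `normalizeFrequency()` divides
each group column by its total, so every non-degenerate column sums to 1
(the normalisation stated in the source heat maps); all-zero columns are
kept as zeros and flagged degenerate, never NaN. When rates are averaged
over a gene set, normalisation happens before averaging by default.

`callPredominant()` reports the maximal-rate family per group (ties all
reported, lexicographic) when that rate reaches `tau_pred = 0.10`.
`callEnvironmentTriggered()` formalises "high under condition 1, low
under condition 2" as rate₁ ≥ 0.10 and rate₂ ≤ 0.05. The defaults are
motivated by the magnitude of published exemplar contrasts (21.6% vs 0%,
18% vs 5%, 10.4% vs 0%) and are fully configurable, since no numeric
rule is published.

# Promoter scanning

`scanPromoters()` measures intrinsic promoter composition by sliding an
IUPAC consensus across each sequence: every position is tested, overlaps
count, `N` in the sequence never matches any pattern symbol, and in
`both` mode hits of the reverse-complemented pattern on the forward
sequence are added. Palindromic patterns therefore count once per strand;
an optional `dedup` flag collapses coincident forward/reverse hits. This
convention is explicit and oracle-checkable; the tests compare the
scanner against an independent regex-lookahead enumerator on random
sequence/pattern pairs and against the closed-form background expectation
`2·(L − m + 1)/4^m` per uniform promoter. The matcher is implemented
in-package with bitmask arithmetic because the stated `N` semantics
(sequence `N` matches nothing, ever) differ from common IUPAC matchers,
which let pattern `N` match a literal `N`.

# Orthology and the conserved-gene screen

`reciprocalBestHits()` filters similarity rows at e-value ≤ 1e-10 (when
e-values are present), finds each gene's best-scoring partner in both
directions and keeps mutual pairs. Score ties are resolved toward the
lexicographically smallest partner and logged, rather than dropped, so
the output is deterministic and auditable.

`conservedExclusiveSets()` formalises "highly expressed exclusively in
the C4 forms of both species": gene g₁ must be in species 1's
C4-condition DE set but not its C3-condition set for cell class k, have
an ortholog g₂, and g₂ must satisfy the same for the corresponding class
in species 2. The class correspondence is fixed to IMC↔mesophyll and
KC↔bundle sheath, the cell types paired across C4 species. The four DE
sets are taken as given — each study's own thresholds may stand behind
them.

# Divergence timing

`timeFromKs()` and `rateFromKs()` implement T = K/(2r) and r = K/(2T) on
mean synonymous substitution values, with strict positivity checks on
the denominator and an exact roundtrip identity. No default substitution
rate is shipped: the calibration rate is study-specific and must be
supplied.

# The synthetic-data generator

`simConfig()` fixes the simulated study conditions. Defaults: three
conditions (terrestrial, submerged, submerged + ABA), eight cell types
including IMC/OMC/KC, 60 cells per (cell type × condition), library
sizes lognormal with mean 1232 UMIs (log-sd 0.3), a shared gamma-Poisson
dispersion of 0.5 (variance `mu + 0.5 mu²`, a typical UMI overdispersion
regime), 2000 lognormal background genes, and five homeolog families
planted at the reported subgenome weights — bCA 0.63, PEPC 0.56, PPDK
0.67 in IMC; NAD-ME 0.31, RuBisCO-SSU 0.29 in KC — each with the pair
counts of the study's enzyme sets and a 3-fold cell-type enrichment.
Homeolog baselines are drawn 10× higher than background, reflecting how
highly photosynthesis genes are expressed; no dispersion or cell-type
proportions are published, so these are stated choices, not inferences.

Dominance is planted at expectation level: within the enriched cell type
a pair's extra expression `2·b·(fold − 1)` is split `w : (1 − w)` between
the B and A copies, making the expected weight equal `w` rather than
forcing it on realised counts. Because per-cell normalisation is
compositional, planted genes' expected expression *proportions* are fixed
exactly per group and only the unplanted background genes absorb the
compositional remainder; otherwise cross-group denominator shifts would
distort the planted contrasts (background genes thus carry small
compensatory shifts, as real compositional data do). The background-gene
count default (2000) puts the detected-genes QC rule in its realistic
regime: with a ~1232-UMI budget spread over two thousand genes the
"genes > 200" rule trims only genuinely empty cells, exactly as on real
data, whereas a few-hundred-gene transcriptome would make the rule
select cells by composition.

Peak-link tables draw each group's element families from the configured
probability vector (defaults shaped after the published contrasts: NAC
and C2H2 dominant in IMC under both environments, bZIP in KC, Homeobox
and MYB-related terrestrial-only in IMC, G2-like terrestrial-only in
KC). Promoters are i.i.d. uniform A/C/G/T — chosen so false-hit
expectations have closed form — with consensus realisations planted at
recorded non-overlapping positions. Ortholog tables plant true pairs
with strictly highest mutual scores, lower-scoring decoys, and a few
high-scoring rows whose e-values fail the filter, to exercise it.

All generators derive independent substreams from one master seed by
fixed labels, so modules are individually reproducible and identical
(config, seed) pairs give byte-identical outputs.

What the simulation does *not* emulate: ambient RNA, doublets, batch
effects, cell-type-specific library sizes, correlated gene programs,
realistic promoter base composition, or motif co-occurrence structure.
Passing tests therefore demonstrate correctness of the statistics under
a clean generative model, not robustness to those artefacts.

# Verification sizes and numerical choices

The test suite verifies, among others: weight recovery within ±0.05 of
planted values 0.3/0.5/0.7 (200 pairs, 300 cells per group, mean over 50
simulations each); marker-screen calibration under a 2000-gene null
(mean flagged proportion ≤ 0.07 with BH over 20 simulations) and ≥ 90%
recall of 50 genes planted at 3-fold; motif-rate recovery within ±0.03
at 1000 elements per group as the mean over 10 simulations, with planted
environment-triggered families reproduced exactly at every simulation;
scanner/oracle identity on 100 random cases; RBH/oracle identity on
random tables up to 50×50; and end-to-end dominance-direction
concordance with byte-level reproducibility over 20 pipeline runs. These
problem sizes were chosen so each check is statistically decisive while
the whole suite stays quick.

Numerical conventions: 0-based half-open coordinates in all on-disk
tables (converted exactly to and from the 1-based in-memory ranges);
frequency columns validated to 1 ± 1e-9; TSV output with fixed column
order, 12 significant digits and sorted ids, so identical runs are
byte-identical.

# Known limitations

* The dominance weight has no uncertainty estimate; none is defined for
  it, and small homeolog sets (2–4 pairs) give noticeably variable
  weights.
* The marker screen is a per-gene two-group test; it does not model
  replicates (no pseudobulk or mixed models).
* The environment-trigger rule is a threshold pair, not a test; families
  whose true rates sit at the thresholds will flicker with sampling
  noise.
* `conservedExclusiveSets()` is limited to two species and a fixed class
  correspondence.
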