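#' Default enzyme-family specifications for the simulator
#'
#' Five homeolog families mirroring the core C4 enzymes: beta-carbonic
#' anhydrase (bCA), PEPC and PPDK enriched in the inner mesophyll (IMC),
#' NAD-ME and the RuBisCO small subunit (RuBisCO-SSU) enriched in Kranz
#' cells (KC). `weight_B_AB` is the planted subgenome-B share of the
#' IMC-vs-KC expression differential.
#'
#' @return data.frame with family, cell_type, fold, weight_B_AB, n_pairs.
#' @export
defaultFamilySpecs <- function() {
  data.frame(
    family = c("bCA", "PEPC", "PPDK", "NAD-ME", "RuBisCO-SSU"),
    cell_type = c("IMC", "IMC", "IMC", "KC", "KC"),
    fold = 3,
    weight_B_AB = c(0.63, 0.56, 0.67, 0.31, 0.29),
    n_pairs = c(4L, 4L, 2L, 4L, 4L),
    stringsAsFactors = FALSE)
}

#' Default motif-family rate vectors for the simulator
#'
#' Per (gene set x cell type x condition) probability vectors over ten
#' transcription-factor motif families, shaped after the element-frequency
#' contrasts of the study system: NAC and C2H2 dominant in IMC under both
#' environments, bZIP dominant in KC, Homeobox and MYB-related high only
#' under terrestrial growth in IMC, G2-like high only under terrestrial
#' growth in KC.
#'
#' @return named list: `"C4|<cell_type>|<condition>"` -> named probability
#'   vector summing to 1.
#' @export
defaultMotifRates <- function() {
  fams <- c("NAC", "C2H2", "bZIP", "Homeobox", "MYB-related", "G2-like",
            "C2C2dof", "WRKY", "AP2-EREBP", "bHLH")
  v <- function(...) setNames(c(...), fams)
  list(
    "C4|IMC|terrestrial" = v(0.242, 0.280, 0.010, 0.216, 0.180, 0.010,
                             0.010, 0.010, 0.021, 0.021),
    "C4|IMC|submerged"   = v(0.242, 0.280, 0.107, 0.000, 0.050, 0.010,
                             0.107, 0.102, 0.051, 0.051),
    "C4|KC|terrestrial"  = v(0.099, 0.000, 0.348, 0.050, 0.050, 0.104,
                             0.114, 0.100, 0.0675, 0.0675),
    "C4|KC|submerged"    = v(0.099, 0.000, 0.348, 0.050, 0.050, 0.000,
                             0.114, 0.150, 0.0945, 0.0945))
}

#' Simulator configuration
#'
#' Builds and validates the configuration driving all synthetic-data
#' generators. Defaults emulate the study design: three growth conditions,
#' eight cell types including the inner/outer mesophyll and Kranz cells,
#' library sizes averaging 1232 UMIs per cell, homeolog families planted at
#' the study's reported subgenome weights, and study-shaped motif-rate
#' vectors.
#'
#' @param n_genes number of background genes, default 2000 (large enough
#'   that the detected-genes QC rule behaves as on real data, trimming only
#'   genuinely empty cells).
#' @param family_specs data.frame as [defaultFamilySpecs()].
#' @param cell_types,conditions group label vocabularies.
#' @param cells_per_group cells per (cell type x condition), default 60.
#' @param mean_library_size mean UMIs per cell, default 1232.
#' @param libsize_sdlog log-sd of the lognormal library sizes, default 0.3.
#' @param nb_dispersion shared negative-binomial dispersion (gamma-Poisson,
#'   variance `mu + dispersion * mu^2`), default 0.5.
#' @param baseline_sdlog log-sd of lognormal baseline gene intensities,
#'   default 1.
#' @param homeolog_intensity multiplier for homeolog-pair baseline intensity
#'   (C4 enzyme genes are highly expressed), default 10.
#' @param n_replicates biological replicate labels per group, default 2.
#' @param de_effects list of planted differential-expression effects, each
#'   `list(set_id =, n_genes =, fold =, cell_type =, condition =)` (NULL
#'   cell_type/condition means all); applied to disjoint blocks of
#'   background genes.
#' @param motif_rate_vectors named list as [defaultMotifRates()]; names are
#'   `"<gene_set>|<cell_type>|<condition>"`.
#' @param elements_per_group accessible elements drawn per group, default
#'   1000.
#' @param planted_motifs named list: family -> `list(consensus =,
#'   occurrences =)` planted in every promoter.
#' @param promoter_length promoter length in bp, default 500.
#' @param n_species2_genes genes in the second species for the ortholog
#'   simulator (also the number of true pairs), default 30.
#' @param seed default master seed used when a generator is called without
#'   one.
#' @return A validated list of class `simConfig`.
#' @export
simConfig <- function(n_genes = 2000,
                      family_specs = defaultFamilySpecs(),
                      cell_types = c("IMC", "OMC", "KC", "epidermis",
                                     "guard_cell", "xylem", "phloem",
                                     "sclerenchyma"),
                      conditions = defaultConditions(),
                      cells_per_group = 60,
                      mean_library_size = 1232,
                      libsize_sdlog = 0.3,
                      nb_dispersion = 0.5,
                      baseline_sdlog = 1,
                      homeolog_intensity = 10,
                      n_replicates = 2,
                      de_effects = list(),
                      motif_rate_vectors = defaultMotifRates(),
                      elements_per_group = 1000,
                      planted_motifs = list(
                        bZIP = list(consensus = "TGACGTCA", occurrences = 3),
                        "MYB-related" = list(consensus = "WAACCA",
                                             occurrences = 2)),
                      promoter_length = 500,
                      n_species2_genes = 30,
                      seed = 1) {
  cfg <- list(n_genes = n_genes, family_specs = family_specs,
              cell_types = cell_types, conditions = conditions,
              cells_per_group = cells_per_group,
              mean_library_size = mean_library_size,
              libsize_sdlog = libsize_sdlog,
              nb_dispersion = nb_dispersion,
              baseline_sdlog = baseline_sdlog,
              homeolog_intensity = homeolog_intensity,
              n_replicates = n_replicates,
              de_effects = de_effects,
              motif_rate_vectors = motif_rate_vectors,
              elements_per_group = elements_per_group,
              planted_motifs = planted_motifs,
              promoter_length = promoter_length,
              n_species2_genes = n_species2_genes,
              seed = seed)
  class(cfg) <- "simConfig"
  validateSimConfig(cfg)
}

#' Validate a simulator configuration
#' @param cfg a `simConfig` list.
#' @return The config, invisibly validated (errors name the offending field).
#' @export
validateSimConfig <- function(cfg) {
  fs <- cfg$family_specs
  .assert(is.data.frame(fs) && all(c("family", "cell_type", "fold",
                                     "weight_B_AB", "n_pairs") %in%
                                   colnames(fs)),
          "family_specs: must have family/cell_type/fold/weight_B_AB/n_pairs")
  .assert(all(fs$fold > 0), "family_specs: folds must be > 0")
  .assert(all(fs$weight_B_AB >= 0 & fs$weight_B_AB <= 1),
          "family_specs: weight_B_AB must lie in [0, 1]")
  .assert(all(fs$n_pairs >= 1), "family_specs: n_pairs must be >= 1")
  .assert(all(fs$cell_type %in% cfg$cell_types),
          "family_specs: unknown cell type(s)")
  .assert(cfg$n_genes >= 1, "n_genes: must be >= 1")
  .assert(cfg$cells_per_group >= 1, "cells_per_group: must be >= 1")
  .assert(cfg$mean_library_size > 0, "mean_library_size: must be > 0")
  .assert(cfg$nb_dispersion > 0, "nb_dispersion: must be > 0")
  .assert(cfg$elements_per_group >= 1, "elements_per_group: must be >= 1")
  for (nm in names(cfg$motif_rate_vectors)) {
    v <- cfg$motif_rate_vectors[[nm]]
    .assert(abs(sum(v) - 1) <= 1e-9,
            "motif_rate_vectors: '%s' sums to %.12f, not 1", nm, sum(v))
    .assert(all(v >= 0), "motif_rate_vectors: '%s' has negative rates", nm)
    .assert(!is.null(names(v)), "motif_rate_vectors: '%s' must be named", nm)
  }
  for (f in names(cfg$planted_motifs)) {
    pm <- cfg$planted_motifs[[f]]
    .patBits(pm$consensus)  # errors on invalid IUPAC
    .assert(nchar(pm$consensus) <= cfg$promoter_length,
            "planted_motifs: '%s' consensus longer than promoter", f)
    .assert(pm$occurrences >= 0, "planted_motifs: negative occurrences")
  }
  for (e in cfg$de_effects) {
    .assert(!is.null(e$set_id) && e$n_genes >= 1 && e$fold > 0,
            "de_effects: each entry needs set_id, n_genes >= 1, fold > 0")
  }
  .assert(cfg$n_species2_genes >= 1, "n_species2_genes: must be >= 1")
  cfg
}

## Deterministic gene universe implied by a config.
.geneUniverse <- function(cfg) {
  fs <- cfg$family_specs
  bg <- sprintf("BG%04d", seq_len(cfg$n_genes))
  hA <- character(); hB <- character(); fam <- character()
  for (i in seq_len(nrow(fs))) {
    k <- fs$n_pairs[i]
    hA <- c(hA, sprintf("%s_A%02d", fs$family[i], seq_len(k)))
    hB <- c(hB, sprintf("%s_B%02d", fs$family[i], seq_len(k)))
    fam <- c(fam, rep(fs$family[i], k))
  }
  list(background = bg, gene_A = hA, gene_B = hB, pair_family = fam)
}

#' Gene ids of the simulated C4 homeolog set
#' @param cfg a `simConfig`.
#' @return Character vector of all homeolog gene ids (A then B copies).
#' @export
homeologGeneIds <- function(cfg) {
  u <- .geneUniverse(cfg)
  c(u$gene_A, u$gene_B)
}

#' Simulate a single-nucleus UMI count experiment with known truth
#'
#' Draws lognormal baseline intensities per gene, applies cell-type and
#' condition effects, splits each enriched homeolog family's expression
#' differential between the A and B copies so that the expected
#' Weight_B/AB equals the planted value, fixes the planted genes' expression
#' proportions exactly per group (background genes absorb the compositional
#' remainder), and samples negative-binomial counts (gamma-Poisson with a
#' shared dispersion) at lognormal library sizes. Identical (config, seed)
#' gives identical output.
#'
#' @param cfg a [simConfig()].
#' @param seed integer master seed (defaults to `cfg$seed`).
#' @return list with `sce` (annotated SingleCellExperiment, assay `counts`),
#'   `gene_annotation`, `cell_annotation`, `homeologs`
#'   ([HomeologPairs-class]) and `truth` (planted weights, folds, ids).
#' @export
simulateExpression <- function(cfg, seed = cfg$seed) {
  validateSimConfig(cfg)
  set.seed(.substream(seed, "expression"))
  u <- .geneUniverse(cfg)
  fs <- cfg$family_specs
  genes <- c(u$background, u$gene_A, u$gene_B)
  n_bg <- length(u$background)
  n_pairs <- length(u$gene_A)

  ## baseline intensities
  b_bg <- rlnorm(n_bg, meanlog = 0, sdlog = cfg$baseline_sdlog)
  b_pair <- cfg$homeolog_intensity *
    rlnorm(n_pairs, meanlog = 0, sdlog = cfg$baseline_sdlog)

  groups <- expand.grid(cell_type = cfg$cell_types,
                        condition = cfg$conditions,
                        stringsAsFactors = FALSE)
  glab <- paste(groups$cell_type, groups$condition, sep = "|")

  ## intensity matrix: genes x groups
  m <- matrix(rep(c(b_bg, b_pair, b_pair), times = nrow(groups)),
              nrow = length(genes),
              dimnames = list(genes, glab))
  pair_fam <- u$pair_family
  for (i in seq_len(nrow(fs))) {
    sel <- which(pair_fam == fs$family[i])
    w <- fs$weight_B_AB[i]
    extra <- 2 * b_pair[sel] * (fs$fold[i] - 1)
    in_ct <- groups$cell_type == fs$cell_type[i]
    iA <- n_bg + sel
    iB <- n_bg + n_pairs + sel
    m[iA, in_ct] <- b_pair[sel] + (1 - w) * extra
    m[iB, in_ct] <- b_pair[sel] + w * extra
  }

  ## planted DE effects on disjoint blocks of background genes
  de_truth <- list()
  cursor <- 1L
  for (e in cfg$de_effects) {
    idx <- cursor:(cursor + e$n_genes - 1L)
    .assert(max(idx) <= n_bg,
            "de_effects: not enough background genes for set '%s'", e$set_id)
    cursor <- cursor + e$n_genes
    in_grp <- rep(TRUE, nrow(groups))
    if (!is.null(e$cell_type))
      in_grp <- in_grp & groups$cell_type %in% e$cell_type
    if (!is.null(e$condition))
      in_grp <- in_grp & groups$condition %in% e$condition
    m[idx, in_grp] <- m[idx, in_grp] * e$fold
    de_truth[[e$set_id]] <- list(gene_ids = u$background[idx],
                                 fold = e$fold,
                                 cell_type = e$cell_type,
                                 condition = e$condition)
  }
  planted <- c(if (cursor > 1L) seq_len(cursor - 1L) else integer(),
               n_bg + seq_len(2L * n_pairs))

  ## fix planted proportions exactly; background fills the remainder
  S_ref <- max(colSums(m))
  p <- m / S_ref
  bg_free <- setdiff(seq_len(n_bg), planted)
  for (j in seq_len(ncol(p))) {
    rem <- 1 - sum(p[planted, j])
    .assert(rem > 0.05,
            "planted expression mass exceeds 95%% of group %s", glab[j])
    p[bg_free, j] <- p[bg_free, j] / sum(p[bg_free, j]) * rem
  }

  ## cells and counts
  n_cells <- cfg$cells_per_group * nrow(groups)
  meanlog <- log(cfg$mean_library_size) - cfg$libsize_sdlog^2 / 2
  counts_list <- vector("list", nrow(groups))
  cell_ids <- character(); ctv <- character(); cdv <- character()
  for (j in seq_len(nrow(groups))) {
    L <- rlnorm(cfg$cells_per_group, meanlog, cfg$libsize_sdlog)
    mu <- p[, j] %o% L
    cnt <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                  nrow = nrow(mu))
    counts_list[[j]] <- cnt
    ids <- sprintf("%s.%s.c%03d", groups$cell_type[j], groups$condition[j],
                   seq_len(cfg$cells_per_group))
    cell_ids <- c(cell_ids, ids)
    ctv <- c(ctv, rep(groups$cell_type[j], cfg$cells_per_group))
    cdv <- c(cdv, rep(groups$condition[j], cfg$cells_per_group))
  }
  counts <- methods::as(Matrix::Matrix(do.call(cbind, counts_list),
                                       sparse = TRUE), "CsparseMatrix")
  dimnames(counts) <- list(genes, cell_ids)

  cell_ann <- data.frame(
    cell_id = cell_ids, cell_type = ctv, condition = cdv,
    replicate = sprintf("rep%d",
                        (seq_len(n_cells) - 1L) %% cfg$n_replicates + 1L),
    stringsAsFactors = FALSE)
  gene_ann <- data.frame(
    gene_id = genes,
    subgenome = c(rep("unassigned", n_bg), rep("A", n_pairs),
                  rep("B", n_pairs)),
    family = c(rep(NA_character_, n_bg), pair_fam, pair_fam),
    stringsAsFactors = FALSE)
  homeologs <- HomeologPairs(gene_A = u$gene_A, gene_B = u$gene_B,
                             family = pair_fam)

  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts))
  sce <- attachCellData(sce, cell_ann)
  SummarizedExperiment::rowData(sce) <- S4Vectors::DataFrame(
    gene_ann[, c("subgenome", "family")], row.names = genes)

  truth <- list(
    family_weights = setNames(fs$weight_B_AB, fs$family),
    family_cell_type = setNames(fs$cell_type, fs$family),
    family_fold = setNames(fs$fold, fs$family),
    de_effects = de_truth,
    proportions = p)
  list(sce = sce, gene_annotation = gene_ann, cell_annotation = cell_ann,
       homeologs = homeologs, truth = truth)
}

#' Simulate a peak-to-gene link table with planted motif-family rates
#'
#' For every group named in `cfg$motif_rate_vectors`
#' (`"<gene_set>|<cell_type>|<condition>"`), draws
#' `cfg$elements_per_group` accessible elements whose motif families follow
#' the group's probability vector, linked to genes of the set (the C4
#' homeolog genes for set `"C4"`). Coordinates are synthetic and 0-based
#' half-open on disk.
#'
#' @param cfg a [simConfig()].
#' @param seed integer master seed.
#' @return list with `links` (GRanges), `gene_sets` (named list of gene
#'   ids) and `truth` (planted rate vectors and expected
#'   environment-triggered / predominant calls computed from them).
#' @export
simulatePeakLinks <- function(cfg, seed = cfg$seed) {
  validateSimConfig(cfg)
  set.seed(.substream(seed, "peaks"))
  gene_sets <- list(C4 = homeologGeneIds(cfg))
  rows <- list()
  for (nm in names(cfg$motif_rate_vectors)) {
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    .assert(length(parts) == 3L,
            "motif_rate_vectors: name '%s' is not 'set|cell_type|condition'",
            nm)
    set_id <- parts[1]; ct <- parts[2]; cond <- parts[3]
    .assert(cond %in% cfg$conditions,
            "motif_rate_vectors: unknown condition in '%s'", nm)
    if (is.null(gene_sets[[set_id]]))
      gene_sets[[set_id]] <- sprintf("%s_g%03d", set_id, 1:20)
    v <- cfg$motif_rate_vectors[[nm]]
    n <- cfg$elements_per_group
    fam <- sample(names(v), n, replace = TRUE, prob = v)
    start0 <- sort(sample.int(1e6, n))
    rows[[nm]] <- data.frame(
      element_id = sprintf("%s.%s.%s.e%04d", set_id, ct, cond, seq_len(n)),
      chromosome = "chr1", start = start0, end = start0 + 500L,
      gene_id = sample(gene_sets[[set_id]], n, replace = TRUE),
      motif_family = fam, cell_type = ct, condition = cond,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  gr <- GenomicRanges::GRanges(
    seqnames = df$chromosome,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    df[, c("element_id", "gene_id", "motif_family", "cell_type",
           "condition")])
  ## expected calls from the true rate vectors
  truth_rates <- cfg$motif_rate_vectors
  trig <- list()
  nms <- names(truth_rates)
  meta <- do.call(rbind, strsplit(nms, "|", fixed = TRUE))
  for (i in seq_len(nrow(meta))) {
    j <- which(meta[, 1] == meta[i, 1] & meta[, 2] == meta[i, 2] &
               meta[, 3] != meta[i, 3])
    for (jj in j) {
      v1 <- truth_rates[[i]]; v2 <- truth_rates[[jj]]
      hit <- names(v1)[v1 >= 0.10 & v2[names(v1)] <= 0.05]
      if (length(hit))
        trig[[paste(nms[i], "vs", meta[jj, 3])]] <- sort(hit)
    }
  }
  pred <- lapply(truth_rates, function(v) sort(names(v)[v == max(v)]))
  list(links = gr, gene_sets = gene_sets,
       truth = list(rates = truth_rates, predominant = pred,
                    environment_triggered = trig))
}

## Draw a concrete realisation of an IUPAC consensus.
.realiseIUPAC <- function(pattern) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
               Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
               K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
               D = c("A", "G", "T"), H = c("A", "C", "T"),
               V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  paste(vapply(strsplit(toupper(pattern), "")[[1]],
               function(ch) sample(sets[[ch]], 1L), ""), collapse = "")
}

#' Simulate promoter sequences with planted motif occurrences
#'
#' Generates an i.i.d. uniform A/C/G/T background of `cfg$promoter_length`
#' per gene and inserts, for every family in `cfg$planted_motifs`, the
#' configured number of concrete consensus realisations at recorded,
#' non-overlapping positions (forward strand).
#'
#' @param cfg a [simConfig()].
#' @param seed integer master seed.
#' @param gene_ids promoters to generate; defaults to the C4 homeolog genes.
#' @return list with `sequences` (named character vector), and `truth`
#'   (per gene and family: planted counts and 1-based start positions).
#' @export
simulatePromoters <- function(cfg, seed = cfg$seed,
                              gene_ids = homeologGeneIds(cfg)) {
  validateSimConfig(cfg)
  set.seed(.substream(seed, "promoters"))
  L <- cfg$promoter_length
  seqs <- character(length(gene_ids))
  names(seqs) <- gene_ids
  truth <- list()
  for (g in gene_ids) {
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    occupied <- rep(FALSE, L)
    truth[[g]] <- list()
    for (f in names(cfg$planted_motifs)) {
      pm <- cfg$planted_motifs[[f]]
      mlen <- nchar(pm$consensus)
      pos <- integer()
      tries <- 0L
      while (length(pos) < pm$occurrences && tries < 1000L) {
        tries <- tries + 1L
        cand <- sample.int(L - mlen + 1L, 1L)
        if (any(occupied[cand:(cand + mlen - 1L)])) next
        inst <- strsplit(.realiseIUPAC(pm$consensus), "")[[1]]
        s[cand:(cand + mlen - 1L)] <- inst
        occupied[cand:(cand + mlen - 1L)] <- TRUE
        pos <- c(pos, cand)
      }
      .assert(length(pos) == pm$occurrences,
              "could not place %d non-overlapping occurrences of %s",
              pm$occurrences, f)
      truth[[g]][[f]] <- list(count = length(pos), positions = sort(pos))
    }
    seqs[g] <- paste(s, collapse = "")
  }
  list(sequences = seqs, truth = truth)
}

#' Simulate an all-vs-all ortholog similarity score table
#'
#' Plants `cfg$n_species2_genes` true one-to-one pairs with the highest
#' mutual scores, adds strictly lower-scoring decoy rows, and a few
#' high-scoring rows with e-values failing the reciprocal-best-hit filter
#' (to exercise it). E-values decrease monotonically with score.
#'
#' @param cfg a [simConfig()].
#' @param seed integer master seed.
#' @return list with `scores` (data.frame gene_sp1/gene_sp2/score/evalue)
#'   and `truth` (the planted pair table).
#' @export
simulateOrthologScores <- function(cfg, seed = cfg$seed) {
  validateSimConfig(cfg)
  set.seed(.substream(seed, "orthologs"))
  n <- cfg$n_species2_genes
  g1 <- sprintf("S1g%04d", seq_len(n))
  g2 <- sprintf("S2g%04d", seq_len(n))
  s_true <- runif(n, 200, 500)
  ev <- function(s) 10^(-s / 20)
  rows <- data.frame(gene_sp1 = g1, gene_sp2 = g2, score = s_true,
                     evalue = ev(s_true), stringsAsFactors = FALSE)
  ## decoys: strictly below both partners' true scores
  for (i in seq_len(n)) {
    j <- sample(setdiff(seq_len(n), i), min(2L, n - 1L))
    sc <- pmin(s_true[i], s_true[j]) * runif(length(j), 0.5, 0.8)
    rows <- rbind(rows, data.frame(gene_sp1 = g1[i], gene_sp2 = g2[j],
                                   score = sc, evalue = ev(sc),
                                   stringsAsFactors = FALSE))
  }
  ## high-score rows failing the e-value filter
  if (n >= 2L) {
    k <- sample(seq_len(n), min(3L, n))
    rows <- rbind(rows, data.frame(
      gene_sp1 = g1[k], gene_sp2 = g2[c(k[-1], k[1])],
      score = max(s_true) + 100, evalue = 1e-5, stringsAsFactors = FALSE))
  }
  rows <- rows[!duplicated(paste(rows$gene_sp1, rows$gene_sp2)), ]
  rownames(rows) <- NULL
  list(scores = rows,
       truth = data.frame(gene_sp1 = g1, gene_sp2 = g2,
                          stringsAsFactors = FALSE))
}

#' Write a full simulated bundle to disk
#'
#' Emits the count matrix (Matrix Market + sidecars), annotation TSVs, the
#' homeolog table, the peak-link table (0-based half-open), promoter FASTA,
#' ortholog score TSV and a ground-truth JSON.
#'
#' @param cfg a [simConfig()].
#' @param dir output directory.
#' @param seed integer master seed.
#' @return Invisibly, the list of generated objects.
#' @export
writeSimulation <- function(cfg, dir, seed = cfg$seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ex <- simulateExpression(cfg, seed)
  pk <- simulatePeakLinks(cfg, seed)
  pr <- simulatePromoters(cfg, seed)
  os <- simulateOrthologScores(cfg, seed)
  writeCountMatrix(ex$sce, dir)
  .writeTSV(ex$cell_annotation, file.path(dir, "cell_annotation.tsv"))
  .writeTSV(ex$gene_annotation, file.path(dir, "gene_annotation.tsv"))
  .writeTSV(as.data.frame(pairTable(ex$homeologs)),
            file.path(dir, "homeologs.tsv"))
  writePeakLinks(pk$links, file.path(dir, "peak_links.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(pr$sequences),
                              file.path(dir, "promoters.fasta"))
  .writeTSV(os$scores, file.path(dir, "ortholog_scores.tsv"))
  truth <- list(expression = ex$truth[c("family_weights",
                                        "family_cell_type", "family_fold")],
                de_effects = ex$truth$de_effects,
                motif = pk$truth[c("rates", "predominant",
                                   "environment_triggered")],
                promoters = pr$truth,
                orthologs = os$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(expression = ex, peaks = pk, promoters = pr,
                 orthologs = os))
}
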