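#' Run the full analysis pipeline
#'
#' Orchestrates every stage from one configuration: input loading (or
#' simulation), cell QC, cp10k normalisation, cell-type expression
#' profiling, the differential-expression screen, D-values and subgenome
#' dominance, motif-family frequency matrices with predominant and
#' environment-triggered calls, reciprocal-best-hit orthology when a score
#' table is available, and a machine-readable summary. Deterministic for a
#' fixed (config, seed).
#'
#' @param config a list, or the path of a YAML file. Top-level keys:
#'   \describe{
#'     \item{simulate}{arguments for [simConfig()]; mutually exclusive with
#'       `inputs`.}
#'     \item{inputs}{paths: matrix/genes/cells, cell_annotation,
#'       gene_annotation, homeologs, peak_links, ortholog_scores
#'       (optional).}
#'     \item{qc}{min_umi (500), min_genes (200).}
#'     \item{markers}{fc_min (1.5), alpha (0.05), pseudocount (0.1),
#'       method ("bonferroni").}
#'     \item{dominance}{cell_a ("IMC"), cell_b ("KC"),
#'       condition ("terrestrial"), margin (0).}
#'     \item{motifs}{tau_pred (0.10), tau_high (0.10), tau_low (0.05),
#'       count_mode ("element"), conditions (c("terrestrial",
#'       "submerged")).}
#'   }
#' @param out_dir output directory for stage TSVs and `summary.json`.
#' @param seed integer master seed (overrides the config's).
#' @return Invisibly, a list with the stage results and the summary.
#' @export
runPipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  .assert(xor(is.null(config$simulate), is.null(config$inputs)),
          "config must contain exactly one of 'simulate' or 'inputs'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prm <- function(block, key, default) {
    v <- config[[block]][[key]]
    if (is.null(v)) default else v
  }
  outputs <- character()
  emit <- function(df, name) {
    .writeTSV(as.data.frame(df), file.path(out_dir, name))
    outputs <<- c(outputs, name)
  }

  ## ---- stage: inputs -----------------------------------------------------
  ortho_scores <- NULL
  if (!is.null(config$simulate)) {
    cfg <- do.call(simConfig, config$simulate)
    if (!is.null(seed)) cfg$seed <- seed
    ex <- simulateExpression(cfg)
    pk <- simulatePeakLinks(cfg)
    os <- simulateOrthologScores(cfg)
    sce <- ex$sce
    homeologs <- ex$homeologs
    links <- pk$links
    gene_sets <- pk$gene_sets
    ortho_scores <- os$scores
    seed_used <- cfg$seed
  } else {
    inp <- config$inputs
    sce <- readCountMatrix(inp$matrix, inp$genes, inp$cells)
    cells <- readCellAnnotation(inp$cell_annotation)
    sce <- attachCellData(sce, as.data.frame(cells))
    genes <- readGeneAnnotation(inp$gene_annotation)
    homeologs <- readHomeologTable(inp$homeologs, genes)
    links <- readPeakLinks(inp$peak_links)
    pt <- pairTable(homeologs)
    gene_sets <- list(C4 = c(pt$gene_A, pt$gene_B))
    if (!is.null(inp$ortholog_scores))
      ortho_scores <- readOrthologScores(inp$ortholog_scores)
    seed_used <- if (is.null(seed)) NA_integer_ else seed
  }

  ## ---- stage: qc + normalisation ----------------------------------------
  sce <- qcFilter(sce, min_umi = prm("qc", "min_umi", 500),
                  min_genes = prm("qc", "min_genes", 200))
  qc <- S4Vectors::metadata(sce)$qc
  sce <- normalizeCP10K(sce)
  profile <- cellTypeProfile(sce)
  prof_df <- data.frame(
    gene_id = rep(rownames(profile), ncol(profile)),
    cell_type = rep(SummarizedExperiment::colData(profile)$cell_type,
                    each = nrow(profile)),
    condition = rep(SummarizedExperiment::colData(profile)$condition,
                    each = nrow(profile)),
    mean = as.vector(SummarizedExperiment::assay(profile, "mean")),
    n_cells = rep(SummarizedExperiment::colData(profile)$n_cells,
                  each = nrow(profile)))
  emit(prof_df, "celltype_profile.tsv")

  ## ---- stage: markers ----------------------------------------------------
  dom_a <- prm("dominance", "cell_a", "IMC")
  dom_b <- prm("dominance", "cell_b", "KC")
  dom_cond <- prm("dominance", "condition", "terrestrial")
  mk <- findMarkerGenes(
    sce,
    group1 = list(cell_type = dom_a, condition = dom_cond),
    group2 = list(cell_type = dom_b, condition = dom_cond),
    fc_min = prm("markers", "fc_min", 1.5),
    alpha = prm("markers", "alpha", 0.05),
    pseudocount = prm("markers", "pseudocount", 0.1),
    method = prm("markers", "method", "bonferroni"))
  emit(mk, "markers_cell_contrast.tsv")

  ## ---- stage: dominance --------------------------------------------------
  pt <- pairTable(homeologs)
  dv <- computeDvalues(profile, dom_a, dom_b, dom_cond,
                       genes = c(pt$gene_A, pt$gene_B))
  weights <- dominanceReport(subgenomeWeights(dv, homeologs),
                             margin = prm("dominance", "margin", 0))
  emit(dv, "dvalues.tsv")
  emit(weights, "dominance_report.tsv")

  ## ---- stage: motif profiles ---------------------------------------------
  motif_conds <- prm("motifs", "conditions", c("terrestrial", "submerged"))
  count_mode <- prm("motifs", "count_mode", "element")
  fam_all <- sort(unique(S4Vectors::mcols(links)$motif_family))
  freqs <- list()
  calls_pred <- list()
  for (cond in motif_conds) {
    sub <- links[S4Vectors::mcols(links)$condition == cond]
    cnt <- countElements(sub, gene_sets$C4, group_by = "cell_type",
                         count_mode = count_mode, families = fam_all)
    fr <- normalizeFrequency(cnt)
    freqs[[cond]] <- fr
    writeMotifMatrix(cnt, file.path(out_dir,
                                    sprintf("motif_counts_%s.tsv", cond)))
    writeMotifMatrix(fr, file.path(out_dir,
                                   sprintf("motif_freq_%s.tsv", cond)))
    outputs <- c(outputs, sprintf("motif_counts_%s.tsv", cond),
                 sprintf("motif_freq_%s.tsv", cond))
    calls_pred[[cond]] <- callPredominant(
      freqs[[cond]], tau_pred = prm("motifs", "tau_pred", 0.10))
    calls_pred[[cond]]$condition <- cond
  }
  emit(do.call(rbind, calls_pred), "motif_predominant.tsv")
  trig <- S4Vectors::DataFrame(family = character(), group = character(),
                               call = character(), rate_cond1 = numeric(),
                               rate_cond2 = numeric())
  if (length(motif_conds) >= 2L &&
      identical(motifGroups(freqs[[1]]), motifGroups(freqs[[2]]))) {
    trig <- callEnvironmentTriggered(
      freqs[[motif_conds[1]]], freqs[[motif_conds[2]]],
      tau_high = prm("motifs", "tau_high", 0.10),
      tau_low = prm("motifs", "tau_low", 0.05))
  }
  emit(trig, "motif_environment_triggered.tsv")

  ## ---- stage: orthology --------------------------------------------------
  rbh <- NULL
  if (!is.null(ortho_scores)) {
    rbh <- reciprocalBestHits(ortho_scores)
    emit(rbh, "rbh_pairs.tsv")
  }

  ## ---- summary -----------------------------------------------------------
  summary <- list(
    seed = seed_used,
    package_version = as.character(utils::packageVersion("kranzC4")),
    qc = qc,
    n_cells = ncol(sce), n_genes = nrow(sce),
    n_markers = nrow(mk),
    dominance = lapply(seq_len(nrow(weights)), function(i)
      list(set_id = weights$set_id[i],
           weight_B_AB = weights$weight_B_AB[i],
           call = weights$call[i])),
    n_environment_triggered = nrow(trig),
    n_rbh_pairs = if (is.null(rbh)) NA else nrow(rbh),
    outputs = sort(outputs))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sce = sce, profile = profile, markers = mk,
                 dvalues = dv, weights = weights, freqs = freqs,
                 predominant = calls_pred, triggered = trig, rbh = rbh,
                 summary = summary))
}
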