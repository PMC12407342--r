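#' Attach cell annotation to a SingleCellExperiment
#'
#' Joins a cell annotation table onto the columns of a count object, in
#' matrix column order. Every matrix cell must be annotated.
#'
#' @param sce SingleCellExperiment with a `counts` assay.
#' @param cells cell annotation (DataFrame/data.frame with cell_id,
#'   cell_type, condition, replicate).
#' @return The SingleCellExperiment with annotation in `colData`.
#' @export
attachCellData <- function(sce, cells) {
  cells <- as.data.frame(cells)
  .assert(all(colnames(sce) %in% cells$cell_id),
          "unannotated cell(s): %s",
          paste(head(setdiff(colnames(sce), cells$cell_id)), collapse = ", "))
  idx <- match(colnames(sce), cells$cell_id)
  cd <- S4Vectors::DataFrame(cells[idx, , drop = FALSE])
  rownames(cd) <- colnames(sce)
  SummarizedExperiment::colData(sce) <- cd
  sce
}

#' Cell quality-control filter
#'
#' Retains cells with strictly more than `min_umi` total UMIs and strictly
#' more than `min_genes` detected genes (the study's retention rule:
#' UMIs > 500 and genes > 200). Genes are never removed. The number of cells
#' removed by each rule is recorded in `metadata(sce)$qc`.
#'
#' @param sce SingleCellExperiment with a `counts` assay.
#' @param min_umi minimum UMI total (exclusive bound), default 500.
#' @param min_genes minimum detected-gene count (exclusive bound), default 200.
#' @return The filtered SingleCellExperiment.
#' @export
qcFilter <- function(sce, min_umi = 500, min_genes = 200) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  tot <- Matrix::colSums(counts)
  ngene <- Matrix::colSums(counts > 0)
  keep <- tot > min_umi & ngene > min_genes
  if (!any(keep))
    stop("qcFilter: no cells survive UMIs > ", min_umi,
         " and genes > ", min_genes, call. = FALSE)
  out <- sce[, keep]
  S4Vectors::metadata(out)$qc <- list(
    n_input = ncol(sce), n_retained = sum(keep),
    n_low_umi = sum(tot <= min_umi), n_low_genes = sum(ngene <= min_genes),
    min_umi = min_umi, min_genes = min_genes)
  out
}

#' Counts-per-10k normalisation with a log1p layer
#'
#' Scales each cell to 10,000 total counts (`cp10k` assay) and adds
#' `logcp10k = log(1 + cp10k)`. Fully deterministic; used in place of a
#' variance-stabilising fit so that fold changes and rank-based tests are
#' exactly reproducible.
#'
#' @param sce SingleCellExperiment with a `counts` assay; no cell may have a
#'   zero total (run [qcFilter()] first).
#' @return The SingleCellExperiment with `cp10k` and `logcp10k` assays added.
#' @export
normalizeCP10K <- function(sce) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  tot <- Matrix::colSums(counts)
  zero <- tot == 0
  .assert(!any(zero), "zero-total cell(s): %s",
          paste(head(colnames(counts)[zero]), collapse = ", "))
  cp10k <- counts %*% Matrix::Diagonal(x = 10000 / tot)
  dimnames(cp10k) <- dimnames(counts)
  SummarizedExperiment::assay(sce, "cp10k") <- cp10k
  SummarizedExperiment::assay(sce, "logcp10k") <- log1p(cp10k)
  sce
}

#' Mean expression per (gene, cell type, condition) group
#'
#' Computes the arithmetic mean of the chosen normalised layer over the
#' cells of every (cell_type, condition) group. This profile carries the
#' expression levels entering the D-value statistic (e.g. Exp in IMC and in
#' Kranz cells under terrestrial conditions).
#'
#' @param sce normalised SingleCellExperiment with annotated `colData`.
#' @param layer assay to average, default `"cp10k"`.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay `mean`
#'   (genes x groups) and colData columns cell_type, condition, n_cells.
#' @export
cellTypeProfile <- function(sce, layer = "cp10k") {
  .assert(layer %in% SummarizedExperiment::assayNames(sce),
          "layer '%s' not present; run normalizeCP10K() first", layer)
  cd <- SummarizedExperiment::colData(sce)
  .assert(all(c("cell_type", "condition") %in% colnames(cd)),
          "colData must carry cell_type and condition; see attachCellData()")
  x <- SummarizedExperiment::assay(sce, layer)
  grp <- paste(cd$cell_type, cd$condition, sep = "|")
  lev <- sort(unique(grp))
  ## group means via a sparse indicator matrix: X %*% G / n
  gi <- Matrix::sparseMatrix(i = seq_along(grp), j = match(grp, lev),
                             x = 1, dims = c(length(grp), length(lev)))
  n <- Matrix::colSums(gi)
  means <- as.matrix(x %*% gi %*% Matrix::Diagonal(x = 1 / n))
  dimnames(means) <- list(rownames(x), lev)
  parts <- do.call(rbind, strsplit(lev, "|", fixed = TRUE))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(mean = means),
    colData = S4Vectors::DataFrame(cell_type = parts[, 1],
                                   condition = parts[, 2],
                                   n_cells = as.integer(n),
                                   row.names = lev))
}

#' Extract one group's mean-expression vector from a profile
#'
#' @param profile a profile from [cellTypeProfile()].
#' @param cell_type,condition group labels.
#' @param genes optional gene ids to extract (all genes by default).
#' @return Named numeric vector of mean expression.
#' @export
profileMeans <- function(profile, cell_type, condition, genes = NULL) {
  cd <- SummarizedExperiment::colData(profile)
  j <- which(cd$cell_type == cell_type & cd$condition == condition)
  .assert(length(j) == 1L, "group (%s, %s) not present in profile",
          cell_type, condition)
  v <- SummarizedExperiment::assay(profile, "mean")[, j]
  if (!is.null(genes)) {
    miss <- setdiff(genes, names(v))
    .assert(length(miss) == 0L, "gene(s) missing from profile: %s",
            paste(head(miss), collapse = ", "))
    v <- v[genes]
  }
  v
}
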