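#' Default condition vocabulary
#'
#' Growth conditions of the study design: terrestrial (C4-like culms),
#' submerged freshwater (C3-like culms) and submerged with ABA treatment.
#' @export
defaultConditions <- function()
  c("terrestrial", "submerged", "submerged_ABA")

## ---------------------------------------------------------------------------
## UMI count matrix (Matrix Market + TSV sidecars) -> SingleCellExperiment
## ---------------------------------------------------------------------------

#' Read a UMI count matrix with gene and cell sidecar files
#'
#' Reads a genes x cells sparse Matrix Market file plus one-id-per-line
#' `genes.tsv` / `cells.tsv` sidecars and returns a validated
#' [SingleCellExperiment::SingleCellExperiment] with a `counts` assay.
#'
#' @param matrix_path path to the .mtx file.
#' @param genes_path,cells_path paths to the id sidecars (first column used).
#' @return A SingleCellExperiment with assay `counts`.
#' @export
readCountMatrix <- function(matrix_path, genes_path, cells_path) {
  .assert(file.exists(matrix_path), "file not found: %s", matrix_path)
  m <- Matrix::readMM(matrix_path)
  genes <- read.table(genes_path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  cells <- read.table(cells_path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  .assert(!anyDuplicated(genes), "duplicated gene id in %s: %s", genes_path,
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  .assert(!anyDuplicated(cells), "duplicated cell id in %s: %s", cells_path,
          paste(unique(cells[duplicated(cells)]), collapse = ", "))
  .assert(nrow(m) == length(genes),
          "matrix has %d rows but %d gene ids", nrow(m), length(genes))
  .assert(ncol(m) == length(cells),
          "matrix has %d columns but %d cell ids", ncol(m), length(cells))
  v <- m@x
  .assert(all(v >= 0), "negative count entries present")
  .assert(all(v == round(v)), "non-integer count entries present")
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(genes, cells)
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

#' Write a count matrix as Matrix Market plus sidecars
#'
#' @param sce a SingleCellExperiment (assay `counts` is written).
#' @param dir output directory (created if needed); files `matrix.mtx`,
#'   `genes.tsv`, `cells.tsv`.
#' @return Invisibly, the three paths.
#' @export
writeCountMatrix <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- SummarizedExperiment::assay(sce, "counts")
  mp <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(methods::as(m, "CsparseMatrix"), mp)
  writeLines(rownames(m), file.path(dir, "genes.tsv"))
  writeLines(colnames(m), file.path(dir, "cells.tsv"))
  invisible(file.path(dir, c("matrix.mtx", "genes.tsv", "cells.tsv")))
}

## ---------------------------------------------------------------------------
## Annotation tables
## ---------------------------------------------------------------------------

#' Read a cell annotation table
#'
#' Expects tab-separated columns cell_id, cell_type, condition, replicate.
#'
#' @param path TSV path.
#' @param conditions allowed condition vocabulary.
#' @return A [S4Vectors::DataFrame] keyed by cell_id.
#' @export
readCellAnnotation <- function(path, conditions = defaultConditions()) {
  df <- .readTSV(path, c("cell_id", "cell_type", "condition", "replicate"))
  validateCellAnnotation(df, conditions)
}

#' Validate a cell annotation table
#' @param df data.frame with cell_id, cell_type, condition, replicate.
#' @param conditions allowed condition labels.
#' @return The validated table as a DataFrame.
#' @export
validateCellAnnotation <- function(df, conditions = defaultConditions()) {
  .assert(!anyDuplicated(df$cell_id), "duplicated cell_id in annotation")
  bad <- !df$condition %in% conditions
  .assert(!any(bad),
          "invalid condition label(s) at row(s) %s: %s (allowed: %s)",
          paste(which(bad), collapse = ","),
          paste(unique(df$condition[bad]), collapse = ", "),
          paste(conditions, collapse = ", "))
  S4Vectors::DataFrame(df)
}

#' Read a gene annotation table
#'
#' Columns: gene_id, subgenome (A/B/unassigned), family (may be empty),
#' optional chromosome/start/end with 0-based half-open coordinates.
#'
#' @param path TSV path.
#' @return A [S4Vectors::DataFrame].
#' @export
readGeneAnnotation <- function(path) {
  df <- .readTSV(path, c("gene_id", "subgenome", "family"))
  .assert(!anyDuplicated(df$gene_id), "duplicated gene_id in annotation")
  bad <- !df$subgenome %in% c("A", "B", "unassigned")
  .assert(!any(bad), "invalid subgenome label at row(s) %s",
          paste(which(bad), collapse = ","))
  if (all(c("start", "end") %in% colnames(df))) {
    has <- !is.na(df$start) & !is.na(df$end)
    .assert(all(df$start[has] < df$end[has]),
            "start >= end at row(s) %s",
            paste(which(has & df$start >= df$end), collapse = ","))
  }
  S4Vectors::DataFrame(df)
}

#' Read a homeolog pair table
#'
#' Columns gene_A, gene_B, family. When `genes` (a gene annotation) is given,
#' each member must exist there with the matching subgenome.
#'
#' @param path TSV path.
#' @param genes optional gene annotation DataFrame.
#' @return A [HomeologPairs-class] object.
#' @export
readHomeologTable <- function(path, genes = NULL) {
  df <- .readTSV(path, c("gene_A", "gene_B", "family"))
  hp <- HomeologPairs(df)
  if (!is.null(genes)) {
    sg <- setNames(genes$subgenome, genes$gene_id)
    .assert(all(df$gene_A %in% genes$gene_id) &&
            all(df$gene_B %in% genes$gene_id),
            "homeolog gene(s) absent from gene annotation")
    .assert(all(sg[df$gene_A] == "A"),
            "gene_A entries not annotated to subgenome A")
    .assert(all(sg[df$gene_B] == "B"),
            "gene_B entries not annotated to subgenome B")
  }
  hp
}

## ---------------------------------------------------------------------------
## Peak-to-gene link table (BED-like, 0-based half-open on disk)
## ---------------------------------------------------------------------------

#' Read a peak-to-gene link table into a GRanges
#'
#' On disk the table is BED-like with 0-based half-open `start`/`end`;
#' in memory it is a [GenomicRanges::GRanges] (1-based closed, so
#' `width(gr) == end - start` of the file). Metadata columns: element_id,
#' gene_id, motif_family, cell_type, condition and optional link_score.
#'
#' @param path TSV path.
#' @param conditions allowed condition vocabulary.
#' @return A GRanges with the link metadata.
#' @export
readPeakLinks <- function(path, conditions = defaultConditions()) {
  need <- c("element_id", "chromosome", "start", "end", "gene_id",
            "motif_family", "cell_type", "condition")
  df <- .readTSV(path, need)
  bad <- df$start >= df$end
  .assert(!any(bad), "start >= end at row(s) %s",
          paste(which(bad), collapse = ","))
  badc <- !df$condition %in% conditions
  .assert(!any(badc), "invalid condition label at row(s) %s",
          paste(which(badc), collapse = ","))
  gr <- GenomicRanges::GRanges(
    seqnames = df$chromosome,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    df[, setdiff(colnames(df), c("chromosome", "start", "end")),
       drop = FALSE])
  gr
}

#' Write a peak-link GRanges back to the BED-like TSV layout
#' @param links GRanges as produced by [readPeakLinks()] / [simulatePeakLinks()].
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
writePeakLinks <- function(links, path) {
  mc <- as.data.frame(S4Vectors::mcols(links))
  df <- data.frame(
    element_id = mc$element_id,
    chromosome = as.character(GenomicRanges::seqnames(links)),
    start = GenomicRanges::start(links) - 1L,
    end = GenomicRanges::end(links),
    mc[, setdiff(colnames(mc), "element_id"), drop = FALSE],
    stringsAsFactors = FALSE, check.names = FALSE)
  .writeTSV(df, path)
}

## ---------------------------------------------------------------------------
## Ortholog similarity scores
## ---------------------------------------------------------------------------

#' Read an all-vs-all ortholog similarity score table
#'
#' Columns gene_sp1, gene_sp2, score (higher = more similar) and optional
#' evalue. Duplicate (gene_sp1, gene_sp2) rows are rejected.
#'
#' @param path TSV path.
#' @return A data.frame.
#' @export
readOrthologScores <- function(path) {
  df <- .readTSV(path, c("gene_sp1", "gene_sp2", "score"))
  key <- paste(df$gene_sp1, df$gene_sp2, sep = "\r")
  .assert(!anyDuplicated(key), "duplicate (gene_sp1, gene_sp2) row(s): %s",
          paste(head(df$gene_sp1[duplicated(key)]), collapse = ", "))
  .assert(all(df$score >= 0), "negative similarity score(s)")
  if ("evalue" %in% colnames(df))
    .assert(all(df$evalue >= 0), "negative e-value(s)")
  df
}

## ---------------------------------------------------------------------------
## Motif matrices
## ---------------------------------------------------------------------------

#' Write a MotifMatrix as TSV (families as rows, groups as columns)
#' @param x a [MotifMatrix-class].
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
writeMotifMatrix <- function(x, path) {
  v <- motifValues(x)
  df <- data.frame(family = rownames(v),
                   apply(v, 2, .fmtNum, digits = 12L),
                   stringsAsFactors = FALSE, check.names = FALSE)
  colnames(df) <- c("family", colnames(v))
  .writeTSV(df, path)
}

#' Read a MotifMatrix written by [writeMotifMatrix()]
#' @param path TSV path.
#' @param normalized logical; whether the stored values are rates.
#' @return A [MotifMatrix-class].
#' @export
readMotifMatrix <- function(path, normalized = FALSE) {
  df <- .readTSV(path, "family")
  v <- as.matrix(df[, setdiff(colnames(df), "family"), drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- df$family
  MotifMatrix(v, normalized = normalized)
}
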