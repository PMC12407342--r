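#' MotifMatrix: motif-family by group count or frequency matrix
#'
#' Holds counts (or per-group rates) of accessible cis-regulatory elements by
#' transcription-factor motif family (rows) across analysis groups (columns,
#' typically combinations of gene set, cell type and growth condition). When
#' `normalized = TRUE`, every non-degenerate column sums to 1; columns whose
#' underlying counts were all zero are flagged as degenerate and kept as zeros
#' rather than NaN.
#'
#' @slot values numeric matrix, families x groups, non-negative.
#' @slot normalized logical scalar; TRUE when columns are rates.
#' @slot degenerate logical vector, one flag per group column.
#'
#' @aliases MotifMatrix
#' @exportClass MotifMatrix
setClass("MotifMatrix",
  representation(values = "matrix", normalized = "logical",
                 degenerate = "logical"),
  prototype(values = matrix(numeric(), 0, 0), normalized = FALSE,
            degenerate = logical())
)

setValidity("MotifMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must have family rownames and group colnames")
  if (anyDuplicated(rownames(v))) return("duplicated family names")
  if (anyDuplicated(colnames(v))) return("duplicated group names")
  if (any(v < 0)) return("negative entries")
  if (length(object@degenerate) != ncol(v))
    return("degenerate flag length must equal number of groups")
  if (isTRUE(object@normalized) && ncol(v) > 0) {
    cs <- colSums(v)
    bad <- !object@degenerate & abs(cs - 1) > 1e-9
    if (any(bad))
      return(sprintf("non-degenerate column(s) not summing to 1: %s",
                     paste(colnames(v)[bad], collapse = ", ")))
    if (any(object@degenerate & cs != 0))
      return("degenerate columns must be all-zero")
  }
  TRUE
})

#' Construct a MotifMatrix
#'
#' @param values numeric matrix with family rownames and group colnames.
#' @param normalized logical; are columns rates summing to 1?
#' @param degenerate optional logical flag per column; defaults to all-zero
#'   columns when `normalized`, otherwise all FALSE.
#' @return A [MotifMatrix-class] object.
#' @export
MotifMatrix <- function(values, normalized = FALSE, degenerate = NULL) {
  if (is.null(degenerate)) {
    degenerate <- if (normalized && ncol(values) > 0)
      colSums(values) == 0 else rep(FALSE, ncol(values))
  }
  new("MotifMatrix", values = values, normalized = normalized,
      degenerate = degenerate)
}

#' @describeIn MotifMatrix-class motif family labels (row names)
#' @param x,object a MotifMatrix
#' @export
motifFamilies <- function(x) rownames(x@values)

#' @describeIn MotifMatrix-class group labels (column names)
#' @export
motifGroups <- function(x) colnames(x@values)

#' @describeIn MotifMatrix-class the underlying numeric matrix
#' @export
motifValues <- function(x) x@values

#' @describeIn MotifMatrix-class TRUE when columns are rates summing to 1
#' @export
isNormalized <- function(x) x@normalized

#' @describeIn MotifMatrix-class logical flag per group column marking
#'   all-zero (degenerate) columns
#' @export
degenerateGroups <- function(x)
  setNames(x@degenerate, colnames(x@values))

setMethod("show", "MotifMatrix", function(object) {
  cat(sprintf("MotifMatrix: %d famil%s x %d group%s (%s)\n",
              nrow(object@values),
              if (nrow(object@values) == 1) "y" else "ies",
              ncol(object@values),
              if (ncol(object@values) == 1) "" else "s",
              if (object@normalized) "rates" else "counts"))
  if (any(object@degenerate))
    cat("  degenerate groups:",
        paste(colnames(object@values)[object@degenerate], collapse = ", "),
        "\n")
  print(head(object@values, 8))
  invisible(NULL)
})

#' HomeologPairs: one-to-one A/B subgenome homeolog pairs
#'
#' Each row pairs one gene from subgenome A with its homeolog from subgenome
#' B, tagged with the enzyme-family label used for per-family dominance
#' aggregation (e.g. beta-carbonic anhydrases, PEPC, PPDK, NAD-ME, RuBisCO
#' small subunit). No gene may appear in more than one pair.
#'
#' @slot pairs a [S4Vectors::DataFrame] with columns gene_A, gene_B, family.
#'
#' @aliases HomeologPairs
#' @exportClass HomeologPairs
setClass("HomeologPairs", representation(pairs = "DataFrame"))

setValidity("HomeologPairs", function(object) {
  p <- object@pairs
  need <- c("gene_A", "gene_B", "family")
  miss <- setdiff(need, colnames(p))
  if (length(miss)) return(paste("missing column(s):",
                                 paste(miss, collapse = ", ")))
  all_genes <- c(p$gene_A, p$gene_B)
  dup <- all_genes[duplicated(all_genes)]
  if (length(dup))
    return(sprintf("gene(s) appearing in more than one pair: %s",
                   paste(unique(dup), collapse = ", ")))
  TRUE
})

#' Construct a HomeologPairs object
#'
#' @param gene_A,gene_B character vectors of paired gene ids (subgenome A and
#'   B respectively), or `gene_A` may be a data.frame with columns
#'   gene_A/gene_B/family.
#' @param family enzyme-family label per pair.
#' @return A [HomeologPairs-class] object.
#' @export
HomeologPairs <- function(gene_A, gene_B = NULL, family = NULL) {
  if (is.data.frame(gene_A) || is(gene_A, "DataFrame")) {
    df <- S4Vectors::DataFrame(gene_A)
  } else {
    df <- S4Vectors::DataFrame(gene_A = as.character(gene_A),
                               gene_B = as.character(gene_B),
                               family = as.character(family))
  }
  new("HomeologPairs", pairs = df)
}

#' @describeIn HomeologPairs-class the pair table as a DataFrame
#' @param x,object a HomeologPairs
#' @export
pairTable <- function(x) x@pairs

setMethod("length", "HomeologPairs", function(x) nrow(x@pairs))

setMethod("show", "HomeologPairs", function(object) {
  cat(sprintf("HomeologPairs: %d pair%s, %d famil%s\n",
              nrow(object@pairs), if (nrow(object@pairs) == 1) "" else "s",
              length(unique(object@pairs$family)),
              if (length(unique(object@pairs$family)) == 1) "y" else "ies"))
  print(head(as.data.frame(object@pairs), 6))
  invisible(NULL)
})
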