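#' Per-gene expression D-values between two cell types
#'
#' For each gene, `D = |Exp_a - Exp_b|`: the absolute difference of mean
#' normalised expression between two cell types under one condition (e.g.
#' inner mesophyll vs Kranz cells under terrestrial growth).
#'
#' @param profile a profile from [cellTypeProfile()].
#' @param cell_a,cell_b cell-type labels.
#' @param condition condition label.
#' @param genes gene ids to evaluate (default: all genes in the profile).
#' @return A [S4Vectors::DataFrame] with gene_id, condition, cell_a, cell_b,
#'   exp_a, exp_b and D.
#' @export
computeDvalues <- function(profile, cell_a, cell_b, condition, genes = NULL) {
  if (is.null(genes))
    genes <- rownames(profile)
  ea <- profileMeans(profile, cell_a, condition, genes)
  eb <- profileMeans(profile, cell_b, condition, genes)
  S4Vectors::DataFrame(gene_id = genes, condition = condition,
                       cell_a = cell_a, cell_b = cell_b,
                       exp_a = unname(ea), exp_b = unname(eb),
                       D = unname(abs(ea - eb)))
}

#' Subgenome expression weight over a homeolog set
#'
#' Aggregates per-gene D-values over a set of A/B homeolog pairs:
#' `Weight_B/AB = sum(D_B) / (sum(D_A) + sum(D_B))`. A weight above 0.5
#' indicates that subgenome B carries the larger share of the cell-type
#' expression differential for the set.
#'
#' @param dvalues D-value table from [computeDvalues()] covering both members
#'   of every pair.
#' @param pairs a [HomeologPairs-class] (the member pairs of the set).
#' @param set_id label for the set (enzyme family or pooled list).
#' @return A one-row [S4Vectors::DataFrame] with set_id, sum_D_A, sum_D_B,
#'   weight_B_AB, n_pairs and n_zero (pairs whose two D-values are both 0).
#' @export
subgenomeWeight <- function(dvalues, pairs, set_id = "set") {
  pt <- pairTable(pairs)
  d <- setNames(dvalues$D, dvalues$gene_id)
  miss <- setdiff(c(pt$gene_A, pt$gene_B), names(d))
  .assert(length(miss) == 0L, "missing D-value(s) for: %s",
          paste(head(miss), collapse = ", "))
  dA <- d[pt$gene_A]; dB <- d[pt$gene_B]
  sA <- sum(dA); sB <- sum(dB)
  if (sA + sB == 0)
    stop("subgenomeWeight: all D-values are zero for set '", set_id,
         "'; the weight is undefined", call. = FALSE)
  S4Vectors::DataFrame(set_id = set_id, sum_D_A = sA, sum_D_B = sB,
                       weight_B_AB = sB / (sA + sB),
                       n_pairs = nrow(pt),
                       n_zero = sum(dA == 0 & dB == 0))
}

#' Per-family subgenome weights
#'
#' Convenience wrapper computing [subgenomeWeight()] for every enzyme family
#' in a homeolog table.
#'
#' @param dvalues D-value table covering all pair members.
#' @param homeologs a [HomeologPairs-class].
#' @return A [S4Vectors::DataFrame], one row per family.
#' @export
subgenomeWeights <- function(dvalues, homeologs) {
  pt <- pairTable(homeologs)
  fams <- sort(unique(pt$family))
  do.call(rbind, lapply(fams, function(f) {
    subgenomeWeight(dvalues,
                    HomeologPairs(pt[pt$family == f, , drop = FALSE]),
                    set_id = f)
  }))
}

#' Dominance calls from subgenome weights
#'
#' Classifies each set as `B-dominant` when `weight > 0.5 + margin`,
#' `A-dominant` when `weight < 0.5 - margin`, otherwise `balanced`.
#'
#' @param weights output of [subgenomeWeight()] / [subgenomeWeights()].
#' @param margin symmetric dead zone around 0.5, default 0.
#' @return The input with a `call` column appended.
#' @export
dominanceReport <- function(weights, margin = 0) {
  w <- weights$weight_B_AB
  call <- ifelse(w > 0.5 + margin, "B-dominant",
                 ifelse(w < 0.5 - margin, "A-dominant", "balanced"))
  weights$call <- call
  weights
}
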