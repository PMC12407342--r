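#' Reciprocal-best-hit orthology
#'
#' Filters similarity rows by e-value (when present), finds each gene's
#' best-scoring partner in both directions, and returns the mutual best
#' pairs. Score ties are broken by the lexicographically smallest partner
#' id; every tie-break is reported via `message()`.
#'
#' @param scores data.frame with gene_sp1, gene_sp2, score and optional
#'   evalue (see [readOrthologScores()]).
#' @param evalue_max maximum e-value retained, default 1e-10.
#' @return A [S4Vectors::DataFrame] of one-to-one pairs (gene_sp1,
#'   gene_sp2, score), sorted by gene_sp1; empty when nothing passes.
#' @export
reciprocalBestHits <- function(scores, evalue_max = 1e-10) {
  df <- as.data.frame(scores)
  if ("evalue" %in% colnames(df))
    df <- df[df$evalue <= evalue_max, , drop = FALSE]
  empty <- S4Vectors::DataFrame(gene_sp1 = character(),
                                gene_sp2 = character(), score = numeric())
  if (nrow(df) == 0) return(empty)
  bestBy <- function(key, partner) {
    o <- order(df[[key]], -df$score, df[[partner]])
    d <- df[o, , drop = FALSE]
    first <- !duplicated(d[[key]])
    ## report ties at the top score
    top <- d[first, , drop = FALSE]
    ties <- merge(d, top[, c(key, "score")], by = c(key, "score"))
    nt <- table(ties[[key]])
    for (g in names(nt)[nt > 1])
      message("reciprocalBestHits: tie for ", g,
              " resolved lexicographically")
    setNames(top[[partner]], top[[key]])
  }
  b12 <- bestBy("gene_sp1", "gene_sp2")
  b21 <- bestBy("gene_sp2", "gene_sp1")
  mutual <- names(b12)[b21[b12] == names(b12)]
  if (length(mutual) == 0) return(empty)
  sc <- df$score[match(paste(mutual, b12[mutual]),
                       paste(df$gene_sp1, df$gene_sp2))]
  res <- S4Vectors::DataFrame(gene_sp1 = mutual,
                              gene_sp2 = unname(b12[mutual]),
                              score = sc)
  res <- res[order(res$gene_sp1), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cross-species conserved cell-specialised gene screen
#'
#' Finds genes highly expressed exclusively in the C4 form of both species:
#' gene g1 must be in species 1's C4-condition DE set but not its C3 set for
#' cell class k, have an ortholog g2, and g2 must be in species 2's C4 set
#' but not its C3 set for the corresponding class. The default class
#' correspondence maps inner mesophyll to mesophyll and Kranz to bundle
#' sheath.
#'
#' @param de_sp1_c4,de_sp1_c3 named lists of gene-id vectors for species 1,
#'   keyed by `names(class_map)`; a class absent from a C3 list is treated
#'   as empty (no exclusion).
#' @param de_sp2_c4,de_sp2_c3 likewise for species 2, keyed by the values of
#'   `class_map`.
#' @param ortholog_map pair table from [reciprocalBestHits()].
#' @param class_map named character vector mapping species-1 cell classes to
#'   species-2 classes, default `c(IMC = "MC", KC = "BSC")`.
#' @return A [S4Vectors::DataFrame] with gene_sp1, gene_sp2, cell_class.
#' @export
conservedExclusiveSets <- function(de_sp1_c4, de_sp1_c3,
                                   de_sp2_c4, de_sp2_c3,
                                   ortholog_map,
                                   class_map = c(IMC = "MC", KC = "BSC")) {
  .assert(all(names(class_map) %in% names(de_sp1_c4)),
          "class label(s) missing from de_sp1_c4: %s",
          paste(setdiff(names(class_map), names(de_sp1_c4)), collapse = ", "))
  .assert(all(class_map %in% names(de_sp2_c4)),
          "class label(s) missing from de_sp2_c4: %s",
          paste(setdiff(class_map, names(de_sp2_c4)), collapse = ", "))
  om <- setNames(ortholog_map$gene_sp2, ortholog_map$gene_sp1)
  out <- list()
  for (k in names(class_map)) {
    k2 <- class_map[[k]]
    ex1 <- setdiff(de_sp1_c4[[k]],
                   if (k %in% names(de_sp1_c3)) de_sp1_c3[[k]] else character())
    ex2 <- setdiff(de_sp2_c4[[k2]],
                   if (k2 %in% names(de_sp2_c3)) de_sp2_c3[[k2]] else
                     character())
    g1 <- ex1[ex1 %in% names(om) & om[ex1] %in% ex2]
    if (length(g1))
      out[[k]] <- S4Vectors::DataFrame(gene_sp1 = sort(g1),
                                       gene_sp2 = unname(om[sort(g1)]),
                                       cell_class = k)
  }
  if (length(out) == 0)
    return(S4Vectors::DataFrame(gene_sp1 = character(),
                                gene_sp2 = character(),
                                cell_class = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
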