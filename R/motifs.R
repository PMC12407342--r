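#' Count accessible elements per motif family and group
#'
#' Restricts a peak-to-gene link table to a gene set and tabulates motif
#' families across analysis groups. `element` mode counts distinct
#' (element_id, family) pairs per group (the default unit for element
#' frequency); `occurrence` mode counts rows.
#'
#' @param links peak-link GRanges (see [readPeakLinks()]).
#' @param gene_set non-empty character vector of gene ids.
#' @param group_by metadata columns defining the group axis, default
#'   `c("cell_type", "condition")`.
#' @param count_mode `"element"` (default) or `"occurrence"`.
#' @param families optional fixed family row order; defaults to all families
#'   in `links`, sorted.
#' @return A counts [MotifMatrix-class] (families x groups). Groups are all
#'   combinations present in the full table, so a gene set absent from a
#'   group yields an all-zero column (with a warning when no row matches at
#'   all).
#' @export
countElements <- function(links, gene_set,
                          group_by = c("cell_type", "condition"),
                          count_mode = c("element", "occurrence"),
                          families = NULL) {
  count_mode <- match.arg(count_mode)
  .assert(length(gene_set) > 0, "gene_set must be non-empty")
  mc <- as.data.frame(S4Vectors::mcols(links))
  .assert(all(group_by %in% colnames(mc)),
          "group_by column(s) absent from links: %s",
          paste(setdiff(group_by, colnames(mc)), collapse = ", "))
  if (is.null(families)) families <- sort(unique(mc$motif_family))
  grp_all <- do.call(paste, c(mc[group_by], sep = "|"))
  groups <- sort(unique(grp_all))
  keep <- mc$gene_id %in% gene_set
  if (!any(keep))
    warning("countElements: no link rows match the gene set")
  sub <- mc[keep, , drop = FALSE]
  grp <- grp_all[keep]
  if (count_mode == "element") {
    dedup <- !duplicated(paste(sub$element_id, sub$motif_family, grp,
                               sep = "\r"))
    sub <- sub[dedup, , drop = FALSE]
    grp <- grp[dedup]
  }
  tab <- table(factor(sub$motif_family, levels = families),
               factor(grp, levels = groups))
  v <- matrix(as.integer(tab), nrow = length(families),
              dimnames = list(families, groups))
  MotifMatrix(v, normalized = FALSE)
}

#' Normalise a motif count matrix to per-group rates
#'
#' Divides each group column by its total so that every non-degenerate
#' column sums to 1 (the element-frequency normalisation used for the
#' cell-type heat maps). All-zero columns stay zero and are flagged
#' degenerate rather than becoming NaN.
#'
#' @param counts a counts [MotifMatrix-class].
#' @return A normalised [MotifMatrix-class].
#' @export
normalizeFrequency <- function(counts) {
  .assert(!isNormalized(counts), "matrix is already normalized")
  v <- motifValues(counts)
  cs <- colSums(v)
  degen <- cs == 0
  out <- v
  if (any(!degen))
    out[, !degen] <- sweep(v[, !degen, drop = FALSE], 2, cs[!degen], "/")
  MotifMatrix(out, normalized = TRUE, degenerate = degen)
}

#' Call the predominant motif family per group
#'
#' Reports, for each non-degenerate group, the family (or families, on an
#' exact tie, in lexicographic order) with the maximal rate, provided that
#' rate reaches `tau_pred`.
#'
#' @param freq a normalised [MotifMatrix-class].
#' @param tau_pred minimum rate for a predominance call, default 0.10.
#' @return A [S4Vectors::DataFrame] with family, group, call and rate.
#' @export
callPredominant <- function(freq, tau_pred = 0.10) {
  .assert(isNormalized(freq), "freq must be normalized")
  v <- motifValues(freq)
  degen <- degenerateGroups(freq)
  out <- list()
  for (g in colnames(v)) {
    if (isTRUE(degen[[g]])) {
      warning("callPredominant: skipping degenerate group ", g)
      next
    }
    col <- v[, g]
    mx <- max(col)
    if (mx < tau_pred) next
    fams <- sort(names(col)[col == mx])
    out[[g]] <- S4Vectors::DataFrame(family = fams, group = g,
                                     call = "predominant", rate = mx)
  }
  if (length(out) == 0)
    return(S4Vectors::DataFrame(family = character(), group = character(),
                                call = character(), rate = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call environment-triggered motif families
#'
#' A family is triggered for condition 1 in a group when its rate under
#' condition 1 reaches `tau_high` while its rate under condition 2 is at
#' most `tau_low` (the high-under-terrestrial versus low-under-submerged
#' contrast). Swap the inputs for the symmetric call.
#'
#' @param freq_cond1,freq_cond2 normalised [MotifMatrix-class] objects
#'   sharing family and group axes (groups typically cell types).
#' @param tau_high minimum rate under condition 1, default 0.10.
#' @param tau_low maximum rate under condition 2, default 0.05.
#' @return A [S4Vectors::DataFrame] with family, group, call,
#'   rate_cond1, rate_cond2.
#' @export
callEnvironmentTriggered <- function(freq_cond1, freq_cond2,
                                     tau_high = 0.10, tau_low = 0.05) {
  .assert(isNormalized(freq_cond1) && isNormalized(freq_cond2),
          "both matrices must be normalized")
  v1 <- motifValues(freq_cond1); v2 <- motifValues(freq_cond2)
  .assert(identical(rownames(v1), rownames(v2)) &&
          identical(colnames(v1), colnames(v2)),
          "family/group axes differ between the two matrices")
  hit <- v1 >= tau_high & v2 <= tau_low
  idx <- which(hit, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(S4Vectors::DataFrame(family = character(), group = character(),
                                call = character(), rate_cond1 = numeric(),
                                rate_cond2 = numeric()))
  res <- S4Vectors::DataFrame(
    family = rownames(v1)[idx[, 1]],
    group = colnames(v1)[idx[, 2]],
    call = "environment_triggered",
    rate_cond1 = v1[idx], rate_cond2 = v2[idx])
  res <- res[order(res$group, res$family), , drop = FALSE]
  rownames(res) <- NULL
  res
}
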