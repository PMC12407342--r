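makeLinks <- function(df) {
  gr <- GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(start = seq_len(nrow(df)) * 100,
                              width = 500))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(df)
  gr
}

test_that("element and occurrence counting modes differ as specified", {
  df <- data.frame(
    element_id = c("e1", "e1", "e1", "e2"),
    gene_id = c("g1", "g1", "g2", "g1"),
    motif_family = c("NAC", "NAC", "NAC", "bZIP"),
    cell_type = "IMC", condition = "terrestrial",
    stringsAsFactors = FALSE)
  links <- makeLinks(df)
  el <- motifValues(countElements(links, c("g1", "g2"),
                                  count_mode = "element"))
  oc <- motifValues(countElements(links, c("g1", "g2"),
                                  count_mode = "occurrence"))
  ## e1/NAC appears on three rows but is one distinct element
  expect_equal(el["NAC", "IMC|terrestrial"], 1)
  expect_equal(oc["NAC", "IMC|terrestrial"], 3)
  expect_equal(el["bZIP", "IMC|terrestrial"], 1)
  ## element mode never exceeds occurrence mode
  expect_true(all(el <= oc))
  ## row permutation invariance
  perm <- makeLinks(df[c(3, 1, 4, 2), ])
  expect_equal(motifValues(countElements(perm, c("g1", "g2"))), el)
  ## single-row table
  one <- countElements(makeLinks(df[4, ]), "g1")
  expect_equal(sum(motifValues(one)), 1)
  expect_error(countElements(links, character()), "non-empty")
  expect_warning(countElements(links, "absent"), "no link rows")
})

test_that("frequency normalisation yields unit columns and flags zeros", {
  v <- matrix(c(2, 2, 0,
                3, 1, 0,
                0, 0, 0), nrow = 3,
              dimnames = list(c("NAC", "bZIP", "MYB"),
                              c("g1", "g2", "g3")))
  fr <- normalizeFrequency(MotifMatrix(v))
  fv <- motifValues(fr)
  expect_equal(unname(fv[, "g1"]), c(0.5, 0.5, 0))
  expect_equal(unname(fv[, "g2"]), c(0.75, 0.25, 0))
  expect_equal(unname(fv[, "g3"]), c(0, 0, 0))
  expect_true(isNormalized(fr))
  expect_equal(unname(degenerateGroups(fr)), c(FALSE, FALSE, TRUE))
  cs <- colSums(fv[, !degenerateGroups(fr), drop = FALSE])
  expect_true(all(abs(cs - 1) < 1e-9))
})

test_that("predominant calls honour the threshold and tie rules", {
  v <- matrix(c(0.242, 0.050, 0.708,
                0.400, 0.400, 0.200,
                0.060, 0.050, 0.890), nrow = 3, byrow = FALSE,
              dimnames = list(c("NAC", "bZIP", "other"),
                              c("IMC", "tie", "max_other")))
  ## column IMC: other (0.708) maximal -> predominant; column tie: NAC and
  ## bZIP tie at 0.4 -> both, lexicographic; all columns sum to 1
  v[, "IMC"] <- c(0.242, 0.050, 0.708)
  v[, "tie"] <- c(0.400, 0.400, 0.200)
  v[, "max_other"] <- c(0.060, 0.050, 0.890)
  fr <- MotifMatrix(v, normalized = TRUE)
  calls <- callPredominant(fr, tau_pred = 0.10)
  imc <- calls[calls$group == "IMC", ]
  expect_equal(imc$family, "other")
  tie <- calls[calls$group == "tie", ]
  expect_equal(tie$family, c("NAC", "bZIP"))
  ## below-threshold maxima yield no call
  u <- matrix(rep(0.05, 20), nrow = 20,
              dimnames = list(sprintf("f%02d", 1:20), "g"))
  expect_equal(nrow(callPredominant(MotifMatrix(u, normalized = TRUE),
                                    tau_pred = 0.10)), 0L)
})

test_that("environment-triggered calls apply the high/low rule", {
  fams <- c("Homeobox", "MYB-related", "G2-like", "rest")
  mk <- function(x) MotifMatrix(
    matrix(x, ncol = 1, dimnames = list(fams, "IMC")), normalized = TRUE)
  terr <- mk(c(0.216, 0.18, 0.08, 0.524))
  subm <- mk(c(0.0, 0.05, 0.0, 0.95))
  calls <- callEnvironmentTriggered(terr, subm)
  ## 21.6% vs 0% and 18% vs 5% trigger; 8% vs 0% fails tau_high
  expect_setequal(calls$family, c("Homeobox", "MYB-related"))
  expect_false("G2-like" %in% calls$family)
  ## axis mismatch is an error
  bad <- MotifMatrix(matrix(c(0.5, 0.5), ncol = 1,
                            dimnames = list(c("x", "y"), "IMC")),
                     normalized = TRUE)
  expect_error(callEnvironmentTriggered(terr, bad), "axes differ")
})
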