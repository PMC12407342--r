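test_that("exact rank-sum p matches enumeration and known cases", {
  r <- rankSumTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)          # 2 extreme of C(6,3)=20 labelings
  expect_equal(r$statistic, 0)

  ## exact mode agrees with the permutation oracle for tie-free n1, n2 <= 6
  set.seed(101)
  for (n1 in 2:6) for (n2 in 2:6) {
    v <- sample(1000, n1 + n2)          # distinct values, no ties
    a <- v[seq_len(n1)]; b <- v[-seq_len(n1)]
    expect_lt(abs(rankSumTest(a, b, mode = "exact")$p_value -
                  permRankSumOracle(a, b)), 1e-12)
  }
})

test_that("exact rank-sum agrees with the reference implementation", {
  set.seed(7)
  for (i in 1:25) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    v <- sample(10000, n1 + n2)
    a <- v[seq_len(n1)]; b <- v[-seq_len(n1)]
    ref <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(rankSumTest(a, b, mode = "exact")$p_value, ref,
                 tolerance = 1e-12)
  }
})

test_that("approximate mode handles ties and symmetry", {
  expect_equal(rankSumTest(c(1, 1, 2), c(1, 1, 2))$p_value, 1)
  ## tie-corrected + continuity-corrected normal mode tracks the reference
  set.seed(8)
  for (i in 1:20) {
    a <- sample(1:5, 30, replace = TRUE)
    b <- sample(1:5, 25, replace = TRUE)
    ref <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    expect_equal(rankSumTest(a, b, mode = "approx")$p_value, ref,
                 tolerance = 1e-10)
  }
  ## documented tolerance vs the full permutation p on small tied samples:
  ## always within 0.5, and mostly within 0.15; the approximation is
  ## intended for the large groups of the marker screen, where it converges
  set.seed(9)
  devs <- replicate(40, {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    a <- sample(1:4, n1, replace = TRUE)
    b <- sample(1:4, n2, replace = TRUE)
    abs(rankSumTest(a, b, mode = "approx")$p_value -
        permRankSumOracle(a, b))
  })
  expect_lt(max(devs), 0.5)
  expect_gte(mean(devs <= 0.15), 0.85)
  expect_error(rankSumTest(numeric(), 1:3), "non-empty")
})

test_that("p-value adjustment matches formulas and the reference", {
  expect_equal(adjustPvalues(c(0.01, 0.4), "bonferroni"), c(0.02, 0.8))
  expect_equal(adjustPvalues(c(0.01, 0.02, 0.03), "bh"),
               c(0.03, 0.03, 0.03))
  expect_equal(adjustPvalues(0.2, "bonferroni"), 0.2)
  expect_equal(adjustPvalues(0.2, "bh"), 0.2)
  expect_error(adjustPvalues(c(0.5, 1.2), "bh"), "outside")
  set.seed(10)
  for (i in 1:10) {
    p <- runif(50)
    expect_equal(adjustPvalues(p, "bh"), stats::p.adjust(p, "BH"))
    expect_equal(adjustPvalues(p, "bonferroni"),
                 stats::p.adjust(p, "bonferroni"))
    ## BH monotonicity: larger raw p never gets a smaller adjusted p
    o <- order(p)
    expect_true(all(diff(adjustPvalues(p, "bh")[o]) >= 0))
  }
})

test_that("marker screen is empty on identical groups and symmetric", {
  set.seed(11)
  counts <- matrix(rpois(200 * 40, 5), nrow = 200)
  half <- counts[, 1:20]
  sce <- normalizeCP10K(toySCE(cbind(half, half),
                               cell_type = rep(c("IMC", "KC"), each = 20),
                               condition = "terrestrial"))
  res <- findMarkerGenes(sce, list(cell_type = "IMC"),
                         list(cell_type = "KC"))
  expect_equal(nrow(res), 0L)

  ## swapping groups inverts the fold change and flips direction
  sce2 <- normalizeCP10K(toySCE(counts,
                                cell_type = rep(c("IMC", "KC"), each = 20),
                                condition = "terrestrial"))
  r12 <- findMarkerGenes(sce2, list(cell_type = "IMC"),
                         list(cell_type = "KC"), return_all = TRUE)
  r21 <- findMarkerGenes(sce2, list(cell_type = "KC"),
                         list(cell_type = "IMC"), return_all = TRUE)
  m <- match(r12$gene_id, r21$gene_id)
  expect_equal(r12$fold_change, 1 / r21$fold_change[m], tolerance = 1e-12)
  expect_equal(r12$p_value, r21$p_value[m], tolerance = 1e-12)
  flip <- c(up_in_group1 = "up_in_group2", up_in_group2 = "up_in_group1")
  expect_equal(unname(flip[r12$direction]), unname(r21$direction[m]))

  expect_error(findMarkerGenes(sce2, list(cell_type = "IMC"),
                               list(cell_type = "missing")), "cells")
})

test_that("planted 3-fold genes are recovered with correct direction", {
  fs <- defaultFamilySpecs()[0, ]
  cfg <- simConfig(n_genes = 500, family_specs = fs,
                   cell_types = c("IMC", "KC"), conditions = "terrestrial",
                   cells_per_group = 150,
                   de_effects = list(list(set_id = "up", n_genes = 25,
                                          fold = 3, cell_type = "IMC",
                                          condition = NULL)))
  ex <- simulateExpression(cfg, seed = 21)
  sce <- normalizeCP10K(ex$sce)
  res <- findMarkerGenes(sce, list(cell_type = "IMC"),
                         list(cell_type = "KC"), method = "bh")
  planted <- ex$truth$de_effects$up$gene_ids
  hit <- res[res$gene_id %in% planted & res$direction == "up_in_group1", ]
  expect_gte(nrow(hit) / length(planted), 0.9)
})
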