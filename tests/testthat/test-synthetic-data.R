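test_that("generators are deterministic for identical (config, seed)", {
  cfg <- smallSimConfig(cells_per_group = 10, n_genes = 50)
  e1 <- simulateExpression(cfg, seed = 7)
  e2 <- simulateExpression(cfg, seed = 7)
  expect_identical(
    SummarizedExperiment::assay(e1$sce, "counts"),
    SummarizedExperiment::assay(e2$sce, "counts"))
  e3 <- simulateExpression(cfg, seed = 8)
  expect_false(identical(
    SummarizedExperiment::assay(e1$sce, "counts"),
    SummarizedExperiment::assay(e3$sce, "counts")))

  p1 <- simulatePeakLinks(cfg, seed = 7)
  p2 <- simulatePeakLinks(cfg, seed = 7)
  expect_identical(as.data.frame(p1$links), as.data.frame(p2$links))

  f1 <- simulatePromoters(cfg, seed = 7, gene_ids = c("gA", "gB"))
  f2 <- simulatePromoters(cfg, seed = 7, gene_ids = c("gA", "gB"))
  expect_identical(f1$sequences, f2$sequences)

  o1 <- simulateOrthologScores(cfg, seed = 7)
  o2 <- simulateOrthologScores(cfg, seed = 7)
  expect_identical(o1$scores, o2$scores)
})

test_that("config validation names the offending field", {
  expect_error(simConfig(n_genes = 0), "n_genes")
  expect_error(simConfig(nb_dispersion = -1), "nb_dispersion")
  expect_error(
    simConfig(motif_rate_vectors = list("C4|IMC|terrestrial" =
                                          c(a = 0.5, b = 0.4))),
    "motif_rate_vectors")
  expect_error(
    simConfig(family_specs = data.frame(
      family = "f", cell_type = "IMC", fold = 3, weight_B_AB = 1.2,
      n_pairs = 1L)),
    "weight_B_AB")
  expect_error(
    simConfig(planted_motifs = list(x = list(consensus = "AXC",
                                             occurrences = 1))),
    "IUPAC")
  expect_error(
    simConfig(planted_motifs = list(x = list(
      consensus = strrep("A", 600), occurrences = 1))),
    "longer than promoter")
})

test_that("counts are non-negative integers with library sizes near target", {
  cfg <- simConfig(n_genes = 500, cell_types = c("IMC", "KC"),
                   conditions = "terrestrial", cells_per_group = 600,
                   de_effects = list())
  ex <- simulateExpression(cfg, seed = 3)
  counts <- SummarizedExperiment::assay(ex$sce, "counts")
  expect_true(all(counts@x >= 0))
  expect_true(all(counts@x == round(counts@x)))
  tot <- Matrix::colSums(counts)
  expect_gt(length(tot), 1000)
  expect_lt(abs(mean(tot) / cfg$mean_library_size - 1), 0.05)
})

test_that("truth entries reference ids present in the generated data", {
  cfg <- smallSimConfig(cells_per_group = 10, n_genes = 50)
  ex <- simulateExpression(cfg, seed = 2)
  expect_true(all(names(ex$truth$family_weights) %in%
                  pairTable(ex$homeologs)$family))
  expect_true(all(homeologGeneIds(cfg) %in% rownames(ex$sce)))

  pk <- simulatePeakLinks(cfg, seed = 2)
  expect_true(all(S4Vectors::mcols(pk$links)$gene_id %in%
                  unlist(pk$gene_sets)))
  expect_true(all(names(pk$truth$rates) %in%
                  names(cfg$motif_rate_vectors)))

  os <- simulateOrthologScores(cfg, seed = 2)
  expect_true(all(os$truth$gene_sp1 %in% os$scores$gene_sp1))
  expect_true(all(os$truth$gene_sp2 %in% os$scores$gene_sp2))
})

test_that("degenerate rate vector yields a single family; planted rates recover", {
  cfg <- smallSimConfig(
    motif_rate_vectors = list("C4|IMC|terrestrial" = c(NAC = 1)),
    elements_per_group = 200)
  pk <- simulatePeakLinks(cfg, seed = 5)
  expect_true(all(S4Vectors::mcols(pk$links)$motif_family == "NAC"))

  cfg2 <- smallSimConfig(
    motif_rate_vectors = list(
      "C4|IMC|terrestrial" = c(NAC = 0.6, bZIP = 0.3, MYB = 0.1)),
    elements_per_group = 1000)
  err <- sapply(1:10, function(s) {
    pk <- simulatePeakLinks(cfg2, seed = s)
    tab <- table(S4Vectors::mcols(pk$links)$motif_family) / 1000
    max(abs(tab[c("NAC", "bZIP", "MYB")] - c(0.6, 0.3, 0.1)))
  })
  expect_true(all(err <= 0.03))
})

test_that("all-unit folds with weight 0.5 give a balanced estimate", {
  fs <- data.frame(family = "flat", cell_type = "IMC", fold = 3,
                   weight_B_AB = 0.5, n_pairs = 50L)
  cfg <- simConfig(n_genes = 300, family_specs = fs,
                   cell_types = c("IMC", "KC"), conditions = "terrestrial",
                   cells_per_group = 150, de_effects = list())
  ex <- simulateExpression(cfg, seed = 11)
  sce <- normalizeCP10K(ex$sce)
  prof <- cellTypeProfile(sce)
  dv <- computeDvalues(prof, "IMC", "KC", "terrestrial",
                       genes = homeologGeneIds(cfg))
  w <- subgenomeWeights(dv, ex$homeologs)$weight_B_AB
  expect_lt(abs(w - 0.5), 0.05)
})

test_that("promoter truth records exact planted positions", {
  cfg <- smallSimConfig(planted_motifs = list(
    bZIP = list(consensus = "TGACGTCA", occurrences = 3)))
  pr <- simulatePromoters(cfg, seed = 4, gene_ids = c("g1", "g2"))
  for (g in c("g1", "g2")) {
    tr <- pr$truth[[g]]$bZIP
    expect_equal(tr$count, 3)
    for (pos in tr$positions)
      expect_equal(substr(pr$sequences[[g]], pos, pos + 7), "TGACGTCA")
  }
})

test_that("background hits of a fixed 12-mer match the closed-form rate", {
  ## no planted motifs: pure uniform background; E[hits per promoter, both
  ## strands] = 2 (L - m + 1) / 4^m
  cfg <- smallSimConfig(planted_motifs = list(), promoter_length = 500)
  motif <- "ACGTACGTTGCA"
  ids <- sprintf("p%03d", 1:300)
  total <- 0
  for (s in 1:4) {
    pr <- simulatePromoters(cfg, seed = s, gene_ids = ids)
    total <- total + sum(vapply(pr$sequences, countMotifHits, 0L,
                                pattern = motif))
  }
  expected <- 4 * 300 * 2 * (500 - 12 + 1) / 4^12
  ## Poisson-scale fluctuation around a mean of ~0.07
  expect_lte(total, stats::qpois(0.9999, expected))
})
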