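test_that("count matrix round trip preserves values and ids", {
  dir <- withr::local_tempdir()
  m <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 2), x = c(5, 1),
                            dims = c(3, 2))
  dimnames(m) <- list(c("g1", "g2", "g3"), c("c1", "c2"))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m))
  writeCountMatrix(sce, dir)
  back <- readCountMatrix(file.path(dir, "matrix.mtx"),
                          file.path(dir, "genes.tsv"),
                          file.path(dir, "cells.tsv"))
  cb <- SummarizedExperiment::assay(back, "counts")
  expect_equal(sum(cb), 6)
  expect_equal(as.matrix(cb), as.matrix(m))
})

test_that("count matrix reader rejects malformed inputs", {
  dir <- withr::local_tempdir()
  m <- Matrix::sparseMatrix(i = 1, j = 1, x = 2, dims = c(2, 2))
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(c("g1", "g1"), file.path(dir, "genes.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "cells.tsv"))
  expect_error(readCountMatrix(file.path(dir, "matrix.mtx"),
                               file.path(dir, "genes.tsv"),
                               file.path(dir, "cells.tsv")),
               "duplicated gene id")
  writeLines(c("g1", "g2", "g3"), file.path(dir, "genes.tsv"))
  expect_error(readCountMatrix(file.path(dir, "matrix.mtx"),
                               file.path(dir, "genes.tsv"),
                               file.path(dir, "cells.tsv")),
               "gene ids")
})

test_that("peak-link table uses 0-based half-open coordinates on disk", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "links.tsv")
  df <- data.frame(element_id = "e1", chromosome = "chr1", start = 10,
                   end = 20, gene_id = "g1", motif_family = "NAC",
                   cell_type = "IMC", condition = "terrestrial")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  gr <- readPeakLinks(path)
  expect_equal(GenomicRanges::width(gr), 10)   # span length = end - start
  ## round trip back to 0-based
  out <- file.path(dir, "links2.tsv")
  writePeakLinks(gr, out)
  df2 <- read.table(out, sep = "\t", header = TRUE)
  expect_equal(df2$start, 10)
  expect_equal(df2$end, 20)

  df$condition <- "aquatic"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readPeakLinks(path), "invalid condition")
  df$condition <- "terrestrial"; df$start <- 25
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readPeakLinks(path), "start >= end")
})

test_that("homeolog table rejects a gene appearing in two pairs", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "hom.tsv")
  df <- data.frame(gene_A = c("a1", "a1"), gene_B = c("b1", "b2"),
                   family = "PEPC")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readHomeologTable(path), "more than one pair")
})

test_that("ortholog score reader rejects duplicate pair rows", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "scores.tsv")
  df <- data.frame(gene_sp1 = c("a", "a"), gene_sp2 = c("b", "b"),
                   score = c(1, 2))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readOrthologScores(path), "duplicate")
})

test_that("motif matrix TSV layout round-trips to 1e-12", {
  dir <- withr::local_tempdir()
  v <- matrix(c(0.75, 0.25, 1 / 3, 2 / 3), 2, 2,
              dimnames = list(c("NAC", "bZIP"), c("IMC", "KC")))
  mm <- MotifMatrix(v, normalized = TRUE)
  path <- file.path(dir, "freq.tsv")
  writeMotifMatrix(mm, path)
  ## families as rows, groups as columns
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_equal(hdr, c("family", "IMC", "KC"))
  back <- readMotifMatrix(path, normalized = TRUE)
  expect_true(all(abs(motifValues(back) - v) < 1e-12))
})

test_that("empty tables write header-only files without error", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "empty.tsv")
  empty <- S4Vectors::DataFrame(gene_sp1 = character(),
                                gene_sp2 = character(), score = numeric())
  kranzC4:::.writeTSV(as.data.frame(empty), path)
  lines <- readLines(path)
  expect_equal(length(lines), 1L)
  expect_match(lines, "gene_sp1\tgene_sp2\tscore")
})

test_that("full simulation bundle writes and re-reads consistently", {
  dir <- withr::local_tempdir()
  cfg <- smallSimConfig(cells_per_group = 10, n_genes = 60,
                        elements_per_group = 50)
  sim <- writeSimulation(cfg, dir, seed = 9)
  sce <- readCountMatrix(file.path(dir, "matrix.mtx"),
                         file.path(dir, "genes.tsv"),
                         file.path(dir, "cells.tsv"))
  expect_equal(dim(sce), dim(sim$expression$sce))
  ann <- readCellAnnotation(file.path(dir, "cell_annotation.tsv"))
  expect_setequal(ann$cell_id, colnames(sce))
  genes <- readGeneAnnotation(file.path(dir, "gene_annotation.tsv"))
  hom <- readHomeologTable(file.path(dir, "homeologs.tsv"), genes)
  expect_equal(length(hom), length(sim$expression$homeologs))
  links <- readPeakLinks(file.path(dir, "peak_links.tsv"))
  expect_equal(length(links), length(sim$peaks$links))
  sc <- readOrthologScores(file.path(dir, "ortholog_scores.tsv"))
  expect_equal(nrow(sc), nrow(sim$orthologs$scores))
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_true(file.exists(file.path(dir, "promoters.fasta")))
})
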