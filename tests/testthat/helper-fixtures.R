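## Small simulator configurations shared across test files.

smallSimConfig <- function(...) {
  defaults <- list(
    n_genes = 400,
    family_specs = data.frame(
      family = c("famB", "famA"), cell_type = c("IMC", "KC"), fold = 3,
      weight_B_AB = c(0.7, 0.3), n_pairs = c(6L, 6L),
      stringsAsFactors = FALSE),
    cell_types = c("IMC", "KC"),
    conditions = c("terrestrial", "submerged"),
    cells_per_group = 40,
    de_effects = list())
  args <- list(...)
  do.call(simConfig, c(args, defaults[setdiff(names(defaults),
                                              names(args))]))
}

## A toy annotated, normalised SingleCellExperiment built by hand.
toySCE <- function(counts, cell_type, condition, replicate = "rep1") {
  genes <- sprintf("g%d", seq_len(nrow(counts)))
  cells <- sprintf("c%d", seq_len(ncol(counts)))
  dimnames(counts) <- list(genes, cells)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)))
  attachCellData(sce, data.frame(
    cell_id = cells, cell_type = cell_type, condition = condition,
    replicate = replicate, stringsAsFactors = FALSE))
}

## Independent regex-based IUPAC match enumerator (test oracle).
## Overlapping matches via zero-width lookahead; N in the sequence can
## never match because classes only contain A/C/G/T.
IUPAC_CLASS <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                 S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                 D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
IUPAC_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                D = "H", H = "D", N = "N")

regexCountOracle <- function(sequence, pattern, strand_mode = "both") {
  toRegex <- function(p) {
    ch <- strsplit(toupper(p), "")[[1]]
    paste0("(?=", paste(sprintf("[%s]", IUPAC_CLASS[ch]), collapse = ""),
           ")")
  }
  countFwd <- function(p) {
    m <- gregexpr(toRegex(p), sequence, perl = TRUE)[[1]]
    sum(m > 0)
  }
  n <- countFwd(pattern)
  if (strand_mode == "both") {
    rc <- paste(rev(IUPAC_COMP[strsplit(toupper(pattern), "")[[1]]]),
                collapse = "")
    n <- n + countFwd(rc)
  }
  n
}

randomIUPAC <- function(len, ambiguous = TRUE) {
  pool <- if (ambiguous) names(IUPAC_CLASS) else c("A", "C", "G", "T")
  ## bias toward concrete bases so matches stay informative
  prob <- if (ambiguous)
    c(rep(0.2, 4), rep(0.2 / 11, 11)) else rep(0.25, 4)
  paste(sample(pool, len, replace = TRUE, prob = prob), collapse = "")
}

## Exhaustive two-sided permutation p-value for the rank-sum statistic
## (oracle): proportion of group-1 assignments at least as extreme, in
## |W - E W|, as observed.
permRankSumOracle <- function(a, b) {
  v <- c(a, b)
  n1 <- length(a)
  r <- rank(v)
  combs <- utils::combn(length(v), n1)
  Ws <- apply(combs, 2, function(i) sum(r[i]))
  W <- sum(r[seq_len(n1)])
  mu <- mean(Ws)
  mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
}

## Brute-force reciprocal-best-hit oracle (double loop).
rbhOracle <- function(df, evalue_max = 1e-10) {
  if ("evalue" %in% colnames(df)) df <- df[df$evalue <= evalue_max, ]
  pairs <- character()
  for (g1 in sort(unique(df$gene_sp1))) {
    d1 <- df[df$gene_sp1 == g1, ]
    d1 <- d1[order(-d1$score, d1$gene_sp2), ]
    b12 <- d1$gene_sp2[1]
    d2 <- df[df$gene_sp2 == b12, ]
    d2 <- d2[order(-d2$score, d2$gene_sp1), ]
    if (d2$gene_sp1[1] == g1) pairs <- c(pairs, paste(g1, b12))
  }
  sort(pairs)
}
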