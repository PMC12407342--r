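#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm rlnorm rnbinom runif rmultinom pnorm setNames
#' @importFrom utils head write.table read.table
#' @importClassesFrom S4Vectors DataFrame
#' @import methods
NULL

## Internal: derive an independent substream seed from a master seed and a
## fixed label, keeping the result inside the 32-bit signed integer range.
.substream <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 48271 + h * 7919) %% 2147483629L)
}

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

## Fixed-format number rendering for deterministic TSV output.
.fmtNum <- function(x, digits = 10L) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}

.writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.readTSV <- function(path, required = character()) {
  .assert(file.exists(path), "file not found: %s", path)
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   comment.char = "", stringsAsFactors = FALSE,
                   check.names = FALSE)
  miss <- setdiff(required, colnames(df))
  .assert(length(miss) == 0L, "missing column(s) in %s: %s",
          path, paste(miss, collapse = ", "))
  df
}
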