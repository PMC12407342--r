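## IUPAC nucleotide codes as 4-bit masks over {A, C, G, T}.
.IUPAC_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, R = 5L, Y = 10L, S = 6L,
                 W = 9L, K = 12L, M = 3L, B = 14L, D = 13L, H = 11L,
                 V = 7L, N = 15L)

## Sequence letters: N (and any other ambiguity) never matches anything.
.seqBits <- function(s) {
  ch <- strsplit(toupper(s), "")[[1]]
  bad <- !ch %in% c("A", "C", "G", "T", "N")
  .assert(!any(bad), "invalid sequence character(s): %s",
          paste(unique(ch[bad]), collapse = ", "))
  unname(c(A = 1L, C = 2L, G = 4L, T = 8L, N = 0L)[ch])
}

.patBits <- function(p) {
  ch <- strsplit(toupper(p), "")[[1]]
  bad <- !ch %in% names(.IUPAC_BITS)
  .assert(!any(bad), "invalid IUPAC symbol(s) in pattern '%s': %s",
          p, paste(unique(ch[bad]), collapse = ", "))
  unname(.IUPAC_BITS[ch])
}

## Complement of a 4-bit mask: swap A<->T and C<->G bits.
.compBits <- function(b) {
  as.integer(bitwShiftL(bitwAnd(b, 1L), 3) + bitwShiftL(bitwAnd(b, 2L), 1) +
             bitwShiftR(bitwAnd(b, 4L), 1) + bitwShiftR(bitwAnd(b, 8L), 3))
}

## 1-based start positions (on the forward sequence) of IUPAC pattern
## matches; overlapping matches counted.
.iupacPositions <- function(sb, pb) {
  L <- length(sb); m <- length(pb)
  if (m > L) return(integer())
  ok <- rep(TRUE, L - m + 1L)
  for (j in seq_len(m))
    ok <- ok & bitwAnd(sb[j:(L - m + j)], pb[j]) > 0L
  which(ok)
}

#' Count IUPAC consensus matches in one sequence
#'
#' Sliding-window matching of an IUPAC consensus at every position;
#' overlapping matches all count. `N` in the sequence never matches any
#' pattern symbol. In `both` mode, reverse-strand hits (matches of the
#' reverse complement of the pattern on the forward sequence) are added;
#' palindromic hits are counted once per strand unless `dedup = TRUE`,
#' which collapses forward/reverse hits at the same start position.
#'
#' @param sequence character scalar over A/C/G/T/N.
#' @param pattern IUPAC consensus string.
#' @param strand_mode `"both"` (default) or `"forward"`.
#' @param dedup collapse coincident forward/reverse hits, default FALSE.
#' @return Integer match count.
#' @export
countMotifHits <- function(sequence, pattern,
                           strand_mode = c("both", "forward"),
                           dedup = FALSE) {
  strand_mode <- match.arg(strand_mode)
  sb <- .seqBits(sequence)
  pb <- .patBits(pattern)
  fwd <- .iupacPositions(sb, pb)
  if (strand_mode == "forward") return(length(fwd))
  rcb <- rev(.compBits(pb))
  rev_ <- .iupacPositions(sb, rcb)
  if (dedup) length(union(fwd, rev_)) else length(fwd) + length(rev_)
}

#' Scan promoter sequences for motif-family consensus occurrences
#'
#' Counts IUPAC consensus matches of each motif family's patterns in each
#' promoter, summing over the family's patterns. This measures intrinsic
#' promoter sequence composition, as opposed to chromatin-accessible element
#' frequencies.
#'
#' @param sequences a [Biostrings::DNAStringSet], a named character vector,
#'   or a FASTA path.
#' @param consensus named list: family -> character vector of IUPAC
#'   consensus patterns.
#' @param strand_mode `"both"` (default) or `"forward"`.
#' @param dedup see [countMotifHits()].
#' @return A counts [MotifMatrix-class], families x sequences (genes);
#'   aggregate to gene sets by summing columns.
#' @export
scanPromoters <- function(sequences, consensus,
                          strand_mode = c("both", "forward"),
                          dedup = FALSE) {
  strand_mode <- match.arg(strand_mode)
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences))
    sequences <- Biostrings::readDNAStringSet(sequences)
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  .assert(is.character(sequences) && !is.null(names(sequences)),
          "sequences must be named")
  .assert(length(consensus) > 0 && !is.null(names(consensus)),
          "consensus must be a named list of pattern vectors")
  sbl <- lapply(sequences, .seqBits)
  fams <- names(consensus)
  v <- matrix(0L, nrow = length(fams), ncol = length(sequences),
              dimnames = list(fams, names(sequences)))
  for (f in fams) {
    for (p in consensus[[f]]) {
      pb <- .patBits(p)
      rcb <- rev(.compBits(pb))
      for (i in seq_along(sbl)) {
        fwd <- .iupacPositions(sbl[[i]], pb)
        n <- length(fwd)
        if (strand_mode == "both") {
          rev_ <- .iupacPositions(sbl[[i]], rcb)
          n <- if (dedup) length(union(fwd, rev_)) else n + length(rev_)
        }
        v[f, i] <- v[f, i] + n
      }
    }
  }
  MotifMatrix(v, normalized = FALSE)
}
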