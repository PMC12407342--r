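#' Divergence time from mean Ks
#'
#' `T = K / (2 r)`: the divergence time in years implied by a mean
#' synonymous substitution value K and a substitution rate r per site per
#' year (molecular-clock assumption; substitutions accumulate on both
#' lineages).
#'
#' @param K mean Ks (synonymous substitutions per synonymous site), >= 0.
#' @param r substitution rate per site per year, > 0.
#' @return Divergence time in years.
#' @export
timeFromKs <- function(K, r) {
  .assert(all(K >= 0), "K must be >= 0")
  .assert(all(r > 0), "rate r must be > 0")
  K / (2 * r)
}

#' Substitution rate from mean Ks and a known divergence time
#'
#' `r = K / (2 T)`: calibrates the per-year synonymous substitution rate
#' from a mean Ks and an externally dated split.
#'
#' @param K mean Ks, >= 0.
#' @param T_years divergence time in years, > 0.
#' @return Rate in substitutions per site per year.
#' @export
rateFromKs <- function(K, T_years) {
  .assert(all(K >= 0), "K must be >= 0")
  .assert(all(T_years > 0), "divergence time must be > 0")
  K / (2 * T_years)
}

#' Convert years to millions of years (Mya) for reporting
#' @param years time in years.
#' @return Time in Mya.
#' @export
yearsToMya <- function(years) years / 1e6
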