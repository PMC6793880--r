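#' Delta notation from isotope ratios
#'
#' Converts a heavy:light isotope ratio, measured against an international
#' standard (V-PDB for carbon, atmospheric air for nitrogen), to delta
#' notation in parts per thousand:
#' \deqn{\delta X = (R_{sample}/R_{standard} - 1) \times 1000}
#' Increasingly positive values indicate enrichment in the heavy isotope.
#'
#' @param r_sample Sample isotope ratio(s) (e.g. \eqn{^{13}C/^{12}C});
#'   strictly positive.
#' @param r_standard Standard isotope ratio(s); strictly positive. Recycled
#'   against `r_sample`.
#' @return Numeric vector of delta values in permil.
#' @seealso [ratio_quotient_from_delta()] for the inverse transform.
#' @examples
#' delta_from_ratios(1.01, 1)   # 10 permil
#' @export
delta_from_ratios <- function(r_sample, r_standard) {
  if (any(!is.finite(r_sample)) || any(!is.finite(r_standard)))
    stop("isotope ratios must be finite")
  if (any(r_sample <= 0) || any(r_standard <= 0))
    stop("isotope ratios must be strictly positive")
  (r_sample / r_standard - 1) * 1000
}

#' Ratio quotient from a delta value
#'
#' Inverts delta notation: returns \eqn{R_{sample}/R_{standard} = 1 +
#' \delta/1000}. Values at or below -1000 permil would imply a non-positive
#' ratio and are rejected.
#'
#' @param delta Delta value(s) in permil; each must exceed -1000.
#' @return The dimensionless ratio quotient(s).
#' @examples
#' ratio_quotient_from_delta(10)  # 1.01
#' @export
ratio_quotient_from_delta <- function(delta) {
  if (any(!is.finite(delta))) stop("delta values must be finite")
  if (any(delta <= -1000))
    stop("delta values must exceed -1000 permil (positive ratio)")
  1 + delta / 1000
}

#' Baseline-referenced delta-15N offsets
#'
#' Expresses each fish's \eqn{\delta^{15}}N relative to a shared isotopic
#' baseline. Long-lived filter feeders (here, rock scallops sampled at the
#' same reefs) provide a time-integrated baseline one trophic level below the
#' smallest fish; the offset above that baseline is a relative measure of
#' trophic position. No trophic enrichment factor is applied, so offsets are
#' in permil, not discrete trophic levels.
#'
#' @param records Isotope record data frame with a `d15N` column (see
#'   [read_isotope_csv()]), or a numeric vector of d15N values.
#' @param baseline_d15N Baseline mean delta-15N in permil (default 10.32).
#' @param baseline_sd Baseline standard deviation, stored as metadata
#'   (default 0.4).
#' @return Numeric vector of offsets (`d15N - baseline_d15N`) with attributes
#'   `baseline_d15N` and `baseline_sd`.
#' @examples
#' baseline_offset(c(10.32, 13.32))
#' @export
baseline_offset <- function(records, baseline_d15N = 10.32, baseline_sd = 0.4) {
  if (!is.finite(baseline_d15N)) stop("baseline_d15N must be finite")
  x <- if (is.data.frame(records)) records$d15N else records
  if (is.null(x)) stop("records must contain a d15N column")
  out <- x - baseline_d15N
  attr(out, "baseline_d15N") <- baseline_d15N
  attr(out, "baseline_sd") <- baseline_sd
  out
}
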