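#' Reference spectral power curve
#'
#' Expected spectral power of a macromolecular structure as a function of
#' inverse resolution, used as a Bayesian prior on the binwise signal
#' spectrum during signal-model refinement. The original tabulation of
#' average macromolecular power spectra is not redistributed; the default is
#' a synthetic smooth stand-in with the characteristic features (a steep
#' low-resolution falloff from molecular shape, a secondary-structure
#' feature near 10 A and the favoured-interatomic-distance peak near 4.5 A,
#' riding on an exponential falloff). Because the prior is only a weak
#' restraint, its exact shape mainly stabilises refinement for weak data. A
#' user-supplied two-column table (s in 1/A, power) can be used instead.
#'
#' @param table optional data frame with columns `s` and `power` (strictly
#'   positive) to interpolate instead of the built-in stand-in curve.
#' @return A function of `s` (1/A) returning strictly positive power values.
#' @export
best_curve <- function(table = NULL) {
  if (is.null(table)) {
    f <- function(s) {
      1.0 * exp(-(s / 0.045)^2) +
        0.055 * exp(-((s - 0.100) / 0.035)^2) +
        0.100 * exp(-((s - 0.222) / 0.030)^2) +
        0.030 * exp(-s / 0.18) +
        0.002
    }
  } else {
    stopifnot(all(c("s", "power") %in% names(table)), all(table$power > 0))
    sp <- stats::splinefun(table$s, log(table$power), method = "natural")
    f <- function(s) exp(sp(s))
  }
  structure(f, class = c("best_curve", "function"))
}
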