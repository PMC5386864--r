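#' Single-predictor NMR oil calibration
#'
#' Benchtop time-domain NMR gives one resonance signal per sample
#' (typically the mean of triplicate acquisitions); oil content is
#' calibrated by a simple least-squares line
#' reference = alpha + beta * resonance.  Model performance is summarised
#' by the correlation r between reference and predicted values and the
#' residual standard error (as [calibration_stats()] with one fitted
#' parameter beyond the intercept).
#'
#' @param resonance Numeric vector of per-sample signals, or a matrix of
#'   replicate acquisitions (rows = samples) averaged per sample.
#' @param reference Reference oil values (% dry matter), same length >= 3.
#' @return An `nmr_calibration`: list with `intercept`, `slope`, `fitted`
#'   and `stats` (a `calibration_stats`).
#' @export
#' @examples
#' sim <- simulate_nmr_readings(n = 45, seed = 1)
#' cal <- nmr_linear_calibration(sim$resonance, sim$reference)
#' cal$stats$r
nmr_linear_calibration <- function(resonance, reference) {
  if (is.matrix(resonance)) resonance <- rowMeans(resonance)
  resonance <- as.numeric(resonance)
  reference <- as.numeric(reference)
  if (length(resonance) != length(reference)) {
    stop_("resonance and reference lengths differ")
  }
  if (length(resonance) < 3) stop_("need at least 3 samples")
  if (stats::var(resonance) == 0) stop_("resonance signal is constant")
  fit <- stats::lm(reference ~ resonance)
  fitted <- unname(stats::fitted(fit))
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 fitted = fitted,
                 stats = calibration_stats(fitted, reference, n_params = 1)),
            class = "nmr_calibration")
}

#' @export
print.nmr_calibration <- function(x, ...) {
  cat(sprintf("NMR linear calibration: reference = %.4g + %.4g * signal\n",
              x$intercept, x$slope))
  print(x$stats)
  invisible(x)
}

#' Seeded random calibration/validation split
#'
#' Splits sample indices into a calibration and a validation set, the
#' usual workflow for NIR model development (e.g. 190 calibration / 20
#' validation out of 210).
#'
#' @param n Total number of samples.
#' @param n_validation Number held out for validation.
#' @param seed Integer seed.
#' @return List with integer vectors `calibration` and `validation`.
#' @export
calibration_split <- function(n, n_validation = 20, seed = 1L) {
  check_number(n, "n", lower = 2)
  check_number(n_validation, "n_validation", lower = 1, upper = n - 1)
  with_seed(seed, {
    val <- sort(sample.int(n, n_validation))
    list(calibration = setdiff(seq_len(n), val), validation = val)
  })
}
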