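#' Simulate bulk-kernel NIR spectra with known chemistry
#'
#' Generates Beer-Lambert mixture spectra of three kernel constituents
#' (starch, protein, oil) on a 400-2500 nm grid at 10-nm steps, the way a
#' scanning NIR instrument records bulk whole grain.  Each constituent
#' contributes Gaussian absorption bands weighted by its concentration;
#' samples get per-sample multiplicative/additive scatter (the effect MSC
#' removes) and i.i.d. instrument noise.  Because kernel oil is
#' concentrated in the embryo, intact-kernel reflectance of oil depends on
#' how kernels happen to face the detector; this orientation effect is
#' emulated by a random per-sample attenuation of the oil bands
#' (`oil_orientation`), which is what makes an intact-kernel NIR oil
#' calibration unreliable while protein calibrates well.
#'
#' Reference chemistry spans the wide ranges used for calibration-set
#' selection: starch ~N(68.65, 5.4^2) in [55.3, 82.3], protein
#' ~N(12.91, 3.08^2) in [6.8, 21.4], oil ~N(3.94, 1.42^2) in [1.7, 6.3]
#' (% dry matter basis).  Because kernel constituents close to a fixed
#' total, compositions are drawn with the strong negative starch-protein
#' correlation seen in real grain (`composition_cor`); without that
#' closure, starch variation is parallel to the mean spectrum and scatter
#' correction would remove it, which no real calibration set exhibits.
#'
#' @param n Number of samples (default 210, a typical calibration set).
#' @param wavelengths Wavelength grid in nm.
#' @param noise_sd Instrument noise standard deviation (absorbance units).
#' @param scatter_sd Length-2 vector: additive offset SD and log-slope SD
#'   of the per-sample scatter transform.
#' @param oil_orientation Emulate embryo-orientation attenuation of the
#'   oil bands (logical).
#' @param composition_cor 3x3 correlation matrix of (starch, protein, oil)
#'   concentrations.
#' @param seed Integer seed.
#' @return A `spectra_set` with `reference` columns `starch`, `protein`,
#'   `oil` and attribute `orientation` (the per-sample oil attenuation).
#' @export
#' @examples
#' s <- simulate_kernel_spectra(n = 20, seed = 1)
#' dim(s$absorbance)
simulate_kernel_spectra <- function(n = 210,
                                    wavelengths = seq(400, 2500, by = 10),
                                    noise_sd = 0.02,
                                    scatter_sd = c(0.05, 0.1),
                                    oil_orientation = TRUE,
                                    composition_cor =
                                      matrix(c(1, -0.82, -0.08,
                                               -0.82, 1, 0.11,
                                               -0.08, 0.11, 1), 3, 3),
                                    seed = 1L) {
  check_number(n, "n", lower = 3)
  wl <- as.numeric(wavelengths)
  bands <- function(centers, widths, amps) {
    rowSums(mapply(function(c0, s0, a0) a0 * exp(-(wl - c0)^2 / (2 * s0^2)),
                   centers, widths, amps))
  }
  eps <- list(
    starch  = bands(c(1450, 1930, 2100), c(60, 70, 80), c(0.6, 0.8, 1.0)),
    protein = bands(c(1510, 2055, 2180), c(40, 50, 50), c(0.9, 1.0, 0.9)),
    oil     = bands(c(1210, 1725, 2310), c(30, 35, 35), c(0.8, 1.0, 0.9))
  )
  baseline <- 0.3 + 2e-4 * (wl - 400)
  with_seed(seed, {
    z <- matrix(stats::rnorm(3 * n), n) %*% chol(composition_cor)
    ref <- data.frame(
      starch  = pmin(pmax(68.65 + 5.40 * z[, 1], 55.3), 82.3),
      protein = pmin(pmax(12.91 + 3.08 * z[, 2], 6.8), 21.4),
      oil     = pmin(pmax(3.94 + 1.42 * z[, 3], 1.7), 6.3),
      row.names = sprintf("s%03d", seq_len(n))
    )
    orient <- if (oil_orientation) stats::runif(n, 0.3, 1) else rep(1, n)
    true <- matrix(baseline, n, length(wl), byrow = TRUE) +
      (ref$starch / 100) %o% eps$starch +
      (ref$protein / 100) %o% eps$protein +
      ((ref$oil / 100) * orient) %o% eps$oil
    a <- stats::rnorm(n, 0, scatter_sd[1])
    b <- exp(stats::rnorm(n, 0, scatter_sd[2]))
    obs <- a + b * true + matrix(stats::rnorm(n * length(wl), 0, noise_sd),
                                 n, length(wl))
    out <- spectra_set(obs, wl, ref)
    rownames(out$absorbance) <- rownames(ref)
    attr(out, "orientation") <- orient
    out
  })
}

#' Simulate triplicate NMR readings with known oil content
#'
#' Linear resonance response to oil content plus acquisition noise,
#' collected in triplicate per sample as on a benchtop NMR analyzer.
#'
#' @param n Number of samples (default 45, a typical NMR calibration set).
#' @param intercept,slope True signal-response line (signal units).
#' @param noise_sd Acquisition noise SD per reading (signal units).
#' @param seed Integer seed.
#' @return List with `resonance` (n x 3 matrix of readings), `reference`
#'   (oil % dry matter) and the true line parameters.
#' @export
simulate_nmr_readings <- function(n = 45, intercept = 50, slope = 120,
                                  noise_sd = 10, seed = 1L) {
  check_number(n, "n", lower = 3)
  with_seed(seed, {
    oil <- stats::runif(n, 1.66, 6.34)
    signal <- intercept + slope * oil
    res <- matrix(stats::rnorm(3 * n, rep(signal, 3), noise_sd), n, 3)
    list(resonance = res, reference = oil,
         intercept = intercept, slope = slope, noise_sd = noise_sd)
  })
}
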