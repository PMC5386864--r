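#' Construct a spectra set
#'
#' A sample-by-wavelength absorbance matrix (log(1/R) units) on a strictly
#' increasing wavelength grid, optionally with reference chemistry values
#' (one column per trait, % dry matter basis).
#'
#' @param absorbance Numeric matrix, samples in rows; column names (or
#'   `wavelengths`) give the grid in nm.
#' @param wavelengths Numeric wavelength grid; defaults to the numeric
#'   column names of `absorbance`.
#' @param reference Optional data frame of reference values with row names
#'   matching the sample row names and one column per trait.
#' @return A `spectra_set`: list with `wavelengths`, `absorbance`,
#'   `reference`.
#' @export
spectra_set <- function(absorbance, wavelengths = NULL, reference = NULL) {
  absorbance <- as.matrix(absorbance)
  if (is.null(wavelengths)) {
    wavelengths <- suppressWarnings(as.numeric(colnames(absorbance)))
    if (anyNA(wavelengths)) {
      stop_("wavelengths not given and column names are not numeric")
    }
  }
  if (length(wavelengths) != ncol(absorbance)) {
    stop_("wavelength grid does not match the absorbance matrix")
  }
  if (any(diff(wavelengths) <= 0)) {
    stop_("wavelengths must be strictly increasing")
  }
  if (!all(is.finite(absorbance))) stop_("absorbance matrix must be finite")
  colnames(absorbance) <- as.character(wavelengths)
  if (is.null(rownames(absorbance))) {
    rownames(absorbance) <- sprintf("s%03d", seq_len(nrow(absorbance)))
  }
  structure(list(wavelengths = as.numeric(wavelengths),
                 absorbance = absorbance, reference = reference),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("Spectra set: %d samples x %d wavelengths (%g-%g nm)\n",
              nrow(x$absorbance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  if (!is.null(x$reference)) {
    cat("reference traits:", paste(colnames(x$reference), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum x on a reference spectrum m by least squares,
#' x = a + b m + e, and returns the corrected spectrum (x - a) / b.  The
#' reference defaults to the mean spectrum of the set.  MSC with a fixed
#' reference is exactly idempotent; with the default (data-dependent) mean
#' reference a second pass is only approximately neutral.
#'
#' @param spectra A `spectra_set`.
#' @param reference Optional reference spectrum (numeric vector on the same
#'   grid).  Required when the set has a single spectrum.
#' @return The corrected `spectra_set`; the fitted intercepts/slopes and
#'   the reference used are in `attr(, "msc")`.  A spectrum uncorrelated
#'   with the reference (slope numerically 0) is an error.
#' @export
#' @examples
#' s <- simulate_kernel_spectra(n = 10, seed = 1)
#' sc <- msc(s)
#' attr(sc, "msc")$b
msc <- function(spectra, reference = NULL) {
  stopifnot(inherits(spectra, "spectra_set"))
  X <- spectra$absorbance
  if (is.null(reference)) {
    if (nrow(X) < 2) stop_("need >= 2 spectra when no reference is supplied")
    reference <- colMeans(X)
  }
  if (length(reference) != ncol(X)) {
    stop_("reference spectrum does not match the wavelength grid")
  }
  mc <- reference - mean(reference)
  vm <- sum(mc^2)
  if (vm < 1e-300) stop_("reference spectrum is constant")
  xbar <- rowMeans(X)
  b <- as.vector((X - xbar) %*% mc) / vm
  if (any(abs(b) < 1e-12)) {
    stop_("spectrum uncorrelated with the reference (b = 0): sample(s) ",
          paste(rownames(X)[abs(b) < 1e-12], collapse = ", "))
  }
  a <- xbar - b * mean(reference)
  out <- spectra_set((X - a) / b, spectra$wavelengths, spectra$reference)
  rownames(out$absorbance) <- rownames(X)
  attr(out, "msc") <- list(a = a, b = b, reference = as.numeric(reference))
  out
}

#' Savitzky-Golay derivative of spectra
#'
#' First derivative (or any lower-order derivative of the local fit) from
#' a moving least-squares polynomial.  Interior points use the symmetric
#' window; edge points are fitted with the asymmetric window clipped to
#' the spectrum (no padding).  The wavelength grid spacing is honoured, so
#' the output is in absorbance per nm.
#'
#' @param spectra A `spectra_set`.
#' @param window Odd window width in points, `window > polyorder`.
#' @param polyorder Polynomial order, at least 1.
#' @return A `spectra_set` of first derivatives.
#' @export
#' @examples
#' s <- simulate_kernel_spectra(n = 5, seed = 1)
#' d <- sg_derivative(s, window = 11, polyorder = 2)
sg_derivative <- function(spectra, window = 11, polyorder = 2) {
  stopifnot(inherits(spectra, "spectra_set"))
  check_number(window, "window", lower = 3)
  check_number(polyorder, "polyorder", lower = 1)
  if (window %% 2 == 0) stop_("window must be odd")
  if (window <= polyorder) stop_("window must exceed polyorder")
  wl <- spectra$wavelengths
  m <- length(wl)
  if (window > m) stop_("window exceeds the number of wavelengths")
  half <- (window - 1) / 2
  D <- matrix(0, m, m)
  for (i in seq_len(m)) {
    idx <- max(1, i - half):min(m, i + half)
    P <- outer(wl[idx] - wl[i], 0:polyorder, "^")
    # row of (P'P)^{-1} P' for the linear coefficient = derivative at wl[i]
    D[i, idx] <- solve(crossprod(P), t(P))[2, ]
  }
  out <- spectra_set(spectra$absorbance %*% t(D), wl, spectra$reference)
  rownames(out$absorbance) <- rownames(spectra$absorbance)
  out
}
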