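# NIPALS PLS1 calibration with a config-driven preprocessing chain.

# apply (and, when fitting, parameterise) a preprocessing chain.
# steps: list of list(type = "sg"/"msc", ...params).  When fit = TRUE the
# MSC reference is learned from the data passing through the chain and
# stored, so prediction reuses the training reference.
.apply_chain <- function(spectra, steps, fit = FALSE) {
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    if (st$type == "sg") {
      spectra <- sg_derivative(spectra, window = st$window %||% 11,
                               polyorder = st$polyorder %||% 2)
    } else if (st$type == "msc") {
      if (fit) {
        spectra <- msc(spectra)
        steps[[i]]$reference <- attr(spectra, "msc")$reference
      } else {
        spectra <- msc(spectra, reference = st$reference)
      }
    } else {
      stop_("unknown preprocessing step: ", st$type)
    }
  }
  list(spectra = spectra, steps = steps)
}

# normalise user-friendly chain notation: c("sg", "msc") or full lists
.normalise_chain <- function(preprocess) {
  if (is.null(preprocess)) return(list())
  if (is.character(preprocess)) {
    preprocess <- lapply(preprocess, function(s) list(type = s))
  }
  preprocess
}

# core NIPALS loop on centered data; returns scores/weights/loadings and
# raw-scale coefficients for 1..ncomp components
.nipals_pls1 <- function(X, y, ncomp) {
  n <- nrow(X)
  p <- ncol(X)
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  W <- P <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  used <- 0L
  for (k in seq_len(ncomp)) {
    w <- as.vector(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) break
    w <- w / nw
    t <- as.vector(Xc %*% w)
    tt <- sum(t^2)
    if (tt < 1e-300) break
    pk <- as.vector(crossprod(Xc, t)) / tt
    qk <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pk)
    yc <- yc - t * qk
    W[, k] <- w
    P[, k] <- pk
    Q[k] <- qk
    used <- k
  }
  if (used == 0L) {
    # y carries no covariance with X: the calibration is the mean of y
    warning("X'y numerically zero: returning the zero-coefficient model",
            call. = FALSE)
    return(list(ncomp = 0L, weights = W[, 0, drop = FALSE],
                loadings = P[, 0, drop = FALSE], q = numeric(0),
                coefficients = rep(0, p), intercept = ym,
                x_center = xm, y_center = ym))
  }
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  Q <- Q[seq_len(used)]
  B <- W %*% solve(crossprod(P, W), Q)
  list(ncomp = used, weights = W, loadings = P, q = Q,
       coefficients = as.vector(B),
       intercept = ym - sum(xm * B), x_center = xm, y_center = ym)
}

#' Fit a PLS1 calibration model
#'
#' NIPALS partial least squares with a single response: iterated weight
#' w proportional to X'y, scores t = Xw, loadings p = X't/t't and
#' q = y't/t't, with deflation of X and y, on column-centered data.
#' Coefficients are assembled for raw-scale prediction.  An optional
#' preprocessing chain (Savitzky-Golay derivative, MSC) is applied before
#' fitting and stored in the model so that [pls1_predict()] replays it; the
#' MSC reference learned here is the mean training spectrum.
#'
#' When `ncomp` is `NULL` the component count is chosen by leave-one-out
#' cross-validation (on the preprocessed matrix) minimising the prediction
#' error, capped at `max_ncomp`.
#'
#' @param X A `spectra_set` or numeric sample x variable matrix.
#' @param y Numeric reference values (non-constant).
#' @param ncomp Number of latent components, or `NULL` for LOO selection.
#' @param preprocess Preprocessing chain: character vector (`"sg"`,
#'   `"msc"`, applied in order) or list of `list(type =, ...)` steps.
#' @param max_ncomp Cap for LOO component selection (default 15).
#' @return A `pls1_model`: preprocessing chain, component count, weights,
#'   loadings, coefficients, centering offsets, fitted values, training
#'   [calibration_stats()], and the LOO curve when selection was used.
#' @export
#' @examples
#' s <- simulate_kernel_spectra(n = 60, seed = 1)
#' fit <- pls1_fit(s, s$reference$protein, ncomp = 5, preprocess = "msc")
#' fit$stats$r
pls1_fit <- function(X, y, ncomp = NULL, preprocess = NULL, max_ncomp = 15) {
  steps <- .normalise_chain(preprocess)
  wavelengths <- NULL
  if (inherits(X, "spectra_set")) {
    ch <- .apply_chain(X, steps, fit = TRUE)
    steps <- ch$steps
    wavelengths <- X$wavelengths
    Xm <- ch$spectra$absorbance
  } else {
    if (length(steps)) {
      stop_("a preprocessing chain needs a spectra_set, not a bare matrix")
    }
    Xm <- as.matrix(X)
  }
  y <- as.numeric(y)
  if (length(y) != nrow(Xm)) stop_("y must have one value per sample")
  if (stats::var(y) == 0) stop_("reference values are constant")
  kmax <- min(max_ncomp, nrow(Xm) - 1, ncol(Xm))
  cv <- NULL
  if (is.null(ncomp)) {
    cv <- .pls1_loo(Xm, y, kmax)
    ncomp <- which.min(cv)
  }
  check_number(ncomp, "ncomp", lower = 1, upper = min(nrow(Xm) - 1, ncol(Xm)))
  core <- .nipals_pls1(Xm, y, ncomp)
  fitted <- as.vector(Xm %*% core$coefficients) + core$intercept
  stats <- calibration_stats(fitted, y, n_params = core$ncomp)
  structure(c(core,
              list(preprocess = steps, wavelengths = wavelengths,
                   fitted = fitted, y = y, stats = stats, cv_press = cv)),
            class = "pls1_model")
}

# leave-one-out RMSEP for 1..kmax components
.pls1_loo <- function(X, y, kmax) {
  n <- nrow(X)
  press <- matrix(NA_real_, n, kmax)
  for (i in seq_len(n)) {
    fit <- .nipals_pls1(X[-i, , drop = FALSE], y[-i], kmax)
    # coefficients per component count from the same decomposition
    for (k in seq_len(fit$ncomp)) {
      Bk <- fit$weights[, 1:k, drop = FALSE] %*%
        solve(crossprod(fit$loadings[, 1:k, drop = FALSE],
                        fit$weights[, 1:k, drop = FALSE]), fit$q[1:k])
      pred <- sum(X[i, ] * Bk) + fit$y_center - sum(fit$x_center * Bk)
      press[i, k] <- (pred - y[i])^2
    }
  }
  sqrt(colMeans(press, na.rm = TRUE))
}

#' Predict from a PLS1 calibration model
#'
#' Replays the stored preprocessing chain (using the training MSC
#' reference) and applies the linear predictor.  The wavelength grid must
#' match the training grid exactly.
#'
#' @param model A `pls1_model`.
#' @param spectra A `spectra_set` (or bare matrix if the model was fitted
#'   on one).
#' @return Numeric vector of predicted trait values.
#' @export
pls1_predict <- function(model, spectra) {
  stopifnot(inherits(model, "pls1_model"))
  if (inherits(spectra, "spectra_set")) {
    if (!is.null(model$wavelengths) &&
        !isTRUE(all.equal(spectra$wavelengths, model$wavelengths))) {
      stop_("wavelength grid does not match the training grid")
    }
    Xm <- .apply_chain(spectra, model$preprocess, fit = FALSE)$spectra$absorbance
  } else {
    Xm <- as.matrix(spectra)
  }
  if (ncol(Xm) != length(model$coefficients)) {
    stop_("spectra dimension does not match the model")
  }
  as.vector(Xm %*% model$coefficients) + model$intercept
}

#' @export
print.pls1_model <- function(x, ...) {
  chain <- if (length(x$preprocess)) {
    paste(vapply(x$preprocess, `[[`, "", "type"), collapse = " -> ")
  } else "none"
  cat(sprintf("PLS1 calibration: %d component(s), preprocessing: %s\n",
              x$ncomp, chain))
  cat(sprintf("training r = %.3f, SEC = %.3f (n = %d)\n",
              x$stats$r, x$stats$sec, x$stats$n))
  invisible(x)
}

#' Calibration statistics
#'
#' Pearson correlation r between reference and predicted values and the
#' standard error of calibration
#' SEC = sqrt(sum((pred - ref)^2) / (n - 1 - n_params)), with `n_params`
#' the number of model parameters beyond the intercept (PLS components, or
#' 1 for a simple regression line).
#'
#' @param predicted Predicted values.
#' @param reference Reference (laboratory) values, same length >= 3.
#' @param n_params Number of fitted parameters beyond the intercept.
#' @return A `calibration_stats` list: `r`, `sec`, `n`, `n_params`.
#'   Constant predictions give `r = NA` with a warning.
#' @export
#' @examples
#' calibration_stats(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8), n_params = 1)
calibration_stats <- function(predicted, reference, n_params = 0) {
  if (length(predicted) != length(reference)) {
    stop_("predicted and reference lengths differ")
  }
  ok <- is.finite(predicted) & is.finite(reference)
  predicted <- predicted[ok]
  reference <- reference[ok]
  n <- length(predicted)
  if (n < 3) stop_("need at least 3 paired values")
  if (n - 1 - n_params <= 0) stop_("too few samples for ", n_params, " parameters")
  r <- if (stats::sd(predicted) == 0 || stats::sd(reference) == 0) {
    warning("constant values: correlation undefined", call. = FALSE)
    NA_real_
  } else {
    stats::cor(predicted, reference)
  }
  structure(list(r = r,
                 sec = sqrt(sum((predicted - reference)^2) /
                              (n - 1 - n_params)),
                 n = n, n_params = n_params),
            class = "calibration_stats")
}

#' @export
print.calibration_stats <- function(x, ...) {
  cat(sprintf("r = %.3f, SEC = %.3f (n = %d)\n", x$r, x$sec, x$n))
  invisible(x)
}
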