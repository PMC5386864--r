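# Forward stepwise joint-linkage model selection and the final OLS fit.

# rank-revealing least squares; drops aliased columns and reports them
.ols <- function(X, y, tol = 1e-9) {
  qx <- qr(X, tol = tol)
  rank <- qx$rank
  keep <- qx$pivot[seq_len(rank)]
  dropped <- colnames(X)[qx$pivot[-seq_len(rank)]]
  Xk <- X[, keep, drop = FALSE]
  qk <- qr(Xk)
  beta <- stats::setNames(as.numeric(qr.coef(qk, y)), colnames(Xk))
  res <- qr.resid(qk, y)
  rss <- sum(res^2)
  df <- length(y) - rank
  R <- qr.R(qk)
  xtx_inv <- chol2inv(R)
  # undo any pivoting inside the second decomposition
  unpiv <- order(qk$pivot)
  se <- sqrt(pmax(diag(xtx_inv)[unpiv], 0) * rss / max(df, 1))
  names(se) <- colnames(Xk)
  list(coef = beta, se = se, residuals = res, rss = rss, rank = rank,
       df_residual = df, kept = colnames(Xk), dropped = dropped)
}

#' Forward stepwise selection with family-nested marker effects
#'
#' Joint step regression across NIL families.  Starting from the
#' family-main-effect-only model, the marker with the smallest
#' family-nested grouped F-test p-value is added while that p-value is
#' below `threshold`, stopping at threshold failure or `max_qtl` markers.
#' Ties are broken in favour of the lower chromosome and then the lower cM
#' position (candidates are scanned in map order).  Candidates whose dose
#' vector is perfectly correlated with an already-selected marker are
#' skipped.  Selection is forward-only; the final model is then refit by
#' [fit_final_model()].
#'
#' @param y Entry means (named numeric vector, or unnamed aligned with the
#'   dosage rows).  Lines with missing values are dropped.
#' @param dosage A `dosage_matrix`.
#' @param threshold Entry p-value threshold in (0, 1), typically from
#'   [permutation_threshold()].
#' @param max_qtl Maximum number of markers to select.
#' @return A `qtl_model` (see [fit_final_model()]) whose `markers` are in
#'   selection order; `threshold` and the per-step entry p-values
#'   (`entry_pvalues`) are recorded.
#' @export
#' @examples
#' map <- synthetic_genetic_map(40)
#' pop <- simulate_nil_population(map, c(A = 60, B = 60), seed = 1)
#' dos <- encode_dosage(pop)
#' q <- qtl_spec("m0010", "oil", c("A", "B"), c(0.6, 0.4))
#' plots <- simulate_phenotypes(pop, q, env_spec(var_G = 0.01, var_GE = 0.01,
#'                                               var_E = 0.05),
#'                              traits = "oil", seed = 2)
#' y <- lsmeans_vector(compute_lsmeans(plots), "oil")
#' forward_select(y, dos, threshold = 1e-4)$markers
forward_select <- function(y, dosage, threshold, max_qtl = 10) {
  stopifnot(inherits(dosage, "dosage_matrix"))
  check_number(threshold, "threshold", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_number(max_qtl, "max_qtl", lower = 0)
  al <- .align_y(y, dosage)
  y <- al$y
  dosage <- al$dosage
  markers <- dosage$map$marker  # map order = tie-break order
  selected <- character(0)
  entry_p <- numeric(0)
  prep <- .scan_prep(dosage)
  while (length(selected) < max_qtl) {
    candidates <- setdiff(markers, selected)
    if (length(selected)) {
      candidates <- candidates[!.perfectly_correlated(dosage, candidates,
                                                      selected)]
    }
    if (!length(candidates)) break
    p <- if (length(selected) == 0) {
      .scan_pvalues_base(prep, y)[candidates]
    } else {
      .scan_general(y, dosage, selected, candidates)
    }
    best <- which.min(p)  # first minimum = lowest chromosome, then cM
    if (!is.finite(p[best]) || p[best] >= threshold) break
    selected <- c(selected, candidates[best])
    entry_p <- c(entry_p, unname(p[best]))
  }
  model <- fit_final_model(y, dosage, selected)
  model$threshold <- threshold
  model$entry_pvalues <- stats::setNames(entry_p, selected)
  model
}

.perfectly_correlated <- function(dosage, candidates, selected) {
  S <- dosage$dose[, selected, drop = FALSE]
  vapply(candidates, function(m) {
    x <- dosage$dose[, m]
    if (stats::var(x) < 1e-12) return(FALSE)
    r <- suppressWarnings(stats::cor(x, S))
    any(abs(r) > 1 - 1e-12, na.rm = TRUE)
  }, logical(1))
}

#' Fit the final joint-linkage model
#'
#' Ordinary least squares on family main effects plus all family-nested
#' dose columns of the selected markers.  Reports per-coefficient
#' estimates, standard errors and two-sided t-tests of each teosinte
#' (donor) allele against the B73 (recurrent) allele, which is the 0-dose
#' baseline; a negative coefficient means the donor allele lowers the
#' trait.  Rank-deficient columns are dropped with a warning.
#'
#' @param y Entry means (named or aligned numeric vector).
#' @param dosage A `dosage_matrix`.
#' @param markers Character vector of selected markers (possibly empty).
#' @return A `qtl_model`: list with `markers`, `coefficients` (data frame
#'   with `term`, `type` ("family" or "marker"), `marker`, `family`,
#'   `estimate`, `std_error`, `t_value`, `p_value`), `r_squared` (total,
#'   including family effects), `r_squared_markers` (increment of the
#'   marker terms over the family-only model), `rss`, `sigma2`, `n`,
#'   `df_residual`, `family_levels`, and `dropped` columns.
#' @export
fit_final_model <- function(y, dosage, markers = character(0)) {
  stopifnot(inherits(dosage, "dosage_matrix"))
  al <- .align_y(y, dosage)
  y <- al$y
  dosage <- al$dosage
  bad <- setdiff(markers, colnames(dosage$dose))
  if (length(bad)) stop_("unknown marker(s): ", paste(bad, collapse = ", "))
  X <- .base_design(dosage, markers)
  fit <- .ols(X, y)
  if (length(fit$dropped)) {
    warning("rank-deficient design; dropped column(s): ",
            paste(fit$dropped, collapse = ", "), call. = FALSE)
  }
  tss <- sum((y - mean(y))^2)
  Xf <- .base_design(dosage, NULL)
  rss_fam <- .ols(Xf, y)$rss
  tval <- fit$coef / fit$se
  pval <- 2 * stats::pt(-abs(tval), fit$df_residual)
  is_marker <- grepl(":", fit$kept) & !grepl("^family:", fit$kept) &
    !grepl("Intercept", fit$kept)
  coefs <- data.frame(
    term = fit$kept,
    type = ifelse(is_marker, "marker", "family"),
    marker = ifelse(is_marker, sub(":.*$", "", fit$kept), NA_character_),
    family = ifelse(is_marker, sub("^.*:", "", fit$kept),
                    sub("^family:", "", fit$kept)),
    estimate = unname(fit$coef),
    std_error = unname(fit$se),
    t_value = unname(tval),
    p_value = unname(pval),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(markers = markers,
                 coefficients = coefs,
                 r_squared = if (tss > 0) 1 - fit$rss / tss else NA_real_,
                 r_squared_markers = if (tss > 0) (rss_fam - fit$rss) / tss
                                     else NA_real_,
                 rss = fit$rss,
                 sigma2 = fit$rss / max(fit$df_residual, 1),
                 n = length(y),
                 df_residual = fit$df_residual,
                 family_levels = levels(dosage$family),
                 dropped = fit$dropped,
                 threshold = NULL),
            class = "qtl_model")
}

#' @export
print.qtl_model <- function(x, ...) {
  cat(sprintf("Joint-linkage QTL model: %d marker(s), n = %d lines\n",
              length(x$markers), x$n))
  if (length(x$markers)) cat("markers:", paste(x$markers, collapse = ", "), "\n")
  cat(sprintf("total R2 = %.3f (marker terms: %.3f)\n",
              x$r_squared, x$r_squared_markers))
  if (!is.null(x$threshold)) {
    cat(sprintf("entry threshold: %.3g\n", x$threshold))
  }
  invisible(x)
}
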