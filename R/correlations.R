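#' Phenotypic correlations among entry means
#'
#' Pairwise-complete Pearson correlations between trait LSmeans with
#' two-sided t-distribution p-values.  A constant trait, or a pair with
#' fewer than three complete observations, yields `NA` with a warning.
#'
#' @param lsmeans An `ls_means` data frame (column `line` plus one numeric
#'   column per trait) or a numeric line x trait matrix.
#' @return A `correlation_report`: list with symmetric matrices `r`
#'   (diagonal 1), `p` and `n` (complete pairs).
#' @export
#' @examples
#' lsm <- data.frame(line = paste0("L", 1:5),
#'                   starch = c(70, 71, 72, 73, 74),
#'                   protein = c(12, 11.5, 11, 10.5, 10))
#' phenotypic_correlations(lsm)$r
phenotypic_correlations <- function(lsmeans) {
  m <- if (is.matrix(lsmeans)) {
    lsmeans
  } else {
    num <- vapply(lsmeans, is.numeric, logical(1))
    as.matrix(lsmeans[, num & names(lsmeans) != "line", drop = FALSE])
  }
  traits <- colnames(m)
  k <- length(traits)
  if (k < 2) stop_("need at least two traits for correlations")
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  diag(r) <- 1
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- stats::complete.cases(m[, c(i, j)])
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < 3) {
        warning("fewer than 3 complete pairs for ", traits[i], "-",
                traits[j], call. = FALSE)
        next
      }
      x <- m[ok, i]
      y <- m[ok, j]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning("constant trait in pair ", traits[i], "-", traits[j],
                "; correlation undefined", call. = FALSE)
        next
      }
      ct <- stats::cor.test(x, y)
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = n), class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, digits = 3, ...) {
  cat("Phenotypic correlations (Pearson r, pairwise complete):\n")
  print(round(x$r, digits))
  cat("two-sided p-values:\n")
  print(signif(x$p, 2))
  invisible(x)
}
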