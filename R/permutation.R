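#' Permutation genome-wide entry threshold
#'
#' Determines the entry p-value threshold controlling the genome-wide
#' error rate (GWER) for the family-nested marker scan.  For each
#' permutation, entry means are shuffled across lines *within* each family
#' (genotypes fixed), which preserves the family main effects under the
#' null; the minimum family-nested grouped F-test p-value over all markers
#' against the family-main-effect-only model is recorded.  The threshold
#' is the `gwer`-quantile of these minima, so forward entry at the
#' returned threshold declares one or more QTL in about `gwer` of null
#' genome scans.
#'
#' @param y Entry means (named or aligned numeric vector).
#' @param dosage A `dosage_matrix`.
#' @param n_perm Number of permutations (>= 100; 1000 is conventional).
#' @param gwer Target genome-wide error rate in (0, 1).
#' @param seed Integer seed; the threshold is deterministic for a fixed
#'   seed.
#' @return A `perm_threshold` object: list with `threshold`, `gwer`,
#'   `n_perm` and the vector `min_pvalues` of per-permutation minima.
#' @export
#' @examples
#' map <- synthetic_genetic_map(40)
#' pop <- simulate_nil_population(map, c(A = 50, B = 50), seed = 1)
#' dos <- encode_dosage(pop)
#' y <- stats::setNames(rnorm(100), rownames(dos$dose))
#' permutation_threshold(y, dos, n_perm = 100, seed = 1)$threshold
permutation_threshold <- function(y, dosage, n_perm = 1000, gwer = 0.05,
                                  seed = 1L) {
  stopifnot(inherits(dosage, "dosage_matrix"))
  check_number(gwer, "gwer", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_number(n_perm, "n_perm", lower = 100)
  al <- .align_y(y, dosage)
  y <- al$y
  prep <- .scan_prep(al$dosage)
  idx_by_fam <- split(seq_along(y), prep$fam)
  minp <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    yp <- y
    for (ix in idx_by_fam) yp[ix] <- yp[ix][sample.int(length(ix))]
    min(.scan_pvalues_base(prep, yp))
  }, numeric(1)))
  thr <- sort(minp)[max(1L, ceiling(gwer * n_perm))]
  structure(list(threshold = unname(thr), gwer = gwer, n_perm = n_perm,
                 min_pvalues = minp),
            class = "perm_threshold")
}

#' @export
print.perm_threshold <- function(x, ...) {
  cat(sprintf(
    "Permutation entry threshold: %.3g (GWER %.2g, %d permutations)\n",
    x$threshold, x$gwer, x$n_perm))
  invisible(x)
}
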