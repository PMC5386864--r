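# Family-nested marker association machinery.
#
# The entry test for a marker is the grouped F-test of all its
# family-nested dose columns (one column per family in which the marker
# segregates, i.e. has within-family dose variance) added to a base model.
# Against the family-main-effect-only base the nested columns of one
# marker have disjoint support across families and are orthogonal to the
# family indicators after within-family centering, so the regression sum
# of squares decomposes into per-family projections; the whole-genome scan
# is a handful of `rowsum` operations.  Against a richer base model
# (earlier selected markers) the test falls back to QR projections.

# precompute within-family-centered doses and per-family sums of squares
.scan_prep <- function(dosage) {
  fam <- droplevels(as.factor(dosage$family))
  X <- dosage$dose
  cnt <- as.vector(table(fam))
  fmean <- rowsum(X, fam) / cnt
  Xc <- X - fmean[as.integer(fam), , drop = FALSE]
  B <- rowsum(Xc * Xc, fam)
  seg <- B > 1e-9
  list(fam = fam, Xc = Xc, B = B, seg = seg, k = colSums(seg),
       n = nrow(X), nf = nlevels(fam))
}

.center_by <- function(y, fam) {
  y - (rowsum(y, fam) / as.vector(table(fam)))[as.integer(fam)]
}

# grouped F-test p-value for every marker against the family-only model
.scan_pvalues_base <- function(prep, y) {
  yc <- .center_by(y, prep$fam)
  A <- rowsum(prep$Xc * yc, prep$fam)
  contrib <- A * A / pmax(prep$B, 1e-300)
  contrib[!prep$seg] <- 0
  ss <- colSums(contrib)
  rss0 <- sum(yc * yc)
  rss1 <- pmax(rss0 - ss, 0)
  df2 <- prep$n - prep$nf - prep$k
  f <- (ss / pmax(prep$k, 1)) / (rss1 / pmax(df2, 1))
  p <- stats::pf(f, pmax(prep$k, 1), pmax(df2, 1), lower.tail = FALSE)
  p[prep$k == 0 | df2 < 1] <- 1
  names(p) <- colnames(prep$Xc)
  p
}

# family-nested dose columns of one marker (segregating families only)
.nested_columns <- function(dosage, marker) {
  x <- dosage$dose[, marker]
  fam <- dosage$family
  segfam <- levels(fam)[tapply(x, fam, stats::var) > 1e-9]
  segfam <- segfam[!is.na(segfam)]
  Z <- vapply(segfam, function(f) x * (fam == f), numeric(length(x)))
  if (length(segfam) == 0) Z <- matrix(0, length(x), 0)
  colnames(Z) <- if (length(segfam)) paste0(marker, ":", segfam)
  Z
}

# family main effects plus nested columns of already-selected markers
.base_design <- function(dosage, markers = NULL) {
  fam <- droplevels(as.factor(dosage$family))
  Xf <- if (nlevels(fam) > 1) {
    stats::model.matrix(~family, data = data.frame(family = fam))
  } else {
    matrix(1, length(fam), 1, dimnames = list(NULL, "(Intercept)"))
  }
  colnames(Xf) <- sub("^family", "family:", colnames(Xf))
  if (length(markers)) {
    Z <- do.call(cbind, lapply(markers, function(m) .nested_columns(dosage, m)))
    Xf <- cbind(Xf, Z)
  }
  Xf
}

# grouped F-test of marker columns given a prepared QR of the base design
.nested_f_test_qr <- function(qr0, res_y, rss0, dosage, marker) {
  n <- length(res_y)
  Z <- .nested_columns(dosage, marker)
  if (ncol(Z) == 0) {
    return(list(p_value = 1, statistic = NA_real_, df1 = 0L,
                df2 = n - qr0$rank, no_segregation = TRUE))
  }
  Zr <- qr.resid(qr0, Z)
  qz <- qr(Zr)
  rank <- qz$rank
  if (rank == 0) {
    return(list(p_value = 1, statistic = NA_real_, df1 = 0L,
                df2 = n - qr0$rank, no_segregation = FALSE))
  }
  ss <- sum(qr.fitted(qz, res_y)^2)
  rss1 <- max(rss0 - ss, 0)
  df2 <- n - qr0$rank - rank
  if (df2 < 1) {
    return(list(p_value = 1, statistic = NA_real_, df1 = rank, df2 = df2,
                no_segregation = FALSE))
  }
  f <- (ss / rank) / (rss1 / df2)
  list(p_value = stats::pf(f, rank, df2, lower.tail = FALSE),
       statistic = f, df1 = rank, df2 = df2, no_segregation = FALSE)
}

#' Family-nested marker entry test
#'
#' Tests whether adding a marker's family-nested dose columns (one per
#' family in which it segregates) improves a base model, by a grouped
#' F-test.  The base model is the family-main-effect-only model when
#' `base_model` is `NULL`, or a fitted [fit_final_model()] /
#' [forward_select()] model whose selected markers then enter the base
#' design.  A marker segregating in no family returns p = 1 with the
#' `no_segregation` flag set.
#'
#' @param y Entry means: named numeric vector (names = line identifiers)
#'   or unnamed vector aligned with the dosage rows.
#' @param dosage A `dosage_matrix` from [encode_dosage()].
#' @param base_model Optional `qtl_model` giving the markers already in
#'   the model.
#' @param marker Marker identifier to test (must not be in the base model).
#' @return List with `p_value`, `statistic`, `df1` (number of segregating
#'   nested columns retained), `df2`, and `no_segregation`.
#' @export
#' @examples
#' map <- synthetic_genetic_map(40)
#' pop <- simulate_nil_population(map, c(A = 40, B = 40), seed = 1)
#' dos <- encode_dosage(pop)
#' y <- stats::setNames(rnorm(80), rownames(dos$dose))
#' nested_marker_pvalue(y, dos, marker = "m0010")$p_value
nested_marker_pvalue <- function(y, dosage, base_model = NULL, marker) {
  stopifnot(inherits(dosage, "dosage_matrix"))
  if (!marker %in% colnames(dosage$dose)) stop_("unknown marker: ", marker)
  base_markers <- base_model$markers
  if (marker %in% base_markers) {
    stop_("marker ", marker, " is already in the base model")
  }
  al <- .align_y(y, dosage)
  X0 <- .base_design(al$dosage, base_markers)
  qr0 <- qr(X0)
  res_y <- qr.resid(qr0, al$y)
  .nested_f_test_qr(qr0, res_y, sum(res_y^2), al$dosage, marker)
}

# scan every candidate marker against an arbitrary base design
.scan_general <- function(y, dosage, base_markers, candidates) {
  X0 <- .base_design(dosage, base_markers)
  qr0 <- qr(X0)
  res_y <- qr.resid(qr0, y)
  rss0 <- sum(res_y^2)
  vapply(candidates, function(m) {
    .nested_f_test_qr(qr0, res_y, rss0, dosage, m)$p_value
  }, numeric(1))
}
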