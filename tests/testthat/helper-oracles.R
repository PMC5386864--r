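# Independent brute-force oracles: everything here solves the normal
# equations directly (solve of X'X), a different algorithm from the
# package's QR-based fitting path.

ols_oracle <- function(X, y) {
  xtx <- crossprod(X)
  beta <- solve(xtx, crossprod(X, y))
  res <- y - X %*% beta
  rss <- sum(res^2)
  df <- length(y) - ncol(X)
  list(coef = as.numeric(beta),
       se = as.numeric(sqrt(diag(solve(xtx)) * rss / df)),
       rss = rss, df = df)
}

f_test_oracle <- function(X0, X1, y) {
  r0 <- ols_oracle(X0, y)$rss
  r1 <- ols_oracle(X1, y)$rss
  df1 <- ncol(X1) - ncol(X0)
  df2 <- length(y) - ncol(X1)
  f <- ((r0 - r1) / df1) / (r1 / df2)
  list(f = f, p = pf(f, df1, df2, lower.tail = FALSE),
       rss0 = r0, rss1 = r1)
}

# nested design built from first principles: family dummies plus
# dose x family-indicator columns for families where the dose varies
oracle_nested_design <- function(dose, fam, markers) {
  X <- stats::model.matrix(~fam)
  for (m in markers) {
    x <- dose[, m]
    for (f in levels(fam)) {
      if (stats::var(x[fam == f]) > 1e-9) {
        X <- cbind(X, x * (fam == f))
        colnames(X)[ncol(X)] <- paste0(m, "@", f)
      }
    }
  }
  X
}

# forward path by exhaustive per-step rescan with the normal-equations F
forward_oracle <- function(y, dose, fam, map, threshold, max_qtl = 5) {
  selected <- character(0)
  markers <- map$marker
  repeat {
    if (length(selected) >= max_qtl) break
    cands <- setdiff(markers, selected)
    X0 <- oracle_nested_design(dose, fam, selected)
    ps <- vapply(cands, function(m) {
      X1 <- oracle_nested_design(dose, fam, c(selected, m))
      if (ncol(X1) == ncol(X0)) return(1)
      if (qr(X1)$rank < ncol(X1)) return(NA_real_)  # skip singular adds
      f_test_oracle(X0, X1, y)$p
    }, numeric(1))
    ps[is.na(ps)] <- 1
    best <- which.min(ps)
    if (ps[best] >= threshold) break
    selected <- c(selected, cands[best])
  }
  selected
}

# small well-segregating population for oracle comparisons: an early
# pedigree (BC1S1) keeps donor alleles frequent so markers segregate
make_oracle_pop <- function(n_per_fam = 12, n_fam = 4, n_markers = 12,
                            seed = 1, pedigree = pedigree_spec(1, 1)) {
  map <- synthetic_genetic_map(n_markers, chr_lengths = c(120, 120))
  sizes <- stats::setNames(rep(n_per_fam, n_fam),
                           sprintf("F%02d", seq_len(n_fam)))
  simulate_nil_population(map, sizes, pedigree, seed = seed)
}

# assemble a nil_genotypes object by hand for targeted edge cases
make_genos <- function(calls, family, map) {
  structure(list(calls = calls,
                 family = stats::setNames(factor(family), rownames(calls)),
                 map = map),
            class = "nil_genotypes")
}

expect_rel_equal <- function(x, y, tol = 1e-8) {
  expect_lt(max(abs(x - y)) / max(1e-12, max(abs(y))), tol)
}
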