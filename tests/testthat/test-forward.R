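test_that("no-QTL data at a strict threshold selects nothing", {
  pop <- make_oracle_pop(n_per_fam = 25, seed = 5)
  dos <- encode_dosage(pop)
  set.seed(101)
  y <- stats::setNames(rnorm(nrow(dos$dose)), rownames(dos$dose))
  m <- forward_select(y, dos, threshold = 1e-10)
  expect_length(m$markers, 0)
  expect_true(m$r_squared_markers == 0)
})

test_that("the selection path equals the exhaustive brute-force path", {
  for (seed in c(2, 9, 17)) {
    pop <- make_oracle_pop(n_per_fam = 12, n_fam = 4, n_markers = 12,
                           seed = seed)
    dos <- encode_dosage(pop)
    fam <- dos$family
    set.seed(seed)
    mk <- colnames(dos$dose)
    y <- rnorm(nrow(dos$dose), sd = 0.6) +
      1.2 * dos$dose[, mk[3]] * (fam == "F01") +
      -1.0 * dos$dose[, mk[9]] * (fam == "F03")
    names(y) <- rownames(dos$dose)
    got <- forward_select(y, dos, threshold = 0.01, max_qtl = 4)
    want <- forward_oracle(unname(y), dos$dose, fam, dos$map,
                           threshold = 0.01, max_qtl = 4)
    expect_identical(got$markers, want)
  }
})

test_that("R2 is non-decreasing and RSS non-increasing along the path", {
  pop <- make_oracle_pop(n_per_fam = 20, n_markers = 12, seed = 4)
  dos <- encode_dosage(pop)
  fam <- dos$family
  set.seed(40)
  y <- rnorm(nrow(dos$dose), sd = 0.5) + dos$dose[, 2] +
    0.8 * dos$dose[, 8] * (fam == "F02")
  names(y) <- rownames(dos$dose)
  sel <- forward_select(y, dos, threshold = 0.2, max_qtl = 4)$markers
  skip_if(length(sel) < 2)
  fits <- lapply(seq_along(sel), function(k) {
    fit_final_model(y, dos, sel[seq_len(k)])
  })
  rss <- vapply(fits, `[[`, 0, "rss")
  r2 <- vapply(fits, `[[`, 0, "r_squared")
  expect_true(all(diff(rss) <= 1e-10))
  expect_true(all(diff(r2) >= -1e-10))
})

test_that("an exact family-nested signal is recovered with R2 = 1", {
  pop <- make_oracle_pop(n_per_fam = 15, seed = 6)
  dos <- encode_dosage(pop)
  fam <- dos$family
  fam_means <- c(F01 = 1, F02 = -2, F03 = 0.5, F04 = 3)
  y <- fam_means[as.character(fam)] + 3 * dos$dose[, 5] * (fam == "F01")
  names(y) <- rownames(dos$dose)
  fit <- fit_final_model(y, dos, colnames(dos$dose)[5])
  co <- fit$coefficients
  b <- co$estimate[co$type == "marker" & co$family == "F01"]
  expect_equal(b, 3, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("final-model coefficients match the normal-equations oracle", {
  pop <- make_oracle_pop(n_per_fam = 14, seed = 10)
  dos <- encode_dosage(pop)
  set.seed(11)
  y <- rnorm(nrow(dos$dose)) + dos$dose[, 3]
  names(y) <- rownames(dos$dose)
  sel <- colnames(dos$dose)[c(3, 8)]
  X <- oracle_nested_design(dos$dose, dos$family, sel)
  skip_if(qr(X)$rank < ncol(X))
  want <- ols_oracle(X, unname(y))
  fit <- fit_final_model(y, dos, sel)
  expect_rel_equal(sort(fit$coefficients$estimate), sort(want$coef))
  expect_rel_equal(sort(fit$coefficients$std_error), sort(want$se))
  expect_rel_equal(fit$rss, want$rss)
})

test_that("rank-deficient designs are repaired with a warning", {
  # two identical markers cannot enter jointly at full rank
  map <- genetic_map(c("m1", "m2"), c(1, 1), c(0, 0))
  calls <- matrix(rep(c("B", "D", "H", "B", "D", "B"), 2), 6, 2,
                  dimnames = list(paste0("L", 1:6), map$marker))
  g <- make_genos(calls, rep(c("A", "B"), each = 3), map)
  dos <- encode_dosage(g)
  y <- stats::setNames(c(1, 5, 3, 0, 4, 1), rownames(calls))
  expect_warning(fit <- fit_final_model(y, dos, c("m1", "m2")),
                 "rank-deficient")
  expect_true(length(fit$dropped) > 0)
  # and forward selection skips perfect proxies instead
  sel <- forward_select(y, dos, threshold = 0.9, max_qtl = 2)
  expect_lte(length(sel$markers), 1)
})
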