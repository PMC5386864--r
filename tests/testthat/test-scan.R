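test_that("entry test matches the brute-force normal-equations F-test", {
  for (seed in 1:4) {
    pop <- make_oracle_pop(seed = seed)
    dos <- encode_dosage(pop)
    fam <- dos$family
    set.seed(seed + 50)
    y <- rnorm(nrow(dos$dose)) + 0.8 * dos$dose[, 3]
    names(y) <- rownames(dos$dose)
    # against the family-only base
    for (m in colnames(dos$dose)[c(1, 3, 7)]) {
      got <- nested_marker_pvalue(y, dos, marker = m)
      X0 <- oracle_nested_design(dos$dose, fam, character(0))
      X1 <- oracle_nested_design(dos$dose, fam, m)
      if (qr(X1)$rank < ncol(X1)) next
      want <- f_test_oracle(X0, X1, unname(y))
      expect_rel_equal(got$p_value, want$p)
      expect_rel_equal(got$statistic, want$f)
    }
    # against a base model that already contains a marker
    base <- fit_final_model(y, dos, colnames(dos$dose)[3])
    m2 <- colnames(dos$dose)[7]
    got <- nested_marker_pvalue(y, dos, base, m2)
    X0 <- oracle_nested_design(dos$dose, fam, colnames(dos$dose)[3])
    X1 <- oracle_nested_design(dos$dose, fam, colnames(dos$dose)[c(3, 7)])
    if (qr(X1)$rank == ncol(X1)) {
      want <- f_test_oracle(X0, X1, unname(y))
      expect_rel_equal(got$p_value, want$p)
    }
  }
})

test_that("the fast family-only scan equals the general QR path", {
  pop <- make_oracle_pop(n_per_fam = 15, n_markers = 10, seed = 8)
  dos <- encode_dosage(pop)
  set.seed(60)
  y <- stats::setNames(rnorm(nrow(dos$dose)), rownames(dos$dose))
  prep <- teonil:::.scan_prep(dos)
  fast <- teonil:::.scan_pvalues_base(prep, unname(y))
  slow <- vapply(colnames(dos$dose), function(m) {
    nested_marker_pvalue(y, dos, marker = m)$p_value
  }, numeric(1))
  expect_equal(fast, slow, tolerance = 1e-10)
})

test_that("a noiseless nested signal gives a numerically-zero p-value", {
  pop <- make_oracle_pop(n_per_fam = 20, seed = 2)
  dos <- encode_dosage(pop)
  fam <- dos$family
  y <- 5 * dos$dose[, 4] * (fam == levels(fam)[1])
  names(y) <- rownames(dos$dose)
  got <- nested_marker_pvalue(y, dos, marker = colnames(dos$dose)[4])
  expect_lt(got$p_value, 1e-30)
})

test_that("the null distribution of entry p-values is uniform", {
  pop <- make_oracle_pop(n_per_fam = 30, n_fam = 4, n_markers = 4, seed = 3)
  dos <- encode_dosage(pop)
  m <- colnames(dos$dose)[2]
  set.seed(77)
  ps <- vapply(seq_len(1000), function(i) {
    y <- rnorm(nrow(dos$dose))
    nested_marker_pvalue(y, dos, marker = m)$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("a marker segregating in no family is flagged with p = 1", {
  map <- genetic_map(c("m1", "m2"), c(1, 1), c(0, 10))
  calls <- matrix(c("B", "D",
                    "B", "B",
                    "B", "D",
                    "B", "B"), 4, 2, byrow = TRUE,
                  dimnames = list(paste0("L", 1:4), map$marker))
  g <- make_genos(calls, rep("A", 4), map)
  dos <- encode_dosage(g)
  y <- stats::setNames(c(1, 2, 3, 4), rownames(calls))
  got <- nested_marker_pvalue(y, dos, marker = "m1")
  expect_equal(got$p_value, 1)
  expect_true(got$no_segregation)
})
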