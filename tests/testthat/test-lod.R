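test_that("LOD values reproduce (n/2) log10 of the oracle RSS ratio", {
  pop <- make_oracle_pop(n_per_fam = 15, n_markers = 10, seed = 12)
  dos <- encode_dosage(pop)
  fam <- dos$family
  set.seed(13)
  mk <- colnames(dos$dose)
  y <- rnorm(nrow(dos$dose), sd = 0.5) + 1.5 * dos$dose[, mk[3]]
  names(y) <- rownames(dos$dose)
  fit <- fit_final_model(y, dos, mk[3])
  prof <- lod_profile(y, dos, fit, mk[3])
  n <- length(y)
  X0 <- oracle_nested_design(dos$dose, fam, character(0))
  rss0 <- ols_oracle(X0, unname(y))$rss
  for (m in prof$marker) {
    X1 <- oracle_nested_design(dos$dose, fam, m)
    if (ncol(X1) == ncol(X0) || qr(X1)$rank < ncol(X1)) next
    rss1 <- ols_oracle(X1, unname(y))$rss
    expect_rel_equal(prof$lod[prof$marker == m],
                     (n / 2) * log10(rss0 / rss1))
  }
  # the fitted peak dominates its chromosome
  expect_equal(prof$marker[which.max(prof$lod)], mk[3])
  expect_true(all(prof$lod >= 0))
})

test_that("support intervals follow the drop rule", {
  prof <- structure(data.frame(marker = paste0("m", 1:5), chromosome = 1,
                               position = c(0, 10, 20, 30, 40),
                               lod = c(2, 9, 10, 9.5, 3)),
                    class = c("lod_profile", "data.frame"))
  si <- support_interval(prof, drop = 1)
  expect_equal(si$start, 10)
  expect_equal(si$end, 30)
  expect_equal(si$peak_marker, "m3")
  # a flat profile spans the whole chromosome
  prof$lod <- rep(4, 5)
  si2 <- support_interval(prof, drop = 1)
  expect_equal(c(si2$start, si2$end), c(0, 40))
})

test_that("a single-marker chromosome yields a flagged degenerate profile", {
  map <- genetic_map(c("m1", "m2", "m3"), c(1, 1, 2), c(0, 30, 0))
  pop <- simulate_nil_population(map, c(A = 40, B = 40),
                                 pedigree_spec(1, 1), seed = 3)
  dos <- encode_dosage(pop)
  set.seed(4)
  y <- rnorm(80) + 2 * dos$dose[, "m3"]
  names(y) <- rownames(dos$dose)
  fit <- fit_final_model(y, dos, "m3")
  expect_warning(prof <- lod_profile(y, dos, fit, "m3"), "degenerate")
  expect_equal(nrow(prof), 1)
  expect_true(attr(prof, "degenerate"))
})

test_that("profiles are conditional on the other selected QTL", {
  pop <- make_oracle_pop(n_per_fam = 15, n_markers = 10, seed = 21)
  dos <- encode_dosage(pop)
  mk <- colnames(dos$dose)
  set.seed(22)
  y <- rnorm(nrow(dos$dose), sd = 0.4) + dos$dose[, mk[2]] +
    1.2 * dos$dose[, mk[8]]
  names(y) <- rownames(dos$dose)
  fit <- fit_final_model(y, dos, mk[c(2, 8)])
  prof <- lod_profile(y, dos, fit, mk[2])
  # oracle: base = family + the other QTL's nested columns
  X0 <- oracle_nested_design(dos$dose, dos$family, mk[8])
  rss0 <- ols_oracle(X0, unname(y))$rss
  X1 <- oracle_nested_design(dos$dose, dos$family, mk[c(8, 2)])
  skip_if(qr(X1)$rank < ncol(X1))
  rss1 <- ols_oracle(X1, unname(y))$rss
  expect_rel_equal(prof$lod[prof$marker == mk[2]],
                   (length(y) / 2) * log10(rss0 / rss1))
})
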