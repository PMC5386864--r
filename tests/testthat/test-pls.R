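test_that("one component reproduces a rank-1 calibration exactly", {
  set.seed(1)
  t <- rnorm(30)
  p <- runif(12)
  X <- t %o% p
  y <- as.numeric(X %*% rnorm(12))
  fit <- pls1_fit(X, y, ncomp = 1)
  expect_equal(fit$fitted, y, tolerance = 1e-8)
  expect_lt(fit$stats$sec, 1e-8)
})

test_that("full-component PLS1 equals ordinary least squares", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(50 * 8), 50)
    y <- as.numeric(X %*% rnorm(8)) + rnorm(50, sd = 0.2)
    b_ols <- ols_oracle(cbind(1, X), y)$coef
    fit <- pls1_fit(X, y, ncomp = 8)
    expect_lt(max(abs(fit$coefficients - b_ols[-1])), 1e-6)
    expect_lt(abs(fit$intercept - b_ols[1]), 1e-6)
  }
})

test_that("a response orthogonal to X collapses to the mean model", {
  set.seed(2)
  y <- rnorm(40)
  X <- matrix(rnorm(40 * 6), 40)
  # orthogonalise every column against y and the constant
  X <- apply(X, 2, function(x) residuals(lm(x ~ y)))
  fit <- suppressWarnings(pls1_fit(X, y, ncomp = 3))
  expect_lt(max(abs(fit$coefficients)), 1e-10)
  expect_equal(pls1_predict(fit, X), rep(mean(y), 40), tolerance = 1e-8)
  # exactly zero covariance collapses to the warned zero-coefficient model
  w <- testthat::capture_warnings(fit0 <- pls1_fit(matrix(0, 40, 3), y,
                                                   ncomp = 2))
  expect_match(w, "zero", all = FALSE)
  expect_true(all(fit0$coefficients == 0))
})

test_that("training RSS and SEC are non-increasing in component count", {
  s <- simulate_kernel_spectra(n = 120, seed = 7)
  Xp <- msc(s)$absorbance
  y <- s$reference$protein
  fits <- lapply(1:10, function(k) pls1_fit(Xp, y, ncomp = k))
  rss <- vapply(fits, function(f) sum((f$fitted - y)^2), 0)
  sec <- vapply(fits, function(f) f$stats$sec, 0)
  expect_true(all(diff(rss) <= 1e-8))
  expect_true(all(diff(sec) <= 1e-8))
})

test_that("prediction replays the preprocessing chain deterministically", {
  s <- simulate_kernel_spectra(n = 50, seed = 8)
  fit <- pls1_fit(s, s$reference$protein, ncomp = 4,
                  preprocess = c("sg", "msc"))
  pred <- pls1_predict(fit, s)
  expect_equal(pred, fit$fitted, tolerance = 1e-10)
  # a duplicated spectrum predicts identically to its original
  dup <- spectra_set(s$absorbance[c(1:50, 1), ], s$wavelengths)
  pd <- pls1_predict(fit, dup)
  expect_equal(pd[51], pd[1])
  # grid mismatch is an error
  shifted <- spectra_set(s$absorbance, s$wavelengths + 5)
  expect_error(pls1_predict(fit, shifted), "grid")
})

test_that("calibration statistics follow their definitions", {
  expect_error(calibration_stats(1:2, 1:2), "at least 3")
  st <- calibration_stats(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5), n_params = 1)
  expect_equal(st$r, 1)
  expect_equal(st$sec, 0)
  st2 <- calibration_stats(c(1, 2, 3, 4), c(1, 2, 4, 3), n_params = 0)
  expect_equal(st2$sec, sqrt(2 / 3))
  expect_warning(st3 <- calibration_stats(rep(2, 5), 1:5), "constant")
  expect_true(is.na(st3$r))
})

test_that("shuffled predictions are uncorrelated with the reference", {
  s <- simulate_kernel_spectra(n = 210, seed = 9)
  y <- s$reference$protein
  set.seed(10)
  ok <- vapply(1:100, function(i) {
    abs(cor(sample(y), y)) < 0.2
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("high-SNR constituents calibrate while orientation-noised oil fails", {
  s <- simulate_kernel_spectra(n = 210, seed = 1)
  fp <- pls1_fit(s, s$reference$protein, preprocess = "msc")
  expect_gte(fp$stats$r, 0.95)
  fs <- pls1_fit(s, s$reference$starch, preprocess = c("sg", "msc"))
  expect_gte(fs$stats$r, 0.8)
  fo <- pls1_fit(s, s$reference$oil, preprocess = "msc")
  expect_lte(fo$stats$r, 0.8)
})

test_that("the NMR line is exact on noiseless data and honest about noise", {
  oil <- seq(1.7, 6.3, length.out = 45)
  res <- 50 + 120 * oil
  cal <- nmr_linear_calibration(res, oil)
  expect_equal(cal$stats$r, 1)
  expect_equal(cal$slope, 1 / 120, tolerance = 1e-10)
  expect_lt(cal$stats$sec, 1e-10)
  # residual SE estimates the known noise SD within 20% on average
  set.seed(11)
  ses <- vapply(1:100, function(i) {
    yy <- 0.4 + 0.01 * res + rnorm(45, sd = 0.09)
    nmr_linear_calibration(res, yy)$stats$sec
  }, numeric(1))
  expect_lt(abs(mean(ses) - 0.09) / 0.09, 0.2)
  expect_error(nmr_linear_calibration(rep(1, 10), rnorm(10)), "constant")
})

test_that("triplicate readings are averaged and recover the simulated line", {
  sim <- simulate_nmr_readings(n = 45, seed = 12)
  cal <- nmr_linear_calibration(sim$resonance, sim$reference)
  expect_gt(cal$stats$r, 0.95)
  # inverse slope of the simulated response
  expect_equal(cal$slope, 1 / sim$slope, tolerance = 0.1)
  man <- nmr_linear_calibration(rowMeans(sim$resonance), sim$reference)
  expect_equal(cal$slope, man$slope)
})

test_that("the calibration split is seeded and disjoint", {
  sp <- calibration_split(210, 20, seed = 3)
  expect_length(sp$validation, 20)
  expect_length(intersect(sp$calibration, sp$validation), 0)
  expect_identical(sp, calibration_split(210, 20, seed = 3))
})
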