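test_that("MSC closed forms hold", {
  s <- simulate_kernel_spectra(n = 12, seed = 2)
  m <- colMeans(s$absorbance)
  # a spectrum that is an affine transform of the reference corrects to it
  X <- rbind(2 + 3 * m, m, 0.5 - 1.2 * m)
  ss <- spectra_set(X, s$wavelengths)
  out <- msc(ss, reference = m)
  expect_equal(unname(out$absorbance[1, ]), unname(m), tolerance = 1e-10)
  expect_equal(unname(out$absorbance[2, ]), unname(m), tolerance = 1e-10)
  cf <- attr(out, "msc")
  expect_equal(unname(cf$a[1]), 2, tolerance = 1e-10)
  expect_equal(unname(cf$b[1]), 3, tolerance = 1e-10)
})

test_that("MSC slopes and intercepts match a two-parameter LS oracle", {
  s <- simulate_kernel_spectra(n = 15, seed = 3)
  out <- msc(s)
  cf <- attr(out, "msc")
  m <- cf$reference
  for (i in c(1, 7, 15)) {
    beta <- solve(crossprod(cbind(1, m)),
                  crossprod(cbind(1, m), s$absorbance[i, ]))
    expect_equal(unname(cf$a[i]), as.numeric(beta[1, 1]), tolerance = 1e-10)
    expect_equal(unname(cf$b[i]), as.numeric(beta[2, 1]), tolerance = 1e-10)
  }
})

test_that("MSC with a fixed reference is idempotent", {
  s <- simulate_kernel_spectra(n = 20, seed = 4)
  s1 <- msc(s)
  ref <- attr(s1, "msc")$reference
  s2 <- msc(s1, reference = ref)
  expect_lt(max(abs(s2$absorbance - s1$absorbance)), 1e-10)
})

test_that("MSC rejects spectra uncorrelated with the reference", {
  s <- simulate_kernel_spectra(n = 5, seed = 5)
  flat <- s
  flat$absorbance[2, ] <- 1  # constant: zero slope on any reference
  expect_error(msc(flat), "b = 0")
})

test_that("SG derivative reproduces polynomials exactly, edges included", {
  wl <- seq(400, 700, by = 10)
  lin <- spectra_set(rbind(5 + 0.002 * wl, 1 - 0.01 * wl), wl)
  d <- sg_derivative(lin, window = 11, polyorder = 2)
  expect_equal(unname(d$absorbance[1, ]), rep(0.002, length(wl)),
               tolerance = 1e-10)
  expect_equal(unname(d$absorbance[2, ]), rep(-0.01, length(wl)),
               tolerance = 1e-10)
  quad <- spectra_set(matrix(wl^2, 1), wl)
  d2 <- sg_derivative(quad, window = 7, polyorder = 2)
  expect_equal(unname(d2$absorbance[1, ]), 2 * wl, tolerance = 1e-8)
  const <- spectra_set(matrix(3, 2, length(wl)), wl)
  d3 <- sg_derivative(const, window = 5, polyorder = 1)
  expect_true(all(abs(d3$absorbance) < 1e-12))
})

test_that("SG derivative is linear and validates its window", {
  s <- simulate_kernel_spectra(n = 4, seed = 6)
  a <- 2.5
  sa <- spectra_set(a * s$absorbance[1:2, ] + s$absorbance[3:4, ],
                    s$wavelengths)
  lhs <- sg_derivative(sa, 11, 2)$absorbance
  rhs <- a * sg_derivative(s, 11, 2)$absorbance[1:2, ] +
    sg_derivative(s, 11, 2)$absorbance[3:4, ]
  expect_equal(unname(lhs), unname(rhs), tolerance = 1e-10)
  expect_error(sg_derivative(s, window = 10), "odd")
  expect_error(sg_derivative(s, window = 3, polyorder = 3), "polyorder")
})
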