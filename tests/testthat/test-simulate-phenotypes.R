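make_phenos_pop <- function(seed = 1) {
  simulate_nil_population(synthetic_genetic_map(40), c(A = 30, B = 30),
                          seed = seed)
}

test_that("with no QTL and zero variances every plot equals the intercept", {
  pop <- make_phenos_pop()
  plots <- simulate_phenotypes(pop, qtl = NULL,
                               env_spec(var_G = 0, var_GE = 0, var_E = 0),
                               traits = "starch", seed = 1)
  expect_true(all(plots$value == 71.41))
  expect_equal(nrow(plots), 60 * 2 * 2)
})

test_that("a planted effect shifts donor homozygotes by exactly that amount", {
  pop <- make_phenos_pop(seed = 4)
  q <- qtl_spec("m0005", "starch", "A", -2.56)
  plots <- simulate_phenotypes(pop, q,
                               env_spec(var_G = 0, var_GE = 0, var_E = 0),
                               traits = "starch", seed = 1)
  v <- tapply(plots$value, plots$line, unique)
  calls <- pop$calls[, "m0005"]
  fam <- as.character(pop$family)
  dd <- names(calls)[calls == "D" & fam == "A"]
  hh <- names(calls)[calls == "H" & fam == "A"]
  bb <- names(calls)[calls == "B" & fam == "A"]
  skip_if(length(dd) == 0 || length(bb) == 0)
  expect_equal(unname(v[dd[1]] - v[bb[1]]), -2.56)
  if (length(hh)) expect_equal(unname(v[hh[1]] - v[bb[1]]), -1.28)
  # the other family is untouched
  expect_true(all(unlist(v[fam[match(names(v), names(calls))] == "B"]) ==
                    71.41))
})

test_that("environment effects and seeds behave as declared", {
  pop <- make_phenos_pop()
  plots <- simulate_phenotypes(pop, qtl = NULL,
                               env_spec(env_effects = c(0, 1.5),
                                        var_G = 0, var_GE = 0, var_E = 0),
                               traits = "oil", seed = 1)
  m <- tapply(plots$value, plots$env, mean)
  expect_equal(unname(m[["E2"]] - m[["E1"]]), 1.5)
  a <- simulate_phenotypes(pop, qtl = NULL, env_spec(), traits = "oil",
                           seed = 9)
  b <- simulate_phenotypes(pop, qtl = NULL, env_spec(), traits = "oil",
                           seed = 9)
  expect_identical(a, b)
})

test_that("unknown markers or families in the QTL spec are rejected", {
  pop <- make_phenos_pop()
  expect_error(simulate_phenotypes(pop, qtl_spec("nope", "starch", "A", 1),
                                   traits = "starch"),
               "not in genotypes")
  expect_error(simulate_phenotypes(pop, qtl_spec("m0005", "starch", "Z", 1),
                                   traits = "starch"),
               "family")
})
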