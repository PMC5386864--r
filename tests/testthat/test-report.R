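test_that("families without introgression are shown as '-'", {
  map <- genetic_map(c("m1", "m2"), c(1, 1), c(0, 20))
  calls <- matrix(c("D", "B",
                    "H", "B",
                    "B", "B",
                    "B", "D",
                    "B", "H",
                    "B", "B"), 6, 2, byrow = TRUE,
                  dimnames = list(paste0("L", 1:6), map$marker))
  g <- make_genos(calls, rep(c("A", "B"), each = 3), map)
  dos <- encode_dosage(g)
  set.seed(5)
  y <- stats::setNames(rnorm(6) + 2 * dos$dose[, "m1"], rownames(calls))
  fit <- fit_final_model(y, dos, "m1")
  tab <- allelic_effect_table(fit, g)
  expect_equal(tab$display["m1", "B"], "-")  # family B never segregates m1
  expect_true(is.na(tab$effects["m1", "B"]))
  expect_false(is.na(tab$effects["m1", "A"]))
})

test_that("stars follow the 0.05 / 0.01 levels", {
  pop <- make_oracle_pop(n_per_fam = 30, seed = 31)
  dos <- encode_dosage(pop)
  fam <- dos$family
  set.seed(32)
  y <- rnorm(nrow(dos$dose), sd = 0.3) +
    3 * dos$dose[, 6] * (fam == "F01")
  names(y) <- rownames(dos$dose)
  fit <- fit_final_model(y, dos, colnames(dos$dose)[6])
  tab <- allelic_effect_table(fit, pop)
  p <- tab$p_values["m0006", ]
  disp <- tab$display["m0006", ]
  for (f in names(p)) {
    if (is.na(p[f])) next
    stars <- if (p[f] < 0.01) "\\*\\*$" else if (p[f] < 0.05) "[^*]\\*$"
      else "[0-9]$"
    expect_match(disp[f], stars)
  }
})

test_that("a single planted positive effect stars only its own cell", {
  map <- synthetic_genetic_map(60)
  hits <- vapply(1:10, function(i) {
    pop <- simulate_nil_population(map,
                                   stats::setNames(rep(90, 4),
                                                   paste0("F0", 1:4)),
                                   seed = 300 + i)
    q <- qtl_spec("m0020", "t", "F02", 2.0)
    plots <- simulate_phenotypes(pop, q,
                                 env_spec(var_G = 0.1, var_GE = 0.05,
                                          var_E = 0.2),
                                 traits = "t", intercepts = c(t = 0),
                                 seed = 400 + i)
    y <- lsmeans_vector(compute_lsmeans(plots), "t")
    dos <- encode_dosage(pop)
    fit <- fit_final_model(y, dos, "m0020")
    tab <- allelic_effect_table(fit, pop)
    sig <- !is.na(tab$p_values) & tab$p_values < 0.05
    sum(sig) == 1 && sig["m0020", "F02"] && tab$n_sig_pos == 1
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("qtl_report assembles intervals, effects and fit statistics", {
  pop <- make_oracle_pop(n_per_fam = 20, n_markers = 10, seed = 41)
  dos <- encode_dosage(pop)
  set.seed(42)
  y <- rnorm(nrow(dos$dose), sd = 0.5) + 2 * dos$dose[, 4]
  names(y) <- rownames(dos$dose)
  fit <- forward_select(y, dos, threshold = 1e-3, max_qtl = 3)
  skip_if(length(fit$markers) == 0)
  rep <- qtl_report(y, dos, fit, pop, trait = "t")
  expect_equal(nrow(rep$summary), length(fit$markers))
  expect_true(all(rep$summary$ci_start <= rep$summary$position))
  expect_true(all(rep$summary$ci_end >= rep$summary$position))
  expect_equal(rep$r_squared, fit$r_squared)
  expect_s3_class(rep$effects, "qtl_effect_table")
})
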