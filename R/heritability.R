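#' Broad-sense heritability from variance components
#'
#' Fits, per trait, the random-effects model
#' `value = mu + env + line + line:env + error` with environment fixed and
#' line and line-by-environment random, and reports the entry-mean
#' broad-sense heritability
#' \deqn{H^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{GE}/e + \sigma^2_e/(e r))}
#' where e and r are the (harmonic-mean, when unbalanced) numbers of
#' environments per line and replicates per line-by-environment cell.
#' Negative component estimates are truncated at zero.
#'
#' Two estimators are provided: restricted maximum likelihood via
#' \pkg{lme4} (the default, matching mixed-model practice) and the
#' method-of-moments ANOVA estimator from expected mean squares, supplied
#' as a fast cross-check that coincides with REML on balanced data with
#' interior estimates.
#'
#' @param plots A plot table (`line`, `env`, `rep`, `trait`, `value`).
#' @param method `"reml"` (default) or `"anova"`.
#' @return A `heritability_estimate` data frame with one row per trait:
#'   `trait`, `var_G`, `var_GE`, `var_E`, `H2`, `n_env`, `n_rep`, `method`.
#' @export
#' @examples
#' map <- synthetic_genetic_map(40)
#' pop <- simulate_nil_population(map, c(A = 60, B = 60), seed = 1)
#' plots <- simulate_phenotypes(pop, env = env_spec(var_G = 1, var_GE = 0.5,
#'                                                  var_E = 1),
#'                              traits = "starch", seed = 2)
#' estimate_heritability(plots, method = "anova")
estimate_heritability <- function(plots, method = c("reml", "anova")) {
  method <- match.arg(method)
  validate_plot_table(plots)
  traits <- unique(plots$trait)
  rows <- lapply(traits, function(tr) {
    d <- plots[plots$trait == tr & !is.na(plots$value), , drop = FALSE]
    lf <- factor(d$line)
    ef <- factor(d$env)
    env_per_line <- rowSums(table(lf, ef) > 0)
    reps_per_cell <- table(paste(d$line, d$env))
    if (nlevels(ef) == 1 && max(reps_per_cell) == 1) {
      stop_("heritability not estimable: single environment and single ",
            "replicate for trait ", tr)
    }
    e_h <- .harmonic_mean(env_per_line)
    r_h <- .harmonic_mean(as.numeric(reps_per_cell))
    vc <- if (method == "reml") .vc_reml(d, lf, ef) else .vc_anova(d, lf, ef)
    h2 <- vc[["var_G"]] /
      (vc[["var_G"]] + vc[["var_GE"]] / e_h + vc[["var_E"]] / (e_h * r_h))
    data.frame(trait = tr, var_G = vc[["var_G"]], var_GE = vc[["var_GE"]],
               var_E = vc[["var_E"]], H2 = h2, n_env = e_h, n_rep = r_h,
               method = method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("heritability_estimate", "data.frame")
  out
}

.harmonic_mean <- function(x) length(x) / sum(1 / x)

# REML variance components; with a single environment the line-by-env term
# is inseparable from line and is reported as 0.
.vc_reml <- function(d, lf, ef) {
  dat <- data.frame(value = d$value, line = lf, env = ef)
  if (nlevels(ef) > 1) {
    fit <- lme4::lmer(value ~ env + (1 | line) + (1 | line:env),
                      data = dat, REML = TRUE,
                      control = lme4::lmerControl(calc.derivs = FALSE,
                                                  check.nobs.vs.nlev = "ignore",
                                                  check.nobs.vs.nRE = "ignore"))
    v <- as.data.frame(lme4::VarCorr(fit))
    get <- function(g) {
      x <- v$vcov[v$grp == g]
      if (length(x)) max(x, 0) else 0
    }
    c(var_G = get("line"), var_GE = get("line:env"), var_E = get("Residual"))
  } else {
    fit <- lme4::lmer(value ~ (1 | line), data = dat, REML = TRUE)
    v <- as.data.frame(lme4::VarCorr(fit))
    c(var_G = max(v$vcov[v$grp == "line"], 0), var_GE = 0,
      var_E = max(v$vcov[v$grp == "Residual"], 0))
  }
}

# Method-of-moments estimator from the two-way ANOVA expected mean squares;
# exact for balanced data, cell-mean approximation otherwise.
.vc_anova <- function(d, lf, ef) {
  g <- nlevels(lf)
  e <- nlevels(ef)
  cell <- paste(as.integer(lf), as.integer(ef), sep = ":")
  r <- mean(table(cell))
  cell_mean <- tapply(d$value, cell, mean)
  line_mean <- tapply(d$value, lf, mean)
  env_mean <- tapply(d$value, ef, mean)
  grand <- mean(d$value)
  ss_err <- sum((d$value - cell_mean[cell])^2)
  df_err <- max(length(d$value) - g * e, 1)
  ms_err <- ss_err / df_err
  li <- as.integer(sub(":.*", "", names(cell_mean)))
  ei <- as.integer(sub(".*:", "", names(cell_mean)))
  if (e > 1) {
    inter <- cell_mean - line_mean[li] - env_mean[ei] + grand
    ms_ge <- r * sum(inter^2) / ((g - 1) * (e - 1))
    ms_g <- e * r * sum((line_mean - grand)^2) / (g - 1)
    c(var_G = max((ms_g - ms_ge) / (e * r), 0),
      var_GE = max((ms_ge - ms_err) / r, 0),
      var_E = ms_err)
  } else {
    ms_g <- r * sum((line_mean - grand)^2) / (g - 1)
    c(var_G = max((ms_g - ms_err) / r, 0), var_GE = 0, var_E = ms_err)
  }
}
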