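#' Entry least-squares means across environments
#'
#' For each trait, fits the two-way fixed-effects model
#' `value = line + environment + error` and reports each line's
#' least-squares mean, i.e. the line effect evaluated at the average of the
#' environment effects.  Replicates are nested in environments and absorb
#' into the error term for entry means.  For fully balanced data the
#' LSmean equals the arithmetic mean of the line's plots, and that exact
#' fast path is used; unbalanced traits go through the full least-squares
#' fit.  Missing plot values are dropped, not imputed.
#'
#' @param plots A plot table (`line`, `env`, `rep`, `trait`, `value`), as
#'   produced by [simulate_phenotypes()] or [read_plot_table()].
#' @return An `ls_means` data frame: column `line` followed by one numeric
#'   column per trait; attribute `n_lines` holds per-trait non-missing
#'   counts.  A line observed in no environment for a trait gets `NA` with
#'   a warning.
#' @export
#' @examples
#' plots <- data.frame(line = rep(c("L1", "L2"), each = 4),
#'                     env = rep(c("E1", "E1", "E2", "E2"), 2),
#'                     rep = rep(c("R1", "R2"), 4),
#'                     trait = "starch",
#'                     value = c(70, 72, 71, 73, 68, 69, 70, 71))
#' compute_lsmeans(plots)
compute_lsmeans <- function(plots) {
  validate_plot_table(plots)
  traits <- unique(plots$trait)
  lines <- unique(plots$line)
  out <- matrix(NA_real_, length(lines), length(traits),
                dimnames = list(lines, traits))
  for (tr in traits) {
    d <- plots[plots$trait == tr & !is.na(plots$value), , drop = FALSE]
    missing_lines <- setdiff(lines, unique(d$line))
    if (length(missing_lines)) {
      warning("trait ", tr, ": no observations for ",
              length(missing_lines), " line(s); LSmean set to NA",
              call. = FALSE)
    }
    if (nrow(d) == 0) next
    out[, tr] <- .lsmeans_one_trait(d, lines)
  }
  res <- data.frame(line = lines, out, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "n_lines") <- colSums(!is.na(out))
  class(res) <- c("ls_means", "data.frame")
  res
}

.lsmeans_one_trait <- function(d, lines) {
  lf <- factor(d$line, levels = lines[lines %in% d$line])
  ef <- factor(d$env)
  tab <- table(lf, ef)
  balanced <- nlevels(ef) == 1 || all(tab == tab[1, 1])
  ls <- rep(NA_real_, length(lines))
  names(ls) <- lines
  if (balanced) {
    m <- tapply(d$value, lf, mean)
    ls[names(m)] <- m
    return(ls)
  }
  fit <- stats::lm(value ~ 0 + line + env,
                   data = data.frame(value = d$value, line = lf, env = ef))
  co <- stats::coef(fit)
  env_eff <- c(0, co[paste0("env", levels(ef)[-1])])  # baseline env = 0
  if (anyNA(env_eff)) {
    warning("inestimable environment contrast(s) treated as 0", call. = FALSE)
    env_eff[is.na(env_eff)] <- 0
  }
  line_co <- co[paste0("line", levels(lf))]
  ls[levels(lf)] <- as.numeric(line_co) + mean(env_eff)
  ls
}

#' Extract one trait from an LSmeans table as a named vector
#'
#' Convenience accessor for the mapping stage, which takes entry means as a
#' named numeric vector aligned to line identifiers.
#'
#' @param lsmeans An `ls_means` data frame.
#' @param trait Trait column name.
#' @return Named numeric vector of entry means.
#' @export
lsmeans_vector <- function(lsmeans, trait) {
  if (!trait %in% names(lsmeans)) stop_("no trait column '", trait, "'")
  stats::setNames(lsmeans[[trait]], lsmeans$line)
}
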