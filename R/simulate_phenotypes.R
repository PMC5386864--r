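#' Specify simulated QTL effects
#'
#' One row per (marker, trait, family) combination giving the additive
#' effect of the donor allele in trait units per donor-allele dose (dose is
#' 0 / 0.5 / 1 for B / H / D, so the effect is the homozygous-substitution
#' effect).  Families not listed for a marker x trait have effect 0.
#'
#' @param marker Marker identifiers.
#' @param trait Trait names.
#' @param family Donor family labels.
#' @param effect Additive effects (trait units per donor dose).
#' @return A `qtl_spec` data frame.
#' @export
#' @examples
#' qtl_spec("m0100", "starch", paste0("F", sprintf("%02d", 1:3)),
#'          c(-2.56, -1.2, 0.82))
qtl_spec <- function(marker, trait, family, effect) {
  out <- data.frame(marker = as.character(marker),
                    trait = as.character(trait),
                    family = as.character(family),
                    effect = as.numeric(effect),
                    stringsAsFactors = FALSE)
  if (anyNA(out)) stop_("qtl_spec fields must be complete")
  class(out) <- c("qtl_spec", "data.frame")
  out
}

#' Specify the environment structure and variance components
#'
#' Defaults mirror a two-location, two-replicate randomized complete block
#' trial.  Variance components are in squared trait units and may be a
#' single value shared by all traits or a named per-trait vector.
#'
#' @param n_env Number of environments.
#' @param n_rep Replicates per environment.
#' @param env_effects Per-environment additive shifts (length `n_env`,
#'   default all 0).
#' @param var_G Polygenic (line) variance not attributable to the
#'   simulated QTL.
#' @param var_GE Line-by-environment interaction variance.
#' @param var_E Plot residual variance.
#' @return An `env_spec` object.
#' @export
#' @examples
#' env_spec()                       # 2 env x 2 rep, H2 = 2/3 with no QTL
#' env_spec(var_G = c(starch = 1.2, oil = 0.1))
env_spec <- function(n_env = 2, n_rep = 2, env_effects = NULL,
                     var_G = 1, var_GE = 0.5, var_E = 1) {
  check_number(n_env, "n_env", lower = 1)
  check_number(n_rep, "n_rep", lower = 1)
  for (v in list(var_G, var_GE, var_E)) {
    if (any(v < 0) || anyNA(v)) stop_("variance components must be non-negative")
  }
  env_effects <- env_effects %||% rep(0, n_env)
  if (length(env_effects) != n_env) {
    stop_("env_effects must have length n_env")
  }
  structure(list(n_env = as.integer(n_env), n_rep = as.integer(n_rep),
                 env_effects = as.numeric(env_effects),
                 var_G = var_G, var_GE = var_GE, var_E = var_E),
            class = "env_spec")
}

# per-trait lookup for scalar-or-named variance components
.vc <- function(x, trait) {
  if (length(x) == 1 && is.null(names(x))) return(as.numeric(x))
  if (!trait %in% names(x)) stop_("no variance component given for trait ", trait)
  as.numeric(x[[trait]])
}

#' Simulate plot-level phenotypes on a NIL population
#'
#' Each plot value is
#' intercept + sum over QTL of effect(family) x dose + polygenic line
#' deviate N(0, var_G) + environment shift + line-by-environment deviate
#' N(0, var_GE) + plot residual N(0, var_E), with one row per
#' line x environment x replicate x trait.  Polygenic deviates for
#' different traits can be correlated through `genetic_cor`.
#'
#' Default trait intercepts are kernel-composition means on a dry matter
#' basis typical of a B73-background NIL trial (starch 71.41%, protein
#' 10.77%, oil 3.89%).
#'
#' @param genos A `nil_genotypes` object.
#' @param qtl A [qtl_spec()] data frame, or `NULL` for no QTL.
#' @param env An [env_spec()].
#' @param traits Traits to simulate; defaults to the names of `intercepts`.
#' @param intercepts Named per-trait intercepts.
#' @param genetic_cor Optional trait x trait correlation matrix for the
#'   polygenic deviates (default identity).
#' @param seed Integer seed; output is deterministic for a fixed seed.
#' @return A plot table: data frame with columns `line`, `env`, `rep`,
#'   `trait`, `value`.
#' @export
#' @examples
#' map <- synthetic_genetic_map(60)
#' pop <- simulate_nil_population(map, c(A = 20, B = 20), seed = 1)
#' q <- qtl_spec("m0010", "oil", "A", 0.61)
#' plots <- simulate_phenotypes(pop, q, env_spec(), traits = "oil", seed = 2)
#' head(plots)
simulate_phenotypes <- function(genos, qtl = NULL, env = env_spec(),
                                traits = names(intercepts),
                                intercepts = c(starch = 71.41,
                                               protein = 10.77, oil = 3.89),
                                genetic_cor = NULL, seed = 1L) {
  stopifnot(inherits(genos, "nil_genotypes"), inherits(env, "env_spec"))
  lines <- rownames(genos$calls)
  fam <- as.character(genos$family)
  n <- length(lines)
  nt <- length(traits)
  if (!is.null(qtl)) {
    bad <- setdiff(qtl$marker, colnames(genos$calls))
    if (length(bad)) {
      stop_("QTL marker(s) not in genotypes: ", paste(bad, collapse = ", "))
    }
    badf <- setdiff(qtl$family, levels(genos$family))
    if (length(badf)) {
      stop_("QTL family label(s) not in population: ",
            paste(badf, collapse = ", "))
    }
  }
  R <- genetic_cor %||% diag(nt)
  if (!all(dim(R) == c(nt, nt))) stop_("genetic_cor must be traits x traits")

  code <- c(B = 0, H = 0.5, D = 1)
  with_seed(seed, {
    # correlated standard normal polygenic deviates, one column per trait
    z <- matrix(stats::rnorm(n * nt), n, nt) %*% chol(R)
    rows <- vector("list", 0)
    for (ti in seq_len(nt)) {
      tr <- traits[ti]
      mu <- if (tr %in% names(intercepts)) intercepts[[tr]] else 0
      g <- rep(0, n)
      if (!is.null(qtl)) {
        qt <- qtl[qtl$trait == tr, , drop = FALSE]
        for (k in seq_len(nrow(qt))) {
          dose <- code[genos$calls[, qt$marker[k]]]
          dose[is.na(dose)] <- 0  # masked calls carry no simulated effect
          g <- g + qt$effect[k] * dose * (fam == qt$family[k])
        }
      }
      poly <- z[, ti] * sqrt(.vc(env$var_G, tr))
      for (e in seq_len(env$n_env)) {
        ge <- stats::rnorm(n, 0, sqrt(.vc(env$var_GE, tr)))
        for (r in seq_len(env$n_rep)) {
          val <- mu + g + poly + env$env_effects[e] + ge +
            stats::rnorm(n, 0, sqrt(.vc(env$var_E, tr)))
          rows[[length(rows) + 1]] <-
            data.frame(line = lines, env = sprintf("E%d", e),
                       rep = sprintf("R%d", r), trait = tr, value = val,
                       stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# plot-table invariant checks shared by the phenotype-stage functions
validate_plot_table <- function(plots) {
  req <- c("line", "env", "rep", "trait", "value")
  if (!is.data.frame(plots) || !all(req %in% names(plots))) {
    stop_("plot table needs columns: ", paste(req, collapse = ", "))
  }
  if (nrow(plots) == 0) stop_("plot table has no records")
  key <- paste(plots$line, plots$env, plots$rep, plots$trait, sep = "\r")
  if (anyDuplicated(key)) {
    stop_("duplicate (line, env, rep, trait) keys in plot table")
  }
  if (!is.numeric(plots$value)) stop_("plot values must be numeric")
  if (any(is.infinite(plots$value))) {
    stop_("plot values must be finite or missing")
  }
  invisible(plots)
}
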