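#' Run the full NIL analysis pipeline
#'
#' Executes simulate-or-load genotypes and phenotypes, entry LSmeans,
#' heritability and phenotypic correlations, then per-trait joint-linkage
#' mapping (permutation threshold, forward selection, allelic effects,
#' 1-LOD intervals) and writes all artifacts to the output directory.
#' Every output file carries a header with the package version, the seed
#' and the stage parameters; a `run.log` records each stage's row counts
#' and thresholds.  Reruns with the same config and seed are byte-identical
#' apart from the date header line.
#'
#' The config is a named list (or path to a YAML file) with entries:
#' \describe{
#'   \item{out_dir}{output directory (required).}
#'   \item{seed}{master seed; per-stage seeds are derived from it.}
#'   \item{map}{either `list(file = path)` or synthetic-map parameters
#'     `list(n_markers =, chr_lengths =)`.}
#'   \item{genotypes}{either `list(file = path)` or simulation parameters
#'     `list(family_sizes =, n_backcross =, n_self =, missing_rate =)`.}
#'   \item{phenotypes}{either `list(file = path)` or simulation parameters
#'     `list(qtl = data frame/list with marker, trait, family, effect;
#'     n_env =, n_rep =, var_G =, var_GE =, var_E =, intercepts =)`.}
#'   \item{traits}{traits to map (default: all traits in the phenotypes).}
#'   \item{mapping}{`list(n_perm = 1000, gwer = 0.05, max_qtl = 10)`.}
#' }
#'
#' @param config Named list or path to a YAML config file.
#' @param seed Optional master seed overriding `config$seed`.
#' @return Invisibly, a list with `genos`, `plots`, `lsmeans`,
#'   `heritability`, `correlations`, `thresholds`, `models`, `reports` and
#'   the expanded `config`.
#' @export
run_pipeline <- function(config, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_("config must be a list or a YAML file path")
  if (is.null(config$out_dir)) stop_("config is missing required field: out_dir")
  # validate referenced files before any compute
  for (stage in c("map", "genotypes", "phenotypes")) {
    f <- config[[stage]]$file
    if (!is.null(f) && !file.exists(f)) {
      stop_("config ", stage, " file does not exist: ", f)
    }
  }
  seed <- seed %||% config$seed %||% 1L
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat(sprintf("pipeline seed %s\n", seed), file = log_path)
  log_line <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  meta <- list(seed = seed)

  # --- genotypes ---------------------------------------------------------
  gcfg <- config$genotypes %||% list()
  mcfg <- config$map %||% list()
  if (!is.null(gcfg$file)) {
    if (is.null(mcfg$file)) stop_("genotype file given without a map file")
    map <- read_genetic_map(mcfg$file)
    genos <- read_genotypes(gcfg$file, map)
    log_line("loaded %d lines x %d markers from %s",
             nrow(genos$calls), ncol(genos$calls), gcfg$file)
  } else {
    map <- if (!is.null(mcfg$file)) {
      read_genetic_map(mcfg$file)
    } else {
      do.call(synthetic_genetic_map,
              mcfg[intersect(names(mcfg), c("n_markers", "chr_lengths"))])
    }
    fs <- unlist(gcfg$family_sizes) %||% default_family_sizes()
    ped <- pedigree_spec(gcfg$n_backcross %||% 4, gcfg$n_self %||% 2)
    genos <- simulate_nil_population(map, fs, ped,
                                     seed = derive_seed(seed, 1),
                                     missing_rate = gcfg$missing_rate %||% 0)
    log_line("simulated %d lines x %d markers (BC%dS%d)",
             nrow(genos$calls), ncol(genos$calls),
             ped$n_backcross, ped$n_self)
    write_genetic_map(map, file.path(out_dir, "map.tsv"), meta)
    write_genotypes(genos, file.path(out_dir, "genotypes.tsv"), meta)
  }

  # --- phenotypes --------------------------------------------------------
  pcfg <- config$phenotypes %||% list()
  if (!is.null(pcfg$file)) {
    plots <- read_plot_table(pcfg$file)
    log_line("loaded %d plot records from %s", nrow(plots), pcfg$file)
  } else {
    qtl <- pcfg$qtl
    if (!is.null(qtl) && !is.data.frame(qtl)) {
      qtl <- do.call(rbind, lapply(qtl, as.data.frame))
    }
    if (!is.null(qtl)) qtl <- qtl_spec(qtl$marker, qtl$trait, qtl$family,
                                       qtl$effect)
    env <- env_spec(pcfg$n_env %||% 2, pcfg$n_rep %||% 2,
                    var_G = pcfg$var_G %||% 1,
                    var_GE = pcfg$var_GE %||% 0.5,
                    var_E = pcfg$var_E %||% 1)
    intercepts <- unlist(pcfg$intercepts) %||%
      c(starch = 71.41, protein = 10.77, oil = 3.89)
    traits <- config$traits %||% names(intercepts)
    plots <- simulate_phenotypes(genos, qtl, env, traits = traits,
                                 intercepts = intercepts,
                                 seed = derive_seed(seed, 2))
    log_line("simulated %d plot records (%d traits)", nrow(plots),
             length(traits))
    write_plot_table(plots, file.path(out_dir, "plots.tsv"), meta)
  }
  traits <- config$traits %||% unique(plots$trait)

  # --- phenotype statistics ---------------------------------------------
  lsm <- compute_lsmeans(plots)
  write_lsmeans(lsm, file.path(out_dir, "lsmeans.tsv"), meta)
  log_line("LSmeans for %d lines x %d traits", nrow(lsm), ncol(lsm) - 1)
  herit <- tryCatch(estimate_heritability(plots), error = function(e) NULL)
  if (!is.null(herit)) {
    .write_table(herit, file.path(out_dir, "heritability.tsv"), meta)
    log_line("heritability: %s",
             paste(sprintf("%s %.2f", herit$trait, herit$H2),
                   collapse = ", "))
  }
  if (length(traits) >= 2) {
    corr <- phenotypic_correlations(lsm)
    .write_table(data.frame(trait = rownames(corr$r), corr$r,
                            check.names = FALSE),
                 file.path(out_dir, "correlations.tsv"), meta)
  } else {
    corr <- NULL
  }

  # --- joint-linkage mapping --------------------------------------------
  mpcfg <- config$mapping %||% list()
  n_perm <- mpcfg$n_perm %||% 1000
  gwer <- mpcfg$gwer %||% 0.05
  max_qtl <- mpcfg$max_qtl %||% 10
  dosage <- encode_dosage(genos)
  thresholds <- models <- reports <- list()
  for (i in seq_along(traits)) {
    tr <- traits[i]
    y <- lsmeans_vector(lsm, tr)
    thr <- permutation_threshold(y, dosage, n_perm = n_perm, gwer = gwer,
                                 seed = derive_seed(seed, 10 + i))
    model <- forward_select(y, dosage, thr$threshold, max_qtl = max_qtl)
    report <- qtl_report(y, dosage, model, genos, trait = tr)
    log_line("%s: threshold %.3g, %d QTL, R2 %.3f", tr, thr$threshold,
             length(model$markers), model$r_squared)
    write_qtl_report(report, out_dir, prefix = tr, meta = meta)
    thresholds[[tr]] <- thr
    models[[tr]] <- model
    reports[[tr]] <- report
  }
  invisible(list(genos = genos, plots = plots, lsmeans = lsm,
                 heritability = herit, correlations = corr,
                 thresholds = thresholds, models = models,
                 reports = reports, config = config, seed = seed))
}
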