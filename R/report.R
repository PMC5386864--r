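#' Per-family allelic-effect table
#'
#' Builds the QTL-by-family matrix of additive donor-allele effects from a
#' fitted joint-linkage model.  Each cell shows the effect estimate with a
#' significance star (`*` for p < 0.05, `**` for p < 0.01, raw per-allele
#' t-test p-values, no multiplicity correction); a family with no line
#' carrying an introgression at that marker is shown as `-` (no donor
#' allele available for the t-test).
#'
#' @param model A fitted `qtl_model`.
#' @param genos The `nil_genotypes` the model was mapped on (used to
#'   detect families without introgression at each QTL).
#' @param alpha Two significance levels for one and two stars.
#' @return A `qtl_effect_table`: list with numeric `effects` and `p_values`
#'   matrices (QTL x family), a character `display` matrix, and counts
#'   `n_sig_pos` / `n_sig_neg` of significant positive and negative donor
#'   alleles at `alpha[1]`.
#' @export
allelic_effect_table <- function(model, genos, alpha = c(0.05, 0.01)) {
  stopifnot(inherits(model, "qtl_model"), inherits(genos, "nil_genotypes"))
  fams <- model$family_levels
  qtl <- model$markers
  eff <- pmat <- matrix(NA_real_, length(qtl), length(fams),
                        dimnames = list(qtl, fams))
  disp <- matrix(".", length(qtl), length(fams),
                 dimnames = list(qtl, fams))
  co <- model$coefficients
  for (m in qtl) {
    for (f in fams) {
      in_fam <- as.character(genos$family) == f
      has_introgression <- any(genos$calls[in_fam, m] %in% c("H", "D"))
      if (!has_introgression) {
        disp[m, f] <- "-"
        next
      }
      row <- co[co$type == "marker" & co$marker == m & co$family == f, ]
      if (nrow(row) == 0) next  # column dropped (non-segregating dose)
      eff[m, f] <- row$estimate
      pmat[m, f] <- row$p_value
      stars <- if (row$p_value < alpha[2]) "**" else
        if (row$p_value < alpha[1]) "*" else ""
      disp[m, f] <- sprintf("%.2f%s", row$estimate, stars)
    }
  }
  sig <- !is.na(pmat) & pmat < alpha[1]
  structure(list(effects = eff, p_values = pmat, display = disp,
                 n_sig_pos = sum(sig & eff > 0, na.rm = TRUE),
                 n_sig_neg = sum(sig & eff < 0, na.rm = TRUE),
                 alpha = alpha),
            class = "qtl_effect_table")
}

#' @export
print.qtl_effect_table <- function(x, ...) {
  cat("Additive donor-allele effects by family\n")
  cat(sprintf("(* p < %g, ** p < %g, '-' no introgression)\n",
              x$alpha[1], x$alpha[2]))
  print(x$display, quote = FALSE)
  cat(sprintf("significant alleles: %d positive, %d negative\n",
              x$n_sig_pos, x$n_sig_neg))
  invisible(x)
}

#' Full QTL report for one trait
#'
#' Combines the fitted model with conditional LOD profiles: one row per
#' QTL with its chromosome, peak marker and position, peak LOD and 1-LOD
#' support interval, plus the per-family allelic-effect table, the model
#' total R-squared and the entry threshold used.
#'
#' @param y Entry means used to fit the model.
#' @param dosage The `dosage_matrix` used to fit the model.
#' @param model A fitted `qtl_model`.
#' @param genos The underlying `nil_genotypes`.
#' @param trait Trait label carried into the report.
#' @param drop LOD drop for support intervals (default 1.0).
#' @return A `qtl_report`: list with `summary` data frame, `effects`
#'   (a `qtl_effect_table`), `profiles` (list of `lod_profile`s), `trait`,
#'   `r_squared`, `r_squared_markers` and `threshold`.
#' @export
qtl_report <- function(y, dosage, model, genos, trait = NA_character_,
                       drop = 1.0) {
  stopifnot(inherits(model, "qtl_model"))
  profiles <- list()
  rows <- lapply(model$markers, function(m) {
    prof <- suppressWarnings(lod_profile(y, dosage, model, m))
    profiles[[m]] <<- prof
    si <- support_interval(prof, drop)
    data.frame(trait = trait, marker = m,
               chromosome = prof$chromosome[1],
               position = prof$position[match(m, prof$marker)],
               peak_lod = prof$lod[match(m, prof$marker)],
               ci_start = si$start, ci_end = si$end,
               ci_start_marker = si$start_marker,
               ci_end_marker = si$end_marker,
               stringsAsFactors = FALSE)
  })
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trait = character(0), marker = character(0),
               chromosome = integer(0), position = numeric(0),
               peak_lod = numeric(0), ci_start = numeric(0),
               ci_end = numeric(0), ci_start_marker = character(0),
               ci_end_marker = character(0))
  structure(list(summary = summary,
                 effects = allelic_effect_table(model, genos),
                 profiles = profiles,
                 trait = trait,
                 r_squared = model$r_squared,
                 r_squared_markers = model$r_squared_markers,
                 threshold = model$threshold),
            class = "qtl_report")
}

#' @export
print.qtl_report <- function(x, ...) {
  cat(sprintf("QTL report%s: %d QTL, total R2 = %.3f\n",
              if (is.na(x$trait)) "" else paste0(" for ", x$trait),
              nrow(x$summary), x$r_squared))
  if (nrow(x$summary)) {
    print(x$summary[, c("marker", "chromosome", "position", "peak_lod",
                        "ci_start", "ci_end")], row.names = FALSE)
    print(x$effects)
  }
  invisible(x)
}
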