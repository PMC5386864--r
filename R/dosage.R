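#' Encode genotype calls as donor-allele doses
#'
#' Additive coding B -> 0, H -> 0.5, D -> 1 (trait effects are then on the
#' homozygous-substitution scale).  Missing calls are imputed by the
#' family-specific mean dose at that marker (default) or set to 0; a family
#' with no observed calls at a marker falls back to the marker's overall
#' mean.  Markers missing in every line are dropped with a warning.
#'
#' @param genos A `nil_genotypes` object.
#' @param impute `"family_mean"` (default) or `"zero"`.
#' @return A `dosage_matrix`: list with `dose` (line x marker numeric
#'   matrix, no missing values), `family` (factor) and `map` (restricted to
#'   retained markers, in map order).
#' @export
#' @examples
#' map <- synthetic_genetic_map(40)
#' pop <- simulate_nil_population(map, c(A = 10, B = 10), seed = 1)
#' dos <- encode_dosage(pop)
#' range(dos$dose)
encode_dosage <- function(genos, impute = c("family_mean", "zero")) {
  impute <- match.arg(impute)
  stopifnot(inherits(genos, "nil_genotypes"))
  calls <- genos$calls
  bad <- setdiff(unique(as.vector(calls)), c("B", "H", "D", NA))
  if (length(bad)) {
    stop_("unknown genotype code(s): ", paste(bad, collapse = ", "))
  }
  code <- c(B = 0, H = 0.5, D = 1)
  dose <- matrix(code[calls], nrow(calls), ncol(calls),
                 dimnames = dimnames(calls))
  all_missing <- colSums(!is.na(dose)) == 0
  if (any(all_missing)) {
    warning("dropping ", sum(all_missing),
            " marker(s) with no observed calls: ",
            paste(utils::head(colnames(dose)[all_missing], 5),
                  collapse = ", "), call. = FALSE)
    dose <- dose[, !all_missing, drop = FALSE]
  }
  fam <- droplevels(as.factor(genos$family))
  if (anyNA(dose)) {
    if (impute == "zero") {
      dose[is.na(dose)] <- 0
    } else {
      for (j in which(colSums(is.na(dose)) > 0)) {
        x <- dose[, j]
        fm <- tapply(x, fam, mean, na.rm = TRUE)
        fm[is.nan(fm)] <- mean(x, na.rm = TRUE)
        x[is.na(x)] <- fm[fam[is.na(x)]]
        dose[, j] <- x
      }
    }
  }
  map <- genos$map[match(colnames(dose), genos$map$marker), , drop = FALSE]
  dose <- dose[, order(match(colnames(dose), genos$map$marker)),
               drop = FALSE]
  map <- map[order(map$chromosome, map$position), , drop = FALSE]
  structure(list(dose = dose, family = fam, map = map),
            class = "dosage_matrix")
}

# restrict a dosage matrix to a subset of lines
.subset_dosage <- function(d, idx) {
  structure(list(dose = d$dose[idx, , drop = FALSE],
                 family = droplevels(d$family[idx]),
                 map = d$map),
            class = "dosage_matrix")
}

# align a (possibly named, possibly incomplete) entry-mean vector with the
# rows of a dosage matrix, dropping lines with missing phenotype
.align_y <- function(y, dosage) {
  if (!is.null(names(y))) {
    common <- intersect(rownames(dosage$dose), names(y))
    if (length(common) == 0) stop_("no line identifiers shared by y and dosage")
    dosage <- .subset_dosage(dosage, match(common, rownames(dosage$dose)))
    y <- as.numeric(y[common])
  } else if (length(y) != nrow(dosage$dose)) {
    stop_("unnamed y must have one value per line")
  }
  keep <- is.finite(y)
  if (!all(keep)) {
    dosage <- .subset_dosage(dosage, which(keep))
    y <- y[keep]
  }
  list(y = as.numeric(y), dosage = dosage)
}
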