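#' Default NIL family sizes
#'
#' Ten donor families with sizes between 58 and 135 lines totalling 961,
#' the scale of the teosinte introgression libraries (10 donor accessions,
#' 58-185 lines per family, 961 lines in all).
#'
#' @return Named integer vector of family sizes.
#' @export
default_family_sizes <- function() {
  c(F01 = 58L, F02 = 70L, F03 = 78L, F04 = 85L, F05 = 92L,
    F06 = 99L, F07 = 106L, F08 = 118L, F09 = 135L, F10 = 120L)
}

#' Simulate a NIL introgression library
#'
#' Simulates each line of every donor family independently through the full
#' backcross-self pedigree as a pair of chromosome haplotypes.  Crossovers
#' follow the Haldane model (no interference): the crossover process along a
#' chromosome is Poisson with rate 1 per 100 cM, so the recombination
#' fraction between map positions d cM apart is r = (1 - exp(-2d/100))/2 and
#' gamete origins along the marker grid form a Markov chain with those
#' switch probabilities, which is how gametes are drawn.  Genotype calls are
#' read off at the marker positions and coded B (recurrent homozygote),
#' H (heterozygote), D (donor homozygote).
#'
#' No selection is applied among progeny: lines carrying zero donor
#' segments are retained, and no introgression-bearing gamete is forced.
#'
#' @param map A [genetic_map()].
#' @param family_sizes Named positive integer vector of lines per donor
#'   family; defaults to [default_family_sizes()].
#' @param pedigree A [pedigree_spec()]; default BC4S2.
#' @param seed Integer seed; output is bit-identical for a fixed seed.
#' @param missing_rate Fraction of calls masked to `NA` uniformly at random
#'   (default 0: the generator emits no missing data).
#' @return A `nil_genotypes` object: list with `calls` (line x marker
#'   character matrix of B/H/D/`NA`), `family` (named factor of per-line
#'   donor family) and `map`.
#' @export
#' @examples
#' map <- synthetic_genetic_map(60)
#' pop <- simulate_nil_population(map, c(A = 5, B = 5), seed = 1)
#' pop$calls[1:3, 1:5]
simulate_nil_population <- function(map,
                                    family_sizes = default_family_sizes(),
                                    pedigree = pedigree_spec(),
                                    seed = 1L,
                                    missing_rate = 0) {
  validate_genetic_map(map)
  if (length(family_sizes) < 1 || any(family_sizes <= 0) ||
      anyNA(family_sizes)) {
    stop_("family sizes must be positive")
  }
  check_number(missing_rate, "missing_rate", lower = 0, upper = 1)
  stopifnot(inherits(pedigree, "pedigree_spec"))
  family_sizes <- stats::setNames(as.integer(family_sizes),
                                  names(family_sizes))
  if (is.null(names(family_sizes))) {
    names(family_sizes) <- sprintf("F%02d", seq_along(family_sizes))
  }
  n <- sum(family_sizes)
  fam <- factor(rep(names(family_sizes), family_sizes),
                levels = names(family_sizes))
  lines <- paste0(fam, "_",
                  unlist(lapply(family_sizes,
                                function(k) sprintf("%03d", seq_len(k)))))
  calls <- matrix(NA_character_, n, nrow(map),
                  dimnames = list(lines, map$marker))
  with_seed(seed, {
    for (idx in split(seq_len(nrow(map)), map$chromosome)) {
      r <- 0.5 * (1 - exp(-2 * diff(map$position[idx]) / 100))
      dose <- .simulate_chr_dose(n, r, pedigree)
      calls[, idx] <- c("B", "H", "D")[dose + 1L]
    }
    if (missing_rate > 0) {
      calls[runif(length(calls)) < missing_rate] <- NA_character_
    }
  })
  structure(list(calls = calls, family = stats::setNames(fam, lines),
                 map = map),
            class = "nil_genotypes")
}

# Draw one gamete per line from parental haplotype matrices h1/h2
# (n x m logical, TRUE = donor allele).  r: switch probability between
# adjacent markers (length m - 1).
.sample_gamete <- function(h1, h2, r) {
  n <- nrow(h1)
  m <- ncol(h1)
  pick <- matrix(FALSE, n, m)
  pick[, 1] <- stats::runif(n) < 0.5
  if (m > 1) {
    sw <- matrix(stats::runif(n * (m - 1)), n) < rep(r, each = n)
    for (j in 2:m) pick[, j] <- xor(pick[, j - 1], sw[, j - 1])
  }
  g <- h2
  g[pick] <- h1[pick]
  g
}

# Per-line donor-allele dose (0/1/2) at the markers of one chromosome after
# the full pedigree; vectorised over lines.
.simulate_chr_dose <- function(n, r, pedigree) {
  m <- length(r) + 1L
  h1 <- matrix(TRUE, n, m)   # donor chromosome of the F1
  h2 <- matrix(FALSE, n, m)  # recurrent-parent chromosome
  for (i in seq_len(pedigree$n_backcross)) {
    h1 <- .sample_gamete(h1, h2, r)
    h2 <- matrix(FALSE, n, m)
  }
  for (i in seq_len(pedigree$n_self)) {
    g1 <- .sample_gamete(h1, h2, r)
    g2 <- .sample_gamete(h1, h2, r)
    h1 <- g1
    h2 <- g2
  }
  h1 + h2
}

#' @export
print.nil_genotypes <- function(x, ...) {
  comp <- genome_composition(x)
  cat(sprintf(paste0("NIL genotypes: %d lines, %d families, %d markers on ",
                     "%d chromosomes\n"),
              nrow(x$calls), nlevels(x$family), ncol(x$calls),
              length(unique(x$map$chromosome))))
  cat(sprintf("mean composition: %.2f%% B, %.2f%% H, %.2f%% D\n",
              100 * comp[["B"]], 100 * comp[["H"]], 100 * comp[["D"]]))
  invisible(x)
}

#' Observed genome composition of a NIL population
#'
#' Mean per-line fractions of markers called B, H and D (missing calls
#' excluded per line).
#'
#' @param genos A `nil_genotypes` object.
#' @return Named numeric vector `c(B =, H =, D =)`.
#' @export
genome_composition <- function(genos) {
  stopifnot(inherits(genos, "nil_genotypes"))
  per_line <- t(apply(genos$calls, 1, function(z) {
    z <- z[!is.na(z)]
    c(B = mean(z == "B"), H = mean(z == "H"), D = mean(z == "D"))
  }))
  colMeans(per_line, na.rm = TRUE)
}
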