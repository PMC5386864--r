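#' Describe a backcross-self pedigree
#'
#' An introgression-library pedigree: an F1 between the donor and the
#' recurrent parent is backcrossed to the recurrent parent for
#' `n_backcross` generations and then self-pollinated for `n_self`
#' generations.  The default BC4S2 matches the teosinte NIL libraries.
#'
#' @param n_backcross Number of backcross generations (>= 0).
#' @param n_self Number of selfing generations (>= 0).
#' @return A `pedigree_spec` object.
#' @export
#' @examples
#' pedigree_spec()           # BC4S2
#' pedigree_spec(2, 3)       # BC2S3
pedigree_spec <- function(n_backcross = 4, n_self = 2) {
  check_number(n_backcross, "n_backcross", lower = 0)
  check_number(n_self, "n_self", lower = 0)
  structure(list(n_backcross = as.integer(n_backcross),
                 n_self = as.integer(n_self)),
            class = "pedigree_spec")
}

#' @export
print.pedigree_spec <- function(x, ...) {
  cat(sprintf("BC%dS%d pedigree (%d backcross, %d selfing generations)\n",
              x$n_backcross, x$n_self, x$n_backcross, x$n_self))
  invisible(x)
}

#' Expected per-locus genome composition of a backcross-self pedigree
#'
#' Computes the neutral Mendelian expectation of the per-locus genotype
#' probabilities (recurrent homozygote B, heterozygote H, donor homozygote
#' D) by iterating the single-locus transition rules: the F1 is fully
#' heterozygous; each backcross to the recurrent parent sends H to H or B
#' with probability 1/2 each (and D, if present, to H); each selfing
#' generation sends H to B, H, D with probabilities 1/4, 1/2, 1/4.
#'
#' For the default BC4S2 pedigree the expectation is about 96.1% B, 1.6% H
#' and 2.3% D, i.e. roughly 4% of the genome donor-derived.
#'
#' @param pedigree A [pedigree_spec()].
#' @return Named numeric vector `c(B =, H =, D =)` summing to 1.
#' @export
#' @examples
#' expected_genome_composition(pedigree_spec(4, 2))
expected_genome_composition <- function(pedigree = pedigree_spec()) {
  stopifnot(inherits(pedigree, "pedigree_spec"))
  p <- c(B = 0, H = 1, D = 0)
  for (i in seq_len(pedigree$n_backcross)) {
    p <- c(B = p[["B"]] + p[["H"]] / 2,
           H = p[["H"]] / 2 + p[["D"]],
           D = 0)
  }
  for (i in seq_len(pedigree$n_self)) {
    p <- c(B = p[["B"]] + p[["H"]] / 4,
           H = p[["H"]] / 2,
           D = p[["D"]] + p[["H"]] / 4)
  }
  p
}
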