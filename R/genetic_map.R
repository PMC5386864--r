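#' Construct a genetic map
#'
#' A genetic map is a data frame with one row per marker giving its
#' identifier, chromosome number and position in centimorgans.  Marker
#' identifiers must be unique, positions must be non-decreasing within each
#' chromosome, and every chromosome must carry at least one marker.
#'
#' @param marker Character vector of unique marker identifiers.
#' @param chromosome Integer chromosome numbers (1-based).
#' @param position Numeric positions in centimorgans (cM), non-negative.
#' @return A `genetic_map` data frame with columns `marker`, `chromosome`,
#'   `position`.
#' @export
#' @examples
#' genetic_map(c("m1", "m2", "m3"), c(1, 1, 2), c(0, 25, 0))
genetic_map <- function(marker, chromosome, position) {
  map <- data.frame(marker = as.character(marker),
                    chromosome = as.integer(chromosome),
                    position = as.numeric(position),
                    stringsAsFactors = FALSE)
  validate_genetic_map(map)
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Validate a genetic map
#'
#' Checks the `genetic_map` invariants: required columns, at least one
#' marker, unique identifiers, non-negative and within-chromosome
#' non-decreasing positions.
#'
#' @param map A data frame of marker, chromosome, position.
#' @return The map, invisibly; errors describe the offending field.
#' @export
validate_genetic_map <- function(map) {
  req <- c("marker", "chromosome", "position")
  if (!is.data.frame(map) || !all(req %in% names(map))) {
    stop_("genetic map needs columns: ", paste(req, collapse = ", "))
  }
  if (nrow(map) == 0) stop_("genetic map has no records")
  dup <- unique(map$marker[duplicated(map$marker)])
  if (length(dup)) {
    stop_("duplicate marker identifiers in map: ",
          paste(utils::head(dup, 5), collapse = ", "))
  }
  if (anyNA(map$chromosome) || anyNA(map$position)) {
    stop_("genetic map has missing chromosome or position values")
  }
  if (any(map$position < 0)) stop_("map positions must be non-negative cM")
  bad <- vapply(split(map$position, map$chromosome),
                function(p) is.unsorted(p), logical(1))
  if (any(bad)) {
    stop_("map positions not non-decreasing on chromosome(s): ",
          paste(names(bad)[bad], collapse = ", "))
  }
  invisible(map)
}

#' Synthetic maize-like genetic map
#'
#' Builds a deterministic map with evenly spaced markers on 10 chromosomes.
#' Defaults mirror the marker panel used for NIL introgression libraries:
#' 728 markers over a genome of roughly 1600 cM, comparable to the maize
#' consensus linkage map.
#'
#' @param n_markers Total number of markers to place.
#' @param chr_lengths Numeric vector of chromosome lengths in cM.
#' @return A `genetic_map`.
#' @export
#' @examples
#' map <- synthetic_genetic_map(100)
#' table(map$chromosome)
synthetic_genetic_map <- function(n_markers = 728,
                                  chr_lengths = c(200, 180, 175, 165, 160,
                                                  150, 150, 145, 140, 135)) {
  stopifnot(n_markers >= 2 * length(chr_lengths), all(chr_lengths > 0))
  per_chr <- pmax(2L, as.integer(round(n_markers * chr_lengths /
                                         sum(chr_lengths))))
  # nudge rounded counts so they total exactly n_markers
  i <- 1L
  while (sum(per_chr) != n_markers) {
    k <- order(chr_lengths, decreasing = TRUE)[1L + (i - 1L) %% length(per_chr)]
    per_chr[k] <- per_chr[k] + sign(n_markers - sum(per_chr))
    i <- i + 1L
  }
  chrom <- rep(seq_along(chr_lengths), per_chr)
  pos <- unlist(lapply(seq_along(chr_lengths), function(c) {
    seq(0, chr_lengths[c], length.out = per_chr[c])
  }))
  genetic_map(sprintf("m%04d", seq_len(n_markers)), chrom, pos)
}
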