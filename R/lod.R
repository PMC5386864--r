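#' Conditional LOD profile for one QTL
#'
#' For every marker m on the focal QTL's chromosome, refits the model with
#' the QTL's family-nested columns replaced by m's columns, keeping all
#' other selected QTL as fixed covariates (a composite-interval-style
#' conditional profile), and reports
#' LOD(m) = (n/2) log10(RSS_without / RSS_with_m), where RSS_without is the
#' residual sum of squares of the model lacking any marker in this
#' chromosome slot.  n is the number of lines with complete data for the
#' trait.
#'
#' @param y Entry means (named or aligned numeric vector).
#' @param dosage A `dosage_matrix`.
#' @param model A fitted `qtl_model`.
#' @param marker The focal QTL marker (must be in `model$markers`).
#' @return A `lod_profile` data frame with columns `marker`, `chromosome`,
#'   `position`, `lod`; attribute `degenerate` flags a single-marker
#'   chromosome.
#' @export
lod_profile <- function(y, dosage, model, marker) {
  stopifnot(inherits(dosage, "dosage_matrix"), inherits(model, "qtl_model"))
  if (!marker %in% model$markers) {
    stop_("marker ", marker, " is not in the fitted model")
  }
  al <- .align_y(y, dosage)
  y <- al$y
  dosage <- al$dosage
  map <- dosage$map
  chr <- map$chromosome[match(marker, map$marker)]
  on_chr <- map[map$chromosome == chr, , drop = FALSE]
  others <- setdiff(model$markers, marker)
  X0 <- .base_design(dosage, others)
  qr0 <- qr(X0)
  res_y <- qr.resid(qr0, y)
  rss0 <- sum(res_y^2)
  n <- length(y)
  lod <- vapply(on_chr$marker, function(m) {
    Z <- .nested_columns(dosage, m)
    if (ncol(Z) == 0) return(0)
    Zr <- qr.resid(qr0, Z)
    qz <- qr(Zr)
    if (qz$rank == 0) return(0)
    ss <- sum(qr.fitted(qz, res_y)^2)
    rss1 <- max(rss0 - ss, rss0 * 1e-15, .Machine$double.xmin)
    (n / 2) * log10(rss0 / rss1)
  }, numeric(1))
  out <- data.frame(marker = on_chr$marker, chromosome = chr,
                    position = on_chr$position, lod = unname(lod),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("lod_profile", "data.frame")
  if (nrow(out) == 1) {
    attr(out, "degenerate") <- TRUE
    warning("single-marker chromosome: degenerate LOD profile",
            call. = FALSE)
  } else {
    attr(out, "degenerate") <- FALSE
  }
  out
}

#' LOD-drop support interval
#'
#' The smallest contiguous marker interval containing the profile peak
#' whose boundary markers still have LOD at least `peak - drop`: the
#' interval is grown outwards from the peak while markers stay within
#' `drop` LOD units of it.  Endpoints are reported as the boundary
#' markers' cM positions (closed interval).  A flat profile spans the
#' whole chromosome.
#'
#' @param profile A `lod_profile`.
#' @param drop LOD drop defining the interval (default 1.0).
#' @return List with `start`, `end` (cM), `start_marker`, `end_marker`,
#'   `peak_marker`, `peak_position`, `peak_lod`.
#' @export
#' @examples
#' prof <- structure(data.frame(marker = paste0("m", 1:5), chromosome = 1,
#'                              position = c(0, 10, 20, 30, 40),
#'                              lod = c(2, 9, 10, 9.5, 3)),
#'                   class = c("lod_profile", "data.frame"))
#' support_interval(prof, drop = 1)[c("start", "end")]
support_interval <- function(profile, drop = 1.0) {
  stopifnot(nrow(profile) >= 1)
  check_number(drop, "drop", lower = 0)
  peak <- which.max(profile$lod)
  thr <- profile$lod[peak] - drop
  lo <- peak
  while (lo > 1 && profile$lod[lo - 1] >= thr) lo <- lo - 1
  hi <- peak
  while (hi < nrow(profile) && profile$lod[hi + 1] >= thr) hi <- hi + 1
  list(start = profile$position[lo], end = profile$position[hi],
       start_marker = profile$marker[lo], end_marker = profile$marker[hi],
       peak_marker = profile$marker[peak],
       peak_position = profile$position[peak],
       peak_lod = profile$lod[peak])
}
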