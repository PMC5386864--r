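# Readers and writers for the pipeline's delimited formats.  All tables
# are tab-delimited UTF-8 with a header row, "NA" for missing values, and
# "#"-prefixed metadata lines (package version, seed, parameters) at the
# top of every output file.

.write_table <- function(df, path, meta = list()) {
  meta <- c(list(package = paste0("teonil ",
                                  as.character(utils::packageVersion("teonil"))),
                 written = format(Sys.time(), "%Y-%m-%d")),
            meta)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta),
                     vapply(meta, function(x) paste(x, collapse = " "), "")),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

.read_table <- function(path, what = "table") {
  if (!file.exists(path)) stop_(what, " file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) stop_("cannot parse ", what, " file ", path, ": ",
                              conditionMessage(e)))
  if (nrow(df) == 0) stop_("no records in ", what, " file ", path)
  df
}

#' Read and write a genetic map
#'
#' Three tab-delimited columns with a header: `marker`, `chromosome`,
#' `position` (cM).  All map invariants are checked on load and the error
#' names the file and field.
#'
#' @param path File path.
#' @param map A `genetic_map` (for the writer).
#' @param meta Named list of extra header metadata.
#' @return `read_genetic_map()` a `genetic_map`; `write_genetic_map()` the
#'   path, invisibly.
#' @export
read_genetic_map <- function(path) {
  df <- .read_table(path, "genetic map")
  req <- c("marker", "chromosome", "position")
  if (!all(req %in% names(df))) {
    stop_("malformed header in ", path, ": need columns ",
          paste(req, collapse = ", "))
  }
  tryCatch(genetic_map(df$marker, df$chromosome, df$position),
           error = function(e) stop_("invalid map in ", path, ": ",
                                     conditionMessage(e)))
}

#' @rdname read_genetic_map
#' @export
write_genetic_map <- function(map, path, meta = list()) {
  validate_genetic_map(map)
  .write_table(as.data.frame(map), path, meta)
}

#' Read and write NIL genotypes
#'
#' Tab-delimited matrix: first column `line`, second column `family`,
#' remaining columns one per marker with calls coded B/H/D/NA.  Every
#' marker must be present in the supplied genetic map; the loaded object
#' keeps markers in map order.
#'
#' @param path File path.
#' @param map A `genetic_map` the genotypes refer to.
#' @param genos A `nil_genotypes` (for the writer).
#' @param meta Named list of extra header metadata.
#' @return `read_genotypes()` a `nil_genotypes`; `write_genotypes()` the
#'   path, invisibly.
#' @export
read_genotypes <- function(path, map) {
  validate_genetic_map(map)
  df <- .read_table(path, "genotype")
  if (ncol(df) < 3 || names(df)[1] != "line" || names(df)[2] != "family") {
    stop_("malformed header in ", path,
          ": expected columns line, family, then markers")
  }
  markers <- names(df)[-(1:2)]
  unknown <- setdiff(markers, map$marker)
  if (length(unknown)) {
    stop_("genotype file ", path, " references marker(s) absent from the ",
          "map: ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (anyDuplicated(df$line)) {
    stop_("duplicate line identifiers in ", path)
  }
  calls <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(calls) <- df$line
  bad <- setdiff(unique(as.vector(calls)), c("B", "H", "D", NA, "NA", ""))
  if (length(bad)) {
    stop_("unknown genotype code(s) in ", path, ": ",
          paste(bad, collapse = ", "))
  }
  calls[calls %in% c("NA", "")] <- NA_character_
  sub_map <- map[map$marker %in% markers, , drop = FALSE]
  calls <- calls[, sub_map$marker, drop = FALSE]
  fam <- factor(df$family)
  structure(list(calls = calls,
                 family = stats::setNames(fam, df$line),
                 map = sub_map),
            class = "nil_genotypes")
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(genos, path, meta = list()) {
  stopifnot(inherits(genos, "nil_genotypes"))
  df <- data.frame(line = rownames(genos$calls),
                   family = as.character(genos$family),
                   genos$calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_table(df, path, meta)
}

#' Read and write a plot-level phenotype table
#'
#' Long-format tab-delimited text with columns `line`, `env`, `rep`,
#' `trait`, `value`; duplicate (line, env, rep, trait) keys are an error.
#'
#' @param path File path.
#' @param plots A plot table (for the writer).
#' @param meta Named list of extra header metadata.
#' @return `read_plot_table()` a validated plot table data frame;
#'   `write_plot_table()` the path, invisibly.
#' @export
read_plot_table <- function(path) {
  df <- .read_table(path, "plot table")
  req <- c("line", "env", "rep", "trait", "value")
  if (!all(req %in% names(df))) {
    stop_("malformed header in ", path, ": need columns ",
          paste(req, collapse = ", "))
  }
  df$value <- as.numeric(df$value)
  tryCatch(validate_plot_table(df),
           error = function(e) stop_("invalid plot table in ", path, ": ",
                                     conditionMessage(e)))
  df[req]
}

#' @rdname read_plot_table
#' @export
write_plot_table <- function(plots, path, meta = list()) {
  validate_plot_table(plots)
  .write_table(plots, path, meta)
}

#' Read and write an entry-means (LSmeans) table
#'
#' Tab-delimited: column `line` followed by one numeric column per trait,
#' the format of a supplementary entry-means table.
#'
#' @param path File path.
#' @param lsmeans An `ls_means` data frame (for the writer).
#' @param meta Named list of extra header metadata.
#' @return `read_lsmeans()` an `ls_means` data frame; `write_lsmeans()`
#'   the path, invisibly.
#' @export
read_lsmeans <- function(path) {
  df <- .read_table(path, "LSmeans")
  if (names(df)[1] != "line" || ncol(df) < 2) {
    stop_("malformed header in ", path, ": expected line then trait columns")
  }
  if (anyDuplicated(df$line)) stop_("duplicate line identifiers in ", path)
  for (j in seq(2, ncol(df))) df[[j]] <- as.numeric(df[[j]])
  class(df) <- c("ls_means", "data.frame")
  df
}

#' @rdname read_lsmeans
#' @export
write_lsmeans <- function(lsmeans, path, meta = list()) {
  .write_table(as.data.frame(lsmeans), path, meta)
}

#' Read and write spectra
#'
#' Wide tab-delimited format: first column `sample`, remaining columns
#' wavelength-labelled absorbances (numeric header labels in nm).
#' Reference chemistry travels separately as a long (sample, trait, value)
#' table passed through `reference_path`.
#'
#' @param path Spectra file path.
#' @param reference_path Optional path to a (sample, trait, value) table.
#' @param spectra A `spectra_set` (for the writer).
#' @param meta Named list of extra header metadata.
#' @return `read_spectra()` a `spectra_set`; `write_spectra()` the path,
#'   invisibly.
#' @export
read_spectra <- function(path, reference_path = NULL) {
  df <- .read_table(path, "spectra")
  if (names(df)[1] != "sample" || ncol(df) < 2) {
    stop_("malformed header in ", path,
          ": expected column sample then wavelengths")
  }
  wl <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(wl)) {
    stop_("non-numeric wavelength label(s) in ", path, ": ",
          paste(utils::head(names(df)[-1][is.na(wl)], 3), collapse = ", "))
  }
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df$sample
  ref <- NULL
  if (!is.null(reference_path)) {
    rdf <- .read_table(reference_path, "reference chemistry")
    req <- c("sample", "trait", "value")
    if (!all(req %in% names(rdf))) {
      stop_("malformed header in ", reference_path, ": need columns ",
            paste(req, collapse = ", "))
    }
    ref <- as.data.frame(tapply(as.numeric(rdf$value),
                                list(rdf$sample, rdf$trait), mean))
    ref <- ref[match(df$sample, rownames(ref)), , drop = FALSE]
    rownames(ref) <- df$sample
  }
  spectra_set(X, wl, ref)
}

#' @rdname read_spectra
#' @export
write_spectra <- function(spectra, path, meta = list()) {
  stopifnot(inherits(spectra, "spectra_set"))
  df <- data.frame(sample = rownames(spectra$absorbance),
                   spectra$absorbance, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_table(df, path, meta)
}

#' Write a QTL report to delimited files
#'
#' Writes the per-QTL summary (trait, marker, chromosome, peak, 1-LOD
#' interval) and the QTL x family effect matrix with star codes, plus one
#' LOD-profile table per QTL.
#'
#' @param report A `qtl_report`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, typically the trait.
#' @param meta Named list of extra header metadata.
#' @return Character vector of files written, invisibly.
#' @export
write_qtl_report <- function(report, dir, prefix = report$trait,
                             meta = list()) {
  stopifnot(inherits(report, "qtl_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.na(prefix) || !nzchar(prefix)) prefix <- "trait"
  meta <- c(meta, list(threshold = report$threshold %||% NA,
                       r_squared = round(report$r_squared, 4)))
  files <- character(0)
  f1 <- file.path(dir, paste0(prefix, "_qtl_summary.tsv"))
  .write_table(report$summary, f1, meta)
  files <- c(files, f1)
  eff <- data.frame(marker = rownames(report$effects$display),
                    report$effects$display, check.names = FALSE,
                    stringsAsFactors = FALSE)
  f2 <- file.path(dir, paste0(prefix, "_effects.tsv"))
  .write_table(eff, f2, meta)
  files <- c(files, f2)
  for (m in names(report$profiles)) {
    f <- file.path(dir, paste0(prefix, "_lod_", m, ".tsv"))
    .write_table(as.data.frame(report$profiles[[m]]), f, meta)
    files <- c(files, f)
  }
  invisible(files)
}
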