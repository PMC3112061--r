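# Readers and writers for the plain-text dialects used around the assay:
# wide melt tables (Temperature + one column per well), plate sample sheets,
# and the per-individual results table. Comma- or tab-delimited files are
# auto-detected from the header line; decimal points only.

detect_sep <- function(path) {
  header <- readLines(path, n = 25L)
  header <- header[!startsWith(header, "#")]
  if (!length(header)) stop("empty file: ", path)
  if (grepl("\t", header[1])) "\t" else ","
}

read_delim_checked <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fill = TRUE, blank.lines.skip = TRUE)
  df
}

#' Read a wide melt table
#'
#' Parses an instrument-style export: a delimited text file whose first column
#' is `Temperature` and whose remaining columns hold the fluorescence trace of
#' one well each. Rows are sorted by temperature (descending exports are
#' accepted); every well column must be declared in `layout`.
#'
#' @param path Path to a CSV/TSV melt table (delimiter auto-detected; lines
#'   starting with `#` are ignored).
#' @param layout A [plate_layout()] describing the wells.
#' @return A list of [melt_curve()] objects, one per well column.
#' @export
read_melt_table <- function(path, layout) {
  if (!file.exists(path)) stop("melt table not found: ", path)
  df <- read_delim_checked(path)
  if (ncol(df) < 2L) stop("melt table needs a Temperature column plus at least one well")
  if (tolower(names(df)[1]) != "temperature")
    stop("first column of a melt table must be 'Temperature', got '", names(df)[1], "'")
  if (anyNA(df))
    stop("melt table contains missing values (ragged rows?): ", path)
  wells <- names(df)[-1]
  unknown <- setdiff(wells, layout$well)
  if (length(unknown))
    stop("well id(s) in melt table absent from the sample sheet: ",
         paste(unknown, collapse = ", "))
  temp <- as.numeric(df[[1]])
  if (anyNA(temp)) stop("non-numeric temperatures in melt table")
  if (any(diff(temp) == 0)) stop("non-monotone temperature column (duplicated values)")
  # melt_curve() sorts ascending and validates monotonicity/uniformity.
  lapply(wells, function(w) {
    meta <- layout[layout$well == w, ]
    melt_curve(well_id = w, sample_id = meta$sample_id, material = meta$material,
               replicate = meta$replicate, marker_snp = meta$marker_snp,
               temperatures = temp, fluorescence = df[[w]])
  })
}

#' Write a wide melt table
#'
#' Inverse of [read_melt_table()]: all curves must share one temperature grid.
#'
#' @param curves List of [melt_curve()] objects.
#' @param path Output path (`.tsv` extension selects tabs, otherwise commas).
#' @param header Optional character vector of comment lines (written with a
#'   leading `#`).
#' @export
write_melt_table <- function(curves, path, header = NULL) {
  if (!length(curves)) stop("no curves to write")
  temp <- curves[[1]]$temperatures
  for (cu in curves)
    if (!isTRUE(all.equal(cu$temperatures, temp)))
      stop("all curves must share one temperature grid to be written wide")
  df <- data.frame(Temperature = temp, check.names = FALSE)
  for (cu in curves) df[[cu$well_id]] <- cu$fluorescence
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plate sample sheet
#'
#' Expects columns `well`, `sample_id`, `material`, `replicate`, `marker_snp`
#' (case-insensitive header). Material tokens are parsed case-insensitively
#' with common aliases ("cdna_puro", "puromycin", ...).
#'
#' @param path Path to a CSV/TSV sample sheet.
#' @param expected_replicates Passed on to [plate_layout()].
#' @return A [plate_layout()].
#' @export
read_sample_sheet <- function(path, expected_replicates = 4L) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- read_delim_checked(path)
  names(df) <- tolower(names(df))
  plate_layout(df, expected_replicates = expected_replicates)
}

#' Write a plate sample sheet
#' @param layout A [plate_layout()].
#' @param path Output path.
#' @param header Optional comment lines.
#' @export
write_sample_sheet <- function(layout, path, header = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(as.data.frame(layout), con, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

.results_numeric <- c("n_gdna", "n_cdna", "n_puro", "mean_log_gdna",
                      "mean_log_cdna", "mean_log_puro", "delta", "dae_percent",
                      "ci_low", "ci_high", "t_stat", "p_value")
.results_logical <- c("crit_magnitude", "crit_pvalue", "crit_ci", "call")

#' Write the per-individual results table
#'
#' One TSV row per individual: replicate counts, mean log allelic ratios per
#' material, the normalized DAE estimate with confidence interval and t-test,
#' the three criteria flags, the call and the NMD class. Values round-trip
#' through [read_results_table()] to at least 6 decimals.
#'
#' @param results A `dae_batch` or list of `dae_result` objects.
#' @param path Output path.
#' @param header Optional comment lines (written with a leading `#`).
#' @export
write_results_table <- function(results, path, header = NULL) {
  df <- if (inherits(results, "dae_batch") || inherits(results, "dae_result")) {
    as.data.frame(results)
  } else if (is.list(results) && length(results) &&
             all(vapply(results, inherits, logical(1), "dae_result"))) {
    do.call(rbind, lapply(results, as.data.frame))
  } else if (is.data.frame(results)) {
    results
  } else if (is.list(results) && length(results) == 0L) {
    stop("no results")
  } else {
    stop("results must be a dae_batch, a list of dae_result objects, or a data.frame")
  }
  if (nrow(df) == 0L) stop("no results")
  out <- df
  for (col in .results_numeric)
    out[[col]] <- ifelse(is.na(df[[col]]), "NA", sprintf("%.10g", df[[col]]))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(out, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#' @param path Path to the TSV.
#' @return A data.frame with one row per individual.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop("results table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, na.strings = "NA")
  for (col in intersect(.results_logical, names(df))) df[[col]] <- as.logical(df[[col]])
  for (col in intersect(.results_numeric, names(df))) df[[col]] <- as.numeric(df[[col]])
  df
}
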