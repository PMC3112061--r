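#' Materials recognised on a DAE plate
#'
#' @format Character vector of the four canonical material tokens.
#' @export
MATERIALS <- c("gDNA", "cDNA", "cDNA_puromycin", "NTC")

# Case-insensitive alias table for material tokens found in sample sheets.
.material_aliases <- c(
  "gdna" = "gDNA", "g" = "gDNA", "genomic" = "gDNA", "genomic_dna" = "gDNA",
  "cdna" = "cDNA", "c" = "cDNA",
  "cdna_puromycin" = "cDNA_puromycin", "cdna_puro" = "cDNA_puromycin",
  "puromycin" = "cDNA_puromycin", "puro" = "cDNA_puromycin",
  "cdna-puromycin" = "cDNA_puromycin",
  "ntc" = "NTC", "no_template" = "NTC", "blank" = "NTC"
)

parse_material <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(.material_aliases[key])
  bad <- is.na(out)
  if (any(bad))
    stop("unknown material token(s): ", paste(unique(x[bad]), collapse = ", "))
  out
}

#' A single well's melting curve
#'
#' Fluorescence intensity versus temperature for one well, annotated with the
#' plate metadata needed downstream. Temperatures are sorted ascending on
#' construction (instrument exports are accepted in either direction); the
#' grid must be uniform to within 1% relative tolerance and lie within
#' 20-100 degC.
#'
#' @param well_id,sample_id,marker_snp Character identifiers.
#' @param material One of "gDNA", "cDNA", "cDNA_puromycin", "NTC" (aliases
#'   such as "cdna_puro" are accepted, case-insensitively).
#' @param replicate Positive integer replicate index.
#' @param temperatures Numeric vector of degC values, strictly monotone.
#' @param fluorescence Numeric vector, same length as `temperatures`.
#' @param background_subtracted Logical flag carried through the pipeline.
#' @return An object of class `melt_curve`.
#' @seealso [subtract_background()], [derivative_curve()]
#' @export
melt_curve <- function(well_id, sample_id, material, replicate, marker_snp,
                       temperatures, fluorescence,
                       background_subtracted = FALSE) {
  temperatures <- as.numeric(temperatures)
  fluorescence <- as.numeric(fluorescence)
  if (length(temperatures) != length(fluorescence))
    stop("temperatures and fluorescence must have the same length")
  if (length(temperatures) < 2L)
    stop("a melt curve needs at least 2 points")
  if (anyNA(temperatures) || anyNA(fluorescence))
    stop("melt curve contains missing values (ragged or malformed input?)")
  o <- order(temperatures)
  temperatures <- temperatures[o]
  fluorescence <- fluorescence[o]
  dT <- diff(temperatures)
  if (any(dT <= 0))
    stop("temperatures must be strictly monotone (duplicated temperature rows?)")
  step <- stats::median(dT)
  if (any(abs(dT - step) > 0.01 * step))
    stop("temperature grid is not uniform (within 1% relative tolerance)")
  if (min(temperatures) < 20 || max(temperatures) > 100)
    stop("temperatures must lie within [20, 100] degC")
  structure(
    list(well_id = as.character(well_id),
         sample_id = as.character(sample_id),
         material = parse_material(material),
         replicate = as.integer(replicate),
         marker_snp = as.character(marker_snp),
         temperatures = temperatures,
         fluorescence = fluorescence,
         background_subtracted = isTRUE(background_subtracted)),
    class = "melt_curve"
  )
}

grid_step <- function(curve) stats::median(diff(curve$temperatures))

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("<melt_curve> well %s | %s %s rep %d | %s | %d points, %.2f-%.2f degC%s\n",
              x$well_id, x$sample_id, x$material, x$replicate, x$marker_snp,
              length(x$temperatures), min(x$temperatures), max(x$temperatures),
              if (x$background_subtracted) " | background-subtracted" else ""))
  invisible(x)
}

#' @export
plot.melt_curve <- function(x, ...,
                            xlab = "Temperature (°C)",
                            ylab = "Fluorescence (a.u.)",
                            type = "l",
                            main = sprintf("%s (%s, rep %d)", x$sample_id,
                                           x$material, x$replicate)) {
  graphics::plot(x$temperatures, x$fluorescence, type = type,
                 xlab = xlab, ylab = ylab, main = main, ...)
  invisible(x)
}

#' Plate layout: mapping from wells to samples
#'
#' @param entries A data.frame with columns `well`, `sample_id`, `material`,
#'   `replicate`, `marker_snp`. Materials are parsed case-insensitively.
#' @param expected_replicates Expected replicate count per
#'   (sample, material) group; a deviation triggers a warning, not an error
#'   (the statistics generalize to any n >= 2). Default 4.
#' @return An object of class `plate_layout` (the validated data.frame with an
#'   `ntc_wells` attribute).
#' @export
plate_layout <- function(entries, expected_replicates = 4L) {
  need <- c("well", "sample_id", "material", "replicate", "marker_snp")
  miss <- setdiff(need, names(entries))
  if (length(miss))
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  entries <- as.data.frame(entries)[need]
  entries$well <- as.character(entries$well)
  entries$sample_id <- as.character(entries$sample_id)
  entries$material <- parse_material(entries$material)
  entries$replicate <- as.integer(entries$replicate)
  entries$marker_snp <- as.character(entries$marker_snp)
  dup <- unique(entries$well[duplicated(entries$well)])
  if (length(dup))
    stop("duplicate well id(s) in sample sheet: ", paste(dup, collapse = ", "))
  if (any(entries$replicate < 1L, na.rm = TRUE))
    stop("replicate indices must be positive integers")

  samples <- entries[entries$material != "NTC", , drop = FALSE]
  if (nrow(samples)) {
    counts <- table(paste(samples$sample_id, samples$material, sep = "\r"))
    off <- counts[counts != expected_replicates]
    if (length(off))
      warning(sprintf("%d (sample, material) group(s) do not have %d replicates",
                      length(off), expected_replicates))
  }
  ntc <- entries$well[entries$material == "NTC"]
  if (length(ntc) == 0L)
    warning("no NTC well in the layout: background subtraction will be disabled")
  structure(entries, ntc_wells = ntc, class = c("plate_layout", "data.frame"))
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> %d wells: %d sample wells (%d individuals), %d NTC\n",
              nrow(x), sum(x$material != "NTC"),
              length(unique(x$sample_id[x$material != "NTC"])),
              length(attr(x, "ntc_wells"))))
  invisible(x)
}
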