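#' Labelled spectra table
#'
#' The common currency of the pipeline: a set of labelled reflectance spectra
#' on one shared wavelength grid. Each record is a single scan of one egg at
#' one storage day.
#'
#' @param scan_id character vector, unique per record.
#' @param egg_id character vector; all scans of a physical egg share one id.
#' @param variety character vector of variety labels.
#' @param day integer vector of storage days.
#' @param reflectance numeric matrix, one row per record, one column per band.
#' @param wavelengths strictly increasing numeric vector of band centres (nm),
#'   length equal to `ncol(reflectance)`.
#'
#' @return An object of class `spectra_table`: a list with fields `scan_id`,
#'   `egg_id`, `variety`, `day`, `reflectance`, `wavelengths`.
#' @export
spectra_table <- function(scan_id, egg_id, variety, day, reflectance, wavelengths) {
  reflectance <- as.matrix(reflectance)
  n <- nrow(reflectance)
  scan_id <- as.character(scan_id)
  egg_id <- as.character(egg_id)
  variety <- as.character(variety)
  day <- as.integer(day)
  if (length(scan_id) != n || length(egg_id) != n || length(variety) != n ||
      length(day) != n) {
    stop("label vectors must match the number of spectra rows")
  }
  if (anyDuplicated(scan_id)) {
    stop("duplicate scan_id: ", paste(scan_id[duplicated(scan_id)][1], collapse = ", "))
  }
  check_grid(wavelengths)
  if (length(wavelengths) != ncol(reflectance)) {
    stop("wavelengths length must equal the number of bands")
  }
  if (!all(is.finite(reflectance))) stop("non-finite reflectance values")
  structure(
    list(scan_id = scan_id, egg_id = egg_id, variety = variety, day = day,
         reflectance = reflectance, wavelengths = wavelengths),
    class = "spectra_table"
  )
}

check_grid <- function(wavelengths) {
  if (!is.numeric(wavelengths) || length(wavelengths) < 2L) {
    stop("wavelength grid must be numeric with at least two points")
  }
  if (any(diff(wavelengths) <= 0)) stop("wavelength grid must be strictly increasing")
  invisible(wavelengths)
}

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf(
    "<spectra_table> %d scans x %d bands (%.1f-%.1f nm)\n",
    nrow(x$reflectance), ncol(x$reflectance),
    min(x$wavelengths), max(x$wavelengths)
  ))
  cat(sprintf("  varieties: %s\n", paste(sort(unique(x$variety)), collapse = ", ")))
  cat(sprintf("  days:      %s\n", paste(sort(unique(x$day)), collapse = ", ")))
  cat(sprintf("  eggs:      %d\n", length(unique(x$egg_id))))
  invisible(x)
}

#' @export
dim.spectra_table <- function(x) dim(x$reflectance)

#' Subset a spectra table by record index
#'
#' @param table a [spectra_table()].
#' @param idx integer or logical index over records (rows).
#' @return A `spectra_table` with the selected records.
#' @export
st_subset <- function(table, idx) {
  spectra_table(table$scan_id[idx], table$egg_id[idx], table$variety[idx],
                table$day[idx], table$reflectance[idx, , drop = FALSE],
                table$wavelengths)
}
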