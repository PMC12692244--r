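#' Two-point reflectance calibration
#'
#' Converts raw detector intensities to reflectance with dark and white
#' reference frames: `(raw - dark) / (white - dark)`, elementwise. The three
#' arrays may be vectors, matrices or 3-D cubes, but must share one shape.
#' Values outside \[0, 1\] (possible with noise) are kept, not clipped:
#' downstream SNV is location/scale invariant, and clipping would bias ROI
#' means.
#'
#' @param raw,dark,white equally shaped numeric arrays.
#' @return Reflectance array of the same shape.
#' @export
calibrate <- function(raw, dark, white) {
  if (!identical(dim2(raw), dim2(dark)) || !identical(dim2(raw), dim2(white))) {
    stop("raw, dark and white must share one shape")
  }
  denom <- white - dark
  dead <- which(denom == 0)
  if (length(dead) > 0) {
    stop("dead pixels (white == dark) at indices: ",
         paste(utils::head(dead, 10), collapse = ", "),
         if (length(dead) > 10) sprintf(" (and %d more)", length(dead) - 10) else "")
  }
  (raw - dark) / denom
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Rectangular region-of-interest specification
#'
#' @param row_start,col_start top-left pixel (1-based).
#' @param height,width extents in pixels, positive.
#' @return A list of class `roi_spec`.
#' @export
roi_spec <- function(row_start = 1L, col_start = 1L, height = 20L, width = 20L) {
  if (height < 1 || width < 1 || row_start < 1 || col_start < 1) {
    stop("ROI extents must be positive")
  }
  structure(list(row_start = as.integer(row_start), col_start = as.integer(col_start),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi_spec")
}

#' Centred ROI for a frame
#'
#' @param frame_rows,frame_cols frame extent in pixels.
#' @param height,width ROI extent (default 20 x 20).
#' @return A [roi_spec()] centred in the frame.
#' @export
centered_roi <- function(frame_rows, frame_cols, height = 20L, width = 20L) {
  roi_spec(row_start = max(1L, 1L + (frame_rows - height) %/% 2L),
           col_start = max(1L, 1L + (frame_cols - width) %/% 2L),
           height = min(height, frame_rows), width = min(width, frame_cols))
}

#' Mean spectrum over a region of interest
#'
#' Per-band arithmetic mean of all pixels inside the ROI of a calibrated
#' reflectance cube.
#'
#' @param reflectance 3-D array (rows x cols x bands).
#' @param roi a [roi_spec()]; must lie inside the frame.
#' @return Numeric vector, one mean reflectance per band.
#' @export
roi_mean_spectrum <- function(reflectance, roi = NULL) {
  d <- dim(reflectance)
  if (length(d) != 3) stop("reflectance must be a rows x cols x bands array")
  if (is.null(roi)) roi <- centered_roi(d[1], d[2])
  rows <- roi$row_start:(roi$row_start + roi$height - 1L)
  cols <- roi$col_start:(roi$col_start + roi$width - 1L)
  if (max(rows) > d[1] || max(cols) > d[2]) stop("ROI lies outside the frame")
  apply(reflectance[rows, cols, , drop = FALSE], 3, mean)
}

#' Average replicate scans with a signal-stability check
#'
#' Returns the per-band mean of repeated scans of one sample together with
#' the per-band coefficient of variation (sample sd / mean, N-1 denominator).
#' A warning is raised when any band's CV exceeds `warn_above` (scan-to-scan
#' instability); bands whose mean is zero make the CV undefined and are
#' reported in `flagged`.
#'
#' @param scans numeric matrix (one row per scan) or list of equal-length
#'   spectra; at least one scan.
#' @param warn_above CV warning ceiling (default 0.02).
#' @return List with `mean` (spectrum), `cv` (per-band CV, `NA` at flagged
#'   bands) and `flagged` (indices of zero-mean bands).
#' @export
average_replicates <- function(scans, warn_above = 0.02) {
  if (is.list(scans)) {
    lens <- lengths(scans)
    if (length(unique(lens)) != 1) stop("scans must share one length")
    scans <- do.call(rbind, scans)
  }
  scans <- as.matrix(scans)
  if (nrow(scans) < 1) stop("need at least one scan")
  m <- colMeans(scans)
  if (nrow(scans) == 1) {
    cv <- rep(0, ncol(scans))
  } else {
    s <- apply(scans, 2, stats::sd)
    cv <- ifelse(m == 0, NA_real_, s / m)
  }
  flagged <- which(m == 0)
  over <- which(!is.na(cv) & cv > warn_above)
  if (length(over) > 0) {
    warning(sprintf("replicate CV above %.3g at %d band(s), worst %.3g",
                    warn_above, length(over), max(cv[over])))
  }
  list(mean = m, cv = cv, flagged = flagged)
}

#' Write / read a spectra table as wide CSV
#'
#' Canonical exchange dialect: columns `scan_id, egg_id, variety, day`, then
#' one column per band named by wavelength (`w1000`, `w1005.5`, ...). Values
#' are written with 17 significant digits so the read/write round trip is
#' bit-faithful. A sidecar JSON file holding the grid is written next to the
#' CSV (`<path>.grid.json`).
#'
#' @param table a [spectra_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(table, path) {
  stopifnot(inherits(table, "spectra_table"))
  bands <- sprintf("w%.17g", table$wavelengths)
  header <- c("scan_id", "egg_id", "variety", "day", bands)
  vals <- matrix(sprintf("%.17g", table$reflectance), nrow = nrow(table$reflectance))
  body <- cbind(table$scan_id, table$egg_id, table$variety,
                as.character(table$day), vals)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  writeLines(apply(body, 1, paste, collapse = ","), con)
  jsonlite::write_json(list(wavelengths_nm = table$wavelengths),
                       paste0(path, ".grid.json"), digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @param check_monotone reject files whose band columns are not strictly
#'   increasing in wavelength (default `TRUE`).
#' @return `read_spectra_csv()` returns a [spectra_table()].
#' @export
read_spectra_csv <- function(path, check_monotone = TRUE) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("scan_id", "egg_id", "variety", "day")
  if (!identical(names(df)[1:4], need)) {
    stop("header must start with: ", paste(need, collapse = ", "))
  }
  band_cols <- names(df)[-(1:4)]
  if (!all(grepl("^w[0-9.]+$", band_cols))) {
    stop("band columns must be named w<wavelength>")
  }
  wl <- as.numeric(sub("^w", "", band_cols))
  if (check_monotone && any(diff(wl) <= 0)) {
    stop("band columns are not in strictly increasing wavelength order")
  }
  vals <- as.matrix(df[, -(1:4), drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("missing or non-numeric value at row %d, column %s",
                 bad[1], band_cols[bad[2]]))
  }
  dimnames(vals) <- NULL
  spectra_table(df$scan_id, df$egg_id, df$variety, as.integer(df$day), vals, wl)
}

#' Calibrate, extract ROI mean and average replicates for one sample
#'
#' Convenience composition of the acquisition chain: each replicate frame
#' triplet is calibrated, reduced to its ROI mean spectrum, and the replicate
#' spectra averaged with the CV stability check.
#'
#' @param triplets list of `frame_triplet` objects (replicate scans).
#' @param roi a [roi_spec()] or `NULL` for a centred default.
#' @param warn_above CV warning ceiling.
#' @return As [average_replicates()].
#' @export
sample_spectrum <- function(triplets, roi = NULL, warn_above = 0.02) {
  specs <- lapply(triplets, function(tr) {
    roi_mean_spectrum(calibrate(tr$raw, tr$dark, tr$white), roi)
  })
  average_replicates(do.call(rbind, specs), warn_above = warn_above)
}
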