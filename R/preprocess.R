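#' Standard normal variate transform
#'
#' Per-spectrum mean-centring and unit-variance scaling,
#' `(x - mean(x)) / sd(x)` with the sample (N-1) standard deviation. SNV
#' removes multiplicative scatter gains and additive baseline offsets, the
#' dominant acquisition artifacts of diffuse-reflectance NIR.
#'
#' @param spectrum numeric vector, length >= 2, nonzero variance.
#' @param id optional scan identifier used in error messages.
#' @return Transformed vector with mean 0 and sample sd 1.
#' @export
snv <- function(spectrum, id = NULL) {
  if (length(spectrum) < 2) stop("spectrum must have length >= 2")
  s <- stats::sd(spectrum)
  if (!is.finite(s) || s == 0) {
    stop("zero-variance spectrum", if (!is.null(id)) paste0(" (scan ", id, ")") else "")
  }
  (spectrum - mean(spectrum)) / s
}

#' Row-wise SNV of a spectra table
#'
#' Applies [snv()] to every record; labels are untouched. Failing rows are
#' aggregated into a single error report.
#'
#' @param table a [spectra_table()].
#' @return A [spectra_table()] of transformed spectra.
#' @export
snv_table <- function(table) {
  stopifnot(inherits(table, "spectra_table"))
  X <- table$reflectance
  mu <- rowMeans(X)
  # sample sd per row, vectorised
  ss <- sqrt(pmax(rowSums((X - mu)^2), 0) / (ncol(X) - 1))
  bad <- which(!is.finite(ss) | ss == 0)
  if (length(bad) > 0) {
    stop("zero-variance spectra: ",
         paste(utils::head(table$scan_id[bad], 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10) else "")
  }
  out <- table
  out$reflectance <- (X - mu) / ss
  out
}
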