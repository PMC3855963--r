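#' Discrete Fourier coefficients of a numeric series
#'
#' Computes the coefficients X(n) = sum_m x(m) exp(-i 2 pi n (m-1)/N) for
#' n = 1, ..., floor(N/2). The DC term (n = 0) is excluded: a constant shift
#' of the series carries no sequence periodicity and never enters the
#' informational spectrum.
#'
#' @param series Numeric vector of length N >= 2 (an EIIP-encoded sequence,
#'   see [encode_sequence()], though any numeric series is accepted).
#' @return Complex vector of length `floor(N/2)`, element n being X(n).
#' @export
fourier_coefficients <- function(series) {
  if (!is.numeric(series)) stop("series must be numeric", call. = FALSE)
  n <- length(series)
  if (n < 2L) stop("series must have length >= 2", call. = FALSE)
  if (anyNA(series)) stop("series contains NA", call. = FALSE)
  x <- stats::fft(series)
  x[seq_len(n %/% 2L) + 1L]
}

#' Informational spectrum of a numeric series
#'
#' The informational spectrum (IS) is the energy-density spectrum
#' S(n) = |X(n)|^2 of a numerically encoded sequence, evaluated on the
#' dimensionless frequency grid f_n = n/N for n = 1, ..., floor(N/2)
#' (unit residue spacing, so the Nyquist bound is 1/2). Peaks mark
#' periodicities of the encoded physicochemical property along the sequence.
#'
#' @param series Numeric vector of length N >= 2, or a protein sequence
#'   string (encoded with `scale` first).
#' @param scale EIIP scale used when `series` is a character sequence.
#' @return Object of class `informational_spectrum`: a list with elements
#'   `frequency` (n/N, strictly increasing, max <= 0.5), `amplitude`
#'   (non-negative S(n)), `index` (the integer frequency indices n) and
#'   `source_length` (N).
#' @seealso [fourier_coefficients()], [write_spectrum()]
#' @export
#' @examples
#' informational_spectrum(c(1, 0, 1, 0, 1, 0, 1, 0))  # single peak at f = 0.5
informational_spectrum <- function(series, scale = eiip_scale()) {
  if (is.character(series)) series <- encode_sequence(series, scale)
  n_total <- length(series)
  coef <- fourier_coefficients(series)
  k <- seq_along(coef)
  structure(
    list(frequency = k / n_total,
         amplitude = Mod(coef)^2,
         index = k,
         source_length = n_total),
    class = "informational_spectrum")
}

#' @export
print.informational_spectrum <- function(x, ...) {
  cat("Informational spectrum: N =", x$source_length, ",",
      length(x$frequency), "frequency bins (f = 1/N ... ",
      format(max(x$frequency)), ")\n")
  top <- order(x$amplitude, decreasing = TRUE)[seq_len(min(3L, length(x$amplitude)))]
  cat("Top amplitudes:\n")
  print(data.frame(index = x$index[top],
                   frequency = round(x$frequency[top], 4),
                   amplitude = signif(x$amplitude[top], 6)),
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.informational_spectrum <- function(x, ...) {
  data.frame(index = x$index, frequency = x$frequency, amplitude = x$amplitude)
}

#' @export
plot.informational_spectrum <- function(x, ...,
                                        xlab = "frequency",
                                        ylab = "amplitude |X(n)|^2",
                                        type = "h") {
  graphics::plot(x$frequency, x$amplitude, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Export a spectrum as two-column delimited text
#'
#' Writes `frequency` and `amplitude` columns, tab-separated, for external
#' plotting.
#'
#' @param spectrum An `informational_spectrum`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "informational_spectrum"))
  utils::write.table(
    data.frame(frequency = spectrum$frequency, amplitude = spectrum$amplitude),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
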