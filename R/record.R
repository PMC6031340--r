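#' Mono acoustic record
#'
#' The universal currency between pipeline stages: a uniformly sampled mono
#' pressure time series with its sampling rate. Amplitudes are dimensionless;
#' synthesis peak-normalizes to \[-1, 1\] so records survive 16-bit WAV
#' round-trips.
#'
#' @param samples Numeric vector of pressure samples.
#' @param fs Sampling rate in Hz (positive).
#' @return An object of class `acoustic_record` with fields `samples`, `fs`
#'   and `duration` (seconds).
#' @examples
#' acoustic_record(sin(2 * pi * 185 * (0:999) / 1e4), 1e4)
#' @export
acoustic_record <- function(samples, fs) {
  if (!is.numeric(samples)) stop("'samples' must be numeric", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive number (Hz)", call. = FALSE)
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         duration = length(samples) / fs),
    class = "acoustic_record"
  )
}

#' @export
print.acoustic_record <- function(x, ...) {
  cat(sprintf("<acoustic_record> %d samples @ %g Hz (%.4g s), peak %.4g\n",
              length(x$samples), x$fs, x$duration,
              if (length(x$samples)) max(abs(x$samples)) else NA_real_))
  invisible(x)
}

#' Centred time axis of a record
#'
#' Sample times `t_i = (i - (N - 1)/2) / fs`, symmetric about the record
#' midpoint t = 0. All modulation and demodulation stages share this
#' convention so their cosine references stay phase-aligned.
#'
#' @param x An [acoustic_record()].
#' @return Numeric vector of sample times in seconds.
#' @export
time_axis <- function(x) {
  stopifnot(inherits(x, "acoustic_record"))
  n <- length(x$samples)
  (seq_len(n) - 1 - (n - 1) / 2) / x$fs
}
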