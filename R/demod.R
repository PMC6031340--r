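# Method 1: blind AM-SSB demodulation, STFT ROI-mean feature extraction and
# normalized cross-correlation (Z1) against per-volume templates.

#' AM-SSB coherent demodulation
#'
#' Demodulates an amplitude-modulated record by coherent mixing: the signal
#' is multiplied by a cosine at the carrier frequency (on the record's
#' centred time grid) and low-pass filtered with a Butterworth filter applied
#' forward-backward (zero phase), so feature time series derived from
#' different records stay lag-aligned. For an input `a(t) cos(2 pi c t)` the
#' output approaches `a(t) / 2`.
#'
#' @param record An [acoustic_record()].
#' @param carrier Carrier frequency c in Hz; must be below Nyquist.
#' @param cutoff Low-pass cutoff in Hz; defaults to the carrier, which passes
#'   the envelope band and rejects the image at 2c.
#' @param order Butterworth order. Default 5.
#' @return An [acoustic_record()] of the demodulated (baseband) signal.
#' @examples
#' r <- acoustic_record(cos(2 * pi * 185 * (0:9999) / 1e4), 1e4)
#' d <- am_ssb_demodulate(r, 185)
#' @export
am_ssb_demodulate <- function(record, carrier, cutoff = carrier, order = 5) {
  stopifnot(inherits(record, "acoustic_record"))
  if (carrier >= record$fs / 2)
    stop("'carrier' must be below the Nyquist frequency fs/2", call. = FALSE)
  if (cutoff <= 0 || cutoff >= record$fs / 2)
    stop("'cutoff' must lie in (0, fs/2)", call. = FALSE)
  mixed <- record$samples * cos(2 * pi * carrier * time_axis(record))
  bf <- signal::butter(order, cutoff / (record$fs / 2), type = "low")
  acoustic_record(signal::filtfilt(bf, mixed), record$fs)
}

#' Carrier residual: remove the remodulated information signal
#'
#' Re-modulates the demodulated information signal `y` onto the carrier and
#' removes its least-squares projection from the received signal `x`. The
#' remainder decorrelates impulse from impulse response and is taken to carry
#' the air-volume ("carrier ID") information. The residual is orthogonal to
#' the remodulated signal by construction.
#'
#' @param x The received [acoustic_record()].
#' @param y The demodulated information signal, from [am_ssb_demodulate()].
#' @param carrier Carrier frequency in Hz used for remodulation.
#' @return An [acoustic_record()]: `x` minus its projection onto
#'   `y(t) cos(2 pi carrier t)`. If `y` has (near-)zero energy, `x` is
#'   returned unchanged with a warning.
#' @export
carrier_residual <- function(x, y, carrier) {
  stopifnot(inherits(x, "acoustic_record"), inherits(y, "acoustic_record"))
  if (length(x$samples) != length(y$samples) || x$fs != y$fs)
    stop("'x' and 'y' must share length and sampling rate", call. = FALSE)
  m <- y$samples * cos(2 * pi * carrier * time_axis(x))
  e <- sum(m^2)
  if (e <= .Machine$double.eps * length(m)) {
    warning("zero-energy information signal; returning 'x' unchanged")
    return(x)
  }
  acoustic_record(x$samples - (sum(x$samples * m) / e) * m, x$fs)
}

#' Short-time Fourier transform magnitude map
#'
#' Hann-windowed STFT magnitudes over (frequency, frame time), the
#' spectrogram representation feeding ROI feature extraction. The default
#' window is short (128 samples at 10 kHz, i.e. 12.8 ms, 75% overlap) so
#' that envelope ripple up to ~100 Hz survives into the frame-time series.
#'
#' @param record An [acoustic_record()].
#' @param window_len Window length in samples. Default 128.
#' @param overlap Overlap fraction in \[0, 1). Default 0.75.
#' @return An object of class `stft_map`: `magnitudes` (frequency x frame),
#'   `f` (Hz), `t` (s, frame centres on the record's absolute time axis
#'   starting at 0), `window_len`, `overlap`, `fs`.
#' @export
stft <- function(record, window_len = 128, overlap = 0.75) {
  stopifnot(inherits(record, "acoustic_record"))
  n <- length(record$samples)
  if (window_len > n) stop("'window_len' exceeds record length", call. = FALSE)
  if (overlap < 0 || overlap >= 1) stop("'overlap' must be in [0, 1)", call. = FALSE)
  sp <- signal::specgram(record$samples, n = window_len, Fs = record$fs,
                         window = signal::hanning(window_len),
                         overlap = floor(window_len * overlap))
  structure(
    list(magnitudes = Mod(sp$S), f = as.numeric(sp$f), t = as.numeric(sp$t),
         window_len = window_len, overlap = overlap, fs = record$fs),
    class = "stft_map"
  )
}

#' Region-of-interest band
#'
#' The spectral band over which features are averaged; the default 150–200 Hz
#' brackets the 185 Hz fundamental of the test vocalization.
#'
#' @param f_lo,f_hi Band edges in Hz, `0 <= f_lo < f_hi`.
#' @return An object of class `roi_band`.
#' @export
roi_band <- function(f_lo = 150, f_hi = 200) {
  if (!(f_lo >= 0 && f_lo < f_hi))
    stop("need 0 <= f_lo < f_hi", call. = FALSE)
  structure(list(f_lo = f_lo, f_hi = f_hi), class = "roi_band")
}

#' Mean ROI magnitude per STFT frame
#'
#' Averages STFT magnitudes over the frequency bins inside the band
#' (inclusive bounds), yielding one smoothed frequency-content value per
#' frame: the method-1 feature time series.
#'
#' @param map An [stft()] map.
#' @param band An [roi_band()].
#' @return An object of class `roi_series`: `values` (one per frame), `t`
#'   (frame times), `band`.
#' @export
roi_mean <- function(map, band) {
  stopifnot(inherits(map, "stft_map"), inherits(band, "roi_band"))
  rows <- which(map$f >= band$f_lo & map$f <= band$f_hi)
  if (length(rows) == 0L)
    stop("band [", band$f_lo, ", ", band$f_hi, "] Hz contains no STFT bins",
         call. = FALSE)
  structure(
    list(values = colMeans(map$magnitudes[rows, , drop = FALSE]),
         t = map$t, band = band),
    class = "roi_series"
  )
}

# Mean-removed, unit-energy normalized cross-correlation over all lags.
# Shared by the Z1 (time) and Z2 (cyclic-frequency) correlators.
normalized_xcorr <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("series too short to correlate", call. = FALSE)
  a0 <- a - mean(a); b0 <- b - mean(b)
  na <- sqrt(sum(a0^2)); nb <- sqrt(sum(b0^2))
  if (na == 0 || nb == 0)
    stop("constant input series: normalization undefined", call. = FALSE)
  vals <- stats::convolve(a0, b0, conj = TRUE, type = "open") / (na * nb)
  lags <- seq.int(-(length(b) - 1L), length(a) - 1L)
  peak_idx <- which.max(vals)
  structure(
    list(values = vals, lags = lags,
         peak = vals[peak_idx], peak_lag = lags[peak_idx]),
    class = "correlation_series"
  )
}

#' @export
print.correlation_series <- function(x, ...) {
  cat(sprintf("<correlation_series> %d lags, peak %.4f at lag %d\n",
              length(x$lags), x$peak, x$peak_lag))
  invisible(x)
}

#' Normalized cross-correlation of two ROI series (Z1)
#'
#' The method-1 match statistic: both series are mean-removed and the
#' cross-correlation over every lag is normalized by the product of their L2
#' norms, so all values lie in \[-1, 1\] and identical series give a peak of
#' exactly 1 at lag 0.
#'
#' @param a,b [roi_mean()] series (or plain numeric vectors).
#' @return An object of class `correlation_series`: `values`, `lags`, `peak`
#'   (maximum value, the classification statistic) and `peak_lag`.
#' @export
z1_correlate <- function(a, b) {
  av <- if (inherits(a, "roi_series")) a$values else as.numeric(a)
  bv <- if (inherits(b, "roi_series")) b$values else as.numeric(b)
  normalized_xcorr(av, bv)
}

#' Estimate the carrier frequency by spectral peak-finding
#'
#' Optional helper when the fundamental is not known a priori: returns the
#' frequency of the largest DFT magnitude inside a search band.
#'
#' @param record An [acoustic_record()].
#' @param band Search band, an [roi_band()]; default 100–300 Hz.
#' @return Estimated carrier frequency in Hz.
#' @export
estimate_carrier <- function(record, band = roi_band(100, 300)) {
  stopifnot(inherits(record, "acoustic_record"))
  n <- length(record$samples)
  f <- (seq_len(n) - 1) * record$fs / n
  keep <- which(f >= band$f_lo & f <= band$f_hi)
  if (length(keep) == 0L) stop("search band contains no DFT bins", call. = FALSE)
  mag <- Mod(stats::fft(record$samples))[keep]
  f[keep][which.max(mag)]
}
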