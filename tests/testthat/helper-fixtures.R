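# Shared fixtures and independent oracles used across the test files.

default_env <- environment_spec()

# A cosine on the package's centred time-grid convention.
tone_record <- function(freq, fs = 10000, n = 20000, amplitude = 1) {
  t <- (seq_len(n) - 1 - (n - 1) / 2) / fs
  acoustic_record(amplitude * cos(2 * pi * freq * t), fs)
}

# O(n^2) double-loop oracle for the mean-removed, unit-energy normalized
# cross-correlation; deliberately naive and independent of the fast path.
brute_xcorr <- function(a, b) {
  a0 <- a - mean(a); b0 <- b - mean(b)
  denom <- sqrt(sum(a0^2)) * sqrt(sum(b0^2))
  lags <- seq.int(-(length(b) - 1L), length(a) - 1L)
  vals <- vapply(lags, function(l) {
    s <- 0
    for (t in seq_along(b0)) {
      i <- t + l
      if (i >= 1 && i <= length(a0)) s <- s + a0[i] * b0[t]
    }
    s / denom
  }, numeric(1))
  list(values = vals, lags = lags)
}

# Analytic-signal envelope by FFT half-spectrum doubling (independent of the
# package's demodulator).
analytic_envelope <- function(x) {
  n <- length(x)
  h <- numeric(n)
  h[1] <- 1
  h[2:floor(n / 2)] <- 2
  if (n %% 2 == 0) h[n / 2 + 1] <- 1
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

# Direct segment-averaged periodogram (Welch) with the same windowing and
# scaling conventions as the cyclic estimator's alpha = 0 slice.
welch_psd <- function(x, fs, nfft, hop, w) {
  starts <- seq.int(1L, length(x) - nfft + 1L, by = hop)
  P <- vapply(starts, function(s)
    Mod(stats::fft(x[s:(s + nfft - 1L)] * w))^2, numeric(nfft))
  rowMeans(P) / (fs * sum(w^2))
}
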