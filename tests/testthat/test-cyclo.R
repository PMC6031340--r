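test_that("cyclic autocorrelation reduces to signal power and the sinusoid
           closed form", {
  set.seed(41)
  fs <- 1024; n <- 4096
  x <- acoustic_record(rnorm(n), fs)
  ca0 <- cyclic_autocorrelation(x, 0, 10)
  expect_equal(Re(ca0$values[ca0$lags == 0]), mean(x$samples^2),
               tolerance = 1e-12)
  expect_equal(max(abs(Im(ca0$values))), 0)

  # pure cosine: |R^alpha(0)| peaks only at alpha in {0, +/- 2 f1}
  f1 <- 128   # on the record's Fourier grid, so off-feature sums vanish
  tone <- acoustic_record(cos(2 * pi * f1 * (0:(n - 1)) / fs), fs)
  alphas <- seq(-384, 384, by = 32)
  mags <- vapply(alphas, function(a)
    Mod(cyclic_autocorrelation(tone, a, 0)$values), numeric(1))
  feature <- alphas %in% c(0, -2 * f1, 2 * f1)
  expect_true(all(mags[!feature] < 0.01 * max(mags)))
  expect_true(all(mags[feature] > 0.2 * max(mags)))

  # white noise: cyclic content at alpha != 0 vanishes as N grows
  n2 <- 2^14
  set.seed(42)
  w <- acoustic_record(rnorm(n2), fs)
  for (a in c(100, 250.5, 400))
    expect_lt(Mod(cyclic_autocorrelation(w, a, 0)$values), 5 / sqrt(n2))
  expect_error(cyclic_autocorrelation(w, 600, 0), "Nyquist")
  expect_error(cyclic_autocorrelation(x, 0, n), "max_lag")
})

test_that("cyclic spectral density equals the autocorrelation-Fourier oracle", {
  set.seed(7)
  fs <- 1024; n <- 1024
  x <- acoustic_record(rnorm(n) + sin(2 * pi * 128 * (0:(n - 1)) / fs), fs)
  w <- signal::hanning(n)
  alphas <- c(0, 64, 129.5, 256)     # includes an off-bin cyclic frequency
  m <- cyclic_spectral_density(x, alphas, nfft = n, overlap = 0, window = w)
  xw <- acoustic_record(x$samples * w, fs)
  for (ai in seq_along(alphas)) {
    ca <- cyclic_autocorrelation(xw, alphas[ai], n - 1)
    oracle <- vapply(m$f, function(ff)
      sum(ca$values * exp(-2i * pi * ff * ca$lags / fs)), complex(1))
    # undo the PSD scaling to compare on the oracle's (1/N) convention
    est <- m$values[ai, ] * (fs * sum(w^2)) / n
    expect_lt(max(Mod(est - oracle)), 1e-6)
  }
})

test_that("the alpha = 0 slice is the segment-averaged PSD, real and
           non-negative", {
  set.seed(8)
  fs <- 10000
  y <- acoustic_record(rnorm(8192), fs)
  m <- cyclic_spectral_density(y, c(0, 100), nfft = 256)
  w <- signal::hanning(256)
  psd <- welch_psd(y$samples, fs, 256, m$hop, w)
  expect_equal(max(abs(Im(m$values[1, ]))), 0)
  expect_true(all(Re(m$values[1, ]) >= 0))
  expect_lt(max(abs(Re(m$values[1, ]) - psd)) / max(psd), 1e-9)
  expect_error(cyclic_spectral_density(y, 6000, nfft = 256), "Nyquist")
  expect_error(cyclic_spectral_density(y, 0, nfft = 10000), "nfft")
})

test_that("a pure tone produces cyclic features only at alpha in
           {0, 2 f1}", {
  fs <- 10000
  f1 <- 156.25                       # 2 f1 lies on the alpha grid
  z <- tone_record(f1, fs = fs, n = 16384)
  ag <- seq(0, 468.75, by = 39.0625)
  m <- cyclic_spectral_density(z, ag, nfft = 256, overlap = 15 / 16)
  rowmax <- apply(Mod(m$values), 1, max)
  feature <- abs(ag - 2 * f1) < 1e-9 | ag == 0
  peak <- max(rowmax)
  expect_true(all(rowmax[!feature] < 0.01 * peak))
  # the alpha = 2 f1 feature sits at spectral frequency f = 0
  row2f1 <- Mod(m$values[which(abs(ag - 2 * f1) < 1e-9), ])
  expect_equal(m$f[which.max(row2f1)], 0)
  expect_gt(max(row2f1), 10 * max(rowmax[!feature]))
})

test_that("cross spectral density reduces to auto and obeys conjugation
           symmetry", {
  set.seed(51)
  fs <- 4096
  x <- acoustic_record(rnorm(2048), fs)
  y <- acoustic_record(rnorm(2048) + 0.5 * x$samples, fs)
  ag <- c(-128, 0, 128)
  auto <- cyclic_spectral_density(x, ag, nfft = 256)
  crossxx <- cross_spectral_density(x, x, ag, nfft = 256)
  expect_equal(crossxx$values, auto$values, tolerance = 1e-12)

  zero <- cross_spectral_density(x, acoustic_record(numeric(2048), fs), ag,
                                 nfft = 256)
  expect_equal(max(Mod(zero$values)), 0)

  sxy <- cross_spectral_density(x, y, ag, nfft = 256)
  syx <- cross_spectral_density(y, x, ag, nfft = 256)
  # S_yx at +alpha equals conj(S_xy) at -alpha, cell by cell
  for (k in seq_along(ag)) {
    k_neg <- which(ag == -ag[k])
    expect_equal(syx$values[k, ], Conj(sxy$values[k_neg, ]),
                 tolerance = 1e-12)
  }
  expect_error(cross_spectral_density(x, acoustic_record(1:10, fs), ag, 256),
               "length")
})

test_that("cross-spectral coherence is bounded, unity for self, small for
           independent noise", {
  set.seed(3)
  fs <- 10000
  x <- acoustic_record(
    as.numeric(signal::filtfilt(signal::butter(4, 0.3), rnorm(16384))), fs)
  self <- cross_spectral_coherence(x, x, 0)
  expect_true(all(self$values[!self$flagged] > 1 - 1e-9))
  expect_true(all(self$values[!self$flagged] <= 1))

  # a small delay preserves magnitude coherence on occupied bins
  d <- 3
  y <- acoustic_record(c(numeric(d), x$samples[1:(16384 - d)]), fs)
  co <- cross_spectral_coherence(x, y, 0)
  occ <- which(co$f < 1200 & !co$flagged)
  expect_gt(min(co$values[occ]), 0.95)

  set.seed(4)
  a <- acoustic_record(rnorm(16384), fs)
  b <- acoustic_record(rnorm(16384), fs)
  ind <- cross_spectral_coherence(a, b, 0)
  expect_lt(mean(ind$values, na.rm = TRUE), 0.1)
  expect_true(all(ind$values[!ind$flagged] >= 0 &
                    ind$values[!ind$flagged] <= 1))
})

test_that("doubling the record length tightens the estimator", {
  fs <- 10000
  cell <- function(n, seed) {
    set.seed(seed)
    r <- acoustic_record(rnorm(n), fs)
    Mod(cyclic_spectral_density(r, 100, nfft = 256)$values[1, 6])
  }
  sd_short <- stats::sd(vapply(1:20, function(s) cell(2048, s), numeric(1)))
  sd_long <- stats::sd(vapply(1:20, function(s) cell(4096, s), numeric(1)))
  expect_lt(sd_long, sd_short)
})

test_that("coherent spectra are normalized, gain-invariant and consistent", {
  g <- generate_growl(growl_spec(), duration = 1)
  x <- transmit_through_volume(g, bladder_spec(3), default_env, 185)
  y <- am_ssb_demodulate(x, 185)
  ag <- default_alpha_grid()
  T <- coherent_spectrum_template(x, y, ag)
  G <- coherent_spectrum_input(x, ag)
  expect_equal(sum(T$values^2), 1, tolerance = 1e-12)
  expect_equal(sum(G$values^2), 1, tolerance = 1e-12)
  expect_identical(T$role, "template")
  expect_identical(G$role, "input")

  x5 <- acoustic_record(5 * x$samples, x$fs)
  G5 <- coherent_spectrum_input(x5, ag)
  expect_equal(G5$values, G$values, tolerance = 1e-12)

  # T built with y = x degenerates to G of x
  Txx <- coherent_spectrum_template(x, x, ag)
  expect_equal(Txx$values, G$values, tolerance = 1e-12)

  # the input's own template shares the dominant cyclic rows in the ROI
  cols <- which(T$f >= 150 & T$f <= 200)
  tv <- rowMeans(T$values[, cols]); gv <- rowMeans(G$values[, cols])
  expect_equal(which.max(tv), which.max(gv))
  ripple_rows <- which(ag > 10)
  expect_equal(ag[ripple_rows[which.max(tv[ripple_rows])]],
               ag[ripple_rows[which.max(gv[ripple_rows])]])

  expect_error(coherent_spectrum_input(
    acoustic_record(numeric(4000), 10000), ag), "degenerate")
})

test_that("Z2 matches the oracle and detects constructed orthogonality", {
  ag <- seq(0, 100, by = 5)
  nf <- 8
  make_cs <- function(vals) {
    structure(list(values = vals, alpha = ag,
                   f = seq(0, 175, by = 25), role = "input",
                   source = NULL, normalization = "unit-energy"),
              class = "coherent_spectrum")
  }
  set.seed(61)
  gmat <- matrix(abs(rnorm(length(ag) * nf)), nrow = length(ag))
  g <- make_cs(gmat / sqrt(sum(gmat^2)))
  self <- z2_correlate(g, g, roi_band(0, 175))
  expect_equal(self$peak, 1, tolerance = 1e-9)
  expect_true(all(abs(self$values) <= 1 + 1e-12))

  tmat <- matrix(abs(rnorm(length(ag) * nf)), nrow = length(ag))
  t_cs <- make_cs(tmat / sqrt(sum(tmat^2)))
  z <- z2_correlate(g, t_cs, roi_band(0, 175))
  oracle <- brute_xcorr(rowMeans(g$values), rowMeans(t_cs$values))
  expect_lt(max(abs(z$values - oracle$values)), 1e-9)

  # orthogonalize the template's ROI vector against the input's: zero-lag
  # correlation vanishes
  gv <- rowMeans(g$values); gv0 <- gv - mean(gv)
  tv <- rowMeans(t_cs$values); tv0 <- tv - mean(tv)
  orth <- tv0 - sum(tv0 * gv0) / sum(gv0^2) * gv0
  t_orth <- make_cs(matrix(rep(orth + mean(tv), nf), ncol = nf))
  z0 <- z2_correlate(g, t_orth, roi_band(0, 175))
  expect_lt(abs(z0$values[z0$lags == 0]), 1e-9)

  expect_error(z2_correlate(g, t_cs, roi_band(1000, 2000)), "no bins")
  bad <- make_cs(gmat); bad$alpha <- ag + 1
  expect_error(z2_correlate(g, bad, roi_band(0, 175)), "axes")
})
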