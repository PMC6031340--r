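#' Specification of a surrogate "growl" vocalization
#'
#' Parameters of the synthetic test signal: a pulsed, harmonically structured
#' call of the kind produced by the red hind grouper, modelled as a
#' sonic-muscle impulse train convolved with a resonant impulse response.
#' Defaults emulate the 185 Hz-fundamental growl used as the playback test
#' signal.
#'
#' @param fundamental Fundamental / drum rate in Hz. Default 185.
#' @param n_harmonics Number of harmonic components in the resonator impulse
#'   response (>= 1). Default 3.
#' @param harmonic_rolloff Per-harmonic amplitude factors, a numeric vector
#'   of length `n_harmonics`. Default `1/k` for harmonic k.
#' @param resonator_q Quality factor of each damped-sinusoid component
#'   (dimensionless; `Inf` gives an undamped tone). Default 10.
#' @param onset_taper Fraction of the record length over which a raised-cosine
#'   ramp is applied at each end, in \[0, 0.5\]. Default 0.1.
#' @param snr_db Signal-to-noise ratio of added white Gaussian noise in dB
#'   (`Inf` for no noise). Default 30.
#' @param seed RNG seed for the noise; recorded in outputs so every record is
#'   reproducible. Default 20180430.
#' @return An object of class `growl_spec`.
#' @examples
#' growl_spec()
#' @export
growl_spec <- function(fundamental = 185, n_harmonics = 3,
                       harmonic_rolloff = 1 / seq_len(n_harmonics),
                       resonator_q = 10, onset_taper = 0.1,
                       snr_db = 30, seed = 20180430) {
  if (!is.numeric(fundamental) || length(fundamental) != 1L || fundamental <= 0)
    stop("'fundamental' must be a single positive number (Hz)", call. = FALSE)
  if (!is.numeric(n_harmonics) || length(n_harmonics) != 1L || n_harmonics < 1)
    stop("'n_harmonics' must be >= 1", call. = FALSE)
  n_harmonics <- as.integer(n_harmonics)
  if (length(harmonic_rolloff) != n_harmonics || any(harmonic_rolloff < 0))
    stop("'harmonic_rolloff' must be ", n_harmonics,
         " non-negative amplitude factors", call. = FALSE)
  if (!is.numeric(resonator_q) || length(resonator_q) != 1L || resonator_q <= 0)
    stop("'resonator_q' must be a single positive number", call. = FALSE)
  if (!is.numeric(onset_taper) || length(onset_taper) != 1L ||
      onset_taper < 0 || onset_taper > 0.5)
    stop("'onset_taper' must be in [0, 0.5]", call. = FALSE)
  if (!is.numeric(snr_db) || length(snr_db) != 1L || is.na(snr_db))
    stop("'snr_db' must be a single number (dB), possibly Inf", call. = FALSE)
  structure(
    list(fundamental = fundamental, n_harmonics = n_harmonics,
         harmonic_rolloff = as.numeric(harmonic_rolloff),
         resonator_q = resonator_q, onset_taper = onset_taper,
         snr_db = snr_db, seed = as.integer(seed)),
    class = "growl_spec"
  )
}

#' @export
print.growl_spec <- function(x, ...) {
  cat(sprintf(
    "<growl_spec> %g Hz fundamental, %d harmonics, Q = %g, taper %g, SNR %g dB, seed %d\n",
    x$fundamental, x$n_harmonics, x$resonator_q, x$onset_taper, x$snr_db, x$seed))
  invisible(x)
}

#' Generate a surrogate growl record
#'
#' Synthesizes the test vocalization as an impulse train at the fundamental
#' rate convolved with a resonator impulse response — a sum of exponentially
#' damped sinusoids at the fundamental and its harmonics, with per-harmonic
#' rolloff and decay time constant `Q / (pi * f)`. The result is tapered with
#' raised-cosine ramps, mixed with seeded white Gaussian noise at `snr_db`,
#' and peak-normalized to \[-1, 1\].
#'
#' @param spec A [growl_spec()].
#' @param fs Sampling rate in Hz. Default 10000.
#' @param duration Record length in seconds. Default 2.
#' @return An [acoustic_record()] with attribute `"growl_spec"` recording the
#'   generating parameters (including the seed).
#' @examples
#' g <- generate_growl(growl_spec(), fs = 10000, duration = 0.5)
#' @export
generate_growl <- function(spec, fs = 10000, duration = 2) {
  stopifnot(inherits(spec, "growl_spec"))
  if (duration <= 0) stop("'duration' must be positive", call. = FALSE)
  if (fs <= 2 * spec$fundamental * spec$n_harmonics)
    stop("Nyquist violation: fs must exceed 2 * fundamental * n_harmonics",
         call. = FALSE)
  n <- round(fs * duration)

  # sonic-muscle impulse train at the fundamental rate
  times <- seq(0, duration - 1 / fs, by = 1 / spec$fundamental)
  train <- numeric(n)
  train[pmin(n, round(times * fs) + 1L)] <- 1

  # resonator impulse response: damped sinusoids at the harmonics
  if (is.finite(spec$resonator_q)) {
    # length to ~1e-4 residual decay of the slowest (fundamental) component
    t_ir <- seq(0, min(duration,
                       spec$resonator_q * log(1e4) / (pi * spec$fundamental)),
                by = 1 / fs)
  } else {
    t_ir <- seq(0, duration - 1 / fs, by = 1 / fs)
  }
  h <- numeric(length(t_ir))
  for (k in seq_len(spec$n_harmonics)) {
    fk <- k * spec$fundamental
    decay <- if (is.finite(spec$resonator_q))
      exp(-pi * fk * t_ir / spec$resonator_q) else 1
    h <- h + spec$harmonic_rolloff[k] * decay * sin(2 * pi * fk * t_ir)
  }

  x <- stats::convolve(train, rev(h), type = "open")[seq_len(n)]

  # raised-cosine onset/offset ramps
  n_ramp <- round(spec$onset_taper * n)
  if (n_ramp > 0L) {
    ramp <- (1 - cos(pi * seq_len(n_ramp) / n_ramp)) / 2
    x[seq_len(n_ramp)] <- x[seq_len(n_ramp)] * ramp
    x[n - seq_len(n_ramp) + 1L] <- x[n - seq_len(n_ramp) + 1L] * ramp
  }

  if (is.finite(spec$snr_db)) {
    rms <- sqrt(mean(x^2))
    if (rms == 0) stop("cannot set an SNR on an all-zero signal", call. = FALSE)
    sigma <- rms * 10^(-spec$snr_db / 20)
    x <- x + withr::with_seed(spec$seed, stats::rnorm(n, sd = sigma))
  }

  x <- x / max(abs(x))
  out <- acoustic_record(x, fs)
  attr(out, "growl_spec") <- spec
  out
}

#' Pass a record through a simulated air volume
#'
#' Applies the bladder's modulation envelope multiplicatively on the record's
#' centred time grid: the in-silico equivalent of playing the test signal
#' through a balloon of the given radius. Linear in the input; an arbitrarily
#' large radius is an all-pass (output equals input).
#'
#' @param record An [acoustic_record()].
#' @param bladder A [bladder_spec()].
#' @param env An [environment_spec()].
#' @param F Forcing frequency in Hz driving the modulation model; defaults to
#'   the record's generating fundamental when present, else must be given.
#' @return An [acoustic_record()] of the same length and rate.
#' @examples
#' g <- generate_growl(growl_spec(), duration = 0.5)
#' tr <- transmit_through_volume(g, bladder_spec(3), environment_spec())
#' @export
transmit_through_volume <- function(record, bladder, env, F = NULL) {
  stopifnot(inherits(record, "acoustic_record"))
  if (length(record$samples) == 0L) stop("empty record", call. = FALSE)
  if (is.null(F)) {
    gs <- attr(record, "growl_spec")
    if (is.null(gs))
      stop("'F' must be given for records without a growl_spec attribute",
           call. = FALSE)
    F <- gs$fundamental
  }
  frame <- vocalization_frame(F, record$duration, record$fs)
  if (length(frame$time_axis) != length(record$samples))
    stop("time grid mismatch between record and frame", call. = FALSE)
  m <- modulation_envelope(frame, bladder, env)
  out <- acoustic_record(record$samples * m$values, record$fs)
  attr(out, "growl_spec") <- attr(record, "growl_spec")
  attr(out, "bladder") <- bladder
  out
}
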