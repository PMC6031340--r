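#' Environment specification for the resonant-bubble model
#'
#' Bundles the physical constants entering the resonant-bubble (Minnaert)
#' model of a gas volume in water: the specific-heat ratio of the gas, the
#' water density, and the combined atmospheric plus hydrostatic pressure at
#' the depth of the volume. Defaults describe fresh water at 0.1 m depth.
#'
#' @param gamma Specific-heat ratio of the enclosed gas (dimensionless,
#'   must exceed 1). Default 1.4 (diatomic gas / air).
#' @param rho Water mass density in kg/m^3. Default 1000 (fresh water).
#' @param depth Depth of the air volume in metres. Default 0.1.
#' @param atmospheric_pressure Surface pressure in Pa. Default 101325.
#' @return An object of class `environment_spec` with fields `gamma`, `rho`,
#'   `depth`, `atmospheric_pressure` and the derived `pressure`
#'   (atmospheric + rho * g * depth, g = 9.81 m/s^2).
#' @examples
#' environment_spec()$pressure
#' @export
environment_spec <- function(gamma = 1.4, rho = 1000, depth = 0.1,
                             atmospheric_pressure = 101325) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 1)
    stop("'gamma' must be a single number > 1", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0)
    stop("'rho' must be a single positive number", call. = FALSE)
  if (!is.numeric(depth) || length(depth) != 1L || depth < 0)
    stop("'depth' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(atmospheric_pressure) || length(atmospheric_pressure) != 1L ||
      atmospheric_pressure <= 0)
    stop("'atmospheric_pressure' must be a single positive number", call. = FALSE)
  g <- 9.81
  structure(
    list(gamma = gamma, rho = rho, depth = depth,
         atmospheric_pressure = atmospheric_pressure,
         pressure = atmospheric_pressure + rho * g * depth),
    class = "environment_spec"
  )
}

#' @export
print.environment_spec <- function(x, ...) {
  cat("<environment_spec>\n")
  cat(sprintf("  gamma = %g, rho = %g kg/m^3, depth = %g m\n",
              x$gamma, x$rho, x$depth))
  cat(sprintf("  pressure = %g Pa (atmospheric %g Pa + hydrostatic)\n",
              x$pressure, x$atmospheric_pressure))
  invisible(x)
}

#' Bladder (air-volume) specification
#'
#' A spherical air volume of given radius, standing in for a swim bladder or
#' a balloon-in-pipe test volume. Radius follows the field convention of
#' centimetres; it is converted to metres internally where SI units are
#' required.
#'
#' @param radius Radius of the air volume in cm (positive).
#' @param label Identifier used in template banks and reports. Defaults to a
#'   string derived from the radius.
#' @return An object of class `bladder_spec`.
#' @examples
#' bladder_spec(3)
#' @export
bladder_spec <- function(radius, label = sprintf("R%gcm", radius)) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0)
    stop("'radius' must be a single positive number (cm)", call. = FALSE)
  structure(list(radius = radius, label = as.character(label)),
            class = "bladder_spec")
}

#' @export
print.bladder_spec <- function(x, ...) {
  cat(sprintf("<bladder_spec> %s: radius %g cm\n", x$label, x$radius))
  invisible(x)
}

#' Vocalization frame: forcing frequency and centred time grid
#'
#' Defines the time support of one vocalization record: a forcing frequency F
#' (the sonic-muscle drum rate) and a uniform time grid of `round(r * fs)`
#' samples centred on t = 0, i.e. `t_i = (i - (N - 1)/2) / fs` spanning
#' approximately \[-r/2, r/2\].
#'
#' @param forcing_frequency Forcing (fundamental) frequency F in Hz, positive.
#' @param record_length Record length r in seconds, positive.
#' @param fs Sampling rate in Hz, positive.
#' @return An object of class `vocalization_frame` with fields
#'   `forcing_frequency`, `record_length`, `fs` and `time_axis`.
#' @examples
#' vocalization_frame(185, 2, 10000)
#' @export
vocalization_frame <- function(forcing_frequency, record_length, fs) {
  if (!is.numeric(forcing_frequency) || length(forcing_frequency) != 1L ||
      forcing_frequency <= 0)
    stop("'forcing_frequency' must be a single positive number (Hz)",
         call. = FALSE)
  if (!is.numeric(record_length) || length(record_length) != 1L ||
      record_length <= 0)
    stop("'record_length' must be a single positive number (s)", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive number (Hz)", call. = FALSE)
  n <- round(record_length * fs)
  if (n < 1L) stop("record is empty: record_length * fs < 1", call. = FALSE)
  t <- (seq_len(n) - 1 - (n - 1) / 2) / fs
  structure(
    list(forcing_frequency = forcing_frequency, record_length = record_length,
         fs = fs, time_axis = t),
    class = "vocalization_frame"
  )
}

#' @export
print.vocalization_frame <- function(x, ...) {
  cat(sprintf("<vocalization_frame> F = %g Hz, r = %g s, fs = %g Hz (%d samples)\n",
              x$forcing_frequency, x$record_length, x$fs, length(x$time_axis)))
  invisible(x)
}

#' Resonance frequency of a spherical air volume in water
#'
#' The classic resonant-bubble (Minnaert) frequency
#' \deqn{f_0 = \frac{1}{2 \pi R} \sqrt{3 \gamma P / \rho}}
#' with R the radius in metres, gamma the specific-heat ratio, P the combined
#' atmospheric and hydrostatic pressure in Pa and rho the water density in
#' kg/m^3. The result decreases as 1/R: larger bladders ring lower.
#'
#' @param bladder A [bladder_spec()] (radius in cm).
#' @param env An [environment_spec()].
#' @return Resonance frequency f0 in Hz.
#' @examples
#' resonance_frequency(bladder_spec(1), environment_spec())  # ~330 Hz
#' @export
resonance_frequency <- function(bladder, env) {
  stopifnot(inherits(bladder, "bladder_spec"), inherits(env, "environment_spec"))
  if (bladder$radius <= 0) stop("'radius' must be positive", call. = FALSE)
  if (env$rho <= 0) stop("'rho' must be positive", call. = FALSE)
  if (env$pressure <= 0) stop("'pressure' must be positive", call. = FALSE)
  r_m <- bladder$radius / 100
  (1 / (2 * pi * r_m)) * sqrt(3 * env$gamma * env$pressure / env$rho)
}

#' Raised-cosine modulation envelope of a forced vocalization
#'
#' Models the swim bladder as an amplitude modulator acting on a vocalization
#' driven at forcing frequency F. With resonance f0 = [resonance_frequency()],
#' the envelope over the frame's centred time grid is the raised cosine
#' \deqn{M(t) = \left| 1 - a \, \frac{1 + \cos(2 \pi f_b t)}{2} \right|}
#' with modulation depth `a = f0 / (f0 + F)` and ripple frequency
#' `f_b = |F - f0|`. The depth decays both with increasing radius (f0 -> 0)
#' and with increasing forcing frequency, so a large bladder or a fast drum
#' rate drives the envelope to unity: an effectively all-pass filter. Driving
#' exactly at resonance (F = f0) gives a constant envelope 1 - a, the deepest
#' sustained modulation.
#'
#' @param frame A [vocalization_frame()].
#' @param bladder A [bladder_spec()].
#' @param env An [environment_spec()].
#' @return An object of class `modulation_envelope` with fields `values`
#'   (dimensionless gain per sample, in (0, 1\]), `frame`, `bladder`, `env`,
#'   `depth` (a), `ripple_frequency` (f_b) and `resonance` (f0).
#' @examples
#' env <- environment_spec()
#' m <- modulation_envelope(vocalization_frame(185, 2, 10000), bladder_spec(3), env)
#' range(m$values)
#' @export
modulation_envelope <- function(frame, bladder, env) {
  stopifnot(inherits(frame, "vocalization_frame"),
            inherits(bladder, "bladder_spec"),
            inherits(env, "environment_spec"))
  if (length(frame$time_axis) == 0L) stop("empty time grid", call. = FALSE)
  f0 <- resonance_frequency(bladder, env)
  F <- frame$forcing_frequency
  a <- f0 / (f0 + F)
  fb <- abs(F - f0)
  m <- abs(1 - a * (1 + cos(2 * pi * fb * frame$time_axis)) / 2)
  structure(
    list(values = m, frame = frame, bladder = bladder, env = env,
         depth = a, ripple_frequency = fb, resonance = f0),
    class = "modulation_envelope"
  )
}

#' @export
print.modulation_envelope <- function(x, ...) {
  cat(sprintf(
    "<modulation_envelope> R = %g cm: f0 = %.2f Hz, depth a = %.3f, ripple %.2f Hz\n",
    x$bladder$radius, x$resonance, x$depth, x$ripple_frequency))
  invisible(x)
}

#' Peak modulation depth over a radius x frequency grid
#'
#' Evaluates `sup_t |M(t) - 1|` of [modulation_envelope()] for every
#' combination of bladder radius and forcing frequency. The surface is
#' non-increasing along the radius axis at fixed frequency and along the
#' frequency axis at fixed radius — the envelope is driven to unity either
#' way.
#'
#' @param radii Vector of radii in cm (positive, non-empty).
#' @param frequencies Vector of forcing frequencies in Hz (positive,
#'   non-empty).
#' @param frame A [vocalization_frame()]; its forcing frequency is replaced
#'   by each grid value, its time grid is reused.
#' @param env An [environment_spec()].
#' @return Numeric matrix of peak modulation depths, radii in rows
#'   (rownames), frequencies in columns (colnames).
#' @examples
#' env <- environment_spec()
#' envelope_surface(1:4, c(100, 185, 400), vocalization_frame(185, 1, 2000), env)
#' @export
envelope_surface <- function(radii, frequencies, frame, env) {
  if (length(radii) == 0L || length(frequencies) == 0L)
    stop("'radii' and 'frequencies' must be non-empty", call. = FALSE)
  if (any(radii <= 0)) stop("'radii' must be positive", call. = FALSE)
  if (any(frequencies <= 0)) stop("'frequencies' must be positive", call. = FALSE)
  out <- matrix(NA_real_, nrow = length(radii), ncol = length(frequencies),
                dimnames = list(format(radii), format(frequencies)))
  for (j in seq_along(frequencies)) {
    fr <- vocalization_frame(frequencies[j], frame$record_length, frame$fs)
    for (i in seq_along(radii)) {
      m <- modulation_envelope(fr, bladder_spec(radii[i]), env)
      out[i, j] <- max(abs(m$values - 1))
    }
  }
  out
}
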