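# Orchestration: template-bank construction, two-method classification and
# the in-silico reproduction of the four-pipe playback experiment.

default_method_params <- function(fs = 10000) {
  list(
    band = roi_band(150, 200),
    stft_window = 128L,
    stft_overlap = 0.75,
    alpha_grid = default_alpha_grid(),
    nfft = 256L,
    scd_overlap = 7 / 8
  )
}

#' The four default test volumes
#'
#' Radii 1.5, 2, 3 and 4 cm, the air-volume radii corresponding to pipe/air
#' diameters of 3, 4, 6 and 8 cm used in the playback experiment.
#'
#' @return A list of [bladder_spec()]s.
#' @export
default_volumes <- function() {
  lapply(c(1.5, 2, 3, 4), bladder_spec)
}

# Method feature of one received record. Method 1: ROI time series of the
# carrier residual. Method 2: coherent spectrum (template needs x and y).
extract_feature <- function(record, method, F, params, role = "input",
                            source = NULL) {
  y <- am_ssb_demodulate(record, F)
  if (method == "demod") {
    res <- carrier_residual(record, y, F)
    roi_mean(stft(res, params$stft_window, params$stft_overlap), params$band)
  } else {
    if (role == "template")
      coherent_spectrum_template(record, y, params$alpha_grid, params$nfft,
                                 params$scd_overlap, source = source)
    else
      coherent_spectrum_input(record, params$alpha_grid, params$nfft,
                              params$scd_overlap, source = source)
  }
}

#' Build a per-volume template bank
#'
#' Synthesizes the transmitted record for each candidate volume (the common
#' growl source passed through that volume) and derives the method's template
#' feature: the ROI time series of the carrier residual for method 1
#' (`"demod"`), or the coherent spectrum T for method 2 (`"cyclo"`). This is
#' the matched-filter set against which unknown records are correlated.
#'
#' @param volumes List of [bladder_spec()]s with unique labels.
#' @param growl A [growl_spec()] describing the common source vocalization.
#' @param env An [environment_spec()].
#' @param F Forcing/carrier frequency in Hz. Default: the growl fundamental.
#' @param fs Sampling rate in Hz. Default 10000.
#' @param duration Record length in s. Default 2.
#' @param method `"demod"` or `"cyclo"`.
#' @param params Method parameters, see `default_method_params()`; entries
#'   given here override the defaults.
#' @return An object of class `template_bank`: `method`, `entries` (each with
#'   `label`, `radius`, `feature`, `meta`), `params`, `F`, `fs`, `duration`,
#'   `env`, `growl`.
#' @export
build_bank <- function(volumes, growl, env, F = growl$fundamental,
                       fs = 10000, duration = 2,
                       method = c("demod", "cyclo"), params = list()) {
  method <- match.arg(method)
  if (length(volumes) < 1L) stop("need at least one volume", call. = FALSE)
  labels <- vapply(volumes, function(v) v$label, character(1))
  if (anyDuplicated(labels))
    stop("duplicate volume labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  p <- utils::modifyList(default_method_params(fs), params)
  src <- generate_growl(growl, fs = fs, duration = duration)
  entries <- lapply(volumes, function(v) {
    rec <- transmit_through_volume(src, v, env, F)
    list(label = v$label, radius = v$radius,
         feature = extract_feature(rec, method, F, p, role = "template",
                                   source = v$label),
         meta = list(seed = growl$seed, radius_cm = v$radius, F = F,
                     fs = fs, duration = duration, params = p))
  })
  structure(
    list(method = method, entries = entries, params = p, F = F, fs = fs,
         duration = duration, env = env, growl = growl),
    class = "template_bank"
  )
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf("<template_bank:%s> %d volumes @ F = %g Hz:\n",
              x$method, length(x$entries), x$F))
  for (e in x$entries)
    cat(sprintf("  %s (%g cm)\n", e$label, e$radius))
  invisible(x)
}

#' Classify a record against a template bank
#'
#' Extracts the bank method's feature from the record, correlates it against
#' every template ([z1_correlate()] or [z2_correlate()]), and reports the
#' peak correlation per template and the winning label. Ties are broken
#' toward the smaller radius with a warning.
#'
#' @param record An [acoustic_record()] at the bank's sampling rate.
#' @param bank A [build_bank()] template bank.
#' @return An object of class `classification_report`: `table` (data.frame
#'   of label, radius, peak correlation), `best_label`, `best_radius`,
#'   `margin` (best minus runner-up peak; `NA` for a single-entry bank) and
#'   `method`.
#' @export
classify <- function(record, bank) {
  stopifnot(inherits(record, "acoustic_record"), inherits(bank, "template_bank"))
  if (length(bank$entries) == 0L) stop("empty template bank", call. = FALSE)
  if (record$fs != bank$fs)
    stop("record sampling rate ", record$fs, " differs from bank rate ",
         bank$fs, call. = FALSE)
  feat <- tryCatch(
    extract_feature(record, bank$method, bank$F, bank$params, role = "input"),
    error = function(e) stop("feature extraction failed (", bank$method,
                             "): ", conditionMessage(e), call. = FALSE))
  peaks <- vapply(bank$entries, function(e) {
    cs <- tryCatch(
      if (bank$method == "demod") z1_correlate(feat, e$feature)
      else z2_correlate(feat, e$feature, bank$params$band),
      error = function(err) stop("correlation against template '", e$label,
                                 "' failed: ", conditionMessage(err),
                                 call. = FALSE))
    max(cs$values)
  }, numeric(1))
  tab <- data.frame(
    label = vapply(bank$entries, `[[`, character(1), "label"),
    radius = vapply(bank$entries, `[[`, numeric(1), "radius"),
    peak = peaks
  )
  best <- which(peaks == max(peaks))
  if (length(best) > 1L) {
    warning("tied peak correlations; choosing the smaller radius")
    best <- best[which.min(tab$radius[best])]
  }
  margin <- if (nrow(tab) > 1L)
    max(peaks) - max(peaks[-best]) else NA_real_
  structure(
    list(table = tab, best_label = tab$label[best],
         best_radius = tab$radius[best], margin = margin,
         method = bank$method),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report:%s> best: %s (margin %.4f)\n",
              x$method, x$best_label,
              if (is.na(x$margin)) NA else x$margin))
  print(x$table, row.names = FALSE)
  invisible(x)
}
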