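#' Spike-detection configuration
#'
#' Defaults follow the offline detection procedure used for the
#' supported datasets: 300-3000 Hz Chebyshev type-II band-pass of order
#' 6 with 20 dB stopband attenuation, a manually set trigger applied to
#' the filtered trace, and optional per-trial trigger overrides.
#'
#' @param band_low_hz,band_high_hz Pass-band edges (Hz).
#' @param filter_order Overall order of the band-pass filter (even).
#' @param stopband_atten_db Stopband attenuation (dB), the `Rs`
#'   parameter of the Chebyshev type-II design.
#' @param trigger_level Global trigger on the filtered trace; positive
#'   values trigger on positive peaks (see `polarity`).
#' @param per_trial_overrides Named list / numeric vector mapping trial
#'   index to a trigger that replaces the global one for that trial.
#' @param polarity `+1` to trigger on positive excursions, `-1` on
#'   negative ones.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(band_low_hz = 300, band_high_hz = 3000,
                             filter_order = 6, stopband_atten_db = 20,
                             trigger_level = NA_real_,
                             per_trial_overrides = NULL, polarity = 1) {
  stopifnot(band_low_hz > 0, band_high_hz > band_low_hz,
            filter_order >= 2, filter_order %% 2 == 0,
            stopband_atten_db > 0, polarity %in% c(-1, 1))
  structure(list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 filter_order = filter_order,
                 stopband_atten_db = stopband_atten_db,
                 trigger_level = trigger_level,
                 per_trial_overrides = per_trial_overrides,
                 polarity = polarity),
            class = "detection_config")
}

#' Zero-phase Chebyshev type-II band-pass filter
#'
#' The filter is applied forward and backward (`signal::filtfilt`) so
#' the phase response is zero and spike-peak times are not biased by
#' filtering. The trace is extended by reflection over one settling
#' length before filtering to suppress edge transients; output length
#' equals input length.
#'
#' @param trace Numeric samples.
#' @param sample_rate_hz Sampling rate (Hz); must exceed twice the upper
#'   band edge.
#' @param cfg A [detection_config].
#' @return Filtered samples, same length as `trace`.
#' @export
bandpass_filter <- function(trace, sample_rate_hz,
                            cfg = detection_config()) {
  if (sample_rate_hz <= 2 * cfg$band_high_hz) {
    abort_anf("sample rate must exceed twice the upper band edge",
              "anfiber_filter_error")
  }
  if (length(trace) <= 3 * cfg$filter_order) {
    abort_anf("trace too short to filter", "anfiber_filter_error")
  }
  # a band-pass of total order N needs design order N/2
  flt <- signal::cheby2(cfg$filter_order / 2, cfg$stopband_atten_db,
                        c(cfg$band_low_hz, cfg$band_high_hz) /
                          (sample_rate_hz / 2), type = "pass")
  pad <- min(length(trace) - 1L,
             max(3L * cfg$filter_order,
                 round(3 * sample_rate_hz / cfg$band_low_hz)))
  n <- length(trace)
  ext <- c(2 * trace[1] - trace[(pad + 1):2],
           trace,
           2 * trace[n] - trace[(n - 1):(n - pad)])
  out <- signal::filtfilt(flt, ext)
  out[(pad + 1):(pad + n)]
}

#' Detect spikes as peaks of supra-trigger excursions
#'
#' Every contiguous run of samples exceeding the trigger yields exactly
#' one spike, at the sample index of the run's maximum; the spike time
#' is `(index - 1) / sample_rate_hz` (the first sample is time 0).
#'
#' @param filtered Filtered samples.
#' @param sample_rate_hz Sampling rate (Hz).
#' @param trigger Positive trigger level.
#' @param polarity `+1` for positive excursions, `-1` to detect on the
#'   inverted trace.
#' @return Sorted spike times in seconds; empty when nothing crosses.
#' @export
detect_spikes <- function(filtered, sample_rate_hz, trigger, polarity = 1) {
  stopifnot(is_scalar_number(sample_rate_hz), polarity %in% c(-1, 1))
  if (!is.finite(trigger)) return(numeric(0))
  if (trigger <= 0) abort_anf("trigger must be positive",
                              "anfiber_invariant_error")
  x <- polarity * filtered
  above <- x > trigger
  if (!any(above)) return(numeric(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  idx <- vapply(runs, function(k) {
    seg <- starts[k]:ends[k]
    seg[which.max(x[seg])]
  }, integer(1))
  (idx - 1) / sample_rate_hz
}

#' Extract spike-aligned waveform snippets
#'
#' Each snippet is centred on the spike-peak sample and spans the given
#' window (default -1.3 to +1.3 ms). Spikes too close to the trace
#' edges are skipped; their count is attached as attribute `n_skipped`.
#'
#' @param filtered Samples the spikes were detected on.
#' @param spike_times_s Spike times in seconds.
#' @param sample_rate_hz Sampling rate (Hz).
#' @param window_ms Length-2 window around the peak (ms).
#' @return A list of equal-length numeric snippets with attribute
#'   `n_skipped`.
#' @export
extract_snippets <- function(filtered, spike_times_s, sample_rate_hz,
                             window_ms = c(-1.3, 1.3)) {
  lo <- round(window_ms[1] / 1000 * sample_rate_hz)
  # snippet length is round(window span * fs) + 1, peak at index -lo + 1
  hi <- lo + round((window_ms[2] - window_ms[1]) / 1000 * sample_rate_hz)
  out <- list()
  n_skipped <- 0L
  for (t in spike_times_s) {
    centre <- round(t * sample_rate_hz) + 1L
    if (centre + lo < 1L || centre + hi > length(filtered)) {
      n_skipped <- n_skipped + 1L
      next
    }
    out[[length(out) + 1L]] <- filtered[(centre + lo):(centre + hi)]
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Run spike detection over all trials of a raw recording
#'
#' Filters each trace, applies the global trigger (or a per-trial
#' override), and returns the detected spike trains as a trial table
#' plus the spike-aligned snippets. The effective trigger per trial is
#' recorded, mirroring how offline-detection settings are stored in the
#' supported datasets.
#'
#' @param raw An [an_raw] object.
#' @param cfg A [detection_config]; its `trigger_level` must be set
#'   unless every trial has an override.
#' @param stim_freq_hz,stim_level_db Optional per-trial stimulus
#'   variables to carry into the trial table.
#' @param trial_duration_s Trial duration (s); defaults to trace length
#'   over sampling rate.
#' @return List with `trials` ([an_trials]), `snippets` (list over
#'   trials), and `effective_trigger` (numeric per trial).
#' @export
run_detection <- function(raw, cfg, stim_freq_hz = NULL,
                          stim_level_db = NULL, trial_duration_s = NULL) {
  if (is.null(raw) || !inherits(raw, "an_raw")) {
    abort_anf("run_detection needs raw voltage traces", "anfiber_raw_error")
  }
  n <- length(raw$traces)
  fs <- raw$sample_rate_hz
  trig <- rep(cfg$trigger_level, n)
  ov <- cfg$per_trial_overrides
  if (!is.null(ov)) {
    ii <- as.integer(names(ov) %||% seq_along(ov))
    trig[ii] <- as.numeric(unlist(ov))
  }
  if (any(is.na(trig))) {
    abort_anf("no trigger level set for some trials", "anfiber_raw_error")
  }
  dur <- trial_duration_s %||% (length(raw$traces[[1]]) / fs)
  spikes <- vector("list", n)
  snippets <- vector("list", n)
  for (i in seq_len(n)) {
    filt <- bandpass_filter(raw$traces[[i]], fs, cfg)
    st <- detect_spikes(filt, fs, trig[i], polarity = cfg$polarity)
    spikes[[i]] <- st
    snippets[[i]] <- extract_snippets(filt, st, fs)
  }
  trials <- an_trials(spike_times = spikes,
                      stim_freq_hz = stim_freq_hz %||% rep(NA_real_, n),
                      stim_level_db = stim_level_db %||% rep(NA_real_, n),
                      trial_duration_s = dur)
  list(trials = trials, snippets = snippets, effective_trigger = trig)
}
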