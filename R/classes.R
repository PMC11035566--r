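#' Recording types
#'
#' The closed set of protocol labels used for single-fibre recordings:
#' `BF` (frequency-response curve at fixed level), `RLF` (rate-level
#' function at best frequency), `CF` (frequency x level response field),
#' `PH` (phase locking: few levels, many repetitions), `CLICK`
#' (condensation clicks), `SR` (spontaneous rate in silence), and the
#' complex-stimulus types `NOISE`, `SPS` (Schroeder-phase) and `CVC`
#' (consonant-vowel-consonant logatomes).
#'
#' @return Character vector of the valid type labels.
#' @export
recording_types <- function() {
  c("BF", "RLF", "CF", "PH", "CLICK", "SR", "NOISE", "SPS", "CVC")
}

tonal_types <- function() c("BF", "RLF", "CF", "PH")
complex_types <- function() c("NOISE", "SPS", "CVC")

check_rec_type <- function(rec_type) {
  if (!is.character(rec_type) || length(rec_type) != 1L ||
      !rec_type %in% recording_types()) {
    abort_anf(paste0("rec_type must be one of: ",
                     paste(recording_types(), collapse = ", ")),
              "anfiber_type_error")
  }
  rec_type
}

#' Recording settings
#'
#' Timing and acquisition parameters shared by all trials of a recording.
#' Times are in seconds from trial start; the stimulus occupies
#' `[stim_onset_s, stim_onset_s + stim_duration_s]`.
#'
#' @param trial_duration_s Total acquired duration of each trial (s).
#' @param stim_onset_s Stimulus onset relative to trial start (s).
#' @param stim_duration_s Stimulus duration (s).
#' @param sample_rate_hz Sampling rate of any raw voltage traces (Hz);
#'   defaults to 48828, the acquisition rate of the supported datasets.
#' @param extras Named list of unmodelled settings (ramps, attenuation,
#'   randomization flags, offline-analysis metadata, ...), kept verbatim.
#' @return An object of class `an_settings`.
#' @export
an_settings <- function(trial_duration_s, stim_onset_s = 0,
                        stim_duration_s = trial_duration_s,
                        sample_rate_hz = 48828, extras = list()) {
  stopifnot(is_scalar_number(trial_duration_s), trial_duration_s > 0,
            is_scalar_number(stim_onset_s), stim_onset_s >= 0,
            is_scalar_number(stim_duration_s), stim_duration_s > 0,
            is_scalar_number(sample_rate_hz), sample_rate_hz > 0,
            is.list(extras))
  if (stim_onset_s + stim_duration_s > trial_duration_s + 1e-12) {
    abort_anf("stim_onset_s + stim_duration_s must not exceed trial_duration_s",
              "anfiber_invariant_error")
  }
  structure(list(trial_duration_s = trial_duration_s,
                 stim_onset_s = stim_onset_s,
                 stim_duration_s = stim_duration_s,
                 sample_rate_hz = sample_rate_hz,
                 extras = extras),
            class = "an_settings")
}

#' Trial table
#'
#' One row per trial. Spike times are seconds from trial start, sorted
#' ascending. Silent trials carry `NA` for both stimulus frequency and
#' level.
#'
#' @param spike_times List of numeric vectors, one per trial.
#' @param stim_freq_hz,stim_level_db Numeric per trial; `NA` for silent
#'   trials.
#' @param repetition_index Integer repetition counter per unique stimulus
#'   condition (1-based).
#' @param duration_s Optional per-trial acquired duration; defaults to
#'   `trial_duration_s` and is used to detect truncated trials in
#'   complex-stimulus bookkeeping.
#' @param trial_duration_s Nominal duration used to validate spike times.
#' @return A `data.frame` of class `an_trials`.
#' @export
an_trials <- function(spike_times, stim_freq_hz, stim_level_db,
                      repetition_index = NULL, duration_s = NULL,
                      trial_duration_s = NULL) {
  stopifnot(is.list(spike_times))
  n <- length(spike_times)
  if (n == 0L) abort_anf("a trial set must contain at least one trial",
                         "anfiber_invariant_error")
  stim_freq_hz <- as.numeric(stim_freq_hz)
  stim_level_db <- as.numeric(stim_level_db)
  stopifnot(length(stim_freq_hz) == n, length(stim_level_db) == n)
  if (any(xor(is.na(stim_freq_hz), is.na(stim_level_db)))) {
    abort_anf("silent trials must have NA for both frequency and level",
              "anfiber_invariant_error")
  }
  repetition_index <- as.integer(repetition_index %||% seq_len(n))
  duration_s <- as.numeric(duration_s %||% rep(trial_duration_s %||% NA_real_, n))
  for (i in seq_len(n)) {
    st <- as.numeric(spike_times[[i]])
    if (is.unsorted(st)) abort_anf(
      sprintf("spike times of trial %d are not sorted", i),
      "anfiber_invariant_error")
    if (!is.null(trial_duration_s) && length(st) &&
        (any(st < 0) || any(st > trial_duration_s))) {
      abort_anf(sprintf(
        "trial %d has spike times outside [0, %g] s", i, trial_duration_s),
        "anfiber_invariant_error")
    }
    spike_times[[i]] <- st
  }
  out <- data.frame(stim_freq_hz = stim_freq_hz,
                    stim_level_db = stim_level_db,
                    repetition_index = repetition_index,
                    duration_s = duration_s)
  out$spike_times <- spike_times
  class(out) <- c("an_trials", "data.frame")
  out
}

#' @export
is_silent <- function(trials) {
  is.na(trials$stim_freq_hz) & is.na(trials$stim_level_db)
}

#' Raw voltage traces
#'
#' @param traces List of numeric vectors (one per trial, arbitrary units).
#' @param trigger_level Per-trial spike trigger used (or to be used) for
#'   detection; recycled if scalar.
#' @param sample_rate_hz Sampling rate (Hz).
#' @return An object of class `an_raw`.
#' @export
an_raw <- function(traces, trigger_level = NA_real_, sample_rate_hz = 48828) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  trigger_level <- rep_len(as.numeric(trigger_level), length(traces))
  structure(list(traces = traces, trigger_level = trigger_level,
                 sample_rate_hz = sample_rate_hz),
            class = "an_raw")
}

#' Single recording of one protocol on one fibre
#'
#' @param rec_type One of [recording_types()].
#' @param trials An [an_trials] table.
#' @param settings An [an_settings] object.
#' @param filename Original acquisition file name (free text).
#' @param raw Optional [an_raw] traces.
#' @param analysis Optional named list of analysed outcomes (filled by
#'   [analyze_recording()]).
#' @return An object of class `an_recording`.
#' @export
an_recording <- function(rec_type, trials, settings, filename = "",
                         raw = NULL, analysis = NULL) {
  check_rec_type(rec_type)
  stopifnot(inherits(trials, "an_trials"), inherits(settings, "an_settings"))
  if (!is.null(raw)) {
    stopifnot(inherits(raw, "an_raw"))
    expected <- round(settings$trial_duration_s * settings$sample_rate_hz)
    for (tr in raw$traces) {
      if (abs(length(tr) - expected) > 1) {
        abort_anf(sprintf(
          "raw trace has %d samples; expected %d (+/-1) from settings",
          length(tr), expected), "anfiber_invariant_error")
      }
    }
  }
  structure(list(rec_type = rec_type, filename = filename, trials = trials,
                 settings = settings, raw = raw, analysis = analysis),
            class = "an_recording")
}

#' Single-unit record: all recordings from one fibre
#'
#' @param unit_name Unique name of the fibre within its experiment.
#' @param recordings Named list of [an_recording] objects, keyed by
#'   recording type; at least one required.
#' @return An object of class `an_unit`.
#' @export
an_unit <- function(unit_name, recordings) {
  stopifnot(is.character(unit_name), nzchar(unit_name), is.list(recordings))
  if (length(recordings) == 0L) {
    abort_anf("a unit must hold at least one recording",
              "anfiber_invariant_error")
  }
  nm <- names(recordings)
  if (is.null(nm) || any(!nzchar(nm))) {
    nm <- vapply(recordings, function(r) r$rec_type, character(1))
    names(recordings) <- nm
  }
  for (k in nm) {
    check_rec_type(k)
    stopifnot(inherits(recordings[[k]], "an_recording"))
    if (recordings[[k]]$rec_type != k) {
      abort_anf(sprintf("recording stored under '%s' has rec_type '%s'",
                        k, recordings[[k]]$rec_type),
                "anfiber_invariant_error")
    }
  }
  if (anyDuplicated(nm)) abort_anf("duplicate recording types within a unit",
                                   "anfiber_invariant_error")
  structure(list(unit_name = unit_name, recordings = recordings),
            class = "an_unit")
}

#' Experiment metadata
#'
#' @param sex `"F"` or `"M"` (or `NA`).
#' @param age_months Age at recording (months), positive.
#' @param weight_g Body weight (grams).
#' @param abr_threshold_dbspl Auditory-brainstem-response threshold
#'   (dB SPL), the whole-animal hearing-sensitivity estimate; must lie in
#'   \[0, 120\] when present.
#' @param sound_system,recording_system Free-text hardware identifiers.
#' @param anesthesia_notes Free text.
#' @param extras Named list of unmodelled metadata, kept verbatim.
#' @return An object of class `an_info`.
#' @export
an_info <- function(sex = NA_character_, age_months, weight_g = NA_real_,
                    abr_threshold_dbspl = NA_real_, sound_system = "",
                    recording_system = "", anesthesia_notes = "",
                    extras = list()) {
  if (!is.na(sex) && !sex %in% c("F", "M")) {
    abort_anf("sex must be 'F', 'M' or NA", "anfiber_type_error")
  }
  stopifnot(is_scalar_number(age_months))
  if (age_months <= 0) abort_anf("age_months must be positive",
                                 "anfiber_invariant_error")
  if (!is.na(abr_threshold_dbspl) &&
      (abr_threshold_dbspl < 0 || abr_threshold_dbspl > 120)) {
    abort_anf("abr_threshold_dbspl must lie in [0, 120]",
              "anfiber_invariant_error")
  }
  structure(list(sex = sex, age_months = age_months, weight_g = weight_g,
                 abr_threshold_dbspl = abr_threshold_dbspl,
                 sound_system = sound_system,
                 recording_system = recording_system,
                 anesthesia_notes = anesthesia_notes, extras = extras),
            class = "an_info")
}

#' Experiment: one animal with its metadata and units
#'
#' @param animal_id Non-empty identifier string.
#' @param info An [an_info] object.
#' @param units List of [an_unit] objects with unique names.
#' @return An object of class `an_experiment`.
#' @export
an_experiment <- function(animal_id, info, units) {
  stopifnot(is.character(animal_id), nzchar(animal_id),
            inherits(info, "an_info"), is.list(units))
  if (length(units) == 0L) {
    abort_anf("an experiment must hold at least one unit",
              "anfiber_invariant_error")
  }
  for (u in units) stopifnot(inherits(u, "an_unit"))
  nm <- vapply(units, function(u) u$unit_name, character(1))
  if (anyDuplicated(nm)) {
    abort_anf("unit names must be unique within an experiment",
              "anfiber_invariant_error")
  }
  names(units) <- nm
  structure(list(animal_id = animal_id, info = info, units = units),
            class = "an_experiment")
}

#' @export
print.an_experiment <- function(x, ...) {
  cat(sprintf("<an_experiment> %s: %d unit(s); age %.1f months, sex %s\n",
              x$animal_id, length(x$units), x$info$age_months,
              x$info$sex))
  for (u in x$units) {
    cat(sprintf("  %s: %s\n", u$unit_name,
                paste(names(u$recordings), collapse = " ")))
  }
  invisible(x)
}

#' @export
print.an_recording <- function(x, ...) {
  cat(sprintf("<an_recording> %s: %d trial(s), %.3g s each%s%s\n",
              x$rec_type, nrow(x$trials), x$settings$trial_duration_s,
              if (!is.null(x$raw)) ", raw traces" else "",
              if (!is.null(x$analysis)) ", analysed" else ""))
  invisible(x)
}

#' Assign an animal to an age group
#'
#' Groups follow the study's definition for quiet-raised gerbils:
#' young-adult below 12 months, middle-aged from 12 to 36 months
#' (both boundaries inclusive), old strictly above 36 months.
#'
#' @param age_months Positive age(s) in months.
#' @return Factor with levels `young`, `middle`, `old`.
#' @export
#' @examples
#' assign_age_group(c(5.5, 12, 36, 38.3))
assign_age_group <- function(age_months) {
  age_months <- as.numeric(age_months)
  if (any(!is.finite(age_months)) || any(age_months <= 0)) {
    abort_anf("age_months must be positive and finite",
              "anfiber_invariant_error")
  }
  out <- ifelse(age_months < 12, "young",
                ifelse(age_months <= 36, "middle", "old"))
  factor(out, levels = c("young", "middle", "old"))
}
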