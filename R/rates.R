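count_in_window <- function(times, lo, hi) {
  # half-open window [lo, hi)
  sum(times >= lo & times < hi)
}

#' Per-trial and per-condition tone-evoked spike rates
#'
#' Counts spikes in the half-open stimulus window
#' `[onset, onset + duration)` per trial, divides by the stimulus
#' duration, and averages over the repetitions of each unique
#' frequency-level combination. Silent trials are excluded from the
#' condition averages.
#'
#' @param trials An [an_trials] table.
#' @param onset_s,duration_s Stimulus window (s); typically from the
#'   recording settings.
#' @return List with `per_trial` (rate per trial, spikes/s; `NA` for
#'   silent trials is not used — silent trials get their spontaneous
#'   rate over the same window) and `stats`, a `data.frame` of class
#'   `rate_stats` with one row per condition: `stim_freq_hz`,
#'   `stim_level_db`, `mean_rate`, `sd_rate`, `n_reps`.
#' @export
trial_rates <- function(trials, onset_s, duration_s) {
  if (!is_scalar_number(duration_s) || duration_s <= 0) {
    abort_anf("duration_s must be positive", "anfiber_invariant_error")
  }
  per_trial <- vapply(trials$spike_times, count_in_window,
                      numeric(1), onset_s, onset_s + duration_s) / duration_s
  tonal <- !is_silent(trials)
  if (any(tonal)) {
    key <- paste(trials$stim_freq_hz[tonal], trials$stim_level_db[tonal],
                 sep = "@")
    grp <- split(per_trial[tonal], key)
    first <- !duplicated(key)
    ord <- order(trials$stim_freq_hz[tonal][first],
                 trials$stim_level_db[tonal][first])
    ukey <- key[first][ord]
    stats <- data.frame(
      stim_freq_hz = trials$stim_freq_hz[tonal][first][ord],
      stim_level_db = trials$stim_level_db[tonal][first][ord],
      mean_rate = vapply(grp[ukey], mean, numeric(1)),
      sd_rate = vapply(grp[ukey], stats::sd, numeric(1)),
      n_reps = vapply(grp[ukey], length, integer(1)),
      row.names = NULL)
  } else {
    stats <- data.frame(stim_freq_hz = numeric(0),
                        stim_level_db = numeric(0), mean_rate = numeric(0),
                        sd_rate = numeric(0), n_reps = integer(0))
  }
  class(stats) <- c("rate_stats", "data.frame")
  list(per_trial = per_trial, stats = stats)
}

#' Spontaneous rate from silent trials
#'
#' Computed over the total trial duration (not the stimulus window):
#' per-silent-trial rate = spike count / trial duration, then mean and
#' SD over those trials. For an `SR` recording every trial counts as
#' silent.
#'
#' @param recording An [an_recording] with silent trials or of type
#'   `SR`.
#' @return List of class `spontaneous_rate`: `sr_mean`, `sr_sd`
#'   (spikes/s), `total_silent_time_s`, `n_trials`, `source` (the
#'   recording type).
#' @export
spontaneous_rate <- function(recording) {
  stopifnot(inherits(recording, "an_recording"))
  silent <- if (recording$rec_type == "SR") {
    rep(TRUE, nrow(recording$trials))
  } else {
    is_silent(recording$trials)
  }
  if (!any(silent)) {
    abort_anf(sprintf("recording of type %s has no silent trials",
                      recording$rec_type), "anfiber_no_sr_error")
  }
  dur <- recording$settings$trial_duration_s
  counts <- vapply(recording$trials$spike_times[silent], length, integer(1))
  rates <- counts / dur
  structure(list(sr_mean = mean(rates),
                 sr_sd = if (length(rates) > 1) stats::sd(rates) else 0,
                 total_silent_time_s = dur * sum(silent),
                 n_trials = sum(silent),
                 source = recording$rec_type),
            class = "spontaneous_rate")
}

#' Peristimulus time histogram
#'
#' Pooled over the selected trials and converted to spikes/s per bin:
#' `rate = count / (n_trials * bin_width)`. The conservation identity
#' `sum(rates) * bin_width * n_trials == total spikes in the window`
#' holds exactly.
#'
#' @param trials An [an_trials] table.
#' @param bin_width_s Bin width (s); 0.005 is the convention for
#'   complex-stimulus summaries.
#' @param window Length-2 histogram window (s from trial start).
#' @param level_select Optional `list(target_level =, tolerance =)`;
#'   keeps trials with `|level - target| <= tolerance` (default
#'   tolerance 5 dB). Silent trials are dropped whenever a selection is
#'   given.
#' @return List of class `an_psth`: `bin_centers_s`, `rates`,
#'   `bin_width_s`, `n_trials`.
#' @export
make_psth <- function(trials, bin_width_s = 0.005,
                      window = c(0, max(trials$duration_s, na.rm = TRUE)),
                      level_select = NULL) {
  if (!is_scalar_number(bin_width_s) || bin_width_s <= 0) {
    abort_anf("bin_width_s must be positive", "anfiber_invariant_error")
  }
  keep <- rep(TRUE, nrow(trials))
  if (!is.null(level_select)) {
    tol <- level_select$tolerance %||% 5
    keep <- !is.na(trials$stim_level_db) &
      abs(trials$stim_level_db - level_select$target_level) <= tol
  }
  n_trials <- sum(keep)
  edges <- seq(window[1], window[2] + bin_width_s / 2, by = bin_width_s)
  if (utils::tail(edges, 1) < window[2]) edges <- c(edges, window[2])
  nb <- length(edges) - 1L
  counts <- integer(nb)
  for (st in trials$spike_times[keep]) {
    st <- st[st >= window[1] & st < utils::tail(edges, 1)]
    if (length(st)) {
      bin <- pmin(floor((st - window[1]) / bin_width_s) + 1L, nb)
      tab <- tabulate(bin, nbins = nb)
      counts <- counts + tab
    }
  }
  rates <- if (n_trials > 0) counts / (n_trials * bin_width_s) else
    rep(NaN, nb)
  structure(list(bin_centers_s = (edges[-length(edges)] + edges[-1]) / 2,
                 rates = rates, bin_width_s = bin_width_s,
                 n_trials = n_trials, counts = counts),
            class = "an_psth")
}

#' Combined tone-burst PSTH of a unit near one level
#'
#' Pools trials from the tonal recordings (`BF`, `RLF`, `PH`) whose
#' level is at or close to the target, the standard visualization for
#' judging a primary-like response shape.
#'
#' @param unit An [an_unit].
#' @param target_level Level of interest (dB SPL), e.g. threshold + 20.
#' @param tolerance Level tolerance (dB); default 5.
#' @param bin_width_s Bin width (s).
#' @return An `an_psth` (see [make_psth()]), pooled across recordings;
#'   `NULL` when no trial qualifies.
#' @export
unit_tone_psth <- function(unit, target_level, tolerance = 5,
                           bin_width_s = 0.005) {
  stopifnot(inherits(unit, "an_unit"))
  picks <- list()
  dur <- Inf
  for (ty in c("BF", "RLF", "PH")) {
    rec <- unit$recordings[[ty]]
    if (is.null(rec)) next
    keep <- !is.na(rec$trials$stim_level_db) &
      abs(rec$trials$stim_level_db - target_level) <= tolerance
    if (!any(keep)) next
    picks[[ty]] <- rec$trials[keep, , drop = FALSE]
    dur <- min(dur, rec$settings$trial_duration_s)
  }
  if (!length(picks)) return(NULL)
  merged <- do.call(rbind, picks)
  class(merged) <- c("an_trials", "data.frame")
  make_psth(merged, bin_width_s = bin_width_s, window = c(0, dur))
}

#' Trial bookkeeping and PSTH for complex-stimulus recordings
#'
#' A trial is included when its acquisition is complete, i.e. its
#' recorded duration matches the nominal trial duration (within
#' `tol_s`). Returns the included-trial indices and the pooled 5-ms
#' PSTH over those trials.
#'
#' @param recording An [an_recording] of type `NOISE`, `SPS` or `CVC`.
#' @param bin_width_s PSTH bin width (s).
#' @param tol_s Duration tolerance for completeness (s).
#' @return List: `ntrials`, `trials` (included indices), `psth`.
#' @export
analyze_complex <- function(recording, bin_width_s = 0.005, tol_s = 1e-6) {
  stopifnot(inherits(recording, "an_recording"))
  if (!recording$rec_type %in% complex_types()) {
    abort_anf("analyze_complex expects a NOISE, SPS or CVC recording",
              "anfiber_type_error")
  }
  nominal <- recording$settings$trial_duration_s
  dur <- recording$trials$duration_s
  dur[is.na(dur)] <- nominal
  included <- which(abs(dur - nominal) <= tol_s)
  sub <- recording$trials[included, , drop = FALSE]
  class(sub) <- c("an_trials", "data.frame")
  psth <- make_psth(sub, bin_width_s = bin_width_s, window = c(0, nominal))
  list(ntrials = length(included), trials = included, psth = psth)
}
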