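# Small hand-built fixtures used across test files.

make_trials <- function(spikes, freqs = NULL, levels = NULL, dur = 1) {
  n <- length(spikes)
  an_trials(spike_times = spikes,
            stim_freq_hz = freqs %||% rep(NA_real_, n),
            stim_level_db = levels %||% rep(NA_real_, n),
            trial_duration_s = dur)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_recording <- function(rec_type = "SR", spikes = list(numeric(0)),
                           freqs = NULL, levels = NULL, dur = 1,
                           onset = 0, stim_dur = dur, raw = NULL) {
  an_recording(rec_type,
               trials = make_trials(spikes, freqs, levels, dur),
               settings = an_settings(trial_duration_s = dur,
                                      stim_onset_s = onset,
                                      stim_duration_s = stim_dur),
               raw = raw)
}

make_unit <- function(name = "u1", recs = NULL) {
  an_unit(name, recs %||% list(SR = make_recording()))
}

make_experiment <- function(id = "G001", age = 6, units = NULL) {
  an_experiment(id, an_info(sex = "F", age_months = age),
                units %||% list(make_unit()))
}

# rate_stats frame straight from numbers (bypasses trial counting)
make_rate_stats <- function(levels = NULL, freqs = NULL, rates,
                            sds = 0, n_reps = 5L) {
  n <- length(rates)
  out <- data.frame(stim_freq_hz = freqs %||% rep(1000, n),
                    stim_level_db = levels %||% rep(40, n),
                    mean_rate = rates,
                    sd_rate = rep_len(sds, n),
                    n_reps = rep_len(as.integer(n_reps), n))
  class(out) <- c("rate_stats", "data.frame")
  out
}

sr_fixture <- function(mean = 0, sd = 0) {
  structure(list(sr_mean = mean, sr_sd = sd, total_silent_time_s = 1,
                 n_trials = 1L, source = "SR"),
            class = "spontaneous_rate")
}
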