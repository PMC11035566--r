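#' Best frequency from a frequency-response curve
#'
#' Fits a smoothing spline to mean rate versus log2 frequency and takes
#' the peak of the fitted curve on a dense grid spanning the measured
#' range. Smoothing is chosen by generalized cross-validation; if that
#' fit degenerates the fixed fallback `spar = 0.5` is used. Ties on the
#' grid resolve to the lowest frequency; a peak on the boundary of the
#' measured range is flagged.
#'
#' @param stats A `rate_stats` frame over frequency (single level), as
#'   from [trial_rates()]; needs >= 4 distinct frequencies.
#' @param grid_points Evaluation grid size.
#' @return List of class `bf_estimate`: `bf_hz`, `fit` (data.frame
#'   `freq_hz`, `rate` of the fitted curve), `boundary` flag.
#' @export
estimate_bf <- function(stats, grid_points = 1000) {
  freqs <- stats$stim_freq_hz
  rates <- stats$mean_rate
  if (length(unique(freqs)) < 4) {
    abort_anf("best-frequency fit needs >= 4 distinct frequencies",
              "anfiber_bf_error")
  }
  x <- log2(freqs)
  fit <- tryCatch(stats::smooth.spline(x, rates, cv = FALSE),
                  error = function(e) NULL)
  if (is.null(fit) || fit$df > length(unique(x)) - 0.5) {
    fit <- stats::smooth.spline(x, rates, spar = 0.5)
  }
  gx <- seq(min(x), max(x), length.out = grid_points)
  gy <- stats::predict(fit, gx)$y
  peak <- which.max(gy)  # which.max: first (lowest-frequency) tie wins
  structure(list(bf_hz = 2^gx[peak],
                 fit = data.frame(freq_hz = 2^gx, rate = gy),
                 boundary = peak %in% c(1L, grid_points)),
            class = "bf_estimate")
}

#' Rate criterion from a spontaneous-rate estimate
#'
#' `T = sr_mean + 1.2 * sr_sd`, the criterion a rate must strictly
#' exceed to count as driven.
#' @noRd
sr_criterion <- function(sr) sr$sr_mean + 1.2 * sr$sr_sd

#' Rate-level function threshold
#'
#' The lowest stimulus level whose mean rate is higher than 15 spikes/s
#' and higher than `sr_mean + 1.2 * sr_sd` (both strict inequalities).
#'
#' @param stats A `rate_stats` frame over level (single frequency),
#'   levels in any order.
#' @param sr A [spontaneous_rate()] result (or a list with `sr_mean`,
#'   `sr_sd`).
#' @return Threshold level in dB, or `NaN` when no level qualifies.
#' @export
rlf_threshold <- function(stats, sr) {
  crit <- max(15, sr_criterion(sr))
  ord <- order(stats$stim_level_db)
  hit <- which(stats$mean_rate[ord] > crit)
  if (!length(hit)) return(NaN)
  stats$stim_level_db[ord][hit[1]]
}

#' Vector strength of a set of spike times
#'
#' `vs = |sum_j exp(i 2 pi f t_j)| / N`: the mean resultant length of
#' the spike phases within the tone period. 0 means no phase locking,
#' 1 perfect locking.
#'
#' @param spike_times Spike times (s), already restricted to the window
#'   of interest (conventionally the stimulus-on window).
#' @param freq_hz Tone frequency (Hz), > 0.
#' @return List: `vs` (NaN when there are no spikes) and `n` (spike
#'   count).
#' @export
vector_strength <- function(spike_times, freq_hz) {
  if (!is_scalar_number(freq_hz) || freq_hz <= 0) {
    abort_anf("freq_hz must be positive", "anfiber_invariant_error")
  }
  n <- length(spike_times)
  if (n == 0L) return(list(vs = NaN, n = 0L))
  ph <- 2 * pi * freq_hz * spike_times
  list(vs = sqrt(sum(cos(ph))^2 + sum(sin(ph))^2) / n, n = n)
}

#' Significance of a vector strength
#'
#' `p = exp(-N vs^2)`; with fewer than 50 spikes the estimate is
#' considered invalid and `p` is `NaN`. A vector strength is deemed
#' significant when `p < 0.001`.
#'
#' @param vs Vector strength in \[0, 1\] (or NaN).
#' @param n Number of spikes.
#' @return p-value, or `NaN` when `n < 50` or `vs` is NaN.
#' @export
vs_significance <- function(vs, n) {
  if (n < 50 || is.nan(vs)) return(NaN)
  exp(-n * vs^2)
}

#' @rdname vs_significance
#' @param p p-value from `vs_significance`.
#' @return `is_significant`: `TRUE` iff `p < 0.001` (`FALSE` for NaN).
#' @export
is_significant <- function(p) !is.nan(p) & !is.na(p) & p < 0.001

#' Phase locking across levels of a PH recording
#'
#' For each stimulus level, pools the spikes of all repetitions that
#' fall in the stimulus-on window `[onset, onset + duration)`, then
#' computes vector strength at the recording's tone frequency and its
#' significance.
#'
#' @param recording An [an_recording] with a single tone frequency and
#'   one or more levels.
#' @return List of class `phase_locking_result`: `frequency_hz`,
#'   `levels`, `vs`, `n_spikes`, `p` (aligned vectors).
#' @export
analyze_ph <- function(recording) {
  stopifnot(inherits(recording, "an_recording"))
  tr <- recording$trials
  tonal <- !is_silent(tr)
  freqs <- unique(tr$stim_freq_hz[tonal])
  if (length(freqs) != 1L) {
    abort_anf("phase-locking analysis expects a single tone frequency",
              "anfiber_type_error")
  }
  s <- recording$settings
  lo <- s$stim_onset_s
  hi <- s$stim_onset_s + s$stim_duration_s
  levels <- sort(unique(tr$stim_level_db[tonal]))
  vs <- n_spikes <- p <- numeric(length(levels))
  for (k in seq_along(levels)) {
    rows <- which(tonal & tr$stim_level_db == levels[k])
    pooled <- unlist(tr$spike_times[rows], use.names = FALSE)
    pooled <- pooled[pooled >= lo & pooled < hi]
    r <- vector_strength(pooled, freqs)
    vs[k] <- r$vs
    n_spikes[k] <- r$n
    p[k] <- vs_significance(r$vs, r$n)
  }
  structure(list(frequency_hz = freqs, levels = levels, vs = vs,
                 n_spikes = as.integer(n_spikes), p = p),
            class = "phase_locking_result")
}

#' Per-frequency rate thresholds of a response field
#'
#' For each stimulus frequency of a frequency x level lattice, the
#' threshold is the lowest level whose mean rate is strictly higher
#' than `T = sr_mean + 1.2 * sr_sd` (or a manual override, useful for
#' fibres with zero spontaneous rate). Frequencies with no qualifying
#' level get `NaN`.
#'
#' @param stats A `rate_stats` frame over the frequency x level grid.
#' @param sr A [spontaneous_rate()] result.
#' @param criterion_override Optional manual criterion `T` (spikes/s).
#' @return List of class `tuning_result`: `freqs`, `threshold_db`
#'   (aligned, `NaN` allowed), `criterion`, plus `cf_hz`,
#'   `min_threshold_db`, `q10` filled by [cf_q10()].
#' @export
tuning_thresholds <- function(stats, sr, criterion_override = NULL) {
  crit <- criterion_override %||% sr_criterion(sr)
  freqs <- sort(unique(stats$stim_freq_hz))
  thr <- vapply(freqs, function(f) {
    sub <- stats[stats$stim_freq_hz == f, , drop = FALSE]
    ord <- order(sub$stim_level_db)
    hit <- which(sub$mean_rate[ord] > crit)
    if (!length(hit)) NaN else sub$stim_level_db[ord][hit[1]]
  }, numeric(1))
  structure(list(freqs = freqs, threshold_db = thr, criterion = crit,
                 cf_hz = NaN, min_threshold_db = NaN, q10 = NaN),
            class = "tuning_result")
}

# Interpolated crossings of `level` on one flank of the threshold
# curve, walking outward from the tip on a log2-frequency axis.
flank_crossing <- function(lx, ly, level, tip_idx, direction) {
  idx <- if (direction < 0) seq(tip_idx, 1L) else seq(tip_idx, length(lx))
  for (k in seq_along(idx)[-1]) {
    i0 <- idx[k - 1L]
    i1 <- idx[k]
    if (is.nan(ly[i1])) return(NaN)  # gap before reaching the level
    if (ly[i1] >= level) {
      frac <- (level - ly[i0]) / (ly[i1] - ly[i0])
      return(lx[i0] + frac * (lx[i1] - lx[i0]))
    }
  }
  NaN
}

#' Characteristic frequency, minimum threshold and Q10dB
#'
#' CF is the frequency of the tuning curve's minimum threshold (ties:
#' geometric mean of the tied frequencies). The 10-dB bandwidth is
#' found by linear interpolation of the threshold curve on a log2
#' frequency axis; `q10 = cf / bandwidth`. Q10dB is `NaN` when either
#' flank fails to reach minimum + 10 dB inside the measured range (for
#' example, when the frequency range is too narrow).
#'
#' @param tuning A `tuning_result` from [tuning_thresholds()].
#' @return The `tuning_result` with `cf_hz`, `min_threshold_db` and
#'   `q10` filled in.
#' @export
cf_q10 <- function(tuning) {
  stopifnot(inherits(tuning, "tuning_result"))
  ok <- !is.nan(tuning$threshold_db)
  if (!any(ok)) {
    abort_anf("no frequency has a measurable threshold", "anfiber_cf_error")
  }
  min_thr <- min(tuning$threshold_db[ok])
  tied <- which(ok & tuning$threshold_db == min_thr)
  cf <- exp(mean(log(tuning$freqs[tied])))
  tuning$cf_hz <- cf
  tuning$min_threshold_db <- min_thr
  lx <- log2(tuning$freqs)
  ly <- tuning$threshold_db
  target <- min_thr + 10
  lo <- flank_crossing(lx, ly, target, tied[1], -1)
  hi <- flank_crossing(lx, ly, target, tied[length(tied)], +1)
  tuning$q10 <- if (is.nan(lo) || is.nan(hi)) NaN else cf / (2^hi - 2^lo)
  tuning
}
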