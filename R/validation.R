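#' Inter-spike-interval metrics of a recording
#'
#' ISIs are computed within trials only — never across trial
#' boundaries. Counts of ISIs shorter than 1 ms and shorter than 0.6 ms
#' (the absolute refractoriness of auditory-nerve fibres) are reported;
#' a unit with multiple (>= 2) sub-0.6-ms intervals is marked for
#' exclusion as a likely multi-unit recording.
#'
#' @param trials An [an_trials] table.
#' @return List of class `isi_metrics`: `isi_s` (all ISIs, seconds),
#'   `n_lt_1ms`, `n_lt_0p6ms`, `refractory_excluded`, `median_isi_s`.
#' @export
isi_metrics <- function(trials) {
  isis <- unlist(lapply(trials$spike_times, function(st) {
    if (length(st) > 1L) diff(st) else numeric(0)
  }), use.names = FALSE)
  n1 <- sum(isis < 0.001)
  n06 <- sum(isis < 0.0006)
  structure(list(isi_s = isis, n_lt_1ms = n1, n_lt_0p6ms = n06,
                 refractory_excluded = n06 >= 2L,
                 median_isi_s = if (length(isis)) stats::median(isis)
                                else NaN),
            class = "isi_metrics")
}

#' Median spike waveform with pointwise 95% CI
#'
#' The summary is the pointwise median of the aligned snippets; the
#' confidence band is the pointwise 2.5th and 97.5th percentile of the
#' snippet distribution (an empirical band, not a standard error of the
#' median).
#'
#' @param snippets List of equal-length aligned waveform snippets.
#' @return List of class `waveform_summary`: `median`, `ci_low`,
#'   `ci_high`, `n_spikes`.
#' @export
median_waveform_ci <- function(snippets) {
  if (length(snippets) == 0L) {
    abort_anf("no snippets to summarize", "anfiber_invariant_error")
  }
  len <- unique(vapply(snippets, length, integer(1)))
  if (length(len) != 1L) {
    abort_anf("snippets must have equal lengths", "anfiber_invariant_error")
  }
  m <- do.call(rbind, snippets)
  structure(list(median = apply(m, 2, stats::median),
                 ci_low = apply(m, 2, stats::quantile, probs = 0.025,
                                names = FALSE),
                 ci_high = apply(m, 2, stats::quantile, probs = 0.975,
                                 names = FALSE),
                 n_spikes = length(snippets)),
            class = "waveform_summary")
}

#' Prepotential triage score for a median waveform
#'
#' A prepotential — a small deflection 0.4-1.0 ms before the main peak —
#' indicates that the spikes came from a cochlear-nucleus bushy cell
#' rather than an auditory-nerve fibre. The score is the maximum
#' absolute deflection in that pre-peak window divided by a robust SD
#' (MAD) of the leading baseline (everything earlier than 1.0 ms before
#' the peak). Scores above `k` raise a flag for human review; nothing
#' is excluded automatically.
#'
#' @param waveform Median waveform centred on the spike peak.
#' @param sample_rate_hz Sampling rate (Hz).
#' @param peak_index Peak sample (defaults to the maximum).
#' @param k Flag threshold on the score.
#' @return List: `score`, `flag`.
#' @export
prepotential_score <- function(waveform, sample_rate_hz,
                               peak_index = which.max(waveform), k = 3) {
  pre10 <- peak_index - round(0.0010 * sample_rate_hz)
  pre04 <- peak_index - round(0.0004 * sample_rate_hz)
  if (pre10 < 2L) {
    return(list(score = NaN, flag = FALSE))
  }
  baseline <- waveform[1:(pre10 - 1L)]
  win <- waveform[pre10:max(pre10, pre04)]
  centre <- stats::median(baseline)
  noise <- stats::mad(baseline)
  if (noise == 0) noise <- .Machine$double.eps
  score <- max(abs(win - centre)) / noise
  list(score = score, flag = score > k)
}

#' Rate-level nonmonotonicity triage below 80 dB SPL
#'
#' Auditory-nerve rate-level functions are monotone (straight or
#' saturating); a pronounced rate drop below 80 dB SPL suggests a
#' non-primary neuron with inhibitory input. The screen flags the
#' function when, at levels below 80 dB, the mean rate falls below its
#' running maximum by more than `max(drop_frac * running max,
#' sem_mult * pooled SEM)`. Both constants are configurable; the flag
#' is a triage aid, not an automatic exclusion.
#'
#' @param stats A `rate_stats` frame over level.
#' @param max_level_db Only levels strictly below this are screened.
#' @param drop_frac Fractional drop from the running maximum that
#'   counts as nonmonotonic.
#' @param sem_mult Multiple of the pooled SEM the drop must also exceed.
#' @return List: `flag`, `max_drop`, `at_level_db`.
#' @export
rlf_nonmonotonicity <- function(stats, max_level_db = 80, drop_frac = 0.25,
                                sem_mult = 2) {
  ord <- order(stats$stim_level_db)
  lev <- stats$stim_level_db[ord]
  rate <- stats$mean_rate[ord]
  keep <- lev < max_level_db
  lev <- lev[keep]
  rate <- rate[keep]
  if (length(rate) < 3L) {
    return(list(flag = FALSE, max_drop = NaN, at_level_db = NaN))
  }
  sem <- stats$sd_rate[ord][keep] / sqrt(pmax(stats$n_reps[ord][keep], 1))
  pooled_sem <- mean(sem, na.rm = TRUE)
  if (!is.finite(pooled_sem)) pooled_sem <- 0
  runmax <- cummax(rate)
  drop <- runmax - rate
  tol <- pmax(drop_frac * runmax, sem_mult * pooled_sem)
  bad <- which(drop > tol)
  list(flag = length(bad) > 0L,
       max_drop = if (length(drop)) max(drop) else NaN,
       at_level_db = if (length(bad)) lev[bad[1]] else NaN)
}

#' Run all single-unit validation screens on a unit
#'
#' Aggregates the ISI refractory screen (over every recording), the
#' waveform summaries and prepotential triage (where snippets can be
#' extracted from raw traces), and the rate-level monotonicity screen
#' (where an RLF recording exists). Screens that cannot be assessed are
#' reported as such; nothing is deleted.
#'
#' @param unit An [an_unit].
#' @param detection_cfg A [detection_config] used when snippets must be
#'   extracted from raw traces.
#' @return List of class `validation_report`: per-recording ISI
#'   metrics, `refractory_excluded`, `waveform` (or `NULL`),
#'   `prepotential`, `rlf_nonmonotonic`, and `notes`.
#' @export
validate_unit <- function(unit, detection_cfg = detection_config()) {
  stopifnot(inherits(unit, "an_unit"))
  notes <- character(0)
  isi <- lapply(unit$recordings, function(r) isi_metrics(r$trials))
  excluded <- any(vapply(isi, function(x) x$refractory_excluded, logical(1)))
  n1 <- sum(vapply(isi, function(x) x$n_lt_1ms, numeric(1)))
  n06 <- sum(vapply(isi, function(x) x$n_lt_0p6ms, numeric(1)))

  waveform <- NULL
  prepot <- list(score = NaN, flag = FALSE)
  for (r in unit$recordings) {
    if (is.null(r$raw)) next
    cfg <- detection_cfg
    if (is.na(cfg$trigger_level)) {
      cfg$trigger_level <- stats::median(r$raw$trigger_level, na.rm = TRUE)
    }
    if (is.na(cfg$trigger_level)) next
    det <- run_detection(r$raw, cfg)
    snips <- do.call(c, lapply(det$snippets, as.list))
    if (length(snips) >= 10) {
      waveform <- median_waveform_ci(snips)
      prepot <- prepotential_score(waveform$median, r$raw$sample_rate_hz)
      break
    }
  }
  if (is.null(waveform)) {
    notes <- c(notes, "waveform screen not assessable (no usable raw traces)")
  }

  rlf <- unit$recordings$RLF
  rlf_flag <- list(flag = FALSE, max_drop = NaN, at_level_db = NaN)
  if (!is.null(rlf)) {
    st <- trial_rates(rlf$trials, rlf$settings$stim_onset_s,
                      rlf$settings$stim_duration_s)$stats
    rlf_flag <- rlf_nonmonotonicity(st)
  } else {
    notes <- c(notes, "RLF screen not assessable (no RLF recording)")
  }

  structure(list(unit_name = unit$unit_name, isi = isi,
                 isi_count_lt_1ms = n1, isi_count_lt_0p6ms = n06,
                 refractory_excluded = excluded, waveform = waveform,
                 prepotential_score = prepot$score,
                 prepotential_flag = prepot$flag,
                 rlf_nonmonotonic_flag = rlf_flag$flag,
                 rlf_nonmonotonic = rlf_flag, notes = notes),
            class = "validation_report")
}
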