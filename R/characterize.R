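analysis_sr_fields <- function(rec) {
  out <- tryCatch(spontaneous_rate(rec), anfiber_no_sr_error = function(c) NULL)
  if (is.null(out)) return(list())
  list(sr = out$sr_mean, sr_std = out$sr_sd,
       sr_total_time_s = out$total_silent_time_s)
}

#' Analyse one recording and fill its `analysis` field
#'
#' Dispatches on the recording type and stores the analysed outcomes
#' under the conventional field names (`bf`, `rates`, `stdevs`,
#' `freqs`, `threshold`, `levels`, `vs`, `prob`, `frequency`, `cf`,
#' `q10`, `latency_poisson`, `latency_2bins`, `fsl_mean` ...,
#' `sr`, `PSTH_rates`, `PSTH_centers`, `ntrials`, `trials`).
#'
#' @param recording An [an_recording].
#' @param sr Optional [spontaneous_rate()] estimate to use for
#'   criteria; defaults to the recording's own silent trials where
#'   needed and available.
#' @param criterion_override Optional manual rate criterion for tuning
#'   thresholds.
#' @return The recording with `analysis` filled.
#' @export
analyze_recording <- function(recording, sr = NULL,
                              criterion_override = NULL) {
  stopifnot(inherits(recording, "an_recording"))
  s <- recording$settings
  ty <- recording$rec_type
  # Rate criteria use the silent trials of the same recording (their SD
  # reflects the variability of the short trials the criterion is
  # applied to); the unit-level estimate is only a fallback.
  own_sr <- function() {
    own <- tryCatch(spontaneous_rate(recording),
                    anfiber_no_sr_error = function(c) NULL)
    own %||% sr %||% abort_anf(
      "no spontaneous-rate source for the rate criterion",
      "anfiber_no_sr_error")
  }
  res <- switch(ty,
    BF = {
      tr <- trial_rates(recording$trials, s$stim_onset_s, s$stim_duration_s)
      bf <- estimate_bf(tr$stats)
      c(list(bf = bf$bf_hz, bf_on_boundary = bf$boundary,
             rates = tr$stats$mean_rate, stdevs = tr$stats$sd_rate,
             freqs = tr$stats$stim_freq_hz),
        analysis_sr_fields(recording))
    },
    RLF = {
      tr <- trial_rates(recording$trials, s$stim_onset_s, s$stim_duration_s)
      c(list(threshold = rlf_threshold(tr$stats, own_sr()),
             rates = tr$stats$mean_rate, stdevs = tr$stats$sd_rate,
             levels = tr$stats$stim_level_db),
        analysis_sr_fields(recording))
    },
    PH = {
      ph <- analyze_ph(recording)
      c(list(vs = ph$vs, prob = ph$p, n_spikes = ph$n_spikes,
             levels = ph$levels, frequency = ph$frequency_hz),
        analysis_sr_fields(recording))
    },
    CF = {
      tr <- trial_rates(recording$trials, s$stim_onset_s, s$stim_duration_s)
      tun <- cf_q10(tuning_thresholds(tr$stats, own_sr(),
                                      criterion_override))
      c(list(cf = tun$cf_hz, threshold = tun$min_threshold_db,
             q10 = tun$q10, tuning_freqs = tun$freqs,
             tuning_thresholds = tun$threshold_db,
             criterion = tun$criterion,
             rates = tr$stats$mean_rate,
             freqs = tr$stats$stim_freq_hz,
             levels = tr$stats$stim_level_db),
        analysis_sr_fields(recording))
    },
    CLICK = {
      onset <- s$stim_onset_s
      fsl <- fsl_stats(recording$trials, onset)
      sr_click <- sr  # NULL -> estimated from pre-onset spikes
      list(latency_poisson = click_latency_poisson(recording$trials, onset,
                                                   sr_click),
           latency_2bins = click_latency_2bins(recording$trials, onset),
           fsl_mean = fsl$fsl_mean_ms, fsl_median = fsl$fsl_median_ms,
           fsl_std = fsl$fsl_sd_ms, fsl_var = fsl$fsl_var,
           fsl_iqr = fsl$fsl_iqr_ms)
    },
    SR = analysis_sr_fields(recording),
    {
      cx <- analyze_complex(recording)
      list(ntrials = cx$ntrials, trials = cx$trials,
           PSTH_rates = cx$psth$rates,
           PSTH_centers = cx$psth$bin_centers_s)
    })
  recording$analysis <- res
  recording
}

#' Characterize every recording of a unit
#'
#' Runs [analyze_recording()] on each recording, using the unit's best
#' spontaneous-rate source ([select_sr_estimate()]) for the rate
#' criteria, and returns the unit plus a one-row summary.
#'
#' @param unit An [an_unit].
#' @return List: `unit` (analyses filled) and `summary` (one-row
#'   `data.frame`: bf, threshold, cf, q10, sr, max significant vs,
#'   latencies, validation flags).
#' @export
characterize_unit <- function(unit) {
  stopifnot(inherits(unit, "an_unit"))
  sr <- tryCatch(select_sr_estimate(unit), anfiber_no_sr_error = function(c) NULL)
  for (ty in names(unit$recordings)) {
    unit$recordings[[ty]] <- tryCatch(
      analyze_recording(unit$recordings[[ty]], sr = sr),
      error = function(e) {
        warning(sprintf("unit '%s' %s analysis failed: %s",
                        unit$unit_name, ty, conditionMessage(e)),
                call. = FALSE)
        unit$recordings[[ty]]
      })
  }
  a <- function(ty, field) {
    v <- unit$recordings[[ty]]$analysis[[field]]
    if (is.null(v) || !length(v)) NaN else v[1]
  }
  vs_max <- {
    ph <- unit$recordings$PH$analysis
    if (is.null(ph)) NaN else {
      sig <- is_significant(ph$prob)
      if (any(sig)) max(ph$vs[sig]) else NaN
    }
  }
  val <- validate_unit(unit)
  summary <- data.frame(
    unit_name = unit$unit_name,
    bf_hz = a("BF", "bf"),
    rlf_threshold_db = a("RLF", "threshold"),
    cf_hz = a("CF", "cf"),
    cf_threshold_db = a("CF", "threshold"),
    q10 = a("CF", "q10"),
    sr_mean = if (is.null(sr)) NaN else sr$sr_mean,
    sr_source = if (is.null(sr)) NA_character_ else sr$source,
    vs_max = vs_max,
    latency_poisson_ms = a("CLICK", "latency_poisson"),
    latency_2bins_ms = a("CLICK", "latency_2bins"),
    fsl_mean_ms = a("CLICK", "fsl_mean"),
    fsl_iqr_ms = a("CLICK", "fsl_iqr"),
    refractory_excluded = val$refractory_excluded,
    rlf_nonmonotonic = val$rlf_nonmonotonic_flag,
    stringsAsFactors = FALSE)
  list(unit = unit, summary = summary)
}

#' Characterize every unit of an experiment
#'
#' @param exp An [an_experiment].
#' @return List: `experiment` (analyses filled) and `summary` (one row
#'   per unit, with `animal_id` prepended).
#' @export
characterize_experiment <- function(exp) {
  stopifnot(inherits(exp, "an_experiment"))
  rows <- list()
  for (nm in names(exp$units)) {
    res <- characterize_unit(exp$units[[nm]])
    exp$units[[nm]] <- res$unit
    rows[[nm]] <- cbind(data.frame(animal_id = exp$animal_id), res$summary)
  }
  list(experiment = exp, summary = do.call(rbind, c(rows,
                                                    make.row.names = FALSE)))
}
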