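#' Ground-truth parameters of a simulated auditory-nerve fibre
#'
#' A phenomenological fibre: V-shaped tuning on a log-frequency axis,
#' clipped-linear saturating rate-level growth, Poisson spiking with an
#' absolute dead time, von Mises phase locking, and a click response at
#' a fixed latency plus a frequency-dependent travelling-wave delay.
#' Cochlear nonlinearities (compression, suppression, adaptation) are
#' deliberately not modelled.
#'
#' @param cf_hz Characteristic frequency (Hz), in \[300, 16000\].
#' @param threshold_dbspl Threshold at CF (dB SPL).
#' @param spont_rate_hz Spontaneous rate (spikes/s).
#' @param max_driven_rate_hz Driven rate above spontaneous at saturation
#'   (spikes/s); must exceed `spont_rate_hz`.
#' @param dynamic_range_db Level range over which rate grows from
#'   spontaneous to saturation (dB).
#' @param q10 Sharpness of tuning: CF divided by the 10-dB bandwidth.
#' @param vs_max Phase-locking strength: target vector strength at CF
#'   for a suprathreshold tone, in \[0, 1).
#' @param latency_base_ms Click latency at the base of the cochlea (ms);
#'   the travelling-wave delay [tw_delay_ms()] is added on top.
#' @param click_jitter_ms Gaussian SD of the first-spike latency (ms).
#' @param refractory_ms Absolute dead time (ms); 0.6 ms is the absolute
#'   refractoriness of auditory-nerve fibres.
#' @param seed Integer seed attached to the fibre for reproducibility.
#' @return An object of class `fiber_ground_truth`.
#' @export
fiber_ground_truth <- function(cf_hz, threshold_dbspl = 20,
                               spont_rate_hz = 50,
                               max_driven_rate_hz = 150,
                               dynamic_range_db = 30, q10 = 3,
                               vs_max = 0, latency_base_ms = 1,
                               click_jitter_ms = 0.1,
                               refractory_ms = 0.6, seed = NULL) {
  stopifnot(is_scalar_number(cf_hz), cf_hz >= 300, cf_hz <= 16000,
            is_scalar_number(threshold_dbspl),
            is_scalar_number(spont_rate_hz), spont_rate_hz >= 0,
            is_scalar_number(max_driven_rate_hz), max_driven_rate_hz > 0,
            is_scalar_number(dynamic_range_db), dynamic_range_db > 0,
            is_scalar_number(q10), q10 > 0,
            is_scalar_number(vs_max), vs_max >= 0, vs_max < 1,
            is_scalar_number(latency_base_ms), latency_base_ms > 0,
            is_scalar_number(refractory_ms), refractory_ms > 0)
  if (max_driven_rate_hz <= spont_rate_hz) {
    abort_anf("max_driven_rate_hz must exceed spont_rate_hz",
              "anfiber_invariant_error")
  }
  structure(list(cf_hz = cf_hz, threshold_dbspl = threshold_dbspl,
                 spont_rate_hz = spont_rate_hz,
                 max_driven_rate_hz = max_driven_rate_hz,
                 dynamic_range_db = dynamic_range_db, q10 = q10,
                 vs_max = vs_max, latency_base_ms = latency_base_ms,
                 click_jitter_ms = click_jitter_ms,
                 refractory_ms = refractory_ms, seed = seed),
            class = "fiber_ground_truth")
}

#' V-shaped tuning-curve threshold of a simulated fibre
#'
#' Threshold rises linearly in octaves away from CF. The slope (dB per
#' octave) is set in closed form so that the curve's bandwidth 10 dB
#' above the tip equals `cf_hz / q10`: with half-width `u` octaves on
#' each side, `2^u - 2^-u = 1/q10`, a quadratic in `2^u`.
#'
#' @param fiber A [fiber_ground_truth].
#' @param freq_hz Tone frequency or vector of frequencies (Hz).
#' @return Threshold(s) in dB SPL.
#' @export
tuning_threshold_true <- function(fiber, freq_hz) {
  x <- (1 / fiber$q10 + sqrt(1 / fiber$q10^2 + 4)) / 2  # 2^halfwidth
  slope <- 10 / log2(x)                                 # dB per octave
  fiber$threshold_dbspl + slope * abs(log2(freq_hz / fiber$cf_hz))
}

#' Expected driven rate of a simulated fibre
#'
#' `rate = spont + max_driven * sat((level - thr(freq)) / dynamic_range)`
#' with `sat` a clipped-linear saturating function; below the tuning
#' threshold the rate equals the spontaneous rate exactly.
#'
#' @param fiber A [fiber_ground_truth].
#' @param freq_hz,level_db Tone frequency (Hz) and level (dB SPL); both
#'   vectorized.
#' @return Expected rate in spikes/s.
#' @export
rate_response <- function(fiber, freq_hz, level_db) {
  stopifnot(all(is.finite(freq_hz)), all(is.finite(level_db)))
  drive <- (level_db - tuning_threshold_true(fiber, freq_hz)) /
    fiber$dynamic_range_db
  fiber$spont_rate_hz + fiber$max_driven_rate_hz * pmin(pmax(drive, 0), 1)
}

#' Travelling-wave delay along the cochlea
#'
#' A decreasing power law of CF, `a * (cf/1 kHz)^-b` with package
#' constants `a = 2` ms and `b = 0.4`, spanning roughly 0.7-3 ms over
#' CFs of 0.4-16 kHz. These constants are modelling choices for the
#' simulator, not measured values.
#'
#' @param cf_hz Characteristic frequency (Hz).
#' @return Delay in ms.
#' @export
tw_delay_ms <- function(cf_hz) 2 * (cf_hz / 1000)^(-0.4)

# Mean resultant length of a von Mises distribution, A(kappa) = I1/I0.
vm_mrl <- function(kappa) {
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

#' Invert the von Mises concentration for a target vector strength
#'
#' Solves `I1(kappa)/I0(kappa) = vs_target` numerically, so that spike
#' phases drawn from a von Mises density have expected mean resultant
#' length (= expected vector strength, before dead-time distortion)
#' equal to the target.
#'
#' @param vs_target Target vector strength in \[0, 1).
#' @return Concentration parameter `kappa` (0 when the target is 0).
#' @export
vs_to_kappa <- function(vs_target) {
  stopifnot(is_scalar_number(vs_target), vs_target >= 0)
  if (vs_target >= 1) abort_anf("vs_target must be < 1",
                                "anfiber_invariant_error")
  if (vs_target == 0) return(0)
  stats::uniroot(function(k) vm_mrl(k) - vs_target,
                 lower = 1e-8, upper = 1e4, tol = 1e-10)$root
}

# Enforce an absolute dead time on a sorted spike train.
apply_dead_time <- function(times, refractory_s) {
  if (length(times) < 2L || refractory_s <= 0) return(times)
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory_s) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Simulate one spike train
#'
#' Inhomogeneous Poisson process generated by thinning, followed by an
#' absolute dead time. When `phase` is given, the rate is multiplied by
#' a von Mises density in the tone phase, `exp(kappa cos(2 pi f t)) /
#' I0(kappa)` (unit mean over a period), with `kappa` from
#' [vs_to_kappa()], so spike phases follow a von Mises law whose mean
#' resultant length equals `vs_target` in expectation.
#'
#' @param rate_fn Vectorized function time (s) -> rate (spikes/s), or a
#'   single number for a homogeneous process.
#' @param duration_s Train duration (s).
#' @param refractory_ms Absolute dead time (ms); 0 disables it.
#' @param phase Optional `list(freq_hz =, vs_target =)` phase locking.
#' @param seed Optional integer seed; identical seeds give identical
#'   trains.
#' @return Sorted numeric vector of spike times in `[0, duration_s]`.
#' @export
simulate_spike_train <- function(rate_fn, duration_s, refractory_ms = 0,
                                 phase = NULL, seed = NULL) {
  stopifnot(is_scalar_number(duration_s), duration_s > 0)
  if (is.numeric(rate_fn)) {
    r0 <- rate_fn
    rate_fn <- function(t) rep_len(r0, length(t))
  }
  kappa <- 0
  if (!is.null(phase)) {
    stopifnot(is.list(phase), is_scalar_number(phase$freq_hz))
    if (phase$vs_target >= 1) abort_anf("vs_target must be < 1",
                                        "anfiber_invariant_error")
    kappa <- vs_to_kappa(phase$vs_target)
  }
  mod_fn <- if (kappa > 0) {
    i0 <- besselI(kappa, 0, expon.scaled = TRUE)  # I0 * exp(-kappa)
    function(t) exp(kappa * (cos(2 * pi * phase$freq_hz * t) - 1)) / i0
  } else {
    function(t) rep_len(1, length(t))
  }
  grid <- seq(0, duration_s, length.out = 1024L)
  base_max <- max(rate_fn(grid), 0)
  mod_max <- if (kappa > 0) exp(kappa) /
    (besselI(kappa, 0, expon.scaled = TRUE) * exp(kappa)) else 1
  m <- base_max * mod_max * 1.05 + 1e-12
  with_seed(seed, {
    n_cand <- stats::rpois(1, m * duration_s)
    if (n_cand == 0) return(numeric(0))
    t_cand <- sort(stats::runif(n_cand, 0, duration_s))
    p <- rate_fn(t_cand) * mod_fn(t_cand) / m
    times <- t_cand[stats::runif(n_cand) < p]
    apply_dead_time(times, refractory_ms / 1000)
  })
}

#' Stimulus specification for a simulated recording
#'
#' @param kind `"tone"`, `"click"`, `"silence"` or `"frozen_noise"`.
#' @param freq_grid,level_grid Stimulus grids (tones); a click or
#'   silence spec needs neither.
#' @param onset_s,duration_s Stimulus timing within the trial.
#' @param trial_duration_s Total trial duration (s).
#' @param repetitions Repetitions per unique grid point.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(kind, freq_grid = NULL, level_grid = NULL,
                          onset_s = 0.05, duration_s = 0.2,
                          trial_duration_s = 0.3, repetitions = 5) {
  kind <- match.arg(kind, c("tone", "click", "silence", "frozen_noise"))
  stopifnot(onset_s >= 0, duration_s > 0, trial_duration_s > 0,
            repetitions >= 1)
  if (onset_s + duration_s > trial_duration_s + 1e-12) {
    abort_anf("stimulus must fit within the trial", "anfiber_invariant_error")
  }
  if (kind == "tone" && (length(freq_grid) == 0L || length(level_grid) == 0L)) {
    abort_anf("a tone spec needs non-empty freq_grid and level_grid",
              "anfiber_grid_error")
  }
  structure(list(kind = kind, freq_grid = freq_grid, level_grid = level_grid,
                 onset_s = onset_s, duration_s = duration_s,
                 trial_duration_s = trial_duration_s,
                 repetitions = as.integer(repetitions)),
            class = "stimulus_spec")
}

# Spike train for one tone trial: spontaneous activity outside the
# stimulus window, driven (possibly phase-locked) activity inside, one
# global dead time.
sim_tone_trial <- function(fiber, freq, level, spec, seed) {
  spont <- fiber$spont_rate_hz
  t_on <- spec$onset_s
  t_off <- spec$onset_s + spec$duration_s
  driven_rate <- rate_response(fiber, freq, level)
  phase <- if (fiber$vs_max > 0) {
    list(freq_hz = freq, vs_target = fiber$vs_max)
  }
  pre <- if (t_on > 0 && spont > 0) {
    simulate_spike_train(spont, t_on, seed = derive_seed(seed, 1))
  } else numeric(0)
  drv <- simulate_spike_train(driven_rate, spec$duration_s, phase = phase,
                              seed = derive_seed(seed, 2)) + t_on
  post_dur <- spec$trial_duration_s - t_off
  post <- if (post_dur > 0 && spont > 0) {
    simulate_spike_train(spont, post_dur, seed = derive_seed(seed, 3)) + t_off
  } else numeric(0)
  apply_dead_time(sort(c(pre, drv, post)), fiber$refractory_ms / 1000)
}

sim_silent_trial <- function(fiber, trial_duration_s, seed) {
  simulate_spike_train(fiber$spont_rate_hz, trial_duration_s,
                       refractory_ms = fiber$refractory_ms, seed = seed)
}

# Click trial: spontaneous spikes with the response window blanked, a
# first spike at the ground-truth latency (Gaussian jitter), and a brief
# exponentially decaying rate transient behind it.
sim_click_trial <- function(fiber, spec, seed) {
  lat_s <- (fiber$latency_base_ms + tw_delay_ms(fiber$cf_hz)) / 1000
  with_seed(seed, {
    fsl <- lat_s + stats::rnorm(1, 0, fiber$click_jitter_ms / 1000)
    fsl <- max(fsl, 1e-4)
    t0 <- spec$onset_s + fsl
    tau <- 0.001
    trans_dur <- min(0.005, spec$trial_duration_s - t0)
    trans <- if (trans_dur > 0) {
      t0 + simulate_spike_train(
        function(t) fiber$max_driven_rate_hz * exp(-t / tau), trans_dur)
    } else numeric(0)
    spont <- if (fiber$spont_rate_hz > 0) {
      simulate_spike_train(fiber$spont_rate_hz, spec$trial_duration_s)
    } else numeric(0)
    # response blanking: the evoked response dominates [onset, t0 + 5 ms]
    blank_hi <- min(t0 + 0.005, spec$trial_duration_s)
    spont <- spont[spont < spec$onset_s | spont > blank_hi]
    times <- sort(c(spont, t0, trans))
    times <- apply_dead_time(times[times <= spec$trial_duration_s],
                             fiber$refractory_ms / 1000)
    times
  })
}

#' Simulate a complete recording of one protocol
#'
#' Builds the trial table for every grid point x repetition in
#' randomized order, optionally with silent trials interleaved as often
#' as the number of repetitions, and draws spike trains from the fibre
#' model. Click trials place a first spike at
#' `latency_base_ms + tw_delay_ms(cf)` plus Gaussian jitter, followed by
#' a brief exponentially decaying transient.
#'
#' @param fiber A [fiber_ground_truth].
#' @param rec_type Target [recording_types()] label.
#' @param spec A [stimulus_spec].
#' @param include_silent Interleave silent trials (tone specs only).
#' @param seed Optional integer seed.
#' @param with_raw Also synthesize raw voltage traces (48828 Hz) via
#'   [synthesize_voltage_trace()].
#' @param noise_sd,spike_amp Raw-trace noise SD and spike amplitude
#'   (arbitrary units) when `with_raw` is `TRUE`.
#' @return An [an_recording].
#' @export
simulate_recording <- function(fiber, rec_type, spec, include_silent = TRUE,
                               seed = NULL, with_raw = FALSE,
                               noise_sd = 1, spike_amp = 8) {
  check_rec_type(rec_type)
  stopifnot(inherits(fiber, "fiber_ground_truth"),
            inherits(spec, "stimulus_spec"))
  if (spec$kind == "tone") {
    grid <- expand.grid(freq = spec$freq_grid, level = spec$level_grid)
    if (nrow(grid) == 0L) abort_anf("empty stimulus grid",
                                    "anfiber_grid_error")
    cond <- do.call(rbind, replicate(spec$repetitions, grid,
                                     simplify = FALSE))
    cond$rep <- rep(seq_len(spec$repetitions), each = nrow(grid))
    if (include_silent) {
      cond <- rbind(cond, data.frame(freq = NA_real_, level = NA_real_,
                                     rep = seq_len(spec$repetitions)))
    }
  } else if (spec$kind == "click") {
    cond <- data.frame(freq = NA_real_, level = NA_real_,
                       rep = seq_len(spec$repetitions))
    cond$click <- TRUE
  } else {
    cond <- data.frame(freq = NA_real_, level = NA_real_,
                       rep = seq_len(spec$repetitions))
  }
  ord <- with_seed(derive_seed(seed, 17), sample.int(nrow(cond)))
  cond <- cond[ord, , drop = FALSE]
  spikes <- vector("list", nrow(cond))
  for (i in seq_len(nrow(cond))) {
    s_i <- derive_seed(seed, 100 + i)
    spikes[[i]] <- if (!is.null(cond$click)) {
      sim_click_trial(fiber, spec, s_i)
    } else if (is.na(cond$freq[i])) {
      if (spec$kind == "frozen_noise") {
        sim_noise_trial(fiber, spec, s_i)
      } else {
        sim_silent_trial(fiber, spec$trial_duration_s, s_i)
      }
    } else {
      sim_tone_trial(fiber, cond$freq[i], cond$level[i], spec, s_i)
    }
  }
  settings <- an_settings(trial_duration_s = spec$trial_duration_s,
                          stim_onset_s = spec$onset_s,
                          stim_duration_s = spec$duration_s,
                          extras = list(kind = spec$kind,
                                        repetitions = as.numeric(spec$repetitions)))
  trials <- an_trials(spike_times = spikes,
                      stim_freq_hz = cond$freq,
                      stim_level_db = cond$level,
                      repetition_index = cond$rep,
                      duration_s = rep(spec$trial_duration_s, nrow(cond)),
                      trial_duration_s = spec$trial_duration_s)
  raw <- NULL
  if (with_raw) {
    tmpl <- spike_template(settings$sample_rate_hz)
    traces <- lapply(seq_along(spikes), function(i) {
      synthesize_voltage_trace(spikes[[i]], spec$trial_duration_s,
                               settings$sample_rate_hz, template = tmpl,
                               noise_sd = noise_sd, amplitude = spike_amp,
                               seed = derive_seed(seed, 9000 + i))
    })
    raw <- an_raw(traces, trigger_level = 4 * noise_sd,
                  sample_rate_hz = settings$sample_rate_hz)
  }
  an_recording(rec_type, trials, settings,
               filename = sprintf("sim_%s.rec", rec_type), raw = raw)
}

# Frozen-noise trial: the envelope is a fixed function of the fibre's
# seed, shared by all repetitions (frozen), but spikes vary by trial.
sim_noise_trial <- function(fiber, spec, seed) {
  env_seed <- derive_seed(fiber$seed %||% 1, 555)
  amps <- with_seed(env_seed, stats::runif(16, 0, 1))
  env <- function(t) {
    idx <- pmin(floor((t - spec$onset_s) / spec$duration_s * 16) + 1, 16)
    inside <- t >= spec$onset_s & t < spec$onset_s + spec$duration_s
    ifelse(inside, amps[pmax(idx, 1)], 0)
  }
  rate_fn <- function(t) fiber$spont_rate_hz +
    fiber$max_driven_rate_hz * env(t)
  simulate_spike_train(rate_fn, spec$trial_duration_s,
                       refractory_ms = fiber$refractory_ms, seed = seed)
}

#' Default stimulus specifications per recording type
#'
#' The grids emulate typical acquisition settings: frequency-response
#' curves ~1.5 octaves around the (audio-visually estimated) CF at 10 dB
#' above threshold; rate-level functions at CF in 5-dB steps; response
#' fields on a frequency x level lattice; phase-locking runs at CF with
#' many repetitions; ~2.4-s silence trials for spontaneous rate; brief
#' click trials with a pre-onset baseline window.
#'
#' @param fiber A [fiber_ground_truth] (grids are centred on its CF and
#'   threshold, playing the role of the experimenter's audio-visual
#'   estimate).
#' @param rec_type One of [recording_types()].
#' @return A [stimulus_spec].
#' @export
default_spec <- function(fiber, rec_type) {
  check_rec_type(rec_type)
  cf <- fiber$cf_hz
  thr <- fiber$threshold_dbspl
  switch(rec_type,
    BF = stimulus_spec("tone",
                       freq_grid = round(2^seq(log2(cf) - 0.75,
                                               log2(cf) + 0.75,
                                               length.out = 25)),
                       level_grid = thr + 10, repetitions = 5),
    RLF = stimulus_spec("tone", freq_grid = cf,
                        level_grid = seq(max(0, thr - 20), thr + 40, by = 5),
                        repetitions = 10),
    CF = stimulus_spec("tone",
                       freq_grid = round(2^seq(log2(cf) - 1, log2(cf) + 1,
                                               length.out = 15)),
                       level_grid = seq(max(0, thr - 15), thr + 30, by = 5),
                       repetitions = 10),
    PH = stimulus_spec("tone", freq_grid = cf,
                       level_grid = thr + c(10, 20, 30), repetitions = 50),
    CLICK = stimulus_spec("click", onset_s = 0.01, duration_s = 0.0001,
                          trial_duration_s = 0.04, repetitions = 100),
    SR = stimulus_spec("silence", onset_s = 0, duration_s = 2.4,
                       trial_duration_s = 2.4, repetitions = 100),
    NOISE = ,
    SPS = ,
    CVC = stimulus_spec("frozen_noise", onset_s = 0.05, duration_s = 1,
                        trial_duration_s = 1.2, repetitions = 60))
}

#' Sample a population of fibres and build a complete experiment
#'
#' CFs are drawn log-uniformly over 428-15825 Hz; spontaneous rates from
#' a bimodal mixture with modes near 5 and 60 spikes/s; phase-locking
#' strength declines with CF and is 0 at and above 5 kHz; thresholds are
#' elevated with age. Each unit gets BF, RLF, CF, CLICK and SR
#' recordings, plus PH when its CF is below 5 kHz.
#'
#' @param n_units Number of fibres (>= 1).
#' @param age_months Animal age in months.
#' @param seed Integer seed; fixes the fibre sample and all spike times.
#' @param animal_id Identifier for the experiment.
#' @param rec_types Recording types to simulate per unit.
#' @param sr_reps Repetitions of the 2.4-s silence trial in SR
#'   recordings (100 emulates the full protocol; tests use fewer).
#' @param with_raw Attach synthesized voltage traces to the BF recording.
#' @return An [an_experiment] with attribute `ground_truth`: the list of
#'   [fiber_ground_truth] objects, one per unit.
#' @export
simulate_experiment <- function(n_units, age_months = 6, seed = NULL,
                                animal_id = "SIM001",
                                rec_types = c("BF", "RLF", "CF", "PH",
                                              "CLICK", "SR"),
                                sr_reps = 100, with_raw = FALSE) {
  if (!is_scalar_number(n_units) || n_units < 1) {
    abort_anf("n_units must be >= 1", "anfiber_invariant_error")
  }
  group <- as.character(assign_age_group(age_months))
  fibers <- with_seed(derive_seed(seed, 1), {
    lapply(seq_len(n_units), function(i) sample_fiber(group, seed, i))
  })
  info <- with_seed(derive_seed(seed, 2), {
    abr <- switch(group,
                  young = stats::rnorm(1, 18.1, 5.3),
                  middle = stats::rnorm(1, 34.2, 10.2),
                  old = stats::rnorm(1, 49.0, 18.0))
    wt <- switch(group,
                 young = stats::rnorm(1, 74.6, 11.1),
                 middle = stats::rnorm(1, 83.4, 12.7),
                 old = stats::rnorm(1, 86.4, 11.6))
    an_info(sex = sample(c("F", "M"), 1), age_months = age_months,
            weight_g = round(max(wt, 40), 1),
            abr_threshold_dbspl = round(min(max(abr, 0), 120)),
            sound_system = "synthetic", recording_system = "synthetic",
            anesthesia_notes = "synthetic fibre model, no animal")
  })
  units <- lapply(seq_len(n_units), function(i) {
    fb <- fibers[[i]]
    recs <- list()
    for (ty in rec_types) {
      if (ty == "PH" && fb$cf_hz >= 5000) next
      spec <- default_spec(fb, ty)
      if (ty == "SR") spec$repetitions <- as.integer(sr_reps)
      recs[[ty]] <- simulate_recording(
        fb, ty, spec, seed = derive_seed(seed, 1000 * i + match(ty, rec_types)),
        with_raw = with_raw && ty == "BF")
    }
    an_unit(sprintf("u%03d", i), recs)
  })
  exp <- an_experiment(animal_id, info, units)
  attr(exp, "ground_truth") <- fibers
  exp
}

# One fibre draw; assumes the caller set the RNG state.
sample_fiber <- function(group, seed, i) {
  cf <- round(exp(stats::runif(1, log(428), log(15825))))
  sr <- if (stats::runif(1) < 0.4) {
    stats::rlnorm(1, log(5), 0.5)        # low-SR mode near 5 spikes/s
  } else {
    max(stats::rnorm(1, 60, 15), 18.5)   # high-SR mode near 60 spikes/s
  }
  age_shift <- switch(group, young = 0, middle = 15, old = 30)
  thr <- min(max(stats::rnorm(1, 20 + age_shift, 7), 0), 90)
  rolloff <- pmin(pmax(log2(5000 / cf) / log2(5000 / 500), 0), 1)
  vs <- 0.9 * rolloff * if (sr < 18) 1 else 0.85
  fiber_ground_truth(
    cf_hz = cf, threshold_dbspl = thr, spont_rate_hz = sr,
    max_driven_rate_hz = stats::runif(1, 120, 250),
    dynamic_range_db = stats::runif(1, 20, 40),
    q10 = stats::runif(1, 2, 8) * (cf / 4000)^0.25,
    vs_max = vs, latency_base_ms = stats::runif(1, 0.8, 1.2),
    click_jitter_ms = 0.1, refractory_ms = 0.6,
    seed = derive_seed(seed, 7000 + i))
}
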