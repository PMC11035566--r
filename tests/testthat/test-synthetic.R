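test_that("rate response is spontaneous below threshold and saturates", {
  fb <- fiber_ground_truth(cf_hz = 2000, threshold_dbspl = 25,
                           spont_rate_hz = 40, max_driven_rate_hz = 160,
                           dynamic_range_db = 30, q10 = 4)
  expect_identical(rate_response(fb, 2000, 15), 40)
  expect_identical(rate_response(fb, 2000, 25 + 30), 200)
  expect_identical(rate_response(fb, 2000, 25 + 60), 200)
  # half-way up the dynamic range
  expect_equal(rate_response(fb, 2000, 25 + 15), 40 + 80)
})

test_that("the V-shaped tuning curve has the prescribed 10-dB bandwidth", {
  for (q10 in c(1.5, 3, 8)) {
    fb <- fiber_ground_truth(cf_hz = 4000, threshold_dbspl = 20, q10 = q10)
    # solve the V analytically: edges at cf * 2^(+/-u)
    x <- (1 / q10 + sqrt(1 / q10^2 + 4)) / 2
    f_lo <- 4000 / x
    f_hi <- 4000 * x
    expect_equal(tuning_threshold_true(fb, f_lo), 30, tolerance = 1e-10)
    expect_equal(tuning_threshold_true(fb, f_hi), 30, tolerance = 1e-10)
    expect_equal(f_hi - f_lo, 4000 / q10, tolerance = 1e-8)
    expect_identical(tuning_threshold_true(fb, 4000), 20)
  }
})

test_that("spike trains obey rate, dead time and determinism", {
  expect_length(simulate_spike_train(0, 1, seed = 1), 0L)

  # homogeneous 100 spikes/s for 100 s: Poisson tail bound
  st <- simulate_spike_train(100, 100, seed = 2)
  expect_true(abs(length(st) - 1e4) < 4 * sqrt(1e4))
  expect_false(is.unsorted(st))

  # empirical rate of an inhomogeneous train within 3 SE of its integral
  rate_fn <- function(t) 50 * (1 + sin(2 * pi * t / 10))
  st2 <- simulate_spike_train(rate_fn, 100, seed = 3)
  expect_true(abs(length(st2) - 5000) < 3 * sqrt(5000))

  # identical seeds give identical trains; different seeds differ
  expect_identical(simulate_spike_train(80, 2, phase = list(freq_hz = 500,
                                                            vs_target = 0.5),
                                        seed = 7),
                   simulate_spike_train(80, 2, phase = list(freq_hz = 500,
                                                            vs_target = 0.5),
                                        seed = 7))
  expect_false(identical(simulate_spike_train(80, 2, seed = 7),
                         simulate_spike_train(80, 2, seed = 8)))

  # dead time: no ISI below the refractory period
  st3 <- simulate_spike_train(400, 20, refractory_ms = 0.6, seed = 4)
  expect_true(all(diff(st3) >= 0.0006))

  expect_error(simulate_spike_train(10, 1, phase = list(freq_hz = 100,
                                                        vs_target = 1)),
               "vs_target")
})

test_that("phase-locking calibration hits the target vector strength", {
  # kappa inversion: mean resultant length matches the target
  for (vs in c(0.1, 0.5, 0.9)) {
    k <- vs_to_kappa(vs)
    expect_equal(besselI(k, 1, TRUE) / besselI(k, 0, TRUE), vs,
                 tolerance = 1e-8)
  }
  expect_identical(vs_to_kappa(0), 0)

  # measured vs on >= 1e4 spikes within +/-0.02 of target (no dead time)
  for (vs_target in c(0.3, 0.7)) {
    st <- simulate_spike_train(500, 30, phase = list(freq_hz = 200,
                                                     vs_target = vs_target),
                               seed = 42)
    expect_gt(length(st), 1e4)
    meas <- vector_strength(st, 200)
    expect_equal(meas$vs, vs_target, tolerance = 0.02)
  }

  # vs_target 0: pooled phases are uniform, locking not significant
  st0 <- simulate_spike_train(200, 10, phase = list(freq_hz = 200,
                                                    vs_target = 0),
                              seed = 5)
  m0 <- vector_strength(st0, 200)
  expect_gt(vs_significance(m0$vs, m0$n), 0.001)
})

test_that("simulated recordings carry the requested structure", {
  fb <- fiber_ground_truth(cf_hz = 1000, threshold_dbspl = 20,
                           spont_rate_hz = 60, max_driven_rate_hz = 150,
                           seed = 1)
  # SR recording recovers the (dead-time corrected) spontaneous rate
  sr_rec <- simulate_recording(fb, "SR",
                               stimulus_spec("silence", onset_s = 0,
                                             duration_s = 2.4,
                                             trial_duration_s = 2.4,
                                             repetitions = 50),
                               seed = 9)
  est <- spontaneous_rate(sr_rec)
  corrected <- 60 / (1 + 60 * 0.0006)
  se <- sqrt(corrected / est$total_silent_time_s)
  expect_lt(abs(est$sr_mean - corrected), 3 * se)

  # BF recording: rate maximum lands at the grid frequency nearest CF
  bf_rec <- simulate_recording(fb, "BF", default_spec(fb, "BF"), seed = 10)
  s <- bf_rec$settings
  st <- trial_rates(bf_rec$trials, s$stim_onset_s, s$stim_duration_s)$stats
  peak_f <- st$stim_freq_hz[which.max(st$mean_rate)]
  expect_lt(abs(log2(peak_f / 1000)), 0.25)

  # silent trials are interleaved as often as the repetitions
  expect_equal(sum(is_silent(bf_rec$trials)), 5L)

  # CLICK with zero jitter: every FSL equals base latency + delay
  fb0 <- fiber_ground_truth(cf_hz = 4000, threshold_dbspl = 20,
                            spont_rate_hz = 0, max_driven_rate_hz = 100,
                            latency_base_ms = 1, click_jitter_ms = 0)
  ck <- simulate_recording(fb0, "CLICK", default_spec(fb0, "CLICK"),
                           seed = 11)
  fsl <- fsl_stats(ck$trials, ck$settings$stim_onset_s)
  expect_equal(fsl$fsl_sd_ms, 0, tolerance = 1e-9)
  expect_equal(fsl$fsl_mean_ms, 1 + tw_delay_ms(4000), tolerance = 1e-6)

  expect_error(stimulus_spec("tone", freq_grid = numeric(0),
                             level_grid = 40),
               class = "anfiber_grid_error")
})

test_that("simulated experiments honour the population structure", {
  expect_error(simulate_experiment(0), "n_units")

  e <- simulate_experiment(4, age_months = 5, seed = 21,
                           rec_types = c("BF", "SR"), sr_reps = 2)
  gt <- attr(e, "ground_truth")
  expect_length(gt, 4L)
  expect_length(e$units, 4L)
  # phase locking is absent above 5 kHz by construction
  for (g in gt) {
    expect_true(g$cf_hz >= 300 && g$cf_hz <= 16000)
    if (g$cf_hz > 5000) expect_identical(g$vs_max, 0)
  }

  # SR population is bimodal with modes near 5 and 60 spikes/s
  srs <- anfiber:::with_seed(99, {
    vapply(1:500, function(i) {
      anfiber:::sample_fiber("young", 99, i)$spont_rate_hz
    }, numeric(1))
  })
  dens <- density(srs, bw = 4)
  peaks <- dens$x[which(diff(sign(diff(dens$y))) == -2) + 1]
  expect_true(any(abs(peaks - 5) < 5))
  expect_true(any(abs(peaks - 60) < 10))

  # determinism end to end: same seed, same spike times
  e2 <- simulate_experiment(4, age_months = 5, seed = 21,
                            rec_types = c("BF", "SR"), sr_reps = 2)
  attr(e, "ground_truth") <- NULL
  attr(e2, "ground_truth") <- NULL
  expect_identical(e, e2)
})

test_that("no simulated train violates the absolute dead time", {
  e <- simulate_experiment(2, seed = 33, rec_types = c("RLF", "CLICK"),
                           sr_reps = 2)
  for (u in e$units) {
    for (r in u$recordings) {
      isis <- unlist(lapply(r$trials$spike_times, diff))
      if (length(isis)) expect_gte(min(isis), 0.0006)
    }
  }
})

test_that("voltage traces place templates at spike peaks", {
  fs <- 48828
  tr0 <- synthesize_voltage_trace(numeric(0), 0.1, fs, noise_sd = 0)
  expect_true(all(tr0 == 0))
  expect_length(tr0, round(0.1 * fs))

  tr1 <- synthesize_voltage_trace(0.05, 0.1, fs, noise_sd = 0, amplitude = 5)
  expect_equal(which.max(tr1), round(0.05 * fs) + 1)
  expect_equal(max(tr1), 5)

  # a spike at the very edge is inserted clipped and counted
  tr2 <- synthesize_voltage_trace(c(0, 0.05), 0.1, fs, noise_sd = 0)
  expect_equal(attr(tr2, "n_clipped"), 1L)
})
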