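test_that("trial rates count spikes in the stimulus window only", {
  tr <- make_trials(list(seq(0.105, 0.195, length.out = 10)),
                    freqs = 1000, levels = 40, dur = 0.3)
  res <- trial_rates(tr, onset_s = 0.1, duration_s = 0.1)
  expect_equal(res$per_trial, 100)

  tr2 <- make_trials(list(c(0.01, 0.05)), freqs = 1000, levels = 40,
                     dur = 0.3)
  expect_equal(trial_rates(tr2, 0.1, 0.1)$per_trial, 0)

  # two repetitions of one condition: mean and SD over repetitions
  tr3 <- make_trials(list(seq(0.1, 0.199, length.out = 5),
                          seq(0.1, 0.199, length.out = 15)),
                     freqs = c(1000, 1000), levels = c(40, 40), dur = 0.3)
  st <- trial_rates(tr3, 0.1, 0.1)$stats
  expect_equal(st$mean_rate, 100)
  expect_equal(st$sd_rate, sd(c(50, 150)))
  expect_equal(st$n_reps, 2L)

  expect_error(trial_rates(tr, 0.1, 0), "positive")
})

test_that("spontaneous rate uses the total trial duration", {
  rec <- make_recording("SR", list(seq(0.1, 2.3, length.out = 10),
                                   seq(0.1, 2.3, length.out = 10)),
                        dur = 2.4)
  sr <- spontaneous_rate(rec)
  expect_equal(sr$sr_mean, 10 / 2.4)
  expect_equal(sr$sr_sd, 0)
  expect_equal(sr$total_silent_time_s, 4.8)
  expect_equal(sr$source, "SR")

  no_silent <- make_recording("BF", list(c(0.1)), freqs = 1000, levels = 40)
  expect_error(spontaneous_rate(no_silent), class = "anfiber_no_sr_error")
})

test_that("best frequency is the smoothing-spline peak on log frequency", {
  freqs <- 2^seq(log2(1000), log2(4000), length.out = 11)
  tri <- 100 - 60 * abs(log2(freqs / 2000))
  bf <- estimate_bf(make_rate_stats(freqs = freqs, rates = tri))
  expect_equal(log2(bf$bf_hz / 2000), 0, tolerance = 0.01)
  expect_false(bf$boundary)

  mono <- estimate_bf(make_rate_stats(freqs = freqs,
                                      rates = seq(10, 110, length.out = 11)))
  expect_equal(mono$bf_hz, 4000, tolerance = 1)
  expect_true(mono$boundary)

  expect_error(estimate_bf(make_rate_stats(freqs = c(1, 2, 3) * 1000,
                                           rates = c(1, 2, 3))),
               ">= 4 distinct")
})

test_that("best frequency recovers the simulated CF within one grid step", {
  errs <- vapply(1:6, function(s) {
    fb <- fiber_ground_truth(cf_hz = 4000, threshold_dbspl = 20,
                             spont_rate_hz = 30, max_driven_rate_hz = 200,
                             q10 = 3)
    rec <- simulate_recording(fb, "BF", default_spec(fb, "BF"),
                              seed = 400 + s)
    st <- trial_rates(rec$trials, rec$settings$stim_onset_s,
                      rec$settings$stim_duration_s)$stats
    abs(log2(estimate_bf(st)$bf_hz / 4000))
  }, numeric(1))
  grid_step <- 1.5 / 24
  expect_lt(median(errs), grid_step)
})

test_that("RLF threshold applies both criteria with strict inequality", {
  st <- make_rate_stats(levels = c(0, 10, 20, 30), rates = c(2, 8, 20, 60))
  expect_equal(rlf_threshold(st, sr_fixture(0, 0)), 20)

  # rate equal to the criterion does not qualify (strict 'higher than')
  st_eq <- make_rate_stats(levels = c(0, 10, 20), rates = c(16, 16, 16))
  expect_true(is.nan(rlf_threshold(st_eq, sr_fixture(10, 5))))  # T = 16
  expect_equal(rlf_threshold(make_rate_stats(levels = 0, rates = 16.001),
                             sr_fixture(10, 5)), 0)

  # the 15 spikes/s floor applies even with zero spontaneous rate
  st2 <- make_rate_stats(levels = c(0, 10), rates = c(14.9, 15.1))
  expect_equal(rlf_threshold(st2, sr_fixture(0, 0)), 10)

  # unsorted level input is handled
  st3 <- make_rate_stats(levels = c(30, 0, 20, 10), rates = c(60, 2, 20, 8))
  expect_equal(rlf_threshold(st3, sr_fixture(0, 0)), 20)
})

test_that("vector strength matches its defining sum", {
  expect_equal(vector_strength(c(1, 2, 3) / 100, 100)$vs, 1)
  expect_equal(vector_strength(1.23, 100)$vs, 1)  # any single spike
  ph4 <- c(0, 0.25, 0.5, 0.75) / 100
  expect_equal(vector_strength(ph4, 100)$vs, 0, tolerance = 1e-12)
  expect_true(is.nan(vector_strength(numeric(0), 100)$vs))
  expect_error(vector_strength(c(0.1), 0), "positive")

  # direct-sum oracle on random spike sets
  set.seed(31)
  for (rep in 1:10) {
    st <- sort(runif(200, 0, 1))
    f <- runif(1, 50, 500)
    oracle <- Mod(sum(exp(1i * 2 * pi * f * st))) / length(st)
    expect_equal(vector_strength(st, f)$vs, oracle, tolerance = 1e-12)
    expect_true(vector_strength(st, f)$vs >= 0 &&
                  vector_strength(st, f)$vs <= 1)
  }

  # 1000 uniform phases: vs near 0, not significant
  st_u <- sort(runif(1000, 0, 1))
  m <- vector_strength(st_u, 173)
  expect_gt(vs_significance(m$vs, m$n), 0.001)
})

test_that("vs significance follows p = exp(-N vs^2) with the N<50 rule", {
  expect_true(is.nan(vs_significance(0.9, 49)))
  expect_equal(vs_significance(0, 100), 1)
  p <- vs_significance(0.3, 100)
  expect_equal(p, exp(-9))
  expect_equal(p, 1.2341e-4, tolerance = 1e-4)
  expect_true(is_significant(p))
  expect_false(is_significant(NaN))
  expect_false(is_significant(0.001))  # strict

  # p decreases in N (fixed vs>0) and in vs (fixed N)
  ns <- seq(50, 500, by = 50)
  expect_true(all(diff(vapply(ns, vs_significance, numeric(1),
                              vs = 0.2)) < 0))
  vss <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(vapply(vss, function(v) vs_significance(v, 100),
                              numeric(1))) < 0))
})

test_that("phase-locking analysis pools repetitions per level", {
  fb <- fiber_ground_truth(cf_hz = 500, threshold_dbspl = 20,
                           spont_rate_hz = 50, max_driven_rate_hz = 150,
                           vs_max = 0.8)
  rec <- simulate_recording(fb, "PH", default_spec(fb, "PH"), seed = 77)
  ph <- analyze_ph(rec)
  expect_equal(ph$frequency_hz, 500)
  expect_length(ph$vs, length(ph$levels))
  expect_length(ph$p, length(ph$levels))
  # suprathreshold levels pool hundreds of spikes: vs near target
  top <- which.max(ph$levels)
  expect_gt(ph$n_spikes[top], 500)
  expect_equal(ph$vs[top], 0.8, tolerance = 0.05)
  expect_true(is_significant(ph$p[top]))
  # p is NaN exactly when N < 50
  expect_identical(is.nan(ph$p), ph$n_spikes < 50)

  # a level with under 50 pooled spikes gets a NaN p-value
  few <- make_trials(rep(list(c(0.06)), 10), freqs = rep(500, 10),
                     levels = rep(10, 10), dur = 0.3)
  rec2 <- an_recording("PH", few, an_settings(0.3, 0.05, 0.2))
  ph2 <- analyze_ph(rec2)
  expect_true(is.nan(ph2$p))
  expect_equal(ph2$n_spikes, 10L)
})

test_that("tuning thresholds honour the criterion and its override", {
  grid <- expand.grid(f = c(1000, 2000, 4000), l = c(0, 10, 20))
  st <- make_rate_stats(freqs = grid$f, levels = grid$l,
                        rates = rep(1, 9))
  tun <- tuning_thresholds(st, sr_fixture(5, 2))
  expect_true(all(is.nan(tun$threshold_db)))

  # override replaces the spontaneous criterion entirely
  # (expand.grid order: frequency varies fastest within each level)
  st2 <- make_rate_stats(freqs = grid$f, levels = grid$l,
                         rates = c(1, 6, 1, 1, 1, 1, 7, 7, 4))
  tun2 <- tuning_thresholds(st2, sr_fixture(0, 0), criterion_override = 5)
  expect_equal(tun2$criterion, 5)
  expect_equal(tun2$threshold_db[tun2$freqs == 2000], 0)
  expect_equal(tun2$threshold_db[tun2$freqs == 1000], 20)
  expect_true(is.nan(tun2$threshold_db[tun2$freqs == 4000]))

  # monotonicity: raising any mean rate can only lower or keep thresholds
  set.seed(41)
  for (rep in 1:10) {
    rates <- runif(9, 0, 30)
    a <- tuning_thresholds(make_rate_stats(freqs = grid$f, levels = grid$l,
                                           rates = rates),
                           sr_fixture(8, 3))
    k <- sample(9, 1)
    rates[k] <- rates[k] + runif(1, 0, 30)
    b <- tuning_thresholds(make_rate_stats(freqs = grid$f, levels = grid$l,
                                           rates = rates),
                           sr_fixture(8, 3))
    worse <- !is.nan(a$threshold_db) &
      (is.nan(b$threshold_db) | b$threshold_db > a$threshold_db)
    expect_false(any(worse))
  }
})

test_that("CF and Q10dB come from the interpolated tuning curve", {
  # analytic V: flanks cross min+10 dB at 0.8 cf and 1.25 cf
  cf <- 2000
  freqs <- c(0.8 * cf, cf, 1.25 * cf)
  tun <- structure(list(freqs = freqs, threshold_db = c(30, 20, 30),
                        criterion = 10, cf_hz = NaN,
                        min_threshold_db = NaN, q10 = NaN),
                   class = "tuning_result")
  out <- cf_q10(tun)
  expect_equal(out$cf_hz, 2000)
  expect_equal(out$min_threshold_db, 20)
  expect_equal(out$q10, 2000 / (2500 - 1600), tolerance = 1e-10)

  # curve entirely within 10 dB of the minimum: Q10 undefined
  flat <- structure(list(freqs = freqs, threshold_db = c(25, 20, 24),
                         criterion = 10, cf_hz = NaN,
                         min_threshold_db = NaN, q10 = NaN),
                    class = "tuning_result")
  expect_true(is.nan(cf_q10(flat)$q10))

  # a single measurable frequency: CF defined, Q10 NaN
  single <- structure(list(freqs = freqs,
                           threshold_db = c(NaN, 20, NaN),
                           criterion = 10, cf_hz = NaN,
                           min_threshold_db = NaN, q10 = NaN),
                      class = "tuning_result")
  out2 <- cf_q10(single)
  expect_equal(out2$cf_hz, 2000)
  expect_true(is.nan(out2$q10))

  # tied minima resolve to the geometric mean of the tied frequencies
  tied <- structure(list(freqs = c(1000, 2000, 4000, 8000),
                         threshold_db = c(40, 20, 20, 40),
                         criterion = 10, cf_hz = NaN,
                         min_threshold_db = NaN, q10 = NaN),
                    class = "tuning_result")
  expect_equal(cf_q10(tied)$cf_hz, sqrt(2000 * 4000))
})

test_that("cf_q10 agrees with a dense brute-force interpolation oracle", {
  oracle_q10 <- function(freqs, thr) {
    ok <- !is.nan(thr)
    min_thr <- min(thr[ok])
    cf <- exp(mean(log(freqs[which(ok & thr == min_thr)])))
    grid <- seq(min(freqs), max(freqs), by = 0.02)  # sub-Hz resolution
    dense <- approx(log2(freqs), thr, xout = log2(grid))$y
    target <- min_thr + 10
    tip <- which.min(abs(grid - cf))
    lo <- which(dense[1:tip] >= target)
    hi <- which(dense[tip:length(grid)] >= target) + tip - 1L
    if (!length(lo) || !length(hi)) return(NaN)
    cf / (grid[hi[1]] - grid[max(lo)])
  }
  set.seed(53)
  for (rep in 1:10) {
    cf <- runif(1, 800, 6000)
    q10_true <- runif(1, 1.5, 6)
    fb <- fiber_ground_truth(cf_hz = cf, threshold_dbspl = 20,
                             q10 = q10_true)
    freqs <- 2^seq(log2(cf) - 1, log2(cf) + 1, length.out = 21)
    thr <- tuning_threshold_true(fb, freqs) + rnorm(21, 0, 0.5)
    tun <- structure(list(freqs = freqs, threshold_db = thr,
                          criterion = 10, cf_hz = NaN,
                          min_threshold_db = NaN, q10 = NaN),
                     class = "tuning_result")
    got <- cf_q10(tun)$q10
    want <- oracle_q10(freqs, thr)
    expect_equal(got, want, tolerance = 1e-3)
  }
})

test_that("2-bin click latency compares post-onset bins to the baseline", {
  # no post-onset spikes
  tr <- make_trials(list(c(0.001), c(0.002)), dur = 0.04)
  expect_true(is.nan(click_latency_2bins(tr, click_onset_s = 0.01)))

  # silent baseline, two consecutive occupied bins starting 1.00 ms post
  spikes <- lapply(1:20, function(i) 0.01 + 0.001 + (i %% 2) * 0.00005)
  tr2 <- make_trials(spikes, dur = 0.04)
  lat <- click_latency_2bins(tr2, click_onset_s = 0.01)
  expect_equal(lat, 1.0, tolerance = 0.026)

  # single occupied bin (no consecutive pair) stays NaN
  tr3 <- make_trials(rep(list(0.0112), 10), dur = 0.04)
  expect_true(is.nan(click_latency_2bins(tr3, click_onset_s = 0.01)))
})

test_that("Poisson-tail click latency crosses the 1e-6 threshold", {
  tr <- make_trials(list(c(0.001), numeric(0)), dur = 0.04)
  expect_true(is.nan(click_latency_poisson(tr, 0.01, sr_fixture(10, 0))))

  # degenerate: zero spontaneous rate makes the first spike significant
  tr2 <- make_trials(list(c(0.0125), numeric(0)), dur = 0.04)
  expect_equal(click_latency_poisson(tr2, 0.01, sr_fixture(0, 0)), 2.5)

  expect_error(click_latency_poisson(tr2, 0.01, sr_fixture(0, 0), alpha = 0),
               "alpha")
  expect_error(click_latency_poisson(tr2, 0.01, sr_fixture(0, 0), alpha = 1),
               "alpha")

  # strong onset response at ~1.5 ms over spontaneous 50 spikes/s
  lats <- vapply(1:10, function(s) {
    fb <- fiber_ground_truth(cf_hz = 2871, threshold_dbspl = 20,
                             spont_rate_hz = 50, max_driven_rate_hz = 400,
                             latency_base_ms = 1.5 - tw_delay_ms(2871),
                             click_jitter_ms = 0.1)
    rec <- simulate_recording(fb, "CLICK", default_spec(fb, "CLICK"),
                              seed = 600 + s)
    click_latency_poisson(rec$trials, rec$settings$stim_onset_s,
                          sr_fixture(50, 2))
  }, numeric(1))
  expect_true(all(lats >= 1.2 & lats <= 1.8))
})

test_that("first-spike latency statistics use the documented conventions", {
  tr <- make_trials(list(0.011, 0.012, 0.013), dur = 0.04)
  f <- fsl_stats(tr, 0.01)
  expect_equal(f$fsl_mean_ms, 2)
  expect_equal(f$fsl_median_ms, 2)
  expect_equal(f$fsl_sd_ms, 1)
  expect_equal(f$fsl_var, 1)
  expect_equal(f$fsl_iqr_ms, 1)  # type-7 linear interpolation quantiles
  expect_equal(f$n_trials_used, 3L)

  # direct arithmetic oracle on random latency sets
  set.seed(61)
  for (rep in 1:5) {
    lats <- runif(12, 0.001, 0.02)
    tr_r <- make_trials(lapply(lats, function(l) 0.01 + l), dur = 0.05)
    f_r <- fsl_stats(tr_r, 0.01)
    expect_equal(f_r$fsl_mean_ms, mean(lats * 1000))
    expect_equal(f_r$fsl_sd_ms, sd(lats * 1000))
    expect_equal(f_r$fsl_iqr_ms, IQR(lats * 1000))
    expect_equal(f_r$fsl_median_ms, median(lats * 1000))
  }

  # single trial: central values defined, spread NaN
  f1 <- fsl_stats(make_trials(list(0.0123), dur = 0.04), 0.01)
  expect_equal(f1$fsl_mean_ms, 2.3)
  expect_equal(f1$fsl_median_ms, 2.3)
  expect_true(is.nan(f1$fsl_sd_ms))

  # trials without post-onset spikes are excluded and counted
  f2 <- fsl_stats(make_trials(list(0.001, 0.015), dur = 0.04), 0.01)
  expect_equal(f2$n_trials_empty, 1L)
  expect_equal(f2$fsl_mean_ms, 5)

  f3 <- fsl_stats(make_trials(list(0.001), dur = 0.04), 0.01)
  expect_true(is.nan(f3$fsl_mean_ms))
})

test_that("PSTHs convert pooled counts to rates and conserve spikes", {
  tr <- make_trials(list(c(0.0125)), dur = 0.05)
  p <- make_psth(tr, bin_width_s = 0.005, window = c(0, 0.05))
  expect_equal(max(p$rates), 200)
  expect_equal(sum(p$rates > 0), 1L)
  expect_length(p$rates, 10L)

  # conservation identity on randomized inputs
  set.seed(71)
  for (rep in 1:10) {
    n_tr <- sample(1:6, 1)
    dur <- runif(1, 0.1, 1.3)
    spikes <- lapply(seq_len(n_tr),
                     function(i) sort(runif(rpois(1, 20), 0, dur)))
    trr <- make_trials(spikes, dur = dur)
    bw <- sample(c(0.005, 0.013), 1)
    pp <- make_psth(trr, bin_width_s = bw, window = c(0, dur))
    expect_identical(sum(pp$counts), length(unlist(spikes)))
    expect_equal(sum(pp$rates) * bw * n_tr, length(unlist(spikes)))
  }

  # level selection keeps trials within the tolerance around the target
  trl <- make_trials(list(c(0.01), c(0.02), c(0.03)),
                     freqs = c(1000, 1000, 1000),
                     levels = c(28, 33, 40), dur = 0.1)
  psel <- make_psth(trl, level_select = list(target_level = 30,
                                             tolerance = 5),
                    window = c(0, 0.1))
  expect_equal(psel$n_trials, 2L)
})

test_that("complex-stimulus bookkeeping excludes truncated trials", {
  tr <- an_trials(spike_times = list(c(0.1), c(0.2), c(0.3)),
                  stim_freq_hz = rep(NA_real_, 3),
                  stim_level_db = rep(NA_real_, 3),
                  duration_s = c(1.2, 0.8, 1.2), trial_duration_s = 1.2)
  rec <- an_recording("NOISE", tr, an_settings(1.2, 0.05, 1))
  res <- analyze_complex(rec)
  expect_equal(res$ntrials, 2L)
  expect_equal(res$trials, c(1L, 3L))
  expect_length(res$psth$rates, ceiling(1.2 / 0.005))

  all_ok <- an_recording("CVC", make_trials(list(c(0.1), c(0.2)), dur = 1.2),
                         an_settings(1.2))
  expect_equal(analyze_complex(all_ok)$ntrials, 2L)
  expect_error(analyze_complex(make_recording("BF", list(c(0.1)),
                                              freqs = 1, levels = 1)),
               class = "anfiber_type_error")
})
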