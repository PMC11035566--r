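#' Click latency by the two-consecutive-bins method
#'
#' Builds a pooled peristimulus histogram at 0.05-ms bins over the
#' whole trial, takes the highest pre-onset bin count as baseline `B`,
#' and reports the centre of the first post-onset bin of the first pair
#' of consecutive bins that are both strictly higher than `B`, relative
#' to the click onset.
#'
#' @param trials An [an_trials] table of click trials.
#' @param click_onset_s Click onset within the trial (s); a pre-onset
#'   baseline window must exist.
#' @param bin_ms Bin width in ms (0.05 by convention).
#' @return Latency in ms, or `NaN` when no qualifying pair exists.
#' @export
click_latency_2bins <- function(trials, click_onset_s, bin_ms = 0.05) {
  stopifnot(nrow(trials) >= 1, click_onset_s > 0)
  bw <- bin_ms / 1000
  dur <- max(trials$duration_s, na.rm = TRUE)
  psth <- make_psth(trials, bin_width_s = bw, window = c(0, dur))
  counts <- psth$counts
  centers <- psth$bin_centers_s
  pre <- which(centers + bw / 2 <= click_onset_s)
  if (!length(pre)) abort_anf("no pre-onset baseline window",
                              "anfiber_click_error")
  b <- max(counts[pre])
  post <- which(centers - bw / 2 >= click_onset_s)
  for (k in post) {
    if (k + 1L <= length(counts) && counts[k] > b && counts[k + 1L] > b) {
      return((centers[k] - click_onset_s) * 1000)
    }
  }
  NaN
}

#' Click latency by the Poisson tail-probability method
#'
#' Pools the post-onset spikes of all `R` repetitions and sorts them.
#' At the k-th pooled spike, time `t_k` after onset, the probability of
#' observing `k` or more spikes from spontaneous activity alone is
#' `P_k = Pr[Poisson(lambda R t_k) >= k]` with `lambda` the
#' spontaneous rate. The latency is the first `t_k` at which this
#' probability falls below `alpha` (default 1e-6) — the earliest time
#' the accumulated response is incompatible with chance.
#'
#' @param trials An [an_trials] table of click trials.
#' @param click_onset_s Click onset (s).
#' @param sr A [spontaneous_rate()] result, or a list with `sr_mean`;
#'   when `NULL` the rate is estimated from the pooled pre-onset spikes.
#' @param alpha Tail-probability threshold in (0, 1).
#' @return Latency in ms, or `NaN` when the probability never falls
#'   below `alpha`.
#' @export
click_latency_poisson <- function(trials, click_onset_s, sr = NULL,
                                  alpha = 1e-6) {
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    abort_anf("alpha must lie strictly between 0 and 1",
              "anfiber_invariant_error")
  }
  n_rep <- nrow(trials)
  pooled <- unlist(trials$spike_times, use.names = FALSE)
  if (is.null(sr)) {
    pre <- sum(pooled < click_onset_s)
    sr <- list(sr_mean = pre / (n_rep * click_onset_s))
  }
  lambda <- sr$sr_mean
  post <- sort(pooled[pooled >= click_onset_s]) - click_onset_s
  if (!length(post)) return(NaN)
  for (k in seq_along(post)) {
    p_k <- stats::ppois(k - 1, lambda * n_rep * post[k], lower.tail = FALSE)
    if (p_k < alpha) return(post[k] * 1000)
  }
  NaN
}

#' First-spike-latency statistics across repetitions
#'
#' Takes the first post-onset spike of each trial (trials without one
#' are excluded; their count is reported), and summarizes the
#' latencies: mean, median, SD, variance and interquartile range. The
#' IQR uses the linear-interpolation quantile rule (R type 7). With a
#' single contributing trial the spread measures are `NaN`; with none,
#' everything is `NaN`.
#'
#' @param trials An [an_trials] table.
#' @param click_onset_s Click onset (s).
#' @return List of class `fsl_stats`: `fsl_mean_ms`, `fsl_median_ms`,
#'   `fsl_sd_ms`, `fsl_var`, `fsl_iqr_ms`, `n_trials_used`,
#'   `n_trials_empty`, `fsl_ms` (the per-trial latencies).
#' @export
fsl_stats <- function(trials, click_onset_s) {
  fsl <- vapply(trials$spike_times, function(st) {
    post <- st[st >= click_onset_s]
    if (length(post)) (post[1] - click_onset_s) * 1000 else NA_real_
  }, numeric(1))
  used <- fsl[!is.na(fsl)]
  n <- length(used)
  out <- list(
    fsl_mean_ms = if (n) mean(used) else NaN,
    fsl_median_ms = if (n) stats::median(used) else NaN,
    fsl_sd_ms = if (n > 1) stats::sd(used) else NaN,
    fsl_var = if (n > 1) stats::var(used) else NaN,
    fsl_iqr_ms = if (n > 1) stats::IQR(used, type = 7) else NaN,
    n_trials_used = n,
    n_trials_empty = sum(is.na(fsl)),
    fsl_ms = used)
  class(out) <- "fsl_stats"
  out
}
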