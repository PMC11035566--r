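#' Canonical biphasic spike template
#'
#' A positive peak followed by a shallower trough, with roughly 1 ms of
#' support, normalized so the peak sample equals exactly 1. The peak
#' index is returned so insertions can be aligned to sample precision.
#'
#' @param sample_rate_hz Sampling rate (Hz).
#' @param width_ms Approximate support of the waveform (ms).
#' @return List with `samples` (numeric vector) and `peak_index`
#'   (1-based position of the +1 peak).
#' @export
spike_template <- function(sample_rate_hz = 48828, width_ms = 1) {
  half <- round(width_ms / 2 / 1000 * sample_rate_hz)
  t <- (seq(-half, half)) / sample_rate_hz * 1000  # ms around the peak
  w <- exp(-(t / (width_ms / 6))^2) - 0.45 * exp(-((t - width_ms / 4) /
                                                     (width_ms / 3.5))^2)
  w <- w / max(w)
  list(samples = w, peak_index = which.max(w))
}

#' Synthesize one raw voltage trace from spike times
#'
#' Gaussian background noise plus template instances whose peak sample
#' lands at `round(spike_time * fs) + 1` (1-based). Spikes whose
#' template would overhang the trace edges are inserted clipped; the
#' number of clipped insertions is attached as attribute `n_clipped`.
#'
#' @param spike_times Spike times (s) within the trial.
#' @param trial_duration_s Trace duration (s).
#' @param sample_rate_hz Sampling rate (Hz).
#' @param template A [spike_template()]-style list.
#' @param noise_sd Background noise SD (arbitrary units).
#' @param amplitude Mean spike peak amplitude.
#' @param amp_jitter_sdlog Log-normal SD of per-spike amplitude (0 for
#'   constant amplitude); emulates the amplitude drift seen in real
#'   recordings.
#' @param seed Optional integer seed.
#' @return Numeric trace of `round(trial_duration_s * sample_rate_hz)`
#'   samples, with attribute `n_clipped`.
#' @export
synthesize_voltage_trace <- function(spike_times, trial_duration_s,
                                     sample_rate_hz = 48828,
                                     template = spike_template(sample_rate_hz),
                                     noise_sd = 1, amplitude = 8,
                                     amp_jitter_sdlog = 0, seed = NULL) {
  n <- round(trial_duration_s * sample_rate_hz)
  w <- template$samples
  pk <- template$peak_index
  with_seed(seed, {
    trace <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
    amps <- if (amp_jitter_sdlog > 0) {
      amplitude * stats::rlnorm(length(spike_times), 0, amp_jitter_sdlog)
    } else {
      rep(amplitude, length(spike_times))
    }
    n_clipped <- 0L
    for (i in seq_along(spike_times)) {
      centre <- round(spike_times[i] * sample_rate_hz) + 1L
      lo <- centre - pk + 1L
      hi <- lo + length(w) - 1L
      src <- seq_along(w)
      if (lo < 1L || hi > n) {
        n_clipped <- n_clipped + 1L
        src <- src[lo + src - 1L >= 1L & lo + src - 1L <= n]
        if (!length(src)) next
      }
      idx <- lo + src - 1L
      trace[idx] <- trace[idx] + amps[i] * w[src]
    }
    attr(trace, "n_clipped") <- n_clipped
    trace
  })
}
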