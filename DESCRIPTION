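Package: anfiber
Title: Analysis and Simulation of Auditory-Nerve Single-Unit Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing single auditory-nerve fibres from
    trial-based spike-train and raw-voltage recordings: offline spike
    detection (zero-phase Chebyshev type-II band-pass filtering and
    trigger-crossing peak detection), best-frequency estimation by
    smoothing-spline fits of frequency-response curves, rate-level
    thresholds, frequency tuning curves with characteristic frequency and
    Q10dB, vector strength with exponential-tail significance, click-response
    latencies (Poisson tail-probability and two-consecutive-bin methods),
    first-spike-latency jitter, peristimulus time histograms, and
    single-unit isolation screens based on inter-spike intervals, spike
    waveforms, and rate-level monotonicity. Includes a seedable
    phenomenological simulator of auditory-nerve fibres (inhomogeneous
    Poisson spiking with absolute dead time and von Mises phase locking)
    that generates complete synthetic experiments with known ground truth
    for end-to-end parameter-recovery testing, loaders for the nested
    MATLAB experiment containers used by published gerbil auditory-nerve
    datasets, a portable JSON serialization, and command-line entry
    points for reproducible batch runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
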