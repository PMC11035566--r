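# Numeric coercion for values coming out of the MATLAB bridge, where NaN
# arrives as the string "NaN".
mat_num <- function(x) {
  if (is.null(x) || (is.list(x) && length(x) == 0L)) return(numeric(0))
  x <- unlist(x, use.names = FALSE)
  if (is.character(x)) x[x == "NA"] <- NA
  suppressWarnings(as.numeric(x))
}

mat_field <- function(node, candidates) {
  for (k in candidates) {
    hit <- which(tolower(names(node)) == tolower(k))
    if (length(hit)) return(node[[hit[1]]])
  }
  NULL
}

mat_chr <- function(x, default = "") {
  if (is.null(x)) return(default)
  as.character(x)[1]
}

mat_parse_error <- function(where) {
  abort_anf(paste0("malformed experiment container: missing '", where, "'"),
            "anfiber_parse_error")
}

run_mat_bridge <- function(path, python = "python") {
  script <- system.file("python", "mat_to_json.py", package = "anfiber")
  if (!nzchar(script)) {
    abort_anf("bridge script mat_to_json.py not found in installed package",
              "anfiber_parse_error")
  }
  out <- tempfile(fileext = ".json")
  on.exit(unlink(out))
  status <- suppressWarnings(
    system2(python, c(shQuote(script), shQuote(path), shQuote(out)),
            stdout = TRUE, stderr = TRUE))
  if (!is.null(attr(status, "status")) || !file.exists(out)) {
    abort_anf(paste0("MATLAB bridge failed for '", path, "': ",
                     paste(status, collapse = "\n")),
              "anfiber_parse_error")
  }
  jsonlite::fromJSON(out, simplifyVector = FALSE)
}

mat_to_settings <- function(cs, n_trials) {
  cs <- cs %||% list()
  trial_dur <- mat_num(mat_field(
    cs, c("trial_duration", "acquisition_duration", "trialdur", "dur")))
  onset <- mat_num(mat_field(cs, c("stim_onset", "stimulus_delay", "delay")))
  stim_dur <- mat_num(mat_field(
    cs, c("stim_duration", "stimulus_duration", "tone_duration")))
  fs <- mat_num(mat_field(cs, c("samplerate", "sample_rate", "fs")))
  if (!length(trial_dur)) mat_parse_error("curvesettings.trial_duration")
  known <- c("trial_duration", "acquisition_duration", "trialdur", "dur",
             "stim_onset", "stimulus_delay", "delay", "stim_duration",
             "stimulus_duration", "tone_duration", "samplerate",
             "sample_rate", "fs")
  extras <- cs[!tolower(names(cs)) %in% known]
  an_settings(trial_duration_s = trial_dur[1],
              stim_onset_s = if (length(onset)) onset[1] else 0,
              stim_duration_s = if (length(stim_dur)) stim_dur[1]
                                else trial_dur[1],
              sample_rate_hz = if (length(fs)) fs[1] else 48828,
              extras = extras)
}

mat_to_recording <- function(node, rec_type) {
  cd <- mat_field(node, "curvedata")
  if (is.null(cd)) mat_parse_error(paste0(rec_type, ".curvedata"))
  st <- mat_field(cd, c("spike_times", "spiketimes"))
  if (is.null(st)) mat_parse_error(paste0(rec_type, ".curvedata.spike_times"))
  spikes <- lapply(st, mat_num)
  n <- length(spikes)
  freqs <- mat_num(mat_field(cd, c("freqs", "frequencies", "stim_freqs")))
  levels <- mat_num(mat_field(cd, c("levels", "stim_levels")))
  reps <- mat_num(mat_field(cd, c("reps", "repetitions")))
  if (!length(freqs)) freqs <- rep(NA_real_, n)
  if (!length(levels)) levels <- rep(NA_real_, n)
  freqs[is.nan(freqs)] <- NA_real_
  levels[is.nan(levels)] <- NA_real_
  # a trial is silent only when both variables are absent
  half_silent <- xor(is.na(freqs), is.na(levels))
  freqs[half_silent] <- NA_real_
  levels[half_silent] <- NA_real_
  settings <- mat_to_settings(mat_field(node, "curvesettings"), n)
  raw <- NULL
  cr <- mat_field(node, "curveresp")
  traces <- mat_field(cr %||% list(), c("traces", "waveforms", "resp"))
  if (!is.null(traces) && length(traces)) {
    trig <- mat_num(mat_field(cr, c("trigger_level", "trigger")))
    raw <- an_raw(lapply(traces, mat_num),
                  trigger_level = if (length(trig)) trig else NA_real_,
                  sample_rate_hz = settings$sample_rate_hz)
  }
  analysis <- mat_field(node, "analysis")
  if (!is.null(analysis) && (!is.list(analysis) || !length(analysis))) {
    analysis <- NULL
  }
  an_recording(rec_type = rec_type,
               trials = an_trials(
                 spike_times = lapply(spikes, sort),
                 stim_freq_hz = freqs, stim_level_db = levels,
                 repetition_index = if (length(reps)) reps else NULL,
                 trial_duration_s = settings$trial_duration_s),
               settings = settings,
               filename = mat_chr(mat_field(node, "filename")),
               raw = raw,
               analysis = if (!is.null(analysis)) simplify_free(analysis))
}

mat_to_info <- function(info) {
  info <- info %||% list()
  known <- c("sex", "age", "age_months", "weight", "weight_g", "abr",
             "abr_threshold", "sound_system", "recording_system",
             "anesthesia")
  abr <- mat_field(info, c("abr_threshold", "abr"))
  if (is.list(abr)) abr <- mat_field(abr, c("threshold", "thr"))
  an_info(
    sex = chr_or_na(mat_field(info, "sex")),
    age_months = mat_num(mat_field(info, c("age_months", "age")))[1],
    weight_g = {
      w <- mat_num(mat_field(info, c("weight_g", "weight")))
      if (length(w)) w[1] else NA_real_
    },
    abr_threshold_dbspl = {
      a <- mat_num(abr)
      if (length(a)) a[1] else NA_real_
    },
    sound_system = mat_chr(mat_field(info, "sound_system")),
    recording_system = mat_chr(mat_field(info, "recording_system")),
    anesthesia_notes = mat_chr(mat_field(info, "anesthesia")),
    extras = info[!tolower(names(info)) %in% known])
}

#' Load one experiment container
#'
#' Reads either a portable JSON container written by [save_portable()]
#' or a nested-struct MATLAB file (`exp` variable with fields
#' `animalID`, `info` and `data`; per-recording fields `filename`,
#' `analysis`, `curvedata`, `curvesettings`, `curveresp`). Both the
#' legacy and the HDF5-based (v7.3) MATLAB dialects are supported via a
#' bundled Python bridge. Metadata fields that are not part of the typed
#' model are preserved in `extras`.
#'
#' @param path Path to a `.json` or `.mat` file.
#' @param python Python interpreter used for `.mat` input.
#' @return An [an_experiment].
#' @export
load_experiment <- function(path, python = "python") {
  if (!file.exists(path)) abort_anf(paste0("no such file: ", path),
                                    "anfiber_parse_error")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    return(load_portable(path))
  }
  tree <- run_mat_bridge(path, python)
  ex <- mat_field(tree, "exp") %||% tree
  if (is.null(mat_field(ex, "animalid"))) mat_parse_error("animalID")
  if (is.null(mat_field(ex, "info"))) mat_parse_error("info")
  data <- mat_field(ex, "data")
  if (is.null(data)) mat_parse_error("data")
  if (!is.null(names(data)) && "unit" %in% tolower(names(data))) {
    data <- list(data)  # single-unit struct, not a struct array
  }
  units <- lapply(data, function(node) {
    uname <- mat_chr(mat_field(node, "unit"), default = NA_character_)
    if (is.na(uname)) mat_parse_error("data.unit")
    recs <- list()
    for (ty in recording_types()) {
      rnode <- mat_field(node, ty)
      if (is.null(rnode) || !is.list(rnode) || !length(rnode)) next
      recs[[ty]] <- mat_to_recording(rnode, ty)
    }
    an_unit(uname, recs)
  })
  an_experiment(chr_or_na(mat_field(ex, "animalid")),
                mat_to_info(mat_field(ex, "info")), units)
}

#' Load and merge a set of experiment containers
#'
#' Multi-part experiments (`<animalID>_1`, `<animalID>_2`, ...) are
#' merged into one experiment per animal via [merge_experiment_parts()].
#'
#' @param paths Character vector of container paths, or a directory.
#' @param python Python interpreter used for `.mat` input.
#' @return List of [an_experiment], one per animal, sorted by ID.
#' @export
load_experiments <- function(paths, python = "python") {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(mat|json)$", full.names = TRUE)
  }
  exps <- lapply(paths, load_experiment, python = python)
  ids <- vapply(exps, function(e) e$animal_id, character(1))
  out <- lapply(split(exps, ids), merge_experiment_parts)
  unname(out[order(names(out))])
}
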