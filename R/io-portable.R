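PORTABLE_FORMAT <- "anfiber-portable"
PORTABLE_VERSION <- "1.0"

# Doubles are written with 17 significant digits, the smallest count that
# round-trips IEEE-754 binary64 exactly, so spike times survive
# save/load bit-identically.
PORTABLE_DIGITS <- 17L

settings_to_list <- function(s) {
  list(trial_duration_s = s$trial_duration_s, stim_onset_s = s$stim_onset_s,
       stim_duration_s = s$stim_duration_s, sample_rate_hz = s$sample_rate_hz,
       extras = s$extras)
}

trials_to_list <- function(tr) {
  list(spike_times = lapply(tr$spike_times, as.numeric),
       stim_freq_hz = tr$stim_freq_hz,
       stim_level_db = tr$stim_level_db,
       repetition_index = tr$repetition_index,
       duration_s = tr$duration_s)
}

recording_to_list <- function(r) {
  out <- list(rec_type = r$rec_type, filename = r$filename,
              settings = settings_to_list(r$settings),
              trials = trials_to_list(r$trials))
  if (!is.null(r$raw)) {
    out$raw <- list(traces = lapply(r$raw$traces, as.numeric),
                    trigger_level = r$raw$trigger_level,
                    sample_rate_hz = r$raw$sample_rate_hz)
  }
  if (!is.null(r$analysis)) out$analysis <- r$analysis
  out
}

#' Save an experiment as a portable container
#'
#' Writes a versioned, self-describing JSON document whose hierarchy
#' mirrors the experiment -> unit -> recording structure. Numeric values
#' are stored with full binary64 precision, so
#' `load_portable(save_portable(e))` reproduces `e` exactly, spike times
#' bit-identical.
#'
#' @param exp An [an_experiment].
#' @param path Output file path (conventionally `.json`).
#' @return `path`, invisibly.
#' @seealso [load_portable()]
#' @export
save_portable <- function(exp, path) {
  stopifnot(inherits(exp, "an_experiment"))
  doc <- list(
    format = PORTABLE_FORMAT,
    version = PORTABLE_VERSION,
    experiment = list(
      animal_id = exp$animal_id,
      info = unclass(exp$info),
      units = lapply(unname(exp$units), function(u) {
        list(unit_name = u$unit_name,
             recordings = lapply(unname(u$recordings), recording_to_list))
      })))
  # na = "string" keeps the NA / NaN / Inf distinction through JSON
  # (jsonlite recognises the tokens when simplifying); the token "NA" is
  # therefore reserved in free-text fields.
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       na = "string", digits = I(PORTABLE_DIGITS),
                       pretty = FALSE)
  invisible(path)
}

num_or_na <- function(x) {
  if (is.null(x)) return(NA_real_)
  if (is.character(x) && x == "NA") return(NA_real_)
  as.numeric(x)
}
chr_or_na <- function(x) {
  if (is.null(x) || (length(x) == 1L && identical(x, "NA"))) {
    return(NA_character_)
  }
  as.character(x)
}

list_to_settings <- function(l) {
  an_settings(trial_duration_s = as.numeric(l$trial_duration_s),
              stim_onset_s = as.numeric(l$stim_onset_s),
              stim_duration_s = as.numeric(l$stim_duration_s),
              sample_rate_hz = as.numeric(l$sample_rate_hz),
              extras = l$extras %||% list())
}

list_to_trials <- function(l, trial_duration_s) {
  an_trials(spike_times = lapply(l$spike_times,
                                 function(v) as.numeric(unlist(v))),
            stim_freq_hz = vapply(l$stim_freq_hz, num_or_na, numeric(1)),
            stim_level_db = vapply(l$stim_level_db, num_or_na, numeric(1)),
            repetition_index = vapply(l$repetition_index, num_or_na, numeric(1)),
            duration_s = vapply(l$duration_s, num_or_na, numeric(1)),
            trial_duration_s = trial_duration_s)
}

# extras/analysis subtrees carry free-form values; simplify vectors but
# never matrices or data frames, so shapes are predictable. Numbers are
# canonically double (JSON does not distinguish 5 from 5L) and the
# NA/NaN/Inf tokens are mapped back to numerics.
canon_free <- function(x) {
  if (is.list(x)) return(lapply(x, canon_free))
  if (is.integer(x)) return(as.double(x))
  if (is.character(x) && length(x) >= 1L &&
      all(x %in% c("NA", "NaN", "Inf", "-Inf"))) {
    out <- suppressWarnings(as.numeric(x))
    out[x == "NA"] <- NA_real_
    return(out)
  }
  x
}

simplify_free <- function(l) {
  if (is.null(l)) return(NULL)
  canon_free(
    jsonlite::fromJSON(jsonlite::toJSON(l, auto_unbox = TRUE, null = "null",
                                        na = "string",
                                        digits = I(PORTABLE_DIGITS)),
                       simplifyVector = TRUE, simplifyMatrix = FALSE,
                       simplifyDataFrame = FALSE))
}

list_to_recording <- function(l) {
  settings <- list_to_settings(l$settings)
  settings$extras <- simplify_free(settings$extras) %||% list()
  raw <- NULL
  if (!is.null(l$raw)) {
    raw <- an_raw(traces = lapply(l$raw$traces,
                                  function(v) as.numeric(unlist(v))),
                  trigger_level = vapply(l$raw$trigger_level, num_or_na,
                                         numeric(1)),
                  sample_rate_hz = as.numeric(l$raw$sample_rate_hz))
  }
  an_recording(rec_type = l$rec_type,
               trials = list_to_trials(l$trials, settings$trial_duration_s),
               settings = settings,
               filename = l$filename %||% "",
               raw = raw,
               analysis = simplify_free(l$analysis))
}

#' Load an experiment from the portable container
#'
#' @param path Path to a file written by [save_portable()].
#' @return The reconstructed [an_experiment].
#' @export
load_portable <- function(path) {
  if (!file.exists(path)) abort_anf(paste0("no such file: ", path),
                                    "anfiber_parse_error")
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, PORTABLE_FORMAT)) {
    abort_anf(sprintf("'%s' is not an %s container", path, PORTABLE_FORMAT),
              "anfiber_parse_error")
  }
  if (!identical(doc$version, PORTABLE_VERSION)) {
    abort_anf(sprintf(
      "portable container version mismatch: file has '%s', reader supports '%s'",
      doc$version %||% "<missing>", PORTABLE_VERSION),
      "anfiber_version_error")
  }
  ex <- doc$experiment
  info_l <- ex$info
  info <- an_info(sex = chr_or_na(info_l$sex),
                  age_months = as.numeric(info_l$age_months),
                  weight_g = num_or_na(info_l$weight_g),
                  abr_threshold_dbspl = num_or_na(info_l$abr_threshold_dbspl),
                  sound_system = chr_or_na(info_l$sound_system),
                  recording_system = chr_or_na(info_l$recording_system),
                  anesthesia_notes = chr_or_na(info_l$anesthesia_notes),
                  extras = simplify_free(info_l$extras) %||% list())
  units <- lapply(ex$units, function(ul) {
    an_unit(ul$unit_name, lapply(ul$recordings, list_to_recording))
  })
  an_experiment(ex$animal_id, info, units)
}
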