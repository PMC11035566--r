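#' Merge multi-part experiments
#'
#' Large experiments are sometimes split over several container files
#' (`<animalID>_1`, `<animalID>_2`, ...) that share the animal ID and
#' metadata but carry disjoint unit lists. This merges such parts into a
#' single experiment.
#'
#' @param parts List of [an_experiment] objects with identical
#'   `animal_id` and `info`.
#' @return One merged [an_experiment].
#' @export
merge_experiment_parts <- function(parts) {
  stopifnot(is.list(parts), length(parts) >= 1L)
  for (p in parts) stopifnot(inherits(p, "an_experiment"))
  ids <- unique(vapply(parts, function(p) p$animal_id, character(1)))
  if (length(ids) != 1L) {
    abort_anf("cannot merge experiments with different animal IDs",
              "anfiber_merge_error")
  }
  base_info <- parts[[1]]$info
  for (p in parts[-1]) {
    if (!identical(unclass(p$info), unclass(base_info))) {
      abort_anf(sprintf(
        "metadata differ between parts of experiment '%s'", ids),
        "anfiber_merge_error")
    }
  }
  units <- do.call(c, lapply(parts, function(p) unname(p$units)))
  an_experiment(ids, base_info, units)
}

#' Choose the most reliable spontaneous-rate source for a unit
#'
#' Spontaneous rate can be estimated from a dedicated silence recording
#' (`SR`) or from the silent trials interleaved in tonal recordings. The
#' preference order is `SR` first (longest total time in silence, about
#' 240 s), then `PH` (many repetitions), then `RLF`, then any other tonal
#' type that contains silent trials — i.e. always the source with the
#' most silence and hence the most precise estimate.
#'
#' @param unit An [an_unit].
#' @return The [spontaneous_rate()] result of the preferred source, a
#'   list with `sr_mean`, `sr_sd`, `total_silent_time_s` and `source`.
#' @export
select_sr_estimate <- function(unit) {
  stopifnot(inherits(unit, "an_unit"))
  order <- c("SR", "PH", "RLF",
             setdiff(tonal_types(), c("PH", "RLF")))
  for (ty in order) {
    rec <- unit$recordings[[ty]]
    if (is.null(rec)) next
    ok <- ty == "SR" || any(is_silent(rec$trials))
    if (ok) return(spontaneous_rate(rec))
  }
  abort_anf(sprintf(
    "unit '%s' has no spontaneous-rate source (no SR recording, no silent trials)",
    unit$unit_name), "anfiber_no_sr_error")
}

#' Build the per-experiment metadata sheet
#'
#' One row per experiment: animal identifier, sex, age (and derived age
#' group), weight, ABR threshold, hardware identifiers, the number of
#' units carrying each recording type, and presence flags for the
#' complex-stimulus protocols.
#'
#' @param experiments List of [an_experiment] objects.
#' @param path Optional file path; when given the sheet is also written
#'   as UTF-8 comma-separated text with a header row.
#' @return A `data.frame`, invisibly when `path` is given.
#' @export
build_metadata_sheet <- function(experiments, path = NULL) {
  stopifnot(is.list(experiments))
  rows <- lapply(experiments, function(e) {
    stopifnot(inherits(e, "an_experiment"))
    types <- unlist(lapply(e$units, function(u) names(u$recordings)))
    counts <- vapply(recording_types(),
                     function(ty) sum(types == ty), integer(1))
    row <- data.frame(
      animal_id = e$animal_id,
      sex = e$info$sex,
      age_months = e$info$age_months,
      age_group = as.character(assign_age_group(e$info$age_months)),
      weight_g = e$info$weight_g,
      abr_threshold_dbspl = e$info$abr_threshold_dbspl,
      sound_system = e$info$sound_system,
      recording_system = e$info$recording_system,
      n_units = length(e$units),
      stringsAsFactors = FALSE)
    for (ty in recording_types()) {
      row[[paste0("n_units_", ty)]] <- counts[[ty]]
    }
    for (ty in complex_types()) {
      row[[paste0("has_", ty)]] <- counts[[ty]] > 0L
    }
    row
  })
  sheet <- do.call(rbind, rows)
  if (is.null(sheet)) {
    # empty input: emit the schema with zero rows
    sheet <- build_metadata_sheet(list(
      an_experiment("placeholder", an_info(age_months = 1),
                    list(an_unit("u", list(
                      SR = an_recording("SR",
                        an_trials(list(numeric(0)), NA, NA,
                                  trial_duration_s = 1),
                        an_settings(1))))))))[0, ]
  }
  rownames(sheet) <- NULL
  if (!is.null(path)) {
    utils::write.csv(sheet, path, row.names = FALSE, fileEncoding = "UTF-8")
    return(invisible(sheet))
  }
  sheet
}

#' Query units across experiments
#'
#' Returns all (experiment, unit) pairs satisfying every given filter,
#' in stable (animal, unit) order. Filters referring to an analysis that
#' a unit lacks skip that unit with a warning rather than failing.
#'
#' @param experiments List of [an_experiment] objects.
#' @param age_group Optional subset of `c("young","middle","old")`.
#' @param bf_range Optional numeric length-2 `(lo, hi)`: keep units whose
#'   best-frequency analysis (`BF` recording, `analysis$bf`) lies in
#'   `[lo, hi]`.
#' @param rec_types Optional character vector: keep units carrying all of
#'   these recording types.
#' @param sr_class Optional `"low"` or `"high"`: spontaneous-rate class
#'   with the conventional cut-off of 18 spikes/s (low: SR < 18).
#' @param sr_cutoff Cut-off rate for `sr_class` (spikes/s).
#' @return A `data.frame` with columns `animal_id` and `unit_name`, plus
#'   list-columns `experiment` and `unit` holding the matched objects.
#' @export
query_units <- function(experiments, age_group = NULL, bf_range = NULL,
                        rec_types = NULL, sr_class = NULL, sr_cutoff = 18) {
  stopifnot(is.list(experiments))
  if (!is.null(sr_class)) sr_class <- match.arg(sr_class, c("low", "high"))
  hits <- list()
  ord <- order(vapply(experiments, function(e) e$animal_id, character(1)))
  for (e in experiments[ord]) {
    grp <- as.character(assign_age_group(e$info$age_months))
    if (!is.null(age_group) && !grp %in% age_group) next
    unames <- names(e$units)[order(names(e$units))]
    for (un in unames) {
      u <- e$units[[un]]
      if (!is.null(rec_types) && !all(rec_types %in% names(u$recordings))) next
      if (!is.null(bf_range)) {
        bf <- u$recordings$BF$analysis$bf
        if (is.null(bf) || !is.finite(bf)) {
          warning(sprintf("unit '%s/%s' skipped: no best-frequency analysis",
                          e$animal_id, un), call. = FALSE)
          next
        }
        if (bf < bf_range[1] || bf > bf_range[2]) next
      }
      if (!is.null(sr_class)) {
        sr <- tryCatch(select_sr_estimate(u), anfiber_no_sr_error = function(c) NULL)
        if (is.null(sr)) {
          warning(sprintf("unit '%s/%s' skipped: no spontaneous-rate source",
                          e$animal_id, un), call. = FALSE)
          next
        }
        cls <- if (sr$sr_mean < sr_cutoff) "low" else "high"
        if (cls != sr_class) next
      }
      hits[[length(hits) + 1L]] <- list(animal_id = e$animal_id,
                                        unit_name = un,
                                        experiment = e, unit = u)
    }
  }
  out <- data.frame(
    animal_id = vapply(hits, `[[`, character(1), "animal_id"),
    unit_name = vapply(hits, `[[`, character(1), "unit_name"),
    stringsAsFactors = FALSE)
  out$experiment <- lapply(hits, `[[`, "experiment")
  out$unit <- lapply(hits, `[[`, "unit")
  out
}
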