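## Tabular interchange is CSV; parameters and reports are JSON. Angles are
## serialized in degrees wrapped to (-180, 180], forces in newtons,
## displacements in cm.

schedule_header <- c("index", "mode", "orientation_deg", "direction",
                     "mass_frac_bm", "phase_label", "block_id",
                     "familiarization")
series_header <- c("trial", "mode", "orientation_deg", "f", "x_net", "error",
                   "abs_error", "adaptation_ratio")
cohort_header <- c("subject_id", "trial", "mode", "orientation_deg",
                   "peak_displacement_cm", "clamp_force_n")

strip_readr_attrs <- function(df) {
  attr(df, "spec") <- NULL
  attr(df, "problems") <- NULL
  df
}

check_header <- function(path, expected, found) {
  if (length(found) == 0) abort(sprintf("empty input file: %s", path))
  if (!all(expected %in% found)) {
    abort(sprintf("%s: expected columns {%s}, found {%s}", path,
                  paste(expected, collapse = ", "),
                  paste(found, collapse = ", ")))
  }
  extra <- setdiff(found, expected)
  if (length(extra) > 0) {
    abort(sprintf("%s: unknown column(s) %s; expected exactly {%s}", path,
                  paste(extra, collapse = ", "),
                  paste(expected, collapse = ", ")))
  }
}

#' Read and write trial schedules
#'
#' CSV round-trip for [build_schedule()] results (one row per trial). The
#' experiment id, group and seed are not stored in the CSV; pass them back
#' via the arguments when reading if downstream analyses need them.
#'
#' @param schedule An `adapt_schedule` tibble.
#' @param path File path.
#' @param experiment_id,group,seed Provenance restored onto the read
#'   schedule.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   the schedule tibble.
#' @export
write_schedule <- function(schedule, path) {
  readr::write_csv(schedule[schedule_header], path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path, experiment_id = NA_character_,
                          group = NA_integer_, seed = NA_integer_) {
  df <- strip_readr_attrs(readr::read_csv(path, show_col_types = FALSE))
  check_header(path, schedule_header, names(df))
  if (nrow(df) == 0) abort(sprintf("no trials in %s", path))
  tibble::new_tibble(df, class = "adapt_schedule",
                     experiment_id = experiment_id,
                     group = group, seed = seed)
}

#' Read and write trial series and cohorts
#'
#' CSV round-trip for simulated trial series ([simulate_model()]) and
#' synthetic cohorts ([generate_cohort()]). Values are written with 9
#' significant digits, which round-trips the quantities used here exactly
#' at the precision of the write.
#'
#' @param x An `adapt_series` or `adapt_cohort` tibble.
#' @param path File path.
#' @return Writers return `path` invisibly; readers the tibble.
#' @export
write_series <- function(x, path) {
  cols <- if (all(cohort_header %in% names(x))) cohort_header else series_header
  out <- x[cols]
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "trial" &
    names(out) != "subject_id"
  out[num] <- lapply(out[num], signif, digits = 9)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  df <- strip_readr_attrs(readr::read_csv(path, show_col_types = FALSE))
  if (all(cohort_header %in% names(df)) &&
      length(names(df)) == length(cohort_header)) {
    check_header(path, cohort_header, names(df))
    cls <- "adapt_cohort"
  } else {
    check_header(path, series_header, names(df))
    cls <- "adapt_series"
  }
  if (nrow(df) == 0) abort(sprintf("no rows in %s", path))
  tibble::new_tibble(df, class = cls)
}

#' Read and write model parameter files
#'
#' JSON serialization of parameter objects, with a `model` key
#' (`"SRM"`, `"DRM"`, `"MCSRM4"`, `"MCSRM10"`) and optionally a nested
#' `compliance` object.
#'
#' @param params An [srm_params()], [drm_params()] or [mcsrm_params()].
#' @param path File path.
#' @param compliance Optional [compliance_profile()] stored alongside.
#' @return `write_params()` returns `path` invisibly; `read_params()` a list
#'   with `params` and `compliance` (possibly `NULL`).
#' @export
write_params <- function(params, path, compliance = NULL) {
  kind <- toupper(model_kind_of(params))
  obj <- c(list(model = kind), params[names(params) != "tuning"])
  if (!is.null(params$tuning)) obj <- c(obj, unclass(params$tuning))
  if (!is.null(compliance)) obj$compliance <- unclass(compliance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- tolower(obj$model)
  params <- switch(kind,
    srm = srm_params(obj$alpha, obj$beta),
    drm = drm_params(obj$alpha1, obj$beta1, obj$alpha2, obj$beta2),
    mcsrm4 = mcsrm_params(obj$alpha, obj$beta, sigma_deg = obj$sigma_deg,
                          offset = obj$offset),
    mcsrm10 = mcsrm_params(obj$alpha, obj$beta, weights = obj$weights),
    abort(sprintf("unknown model kind '%s' in %s", obj$model, path)))
  compliance <- NULL
  if (!is.null(obj$compliance)) {
    compliance <- compliance_profile(obj$compliance$k_plus,
                                     obj$compliance$k_minus,
                                     obj$compliance$gain,
                                     obj$compliance$orientations)
  }
  list(params = params, compliance = compliance)
}
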