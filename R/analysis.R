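#' Normalize the single-context trial series
#'
#' Normalizes a mean peak-displacement series from the single-context
#' experiment for model fitting: subtract the mean displacement over the
#' final 8 trials of the pre-exposure phase, then divide by the maximum
#' displacement across all trials. The output has final-8 pre-exposure mean
#' 0 and maximum exactly 1, and is invariant to affine transformations of
#' the input. A variant anchored on the whole pre-exposure mean is available
#' via `anchor = "all_pre"`.
#'
#' @param series Numeric series aligned to `schedule` (`NA` allowed on
#'   clamp trials).
#' @param schedule An `exp1` [build_schedule()] result.
#' @param anchor `"final8"` (default) or `"all_pre"`.
#' @return Normalized numeric series (same length, `NA`s preserved).
#' @export
normalize_exp1 <- function(series, schedule, anchor = c("final8", "all_pre")) {
  anchor <- match.arg(anchor)
  if (!identical(attr(schedule, "experiment_id"), "exp1")) {
    abort("normalize_exp1 expects an exp1 schedule")
  }
  pre <- which(schedule$phase_label == "pre")
  base_idx <- if (anchor == "final8") tail(pre, 8) else pre
  out <- series - mean(series[base_idx], na.rm = TRUE)
  mx <- max(out, na.rm = TRUE)
  if (mx <= 0) abort("degenerate series: zero range after baseline subtraction")
  out / mx
}

#' Composite multiple-context de-adaptation series and generalization curve
#'
#' Reduces a multiple-context de-adaptation cohort (or a single noise-free
#' model series) to the composite used for fitting and display: the three
#' repeats of each probe orientation are averaged within subject, then
#' across subjects, and the blocks are concatenated in descending relative
#' orientation (180 down to 0 deg) after the initial exposure phase. For
#' each probe the de-adaptation error (mean peak displacement over the first
#' 4 zero-force trials) and re-exposure error (mean over the first 4
#' re-exposure trials) are computed, and a half-Gaussian
#' `error = offset + amplitude * exp(-rel^2 / (2 * width^2))` centered on
#' the training orientation is fit to each error-vs-orientation profile.
#'
#' @param data An `adapt_cohort` on the `exp2` schedule, or a per-trial
#'   numeric series (e.g. `abs_error` from [simulate_model()]).
#' @param schedule The matching `exp2` [build_schedule()] result.
#' @return A list of class `exp2_composite`: `composite` (tibble `trial`,
#'   `displacement`, `segment`, `relative_orientation_deg`), `curve` (tibble
#'   `relative_orientation_deg`, `deadaptation_error_cm`,
#'   `reexposure_error_cm`), and `fits` (half-Gaussian [half_gaussian_fit()]
#'   results for both error profiles).
#' @export
composite_exp2 <- function(data, schedule) {
  if (!identical(attr(schedule, "experiment_id"), "exp2")) {
    abort("composite_exp2 expects an exp2 schedule")
  }
  training <- schedule$orientation_deg[1]
  if (is.data.frame(data)) {
    wide <- tidyr::pivot_wider(
      dplyr::select(data, "subject_id", "trial", "peak_displacement_cm"),
      names_from = "subject_id", values_from = "peak_displacement_cm")
    series_mat <- as.matrix(dplyr::select(dplyr::arrange(wide, .data$trial),
                                          -"trial"))
  } else {
    series_mat <- matrix(as.numeric(data), ncol = 1)
  }
  if (nrow(series_mat) != nrow(schedule)) {
    abort("series length does not match the schedule")
  }

  deadapt_blocks <- grepl("^deadapt_block", schedule$phase_label)
  probe_of_block <- dplyr::distinct(
    tibble::tibble(block_id = schedule$block_id[deadapt_blocks],
                   probe = schedule$orientation_deg[deadapt_blocks]))
  probe_of_block$rel <- abs(circ_diff(probe_of_block$probe, training))
  if (any(table(probe_of_block$probe) != 3)) {
    abort("expected 3 repeats of every probe orientation")
  }

  block_rows <- function(b) which(schedule$block_id == b & schedule$block_id > 0)
  avg_block <- function(probe) {
    ids <- probe_of_block$block_id[probe_of_block$probe == probe]
    # within-subject mean over the 3 repeats, then across subjects
    per_subj <- lapply(ids, function(b) series_mat[block_rows(b), , drop = FALSE])
    rowMeans(Reduce(`+`, per_subj) / length(per_subj), na.rm = TRUE)
  }

  ord <- dplyr::arrange(dplyr::distinct(probe_of_block[c("probe", "rel")]),
                        dplyr::desc(.data$rel))
  blocks <- lapply(ord$probe, avg_block)
  exposure_rows <- which(schedule$block_id == 0)
  composite <- tibble::tibble(
    displacement = c(rowMeans(series_mat[exposure_rows, , drop = FALSE]),
                     unlist(blocks)),
    segment = c(rep("exposure", length(exposure_rows)),
                rep(sprintf("rel_%g", ord$rel), each = 30L)),
    relative_orientation_deg = c(rep(0, length(exposure_rows)),
                                 rep(ord$rel, each = 30L))
  )
  composite$trial <- seq_len(nrow(composite)) - 1L

  # within each 30-trial block: trials 3-10 are the zero-force de-adaptation
  # trials and trials 13-30 the re-exposure trials
  curve <- tibble::tibble(
    relative_orientation_deg = ord$rel,
    deadaptation_error_cm = vapply(blocks, function(b) mean(b[3:6]), numeric(1)),
    reexposure_error_cm = vapply(blocks, function(b) mean(b[13:16]), numeric(1))
  )
  curve <- dplyr::arrange(curve, .data$relative_orientation_deg)
  fits <- list(
    deadaptation = half_gaussian_fit(curve$relative_orientation_deg,
                                     curve$deadaptation_error_cm),
    reexposure = half_gaussian_fit(curve$relative_orientation_deg,
                                   curve$reexposure_error_cm)
  )
  structure(list(composite = composite, curve = curve, fits = fits,
                 training_orientation_deg = training),
            class = "exp2_composite")
}

#' Half-Gaussian fit to a generalization profile
#'
#' Fits `y = offset + amplitude * exp(-x^2 / (2 * width^2))` over
#' non-negative relative orientations by bounded least squares (width
#' profiled over a grid and polished). A flat profile drives the width to
#' its upper bound and is flagged degenerate.
#'
#' @param rel_deg Non-negative relative orientations (degrees).
#' @param y Error values at those orientations.
#' @param width_max Upper bound for the width (degrees).
#' @return List with `width_deg`, `offset`, `amplitude`, `r_squared`,
#'   `degenerate`.
#' @export
half_gaussian_fit <- function(rel_deg, y, width_max = 360) {
  sse_for <- function(w) {
    X <- cbind(1, exp(-rel_deg^2 / (2 * w^2)))
    sum(stats::lm.fit(X, y)$residuals^2)
  }
  grid <- exp(seq(log(5), log(width_max), length.out = 60))
  w0 <- grid[which.min(vapply(grid, sse_for, numeric(1)))]
  opt <- nlminb(log(w0), function(lw) sse_for(exp(lw)),
                lower = log(1), upper = log(width_max),
                control = list(rel.tol = 1e-13))
  w <- exp(opt$par)
  ab <- stats::lm.fit(cbind(1, exp(-rel_deg^2 / (2 * w^2))), y)$coefficients
  sst <- sum((y - mean(y))^2)
  list(width_deg = w, offset = unname(ab[1]), amplitude = unname(ab[2]),
       r_squared = if (sst > 0) 1 - opt$objective / sst else 0,
       degenerate = w > 0.98 * width_max || sst == 0)
}

#' Adaptation ratio from a clamp-trial force
#'
#' On error-clamp trials the subject's peak force divided by the peak force
#' the object would have generated gives the dimensionless adaptation: 1
#' means forces exactly compensate the object. When masses vary across
#' blocks, adaptation can be expressed relative to a reference object (the
#' 1% body-mass object) by normalizing with the reference peak force
#' instead, so that perfect adaptation to a 0.7%/1.0%/1.3% object maps to
#' 0.7/1.0/1.3.
#'
#' @param clamp_force_n Subject peak force (N) on clamp trials.
#' @param object The [object_spec()] presented on those trials.
#' @param reference An optional reference [object_spec()] whose peak force
#'   normalizes instead (relative adaptation).
#' @param profile Rotation profile for the peak-force computation.
#' @return Dimensionless adaptation ratio(s).
#' @export
adaptation_from_clamp <- function(clamp_force_n, object, reference = NULL,
                                  profile = minimum_jerk_profile(40)) {
  denom <- peak_object_force(if (is.null(reference)) object else reference,
                             profile)
  if (denom <= 0) abort("peak object force must be > 0")
  clamp_force_n / denom
}

#' Per-subject mass slopes (training vs transfer)
#'
#' From a cohort on the different-masses schedule (`exp3`), computes each
#' subject's relative adaptation (clamp force normalized by the 1% body-mass
#' object's peak force) at every mass and orientation, fits an ordinary
#' least-squares line of relative adaptation against relative mass per
#' subject and orientation, and summarizes the slopes. A perfectly adapting
#' subject has slope 1 at the training orientation; absent transfer gives
#' slope 0 at the transfer orientation.
#'
#' @param cohort An `adapt_cohort` on the `exp3` schedule.
#' @param schedule The matching schedule.
#' @param body_mass_kg Body mass used for the force normalizer (must match
#'   the cohort's generative spec for synthetic data).
#' @return A list with `slopes` (tibble `subject_id`, `orientation`,
#'   `slope`) and `summary` (tibble `orientation`, `mean_slope`, `se_slope`).
#' @export
mass_slopes <- function(cohort, schedule, body_mass_kg = 70) {
  if (!identical(attr(schedule, "experiment_id"), "exp3")) {
    abort("mass_slopes expects an exp3 schedule")
  }
  sched_cols <- tibble::tibble(trial = schedule$index,
                               mass_frac_bm = schedule$mass_frac_bm)
  ref <- object_spec(0.01 * body_mass_kg)
  clamp <- dplyr::inner_join(
    dplyr::filter(cohort, .data$mode == "error_clamp"), sched_cols,
    by = "trial")
  clamp$rel_adaptation <- adaptation_from_clamp(clamp$clamp_force_n,
                                                object = NULL, reference = ref)
  clamp$rel_mass <- clamp$mass_frac_bm / 0.01
  clamp$orientation <- ifelse(clamp$orientation_deg == 0, "training", "transfer")
  if (dplyr::n_distinct(clamp$rel_mass) < 2) abort("need at least 2 masses")
  per_subject <- dplyr::summarise(
    dplyr::group_by(clamp, .data$subject_id, .data$orientation, .data$rel_mass),
    adaptation = mean(.data$rel_adaptation), .groups = "drop")
  slopes <- dplyr::summarise(
    dplyr::group_by(per_subject, .data$subject_id, .data$orientation),
    slope = coef(lm(adaptation ~ rel_mass,
                    data = dplyr::pick(dplyr::everything())))[["rel_mass"]],
    .groups = "drop")
  summary <- dplyr::summarise(
    dplyr::group_by(slopes, .data$orientation),
    mean_slope = mean(.data$slope),
    se_slope = sd(.data$slope) / sqrt(dplyr::n()),
    .groups = "drop")
  list(slopes = slopes, summary = summary)
}

#' Bin multiple-context blocks by orientation change
#'
#' For the multiple-context adaptation protocol (`exp5`), assigns every
#' exposure block from cycles 2 onward to the `45` bin (absolute circular
#' change of 45 deg in orientation relative to the previous block) or the
#' `90+` bin (changes of 90 deg or more), and reports per bin the
#' block-initial and block-final adaptation (mean of the model's adaptation
#' ratio, or the cohort clamp-force ratio, over the 2 clamp trials at block
#' start/end) and the mean 16-trial exposure displacement trajectory.
#'
#' @param series An `adapt_series` from [simulate_model()] on the `exp5`
#'   schedule, or an `adapt_cohort` (reduced to its across-subject mean).
#' @param schedule The matching schedule.
#' @param body_mass_kg Body mass for the cohort clamp-force normalizer.
#' @return A list of class `exp5_bins`: `blocks` (tibble `block_id`,
#'   `orientation_deg`, `delta_deg`, `bin`, `initial_adaptation`,
#'   `final_adaptation`), `bins` (per-bin means) and `trajectory` (tibble
#'   `bin`, `exposure_trial`, `displacement`).
#' @export
bin_exp5 <- function(series, schedule, body_mass_kg = 70) {
  if (!identical(attr(schedule, "experiment_id"), "exp5")) {
    abort("bin_exp5 expects an exp5 schedule")
  }
  if (inherits(series, "adapt_cohort")) {
    disp <- cohort_mean_series(series)
    force <- dplyr::arrange(
      dplyr::summarise(dplyr::group_by(series, .data$trial),
                       f = mean(.data$clamp_force_n), .groups = "drop"),
      .data$trial)$f
    ref <- object_spec(0.01 * body_mass_kg)
    adapt <- adaptation_from_clamp(force, object = NULL, reference = ref)
  } else {
    disp <- series$abs_error
    adapt <- series$adaptation_ratio
  }
  blocks <- dplyr::distinct(tibble::tibble(
    block_id = schedule$block_id,
    orientation_deg = schedule$orientation_deg,
    phase = sub("_cycle.*$", "", schedule$phase_label),
    cycle = as.integer(sub(".*_cycle_", "", schedule$phase_label))))
  expo <- blocks[blocks$phase == "exposure", ]
  expo$delta_deg <- c(NA, abs(circ_diff(expo$orientation_deg[-1],
                                        expo$orientation_deg[-nrow(expo)])))
  # first exposure cycle is initial adaptation to the object; excluded
  eligible <- expo[expo$cycle > 1, ]
  eligible$bin <- ifelse(eligible$delta_deg >= 90, "90+", "45")
  per_block <- purrr::map_dfr(seq_len(nrow(eligible)), function(i) {
    rows <- which(schedule$block_id == eligible$block_id[i])
    is_clamp <- schedule$mode[rows] == "error_clamp"
    clamp_rows <- rows[is_clamp]
    expo_rows <- rows[!is_clamp]
    tibble::tibble(
      block_id = eligible$block_id[i],
      orientation_deg = eligible$orientation_deg[i],
      delta_deg = eligible$delta_deg[i],
      bin = eligible$bin[i],
      initial_adaptation = mean(adapt[head(clamp_rows, 2)]),
      final_adaptation = mean(adapt[tail(clamp_rows, 2)]),
      trajectory = list(disp[expo_rows])
    )
  })
  bins <- dplyr::summarise(
    dplyr::group_by(per_block, .data$bin),
    initial_adaptation = mean(.data$initial_adaptation),
    final_adaptation = mean(.data$final_adaptation),
    n_blocks = dplyr::n(), .groups = "drop")
  trajectory <- tidyr::unnest(
    dplyr::mutate(
      dplyr::select(per_block, "bin", "trajectory"),
      exposure_trial = purrr::map(.data$trajectory, seq_along)),
    c("trajectory", "exposure_trial"))
  trajectory <- dplyr::summarise(
    dplyr::group_by(trajectory, .data$bin, .data$exposure_trial),
    displacement = mean(.data$trajectory), .groups = "drop")
  structure(list(blocks = dplyr::select(per_block, -"trajectory"),
                 bins = bins, trajectory = trajectory),
            class = "exp5_bins")
}
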