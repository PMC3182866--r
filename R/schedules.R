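#' Build a deterministic trial schedule for one of the experiments
#'
#' Constructs the full ordered trial list for the six experimental protocols
#' of the object-rotation task. Each trial has a mode (`exposure`: full object
#' dynamics on; `zero_force`: object forces off, subject forces displace the
#' handle; `error_clamp`: a stiff virtual spring measures the subject's
#' anticipatory force without kinematic error), a visual orientation of the
#' object on the 22.5 degree grid, a rotation direction that alternates
#' CW/CCW within each block, and an object mass as a fraction of body mass.
#'
#' The protocols are:
#' * `exp1` single-context adaptation/de-adaptation at 0 deg: a 48-trial
#'   zero-force familiarization block (flagged `familiarization`, excluded
#'   from fitting) followed by the 320-trial main experiment: 48 zero-force
#'   pre-exposure, 224 exposure (one error clamp placed at a seeded position
#'   in each 8-trial bin of the final 128 trials, balanced 8 CW / 8 CCW), and
#'   48 zero-force post-exposure.
#' * `exp2` multiple-context de-adaptation (needs `group`): 64 exposure
#'   trials at the training orientation (group 1: 0 deg, group 2: 180 deg),
#'   then 15 blocks of 30 trials: 2 error clamps at training, 8 zero-force at
#'   a probe orientation, 2 error clamps at training, 18 re-exposure at
#'   training. Probes (group 1: 0, -22.5, -45, -90, 180; group 2: 180,
#'   -157.5, -135, -90, 0) are presented once per cycle in a per-cycle seeded
#'   permutation, for 3 cycles.
#' * `exp3` adaptation to different masses: three 90-trial blocks, one per
#'   mass (default 0.7/1.0/1.3% body mass, seeded block order): 60 exposure
#'   at 0 deg, then 30 trials with one error clamp per 5-trial bin (3 clamps
#'   at the 0 deg training orientation, 3 at the -90 deg transfer
#'   orientation, in a seeded arrangement).
#' * `exp4` dual-context adaptation: 11 cycles of paired 24-trial blocks at
#'   180 then 0 deg (528 trials). The first and last cycles are zero-force;
#'   the 9 exposure cycles have 4 seeded error clamps per block (never the
#'   block's first trial) among 20 exposure trials.
#' * `exp5` multiple-context adaptation: 2 pre-exposure cycles of 5 blocks
#'   of 4 error clamps, 5 exposure cycles of 5 blocks of
#'   (2 clamps, 16 exposure, 2 clamps), 2 post-exposure cycles as pre
#'   (580 trials). Each cycle presents the orientations 0, -45, -90, -135,
#'   180 once, in a per-cycle seeded permutation.
#' * `expS1` compliance calibration: `n_cycles` (default 3) cycles over the
#'   five orientations; each block is 30 exposure then 20 zero-force trials.
#'
#' @param experiment_id One of `"exp1"`, `"exp2"`, `"exp3"`, `"exp4"`,
#'   `"exp5"`, `"expS1"`.
#' @param seed Integer seed controlling every pseudo-random element
#'   (clamp placement, probe/mass/orientation orders). The same seed always
#'   yields an identical schedule.
#' @param group For `exp2`: 1 (training at 0 deg) or 2 (training at 180 deg).
#' @param masses For `exp3`: object masses as body-mass fractions.
#' @param n_cycles For `expS1`: number of adapt/de-adapt cycles.
#' @return A tibble of class `adapt_schedule` with one row per trial and
#'   columns `index` (0-based), `mode`, `orientation_deg`, `direction`,
#'   `mass_frac_bm`, `phase_label`, `block_id`, `familiarization`.
#'   Attributes `experiment_id`, `group` and `seed` record provenance.
#' @examples
#' sched <- build_schedule("exp1", seed = 1)
#' table(sched$mode[!sched$familiarization])
#' @export
build_schedule <- function(experiment_id, seed = 1L, group = NULL,
                           masses = c(0.007, 0.010, 0.013), n_cycles = 3L) {
  experiment_id <- match.arg(experiment_id,
                             c("exp1", "exp2", "exp3", "exp4", "exp5", "expS1"))
  if (experiment_id == "exp2" && is.null(group)) {
    abort("exp2 requires group = 1 or 2")
  }
  if (experiment_id == "exp3" && (is.null(masses) || length(masses) < 2)) {
    abort("exp3 requires at least two masses")
  }
  trials <- withr::with_seed(seed, switch(
    experiment_id,
    exp1 = sched_exp1(),
    exp2 = sched_exp2(group),
    exp3 = sched_exp3(masses),
    exp4 = sched_exp4(),
    exp5 = sched_exp5(),
    expS1 = sched_expS1(n_cycles)
  ))
  trials$index <- seq_len(nrow(trials)) - 1L
  trials$orientation_deg <- wrap_angle(trials$orientation_deg)
  trials <- dplyr::relocate(trials, "index")
  out <- tibble::new_tibble(trials, class = "adapt_schedule",
                            experiment_id = experiment_id,
                            group = if (is.null(group)) NA_integer_ else as.integer(group),
                            seed = as.integer(seed))
  out
}

## One block of trials; direction alternation restarts at CW at each block.
make_block <- function(modes, orientation, phase, block, mass = 0.01,
                       familiarization = FALSE) {
  n <- length(modes)
  tibble::tibble(
    mode = modes,
    orientation_deg = rep_len(orientation, n),
    direction = rep_len(c("CW", "CCW"), n),
    mass_frac_bm = rep_len(mass, n),
    phase_label = phase,
    block_id = as.integer(block),
    familiarization = familiarization
  )
}

## Place one clamp per `bin_size`-trial bin at a uniform seeded position.
clamp_positions <- function(n, bin_size) {
  starts <- seq(1L, n, by = bin_size)
  starts + sample.int(bin_size, length(starts), replace = TRUE) - 1L
}

sched_exp1 <- function() {
  # exposure phase: 96 pure exposure, then 128 with one clamp per 8-trial
  # bin, rejection-sampled until the clamps split 8 CW / 8 CCW
  repeat {
    pos <- clamp_positions(128L, 8L)
    # direction within the 224-trial exposure block: CW on odd positions;
    # clamp positions are offset by the 96 leading exposure trials
    cw <- (96L + pos) %% 2L == 1L
    if (sum(cw) == 8L) break
  }
  exposure_modes <- rep("exposure", 224L)
  exposure_modes[96L + pos] <- "error_clamp"
  dplyr::bind_rows(
    make_block(rep("zero_force", 48L), 0, "familiarization", 0L,
               familiarization = TRUE),
    make_block(rep("zero_force", 48L), 0, "pre", 1L),
    make_block(exposure_modes, 0, "exposure", 2L),
    make_block(rep("zero_force", 48L), 0, "post", 3L)
  )
}

sched_exp2 <- function(group) {
  if (!group %in% 1:2) abort("group must be 1 or 2")
  training <- if (group == 1) 0 else 180
  probes <- if (group == 1) c(0, -22.5, -45, -90, 180)
            else c(180, -157.5, -135, -90, 0)
  probe_order <- unlist(lapply(1:3, function(cyc) sample(probes)))
  blocks <- purrr::imap(probe_order, function(probe, b) {
    dplyr::bind_rows(
      make_block(rep("error_clamp", 2L), training,
                 sprintf("clamp_pre_block_%d", b), b),
      make_block(rep("zero_force", 8L), probe,
                 sprintf("deadapt_block_%d", b), b),
      make_block(rep("error_clamp", 2L), training,
                 sprintf("clamp_post_block_%d", b), b),
      make_block(rep("exposure", 18L), training,
                 sprintf("reexposure_block_%d", b), b)
    )
  })
  dplyr::bind_rows(
    make_block(rep("exposure", 64L), training, "exposure", 0L),
    blocks
  )
}

sched_exp3 <- function(masses) {
  mass_order <- sample(masses)
  blocks <- purrr::imap(mass_order, function(mass, b) {
    pos <- clamp_positions(30L, 5L)
    probe_modes <- rep("exposure", 30L)
    probe_modes[pos] <- "error_clamp"
    probe_orient <- rep(0, 30L)
    probe_orient[pos] <- sample(rep(c(0, -90), each = 3L))
    dplyr::bind_rows(
      make_block(rep("exposure", 60L), 0,
                 sprintf("exposure_mass_%g", mass), b, mass = mass),
      make_block(probe_modes, probe_orient,
                 sprintf("probe_mass_%g", mass), b, mass = mass)
    )
  })
  dplyr::bind_rows(blocks)
}

sched_exp4 <- function() {
  blocks <- list()
  b <- 0L
  for (cycle in 1:11) {
    zero_cycle <- cycle %in% c(1L, 11L)
    phase <- if (cycle == 1L) "pre" else if (cycle == 11L) "post" else "exposure"
    for (orient in c(180, 0)) {
      b <- b + 1L
      if (zero_cycle) {
        modes <- rep("zero_force", 24L)
      } else {
        modes <- rep("exposure", 24L)
        # 4 clamps at seeded positions, never the block-initial trial
        modes[sample(2:24, 4L)] <- "error_clamp"
      }
      blocks[[b]] <- make_block(modes, orient,
                                sprintf("%s_cycle_%d", phase, cycle), b)
    }
  }
  dplyr::bind_rows(blocks)
}

sched_exp5 <- function() {
  orients <- c(0, -45, -90, -135, 180)
  blocks <- list()
  b <- 0L
  add_cycle <- function(phase, cycle, block_modes) {
    for (orient in sample(orients)) {
      b <<- b + 1L
      blocks[[b]] <<- make_block(block_modes, orient,
                                 sprintf("%s_cycle_%d", phase, cycle), b)
    }
  }
  for (cycle in 1:2) add_cycle("pre", cycle, rep("error_clamp", 4L))
  for (cycle in 1:5) add_cycle("exposure", cycle,
                               c(rep("error_clamp", 2L), rep("exposure", 16L),
                                 rep("error_clamp", 2L)))
  for (cycle in 1:2) add_cycle("post", cycle, rep("error_clamp", 4L))
  dplyr::bind_rows(blocks)
}

sched_expS1 <- function(n_cycles) {
  orients <- c(0, -45, -90, -135, 180)
  blocks <- list()
  b <- 0L
  for (cycle in seq_len(n_cycles)) {
    for (orient in sample(orients)) {
      b <- b + 1L
      blocks[[b]] <- dplyr::bind_rows(
        make_block(rep("exposure", 30L), orient,
                   sprintf("adapt_cycle_%d", cycle), b),
        make_block(rep("zero_force", 20L), orient,
                   sprintf("deadapt_cycle_%d", cycle), b)
      )
    }
  }
  dplyr::bind_rows(blocks)
}

#' @export
print.adapt_schedule <- function(x, ...) {
  cat(sprintf("<adapt_schedule %s, %d trials, seed %d>\n",
              attr(x, "experiment_id"), nrow(x), attr(x, "seed")))
  NextMethod()
}
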