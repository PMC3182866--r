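#' Context-selection (generalization) vector
#'
#' Returns the 16-element context-selection vector `c` for the current object
#' orientation. For Gaussian tuning (MCSRM4) the weight at circular lag `l`
#' from the current orientation is the affine-rescaled Gaussian
#' `c(l) = d + (1 - d) * (N(l, sigma) - N(180, sigma)) / (N(0, sigma) - N(180, sigma))`,
#' where `N` is an (unnormalized) zero-mean Gaussian. This satisfies the two
#' anchor conditions exactly: the weight is 1 at the current orientation and
#' decays to the offset `d` at +/-180 degrees, and it is symmetric in lag.
#' For free tuning (MCSRM10) weights are looked up by absolute lag (lag 0
#' fixed at 1).
#'
#' @param orientation_deg Current object orientation, on the 22.5 deg grid.
#' @param tuning The `tuning` element of [mcsrm_params()], or a list with
#'   `sigma_deg` and `offset` (Gaussian) or `weights` (free).
#' @return Named numeric vector of 16 weights, one per context orientation.
#' @examples
#' p <- mcsrm_params(0.9811, 0.0451, sigma_deg = 26.3, offset = 0.09)
#' cv <- tuning_vector(0, p$tuning)
#' cv[["0"]]    # 1
#' cv[["180"]]  # 0.09
#' @export
tuning_vector <- function(orientation_deg, tuning) {
  assert_on_grid(orientation_deg)
  ctx <- context_orientations()
  lag <- abs(circ_diff(ctx, orientation_deg))
  if (!is.null(tuning$weights)) {
    w <- c(1, tuning$weights)           # absolute lags 0, 22.5, ..., 180
    out <- w[round(lag / 22.5) + 1L]
  } else {
    sigma <- tuning$sigma_deg
    d <- tuning$offset
    if (d == 1) {
      out <- rep(1, length(ctx))
    } else {
      g <- function(x) exp(-x^2 / (2 * sigma^2))
      out <- d + (1 - d) * (g(lag) - g(180)) / (g(0) - g(180))
    }
  }
  setNames(out, as.character(ctx))
}

#' Compliance factor at an orientation
#'
#' Linear interpolation of the calibrated compliance values around the
#' circle. Orientations between the five calibrated angles get the
#' arc-length-weighted mean of the two neighbouring calibrated values.
#'
#' @param orientation_deg Query orientation (degrees, any value on the
#'   circle).
#' @param profile A [compliance_profile()].
#' @param sign `"plus"` (adaptation, `f > x`) or `"minus"` (de-adaptation).
#' @return Interpolated compliance factor (cm per unit mass-estimate error).
#' @export
compliance_at <- function(orientation_deg, profile, sign = c("plus", "minus")) {
  sign <- match.arg(sign)
  k <- if (sign == "plus") profile$k_plus else profile$k_minus
  ord <- order(profile$orientations)
  ang <- profile$orientations[ord]
  k <- k[ord]
  # extend around the circle so every query angle is bracketed
  ang_ext <- c(ang[length(ang)] - 360, ang, ang[1] + 360)
  k_ext <- c(k[length(k)], k, k[1])
  stats::approx(ang_ext, k_ext, xout = wrap_angle(orientation_deg))$y
}

#' Compliance-dependent error
#'
#' Converts a mass-estimate discrepancy into the predicted handle
#' displacement (cm): `e = g * k * (f - x)`, with `k = k_plus` at the current
#' orientation when `f > x` (the object displaces the subject) and `k_minus`
#' when `f < x` (the subject displaces the object); either applies when equal.
#'
#' @param f Actual object mass (dimensionless, relative to the 1% body-mass
#'   standard), or 0 on zero-force trials.
#' @param x Net mass estimate of the model.
#' @param orientation_deg Object orientation, on the 22.5 deg grid.
#' @param profile A [compliance_profile()].
#' @return Signed error in cm.
#' @examples
#' compliance_error(1, 0, 0, unit_compliance())
#' @export
compliance_error <- function(f, x, orientation_deg, profile) {
  assert_on_grid(orientation_deg)
  k <- compliance_at(orientation_deg, profile,
                     sign = if (f >= x) "plus" else "minus")
  profile$gain * k * (f - x)
}

#' One trial of the single-rate model
#'
#' @param x Current state (mass estimate).
#' @param f Perturbation on this trial: the object mass on exposure trials,
#'   0 on zero-force trials (object forces off). Ignored for the update on
#'   error-clamp trials.
#' @param params An [srm_params()].
#' @param mode Trial mode; on `"error_clamp"` trials the error is recorded
#'   for reporting but the update uses zero error, so the state purely decays
#'   (`x <- alpha * x`).
#' @return List with `x_next` and the (reported) error `e = f - x`.
#' @examples
#' step_srm(0, 1, srm_params(0.9513, 0.2150))
#' @export
step_srm <- function(x, f, params, mode = "exposure") {
  e <- f - x
  e_update <- if (identical(mode, "error_clamp")) 0 else e
  list(x_next = params$alpha * x + params$beta * e_update, e = e)
}

#' One trial of the dual-rate model
#'
#' The two states share the net error `e = f - (x1 + x2)` and update
#' independently with their own retention and learning rates.
#'
#' @param x1,x2 Current slow and fast states.
#' @inheritParams step_srm
#' @param params A [drm_params()].
#' @return List with `x1_next`, `x2_next` and the reported net error `e`.
#' @export
step_drm <- function(x1, x2, f, params, mode = "exposure") {
  e <- f - (x1 + x2)
  e_update <- if (identical(mode, "error_clamp")) 0 else e
  list(x1_next = params$alpha1 * x1 + params$beta1 * e_update,
       x2_next = params$alpha2 * x2 + params$beta2 * e_update,
       e = e)
}

#' One trial of the multiple-context single-rate model
#'
#' Computes the context-selection vector for the trial orientation, the net
#' output state `x = c . z`, and the compliance-dependent error in cm, then
#' updates all context states: `z <- alpha * z + beta * e_hat * c`. By
#' default (`error_drive = "mass_units"`) the update is driven by the
#' mass-estimate discrepancy `f - x`, so that with degenerate tuning the
#' model reduces exactly to the SRM; with `"cm_units"` the cm-valued
#' compliance error drives learning.
#'
#' @param z Length-16 context state vector.
#' @inheritParams step_srm
#' @param params An [mcsrm_params()].
#' @param orientation_deg Trial orientation on the 22.5 deg grid.
#' @param compliance A [compliance_profile()].
#' @param error_drive `"mass_units"` (default) or `"cm_units"`.
#' @return List with `z_next`, the cm-valued error `e_cm` and the net state
#'   `x_net`.
#' @export
step_mcsrm <- function(z, f, orientation_deg, params, compliance,
                       mode = "exposure", error_drive = "mass_units") {
  cv <- tuning_vector(orientation_deg, params$tuning)
  x_net <- sum(cv * z)
  e_cm <- compliance_error(f, x_net, orientation_deg, compliance)
  e_hat <- if (identical(mode, "error_clamp")) 0
           else if (identical(error_drive, "cm_units")) e_cm
           else f - x_net
  list(z_next = params$alpha * z + params$beta * e_hat * cv,
       e_cm = e_cm, x_net = x_net)
}

## Per-trial drive f: mass on exposure and clamp trials (clamp errors are
## reported against the object the subject expects), 0 on zero-force trials.
schedule_drive <- function(schedule) {
  f_mass <- schedule$mass_frac_bm / 0.01
  f_drive <- ifelse(schedule$mode == "zero_force", 0, f_mass)
  list(f_mass = f_mass, f_drive = f_drive,
       clamp = schedule$mode == "error_clamp",
       zero = schedule$mode == "zero_force")
}

#' Simulate a state-space learner over a trial schedule
#'
#' Steps the chosen model over every trial of a schedule in order, starting
#' from a naive (all-zero) state unless `initial_state` is given. The
#' simulation is fully deterministic. The perturbation `f` is the trial's
#' object mass expressed relative to the 1% body-mass standard (so the
#' standard object gives `f = 1`), and is 0 on zero-force trials. Error-clamp
#' trials update with zero error but full retention decay by default
#' (`clamp_update = "zero_error"`); `"frozen"` leaves the state untouched.
#' Setting `deadapt = "passive"` makes zero-force trials decay-only as well
#' (no error-driven de-adaptation), the variant appropriate for tasks where
#' unopposed responses cause no kinematic error.
#'
#' @param schedule An [build_schedule()] tibble (or any tibble with columns
#'   `mode`, `orientation_deg`, `mass_frac_bm`).
#' @param params An [srm_params()], [drm_params()] or [mcsrm_params()].
#' @param compliance A [compliance_profile()]; required for MCSRM, and
#'   optional for the SRM (yielding the compliance-modified SRM used for
#'   calibration, whose error output is in cm).
#' @param initial_state Numeric scalar (SRM), length-2 (DRM) or length-16
#'   (MCSRM) starting state; defaults to zeros.
#' @param clamp_update `"zero_error"` or `"frozen"`.
#' @param deadapt `"error"` (zero-force trials drive de-adaptation through
#'   their error) or `"passive"` (decay only).
#' @param error_drive Passed to [step_mcsrm()] for MCSRM models.
#' @return A tibble of class `adapt_series` with one row per trial: `trial`
#'   (0-based index), `mode`, `orientation_deg`, `f` (drive), `x_net`,
#'   `error` (signed; cm when a compliance profile is in play, dimensionless
#'   otherwise), `abs_error` (the model's predicted peak displacement), and
#'   `adaptation_ratio` (`x_net / f_mass`, the model analogue of the
#'   clamp-trial force ratio).
#' @examples
#' sched <- build_schedule("exp1", seed = 1)
#' series <- simulate_model(sched, srm_params(0.9513, 0.2150))
#' head(series)
#' @export
simulate_model <- function(schedule, params, compliance = NULL,
                           initial_state = NULL,
                           clamp_update = c("zero_error", "frozen"),
                           deadapt = c("error", "passive"),
                           error_drive = c("mass_units", "cm_units")) {
  clamp_update <- match.arg(clamp_update)
  deadapt <- match.arg(deadapt)
  error_drive <- match.arg(error_drive)
  kind <- model_kind_of(params)
  if (kind %in% c("mcsrm4", "mcsrm10") && is.null(compliance)) {
    abort("MCSRM simulation requires a compliance profile")
  }
  drv <- schedule_drive(schedule)
  sim <- switch(kind,
    srm = sim_srm(schedule, params, compliance, drv, initial_state,
                  clamp_update, deadapt),
    drm = sim_drm(schedule, params, drv, initial_state, clamp_update, deadapt),
    sim_mcsrm(schedule, params, compliance, drv, initial_state,
              clamp_update, deadapt, error_drive)
  )
  out <- tibble::tibble(
    trial = seq_len(nrow(schedule)) - 1L,
    mode = schedule$mode,
    orientation_deg = schedule$orientation_deg,
    f = drv$f_drive,
    x_net = sim$x_net,
    error = sim$error,
    abs_error = abs(sim$error),
    adaptation_ratio = ifelse(drv$f_mass > 0, sim$x_net / drv$f_mass, NA_real_)
  )
  if ("phase_label" %in% names(schedule)) out$phase_label <- schedule$phase_label
  if ("block_id" %in% names(schedule)) out$block_id <- schedule$block_id
  tibble::new_tibble(out, class = "adapt_series", model_kind = kind)
}

## Fast internal simulators (plain loops over precomputed per-trial vectors).
sim_srm <- function(schedule, params, compliance, drv, initial_state,
                    clamp_update, deadapt) {
  n <- nrow(schedule)
  alpha <- params$alpha; beta <- params$beta
  x <- if (is.null(initial_state)) 0 else initial_state[1]
  with_k <- !is.null(compliance)
  if (with_k) {
    kp <- compliance_at(schedule$orientation_deg, compliance, "plus") * compliance$gain
    km <- compliance_at(schedule$orientation_deg, compliance, "minus") * compliance$gain
  }
  x_out <- numeric(n); e_out <- numeric(n)
  for (i in seq_len(n)) {
    f <- drv$f_drive[i]
    e <- f - x
    e_out[i] <- if (with_k) (if (f >= x) kp[i] else km[i]) * e else e
    e_upd <- e
    if (drv$clamp[i]) e_upd <- 0
    if (deadapt == "passive" && drv$zero[i]) e_upd <- 0
    x_out[i] <- x
    x <- if (drv$clamp[i] && clamp_update == "frozen") x
         else alpha * x + beta * e_upd
  }
  list(x_net = x_out, error = e_out)
}

sim_drm <- function(schedule, params, drv, initial_state, clamp_update, deadapt) {
  n <- nrow(schedule)
  a1 <- params$alpha1; b1 <- params$beta1
  a2 <- params$alpha2; b2 <- params$beta2
  x1 <- 0; x2 <- 0
  if (!is.null(initial_state)) { x1 <- initial_state[1]; x2 <- initial_state[2] }
  x_out <- numeric(n); e_out <- numeric(n)
  for (i in seq_len(n)) {
    f <- drv$f_drive[i]
    x <- x1 + x2
    e <- f - x
    e_out[i] <- e
    x_out[i] <- x
    e_upd <- e
    if (drv$clamp[i]) e_upd <- 0
    if (deadapt == "passive" && drv$zero[i]) e_upd <- 0
    if (drv$clamp[i] && clamp_update == "frozen") next
    x1 <- a1 * x1 + b1 * e_upd
    x2 <- a2 * x2 + b2 * e_upd
  }
  list(x_net = x_out, error = e_out)
}

sim_mcsrm <- function(schedule, params, compliance, drv, initial_state,
                      clamp_update, deadapt, error_drive) {
  n <- nrow(schedule)
  alpha <- params$alpha; beta <- params$beta
  z <- if (is.null(initial_state)) numeric(16L) else as.numeric(initial_state)
  if (length(z) != 16L) abort("MCSRM initial state must have length 16")
  orients <- schedule$orientation_deg
  uo <- unique(orients)
  cmat <- vapply(uo, function(o) tuning_vector(o, params$tuning), numeric(16L))
  oi <- match(orients, uo)
  kp <- compliance_at(uo, compliance, "plus") * compliance$gain
  km <- compliance_at(uo, compliance, "minus") * compliance$gain
  cm_drive <- identical(error_drive, "cm_units")
  x_out <- numeric(n); e_out <- numeric(n)
  for (i in seq_len(n)) {
    j <- oi[i]
    cv <- cmat[, j]
    x <- sum(cv * z)
    f <- drv$f_drive[i]
    e_cm <- (if (f >= x) kp[j] else km[j]) * (f - x)
    x_out[i] <- x
    e_out[i] <- e_cm
    e_upd <- if (cm_drive) e_cm else f - x
    if (drv$clamp[i]) e_upd <- 0
    if (deadapt == "passive" && drv$zero[i]) e_upd <- 0
    if (drv$clamp[i] && clamp_update == "frozen") next
    z <- alpha * z + beta * e_upd * cv
  }
  list(x_net = x_out, error = e_out)
}

#' Dual-rate diagnostics: spontaneous recovery and savings
#'
#' Two behavioural signatures separate genuine dual-rate dynamics from
#' single-rate parameterizations of the dual-rate model.
#'
#' *Spontaneous recovery*: the model is adapted to `f = 1` until asymptote,
#' counter-adapted with `f = -1` until the net state first crosses zero, then
#' observed over a long error-clamp phase (pure retention). The score is the
#' maximum net state during the clamp phase (floored at 0): a fast process
#' that de-adapted below zero decays away faster than the still-adapted slow
#' process, producing a positive rebound.
#'
#' *Savings*: naive adaptation to `f = 1`, washout by counter-adaptation
#' (`f = -1`) until the net state first returns to zero, then re-exposure.
#' The score is the error drop over the first 5 re-exposure trials minus the
#' drop over the first 5 naive trials: positive when relearning is faster.
#' (Washout stops at the first return to baseline: prolonged washout also
#' drains the slow state and is well known to abolish savings.)
#'
#' Both scores are (approximately) zero for any single-rate parameterization.
#'
#' @param params A [drm_params()].
#' @param protocol `"spontaneous_recovery"` or `"savings"`.
#' @param n_adapt,n_clamp Lengths of the adaptation and error-clamp phases.
#' @return Diagnostic score (dimensionless, on the scale of full adaptation).
#' @examples
#' diagnose_drm(drm_params(0.996, 0.01, 0.70, 0.30), "spontaneous_recovery")
#' @export
diagnose_drm <- function(params,
                         protocol = c("spontaneous_recovery", "savings"),
                         n_adapt = 200L, n_clamp = 150L) {
  protocol <- match.arg(protocol)
  step_phase <- function(x1, x2, f, n, clamp = FALSE) {
    x1s <- numeric(n); x2s <- numeric(n); es <- numeric(n)
    for (i in seq_len(n)) {
      st <- step_drm(x1, x2, f, params, mode = if (clamp) "error_clamp" else "exposure")
      es[i] <- st$e; x1s[i] <- x1; x2s[i] <- x2
      x1 <- st$x1_next; x2 <- st$x2_next
    }
    list(x1 = x1, x2 = x2, net = x1s + x2s, e = es)
  }
  # counter-adapt until the net state crosses zero, then interpolate the
  # state pair to the exact crossing so the washout endpoint is net = 0
  # (a discrete overshoot would otherwise contaminate both scores)
  washout_to_zero <- function(x1, x2) {
    for (i in seq_len(1000L)) {
      if (x1 + x2 <= 0) break
      st <- step_drm(x1, x2, -1, params)
      if (st$x1_next + st$x2_next <= 0) {
        lambda <- (x1 + x2) / ((x1 + x2) - (st$x1_next + st$x2_next))
        return(list(x1 = x1 + lambda * (st$x1_next - x1),
                    x2 = x2 + lambda * (st$x2_next - x2)))
      }
      x1 <- st$x1_next; x2 <- st$x2_next
    }
    list(x1 = x1, x2 = x2)
  }
  if (protocol == "spontaneous_recovery") {
    ad <- step_phase(0, 0, 1, n_adapt)
    w <- washout_to_zero(ad$x1, ad$x2)
    cl <- step_phase(w$x1, w$x2, 0, n_clamp, clamp = TRUE)
    return(max(0, max(cl$net)))
  }
  # savings
  first <- step_phase(0, 0, 1, n_adapt)
  drop1 <- first$e[1] - first$e[5]
  w <- washout_to_zero(first$x1, first$x2)
  second <- step_phase(w$x1, w$x2, 1, n_adapt)
  drop2 <- second$e[1] - second$e[5]
  drop2 - drop1
}
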