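## Parameter-vector plumbing shared by the fitters ---------------------------

par_spec <- function(model_kind, fit_gain = FALSE) {
  base <- switch(model_kind,
    srm = list(names = c("alpha", "beta"),
               lower = c(0, 0), upper = c(1, 1),
               default = c(0.9, 0.2)),
    drm = list(names = c("alpha1", "beta1", "alpha2", "beta2"),
               lower = rep(0, 4), upper = rep(1, 4),
               default = c(0.99, 0.01, 0.9, 0.2)),
    mcsrm4 = list(names = c("alpha", "beta", "sigma_deg", "offset"),
                  lower = c(0, 0, 1, 0), upper = c(1, 1, 180, 1),
                  default = c(0.95, 0.05, 30, 0.1)),
    mcsrm10 = list(names = c("alpha", "beta", paste0("w", 1:8)),
                   lower = rep(0, 10), upper = rep(1, 10),
                   default = c(0.95, 0.05, seq(0.8, 0.1, length.out = 8))),
    srm_compliance = list(
      names = c("alpha", "beta", paste0("k_plus", 1:5), paste0("k_minus", 1:5)),
      lower = c(0, 0, rep(0.01, 10)), upper = c(1, 1, rep(10, 10)),
      default = c(0.9, 0.2, rep(1, 10))),
    abort(sprintf("unknown model kind '%s'", model_kind))
  )
  if (fit_gain) {
    base$names <- c(base$names, "gain")
    base$lower <- c(base$lower, 0.5)
    base$upper <- c(base$upper, 2)
    base$default <- c(base$default, 1)
  }
  base
}

par_to_model <- function(model_kind, par, spec, compliance = NULL) {
  p <- setNames(as.numeric(par), spec$names)
  gain <- if ("gain" %in% spec$names) p[["gain"]]
          else if (!is.null(compliance)) compliance$gain else 1
  switch(model_kind,
    srm = list(params = srm_params(p[["alpha"]], p[["beta"]]),
               compliance = compliance),
    drm = list(params = drm_params(p[["alpha1"]], p[["beta1"]],
                                   p[["alpha2"]], p[["beta2"]]),
               compliance = NULL),
    mcsrm4 = list(params = mcsrm_params(p[["alpha"]], p[["beta"]],
                                        sigma_deg = p[["sigma_deg"]],
                                        offset = p[["offset"]]),
                  compliance = compliance_profile(compliance$k_plus,
                                                  compliance$k_minus, gain,
                                                  compliance$orientations)),
    mcsrm10 = list(params = mcsrm_params(p[["alpha"]], p[["beta"]],
                                         weights = p[paste0("w", 1:8)]),
                   compliance = compliance_profile(compliance$k_plus,
                                                   compliance$k_minus, gain,
                                                   compliance$orientations)),
    srm_compliance = list(
      params = srm_params(p[["alpha"]], p[["beta"]]),
      compliance = compliance_profile(p[paste0("k_plus", 1:5)],
                                      p[paste0("k_minus", 1:5)], gain = 1))
  )
}

## Seeded multi-start matrix: one canonical start plus Latin-hypercube draws.
make_starts <- function(spec, n_starts, seed) {
  npar <- length(spec$names)
  starts <- matrix(spec$default, nrow = 1)
  if (n_starts > 1) {
    u <- withr::with_seed(seed, lhs::randomLHS(n_starts - 1L, npar))
    rng <- sweep(u, 2, spec$upper - spec$lower, `*`)
    starts <- rbind(starts, sweep(rng, 2, spec$lower, `+`))
  }
  starts
}

#' Fit a state-space model to peak-displacement trial series
#'
#' Minimizes the summed squared difference between the model's absolute error
#' output (predicted peak displacement) and one or more observed series by
#' bounded nonlinear least squares with seeded Latin-hypercube multi-start.
#' Several series sharing one parameter set can be fit concurrently by
#' passing lists (e.g. the two training-orientation groups of the
#' multiple-context de-adaptation experiment). Trials with `NA` observations
#' (error-clamp trials, where displacement is not measured) are ignored.
#'
#' @param observed Numeric series of observed peak displacement aligned to
#'   `schedule` (`NA` allowed), or a list of such series.
#' @param schedule An `adapt_schedule`, or a list matching `observed`.
#' @param model_kind `"srm"`, `"drm"`, `"mcsrm4"` or `"mcsrm10"`.
#' @param compliance A [compliance_profile()]; required for MCSRM kinds. When
#'   supplied, the gain `g` is a free parameter unless `fit_gain = FALSE`.
#' @param fit_gain Include the gain factor as a free parameter (default: yes
#'   for MCSRM kinds, where the calibrated compliance is held fixed and only
#'   the overall gain adapts to the cohort).
#' @param n_starts Number of optimizer starts (1 canonical + LHS draws).
#' @param seed Seed for the start draws.
#' @param bounds Optional named list with `lower`/`upper` numeric vectors to
#'   override the default box constraints.
#' @param error_drive,clamp_update,deadapt Passed to [simulate_model()].
#' @return An object of class `adapt_fit`: estimated parameters, residual
#'   variance, R-squared, BIC, trial and parameter counts, convergence
#'   diagnostics. Use [generics::tidy()] / [generics::glance()] on it.
#' @examples
#' sched <- build_schedule("exp1", seed = 1)
#' truth <- srm_params(0.9513, 0.2150)
#' sim <- simulate_model(sched, truth)
#' obs <- ifelse(sim$mode == "error_clamp", NA, sim$abs_error)
#' fit <- fit_model(obs, sched, "srm", n_starts = 5)
#' tidy(fit)
#' @export
fit_model <- function(observed, schedule, model_kind, compliance = NULL,
                      fit_gain = NULL, n_starts = 20L, seed = 1L,
                      bounds = NULL, error_drive = "mass_units",
                      clamp_update = "zero_error", deadapt = "error") {
  if (!is.list(observed) || is.data.frame(observed)) observed <- list(observed)
  if (inherits(schedule, "data.frame")) schedule <- list(schedule)
  stopifnot(length(observed) == length(schedule))
  model_kind <- match.arg(model_kind,
                          c("srm", "drm", "mcsrm4", "mcsrm10", "srm_compliance"))
  mcsrm <- model_kind %in% c("mcsrm4", "mcsrm10")
  if (mcsrm && is.null(compliance)) {
    abort("MCSRM fitting requires a compliance profile")
  }
  if (is.null(fit_gain)) fit_gain <- mcsrm
  observed <- lapply(observed, as.numeric)
  bad <- vapply(observed, function(y) any(is.infinite(y)) || any(is.nan(y)),
                logical(1))
  if (any(bad)) abort("observed series contain non-finite values")
  spec <- par_spec(model_kind, fit_gain)
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) spec$lower <- bounds$lower
    if (!is.null(bounds$upper)) spec$upper <- bounds$upper
    if (any(spec$lower > spec$upper)) abort("infeasible bounds")
    spec$default <- pmin(pmax(spec$default, spec$lower), spec$upper)
  }

  keep <- lapply(observed, function(y) which(!is.na(y)))
  objective <- function(par) {
    mdl <- par_to_model(model_kind, par, spec, compliance)
    sse <- 0
    for (i in seq_along(observed)) {
      sim <- simulate_model(schedule[[i]], mdl$params,
                            compliance = mdl$compliance,
                            clamp_update = clamp_update, deadapt = deadapt,
                            error_drive = error_drive)
      r <- observed[[i]][keep[[i]]] - sim$abs_error[keep[[i]]]
      sse <- sse + sum(r * r)
    }
    sse
  }

  starts <- make_starts(spec, n_starts, seed)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      nlminb(starts[s, ], objective, lower = spec$lower, upper = spec$upper,
             control = list(iter.max = 500, eval.max = 1000,
                            abs.tol = 0, rel.tol = 1e-12, x.tol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$objective < best$objective)) {
      best <- res
    }
  }
  if (is.null(best)) abort("all optimizer starts failed")

  par <- setNames(best$par, spec$names)
  if (model_kind == "drm" && par[["beta1"]] > par[["beta2"]]) {
    par <- par[c("alpha2", "beta2", "alpha1", "beta1")]
    names(par) <- spec$names
  }
  obs_all <- unlist(purrr::map2(observed, keep, ~ .x[.y]))
  n <- length(obs_all)
  k <- length(spec$names)
  sse <- best$objective
  sigma2 <- sse / n
  sst <- sum((obs_all - mean(obs_all))^2)
  structure(list(
    model_kind = model_kind,
    estimate = par,
    residual_variance = sigma2,
    r_squared = if (sst > 0) 1 - sse / sst else 0,
    bic = bic_score(sigma2, k, n),
    n_trials = n,
    n_params = k,
    n_starts = nrow(starts),
    # PORT reports degenerate-but-converged states (singular/false/x-
    # convergence) with a nonzero code; all carry "convergence" in the message
    converged = best$convergence == 0 || grepl("convergence", best$message),
    objective = sse,
    message = best$message,
    bounds = list(lower = setNames(spec$lower, spec$names),
                  upper = setNames(spec$upper, spec$names)),
    compliance = compliance,
    ci = NULL
  ), class = "adapt_fit")
}

#' Fitted parameter object from an `adapt_fit`
#'
#' @param fit An [fit_model()] result.
#' @return The matching [srm_params()], [drm_params()] or [mcsrm_params()].
#' @export
fitted_params <- function(fit) {
  spec <- par_spec(fit$model_kind, "gain" %in% names(fit$estimate))
  par_to_model(fit$model_kind, fit$estimate, spec, fit$compliance)$params
}

#' Bayesian Information Criterion for a least-squares fit
#'
#' `BIC = n * ln(sigma2_e) + k * ln(n)`, where `sigma2_e` is the residual
#' variance, `k` the number of free parameters and `n` the number of fitted
#' trials. With this convention a BIC difference of `2 ln(10) ~ 4.6` between
#' two models corresponds to a Bayes factor of 10.
#'
#' @param residual_variance Residual variance of the fit (> 0).
#' @param n_params Number of free parameters.
#' @param n_trials Number of fitted data points (> `n_params`).
#' @return BIC value (dimensionless); `-Inf` with a warning when the
#'   residual variance is 0 (a perfect fit dominates any comparison).
#' @examples
#' bic_score(1, 0, 100)                     # 0
#' bic_score(0.5, 2, 320) - bic_score(0.5, 4, 320)  # -2 log(320)
#' @export
bic_score <- function(residual_variance, n_params, n_trials) {
  if (n_trials <= n_params) abort("need more trials than parameters")
  if (residual_variance < 0) abort("residual variance must be >= 0")
  if (residual_variance == 0) {
    warn("zero residual variance: BIC is -Inf")
    return(-Inf)
  }
  n_trials * log(residual_variance) + n_params * log(n_trials)
}

#' Compare two fits by BIC
#'
#' Reports the BIC difference and the favored model; the difference counts
#' as strong evidence only when it exceeds the threshold (default
#' `2 ln(10) ~ 4.6`, a Bayes factor of 10).
#'
#' @param fit_a,fit_b Two [fit_model()] results on the same series.
#' @param threshold Strong-evidence threshold on `|delta BIC|`.
#' @return A one-row tibble with columns `model_a`, `model_b`, `bic_a`,
#'   `bic_b`, `delta_bic` (`bic_a - bic_b`), `favored`, `strong_evidence`.
#' @export
select_model <- function(fit_a, fit_b, threshold = 2 * log(10)) {
  if (fit_a$n_trials != fit_b$n_trials) {
    abort("fits were made on different numbers of trials")
  }
  delta <- fit_a$bic - fit_b$bic
  tibble::tibble(
    model_a = fit_a$model_kind, model_b = fit_b$model_kind,
    bic_a = fit_a$bic, bic_b = fit_b$bic,
    delta_bic = delta,
    favored = if (delta <= 0) fit_a$model_kind else fit_b$model_kind,
    strong_evidence = abs(delta) > threshold
  )
}

#' Exponential time-constant fit
#'
#' Fits `y(n) = a + b * exp(-n / t)` (offset plus a single exponential) to a
#' learning or washout series by least squares, profiling the time constant
#' over a log-spaced grid (the model is linear in `a`, `b` given `t`) and
#' polishing the best grid point. A geometric series with per-trial ratio
#' `r` has `t = -1 / ln(r)` exactly.
#'
#' @param y Observed series (e.g. per-trial error of one phase).
#' @param trials Trial numbers `n` (default `1..length(y)`).
#' @return An object of class `exp_fit` with fields `asymptote` (`a`),
#'   `amplitude` (`b`), `time_constant_trials` (`t`), `r_squared` and
#'   `degenerate` (`TRUE` when the series carries no decay to fit).
#' @examples
#' n <- 1:60
#' fit_exponential(0.2 + 0.8 * exp(-n / 5))$time_constant_trials
#' @export
fit_exponential <- function(y, trials = seq_along(y)) {
  if (length(y) < 4) abort("need at least 4 points")
  if (sd(y) == 0) {
    warn("constant series: time constant unidentifiable")
    return(structure(list(asymptote = y[1], amplitude = 0,
                          time_constant_trials = NA_real_, r_squared = 0,
                          degenerate = TRUE), class = "exp_fit"))
  }
  sse_for <- function(t) {
    X <- cbind(1, exp(-trials / t))
    f <- stats::lm.fit(X, y)
    sum(f$residuals^2)
  }
  grid <- exp(seq(log(0.2), log(10 * length(y)), length.out = 80))
  sses <- vapply(grid, sse_for, numeric(1))
  t0 <- grid[which.min(sses)]
  opt <- nlminb(log(t0), function(lt) sse_for(exp(lt)),
                control = list(abs.tol = 0, rel.tol = 1e-14, x.tol = 1e-12))
  t_hat <- exp(opt$par)
  X <- cbind(1, exp(-trials / t_hat))
  ab <- stats::lm.fit(X, y)$coefficients
  sse <- opt$objective
  sst <- sum((y - mean(y))^2)
  structure(list(asymptote = unname(ab[1]), amplitude = unname(ab[2]),
                 time_constant_trials = t_hat,
                 r_squared = 1 - sse / sst,
                 degenerate = abs(ab[2]) < 1e-10), class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> y(n) = %.4g + %.4g * exp(-n / %.4g)  (R^2 = %.4f)\n",
              x$asymptote, x$amplitude, x$time_constant_trials, x$r_squared))
  invisible(x)
}

#' Bootstrap confidence intervals over subjects
#'
#' Draws seeded with-replacement resamples of the subject pool, refits the
#' model to each resample's mean peak-displacement series, and returns the
#' 2.5 and 97.5 percentiles of each parameter. Resamples are deduplicated to
#' unique subject multisets where possible (re-drawing duplicates up to a
#' retry cap, then accepting them with a warning).
#'
#' @param cohort A cohort tibble from [generate_cohort()] (columns
#'   `subject_id`, `trial`, `peak_displacement_cm`), with at least 2
#'   subjects.
#' @param schedule The `adapt_schedule` the cohort was measured on.
#' @param model_kind,compliance,fit_gain,bounds,... Passed to [fit_model()].
#' @param n_boot Number of bootstrap resamples (the study used 1,000).
#' @param seed Seed for resampling.
#' @param n_starts Optimizer starts per refit (kept small: each refit is a
#'   smooth low-dimensional problem near the full-sample optimum).
#' @return A tibble with columns `term`, `conf.low`, `conf.high`, plus an
#'   attribute `draws` holding the per-resample estimates.
#' @export
bootstrap_ci <- function(cohort, schedule, model_kind, compliance = NULL,
                         n_boot = 1000L, seed = 1L, n_starts = 3L,
                         fit_gain = NULL, bounds = NULL, ...) {
  if (n_boot < 1) abort("n_boot must be >= 1")
  subjects <- unique(cohort$subject_id)
  if (length(subjects) < 2) abort("bootstrap CI needs at least 2 subjects")
  draws_idx <- withr::with_seed(seed, {
    seen <- new.env(parent = emptyenv())
    dup_accepted <- FALSE
    out <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      for (try in 1:50) {
        idx <- sort(sample(length(subjects), replace = TRUE))
        key <- paste(idx, collapse = ",")
        if (is.null(seen[[key]])) break
      }
      if (!is.null(seen[[key]])) dup_accepted <- TRUE
      seen[[key]] <- TRUE
      out[[b]] <- idx
    }
    if (dup_accepted) warn("could not make all bootstrap resamples unique")
    out
  })
  est <- purrr::map(draws_idx, function(idx) {
    ids <- subjects[idx]
    # mean series over the resampled subjects (duplicates count twice)
    series <- purrr::map(ids, function(s) {
      cohort$peak_displacement_cm[cohort$subject_id == s]
    })
    mean_series <- Reduce(`+`, series) / length(series)
    fit_model(mean_series, schedule, model_kind, compliance = compliance,
              fit_gain = fit_gain, n_starts = n_starts, seed = seed,
              bounds = bounds, ...)$estimate
  })
  draws <- do.call(rbind, est)
  ci <- tibble::tibble(
    term = colnames(draws),
    conf.low = unname(apply(draws, 2, quantile, probs = 0.025, names = FALSE)),
    conf.high = unname(apply(draws, 2, quantile, probs = 0.975, names = FALSE))
  )
  attr(ci, "draws") <- draws
  ci
}

#' Fit the compliance profile (calibration experiment)
#'
#' Jointly fits the retention and learning-rate constants of a single-state
#' learner and the 10 compliance factors (`k_plus`, `k_minus` at the five
#' calibrated orientations) to a peak-displacement series from the
#' calibration schedule (`expS1`), in which subjects are repeatedly adapted
#' and de-adapted at each orientation. The gain is fixed at 1 here: this fit
#' IS the calibration. Because the state update is driven by the
#' mass-estimate discrepancy (not the cm-valued output), the compliance
#' factors are identified jointly with `beta` without a scale convention;
#' under `error_drive = "cm_units"` only the products `beta * k` would be
#' identified.
#'
#' @param observed Peak-displacement series aligned to `schedule`
#'   (`NA` on clamp trials if any).
#' @param schedule An `expS1` [build_schedule()] result covering all five
#'   orientations.
#' @param n_starts,seed,... Passed to [fit_model()].
#' @return A list with `fit` (the `adapt_fit`), `params` (the fitted
#'   [srm_params()]) and `compliance` (the fitted [compliance_profile()],
#'   gain 1).
#' @export
fit_compliance <- function(observed, schedule, n_starts = 20L, seed = 1L, ...) {
  need <- wrap_angle(c(0, -45, -90, -135, 180))
  have <- unique(wrap_angle(schedule$orientation_deg))
  if (!all(need %in% have)) {
    abort("schedule must cover all five calibrated orientations")
  }
  fit <- fit_model(observed, schedule, "srm_compliance", n_starts = n_starts,
                   seed = seed, ...)
  est <- fit$estimate
  list(fit = fit,
       params = srm_params(est[["alpha"]], est[["beta"]]),
       compliance = compliance_profile(est[paste0("k_plus", 1:5)],
                                       est[paste0("k_minus", 1:5)], gain = 1))
}
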