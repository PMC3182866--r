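#' Generative specification for synthetic cohorts
#'
#' Describes how to simulate a cohort of subjects: a generative state-space
#' model and its true parameters, per-subject parameter heterogeneity,
#' additive observation noise on peak displacement, and multiplicative noise
#' on error-clamp force measurements.
#'
#' @param params True generative parameters ([srm_params()], [drm_params()]
#'   or [mcsrm_params()]).
#' @param compliance A [compliance_profile()] (required for MCSRM kinds).
#' @param n_subjects Number of subjects (>= 1).
#' @param observation_noise_sd SD (cm) of the additive Gaussian noise on
#'   peak displacement, truncated so displacements stay non-negative. The
#'   default 0.15 cm is on the order of the pre-exposure variability of the
#'   task (subject SDs of roughly 0.08-0.13 cm).
#' @param heterogeneity_cv Relative SD of the multiplicative lognormal
#'   perturbation applied to each subject's retention and learning-rate
#'   constants (clipped into `(0, 1]`). Default 5%.
#' @param clamp_force_noise_sd Relative SD of the multiplicative noise on
#'   clamp-trial peak forces.
#' @param body_mass_kg Body mass used to convert mass fractions to
#'   kilograms for the clamp-force normalizer (a pure scale factor).
#' @param seed Integer seed; cohorts are bit-reproducible per seed.
#' @return An object of class `generative_spec`.
#' @export
generative_spec <- function(params, compliance = NULL, n_subjects = 8L,
                            observation_noise_sd = 0.15,
                            heterogeneity_cv = 0.05,
                            clamp_force_noise_sd = 0.05,
                            body_mass_kg = 70, seed = 1L) {
  if (n_subjects < 1) abort("n_subjects must be >= 1")
  if (observation_noise_sd < 0 || heterogeneity_cv < 0 || clamp_force_noise_sd < 0) {
    abort("noise SDs must be >= 0")
  }
  kind <- model_kind_of(params)
  if (kind %in% c("mcsrm4", "mcsrm10") && is.null(compliance)) {
    abort("MCSRM generative spec requires a compliance profile")
  }
  structure(list(params = params, compliance = compliance,
                 n_subjects = as.integer(n_subjects),
                 observation_noise_sd = observation_noise_sd,
                 heterogeneity_cv = heterogeneity_cv,
                 clamp_force_noise_sd = clamp_force_noise_sd,
                 body_mass_kg = body_mass_kg, seed = as.integer(seed)),
            class = "generative_spec")
}

perturb_rate <- function(value, cv) {
  if (cv == 0) return(value)
  min(max(value * exp(rnorm(1, 0, cv)), 1e-6), 1)
}

#' Generate a synthetic cohort on a schedule
#'
#' For each subject, the generative model's rate constants are perturbed by
#' seeded multiplicative lognormal heterogeneity, the model is simulated
#' noise-free over the schedule, and observations are emitted per trial:
#' on exposure and zero-force trials the observed peak displacement is the
#' model's absolute error plus zero-truncated Gaussian noise; on error-clamp
#' trials the observed peak subject force is the model's adaptation ratio
#' times the peak force the object would generate, times multiplicative
#' noise. Deterministic per seed.
#'
#' @param schedule An [build_schedule()] tibble.
#' @param spec A [generative_spec()].
#' @return A tibble of class `adapt_cohort` with columns `subject_id`,
#'   `trial`, `mode`, `orientation_deg`, `peak_displacement_cm` (`NA` on
#'   clamp trials) and `clamp_force_n` (`NA` elsewhere). The noise-free
#'   generative series and the spec are attached as attributes `truth` and
#'   `spec`.
#' @examples
#' sched <- build_schedule("exp1", seed = 1)
#' spec <- generative_spec(srm_params(0.9513, 0.2150), n_subjects = 2, seed = 7)
#' cohort <- generate_cohort(sched, spec)
#' @export
generate_cohort <- function(schedule, spec) {
  stopifnot(inherits(spec, "generative_spec"))
  kind <- model_kind_of(spec$params)
  mass_kg <- schedule$mass_frac_bm * spec$body_mass_kg
  peak_force <- vapply(unique(mass_kg), function(m) {
    peak_object_force(object_spec(m))
  }, numeric(1))
  peak_force <- peak_force[match(mass_kg, unique(mass_kg))]
  clamp <- schedule$mode == "error_clamp"
  truth <- simulate_model(schedule, spec$params, compliance = spec$compliance)
  subjects <- withr::with_seed(spec$seed, {
    purrr::map(seq_len(spec$n_subjects), function(s) {
      p <- spec$params
      rates <- if (kind == "drm") c("alpha1", "beta1", "alpha2", "beta2")
               else c("alpha", "beta")
      for (nm in rates) p[[nm]] <- perturb_rate(p[[nm]], spec$heterogeneity_cv)
      sim <- simulate_model(schedule, p, compliance = spec$compliance)
      disp <- pmax(sim$abs_error +
                     rnorm(nrow(schedule), 0, spec$observation_noise_sd), 0)
      force <- sim$adaptation_ratio * peak_force *
        (1 + rnorm(nrow(schedule), 0, spec$clamp_force_noise_sd))
      tibble::tibble(
        subject_id = s,
        trial = seq_len(nrow(schedule)) - 1L,
        mode = schedule$mode,
        orientation_deg = schedule$orientation_deg,
        peak_displacement_cm = ifelse(clamp, NA_real_, disp),
        clamp_force_n = ifelse(clamp, force, NA_real_)
      )
    })
  })
  out <- dplyr::bind_rows(subjects)
  tibble::new_tibble(out, class = "adapt_cohort", truth = truth, spec = spec)
}

#' Mean trial series of a cohort
#'
#' @param cohort An [generate_cohort()] tibble (or any tibble with
#'   `subject_id`, `trial` and `peak_displacement_cm`).
#' @return Numeric vector of across-subject mean peak displacement per trial
#'   (`NA` where no subject has a measurement, i.e. clamp trials).
#' @export
cohort_mean_series <- function(cohort) {
  dplyr::arrange(
    dplyr::summarise(dplyr::group_by(cohort, .data$trial),
                     m = mean(.data$peak_displacement_cm), .groups = "drop"),
    .data$trial)$m
}

fixture_table <- function() {
  list(
    exp1_srm = list(experiment = "exp1", group = NULL,
                    params = srm_params(0.9513, 0.2150), compliance = NULL),
    exp2_mcsrm = list(experiment = "exp2", group = 1L,
                      params = mcsrm_params(0.9811, 0.0451,
                                            sigma_deg = 26.3, offset = 0.09),
                      compliance = unit_compliance()),
    exp4_mcsrm = list(experiment = "exp4", group = NULL,
                      params = mcsrm_params(0.9811, 0.0451,
                                            sigma_deg = 26.3, offset = 0.09),
                      compliance = unit_compliance()),
    exp5_mcsrm = list(experiment = "exp5", group = NULL,
                      params = mcsrm_params(0.9811, 0.0451,
                                            sigma_deg = 26.3, offset = 0.09),
                      compliance = unit_compliance()),
    expS1_compliance = list(experiment = "expS1", group = NULL,
                            params = srm_params(0.9513, 0.2150),
                            compliance = compliance_profile(
                              k_plus = c(1.0, 1.2, 1.5, 1.2, 0.8),
                              k_minus = c(0.8, 1.0, 1.2, 1.0, 0.7)))
  )
}

#' Canonical seeded fixtures
#'
#' Builds a named fixture: the schedule, a synthetic cohort generated with
#' the published best-fit parameters as ground truth, and the truth record.
#' `exp1_srm` uses the single-context SRM estimates (alpha 0.9513, beta
#' 0.2150); the MCSRM fixtures use the multiple-context estimates (alpha
#' 0.9811, beta 0.0451, sigma 26.3 deg, offset 0.09) with the declared unit
#' compliance; `expS1_compliance` uses a synthetic, asymmetric compliance
#' profile as truth for calibration-recovery tests.
#'
#' @param name One of `"exp1_srm"`, `"exp2_mcsrm"`, `"exp4_mcsrm"`,
#'   `"exp5_mcsrm"`, `"expS1_compliance"`.
#' @param n_subjects,seed,... Overrides forwarded to [generative_spec()].
#' @return A list with elements `schedule`, `cohort` and `truth` (the
#'   generative parameters, compliance and spec).
#' @export
make_fixture <- function(name, n_subjects = 8L, seed = 20L, ...) {
  tab <- fixture_table()
  if (!name %in% names(tab)) {
    abort(sprintf("unknown fixture '%s' (available: %s)", name,
                  paste(names(tab), collapse = ", ")))
  }
  fx <- tab[[name]]
  schedule <- build_schedule(fx$experiment, seed = seed, group = fx$group)
  spec <- generative_spec(fx$params, compliance = fx$compliance,
                          n_subjects = n_subjects, seed = seed, ...)
  cohort <- generate_cohort(schedule, spec)
  list(schedule = schedule, cohort = cohort,
       truth = list(params = fx$params, compliance = fx$compliance,
                    spec = spec))
}
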