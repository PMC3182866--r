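test_that("BIC arithmetic and the strong-evidence threshold behave as specified", {
  expect_equal(bic_score(1, 0, 100), 0)
  # equal residual variance: the parameter penalty decides, by 2 ln(n)
  expect_equal(bic_score(0.5, 4, 320) - bic_score(0.5, 2, 320), 2 * log(320))
  expect_equal(2 * log(10), 4.605, tolerance = 1e-3)
  expect_warning(b <- bic_score(0, 2, 100), "residual")
  expect_identical(b, -Inf)
  expect_error(bic_score(1, 10, 5), "trials")
})

test_that("model selection reports delta BIC and strong evidence only beyond threshold", {
  fake_fit <- function(kind, bic) {
    structure(list(model_kind = kind, bic = bic, n_trials = 320),
              class = "adapt_fit")
  }
  sel <- select_model(fake_fit("srm", 100), fake_fit("drm", 108.3))
  expect_equal(sel$delta_bic, -8.3)
  expect_equal(sel$favored, "srm")
  expect_true(sel$strong_evidence)
  sel2 <- select_model(fake_fit("srm", 100), fake_fit("drm", 102))
  expect_equal(sel2$favored, "srm")
  expect_false(sel2$strong_evidence)
  sel3 <- select_model(fake_fit("mcsrm4", 100), fake_fit("mcsrm10", 123.8))
  expect_true(sel3$strong_evidence)
  expect_error(select_model(fake_fit("srm", 1),
                            structure(list(model_kind = "drm", bic = 2,
                                           n_trials = 10),
                                      class = "adapt_fit")),
               "different numbers")
})

test_that("exponential fits recover exact time constants, including the geometric closed form", {
  n <- 1:60
  f <- fit_exponential(0.2 + 0.8 * exp(-n / 5))
  expect_equal(f$time_constant_trials, 5, tolerance = 1e-6)
  expect_equal(f$asymptote, 0.2, tolerance = 1e-6)
  expect_equal(f$amplitude, 0.8, tolerance = 1e-5)
  # geometric decay with ratio r has t = -1 / ln(r)
  r <- 0.7363
  g <- fit_exponential(0.1 + 0.9 * r^(n - 1))
  expect_equal(g$time_constant_trials, -1 / log(r), tolerance = 1e-6)
  expect_warning(flat <- fit_exponential(rep(1, 10)), "constant")
  expect_true(flat$degenerate)
  expect_error(fit_exponential(1:3), "4 points")
})

test_that("adaptation and de-adaptation share one time constant under a single-rate process", {
  sched <- main_exp1()
  sim <- simulate_model(sched, SRM_EXP1)
  post <- sim$abs_error[sched$phase_label == "post"]
  t_post <- fit_exponential(post)$time_constant_trials
  expect_equal(t_post, -1 / log(SRM_EXP1$alpha - SRM_EXP1$beta),
               tolerance = 1e-4)
})

test_that("noise-free series refit recovers the generating parameters (reduced starts)", {
  sched <- main_exp1()
  obs <- noise_free_obs(sched, SRM_EXP1)
  fit <- fit_model(obs, sched, "srm", n_starts = 3, seed = 7)
  expect_equal(unname(fit$estimate), c(0.9513, 0.2150), tolerance = 1e-5)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_true(fit$converged)
  expect_equal(fit$n_trials, 304)   # 320 minus 16 unmeasured clamp trials
})

test_that("a constant series yields a flat converged fit with zero R-squared", {
  sched <- main_exp1()
  obs <- rep(0.5, nrow(sched))
  fit <- fit_model(obs, sched, "srm", n_starts = 3, seed = 2)
  expect_true(fit$converged)
  expect_equal(fit$r_squared, 0, tolerance = 1e-6)
  expect_lt(fit$estimate[["beta"]], 0.02)
})

test_that("fit inputs are validated", {
  sched <- main_exp1()
  expect_error(fit_model(rep(Inf, nrow(sched)), sched, "srm"), "non-finite")
  expect_error(fit_model(rep(1, nrow(sched)), sched, "mcsrm4"), "compliance")
  expect_error(fit_model(rep(1, nrow(sched)), sched, "srm",
                         bounds = list(lower = c(1, 1), upper = c(0, 0))),
               "infeasible")
})

test_that("bootstrap CIs are seed-reproducible and collapse for identical subjects", {
  sched <- main_exp1()
  sim <- simulate_model(sched, SRM_EXP1)
  one <- tibble::tibble(trial = sim$trial, mode = sim$mode,
                        orientation_deg = sim$orientation_deg,
                        peak_displacement_cm = ifelse(sim$mode == "error_clamp",
                                                      NA, sim$abs_error))
  cohort <- dplyr::bind_rows(
    dplyr::mutate(one, subject_id = 1L),
    dplyr::mutate(one, subject_id = 2L),
    dplyr::mutate(one, subject_id = 3L))
  ci <- bootstrap_ci(cohort, sched, "srm", n_boot = 5, seed = 9, n_starts = 2)
  expect_equal(ci$conf.low, ci$conf.high, tolerance = 1e-5)
  expect_equal(ci$conf.low, c(0.9513, 0.2150), tolerance = 1e-4)
  ci2 <- bootstrap_ci(cohort, sched, "srm", n_boot = 5, seed = 9, n_starts = 2)
  expect_identical(ci, ci2)
  expect_error(bootstrap_ci(dplyr::mutate(one, subject_id = 1L), sched, "srm",
                            n_boot = 5, seed = 1), "2 subjects")
})

test_that("bootstrap draws cover the point estimate on a small noisy cohort", {
  sched <- main_exp1()
  spec <- generative_spec(SRM_EXP1, n_subjects = 6, seed = 31)
  cohort <- generate_cohort(sched, spec)
  fit <- fit_model(cohort_mean_series(cohort), sched, "srm",
                   n_starts = 3, seed = 1)
  ci <- bootstrap_ci(cohort, sched, "srm", n_boot = 30, seed = 5, n_starts = 2)
  expect_true(all(fit$estimate >= ci$conf.low - 1e-6 &
                    fit$estimate <= ci$conf.high + 1e-6))
})

test_that("compliance calibration recovers an asymmetric profile from noise-free data", {
  sched <- build_schedule("expS1", seed = 5, n_cycles = 2)
  truth_k <- compliance_profile(k_plus = c(1.0, 1.2, 1.5, 1.2, 0.8),
                                k_minus = c(0.8, 1.0, 1.2, 1.0, 0.7))
  sim <- simulate_model(sched, SRM_EXP1, compliance = truth_k)
  fc <- fit_compliance(sim$abs_error, sched, n_starts = 8, seed = 3)
  expect_equal(fc$params$alpha, 0.9513, tolerance = 1e-3)
  expect_equal(fc$params$beta, 0.2150, tolerance = 1e-3)
  expect_equal(fc$compliance$k_plus, truth_k$k_plus, tolerance = 1e-2)
  expect_equal(fc$compliance$k_minus, truth_k$k_minus, tolerance = 1e-2)
  # symmetric truth begets symmetric estimates
  sym <- compliance_profile(k_plus = c(1, 1.2, 1.4, 1.2, 1),
                            k_minus = c(1, 1.2, 1.4, 1.2, 1))
  sim2 <- simulate_model(sched, SRM_EXP1, compliance = sym)
  fc2 <- fit_compliance(sim2$abs_error, sched, n_starts = 8, seed = 4)
  expect_equal(fc2$compliance$k_plus, fc2$compliance$k_minus, tolerance = 0.05)
  expect_error(fit_compliance(sim$abs_error[1:100], sched[1:100, ]),
               "orientations")
})
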