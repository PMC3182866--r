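test_that("Gaussian tuning hits its anchors, is symmetric and monotone in lag", {
  tun <- MCSRM4_EXP2$tuning
  cv <- tuning_vector(0, tun)
  expect_equal(cv[["0"]], 1)
  expect_equal(cv[["180"]], 0.09)
  expect_equal(cv[["22.5"]], cv[["-22.5"]])
  expect_equal(cv[["90"]], cv[["-90"]])
  lags <- abs(circ_diff(as.numeric(names(cv)), 0))
  ord <- order(lags)
  expect_true(all(diff(cv[ord]) <= 1e-12))  # non-increasing in |lag|
  # recentering moves the peak without changing the lag profile
  cv90 <- tuning_vector(-90, tun)
  expect_equal(cv90[["-90"]], 1)
  expect_equal(cv90[["90"]], 0.09)
  expect_equal(unname(sort(cv90)), unname(sort(cv)))
  # flat limit: offset 1 gives uniform weights
  expect_equal(unname(tuning_vector(-90, list(sigma_deg = 1e6, offset = 1))),
               rep(1, 16))
  expect_error(tuning_vector(10, tun), "grid")
})

test_that("free-tuning weights are looked up by absolute lag with lag 0 fixed at 1", {
  w <- seq(0.8, 0.1, length.out = 8)
  p10 <- mcsrm_params(0.98, 0.05, weights = w)
  cv <- tuning_vector(-45, p10$tuning)
  expect_equal(cv[["-45"]], 1)
  expect_equal(cv[["-22.5"]], w[1])
  expect_equal(cv[["-67.5"]], w[1])
  expect_equal(cv[["135"]], w[8])
})

test_that("single-rate steps reproduce first-trial, fixed-point and zero-force algebra", {
  p <- SRM_EXP1
  st <- step_srm(0, 1, p)
  expect_equal(st$e, 1)
  expect_equal(st$x_next, 0.2150)
  xstar <- p$beta / (1 - p$alpha + p$beta)
  st2 <- step_srm(xstar, 1, p)
  expect_equal(st2$x_next, xstar, tolerance = 1e-12)
  expect_equal(st2$e, (1 - p$alpha) / (1 - p$alpha + p$beta), tolerance = 1e-12)
  st3 <- step_srm(0.5, 0, p)
  expect_equal(st3$e, -0.5)
  expect_equal(st3$x_next, (p$alpha - p$beta) * 0.5)
  # clamp trials report the error but decay the state
  st4 <- step_srm(0.5, 1, p, mode = "error_clamp")
  expect_equal(st4$e, 0.5)
  expect_equal(st4$x_next, p$alpha * 0.5)
})

test_that("exposure-phase error is exactly geometric toward its asymptote", {
  p <- srm_params(0.92, 0.18)
  sched <- tibble::tibble(mode = rep("exposure", 1000),
                          orientation_deg = 0, mass_frac_bm = 0.01)
  sim <- simulate_model(sched, p)
  n <- seq_len(1000)
  einf <- (1 - p$alpha) / (1 - p$alpha + p$beta)
  expect_equal(sim$error, einf + (1 - einf) * (p$alpha - p$beta)^(n - 1),
               tolerance = 1e-10)
})

test_that("dual-rate model with equal rate pairs collapses to a single-rate model", {
  sched <- main_exp1()
  dp <- drm_params(0.95, 0.05, 0.95, 0.05)
  sp <- srm_params(0.95, 0.10)
  expect_equal(simulate_model(sched, dp)$x_net, simulate_model(sched, sp)$x_net,
               tolerance = 1e-12)
  # first trial from rest
  st <- step_drm(0, 0, 1, DRM_EXP1)
  expect_equal(st$e, 1)
  expect_equal(st$x1_next, DRM_EXP1$beta1)
  expect_equal(st$x2_next, DRM_EXP1$beta2)
})

test_that("degenerate tuning makes the multiple-context model reproduce the SRM exactly", {
  sched <- main_exp1()
  mp <- mcsrm_params(SRM_EXP1$alpha, SRM_EXP1$beta, sigma_deg = 1e-3, offset = 0)
  simM <- simulate_model(sched, mp, compliance = unit_compliance())
  simS <- simulate_model(sched, SRM_EXP1)
  expect_equal(simM$x_net, simS$x_net, tolerance = 1e-12)
  expect_equal(simM$error, simS$error, tolerance = 1e-12)
})

test_that("with zero learning rate the context-state norm decays as alpha^n on any schedule", {
  sched <- build_schedule("exp5", seed = 2)
  p <- mcsrm_params(0.9, 0, sigma_deg = 26.3, offset = 0.09)
  z <- withr::with_seed(4, runif(16))
  z0 <- z
  uc <- unit_compliance()
  for (i in 1:120) {
    z <- step_mcsrm(z, sched$mass_frac_bm[i] / 0.01, sched$orientation_deg[i],
                    p, uc, mode = sched$mode[i])$z_next
  }
  expect_equal(sqrt(sum(z^2)), 0.9^120 * sqrt(sum(z0^2)), tolerance = 1e-12)
})

test_that("compliance interpolates linearly around the circle and signs select k", {
  prof <- compliance_profile(k_plus = c(1.0, 2.0, 1.5, 1.0, 3.0), k_minus = 0.5)
  expect_equal(compliance_at(-22.5, prof, "plus"), 1.5)     # midpoint 0 / -45
  expect_equal(compliance_at(90, prof, "plus"), 2.0)        # midpoint 0 / 180
  expect_equal(compliance_at(-157.5, prof, "plus"), 2.0)    # midpoint -135 / 180
  expect_equal(compliance_error(1, 1, 0, prof), 0)
  expect_equal(compliance_error(1, 0, 0, compliance_profile(k_plus = 1.2)), 1.2)
  expect_equal(compliance_error(0, 1, 0, prof), -0.5)       # f < x uses k_minus
})

test_that("first exposure spreads credit by the tuning vector; clamp trials purely retain", {
  p <- MCSRM4_EXP2
  uc <- unit_compliance()
  st <- step_mcsrm(numeric(16), 1, 0, p, uc)
  expect_equal(st$x_net, 0)
  expect_equal(st$e_cm, 1)
  inc <- st$z_next
  expect_equal(inc[["180"]] / inc[["0"]], 0.09, tolerance = 1e-12)
  z <- withr::with_seed(1, runif(16))
  st2 <- step_mcsrm(z, 1, 0, p, uc, mode = "error_clamp")
  expect_equal(unname(st2$z_next), p$alpha * z, tolerance = 1e-12)
})

test_that("simulation is deterministic and validates its inputs", {
  sched <- build_schedule("exp2", group = 1, seed = 5)
  uc <- unit_compliance()
  a <- simulate_model(sched, MCSRM4_EXP2, compliance = uc)
  b <- simulate_model(sched, MCSRM4_EXP2, compliance = uc)
  expect_identical(a, b)
  expect_error(simulate_model(sched, MCSRM4_EXP2), "compliance")
})

test_that("fitted single-context DRM parameters show neither spontaneous recovery nor savings; textbook fast/slow parameters show both", {
  expect_equal(diagnose_drm(drm_params(0.95, 0.1, 0.95, 0.1),
                            "spontaneous_recovery"), 0)
  expect_equal(diagnose_drm(drm_params(0.95, 0.1, 0.95, 0.1), "savings"), 0,
               tolerance = 1e-10)
  expect_lt(diagnose_drm(DRM_EXP1, "spontaneous_recovery"), 0.05)
  expect_lt(diagnose_drm(DRM_EXP1, "savings"), 0.05)
  textbook <- drm_params(0.996, 0.01, 0.70, 0.30)
  expect_gt(diagnose_drm(textbook, "spontaneous_recovery"), 0.1)
  expect_gt(diagnose_drm(textbook, "savings"), 0.1)
})
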