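test_that("single-context normalization anchors hold and the map is affine-invariant", {
  sched <- main_exp1()
  sim <- simulate_model(sched, SRM_EXP1)
  y <- ifelse(sim$mode == "error_clamp", NA, sim$abs_error) + 0.3
  z <- normalize_exp1(y, sched)
  pre_final8 <- tail(which(sched$phase_label == "pre"), 8)
  expect_equal(mean(z[pre_final8]), 0, tolerance = 1e-12)
  expect_equal(max(z, na.rm = TRUE), 1)
  # affine transforms of the input give the identical normalized series
  expect_equal(normalize_exp1(2.7 * y + 0.4, sched), z, tolerance = 1e-12)
  # an already-normalized series passes through unchanged
  expect_equal(normalize_exp1(z, sched), z, tolerance = 1e-12)
  expect_error(normalize_exp1(rep(1, nrow(sched)), sched), "degenerate")
  expect_error(normalize_exp1(y, build_schedule("exp4", seed = 1)), "exp1")
})

test_that("the composite generalization curve from a noise-free model falls off with relative orientation", {
  sched <- build_schedule("exp2", group = 1, seed = 3)
  sim <- simulate_model(sched, MCSRM4_EXP2, compliance = unit_compliance())
  comp <- composite_exp2(sim$abs_error, sched)
  curve <- comp$curve
  expect_equal(curve$relative_orientation_deg, c(0, 22.5, 45, 90, 180))
  expect_equal(which.max(curve$deadaptation_error_cm), 1)
  expect_lt(curve$deadaptation_error_cm[5], curve$deadaptation_error_cm[3])
  expect_true(all(diff(curve$deadaptation_error_cm[1:4]) < 0))
  expect_true(all(diff(curve$reexposure_error_cm[1:4]) < 0))
  # half-Gaussian width lands near the generative tuning scale
  expect_gt(comp$fits$deadaptation$width_deg, 15)
  expect_lt(comp$fits$deadaptation$width_deg, 60)
  # composite layout: 64 exposure trials + 5 blocks of 30
  expect_equal(nrow(comp$composite), 64 + 150)
  expect_equal(comp$composite$relative_orientation_deg[65], 180)
})

test_that("a flat generalization truth degenerates the half-Gaussian width", {
  fit <- half_gaussian_fit(c(0, 22.5, 45, 90, 180), rep(0.4, 5))
  expect_true(fit$degenerate)
})

test_that("composite analysis of a cohort matches the noise-free model composite", {
  sched <- build_schedule("exp2", group = 1, seed = 3)
  spec <- generative_spec(MCSRM4_EXP2, compliance = unit_compliance(),
                          n_subjects = 2, seed = 1, observation_noise_sd = 0,
                          heterogeneity_cv = 0, clamp_force_noise_sd = 0)
  cohort <- generate_cohort(sched, spec)
  sim <- simulate_model(sched, MCSRM4_EXP2, compliance = unit_compliance())
  comp_cohort <- composite_exp2(cohort, sched)
  comp_model <- composite_exp2(sim$abs_error, sched)
  expect_equal(comp_cohort$curve, comp_model$curve, tolerance = 1e-12)
})

test_that("clamp forces convert to adaptation ratios with the published conventions", {
  obj <- object_spec(0.7)
  pf <- peak_object_force(obj)
  expect_equal(adaptation_from_clamp(pf, obj), 1)
  expect_equal(adaptation_from_clamp(0, obj), 0)
  # relative scaling: perfect adaptation to 0.7/1.0/1.3% BM objects maps to
  # 0.7/1.0/1.3 when normalized by the 1.0% BM object's peak force
  ref <- object_spec(1.0)
  for (m in c(0.7, 1.0, 1.3)) {
    expect_equal(adaptation_from_clamp(peak_object_force(object_spec(m)),
                                       object_spec(m), reference = ref),
                 m, tolerance = 1e-12)
  }
})

test_that("mass slopes separate training from transfer orientations", {
  sched <- build_schedule("exp3", seed = 2)
  spec <- generative_spec(MCSRM4_EXP2, compliance = unit_compliance(),
                          n_subjects = 3, seed = 6, observation_noise_sd = 0,
                          heterogeneity_cv = 0, clamp_force_noise_sd = 0)
  cohort <- generate_cohort(sched, spec)
  res <- mass_slopes(cohort, sched, body_mass_kg = spec$body_mass_kg)
  s <- res$summary
  training <- s$mean_slope[s$orientation == "training"]
  transfer <- s$mean_slope[s$orientation == "transfer"]
  expect_gt(training, transfer)
  expect_gt(training, 0.5)
  expect_lt(transfer, 0.3)
  # a perfectly adapting subject has slope exactly 1 at training
  perfect <- cohort[cohort$subject_id == 1, ]
  sched_mass <- sched$mass_frac_bm[match(perfect$trial, sched$index)]
  clamp <- perfect$mode == "error_clamp" & perfect$orientation_deg == 0
  perfect$clamp_force_n[clamp] <- vapply(which(clamp), function(i) {
    peak_object_force(object_spec(sched_mass[i] * spec$body_mass_kg))
  }, numeric(1))
  res_p <- mass_slopes(perfect, sched, body_mass_kg = spec$body_mass_kg)
  sl <- res_p$slopes
  expect_equal(sl$slope[sl$orientation == "training"], 1, tolerance = 1e-9)
})

test_that("orientation-change binning uses circular distance and skips the first exposure cycle", {
  sched <- build_schedule("exp5", seed = 7)
  sim <- simulate_model(sched, MCSRM4_EXP2, compliance = unit_compliance())
  bins <- bin_exp5(sim, sched)
  expect_true(all(bins$blocks$delta_deg %in% c(45, 90, 135, 180)))
  expect_true(all(bins$blocks$bin[bins$blocks$delta_deg >= 90] == "90+"))
  expect_true(all(bins$blocks$bin[bins$blocks$delta_deg == 45] == "45"))
  expect_equal(nrow(bins$blocks), 20)   # cycles 2-5, 5 blocks each
  # model prediction: higher block-initial adaptation after a 45 deg change,
  # equal block-final adaptation
  b <- bins$bins
  expect_gt(b$initial_adaptation[b$bin == "45"],
            b$initial_adaptation[b$bin == "90+"])
  expect_equal(b$final_adaptation[b$bin == "45"],
               b$final_adaptation[b$bin == "90+"], tolerance = 0.05)
  expect_equal(unique(bins$trajectory$exposure_trial), 1:16)
})

test_that("wraparound orientation changes land in the far bin", {
  expect_equal(abs(circ_diff(0, 180)), 180)
  expect_equal(abs(circ_diff(-135, 180)), 45)
  expect_equal(abs(circ_diff(-45, -135)), 90)
})
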