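test_that("trial counts and block arithmetic match every protocol", {
  s1 <- build_schedule("exp1", seed = 1)
  expect_equal(nrow(s1), 368)                         # incl. familiarization
  expect_equal(sum(!s1$familiarization), 320)
  expect_equal(sum(s1$phase_label == "exposure"), 224)
  expect_equal(sum(s1$mode == "error_clamp"), 16)

  s2 <- build_schedule("exp2", group = 1, seed = 3)
  expect_equal(nrow(s2), 64 + 15 * 30)
  expect_true(all(table(s2$block_id[s2$block_id > 0]) == 30))
  expect_equal(dplyr::n_distinct(s2$block_id[s2$block_id > 0]), 15)

  s3 <- build_schedule("exp3", seed = 2)
  expect_equal(nrow(s3), 3 * 90)

  s4 <- build_schedule("exp4", seed = 1)
  expect_equal(nrow(s4), 528)

  s5 <- build_schedule("exp5", seed = 7)
  expect_equal(nrow(s5), 40 + 500 + 40)

  expect_equal(nrow(build_schedule("expS1", seed = 1, n_cycles = 2)),
               2 * 5 * 50)
})

test_that("single-context error clamps sit one per 8-trial bin in the final 128 exposure trials, direction-balanced", {
  for (seed in c(1, 5, 99)) {
    s1 <- build_schedule("exp1", seed = seed)
    expo <- s1[s1$phase_label == "exposure", ]
    pos <- which(expo$mode == "error_clamp")
    expect_length(pos, 16)
    expect_true(all(pos > 96))                          # only final 128
    bins <- floor((pos - 97) / 8)
    expect_equal(sort(bins), 0:15)                      # one per bin
    expect_equal(as.integer(table(expo$direction[pos])), c(8L, 8L))
  }
})

test_that("probe, mass and orientation orders are per-cycle permutations", {
  s2 <- build_schedule("exp2", group = 2, seed = 11)
  dead <- s2[grepl("^deadapt", s2$phase_label), ]
  probes_by_block <- dplyr::distinct(dead[c("block_id", "orientation_deg")])
  expect_equal(nrow(probes_by_block), 15)
  for (cyc in 0:2) {
    cycle_probes <- probes_by_block$orientation_deg[cyc * 5 + 1:5]
    expect_setequal(cycle_probes, c(180, -157.5, -135, -90, 0))
  }

  s3 <- build_schedule("exp3", seed = 4)
  masses <- unique(s3$mass_frac_bm)
  expect_setequal(masses, c(0.007, 0.010, 0.013))
  # 6 clamps per mass block: 3 at training, 3 at transfer orientation
  for (b in unique(s3$block_id)) {
    blk <- s3[s3$block_id == b, ]
    clamps <- blk[blk$mode == "error_clamp", ]
    expect_equal(nrow(clamps), 6)
    expect_equal(sum(clamps$orientation_deg == 0), 3)
    expect_equal(sum(clamps$orientation_deg == -90), 3)
  }

  s5 <- build_schedule("exp5", seed = 7)
  blocks <- dplyr::distinct(s5[c("block_id", "orientation_deg", "phase_label")])
  expo_cycles <- split(blocks$orientation_deg[grepl("^exposure", blocks$phase_label)],
                       blocks$phase_label[grepl("^exposure", blocks$phase_label)])
  for (cyc in expo_cycles) expect_setequal(cyc, c(0, -45, -90, -135, 180))
})

test_that("dual-context blocks alternate orientations with seeded clamps never block-initial", {
  s4 <- build_schedule("exp4", seed = 6)
  blocks <- split(s4, s4$block_id)
  expect_length(blocks, 22)
  zero_blocks <- vapply(blocks, function(b) all(b$mode == "zero_force"), logical(1))
  expect_equal(sum(zero_blocks), 4)                    # first + last cycles
  for (b in blocks[!zero_blocks]) {
    expect_equal(sum(b$mode == "error_clamp"), 4)
    expect_equal(b$mode[1], "exposure")                # never the first trial
    expect_length(unique(b$orientation_deg), 1)
  }
  orient_per_block <- vapply(blocks, function(b) b$orientation_deg[1], numeric(1))
  expect_equal(unname(orient_per_block[order(as.integer(names(blocks)))]),
               rep(c(180, 0), 11))
})

test_that("directions strictly alternate within blocks and schedules are seed-reproducible", {
  for (id in c("exp1", "exp4", "exp5")) {
    s <- build_schedule(id, seed = 13)
    for (b in split(s, s$block_id)) {
      expect_true(all(b$direction == rep_len(c("CW", "CCW"), nrow(b))))
    }
    expect_identical(build_schedule(id, seed = 13), s)
    other <- build_schedule(id, seed = 14)
    expect_false(identical(other[c("mode", "orientation_deg")],
                           s[c("mode", "orientation_deg")]))
  }
  expect_identical(build_schedule("exp2", group = 1, seed = 2),
                   build_schedule("exp2", group = 1, seed = 2))
})

test_that("invalid schedule requests are rejected", {
  expect_error(build_schedule("exp9"), "arg")
  expect_error(build_schedule("exp2", seed = 1), "group")
  expect_error(build_schedule("exp3", seed = 1, masses = 0.01), "masses")
})
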