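test_that("torque census matches the brute-force cross-product oracle", {
  p <- forcefield_params(temperature_K = 0)
  for (seed in 1:15) {
    ch <- make_random_chain(8, seed)
    got <- torque_census(ch, p)
    want <- oracle_torque_census(ch, p)
    expect_equal(got$pivot, want$pivot)
    expect_equal(got$lever, want$lever, tolerance = 1e-12)
    # scale-aware: exact-zero torques cancel catastrophically on both paths
    expect_true(all(abs(got$torque - want$torque) <=
                      1e-10 * (1e-6 + abs(want$torque))))
    expect_true(all(abs(got$force - want$force) <=
                      1e-10 * (1e-6 + abs(want$force))))
    nz <- want$torque > 1e-12
    expect_equal(got$sign[nz], want$sign[nz])
  }
  # frozen pivots are excluded from the census
  ch <- make_random_chain(8, 1)
  ch$pivots$frozen[c(2, 5)] <- TRUE
  expect_false(any(c(2, 5) %in% torque_census(ch, p)$pivot))
  ch$pivots$frozen <- rep(TRUE, 7)
  expect_error(torque_census(ch, p), "terminated")
})

test_that("torque is the axial moment of the pair force on the mobile block", {
  p <- forcefield_params(temperature_K = 0)
  # neutral chain: zero torque everywhere
  ch <- make_chain(rbind(c(-1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(1, 1, 1)),
                   q = rep(0, 4), h = rep(-1, 4))
  tc <- torque_census(ch, p)
  expect_equal(tc$torque, rep(0, nrow(tc)))

  # one interacting pair: charge at site 1 repels charge at site 4; pivot 2
  # has axis z through the origin and mobile block {4} (tie -> C flank)
  ch$q <- c(1, 0, 0, 1)
  tc <- torque_census(ch, p)
  r14 <- ch$xyz[4, ] - ch$xyz[1, ]
  Fvec <- coulomb_force(1, 1, sqrt(sum(r14^2)), p$eps_rel) *
    r14 / sqrt(sum(r14^2))
  lever <- ch$xyz[4, ] - ch$xyz[2, ]        # moment about the pivot site
  tz <- lever[1] * Fvec[2] - lever[2] * Fvec[1]   # projection on the z axis
  expect_gt(abs(tz), 0)
  expect_equal(tc$torque[tc$pivot == 2], abs(tz), tolerance = 1e-12)
  expect_equal(tc$force[tc$pivot == 2], abs(tz) / sqrt(sum(lever^2)),
               tolerance = 1e-12)
})

test_that("neutral chains at zero temperature generate an all-zero trace", {
  f <- run_fold(strrep("A", 8),
                config = fold_config(max_steps = 20, seed = 1),
                params = forcefield_params(temperature_K = 0))
  expect_true(all(f$trace$dE_eV == 0))
  expect_true(all(f$trace$E_eV == 0))
  expect_true(all(f$trace$theta_rad == 0))
})

test_that("folding runs are deterministic per seed and respect max_steps", {
  s <- generate_fixture(32, "amphipathic")
  cfg <- fold_config(max_steps = 60, seed = 4)
  f1 <- run_fold(s, config = cfg)
  f2 <- run_fold(s, config = cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$coords, f2$coords)
  expect_lte(nrow(f1$trace), 60L)
  f3 <- run_fold(s, config = fold_config(max_steps = 60, seed = 5))
  expect_false(identical(f1$trace$dE_eV, f3$trace$dE_eV))
  # max_steps = 0: initial structure, empty trace
  f0 <- run_fold(s, config = fold_config(max_steps = 0, seed = 1))
  expect_equal(nrow(f0$trace), 0L)
  expect_equal(nrow(f0$coords), 32L)
})

test_that("energy bookkeeping is exact and work per step is non-negative", {
  f <- run_fold(generate_fixture(32, "amphipathic"),
                config = fold_config(max_steps = 150, seed = 2))
  tr <- f$trace
  # bookkeeping identity: E_t = E_{t-1} - dE_t, bit-exact sequential recompute
  E <- 0
  expect_identical(tr$E_eV,
                   vapply(tr$dE_eV, function(d) (E <<- E - d), numeric(1)))
  expect_true(all(tr$dE_eV >= 0))
  expect_equal(tr$dE_eV,
               tr$F_eV_per_nm * abs(tr$theta_rad) * tr$r0_nm,
               tolerance = 1e-12)
})

test_that("five consecutive census wins freeze a pivot permanently", {
  f <- run_fold(generate_fixture(48, "amphipathic"),
                config = fold_config(max_steps = 800, seed = 1))
  tr <- f$trace
  expect_gt(max(tr$n_frozen), 0)              # at least one freeze occurred
  expect_true(all(diff(tr$n_frozen) >= 0))    # frozen set grows monotonically
  runs <- rle(tr$pivot)
  ends <- cumsum(runs$lengths)
  for (i in seq_along(runs$lengths)) {
    # no run outlives the freeze threshold
    expect_lte(runs$lengths[i], 5L)
    if (runs$lengths[i] == 5L) {
      # frozen exactly at the fifth win, never selected again
      expect_equal(tr$n_frozen[ends[i]], tr$n_frozen[ends[i] - 1L] + 1)
      if (ends[i] < nrow(tr))
        expect_false(runs$values[i] %in% tr$pivot[(ends[i] + 1L):nrow(tr)])
    }
  }
  # threshold 1 freezes the winner of every step
  f1 <- run_fold(generate_fixture(24, "amphipathic"),
                 config = fold_config(max_steps = 10, seed = 1,
                                      freeze_threshold = 1))
  expect_equal(f1$trace$n_frozen, seq_len(nrow(f1$trace)))
  expect_equal(anyDuplicated(f1$trace$pivot), 0L)
})

test_that("fluctuation profile computes rolling standard deviations", {
  expect_equal(fluctuation_profile(rep(2, 10), 3), rep(0, 8))
  two_phase <- c(rnorm(50, sd = 5), rnorm(50, sd = 0.01))
  prof <- fluctuation_profile(two_phase, 10)
  expect_gt(prof[1], prof[length(prof)])
  expect_error(fluctuation_profile(rep(1, 5), 3), "2\\*window")
})

test_that("step_once reports the winning pivot and advances the chain", {
  s <- generate_fixture(24, "amphipathic")
  a <- annotate_sequence(s)
  cg <- coarse_grain_regions(insert_templates(build_extended_chain(a),
                                              predict_secondary(a)))
  set.seed(7)
  cg <- driftfold:::.perturb_chain(cg)
  st <- step_once(cg, fold_config(seed = 7), forcefield_params())
  expect_true(st$row[["pivot"]] %in% cg$pivots$from)
  expect_equal(st$chain$pivots$win_count[st$row[["pivot"]]], 1L)
  expect_true(all(st$chain$pivots$win_count[-st$row[["pivot"]]] == 0L))
  expect_equal(st$row[["dE"]],
               st$row[["force"]] * abs(st$row[["theta"]]) * st$row[["lever"]])
})
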