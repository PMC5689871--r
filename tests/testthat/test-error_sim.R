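test_that("zero-magnitude injection returns an identical plan", {
  beams <- fix_arc(cps = 9, seed = 6)
  sp <- error_spec("gantry", low = 0, high = 0, seed = 2)
  expect_identical(inject_errors(beams, sp), beams)
})

test_that("injection is deterministic under a fixed spec and seed", {
  beams <- fix_arc(cps = 9, seed = 6)
  for (ty in c("gantry", "MU", "jaw", "collimator", "MLC")) {
    sp <- error_spec(ty, seed = 77)
    expect_identical(inject_errors(beams, sp), inject_errors(beams, sp))
  }
  # different seed, different plan
  expect_false(identical(inject_errors(beams, error_spec("gantry", seed = 1)),
                         inject_errors(beams, error_spec("gantry", seed = 2))))
})

test_that("injection touches only the targeted axis", {
  beams <- fix_arc(cps = 9, seed = 6)
  cp0 <- beams[[1]]$control_points
  mod <- inject_errors(beams, error_spec("gantry", seed = 3))[[1]]$control_points
  for (i in seq_along(cp0)) {
    expect_identical(mod[[i]]$jaws, cp0[[i]]$jaws)
    expect_identical(mod[[i]]$bank_A, cp0[[i]]$bank_A)
    expect_identical(mod[[i]]$weight, cp0[[i]]$weight)
    expect_equal(mod[[i]]$angles[["collimator_deg"]],
                 cp0[[i]]$angles[["collimator_deg"]])
  }
  modm <- inject_errors(beams, error_spec("MLC", seed = 3))[[1]]$control_points
  for (i in seq_along(cp0)) {
    expect_equal(modm[[i]]$angles, cp0[[i]]$angles)
    expect_identical(modm[[i]]$jaws, cp0[[i]]$jaws)
  }
})

test_that("within-tolerance gantry errors are bounded and uniform", {
  beams <- fix_arc(cps = 91, seed = 6)
  # collect many draws over repeated injections for a distribution check
  d <- unlist(lapply(1:120, function(s) {
    mod <- inject_errors(beams, error_spec("gantry", seed = s))
    angle_diff(vapply(mod[[1]]$control_points,
                      function(cp) cp$angles[["gantry_deg"]], numeric(1)),
               vapply(beams[[1]]$control_points,
                      function(cp) cp$angles[["gantry_deg"]], numeric(1)))
  }))
  expect_true(all(abs(d) <= 1 + 1e-12))
  ks <- suppressWarnings(ks.test(d, "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("out-of-tolerance MLC shifts stay in [2, 3] mm either direction", {
  beams <- fix_arc(cps = 21, seed = 6)
  mod <- inject_errors(beams, error_spec("MLC", regime = "outside", seed = 4))
  jaws <- beams[[1]]$control_points[[1]]$jaws
  b <- mlc_layout()$boundaries
  shifts <- c()
  for (i in seq_along(mod[[1]]$control_points)) {
    s <- c(mod[[1]]$control_points[[i]]$bank_A - beams[[1]]$control_points[[i]]$bank_A,
           mod[[1]]$control_points[[i]]$bank_B - beams[[1]]$control_points[[i]]$bank_B)
    shifts <- c(shifts, s[s != 0])
  }
  expect_true(length(shifts) > 100)
  expect_true(all(abs(shifts) >= 0.2 - 1e-9 & abs(shifts) <= 0.3 + 1e-9))
  expect_true(any(shifts > 0) && any(shifts < 0))
})

test_that("MLC errors only move leaves that contribute to the fluence", {
  beams <- fix_arc(cps = 9, fs = 6, seed = 6)   # jaw window |w| < 3 cm
  mod <- inject_errors(beams, error_spec("MLC", seed = 9))
  b <- mlc_layout()$boundaries
  outside <- b[-length(b)] >= 3 | b[-1] <= -3
  for (i in seq_along(mod[[1]]$control_points)) {
    expect_identical(mod[[1]]$control_points[[i]]$bank_A[outside],
                     beams[[1]]$control_points[[i]]$bank_A[outside])
    # closed pairs (zero gap) are never adjusted
    closed <- beams[[1]]$control_points[[i]]$bank_B -
      beams[[1]]$control_points[[i]]$bank_A <= 1e-6
    expect_identical(mod[[1]]$control_points[[i]]$bank_A[closed],
                     beams[[1]]$control_points[[i]]$bank_A[closed])
  }
})

test_that("MU errors rebuild consistent cumulative weights", {
  beams <- fix_arc(cps = 21, seed = 6)
  mod <- inject_errors(beams, error_spec("MU", regime = "outside", seed = 5))
  w <- vapply(mod[[1]]$control_points, `[[`, numeric(1), "weight")
  expect_equal(w[1], 0)
  expect_equal(w[length(w)], 1)
  expect_true(all(diff(w) >= 0))
  d_old <- delta_mu_sequence(beams[[1]])
  d_new <- delta_mu_sequence(mod[[1]])
  expect_true(all(abs(d_new - d_old) <= 2 + 1e-9))
  expect_gt(max(abs(d_new - d_old)), 1 - 1e-9)  # outside regime: at least 1 MU
  expect_error(inject_errors(beams, error_spec("bogus")), "arg")
})

test_that("2DFC is blind to gantry errors while 3DFC detects them", {
  beams <- cached("arc_sens", generate_synthetic_plan(plan_recipe(
    cps_per_arc = 37, total_MU = 600, field_size_cm = 6,
    modulation = "sliding-window", gap_cm = 1, seed = 21)))
  grid <- cached("grid_sens", compute_volume_bounds(beams))
  sp <- error_spec("gantry", seed = 33)      # within tolerance, <= 1 deg
  mod <- inject_errors(beams, sp)
  m_ref <- composite_2d_fluence(beams, grid)
  m_mod <- composite_2d_fluence(mod, grid)
  expect_identical(m_ref$values, m_mod$values)
  v_ref <- cached("vol_sens", fluence_from_plan(beams, grid))
  v_mod <- fluence_from_plan(mod, grid)
  expect_gt(intensity_difference_test(v_ref, v_mod)$F_I, 0)
})

test_that("correlation of passing-rate groups matches hand computations", {
  # monotone nonlinear: rho = 1 exactly, r < 1
  x <- c(1, 2, 3, 4, 5); y <- exp(x)
  ct <- correlate_passing_rates(x, y)
  expect_equal(ct$spearman_rho, 1)
  expect_lt(ct$pearson_r, 1)
  # anti-monotone: rho = -1
  expect_equal(correlate_passing_rates(x, rev(y))$spearman_rho, -1)
  # hand-sized 5-pair list against the rank-difference formula
  a <- c(2.3, 7.4, 1.2, 14.3, 6.2)
  b <- c(1.4, 6.1, 0.8, 13.5, 7.0)
  ct2 <- correlate_passing_rates(a, b)
  expect_equal(ct2$spearman_rho, oracle_spearman_notie(a, b))
  expect_equal(ct2$pearson_r, sum(scale(a) * scale(b)) / 4)
  expect_true(ct2$spearman_p >= 0 && ct2$spearman_p <= 1)
  expect_error(correlate_passing_rates(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(correlate_passing_rates(1:2, 2:3), "length")
})
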