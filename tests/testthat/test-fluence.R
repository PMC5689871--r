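test_that("automatic volume bounds follow the maximal jaw opening plus margin", {
  bm <- fix_static_beam(field = 10)        # jaws at +/- 5 cm
  g <- compute_volume_bounds(bm)
  expect_equal(g$dims, rep(40L, 3))        # (5 + 1) * 2 / 0.3
  expect_equal(g$origin, rep(-6, 3))
  # asymmetric jaws: half-extent from the largest |edge|
  cps <- lapply(0:1, function(i)
    control_point(i, beam_angles(0, 0, 0), c(-2, 6, -3, 3),
                  rep(-2, 60), rep(6, 60), i))
  ba <- beam(1, cps, total_MU = 10)
  g2 <- compute_volume_bounds(ba)
  # half-extent max(|-2|, 6) + 1 = 7, snapped up to a whole voxel count
  expect_gte(-g2$origin[1], 7)
  expect_lt(-g2$origin[1], 7 + 0.3)
  # extent always covers the jaw span plus 2 cm of margin
  expect_gte(g2$dims[1] * g2$voxel_size, 12 + 2)
})

test_that("a static open beam deposits MU with inverse-square scaling", {
  bm <- fix_static_beam(field = 10, mu = 100, gantry = 0)
  grid <- fix_small_grid(half = 3)
  v <- fluence_from_plan(bm, grid)
  axc <- grid_axes(grid)
  ic <- which.min(abs(axc$x))   # voxel at +/- 0.15; central axis pair
  # isocenter-plane voxel: inverse square ~ 1 within the voxel offset
  iso <- v$values[ic, ic, ic]
  expect_equal(iso, 100 * 100^2 / sum((c(axc$x[ic], axc$y[ic], axc$z[ic]) -
                                         c(0, -100, 0))^2), tolerance = 1e-12)
  # on-axis voxel 2.85 cm downstream
  iy <- which(abs(axc$y - 2.85) < 1e-9)
  expect_equal(v$values[ic, iy, ic],
               100 * 100^2 / (axc$x[ic]^2 + (axc$y[iy] + 100)^2 + axc$z[ic]^2),
               tolerance = 1e-12)
  # a voxel outside the field at all angles stays zero
  bm4 <- fix_static_beam(field = 4, mu = 100)
  v4 <- fluence_from_plan(bm4, grid)
  expect_equal(v4$values[1, 1, 1], 0)   # corner at 2.85 cm lateral, field edge 2 cm
})

test_that("central-axis fall-off follows SAD^2/(SAD+y)^2 with R^2 >= 0.999", {
  bm <- fix_static_beam(field = 10, mu = 100)
  grid <- grid_spec(origin = c(-0.3, -6, -0.3), voxel_size = 0.3,
                    dims = c(2L, 40L, 2L))
  v <- fluence_from_plan(bm, grid)
  y <- grid_axes(grid)$y
  prof <- v$values[1, , 1]
  pred <- 100 * 100^2 / ((100 + y)^2 + 2 * 0.15^2)
  r2 <- 1 - sum((prof - pred)^2) / sum((prof - mean(prof))^2)
  expect_gte(r2, 0.999)
})

test_that("fluence is linear in MU and additive over beams", {
  beams <- fix_arc(cps = 7, fs = 4, seed = 8)
  grid <- fix_small_grid(half = 2.1)
  v1 <- fluence_from_plan(beams, grid)
  scaled <- beams
  scaled[[1]]$total_MU <- beams[[1]]$total_MU * 2.5
  v2 <- fluence_from_plan(scaled, grid)
  expect_equal(v2$values, 2.5 * v1$values, tolerance = 1e-12)
  # superposition: two arcs equal the sum of each alone
  two <- fix_arc(cps = 7, fs = 4, seed = 8, n_arcs = 2)
  va <- fluence_from_plan(two[1], grid)
  vb <- fluence_from_plan(two[2], grid)
  vab <- fluence_from_plan(two, grid)
  expect_equal(vab$values, va$values + vb$values, tolerance = 1e-12)
})

test_that("segment order does not matter and empty logs give zero volumes", {
  beams <- fix_arc(cps = 7, fs = 4, seed = 8)
  segs <- upsample_beam(beams[[1]])
  grid <- fix_small_grid(half = 2.1)
  v <- accumulate_fluence(segs, grid)
  # doubled dose rate / halved duration with identical per-record states:
  # the MU parameterization, not time, determines the volume
  lg <- generate_matched_log(beams, duration_s = 60)
  fast <- log_records(time = lg$time / 2, couch = lg$couch, gantry = lg$gantry,
                      coll = lg$coll, jaws = lg$jaws, bank_A = lg$bank_A,
                      bank_B = lg$bank_B, cumulative_MU = lg$cumulative_MU,
                      dose_rate = lg$dose_rate * 2,
                      sampling_interval_s = 0.010, SAD = lg$SAD)
  expect_equal(fluence_from_log(fast, grid)$values,
               fluence_from_log(lg, grid)$values, tolerance = 1e-12)
  # zero-MU segments contribute nothing
  segs0 <- segs
  segs0$delta_mu[] <- 0
  expect_true(all(accumulate_fluence(segs0, grid)$values == 0))
})

test_that("rotating all gantry angles by 90 deg rotates the volume", {
  beams <- fix_arc(mod = "open", cps = 13, fs = 4, seed = 8, span = 90)
  grid <- fix_small_grid(half = 2.1, voxel = 0.3)
  segs <- upsample_beam(beams[[1]])
  rot <- segs
  rot$gantry <- segs$gantry + 90
  rot$source <- NULL
  rot <- delivery_segments(rot$couch, rot$gantry, rot$coll, rot$jaws,
                           rot$bank_A, rot$bank_B, rot$delta_mu,
                           SAD = segs$SAD, machine = segs$machine)
  v <- accumulate_fluence(segs, grid)$values
  vr <- accumulate_fluence(rot, grid)$values
  # rotate volume about z by 90 deg: (x, y) -> (-y, x)
  n <- dim(v)[1]
  v_rot <- aperm(v, c(2, 1, 3))[n:1, , ]
  expect_lt(mean(abs(vr - v_rot)) / max(v), 0.02)
  d <- dim(v)[1]
  expect_equal(sum(vr), sum(v_rot), tolerance = 0.02)
})

test_that("plan and log paths converge at matched fine resolution", {
  beams <- cached("arc_sw_fs5",
                  fix_arc(mod = "sliding-window", cps = 91, fs = 5, seed = 3))
  grid <- fix_small_grid(half = 3)
  vp <- fluence_from_plan(beams, grid, step_deg = 0.25)
  lg <- cached("log_sw_fs5", generate_matched_log(beams, duration_s = 120))
  vl <- fluence_from_log(lg, grid, factor = 1)
  expect_lt(max(abs(vl$values - vp$values)) / max(vp$values), 0.005)
  # at production resolution the two paths agree within the QA threshold
  vp1 <- fluence_from_plan(beams, grid, step_deg = 1)
  vl16 <- fluence_from_log(lg, grid, factor = 16)
  expect_lt(max(abs(vl16$values - vp1$values)) / max(vp1$values), 0.03)
})

test_that("composite 2D fluence ignores gantry but sees collimator and MU", {
  beams <- fix_arc(cps = 13, fs = 6, seed = 4)
  grid <- fix_small_grid(half = 4)
  m <- composite_2d_fluence(beams, grid)
  # forcing all gantry angles to zero leaves the map bit-identical
  zeroed <- beams
  for (i in seq_along(zeroed[[1]]$control_points)) {
    a <- zeroed[[1]]$control_points[[i]]$angles
    zeroed[[1]]$control_points[[i]]$angles <-
      beam_angles(a[["couch_deg"]], 0, a[["collimator_deg"]])
  }
  m0 <- composite_2d_fluence(zeroed, grid)
  expect_identical(m$values, m0$values)
  # MU scaling is linear
  sc <- beams
  sc[[1]]$total_MU <- sc[[1]]$total_MU * 3
  expect_equal(composite_2d_fluence(sc, grid)$values, 3 * m$values,
               tolerance = 1e-12)
  # collimator rotation changes the map
  rot <- beams
  for (i in seq_along(rot[[1]]$control_points)) {
    a <- rot[[1]]$control_points[[i]]$angles
    rot[[1]]$control_points[[i]]$angles <-
      beam_angles(a[["couch_deg"]], a[["gantry_deg"]], 30)
  }
  expect_gt(max(abs(composite_2d_fluence(rot, grid)$values - m$values)), 0)
})

test_that("gantry-0 static beam: 2D map matches the volume's isocenter plane", {
  bm <- fix_static_beam(field = 6, mu = 50)
  grid <- fix_small_grid(half = 2.1)
  m <- composite_2d_fluence(bm, grid)
  v <- fluence_from_plan(bm, grid)
  # at y = 0 the 3D inverse-square factor is SAD^2/|r - s|^2 with |r-s| ~ SAD
  iy <- which.min(abs(grid_axes(grid)$y))
  slice <- v$values[, iy, ]
  inside <- m$values > 0
  expect_equal(slice[inside] / m$values[inside],
               rep(1, sum(inside)), tolerance = 0.005)
  expect_true(all((slice > 0) == inside))
})

test_that("NRRD export round-trips volumes losslessly", {
  beams <- fix_arc(cps = 7, fs = 4, seed = 8)
  v <- fluence_from_plan(beams, fix_small_grid(half = 2.1))
  f <- withr::local_tempfile(fileext = ".nrrd")
  export_volume(v, f)
  back <- import_volume(f)
  expect_identical(back$values, v$values)
  expect_equal(back$grid$voxel_size, 0.3)
  expect_equal(back$grid$origin, v$grid$origin)
  expect_equal(back$provenance, "plan")
  # header records 3 mm spacing
  hdr <- readLines(f, n = 12, warn = FALSE)
  expect_true(any(grepl("space directions: \\(0.3,0,0\\)", hdr)))
})
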