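test_that("a static 2-CP beam round-trips through DICOM", {
  bm <- fix_static_beam(field = 10, mu = 100)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtplan(bm, f)
  back <- read_rtplan(f)
  expect_length(back, 1)
  b2 <- back[[1]]
  expect_length(b2$control_points, 2)
  expect_equal(delta_mu_sequence(b2), 100)
  expect_equal(b2$SAD, 100)
  expect_equal(b2$control_points[[1]]$jaws, c(-5, 5, -5, 5))
})

test_that("a 91-CP arc round-trips with sparse control-point inheritance", {
  beams <- fix_arc(cps = 91, seed = 5)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtplan(beams, f)
  b2 <- read_rtplan(f)[[1]]
  expect_length(b2$control_points, 91)
  w <- vapply(b2$control_points, `[[`, numeric(1), "weight")
  expect_equal(w, seq(0, 1, length.out = 91))
  # jaws written only at CP 0 must be inherited everywhere
  expect_equal(b2$control_points[[50]]$jaws, beams[[1]]$control_points[[50]]$jaws)
  # leaves and gantry vary per CP and must survive the round trip
  for (i in c(1, 17, 91)) {
    expect_equal(b2$control_points[[i]]$bank_A,
                 beams[[1]]$control_points[[i]]$bank_A, tolerance = 1e-7)
    expect_equal(b2$control_points[[i]]$angles[["gantry_deg"]],
                 beams[[1]]$control_points[[i]]$angles[["gantry_deg"]],
                 tolerance = 1e-7)
  }
})

test_that("non-RT-Plan DICOM and malformed plans are rejected", {
  f <- withr::local_tempfile(fileext = ".bin")
  writeBin(as.raw(1:64), f)
  expect_error(read_rtplan(f), "DICOM")
  # valid DICOM wrapper but wrong SOP class
  f2 <- withr::local_tempfile(fileext = ".dcm")
  fluqa:::dcm_write_file(list(fluqa:::el(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2")),
                         f2, sop_class_uid = "1.2.840.10008.5.1.4.1.1.2")
  expect_error(read_rtplan(f2), "not a DICOM RT Plan")
})

test_that("pydicom independently reads our RT Plan writer's output", {
  beams <- fix_arc(cps = 11, seed = 5)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtplan(beams, f)
  script <- sprintf(paste0(
    "import pydicom, json\n",
    "ds = pydicom.dcmread(r'%s')\n",
    "b = ds.BeamSequence[0]\n",
    "cp = b.ControlPointSequence[5]\n",
    "mlc = [x for x in cp.BeamLimitingDevicePositionSequence",
    " if x.RTBeamLimitingDeviceType == 'MLCX'][0]\n",
    "print(json.dumps({'sop': str(ds.SOPClassUID),",
    " 'n_cp': int(b.NumberOfControlPoints),",
    " 'gantry': float(cp.GantryAngle),",
    " 'mlc5_first': float(mlc.LeafJawPositions[0]),",
    " 'mu': float(ds.FractionGroupSequence[0].ReferencedBeamSequence[0].BeamMeterset)}))\n"),
    f)
  out <- system2("python", "-", stdout = TRUE, stderr = TRUE, input = script)
  parsed <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_equal(parsed$sop, "1.2.840.10008.5.1.4.1.1.481.5")
  expect_equal(parsed$n_cp, 11)
  expect_equal(parsed$gantry,
               beams[[1]]$control_points[[6]]$angles[["gantry_deg"]],
               tolerance = 1e-7)
  expect_equal(parsed$mlc5_first, beams[[1]]$control_points[[6]]$bank_A[1] * 10,
               tolerance = 1e-6)
  expect_equal(parsed$mu, 200)
})

test_that("MU increments follow the cumulative weights and conserve meterset", {
  mk <- function(i, w) control_point(i, beam_angles(0, 0, 0), c(-5, 5, -5, 5),
                                     rep(-5, 60), rep(5, 60), w)
  bm <- beam(1, list(mk(0, 0), mk(1, 0.5), mk(2, 1)), total_MU = 200)
  expect_equal(delta_mu_sequence(bm), c(100, 100))
  # multi-arc fixture at the clinical meterset magnitude: 4 arcs, 4328 MU
  beams <- fix_arc(n_arcs = 4, cps = 11, mu = 4328, seed = 2)
  total <- sum(vapply(beams, function(b) sum(delta_mu_sequence(b)), numeric(1)))
  expect_equal(total, 4328)
})

test_that("up-sampling yields the expected segment counts and conserves MU", {
  # 2 CPs 4 degrees apart, 1-degree step -> 4 equal segments
  mk <- function(i, g, w) control_point(i, beam_angles(0, g, 0), c(-5, 5, -5, 5),
                                        rep(-5, 60), rep(5, 60), w)
  bm <- beam(1, list(mk(0, 180, 0), mk(1, 184, 1)), total_MU = 40)
  segs <- upsample_beam(bm, 1)
  expect_equal(segs$n, 4)
  expect_equal(segs$delta_mu, rep(10, 4))
  expect_equal(segs$gantry, c(180.5, 181.5, 182.5, 183.5))
  # static beam: one segment per CP interval
  st <- upsample_beam(fix_static_beam(), 1)
  expect_equal(st$n, 1)
  # 91-CP 360-degree arc at 4 deg/CP -> 360 one-degree segments
  arc <- fix_arc(cps = 91, seed = 5)[[1]]
  s <- upsample_beam(arc, 1)
  expect_equal(s$n, 360)
  expect_equal(sum(s$delta_mu), arc$total_MU)
  # MU conserved at any step
  for (step in c(0.5, 2, 4)) {
    expect_equal(sum(upsample_beam(arc, step)$delta_mu), arc$total_MU)
  }
  expect_error(upsample_beam(arc, 0), "positive")
})

test_that("segment states are linear mid-interval interpolations", {
  mk <- function(i, g, a1, w) {
    A <- rep(-5, 60); A[31] <- a1
    control_point(i, beam_angles(0, g, 0), c(-5, 5, -5, 5), A, rep(5, 60), w)
  }
  bm <- beam(1, list(mk(0, 0, -4, 0), mk(1, 2, 0, 1)), total_MU = 10)
  segs <- upsample_beam(bm, 1)
  expect_equal(segs$n, 2)
  expect_equal(segs$bank_A[, 31], c(-3, -1))     # midpoints of linear travel
  # the segment source is the mean of its end-point sources
  ang <- function(g) beam_angles(0, g, 0)
  expect_equal(segs$source[1, ],
               (source_position(ang(0)) + source_position(ang(1))) / 2)
})

test_that("arc up-sampling interpolates across the 0/360 gantry seam", {
  mk <- function(i, g, w) control_point(i, beam_angles(0, g, 0), c(-5, 5, -5, 5),
                                        rep(-5, 60), rep(5, 60), w)
  bm <- beam(1, list(mk(0, 358, 0), mk(1, 2, 1)), total_MU = 4)
  segs <- upsample_beam(bm, 1)
  expect_equal(segs$n, 4)
  expect_equal(signed_angle(segs$gantry), c(-1.5, -0.5, 0.5, 1.5))
})
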