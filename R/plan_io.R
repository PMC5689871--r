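# DICOM-RT plan I/O and control-point up-sampling.
#
# A Beam holds ordered control points (CPs); the machine interpolates every
# axis linearly between CPs, so the planned fluence is integrated over
# sub-CP segments obtained by up-sampling to ~1 degree of gantry travel.

#' Construct a control point
#'
#' @param index 0-based control point index.
#' @param angles a [beam_angles()] object.
#' @param jaws numeric `c(x1, x2, y1, y2)` cm at isocenter.
#' @param bank_A,bank_B leaf-tip u-positions (cm), one per pair.
#' @param weight cumulative meterset weight (dimensionless, non-decreasing).
#' @return object of class `control_point`.
#' @export
control_point <- function(index, angles, jaws, bank_A, bank_B, weight) {
  stopifnot(inherits(angles, "beam_angles"), length(jaws) == 4,
            length(bank_A) == length(bank_B), weight >= 0)
  structure(list(index = as.integer(index), angles = angles,
                 jaws = as.numeric(jaws), bank_A = as.numeric(bank_A),
                 bank_B = as.numeric(bank_B), weight = as.numeric(weight)),
            class = "control_point")
}

#' Construct a beam
#'
#' @param beam_id integer beam number.
#' @param control_points list of [control_point()]s, ordered, first weight 0.
#' @param total_MU beam meterset in MU.
#' @param SAD source-to-axis distance (cm).
#' @param machine MLC layout name (see [mlc_layout()]).
#' @param name beam name.
#' @return object of class `beam`.
#' @export
beam <- function(beam_id, control_points, total_MU, SAD = 100,
                 machine = "Varian_Millennium_120", name = paste0("Beam", beam_id)) {
  if (length(control_points) < 2) stop("a beam needs at least 2 control points")
  w <- vapply(control_points, `[[`, numeric(1), "weight")
  if (w[1] != 0) stop("first control point weight must be 0")
  if (any(diff(w) < 0)) stop("cumulative meterset weight must be non-decreasing")
  stopifnot(total_MU > 0, SAD > 0)
  structure(list(beam_id = as.integer(beam_id), name = name, SAD = SAD,
                 total_MU = total_MU, machine = machine,
                 control_points = control_points),
            class = "beam")
}

#' @export
print.beam <- function(x, ...) {
  g <- vapply(x$control_points, function(cp) cp$angles[["gantry_deg"]], numeric(1))
  cat(sprintf("<beam #%d '%s': %d CPs, %.1f MU, gantry %.1f..%.1f deg, SAD %g cm>\n",
              x$beam_id, x$name, length(x$control_points), x$total_MU,
              g[1], g[length(g)], x$SAD))
  invisible(x)
}

#' MU increments between consecutive control points
#'
#' `delta_MU[k] = (weight[k+1] - weight[k]) / final_weight * total_MU`; the
#' increments sum to the beam meterset.
#'
#' @param bm a [beam()].
#' @return numeric vector of length `n_cp - 1` (MU).
#' @export
delta_mu_sequence <- function(bm) {
  w <- vapply(bm$control_points, `[[`, numeric(1), "weight")
  final <- w[length(w)]
  if (final <= 0) stop("final cumulative meterset weight must be positive")
  diff(w) / final * bm$total_MU
}

# Unwraps a degree sequence into a continuous signed path (shortest arc
# between consecutive samples), anchored at the signed first value.
unwrap_deg <- function(deg) {
  if (length(deg) == 1) return(signed_angle(deg))
  signed_angle(deg[1]) + cumsum(c(0, angle_diff(deg[-1], deg[-length(deg)])))
}

#' Up-sample a beam into delivery segments
#'
#' Splits every control-point interval into sub-intervals so that
#' consecutive segment gantry centres differ by at most `step_deg`.  Within
#' a sub-interval all axes interpolate linearly and the interval's MU splits
#' proportionally; each segment carries the mid-interval state and the mean
#' of its end-point source positions.  Fixed-gantry intervals yield one
#' segment each.  Total MU is conserved.
#'
#' @param bm a [beam()].
#' @param step_deg maximum gantry travel per segment (degrees, default 1).
#' @return a `delivery_segments` object (see [delivery_segments()]).
#' @export
upsample_beam <- function(bm, step_deg = 1.0) {
  if (step_deg <= 0) stop("step_deg must be positive")
  cps <- bm$control_points
  n <- length(cps)
  g <- unwrap_deg(vapply(cps, function(cp) cp$angles[["gantry_deg"]], numeric(1)))
  cth <- unwrap_deg(vapply(cps, function(cp) cp$angles[["couch_deg"]], numeric(1)))
  col <- unwrap_deg(vapply(cps, function(cp) cp$angles[["collimator_deg"]], numeric(1)))
  jaws <- t(vapply(cps, `[[`, numeric(4), "jaws"))
  nl <- length(cps[[1]]$bank_A)
  bA <- t(vapply(cps, `[[`, numeric(nl), "bank_A"))
  bB <- t(vapply(cps, `[[`, numeric(nl), "bank_B"))
  dmu <- delta_mu_sequence(bm)

  seg_list <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    nsub <- max(1L, ceiling(abs(g[k + 1] - g[k]) / step_deg - 1e-9))
    fb <- seq(0, 1, length.out = nsub + 1)     # sub-interval boundaries
    fm <- (fb[-1] + fb[-(nsub + 1)]) / 2       # midpoints
    lerp <- function(a, b, f) a + (b - a) * f
    # end-point source positions per Eq.-7-style averaging
    src_b <- vapply(fb, function(f) {
      ang <- beam_angles(lerp(cth[k], cth[k + 1], f),
                         lerp(g[k], g[k + 1], f),
                         lerp(col[k], col[k + 1], f))
      source_position(ang, bm$SAD)
    }, numeric(3))
    seg_list[[k]] <- list(
      couch = lerp(cth[k], cth[k + 1], fm),
      gantry = lerp(g[k], g[k + 1], fm),
      coll = lerp(col[k], col[k + 1], fm),
      jaws = outer(1 - fm, jaws[k, ]) + outer(fm, jaws[k + 1, ]),
      bank_A = outer(1 - fm, bA[k, ]) + outer(fm, bA[k + 1, ]),
      bank_B = outer(1 - fm, bB[k, ]) + outer(fm, bB[k + 1, ]),
      delta_mu = rep(dmu[k] / nsub, nsub),
      source = t((src_b[, -(nsub + 1), drop = FALSE] + src_b[, -1, drop = FALSE]) / 2))
  }
  delivery_segments(
    couch = unlist(lapply(seg_list, `[[`, "couch")),
    gantry = unlist(lapply(seg_list, `[[`, "gantry")),
    coll = unlist(lapply(seg_list, `[[`, "coll")),
    jaws = do.call(rbind, lapply(seg_list, `[[`, "jaws")),
    bank_A = do.call(rbind, lapply(seg_list, `[[`, "bank_A")),
    bank_B = do.call(rbind, lapply(seg_list, `[[`, "bank_B")),
    delta_mu = unlist(lapply(seg_list, `[[`, "delta_mu")),
    source = do.call(rbind, lapply(seg_list, `[[`, "source")),
    SAD = bm$SAD, machine = bm$machine)
}

# --- DICOM RT Plan ---------------------------------------------------------

.bld_item <- function(type, positions_mm) {
  list(el(0x300A, 0x00B8, "CS", type),
       el(0x300A, 0x011C, "DS", positions_mm))
}

.cp_item <- function(cp, prev, final) {
  items <- list(el(0x300A, 0x0112, "IS", cp$index),
                el(0x300A, 0x0134, "DS", cp$weight))
  first <- is.null(prev)
  dev <- list()
  if (first || any(cp$jaws[1:2] != prev$jaws[1:2]))
    dev <- c(dev, list(.bld_item("ASYMX", cp$jaws[1:2] * 10)))
  if (first || any(cp$jaws[3:4] != prev$jaws[3:4]))
    dev <- c(dev, list(.bld_item("ASYMY", cp$jaws[3:4] * 10)))
  if (first || any(cp$bank_A != prev$bank_A) || any(cp$bank_B != prev$bank_B))
    dev <- c(dev, list(.bld_item("MLCX", c(cp$bank_A, cp$bank_B) * 10)))
  if (length(dev))
    items <- c(items, list(el(0x300A, 0x011A, "SQ", dev)))
  if (first || cp$angles[["gantry_deg"]] != prev$angles[["gantry_deg"]])
    items <- c(items, list(el(0x300A, 0x011E, "DS", cp$angles[["gantry_deg"]])))
  if (first || cp$angles[["collimator_deg"]] != prev$angles[["collimator_deg"]])
    items <- c(items, list(el(0x300A, 0x0120, "DS", cp$angles[["collimator_deg"]])))
  if (first || cp$angles[["couch_deg"]] != prev$angles[["couch_deg"]])
    items <- c(items, list(el(0x300A, 0x0122, "DS", cp$angles[["couch_deg"]])))
  items
}

#' Write beams to a DICOM RT Plan file
#'
#' Emits a valid explicit-VR-little-endian RT Plan with beam, MLC-boundary,
#' control-point and fraction-group (beam meterset) content.  Axis values
#' that do not change between control points are written sparsely, per the
#' DICOM rule that unchanged parameters are inherited from the last control
#' point that specified them.
#'
#' @param beams a [beam()] or list of beams.
#' @param path output file path.
#' @param plan_label RT plan label string.
#' @return `path`, invisibly.
#' @export
write_rtplan <- function(beams, path, plan_label = "fluqa-plan") {
  if (inherits(beams, "beam")) beams <- list(beams)
  layout <- mlc_layout(beams[[1]]$machine)
  beam_items <- lapply(beams, function(bm) {
    cps <- bm$control_points
    cp_items <- vector("list", length(cps))
    for (i in seq_along(cps))
      cp_items[[i]] <- .cp_item(cps[[i]], if (i > 1) cps[[i - 1]], NULL)
    bld <- list(
      list(el(0x300A, 0x00B8, "CS", "ASYMX"), el(0x300A, 0x00BC, "IS", 1)),
      list(el(0x300A, 0x00B8, "CS", "ASYMY"), el(0x300A, 0x00BC, "IS", 1)),
      list(el(0x300A, 0x00B8, "CS", "MLCX"),
           el(0x300A, 0x00BC, "IS", layout$leaf_count_per_bank),
           el(0x300A, 0x00BE, "DS", layout$boundaries * 10)))
    list(el(0x300A, 0x00B2, "SH", bm$machine),
         el(0x300A, 0x00B4, "DS", bm$SAD * 10),
         el(0x300A, 0x00B6, "SQ", bld),
         el(0x300A, 0x00C0, "IS", bm$beam_id),
         el(0x300A, 0x00C2, "LO", bm$name),
         el(0x300A, 0x010E, "DS", cps[[length(cps)]]$weight),
         el(0x300A, 0x0110, "IS", length(cps)),
         el(0x300A, 0x0111, "SQ", cp_items))
  })
  ref_beams <- lapply(beams, function(bm)
    list(el(0x300A, 0x0086, "DS", bm$total_MU),
         el(0x300C, 0x0006, "IS", bm$beam_id)))
  fg <- list(list(el(0x300A, 0x0071, "IS", 1),
                  el(0x300A, 0x0078, "IS", 1),
                  el(0x300A, 0x0080, "IS", length(beams)),
                  el(0x300C, 0x0004, "SQ", ref_beams)))
  uid <- dcm_new_uid()
  ds <- list(el(0x0008, 0x0016, "UI", SOP_CLASS_RTPLAN),
             el(0x0008, 0x0018, "UI", uid),
             el(0x0008, 0x0060, "CS", "RTPLAN"),
             el(0x300A, 0x0002, "SH", plan_label),
             el(0x300A, 0x0070, "SQ", fg),
             el(0x300A, 0x00B0, "SQ", beam_items))
  dcm_write_file(ds, path, sop_instance_uid = uid)
}

.first <- function(x, default = NULL) if (is.null(x)) default else x

#' Read a DICOM RT Plan into beams
#'
#' Parses the beam sequence, control points, jaw/MLC positions (mm converted
#' to cm) and the fraction-group beam metersets.  Parameters omitted from a
#' control point are inherited from the last control point that specified
#' them.
#'
#' @param path DICOM RT Plan file.
#' @return list of [beam()] objects.
#' @export
read_rtplan <- function(path) {
  ds <- dcm_read_file(path)
  sop <- ds[["00080016"]]
  if (is.null(sop) || sop != SOP_CLASS_RTPLAN)
    stop("not a DICOM RT Plan file: ", path)
  mu_by_beam <- list()
  for (fg in .first(ds[["300A0070"]], list()))
    for (rb in .first(fg[["300C0004"]], list()))
      mu_by_beam[[as.character(rb[["300C0006"]])]] <- rb[["300A0086"]]
  lapply(.first(ds[["300A00B0"]], stop("malformed plan: no BeamSequence")),
         function(bs) .parse_beam(bs, mu_by_beam))
}

.parse_beam <- function(bs, mu_by_beam) {
  machine <- .first(bs[["300A00B2"]], "Varian_Millennium_120")
  sad_cm <- .first(bs[["300A00B4"]], 1000) / 10
  has_mlc <- any(vapply(.first(bs[["300A00B6"]], list()),
                        function(d) identical(d[["300A00B8"]], "MLCX"), logical(1)))
  if (!has_mlc) stop("unsupported beam: no MLCX beam limiting device")
  cps_raw <- bs[["300A0111"]]
  if (is.null(cps_raw)) stop("malformed plan: no ControlPointSequence")
  state <- list(gantry = NA_real_, coll = 0, couch = 0,
                jx = NULL, jy = NULL, bank = NULL)
  cps <- vector("list", length(cps_raw))
  for (i in seq_along(cps_raw)) {
    item <- cps_raw[[i]]
    state$gantry <- .first(item[["300A011E"]], state$gantry)
    state$coll <- .first(item[["300A0120"]], state$coll)
    state$couch <- .first(item[["300A0122"]], state$couch)
    for (dev in .first(item[["300A011A"]], list())) {
      pos <- dev[["300A011C"]] / 10
      switch(dev[["300A00B8"]],
             X = , ASYMX = state$jx <- pos,
             Y = , ASYMY = state$jy <- pos,
             MLCX = state$bank <- pos)
    }
    w <- item[["300A0134"]]
    if (is.null(w)) stop("malformed plan: control point without CumulativeMetersetWeight")
    if (i == 1 && (is.null(state$jx) || is.null(state$jy) || is.null(state$bank) ||
                   is.na(state$gantry)))
      stop("malformed plan: first control point must define all axes")
    nl <- length(state$bank) / 2
    cps[[i]] <- control_point(
      index = .first(item[["300A0112"]], i - 1),
      angles = beam_angles(state$couch, state$gantry, state$coll),
      jaws = c(state$jx, state$jy),
      bank_A = state$bank[seq_len(nl)], bank_B = state$bank[nl + seq_len(nl)],
      weight = w)
  }
  id <- .first(bs[["300A00C0"]], 1)
  total_mu <- .first(mu_by_beam[[as.character(id)]],
                     stop("malformed plan: no BeamMeterset for beam ", id))
  beam(id, cps, total_MU = total_mu, SAD = sad_cm, machine = machine,
       name = .first(bs[["300A00C2"]], paste0("Beam", id)))
}
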