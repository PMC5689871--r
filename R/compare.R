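# QA verdicts: intensity-difference test, 3D gamma analysis, report.
#
# Both tests normalise globally to the maximum of the reference (plan)
# volume and evaluate only voxels whose reference value reaches the
# low-intensity cutoff (default 10% of max); the failing rate denominator
# is the number of evaluated voxels.

#' QA test criteria
#'
#' @param diff_pct intensity-difference threshold, % of the reference
#'   maximum (default 3).
#' @param gamma_pct gamma dose criterion, % of the reference maximum
#'   (default 3).
#' @param gamma_dta_mm gamma distance-to-agreement (mm, default 3).
#' @param low_cutoff_fraction voxels with reference intensity below this
#'   fraction of the maximum are excluded (default 0.10).
#' @param action_level_fraction gamma failing-rate fraction above which the
#'   verdict becomes "investigate" (default 0.05).
#' @return object of class `test_criteria`.
#' @export
test_criteria <- function(diff_pct = 3, gamma_pct = 3, gamma_dta_mm = 3,
                          low_cutoff_fraction = 0.10,
                          action_level_fraction = 0.05) {
  stopifnot(diff_pct > 0, gamma_pct > 0, gamma_dta_mm > 0,
            low_cutoff_fraction > 0, low_cutoff_fraction < 1,
            action_level_fraction > 0)
  structure(list(diff_pct = diff_pct, gamma_pct = gamma_pct,
                 gamma_dta_mm = gamma_dta_mm,
                 low_cutoff_fraction = low_cutoff_fraction,
                 action_level_fraction = action_level_fraction),
            class = "test_criteria")
}

.check_same_grid <- function(reference, evaluated) {
  g1 <- reference$grid; g2 <- evaluated$grid
  if (!isTRUE(all.equal(g1$origin, g2$origin)) ||
      g1$voxel_size != g2$voxel_size || any(g1$dims != g2$dims))
    stop("grid mismatch: reference and evaluated volumes must share a grid")
  if (max(reference$values) <= 0)
    stop("all-zero reference volume")
}

#' Intensity-difference test
#'
#' A voxel fails when `|evaluated - reference| >= diff_pct% * max(reference)`
#' and its reference value is at or above the low-intensity cutoff.  The
#' failing rate `F_I` is failing voxels over evaluated (above-cutoff)
#' voxels.
#'
#' @param reference,evaluated [fluence_volume()]s on identical grids
#'   (reference is the plan).
#' @param criteria a [test_criteria()].
#' @return list with `diff_map` (evaluated - reference, 3D array, MU),
#'   `F_I` (fraction), `evaluated_voxels`, `failing_voxels`.
#' @export
intensity_difference_test <- function(reference, evaluated,
                                      criteria = test_criteria()) {
  .check_same_grid(reference, evaluated)
  mx <- max(reference$values)
  diff_map <- evaluated$values - reference$values
  eval_mask <- reference$values >= criteria$low_cutoff_fraction * mx
  thr <- criteria$diff_pct / 100 * mx
  fail <- eval_mask & abs(diff_map) >= thr
  n_eval <- sum(eval_mask)
  list(diff_map = diff_map,
       F_I = if (n_eval) sum(fail) / n_eval else 0,
       evaluated_voxels = n_eval, failing_voxels = sum(fail))
}

# Offset lattice for the gamma search: sub-voxel steps of voxel/3 within a
# search radius of 3 * DTA, sorted by distance so the running minimum can
# retire voxels early (any farther offset alone carries gamma > current
# bound).  Restricting the search to 3 * DTA only affects gamma values
# already above 3, never the pass/fail decision at gamma = 1.
.gamma_offsets <- function(voxel_size, dta_cm) {
  step <- voxel_size / 3
  radius <- 3 * dta_cm
  k <- floor(radius / step + 1e-9)
  s <- step * (-k:k)
  off <- as.matrix(expand.grid(dx = s, dy = s, dz = s))
  d2 <- rowSums(off^2)
  keep <- d2 <= radius^2 + 1e-12
  off <- off[keep, , drop = FALSE]
  d2 <- d2[keep]
  ord <- order(d2)
  list(off_vox = off[ord, , drop = FALSE] / voxel_size, dist2 = d2[ord])
}

# Trilinear interpolation of array `e` at fractional voxel positions
# ijk + off (n x 3); positions outside the grid give NA.
.trilinear_at <- function(e, d, ijk, off) {
  pos <- sweep(ijk, 2, off, `+`)
  inside <- pos[, 1] >= 1 & pos[, 1] <= d[1] &
            pos[, 2] >= 1 & pos[, 2] <= d[2] &
            pos[, 3] >= 1 & pos[, 3] <= d[3]
  out <- rep(NA_real_, nrow(pos))
  if (!any(inside)) return(out)
  p <- pos[inside, , drop = FALSE]
  i0 <- floor(p)
  t <- p - i0
  i1 <- pmin(i0 + 1, matrix(d, nrow(i0), 3, byrow = TRUE))
  acc <- numeric(nrow(p))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wt <- (if (cx) t[, 1] else 1 - t[, 1]) *
          (if (cy) t[, 2] else 1 - t[, 2]) *
          (if (cz) t[, 3] else 1 - t[, 3])
    nz <- wt > 0
    if (any(nz)) {
      ii <- (if (cx) i1[nz, 1] else i0[nz, 1]) +
        d[1] * ((if (cy) i1[nz, 2] else i0[nz, 2]) - 1) +
        d[1] * d[2] * ((if (cz) i1[nz, 3] else i0[nz, 3]) - 1)
      acc[nz] <- acc[nz] + wt[nz] * e[ii]
    }
  }
  out[inside] <- acc
  out
}

#' 3D gamma analysis
#'
#' Global-normalisation gamma index: for every reference voxel at or above
#' the low-intensity cutoff,
#' `gamma = min over search points sqrt(dI^2 / (gamma_pct% * max_ref)^2 +
#' d^2 / DTA^2)`, where the search points are the evaluated volume sampled
#' by trilinear interpolation on a voxel/3 lattice within 3 * DTA.  A voxel
#' fails iff `gamma > 1` (gamma of exactly 1 passes); `F_gamma` is failing
#' over evaluated voxels.
#'
#' @inheritParams intensity_difference_test
#' @return list with `gamma_map` (3D array, NA below cutoff), `F_gamma`,
#'   `evaluated_voxels`, `failing_voxels`.
#' @export
gamma_analysis_3d <- function(reference, evaluated,
                              criteria = test_criteria()) {
  .check_same_grid(reference, evaluated)
  g <- reference$grid
  d <- g$dims
  mx <- max(reference$values)
  dd <- criteria$gamma_pct / 100 * mx
  dta <- criteria$gamma_dta_mm / 10       # mm -> cm
  eval_mask <- reference$values >= criteria$low_cutoff_fraction * mx
  idx <- which(eval_mask)
  gamma_map <- array(NA_real_, dim = d)
  if (!length(idx))
    return(list(gamma_map = gamma_map, F_gamma = 0,
                evaluated_voxels = 0L, failing_voxels = 0L))
  ijk <- arrayInd(idx, d)
  ref_v <- reference$values[idx]
  lat <- .gamma_offsets(g$voxel_size, dta)
  g2 <- rep(Inf, length(idx))
  active <- seq_along(idx)
  for (m in seq_len(nrow(lat$off_vox))) {
    dist_term <- lat$dist2[m] / dta^2
    active <- active[g2[active] > dist_term]
    if (!length(active)) break
    ev <- .trilinear_at(evaluated$values, d, ijk[active, , drop = FALSE],
                        lat$off_vox[m, ])
    cand <- (ev - ref_v[active])^2 / dd^2 + dist_term
    upd <- !is.na(cand) & cand < g2[active]
    g2[active[upd]] <- cand[upd]
  }
  gam <- sqrt(g2)
  gamma_map[idx] <- gam
  fail <- sum(gam > 1 + 1e-12)
  list(gamma_map = gamma_map, F_gamma = fail / length(idx),
       evaluated_voxels = length(idx), failing_voxels = fail)
}

#' QA report comparing planned and delivered fluence
#'
#' Runs both tests and assembles a machine-readable report: criteria,
#' failing rates, mean +/- sd and maximum absolute fluence error over the
#' evaluated voxels, and the pass / investigate verdict (investigate iff the
#' gamma failing rate exceeds the action level).
#'
#' @param plan_volume,log_volume [fluence_volume()]s on identical grids.
#' @param criteria a [test_criteria()].
#' @param slice_png optional path prefix; when given, writes axial, coronal
#'   and sagittal mid-plane slice images of the plan, log and difference
#'   volumes as `<prefix>_<view>.png`.
#' @return object of class `qa_report`.
#' @export
qa_report <- function(plan_volume, log_volume, criteria = test_criteria(),
                      slice_png = NULL) {
  it <- intensity_difference_test(plan_volume, log_volume, criteria)
  gt <- gamma_analysis_3d(plan_volume, log_volume, criteria)
  mx <- max(plan_volume$values)
  em <- abs(it$diff_map)[plan_volume$values >= criteria$low_cutoff_fraction * mx]
  rep <- structure(list(
    criteria = unclass(criteria),
    F_I = it$F_I, F_gamma = gt$F_gamma,
    evaluated_voxel_count = it$evaluated_voxels,
    mean_abs_error_MU = mean(em), sd_abs_error_MU = stats::sd(em),
    max_abs_error_MU = max(em),
    verdict = if (gt$F_gamma > criteria$action_level_fraction)
      "investigate" else "pass"),
    class = "qa_report")
  if (!is.null(slice_png))
    .write_slice_pngs(plan_volume, log_volume, it$diff_map, slice_png)
  rep
}

.write_slice_pngs <- function(pv, lv, diff_map, prefix) {
  d <- pv$grid$dims
  mids <- ceiling(d / 2)
  views <- list(axial = function(a) a[, , mids[3]],
                coronal = function(a) a[, mids[2], ],
                sagittal = function(a) a[mids[1], , ])
  for (vn in names(views)) {
    f <- views[[vn]]
    grDevices::png(paste0(prefix, "_", vn, ".png"), width = 900, height = 320)
    op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
    for (panel in list(list(f(pv$values), "plan"), list(f(lv$values), "log"),
                       list(f(diff_map), "difference"))) {
      graphics::image(panel[[1]], axes = FALSE, main = paste(vn, panel[[2]]),
                      col = grDevices::hcl.colors(64, "viridis"))
    }
    graphics::par(op)
    grDevices::dev.off()
  }
}

#' @export
print.qa_report <- function(x, ...) {
  cat("QA report (3D fluence comparison)\n")
  cat(sprintf("  criteria: %.3g%% diff; %.3g%%/%.3g mm gamma; cutoff %.0f%%\n",
              x$criteria$diff_pct, x$criteria$gamma_pct, x$criteria$gamma_dta_mm,
              100 * x$criteria$low_cutoff_fraction))
  cat(sprintf("  F_I = %.2f%%   F_gamma = %.2f%%   (%d voxels evaluated)\n",
              100 * x$F_I, 100 * x$F_gamma, x$evaluated_voxel_count))
  cat(sprintf("  |error|: %.2f +/- %.2f MU, max %.2f MU\n",
              x$mean_abs_error_MU, x$sd_abs_error_MU, x$max_abs_error_MU))
  cat(sprintf("  verdict: %s\n", x$verdict))
  invisible(x)
}

#' Serialise / restore a QA report as JSON
#' @param report a [qa_report()].
#' @param path file path.
#' @return `write_qa_report`: `path` invisibly; `read_qa_report`: the report.
#' @export
write_qa_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_qa_report
#' @export
read_qa_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "qa_report")
}
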