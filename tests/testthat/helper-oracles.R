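# Independent reference implementations used as oracles.  These are kept
# deliberately separate from the package's production code paths: rotations
# are written out in explicit trigonometric component form, leaf lookup goes
# through the boundary table, and the gamma search enumerates the full
# sub-voxel lattice over the whole grid.

# Millennium 120 leaf-edge table, built directly from the stated widths.
oracle_boundaries <- c(-20 + 0:10 * 1, -10 + 1:40 * 0.5, 10 + 1:10 * 1)

oracle_leaf_lookup <- function(w) {
  findInterval(w, oracle_boundaries)
}

# Fluence accumulation from an explicit per-state description.  states: list
# with vectors gantry, couch, coll (deg), matrices jaws, bank_A, bank_B and
# vector delta_mu, plus an n x 3 source matrix.  Loops records; voxel math in
# explicit component form.
oracle_accumulate <- function(states, grid, SAD = 100) {
  ax <- list(
    x = grid$origin[1] + (seq_len(grid$dims[1]) - 0.5) * grid$voxel_size,
    y = grid$origin[2] + (seq_len(grid$dims[2]) - 0.5) * grid$voxel_size,
    z = grid$origin[3] + (seq_len(grid$dims[3]) - 0.5) * grid$voxel_size)
  vox <- expand.grid(x = ax$x, y = ax$y, z = ax$z)  # x fastest, matches array order
  acc <- numeric(nrow(vox))
  d2r <- pi / 180
  for (i in seq_along(states$gantry)) {
    dmu <- states$delta_mu[i]
    if (dmu == 0) next
    a <- states$couch[i] * d2r; b <- states$gantry[i] * d2r
    th <- states$coll[i] * d2r
    # couch^-1 (about y, angle -a), then gantry^-1 (about z, angle -b)
    x1 <- cos(a) * vox$x - sin(a) * vox$z
    z1 <- sin(a) * vox$x + cos(a) * vox$z
    xb <- cos(b) * x1 + sin(b) * vox$y
    yb <- -sin(b) * x1 + cos(b) * vox$y
    zb <- z1
    f <- SAD / (yb + SAD)
    u0 <- xb * f; w0 <- zb * f
    u <- cos(th) * u0 - sin(th) * w0
    w <- sin(th) * u0 + cos(th) * w0
    li <- oracle_leaf_lookup(w)
    inside <- yb > -SAD + 1e-6 &
      u >= states$jaws[i, 1] & u < states$jaws[i, 2] &
      w >= states$jaws[i, 3] & w < states$jaws[i, 4] &
      li >= 1 & li <= 60 & w < 20 & w >= -20
    li_ok <- li[inside]
    ui <- u[inside]
    inside[inside] <- states$bank_A[i, ][li_ok] <= ui & ui < states$bank_B[i, ][li_ok]
    sx <- states$source[i, 1]; sy <- states$source[i, 2]; sz <- states$source[i, 3]
    r2 <- (vox$x - sx)^2 + (vox$y - sy)^2 + (vox$z - sz)^2
    acc[inside] <- acc[inside] + dmu * SAD^2 / r2[inside]
  }
  array(acc, dim = grid$dims)
}

# Plan-side oracle: interpolates the control points itself at a fine angular
# step (default 0.25 deg), averaging end-point source positions per
# sub-interval.
oracle_plan_fluence <- function(bm, grid, step_deg = 0.25) {
  cps <- bm$control_points
  n <- length(cps)
  getv <- function(f) vapply(cps, f, numeric(1))
  g <- getv(function(cp) cp$angles[["gantry_deg"]])
  gu <- numeric(n); gu[1] <- fluqa::signed_angle(g[1])
  for (k in 2:n) gu[k] <- gu[k - 1] + fluqa::angle_diff(g[k], g[k - 1])
  co <- getv(function(cp) fluqa::signed_angle(cp$angles[["couch_deg"]]))
  cl <- getv(function(cp) fluqa::signed_angle(cp$angles[["collimator_deg"]]))
  wts <- getv(function(cp) cp$weight)
  dmu <- diff(wts) / wts[n] * bm$total_MU
  st <- list(gantry = c(), couch = c(), coll = c(), delta_mu = c(),
             jaws = NULL, bank_A = NULL, bank_B = NULL, source = NULL)
  src_at <- function(couch, gantry) {
    b <- gantry * pi / 180; a <- couch * pi / 180
    # gantry about z applied to (0, -SAD, 0), then couch about y
    p <- c(100 * sin(b), -100 * cos(b), 0)
    c(cos(a) * p[1] + sin(a) * p[3], p[2], -sin(a) * p[1] + cos(a) * p[3])
  }
  for (k in seq_len(n - 1)) {
    m <- max(1, ceiling(abs(gu[k + 1] - gu[k]) / step_deg - 1e-9))
    for (j in seq_len(m)) {
      f0 <- (j - 1) / m; f1 <- j / m; fm <- (f0 + f1) / 2
      mix <- function(a, b, f) a * (1 - f) + b * f
      st$gantry <- c(st$gantry, mix(gu[k], gu[k + 1], fm))
      st$couch <- c(st$couch, mix(co[k], co[k + 1], fm))
      st$coll <- c(st$coll, mix(cl[k], cl[k + 1], fm))
      st$delta_mu <- c(st$delta_mu, dmu[k] / m)
      st$jaws <- rbind(st$jaws, mix(cps[[k]]$jaws, cps[[k + 1]]$jaws, fm))
      st$bank_A <- rbind(st$bank_A, mix(cps[[k]]$bank_A, cps[[k + 1]]$bank_A, fm))
      st$bank_B <- rbind(st$bank_B, mix(cps[[k]]$bank_B, cps[[k + 1]]$bank_B, fm))
      s0 <- src_at(mix(co[k], co[k + 1], f0), mix(gu[k], gu[k + 1], f0))
      s1 <- src_at(mix(co[k], co[k + 1], f1), mix(gu[k], gu[k + 1], f1))
      st$source <- rbind(st$source, (s0 + s1) / 2)
    }
  }
  oracle_accumulate(st, grid, SAD = bm$SAD)
}

# Log-side oracle: every record is its own segment (no down-sampling); the
# MU increment of record i is cum[i] - cum[i-1].
oracle_log_fluence <- function(records, grid) {
  n <- records$n
  st <- list(gantry = records$gantry, couch = records$couch,
             coll = records$coll, jaws = records$jaws,
             bank_A = records$bank_A, bank_B = records$bank_B,
             delta_mu = diff(c(records$cumulative_MU[1], records$cumulative_MU)),
             source = t(vapply(seq_len(n), function(i) {
               b <- records$gantry[i] * pi / 180
               a <- records$couch[i] * pi / 180
               p <- c(records$SAD * sin(b), -records$SAD * cos(b), 0)
               c(cos(a) * p[1] + sin(a) * p[3], p[2], -sin(a) * p[1] + cos(a) * p[3])
             }, numeric(3))))
  oracle_accumulate(st, grid, SAD = records$SAD)
}

# Exhaustive gamma oracle: interpolates the evaluated volume onto the global
# 1/3-voxel lattice (separable linear interpolation) and, for every
# above-cutoff reference voxel, minimises over ALL lattice points.
oracle_gamma <- function(ref, ev, criteria = test_criteria()) {
  g <- ref$grid; d <- g$dims
  mx <- max(ref$values)
  dd <- criteria$gamma_pct / 100 * mx
  dta <- criteria$gamma_dta_mm / 10
  lat_ax <- lapply(d, function(k) seq(1, k, by = 1 / 3))
  interp_axis <- function(a, dim_idx, pts) {
    apply(a, setdiff(1:3, dim_idx), function(v)
      approx(seq_along(v), v, xout = pts)$y)
  }
  # interpolate successively along each axis; rebuild orientation each time
  e1 <- interp_axis(ev$values, 1, lat_ax[[1]])                 # dims: n1, d2, d3
  e1 <- array(e1, dim = c(length(lat_ax[[1]]), d[2], d[3]))
  e2 <- apply(e1, c(1, 3), function(v) approx(seq_along(v), v, xout = lat_ax[[2]])$y)
  e2 <- aperm(array(e2, dim = c(length(lat_ax[[2]]), length(lat_ax[[1]]), d[3])),
              c(2, 1, 3))
  e3 <- apply(e2, c(1, 2), function(v) approx(seq_along(v), v, xout = lat_ax[[3]])$y)
  e3 <- aperm(array(e3, dim = c(length(lat_ax[[3]]), length(lat_ax[[1]]),
                                length(lat_ax[[2]]))), c(2, 3, 1))
  lat_pos <- as.matrix(expand.grid(x = lat_ax[[1]], y = lat_ax[[2]], z = lat_ax[[3]]))
  lat_val <- as.numeric(e3)
  gamma_map <- array(NA_real_, dim = d)
  for (idx in which(ref$values >= criteria$low_cutoff_fraction * mx)) {
    ijk <- arrayInd(idx, d)
    dist2 <- ((lat_pos[, 1] - ijk[1])^2 + (lat_pos[, 2] - ijk[2])^2 +
                (lat_pos[, 3] - ijk[3])^2) * g$voxel_size^2
    g2 <- (lat_val - ref$values[idx])^2 / dd^2 + dist2 / dta^2
    gamma_map[idx] <- sqrt(min(g2))
  }
  gamma_map
}

# Hand Spearman for tie-free pairs: rho = 1 - 6 sum(d^2) / (n (n^2 - 1)).
oracle_spearman_notie <- function(x, y) {
  dr <- rank(x) - rank(y)
  1 - 6 * sum(dr^2) / (length(x) * (length(x)^2 - 1))
}
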