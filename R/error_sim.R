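# Delivery-error injection, sensitivity sweeps, passing-rate correlation.
#
# Five error families are simulated by perturbing the plan (per control
# point by default): gantry angle, MU, jaw position, collimator angle and
# MLC leaf position.  Normal machine tolerances (TG-142-style) and the
# error distributions:
#   gantry 1 deg, MU 1 MU, jaw 1 mm, collimator 1 deg  -- uniform;
#   MLC 2 mm                                           -- gaussian.
# The "within"-tolerance regime draws magnitudes in [0, tolerance]; the
# "outside" regime in [tol, 2*tol] (MLC: [2, 3] mm).  Signs are random.

.error_tolerances <- c(gantry = 1, MU = 1, jaw = 0.1, collimator = 1, MLC = 0.2)
.error_outside_high <- c(gantry = 2, MU = 2, jaw = 0.2, collimator = 2, MLC = 0.3)

#' Specify a delivery-error injection
#'
#' @param error_type one of "gantry", "MU", "jaw", "collimator", "MLC".
#' @param regime "within" (magnitudes in `[0, tolerance]`) or "outside"
#'   (`[tolerance, 2 tolerance]`; MLC `[2, 3]` mm).  Ignored when `low` and
#'   `high` are given.
#' @param low,high explicit magnitude bounds (deg, MU or cm by type).
#' @param distribution "uniform" or "gaussian"; defaults to the family's
#'   convention (gaussian for MLC, uniform otherwise).  Gaussian magnitudes
#'   use sd = high/2 and are redrawn until they land in `[low, high]`.
#' @param per_control_point draw independently per control point (default
#'   `TRUE`); otherwise one draw is applied to every control point.
#' @param seed RNG seed; injection is bit-reproducible given spec + seed.
#' @return object of class `error_spec`.
#' @export
error_spec <- function(error_type = c("gantry", "MU", "jaw", "collimator", "MLC"),
                       regime = c("within", "outside"),
                       low = NULL, high = NULL, distribution = NULL,
                       per_control_point = TRUE, seed = 1L) {
  error_type <- match.arg(error_type)
  regime <- match.arg(regime)
  tol <- .error_tolerances[[error_type]]
  if (is.null(low) || is.null(high)) {
    if (regime == "within") { low <- 0; high <- tol }
    else { low <- tol; high <- .error_outside_high[[error_type]] }
  }
  stopifnot(low >= 0, high >= low)
  if (is.null(distribution))
    distribution <- if (error_type == "MLC") "gaussian" else "uniform"
  distribution <- match.arg(distribution, c("uniform", "gaussian"))
  structure(list(error_type = error_type, distribution = distribution,
                 low = low, high = high,
                 per_control_point = isTRUE(per_control_point),
                 seed = as.integer(seed)),
            class = "error_spec")
}

# Runs expr with a private RNG state seeded from `seed`, restoring the
# caller's stream afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# n signed draws: |delta| from the spec's distribution in [low, high],
# sign uniform.
.draw_errors <- function(spec, n) {
  if (spec$high == 0) return(numeric(n))
  mag <- if (spec$distribution == "uniform") {
    stats::runif(n, spec$low, spec$high)
  } else {
    s <- spec$high / 2
    m <- numeric(n)
    todo <- seq_len(n)
    while (length(todo)) {
      m[todo] <- abs(stats::rnorm(length(todo), 0, s))
      todo <- todo[m[todo] < spec$low | m[todo] > spec$high]
    }
    m
  }
  mag * sample(c(-1, 1), n, replace = TRUE)
}

#' Inject simulated delivery errors into a plan
#'
#' Perturbs only the targeted axis, per control point, drawing from the
#' spec's distribution; everything else in the plan is untouched.  MLC
#' shifts are applied, in either direction independently per leaf, only to
#' leaf pairs that contribute to the fluence (open pairs overlapping the
#' Y-jaw window); a shift that would cross the banks collapses the pair to
#' closed at the midpoint.  MU errors perturb the per-interval MU and
#' rebuild the cumulative weights.  Deterministic under a fixed spec + seed.
#'
#' @param beams a [beam()] or list of beams.
#' @param spec an [error_spec()].
#' @return perturbed beams, same shape as the input.
#' @export
inject_errors <- function(beams, spec) {
  stopifnot(inherits(spec, "error_spec"))
  single <- inherits(beams, "beam")
  if (single) beams <- list(beams)
  out <- .with_seed(spec$seed, lapply(beams, .inject_beam, spec = spec))
  if (single) out[[1]] else out
}

.inject_beam <- function(bm, spec) {
  cps <- bm$control_points
  n <- length(cps)
  shared_val <- if (!spec$per_control_point) .draw_errors(spec, 1)
  draw <- function(k) {
    if (spec$per_control_point) .draw_errors(spec, k)
    else rep(shared_val, length.out = k)
  }
  if (spec$error_type %in% c("gantry", "collimator")) {
    d <- draw(n)
    slot <- if (spec$error_type == "gantry") "gantry_deg" else "collimator_deg"
    for (i in seq_len(n)) {
      a <- cps[[i]]$angles
      a[[slot]] <- (a[[slot]] + d[i]) %% 360
      cps[[i]]$angles <- beam_angles(a[["couch_deg"]], a[["gantry_deg"]],
                                     a[["collimator_deg"]])
    }
  } else if (spec$error_type == "jaw") {
    shared <- if (!spec$per_control_point) .draw_errors(spec, 4)
    for (i in seq_len(n)) {
      d <- if (spec$per_control_point) .draw_errors(spec, 4) else shared
      j <- cps[[i]]$jaws + d
      if (j[1] >= j[2]) j[1:2] <- mean(j[1:2]) + c(-1e-4, 1e-4)
      if (j[3] >= j[4]) j[3:4] <- mean(j[3:4]) + c(-1e-4, 1e-4)
      cps[[i]]$jaws <- j
    }
  } else if (spec$error_type == "MU") {
    dmu <- delta_mu_sequence(bm)
    dmu_new <- pmax(dmu + draw(n - 1), 0)
    total <- sum(dmu_new)
    if (total <= 0) stop("MU injection removed all beam output")
    w <- c(0, cumsum(dmu_new)) / total
    for (i in seq_len(n)) cps[[i]]$weight <- w[i]
    bm$total_MU <- total
  } else if (spec$error_type == "MLC") {
    for (i in seq_len(n)) {
      cp <- cps[[i]]
      layout <- mlc_layout(bm$machine)
      b <- layout$boundaries
      np <- length(cp$bank_A)
      contrib <- b[-length(b)] < cp$jaws[4] & b[-1] > cp$jaws[3] &
        (cp$bank_B - cp$bank_A) > 1e-6
      k <- sum(contrib)
      if (!k) next
      dA <- numeric(np); dB <- numeric(np)
      dA[contrib] <- draw(k); dB[contrib] <- draw(k)
      A <- pmin(pmax(cp$bank_A + dA, -20), 20)
      B <- pmin(pmax(cp$bank_B + dB, -20), 20)
      crossed <- A > B
      mid <- (A[crossed] + B[crossed]) / 2
      A[crossed] <- mid; B[crossed] <- mid
      cps[[i]]$bank_A <- A; cps[[i]]$bank_B <- B
    }
  } else stop("unknown error type: ", spec$error_type)
  bm$control_points <- cps
  bm
}

.map_as_volume <- function(map) {
  vs <- map$u[2] - map$u[1]
  g <- grid_spec(origin = c(map$u[1] - vs / 2, -vs / 2, map$w[1] - vs / 2),
                 voxel_size = vs,
                 dims = c(length(map$u), 1L, length(map$w)))
  fluence_volume(g, array(map$values, dim = g$dims), provenance = "2dfc")
}

#' Compare two composite 2D fluence maps
#'
#' Runs the intensity-difference and gamma tests on portal-plane maps (the
#' gamma search is then effectively 2D).
#'
#' @param reference,evaluated `fluence_map_2d` objects on the same portal
#'   grid.
#' @param criteria a [test_criteria()].
#' @return list with `F_I` and `F_gamma`.
#' @export
compare_2d <- function(reference, evaluated, criteria = test_criteria()) {
  rv <- .map_as_volume(reference); ev <- .map_as_volume(evaluated)
  list(F_I = intensity_difference_test(rv, ev, criteria)$F_I,
       F_gamma = gamma_analysis_3d(rv, ev, criteria)$F_gamma)
}

#' Sweep error magnitudes and record failing rates
#'
#' For each error type and normalized level (percent of the family's
#' tolerance) injects `n_reps` random error realisations into the plan,
#' reconstructs the 3D fluence and the composite 2D fluence, compares each
#' against the unmodified plan's fluences, and records the mean failing
#' rates.  Magnitude bounds at level L are `[0, L/100 * tolerance]`.
#'
#' @param beams a [beam()] or list of beams (the unmodified plan).
#' @param error_types subset of the five families.
#' @param levels normalized error levels in percent of tolerance.
#' @param n_reps random realisations per (type, level).
#' @param seed base RNG seed; each (type, level, rep) derives its own.
#' @param grid reconstruction [grid_spec()] (auto bounds when `NULL`).
#' @param criteria a [test_criteria()].
#' @param step_deg plan up-sampling step (degrees).
#' @return `sensitivity_curve`: data.frame with columns `error_type`,
#'   `level`, `method` ("3DFC"/"2DFC"), `F_I`, `F_gamma` (means over reps).
#' @export
sensitivity_sweep <- function(beams,
                              error_types = c("gantry", "MU", "jaw",
                                              "collimator", "MLC"),
                              levels = c(25, 50, 100, 150, 200),
                              n_reps = 10, seed = 1L, grid = NULL,
                              criteria = test_criteria(), step_deg = 1.0) {
  if (inherits(beams, "beam")) beams <- list(beams)
  if (is.null(grid)) grid <- compute_volume_bounds(beams)
  levels <- sort(levels)
  ref3 <- fluence_from_plan(beams, grid, step_deg = step_deg)
  ref2 <- composite_2d_fluence(beams, grid)
  rows <- list()
  for (ty in error_types) {
    tol <- .error_tolerances[[ty]]
    for (li in seq_along(levels)) {
      f3i <- f3g <- f2i <- f2g <- numeric(n_reps)
      for (r in seq_len(n_reps)) {
        sd_r <- (seed + 7919L * match(ty, names(.error_tolerances)) +
                   131L * li + r) %% .Machine$integer.max
        sp <- error_spec(ty, low = 0, high = levels[li] / 100 * tol,
                         seed = sd_r)
        mod <- inject_errors(beams, sp)
        v3 <- fluence_from_plan(mod, grid, step_deg = step_deg)
        f3i[r] <- intensity_difference_test(ref3, v3, criteria)$F_I
        f3g[r] <- gamma_analysis_3d(ref3, v3, criteria)$F_gamma
        m2 <- composite_2d_fluence(mod, grid)
        c2 <- compare_2d(ref2, m2, criteria)
        f2i[r] <- c2$F_I; f2g[r] <- c2$F_gamma
      }
      rows[[length(rows) + 1L]] <- data.frame(
        error_type = ty, level = levels[li],
        method = c("3DFC", "2DFC"),
        F_I = c(mean(f3i), mean(f2i)),
        F_gamma = c(mean(f3g), mean(f2g)))
    }
  }
  structure(do.call(rbind, rows), class = c("sensitivity_curve", "data.frame"))
}

#' Correlate two groups of QA passing rates
#'
#' Pearson's r and Spearman's rho (average ranks for ties) with the
#' two-sided p-value for rho, via [stats::cor()] / [stats::cor.test()].
#'
#' @param group_a,group_b equal-length paired passing-rate samples, n >= 3.
#' @return list with `pearson_r`, `spearman_rho`, `spearman_p`, `n`.
#' @export
correlate_passing_rates <- function(group_a, group_b) {
  stopifnot(length(group_a) == length(group_b), length(group_a) >= 3)
  if (stats::sd(group_a) == 0 || stats::sd(group_b) == 0)
    stop("undefined correlation: zero variance in a passing-rate group")
  ct <- suppressWarnings(
    stats::cor.test(group_a, group_b, method = "spearman", exact = FALSE))
  list(pearson_r = stats::cor(group_a, group_b),
       spearman_rho = unname(ct$estimate),
       spearman_p = ct$p.value,
       n = length(group_a))
}
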