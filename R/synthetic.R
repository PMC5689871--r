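# Synthetic VMAT/IMRT plan and delivery-log factory.
#
# Generates deterministic, physically plausible fixtures: multi-arc VMAT
# plans whose consecutive arcs alternate rotation direction (so the
# combined trajectory is continuous), and matched 20 ms delivery logs that
# trace the plan's linear inter-control-point trajectories, optionally with
# zero-mean tracking noise.

#' Synthetic plan recipe
#'
#' @param n_arcs number of VMAT arcs (beams).
#' @param cps_per_arc control points per arc (default 91, i.e. 4 deg per CP
#'   on a full arc).
#' @param arc_span_deg gantry span of each arc (default 360).
#' @param total_MU plan meterset, split evenly across arcs.
#' @param field_size_cm square jaw opening (cm at isocenter).
#' @param modulation leaf pattern: "open" (leaves at the jaw edges),
#'   "sliding-window" (a gap sweeping across the field),
#'   "random-leaf" (seeded bounded random walk per leaf),
#'   "closed-junction" (sliding window with closed leaf-pair junctions left
#'   inside the jaw field).
#' @param gap_cm sliding-window gap width (cm); small gaps give highly
#'   modulated deliveries.
#' @param collimator_deg,couch_deg static collimator / couch angles.
#' @param start_gantry_deg gantry angle at the start of the first arc.
#' @param seed RNG seed for the "random-leaf" pattern.
#' @return object of class `plan_recipe`.
#' @export
plan_recipe <- function(n_arcs = 1, cps_per_arc = 91, arc_span_deg = 360,
                        total_MU = 400, field_size_cm = 10,
                        modulation = c("sliding-window", "open",
                                       "random-leaf", "closed-junction"),
                        gap_cm = 2, collimator_deg = 0, couch_deg = 0,
                        start_gantry_deg = 180, seed = 1L) {
  modulation <- match.arg(modulation)
  stopifnot(n_arcs >= 1, cps_per_arc >= 2, total_MU > 0, field_size_cm > 0,
            arc_span_deg >= 0, gap_cm > 0)
  structure(list(n_arcs = n_arcs, cps_per_arc = cps_per_arc,
                 arc_span_deg = arc_span_deg, total_MU = total_MU,
                 field_size_cm = field_size_cm, modulation = modulation,
                 gap_cm = gap_cm, collimator_deg = collimator_deg,
                 couch_deg = couch_deg,
                 start_gantry_deg = start_gantry_deg, seed = as.integer(seed)),
            class = "plan_recipe")
}

# Leaf banks for control point i of n given the jaw window; returns
# list(A, B) of length n_pairs.
.recipe_banks <- function(recipe, jaws, i, n, walk_state, layout) {
  b <- layout$boundaries
  np <- layout$leaf_count_per_bank
  inside <- b[-length(b)] < jaws[4] & b[-1] > jaws[3]
  A <- rep(jaws[1], np)   # parked closed at the left jaw edge
  B <- rep(jaws[1], np)
  gap <- recipe$gap_cm
  if (recipe$modulation == "open") {
    A[inside] <- jaws[1]; B[inside] <- jaws[2]
  } else if (recipe$modulation %in% c("sliding-window", "closed-junction")) {
    centre <- jaws[1] + (i - 1) / max(n - 1, 1) * (jaws[2] - jaws[1])
    A[inside] <- pmax(jaws[1], centre - gap / 2)
    B[inside] <- pmin(jaws[2], centre + gap / 2)
    if (recipe$modulation == "closed-junction") {
      pairs_in <- which(inside)
      junction <- pairs_in[seq_len(min(4, length(pairs_in))) +
                             length(pairs_in) %/% 2 - 2]
      A[junction] <- 0; B[junction] <- 0   # closed junction inside the field
    }
  } else { # random-leaf: bounded random walk, one step per CP
    A[inside] <- walk_state$A
    B[inside] <- walk_state$B
  }
  bad <- A > B
  mid <- (A[bad] + B[bad]) / 2
  A[bad] <- mid; B[bad] <- mid
  list(A = A, B = B)
}

#' Generate a synthetic VMAT plan
#'
#' Deterministic multi-arc plan satisfying all beam and control-point
#' invariants: evenly spaced cumulative weights 0..1, alternating arc
#' directions so arc k + 1 starts at arc k's final gantry angle, static
#' jaws, and the recipe's leaf modulation pattern.
#'
#' @param recipe a [plan_recipe()].
#' @param path optional file path; when given the plan is also written as a
#'   DICOM RT Plan.
#' @return list of [beam()]s (one per arc).
#' @export
generate_synthetic_plan <- function(recipe, path = NULL) {
  stopifnot(inherits(recipe, "plan_recipe"))
  layout <- mlc_layout("Varian_Millennium_120")
  fs <- recipe$field_size_cm / 2
  jaws <- c(-fs, fs, -fs, fs)
  n <- recipe$cps_per_arc
  np <- layout$leaf_count_per_bank
  beams <- .with_seed(recipe$seed, {
    g0 <- recipe$start_gantry_deg
    lapply(seq_len(recipe$n_arcs), function(a) {
      # arcs alternate direction and chain end-to-start
      dirn <- if (a %% 2 == 1) 1 else -1
      g_start <- g0 + (if (a %% 2 == 1) 0 else recipe$arc_span_deg)
      gant <- g_start + dirn * recipe$arc_span_deg * (seq_len(n) - 1) / (n - 1)
      b <- layout$boundaries
      inside <- b[-length(b)] < jaws[4] & b[-1] > jaws[3]
      k <- sum(inside)
      walk <- list(A = stats::runif(k, jaws[1], 0), B = stats::runif(k, 0.5, jaws[2]))
      cps <- vector("list", n)
      for (i in seq_len(n)) {
        if (recipe$modulation == "random-leaf" && i > 1) {
          walk$A <- pmin(pmax(walk$A + stats::rnorm(k, 0, 0.4), jaws[1]), jaws[2] - 0.5)
          walk$B <- pmin(pmax(walk$B + stats::rnorm(k, 0, 0.4), walk$A + 0.5), jaws[2])
        }
        banks <- .recipe_banks(recipe, jaws, i, n, walk, layout)
        cps[[i]] <- control_point(
          index = i - 1,
          angles = beam_angles(recipe$couch_deg, gant[i], recipe$collimator_deg),
          jaws = jaws, bank_A = banks$A, bank_B = banks$B,
          weight = (i - 1) / (n - 1))
      }
      beam(a, cps, total_MU = recipe$total_MU / recipe$n_arcs,
           name = sprintf("Arc%d", a))
    })
  })
  if (!is.null(path)) write_rtplan(beams, path)
  beams
}

#' Generate a delivery log matched to a plan
#'
#' Traces each beam's linear inter-control-point trajectories at the log
#' sampling interval (20 ms), with cumulative MU following the plan's
#' meterset weights at constant dose rate per beam.  Beams are concatenated
#' into one record stream with continuous time and an absolute MU counter.
#' With `noise` all zero the log is an exact delivery of the plan.
#'
#' @param beams a [beam()] or list of beams.
#' @param duration_s delivery duration per beam (s), default 120.
#' @param noise list of zero-mean tracking-noise sd values:
#'   `gantry`, `collimator`, `couch` (deg), `jaw`, `mlc` (cm), `mu`
#'   (MU per record increment); missing entries default to 0.
#' @param sampling_interval_s record spacing (s), default 0.020.
#' @param seed RNG seed for the noise draws.
#' @param keep_fraction fraction of each beam's records kept (default 1);
#'   lower values emulate an interrupted delivery.
#' @return a [log_records()] object.
#' @export
generate_matched_log <- function(beams, duration_s = 120, noise = list(),
                                 sampling_interval_s = 0.020, seed = 1L,
                                 keep_fraction = 1) {
  if (inherits(beams, "beam")) beams <- list(beams)
  stopifnot(duration_s > 0, keep_fraction > 0, keep_fraction <= 1)
  nz <- function(nm) if (is.null(noise[[nm]])) 0 else noise[[nm]]
  dt <- sampling_interval_s
  .with_seed(seed, {
    t_off <- 0; mu_off <- 0
    parts <- lapply(beams, function(bm) {
      cps <- bm$control_points
      ncp <- length(cps)
      nrec <- round(duration_s / dt)
      keep <- seq_len(max(2, round(nrec * keep_fraction)))
      tt <- (seq_len(nrec) - 1) * dt
      s <- tt / duration_s * (ncp - 1)        # CP-index trajectory
      k0 <- pmin(floor(s) + 1, ncp - 1)
      f <- s - (k0 - 1)
      lerp_cp <- function(get) {
        lo <- vapply(cps[k0], get, numeric(1))
        hi <- vapply(cps[k0 + 1], get, numeric(1))
        lo + (hi - lo) * f
      }
      g_un <- unwrap_deg(vapply(cps, function(cp) cp$angles[["gantry_deg"]], numeric(1)))
      gant <- g_un[k0] + (g_un[k0 + 1] - g_un[k0]) * f
      coll <- lerp_cp(function(cp) signed_angle(cp$angles[["collimator_deg"]]))
      couch <- lerp_cp(function(cp) signed_angle(cp$angles[["couch_deg"]]))
      lerp_mat <- function(field) {
        lo <- t(vapply(cps[k0], `[[`, numeric(length(cps[[1]][[field]])), field))
        hi <- t(vapply(cps[k0 + 1], `[[`, numeric(length(cps[[1]][[field]])), field))
        lo + (hi - lo) * f
      }
      jaws <- matrix(rep(cps[[1]]$jaws, each = nrec), nrow = nrec)
      bA <- lerp_mat("bank_A"); bB <- lerp_mat("bank_B")
      w <- lerp_cp(function(cp) cp$weight)
      cum <- w / cps[[ncp]]$weight * bm$total_MU
      if (nz("gantry") > 0) gant <- gant + stats::rnorm(nrec, 0, nz("gantry"))
      if (nz("collimator") > 0) coll <- coll + stats::rnorm(nrec, 0, nz("collimator"))
      if (nz("couch") > 0) couch <- couch + stats::rnorm(nrec, 0, nz("couch"))
      if (nz("jaw") > 0) jaws <- jaws + matrix(stats::rnorm(nrec * 4, 0, nz("jaw")), nrec)
      if (nz("mlc") > 0) {
        bA <- bA + matrix(stats::rnorm(length(bA), 0, nz("mlc")), nrec)
        bB <- bB + matrix(stats::rnorm(length(bB), 0, nz("mlc")), nrec)
        cross <- bA > bB
        mids <- (bA[cross] + bB[cross]) / 2
        bA[cross] <- mids; bB[cross] <- mids
      }
      if (nz("mu") > 0) {
        inc <- pmax(diff(c(0, cum)) + stats::rnorm(nrec, 0, nz("mu")), 0)
        cum <- cumsum(inc)
      }
      dose_rate <- c(diff(cum) / dt, 0)
      out <- list(time = tt[keep] + t_off, couch = couch[keep],
                  gantry = gant[keep], coll = coll[keep],
                  jaws = jaws[keep, , drop = FALSE],
                  bank_A = bA[keep, , drop = FALSE],
                  bank_B = bB[keep, , drop = FALSE],
                  cum = cum[keep] + mu_off, dose_rate = dose_rate[keep])
      t_off <<- out$time[length(out$time)] + dt
      mu_off <<- out$cum[length(out$cum)]
      out
    })
    log_records(
      time = unlist(lapply(parts, `[[`, "time")),
      couch = unlist(lapply(parts, `[[`, "couch")),
      gantry = unlist(lapply(parts, `[[`, "gantry")),
      coll = unlist(lapply(parts, `[[`, "coll")),
      jaws = do.call(rbind, lapply(parts, `[[`, "jaws")),
      bank_A = do.call(rbind, lapply(parts, `[[`, "bank_A")),
      bank_B = do.call(rbind, lapply(parts, `[[`, "bank_B")),
      cumulative_MU = unlist(lapply(parts, `[[`, "cum")),
      dose_rate = unlist(lapply(parts, `[[`, "dose_rate")),
      sampling_interval_s = dt, SAD = beams[[1]]$SAD,
      machine = beams[[1]]$machine)
  })
}
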