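# Shared fixtures, generated in code.  Expensive volumes are cached per
# session so several test files can reuse them.

.fix_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fix_cache[[key]])) .fix_cache[[key]] <- force(expr)
  .fix_cache[[key]]
}

# A small modulated test arc: 37 CPs over 360 deg, 6 cm field, sliding
# window, 200 MU.  Auto bounds give a 28^3 grid at 3 mm voxels.
fix_arc <- function(mod = "sliding-window", seed = 11, cps = 37, fs = 6,
                    mu = 200, n_arcs = 1, span = 360) {
  generate_synthetic_plan(plan_recipe(
    n_arcs = n_arcs, cps_per_arc = cps, arc_span_deg = span, total_MU = mu,
    field_size_cm = fs, modulation = mod, seed = seed))
}

# Minimal static two-CP beam: open square field delivered at a fixed gantry
# angle; the analytic workhorse for physics checks.
fix_static_beam <- function(field = 10, mu = 100, gantry = 0) {
  layout <- mlc_layout()
  np <- layout$leaf_count_per_bank
  fs <- field / 2
  jaws <- c(-fs, fs, -fs, fs)
  b <- layout$boundaries
  inside <- b[-length(b)] < fs & b[-1] > -fs
  A <- rep(jaws[1], np); B <- rep(jaws[1], np)
  A[inside] <- jaws[1]; B[inside] <- jaws[2]
  mk <- function(i, w) control_point(i, beam_angles(0, gantry, 0), jaws, A, B, w)
  beam(1, list(mk(0, 0), mk(1, 1)), total_MU = mu)
}

fix_small_grid <- function(half = 3, voxel = 0.3) {
  n <- round(2 * half / voxel)
  grid_spec(origin = rep(-half, 3), voxel_size = voxel, dims = rep(n, 3))
}

# Tiny 7^3 volumes for exhaustive gamma comparisons.
fix_gamma_pair <- function(seed, scale = 10, noise = 0.6) {
  set.seed(seed)
  g <- grid_spec(origin = rep(-1.05, 3), voxel_size = 0.3, dims = rep(7, 3))
  base <- array(scale * exp(-(outer(1:7, rep(1, 7)) - 4)^2 / 8), dim = rep(7, 3))
  base <- base * rep(exp(-((1:7) - 4)^2 / 10), each = 49)
  ref <- fluence_volume(g, base, "test")
  ev <- fluence_volume(g, pmax(base + array(rnorm(343, 0, noise), rep(7, 3)), 0),
                       "test")
  list(ref = ref, ev = ev)
}
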