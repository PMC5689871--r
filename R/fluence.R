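# 3D fluence reconstruction engine.
#
# For every voxel centre r and every delivery segment the engine rotates r
# into the beam frame, projects it divergently onto the portal plane,
# evaluates the binary aperture mask, and accumulates
#   delta_MU * F(u, w) * SAD^2 / |r - s|^2
# where s is the segment's source position.  The result is the in-air
# primary fluence I(r) in MU: the total MU delivered to the point through
# the cumulative aperture, ignoring attenuation and scatter.

#' Reconstruction grid specification
#'
#' Isotropic voxel grid centred on the isocenter.  `origin` is the corner of
#' the volume (cm); voxel centres sit at `origin + (i - 0.5) * voxel_size`.
#'
#' @param origin numeric length 3, corner position (cm).
#' @param voxel_size isotropic voxel edge (cm), default 0.3.
#' @param dims integer length 3.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(origin, voxel_size = 0.3, dims) {
  stopifnot(voxel_size > 0, length(dims) == 3, all(dims >= 1),
            length(origin) == 3)
  ext <- origin + dims * voxel_size
  if (any(origin > 0) || any(ext < 0))
    stop("grid must contain the isocenter")
  structure(list(origin = as.numeric(origin), voxel_size = voxel_size,
                 dims = as.integer(dims)),
            class = "grid_spec")
}

#' Voxel-centre coordinates of a grid
#' @param grid a [grid_spec()].
#' @return list of numeric vectors `x`, `y`, `z` (cm).
#' @export
grid_axes <- function(grid) {
  ax <- function(i) grid$origin[i] + (seq_len(grid$dims[i]) - 0.5) * grid$voxel_size
  list(x = ax(1), y = ax(2), z = ax(3))
}

#' Automatic reconstruction volume bounds
#'
#' Cubic grid centred on the isocenter whose half-extent is the maximal jaw
#' opening over all beams and control points plus a margin, snapped up to a
#' whole number of voxels (at least 3 per axis).
#'
#' @param beams a [beam()] or list of beams.
#' @param voxel_size voxel edge in cm (default 0.3).
#' @param margin_cm margin beyond the maximal jaw opening (default 1).
#' @return a [grid_spec()].
#' @export
compute_volume_bounds <- function(beams, voxel_size = 0.3, margin_cm = 1) {
  if (inherits(beams, "beam")) beams <- list(beams)
  if (length(beams) < 1) stop("need at least one beam")
  half_jaw <- max(vapply(beams, function(bm)
    max(vapply(bm$control_points, function(cp) max(abs(cp$jaws)), numeric(1))),
    numeric(1)))
  half <- half_jaw + margin_cm
  n_half <- max(2L, as.integer(ceiling(half / voxel_size - 1e-9)))
  dims <- rep(2L * n_half, 3)
  grid_spec(origin = rep(-n_half * voxel_size, 3), voxel_size = voxel_size,
            dims = dims)
}

#' Construct a 3D fluence volume
#' @param grid a [grid_spec()].
#' @param values 3D array (MU), non-negative.
#' @param provenance character tag ("plan", "log", ...).
#' @return object of class `fluence_volume`.
#' @export
fluence_volume <- function(grid, values, provenance = "unknown") {
  stopifnot(inherits(grid, "grid_spec"), all(dim(values) == grid$dims))
  if (any(!is.finite(values)) || any(values < 0))
    stop("fluence values must be finite and non-negative")
  structure(list(grid = grid, values = values, provenance = provenance),
            class = "fluence_volume")
}

#' @export
print.fluence_volume <- function(x, ...) {
  cat(sprintf("<fluence_volume [%s]: %dx%dx%d @ %.1f mm, max %.2f MU>\n",
              x$provenance, x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              x$grid$voxel_size * 10, max(x$values)))
  invisible(x)
}

#' In-air beam intensity profile
#'
#' The 2D profile F(u, w) multiplying the aperture mask; the default is the
#' flat unit profile.  Supply `radial_fn(rho)` for a radially symmetric
#' profile (rho in cm on the portal plane).
#'
#' @param radial_fn function of off-axis distance (cm) returning a positive
#'   factor, or `NULL` for flat.
#' @return function `(u, w) -> numeric`.
#' @export
beam_profile <- function(radial_fn = NULL) {
  if (is.null(radial_fn)) function(u, w) rep(1, length(u))
  else function(u, w) radial_fn(sqrt(u^2 + w^2))
}

#' Accumulate segment contributions into a fluence volume
#'
#' The workhorse shared by the plan and log paths: the discrete realisation
#' of the MU-weighted, inverse-square-scaled aperture projection integral.
#'
#' @param segments a [delivery_segments()] object.
#' @param grid a [grid_spec()].
#' @param profile a [beam_profile()] (default flat).
#' @param provenance tag stored on the result.
#' @return a [fluence_volume()].
#' @export
accumulate_fluence <- function(segments, grid, profile = beam_profile(),
                               provenance = "segments") {
  stopifnot(inherits(segments, "delivery_segments"), inherits(grid, "grid_spec"))
  ax <- grid_axes(grid)
  d <- grid$dims
  # 3 x N voxel-centre matrix in x-fastest order matching array indexing
  P <- rbind(rep(ax$x, times = d[2] * d[3]),
             rep(rep(ax$y, each = d[1]), times = d[3]),
             rep(ax$z, each = d[1] * d[2]))
  vals <- numeric(ncol(P))
  SAD <- segments$SAD
  layout <- mlc_layout(segments$machine)
  for (i in seq_len(segments$n)) {
    if (segments$delta_mu[i] == 0) next
    R <- rot_z(-segments$gantry[i]) %*% rot_y(-segments$couch[i])
    Pb <- R %*% P
    y <- Pb[2, ]
    ok <- y > -SAD + 1e-6
    f <- SAD / (y + SAD)
    th <- deg2rad(segments$coll[i])
    u <- (cos(th) * Pb[1, ] - sin(th) * Pb[3, ]) * f
    w <- (sin(th) * Pb[1, ] + cos(th) * Pb[3, ]) * f
    ap <- aperture_from_state(segments$jaws[i, ], segments$bank_A[i, ],
                              segments$bank_B[i, ])
    m <- ok & in_aperture(u, w, ap, layout)
    idx <- which(m)
    if (!length(idx)) next
    s <- segments$source[i, ]
    d2 <- (P[1, idx] - s[1])^2 + (P[2, idx] - s[2])^2 + (P[3, idx] - s[3])^2
    if (any(d2 < 1e-12)) stop("degenerate geometry: voxel coincides with source")
    vals[idx] <- vals[idx] +
      segments$delta_mu[i] * profile(u[idx], w[idx]) * SAD^2 / d2
  }
  fluence_volume(grid, array(vals, dim = d), provenance)
}

#' Planned 3D fluence from DICOM-derived beams
#'
#' Up-samples each beam to `step_deg` gantry resolution and accumulates all
#' beams into one volume.
#'
#' @param beams a [beam()] or list of beams.
#' @param grid a [grid_spec()]; computed with [compute_volume_bounds()] when
#'   `NULL`.
#' @param profile a [beam_profile()].
#' @param step_deg up-sampling resolution in degrees (default 1).
#' @return a [fluence_volume()] with provenance "plan".
#' @export
fluence_from_plan <- function(beams, grid = NULL, profile = beam_profile(),
                              step_deg = 1.0) {
  if (inherits(beams, "beam")) beams <- list(beams)
  if (is.null(grid)) grid <- compute_volume_bounds(beams)
  segs <- lapply(beams, upsample_beam, step_deg = step_deg)
  accumulate_fluence(do.call(c, segs), grid, profile, provenance = "plan")
}

#' Delivered 3D fluence from log records
#'
#' Down-samples the log by `factor` and accumulates the resulting segments.
#'
#' @param records a [log_records()] object.
#' @param grid a [grid_spec()].
#' @param profile a [beam_profile()].
#' @param factor down-sampling factor (default 16).
#' @return a [fluence_volume()] with provenance "log".
#' @export
fluence_from_log <- function(records, grid, profile = beam_profile(),
                             factor = 16) {
  accumulate_fluence(downsample_log(records, factor), grid, profile,
                     provenance = "log")
}

#' Composite 2D fluence on the portal plane
#'
#' The 2D baseline (2DFC): the same MU-weighted aperture accumulation with
#' gantry and couch forced to 0 and no divergence scaling, yielding a map on
#' the isocenter portal plane.  Collimator rotation, jaws, leaves and MU all
#' enter; gantry and couch angles do not — including for plan segmentation,
#' which here is one segment per control-point interval, so that the map is
#' completely independent of gantry information.  This is exactly the
#' blindness the 3D method addresses.
#'
#' @param x a [beam()], list of beams, [log_records()], or
#'   [delivery_segments()].
#' @param grid a [grid_spec()]; its x and z axes define the u and w portal
#'   axes.
#' @param profile a [beam_profile()].
#' @param factor log down-sampling factor.
#' @return object of class `fluence_map_2d`: list with `u`, `w` axis centres
#'   and a `values` matrix (MU).
#' @export
composite_2d_fluence <- function(x, grid, profile = beam_profile(),
                                 factor = 16) {
  segments <- as_delivery_segments(x, step_deg = Inf, factor = factor)
  ax <- grid_axes(grid)
  U <- rep(ax$x, times = grid$dims[3])
  W <- rep(ax$z, each = grid$dims[1])
  vals <- numeric(length(U))
  layout <- mlc_layout(segments$machine)
  for (i in seq_len(segments$n)) {
    if (segments$delta_mu[i] == 0) next
    th <- deg2rad(segments$coll[i])
    u <- cos(th) * U - sin(th) * W
    w <- sin(th) * U + cos(th) * W
    ap <- aperture_from_state(segments$jaws[i, ], segments$bank_A[i, ],
                              segments$bank_B[i, ])
    m <- in_aperture(u, w, ap, layout)
    idx <- which(m)
    if (!length(idx)) next
    vals[idx] <- vals[idx] + segments$delta_mu[i] * profile(u[idx], w[idx])
  }
  structure(list(u = ax$x, w = ax$z,
                 values = matrix(vals, nrow = grid$dims[1])),
            class = "fluence_map_2d")
}

#' Coerce plans, logs or segments to delivery segments
#' @param x input object.
#' @param step_deg plan up-sampling step (degrees).
#' @param factor log down-sampling factor.
#' @return a [delivery_segments()] object.
#' @export
as_delivery_segments <- function(x, step_deg = 1.0, factor = 16) {
  if (inherits(x, "delivery_segments")) return(x)
  if (inherits(x, "log_records")) return(downsample_log(x, factor))
  if (inherits(x, "beam")) x <- list(x)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "beam")))
    return(do.call(c, lapply(x, upsample_beam, step_deg = step_deg)))
  stop("cannot interpret input as delivery segments")
}

# --- NRRD volume I/O -------------------------------------------------------

#' Export a fluence volume to NRRD
#'
#' Writes an NRRD0004 file (raw little-endian doubles) with the voxel
#' spacing and isocenter-relative origin in the header; losslessly
#' re-readable with [import_volume()].
#'
#' @param v a [fluence_volume()].
#' @param path output file (conventionally `.nrrd`).
#' @return `path`, invisibly.
#' @export
export_volume <- function(v, path) {
  stopifnot(inherits(v, "fluence_volume"))
  g <- v$grid
  vs <- g$voxel_size
  # space origin = centre of the first voxel
  org <- g$origin + vs / 2
  hdr <- c("NRRD0004",
           "# fluence volume (MU in air)",
           "type: double",
           "dimension: 3",
           "space: left-posterior-superior",
           sprintf("sizes: %d %d %d", g$dims[1], g$dims[2], g$dims[3]),
           sprintf("space directions: (%.10g,0,0) (0,%.10g,0) (0,0,%.10g)", vs, vs, vs),
           "kinds: domain domain domain",
           "endian: little",
           "encoding: raw",
           sprintf("space origin: (%.10g,%.10g,%.10g)", org[1], org[2], org[3]),
           sprintf("# provenance: %s", v$provenance))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n\n")), con)
  writeBin(as.numeric(v$values), con, size = 8, endian = "little")
  invisible(path)
}

#' Import a fluence volume from NRRD
#'
#' Reads NRRD0004/0005 files with raw encoding and double type, as written
#' by [export_volume()].
#'
#' @param path NRRD file.
#' @return a [fluence_volume()].
#' @export
import_volume <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  # header ends at the first blank line
  nl <- which(bytes == as.raw(0x0A))
  hdr_end <- NA
  prev <- 0L
  for (p in nl) {
    if (p == prev + 1L) { hdr_end <- p; break }
    prev <- p
  }
  if (is.na(hdr_end)) stop("malformed NRRD: no blank line after header")
  hdr <- strsplit(rawToChar(bytes[seq_len(hdr_end - 2)]), "\n")[[1]]
  if (!grepl("^NRRD000[0-9]$", hdr[1])) stop("not an NRRD file: ", path)
  field <- function(name) {
    ln <- grep(paste0("^", name, ": "), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^", name, ": "), "", ln[1])
  }
  if (!identical(field("encoding"), "raw") || !identical(field("type"), "double"))
    stop("unsupported NRRD variant (need raw double)")
  dims <- as.integer(strsplit(field("sizes"), " ")[[1]])
  nums <- function(s) as.numeric(regmatches(s, gregexpr("-?[0-9.eE+-]+", s))[[1]])
  sd <- nums(field("space directions"))
  vs <- sd[1]
  org <- nums(field("space origin"))
  vals <- readBin(bytes[(hdr_end + 1):length(bytes)], "double",
                  n = prod(dims), size = 8, endian = "little")
  prov <- grep("^# provenance: ", hdr, value = TRUE)
  fluence_volume(
    grid_spec(origin = org - vs / 2, voxel_size = vs, dims = dims),
    array(vals, dim = dims),
    provenance = if (length(prov)) sub("^# provenance: ", "", prov[1]) else "file")
}
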