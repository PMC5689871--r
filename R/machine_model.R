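# MLC leaf geometry and the binary aperture mask.
#
# The built-in layout is the Varian Millennium 120: 60 leaf pairs spanning
# w in [-20, 20] cm at the isocenter plane, 1 cm wide for pairs 1-10 and
# 51-60 and 0.5 cm wide for pairs 11-50.  Leaf and jaw positions are
# interpreted at the isocenter plane (already divergence-scaled), matching
# DICOM-RT semantics.  All aperture edges use the half-open convention
# [lower, upper) so points exactly on a boundary resolve deterministically.

.layout_registry <- new.env(parent = emptyenv())

#' MLC layout lookup
#'
#' Returns a named MLC layout from the registry.  `"Varian_Millennium_120"`
#' is built in; additional layouts can be registered with
#' [register_mlc_layout()] or loaded from a plain-text file of 61 boundary
#' values with [read_mlc_layout()].
#'
#' @param name layout name.
#' @return an object of class `mlc_layout`: list with `name`,
#'   `leaf_count_per_bank`, and `boundaries` (61 strictly increasing leaf-edge
#'   w-coordinates, cm at isocenter).
#' @export
mlc_layout <- function(name = "Varian_Millennium_120") {
  if (!exists(name, envir = .layout_registry))
    stop("unknown MLC layout: ", name)
  get(name, envir = .layout_registry)
}

#' Register a custom MLC layout
#' @param name layout name used for lookup.
#' @param boundaries strictly increasing leaf-edge w-coordinates (cm);
#'   `length(boundaries) - 1` leaf pairs.
#' @return the registered `mlc_layout`, invisibly.
#' @export
register_mlc_layout <- function(name, boundaries) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2 || any(diff(boundaries) <= 0))
    stop("boundaries must be strictly increasing with length >= 2")
  layout <- structure(
    list(name = name, leaf_count_per_bank = length(boundaries) - 1L,
         boundaries = boundaries),
    class = "mlc_layout")
  assign(name, layout, envir = .layout_registry)
  invisible(layout)
}

#' Load an MLC layout from a plain-text file
#' @param path file with one boundary value (cm) per line.
#' @param name registry name for the layout.
#' @return the registered `mlc_layout`, invisibly.
#' @export
read_mlc_layout <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  register_mlc_layout(name, scan(path, quiet = TRUE))
}

local({
  b <- c(seq(-20, -10, by = 1),      # pairs 1-10, 1 cm
         seq(-9.5, 9.5, by = 0.5),   # pairs 11-50, 0.5 cm
         seq(10, 20, by = 1))        # pairs 51-60, 1 cm
  register_mlc_layout("Varian_Millennium_120", b)
})

#' Leaf pair index from the portal w coordinate
#'
#' Millennium-120 leaf pair number for a point at `w` cm (isocenter plane):
#' the half-centimeter bin `v = int((w + 20)/0.5) + 1` in `[1, 80]` is folded
#' onto the 60 physical pairs (pairs 1-10 and 51-60 span two bins each).
#'
#' @param w numeric vector of portal w coordinates (cm); must satisfy
#'   `-20 <= w < 20`.
#' @return integer vector of leaf pair numbers in `[1, 60]`.
#' @export
leaf_index <- function(w) {
  if (any(w < -20 | w >= 20)) stop("out-of-field: leaf_index requires -20 <= w < 20")
  v <- as.integer(floor((w + 20) / 0.5)) + 1L
  f <- integer(length(v))
  lo <- v <= 20L
  hi <- v >= 61L
  mid <- !lo & !hi
  f[lo]  <- (v[lo] - 1L) %/% 2L + 1L
  f[mid] <- v[mid] - 10L
  f[hi]  <- (v[hi] - 61L) %/% 2L + 51L
  f
}

#' Construct a validated beam aperture
#'
#' An aperture is the jaw rectangle plus 60 leaf-pair openings.  Bank A is
#' the left (negative-u) bank, bank B the right bank; a closed pair has
#' `bank_A[i] == bank_B[i]`.  Tiny bank crossings (< 1e-4 cm, typical of
#' rounded plan data) are snapped closed; larger crossings are an error.
#'
#' @param jaws numeric length 4: `c(x1, x2, y1, y2)` cm at isocenter,
#'   `x1 < x2`, `y1 < y2`.
#' @param bank_A,bank_B numeric leaf-tip u-positions (cm), one per pair;
#'   `bank_A[i] <= bank_B[i]`, tips within +/- 20 cm.
#' @return object of class `aperture`.
#' @export
aperture_from_state <- function(jaws, bank_A, bank_B) {
  stopifnot(length(jaws) == 4, length(bank_A) == length(bank_B))
  jaws <- as.numeric(jaws); bank_A <- as.numeric(bank_A); bank_B <- as.numeric(bank_B)
  if (jaws[1] >= jaws[2] || jaws[3] >= jaws[4])
    stop("invalid jaws: need x1 < x2 and y1 < y2")
  if (any(abs(c(bank_A, bank_B)) > 20))
    stop("leaf tip outside +/- 20 cm travel range")
  cross <- bank_A - bank_B
  if (any(cross > 1e-4))
    stop("crossed leaf pair: bank_A exceeds bank_B beyond tolerance")
  snap <- cross > 0
  if (any(snap)) {
    mid <- (bank_A[snap] + bank_B[snap]) / 2
    bank_A[snap] <- mid; bank_B[snap] <- mid
  }
  structure(list(x1 = jaws[1], x2 = jaws[2], y1 = jaws[3], y2 = jaws[4],
                 bank_A = bank_A, bank_B = bank_B),
            class = "aperture")
}

#' Binary aperture mask value
#'
#' Whether portal point(s) lie inside the beam opening: within the X and Y
#' jaws and between the two leaf tips of the relevant pair.  Points outside
#' the leaf travel range are outside the aperture.  All comparisons use
#' half-open intervals `[lower, upper)`.
#'
#' @param u,w portal coordinates (cm), equal-length numeric vectors.
#' @param ap an [aperture_from_state()] object.
#' @param layout an [mlc_layout()].
#' @return logical vector, `TRUE` where the mask M = 1.
#' @export
in_aperture <- function(u, w, ap, layout = mlc_layout()) {
  b <- layout$boundaries
  ok <- u >= ap$x1 & u < ap$x2 & w >= ap$y1 & w < ap$y2 &
    w >= b[1] & w < b[length(b)]
  if (any(ok)) {
    li <- if (identical(layout$name, "Varian_Millennium_120"))
      leaf_index(w[ok]) else findInterval(w[ok], b)
    ok[ok] <- u[ok] >= ap$bank_A[li] & u[ok] < ap$bank_B[li]
  }
  ok
}
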