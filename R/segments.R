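# The unified discretized integration element consumed by the fluence
# engine: both up-sampled plans and down-sampled logs reduce to a sequence
# of segments, each holding a mean machine state, an MU increment, and an
# effective source position.

#' Construct a delivery-segment sequence
#'
#' Column-oriented container: `n` segments with mean axis states (degrees,
#' cm), MU increments and room-frame source positions.  This is the common
#' currency of the plan and log fluence paths.
#'
#' @param couch,gantry,coll numeric angle vectors (degrees, any winding).
#' @param jaws `n x 4` matrix `(x1, x2, y1, y2)` in cm.
#' @param bank_A,bank_B `n x n_pairs` leaf-tip matrices (cm).
#' @param delta_mu MU increment per segment (>= 0).
#' @param source `n x 3` room-frame source positions (cm); computed from the
#'   segment angles when omitted.
#' @param SAD source-to-axis distance (cm).
#' @param machine MLC layout name.
#' @return object of class `delivery_segments`.
#' @export
delivery_segments <- function(couch, gantry, coll, jaws, bank_A, bank_B,
                              delta_mu, source = NULL, SAD = 100,
                              machine = "Varian_Millennium_120") {
  n <- length(gantry)
  jaws <- matrix(jaws, nrow = n)
  bank_A <- matrix(bank_A, nrow = n)
  bank_B <- matrix(bank_B, nrow = n)
  stopifnot(length(couch) == n, length(coll) == n, length(delta_mu) == n,
            ncol(jaws) == 4, ncol(bank_A) == ncol(bank_B))
  if (any(delta_mu < -1e-9)) stop("delta_mu must be non-negative")
  delta_mu <- pmax(delta_mu, 0)
  if (is.null(source)) {
    source <- t(vapply(seq_len(n), function(i)
      source_position(beam_angles(couch[i], gantry[i], coll[i]), SAD),
      numeric(3)))
  }
  source <- matrix(source, nrow = n)
  structure(list(n = n, couch = couch, gantry = gantry, coll = coll,
                 jaws = jaws, bank_A = bank_A, bank_B = bank_B,
                 delta_mu = as.numeric(delta_mu), source = source,
                 SAD = SAD, machine = machine),
            class = "delivery_segments")
}

#' Concatenate delivery-segment sequences
#' @param ... `delivery_segments` objects sharing SAD and machine.
#' @return combined `delivery_segments`.
#' @export
c.delivery_segments <- function(...) {
  parts <- list(...)
  stopifnot(length(unique(vapply(parts, `[[`, numeric(1), "SAD"))) == 1)
  delivery_segments(
    couch = unlist(lapply(parts, `[[`, "couch")),
    gantry = unlist(lapply(parts, `[[`, "gantry")),
    coll = unlist(lapply(parts, `[[`, "coll")),
    jaws = do.call(rbind, lapply(parts, `[[`, "jaws")),
    bank_A = do.call(rbind, lapply(parts, `[[`, "bank_A")),
    bank_B = do.call(rbind, lapply(parts, `[[`, "bank_B")),
    delta_mu = unlist(lapply(parts, `[[`, "delta_mu")),
    source = do.call(rbind, lapply(parts, `[[`, "source")),
    SAD = parts[[1]]$SAD, machine = parts[[1]]$machine)
}

#' @export
print.delivery_segments <- function(x, ...) {
  cat(sprintf("<delivery_segments: %d segments, %.2f MU total, gantry %.1f..%.1f deg>\n",
              x$n, sum(x$delta_mu), min(x$gantry), max(x$gantry)))
  invisible(x)
}
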