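# Delivery-log I/O and down-sampling.
#
# Binary log layout (documented, little endian throughout; designed to
# mirror TrueBeam trajectory-log content without the proprietary format):
#
#   bytes 0-7   magic "FLQALOG1"
#   uint16      format version (1)
#   uint16      leaf pairs per bank (60 for Millennium 120)
#   uint32      record count
#   float64     sampling interval in seconds (0.020 for TrueBeam)
#   float64     SAD in cm
#
# followed by `record count` fixed-size records of float64 fields:
#   time_s, couch_deg, gantry_deg, collimator_deg, jaws x1 x2 y1 y2 (cm),
#   bank_A[pairs] (cm), bank_B[pairs] (cm), cumulative_MU, dose_rate (MU/s).
#
# A reader for a vendor format can be plugged in via `log_reader_hook`.

LOG_MAGIC <- "FLQALOG1"
LOG_VERSION <- 1L

#' Construct a delivery-log record set
#'
#' Column-oriented container of fixed-interval machine-state records.
#'
#' @param time strictly increasing times (s).
#' @param couch,gantry,coll axis angles (degrees).
#' @param jaws `n x 4` matrix (cm).
#' @param bank_A,bank_B `n x n_pairs` leaf matrices (cm).
#' @param cumulative_MU non-decreasing absolute MU counter.
#' @param dose_rate instantaneous dose rate (MU/s).
#' @param sampling_interval_s nominal record spacing (s), default 0.020.
#' @param SAD source-to-axis distance (cm).
#' @param machine MLC layout name.
#' @return object of class `log_records`.
#' @export
log_records <- function(time, couch, gantry, coll, jaws, bank_A, bank_B,
                        cumulative_MU, dose_rate,
                        sampling_interval_s = 0.020, SAD = 100,
                        machine = "Varian_Millennium_120") {
  n <- length(time)
  if (n == 0) stop("empty record set")
  if (any(diff(time) <= 0)) stop("record times must be strictly increasing")
  if (any(diff(cumulative_MU) < -1e-9))
    stop("cumulative MU must be non-decreasing")
  structure(list(n = n, time = as.numeric(time),
                 couch = as.numeric(couch) %% 360,
                 gantry = as.numeric(gantry) %% 360,
                 coll = as.numeric(coll) %% 360,
                 jaws = matrix(jaws, nrow = n),
                 bank_A = matrix(bank_A, nrow = n),
                 bank_B = matrix(bank_B, nrow = n),
                 cumulative_MU = as.numeric(cumulative_MU),
                 dose_rate = as.numeric(dose_rate),
                 sampling_interval_s = sampling_interval_s,
                 SAD = SAD, machine = machine),
            class = "log_records")
}

#' @export
print.log_records <- function(x, ...) {
  cat(sprintf(paste0("<log_records: %d records @ %.0f ms, %.1f s, %.2f MU, ",
                     "gantry %.1f..%.1f deg>\n"),
              x$n, x$sampling_interval_s * 1000, x$time[x$n] - x$time[1],
              x$cumulative_MU[x$n] - x$cumulative_MU[1],
              min(x$gantry), max(x$gantry)))
  invisible(x)
}

#' Write a delivery log file
#'
#' Byte-exact, re-readable serialisation of a [log_records()] object in the
#' documented binary layout.
#'
#' @param records a [log_records()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_log <- function(records, path) {
  stopifnot(inherits(records, "log_records"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(LOG_MAGIC), con)
  writeBin(c(LOG_VERSION, ncol(records$bank_A)), con, size = 2, endian = "little")
  writeBin(records$n, con, size = 4, endian = "little")
  writeBin(c(records$sampling_interval_s, records$SAD), con, size = 8,
           endian = "little")
  recs <- cbind(records$time, records$couch, records$gantry, records$coll,
                records$jaws, records$bank_A, records$bank_B,
                records$cumulative_MU, records$dose_rate)
  writeBin(as.numeric(t(recs)), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a delivery log file
#'
#' Reads the documented binary layout and validates monotonicity.  A reader
#' for another (e.g. vendor) format may be supplied via `reader`; it must
#' accept a path and return a [log_records()] object.
#'
#' @param path log file.
#' @param reader optional adapter function `(path) -> log_records`.
#' @return a [log_records()] object.
#' @export
read_log <- function(path, reader = NULL) {
  if (!is.null(reader)) return(reader(path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", n = 8))
  if (!identical(magic, LOG_MAGIC)) stop("format error: bad log magic in ", path)
  hdr <- readBin(con, "integer", n = 2, size = 2, endian = "little")
  if (hdr[1] != LOG_VERSION) stop("format error: unsupported log version ", hdr[1])
  n_pairs <- hdr[2]
  n <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (is.na(n) || n <= 0) stop("format error: empty record section")
  hdr2 <- readBin(con, "double", n = 2, size = 8, endian = "little")
  rec_len <- 4 + 4 + 2 * n_pairs + 2
  vals <- readBin(con, "double", n = n * rec_len, size = 8, endian = "little")
  if (length(vals) < n * rec_len) stop("format error: truncated log file ", path)
  m <- matrix(vals, ncol = rec_len, byrow = TRUE)
  iA <- 8 + seq_len(n_pairs); iB <- 8 + n_pairs + seq_len(n_pairs)
  if (any(diff(m[, 7 + 2 * n_pairs + 1]) < -1e-9))
    stop("data error: non-monotone cumulative MU")
  log_records(time = m[, 1], couch = m[, 2], gantry = m[, 3], coll = m[, 4],
              jaws = m[, 5:8], bank_A = m[, iA], bank_B = m[, iB],
              cumulative_MU = m[, 8 + 2 * n_pairs + 1],
              dose_rate = m[, 8 + 2 * n_pairs + 2],
              sampling_interval_s = hdr2[1], SAD = hdr2[2],
              machine = if (n_pairs == 60) "Varian_Millennium_120"
                        else paste0("generic_", n_pairs))
}

#' Log header summary
#'
#' @param path log file.
#' @return list with record count, sampling interval, duration, total MU and
#'   the equivalent angular resolution (gantry degrees per record).
#' @export
log_info <- function(path) {
  r <- read_log(path)
  span <- sum(abs(angle_diff(r$gantry[-1], r$gantry[-r$n])))
  list(records = r$n, sampling_interval_s = r$sampling_interval_s,
       duration_s = r$time[r$n] - r$time[1],
       total_MU = r$cumulative_MU[r$n] - r$cumulative_MU[1],
       leaf_pairs = ncol(r$bank_A), SAD = r$SAD,
       angular_resolution_deg = if (r$n > 1) span / (r$n - 1) else NA_real_)
}

#' Down-sample log records into delivery segments
#'
#' Merges consecutive groups of `factor` records into one segment each:
#' angles are combined by circular mean, jaws and leaves by arithmetic mean,
#' and the segment MU is the cumulative-MU increment across the group.  A
#' final partial group is merged the same way, so total MU is conserved for
#' any factor.
#'
#' @param records a [log_records()] object.
#' @param factor group size (default 16).
#' @return a [delivery_segments()] object.
#' @export
downsample_log <- function(records, factor = 16) {
  stopifnot(inherits(records, "log_records"), factor >= 1)
  factor <- as.integer(factor)
  n <- records$n
  grp <- (seq_len(n) - 1L) %/% factor + 1L
  ng <- max(grp)
  cmean_by <- function(deg) {
    as.numeric(tapply(deg, grp, circular_mean_deg))
  }
  mean_cols <- function(m) {
    apply(m, 2, function(col) as.numeric(tapply(col, grp, mean)))
  }
  last_idx <- cumsum(tabulate(grp))
  base <- c(records$cumulative_MU[1], records$cumulative_MU[last_idx[-ng]])
  dmu <- records$cumulative_MU[last_idx] - base
  delivery_segments(
    couch = cmean_by(records$couch), gantry = cmean_by(records$gantry),
    coll = cmean_by(records$coll),
    jaws = mean_cols(records$jaws),
    bank_A = mean_cols(records$bank_A), bank_B = mean_cols(records$bank_B),
    delta_mu = dmu, SAD = records$SAD, machine = records$machine)
}
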