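# Minimal DICOM reader/writer, explicit VR little endian only.
#
# Covers just what RT Plan I/O needs: the part-10 preamble and file meta
# group, string VRs (UI, CS, LO, SH, PN, DA, TM, DS, IS), binary VRs
# (US, UL, FL, FD, OB) and nested sequences (SQ) with defined or undefined
# item lengths.  Datasets are represented as named lists keyed by
# "GGGGEEEE" (uppercase hex); SQ values are lists of child datasets.
# Decimal strings (DS/IS) are parsed to numeric vectors.

TRANSFER_SYNTAX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_CLASS_RTPLAN <- "1.2.840.10008.5.1.4.1.1.481.5"

.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.dcm_string_vrs <- c("UI", "CS", "LO", "SH", "PN", "DA", "TM", "DS", "IS", "ST", "LT", "AE", "AS")

dcm_tag <- function(group, element) sprintf("%04X%04X", group, element)

.uid_counter <- new.env(parent = emptyenv())
.uid_counter$n <- 0L

# Deterministic-per-session UID under a private (non-registered) root.
dcm_new_uid <- function() {
  .uid_counter$n <- .uid_counter$n + 1L
  paste0("2.25.", format(as.integer(Sys.time()) %% 1e9), ".",
         Sys.getpid() %% 1e5, ".", .uid_counter$n)
}

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.pad_even <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2 == 1) c(bytes, pad) else bytes
}

.encode_value <- function(vr, value) {
  if (vr %in% c("DS", "IS")) {
    s <- paste(vapply(value, function(v)
      if (vr == "IS") sprintf("%d", as.integer(v)) else format(as.numeric(v), digits = 10, scientific = FALSE, trim = TRUE),
      character(1)), collapse = "\\")
    .pad_even(charToRaw(s))
  } else if (vr %in% .dcm_string_vrs) {
    .pad_even(charToRaw(paste(value, collapse = "\\")),
              pad = if (vr == "UI") as.raw(0) else as.raw(0x20))
  } else if (vr %in% c("US", "UL")) {
    writeBin(as.integer(value), raw(), size = if (vr == "US") 2 else 4, endian = "little")
  } else if (vr %in% c("FL", "FD")) {
    writeBin(as.numeric(value), raw(), size = if (vr == "FL") 4 else 8, endian = "little")
  } else if (vr == "OB") {
    .pad_even(as.raw(value), pad = as.raw(0))
  } else stop("unsupported VR for encoding: ", vr)
}

.encode_element <- function(group, element, vr, value) {
  body <- if (vr == "SQ") {
    items <- lapply(value, function(item) {
      b <- dcm_encode_dataset(item)
      c(.u16(0xFFFE), .u16(0xE000), .u32(length(b)), b)
    })
    do.call(c, c(items, list(raw(0))))
  } else .encode_value(vr, value)
  head <- c(.u16(group), .u16(element), charToRaw(vr))
  if (vr %in% .dcm_long_vrs) {
    c(head, as.raw(c(0, 0)), .u32(length(body)), body)
  } else {
    if (length(body) > 65534) stop("value too long for short VR ", vr)
    c(head, .u16(length(body)), body)
  }
}

# elements: list of list(group=, element=, vr=, value=); sorted here.
dcm_encode_dataset <- function(elements) {
  if (length(elements) == 0) return(raw(0))
  ord <- order(vapply(elements, function(e) e$group * 2^16 + e$element, numeric(1)))
  do.call(c, lapply(elements[ord], function(e)
    .encode_element(e$group, e$element, e$vr, e$value)))
}

el <- function(group, element, vr, value) list(group = group, element = element, vr = vr, value = value)

#' Write a DICOM part-10 file (explicit VR little endian)
#'
#' Low-level writer used by [write_rtplan()]: emits the 128-byte preamble,
#' "DICM" marker, file meta group and the given dataset elements.
#'
#' @param elements list of elements as built by the internal `el()` helper.
#' @param path output file path.
#' @param sop_class_uid,sop_instance_uid media storage SOP identifiers.
#' @return `path`, invisibly.
#' @keywords internal
dcm_write_file <- function(elements, path,
                           sop_class_uid = SOP_CLASS_RTPLAN,
                           sop_instance_uid = dcm_new_uid()) {
  meta <- list(
    el(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    el(0x0002, 0x0002, "UI", sop_class_uid),
    el(0x0002, 0x0003, "UI", sop_instance_uid),
    el(0x0002, 0x0010, "UI", TRANSFER_SYNTAX_EXPLICIT_LE),
    el(0x0002, 0x0012, "UI", "2.25.4242424242"))
  meta_bytes <- dcm_encode_dataset(meta)
  meta_bytes <- c(.encode_element(0x0002, 0x0000, "UL", length(meta_bytes)), meta_bytes)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(meta_bytes, con)
  writeBin(dcm_encode_dataset(elements), con)
  invisible(path)
}

# --- reading ---------------------------------------------------------------

.rd_u16 <- function(bytes, at) {
  sum(as.integer(bytes[at + 0:1]) * c(1, 256))
}
.rd_u32 <- function(bytes, at) {
  sum(as.numeric(bytes[at + 0:3]) * c(1, 256, 65536, 16777216))
}

.decode_value <- function(vr, bytes) {
  if (vr %in% c("DS", "IS")) {
    s <- trimws(rawToChar(bytes[bytes != as.raw(0)]))
    if (!nzchar(s)) return(numeric(0))
    as.numeric(strsplit(s, "\\", fixed = TRUE)[[1]])
  } else if (vr %in% .dcm_string_vrs) {
    s <- rawToChar(bytes[bytes != as.raw(0)])
    trimws(s, which = "right")
  } else if (vr %in% c("US", "UL")) {
    if (vr == "US")
      readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
              endian = "little", signed = FALSE)
    else readBin(bytes, "integer", n = length(bytes) / 4, size = 4,
                 endian = "little")
  } else if (vr %in% c("FL", "FD")) {
    readBin(bytes, "double", n = length(bytes) / (if (vr == "FL") 4 else 8),
            size = if (vr == "FL") 4 else 8, endian = "little")
  } else bytes
}

# Parses one dataset from `bytes` starting at `pos` (1-based) up to `end`;
# returns list(ds = named list, pos = next position).
.parse_dataset <- function(bytes, pos, end) {
  ds <- list()
  while (pos <= end) {
    group <- .rd_u16(bytes, pos); element <- .rd_u16(bytes, pos + 2)
    if (group == 0xFFFE) { # item delimitation inside undefined-length SQ item
      len <- .rd_u32(bytes, pos + 4)
      pos <- pos + 8
      if (element %in% c(0xE00D, 0xE0DD)) break
      stop("unexpected item tag in dataset")
    }
    vr <- rawToChar(bytes[pos + 4:5])
    if (vr %in% .dcm_long_vrs) {
      len <- .rd_u32(bytes, pos + 8)
      pos <- pos + 12
    } else {
      len <- .rd_u16(bytes, pos + 6)
      pos <- pos + 8
    }
    key <- dcm_tag(group, element)
    if (vr == "SQ") {
      sq_end <- if (len == 0xFFFFFFFF) end else pos + len - 1
      items <- list()
      while (pos <= sq_end) {
        ig <- .rd_u16(bytes, pos); ie <- .rd_u16(bytes, pos + 2)
        ilen <- .rd_u32(bytes, pos + 4)
        pos <- pos + 8
        if (ig != 0xFFFE) stop("malformed sequence: expected item tag")
        if (ie == 0xE0DD) break # sequence delimiter (undefined-length SQ)
        if (ie != 0xE000) stop("malformed sequence item tag")
        item_end <- if (ilen == 0xFFFFFFFF) sq_end else pos + ilen - 1
        parsed <- .parse_dataset(bytes, pos, item_end)
        items[[length(items) + 1L]] <- parsed$ds
        pos <- parsed$pos
      }
      ds[[key]] <- items
    } else {
      if (len == 0xFFFFFFFF) stop("undefined length on non-SQ element")
      if (pos + len - 1 > length(bytes)) stop("truncated DICOM element ", key)
      ds[[key]] <- .decode_value(vr, bytes[seq_len(len) + pos - 1])
      pos <- pos + len
    }
  }
  list(ds = ds, pos = pos)
}

#' Read a DICOM part-10 file into a tag-keyed list
#'
#' @param path DICOM file path.
#' @return named list keyed by "GGGGEEEE"; sequences are lists of such lists.
#'   File meta elements (group 0002) are included.
#' @keywords internal
dcm_read_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 132 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM part-10 file (missing DICM marker): ", path)
  # file meta group is always explicit LE
  meta_len_el <- .parse_dataset(bytes, 133, 132 + 12)  # (0002,0000) UL
  meta_len <- meta_len_el$ds[["00020000"]]
  meta <- .parse_dataset(bytes, meta_len_el$pos, meta_len_el$pos + meta_len - 1)
  ts <- meta$ds[["00020010"]]
  if (!is.null(ts) && ts != TRANSFER_SYNTAX_EXPLICIT_LE)
    stop("unsupported transfer syntax: ", ts)
  body <- .parse_dataset(bytes, meta$pos, length(bytes))
  c(meta$ds, body$ds)
}
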