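# Minimal DICOM series I/O. No R DICOM reader is available to this
# package, so a small single-frame parser is provided: uncompressed
# little-endian transfer syntaxes (explicit or implicit VR), 16-bit pixel
# data, the tags a CT slice needs (dimensions, pixel representation,
# rescale slope/intercept, position). The writer exists to build synthetic
# test series and round-trip fixtures; it is not a clinical exporter.

.u16 <- function(raw, off) {
  as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
}
.u32 <- function(raw, off) {
  .u16(raw, off) + 65536 * .u16(raw, off + 2)
}

# VRs with the 2-byte reserved + 4-byte length layout in explicit VR
.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# parse one DICOM file into list(tags = named list, pixel = raw)
parse_dicom <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM") {
    stop("format error: ", path, " is not a DICOM part-10 file")
  }
  off <- 132L
  tags <- list()
  pixel <- NULL
  n <- length(raw)
  while (off + 8 <= n) {
    grp <- .u16(raw, off); el <- .u16(raw, off + 2)
    key <- sprintf("%04x,%04x", grp, el)
    vr <- rawToChar(raw[(off + 5):(off + 6)])
    explicit <- grepl("^[A-Z]{2}$", vr)
    if (explicit) {
      if (vr %in% .long_vrs) {
        len <- .u32(raw, off + 8); hdr <- 12L
      } else {
        len <- .u16(raw, off + 6); hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- .u32(raw, off + 4); hdr <- 8L
    }
    body_off <- off + hdr
    if (body_off + len > n) stop("format error: truncated element in ", path)
    body <- raw[(body_off + 1):(body_off + len)]
    if (grp == 0x7fe0 && el == 0x0010) {
      pixel <- body
    } else if (identical(vr, "US") || (is.na(vr) && len == 2 && grp == 0x0028)) {
      tags[[key]] <- .u16(body, 0)
    } else {
      tags[[key]] <- trimws(rawToChar(body))
    }
    off <- body_off + len
  }
  list(tags = tags, pixel = pixel, path = path)
}

dicom_numeric <- function(parsed, key) {
  v <- parsed$tags[[key]]
  if (is.null(v)) return(NULL)
  as.numeric(strsplit(as.character(v), "\\\\")[[1]])
}

#' Read a DICOM series directory as a CT volume
#'
#' Parses every `.dcm` file, checks grid consistency, applies
#' `HU = slope * stored + intercept`, and sorts slices by the z component
#' of Image Position (Patient), falling back to Instance Number.
#'
#' @param dir directory of single-frame DICOM files.
#' @param slice_levels optional per-slice level annotation.
#' @return a [ct_volume()].
#' @export
read_dicom_series <- function(dir, slice_levels = NULL) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0) stop("format error: no DICOM files in ", dir)
  parsed <- lapply(files, parse_dicom)
  dims <- vapply(parsed, function(p) {
    c(p$tags[["0028,0010"]], p$tags[["0028,0011"]])
  }, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("format error: mixed series (inconsistent dimensions) in ", dir)
  }
  zpos <- vapply(parsed, function(p) {
    ipp <- dicom_numeric(p, "0020,0032")
    if (!is.null(ipp) && length(ipp) == 3) return(ipp[3])
    inst <- dicom_numeric(p, "0020,0013")
    if (!is.null(inst)) return(inst)
    NA_real_
  }, 0)
  parsed <- parsed[order(zpos)]
  rows <- dims[1, 1]; cols <- dims[2, 1]
  slices <- lapply(parsed, function(p) {
    slope <- dicom_numeric(p, "0028,1053")
    inter <- dicom_numeric(p, "0028,1052")
    if (is.null(slope) || is.null(inter)) {
      stop("format error: missing rescale slope/intercept in ", p$path)
    }
    signed <- identical(p$tags[["0028,0103"]], 1L)
    stored <- readBin(p$pixel, "integer", n = rows * cols, size = 2,
                      signed = signed, endian = "little")
    if (!signed) stored[stored < 0] <- stored[stored < 0] + 65536
    matrix(slope * stored + inter, rows, cols, byrow = TRUE)
  })
  spacing <- dicom_numeric(parsed[[1]], "0028,0030")
  if (is.null(spacing)) spacing <- c(1, 1)
  ct_volume(array(unlist(slices), c(rows, cols, length(slices))),
            spacing = c(spacing, 10), slice_levels = slice_levels)
}

.dcm_element <- function(grp, el, vr, body) {
  if (length(body) %% 2 == 1) {
    body <- c(body, as.raw(if (vr %in% c("UI")) 0L else 0x20))
  }
  tag <- writeBin(as.integer(c(grp, el)), raw(), size = 2,
                  endian = "little")
  if (vr %in% .long_vrs) {
    c(tag, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(body), raw(), size = 4, endian = "little"), body)
  } else {
    c(tag, charToRaw(vr),
      writeBin(length(body), raw(), size = 2, endian = "little"), body)
  }
}

.dcm_str <- function(grp, el, vr, value) {
  .dcm_element(grp, el, vr, charToRaw(paste(value, collapse = "\\")))
}
.dcm_us <- function(grp, el, value) {
  .dcm_element(grp, el, "US",
               writeBin(as.integer(value), raw(), size = 2,
                        endian = "little"))
}

#' Write one synthetic DICOM slice (explicit VR little endian)
#'
#' Fixture writer: stores the slice as signed 16-bit with the given
#' rescale so that `HU = slope * stored + intercept`. Only the tags the
#' package reader consumes are emitted.
#'
#' @param slice numeric matrix in HU.
#' @param path output `.dcm` path.
#' @param slope,intercept rescale parameters.
#' @param instance instance number (z order).
#' @param spacing in-plane pixel spacing (mm).
#' @export
write_dicom_slice <- function(slice, path, slope = 1, intercept = -1024,
                              instance = 1, spacing = c(1, 1)) {
  stored <- as.integer(round((slice - intercept) / slope))
  if (any(stored < -32768 | stored > 32767)) stop("stored values overflow int16")
  # row-major pixel order, as the reader expects
  pix <- writeBin(as.integer(t(matrix(stored, nrow(slice), ncol(slice)))),
                  raw(), size = 2, endian = "little")
  body <- c(
    .dcm_str(0x0008, 0x0060, "CS", "CT"),
    .dcm_str(0x0020, 0x0013, "IS", as.character(instance)),
    .dcm_str(0x0020, 0x0032, "DS",
             c("0", "0", as.character(instance * 10))),
    .dcm_us(0x0028, 0x0010, nrow(slice)),
    .dcm_us(0x0028, 0x0011, ncol(slice)),
    .dcm_str(0x0028, 0x0030, "DS", as.character(spacing)),
    .dcm_us(0x0028, 0x0100, 16), .dcm_us(0x0028, 0x0101, 16),
    .dcm_us(0x0028, 0x0103, 1),
    .dcm_str(0x0028, 0x1052, "DS", as.character(intercept)),
    .dcm_str(0x0028, 0x1053, "DS", as.character(slope)),
    .dcm_element(0x7fe0, 0x0010, "OW", pix))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(body, con)
  invisible(path)
}
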