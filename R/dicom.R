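# Minimal single-frame DICOM series I/O (explicit/implicit VR little endian,
# uncompressed). No DICOM package is available in the target environment, so
# the small subset of the standard needed for CBCT slice series is
# implemented here: preamble + DICM magic, file meta group, and the
# geometry/pixel attributes the pipeline requires. Compressed transfer
# syntaxes are out of scope.

EXPLICIT_LE <- "1.2.840.10008.1.2.1"
IMPLICIT_LE <- "1.2.840.10008.1.2"
CT_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.2"
UID_ROOT <- "1.2.826.0.1.3680043.10.474"

uint16_le <- function(x) {
  x <- as.integer(round(x))
  as.raw(as.vector(rbind(x %% 256L, x %/% 256L)))
}
uint32_le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}
pad_even <- function(r, pad = as.raw(0L)) {
  if (length(r) %% 2L == 1L) c(r, pad) else r
}

# one explicit-VR element
dcm_element <- function(group, elem, vr, value_raw) {
  head <- c(uint16_le(group), uint16_le(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0L, 0L)), uint32_le(length(value_raw)), value_raw)
  } else {
    if (length(value_raw) > 65534) stop("value too long for short VR")
    c(head, uint16_le(length(value_raw)), value_raw)
  }
}
dcm_str <- function(group, elem, vr, s) {
  pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
  dcm_element(group, elem, vr, pad_even(charToRaw(s), pad))
}
dcm_us <- function(group, elem, x) dcm_element(group, elem, "US", uint16_le(x))

# Write one slice as a DICOM Part-10 file.
write_dicom_slice <- function(path, pixels, row_spacing, col_spacing,
                              slice_thickness, z_mm, instance_number,
                              series_uid, study_uid, bits_stored = 16L) {
  rows <- nrow(pixels); cols <- ncol(pixels)
  sop_uid <- paste(series_uid, instance_number, sep = ".")
  fmt <- function(x) sub("0+$", "", sub("\\.$", ".0", sprintf("%.10f", x)))
  ds <- c(
    dcm_str(0x0008, 0x0016, "UI", CT_SOP_CLASS),
    dcm_str(0x0008, 0x0018, "UI", sop_uid),
    dcm_str(0x0008, 0x0060, "CS", "CT"),
    dcm_str(0x0020, 0x000D, "UI", study_uid),
    dcm_str(0x0020, 0x000E, "UI", series_uid),
    dcm_str(0x0020, 0x0013, "IS", as.character(instance_number)),
    dcm_str(0x0020, 0x0032, "DS", paste(0, 0, fmt(z_mm), sep = "\\")),
    dcm_str(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
    dcm_str(0x0018, 0x0050, "DS", fmt(slice_thickness)),
    dcm_us(0x0028, 0x0002, 1L),
    dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_us(0x0028, 0x0010, rows),
    dcm_us(0x0028, 0x0011, cols),
    dcm_str(0x0028, 0x0030, "DS", paste(fmt(row_spacing), fmt(col_spacing),
                                        sep = "\\")),
    dcm_us(0x0028, 0x0100, 16L),
    dcm_us(0x0028, 0x0101, bits_stored),
    dcm_us(0x0028, 0x0102, bits_stored - 1L),
    dcm_us(0x0028, 0x0103, 0L),
    dcm_element(0x7FE0, 0x0010, "OW",
                uint16_le(as.vector(t(pixels))))  # row-major pixel order
  )
  meta <- c(
    dcm_str(0x0002, 0x0002, "UI", CT_SOP_CLASS),
    dcm_str(0x0002, 0x0003, "UI", sop_uid),
    dcm_str(0x0002, 0x0010, "UI", EXPLICIT_LE)
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", uint32_le(length(meta))), meta)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0L), 128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

read_uint16 <- function(r, i) as.integer(r[i]) + 256L * as.integer(r[i + 1L])
read_uint32 <- function(r, i) {
  as.numeric(r[i]) + 256 * as.numeric(r[i + 1L]) +
    65536 * as.numeric(r[i + 2L]) + 16777216 * as.numeric(r[i + 3L])
}

# Parse a single-frame DICOM file into a named list of raw element values
# keyed "GGGG,EEEE". Handles explicit and implicit VR little endian.
parse_dicom_file <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stop(sprintf("not a DICOM part-10 file: %s", path), call. = FALSE)
  pos <- 133L
  elements <- list()
  explicit <- TRUE       # file meta group is always explicit
  ts <- EXPLICIT_LE
  meta_end <- Inf
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= length(r)) {
    if (pos >= meta_end && !identical(ts, EXPLICIT_LE))
      explicit <- FALSE
    group <- read_uint16(r, pos); elem <- read_uint16(r, pos + 2L)
    if (explicit) {
      vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- read_uint32(r, pos + 8L); vstart <- pos + 12L
      } else {
        len <- read_uint16(r, pos + 6L); vstart <- pos + 8L
      }
    } else {
      len <- read_uint32(r, pos + 4L); vstart <- pos + 8L
    }
    if (len > length(r) - vstart + 1L)
      stop(sprintf("truncated DICOM element in %s", path), call. = FALSE)
    key <- sprintf("%04X,%04X", group, elem)
    val <- if (len > 0) r[vstart:(vstart + len - 1L)] else raw(0)
    elements[[key]] <- val
    if (key == "0002,0000") meta_end <- vstart + len + read_uint32(val, 1L)
    if (key == "0002,0010")
      ts <- trimws(rawToChar(val[val != as.raw(0L)]))
    pos <- vstart + len
  }
  if (!ts %in% c(EXPLICIT_LE, IMPLICIT_LE))
    stop(sprintf("unsupported transfer syntax %s (only uncompressed little endian)", ts),
         call. = FALSE)
  elements
}

el_str <- function(el, key) {
  v <- el[[key]]
  if (is.null(v)) return(NULL)
  trimws(rawToChar(v[v != as.raw(0L)]))
}
el_nums <- function(el, key) {
  s <- el_str(el, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
el_us <- function(el, key) {
  v <- el[[key]]
  if (is.null(v)) return(NULL)
  read_uint16(v, 1L)
}

#' Load a DICOM series as a volume stack
#'
#' Reads all single-frame DICOM slice files in `directory`, sorts them by
#' spatial position along the scan axis (image position patient; instance
#' number as fallback), and assembles them into a [volume_stack()]. The
#' voxel size is taken from the pixel-spacing attribute and the spacing
#' between consecutive slice positions (falling back to the slice-thickness
#' attribute for a single slice). Grey values are preserved at the source
#' bit depth.
#'
#' @param directory path containing the slice files of exactly one series.
#' @return A [volume_stack()]; slice 1 is the slice with the smallest
#'   position along the scan axis.
#' @seealso [write_fixture()] to generate a readable synthetic series.
#' @export
load_dicom_series <- function(directory) {
  if (!dir.exists(directory))
    stop(sprintf("no such directory: %s", directory), call. = FALSE)
  files <- list.files(directory, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0)
    files <- Filter(function(f) !dir.exists(f),
                    list.files(directory, full.names = TRUE))
  if (length(files) == 0)
    stop(sprintf("no DICOM files in %s", directory), call. = FALSE)

  parsed <- lapply(files, parse_dicom_file)
  series <- vapply(parsed, function(el) {
    s <- el_str(el, "0020,000E"); if (is.null(s)) "" else s
  }, "")
  if (length(unique(series)) > 1)
    stop("directory mixes multiple DICOM series", call. = FALSE)

  info <- lapply(parsed, function(el) {
    spacing <- el_nums(el, "0028,0030")
    rows <- el_us(el, "0028,0010"); cols <- el_us(el, "0028,0011")
    if (is.null(spacing) || length(spacing) != 2 || any(!is.finite(spacing)) ||
        any(spacing <= 0) || is.null(rows) || is.null(cols))
      stop("DICOM slice lacks valid pixel spacing or dimensions", call. = FALSE)
    bits_alloc <- el_us(el, "0028,0100"); if (is.null(bits_alloc)) bits_alloc <- 16L
    bits_stored <- el_us(el, "0028,0101"); if (is.null(bits_stored)) bits_stored <- bits_alloc
    ipp <- el_nums(el, "0020,0032")
    z <- if (!is.null(ipp) && length(ipp) == 3) ipp[3] else NA_real_
    inst <- el_nums(el, "0020,0013")
    px <- el[["7FE0,0010"]]
    if (is.null(px)) stop("DICOM slice has no pixel data", call. = FALSE)
    vals <- if (bits_alloc == 16L) {
      readBin(px, "integer", n = length(px) / 2L, size = 2L,
              signed = FALSE, endian = "little")
    } else {
      as.integer(px)
    }
    if (length(vals) != rows * cols)
      stop("DICOM pixel data does not match Rows x Columns", call. = FALSE)
    list(m = matrix(vals, nrow = rows, byrow = TRUE), spacing = spacing,
         z = z, inst = if (is.null(inst)) NA_real_ else inst[1],
         thick = el_nums(el, "0018,0050"), bits = bits_stored)
  })

  spc <- vapply(info, function(i) i$spacing, numeric(2))
  if (any(abs(spc - spc[, 1]) > 1e-9))
    stop("contradictory pixel spacing across slices", call. = FALSE)
  dims <- vapply(info, function(i) dim(i$m), integer(2))
  if (any(dims != dims[, 1]))
    stop("slices have differing dimensions", call. = FALSE)

  z <- vapply(info, function(i) i$z, 0)
  ord <- if (all(is.finite(z))) order(z) else
    order(vapply(info, function(i) i$inst, 0))
  info <- info[ord]
  z <- z[ord]

  n <- length(info)
  if (n > 1 && all(is.finite(z))) {
    dz <- diff(z)
    if (any(dz <= 0) || any(abs(dz - dz[1]) > 1e-6))
      stop("contradictory slice positions (non-uniform spacing)", call. = FALSE)
    thick <- dz[1]
  } else {
    th <- info[[1]]$thick
    if (is.null(th) || !is.finite(th[1]) || th[1] <= 0)
      stop("cannot determine slice thickness from metadata", call. = FALSE)
    thick <- th[1]
  }

  vox <- array(0, c(n, nrow(info[[1]]$m), ncol(info[[1]]$m)))
  for (i in seq_len(n)) vox[i, , ] <- info[[i]]$m
  volume_stack(vox,
               voxel_size = c(thick, info[[1]]$spacing[1], info[[1]]$spacing[2]),
               bit_depth = info[[1]]$bits,
               axial_direction = "apical",
               provenance = sprintf("load_dicom_series[%d slices]", n))
}

# Write a volume stack as a DICOM series (one file per axial slice).
write_dicom_series <- function(stack, directory, series_number = 1L) {
  stopifnot(inherits(stack, "volume_stack"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  d <- dim(stack$voxels)
  series_uid <- paste(UID_ROOT, "2", series_number, sep = ".")
  study_uid <- paste(UID_ROOT, "1.1", sep = ".")
  for (i in seq_len(d[1])) {
    write_dicom_slice(
      file.path(directory, sprintf("slice_%04d.dcm", i)),
      pixels = stack$voxels[i, , ],
      row_spacing = stack$voxel_size[2], col_spacing = stack$voxel_size[3],
      slice_thickness = stack$voxel_size[1],
      z_mm = (i - 1) * stack$voxel_size[1],
      instance_number = i, series_uid = series_uid, study_uid = study_uid,
      bits_stored = as.integer(stack$bit_depth))
  }
  invisible(directory)
}
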