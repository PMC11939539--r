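# Minimal classic (little endian) multi-page 8-bit grayscale TIFF I/O,
# uncompressed — the interchange format of the workflow. A JSON sidecar
# (<path>.json) carries the voxel size and provenance, since baseline TIFF
# has no reliable 3D voxel metadata; on read the caller-supplied voxel size
# is authoritative and wins over the sidecar (the "verify and readjust"
# step of the workflow).

tiff_ifd_entry <- function(tag, type, count, value) {
  # type 3 = SHORT, 4 = LONG; value fits inline (count 1)
  inline <- if (type == 3L) c(uint16_le(value), as.raw(c(0L, 0L)))
            else uint32_le(value)
  c(uint16_le(tag), uint16_le(type), uint32_le(count), inline)
}

#' Write a volume stack as a multi-page 8-bit grayscale TIFF
#'
#' Pages are axial slices in stack order. A JSON sidecar `<path>.json`
#' records voxel size, bit depth, axial direction and provenance so the
#' stack round-trips through [read_tiff_stack()].
#'
#' @param stack an 8-bit [volume_stack()] (see [normalize_to_8bit()]).
#' @param path output file path (conventionally `.tif`).
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(stack, path) {
  stopifnot(inherits(stack, "volume_stack"))
  v <- stack$voxels
  if (min(v) < 0 || max(v) > 255)
    stop("write_tiff_stack() requires an 8-bit stack in [0, 255]; run normalize_to_8bit() first",
         call. = FALSE)
  d <- dim(v)
  n_slices <- d[1]; h <- d[2]; w <- d[3]
  strip_len <- h * w
  n_entries <- 9L
  ifd_size <- 2 + 12 * n_entries + 4
  # layout: 8-byte header, then per page [pixel strip][IFD]
  data_off <- function(i) 8 + (i - 1) * (strip_len + ifd_size)
  ifd_off <- function(i) data_off(i) + strip_len
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), uint16_le(42L), uint32_le(ifd_off(1))), con)
  for (i in seq_len(n_slices)) {
    writeBin(as.raw(as.vector(t(v[i, , ]))), con)  # row-major strip
    entries <- c(
      tiff_ifd_entry(256L, 4L, 1L, w),            # ImageWidth
      tiff_ifd_entry(257L, 4L, 1L, h),            # ImageLength
      tiff_ifd_entry(258L, 3L, 1L, 8L),           # BitsPerSample
      tiff_ifd_entry(259L, 3L, 1L, 1L),           # Compression: none
      tiff_ifd_entry(262L, 3L, 1L, 1L),           # Photometric: BlackIsZero
      tiff_ifd_entry(273L, 4L, 1L, data_off(i)),  # StripOffsets
      tiff_ifd_entry(277L, 3L, 1L, 1L),           # SamplesPerPixel
      tiff_ifd_entry(278L, 4L, 1L, h),            # RowsPerStrip
      tiff_ifd_entry(279L, 4L, 1L, strip_len))    # StripByteCounts
    next_ifd <- if (i < n_slices) ifd_off(i + 1) else 0
    writeBin(c(uint16_le(n_entries), entries, uint32_le(next_ifd)), con)
  }
  jsonlite::write_json(
    list(voxel_size = stack$voxel_size, bit_depth = stack$bit_depth,
         axial_direction = stack$axial_direction,
         provenance = stack$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page grayscale TIFF as a volume stack
#'
#' Since TIFF itself carries no trustworthy voxel size, the caller-supplied
#' `voxel_size` is authoritative: when it conflicts with the JSON sidecar
#' written by [write_tiff_stack()], the caller value wins and the override is
#' recorded in the provenance. With no sidecar and no caller value the read
#' fails rather than guessing.
#'
#' @param path TIFF file written by [write_tiff_stack()] (or any
#'   uncompressed little-endian 8-bit grayscale multi-page TIFF).
#' @param voxel_size optional numeric length-3 `(slice, row, col)` in mm.
#' @return A [volume_stack()].
#' @export
read_tiff_stack <- function(path, voxel_size = NULL) {
  if (!file.exists(path))
    stop(sprintf("cannot read TIFF: no such file %s", path), call. = FALSE)
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 8 || rawToChar(r[1:2]) != "II" || read_uint16(r, 3L) != 42L)
    stop(sprintf("not a little-endian TIFF: %s", path), call. = FALSE)

  read_value <- function(type, count, field_at) {
    size <- if (type == 3L) 2L else 4L
    rd <- function(at) if (type == 3L) read_uint16(r, at) else read_uint32(r, at)
    if (count * size <= 4L) {
      vapply(seq_len(count), function(k) rd(field_at + (k - 1L) * size), 0)
    } else {
      off <- read_uint32(r, field_at)
      vapply(seq_len(count), function(k) rd(off + 1L + (k - 1L) * size), 0)
    }
  }

  pages <- list()
  ifd <- read_uint32(r, 5L)
  while (ifd != 0) {
    n <- read_uint16(r, ifd + 1L)
    tags <- list()
    for (e in seq_len(n)) {
      at <- ifd + 3L + (e - 1L) * 12L
      tag <- read_uint16(r, at); type <- read_uint16(r, at + 2L)
      count <- read_uint32(r, at + 4L)
      tags[[as.character(tag)]] <- read_value(type, count, at + 8L)
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    if (!identical(g(259L, 1)[1], 1)) stop("compressed TIFF not supported", call. = FALSE)
    if (!identical(g(258L, 8)[1], 8)) stop("only 8-bit grayscale TIFF supported", call. = FALSE)
    w <- g(256L); h <- g(257L)
    offs <- g(273L); counts <- g(279L, h * w)
    bytes <- unlist(lapply(seq_along(offs), function(k)
      as.integer(r[(offs[k] + 1L):(offs[k] + counts[k])])))
    pages[[length(pages) + 1L]] <- matrix(bytes, nrow = h, byrow = TRUE)
    ifd <- read_uint32(r, ifd + 3L + n * 12L)
  }
  if (length(pages) == 0) stop("TIFF contains no pages", call. = FALSE)

  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path))
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE) else NULL
  prov <- c(if (!is.null(sidecar)) as.character(sidecar$provenance),
            sprintf("read_tiff_stack[%d pages]", length(pages)))
  vs <- voxel_size
  if (is.null(vs)) {
    if (is.null(sidecar))
      stop("no voxel size: supply `voxel_size` (no sidecar metadata found)",
           call. = FALSE)
    vs <- as.numeric(sidecar$voxel_size)
  } else if (!is.null(sidecar) &&
             any(abs(as.numeric(sidecar$voxel_size) - as.numeric(vs)) > 1e-12)) {
    prov <- c(prov, sprintf("voxel_size readjusted to %s (sidecar said %s)",
                            paste(vs, collapse = "x"),
                            paste(sidecar$voxel_size, collapse = "x")))
  }
  vox <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) vox[i, , ] <- pages[[i]]
  volume_stack(vox, voxel_size = vs, bit_depth = 8L,
               axial_direction = if (!is.null(sidecar) &&
                                     !is.null(sidecar$axial_direction))
                 sidecar$axial_direction else "apical",
               provenance = prov)
}
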