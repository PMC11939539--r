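#' Region-of-interest specification
#'
#' Describes how a raw CBCT stack is reduced to the socket region: which
#' axial slices to keep, the axial crop rectangle, and an in-plane rotation
#' (applied after cropping, about the rectangle center) that brings the
#' socket and adjacent teeth onto a vertical axis. The same `roi_spec` is
#' applied to both timepoints so measurements share one frame; it
#' serializes to YAML/JSON via [write_roi_spec()].
#'
#' All indices are 1-based and inclusive.
#'
#' @param slice_first,slice_last first/last axial slice to keep.
#' @param row0,col0 top-left corner of the crop rectangle.
#' @param height,width crop rectangle extents in voxels.
#' @param rotation_deg in-plane rotation in degrees, in (-180, 180].
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(slice_first, slice_last, row0, col0, height, width,
                     rotation_deg = 0) {
  if (slice_first < 1 || slice_last < slice_first)
    stop("invalid slice range", call. = FALSE)
  if (row0 < 1 || col0 < 1 || height < 1 || width < 1)
    stop("invalid crop rectangle", call. = FALSE)
  if (!is.finite(rotation_deg) || rotation_deg <= -180 || rotation_deg > 180)
    stop("rotation_deg must lie in (-180, 180]", call. = FALSE)
  structure(list(slice_first = as.integer(slice_first),
                 slice_last = as.integer(slice_last),
                 row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width),
                 rotation_deg = as.numeric(rotation_deg)),
            class = "roi_spec")
}

#' @rdname roi_spec
#' @param spec a `roi_spec`.
#' @param path file path; `.yaml`/`.yml` writes YAML, anything else JSON.
#' @export
write_roi_spec <- function(spec, path) {
  stopifnot(inherits(spec, "roi_spec"))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(unclass(spec), path)
  } else {
    jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname roi_spec
#' @export
read_roi_spec <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  roi_spec(x$slice_first, x$slice_last, x$row0, x$col0, x$height, x$width,
           if (is.null(x$rotation_deg)) 0 else x$rotation_deg)
}

#' Keep a contiguous range of axial slices
#'
#' Removes irrelevant apical and coronal regions (opposing jaw, sinus floor)
#' while retaining the slices containing the socket and adjacent teeth.
#'
#' @param stack a [volume_stack()].
#' @param first,last 1-based inclusive axial indices.
#' @return A `volume_stack` of depth `last - first + 1`; voxel values
#'   unchanged.
#' @export
keep_slices <- function(stack, first, last) {
  stopifnot(inherits(stack, "volume_stack"))
  depth <- dim(stack$voxels)[1]
  if (first < 1 || last > depth || first > last)
    stop(sprintf("slice range [%d, %d] out of bounds for depth %d",
                 first, last, depth), call. = FALSE)
  stack$voxels <- stack$voxels[first:last, , , drop = FALSE]
  stack_record(stack, sprintf("keep_slices[%d..%d]", first, last))
}

# Rotate a 2D matrix by `deg` about `center` (row, col), bilinear, zero fill.
# cospi/sinpi make quarter turns exact index permutations.
rotate_slice <- function(m, deg, center = (dim(m) + 1) / 2) {
  h <- nrow(m); w <- ncol(m)
  ct <- cospi(deg / 180); st <- sinpi(deg / 180)
  out_r <- matrix(seq_len(h), h, w) - center[1]
  out_c <- matrix(seq_len(w), h, w, byrow = TRUE) - center[2]
  src_r <- center[1] + ct * out_r - st * out_c
  src_c <- center[2] + st * out_r + ct * out_c
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  val <- function(rr, cc) {
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    v <- numeric(length(rr))
    v[ok] <- m[cbind(rr[ok], cc[ok])]
    v
  }
  out <- (1 - fr) * (1 - fc) * val(r0, c0) +
         (1 - fr) * fc       * val(r0, c0 + 1) +
         fr       * (1 - fc) * val(r0 + 1, c0) +
         fr       * fc       * val(r0 + 1, c0 + 1)
  matrix(out, h, w)
}

#' Crop a stack to an ROI and rotate it in-plane
#'
#' Applies the `roi_spec` in full: keeps the slice range, crops the axial
#' rectangle, and rotates every axial slice by `rotation_deg` about the
#' rectangle center (bilinear interpolation, out-of-support samples filled
#' with 0). The transform is rigid in-plane, so the voxel size is unchanged.
#'
#' @param stack a [volume_stack()].
#' @param roi a [roi_spec()].
#' @return A `volume_stack` with dimensions equal to the ROI extents.
#' @export
crop_rotate <- function(stack, roi) {
  stopifnot(inherits(stack, "volume_stack"), inherits(roi, "roi_spec"))
  d <- dim(stack$voxels)
  if (roi$slice_last > d[1] ||
      roi$row0 + roi$height - 1 > d[2] ||
      roi$col0 + roi$width - 1 > d[3])
    stop("roi_spec exceeds stack bounds", call. = FALSE)
  if (roi$rotation_deg != 0 &&
      abs(stack$voxel_size[2] - stack$voxel_size[3]) > 1e-9)
    stop("in-plane rotation requires square in-plane voxels", call. = FALSE)
  sub <- stack$voxels[roi$slice_first:roi$slice_last,
                      roi$row0:(roi$row0 + roi$height - 1),
                      roi$col0:(roi$col0 + roi$width - 1), drop = FALSE]
  if (roi$rotation_deg != 0) {
    for (i in seq_len(dim(sub)[1]))
      sub[i, , ] <- rotate_slice(sub[i, , ], roi$rotation_deg)
  }
  stack$voxels <- sub
  stack_record(stack,
               sprintf("crop_rotate[slices %d..%d, rect (%d,%d)+%dx%d, rot %g deg]",
                       roi$slice_first, roi$slice_last, roi$row0, roi$col0,
                       roi$height, roi$width, roi$rotation_deg))
}

ncc_score <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(if (isTRUE(all.equal(a, b))) 1 else 0)
  stats::cor(a, b)
}

#' Align the follow-up scan to the cropped baseline reference
#'
#' Applies the baseline `roi_spec` to the raw follow-up volume and refines
#' the placement by an exhaustive integer-voxel rigid translation search
#' maximizing normalized cross-correlation (NCC) with the reference. The
#' search is brute force over the configured radius — the cropped volumes
#' are small, and exhaustive search is exactly reproducible. Rotation is not
#' refined (timepoint rotational discrepancies are assumed minimal once the
#' shared ROI rotation is applied); the NCC score is returned so alignment
#' quality can be judged.
#'
#' When `roi$rotation_deg != 0` the search operates in the rotated reference
#' frame: the padded follow-up crop is rotated once and candidate windows are
#' shifted within it, so the reported translation is expressed in reference
#' coordinates.
#'
#' @param reference the cropped+rotated baseline `volume_stack` (output of
#'   [crop_rotate()]).
#' @param followup_raw the raw follow-up `volume_stack` (same voxel size).
#' @param roi the [roi_spec()] that produced `reference`.
#' @param search_radius_voxels integer length-3 `(axial, row, col)` search
#'   radius; default `c(3, 10, 10)`.
#' @param score_floor NCC below which the result is flagged as questionable.
#' @return A list with `stack` (aligned follow-up, same dimensions as the
#'   reference) and `result` (`translation_voxels`, `score`,
#'   `quality_warning`).
#' @export
align_followup <- function(reference, followup_raw, roi,
                           search_radius_voxels = c(3L, 10L, 10L),
                           score_floor = 0.5) {
  stopifnot(inherits(reference, "volume_stack"),
            inherits(followup_raw, "volume_stack"),
            inherits(roi, "roi_spec"))
  if (any(abs(reference$voxel_size - followup_raw$voxel_size) > 1e-9))
    stop("voxel sizes of the two timepoints differ; resample before aligning",
         call. = FALSE)
  d <- dim(followup_raw$voxels)
  rad <- as.integer(rep_len(search_radius_voxels, 3L))

  # padded crop: rect grown by the in-plane radius, slice range by the axial
  # radius, clipped to the volume
  pad_lo <- c(min(rad[1], roi$slice_first - 1L),
              min(rad[2], roi$row0 - 1L),
              min(rad[3], roi$col0 - 1L))
  pad_hi <- c(min(rad[1], d[1] - roi$slice_last),
              min(rad[2], d[2] - (roi$row0 + roi$height - 1L)),
              min(rad[3], d[3] - (roi$col0 + roi$width - 1L)))
  pad <- followup_raw$voxels[
    (roi$slice_first - pad_lo[1]):(roi$slice_last + pad_hi[1]),
    (roi$row0 - pad_lo[2]):(roi$row0 + roi$height - 1L + pad_hi[2]),
    (roi$col0 - pad_lo[3]):(roi$col0 + roi$width - 1L + pad_hi[3]),
    drop = FALSE]
  if (roi$rotation_deg != 0) {
    # rotate once about the unshifted rect center inside the padded array
    center <- c(pad_lo[2] + (roi$height + 1) / 2,
                pad_lo[3] + (roi$width + 1) / 2)
    for (i in seq_len(dim(pad)[1]))
      pad[i, , ] <- rotate_slice(pad[i, , ], roi$rotation_deg, center = center)
  }

  ref <- reference$voxels
  best <- list(score = -Inf, t = c(0L, 0L, 0L))
  for (dz in -pad_lo[1]:pad_hi[1])
    for (dy in -pad_lo[2]:pad_hi[2])
      for (dx in -pad_lo[3]:pad_hi[3]) {
        cand <- pad[(pad_lo[1] + 1L + dz):(pad_lo[1] + dim(ref)[1] + dz),
                    (pad_lo[2] + 1L + dy):(pad_lo[2] + dim(ref)[2] + dy),
                    (pad_lo[3] + 1L + dx):(pad_lo[3] + dim(ref)[3] + dx),
                    drop = FALSE]
        s <- ncc_score(ref, cand)
        if (s > best$score) best <- list(score = s, t = c(dz, dy, dx))
      }

  t <- best$t
  aligned <- followup_raw
  aligned$voxels <- pad[(pad_lo[1] + 1L + t[1]):(pad_lo[1] + dim(ref)[1] + t[1]),
                        (pad_lo[2] + 1L + t[2]):(pad_lo[2] + dim(ref)[2] + t[2]),
                        (pad_lo[3] + 1L + t[3]):(pad_lo[3] + dim(ref)[3] + t[3]),
                        drop = FALSE]
  aligned <- stack_record(aligned,
                          sprintf("align_followup[shift (%d,%d,%d), ncc %.4f]",
                                  t[1], t[2], t[3], best$score))
  list(stack = aligned,
       result = list(translation_voxels = t, score = best$score,
                     quality_warning = best$score < score_floor))
}
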