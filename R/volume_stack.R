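#' ridgewidth: semi-automated CBCT measurement of alveolar ridge width change
#'
#' The package implements a peak-based, semi-automated workflow for
#' quantifying how the width of the alveolar ridge changes between a
#' post-extraction CBCT scan and a pre-implantation follow-up: volume I/O
#' ([load_dicom_series()], [write_tiff_stack()]), region-of-interest
#' preprocessing and rigid alignment ([crop_rotate()], [align_followup()]),
#' construction of the 15-position measurement grid from one user-drawn
#' crestal line ([build_grid()]), grey-value profile width measurement
#' ([measure_grid()]), longitudinal change and agreement statistics
#' ([width_change()], [icc()], [bland_altman()], [sample_size_ttest()]),
#' and a synthetic socket phantom with known ground truth
#' ([generate_phantom()]).
#'
#' @keywords internal
"_PACKAGE"

#' Construct a CBCT volume stack
#'
#' A `volume_stack` is the container every imaging stage of the pipeline
#' consumes and produces: a 3D array of grey values plus the physical voxel
#' size and a provenance trail of applied transforms.
#'
#' Axis convention: `voxels[slice, row, col]`. Slice 1 is the most
#' crestal/coronal slice retained; when `axial_direction = "apical"`
#' (the default) the slice index increases apically. In-plane mm coordinates
#' are `x = (col - 1) * col_spacing`, `y = (row - 1) * row_spacing`, i.e. the
#' center of voxel `(1, 1, 1)` is the mm origin.
#'
#' @param voxels 3D numeric array, `slices x rows x cols`.
#' @param voxel_size numeric length-3: `(slice_thickness_mm, row_spacing_mm,
#'   col_spacing_mm)`, all strictly positive.
#' @param bit_depth source bit depth of the grey values (e.g. 8, 12, 16).
#' @param axial_direction `"apical"` if the slice index increases apically,
#'   `"coronal"` otherwise.
#' @param provenance character vector of transforms already applied.
#' @return An object of class `volume_stack`.
#' @examples
#' v <- volume_stack(array(0, c(4, 8, 8)), voxel_size = c(0.15, 0.15, 0.15))
#' dim(v$voxels)
#' @export
volume_stack <- function(voxels, voxel_size, bit_depth = 8L,
                         axial_direction = c("apical", "coronal"),
                         provenance = character()) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array (slices x rows x cols)", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be 3 strictly positive values (mm)", call. = FALSE)
  axial_direction <- match.arg(axial_direction)
  structure(
    list(voxels = voxels,
         voxel_size = voxel_size,
         bit_depth = as.integer(bit_depth),
         axial_direction = axial_direction,
         provenance = as.character(provenance)),
    class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume_stack> %d slices x %d rows x %d cols\n", d[1], d[2], d[3]))
  cat(sprintf("  voxel size (mm): %g x %g x %g (slice x row x col)\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  bit depth: %d, slice index increases: %s\n",
              x$bit_depth, x$axial_direction))
  cat(sprintf("  grey range: [%g, %g]\n", min(x$voxels), max(x$voxels)))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

# append one provenance entry; provenance never shrinks
stack_record <- function(stack, entry) {
  stack$provenance <- c(stack$provenance, entry)
  stack
}

# round half away from zero (base round() is banker's)
round_half_up <- function(x) floor(x + 0.5)

#' Standardize the grey-value range to 8 bit
#'
#' Linearly rescales the whole stack onto `[0, 255]` using the global
#' minimum and maximum (one window for all slices, so that slices remain
#' comparable and peak locations — which the width measurement depends on —
#' are preserved by the monotone map). Values are rounded half-up to
#' integers. A constant-valued stack maps to all zeros by convention.
#'
#' @param stack a [volume_stack()].
#' @return A `volume_stack` with `bit_depth = 8` and voxels in `[0, 255]`.
#' @examples
#' v <- volume_stack(array(c(0, 2048, 4095), c(3, 1, 1)),
#'                   c(0.15, 0.15, 0.15), bit_depth = 12)
#' normalize_to_8bit(v)$voxels[, 1, 1]  # 0 128 255
#' @export
normalize_to_8bit <- function(stack) {
  stopifnot(inherits(stack, "volume_stack"))
  lo <- min(stack$voxels)
  hi <- max(stack$voxels)
  if (hi > lo) {
    stack$voxels[] <- round_half_up((stack$voxels - lo) * (255 / (hi - lo)))
  } else {
    stack$voxels[] <- 0
  }
  stack$bit_depth <- 8L
  stack_record(stack, sprintf("normalize_to_8bit[window %g..%g]", lo, hi))
}
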