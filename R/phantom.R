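# Synthetic CBCT socket phantom: paired baseline/follow-up volumes of an
# alveolar ridge cross-section with known per-position widths and a
# programmable, crestally weighted resorption gradient. The ridge is
# modelled as the measurement method sees it — two bright cortical rim
# bands on a trabecular plateau with a low-intensity socket channel —
# because the width measurement reads exactly one wide line profile per
# position; anatomy beyond rim geometry adds nothing testable.

#' Specify a synthetic socket phantom
#'
#' Defaults describe a premolar-sized ridge at the scanner settings of the
#' motivating protocol: isotropic 0.15 mm voxels, a crestal width of 8.1 mm
#' flaring slightly apically, and a follow-up resorption gradient that is
#' maximal centrally and crestally and tapers laterally and apically
#' (central-crestal loss 2.1 mm). True rim positions and programmed losses
#' are multiples of the voxel pitch so that ground truth is representable on
#' the profile sampling grid. Loss is applied to the buccal rim and is
#' piecewise constant over 1 mm mesio-distal strips centered on the
#' measurement offsets.
#'
#' @param shape `(slices, rows, cols)`; default `c(44, 60, 100)`.
#' @param voxel_size_mm isotropic voxel size; default 0.15.
#' @param crestal_slice axial index of the crestal plane; default 5.
#' @param crestal_width_mm true rim-to-rim width at the crestal plane.
#' @param flare_per_mm apical widening rate (mm width per mm depth),
#'   quantized to the voxel grid per slice.
#' @param depth_targets_mm apical measurement depths; default `c(2.5, 5)`.
#' @param loss_mm 3 x 3 matrix of programmed follow-up width loss:
#'   rows = depth planes (crestal, first, second target), columns =
#'   `|offset|` 0, 1, 2 mm. Extended laterally by continuing the 1-2 mm
#'   step, clamped at 0.
#' @param intensity named list: `background`, `trabecular`, `rim_amp`
#'   (rim peak height above trabecular), `socket_dip` (depth of the socket
#'   channel below trabecular), on the 8-bit grey scale.
#' @param rim_sigma_mm Gaussian cross-profile sigma of a cortical rim.
#' @param ridge_margin_mm distance from a rim center to the outer edge of
#'   the trabecular plateau.
#' @param socket_sigma_mm `(x, y)` sigmas of the socket channel.
#' @param psf_sigma_mm in-plane partial-volume blur; default 0.1.
#' @param noise_sd additive Gaussian noise SD in 8-bit grey levels;
#'   default 5.
#' @param bit_depth stored bit depth of the emitted volumes; default 12
#'   (values are rescaled from the 8-bit model range, exercising the
#'   normalization step of the pipeline).
#' @param seed RNG seed fixing all randomness; default 1.
#' @return A validated `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(44L, 60L, 100L),
                         voxel_size_mm = 0.15,
                         crestal_slice = 5L,
                         crestal_width_mm = 8.1,
                         flare_per_mm = 0.12,
                         depth_targets_mm = c(2.5, 5.0),
                         loss_mm = rbind(c(2.1, 1.8, 1.5),
                                         c(0.9, 0.75, 0.6),
                                         c(0.45, 0.3, 0.15)),
                         intensity = list(background = 20, trabecular = 100,
                                          rim_amp = 120, socket_dip = 60),
                         rim_sigma_mm = 0.25,
                         ridge_margin_mm = 0.75,
                         socket_sigma_mm = c(0.8, 1.2),
                         psf_sigma_mm = 0.1,
                         noise_sd = 5,
                         bit_depth = 12L,
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L), voxel_size_mm > 0,
            crestal_width_mm > 0, is.matrix(loss_mm),
            nrow(loss_mm) == 1L + length(depth_targets_mm), ncol(loss_mm) == 3L)
  rim_peak <- intensity$trabecular + intensity$rim_amp
  socket <- intensity$trabecular - intensity$socket_dip
  if (!(rim_peak > intensity$trabecular && intensity$trabecular > socket &&
        socket >= intensity$background))
    stop("intensities must satisfy rim > trabecular > socket >= background",
         call. = FALSE)
  if (rim_peak > 255 || intensity$background < 0)
    stop("intensities must lie in [0, 255]", call. = FALSE)
  if (any(loss_mm < 0))
    stop("programmed losses must be non-negative", call. = FALSE)
  spec <- structure(
    list(shape = shape, voxel_size_mm = voxel_size_mm,
         crestal_slice = as.integer(crestal_slice),
         crestal_width_mm = crestal_width_mm, flare_per_mm = flare_per_mm,
         depth_targets_mm = depth_targets_mm, loss_mm = loss_mm,
         intensity = intensity, rim_sigma_mm = rim_sigma_mm,
         ridge_margin_mm = ridge_margin_mm,
         socket_sigma_mm = socket_sigma_mm, psf_sigma_mm = psf_sigma_mm,
         noise_sd = noise_sd, bit_depth = as.integer(bit_depth),
         seed = as.integer(seed)),
    class = "phantom_spec")
  tr <- phantom_truth(spec)
  if (any(tr$width_mm <= 0))
    stop("programmed loss leaves a non-positive width", call. = FALSE)
  spec
}

# ridge center in mm; y center sits on the voxel grid
phantom_center <- function(spec) {
  p <- spec$voxel_size_mm
  c(x = p * round((spec$shape[3] - 1) / 2),
    y = p * round((spec$shape[2] - 1) / 2))
}

# achieved depths of the apical measurement planes (same slice arithmetic
# as select_depth_slices)
phantom_plane_depths <- function(spec) {
  k <- ceiling(spec$depth_targets_mm / spec$voxel_size_mm - 0.5)
  k * spec$voxel_size_mm
}

# true width at a given depth below the crest, quantized to the voxel grid
phantom_width_at <- function(spec, depth_mm) {
  p <- spec$voxel_size_mm
  spec$crestal_width_mm + p * round_half_up(spec$flare_per_mm * depth_mm / p)
}

# programmed loss at mesio-distal position y (mm) and depth below crest:
# linear interpolation between the depth planes (constant beyond), lateral
# 1 mm strips centered on the offsets with the 1->2 mm step continued and
# clamped at 0, then snapped to the voxel grid
phantom_loss_at <- function(spec, y_mm, depth_mm, timepoint = "t1") {
  if (timepoint == "t0") return(0)
  p <- spec$voxel_size_mm
  yc <- phantom_center(spec)["y"]
  depths <- c(0, phantom_plane_depths(spec))
  by_off <- vapply(1:3, function(j) {
    stats::approx(depths, spec$loss_mm[, j], xout = min(depth_mm, max(depths)),
                  rule = 2)$y
  }, 0)
  s <- as.numeric(round_half_up(abs(y_mm - yc)))  # strip index = |offset| in mm
  v <- if (s <= 2) by_off[s + 1]
       else max(0, by_off[3] - (s - 2) * (by_off[2] - by_off[3]))
  as.numeric(p * round_half_up(v / p))
}

#' Ground-truth width table of a phantom
#'
#' True rim-to-rim width per (offset, depth level, timepoint) — by
#' construction, independent of seed, PSF and noise.
#'
#' @param spec a [phantom_spec()].
#' @return A data frame: `timepoint`, `offset_mm`, `depth_level`,
#'   `depth_below_crest_mm`, `width_mm`.
#' @export
phantom_truth <- function(spec) {
  depths <- c(0, phantom_plane_depths(spec))
  labels <- c("crestal", depth_level_label(spec$depth_targets_mm))
  yc <- phantom_center(spec)["y"]
  rows <- list()
  for (tp in c("t0", "t1"))
    for (i in seq_along(depths))
      for (off in c(-2, -1, 0, 1, 2)) {
        w <- phantom_width_at(spec, depths[i]) -
          phantom_loss_at(spec, yc + off, depths[i], tp)
        rows[[length(rows) + 1L]] <-
          data.frame(timepoint = tp, offset_mm = off, depth_level = labels[i],
                     depth_below_crest_mm = depths[i], width_mm = w,
                     stringsAsFactors = FALSE)
      }
  do.call(rbind, rows)
}

# separable Gaussian blur of a matrix; truncated kernel, renormalized at the
# edges so flat regions stay flat
blur_matrix <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  kmat <- function(n) {
    idx <- seq_len(n)
    k <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * sigma_px^2)))
    k[abs(outer(idx, idx, `-`)) > ceiling(4 * sigma_px)] <- 0
    k / rowSums(k)
  }
  kmat(nrow(m)) %*% m %*% t(kmat(ncol(m)))
}

render_phantom_slice <- function(spec, z, timepoint) {
  p <- spec$voxel_size_mm
  ctr <- phantom_center(spec)
  depth <- max(0, z - spec$crestal_slice) * p
  w <- phantom_width_at(spec, depth)
  x <- (seq_len(spec$shape[3]) - 1) * p
  ii <- spec$intensity
  out <- matrix(0, spec$shape[2], spec$shape[3])
  xr <- ctr["x"] + w / 2
  for (r in seq_len(spec$shape[2])) {
    y <- (r - 1) * p
    xl <- ctr["x"] - w / 2 + phantom_loss_at(spec, y, depth, timepoint)
    xs <- (xl + xr) / 2  # socket follows the resorbing ridge center
    v <- ii$background +
      (ii$trabecular - ii$background) *
        (x >= xl - spec$ridge_margin_mm & x <= xr + spec$ridge_margin_mm) +
      ii$rim_amp * exp(-(x - xl)^2 / (2 * spec$rim_sigma_mm^2)) +
      ii$rim_amp * exp(-(x - xr)^2 / (2 * spec$rim_sigma_mm^2)) -
      ii$socket_dip * exp(-(x - xs)^2 / (2 * spec$socket_sigma_mm[1]^2)
                          - (y - ctr["y"])^2 / (2 * spec$socket_sigma_mm[2]^2))
    out[r, ] <- v
  }
  out
}

#' Generate a paired synthetic phantom
#'
#' Renders baseline (`t0`) and follow-up (`t1`) volumes from the spec,
#' applies the in-plane Gaussian PSF, adds Gaussian noise (seeded — the same
#' seed always yields bit-identical volumes), clamps to the 8-bit model
#' range, and rescales to the spec's stored bit depth.
#'
#' @param spec a [phantom_spec()].
#' @return A list: `t0`, `t1` ([volume_stack()]s), `truth`
#'   ([phantom_truth()] table), `central_line` (the pre-positioned central
#'   crestal [make_central_line()]), `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  p <- spec$voxel_size_mm
  sigma_px <- spec$psf_sigma_mm / p
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  render <- function(tp) {
    vox <- array(0, spec$shape)
    for (z in seq_len(spec$shape[1])) {
      s <- blur_matrix(render_phantom_slice(spec, z, tp), sigma_px)
      if (spec$noise_sd > 0)
        s <- s + matrix(stats::rnorm(length(s), sd = spec$noise_sd),
                        nrow(s), ncol(s))
      vox[z, , ] <- pmin(pmax(s, 0), 255)
    }
    scale <- (2^spec$bit_depth - 1) / 255
    vox[] <- round_half_up(vox * scale)
    volume_stack(vox, voxel_size = rep(p, 3), bit_depth = spec$bit_depth,
                 axial_direction = "apical",
                 provenance = sprintf("generate_phantom[%s, seed %d]",
                                      tp, spec$seed))
  }
  t0 <- render("t0")
  t1 <- render("t1")
  list(t0 = t0, t1 = t1, truth = phantom_truth(spec),
       central_line = generate_phantom_line(spec), spec = spec)
}

#' Build the default measurement grid for a phantom
#'
#' Convenience wrapper: central line at the socket center, depth planes per
#' the spec's targets, default offsets.
#'
#' @param spec a [phantom_spec()].
#' @param tolerance_mm depth tolerance passed to [select_depth_slices()].
#' @return A `measurement_grid`.
#' @export
phantom_grid <- function(spec, tolerance_mm = 0.25) {
  ph_line <- generate_phantom_line(spec)
  ds <- select_depth_slices(spec$crestal_slice, spec$voxel_size_mm,
                            spec$depth_targets_mm, tolerance_mm,
                            stack_depth = spec$shape[1])
  build_grid(ph_line, ds,
             extent_mm = (spec$shape[c(3, 2)] - 1) * spec$voxel_size_mm,
             tolerance_mm = tolerance_mm)
}

# the central line without rendering any voxels
generate_phantom_line <- function(spec) {
  p <- spec$voxel_size_mm
  ctr <- phantom_center(spec)
  make_central_line(spec$crestal_slice,
                    p_start = c(5 * p, ctr[["y"]]),
                    p_end = c((spec$shape[3] - 6) * p, ctr[["y"]]))
}

#' Write a phantom fixture to disk
#'
#' Emits both timepoints as DICOM series readable by [load_dicom_series()],
#' the ground-truth table, the pre-positioned central-line definition, a
#' whole-volume ROI, and a manifest recording the spec and seed.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory; created if needed. Layout: `t0/`,
#'   `t1/` (DICOM), `truth.csv`, `central_line.json`, `roi.json`,
#'   `manifest.yaml`.
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ph <- generate_phantom(spec)
  write_dicom_series(ph$t0, file.path(out_dir, "t0"), series_number = 1L)
  write_dicom_series(ph$t1, file.path(out_dir, "t1"), series_number = 2L)
  utils::write.csv(ph$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(ph$central_line),
                       file.path(out_dir, "central_line.json"),
                       auto_unbox = TRUE, digits = NA)
  write_roi_spec(roi_spec(1L, spec$shape[1], 1L, 1L, spec$shape[2],
                          spec$shape[3], 0),
                 file.path(out_dir, "roi.json"))
  manifest <- unclass(spec)
  manifest$loss_mm <- apply(spec$loss_mm, 1, as.numeric, simplify = FALSE)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
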