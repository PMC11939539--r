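# Ridge width from grey-value line profiles: the cortical rims bounding the
# ridge appear as the two outermost maxima of a wide line profile drawn
# vestibular-to-oral; their x-distance is the ridge width at that position.

bilinear_sample <- function(m, r, c) {
  h <- nrow(m); w <- ncol(m)
  # guard against float overshoot at the exact boundary
  r <- pmin(pmax(r, 1), h); c <- pmin(pmax(c, 1), w)
  r0 <- pmin(floor(r), h - 1L); c0 <- pmin(floor(c), w - 1L)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

#' Sample a wide grey-value profile along a measurement line
#'
#' Samples are taken at steps equal to the in-plane voxel pitch along the
#' line (no oversampling, so profile x-coordinates are commensurate with the
#' image grid). Each sample is the arithmetic mean of `sampling_width_px`
#' bilinearly interpolated values spaced one pixel apart along the
#' perpendicular, centered on the line — the wide-line profile of the
#' original protocol.
#'
#' @param stack a [volume_stack()].
#' @param line a `measurement_line` whose sampling band lies inside the
#'   slice.
#' @return A `grey_profile`: `distance_mm` (from `p_start`), `value`
#'   (mean grey), `line`, `step_mm`.
#' @export
extract_profile <- function(stack, line) {
  stopifnot(inherits(stack, "volume_stack"), inherits(line, "measurement_line"))
  d <- dim(stack$voxels)
  if (line$slice_index < 1 || line$slice_index > d[1])
    stop("line slice index outside the stack", call. = FALSE)
  if (abs(stack$voxel_size[2] - stack$voxel_size[3]) > 1e-9)
    stop("profile sampling requires square in-plane voxels", call. = FALSE)
  pitch <- stack$voxel_size[3]
  len <- line_length(line)
  n <- as.integer(floor(len / pitch + 1e-9)) + 1L
  t_mm <- (seq_len(n) - 1L) * pitch
  dir <- line_direction(line)
  perp <- line_perpendicular(line)
  wpx <- line$sampling_width_px
  off <- (seq_len(wpx) - (wpx + 1) / 2) * pitch

  # (n x wpx) sample coordinates in mm
  x <- outer(line$p_start[1] + t_mm * dir[1], off * perp[1], `+`)
  y <- outer(line$p_start[2] + t_mm * dir[2], off * perp[2], `+`)
  x_max <- (d[3] - 1) * stack$voxel_size[3]
  y_max <- (d[2] - 1) * stack$voxel_size[2]
  if (any(x < -1e-9) || any(x > x_max + 1e-9) ||
      any(y < -1e-9) || any(y > y_max + 1e-9))
    stop("sampling band exits the volume; shorten the line or reduce its width",
         call. = FALSE)

  slice <- stack$voxels[line$slice_index, , ]
  vals <- bilinear_sample(slice, as.vector(y) / stack$voxel_size[2] + 1,
                          as.vector(x) / stack$voxel_size[3] + 1)
  structure(list(distance_mm = t_mm,
                 value = rowMeans(matrix(vals, nrow = n)),
                 line = line, step_mm = pitch),
            class = "grey_profile")
}

# collapse consecutive equal samples into runs; returns per-run value and
# start/end sample indices
profile_runs <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  data.frame(value = r$values, start = ends - r$lengths + 1L, end = ends)
}

# topographic prominence of run j among run values `vals`: on each side walk
# to the nearest strictly higher run (or the boundary); the base on that
# side is the minimum encountered; prominence = value - max(left, right base)
run_prominence <- function(vals, j) {
  v <- vals[j]
  base <- function(idx) {
    if (length(idx) == 0) return(v)  # peak at the very boundary run
    lo <- Inf
    for (i in idx) {
      if (vals[i] > v) break
      lo <- min(lo, vals[i])
    }
    if (is.infinite(lo)) v else lo
  }
  left <- base(rev(seq_len(j - 1L)))
  right <- base(if (j < length(vals)) (j + 1L):length(vals) else integer())
  v - max(left, right)
}

#' Find profile minima and maxima above a prominence threshold
#'
#' Local extrema of the profile, filtered by topographic prominence of at
#' least `prominence_fraction` times the profile dynamic range (max - min).
#' Plateaus report their center; profile endpoints are not peaks. A flat
#' profile yields empty peak sets flagged `"FLAT"`.
#'
#' @param profile a `grey_profile` with at least 3 samples.
#' @param prominence_fraction fraction of the dynamic range required as
#'   prominence; default 0.1.
#' @return A `peak_set`: `maxima` and `minima` data frames (`x_mm`,
#'   `value`), `prominence_threshold` (absolute grey levels), `flags`,
#'   plus the profile span and step needed downstream.
#' @export
find_profile_peaks <- function(profile, prominence_fraction = 0.1) {
  stopifnot(inherits(profile, "grey_profile"))
  v <- profile$value
  if (length(v) < 3L)
    stop("peak finding needs a profile of at least 3 samples", call. = FALSE)
  rng <- max(v) - min(v)
  thr <- prominence_fraction * rng
  empty <- data.frame(x_mm = numeric(), value = numeric())

  # peaks of `vals` reported with the original profile value at the peak
  extrema <- function(vals) {
    runs <- profile_runs(vals)
    keep <- integer()
    if (nrow(runs) >= 3L) {
      for (j in 2L:(nrow(runs) - 1L)) {
        if (runs$value[j] > runs$value[j - 1L] &&
            runs$value[j] > runs$value[j + 1L] &&
            run_prominence(runs$value, j) >= thr - 1e-12)
          keep <- c(keep, j)
      }
    }
    if (length(keep) == 0) return(empty)
    data.frame(
      x_mm = (profile$distance_mm[runs$start[keep]] +
              profile$distance_mm[runs$end[keep]]) / 2,
      value = v[runs$start[keep]])
  }

  if (rng == 0) {
    maxima <- empty; minima <- empty; flags <- "FLAT"
  } else {
    maxima <- extrema(v)
    minima <- extrema(-v)
    flags <- character()
  }
  structure(list(maxima = maxima, minima = minima,
                 prominence_threshold = thr, flags = flags,
                 span_mm = range(profile$distance_mm),
                 step_mm = profile$step_mm, line = profile$line),
            class = "peak_set")
}

#' Ridge width from a peak set
#'
#' The width is the x-distance between the two outermost maxima — the
#' buccal and oral cortical rims that bound the ridge. With more than two
#' maxima the outermost pair is used and `EXTRA_PEAKS` is flagged for
#' review; an outer maximum within one sampling step of the profile
#' boundary flags `BOUNDARY_PEAK` (the line may not have extended beyond
#' the ridge). Fewer than two maxima is a measurement error.
#'
#' @param peaks a `peak_set` from [find_profile_peaks()].
#' @return A `width_measurement`: `offset_mm`, `depth_level`, `width_mm`,
#'   `peak_left_mm`, `peak_right_mm`, `qc_flags`.
#' @export
ridge_width <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  m <- peaks$maxima
  if (nrow(m) < 2L)
    stop(sprintf("position unmeasurable: %d maxima found (need 2)", nrow(m)),
         call. = FALSE)
  left <- m$x_mm[1L]; right <- m$x_mm[nrow(m)]
  flags <- character()
  if (nrow(m) > 2L) flags <- c(flags, "EXTRA_PEAKS")
  if (left - peaks$span_mm[1] <= peaks$step_mm + 1e-9 ||
      peaks$span_mm[2] - right <= peaks$step_mm + 1e-9)
    flags <- c(flags, "BOUNDARY_PEAK")
  line <- peaks$line
  structure(list(offset_mm = line$offset_mm, depth_level = line$depth_level,
                 slice_index = line$slice_index,
                 width_mm = right - left,
                 peak_left_mm = left, peak_right_mm = right,
                 qc_flags = flags),
            class = "width_measurement")
}

#' Measure ridge width at every grid position
#'
#' Runs [extract_profile()], [find_profile_peaks()] and [ridge_width()] for
#' all positions of the grid, in deterministic label order. Positions where
#' a width cannot be established (fewer than two maxima, geometry errors)
#' are reported as explicit unmeasurable rows — never silently dropped.
#'
#' @param stack an 8-bit [volume_stack()].
#' @param grid a `measurement_grid` from [build_grid()].
#' @param prominence_fraction passed to [find_profile_peaks()].
#' @return A data frame with one row per position: `offset_mm`,
#'   `depth_level`, `slice_index`, `width_mm` (`NA` when unmeasurable),
#'   `peak_left_mm`, `peak_right_mm`, `flags` (`;`-separated).
#' @export
measure_grid <- function(stack, grid, prominence_fraction = 0.1) {
  stopifnot(inherits(stack, "volume_stack"), inherits(grid, "measurement_grid"))
  rows <- lapply(grid$lines, function(line) {
    res <- tryCatch({
      peaks <- find_profile_peaks(extract_profile(stack, line),
                                  prominence_fraction)
      w <- ridge_width(peaks)
      data.frame(offset_mm = w$offset_mm, depth_level = w$depth_level,
                 slice_index = w$slice_index, width_mm = w$width_mm,
                 peak_left_mm = w$peak_left_mm, peak_right_mm = w$peak_right_mm,
                 flags = paste(w$qc_flags, collapse = ";"),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(offset_mm = line$offset_mm, depth_level = line$depth_level,
                 slice_index = line$slice_index, width_mm = NA_real_,
                 peak_left_mm = NA_real_, peak_right_mm = NA_real_,
                 flags = paste0("UNMEASURABLE: ", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    res
  })
  do.call(rbind, rows)
}
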