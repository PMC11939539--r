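#' Measurement lines and the 15-position grid
#'
#' A `measurement_line` is one oriented in-plane segment along which a
#' wide grey-value profile is sampled: mm endpoints on an axial slice, a
#' perpendicular averaging width in pixels, and a position label (mesio-
#' distal offset in mm, depth level). The user draws a single central
#' crestal line perpendicular to the ridge, extending beyond its width;
#' everything else is generated from it.
#'
#' @param crestal_slice 1-based axial index of the crestal plane.
#' @param p_start,p_end numeric length-2 in-plane endpoints `(x, y)` in mm
#'   (`x` along columns, vestibular to oral; `y` along rows, the mesio-distal
#'   axis). The direction from `p_start` to `p_end` defines the profile axis
#'   and distances are reported from `p_start`.
#' @param sampling_width_px perpendicular averaging width in pixels
#'   (default 10, the minimum line width of the original protocol).
#' @return A `measurement_line` labelled `(offset 0, crestal)`.
#' @export
make_central_line <- function(crestal_slice, p_start, p_end,
                              sampling_width_px = 10L) {
  new_measurement_line(crestal_slice, p_start, p_end, sampling_width_px,
                       offset_mm = 0, depth_level = "crestal")
}

new_measurement_line <- function(slice_index, p_start, p_end,
                                 sampling_width_px, offset_mm, depth_level) {
  p_start <- as.numeric(p_start); p_end <- as.numeric(p_end)
  if (length(p_start) != 2L || length(p_end) != 2L ||
      any(!is.finite(c(p_start, p_end))))
    stop("line endpoints must be finite (x, y) mm pairs", call. = FALSE)
  len <- sqrt(sum((p_end - p_start)^2))
  if (len <= 0)
    stop("zero-length measurement line (p_start == p_end)", call. = FALSE)
  if (sampling_width_px < 1)
    stop("sampling_width_px must be >= 1", call. = FALSE)
  structure(list(slice_index = as.integer(slice_index),
                 p_start = p_start, p_end = p_end,
                 sampling_width_px = as.integer(sampling_width_px),
                 offset_mm = as.numeric(offset_mm),
                 depth_level = as.character(depth_level)),
            class = "measurement_line")
}

#' @rdname make_central_line
#' @param line a `measurement_line`.
#' @export
line_length <- function(line) {
  stopifnot(inherits(line, "measurement_line"))
  sqrt(sum((line$p_end - line$p_start)^2))
}

# unit vectors along and perpendicular to the line; positive perpendicular
# offsets are the distal direction by convention
line_direction <- function(line) {
  d <- line$p_end - line$p_start
  d / sqrt(sum(d^2))
}
line_perpendicular <- function(line) {
  d <- line_direction(line)
  c(-d[2], d[1])
}

#' Duplicate the central line at mesio-distal offsets
#'
#' Translates the central crestal line along the in-plane unit vector
#' perpendicular to its direction (the mesio-distal axis), by the stated
#' offsets. Positive offsets are distal. All output lines are parallel to
#' and the same length as the central line.
#'
#' @param central the central crestal `measurement_line` (offset 0).
#' @param offsets_mm offsets to generate; default 1 and 2 mm to each side.
#' @param extent_mm optional `(x_max, y_max)` mm extent of the slice; when
#'   given, an offset that pushes the line out of bounds is a geometry error
#'   naming the offending offset.
#' @return A list of `measurement_line`s, one per offset.
#' @export
expand_horizontal <- function(central, offsets_mm = c(-2, -1, 1, 2),
                              extent_mm = NULL) {
  stopifnot(inherits(central, "measurement_line"))
  if (central$offset_mm != 0)
    stop("expand_horizontal() expects the central (offset 0) line", call. = FALSE)
  perp <- line_perpendicular(central)
  lapply(offsets_mm, function(off) {
    s <- central$p_start + off * perp
    e <- central$p_end + off * perp
    if (!is.null(extent_mm)) {
      pts <- rbind(s, e)
      if (any(pts < -1e-9) || any(pts[, 1] > extent_mm[1] + 1e-9) ||
          any(pts[, 2] > extent_mm[2] + 1e-9))
        stop(sprintf("offset %+g mm shifts the line outside the slice", off),
             call. = FALSE)
    }
    new_measurement_line(central$slice_index, s, e, central$sampling_width_px,
                         offset_mm = off, depth_level = central$depth_level)
  })
}

#' Select the axial slices for the apical measurement planes
#'
#' For each target depth, the slice offset is `k = round(target /
#' slice_thickness)` (half-up, ties broken toward the more crestal slice),
#' accepted only when the achieved depth `k * slice_thickness` deviates from
#' the target by at most `tolerance_mm` — the comparability tolerance of the
#' protocol. With 0.15 mm slices the 2.5 and 5.0 mm targets resolve to
#' achieved depths of 2.55 and 4.95 mm.
#'
#' @param crestal_slice 1-based index of the crestal plane.
#' @param slice_thickness_mm axial spacing in mm (> 0).
#' @param targets_mm apical depths to reach; default `c(2.5, 5.0)`.
#' @param tolerance_mm maximum allowed deviation; default 0.25.
#' @param stack_depth optional number of slices, for a bounds check.
#' @param axial_direction `"apical"` if the slice index increases apically.
#' @return A data frame with one row per target: `target_mm`, `k` (slice
#'   offset), `slice_index`, `achieved_mm`, `deviation_mm`.
#' @export
select_depth_slices <- function(crestal_slice, slice_thickness_mm,
                                targets_mm = c(2.5, 5.0),
                                tolerance_mm = 0.25,
                                stack_depth = NULL,
                                axial_direction = "apical") {
  if (!is.finite(slice_thickness_mm) || slice_thickness_mm <= 0)
    stop("slice_thickness_mm must be > 0", call. = FALSE)
  rows <- lapply(targets_mm, function(target) {
    r <- target / slice_thickness_mm
    k <- as.integer(ceiling(r - 0.5))  # half-up, tie toward smaller (more crestal) k
    dev <- abs(k * slice_thickness_mm - target)
    if (dev > tolerance_mm + 1e-12) {
      lo <- floor(r) * slice_thickness_mm; hi <- ceiling(r) * slice_thickness_mm
      stop(sprintf(paste0("no slice within %.2f mm of the %.2f mm target: ",
                          "achievable depths are %.3f and %.3f mm"),
                   tolerance_mm, target, lo, hi), call. = FALSE)
    }
    idx <- if (identical(axial_direction, "apical")) crestal_slice + k
           else crestal_slice - k
    if (!is.null(stack_depth) && (idx < 1 || idx > stack_depth))
      stop(sprintf("depth plane at %.2f mm falls outside the stack (slice %d of %d)",
                   target, idx, stack_depth), call. = FALSE)
    data.frame(target_mm = target, k = k, slice_index = idx,
               achieved_mm = k * slice_thickness_mm, deviation_mm = dev)
  })
  do.call(rbind, rows)
}

depth_level_label <- function(target_mm) sprintf("-%.1fmm", target_mm)

#' Build the full 15-position measurement grid
#'
#' Expands the central crestal line into five mesio-distal offsets and
#' copies the five crestal lines verbatim (identical in-plane endpoints)
#' onto each apical depth plane: 5 offsets x 3 depth levels = 15 positions.
#'
#' @param central the central crestal line ([make_central_line()]).
#' @param depth_slices data frame from [select_depth_slices()].
#' @param offsets_mm non-central offsets; default `c(-2, -1, 1, 2)`.
#' @param extent_mm optional slice extent for bounds checking (see
#'   [expand_horizontal()]).
#' @param tolerance_mm recorded depth tolerance (metadata only).
#' @return A `measurement_grid`: `lines` (15 `measurement_line`s in
#'   deterministic depth-major, offset-minor order), `crestal_slice`,
#'   `depth_slices`, `tolerance_mm`.
#' @export
build_grid <- function(central, depth_slices, offsets_mm = c(-2, -1, 1, 2),
                       extent_mm = NULL, tolerance_mm = 0.25) {
  stopifnot(inherits(central, "measurement_line"))
  if (0 %in% offsets_mm)
    stop("offsets_mm lists the non-central offsets; 0 is implied", call. = FALSE)
  side <- expand_horizontal(central, offsets_mm, extent_mm)
  crestal_set <- c(side, list(central))
  ord <- order(vapply(crestal_set, function(l) l$offset_mm, 0))
  crestal_set <- crestal_set[ord]

  lines <- crestal_set
  for (i in seq_len(nrow(depth_slices))) {
    lvl <- depth_level_label(depth_slices$target_mm[i])
    idx <- depth_slices$slice_index[i]
    lines <- c(lines, lapply(crestal_set, function(l) {
      new_measurement_line(idx, l$p_start, l$p_end, l$sampling_width_px,
                           offset_mm = l$offset_mm, depth_level = lvl)
    }))
  }
  structure(list(lines = lines,
                 crestal_slice = central$slice_index,
                 depth_slices = depth_slices,
                 tolerance_mm = tolerance_mm),
            class = "measurement_grid")
}

#' @export
print.measurement_grid <- function(x, ...) {
  cat(sprintf("<measurement_grid> %d positions, crestal slice %d\n",
              length(x$lines), x$crestal_slice))
  print(x$depth_slices, row.names = FALSE)
  invisible(x)
}

#' Serialize a measurement grid to JSON and back
#'
#' The grid round-trips losslessly: `read_grid(write_grid(g, path))` equals
#' `g`.
#'
#' @param grid a `measurement_grid`.
#' @param path JSON file path.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "measurement_grid"))
  jsonlite::write_json(
    list(crestal_slice = grid$crestal_slice,
         tolerance_mm = grid$tolerance_mm,
         depth_slices = grid$depth_slices,
         lines = lapply(grid$lines, unclass)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  lines <- lapply(seq_len(nrow(x$lines)), function(i) {
    l <- x$lines[i, ]
    new_measurement_line(l$slice_index, unlist(l$p_start), unlist(l$p_end),
                         l$sampling_width_px, l$offset_mm, l$depth_level)
  })
  structure(list(lines = lines,
                 crestal_slice = as.integer(x$crestal_slice),
                 depth_slices = as.data.frame(x$depth_slices),
                 tolerance_mm = x$tolerance_mm),
            class = "measurement_grid")
}
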