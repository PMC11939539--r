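# Independent oracles and shared fixtures for the suite. The oracles are
# deliberately naive re-derivations (exhaustive scans, direct sums of
# squares) kept separate from the package implementations they check.

# Brute-force local-extremum + prominence scan for tie-free profiles.
# For each interior strict local maximum, walk each side to the nearest
# strictly higher sample (or the boundary); the base on a side is the
# minimum encountered; prominence = value - max(left base, right base).
bf_find_maxima <- function(x, v, prominence_fraction) {
  n <- length(v)
  thr <- prominence_fraction * (max(v) - min(v))
  out <- data.frame(x_mm = numeric(), value = numeric())
  for (i in 2:(n - 1)) {
    if (!(v[i] > v[i - 1] && v[i] > v[i + 1])) next
    left <- v[1:(i - 1)]
    hi <- which(left > v[i])
    lbase <- if (length(hi)) {
      seg <- left[(max(hi) + 1):(i - 1)]
      if (length(seg)) min(seg) else v[i]
    } else min(left)
    right <- v[(i + 1):n]
    hi <- which(right > v[i])
    rbase <- if (length(hi)) {
      if (hi[1] > 1) min(right[1:(hi[1] - 1)]) else v[i]
    } else min(right)
    if (v[i] - max(lbase, rbase) >= thr - 1e-12)
      out <- rbind(out, data.frame(x_mm = x[i], value = v[i]))
  }
  out
}

# random tie-free grey profile wrapped as the object the package emits
random_profile <- function(n, step = 0.15) {
  line <- make_central_line(1L, c(0, 0), c((n - 1) * step, 0))
  structure(list(distance_mm = (seq_len(n) - 1) * step,
                 value = runif(n, 0, 255), line = line, step_mm = step),
            class = "grey_profile")
}

position_key <- function(d) paste(d$offset_mm, d$depth_level)

truth_for <- function(ph, timepoint, measured) {
  tr <- ph$truth[ph$truth$timepoint == timepoint, ]
  tr$width_mm[match(position_key(measured), position_key(tr))]
}

# small, geometrically consistent phantom for I/O and fixture tests
tiny_spec <- function(seed = 1L, ...) {
  phantom_spec(shape = c(10L, 20L, 30L), crestal_slice = 2L,
               crestal_width_mm = 1.8, flare_per_mm = 0,
               depth_targets_mm = c(0.3, 0.6),
               loss_mm = rbind(c(0.3, 0.15, 0), c(0.15, 0.15, 0), c(0, 0, 0)),
               ridge_margin_mm = 0.3, rim_sigma_mm = 0.15,
               socket_sigma_mm = c(0.2, 0.3),
               seed = seed, ...)
}
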