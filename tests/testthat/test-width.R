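test_that("profiles sample at the voxel pitch with perpendicular averaging", {
  st <- volume_stack(array(100, c(3, 60, 60)), c(0.15, 0.15, 0.15))
  line <- make_central_line(2, c(1.0, 4.0), c(7.0, 4.0))  # 6.0 mm long
  p <- extract_profile(st, line)
  expect_length(p$value, 41L)                     # 6.0 / 0.15 + 1
  expect_equal(range(p$distance_mm), c(0, 6.0))
  expect_true(all(p$value == 100))                # constant field

  # a single one-pixel bright column crossing a width-1 line gives a single
  # local maximum at the crossing (line start on the voxel grid)
  st$voxels[2, , 21] <- 200                        # x = 3.0 mm
  narrow <- make_central_line(2, c(0.9, 4.0), c(6.9, 4.0), sampling_width_px = 1)
  pk <- find_profile_peaks(extract_profile(st, narrow))
  expect_identical(nrow(pk$maxima), 1L)
  expect_equal(pk$maxima$x_mm, 2.1)                # 3.0 mm - line start 0.9 mm

  wide <- make_central_line(2, c(1.0, 0.3), c(7.0, 0.3))
  expect_error(extract_profile(st, wide), "exits the volume")
})

test_that("peak finding matches the exhaustive scan oracle on random profiles", {
  set.seed(202)
  for (i in 1:60) {
    pr <- random_profile(sample(10:200, 1))
    ps <- find_profile_peaks(pr, prominence_fraction = 0.1)
    oracle_max <- bf_find_maxima(pr$distance_mm, pr$value, 0.1)
    oracle_min <- bf_find_maxima(pr$distance_mm, -pr$value, 0.1)
    expect_equal(ps$maxima$x_mm, oracle_max$x_mm)
    expect_equal(ps$maxima$value, oracle_max$value)
    expect_equal(ps$minima$x_mm, oracle_min$x_mm)
  }
})

test_that("peak finding handles bumps, ramps, symmetry, plateaus and flat profiles", {
  x <- seq(0, 10.5, by = 0.15)
  line <- make_central_line(1, c(0, 0), c(10.5, 0))
  as_profile <- function(v) structure(
    list(distance_mm = x, value = v, line = line, step_mm = 0.15),
    class = "grey_profile")

  # two clean Gaussian bumps over a flat background
  v <- 20 + 200 * (exp(-(x - 2)^2 / 0.18) + exp(-(x - 8.4)^2 / 0.18))
  ps <- find_profile_peaks(as_profile(v))
  expect_identical(nrow(ps$maxima), 2L)
  expect_equal(ps$maxima$x_mm, c(2.0, 8.4), tolerance = 0.15)

  # monotone ramp: no interior extrema
  ramp <- find_profile_peaks(as_profile(seq_along(x)))
  expect_identical(nrow(ramp$maxima), 0L)

  # symmetric profile -> peak set symmetric about the midpoint
  sym <- 50 + 100 * cos((x - 5.25) * 2)
  pss <- find_profile_peaks(as_profile(sym))
  expect_equal(pss$maxima$x_mm, rev(max(x) - pss$maxima$x_mm), tolerance = 1e-9)

  # plateau peaks report their center
  v2 <- rep(10, length(x)); v2[20:23] <- 100
  psp <- find_profile_peaks(as_profile(v2))
  expect_equal(psp$maxima$x_mm, mean(x[c(20, 23)]))

  # flat profile: empty sets, flagged
  fl <- find_profile_peaks(as_profile(rep(7, length(x))))
  expect_identical(nrow(fl$maxima), 0L)
  expect_true("FLAT" %in% fl$flags)
  expect_error(find_profile_peaks(as_profile(1:2)), "3 samples")
})

test_that("ridge width is the distance between the outermost maxima, with QC flags", {
  line <- make_central_line(1, c(0, 0), c(12, 0))
  mk <- function(xs) structure(
    list(maxima = data.frame(x_mm = xs, value = 200),
         minima = data.frame(x_mm = numeric(), value = numeric()),
         prominence_threshold = 20, flags = character(),
         span_mm = c(0, 12), step_mm = 0.15, line = line),
    class = "peak_set")

  w <- ridge_width(mk(c(2.0, 8.4)))
  expect_equal(w$width_mm, 6.4)
  expect_length(w$qc_flags, 0L)

  w3 <- ridge_width(mk(c(2.0, 5.0, 8.4)))
  expect_equal(w3$width_mm, 6.4)
  expect_true("EXTRA_PEAKS" %in% w3$qc_flags)

  wb <- ridge_width(mk(c(0.15, 8.4)))
  expect_true("BOUNDARY_PEAK" %in% wb$qc_flags)

  expect_error(ridge_width(mk(5.0)), "unmeasurable")
})

test_that("grid measurement is deterministic and reports unmeasurable positions", {
  spec <- phantom_spec(noise_sd = 0)
  st <- normalize_to_8bit(generate_phantom(spec)$t0)
  g <- phantom_grid(spec)
  m1 <- measure_grid(st, g)
  m2 <- measure_grid(st, g)
  expect_identical(m1, m2)
  expect_identical(nrow(m1), 15L)
  expect_false(anyNA(m1$width_mm))

  flat <- volume_stack(array(90, dim(st$voxels)), st$voxel_size)
  mu <- measure_grid(flat, g)
  expect_identical(nrow(mu), 15L)
  expect_true(all(is.na(mu$width_mm)))
  expect_true(all(grepl("UNMEASURABLE", mu$flags)))
})

test_that("widths are invariant under strictly increasing grey maps", {
  spec <- phantom_spec(seed = 8)
  st <- normalize_to_8bit(generate_phantom(spec)$t0)
  g <- phantom_grid(spec)
  base <- measure_grid(st, g)
  maps <- list(function(v) 30 + 0.7 * v,
               function(v) (v / 255)^2 * 255,
               function(v) sqrt(v + 1) * 10)
  for (f in maps) {
    mapped <- st
    mapped$voxels[] <- f(st$voxels)
    m <- measure_grid(mapped, g)
    expect_equal(m$width_mm, base$width_mm)
    expect_equal(m$peak_left_mm, base$peak_left_mm)
  }
})

test_that("widths are equivariant under a common in-plane translation", {
  spec <- phantom_spec(noise_sd = 0)
  ph <- generate_phantom(spec)
  st <- normalize_to_8bit(ph$t0)
  g <- phantom_grid(spec)
  base <- measure_grid(st, g)

  # shift the volume 3 voxels in x and 2 in y, and the grid with it
  sh_vox <- c(2, 3)  # (rows, cols)
  d <- dim(st$voxels)
  shifted <- st
  shifted$voxels[] <- 0
  shifted$voxels[, (1 + sh_vox[1]):d[2], (1 + sh_vox[2]):d[3]] <-
    st$voxels[, 1:(d[2] - sh_vox[1]), 1:(d[3] - sh_vox[2])]
  dmm <- sh_vox * 0.15
  g2 <- g
  g2$lines <- lapply(g$lines, function(l) {
    l$p_start <- l$p_start + c(dmm[2], dmm[1])
    l$p_end <- l$p_end + c(dmm[2], dmm[1])
    l
  })
  m <- measure_grid(shifted, g2)
  expect_equal(m$width_mm, base$width_mm)
})
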