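test_that("phantom generation is seed-deterministic with seed-invariant truth", {
  s1 <- tiny_spec(seed = 12)
  a <- generate_phantom(s1)
  b <- generate_phantom(tiny_spec(seed = 12))
  expect_identical(a$t0$voxels, b$t0$voxels)
  expect_identical(a$t1$voxels, b$t1$voxels)

  c_ <- generate_phantom(tiny_spec(seed = 13))
  expect_false(identical(a$t0$voxels, c_$t0$voxels))  # noise varies
  expect_identical(a$truth, c_$truth)                 # geometry does not
})

test_that("null resorption with zero noise and PSF gives bit-identical timepoints", {
  spec <- phantom_spec(loss_mm = matrix(0, 3, 3), noise_sd = 0,
                       psf_sigma_mm = 0)
  ph <- generate_phantom(spec)
  expect_identical(ph$t0$voxels, ph$t1$voxels)
  expect_true(all(ph$truth$width_mm[ph$truth$timepoint == "t0"] ==
                  ph$truth$width_mm[ph$truth$timepoint == "t1"]))
})

test_that("phantom intensities and spec invariants are enforced", {
  expect_error(phantom_spec(intensity = list(background = 120, trabecular = 100,
                                             rim_amp = 120, socket_dip = 60)),
               "rim > trabecular > socket")
  expect_error(phantom_spec(loss_mm = rbind(c(9, 9, 9), c(0, 0, 0), c(0, 0, 0))),
               "non-positive width")
  expect_error(phantom_spec(loss_mm = rbind(c(-1, 0, 0), c(0, 0, 0), c(0, 0, 0))),
               "non-negative")
})

test_that("truth table lists 15 positions per timepoint on the default grid", {
  tr <- phantom_truth(phantom_spec())
  expect_identical(nrow(tr), 30L)
  expect_identical(as.integer(table(tr$timepoint)), c(15L, 15L))
  # crestally weighted gradient: loss decreases apically and laterally
  loss <- tr$width_mm[tr$timepoint == "t0"] - tr$width_mm[tr$timepoint == "t1"]
  tt <- cbind(tr[tr$timepoint == "t0", c("offset_mm", "depth_level")], loss)
  by_lvl <- tapply(tt$loss, tt$depth_level, mean)
  expect_gt(by_lvl[["crestal"]], by_lvl[["-2.5mm"]])
  expect_gt(by_lvl[["-2.5mm"]], by_lvl[["-5.0mm"]])
  central <- tt$loss[tt$offset_mm == 0]
  lateral <- tt$loss[abs(tt$offset_mm) == 2]
  expect_true(all(central > 0))
  expect_gt(mean(central), mean(lateral))
})

test_that("increasing programmed central-crestal loss increases measured loss", {
  measured_central_loss <- function(central_loss) {
    # keep the lateral taper of the stated resorption pattern: adjacent
    # strips step by 0.3 mm so the rim stays a single band-averaged peak
    spec <- phantom_spec(loss_mm = rbind(central_loss - c(0, 0.3, 0.6),
                                         c(0.45, 0.3, 0.3), c(0, 0, 0)),
                         noise_sd = 0)
    ph <- generate_phantom(spec)
    g <- phantom_grid(spec)
    ch <- width_change(measure_grid(normalize_to_8bit(ph$t0), g),
                       measure_grid(normalize_to_8bit(ph$t1), g))
    ch$loss_mm[ch$offset_mm == 0 & ch$depth_level == "crestal"]
  }
  losses <- vapply(c(1.2, 1.8, 2.4), measured_central_loss, 0)
  expect_true(all(diff(losses) > 0))
  expect_equal(losses, c(1.2, 1.8, 2.4), tolerance = 1e-6)
})

test_that("fixtures carry a manifest whose seed reproduces the pixel data", {
  spec <- tiny_spec(seed = 21)
  dir <- withr::local_tempdir()
  write_fixture(spec, dir)
  expect_true(all(file.exists(file.path(dir, c("truth.csv", "central_line.json",
                                               "roi.json", "manifest.yaml")))))
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_identical(man$seed, 21L)

  respec <- phantom_spec(shape = unlist(man$shape),
                         voxel_size_mm = man$voxel_size_mm,
                         crestal_slice = man$crestal_slice,
                         crestal_width_mm = man$crestal_width_mm,
                         flare_per_mm = man$flare_per_mm,
                         depth_targets_mm = unlist(man$depth_targets_mm),
                         loss_mm = do.call(rbind, lapply(man$loss_mm, unlist)),
                         intensity = man$intensity,
                         rim_sigma_mm = man$rim_sigma_mm,
                         ridge_margin_mm = man$ridge_margin_mm,
                         socket_sigma_mm = unlist(man$socket_sigma_mm),
                         psf_sigma_mm = man$psf_sigma_mm,
                         noise_sd = man$noise_sd, bit_depth = man$bit_depth,
                         seed = man$seed)
  redone <- generate_phantom(respec)
  orig <- load_dicom_series(file.path(dir, "t0"))
  expect_identical(orig$voxels, redone$t0$voxels)

  tr <- read.csv(file.path(dir, "truth.csv"))
  expect_identical(nrow(tr), 30L)
})
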