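# Synthetic phantom and assay generators: ground truth handling,
# determinism, and agreement with the paper-scale signal regime.

test_that("enzyme focus tapers radially and converts to the expected peak rate", {
  spec <- phantom_spec(grid_shape = c(20, 20, 3), n_frames = 10)
  ph <- make_fap_phantom(spec, center = c(15, 10, 2), radius = 1,
                         peak_fap = 10)
  expect_equal(max(ph$k_map), 0.015, tolerance = 1e-9)
  # zero peak gives an all-zero map
  ph0 <- make_fap_phantom(spec, center = c(15, 10, 2), radius = 1,
                          peak_fap = 0)
  expect_true(all(ph0$k_map == 0))
  # control hemisphere carries no activity
  expect_true(all(ph$k_map[1:10, , ] == 0))
  expect_error(make_fap_phantom(spec, center = c(40, 10, 2), radius = 1,
                                peak_fap = 1), "inside the grid")
})

test_that("voxels above half-max activity match a brute-force geometric count", {
  spec <- phantom_spec(grid_shape = c(20, 20, 5), n_frames = 10)
  ph <- make_fap_phantom(spec, center = c(15, 10, 3), radius = 1.2,
                         peak_fap = 10)
  got <- sum(ph$k_map > max(ph$k_map) / 2)
  # independent count: voxel centers within `radius` mm of the focus
  vs <- spec$voxel_size
  cnt <- 0L
  for (i in 1:20) for (j in 1:20) for (k in 1:5) {
    d <- sqrt(sum((((c(i, j, k)) - c(15, 10, 3)) * vs)^2))
    if (d < 1.2 && i > 10) cnt <- cnt + 1L
  }
  expect_equal(got, cnt)
})

test_that("noise-free enzyme-free phantoms are flat at baseline", {
  spec <- phantom_spec(grid_shape = c(6, 6, 1), n_frames = 30,
                       noise_sd = 0)
  ser <- generate_image_series(spec)
  expect_true(all(ser$data == spec$baseline))
})

test_that("generation is a pure function of the seed", {
  spec <- small_phantom(noise_sd = 0.5, n_frames = 40, seed = 9)
  a <- generate_image_series(spec)
  b <- generate_image_series(spec)
  expect_identical(a$data, b$data)
  spec2 <- spec; spec2$seed <- 10
  c2 <- generate_image_series(spec2)
  expect_false(identical(a$data, c2$data))
  # generation does not disturb the session RNG stream
  set.seed(123); x1 <- rnorm(3)
  set.seed(123); invisible(generate_image_series(spec)); x2 <- rnorm(3)
  expect_identical(x1, x2)
})

test_that("radial delivery field is symmetric and falls off as inverse square", {
  spec <- phantom_spec(grid_shape = c(11, 11, 9), voxel_size = c(1, 1, 1),
                       n_frames = 10)
  site <- c(6, 6, 5)
  f <- generate_radial_vin_field(1, 100, site, spec)
  expect_equal(f, f[11:1, , ])      # mirror symmetry about the site
  expect_equal(f, f[, 11:1, ])
  # inverse-square ratio between voxels 2 and 4 slices from the site
  expect_equal(f[6, 6, 7] / f[6, 6, 9], 4, tolerance = 1e-10)
  # matches the scalar geometry operation at a known distance (1 mm^3 voxel
  # volume is 1 uL)
  vv <- prod(spec$voxel_size)
  expect_equal(f[6, 6, 9], radial_infusion_rate(1, 100, 1, 4, vv),
               tolerance = 1e-12)
  # near-site clamp: site voxel equals the value at one voxel pitch
  expect_equal(f[6, 6, 5], radial_infusion_rate(1, 100, 1, 1, vv),
               tolerance = 1e-12)
})

test_that("paper-scale phantoms produce single-digit-to-low-teens peak responses", {
  # A = 20 %/nM, 10-min infusion at the remote-delivery rate, activity peaks
  # spanning the fitted in vivo range
  sched <- infusion_schedule(300, 600, 0.0108)
  tt <- seq(0, 1800, by = 4)
  peaks <- sapply(c(0.015, 0.03), function(k) {
    tr <- closed_form_concentrations(
      kinetic_params(k, v_out = 0.3, c_out = 1e-4), sched, tt)
    max(20 * tr$C)
  })
  expect_gt(peaks[1], 4); expect_lt(peaks[1], 10)
  expect_gt(peaks[2], 10); expect_lt(peaks[2], 18)
})

test_that("the infusion-dip artifact subtracts a boxcar during its window", {
  spec <- small_phantom(k = 0, noise_sd = 0, n_frames = 100)
  spec$artifact_dip <- list(amplitude = 2, window = c(300, 900))
  ser <- generate_image_series(spec)
  tt <- frame_times(ser)
  v <- ser$data[4, 4, 1, ]
  expect_equal(unique(v[tt < 300]), 100)
  expect_equal(unique(v[tt >= 300 & tt <= 900]), 100 * (1 - 2 / 100))
})

test_that("dose-response generator hits the Hill midpoint and asymptotes", {
  spec <- assay_spec(ec50_true = 6.7, noise_sd = 0,
                     concentrations = c(0.1, 1, 6.7, 50, 1e6))
  tab <- generate_dose_response(spec)
  mid <- tab$response[tab$conc_nM == 6.7]
  expect_equal(unique(mid), (spec$bottom + spec$top) / 2, tolerance = 1e-12)
  expect_equal(unique(tab$response[tab$conc_nM == 1e6]), spec$top,
               tolerance = 1e-4)
  # determinism
  spec2 <- assay_spec(ec50_true = 6.7, seed = 4)
  expect_identical(generate_dose_response(spec2),
                   generate_dose_response(spec2))
})
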