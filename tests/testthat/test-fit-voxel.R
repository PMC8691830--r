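# Voxel-level maps, jackknife errors, significance tests and the
# detection-limit simulation.

make_two_level_series <- function(noise_sd = 0, seed = 1) {
  # 6 x 6 x 1 phantom, two activity levels plus enzyme-free voxels; probe
  # efflux truth 0 so the amplitude is identifiable (with interior efflux
  # truth, A and k trade off exactly and only A*k is determined)
  spec <- small_phantom(noise_sd = noise_sd, n_frames = 120,
                        frame_time = 10, grid = c(6, 6, 1), seed = seed,
                        v_out_true = 0)
  km <- array(0, c(6, 6, 1))
  km[2:3, 2:4, 1] <- 0.01
  km[4:5, 2:4, 1] <- 0.02
  spec$k_map <- km
  spec
}

test_that("the global-amplitude grid search recovers truth on noiseless data", {
  spec <- make_two_level_series()
  ser <- generate_image_series(spec)
  pre <- percent_signal_change(ser, baseline_window = 100)
  vf <- fit_voxelwise(pre, schedule = infusion_schedule(300, 600, 0.0108),
                      A_grid = c(10, 20, 30))
  expect_equal(vf$A_global, 20)
  act <- spec$k_map > 0 & pre$brain_mask
  expect_lt(max(abs(vf$k_map[act] - spec$k_map[act]) / spec$k_map[act]),
            0.01)
  expect_true(all(vf$r2_map[act] > 0.99))
  # enzyme-free voxels come back at (numerically) zero activity
  nul <- spec$k_map == 0 & pre$brain_mask
  expect_lt(max(vf$k_map[nul]), 1e-6)
  expect_output(print(vf), "global A = 20")
})

test_that("a null phantom produces a null map with no significant voxels", {
  spec <- make_two_level_series()
  spec$k_map <- array(0, c(6, 6, 1))
  ser <- generate_image_series(spec)
  pre <- percent_signal_change(ser, baseline_window = 100)
  sched <- infusion_schedule(300, 600, 0.0108)
  vf1 <- fit_voxelwise(pre, schedule = sched, A_grid = 20)
  expect_lt(max(vf1$k_map, na.rm = TRUE), 1e-6)
  jk <- jackknife_k_sem(list(vf1$k_map, vf1$k_map), list(vf1$r2_map, vf1$r2_map),
                        r2_min = -Inf)
  tst <- voxel_ttests(jk$k_mean_map, jk$k_sem_map, jk$n_map)
  expect_false(any(tst$sig_mask))
})

test_that("jackknife SEM matches its closed forms and applies exclusions", {
  gs <- c(3, 3, 1)
  a <- array(1:9 / 100, gs); b <- array((9:1) / 100, gs)
  good <- array(0.99, gs)
  # identical maps: SEM 0
  jk0 <- jackknife_k_sem(list(a, a, a), list(good, good, good))
  expect_true(all(jk0$k_sem_map == 0))
  # two datasets: SEM = |a - b| / 2
  jk2 <- jackknife_k_sem(list(a, b), list(good, good))
  expect_equal(jk2$k_sem_map, abs(a - b) / 2, tolerance = 1e-12)
  # an R^2 below threshold excludes that dataset at that voxel
  bad <- good; bad[2, 2, 1] <- 0.85
  jk3 <- jackknife_k_sem(list(a, b, a), list(good, bad, good))
  expect_equal(jk3$n_map[2, 2, 1], 2L)
  expect_equal(jk3$reason_codes[2, 2, 1, 2], 1L)
  expect_equal(jk3$n_map[1, 1, 1], 3L)
  # unphysical k excluded with its own code
  hot <- a; hot[1, 2, 1] <- 11
  jk4 <- jackknife_k_sem(list(hot, b, a), list(good, good, good))
  expect_equal(jk4$reason_codes[1, 2, 1, 1], 2L)
  expect_equal(jk4$n_map[1, 2, 1], 2L)
})

test_that("voxel t-tests convert mean/SEM maps to two-sided p-values", {
  gs <- c(2, 2, 1)
  mu <- array(c(0, 0.0127, 0.01, 0.02), gs)
  se <- array(c(0.01, 0.001, 0, 0.005), gs)
  n <- array(2L, gs)
  tst <- voxel_ttests(mu, se, n, alpha = 0.05)
  expect_equal(tst$p_map[1, 1, 1], 1)                  # zero mean
  # mean/SEM = 12.7 at df = 1 sits right at p = 0.05
  expect_equal(tst$p_map[2, 1, 1], 0.05, tolerance = 1e-3)
  # zero SEM with nonzero mean: smallest representable p
  expect_equal(tst$p_map[1, 2, 1], .Machine$double.xmin)
  # alpha = 0 masks everything out
  expect_false(any(voxel_ttests(mu, se, n, alpha = 0)$sig_mask))
  # n below the minimum is never significant
  n2 <- n; n2[2, 2, 1] <- 1L
  expect_false(voxel_ttests(mu, se, n2)$sig_mask[2, 2, 1])
})

test_that("group amplitude comparisons behave at the edges and under power", {
  tt <- seq(0, 1000, 10)
  mk <- function(v) signal_ts(tt, rep(v, length(tt)))
  same <- list(mk(5), mk(5), mk(5))
  out <- response_amplitude_test(same, same, timepoint = 900)
  expect_equal(out$p.value, 1)
  expect_equal(out$difference, 0)
  expect_equal(response_amplitude_test(list(mk(13.1), mk(13.1)),
                                       list(mk(0), mk(0)),
                                       timepoint = 900)$mean_test, 13.1)
  # power: true difference 12%, subject SD 2%, n = 3 -> significant in
  # at least 95% of simulation rounds
  set.seed(99)
  hits <- replicate(400, {
    test <- lapply(rnorm(3, 12, 2), mk)
    ctrl <- lapply(rnorm(3, 0, 2), mk)
    response_amplitude_test(test, ctrl, timepoint = 500,
                            paired = FALSE)$p.value <= 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("the detection limit is reached at the first grid point without noise and grows with noise", {
  sched <- infusion_schedule(120, 600, 0.0108)
  tt <- seq(0, 1200, by = 10)
  grid <- c(0.002, 0.005, 0.012, 0.03)
  d0 <- detection_limit(grid, noise_sd = 0, v_in = 0.0108, schedule = sched,
                        times = tt, n_reps = 4, n_null = 4, seed = 2)
  expect_equal(d0$k_min, 0.002)
  d1 <- detection_limit(grid, noise_sd = 0.3, v_in = 0.0108,
                        schedule = sched, times = tt, n_reps = 10,
                        n_null = 12, seed = 2)
  d2 <- detection_limit(grid, noise_sd = 1.2, v_in = 0.0108,
                        schedule = sched, times = tt, n_reps = 10,
                        n_null = 12, seed = 2)
  expect_gte(d2$k_min, d1$k_min)
  expect_gte(d1$k_min, d0$k_min)
  # concentration conversion rides along
  expect_equal(d1$fap_min, fap_from_rate(d1$k_min))
})

test_that("ROI and voxel fits agree on uniform-activity phantoms", {
  spec <- small_phantom(k = 0.01, noise_sd = 0, n_frames = 120,
                        frame_time = 10, grid = c(4, 4, 1))
  ser <- generate_image_series(spec)
  pre <- percent_signal_change(ser, baseline_window = 100)
  sched <- infusion_schedule(300, 600, 0.0108)
  vf <- fit_voxelwise(pre, schedule = sched, A_grid = 20)
  roi <- roi_spec(center = c(2, 2, 1), extent = c(0.5, 0.5))
  rf <- fit_roi(roi_timecourse(pre, roi), v_in = 0.0108, schedule = sched,
                A_fixed = 20)
  k_vox <- median(vf$k_map, na.rm = TRUE)
  expect_lt(abs(k_vox - coef(rf)["k"]) / coef(rf)["k"], 0.05)
})
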