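# Preprocessing operators: smoothing, normalization, percent signal change,
# ROI extraction, and the optical transect width measurement.

series_from_array <- function(arr, frame_time = 10, onset = 600, ...) {
  image_series(arr, frame_time = frame_time, onset = onset, ...)
}

test_that("temporal smoothing is a truncated centered moving average", {
  nt <- 60
  arr <- array(5, c(2, 2, 1, nt))
  s <- series_from_array(arr)
  expect_equal(temporal_smooth(s, 60)$data, arr)
  # impulse spreads into a plateau of h/n
  arr2 <- array(0, c(1, 1, 1, nt)); arr2[1, 1, 1, 30] <- 12
  sm <- temporal_smooth(series_from_array(arr2), 60)  # n = 6 frames
  expect_equal(max(sm$data), 2)
  expect_equal(sum(sm$data[1, 1, 1, ] == 2), 6)
  # brute-force oracle on random data at interior and edge indices
  set.seed(5)
  arr3 <- array(rnorm(4 * nt), c(2, 2, 1, nt))
  sm3 <- temporal_smooth(series_from_array(arr3), 50)  # n = 5 frames
  for (t in c(1, 2, 17, 40, nt)) {
    lo <- max(1, t - 2); hi <- min(nt, t + 2)
    expect_equal(sm3$data[2, 1, 1, t], mean(arr3[2, 1, 1, lo:hi]),
                 tolerance = 1e-12)
  }
  expect_error(temporal_smooth(series_from_array(arr), 5), "frame time")
})

test_that("global normalization removes a purely global multiplicative drift", {
  nt <- 50
  base <- array(runif(16, 90, 110), c(4, 4, 1))
  g <- 1 + 0.05 * sin(seq_len(nt) / 5)
  arr <- outer(array(base, c(4, 4, 1)), g)
  s <- global_normalize(series_from_array(arr))
  # every voxel flat after normalization (up to the constant mean(g) factor)
  for (v in list(c(1, 1), c(3, 2))) {
    trace <- s$data[v[1], v[2], 1, ]
    expect_lt(diff(range(trace)) / mean(trace), 1e-12)
  }
  # a drift-free series is unchanged
  arr2 <- outer(array(base, c(4, 4, 1)), rep(1, nt))
  s2 <- global_normalize(series_from_array(arr2))
  expect_equal(s2$data, arr2, tolerance = 1e-12)
})

test_that("local signal survives global normalization on a mixed construction", {
  nt <- 80
  g <- 1 + 0.03 * cos(seq_len(nt) / 7)
  arr <- array(100, c(10, 10, 1, nt))
  local_sig <- 5 * pmin(pmax((seq_len(nt) - 30) / 20, 0), 1)
  arr[5, 5, 1, ] <- 100 + local_sig
  for (t in seq_len(nt)) arr[, , , t] <- arr[, , , t] * g[t]
  s <- global_normalize(series_from_array(arr))
  rec <- s$data[5, 5, 1, ] - s$data[2, 2, 1, ]
  expect_equal(rec, local_sig, tolerance = 0.05)
})

test_that("percent signal change uses the pre-onset baseline and guards reapplication", {
  nt <- 100
  arr <- array(100, c(3, 3, 1, nt))
  arr[, , , 61:nt] <- 113.1
  s <- series_from_array(arr, frame_time = 10, onset = 600)
  p <- percent_signal_change(s)        # baseline = 60 s before onset
  expect_equal(unique(as.vector(p$data[, , , 1:60])), 0)
  expect_equal(unique(as.vector(p$data[, , , 61:nt])), 13.1,
               tolerance = 1e-9)
  expect_error(percent_signal_change(p), "already")
  # non-positive baseline flags the voxel instead of erroring
  arr2 <- arr; arr2[2, 2, 1, ] <- 0
  p2 <- percent_signal_change(series_from_array(arr2))
  expect_false(p2$brain_mask[2, 2, 1])
  expect_true(all(is.na(p2$data[2, 2, 1, ])))
})

test_that("spatial smoothing conserves mass and realizes the requested width", {
  arr <- array(0, c(21, 21, 1, 1))
  arr[11, 11, 1, 1] <- 100
  s <- image_series(arr, frame_time = 1, voxel_size = c(0.5, 0.5, 1))
  expect_identical(spatial_smooth(s, 0)$data, arr)
  sm <- spatial_smooth(s, 1.5)
  expect_equal(sum(sm$data), 100, tolerance = 1e-6)
  # width of the point-spread along x, in mm
  prof <- sm$data[, 11, 1, 1]
  w <- vessel_fwhm(prof, coords = (1:21) * 0.5)
  expect_equal(w, 1.5, tolerance = 0.1 * 1.5)
  # random image: mass still conserved under reflective padding
  set.seed(8)
  arr2 <- array(runif(21 * 21), c(21, 21, 1, 1))
  s2 <- image_series(arr2, frame_time = 1, voxel_size = c(0.5, 0.5, 1))
  expect_equal(sum(spatial_smooth(s2, 1)$data), sum(arr2), tolerance = 1e-6)
})

test_that("ROI time courses are plain in-mask means", {
  nt <- 20
  set.seed(2)
  arr <- array(rnorm(5 * 5 * 1 * nt, 100), c(5, 5, 1, nt))
  s <- series_from_array(arr, onset = 100)
  roi <- roi_spec(center = c(3, 3, 1), extent = c(1.2, 1.2))
  tc <- roi_timecourse(s, roi)
  # brute force: voxel box from the spec extent (1.2 mm at 1 mm pitch -> 1
  # voxel half-width would be 0; defaults voxel_size 1 so half = 0)
  expect_equal(tc$values, arr[3, 3, 1, ], tolerance = 1e-12)
  # wider ROI on a finer grid
  s2 <- image_series(arr, frame_time = 10, voxel_size = c(0.39, 0.39, 1),
                     onset = 100)
  tc2 <- roi_timecourse(s2, roi)
  expect_equal(tc2$values,
               apply(arr[2:4, 2:4, 1, , drop = FALSE], 4, mean),
               tolerance = 1e-12)
  # uniform frames return the uniform value
  arr3 <- array(rep(seq_len(nt), each = 25), c(5, 5, 1, nt))
  expect_equal(roi_timecourse(series_from_array(arr3, onset = 100),
                              roi)$values, as.numeric(seq_len(nt)))
})

test_that("vessel transect width is exact for a rectangular dip and 2.355 sigma for a Gaussian", {
  x <- seq(0, 60)
  prof <- rep(100, length(x)); prof[26:33] <- 40   # 8-sample dip
  expect_equal(vessel_fwhm(prof), 8)
  sig <- 4
  g <- 100 - 60 * exp(-(x - 30)^2 / (2 * sig^2))
  expect_equal(vessel_fwhm(g), 2.355 * sig, tolerance = 0.02 * 2.355 * sig)
  # intensity scaling leaves the width unchanged
  expect_equal(vessel_fwhm(3.7 * g), vessel_fwhm(g))
  expect_error(vessel_fwhm(rep(1, 20) + c(rep(0, 19), 5)), "crossing")
})

test_that("the full noiseless pipeline recovers the modeled signal change", {
  # uniform activity: every voxel shares one true trace, so smoothing
  # leaves spatial structure untouched and the output should match
  # A_true * C(t) closely away from the temporal edges
  spec <- small_phantom(k = 0.008, noise_sd = 0, n_frames = 160,
                        frame_time = 10)
  ser <- generate_image_series(spec)
  pre <- preprocess_series(ser, steps = c("temporal_smooth",
                                          "percent_signal_change",
                                          "spatial_smooth"))
  tt <- frame_times(ser)
  truth <- closed_form_concentrations(
    kinetic_params(0.008, spec$v_out_true, spec$c_out_true),
    infusion_schedule(300, 600, 0.0108), tt)
  want <- spec$A_true * truth$C
  got <- pre$data[4, 4, 1, ]
  interior <- tt > 100 & tt < max(tt) - 100
  expect_lt(max(abs(got - want)[interior]), 0.5)
})

test_that("preprocessing is mask-aware and validates steps", {
  arr <- array(100, c(4, 4, 1, 30))
  msk <- array(TRUE, c(4, 4, 1)); msk[1, 1, 1] <- FALSE
  s <- image_series(arr, frame_time = 10, onset = 200, brain_mask = msk)
  expect_error(preprocess_series(s, steps = "despike"), "unknown")
  p <- preprocess_series(s, steps = c("global_normalize",
                                      "percent_signal_change"),
                         baseline_window = 100)
  expect_equal(sum(p$brain_mask), 15)
})
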