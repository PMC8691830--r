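# Preprocessing of 4D hemodynamic image series.
#
# The container is a light S3 list around an (x, y, z, t) array plus the
# acquisition metadata needed downstream: frame time, voxel size, infusion
# onset, a brain mask, and a provenance record of applied steps.  Voxels
# outside the brain mask are carried as NA and excluded from statistics.

#' Construct a 4D image-series container
#'
#' @param data Numeric 4D array with dimensions (x, y, z, t).
#' @param frame_time Time per frame (s), positive.
#' @param voxel_size Length-3 numeric, voxel pitch per spatial axis (mm).
#' @param onset Infusion onset time (s), or `NULL` if not applicable.
#' @param brain_mask Logical 3D array matching the spatial grid; `NULL` means
#'   all voxels in-brain.
#' @param provenance Character vector of processing steps already applied.
#' @return An object of class `"image_series"`.
#' @export
image_series <- function(data, frame_time, voxel_size = c(1, 1, 1),
                         onset = NULL, brain_mask = NULL,
                         provenance = character()) {
  stopifnot(is.array(data), length(dim(data)) == 4L,
            is.numeric(frame_time), frame_time > 0,
            length(voxel_size) == 3L, all(voxel_size > 0))
  if (is.null(brain_mask)) {
    brain_mask <- array(TRUE, dim(data)[1:3])
  }
  stopifnot(is.logical(brain_mask),
            all(dim(brain_mask) == dim(data)[1:3]))
  structure(list(data = data, frame_time = frame_time,
                 voxel_size = as.numeric(voxel_size), onset = onset,
                 brain_mask = brain_mask, provenance = provenance),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Image series: %d x %d x %d voxels, %d frames @ %g s\n",
              d[1], d[2], d[3], d[4], x$frame_time))
  cat(sprintf("  voxel size: %s mm; %d in-mask voxels\n",
              paste(signif(x$voxel_size, 3), collapse = " x "),
              sum(x$brain_mask)))
  if (length(x$provenance))
    cat("  applied:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Frame acquisition times of an image series
#'
#' Frame n is stamped at `(n - 1) * frame_time`, i.e. time 0 is the first
#' frame.
#'
#' @param series An `"image_series"`.
#' @return Numeric vector of frame times (s).
#' @export
frame_times <- function(series) {
  stopifnot(inherits(series, "image_series"))
  (seq_len(dim(series$data)[4]) - 1) * series$frame_time
}

# flatten the spatial dims: voxels x time matrix
.as_vox_time <- function(series) {
  d <- dim(series$data)
  matrix(series$data, nrow = prod(d[1:3]), ncol = d[4])
}

.from_vox_time <- function(series, m) {
  series$data <- array(m, dim(series$data))
  series
}

#' Temporal smoothing by centered moving average
#'
#' Each voxel's time course is replaced by a centered moving average over
#' `ceiling(window / frame_time)` frames.  Edge windows are truncated and
#' renormalized (mean over the available frames).
#'
#' @param series An `"image_series"`.
#' @param window Smoothing window (s); must be at least one frame time.
#' @return The smoothed `"image_series"` with provenance updated.
#' @export
temporal_smooth <- function(series, window = 60) {
  stopifnot(inherits(series, "image_series"))
  if (window < series$frame_time)
    stop("`window` must be at least one frame time")
  n <- ceiling(window / series$frame_time)
  nt <- dim(series$data)[4]
  half_l <- (n - 1L) %/% 2L
  half_r <- n - 1L - half_l
  m <- .as_vox_time(series)
  out <- matrix(NA_real_, nrow(m), nt)
  for (t in seq_len(nt)) {
    lo <- max(1L, t - half_l)
    hi <- min(nt, t + half_r)
    out[, t] <- rowMeans(m[, lo:hi, drop = FALSE])
  }
  series <- .from_vox_time(series, out)
  series$provenance <- c(series$provenance, sprintf("temporal_smooth(%gs)", window))
  series
}

#' Remove global multiplicative signal fluctuations
#'
#' Divides each frame by its mean over the brain mask, rescaled by the time
#' average of those frame means, so a purely global multiplicative drift
#' g(t) is removed while the overall signal level is preserved.  With
#' `method = "additive"` the frame-mean deviation is subtracted instead.
#'
#' @param series An `"image_series"`.
#' @param method `"multiplicative"` (default) or `"additive"`.
#' @return The normalized `"image_series"`.
#' @export
global_normalize <- function(series,
                             method = c("multiplicative", "additive")) {
  stopifnot(inherits(series, "image_series"))
  method <- match.arg(method)
  if (!any(series$brain_mask)) stop("brain mask is empty")
  m <- .as_vox_time(series)
  msk <- as.vector(series$brain_mask)
  g <- colMeans(m[msk, , drop = FALSE], na.rm = TRUE)
  gbar <- mean(g)
  if (method == "multiplicative") {
    if (any(g <= 0)) stop("non-positive frame means; cannot normalize multiplicatively")
    m <- sweep(m, 2, g / gbar, "/")
  } else {
    m <- sweep(m, 2, g - gbar, "-")
  }
  series <- .from_vox_time(series, m)
  series$provenance <- c(series$provenance, paste0("global_normalize(", method, ")"))
  series
}

#' Convert raw signal to percent change from a pre-infusion baseline
#'
#' Per voxel, `100 * (S(t) - B) / B` with `B` the mean over a baseline
#' window ending at infusion onset.  Voxels with non-positive baseline are
#' not an error: they are removed from the brain mask and set to `NA`.
#' Guarded against double application via the provenance record.
#'
#' @param series An `"image_series"` with a known infusion `onset`.
#' @param baseline_window Baseline averaging window (s) immediately before
#'   onset; default 60 s.
#' @param onset Infusion onset (s); defaults to `series$onset`.
#' @return An `"image_series"` in percent-signal-change units.
#' @export
percent_signal_change <- function(series, baseline_window = 60, onset = NULL) {
  stopifnot(inherits(series, "image_series"))
  if (any(grepl("^percent_signal_change", series$provenance)))
    stop("series is already in percent-signal-change units")
  if (is.null(onset)) onset <- series$onset
  if (is.null(onset)) stop("infusion `onset` must be provided")
  tt <- frame_times(series)
  base_idx <- which(tt < onset & tt >= onset - baseline_window)
  if (!length(base_idx)) stop("baseline window contains no frames before onset")
  m <- .as_vox_time(series)
  B <- rowMeans(m[, base_idx, drop = FALSE])
  bad <- !is.na(B) & B <= 0
  B[bad | is.na(B)] <- NA_real_
  m <- 100 * (m - B) / B
  series <- .from_vox_time(series, m)
  series$brain_mask <- series$brain_mask & !array(bad, dim(series$brain_mask))
  series$provenance <- c(series$provenance,
                         sprintf("percent_signal_change(%gs)", baseline_window))
  series
}

# 1D Gaussian kernel for a given FWHM (in voxels); returns NULL when no
# smoothing is needed along this axis.
.gauss_kernel <- function(fwhm_vox) {
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  if (sigma <= 0) return(NULL)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# convolve along one margin of a 3D array with half-sample symmetric
# (reflective) padding; conserves total mass for kernel radius <= axis length
.convolve_axis <- function(vol, kernel, axis) {
  if (is.null(kernel)) return(vol)
  d <- dim(vol)
  n <- d[axis]
  r <- (length(kernel) - 1L) %/% 2L
  idx <- seq(1L - r, n + r)
  idx[idx < 1L] <- 1L - idx[idx < 1L]        # reflect low edge
  idx[idx > n] <- 2L * n + 1L - idx[idx > n] # reflect high edge
  idx[idx < 1L] <- 1L; idx[idx > n] <- n     # guard: kernel wider than axis
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(vol, perm)
  dm <- dim(m)
  m <- matrix(m, nrow = dm[1])
  padded <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * padded[j:(j + n - 1L), , drop = FALSE]
  }
  out <- array(out, dm)
  aperm(out, order(perm))
}

#' Spatial Gaussian smoothing of each frame
#'
#' Separable Gaussian convolution with the requested full width at half
#' maximum in mm, converted per axis to voxel units so anisotropic voxels
#' are respected.  Boundaries use half-sample symmetric (reflective)
#' padding, which conserves the in-frame total.  `fwhm = 0` is the
#' identity.
#'
#' @param series An `"image_series"`.
#' @param fwhm Kernel full width at half maximum (mm), >= 0.
#' @return The smoothed `"image_series"`.
#' @export
spatial_smooth <- function(series, fwhm = 1) {
  stopifnot(inherits(series, "image_series"), is.numeric(fwhm), fwhm >= 0)
  if (fwhm == 0) return(series)
  kernels <- lapply(series$voxel_size, function(vs) .gauss_kernel(fwhm / vs))
  d <- dim(series$data)
  for (t in seq_len(d[4])) {
    vol <- series$data[, , , t, drop = FALSE]
    dim(vol) <- d[1:3]
    for (ax in 1:3) vol <- .convolve_axis(vol, kernels[[ax]], ax)
    series$data[, , , t] <- vol
  }
  series$provenance <- c(series$provenance, sprintf("spatial_smooth(%gmm)", fwhm))
  series
}

#' Default preprocessing pipeline
#'
#' Applies, in order: global normalization, temporal smoothing, conversion
#' to percent signal change, and spatial smoothing.  The order and the
#' individual steps are configurable through the `steps` argument.
#'
#' @param series A raw `"image_series"`.
#' @param steps Character vector drawn from `"global_normalize"`,
#'   `"temporal_smooth"`, `"percent_signal_change"`, `"spatial_smooth"`,
#'   applied in the given order.
#' @param temporal_window Temporal smoothing window (s).
#' @param baseline_window Baseline window for percent signal change (s).
#' @param fwhm Spatial smoothing FWHM (mm).
#' @return The preprocessed `"image_series"`.
#' @export
preprocess_series <- function(series,
                              steps = c("global_normalize", "temporal_smooth",
                                        "percent_signal_change", "spatial_smooth"),
                              temporal_window = 60, baseline_window = 60,
                              fwhm = 1) {
  stopifnot(inherits(series, "image_series"))
  known <- c("global_normalize", "temporal_smooth", "percent_signal_change",
             "spatial_smooth")
  bad <- setdiff(steps, known)
  if (length(bad)) stop("unknown preprocessing steps: ", paste(bad, collapse = ", "))
  for (s in steps) {
    series <- switch(s,
      global_normalize = global_normalize(series),
      temporal_smooth = temporal_smooth(series, temporal_window),
      percent_signal_change = percent_signal_change(series, baseline_window),
      spatial_smooth = spatial_smooth(series, fwhm))
  }
  series
}

#' Region-of-interest specification
#'
#' A box-shaped ROI given by its center voxel and in-plane extent in mm.
#'
#' @param center Length-3 voxel coordinates (1-based) of the ROI center.
#' @param extent Length-2 in-plane extent (mm), e.g. `c(1.2, 1.2)`.
#' @param slices Slice indices included; defaults to the center slice.
#' @return An object of class `"roi_spec"`.
#' @export
roi_spec <- function(center, extent = c(1.2, 1.2), slices = center[3]) {
  stopifnot(length(center) == 3L, length(extent) == 2L, all(extent > 0))
  structure(list(center = center, extent = extent, slices = slices),
            class = "roi_spec")
}

# indices of ROI voxels within a series grid
.roi_indices <- function(series, roi) {
  d <- dim(series$data)[1:3]
  half <- pmax(0L, floor(roi$extent / series$voxel_size[1:2] / 2))
  xr <- (roi$center[1] - half[1]):(roi$center[1] + half[1])
  yr <- (roi$center[2] - half[2]):(roi$center[2] + half[2])
  xr <- xr[xr >= 1 & xr <= d[1]]
  yr <- yr[yr >= 1 & yr <= d[2]]
  zr <- roi$slices[roi$slices >= 1 & roi$slices <= d[3]]
  if (!length(xr) || !length(yr) || !length(zr)) stop("ROI outside the grid")
  list(x = xr, y = yr, z = zr)
}

#' Mean ROI time course
#'
#' Unweighted mean over in-mask ROI voxels per frame.
#'
#' @param series An `"image_series"` (typically percent signal change).
#' @param roi An [roi_spec()].
#' @return A `"signal_ts"` with the ROI-mean time course.
#' @export
roi_timecourse <- function(series, roi) {
  stopifnot(inherits(series, "image_series"), inherits(roi, "roi_spec"))
  ix <- .roi_indices(series, roi)
  sub <- series$data[ix$x, ix$y, ix$z, , drop = FALSE]
  msk <- series$brain_mask[ix$x, ix$y, ix$z, drop = FALSE]
  nt <- dim(sub)[4]
  m <- matrix(sub, nrow = prod(dim(sub)[1:3]), ncol = nt)
  m <- m[as.vector(msk), , drop = FALSE]
  if (!nrow(m)) stop("ROI contains no in-mask voxels")
  signal_ts(frame_times(series), colMeans(m))
}

#' Full width at half height of a vessel transect
#'
#' Measures the width of the dominant extremum (dip or peak) in a 1D
#' intensity profile: the local background is estimated from the profile
#' ends, the half-height level is set midway between background and
#' extremum, and the two crossings are located by linear interpolation.
#'
#' @param profile Numeric intensity profile along the transect.
#' @param coords Positions of the samples (same units as the returned
#'   width); defaults to `seq_along(profile)`.
#' @param background_frac Fraction of samples at each end used to estimate
#'   the local background (default 0.1, at least 2 samples).
#' @return Width at half height, in `coords` units.
#' @export
vessel_fwhm <- function(profile, coords = seq_along(profile),
                        background_frac = 0.1) {
  stopifnot(is.numeric(profile), length(profile) >= 5L,
            length(coords) == length(profile))
  n <- length(profile)
  ne <- max(2L, floor(n * background_frac))
  bg <- mean(c(profile[seq_len(ne)], profile[(n - ne + 1L):n]))
  dev <- profile - bg
  i0 <- which.max(abs(dev))
  half <- bg + dev[i0] / 2
  cross <- function(idx_seq) {
    # walk away from the extremum until the profile crosses the half level
    prev <- i0
    for (i in idx_seq) {
      if ((profile[i] - half) * (profile[prev] - half) <= 0 &&
          profile[i] != profile[prev]) {
        f <- (half - profile[prev]) / (profile[i] - profile[prev])
        return(coords[prev] + f * (coords[i] - coords[prev]))
      }
      prev <- i
    }
    NA_real_
  }
  left <- if (i0 > 1) cross((i0 - 1):1) else NA_real_
  right <- if (i0 < n) cross((i0 + 1):n) else NA_real_
  if (is.na(left) || is.na(right))
    stop("no half-height crossing on one side of the extremum")
  abs(right - left)
}
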