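# Ground-truth-known synthetic data generators.
#
# The image phantom emulates the in vivo rat acquisitions: a baseline raw
# signal volume, a localized region of enzymatic activity (a k-map derived
# from an enzyme-concentration field), piecewise-constant probe infusion
# (uniform, or an inverse-square field radiating from a remote site), a
# hemodynamic signal proportional to activated-product concentration,
# additive Gaussian noise, and an optional infusion-period dip artifact.
# Every generator is a pure function of (spec, seed).

#' Phantom specification for synthetic 4D image series
#'
#' Defaults emulate the wide-field echo-planar acquisitions: 390 um x 390 um
#' x 1 mm voxels, 4 s frames, 5 min baseline followed by a 10 min infusion
#' and a post-infusion period, hemodynamic amplitude 20 %/nM, and efflux
#' rates in the regime seen in voxel-level fits (probe efflux a few tenths
#' per second, product efflux below 1e-3 per second).
#'
#' @param grid_shape Length-3 integer, voxels per axis.
#' @param voxel_size Length-3 numeric, mm per axis.
#' @param frame_time Seconds per frame.
#' @param n_frames Number of frames.
#' @param baseline Raw baseline signal level (arbitrary units).
#' @param A_true Hemodynamic amplitude (percent signal change per nM).
#' @param v_out_true,c_out_true True efflux rates (s^-1).
#' @param infusion An [infusion_schedule()] (uniform delivery to all voxels),
#'   or a list with fields `pump_rate` (uL/min), `probe_conc` (nM), `site`
#'   (length-3 voxel coordinates) for inverse-square radial delivery from a
#'   remote site; `onset` and `duration` (s) are required either way.
#' @param noise_sd Additive Gaussian noise SD on the raw signal.
#' @param artifact_dip Optional list `list(amplitude, window)`: a negative
#'   boxcar of `amplitude` percent during `window = c(from, to)` seconds,
#'   emulating the infusion-period dip artifact; `NULL` disables it.
#' @param seed RNG seed making generation deterministic.
#' @return An object of class `"phantom_spec"`.  The enzyme field is added
#'   with [make_fap_phantom()] (or set `k_map` directly).
#' @export
phantom_spec <- function(grid_shape = c(24, 24, 3),
                         voxel_size = c(0.39, 0.39, 1),
                         frame_time = 4, n_frames = 450,
                         baseline = 100, A_true = 20,
                         v_out_true = 0.3, c_out_true = 1e-4,
                         infusion = infusion_schedule(300, 600, 0.0108),
                         noise_sd = 0.5, artifact_dip = NULL, seed = 1) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1),
            length(voxel_size) == 3L, all(voxel_size > 0),
            frame_time > 0, n_frames >= 1, baseline > 0,
            A_true >= 0, v_out_true >= 0, c_out_true >= 0, noise_sd >= 0)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 frame_time = frame_time, n_frames = as.integer(n_frames),
                 baseline = baseline, A_true = A_true,
                 v_out_true = v_out_true, c_out_true = c_out_true,
                 infusion = infusion, noise_sd = noise_sd,
                 artifact_dip = artifact_dip, seed = seed,
                 fap_map = NULL, k_map = NULL),
            class = "phantom_spec")
}

# mm coordinates of voxel centers along each axis (0-based voxel indexing
# maps center of voxel i to (i - 1) * pitch in this convention; R arrays are
# 1-based so voxel j has center (j - 1) * pitch)
.voxel_centers <- function(grid_shape, voxel_size) {
  lapply(1:3, function(ax) (seq_len(grid_shape[ax]) - 1) * voxel_size[ax])
}

# Euclidean distance (mm) of every voxel center from a site given in voxel
# coordinates (may be fractional or outside the grid)
.voxel_distances <- function(grid_shape, voxel_size, site) {
  ctr <- .voxel_centers(grid_shape, voxel_size)
  site_mm <- (site - 1) * voxel_size
  dx <- ctr[[1]] - site_mm[1]
  dy <- ctr[[2]] - site_mm[2]
  dz <- ctr[[3]] - site_mm[3]
  d2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
  sqrt(d2)
}

#' Add a localized enzyme-activity region to a phantom
#'
#' Places an isotropic, radially tapered enzyme concentration field
#' `fap(d) = peak_fap * 2^-(d / radius)^2` (a Gaussian taper whose half-max
#' falls exactly at `d = radius`) around `center`, converts it to a k-map
#' via [rate_from_fap()], and zeroes the opposite hemisphere (split along
#' the first axis) so the phantom carries an enzyme-free control side.
#'
#' @param spec A [phantom_spec()].
#' @param center Length-3 voxel coordinates of the enzyme focus; must lie
#'   inside the grid.
#' @param radius Half-maximum radius of the taper (mm), positive.
#' @param peak_fap Peak enzyme concentration (nM), >= 0.
#' @param enz [enzyme_constants()] used for the rate conversion.
#' @return The spec with `fap_map` and `k_map` filled in.
#' @export
make_fap_phantom <- function(spec, center, radius, peak_fap,
                             enz = enzyme_constants()) {
  stopifnot(inherits(spec, "phantom_spec"), length(center) == 3L,
            radius > 0, peak_fap >= 0)
  if (any(center < 1) || any(center > spec$grid_shape))
    stop("`center` must lie inside the grid")
  d <- .voxel_distances(spec$grid_shape, spec$voxel_size, center)
  fap <- peak_fap * 2^(-(d / radius)^2)
  # enzyme-free control hemisphere: the half of the first axis not
  # containing the focus
  mid <- (spec$grid_shape[1] + 1) / 2
  xi <- seq_len(spec$grid_shape[1])
  ctrl <- if (center[1] >= mid) xi < mid else xi > mid
  fap[ctrl, , ] <- 0
  spec$fap_map <- fap
  spec$k_map <- array(rate_from_fap(fap, enz), dim(fap))
  spec$enz <- enz
  spec
}

#' Per-voxel delivery-rate field for remote radial infusion
#'
#' Evaluates [radial_infusion_rate()] at every voxel center's distance from
#' the infusion site.  Voxels closer than one voxel pitch are clamped to
#' the value at one pitch to avoid the point-source singularity; the pitch
#' is the largest voxel dimension.
#'
#' @param pump_rate Pump rate (uL/min).
#' @param probe_conc Injected probe concentration (nM).
#' @param site Length-3 voxel coordinates of the infusion site (may be
#'   fractional or just outside the grid).
#' @param spec A [phantom_spec()] supplying the grid and voxel size.
#' @return 3D array of per-voxel v_in (nM/s).
#' @export
generate_radial_vin_field <- function(pump_rate, probe_conc, site, spec) {
  stopifnot(inherits(spec, "phantom_spec"), length(site) == 3L)
  vs <- spec$voxel_size
  vcs <- prod(sort(vs)[1:2])  # nominal cross-section: two smallest pitches
  vv <- prod(vs)              # mm^3 == uL
  d <- .voxel_distances(spec$grid_shape, vs, site)
  pitch <- max(vs)
  d <- pmax(d, pitch)
  array(radial_infusion_rate(pump_rate, probe_conc, vcs, d, vv), dim(d))
}

# resolve the per-voxel v_in vector and the (onset, duration) window from a
# phantom spec's infusion field
.phantom_vin <- function(spec) {
  inf <- spec$infusion
  nvox <- prod(spec$grid_shape)
  if (inherits(inf, "infusion_schedule")) {
    list(v_in = rep(inf$v_in, nvox), onset = inf$onset, duration = inf$duration)
  } else if (is.list(inf)) {
    need <- c("pump_rate", "probe_conc", "site", "onset", "duration")
    miss <- setdiff(need, names(inf))
    if (length(miss)) stop("radial infusion spec missing: ",
                           paste(miss, collapse = ", "))
    vmap <- generate_radial_vin_field(inf$pump_rate, inf$probe_conc,
                                      inf$site, spec)
    list(v_in = as.vector(vmap), onset = inf$onset, duration = inf$duration)
  } else stop("unsupported `infusion` specification")
}

#' Generate a synthetic 4D image series from a phantom specification
#'
#' Per voxel, the raw signal is
#' `baseline * (1 + (A_true * C(t) + artifact(t)) / 100) + N(0, noise_sd)`,
#' with `C(t)` the closed-form activated-product concentration for the
#' voxel's activation rate and delivery rate.  Output is deterministic
#' given the spec's seed.
#'
#' @param spec A [phantom_spec()] with a `k_map` (see [make_fap_phantom()];
#'   a missing `k_map` is treated as all-zero, i.e. an enzyme-free phantom).
#' @return An object of class `"synthetic_series"`, which is an
#'   [image_series()] carrying the generating spec in `$truth`.
#' @export
generate_image_series <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  nvox <- prod(gs)
  k <- if (is.null(spec$k_map)) rep(0, nvox) else as.vector(spec$k_map)
  vin <- .phantom_vin(spec)
  tt <- (seq_len(spec$n_frames) - 1) * spec$frame_time
  pr <- .conc_profile(k, spec$v_out_true, spec$c_out_true, vin$v_in,
                      vin$onset, vin$duration, tt)
  psc <- spec$A_true * pr$C
  if (!is.null(spec$artifact_dip)) {
    ad <- spec$artifact_dip
    in_win <- tt >= ad$window[1] & tt <= ad$window[2]
    psc[, in_win] <- psc[, in_win] - ad$amplitude
  }
  raw <- spec$baseline * (1 + psc / 100)
  if (spec$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(spec$seed)
    raw <- raw + matrix(stats::rnorm(nvox * spec$n_frames, 0, spec$noise_sd),
                        nvox, spec$n_frames)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }
  # brain mask: everything except a one-voxel in-plane border
  msk <- array(TRUE, gs)
  if (gs[1] > 2) msk[c(1, gs[1]), , ] <- FALSE
  if (gs[2] > 2) msk[, c(1, gs[2]), ] <- FALSE
  out <- image_series(array(raw, c(gs, spec$n_frames)),
                      frame_time = spec$frame_time,
                      voxel_size = spec$voxel_size,
                      onset = vin$onset, brain_mask = msk)
  out$truth <- spec
  out$vin_map <- array(vin$v_in, gs)
  class(out) <- c("synthetic_series", class(out))
  out
}

#' Dose-response assay specification
#'
#' Emulates the replicate structure of the cell-based receptor-activation
#' bioassay: a log-spaced dilution series measured in technical replicates
#' with additive Gaussian response noise around a four-parameter Hill curve.
#'
#' @param ec50_true True EC50 (nM), positive.
#' @param hill_true True Hill slope.
#' @param bottom,top Response asymptotes (luminescence units).
#' @param concentrations Dilution series (nM), positive.
#' @param replicates Number of technical replicates per concentration.
#' @param noise_sd Response noise SD; defaults to 2% of the dynamic range.
#' @param seed RNG seed.
#' @return An object of class `"assay_spec"`.
#' @export
assay_spec <- function(ec50_true, hill_true = 1, bottom = 0, top = 1,
                       concentrations = 10^seq(-2, 2, length.out = 10),
                       replicates = 3,
                       noise_sd = 0.02 * (top - bottom), seed = 1) {
  stopifnot(ec50_true > 0, all(concentrations > 0), replicates >= 1,
            noise_sd >= 0, top > bottom)
  structure(list(ec50_true = ec50_true, hill_true = hill_true,
                 bottom = bottom, top = top,
                 concentrations = sort(concentrations),
                 replicates = as.integer(replicates),
                 noise_sd = noise_sd, seed = seed),
            class = "assay_spec")
}

# the four-parameter Hill response
.hill_response <- function(conc, bottom, top, ec50, hill) {
  ifelse(conc <= 0, bottom,
         bottom + (top - bottom) / (1 + (ec50 / conc)^hill))
}

#' Generate a synthetic dose-response table
#'
#' Replicate responses are `bottom + (top - bottom) / (1 + (EC50/c)^h)`
#' plus seeded Gaussian noise.
#'
#' @param spec An [assay_spec()].
#' @return A data frame with columns `conc_nM`, `replicate`, `response`,
#'   carrying the generating spec as attribute `"truth"`.
#' @export
generate_dose_response <- function(spec) {
  stopifnot(inherits(spec, "assay_spec"))
  conc <- rep(spec$concentrations, each = spec$replicates)
  mu <- .hill_response(conc, spec$bottom, spec$top, spec$ec50_true,
                       spec$hill_true)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(spec$seed)
  resp <- mu + stats::rnorm(length(mu), 0, spec$noise_sd)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  out <- data.frame(conc_nM = conc,
                    replicate = rep(seq_len(spec$replicates),
                                    times = length(spec$concentrations)),
                    response = resp)
  attr(out, "truth") <- spec
  out
}
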