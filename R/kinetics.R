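# Forward kinetic model of vasoprobe infusion, enzymatic activation and efflux.
#
# State variables (per voxel or ROI):
#   V  intact probe concentration (nM)
#   C  activated product concentration (nM)
# Dynamics:
#   dV/dt = v_in(t) - (k + v_out) V
#   dC/dt = k V - c_out C
# with v_in(t) piecewise constant (nonzero only during the infusion window)
# and V(0) = C(0) = 0.  All rates are s^-1, concentrations nM, times s.

#' Infusion schedule
#'
#' A piecewise-constant delivery schedule: the probe enters the compartment at
#' a zeroth-order rate `v_in` (nM/s) between `onset` and `onset + duration`
#' seconds, and not at all outside that window.
#'
#' @param onset Infusion onset time (s), non-negative.
#' @param duration Infusion duration (s), positive.
#' @param v_in Zeroth-order probe delivery rate (nM/s), non-negative.
#' @return An object of class `"infusion_schedule"`.
#' @seealso [point_infusion_rate()], [radial_infusion_rate()] to compute
#'   `v_in` from pump settings and geometry.
#' @export
#' @examples
#' infusion_schedule(onset = 300, duration = 600, v_in = 0.107)
infusion_schedule <- function(onset, duration, v_in) {
  stopifnot(is.numeric(onset), length(onset) == 1L, is.finite(onset),
            is.numeric(duration), length(duration) == 1L, is.finite(duration),
            is.numeric(v_in), length(v_in) == 1L, is.finite(v_in))
  if (onset < 0) stop("`onset` must be >= 0")
  if (duration <= 0) stop("`duration` must be > 0")
  if (v_in < 0) stop("`v_in` must be >= 0")
  structure(list(onset = onset, duration = duration, v_in = v_in),
            class = "infusion_schedule")
}

#' Kinetic model parameters
#'
#' Rate constants of the two-compartment activation model plus the
#' hemodynamic amplitude `A` relating activated-product concentration to
#' percent signal change.
#'
#' @param k First-order enzymatic activation rate (s^-1).
#' @param v_out First-order intact-probe efflux rate (s^-1).
#' @param c_out First-order activated-product efflux rate (s^-1).
#' @param A Hemodynamic amplitude (percent signal change per nM product).
#' @return An object of class `"kinetic_params"`.
#' @export
#' @examples
#' kinetic_params(k = 0.0015, v_out = 0, c_out = 0, A = 20)
kinetic_params <- function(k, v_out = 0, c_out = 0, A = 1) {
  vals <- c(k = k, v_out = v_out, c_out = c_out, A = A)
  if (!all(is.finite(vals))) stop("kinetic parameters must be finite")
  if (any(vals < 0)) stop("kinetic parameters must be >= 0")
  structure(as.list(vals), class = "kinetic_params")
}

#' Michaelis-Menten constants of the activating enzyme
#'
#' Defaults are literature-typical values for FAP acting on peptide
#' substrates: turnover `k_cat` = 3 s^-1 and Michaelis constant `K_m` = 2 uM.
#' `K_m` is stored in nM internally.
#'
#' @param k_cat Turnover rate (s^-1), positive.
#' @param K_m Michaelis constant, positive, in units given by `K_m_unit`.
#' @param K_m_unit Either `"uM"` (default) or `"nM"`.
#' @return An object of class `"enzyme_constants"` with `K_m` in nM.
#' @export
#' @examples
#' enzyme_constants()                  # k_cat = 3 s^-1, K_m = 2000 nM
#' enzyme_constants(3, 2000, "nM")     # identical
enzyme_constants <- function(k_cat = 3, K_m = 2, K_m_unit = c("uM", "nM")) {
  K_m_unit <- match.arg(K_m_unit)
  stopifnot(is.numeric(k_cat), length(k_cat) == 1L, is.numeric(K_m),
            length(K_m) == 1L)
  if (!(k_cat > 0)) stop("`k_cat` must be > 0")
  if (!(K_m > 0)) stop("`K_m` must be > 0")
  if (K_m_unit == "uM") K_m <- K_m * 1000
  structure(list(k_cat = k_cat, K_m = K_m), class = "enzyme_constants")
}

#' Convert enzyme concentration to an effective first-order cleavage rate
#'
#' Under Michaelis-Menten kinetics with substrate concentration well below
#' `K_m`, probe activation is pseudo-first-order with rate
#' `k = k_cat * [E] / K_m`.
#'
#' @param fap_conc Enzyme concentration (nM), non-negative; vectorized.
#' @param enz An [enzyme_constants()] object.
#' @return Effective activation rate(s) k (s^-1).
#' @export
#' @examples
#' rate_from_fap(1, enzyme_constants())    # 0.0015 s^-1
#' rate_from_fap(10, enzyme_constants())   # 0.015 s^-1
rate_from_fap <- function(fap_conc, enz = enzyme_constants()) {
  stopifnot(inherits(enz, "enzyme_constants"), is.numeric(fap_conc))
  if (any(fap_conc < 0, na.rm = TRUE)) stop("`fap_conc` must be >= 0")
  enz$k_cat * fap_conc / enz$K_m
}

#' Convert an effective cleavage rate back to an enzyme concentration
#'
#' Inverse of [rate_from_fap()]: `[E] = k * K_m / k_cat`.
#'
#' @param k Effective activation rate (s^-1), non-negative; vectorized.
#' @inheritParams rate_from_fap
#' @return Enzyme concentration(s) in nM.
#' @export
#' @examples
#' fap_from_rate(0.019, enzyme_constants())  # ~12.7 nM
fap_from_rate <- function(k, enz = enzyme_constants()) {
  stopifnot(inherits(enz, "enzyme_constants"), is.numeric(k))
  if (any(k < 0, na.rm = TRUE)) stop("`k` must be >= 0")
  k * enz$K_m / enz$k_cat
}

#' Probe delivery rate for direct infusion into a target volume
#'
#' The zeroth-order delivery rate when the pump output is assumed to mix
#' directly into the ROI or voxel volume:
#' `v_in = (pump_rate / 60) * probe_conc / target_volume`.
#'
#' @param pump_rate Volumetric pump rate (uL/min), positive.
#' @param probe_conc Injected probe concentration (nM), positive.
#' @param target_volume ROI or voxel volume (uL), positive.
#' @return Delivery rate v_in (nM/s).
#' @export
#' @examples
#' point_infusion_rate(0.1, 100, 1.56)  # 0.107 nM/s
point_infusion_rate <- function(pump_rate, probe_conc, target_volume) {
  vals <- c(pump_rate, probe_conc, target_volume)
  stopifnot(is.numeric(vals), all(is.finite(vals)))
  if (any(vals <= 0)) stop("all geometry fields must be > 0")
  (pump_rate / 60) * probe_conc / target_volume
}

#' Probe delivery rate under spherically symmetric spread from a remote site
#'
#' For infusion at a site remote from the voxel (e.g., into CSF), the probe is
#' assumed to spread spherically with constant flux versus distance, so the
#' delivery rate into a voxel of cross-section `voxel_cross_section` at
#' distance `distance` is
#' `v_in = (pump_rate / 60) * probe_conc * voxel_cross_section /
#'  (4 * pi * distance^2 * voxel_volume)`.
#'
#' @param pump_rate Volumetric pump rate (uL/min), positive.
#' @param probe_conc Injected probe concentration (nM), positive.
#' @param voxel_cross_section Voxel cross-sectional area facing the source
#'   (mm^2), positive.
#' @param distance Distance from the infusion site (mm), positive; vectorized.
#' @param voxel_volume Voxel volume (uL), positive.
#' @return Delivery rate(s) v_in (nM/s).
#' @export
#' @examples
#' radial_infusion_rate(1, 100, 0.15, 3.5, 0.15)  # 0.0108 nM/s
radial_infusion_rate <- function(pump_rate, probe_conc, voxel_cross_section,
                                 distance, voxel_volume) {
  stopifnot(is.numeric(distance), all(is.finite(distance)))
  vals <- c(pump_rate, probe_conc, voxel_cross_section, voxel_volume)
  stopifnot(is.numeric(vals), all(is.finite(vals)))
  if (any(vals <= 0)) stop("geometry fields must be > 0")
  if (any(distance <= 0)) stop("`distance` must be > 0 (point-source singularity)")
  (pump_rate / 60) * probe_conc * voxel_cross_section /
    (4 * pi * distance^2 * voxel_volume)
}

# ---------------------------------------------------------------------------
# Closed-form solution engine.
#
# Vectorized over voxels (rows: k, v_in may be vectors) and times (columns).
# Within a constant-forcing segment, with a = k + v_out, c = c_out:
#   V(t) = Vss + (V0 - Vss) e^{-a t},         Vss = w/a          (a > 0)
#   V(t) = V0 + w t                                              (a = 0)
#   C(t) = C0 e^{-c t} + k [ Vss E_c(t) + (V0 - Vss) D(a,c,t) ]  (a > 0)
#   C(t) = C0 e^{-c t} + k [ V0 E_c(t) + w (t - E_c(t))/c ]      (a = 0)
# where E_c(t) = (1 - e^{-c t})/c  -> t as c -> 0, and
#       D(a,c,t) = (e^{-a t} - e^{-c t})/(c - a) -> t e^{-a t} as c -> a.
# Degenerate coincidences are switched to the limiting branch when the
# relative difference falls below 1e-10.

.kin_reltol <- 1e-10

# E_c(t) elementwise for rate vector cc (len n) and times dt (len m) -> n x m
.Ec <- function(cc, dt) {
  n <- length(cc); m <- length(dt)
  ct <- outer(cc, dt)
  out <- matrix(rep(dt, each = n), n, m)      # c -> 0 limit
  nz <- cc > .kin_reltol
  if (any(nz)) out[nz, ] <- -expm1(-ct[nz, , drop = FALSE]) / cc[nz]
  out
}

# Propagate state and evaluate (V, C) at offsets dt within one segment.
# k, w, V0, C0: length-n vectors; v_out, c_out scalars; dt: length-m vector.
.conc_segment <- function(k, v_out, c_out, w, V0, C0, dt) {
  n <- length(k); m <- length(dt)
  a <- k + v_out
  cc <- rep_len(c_out, n)
  Ea <- exp(-outer(a, dt))
  Ec <- exp(-outer(cc, dt))
  Ect <- .Ec(cc, dt)
  dtm <- matrix(rep(dt, each = n), n, m)

  V <- matrix(0, n, m)
  I <- matrix(0, n, m)   # \int_0^t e^{-c(t-s)} V(s) ds

  apos <- a > .kin_reltol
  if (any(apos)) {
    Vss <- w[apos] / a[apos]
    dV0 <- V0[apos] - Vss
    V[apos, ] <- Vss + dV0 * Ea[apos, , drop = FALSE]
    # D(a, c, t) with limiting branch at c ~ a
    aa <- a[apos]; ca <- cc[apos]
    D <- (Ea[apos, , drop = FALSE] - Ec[apos, , drop = FALSE]) / (ca - aa)
    deg <- abs(ca - aa) <= .kin_reltol * pmax(ca, aa)
    if (any(deg)) {
      lim <- dtm[apos, , drop = FALSE] * Ea[apos, , drop = FALSE]
      D[deg, ] <- lim[deg, , drop = FALSE]
    }
    I[apos, ] <- Vss * Ect[apos, , drop = FALSE] + dV0 * D
  }
  if (any(!apos)) {
    ia <- !apos
    V[ia, ] <- V0[ia] + w[ia] * dtm[ia, , drop = FALSE]
    ca <- cc[ia]
    J <- (dtm[ia, , drop = FALSE] - Ect[ia, , drop = FALSE]) / ca
    cz <- ca <= .kin_reltol
    if (any(cz)) {
      lim <- dtm[ia, , drop = FALSE]^2 / 2
      J[cz, ] <- lim[cz, , drop = FALSE]
    }
    I[ia, ] <- V0[ia] * Ect[ia, , drop = FALSE] + w[ia] * J
  }
  C <- C0 * Ec + k * I
  list(V = V, C = C)
}

# Full piecewise profile on a time grid starting from V = C = 0 at t = 0.
# k, v_in: length-n vectors (recycled); returns list(V, C) as n x length(times)
# matrices.  times must be >= 0, strictly increasing.
.conc_profile <- function(k, v_out, c_out, v_in, onset, duration, times) {
  n <- max(length(k), length(v_in))
  k <- rep_len(k, n); v_in <- rep_len(v_in, n)
  breaks <- c(0, onset, onset + duration)
  w_seg <- list(rep(0, n), v_in, rep(0, n))
  V <- matrix(0, n, length(times))
  C <- matrix(0, n, length(times))
  V0 <- rep(0, n); C0 <- rep(0, n)
  for (s in 1:3) {
    t0 <- breaks[s]
    t1 <- if (s < 3) breaks[s + 1] else Inf
    idx <- which(times >= t0 & times < t1)
    if (s == 3) idx <- which(times >= t0)
    if (length(idx)) {
      seg <- .conc_segment(k, v_out, c_out, w_seg[[s]], V0, C0, times[idx] - t0)
      V[, idx] <- seg$V
      C[, idx] <- seg$C
    }
    if (s < 3 && breaks[s + 1] > t0) {
      st <- .conc_segment(k, v_out, c_out, w_seg[[s]], V0, C0, breaks[s + 1] - t0)
      V0 <- st$V[, 1]; C0 <- st$C[, 1]
    }
  }
  list(V = V, C = C)
}

# scalar fast path: same piecewise solution for a single (k, v_in) pair,
# returning plain vectors; this is the hot loop of the model fitters
.conc_profile1 <- function(k, v_out, c_out, v_in, onset, duration, times) {
  a <- k + v_out
  cc <- c_out
  t2 <- onset + duration
  seg_eval <- function(V0, C0, w, dt) {
    Ea <- exp(-a * dt)
    Ec <- exp(-cc * dt)
    Ect <- if (cc > .kin_reltol) -expm1(-cc * dt) / cc else dt
    if (a > .kin_reltol) {
      Vss <- w / a
      dV0 <- V0 - Vss
      V <- Vss + dV0 * Ea
      D <- if (abs(cc - a) <= .kin_reltol * max(cc, a)) dt * Ea
           else (Ea - Ec) / (cc - a)
      I <- Vss * Ect + dV0 * D
    } else {
      V <- V0 + w * dt
      J <- if (cc > .kin_reltol) (dt - Ect) / cc else dt^2 / 2
      I <- V0 * Ect + w * J
    }
    list(V = V, C = C0 * Ec + k * I)
  }
  V <- numeric(length(times))
  C <- numeric(length(times))
  i2 <- which(times >= onset & times < t2)
  if (length(i2)) {
    r <- seg_eval(0, 0, v_in, times[i2] - onset)
    V[i2] <- r$V; C[i2] <- r$C
  }
  i3 <- which(times >= t2)
  if (length(i3)) {
    st <- seg_eval(0, 0, v_in, duration)
    r <- seg_eval(st$V, st$C, 0, times[i3] - t2)
    V[i3] <- r$V; C[i3] <- r$C
  }
  list(V = V, C = C)
}

.check_time_grid <- function(times) {
  if (!is.numeric(times) || length(times) < 1L || any(!is.finite(times)))
    stop("`times` must be a finite numeric vector")
  if (any(times < 0)) stop("`times` must be >= 0")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("`times` must be strictly increasing")
  invisible(times)
}

.new_trajectory <- function(times, V, C) {
  structure(list(times = times, V = pmax(V, 0), C = pmax(C, 0)),
            class = "conc_trajectory")
}

#' Closed-form concentration trajectories
#'
#' Exact analytic solution of the linear two-compartment system for a
#' piecewise-constant infusion, evaluated on an arbitrary time grid.
#' Degenerate rate coincidences (e.g. `k + v_out == c_out`) are handled by
#' the `t * exp(-lambda * t)` limiting branch.
#'
#' @param params A [kinetic_params()] object.
#' @param schedule An [infusion_schedule()] object.
#' @param times Strictly increasing, non-negative time grid (s).
#' @return An object of class `"conc_trajectory"`: list with `times`, `V`
#'   (intact probe, nM) and `C` (activated product, nM).
#' @export
#' @examples
#' tr <- closed_form_concentrations(
#'   kinetic_params(k = 0.0015), infusion_schedule(0, 600, 0.107),
#'   times = seq(0, 1800, by = 5))
#' head(as.data.frame(tr))
closed_form_concentrations <- function(params, schedule, times) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(schedule, "infusion_schedule"))
  .check_time_grid(times)
  pr <- .conc_profile1(params$k, params$v_out, params$c_out,
                       schedule$v_in, schedule$onset, schedule$duration,
                       times)
  .new_trajectory(times, pr$V, pr$C)
}

#' Numerically integrated concentration trajectories
#'
#' Solves the same two-compartment system as
#' [closed_form_concentrations()] by numeric integration
#' (`deSolve::lsoda`, integrated segment-by-segment so the forcing
#' discontinuities fall on segment boundaries).  The closed form is the
#' reference; this path exists for generality and as a cross-check.
#'
#' @inheritParams closed_form_concentrations
#' @param rtol,atol Integrator tolerances.
#' @return An object of class `"conc_trajectory"`.
#' @export
simulate_concentrations <- function(params, schedule, times,
                                    rtol = 1e-12, atol = 1e-12) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(schedule, "infusion_schedule"))
  .check_time_grid(times)
  deriv <- function(t, y, p) {
    list(c(p$w - (p$k + p$v_out) * y[1],
           p$k * y[1] - p$c_out * y[2]))
  }
  breaks <- c(0, schedule$onset, schedule$onset + schedule$duration, Inf)
  w_seg <- c(0, schedule$v_in, 0)
  V <- C <- numeric(length(times))
  state <- c(V = 0, C = 0)
  for (s in 1:3) {
    t0 <- breaks[s]; t1 <- breaks[s + 1]
    idx <- which(times >= t0 & times < t1)
    seg_end <- if (is.finite(t1)) t1 else if (length(idx)) max(times[idx]) else t0
    grid <- sort(unique(c(t0, times[idx], seg_end)))
    if (length(grid) > 1L) {
      p <- list(w = w_seg[s], k = params$k, v_out = params$v_out,
                c_out = params$c_out)
      sol <- deSolve::lsoda(y = state, times = grid, func = deriv, parms = p,
                            rtol = rtol, atol = atol)
      if (length(idx)) {
        rows <- match(times[idx], grid)
        V[idx] <- sol[rows, "V"]; C[idx] <- sol[rows, "C"]
      }
      state <- c(V = unname(sol[nrow(sol), "V"]),
                 C = unname(sol[nrow(sol), "C"]))
    } else if (length(idx)) {
      V[idx] <- state["V"]; C[idx] <- state["C"]
    }
  }
  .new_trajectory(times, V, C)
}

#' Hemodynamic signal predicted from a concentration trajectory
#'
#' The model ties percent signal change linearly to the activated-product
#' concentration: `S(t) = A * C(t)`.
#'
#' @param traj A `"conc_trajectory"`.
#' @param A Hemodynamic amplitude (percent signal change per nM), >= 0.
#' @return An object of class `"signal_ts"`: list with `times` (s) and
#'   `values` (percent signal change).
#' @export
signal_from_concentration <- function(traj, A) {
  stopifnot(inherits(traj, "conc_trajectory"), is.numeric(A), length(A) == 1L)
  if (!is.finite(A) || A < 0) stop("`A` must be a finite value >= 0")
  signal_ts(traj$times, A * traj$C)
}

#' Construct a signal time series
#'
#' @param times Sample times (s).
#' @param values Percent signal change values; same length as `times`.
#' @return An object of class `"signal_ts"`.
#' @export
signal_ts <- function(times, values) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values))
  if (any(!is.finite(values))) stop("signal values must be finite")
  structure(list(times = times, values = values), class = "signal_ts")
}

#' @export
as.data.frame.conc_trajectory <- function(x, ...) {
  data.frame(time_s = x$times, V_nM = x$V, C_nM = x$C)
}

#' @export
print.conc_trajectory <- function(x, ...) {
  cat(sprintf(
    "Concentration trajectory: %d time points over [%g, %g] s\n",
    length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  final V = %.4g nM, final C = %.4g nM\n",
              x$V[length(x$V)], x$C[length(x$C)]))
  invisible(x)
}

#' @export
print.infusion_schedule <- function(x, ...) {
  cat(sprintf("Infusion: v_in = %g nM/s over [%g, %g] s\n",
              x$v_in, x$onset, x$onset + x$duration))
  invisible(x)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("Kinetic parameters: k = %g /s, v_out = %g /s, c_out = %g /s, A = %g %%/nM\n",
              x$k, x$v_out, x$c_out, x$A))
  invisible(x)
}

#' Write a concentration trajectory to CSV
#'
#' Columns: `time_s`, `V_nM`, `C_nM`.
#'
#' @param traj A `"conc_trajectory"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "conc_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Read a concentration trajectory from CSV
#'
#' @param path CSV written by [write_trajectory_csv()].
#' @return A `"conc_trajectory"`.
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "V_nM", "C_nM") %in% names(d)))
  .new_trajectory(d$time_s, d$V_nM, d$C_nM)
}

#' Serialize kinetic parameters and schedule to a flat YAML config
#'
#' @param params A [kinetic_params()] object.
#' @param schedule An [infusion_schedule()] object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_kinetic_config <- function(params, schedule, path) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(schedule, "infusion_schedule"))
  yaml::write_yaml(list(
    k = params$k, v_out = params$v_out, c_out = params$c_out, A = params$A,
    onset = schedule$onset, duration = schedule$duration,
    v_in = schedule$v_in), path)
  invisible(path)
}

#' Read kinetic parameters and schedule from a flat YAML config
#'
#' @param path YAML written by [write_kinetic_config()].
#' @return List with elements `params` and `schedule`.
#' @export
read_kinetic_config <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("k", "v_out", "c_out", "A", "onset", "duration", "v_in")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("kinetic config missing keys: ",
                         paste(miss, collapse = ", "))
  list(params = kinetic_params(x$k, x$v_out, x$c_out, x$A),
       schedule = infusion_schedule(x$onset, x$duration, x$v_in))
}
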