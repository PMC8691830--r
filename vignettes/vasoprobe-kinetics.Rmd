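---
title: "Kinetic modelling of enzyme-activated vasoprobe imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling of enzyme-activated vasoprobe imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(vasokin)
```

## The model

Vasoactive probes report extracellular enzyme activity through hemodynamic
image contrast: an intact, receptor-blocked probe is infused near the
tissue of interest, local enzyme (here fibroblast activation protein, FAP)
cleaves the blocking group, and the activated product dilates nearby
vessels, raising the T2/T2*-weighted MRI signal.  Within a voxel or ROI the
package models the intact-probe concentration $V$ (nM) and the activated
product $C$ (nM) as a linear two-compartment system,

$$\frac{dV}{dt} = v_{in}(t) - (k + v_{out})\,V, \qquad
  \frac{dC}{dt} = k\,V - c_{out}\,C,$$

with $V(0) = C(0) = 0$ and the measured percent signal change modelled as
$\hat S(t) = A\,C(t)$.  The parameters:

* `k` (s$^{-1}$) — effective first-order activation rate.  Because probe
  concentrations (≤ 100 nM) sit far below the enzyme's Michaelis constant
  (micromolar for FAP), activation is pseudo-first-order with
  $k = k_{cat}\,[\mathrm{FAP}]/K_m$; `rate_from_fap()` and
  `fap_from_rate()` convert between rate and enzyme concentration using
  literature constants $k_{cat} = 3\ \mathrm{s^{-1}}$, $K_m = 2\ \mu M$.
* `v_out`, `c_out` (s$^{-1}$) — first-order efflux of intact probe and
  product.
* `A` (%/nM) — hemodynamic amplitude tying product concentration to
  percent signal change; assumed constant across a field of view in
  voxel-level fitting.
* `v_in` (nM/s) — zeroth-order delivery, piecewise constant over the
  infusion window.  For infusion directly into the target volume,
  `point_infusion_rate()` gives $v_{in} = (\text{pump rate}/60)\cdot
  [\text{probe}]/\text{volume}$; for remote (e.g. intra-CSF) delivery,
  `radial_infusion_rate()` assumes spherically symmetric spread with
  constant flux versus distance, so delivery falls off as $1/d^2$.

Units are fixed internally to seconds, nM, µL, mm and percent; constructor
arguments state their units explicitly (pump rates in µL/min, $K_m$ in µM
by default) and are converted on entry, because mixing minutes/seconds and
µM/nM silently is the classic failure mode for this kind of model.

Note one unit subtlety handled deliberately: `k` is strictly a first-order
rate in s$^{-1}$ throughout.  Dimensional consistency of the ODE system
requires this even where source material quotes activation rates with
concentration-rate units.

## Solutions: closed form first, integrator second

The system is linear with piecewise-constant forcing, so it has an exact
solution assembled segment by segment (`closed_form_concentrations()`).
Degenerate eigenvalue coincidences — $c_{out} \to 0$, $k + v_{out} \to 0$,
or $k + v_{out} \to c_{out}$ — are switched to their
$t\,e^{-\lambda t}$-type limiting branches at a relative difference of
$10^{-10}$.  A numeric path (`simulate_concentrations()`, `deSolve::lsoda`
run per forcing segment at `rtol = atol = 1e-12`) exists for generality
and serves as the cross-check: the test suite holds the two routes
together to $10^{-8}$ relative over random parameter draws, and checks
mass balance ($V + C$ equals the infused dose when efflux is off) to
$10^{-6}$ relative.

## The synthetic phantom

`phantom_spec()` + `make_fap_phantom()` + `generate_image_series()`
generate 4D raw-signal series with known ground truth.  What they emulate,
with defaults chosen to mirror the wide-field rat experiments:

* grid of 390 µm × 390 µm × 1 mm voxels, 4 s frames, 5 min baseline,
  10 min infusion, ~20 min post-infusion observation;
* an enzyme focus as an isotropic Gaussian taper
  $[\mathrm{FAP}](d) = \text{peak} \cdot 2^{-(d/r)^2}$ whose half-max falls
  exactly at the stated radius (~1 mm-scale response regions), converted to
  a k-map; the opposite hemisphere is enzyme-free as a built-in control;
* delivery either uniform or an inverse-square radial field from a remote
  site (`generate_radial_vin_field()`, clamped at one voxel pitch from the
  site to avoid the point-source singularity);
* raw signal `baseline * (1 + (A*C(t) + artifact)/100)` plus i.i.d.
  Gaussian noise, seeded and purely deterministic given the spec;
* an optional negative boxcar during the infusion window, mimicking the
  pressure-artifact dip some in vivo traces show.

Default truth parameters are `A_true = 20` %/nM, probe efflux
`v_out_true = 0.3` s$^{-1}$ and product efflux `c_out_true = 1e-4`
s$^{-1}$ — the regime the voxel-level in vivo fits land in — so activity
peaks of 0.015–0.03 s$^{-1}$ yield peak signal changes in the
single-digit-to-low-teens percent range, bracketing observed responses.
The raw noise SD defaults to 0.5 raw units on a baseline of 100 (0.5% per
frame per voxel).  Real EPI noise levels are not published for these
acquisitions, so this value is an assumption; the detection-limit tooling
sweeps it.  What the phantom does **not** emulate: MRI physics (relaxation,
EPI distortion), motion, physiological noise with temporal autocorrelation,
partial-volume anatomy, or probe transport between voxels.  Passing
recovery tests on these phantoms therefore demonstrates correctness of the
estimation machinery, not robustness to every property of real data.

## Preprocessing

`preprocess_series()` chains the standard steps in the published order,
each also exported on its own: multiplicative global-mean normalization
(an additive variant is available by flag), a 60 s centered moving-average
temporal smooth with truncated, renormalized edge windows, percent signal
change against the 60 s pre-onset baseline, and separable Gaussian spatial
smoothing (default 1 mm FWHM) that respects anisotropic voxel sizes and
uses half-sample reflective padding, which conserves the in-frame total.
Choices the source material leaves open, fixed here and covered by tests:
edge handling (truncation temporally, reflection spatially), the
multiplicative reading of "normalizing out" global fluctuations, and
performing temporal smoothing before percent-change conversion (the two
nearly commute; the order is configurable via `steps`).  Percent-change
conversion is guarded against double application through the provenance
record, and voxels with non-positive baseline are masked with a reason
rather than raising an error.  Monkey-style analyses (running window of 40
frames, map at a late time point) are the same operators under different
configuration, not separate code.

## ROI fitting and identifiability

`fit_roi()` minimizes $\sum_t (S(t) - A\,C(t;k,v_{out},c_{out}))^2$ with
$v_{in}$ fixed (delivery is known from the pump settings, not fitted).
Numerical design:

* $A$ enters linearly, so it is profiled analytically at every step
  (clamped to its bounds) and the optimizer works on the three rates only.
* Rates are optimized on a log$_{10}$ scale within bounds $k \in [0, 10]$,
  effluxes $\in [0, 1]$ s$^{-1}$, $A \in [0, 40]$ %/nM, with a floor of
  $10^{-12}$ standing in for zero; fitted rates at the floor are reported
  as exactly zero.
* Multistart: eight log-spaced `k` initials, alternating between interior
  efflux guesses and the zero-efflux boundary face.  The latter matters:
  the no-removal regime is a corner of the feasible set, and approaching
  it along the face is far better conditioned than descending the
  interior valley.  Every start runs at tight tolerances (`factr = 1`,
  fine finite-difference steps): the valley is shallow enough that
  loosely converged intermediate values would pick the wrong winner.
* The multistart optima are compared by AIC rather than raw SSE, with a
  rate counting as an active parameter only when it sits off its zero
  boundary, and with the SSE floored at $10^{-12}\sum S^2$ so numerically
  exact fits tie in the likelihood term.  The reason is an *exact*
  degeneracy of the model: because $V$ depends on the rates only through
  $a = k + v_{out}$ and $C$ is linear in $k$, the signal is invariant
  under
  $(A, k, v_{out}) \mapsto (\lambda A,\; k/\lambda,\; v_{out} + k(1 - 1/\lambda))$
  for any $\lambda$ keeping $v_{out} \ge 0$.  Only the combinations
  $A\,k$, $k + v_{out}$ and $c_{out}$ are identified by the data; the
  individual $k$ is pinned solely by the non-negativity boundary, whose
  unique zero-efflux member is the parsimonious representative of the
  family.  Raw SSE comparison between these exactly tied optima would
  select among them by floating-point accident, scattering $\hat k$
  across the family; the information-criterion margin (2 units per extra
  active rate) resolves the ties toward parsimony while leaving any
  genuinely supported efflux estimate untouched, since real SSE
  improvements dominate the penalty.
* Non-convergence from every start yields a flagged result
  (`converged = FALSE`), never an exception.
* When the data trace was temporally smoothed during preprocessing, pass
  `smooth_window` so the model prediction goes through the identical
  moving-average filter; otherwise the filter's shape bias leaks into the
  rate estimates.

The practical consequence: per-parameter estimates of `k` and `A` are
trustworthy exactly when the generating process sits in the zero-efflux
regime (the protracted-rise signal shape), where the boundary pins the
family; when the truth lies strictly inside the efflux ridge, only
$A \cdot k$, $k + v_{out}$ and $c_{out}$ are recoverable and the
zero-efflux representative overstates `k` by the true probe-efflux rate.
The fit object reports `ka_correlation`, the local estimate correlation
between $\hat k$ and $\hat A$ (typically < −0.9), as a standing caution.
The package's recovery study conditions follow: a 60-minute session
(5 min baseline, 10 min infusion at 0.107 nM/s, 45 min post-infusion
observation at 5 s frames) in the zero-efflux regime, with 0.1%
per-frame noise on the ROI-mean trace (the level implied by ~0.5%
per-voxel noise averaged over a 1.2 mm × 1.2 mm ROI).  Under those
conditions the median relative error on `k` over 50 draws is well under
20% (the acceptance suite recomputes this).  This identifiability
structure is also why the voxel-level scheme fixes `A` globally: with
`A` known, the scale pins `k` and the sum pins `v_out`, and all three
rates are individually recoverable even in the interior-efflux regime.

## Voxel-level maps and their statistics

`fit_voxelwise()` implements the global-amplitude scheme: for each
candidate `A` on a grid (default 0–40 %/nM in steps of 1 — the published
description says only "coarse", so the step is an explicit package
default), the three rates are fitted separately per voxel with `A` fixed
and the fit quality is accumulated over all in-mask voxels at once.  The
amplitude invariance described above means every `A` at or above the
level demanded by the least-efflux voxel can fit the data essentially
equally well (amplitudes below it are excluded by the $v_{out} \ge 0$
constraint), so the global `A` is selected by the summed per-voxel AIC —
equivalent to least total error whenever the differences are
informative, and resolving exact ties to the smallest amplitude
consistent with non-negative efflux.  Per-voxel $R^2$, SSE and
convergence maps ride along, and per-voxel fits are warm-started from
the previous grid point's solution.

`jackknife_k_sem()` combines k-maps from repeated datasets: per voxel it
excludes datasets with poor fits ($R^2 < 0.9$), unphysical rates
($k > 10\ \mathrm{s^{-1}}$) or missing values — every exclusion carries a
machine-readable reason code — and computes the leave-one-out jackknife
SEM of the mean over the survivors (for the mean this equals
$sd/\sqrt{n}$; with two datasets, $|a-b|/2$).  `voxel_ttests()` turns
mean/SEM/n maps into two-sided one-sample t-tests with $n-1$ degrees of
freedom and a significance mask at `p <= alpha` with `n >= 2`;
per-voxel thresholds are uncorrected by default, replicating the published
convention, with Benjamini–Hochberg available via `adjust = "BH"`.  A zero
SEM with nonzero mean maps to the smallest representable p-value rather
than an error.  Sidedness is two-sided throughout (the source does not
state it).

`response_amplitude_test()` compares per-subject response amplitudes at a
stated time point between test and control groups (paired by default).

## Detection limit

The published sensitivity analysis is not described procedurally, so
`detection_limit()` defines it operationally and documents the
definition: simulate single-voxel traces over a sweep of true `k` at a
given noise SD, refit each with `A` fixed at its global value, build a
null distribution of fitted rates from enzyme-free traces, and declare a
repetition detected when its $\hat k$ exceeds the null mean plus `z` null
SDs (default $z = 2$).  `k_min` is the smallest swept rate detected in at
least half the repetitions, converted to an equivalent enzyme
concentration via `fap_from_rate()`.  With zero noise the limit collapses
to the smallest swept value; the suite checks that it grows monotonically
with noise.

## Dose-response analytics

`fit_hill()` fits the four-parameter Hill curve
$R(c) = \text{bottom} + (\text{top}-\text{bottom})/(1 + (EC_{50}/c)^h)$
by Levenberg–Marquardt least squares on a log-concentration axis (the
midpoint is fitted as $\log_{10} EC_{50}$).  The Hill slope is free by
default with a fixed-slope option for degenerate data; zero-concentration
wells anchor the bottom asymptote through a pseudo log-concentration far
below the dilution grid while staying off the log axis proper.  Because a
single Levenberg–Marquardt start can stall on a singular Jacobian or a
local minimum, the fit multistarts over shifted midpoint initials and
keeps the lowest-deviance solution.  The EC50 uncertainty defaults to the
SD across replicate-wise refits — matching how triplicate assay midpoints
are conventionally summarized — with a covariance-based SE as the
alternative.  `fold_activation()` forms the potency ratio of two fits
with propagated uncertainty; `standard_curve()` /
`interpolate_standard()` invert a monotone (Hyman spline, isotonic-guarded)
calibration exactly at its knots; `quantify_fap_per_cell()` chains
nM × µL → pmol per $10^6$ cells.

## Configured runs

`run_config()` validates a single YAML/list configuration (unknown keys
are rejected by name), and `run_simulate()` / `run_fit()` / `run_report()`
execute the stages, writing NIfTI volumes, JSON fit summaries (including
v_in provenance: point versus radial model) and a manifest with the
config, seed, package version and MD5 hashes of all outputs, so
deterministic stages reproduce byte-for-byte.  These R functions, the
exported operators and this vignette are the package's operational
surface; there is no shell executable, since the audience for an analysis
package of this kind works in R.

## Problem sizes in the test suite

The suite exercises deliberately small instances chosen to probe the
mathematics rather than the scale of real data: phantoms of 4×4 to 24×24
voxels with 100–160 frames, 50-draw recovery studies, detection-limit
sweeps with ~10 repetitions per grid point, and 100-draw oracle
comparisons for the closed-form/integrator equivalence.  All expected
values are either exact arithmetic, independent brute-force recomputations
inside the tests, or round-trips against the generators' known truth.

## Known limitations

* The hemodynamic response is assumed linear in product concentration with
  no ceiling; saturation at high dilator concentrations is out of scope.
* No spatial coupling: each voxel is an independent compartment, so probe
  diffusion/advection between voxels is not modelled.
* The efflux/activation trade-off limits per-parameter interpretation of
  short-session fits; report $A\hat k$ or use fixed-`A` fitting when the
  session is short relative to $1/k$.
* Receptor pharmacology downstream of product formation (cAMP cascade
  dynamics in the bioassay) is summarized entirely by the Hill curve.
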