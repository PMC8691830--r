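# vasokin

Kinetic modelling and inversion for **vasoactive-probe molecular imaging**
— hemodynamic imaging of extracellular enzyme activity in the brain.

Vasoactive probes are receptor-blocked peptides (e.g. CGRP fused to a
protease-labile blocking domain) that are activated by a target enzyme
such as fibroblast activation protein (FAP), a dipeptidase overexpressed
by some glioblastomas.  The activated product dilates nearby vessels and
raises the T2/T2*-weighted MRI signal, so the image time course encodes
the local enzymatic activation rate.  This package is for imaging
scientists who want to simulate such experiments, preprocess the
resulting 4D series, and estimate enzyme-activity maps from them — plus
analyze the companion cell-based receptor-activation bioassay.

## The model

Within a voxel or ROI, intact probe *V* and activated product *C* (nM)
follow

```
dV/dt = v_in(t) − (k + v_out) V
dC/dt = k V − c_out C,          Ŝ(t) = A · C(t)
```

where `v_in` is the zeroth-order delivery rate (piecewise-constant over
the infusion window), `k` the effective first-order activation rate
(≈ k_cat[FAP]/K_m far below saturation), `v_out`/`c_out` first-order
efflux rates, and `A` the hemodynamic amplitude (% signal change per nM).
The package provides the exact closed-form solution, a numeric-integrator
cross-check, synthetic 4D phantoms with known ground truth, MRI-style
preprocessing, ROI- and voxel-level nonlinear least-squares inversion
(with a global-amplitude grid search, jackknife SEM maps, voxel t-tests
and a simulation-based detection limit), and four-parameter Hill
dose-response fitting for the bioassay.

## Worked example

Simulate a direct-infusion ROI experiment (10 min infusion at
`v_in = 0.107` nM/s, the rate implied by a 0.1 µL/min pump delivering
100 nM probe into a 1.56 µL ROI) and recover the kinetic parameters:

```r
library(vasokin)

sched <- infusion_schedule(onset = 300, duration = 600, v_in = 0.107)
tt    <- seq(0, 3600, by = 5)
truth <- kinetic_params(k = 4e-4, v_out = 0, c_out = 0, A = 0.8)
traj  <- closed_form_concentrations(truth, sched, tt)

set.seed(1)
obs <- signal_ts(tt, truth$A * traj$C + rnorm(length(tt), 0, 0.1))
fit <- fit_roi(obs, v_in = 0.107, schedule = sched)
summary(fit)
#> Kinetic model fit of a hemodynamic time course
#>
#>   n = 721 time points, fit window [0, 3600] s, v_in = 0.107 nM/s
#>
#> Coefficients:
#>         k     v_out     c_out         A
#> 0.0004008 0.0000000 0.0000000 0.7988000
#>
#> Residual SD: 0.1024 %  R-squared: 0.9999
#> Correlation of k-hat and A-hat estimates: -0.989
```

The true activation rate (4×10⁻⁴ s⁻¹) and amplitude (0.8 %/nM) are
recovered to a fraction of a percent; the reported k̂–Â correlation warns
that these two parameters trade off strongly, which is why voxel-level
fitting (`fit_voxelwise()`) holds `A` fixed across the field of view.
Converting a fitted rate to an equivalent enzyme concentration:

```r
fap_from_rate(0.019)   # ≈ 12.7 nM — the single-voxel detectability scale
```

Dose-response analytics for the receptor-activation bioassay:

```r
tab  <- generate_dose_response(assay_spec(ec50_true = 6.7, seed = 2))
hill <- fit_hill(tab)
coef(hill)["ec50"]
#>     ec50
#> 6.205419     # one noisy triplicate draw; truth 6.7 nM
```

See the methods vignette (`vignettes/vasoprobe-kinetics.Rmd`) for the
model assumptions, numerical choices and identifiability caveats.

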