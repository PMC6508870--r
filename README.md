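# neckdyn

Multibody forward dynamics of the C2–C6 cervical spine and identification of
**impact-specific** viscoelastic joint parameters from high-speed marker
tracking.

## The problem

Cervical spine injuries in collision sports arise from axial head impacts
that reach 2–5 kN within 5–10 ms. Multibody neck models represent each
intervertebral joint as a six degree-of-freedom Kelvin–Voigt bushing — a
linear spring and damper in parallel, with joint wrench

    F_i = -k_i * d_i - b_i * d'_i

in a joint frame seated on the intervertebral mid-plane (x anterior shear,
y axial, z lateral). The stiffness/damping values in circulation come from
static or quasi-static tests (~100 N over seconds) and badly misrepresent
the disc's much stiffer response to impulsive loads. `neckdyn` implements,
end to end, the pipeline that estimates impact-specific axial (k_y, b_y) and
anteroposterior shear (k_x, b_x) parameters for the four joints of a C2–C6
specimen — 16 parameters in all — by minimising the RMSE between measured
and simulated 3D marker trajectories over the 5 ms after impact, plus the
analyses that qualify them:

* a rigid-body chain simulator (fixed-step RK4 in compiled code) with the
  experimental constraints (C6 fixed, C2 axial-only, 152 N preload),
* zero-lag Butterworth preprocessing, 200 N onset detection, 5 ms windowing,
* a real-coded genetic algorithm over log-spaced parameters
  (`fit_bushings()`, returning a classed fit with `print`/`summary`/`coef`/
  `fitted`/`residuals`/`simulate`/`plot` methods),
* median aggregation and five-fold leave-one-specimen-out cross-validation,
* Monte Carlo sensitivity (p_i = p(1+r), r ~ U(−0.5, 0.5) per functional
  parameter set), cubic response surfaces over the six set pairs, and
  anteroposterior joint-frame-position sweeps,
* a head-impact scenario comparing kinematically constrained,
  impact-specific and quasi-static model variants,
* a synthetic-specimen generator with known ground truth (no experimental
  recordings are publicly deposited), so every stage is testable offline.

The audience: musculoskeletal modellers and injury-biomechanics researchers
who need joint parameters valid for impulsive axial loading, or a tested
reference implementation of the identification pipeline.

## Worked example

```r
library(neckdyn)

specimen <- generate_specimen(seed = 42)           # mass, geometry, truth params
pulse    <- generate_load_pulse(peak_N = 3500, rise_s = 0.0025)
trial    <- generate_trial(specimen, pulse, marker_noise_sd_m = 3e-4, seed = 7)
trial
#> Synthetic trial with known ground truth
#>   onset at 6.385 ms (baseline 152.0 N), window 21 marker frames
#>   marker noise SD: 0.30 mm

fit <- fit_bushings(specimen$model, trial$markers_noisy, trial$force_window,
                    control = ga_control(pop_size = 20, generations = 10,
                                         seed = 1))
fit
#> Impact-specific bushing parameter fit
#>   tracking RMSE at optimum: 0.5931 mm
#>   GA: 20 individuals x 10 generations (200 evaluations, seed 1)
#>   penalised (diverged) evaluations: 15
summary(fit)
#> Identified axial/shear viscoelastic bushing parameters
#>   k_y  [N/m]: C2C3=1.542e+06  C3C4=1.42e+06  C4C5=1.063e+07  C5C6=4.943e+06
#>   b_y  [Ns/m]: C2C3=1656  C3C4=2861  C4C5=1811  C5C6=879
#>   k_x  [N/m]: C2C3=8.661e+04  C3C4=5.928e+05  C4C5=5.501e+04  C5C6=2.975e+05
#>   b_x  [Ns/m]: C2C3=144  C3C4=6175  C4C5=504  C5C6=17.04
#> Tracking RMSE at optimum: 0.5931 mm (200 objective evaluations)
```

The tracking RMSE of 0.59 mm sits at the noise floor of the 0.3 mm-per-axis
marker noise (isotropic noise alone contributes √3 × 0.3 ≈ 0.52 mm), i.e.
the fit tracks the markers about as well as the measurement allows. This
demonstration GA (200 evaluations) is far too small to pin down individual
parameters — the identifiability analysis in the methods vignette
(`vignettes/neckdyn-methods.Rmd`) quantifies how hard that is; use the
defaults (`ga_control()`: population 100 × 15 generations) or larger for
real work.

Downstream stages take the fit (or any 16-vector) directly:

```r
data <- list(force = trial$force_window, markers = trial$markers_noisy)
mc <- run_monte_carlo(specimen$model, data, coef(fit), n = 1000, seed = 7)
surfaces <- fit_all_pair_surfaces(mc)              # six bivariate cubics
cv <- cross_validate_five_fold(cohort)             # see ?cross_validate_five_fold
sc <- run_scenario_comparison()                    # head-impact variant comparison
```

The scenario comparison reproduces the headline contrast between parameter
regimes — quasi-static bushings (k_y = 1.1 MN/m) allow ~2 mm peak axial
joint compression under a 2 kN head pulse, past the 0.84 mm near-failure
reference, while impact-specific values (~23 MN/m) keep it near 0.1 mm:

```r
sc
#> -- impact_specific --   peak axial displacements 0.104–0.107 mm
#> -- quasi_static --      peak axial displacements 1.81–2.03 mm
```

Published per-specimen identified values and cohort descriptives ship as
plain CSV (`published_bushing_parameters()`, `specimen_descriptives()`);
`aggregate_median_parameters()` reproduces the per-joint median parameter
table from them.

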