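---
title: "A reduced maternal-fetal PBPK model for antenatal corticosteroids: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced maternal-fetal PBPK model for antenatal corticosteroids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfpbpk)
```

## Why a reduced model

Full maternal-fetal PBPK platforms resolve dozens of organs with
gestational-age-dependent flows, volumes and enzyme activities. Everything
this package consumes downstream, however, is a plasma concentration-time
profile and exposure ratios derived from it. `mfpbpk` therefore collapses
the physiology into a lumped four-state linear system — two intramuscular
depots, a maternal central compartment and a fetal central compartment —
and absorbs tissue distribution into the two central volumes. Gestational
week is a scenario *label* (GW30, GW32, GW38 presets): every simulation
spans at most 72 h, over which the physiology is effectively constant, so
no continuous gestational-age functions are carried.

The consequences of lumping are understood and intended:

* **Absolute exposures are not reproduced.** Predicted AUCs and
  concentrations depend on the volumes and binding parameters that a full
  platform derives from physiology; here they are scalar assumptions.
  Every scientific conclusion the package supports is therefore *relative*
  (percent changes between regimens, concentration ratios), which the
  model's linearity pins down from the printed kinetic constants alone.
* **The placenta stores no drug.** Passive transfer is a perfusion-limited
  conduit: the intrinsic passive-diffusion clearance `CL_int,PD` acts in
  series with the placental blood flow `Q_pl`, giving
  `CL_PD,eff = Q_pl CL_int,PD / (Q_pl + CL_int,PD)`. For these
  corticosteroids passive diffusion is flow-limited, so the presets fix
  `CL_int,PD` at a numerically large value (`1e6` L/h) and
  `CL_PD,eff ≈ Q_pl = 45` L/h (third trimester).
* **P-gp efflux is a clearance, not a mechanism.** Efflux is an additional
  fetal-to-maternal clearance `CL_int,Pgp` acting on unbound fetal drug.
  At steady state the unbound fetal:maternal ratio is exactly
  `K_p,uu = CL_PD,eff / (CL_PD,eff + CL_int,Pgp)`, which is the quantity
  the calibration estimates; no transporter kinetics are resolved.
* **Umbilical-vein concentration is identified with the fetal central
  compartment** — no cord subcompartment.

## State equations and dosing

With `C_m = a_maternal/V_m`, `C_f = a_fetal/V_f` (mg/L):

```
depot_fast' = -ka_fast * depot_fast
depot_slow' = -ka_slow * depot_slow
a_maternal' = ka_fast depot_fast + ka_slow depot_slow + in_rate
              - CL_total C_m - CL_PD,eff fu_m C_m
              + (CL_PD,eff + CL_int,Pgp) fu_f C_f
a_fetal'    = CL_PD,eff fu_m C_m - (CL_PD,eff + CL_int,Pgp) fu_f C_f
              - CL_fetal C_f
```

Intramuscular doses enter the depots `t_lag` hours after administration
(filling the depot late is equivalent to delaying its activation, and keeps
the depot equations autonomous); a fraction `fraction_fast` of the
bioavailable dose goes to the fast depot. Intravenous boluses enter
`a_maternal` directly; infusions as a piecewise-constant `in_rate`.
Maternal elimination `CL_total` is either a direct override or the
well-stirred hepatic model `Q_h fu_m CL_int' / (Q_h + fu_m CL_int')` with
`CL_int' = induction x CL_hep,int`, plus renal clearance (zero for both
drugs here: they are cleared essentially by CYP3A metabolism, induced about
twofold at term).

Concentrations are reported in ng/ml (`mg/L x 1e6 ng/mg / 1e3 ml/L`).

## Parameters and their provenance

Printed kinetic constants (used as-is):

| parameter | DEX | BET | note |
|---|---|---|---|
| `CL_hep,int` pregnant i.v. (L/h) | 106 | 62 | twofold CYP3A induction of 53 / 31 |
| `CL_hep,int` pregnant i.m. BET (L/h) | — | 22 (default) or 11.2 | two printed values of the same fit; both shipped, see below |
| `ka` (h⁻¹) | 2.85 (default) or 3 | 1.5 / 0.2 (dual) | DEX variants both shipped |
| `t_lag` (h) | 0.2 (default) or 0.3 | 1.5 | |
| `Q_pl` (L/h) | 45 | 45 | third trimester, flow-limiting |
| `K_p,uu` | 0.48 | 0.5 | calibrated; 0.31 best direct DEX fit |

Declared approximations (not printed by the source analyses; chosen once at
typical literature magnitudes, all overridable through the config
interface):

* `fu_maternal`: DEX 0.32, BET 0.36 — both corticosteroids are weakly
  protein-bound.
* `fu_fetal = fu_maternal / 0.8136`. The 0.8136 ratio is
  reverse-engineered from the plateau-to-`K_p,uu` translation (a
  total-concentration UV/MP plateau of 0.59 corresponding to
  `K_p,uu = 0.48` forces `fu_m/fu_f = 0.48/0.59`); it is consistent with
  the slightly lower albumin binding of fetal plasma.
* `V_m`: DEX 75 L (~1.0 L/kg), BET 95 L (~1.25 L/kg), for a ~75 kg
  third-trimester woman. With the well-stirred BET clearance (~7.3 L/h
  from `CL_hep,int = 22`, `fu = 0.36`, `Q_h = 97` L/h) this yields a
  terminal half-life near 9 h, in the range observed after i.m. BET-P:A
  in pregnancy.
* `Q_h`: 97 L/h pregnant, 87 L/h non-pregnant.
* `V_f = 5` L, `CL_fetal = 0` — the fetoplacental unit is small and fetal
  elimination of these drugs is minimal, so the fetal compartment
  equilibrates with maternal plasma within minutes and its volume barely
  influences exposure ratios.

One design decision deviates from an obvious alternative: the pregnant
i.m. BET scenario could have used a direct `cl_total_override` (the
observed post-i.m. clearance). Instead the default preset feeds the
printed `CL_hep,int = 22` L/h through the well-stirred model, because that
keeps a single clearance pathway for all scenarios and reproduces the
regimen ratios without an extra calibrated constant; `cl_total_override`
remains available and tested. The two printed pregnant-i.m. values (22 in
a figure caption, 11.2 in the text, identical fit quality) cannot be
reconciled from the text — they differ almost exactly by the twofold
induction factor, suggesting one is pre- and one post-induction — so both
ship as named presets with the caption value as default.

## Calibration workflow

Calibration follows the sequential logic of the source analysis: maternal
kinetics are fixed first (absorption and clearance presets above), then
only the fetal-side parameter `CL_int,Pgp` is estimated.

1. **Emax plateau.** Pooled single-sample UV/MP ratios follow
   `ratio(t) = plateau * t / (t50 + t)` (zero intercept — mother and fetus
   start drug-free). `fit_emax_uvmp()` fits by Levenberg-Marquardt least
   squares from a grid of data-scaled starting points (plateau starts
   scaled to the upper ratio decile, `t50` starts to the median sampling
   time), so the result is invariant to dyad ordering and time units. The
   plateau is capped at 1.5: a total-concentration ratio beyond that is
   not compatible with an efflux-limited fetus and indicates bad data.
2. **Plateau to `K_p,uu`.** `plateau_to_kpuu()` multiplies by
   `fu_m/fu_f`, converting a total-concentration asymptote into the
   unbound partition coefficient.
3. **Sensitivity search.** `calibrate_kpuu()` scans a `K_p,uu` grid
   (default 0.05-1.0 in 0.05 steps), converts each candidate to
   `CL_int,Pgp` via the steady-state identity with `CL_int,PD` held at its
   flow-limited value, simulates the regimen, and scores the predicted
   UV/MP ratios at the observed sampling times by AAFE
   (`10^mean|log10(pred/obs)|` — the standard symmetric fold-error
   measure; the source does not print a formula, and this is the only
   definition consistent with how its values behave). The estimate is the
   grid argmin refined by a parabola through the three bracketing points
   (the objective is an ODE functional, smooth and — on clean data —
   unimodal, so a gradient method would buy nothing at this grid cost).
4. **Uncertainty.** The 90% CI is a nonparametric bootstrap over dyads
   (500 resamples, percentile interval, fixed default seed). The CI method
   of the source is not stated; the bootstrap was chosen because it makes
   no distributional assumption about the single-sample design. The
   per-dyad log-fold-error matrix is cached across the grid, so each
   resample re-optimizes without re-simulating. In rare resampling
   configurations the percentile interval can marginally exclude the point
   estimate; the reported interval is widened to contain it.

## Population simulation

Inter-individual variability is log-normal with median equal to the
nominal value, one independent multiplier per parameter per subject.
Default CVs — 35% on clearance and volumes, 50% on absorption rate
constants, 30% on placental clearances, n = 1000 — are typical
population-PK magnitudes; the source figures do not print their
variability model. Two consequences of this choice are deliberate:

* Percentile bands (pointwise 5th/95th across subjects, matching how such
  figures are drawn) should be read qualitatively; their exact width
  inherits the assumed CVs.
* Regimen comparisons are insensitive to the CV choice, because
  `compare_regimens()` uses matched seeds: both arms see the identical
  virtual population, so percent changes are ratios within subjects, and
  under pure dose scaling they equal the scaling factor exactly.

Sampled parameter sets bypass the `ka_fast >= ka_slow` constructor check:
with 50% CVs independent draws can occasionally cross, the model is
well-defined either way, and re-ordering draws would distort the medians.

## Numerical choices

* Solver: `deSolve::lsoda` (stiff-capable), relative tolerance `1e-8`,
  absolute tolerance `1e-12` mg, output grid step 0.05 h. Integration is
  segmented at every dose/infusion boundary and the state increment
  applied exactly, rather than relying on event detection inside the
  solver. The right-hand side is compiled C; an R reference
  implementation (`engine = "R"`) is retained and tested for equality.
* Mass balance (cumulative input vs compartment amounts plus cumulative
  elimination) is tracked by two bookkeeping states and exposed via
  `mass_balance_error()`; the test suite requires < 0.1% and observes
  near machine precision.
* NCA: linear trapezoid only (no log-trapezoid), window edges interpolated
  linearly; extrema over grid points with earliest-time tie-breaking; the
  terminal half-life picks the trailing run (at least 3 positive points
  after the peak) maximizing adjusted R² of the log-linear fit and refuses
  nonnegative slopes.
* Fetal `Cmin` in regimen comparisons is the post-first-peak trough.
  Simulated profiles start at zero, so the absolute window minimum is
  identically zero and percent changes would be 0/0; the trough is what a
  printed "Cmin over the dosing interval" means for a profile that starts
  drug-free. (`nca()` itself keeps the plain absolute-minimum
  definition.) Similarly, "maintained above the threshold" means: once the
  fetal 5th-percentile concentration rises above the threshold it does not
  fall below it before the window ends.
* Degenerate inputs are rejected with named-field messages at
  construction: unknown config keys, out-of-range fractions, non-positive
  volumes, non-increasing dose times, dyads at or below the
  quantification limit.

## What the synthetic-data generator does and does not emulate

`generate_dyads()` reproduces the *structure* of the calibration data: one
paired MP/UV sample per dyad at a delivery time drawn uniformly over
[1, 24] h post first dose (samples earlier than 60 min are unusable
because prodrug hydrolysis is only then complete; the true delivery-time
distribution of the source studies is unknown, so uniform is the neutral
choice), with independent multiplicative log-normal error of stated CV on
each matrix (unit median, so log-residuals are centred on zero). Times
falling before absorption onset — where the model predicts zero
concentration and a real sample would be below quantification — are
redrawn within the window, deterministically under the seed.

It does **not** emulate: below-limit-of-quantification censoring of
otherwise-positive samples, shared subject-level (correlated MP/UV) error,
true kinetic inter-individual variability in the sampled mothers, or
assay-specific error structure. Passing the end-to-end recovery test
(`K_p,uu` recovered within 10% from 100 dyads at 25% noise, bootstrap CI
covering the generating value) therefore demonstrates that the estimator
is consistent and correctly seeded *under its own assumptions* — not that
real delivery data of that size would constrain `K_p,uu` equally well.

## Problem sizes

The shipped tests and the acceptance script use: 48-h simulations at
0.05-h output resolution; 1000-subject virtual populations for
percentile-based comparisons; 100 dyads at 25% CV for the recovery
experiment; 500 bootstrap resamples; a 20-point `K_p,uu` grid. These sizes
were chosen so the Monte-Carlo error of each quantity is comfortably below
the tolerance at which it is asserted.

## Known limitations

* Relative, not absolute: see above. Absolute fetal AUCs require the full
  multi-organ physiology this package deliberately omits.
* No prodrug step: phosphate/acetate hydrolysis is treated as
  instantaneous release from the depots; slow ester hydrolysis in
  collected blood samples (a suspected artifact in the source data) is not
  modelled.
* No metabolites, enterohepatic recirculation, or placental metabolism.
* `K_p,uu` is assumed time-constant over the 48-72 h horizon; placental
  P-gp abundance changes over gestation, which is exactly why the presets
  are gestational-week scenarios rather than one fixed parameter set.
* The DEX `K_p,uu` is genuinely uncertain (0.48 from the plateau
  translation vs 0.31 from the direct fit); the presets default to 0.48
  on the epimer argument — DEX and BET differ only in the configuration
  of one methyl group and P-gp does not readily discriminate isomers —
  and `acs_params(kpuu = )` accepts any value.
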