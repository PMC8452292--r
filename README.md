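# mfpbpk

Maternal–fetal pharmacokinetic simulation of the antenatal corticosteroids
dexamethasone (DEX) and betamethasone (BET).

Antenatal corticosteroids are given to women at risk of preterm delivery to
mature the fetal lung and prevent neonatal respiratory distress syndrome.
The drug acts in the fetus, but only the mother can be dosed — and fetal
exposure is nearly unmeasurable: at most one paired umbilical-vein /
maternal-plasma (UV/MP) sample can be drawn, at delivery. Both DEX and BET
are substrates of placental P-glycoprotein (P-gp), which pumps drug back
from the fetal to the maternal circulation, so maternal exposure is a poor
surrogate for fetal exposure. `mfpbpk` implements a reduced maternal–fetal
PBPK workflow for this problem: estimate the placental efflux clearance
from sparse UV/MP data, then simulate fetal concentration–time profiles
under candidate maternal dosing regimens.

## The model

A lumped four-state linear system (amounts in mg):

* `depot_fast`, `depot_slow` — intramuscular depot(s). DEX phosphate is
  absorbed in a single fast phase (`ka = 2.85 h⁻¹`, `t_lag = 0.2 h`); the
  1:1 BET phosphate:acetate mixture in two phases (`ka₁ = 1.5 h⁻¹`,
  `ka₂ = 0.2 h⁻¹`, `t_lag = 1.5 h`), half the dose in each.
* `a_maternal` — maternal central compartment. Elimination is hepatic via
  the well-stirred model, `CL = Q·fu·CL_int′ / (Q + fu·CL_int′)`, with
  `CL_int′` doubled at term by pregnancy CYP3A induction (DEX
  `CL_hep,int = 106 L/h`, BET 62 L/h i.v.; the pregnant i.m. BET scenario
  uses a re-estimated 22 L/h).
* `a_fetal` — fetal central compartment. Transplacental exchange on
  *unbound* drug: a perfusion-limited passive conduit
  `CL_PD,eff = Q_pl·CL_int,PD/(Q_pl + CL_int,PD)` (flow-limited at
  `Q_pl ≈ 45 L/h` in the third trimester) in both directions, plus a
  fetal→maternal P-gp efflux clearance `CL_int,Pgp`.

At steady state the unbound fetal:maternal partition coefficient is

```
K_p,uu = CL_PD,eff / (CL_PD,eff + CL_int,Pgp)
```

`K_p,uu = 1` for a pure passive-diffusion drug; P-gp pushes it below 1
(calibrated values: BET 0.5, DEX 0.48, with 0.31 as the best direct fit to
the DEX UV/MP data). Pooled single-sample UV/MP ratios rise with time post
dose toward a plateau; fitting the simple Emax curve
`ratio(t) = plateau·t/(t50 + t)` and correcting by the unbound-fraction
ratio turns that plateau into `K_p,uu`, and a grid search over `K_p,uu`
scored by absolute average fold error (AAFE = `10^mean|log10(pred/obs)|`)
with a bootstrap over dyads gives the calibrated estimate and its CI.

On top of the simulator sit noncompartmental metrics (linear-trapezoid AUC,
Cmax/Cmin, terminal half-life, time above a threshold), Monte-Carlo
population variability with pointwise percentile bands, and a
reference-vs-alternative regimen comparison that uses matched population
seeds so percent changes isolate the regimen effect.

## Worked example

Compare the clinical BET reference regimen (12 mg BET-P:A i.m. at 0 and
24 h) with alternative regimen 1 (2.4 mg at the same times) at gestational
week 30, in a 1000-subject virtual population:

```r
library(mfpbpk)

regs   <- builtin_regimens()
params <- acs_params("BET", gw = 30)       # calibrated BET preset, Kp,uu = 0.5
spec   <- population_spec(1000, seed = 1)

cmp <- compare_regimens(regs$BET_ref, regs$BET_alt1, params, pop_spec = spec)
cmp
#> <regimen_comparison> BET_ref vs BET_alt1 over [0, 48] h (n = 1000)
#>            metric profile reference alternative pct_change
#>      maternal_auc    mean  2811.000    562.2000      -80.0
#>     maternal_cmax    mean    99.170     19.8300      -80.0
#>         fetal_auc    mean  1145.000    229.0000      -80.0
#>        fetal_cmin    mean    10.770      2.1550      -80.0
#>  fetal_time_above    mean    46.430     46.2800       -0.3
#>      maternal_auc      p5  1542.000    308.3000      -80.0
#>     maternal_cmax      p5    64.300     12.8600      -80.0
#>         fetal_auc      p5   579.600    115.9000      -80.0
#>        fetal_cmin      p5     3.039      0.6077      -80.0
#>  fetal_time_above      p5    46.350     40.2900      -13.1
#>      maternal_auc     p95  4381.000    876.2000      -80.0
#>     maternal_cmax     p95   145.700     29.1400      -80.0
#>         fetal_auc     p95  1875.000    375.1000      -80.0
#>        fetal_cmin     p95    20.160      4.0320      -80.0
#>  fetal_time_above     p95    46.450     46.3700       -0.2
#> fetal conc maintained > 1 ng/ml: reference TRUE, alternative FALSE
#> doses per day: reference 1, alternative 1
```

Cutting every dose to 20% cuts every concentration-scale metric by exactly
80% — the model is dose-linear — while the time above the 1 ng/ml fetal
threshold, which is not dose-linear, degrades only slightly. The same
machinery drives the DEX redesign (12 mg q24h maintains the AUC of 6 mg
q12h while doubling the maternal 95th-percentile Cmax) and the single-dose
BET alternatives. Calibration runs the other direction:

```r
dyads <- generate_dyads(100, regs$BET_ref, params, noise_cv = 25, seed = 7)
calibrate_kpuu(dyads, regs$BET_ref, params)
#> <calibration_result> Kp,uu = 0.491 (90% CI 0.458-0.526), AAFE = 1.317
#>   implied CL_int,Pgp = 46.7 L/h over 100 dyads (500 bootstrap resamples)
```

A thin command-line wrapper over the same functions ships in
`inst/cli/mfpbpk` (subcommands `simulate`, `population`, `nca`, `fit-emax`,
`calibrate-kpuu`, `compare-regimens`, `synth`).

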