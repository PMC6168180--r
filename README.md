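# snapcea

Individual-level microsimulation of the health and economic impact of
food **incentives, disincentives, and restrictions in SNAP** (the US
Supplemental Nutrition Assistance Program), for health-policy modellers
and cost-effectiveness analysts.

SNAP supports food purchases for roughly 1 in 7 Americans through an
electronic benefits (EBT) card, which makes product-specific financial
nudges technically feasible: return $0.30 per SNAP dollar spent on
incentivized foods, debit $1.30 per dollar spent on disincentivized
foods, or remove a food from eligibility altogether. `snapcea` estimates
what three such reforms would do to cardiometabolic disease, QALYs, and
costs among adult participants aged 35–80:

1. **fv_incentive** — 30% incentive for fruits and vegetables (F&V);
2. **fv_ssb_restriction** — the F&V incentive plus restriction of
   sugar-sweetened beverages (SSBs);
3. **snap_plus** — 30% incentives for F&V, nuts, whole grains, fish, and
   plant-based oils combined with 30% disincentives for SSBs, junk food,
   and processed meats.

## Model

The pipeline has five stages, each an exported module:

- **Synthetic population** — a weighted synthetic SNAP adult cohort
  (Gaussian copula over age, SBP, cholesterol, HDL, BMI and a latent
  diabetes score; categorical demographics matched to published
  marginals; gamma-distributed intakes of 9 food categories), expanded to
  the 14.5 million represented adults.
- **Policy effects** — each price instrument becomes an overall intake
  change via
  Δ% = price response × SNAP-venue share × SNAP-dollar share × (1 − spend shift);
  a restriction contributes −(SNAP retail share) × (1 − shift). Shipped
  components are calibrated so the composites equal the published
  per-food effects (e.g. vegetables +19.0%, SSB restriction −33.2%).
- **Diet–disease effects** — log-linear dose–response relative risks
  ln RR(age) scaled per g/d, attenuating with age; BMI-mediated SSB
  effects and sodium→blood-pressure effects by stratum; junk food as a
  composite of nine joint associations.
- **Engine** — annual-cycle state-transition simulation (well, acute and
  chronic MI/angina/resuscitated arrest/stroke, CVD and non-CVD death,
  plus an absorbing diabetes flag) driven by the published general-CVD
  risk function, annualized as p₁ = 1 − (1 − p₁₀)^{1/10}, with
  common random numbers across scenarios so incremental results are
  exactly coupled.
- **CEA + PSA** — 3%/yr discounting, net costs from societal,
  government-affordability (adults 35+ / all participants), and
  SNAP-budget perspectives, ICERs classified exactly at $50,000 and
  $150,000 per QALY, and a probabilistic sensitivity analysis over
  effect sizes, relative risks, risks, costs, and utilities.

See `vignettes/snapcea-methods.Rmd` for assumptions, calibration inputs,
and numerical choices.

## Worked example

```r
library(snapcea)
res <- snap_cea(pop_size = 20000, seed = 1, horizons = list(5, "lifetime"))
print(res)
```

```
<snap_cea> 20000 simulated persons, scenarios: fv_incentive, fv_ssb_restriction, snap_plus

  fv_incentive         5        events averted   90,860  QALYs gained    81,322  HC savings $  2.92B
  fv_incentive         lifetime events averted  827,190  QALYs gained 1,733,378  HC savings $ 15.59B
  fv_ssb_restriction   5        events averted  143,195  QALYs gained   122,294  HC savings $  5.94B
  fv_ssb_restriction   lifetime events averted 1,405,787  QALYs gained 2,982,266  HC savings $ 45.83B
  snap_plus            5        events averted  197,711  QALYs gained   184,478  HC savings $  7.47B
  snap_plus            lifetime events averted 1,940,771  QALYs gained 4,149,786  HC savings $ 47.47B

  fv_incentive         5        societal     Saving ($2.80B)
  fv_incentive         5        govt_adults  $26,242/QALY
  fv_incentive         5        govt_all     $104,464/QALY
  fv_incentive         lifetime societal     Saving ($15.38B)
  ...
  snap_plus            lifetime govt_all     Saving ($65.84B)
```

Reading it: with a 20,000-person cohort expanded to 14.5M adults, the
F&V incentive averts ~91k CVD events over 5 years nationally and is
cost-saving from the societal perspective (healthcare savings exceed
administrative costs) but costly per QALY when the food subsidies for
all 42M participants are counted; adding the SSB restriction and then
the full incentive/disincentive program increases health gains
monotonically, and SNAP-plus is cost-saving from *every* perspective
because the disincentive receipts fund the incentives. These qualitative
orderings reproduce the published evaluation; exact totals differ
because the population and several parameter tables are synthetic
calibration inputs (see the vignette).

Other entry points: `generate_population()`, `apply_scenario()`,
`person_modifiers()`, `simulate_cohort()`, `run_psa()`,
`write_results()`, and a thin CLI at `inst/cli/snapcea.R`.

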