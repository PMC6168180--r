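---
title: "Modelling food incentives and disincentives in SNAP: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling food incentives and disincentives in SNAP: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

snapcea estimates the health gains, costs, and cost-effectiveness of three
food-pricing reforms of the US Supplemental Nutrition Assistance Program
(SNAP) among adult participants aged 35–80: a 30% fruit-and-vegetable
(F&V) purchase incentive; the same incentive plus removal of
sugar-sweetened beverages (SSBs) from SNAP eligibility; and a broader
combined program ("SNAP-plus") pairing 30% incentives for F&V, nuts,
whole grains, fish, and plant-based oils with 30% disincentives for SSBs,
junk food, and processed meats. This vignette documents the model, its
assumptions, the calibration inputs, and the numerical choices, in the
order the pipeline runs.

## 1. Synthetic population

The simulation operates on an individual-level synthetic population that
stands in for survey microdata of adult SNAP participants. Categorical
demographics (sex, race/ethnicity, education, income-to-poverty band,
federal insurance) are drawn independently against published marginal
targets. Continuous cardiometabolic risk factors — age, systolic blood
pressure (SBP), total and HDL cholesterol, body-mass index (BMI) — plus a
latent diabetes score are linked through a Gaussian copula with modest
default rank correlations (age–SBP 0.30, age–total-cholesterol 0.15,
BMI–HDL −0.25, BMI–diabetes 0.30), so the generated joint structure is
plausible while every marginal remains exactly configurable.

Ages are drawn band-stratified: the five published age-band proportions
are matched exactly in expectation, and a common within-band Beta shape
is calibrated analytically so the overall mean equals the 52.1-year
target. One consequence worth stating: *no* distribution supported on
[35, 80] with those band masses can have a standard deviation above about
12.08 years, so the published mean/SD pair (52.1, 12.3) is not jointly
attainable; the generator's implied SD is ≈ 11.7 years
(`implied_age_moments()` returns the exact value and the tests check the
realized SD against it, not against 12.3).

Dietary intakes of the nine food categories are gamma-distributed with
means equal to the published baseline consumption levels and a
coefficient of variation of 1 (right-skewed, non-negative; only means are
published). SSB mass/volume uses 29.57 g per fluid ounce, the only
conversion consistent with the printed 414 g/d = 14.0 fl oz/d pair.
Baseline risk-factor levels (SBP 127 ± 17 mmHg, total cholesterol
196 ± 40, log-normal HDL ≈ 50 and BMI ≈ 30, smoking 30%, diabetes 25%)
are calibration inputs — the source evaluation does not print them for
the SNAP subsample — chosen to reflect a lower-income, higher-risk US
adult population; all are configurable.

Survey weights are 1 (synthetic persons are already draws from the target
distribution); `scale_to_national()` expands the cohort to the
42,138,000 × 34.5% = 14,537,610 represented adults.

## 2. Policy effects on intake

Each scenario's price instruments become per-food *overall* fractional
intake changes through a multiplicative composition:

\[
\Delta\% \;=\; \text{price response} \times \text{SNAP-venue share}
\times \text{SNAP-dollar share} \times (1 - \text{spend shift}),
\]

i.e. the intake response to a 30% price change at the point of purchase,
discounted by the fractions of the food actually bought at SNAP-eligible
venues and with SNAP dollars, and by compensating shifts of spending to
non-SNAP dollars. A restriction instead removes the SNAP-dollar share of
retail purchases, half of which is assumed to shift to other food
dollars: \(\Delta\% = -\text{SNAP retail share} \times (1-\text{shift})\),
giving −0.664 × 0.5 = −33.2% for SSBs.

The exact decomposition used by the source evaluation is not published,
so the shipped component table fixes the shares at plausible values
(venue 0.9, SNAP-dollar 0.9, shift 0.1) and back-solves the price
response per scenario × food so the *composite* equals the published
overall effect — the composites, not the components, are the ground
truth. Four printed inconsistencies are preserved rather than forced:
fruits 23.4% × 81.3 g/d = 19.02 vs the printed 19.1 g/d; SSB restriction
−33.2% × 414 = −137.4 vs the printed −139; the nuts composite (31.5%)
exceeds the stated 19.0–24.2% incentive band; and SNAP-plus vegetables
(+28.8 g/d) exceeds the F&V-only change (+25.6). Tests record both
values.

Changes apply uniformly (the same Δ% for every person, multiplicatively
on each person's own baseline intake) from year 1 with no adoption lag,
matching the rapid responses seen in pricing interventions.

## 3. Diet–disease effects

Direct effects use the standard comparative-risk-assessment convention:
log-linear dose–response, with the log relative risk attenuating linearly
with age (25% per decade above a reference age of 60 by default, floored
at zero so an effect can vanish but never reverse). There is deliberately
no F&V–diabetes entry: the evidence review behind the source evaluation
found no probable or convincing etiologic effect, which is what produces
the diabetes "survival artifact" under the F&V-only scenario (see §4).

Two mediated pathways are modelled. SSB changes shift BMI via
age- and adiposity-stratified slopes (kg/m² per 8-fl-oz serving/d), and
the BMI shift acts on CHD, stroke, and diabetes through per-kg/m²
relative risks; the direct SSB terms in the RR table are the
*BMI-independent* components, so the two do not double-count. The
engine's diabetes-incidence model stratifies on the *unshifted* BMI
trajectory for the same reason. Junk food has no etiologic effect of its
own; its composite relative risk multiplies the effects of nine retained
joint associations with linked dietary components (some protective, some
harmful when junk food falls), and its sodium component acts on SBP via
race/hypertension/age-stratified slopes.

Per-food, per-outcome relative-risk multipliers are clamped to
[0.5, 2.0] per simulated change as a guard against extreme synthetic
intakes in the gamma tails (configurable). The specific RR values,
junk-food profile, and mediated slopes shipped in `inst/extdata/` are
calibration inputs drawn from the diet–cardiometabolic meta-analysis
literature; the package's correctness surface is the mechanism plus the
published composite effects, not individual unpublished cells.

## 4. State-transition engine

The engine is an annual-cycle, individual-level state-transition model
with states well → {acute MI, angina, resuscitated cardiac arrest, acute
stroke} → chronic counterparts → death (CVD or other cause), plus an
orthogonal absorbing diabetes flag. Each cycle resolves competing risks
by sequential conditional draws — non-CVD death, then a CVD event (typed
by the event split; fatal per type- and age-specific case fatality), then
diabetes onset for event-free survivors — so at most one event occurs per
person-year. Acute states last exactly one cycle. Everyone starts
CVD-free; persons are followed to the horizon (5/10/20 years) or until
death or age 100 ("lifetime", implemented as a closed cohort of the
baseline population; entrant dynamics are out of scope).

Annual CVD risk comes from the published sex-specific general-CVD risk
function (log age, log total cholesterol, log HDL, log untreated SBP,
smoking, diabetes), annualized by
\(p_1 = 1-(1-p_{10})^{1/10}\), scaled by a calibration multiplier
(default 1.3, chosen once so baseline event counts sit in the vicinity of
the published national magnitudes), multiplied by the scenario's CHD- and
stroke-specific relative-risk modifiers, and doubled (default) for
persons with established CVD. Scenario ΔSBP feeds the risk score
directly; ΔBMI acts only through the mediated relative risks (§3).
Risk factors receive small secular drifts (SBP +0.1 mmHg/yr, BMI
+0.05 kg/m²/yr by default) on top of ageing. Non-CVD mortality is a
Gompertz schedule by sex; diabetes incidence is log-linear in age and
baseline-trajectory BMI (base 0.8%/yr at age 50, BMI 30, capped at 5%).
Event splits, case fatality, utilities, state costs, and the diabetes
model are unpublished in the source evaluation and are all declared
calibration inputs.

QALYs accrue on the end-of-cycle state: state utility × an age decrement
(0.0015/yr above 35) × a diabetes multiplier (0.97), discounted at 3%/yr
with year 1 undiscounted; the year of death contributes zero. Healthcare
costs (2017 USD) accrue the event-type cost in an event year, the chronic
state cost otherwise, a diabetes add-on while diabetic, and a fixed cost
in the year of CVD death, discounted identically.

**Common random numbers.** Each cycle draws one seeded block of five
uniforms per person, regenerated identically for the base case and every
scenario. Where hazards coincide, trajectories coincide *exactly*: a null
policy yields zero incremental everything bit-for-bit, and a protective
policy can only remove events, never add them. This coupling also makes
the diabetes survival artifact deterministic: under the F&V-only scenario
the per-person-year diabetes hazard is unchanged, so scenario diabetes
onsets are a superset of base-case onsets and lifetime "cases averted"
is necessarily ≤ 0 while CVD events averted is > 0.

**Validation.** With a homogeneous cohort, a fixed annual event
probability, flat non-CVD mortality, and zeroed age gradients, the engine
is an exact constant-hazard Markov chain; the test suite re-derives the
expected cumulative events and discounted QALYs with an independent
transition-matrix loop and requires agreement within 3 Monte-Carlo
standard errors at n = 50,000.

## 5. Costs and cost-effectiveness

Administrative costs follow a per-scenario startup + flat-annual schedule
fitted to the published near-flat cumulative discounted values. Food
program flows are incentive payments minus disincentive receipts on
per-participant annual SNAP-dollar spending by category (separate adult
and child spends, back-solved so the 5-year discounted F&V subsidy for
all participants is ≈ $11.54B and the SNAP-plus net flows match the
published scale; the back-solve ignores mortality, a conservative few-%
offset). Restrictions produce no program savings. Yearly flows follow the
simulated adult cohort's survival profile — the published tables apply
the same time-profile to the child scope, and so does the package.
Children and adults under 35 contribute subsidy costs only, never health
benefits.

Net costs by perspective: *societal* = administrative − healthcare
savings (food subsidies are an intra-societal transfer); the two
*government-affordability* perspectives add the net food cost for adults
35+ or for all participants; a *SNAP-budget* view (administrative + food
cost, ignoring healthcare) supports the fiscal-integrity headline. ICERs
are net cost / QALYs gained, with cost-saving (dominant) and dominated
flags, and willingness-to-pay classification exactly at $50,000 and
$150,000 per QALY.

## 6. Probabilistic sensitivity analysis

The PSA perturbs seven multiplier-type parameters — policy effect sizes
and the log relative risks (truncated normal, SD 0.15), CVD risk
calibration (lognormal, SD 0.10), administrative, healthcare-state, and
utility-decrement multipliers (gamma, CV 0.20), food spends (gamma, CV
0.10) — all centered on 1, drawn independently, with hard truncation
bounds enforced by retry. Each iteration re-runs the full pipeline on a
fixed reduced population (parameters are redrawn, the population is not),
under common random numbers across scenarios *and* iterations, so a
degenerate registry reproduces the point estimate exactly and all
iteration-to-iteration variation is parametric. Percentile summaries
(median, 2.5th/97.5th) use linear interpolation between order statistics.

## 7. Problem sizes and reproducibility

Default analysis runs use 20,000 synthetic persons expanded to the
14.5M represented adults; the PSA design is 20,000 persons × ≥100
iterations at the 5-year horizon (the published design was 1,000,000
persons × 1,000 iterations — the scaled-down design keeps Monte-Carlo
error well below the societal cost-saving margins being tested, since
healthcare savings exceed administrative costs several-fold in every
scenario). All randomness derives from explicit integer seeds; repeated
runs are byte-identical, and `write_results()` emits a manifest (seeds,
sizes, versions) sufficient to reproduce any table.

## 8. What the synthetic design does and does not show

Passing tests demonstrate that the mechanisms are implemented correctly
(composition arithmetic, dose–response, state-transition bookkeeping,
discounting, perspectives, PSA propagation) and that the published
*in-table* identities and qualitative findings (scenario orderings,
universal societal cost-saving, the diabetes survival artifact) are
reproduced under the stated study conditions. They do not certify the
headline point totals: those depend on restricted survey microdata and on
unpublished calibration tables (relative risks by age, costs, utilities),
for which this package ships clearly-labelled synthetic calibration
inputs. Known limitations: independent categorical demographics (no
joint demographic structure); no treatment indicator in the risk score;
no entrant dynamics in the open-cohort horizons; no cancer or
productivity effects (deliberately excluded, as in the source
evaluation); and uniform policy response across persons.
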