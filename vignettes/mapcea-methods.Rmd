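---
title: "Methods: a Markov cohort model of MDMA-assisted psychotherapy for chronic PTSD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model of MDMA-assisted psychotherapy for chronic PTSD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapcea)
```

## The model

`mapcea` implements a deterministic Markov cohort model of MDMA-assisted
psychotherapy (MAP) for chronic, treatment-resistant PTSD, from the
health-care payer's perspective. The state space is five CAPS-IV severity
bands — asymptomatic (0–19), mild (20–39), moderate (40–59), severe (60–79),
extreme (80+) — plus an absorbing death state. Two arms portray the same
1,000-patient cohort: the treated arm starts from the post-treatment
severity distribution and carries the per-patient intervention cost; the
comparator starts from the cohort's own intake distribution under continued
standard care. This self-comparison reflects the view that the trial control
condition (low-dose MDMA or placebo plus psychotherapy) is not a purchasable
real-world alternative.

Three structural assumptions carry the model:

1. **Severity is sticky.** In the base case survivors remain in the severity
   state reached at the trial endpoint, in both arms — no remission and no
   relapse. Long-term follow-up of trial completers and the chronicity of
   the enrolled population motivate this; the progression scenario relaxes
   it.
2. **Mortality is background risk times a severity relative risk.** Each
   cycle, state *s* loses `occupancy * min(1, q(age) * RR_s)` patients,
   where `q` comes from an age-indexed life table and `RR` rises from 1
   (asymptomatic) to 2.76 (extreme).
3. **Cost reductions phase in over five years.** Improved patients do not
   instantly cost less (chronic comorbidities persist): the treated arm's
   cycle-*t* medical cost is `(1 - f_t) * C_baseline(t) + f_t * C_post(t)`
   with `f = 0, 0.25, 0.5, 0.75, 1, 1, ...`. `C_post` prices current
   survivors at their state costs; `C_baseline` prices the same person-years
   at the intake-distribution cost mix. Only costs are phased — mortality
   and utilities follow the post-treatment states immediately.

Outcomes at a horizon are differences of cumulative discounted costs and
QALYs and cumulative undiscounted deaths, plus an ICER when the intervention
costs more and gains QALYs, or a dominance flag when it is cheaper and more
effective. The break-even horizon interpolates cumulative net cost linearly
between the bracketing integer cycles and is reported to one decimal.

## Parameters

All money is in 2019 USD; rates are per year. The base case
(`default_params()`):

| Parameter | Default | Notes |
|---|---|---|
| Intake distribution | 0 / 0 / 122 / 311 / 567 | see "printed counts" below |
| Follow-up distribution | 216 / 270 / 135 / 230 / 149 | trial endpoint |
| Utilities | 1 / 0.97 / 0.851 / 0.477 / 0.369 | anxiety-disorder weights; extreme from a veteran cohort |
| Annual medical cost | \$4,946 / \$9,944 / \$14,916 / \$19,888 / \$23,866 | severe anchor pooled from literature by sqrt-n weighting; others derived (50% / 75% / 120% of severe) |
| Mortality RR | 1 / 1.74 / 2.05 / 2.51 / 2.76 | derived from pooled RR 2.28 (severe = +10%, extreme = +21%, moderate = −10%, mild = −23.5%) |
| Intervention cost | \$7,544 (therapists \$6,194, screening \$997, MDMA \$353) | micro-costed; the printed total \$7,543 reflects component rounding |
| Effectiveness | mean CAPS change −37.9 (patient SD 28.9, n = 105) | drives the follow-up distribution via the synthetic cohort |
| Discount rate | 3.0%/yr | costs and QALYs alike |
| Cohort, age, horizon | 1,000 patients, age 40, 30 yr | horizons 1/10/30 reported |

Two printed inputs conflict in the source material; the package defaults to
the tabulated values (severe-cost anchor \$19,888, asymptomatic cost
\$4,946) because they regenerate the other printed state costs exactly; the
running-text variants (\$19,899, \$4,949) remain reachable through
`derive_state_costs()`.

**Printed counts that sum to 1,001.** The intake counts (122, 311, 568) sum
to 1,001 for a 1,000-patient cohort. The default resolves this by
largest-remainder rounding of the underlying percentages (12.2 / 31.1 /
56.8), giving (122, 311, 567) — the moderate and severe cells have the
largest fractional remainders, so the extreme cell loses the surplus unit.
`default_params(intake = "printed")` keeps the raw counts.

**Background mortality.** The bundled schedule is a *synthetic* Gompertz
life table (`us_lifetable_2007_synthetic.csv`), `q(a) = 0.00139 *
exp(0.085 * (a - 40))` over ages 20–110, anchored at the published
q(40) = 0.00139 and with a slope typical of U.S. adult all-cause mortality.
A real national life table can be substituted without code change
(`read_life_table()`); the engine treats the schedule as a swappable input
because the published death counts imply a background rate about twice the
printed anchor, a convention that cannot be recovered from the source
alone. Ages beyond the table clamp to its last entry rather than
extrapolating; when `q * RR` would exceed 1 it is clamped with a warning.

## Accounting conventions

* **End-of-cycle discounting**: cycle *t* flows are divided by
  `(1 + r)^t`, so year 1 is discounted one full period. This reproduces the
  published one-year control-arm QALYs from the printed utilities.
* **Decedent half-cycle credit**: patients dying in a cycle accrue half a
  year of utility and medical cost (`decedent_credit = 0.5`); a zero-credit
  variant is available since the source is silent. The two differ by well
  under 1% on every reported outcome.
* **Upfront intervention cost** is charged undiscounted at time zero; the
  published one-year treated-arm cost (intervention plus one discounted
  year of medical care) is consistent with this.
* **Fractional persons** are carried exactly — this is a cohort model, not
  a microsimulation — and deaths are reported undiscounted.
* **Thresholds** are located by plain bisection (the output is monotone in
  every knob searched), narrowing the bracket far enough that substituting
  the threshold back moves net cost by less than a dollar. The
  symptomatic-cost threshold scales the four symptomatic state costs while
  leaving the asymptomatic cost fixed; this convention reproduces both
  published threshold figures (savings vanish near 19% of base-case costs,
  and the ICER at 10% of costs is near \$2,100/QALY), whereas scaling all
  five states would place the threshold near 7%.

## The synthetic patient cohort

Trial microdata are not deposited, so effectiveness sweeps need a declared
mapping from "mean CAPS change" to a severity distribution.
`calibrate_cohort()` generates 1,000 patient records whose baseline
classification reproduces the intake distribution exactly (truncated-normal
draws within each band, baseline mean 85.8, SD 19.3) and whose follow-up
classification reproduces the follow-up distribution exactly (uniform draws
within each band; the open extreme band is sampled on 80–115). Baseline and
follow-up scores are paired by rank: most severe baseline with most severe
follow-up.

`apply_effect_shift()` rescales each record's CAPS change proportionally:
`followup' = baseline + (new_mean / base_mean) * (followup - baseline)`,
floored at zero. Proportional scaling (rather than a uniform additive
shift) is the package's design choice because it makes the two anchor cases
exact: at the base mean the calibrated follow-up distribution is returned
unchanged, and at a mean change of zero the intake distribution is
recovered exactly. It is also monotone — a weaker effect never increases
the count at or below any severity level — which the test suite checks as a
first-order-dominance property.

The generator emulates marginal severity distributions and the mean effect
size; it does not emulate within-patient trajectories, covariates,
dose–response or the trial's control arm, and the realized mean change of
the synthetic records (≈ −36 to −38 depending on seed) tracks but does not
exactly equal the published −37.9, because the published distributions
constrain it only up to band widths. Tests passing on this cohort therefore
show that the *mapping* behaves as declared, not that real microdata would
produce identical sweeps.

## Sensitivity analyses

* **One-way (tornado)**: each parameter to its endpoints, others at base,
  sorted by output span. Published ranges are used where printed
  (intervention cost ±30%, discount 2.3–3.8%, age 35–45, mild utility
  0.9–1.0, moderate ±10%); severe and extreme utilities take the same ±10%
  as moderate, relative risks sweep ±1 SD of their lognormal
  specifications, and the symptomatic medical-cost multiplier — which has
  no printed range — defaults to 0.5–1.5. The cost multiplier dominates the
  tornado, followed by effectiveness, matching the published ordering.
* **Two-way**: full-factorial grids; `"horizon"` is addressable, so the
  published intervention-cost × horizon grid is expressible.
* **Progression scenario**: from cycle 6 onward a fraction of treated-arm
  survivors moves one severity state worse per cycle (extreme progresses no
  further). The default rate is 6%/yr swept over 0–12% (the published
  scenario sweep); the alternative printed base of 5% (0–10%) can be passed
  explicitly. Progression includes asymptomatic patients — relapse into
  subthreshold PTSD — which is required for the scenario's limiting
  behaviour (at rate 1, all survivors reach the extreme state in four
  cycles).
* **PSA**: beta distributions for range-bounded quantities (a symmetric
  Beta(4, 4) rescaled to the range, keeping mass centred with soft tails —
  the published material gives only ranges), gamma/lognormal/normal by
  method of moments, truncation by rejection. Parameters are drawn
  independently (no correlation structure is published). Health-care costs
  are held fixed in the PSA (their printed dispersion is zero; they are
  explored deterministically instead). One master seed spawns per-iteration
  substreams, so results are bit-for-bit reproducible and independent of
  evaluation order.

**Effectiveness uncertainty.** The printed SD of the mean CAPS change,
28.9, is the patient-level SD (n = 105). Sampling the *mean* effect with
that SD would conflate individual variability with parameter uncertainty
and makes roughly a tenth of draws cost-incurring at 30 years —
contradicting the published claim that all 10,000 effectiveness iterations
remain cost-saving. The PSA therefore defaults to the standard error of the
mean, 28.9 / sqrt(105) ≈ 2.82, under which the test suite verifies ≥ 99% of
10,000 iterations are cost-saving; `use_patient_sd = TRUE` restores the
literal 28.9.

## A published figure the model cannot reproduce

The model reproduces the published one-, ten- and thirty-year rows within a
few percent, both published threshold figures, and the approximate \$80M
savings at the low effectiveness endpoint. It does **not** reproduce the
published 3.1-year break-even: under the published phase-in (0/25/50/75/100%)
and cost inputs the crossing falls at ≈ 3.5 years. The published figures are
internally inconsistent on this point: the published five-year per-patient
savings (\$16,232) combined with the published phase-in weights implies a
break-even of ≈ 3.5 years as well, and producing 3.1 would require annual
savings beyond what the printed distributions and state costs can generate.
The corresponding acceptance test asserts the published value and fails;
the package reports its own computed value rather than matching the
printed one. Published death counts are likewise treated as the
least-constrained output (they imply a background mortality roughly twice
the printed anchor); tests check deaths averted for sign and ordering
across horizons only.

## Problem sizes and determinism

The deterministic base case runs in milliseconds (30 annual cycles over 5
states). The test suite uses 10,000 iterations for the effectiveness-only
PSA and 1,000 for the joint PSA interval check — enough for stable
percentile intervals at the tested tolerances — with fixed seeds
throughout; the full suite completes in well under a minute. Calibration of
the synthetic cohort is seeded (`calibration_seed`, default 20231) and
restores the caller's RNG state, as does `run_psa()`.

## Known limitations

* Payer perspective only: productivity, disability, family and
  criminal-justice effects are out of scope, so societal benefits are
  understated.
* No remission in either arm and no treated-arm relapse outside the
  progression scenario; benefits beyond the four-year follow-up window are
  extrapolated by assumption.
* The severity-stratified mortality relative risks are constructed from a
  single unstratified estimate, and the background schedule is synthetic
  (anchored, not observed).
* CPI inflation of literature costs is pre-applied in the printed inputs
  and exposed only as the scalar `inflation_multiplier`.
* The CAPS-to-distribution mapping is a declared convention validated
  against qualitative published claims, not against microdata.
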