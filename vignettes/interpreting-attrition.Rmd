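---
title: "Bounding the true quit rate when most participants are lost to follow-up"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounding the true quit rate when most participants are lost to follow-up}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cessbounds)
```

## The problem

Fully automated Internet trials of smoking cessation interventions can
randomize tens of thousands of smokers at negligible marginal cost, but
they retain only a fraction of them at follow-up: in the setting this
package models, around 40% of 16,430 participants completed the 1-month
assessment and only 22% the 12-month one. Abstinence is a binary,
self-reported outcome, and the standard reporting convention —
*missing = smoking* (M=S), a conservative variant of intent-to-treat —
counts every unreachable participant as a smoker. Under severe attrition
the M=S rate therefore measures follow-up success as much as treatment
effect: a trial with true quit rate $p$ and follow-up completeness $f$
reports, when responders are representative, an M=S rate of roughly
$p \times f$ (`projected_ms_rate()`), so 20% efficacy looks like 8%
at 40% follow-up.

The package implements three layers of response to this problem:

1. **Conventions.** For each cell (wave $\times$ abstinence window),
   with $q$ reported quitters out of $a$ answered items among $N$
   randomized:
   $$\text{observed} = q/a, \qquad
     \text{M=S} = q/N, \qquad
     \text{M=Quit} = (q + N - a)/N.$$
2. **Worst-case bounds.** Because the outcome is binary, the unknown
   outcomes of the $N - a$ nonresponders are bracketed by all-smoking
   and all-quit, so the true rate lies in $[\text{M=S}, \text{M=Quit}]$
   with certainty. The width of this interval is exactly the
   missingness fraction $(N-a)/N$ — guaranteed coverage, little
   information when attrition is severe.
3. **Reference-anchored bounds.** If a smaller trial ran the *identical*
   intervention with intensive (live) follow-up, its M=S rate is a lower
   anchor and its observed rate an upper anchor for the automated
   trial's true rate. The upper-anchor argument rests on a measurable
   fact: responders reached by automated email report quitting at much
   higher rates than responders reached live (16.3% vs 9.8% across
   follow-ups in the reference data, `responder_excess()` ≈ 0.66), so an
   automated-only observed rate overshoots the truth, while the
   reference trial's observed rate — computed on a less selected
   responder pool — still bounds it from above.

```{r chain}
chain <- interval_chain(convention_rates(1361, 3292, 16430),
                        fixture_reference_trial())
chain
```

The three stages narrow the month-12 interval from [8%, 88%] to
[21%, 52%] (the reference trial's own worst case) to [21%, 30%].
The anchors are taken as published inputs (`fixture_reference_trial()`);
the package deliberately does not try to re-derive them from
participant-level reference data, which is not available.

## Assumptions, and what can go wrong

The worst-case interval assumes only that the outcome is binary; it can
never miss. The reference-anchored interval adds two substantive
assumptions: the two trials delivered the identical intervention to
comparable cohorts, and automated responders over-report quitting
relative to the cohort (positive missing-not-at-random selection). If
the second assumption fails in the *other* direction — responders quit
*less* than nonresponders — the reference observed rate is no longer an
upper bound. `reference_trial_summary()` refuses inverted anchors
(M=S above observed), and `coverage_experiment()` *measures* coverage
rather than assuming it, flagging configurations that violate the
identical-intervention premise.

Multiple imputation is intentionally out of scope: with 60–80% of
outcomes missing not at random, an imputation model is driven almost
entirely by untestable assumptions; bounding is the honest summary.

## The synthetic cohort generator

Real trials never reveal the outcomes of their nonresponders, so every
coverage claim is verified on simulated cohorts with known ground truth.
`simulate_cohort()` generates, per participant: stratum variables
(gender, history of major depressive episodes), a language, a
stratified permuted-block condition assignment (block size = number of
arms, truncated, so arm sizes within a stratum differ by at most 1),
then per wave a true 7-day abstinence draw, a nested 30-day draw, and a
follow-up response draw from the MNAR model
$$\operatorname{logit} P(\text{respond at wave } w)
  = b_w + \delta \cdot 1[\text{truly abstinent at } w].$$
Responded records carry truthful answers; there is no reporting-error
model. Waves are simulated independently given the per-wave quit
probabilities — the analyses here are all marginal per wave, so a
longitudinal abstinence trajectory would add machinery without changing
any tested quantity.

Defaults, chosen once to emulate the modelled trial:

* **4 arms × 4100 participants**, waves at 1/3/6/12 months.
* **Wave response targets 39.95/30.38/23.21/21.95%** — the completed
  follow-up rates of the automated trial. The base log-odds $b_w$ are
  calibrated by root-finding (`calibrate_response_logodds()`) so that
  the *expected* marginal response rate $(1-\bar q_w)\,
  \sigma(b_w) + \bar q_w\, \sigma(b_w + \delta)$ hits the target
  essentially exactly; the acceptance test verifies the realized rates
  over 50 replicates.
* **True 7-day quit probabilities 0.20/0.22/0.24/0.25** across waves,
  equal arms. The month-12 value sits inside the anchored 21–30% range;
  the mild upward drift mirrors the published observed-rate drift.
* **MNAR shift $\delta = 1.0$.** A single logit shift is the simplest
  mechanism that reproduces the responder-inflation observation; at the
  default truth and 22% follow-up it yields an observed month-12 rate
  near 41%, the inflation seen in the real data. $\delta = 0$ is the
  missing-at-random limit, in which the observed rate is unbiased and
  the M=S rate averages to $p \times f$ — both property-tested.
* **P(30-day | 7-day abstinent) = 0.8**, within the 0.73–0.89 range the
  published observed 30-day/7-day ratios span.
* **Stratum prevalences**: male 52.84%, MDE history 31.05% (split
  18.05% past / 13% current, guided by the reference trial's subgroup
  counts); language mix 20/80 English/Spanish.

What the generator does **not** emulate: the recruitment funnel and its
economics, website usage, reporting error, within-person abstinence
trajectories, covariate effects on quitting, or seasonal/history
effects. Passing coverage tests therefore show that the bounding logic
is correct *under the stated MNAR mechanism*, not that any particular
real trial satisfies it.

## Numerical and design choices

* Rates are stored as proportions; percentages appear only at the
  display layer, rounded half-up to 2 decimals (`as_pct()`), matching
  printed-table style. Tests compare unrounded values.
* "Missing" in M=Quit uses the answered-item denominator
  ($N - a$), not the completed-follow-up denominator: item nonresponse
  within a completed follow-up counts as missing for bounding. The
  alternative is exposed via `missing_from = "responded"` in the table
  builders; both denominators are always carried because they genuinely
  differ (e.g. 3606 completed the 12-month follow-up but 3292 answered
  the 7-day item).
* Zero denominators raise classed errors (`undefined-rate`), never a
  silent 0; missing table cells are returned with an explicit
  `missing_cell` flag, never zero-filled.
* The logistic fitter is IRLS via `stats::glm` (deviance tolerance
  1e-8, max 100 iterations) with explicit rank-deficiency and
  separation (|coefficient| > 15 on the logit scale) errors. Wald — not
  profile — intervals are reported, and significance is flagged at
  α = .01, the threshold appropriate to a sample of this size.
* The 2×2 odds ratio applies the Haldane–Anscombe 0.5 correction only
  when a cell is zero, and flags it.
* Seeded runs restore the caller's RNG state (`withr::with_seed`);
  identical config + seed reproduces a cohort byte-for-byte through CSV
  export. Replicate seeds in experiments are drawn from a master seed.
* Problem sizes in the test suite: property tests use 1000 random count
  tables, 200 small MNAR cohorts (200 participants each) for worst-case
  coverage, 200 replicates for the missing-at-random bias check, and 50
  full-size cohorts for response-rate calibration — sizes at which
  Monte-Carlo error is well below every asserted tolerance while the
  suite stays quick.

## Economics

`per_protocol_cost_per_quitter(unit_daily_cost, duration_days,
quit_rate)` gives the expected cost per successful quitter of a
consumable treatment; the benchmark — a nicotine patch at US $3.91/day
for 10 weeks (70 days) at a 20% quit rate — comes to $1368.50, quoted
as "about $1370" under nearest-$10 rounding (`round_cost()`). Weekly
quitter throughput uses 52/12 weeks per month. No discounting or QALY
modelling is attempted.

## Known limitations

* Reference anchors are user-supplied published rates; their sampling
  error is not propagated into the anchored interval.
* The covariate-adjusted repeated-measures estimates of the original
  analyses are not reproduction targets: the individual-level data
  behind them is unavailable, and the exact repeated-measures machinery
  is unspecified. The package provides per-wave logistic fits and a
  crude odds ratio instead.
* Coverage of the reference-anchored interval is a simulation result
  under the stated mechanism, not a mathematical guarantee; with small
  reference cohorts the anchors are noisy and coverage can drop
  slightly below 100%.
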