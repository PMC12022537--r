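---
title: "Quantifying learning effects and measurement error in repeated neurocognitive testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying learning effects and measurement error in repeated neurocognitive testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitest)
```

## The measurement model

`habitest` treats a repeated neurocognitive testing protocol — the same
test administered twice per day over several consecutive days — as a
measurement instrument whose error has two distinct components:

* **Systematic error**: a directional shift between occasions. With no
  intervention between sessions, a systematic improvement is a learning
  (habituation) effect, and it invalidates the usual reading of
  reliability coefficients: the protocol is partly measuring how fast the
  participant learns the test.
* **Random error**: non-directional scatter between repeated measurements,
  arising from lapses of attention, hardware timing, ambient conditions
  and other unmodeled sources.

For each test–retest pair (trial 1 vs trial 2 within a day, or the day
means of two days, always with the chronologically earlier measurement as
reference `x`), the pipeline computes:

* the two-way subjects × occasions ANOVA mean squares (`ms_decomposition()`),
  from which the absolute-agreement single-measure intraclass correlation
  is formed,
  $$\mathrm{ICC}(A,1) = \frac{MSR - MSE}{MSR + (k-1)MSE + \tfrac{k}{n}(MSC - MSE)},$$
  with an F-based confidence interval after McGraw & Wong. The
  absolute-agreement form is the right one here because a systematic shift
  between occasions *should* cost reliability; the consistency form would
  hide exactly the learning effect under study.
* $\mathrm{SEM} = SD\sqrt{1-\mathrm{ICC}}$ and
  $\mathrm{MDC} = \mathrm{SEM}\times 1.96 \times \sqrt 2$, the smallest
  individual change exceeding measurement error with 95% confidence;
* a paired t-test on $d_i = x_i - y_i$ for the systematic bias, corrected
  for multiplicity across the whole table;
* MAE and MAPE ($x$ as reference) and the Bland–Altman bias, limits of
  agreement $\bar d \pm 1.96\,SD_d$, and their confidence intervals.

### Why the SEM uses the SD of paired differences

The SEM's "SD" is ambiguous in much of the applied literature. We default
to the standard deviation of the paired differences because published SEM
values for these tasks are numerically consistent only with that reading:
a Stroop pair with score SDs around 8–9 s, ICC 0.97 and a printed SEM of
0.49 s implies $SD \approx 2.8$ s — the difference SD, not the score SD.
A pooled-scores basis remains available (`sem_basis = "pooled"`), and all
internal arithmetic is unrounded; two-decimal rounding is applied only in
the display layer. When checking published tables against
$\mathrm{MDC} = \mathrm{SEM} \times 1.96 \times \sqrt2$, note that rows
rounded upstream can be off by ±0.01, and occasional rows are grossly
inconsistent with their own SEM (a known hazard of transcribed tables);
the package never emulates such inconsistencies.

### The two ICC variants

Reports of this design sometimes print the reduced expression
$(MSR - MSE)/(MSR + (MSC - MSE)/n)$, which drops the $(k-1)MSE$ term of
the standard ICC(A,1). Statistical packages (JASP, SPSS, `pingouin`)
compute the standard form, so that is our default
(`icc_variant = "standard"`); the literal reduced expression is available
as `icc_variant = "paper"` for comparability, without an analytic
confidence interval. Both coincide when $MSC = MSE = 0$.

## Deciding when a protocol is habituated

Testing is considered habituated when (a) the consecutive-day systematic
bias is statistically nonsignificant and (b) the random error has stopped
changing. `detect_stabilization()` operationalizes this per test:

* `bias_ok` for the comparison (d, d+1): Holm-adjusted p ≥ α (default
  0.05; adjustment within the curve's consecutive comparisons);
* `random_error_ok`: |MAPE(d, d+1) − MAPE(d−1, d)| ≤ 5 percentage points
  by default (`mape_tolerance`). "Random error stabilizes" has no agreed
  quantitative definition; an absolute consecutive-change tolerance on
  MAPE is simple, unit-free and matches the plateau one sees in practice
  (e.g. Stroop MAPE falling from > 11% to < 5% over four sessions). The
  first comparison is vacuously stable.
* The stabilization day is the earliest day **from which every remaining
  comparison satisfies both criteria**. Requiring all later comparisons —
  not just the first passing one — guards against the non-monotone MAPE
  sequences that ruler-drop-type tasks produce.

Two caveats are built into the output. First, nonsignificance is not
evidence of irrelevance: the decision trace always reports the bias point
estimate next to the comparison's MDC, so residual learning below the
detection limit stays visible. Second, tests whose random error never
settles (the ruler drop, with MAPEs of 40–110%, is the canonical example)
correctly propagate "undetermined" into the overall recommendation rather
than being forced to a number. An optional strict mode is deliberately
absent: whether *intraday* bias should also gate stabilization is
ambiguous (trail-making-type tasks can stay intraday-significant across
all sessions while their interday bias vanishes), so intraday results are
reported in their own table but do not enter the decision.

## Group comparisons

Age groups differ both in baseline and in learning rate, so
`rm_anova()` fits the mixed group × time design on per-subject day means
(day-level aggregation mirrors how interday reliability is computed).
Sums of squares come from the classical stratified decomposition;
partial η² is $SS_{\mathrm{eff}}/(SS_{\mathrm{eff}}+SS_{\mathrm{err}})$
within each effect's stratum, banded at 0.06/0.14. With more than two
within-subject levels the sphericity assumption is unlikely to hold, so
Greenhouse–Geisser-corrected p-values (ε from the pooled within-group
covariance matrix, capped at 1) are reported alongside the uncorrected
ones — the correction is always computed rather than gated on a
pretest, since Mauchly's test is underpowered exactly where the
correction matters. Scheffé post hoc contrasts control the family-wise
error over all possible contrasts; Cohen's d uses the pooled SD of the
two groups being compared (banded at 0.2/0.5/0.8).
`change_scores()` additionally provides the simpler first-to-last-day
one-way ANOVA on per-subject improvement, since both framings appear in
applied work and they answer slightly different questions.

## The synthetic cohort generator

Raw data from habituation studies are rarely deposited, so the package
carries its own generator (`simulate_cohort()`), which doubles as the
ground truth for every statistical property in the test suite. The score
of subject $s$ (group $g$) on day $d$, trial $t$ is

$$y_{sdt} = \mu_g + b_s + \mathrm{sign}\cdot c_g\left[A\,e^{-\lambda_g (d-1)}
          + a\,e^{-\lambda_g (d-1)}\,\mathbb 1\{t=1\}\right] + \varepsilon_{sdt},$$

with $b_s \sim N(0, \sigma_s^2)$ between-subject ability,
$\varepsilon \sim N(0, \sigma_e(d)^2)$ residual error on a per-day
schedule, and the sign chosen so that the learning term worsens early
scores in the test's own direction (slower times, fewer hits). The
separate trial-1 amplitude $a$ lets within-day improvement persist
independently of the day-level decay — needed because some tasks remain
intraday-significant even after their interday bias has vanished.
Censoring is applied last (a ruler-drop score beyond the 50 cm ruler is
recorded as 51 cm). `sim_truth()` returns the analytically implied
quantities: the trial-level intraclass correlation
$\sigma_s^2/(\sigma_s^2+\sigma_e(d)^2)$ per day, and the consecutive
day-mean bias $(A + a/k)\,c_g(e^{-\lambda_g(d-1)} - e^{-\lambda_g d})$.

Exponential decay was chosen for the learning curve because observed
curves for these tasks are convex and approach an asymptote; the model is
not fitted to any dataset. Heteroscedasticity is per-day only —
per-subject error scaling, non-Gaussian tails, and correlation of ability
across tests are *not* modeled, so passing tests demonstrate the
pipeline's statistical correctness under a well-specified model, not
robustness to every feature of real data.

### The preset

`cohort_preset()` encodes the study design the package is built around:
three age groups of 22 children, 20 young adults and 23 older adults
(n = 65), five tests (ruler drop in cm, censored at 51; trail making and
Stroop in s; choice-reaction hits; choice reaction time in ms), five days
× two trials. Group baselines put children lowest-performing with large
gaps to adults; children carry a 1.4× learning amplitude (young adults
0.8×, older adults 1.0×). Amplitudes and the decay rate
($\lambda = 1.2$ per day for the cleanly-decaying tests, 0.8 for the
noisy ruler drop) were set once so that the true consecutive-day bias
falls below what a cohort of this size can detect by about the fourth
session, with per-day error SDs shrinking across days — the qualitative
pattern reported for these tasks (significant early learning that
subsides between the third and fifth session, random error decreasing
with familiarity). The preset is illustrative scaffolding for tests and
demos, not a fit to any empirical dataset.

## Numerical choices and edge cases

* Zero-variance differences: identical paired scores give the degenerate
  p = 1 convention with a flag; a constant *nonzero* shift is an error
  (no t-test exists), never a silent NaN.
* A zero ICC denominator (all scores identical) raises an error rather
  than returning NaN.
* Negative ICC estimates are reported as-is with a warning; the SEM in
  the reliability table clamps them to 0, and `sem_from()` itself rejects
  them so a caller must decide.
* MAPE with a zero reference value errors with the offending subject
  named.
* Complete-case pairing is applied per comparison, not listwise: a
  subject missing day 2 drops out of the 1_2 and 2_3 comparisons only.
* Day and trial indices are 1-based throughout, matching how such tables
  are labeled ("1_2", "4_5", "1_5").
* All randomness in `simulate_cohort()` flows from a single seed, and the
  caller's RNG state is restored afterwards.

## Problem sizes in the test suite

The suite generates all of its data at run time. Calibration checks use
the cohort sizes the methods are meant for: single replicates at n = 500
for variance-component recovery (±0.03), 200 replicates at n = 65 for
the mean ICC (±0.01), 10,000 replicates of the paired t-test under the
no-learning null (rejection rate 0.05 ± 0.01), 400 full habituation
pipelines under the null (family-wise false-stabilization bound), and 50
preset cohorts for stabilization-day recovery (median within day 3–5).

## Known limitations

* Only two occasions per comparison are supported (the pairwise design);
  consistency-type and average-measures ICCs are out of scope.
* The Bland–Altman analysis assumes constant bias and limits; no
  regression-based proportional-bias extension.
* The learning curve is never extrapolated beyond the observed days.
* With data from a single real study, confidence intervals of ICCs across
  age groups will usually overlap; group differences in learning are
  better assessed through the interaction term and change scores than
  through per-group ICC comparison.
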