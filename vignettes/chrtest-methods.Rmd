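---
title: "Critical speed and critical heart rate from timed walking efforts: models, reliability battery, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Critical speed and critical heart rate: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chrtest)
```

## The model

The critical-power framework describes maximal constant-effort exercise with
a two-parameter linear relationship. For walking over fixed distances it is
written in its distance–time form,

$$d = \mathrm{CS}\cdot t + D',$$

where the slope CS (m·s⁻¹) is the **critical speed** — the boundary between
the heavy and severe exercise-intensity domains, sustainable continuously
for roughly 30–60 min — and the intercept $D'$ (m) is a finite distance
reserve usable above CS. Fitting the line to three maximal efforts over
400, 800 and 1200 m, timed by stopwatch, gives both parameters.

The same protocol yields an internal-load analogue. The **total heartbeats**
of an effort, $\mathrm{HB} = \overline{\mathrm{HR}} \cdot t/60$ (mean of the
recorded 5-s HR averages times the duration in minutes), is regressed on the
duration in minutes:

$$\mathrm{HB} = \mathrm{CHR}\cdot t_{\min} + \mathrm{HB}',$$

whose slope CHR (beats·min⁻¹) is the **critical heart rate** — the heart
rate sustainable at the critical intensity — and whose intercept
$\mathrm{HB}'$ is the heartbeat analogue of $D'$. CHR is directly usable for
prescription with nothing but a chest-strap monitor, which is the point of
the protocol for populations, such as people with Parkinson's disease, for
whom laboratory gas-exchange testing is impractical.

Both fits are ordinary least squares with an intercept and time as the
independent variable, matching how the protocol's slopes are conventionally
read. No weighting is applied. Two efforts are mathematically sufficient and
accepted with a warning; three distinct distances are the protocol. The
alternative parameterization $\,d/t = D'(1/t) + \mathrm{CS}\,$ is provided
(`fit_inverse_time_form()`) purely as a sensitivity check: the two forms
agree exactly on collinear data and weight noise differently otherwise; the
package reports both and never reconciles them.

## Per-effort metrics and the duration window

`summarize_effort()` derives mean/maximal HR, HB, mean speed and a duration
flag. Mean HR is the unweighted arithmetic mean of the recorded window
averages — the natural reading of "average 5-s HR" — and every sample from
effort start is included; no pre-steady-state samples are trimmed. Sample
timestamps mark the *end* of their averaging window, so a constant-HR
series integrates to the same HB at any uniform sampling interval.

The duration-validity window is **3–12 min** per effort. Below ~3 min the
$D'$ term dominates and the point pulls the line away from the aerobic
asymptote; well beyond ~12 min pacing drops below a truly maximal effort.
Older recommendations (8–20 min, or 12–15 min maxima) exist in the
critical-power literature; the package flags against the 3–12 min window
(both bounds configurable) and treats violations as warnings, not errors —
slow walkers routinely need ~16 min for 1200 m, and the fit is still
produced, flagged, exactly because that overrun plausibly blunts the
sensitivity of CS to training at the longest distance.

## The reliability battery

For each metric measured in two sessions one week apart (times and HBs at
each distance, CS, CHR), `reliability_report()` computes:

* **Paired comparison** — two-sided Student's t for dependent samples, with
  Cohen's *d*. The default *d* divides the mean difference by the SD pooled
  over the two sessions; a $d_z$ variant (SD of difference scores) is
  selectable.
* **Effect-size bands** — read *literally* as upper bounds on $|d|$:
  small (≤ 0.20), moderate (≤ 0.50), large (≤ 0.80), very large (> 0.80).
  This inverts the common "large means ≥ 0.8" phrasing; the banding is
  deliberate, documented, and implemented in one place (`effect_band()`).
* **Typical error** — $\mathrm{TE} = \mathrm{SD}(\Delta)/\sqrt{2}$ with the
  $n-1$ SD; under independent session noise of SD $\sigma$, TE estimates
  $\sigma$.
* **CV%** — by default $100\cdot\mathrm{TE}/\text{grand mean}$; the
  log-transform method $100(\exp(\mathrm{SD}(\Delta\log)/\sqrt2)-1)$ is
  available via `cv_method = "log"` for strictly positive data.
* **ICC** — from the two-way participant × session mean squares. Both
  single-measurement forms are always computed: ICC(2,1) (two-way random,
  absolute agreement; penalises a systematic session shift) and ICC(3,1)
  (two-way mixed, consistency). ICC(2,1) is the default entering SEM
  because a test–retest protocol cares about agreement, but reporting both
  avoids silent misinterpretation since the form is rarely stated in
  applied papers. With zero between-participant variance the ICC is
  undefined and returned as flagged `NaN`. Note that ICC(3,1) ≥ ICC(2,1)
  is guaranteed only when the session mean square is at least the error
  mean square; with two sessions the sample session effect can dip below
  the error term by chance and reverse the inequality slightly.
* **SEM and MDC** — $\mathrm{SEM} = \mathrm{SD}\sqrt{1-\mathrm{ICC}}$ and
  $\mathrm{MDC} = \mathrm{SEM}\cdot 1.96\sqrt2 \approx 2.772\,\mathrm{SEM}$.
  The SD entering SEM is, by default, pooled over both sessions
  (`sd_method = "baseline"` switches to session-1 only; the literature is
  split and rarely explicit). The two identities hold to 1e-9 on every
  report by construction and are asserted in the test suite.

No multiple-testing correction is applied across the per-distance tests,
matching standard practice for this battery; the package applies the tests
metric by metric.

## Training-effect analysis

`experiment2_training()` mirrors the pre/post design: an adherence filter
(retain participants attending ≥ 90% of the 16 sessions of an 8-week,
twice-weekly program), then paired t-tests with effect sizes for the effort
times, HBs, CS, CHR and optionally the six-minute walk test. The sign
convention is change = post − pre: effort-time improvements are negative,
6MWT gains positive. When all change scores are identical the paired t is
degenerate; the report then carries the limiting p (1 for zero change, 0
otherwise) and an explicit `degenerate` flag instead of an error.

## The synthetic cohort generator

No raw per-effort recordings are publicly available for this protocol, so
validation runs on simulated cohorts with known ground truth
(`simulate_cohort()`). Design:

* **Pacing.** Each participant owns a true (CS, $D'$) pair; a maximal
  effort over distance $d$ takes $t = (d-D')/\mathrm{CS}$ times a mean-one
  multiplicative lognormal factor with configurable CV. Because generator
  and fitted model share the same truth line, recovery is exact as noise
  vanishes — by design, so parameter-recovery tests have a sharp target.
* **Heart rate.** Each participant also owns a true (CHR, $\mathrm{HB}'$)
  pair. The HB of an effort is the truth-line value at the realized time,
  times an *independent* mean-one lognormal factor (`hb_noise_cv`). The
  independence matters: HB derived solely from the noisy time would sit
  exactly on the heartbeats–time line, and CHR reliability would be
  artificially perfect. The emitted HR trace has the mono-exponential
  on-kinetics-plus-drift shape
  $\mathrm{HR}(t) = \mathrm{rest} + A(1-e^{-t/\tau}) + \beta t/60$
  (τ drawn in 25–60 s, drift 0.5–2 beats·min⁻¹ per min, capped at a
  ceiling), uniformly rescaled so its window averages integrate exactly to
  the HB target: the kinetic profile sets the *shape*, the truth line sets
  the *area*. This keeps the trace visually physiological while making the
  pipeline exactly self-consistent (`total_heartbeats()` of a simulated
  trial equals its HB target to machine precision).
* **Defaults as study conditions.** 15 participants; distances 400/800/1200
  m sampled at 5-s intervals; mean CS 1.2 m·s⁻¹ with 15% between-participant
  CV (so 400 m takes ≈ 5 min and 1200 m ≈ 16 min — the long effort
  deliberately overruns the 12-min recommendation, as observed in slow
  clinical walkers); $D'$ 30 ± 10 m; CHR centred at 69.5% of the
  age-predicted maximal HR (208 − 0.7·age at the cohort mean age of 72);
  $\mathrm{HB}'$ 20 ± 8 beats; timing and HB noise CV 2%, re-sampled at
  retest. The training design applies −8%/−4%/−2% time reductions at
  400/800/1200 m with HB reduced proportionally to time at unchanged mean
  HR — a pattern that leaves CS and CHR nearly unchanged (the −8/−4/−2
  gradient tilts the fitted slope by under 1%) while clearly shortening the
  shorter efforts, which is exactly the sensitivity signature the analysis
  should detect.
* **Reproducibility.** One master seed per run; per-participant substreams
  are drawn from it, so a fixed configuration reproduces the dataset
  exactly.

What the generator does **not** emulate: within-effort pacing dynamics and
fatigue, freezing-of-gait episodes, medication-state fluctuation,
beat-to-beat HR variability, device dropout, or any dose–response model of
training (the planted reductions are imposed, not emergent). Passing
recovery and reliability tests on this generator therefore demonstrates the
*statistical machinery* is correct under the stated noise model — not that
the protocol behaves identically in real patients.

## Numerical choices and degenerate inputs

OLS is delegated to `stats::lm` and verified in the tests against the
closed-form normal equations to 1e-9 on randomized instances; collinear
triples are recovered to machine precision. Identical effort times raise a
singular-design error rather than returning an unstable slope.
`predict_time()` refuses distances at or below $D'$. Rounding for display
against the published cohort table is half-up at the printed precision
(base R's `round()` is half-even and mismatches typeset tables); full
precision is retained internally. Physiologically implausible HR samples
(outside 20–250) are flagged, never dropped; recording gaps are logged,
never imputed, since imputation would silently change HB.

The packaged 15-row cohort table reproduces 32 of the 40 published group
Average/SD cells at printed precision; the remaining 8 are arithmetically
inconsistent with the individual rows they summarise (several look
truncated rather than rounded, two subset means are not the column
statistics of the flagged rows). These cells are annotated
(`table1_printed()$matches_rows`) and excluded from strict golden checks
rather than silently corrected.

## Problem sizes

The validation battery runs at: 1000 random instances for the OLS oracle
check; 200 replicates of the 15-participant test–retest design for the
reliability-under-noise study; 200 replicates each of the planted-effect
and null 8-participant training designs; 4000 draws for the empirical
timing-noise check. These sizes give Monte-Carlo error comfortably below
the decision margins involved (e.g. binomial SE ≈ 1.5% for a 5% rejection
rate at 200 replicates) while keeping a full run in the low minutes on a
single core.

## Known limitations

* CHR reliability is intrinsically weaker than CS reliability: CHR's
  between-participant spread is small relative to its measurement noise,
  so its ICC is moderate even when TE and CV% are low — a discrimination
  limit, not a computation artifact.
* The duration-window recommendation and the fixed distance set are taken
  as given; the package does not optimise distances for a target duration
  range.
* The age-predicted HRmax formulas (220 − age, 208 − 0.7·age,
  207 − 0.7·age) disagree by several beats·min⁻¹ in the relevant age
  range; `relative_intensity()` exposes the choice rather than defending
  one.
* All validation is synthetic; no deposited clinical recordings exist to
  test against.
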