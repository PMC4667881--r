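---
title: "Circadian telemetry descriptors and Poincaré asymmetry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian telemetry descriptors and Poincaré asymmetry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actitherm)
```

# The measurement problem

Implanted telemetry transponders record a rodent's abdominal temperature
(°C) and gross locomotor activity (arbitrary counts) once per minute in
the home cage, for days to weeks, under a 12:12 light cycle. Two families
of questions are asked of such records:

1. **Circadian structure.** How is motor activity organized into bouts,
   and how do activity and body temperature differ between the light
   (rest) and dark (active) phases? Fragmentation of the rest–activity
   rhythm — more, shorter bouts — is a behavioural marker in several
   disease models.
2. **Regulation dynamics.** Minute-to-minute temperature variability
   carries information about thermoregulatory control. The Poincaré plot
   (the lag-1 return map) separates short-term from long-term
   variability, and the *asymmetry* of that plot — whether falls and
   rises contribute unequally to the variance — indexes the
   non-equilibrium character of a healthy control loop. Loss of asymmetry
   is treated as a dysregulation marker.

`actitherm` implements both, plus the surrounding pipeline: phase
splitting, pooling of animal-days by disturbance condition, group-level
asymmetry inference, event-response profiling, and a calibrated cohort
simulator that provides ground truth for every estimator.

# Units of analysis

The unit of all descriptor computation is the **phase recording**: one
animal's samples for one 12-h light or dark phase of one calendar day —
720 samples when complete. Windows are half-open `[lights_on,
lights_off)`, so a sample stamped exactly at a transition belongs to the
phase that starts there and a complete day partitions into exactly
720 + 720 samples. A dark phase is attributed to the calendar day on
which it starts; the attribution is a convention (any choice works, this
one keeps one dark recording per calendar day).

Because within-animal day-to-day variability is high, recordings of
different days under the same condition are pooled as replicates. A
calendar day is *disturbed* when any handling, bed-change or injection
event falls on it, and both phase recordings of that day inherit the
label — including the dark phase that extends past midnight. Whether the
dark phase *preceding* a morning intervention should count as disturbed
is genuinely ambiguous; we adopt the whole-day rule because conditions
are assigned day-wise in the emulated design, and expose the policy as
the `policy` argument of `label_conditions()` so a stricter rule can be
added without touching callers.

Missing samples are permitted everywhere. Descriptors are computed over
non-missing samples only; a recording with more than 5 % missing in
either signal (configurable `max_missing_frac`) is excluded from pooling,
on the reasoning that bout segmentation and lag-1 statistics degrade
qualitatively once gaps are frequent.

# Activity descriptors

For one phase recording with counts $a_t$:

* **AL** (activity level): mean of the per-hour count sums, over the 12
  non-overlapping hourly epochs aligned to the phase start. Hours with a
  missing minute are excluded rather than rescaled.
* **MI** (movement index): percentage of valid minutes with $a_t > 0$.
* **RMI** (relative movement index): mean count over active minutes —
  intensity within bouts, `NA` (never 0) when no minute is active.
* **PN / DI / DA**: number of maximal runs of constant state
  (active/inactive), and the mean durations of inactive and active runs
  in minutes. Missing minutes break runs, because a run is by definition
  uninterrupted; an opt-in flag bridges isolated single gaps.

The activity threshold is strictly `> 0` by definition of MI; it is
exposed (`threshold`) for sensitivity analysis only. No minimum bout
duration is imposed by default (`min_bout = 1`); the option exists
because actigraphy pipelines sometimes smooth 1-min blips, but the
descriptor definitions here do not.

Two identities tie the descriptors together and are enforced in the test
suite: run lengths sum to the number of valid minutes, and
$DI \cdot n_{inactive} + DA \cdot n_{active}$ equals the valid minutes.

# Temperature descriptors

Mean BT is computed as the mean of hourly means — with complete data this
equals the grand mean, and it mirrors how per-epoch telemetry summaries
are conventionally reported. Extrema and amplitude (`bt_max - bt_min`)
are taken over valid samples. The mean consecutive *increase* and
*decrease* are averaged separately over the positive and negative lag-1
differences; zero differences belong to neither, and differences are
never computed across a missing-value gap (the 1-min lag is part of the
definition).

# Poincaré analysis

For the temperature series of one recording, the return map plots
$(BT_n, BT_{n+1})$; with 720 samples there are at most 719 points. With
$\Delta_n = BT_{n+1} - BT_n$ and $n_p$ valid pairs:

$$SD1^2 = \frac{\sum_n \Delta_n^2}{2\,(n_p - 1)}, \qquad
  SD2^2 = \frac{\sum_n D_n^2}{n_p - 1}, \qquad
  SDNN^2 = \frac{SD1^2 + SD2^2}{2},$$

where $D_n = (BT_n + BT_{n+1} - 2m)/\sqrt{2}$ and $m$ is the mean over
all coordinates entering the pairs. $SD1$ is the dispersion perpendicular
to the identity line, referenced to *the line itself*; $SD2$ is the
dispersion along the line about the centroid. SDNN matches the series'
overall standard deviation and is dominated by SD2 whenever the plot is
a "slim cigar" ($SD1 \ll SD2$), which is the empirical regime for 1-min
body temperature.

The asymmetry partition splits both variances by the sign of $\Delta_n$:
points above the identity line are increases, below it decreases.

$$SD1d^2 = \frac{\sum_{\Delta_n<0} \Delta_n^2}{2(n_p-1)}, \quad
  SD2d^2 = \frac{\sum_{\Delta_n<0} D_n^2 + \tfrac12\sum_{\Delta_n=0} D_n^2}{n_p-1},$$

with $SD1i^2, SD2i^2$ defined symmetrically and the relative
contributions $C1d = SD1d^2/SD1^2$ etc. A recording is *short-term
asymmetric* when $SD1d > SD1i$ strictly and *long-term asymmetric* when
$SD2i > SD2d$ strictly; exact ties classify as symmetric.

## Numerical conventions, and why

Three choices deserve justification because the quantities are often
written loosely:

* **Reference points.** $SD1$ uses the raw second moment about the
  identity line, while $SD2$ centres at the grand mean $m$. This is the
  convention of the heart-rate-asymmetry literature from which the
  partition originates, and it is the only pair of choices under which
  the decompositions $SD1d^2 + SD1i^2 = SD1^2$ and
  $SD2d^2 + SD2i^2 = SD2^2$ hold *exactly* (to machine precision, as the
  tests assert) rather than up to a mean-drift term. The price is that
  $SD1^2 + SD2^2$ equals $\mathrm{Var}(BT_n) + \mathrm{Var}(BT_{n+1})$
  only up to $n_p \overline{\Delta}^2 / (2(n_p-1))$ — the exact corrected
  identity is what the suite checks. For a stationary 720-sample series
  the drift term is negligible ($\overline{\Delta}$ is the net
  temperature change divided by $n_p$).
* **On-line points.** Pairs with $\Delta_n = 0$ contribute nothing to the
  short-term components (their perpendicular distance is zero) and are
  split equally between $SD2d^2$ and $SD2i^2$, preserving the exact
  decomposition without biasing either side.
* **Denominators.** Sample $(n_p - 1)$ denominators throughout;
  temperature series are short enough (719 pairs) that the distinction
  is visible in the third decimal.

The lag is fixed at 1 sample (1 min) by default — the slimness of the
observed plots indicates 1 min is already an appropriately short lag —
and exposed as `lag` for sensitivity analysis. Pairs whose span contains
a missing sample are dropped.

# Group-level inference

Across a pooled set of recordings, asymmetry is tested two ways, and
both must reject for the summary's `significant` flag (the per-test
p-values are always reported separately, since the two tests answer
different questions):

* **Counts**: the number of asymmetric recordings against chance
  (p = 0.5) with the exact two-sided binomial test, using the
  minimum-likelihood two-sided rule (`stats::binom.test`).
* **Magnitudes**: the relative contributions ($C1d$ for the short term,
  $C2i$ for the long term) against 0.5 with the Wilcoxon signed-rank
  test. Because a recording's two contributions sum to 1, the paired
  decrease-vs-increase comparison reduces exactly to this one-sample
  test. The exact null distribution is used for up to 25 non-zero
  differences, the normal approximation with continuity correction
  above; all differences zero returns p = 1.

Between-group comparisons of descriptor *means* (activity level, mean
BT, SD1, …) are routine statistics: the pipeline emits the tidy
per-recording table and leaves ANOVA/post-hoc machinery to standard
tools rather than wrapping it.

# Event-response profiling

For each event, the baseline is the signal mean over the 60 min before
the event minute; the response is the sequence of 10-min epoch means
after it, expressed as deltas from baseline. The event minute itself
opens the first epoch (the convention is arbitrary; it is documented and
applied uniformly). Light transitions are profiled over 1 h, the three
intervention kinds over 2 h, reflecting the slower decay of
handling-induced hyperthermia. Profiles whose windows exceed the series,
or whose baseline window is more than half missing, are flagged
incomplete and excluded from pooling. The three intervention kinds
produce similar transients and pool under a single `"intervention"`
label; epoch-wise mean ± SEM across profiles is the pooled summary.

# The synthetic cohort

No public telemetry archive accompanies the emulated design, so the
package ships a generator whose *structure* — not merely its marginals —
matches minute-resolution rodent telemetry, and whose parameters have
closed-form consequences that the estimators must recover.

**Design.** Two groups of 6 animals, 13 days starting at lights-on
(06:00), interventions on the last 5 days (handling ×2, bed change ×2,
one morning injection), giving 8 undisturbed and 5 disturbed days — 48
and 30 recordings per group and phase after pooling.

**Activity** is a two-state Markov chain over minutes with
phase-dependent transition probabilities $q_{ai}$ (active→inactive) and
$q_{ia}$ (inactive→active). Bout lengths are geometric with means
$1/q_{ai}$ and $1/q_{ia}$, the stationary active fraction is
$q_{ia}/(q_{ia}+q_{ai})$, and hence MI, DI and DA have closed forms that
the recovery tests check at $10^5$ minutes. Active minutes emit
$1 + \mathrm{NB}(\text{size}=2, \mu = \text{activity\_mean}-1)$ counts —
right-skewed positive integers, as count telemetry is.

**Temperature** is a phase baseline plus activity coupling plus an AR(1)
deviation: $BT_t = b(\text{phase}_t) + g\,\mathrm{MA}_{30}(a)_t + X_t$,
$X_t = \varphi X_{t-1} + \varepsilon_t$. The 30-min trailing moving
average models the physiological lag between movement and heat; the
innovations $\varepsilon_t$ are a zero-mean two-sided half-normal
mixture (positive scale $\sigma_u$ with probability $p$, negative scale
$\sigma_d$ otherwise) — the knob that injects Poincaré asymmetry. Under
the zero-mean constraint the mixture is fully determined by a target
C1d: `calibrate_mixture()` solves $p = C1d$, $\sigma_d/\sigma_u =
C1d/(1-C1d)$. An **iid-increment mode** draws $\Delta BT_t$ from the
mixture directly, making the asymptotic C1d exactly `mixture_c1d()` —
the sharpest available ground truth, used by the recovery tests
(720-sample recordings recover a 0.577 target within ±0.02 on average
over 50 replicates). Output is clipped to the physiological 30–42 °C
range; clips are counted and are absent under default parameters.

**Calibration of the defaults.** The defaults are a calibration to the
emulated study's reported magnitudes and directions, chosen once and
documented here rather than fitted:

* $\varphi = 0.984$ for both groups. For an AR(1), the population ratio
  is $SD2/SD1 = \sqrt{(1+\varphi)/(1-\varphi)}$, but a 720-sample window
  under-represents the slowest variance components, so the *realized*
  per-recording ratio sits below the population value. $\varphi$ was set
  so that the realized geometric mean over dark-phase control recordings
  is ≈ 10, the reported order of magnitude of the "slim cigar".
* Mixture C1d targets per group and phase: control 0.577 (light) /
  0.525 (dark); substrain 0.525 / 0.512 — the reported contribution
  levels, with the substrain nearer symmetry. In AR mode the realized
  C1d is slightly diluted toward 0.5 relative to the mixture target
  (the $(1-\varphi)X_{t-1}$ term adds a small symmetric component to
  $\Delta$), which the qualitative tests tolerate by testing directions,
  not levels.
* Innovation scales: control 0.035 °C (light) / 0.050 (dark); substrain
  0.050 / 0.070 — dark-phase variability higher in both groups, both
  variabilities higher in the substrain.
* Bout parameters: control light $q_{ai}=0.40, q_{ia}=0.10$, dark
  $0.20/0.25$; substrain light $0.50/0.08$, dark $0.40/0.45$. These give
  the substrain fewer active minutes, more and shorter bouts in the dark
  (fragmentation), and preserve the dark > light active fraction in both
  groups (a config invariant).
* Baselines: control 36.8/37.5 °C, substrain 36.8/37.9 °C (dark
  hyperthermia); activity means 5/8 vs 3.5/5 counts (reduced intensity);
  intervention responses 0.8 °C and 12 counts/min with no latency
  (control) vs 0.5 °C and 5 counts/min with a 10-min latency (substrain
  — blunted, delayed).

**Randomness.** One master seed; per-animal sub-seeds are drawn with
`sample.int()` under the master seed, so any animal's record is
reproducible independently of cohort size. The config hash in the run
metadata deliberately excludes the seed: it identifies the design, not
the realization.

## What the generator does and does not emulate

It reproduces: 1-min sampling, the 12:12 cycle with dark-phase maxima in
both signals, bout-structured activity with phase-dependent run lengths,
activity-coupled autocorrelated temperature in the 35–39 °C band,
rise/fall asymmetry of controlled magnitude, and transient intervention
responses. It does not emulate: ultradian rhythms beyond the bout
process, gradual drifts across days (each day is statistically
identical), sensor artifacts other than missingness, the
light-transition anticipation real animals show, or any correlation
between an animal's activity phenotype and its temperature phenotype
beyond the explicit coupling term. Long-term (SD2-side) asymmetry is an
emergent property of the AR/mixture interaction rather than a directly
controlled target. Passing the recovery suite therefore demonstrates
estimator correctness under a faithful *structural* model — it does not
certify behaviour under artifact regimes the generator never produces.

# Problem sizes in the validation suite

The suite exercises the full default design (12 animals × 13 days at
minute resolution, ≈ 225k samples per group) for the bookkeeping and
group-contrast checks; identity checks run on 1,000 random series of
10–720 samples; recovery checks use 50 recordings of 720 samples for the
asymmetry target, 200 for the null classification rate, and $10^5$
minutes for the bout closed forms. These sizes put Monte-Carlo error
well inside each asserted tolerance while keeping a full run in tens of
seconds.

# Known limitations

* The whole-day disturbance rule discards the possibility that the dark
  phase *before* a morning intervention is effectively undisturbed;
  with only day-level condition labels this is the conservative choice.
* `bt_mean` averages hourly means with equal weight even when hours have
  unequal numbers of valid minutes; with ≤ 5 % missingness the
  difference from a weighted mean is far below reported precision.
* The exact Wilcoxon path switches to the normal approximation in the
  presence of mid-rank ties, as the underlying routine requires; for
  720-pair contribution values ties are practically impossible.
* The CLI wrapper (`inst/cli/actitherm.R`) is a convenience over
  `run_pipeline()`; programmatic use of the functions is the primary
  interface.
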