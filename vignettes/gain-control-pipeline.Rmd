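---
title: "Binocular gain control from staircase to group report: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binocular gain control from staircase to group report: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dichoptics)
```

This vignette is the package's own account of the science it implements:
the two-stage interocular gain-control model, the adaptive measurement
procedures it is fitted to, the synthetic observers used to validate the
pipeline, and the statistical battery applied at the group level. It also
records the design decisions that were genuinely open, the numerical
choices, and the known limitations.

## Units and conventions

* **Contrast** is linear RMS contrast in (0, 1]; the working scale is
  decibels, `dB = 20 log10(c)`, so physical stimuli are at or below 0 dB.
* **Interocular ratio** (balance-point axis) is `20 log10(cL / cR)` dB;
  0 dB means equal contrast in the two eyes. The fitted balance point is
  the 50% point of the left-eye-dominance psychometric function; a
  positive value means the left eye needed the *higher* contrast for
  equal contribution, i.e. right-eye sensory dominance. Only the absolute
  balance point enters group comparisons, so the sign convention is
  documentation, not substance. A raw log10 accessor
  (`ratio_to_log10()`) is provided alongside the canonical dB form so
  both conventions found in the literature are available.
* **Disparity** is in arc seconds and analysed as log2(arc seconds);
  a multiplicative staircase factor of sqrt(2) is an additive step of
  0.5 log2 units. Printed integer arc-second values round half away from
  zero.
* **Model parameters** (gains, weights) are linear multipliers with dB
  forms `20 log10`. Because gains multiply contrast, their dB values
  depend on the contrast unit: expressing contrast in percent rather
  than a fraction lowers every gain, and hence every suppression
  strength `G + W`, by exactly `20 log10(100) = 40` dB. All interocular
  differences, group comparisons, and correlations are invariant to this
  choice. This package uses the fractional convention throughout.

## The two-stage gain-control model

The monocular (stage-1) response of the target eye to target contrast
`C_T` under a contralateral mask `C_M` is

$$resp_R = \frac{(g_t C_T)^m}{S + g_t C_T + w\,g_m C_M},$$

followed by the binocular (stage-2) transducer

$$resp = \frac{resp_R^{\,p}}{Z + resp_R^{\,q}}.$$

The exponents and saturation constants are fixed (`m = 1.3`, `p = 8`,
`q = 6.6`, `S = Z = 1`); `p > q` makes stage 2 strictly increasing, and
the full transducer is strictly increasing in target contrast and
strictly decreasing in mask contrast (property-tested). The suppression
weight `w` is indexed by the *receiving* (target) eye: `wR` is the weight
of suppression the right-eye target receives from a left-eye mask. That
indexing is the only one consistent with the strength definitions
`supstrR = GL + WR` and `supstrL = GR + WL`, which combine the masking
eye's gain with the weight the target eye receives.

Thresholds assume unit-SD internal noise: the threshold is the contrast
at which `resp = 1`. Two consequences give the model its tractable
structure:

* the stage-2 equation `r^p = Z + r^q` has a unique unit-response root
  `r* = 1.202995` (defaults), computed once per constants set by
  bracketed bisection to 1e-12 and cached;
* with no mask, contrast enters only through `g c`, so `g c = x*` at
  threshold, where `x*` solves `x^m/(S + x) = r*` (`x* = 3.93722` for
  defaults). Detection thresholds are therefore exactly `x*/g`, and the
  "sideways" mask threshold (target fixed, mask varied) has the closed
  form

$$C_M = \frac{(g_t C_T)^m / r^* - S - g_t C_T}{w\, g_m}.$$

The closed form exists only when the fixed target is above its own
detection threshold; at or below it, no positive mask contrast brings the
response down to criterion and the package raises an explicit
degenerate-input error rather than returning a sign-flipped value.

### Fitting

With four observed thresholds (two detection, two mask) and four free
parameters the fit is exactly determined, and the sequential closed form
(`gc_solve_quartet()`) interpolates the data whenever it exists. The
fitting routine proper (`fit_gain_control()`) minimises the RMSE between
observed and predicted thresholds **in dB space** — thresholds span a log
range, and dB errors weight the four numbers comparably — using a
derivative-free Nelder-Mead simplex over the dB parameterisation (which
keeps the linear parameters positive by construction), started from the
closed-form solution plus up to four perturbed restarts. The restarts
short-circuit once a start reaches numerically zero RMSE. Because the
closed form could make an agreement test circular, the fitter has an
independent mode (`use_closed_form_start = FALSE`) whose every start is
perturbed; the test suite verifies optimizer/closed-form agreement to
well under 0.01 dB through that independent route. Whether the RMSE is
better computed in linear or dB units is not settled by the model itself;
dB was chosen here and is the convention all reported tolerances refer
to.

## Adaptive staircases

All staircases are transformed up-down rules, additive on their working
axis:

| task | rule | step | start | caps |
|---|---|---|---|---|
| detection | 3-down-1-up | 3 dB | -12 dB | 9 reversals / 120 trials |
| masking | 3-up-1-down (correct raises the mask) | 3 dB | -36 dB | 9 reversals / 120 trials |
| stereo | 2-down-1-up | 0.5 log2 (x sqrt 2) | 512 arc sec | 9 reversals / 30 trials |

An n-down-1-up rule equilibrates where `p(correct)^n = 1/2`, i.e. at
79.4% correct for n = 3 and 70.7% for n = 2. Decisions the rule itself
does not fix, fixed here: step sizes are equal up and down (no halving
schedule); the consecutive-correct counter resets on every level change
and every incorrect response; a reversal is counted from the first change
of step direction; trial and reversal caps apply per staircase, not per
interleaved pair. Levels are clamped to physical bounds (contrast at most
0 dB, disparity at least 1 arc sec); clamped trials still count. The
per-eye (and per-disparity-sign) staircase pairs are randomly
interleaved, each trial drawn uniformly from the non-terminated members.

The empirical convergence of the implementation is checked by simulation:
across 1000 runs against a stationary logistic observer, the mean percent
correct over the final half of trials falls within 2 percentage points of
the analytic target for both rules. For that check the trial budget is
extended to 120 trials for the 2-down-1-up rule as well, so the average
reflects the asymptotic regime rather than the initial descent from an
easy starting level.

## Psychometric fitting

Performance data are fitted with a logistic

$$p(x) = \gamma + \frac{1-\gamma-\lambda}{1 + e^{-\beta(x-\alpha)}}$$

by maximum likelihood (Nelder-Mead from data-driven starts covering both
slope signs, so masking-style falling performance needs no
special-casing). Policy choices, stated rather than inferred:

* the guess rate is fixed at chance — 0.5 for the single-interval
  orientation tasks, 0.25 for the 4AFC stereo task, 0 for the
  appearance-based balance-point task;
* the lapse rate is fixed at 0 by default, with an optional fixed small
  value (e.g. 0.02); it is never free;
* fitting axes are dB contrast (detection, masking), dB ratio (balance
  point), and log2 arc seconds (stereo) — the axes on which the
  staircases are linear;
* repetitions are pooled at the trial level before fitting; crossed and
  uncrossed stereo staircases are pooled into a single fit;
* thresholds are read off at 75% correct (single-interval) and 62.5%
  (4AFC); with zero lapse these criteria sit at the midpoint of the
  performance range, where the threshold equals the location parameter
  exactly.

Degenerate data — all correct, all incorrect, a single level, or
separation driving the slope to the bound — yield a flagged
non-convergent fit with `NA` estimates, never a silent extrapolation.
Subject summaries carry per-fit convergence flags.

## Synthetic observers and cohorts

The simulated-observer module inverts the analysis: an `observer_spec`
holds per-eye detection thresholds, per-eye received weights, a balance
point, a 4-C stereo threshold, psychometric spreads, and a lapse rate.
`make_observer()` derives the internal gains (`g = x*/threshold`) and
anchors each task's response function so that the probability correct
equals the task criterion exactly at the model-implied threshold — so a
perfect analysis of infinite data would recover the spec exactly, and
finite-data recovery error is attributable to the measurement protocol.
If a (measured) masking target happens to fall below an eye's true
threshold, the observer responds at chance — an invisible target — and
the analysis flags that condition as non-convergent instead of inventing
a threshold.

Cohort generation reproduces the group structure of the reference aging
study the validation suite emulates: 28 subjects per group; detection
thresholds -38.3 ± 3.6 dB (aging) vs -44.0 ± 3.6 (control); masking
weights -7.9 ± 3.6 vs -11.8 ± 2.3 dB; mean absolute balance point 2.8 vs
1.7 dB; log2 stereoacuity 6.3 ± 1.0 vs 5.5 ± 0.7 (4-C), with the two
clinical tests drawn from their own printed distributions (plate
administration itself is out of scope, so those values enter the group
ANOVA as given). Structural choices:

* the signed balance point is zero-mean Gaussian with
  `sigma = mean|BP| / sqrt(2/pi)`, making its absolute value half-normal
  with the published mean (only absolute statistics are published);
* the interocular (right-minus-left) spread of thresholds and weights is
  not published; it is fixed a priori at 2 dB SD, a typical magnitude
  for normal observers;
* gains and weights are *negatively correlated* within groups, with the
  correlation solved in closed form from the published masking-strength
  SDs (`rho = (sd_str^2 - sd_det^2 - sd_w^2) / (2 sd_det sd_w)`:
  -0.41 aging, -0.32 control). Independent draws would inflate the
  derived strength SD from the published 3.9/3.6 dB to 5.1/4.3 dB, so
  independence is demonstrably the wrong generative model for this
  derived quantity; the negative correlation is also what a homeostatic
  gain-weight trade-off predicts;
* psychometric spreads default to 2 dB (detection, masking), 3 dB
  (balance point), and 0.5 log2 units (stereo), chosen once so that the
  staircases converge comfortably within their trial budgets;
* an optional correlation matrix can couple the threshold difference,
  weight difference, and balance point for correlation-analysis studies;
  fields are otherwise independent.

What the generator deliberately does **not** emulate: attentional lapses
beyond a fixed rate, learning or fatigue across blocks, serial
dependencies between trials, non-logistic psychometric shapes, optical
factors, and monocular cues in clinical stereo tests. Passing recovery
tests therefore validates the pipeline's statistical machinery under the
stated generative model, not the robustness of the protocol to every
feature of real data.

## Group statistics

* **Mann-Whitney U** (two-sided) compares the groups on one value per
  subject (eye means for thresholds, weights, strengths; the absolute
  balance point; 4-C log2 stereoacuity). The reported statistic is the
  tie-corrected normal approximation with continuity correction — checked
  in the tests against exact enumeration over rank assignments at small
  n, where the corrected form tracks the exact p closely.
* **Stereo ANOVA**: a 2 (group) x 3 (test method) between-subjects ANOVA
  on log2 stereoacuity with Bonferroni-corrected pairwise comparisons
  among test methods using the pooled error term. The three test values
  per subject are treated as independent observations (error df
  `N - 6`), replicating the reference analysis; this ignores the
  within-subject correlation across tests and is anti-conservative for
  the test-method effect — a documented caveat, not an endorsement.
  A summary-statistic variant reconstructs per-cell data with exactly
  the given mean and SD; every sum of squares depends on the data only
  through those summaries, so the variant is exact.
* **Correlations**: Spearman rank correlations (midranks, t
  approximation) among the four *signed* imbalances, per group and
  combined; correlations of the *absolute* imbalances with stereoacuity,
  since a strong preference for either eye is what is expected to impair
  stereopsis. Group differences in correlation use the Fisher r-to-z
  transformation applied directly to Spearman rho with SE
  `sqrt(1/(n-3))` — the common applied procedure, without the
  rank-correlation variance adjustment.
* **Power**: two-sided Wilcoxon-Mann-Whitney power via the
  asymptotic-relative-efficiency route under normal parents (effective
  n = 0.955 n, noncentral t). On the published group statistics this
  returns 91.4% (4-C stereo) and 99.6% (masking weights) at alpha = .05,
  n = 28/group, matching the published values; for detection thresholds
  it returns 99.99% where 99.9% was printed, a discrepancy consistent
  with truncation that we report but do not chase.

## Numerical choices

Model roots: bracketed bisection to 1e-12, cached per constants object.
Gain-control simplex: relative tolerance 1e-12, max 2000 iterations,
5 starts, 3 dB restart jitter. Psychometric ML: relative tolerance 1e-10,
probabilities clamped at 1e-12 for the log-likelihood, slope bound of
50 per axis unit treated as separation. Thresholds used to set the
masking target are sanity-checked against the sampled level range; an
estimate more than 6 dB outside it falls back to the late-trial mean of
the staircase (an extrapolation guard for the simulation loop).
Reported JSON artifacts carry a schema version, the package version, and
the seed; mismatched schema versions are refused on read.

## Validation problem sizes

The test suite and the acceptance script size their simulations as
follows (chosen once, as the package's validation design): 1000 runs per
staircase rule for convergence; 100 random noiseless quartets for
optimizer/closed-form agreement; 200 noisy quartets (0.5 dB Gaussian
threshold noise) for parameter recovery; 100 simulated observers
(50 aging, 50 control) for end-to-end recovery bias; 100 replicate
two-cohort studies (n = 28 per group) in the test suite, 40 in the
acceptance script, for group-effect reproduction.

## Known limitations

* The masking-strength group difference is intrinsically marginal: the
  generative difference is about 1.9 dB against a within-group SD near
  3.9 dB, so even with perfect measurement its direction reproduces in
  only about 97% of replicate studies, and mask-threshold estimation
  noise brings the expected rate near 95%. It is the one group effect
  whose reproduction rate hovers at, rather than above, that level — a
  property of the effect size, not of the implementation.
* End-to-end weight recovery inherits mask-threshold noise roughly 1:1
  (about 2.7 dB RMSE per eye under the default protocol); weights are
  the noisiest per-subject quantities the pipeline reports.
* The between-subjects treatment of the three stereo tests in the ANOVA
  is replicated for comparability despite its repeated-measures caveat.
* The pipeline estimates thresholds on dB / log2 axes with logistic
  functions; observers whose true psychometric functions differ
  materially from that family are outside the stated guarantees.
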