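---
title: "Keystroke dynamics screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Keystroke dynamics screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keydyn)
```

## The screening problem

Depressive tendency (DT) is operationalised here as a PHQ-9 compound score
at or above a cutoff — 5 for mild-or-worse symptoms, 10 for
moderate/major depression; both presets ship with `assign_group()`.
The behavioural signal is psychomotor: slowed and more variable fine
motor sequences during natural touchscreen typing. `keydyn` converts raw
typing-session event streams into subject-level DT probabilities without
ever seeing typed content — only press/release timestamps, key positions
(or, in privacy mode, on-device-computed inter-key distances) and delete
flags.

## From events to dynamics sequences

Within a session of $N$ keys with press times $t^p_n$ and release times
$t^r_n$:

$$HT_n = t^r_n - t^p_n, \qquad FT_n = t^p_{n+1} - t^r_n,$$

$$D_n = \sqrt{\Big(\tfrac{X_{n+1}-X_n}{\text{density}_X}\,25.4\Big)^2 +
             \Big(\tfrac{Y_{n+1}-Y_n}{\text{density}_Y}\,25.4\Big)^2},
\qquad SP_n = D_n / FT_n, \qquad PFR_n = HT_n / FT_n.$$

All times are integer epoch milliseconds (matching mobile-OS event
clocks); distances are millimetres via the pixels-per-inch densities of
the portrait-oriented screen. Flight times can be negative when the next
key is pressed before the previous is released (two-handed typing), so
raw sessions only require the press sequence and the release sequence to
each be strictly increasing.

Although $SP$ and $PFR$ are sometimes written with index ranges up to
$N$, only $N-1$ flights exist; the package pairs $HT_n$ with $FT_n$ (the
hold of the key that starts flight $n$), the only well-defined alignment.

### Conditional filters

`filter_config()` holds the thresholds, all configurable:

| parameter | default | unit | role |
|---|---|---|---|
| `ft_max_ms` | 3000 | ms | removes idle-keyboard pauses |
| `ft_min_exclusive_ms` | 0 | ms | removes two-handed overlaps (FT ≤ 0) |
| `long_press_ms` | 300 | ms | removes deliberate long presses |
| `min_keys` | 8 | keys | session validity |
| `outlier_sigma` | 3 | σ | per-user session outlier rule |

The non-positive-flight filter is required for the ratio variables to be
defined (division by $FT$), which is also why speed/press-flight-rate
computation sits strictly after the flight filters and treats a
non-positive flight reaching it as a contract violation.

Removals cascade by operand dependence: dropping $FT_n$ drops $SP_n$ and
$PFR_n$; dropping $HT_n$ as a long press drops $PFR_n$ only (the flight
and its speed do not involve that hold). Filtering is idempotent and
always yields order-preserving subsequences — both are tested as
properties.

The outlier rule operates at session granularity: for each user, the mean
$\mu$ and standard deviation $\sigma$ of the session-level $FT$ medians
are computed, and sessions with $|\tilde{\mu}^{FT} - \mu| > 3\sigma$ have
their FT-derived sequences (FT, SP, PFR) excluded. Since the criterion is
a per-session median it cannot select individual values, so the whole
session's flight-derived features are dropped (which, with the complete
20-feature contract below, removes the session from the feature table).
Degenerate cases — fewer than two usable sessions, zero dispersion —
flag nothing. The ordering of stages is: validity check → long-press
filter → flight filters → SP/PFR computation → per-user outlier
flagging; the outlier rule needs the filtered flight medians.

## The session feature vector

Each session becomes exactly 20 named features in a fixed order
(`feature_names()`): median, standard deviation, skewness and kurtosis of
each of HT, FT, SP, PFR, then duration `t_s` (s, keyboard launch to last
release), characters typed `l_chars` (non-delete registrations), delete
rate `dr` (deletes over all presses) and `cpm` (characters per minute).

Numerical conventions, chosen for fidelity to the method's published
formulation:

* the median uses the ceiling/floor midpoint rule on the ascending-sorted
  sequence, $\tilde{\mu} = (a_{\lceil n/2\rceil} + a_{\lfloor n/2+1\rfloor})/2$,
  which coincides with the usual midpoint median;
* the standard deviation is the population form
  $\sqrt{\sum_k (a_k-\mu)^2 / N}$;
* skewness and kurtosis divide the summed third/fourth powers of
  z-scores by $N+1$; the conventional $N$ denominator is available via
  `standard_moments = TRUE` (the difference is a per-session scalar
  factor and does not change rank-based downstream analyses);
* zero-dispersion sequences get skewness and kurtosis 0 with a
  degenerate flag rather than NaN;
* statistics require at least 4 values (kurtosis needs spread); a session
  whose filtered sequences fall below that — or which lost FT/SP/PFR to
  the outlier rule — raises an incomplete-session condition and is
  skipped and counted, never padded.

## The LOSO classification pipeline

Each subject is held out once. Per iteration:

1. **Balancing.** The training sessions of the other subjects are
   class-balanced by seeded under-sampling of the majority class at the
   session level. Under-sampling (rather than over-sampling or class
   weights) was chosen as the least invasive mechanism: no synthetic rows
   enter the fit, and the large observation space of sessions makes the
   discarded information cheap.
2. **Nested 5-fold selection and tuning.** Folds are grouped by subject
   so no subject straddles a fold boundary — within-subject correlation
   would otherwise leak into the inner AUC; a session-level fold mode is
   available (`subject_folds = FALSE`) for comparison. In each fold pass
   the other folds select the `k_best = 5` features by ANOVA F-value and
   grid-search the hyperparameters; the held-out fold scores candidates
   by the AUC of subject-mean probabilities, aligning the tuning
   objective with the subject-level decision rule. The configuration of
   the fold with the highest held-out AUC wins (ties: lowest fold index).
   This literal winner-fold rule is high-variance; a conventional
   mean-across-folds mode is available via `fold_rule = "mean"`.
   Single-class folds are re-drawn with a new seeded permutation (at most
   10 times, then an error): with very small cohorts two-class folds may
   not exist, which is why pipeline tests use 20 subjects.
3. **Final fit and prediction.** The winning features/hyperparameters are
   refit on all balanced training rows. Features are standardized (zero
   mean, unit variance, fit on training rows only — required for the SVM,
   harmless for trees); constant features are dropped with a warning.
   The held-out subject's session probabilities are averaged into the
   subject score; the default decision threshold is 0.5, with the Youden
   threshold available from the evaluation module.

Hyperparameter grids (kept small for desk-scale runtime): random forest —
trees {100, 300} × depth {unlimited, 5, 10}; gradient boosting — learning
rate {0.05, 0.1} × stages {100, 300}; SVM — cost {0.1, 1, 10}, RBF kernel
with automatic bandwidth and probability outputs via sigmoid calibration.
Random forests and gradient boosting expose impurity (GINI) importances;
`selection_frequency_report()` averages them only over iterations where
the feature was selected and flags features selected in ≥ 90% of
iterations as consistent.

Every random draw — balancing, fold assignment, model seeds — derives
from the pipeline seed, so identical cohort + config + seed reproduce the
result exactly (tested). Each iteration also records the identities of
all rows used for training, which the test suite uses to assert the
leakage guard: the held-out subject's rows never appear in balancing,
selection, tuning or fitting, even under adversarial session duplication.

## Evaluation

* **Bootstrap ROC** resamples *subjects* (the decision unit) with
  replacement, 1,000 times by default; single-class replicates are
  redrawn. Per replicate the AUC uses the rank (Mann-Whitney)
  formulation; the mean curve is vertically averaged on a fixed FPR grid
  with step interpolation; the CI is the percentile 2.5/97.5 interval.
* **Youden operating point** maximizes $J = \text{sens} + \text{spec} - 1$
  over all distinct score cutpoints (decision: positive iff score ≥
  threshold), ties broken by higher sensitivity, then lower threshold.
* **Group-wise feature tests** are two-sided Mann-Whitney U tests on
  per-subject feature means (never on sessions, whose within-subject
  correlation would inflate significance). The exact null distribution is
  used when both groups have ≤ 12 subjects and no ties occur, the
  tie-corrected normal approximation otherwise. Raw p-values are reported
  by default, matching the univariate-screening presentation this mirrors;
  Benjamini–Hochberg adjustment is available behind `adjust = "BH"`.
* **Covariate logistic test** regresses the group on prediction
  probability, age, education, gender, convergence session count and
  sessions per day (constant first, seven rows), flagging separation.
* **Convergence** is the smallest $n$ such that every cumulative mean
  from $n$ on stays within 0.05 of the final subject mean. An alternative
  reading of the convergence criterion phrased through the cumulative
  distribution function is not mathematically well-defined for a
  probability stream, so the cumulative-mean deviation form is
  implemented. **Daily trajectories** aggregate session probabilities by
  calendar day (UTC day of the session start, indexed from the subject's
  first day), and the daily-variability analysis correlates each
  subject's standard deviation of daily means with their mean daily
  session count, via the same Spearman core as the PHQ-9 correlation.

## The synthetic cohort generator

Real typing-session cohorts of this kind are not publicly available, so
`generate_cohort()` is a first-class, tested module that emulates the
statistical structure the pipeline assumes:

* **Group scales**: 11 DT / 14 HC subjects; 55.14 / 66.46 sessions per
  day; PHQ-9 group means 2.29 (HC, range 0–4) and 10.64 (DT, range 5–15),
  drawn as truncated normals and decomposed into nine items capped at 3.
  These defaults reproduce the published cohort anchors of the motivating
  study design.
* **Timing model**: hold and flight times are log-normal (positive,
  right-skewed, the standard shape for typing latencies), with medians
  100 ms (HC hold), 140 ms (DT hold, i.e. a 40 ms planted shift) and
  250 ms (flight), within-session log-sds 0.2/0.25, and per-subject
  log-normal random effects (sd 0.12/0.15) so that between-subject
  variance makes LOSO non-trivial.
* **Dispersion effect**: the DT group's within-session hold/flight
  deviations are scaled linearly about the median by
  `pfr_dispersion_multiplier` (default 1.5), which by the delta method
  scales per-session SP/PFR spread approximately linearly with the
  multiplier. Scaled flight draws keep a guard band of 60% of the median:
  flight times have a physiological lower bound for sequential taps, and
  without the guard the $1/FT$ tail would make ratio-variable dispersion
  explode superlinearly.
* **Event injection**: two-handed overlaps with probability `p_overlap`
  (0.05) bounded to 10–80% of the neighbouring holds so press/release
  monotonicity survives; pauses > 3 s (`p_pause` 0.02); deliberate long
  presses 320–900 ms (`p_longpress` 0.01); deletes at rate 0.07.
* **Geometry**: a content-free virtual 10×4 QWERTY grid with 6 mm key
  pitch at 420 ppi — only distances matter downstream, and content is
  never modelled.

`plant_effect(spec, shift, multiplier)` adjusts the DT effect relative to
the current spec (so `(0, 1)` is the identity); zero-effect specs set the
DT parameters equal to HC's.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: linguistic/autocorrect structure,
circadian and day-of-week rhythms, device heterogeneity, within-day mood
drift, and any coupling between typing metadata (deletes, session length)
and group beyond the planted timing effects. Tests on generated cohorts
validate the pipeline's mechanics (calibration under the null, recovery
of planted effects, leakage guards), not clinical performance.

## Problem sizes and runtime choices

Simulation-based tests run at desk scale as the package's own choice of
problem size: 20-subject cohorts with a handful of sessions per day
rather than the study-scale 55–66, reduced single-combination grids for
the 50-permutation null-calibration check, and 6–10 generator seeds for
planted-effect and monotonicity checks. Effect-size defaults are never
adjusted per test. The null-calibration check asserts the mean
subject-level AUC over ≥ 50 label permutations lies in [0.45, 0.55];
individual permutations scatter with the combinatorial null spread of a
20-subject AUC (sd ≈ 0.13), so only a clear majority — not all — of
per-permutation values can be expected inside [0.35, 0.65].

## Known limitations

* The winner-fold tuning rule is noisy on small cohorts; prefer
  `fold_rule = "mean"` when stability matters more than fidelity.
* SVM probability calibration (sigmoid, internal cross-validation) is the
  least reproducible component across platforms; the random forest and
  gradient boosting paths are exactly seeded.
* The per-user outlier rule assumes enough sessions per user for the
  3σ criterion to be meaningful; with very few sessions it flags nothing.
* Subject scores average session probabilities uniformly; no weighting by
  session length or recency is attempted.
* Headline clinical numbers reported for this class of method on private
  cohorts (e.g. subject-level AUC near 0.9) are context, not reproduction
  targets: no real cohort ships with the package.
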