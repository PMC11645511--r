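---
title: "Assessing survey-panel data quality: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing survey-panel data quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelqc)
```

## The problem

Web survey panels differ sharply in who answers and why. Probability-based
panels recruit members from a population frame, so each member has a known
selection probability; convenience panels (crowdworker pools) are open to
anyone, and some respondents are paid-by-the-task workers with an incentive
to answer fast or to misrepresent their health to qualify for follow-up
studies. A researcher comparing the two needs a battery of quality
diagnostics: respondent screening rules, careless-response metrics,
reliability comparison, duplicate-text detection, poststratification
weighting with imbalance diagnostics, and cross-sample comparison of point
estimates and correlation structures. `panelqc` implements that battery and
couples it to a synthetic-cohort generator with known ground truth, so every
stage can be validated end to end without access to any proprietary
respondent data.

## The synthetic cohort

The generator assigns each respondent exactly one persona:

* **attentive** — answers through a latent-trait ordinal model. Eight latent
  health traits (one per scale: physical function, fatigue, pain
  interference, depressive symptoms, anxiety, ability to participate, sleep
  disturbance, cognitive function) are drawn from a correlation matrix with
  a single general-health factor (symptom traits load positively,
  functioning traits negatively). Item `j` of domain `d` has latent value
  `loading * trait_d + noise`, cut into categories 1–5 at the equal-spaced
  thresholds (−1.5, −0.5, 0.5, 1.5); reverse-worded items are answered in
  the opposite direction. The default loading of 0.85 produces inter-item
  correlations near 0.72, hence Cronbach alpha near 0.9 for 4-item scales
  and near 0.84 for the 2-item cognitive scale — the range reported for
  PROMIS-style scales. A graded-response calibration would add realism but
  is deliberately out of scope: the equal-threshold model is the simplest
  one whose alpha and kappa are tunable.
* **straightliner** — one constant category for every item. The constant is
  drawn from {1, 2, 4} by default, avoiding the two allowed categories
  (5 on the physical-function battery, 3 on the sleep sets), so every exact
  plant violates all three straight-lining rules and sensitivity is
  decidable.
* **speeder** — uniform random responses with a lognormal seconds-per-item
  rate centred at 0.5 and truncated at 0.98, so total duration always sits
  strictly below the 1 s/item screening boundary.
* **misrepresenter** — endorses each of the two fake conditions
  ("syndomitis", "chekalism") with probability 0.9 and each real condition
  with probability 0.8. The real-condition rate is a free parameter: pilot
  reports of crowdworker over-endorsement describe respondents claiming
  essentially all conditions, and 0.8 reproduces a mean endorsement count
  near 19 of 24 for misrepresenters, which is what the published all-versus-
  screened means imply. An optional secondary toggle
  (`misrep_straightline_prob`, default 0 so ground truth stays a partition)
  lets misrepresenters also straight-line the sleep sets; the two-panel
  pipeline switches it to 0.3, which reproduces the observed pattern that
  removing fake-condition endorsers lowers the straight-lining rate and
  raises the reverse-coded sleep scale's alpha.
* **copier** — open text is a verbatim template sentence (≥ 10 words) plus
  at most two random words, shared with at least one other copier; everyone
  else emits a salad of ≥ 12 distinct words from a 2500-word synthetic
  vocabulary. This makes the 10-word/75%-coverage rule exactly decidable
  and drives the false-positive probability of the detector to effectively
  zero for non-copiers.

Default persona proportions (convenience-panel conditions) are 81.6%
attentive, 2% straight-liners, 0 speeders, 14.4% misrepresenters and 2%
copiers, with a 3.5% incompleteness overlay (respondents answering less
than half their items, recorded in the truth table). The published
comparison that motivates these defaults reported 14.4% fake-condition
endorsement and 3.5% incompletes on the convenience panel against 0.5% and
0.4% on the probability panel, and zero speed violations on either; the
probability-panel configuration in `pipeline_config()` mirrors those lower
rates.

Demographics use six weighting variables (age, gender, race/ethnicity,
education, income, census region). Sampling probability is proportional to
`marginal × bias`; the default bias vector is the ratio of the published
convenience-panel fake-excluded shares to the national shares — younger,
more male, far better educated, lower income. Latent traits are linked to
demographics (`trait_demo_effects`): by default older age lowers physical
function and lower income raises depressive symptoms, which gives the
raking tests an estimand computable from the generator's own marginals. The
two-panel pipeline additionally links education to physical function with
*opposite* signs in the two cohorts, planting the education-correlation
anomaly that cross-panel comparisons are designed to surface.

## Screening rules

Both removal rules are strict inequalities, matching their verbal
definitions: a respondent is removed for speed only when mean time per item
is *below* 1 second (exactly 1 s/item is retained), and for incompleteness
only when *less than* half of the assigned items are answered (exactly half
is retained). Only total durations are modelled, so the speed rule uses
total duration over items assigned rather than per-item timestamps.
Out-of-range responses are coerced to missing and counted, not grounds for
exclusion. A respondent failing both rules is counted once, under the speed
category. Fake-condition endorsement is evaluated only on the analytic
(retained) set, and the fake-excluded subset is always the analytic set
minus fake endorsers.

## Careless-response metrics

**Weighted kappa.** Agreement on repeated item pairs uses
`1 − Σw·O / Σw·E` with quadratic weights `(i−j)²` built on the full
declared 1–5 range even when categories are unobserved — the penalty is a
property of the scale's metric, not of the sample. Pairwise-complete
respondents enter; a constant joint distribution leaves chance disagreement
zero and kappa undefined (`NA`), never silently 0. Interpretation follows
the conventional agreement bands (≤ 0 poor, then slight / fair / moderate /
substantial / almost perfect in 0.2-wide steps), applied after half-up
rounding to two decimals so that a kappa of 0.205 lands in "fair".

**Straight-lining.** Three rules: constancy within *every* declared
same-response-category battery; constancy on the 6-item physical-function
battery unless the shared answer is 5 ("without any difficulty", a
plausible uniform answer); and constancy on one or both 3-item
mixed-direction sleep sets unless the shared answer is the middle category
3. Batteries with any missing item never flag their respondent — a
conservative choice where the source rules are silent on missingness.

**Mean root of pairs.** For a battery,
`rp = 1 − mean(sqrt(|r_i − r_j|)) / sqrt(max − min)` over all item pairs,
so 1 is maximal straight-lining and 0 maximal spread. The rescaling divides
by the square root of the range span; the originally cited rescaling is not
reprinted anywhere we can verify, so the literal reading is implemented and
surfaced as the `sqrt`-range convention (hand anchors: constant → 1, a
(1,5) pair → 0, (1,5,1) → 1/3). Respondents with fewer than two answered
items in the battery are excluded from the battery mean.

**Winsorized burden.** Durations above the 97.5th percentile
(linear-interpolation percentile, `type = 7`) are capped to it before
summarising. Two properties one might expect — interpolated percentiles and
idempotence of the capping — are jointly unsatisfiable: capping lowers the
next estimated percentile whenever the top order statistics were distinct.
The interpolated-percentile definition is kept, and idempotence holds in
the projection sense: `winsorized_burden()` accepts a pre-computed `cap`,
and capping under a fixed cap is a fixed point.

## Reliability

Cronbach alpha is computed from the listwise covariance matrix (pairwise
optional) after recoding reverse-worded items as `min + max − response`.
The cross-sample comparison is a Feldt-type test on
`W = (1 − α₁)/(1 − α₂)`. Under the parallel model each `(1 − α̂)` is
proportional to an F variate with `(n−1, (n−1)(k−1))` degrees of freedom.
Referring `W` directly to `F(n₁−1, n₂−1)` ignores the error degrees of
freedom and, for 4-item scales at n = 500 per arm, inflates the empirical
type-I rate to roughly twice the nominal 5% — we therefore take the
primary p-value from a normal approximation to `log W` whose mean and
variance are the exact digamma/trigamma moments of the two log-F
components (this is why the test needs `k₁` and `k₂`). The classical
`F(n₁−1, n₂−1)` p-value and a chi-square form (`z²` on 1 df) are returned
alongside, so either reporting convention found in the applied literature
("chi-square test for independent samples") can be matched. Calibration is
part of the test suite: 1000 null replicates at n = 500 per arm must
reject between 3% and 7% at nominal 5%.

## Copied-text detection

Answers are tokenized (casefold, punctuation stripped, whitespace
collapsed — "identical" is judged on words, not bytes). A respondent is
flagged when a contiguous run of at least 10 tokens is shared verbatim with
another answer *and* covers at least 75% of the respondent's own token
count; coverage is per-respondent, so in an asymmetric pair only the
sufficiently covered member is flagged. Candidate pairs are prefiltered by
shared 10-token shingles and exact run lengths come from a
longest-common-substring dynamic program, so a corpus with no verbatim
overlap is processed in linear time. Comparison is within-collection; a
cross-collection sweep is a trivial concatenation. The separate
"nonsensical answer" judgment is human work; only a clearly labelled
length/stop-list heuristic (`flag_low_effort()`) is provided, excluded from
all headline metrics.

## Raking

`rake()` is plain iterative proportional fitting with trimming and scaling
inside the loop: cycle through the variables multiplying weights by
`target/current`, then trim to the cap and rescale to mean 1 after each
full cycle (repeating the trim-rescale pair so rescaling can never push a
weight back above the cap). Convergence is declared when the total absolute
imbalance — the sum over all categories of all raking variables of
`|weighted share − target|`, a literal reading of "total absolute imbalance
across the six demographic variables" — falls to `tol` (default 1e-6; the
published 0.01 threshold is a diagnostic level, not the stopping rule).
Missing demographic values form an explicit category raked to its own
sample share, which is weight-neutral. With six variables the per-variable
factors compound, so individual weights legitimately exceed small caps even
when every margin converges: the uncapped fixed point is the unique IPF
solution, and the order-insensitivity and exact-margin properties are
tested there, while cap behaviour (cap honoured every cycle, paper-scale
imbalance at cap 30) is tested separately. The cap-30 balance of the
emulated convenience panel is intrinsically knife-edge: its smallest
education category (~0.3% of the sample against a 9.6% target) needs
weights of about 30, so binomial noise in that category decides whether
the capped weights can close the gap — the same arithmetic is visible in
the published table (18 respondents × weight 30 ≈ 9.35% against 9.6%).

## Cross-sample comparison

Scale scores are standardized to `T = 50 + 10(x − mean_ref)/sd_ref`. The
reference here is a synthetic cohort designated by the analysis (the
probability panel in the pipeline); this is a documented stand-in, not the
official PROMIS item-calibration lookup. Differences beyond 2 T-score
points — the conventional "small" effect — are flagged with a strict
inequality. Correlation matrices are Pearson (Spearman optional),
pairwise-complete, with Fisher-z 95% intervals; matrix comparison runs over
the lower triangle and reports mean and maximum absolute difference,
exceedance shares at 0.05/0.10/0.15/0.20, sign flips and the share where
the second panel's coefficient is larger in magnitude. One bookkeeping note
from the motivating study is surfaced rather than resolved: its abstract
counts 137 correlation pairs while its results enumerate 105 + 31 + 17 =
153; the pair set here is defined by the matrix structure alone.

## Problem sizes and determinism

The packaged two-panel pipeline uses cohorts of 6997 and 4149 respondents
at field close (13,608 and 7224 fielded) — the published accounting sizes —
and runs in well under a minute. Property and calibration tests use 1000
replicates at the sizes stated above; oracle tests (direct-summation kappa,
closed-form alpha, closed-form one-variable raking, brute-force percentile)
run at small n where enumeration is exact. One base seed is fanned out to
named substreams (`substream_seed()`), so disabling one pipeline stage
never shifts another stage's randomness, and identical configurations
reproduce byte-identical reports.

## What passing tests do and do not show

The generator emulates the behavioural mix, selection bias, and
reliability structure of real panels, but real data differ in ways the
model deliberately omits: items are not equally spaced in difficulty,
careless behaviour is graded rather than all-or-none, misrepresentation
correlates with demographics in unmodelled ways, text answers are natural
language rather than synthetic vocabulary, and durations have heavier
tails. Passing the suite therefore certifies the *metrics and pipeline* —
formulas, boundary decisions, detection guarantees on decidable plants,
weighting convergence — not any claim about how a particular real panel
would score.
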