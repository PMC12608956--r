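---
title: "Methods: quantifying step-count reproducibility under a low-impact gait protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying step-count reproducibility under a low-impact gait protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patsteps)
```

## The problem

Physical activity trackers (PATs) are attractive for monitoring patients
recovering from knee surgery, but early remobilization produces slow,
small, low-impact steps that consumer devices were not validated on. A
practical way for a health care professional (HCP) to learn a device's
detection limits is to wear it and walk a structured protocol: 20 steps
under each of 14 conditions varying intended step size (25/40/75/100% of
normal), direction (straight, 90° turn, zigzag, 360° circle), use of
forearm crutches, and footwear (street shoes vs. slippers), reading off the
device's count after each walk. `patsteps` implements the statistical
machinery for evaluating such a protocol: does a device show systematic
differences across conditions, does one rater experience the same
differences twice (intra-rater reproducibility), and do different raters
experience the same differences (inter-rater reproducibility)?

The unit of analysis is the **step-count ratio**, the device count divided
by the true (assistant-counted) number of steps. A walk sits in one of
three regimes: detectable (ratio near 1), undetectable (ratio 0), or near
the device's detection limit, where the ratio is unstable and can range
from 0 to above 1.5 (overcounting occurs).

## Banded agreement and weighted kappa

Classical ICCs presume reproducibility over the whole 0–1 scale, but the
scientifically relevant distinction is coarser: did the device detect
steps, fail, or sit near its limit? The package therefore scores the
agreement of two ratios from the same condition through bands with cut
points 0.2, 0.5 and 0.8. The outer thresholds acknowledge noise around
truly perfect or truly blind detection. A pair of ratios gets weight 0 when
one is above 0.8 and the other below 0.2; weight 0.5 when one is between
0.5 and 0.8 and the other below 0.2, or one between 0.2 and 0.5 and the
other above 0.8; and weight 1 otherwise. The **agreement rate** of a pair
set is the mean weight.

Two numerical conventions had to be fixed:

* **Boundary convention.** The verbal clauses become a gapless partition
  with "below 0.2" = [0, 0.2), "between 0.2 and 0.5" = [0.2, 0.5),
  "between 0.5 and 0.8" = [0.5, 0.8], "above 0.8" = (0.8, ∞). The values
  0.5 and 0.8 — both attainable as counts over 20 steps — land in the
  mid-high band, so 0.8 still counts as "between 0.2 and 0.8" (the
  full-weight clause). `weight_table()` exposes the resulting 4×4 matrix,
  and the test suite verifies it clause by clause.
* **Chance correction.** Agreement rates are transformed into kappa values
  following Cohen's principle, \(\kappa = (P_o - P_e)/(1 - P_e)\), with
  \(P_e = \sum_{a,b} p_A(a)\,p_B(b)\,w(a,b)\). By default \(p_A, p_B\) are
  the band distributions of the first and second pair members (Cohen's
  asymmetric-marginals convention); a pooled-marginals policy is available
  via `chance_marginals = "pooled"`. The exact chance formula used in the
  original analysis is not restated in the main text of the source study,
  so this policy toggle is the main reproduction risk for its headline
  inter-rater numbers; both policies agree closely when the two members
  are exchangeable.

Kappa reporting is suppressed when all ratios in the pair set exceed 0.5
(the device simply detected steps throughout; banded agreement carries no
information) or when the marginals are degenerate (\(P_e = 1\)). Kappas are
verbalized on the Landis–Koch scale (cut-offs 0.2/0.4/0.6/0.8).

**Pairing designs.** Intra-rater agreement pairs each condition's round-1
ratio with its round-2 ratio within one HCP (≤ 12 pairs after cleaning).
Inter-rater agreement computes a kappa for every unordered HCP pair and
every round combination — all four of (1,1), (1,2), (2,1), (2,2) by
default, read off the stated averaging "over all combinations of rounds";
a `round_combos = "cross"` toggle restricts to cross-round combinations in
case the narrower reading is wanted — and averages the non-suppressed
kappas with equal weight (suppressed combinations are excluded and
counted, not imputed).

## Condition-level ICC

For a quantitative companion measure, `fit_condition_icc()` fits the
intercept-only random-effects model \(y_{cj} = \mu + b_c + e_{cj}\) with
conditions as random intercepts by REML and reports
\(\sigma^2_{cond}/(\sigma^2_{cond} + \sigma^2_{res})\). Reporting is
suppressed when the estimated random-effect SD falls below 0.1 — with no
between-condition signal there is nothing whose reproduction could be
quantified. Negative variance estimates are truncated at zero (the REML
boundary), after which the suppression rule fires.

Because the inter-rater design requires hundreds of small fits (78 HCP
pairs × 4 round combinations per tracker at 14 raters), the package uses
the closed-form balanced one-way estimator
(\(\hat\sigma^2_{res} = MS_W\), \(\hat\sigma^2_{cond} =
(MS_B - MS_W)/k\), with the pooled-variance boundary solution when
\(MS_B \le MS_W\)) whenever the design is perfectly balanced; this is
algebraically the REML solution, and the suite verifies agreement with
`lme4::lmer()` to 10⁻⁶. Unbalanced data (missing rounds, device failures)
go through `lme4` with a tightened optimizer tolerance; the closed form
also serves as fallback if the iterative fit fails. ICC is invariant to
shifting or positively scaling all ratios, which the suite checks.

## Zero-inflated negative binomial condition effects

The effect of conditions on the counts themselves is modelled with a
zero-inflated negative binomial regression: conditions may push the device
below its detection limit (no steps detected at all — the inflation
component, a logit model with the condition factor) and may degrade
counting above the limit (the NB2 count component with log link, the
condition factor, and the true step count as exposure with a fixed unit
coefficient). Participant heterogeneity in counts is absorbed by the NB
overdispersion and, for inference, by a cluster-robust Huber–White
sandwich covariance with participants as clusters (G/(G−1) small-sample
factor). The likelihood, its optimization (L-BFGS-B within generous
parameter bounds ±15 on coefficients, followed by a BFGS polish), the
observed information, and per-cluster scores (central finite differences)
are implemented in the package; `glmmTMB` serves as an independent
cross-check in the test suite, agreeing in coefficients and log-likelihood.

Whether the inflation component should carry the condition factor or only
an intercept is genuinely open; the package defaults to the full factor —
the model's motivation is precisely that conditions influence the
detection limit — with `inflation = "intercept"` available, plus an
automatic intercept-only retry if the full-factor fit fails to converge
and a plain-NB fallback when the data contain no zeros at all.

Reporting is on the **marginal-mean scale**: the expected counted steps at
20 true steps, \((1-\pi_c)\,\mu_c\), with delta-method standard errors from
the sandwich covariance. `contrast_tests()` emits (i) step-size effects
within each condition category — pairwise differences between adjacent
step sizes plus a joint Wald equality test where a category has more than
two levels (the straight-line category S has four), (ii) each category's
difference from S averaged over the step sizes present in both (e.g.
crutches vs. straight walking averaged over 75% and 40%, matching how a
single "average decrease" with crutches is naturally summarized), and
(iii) a global Wald test of no difference between any conditions. All
tests use large-sample chi-square references; small-cluster df corrections
are out of scope and would matter most with very few raters.

## The synthetic-data generator

`simulate_dataset()` produces trial records with the statistical structure
the analysis assumes, so every stage is testable without the original
study data. Each tracker × condition carries a `detection_scenario()`:
with probability `zero_prob` the walk registers nothing; otherwise the
count is NB with mean `true_steps × mean_ratio × participant effect`
(`dispersion = Inf` gives a deterministic rounded count for near-perfect
devices). The zero and count processes are deliberately separate, mirroring
the ZINB analysis model so that parameter recovery is well-posed. On top
of this sit: a log-normal participant effect on the count mean (shared
across conditions within a tracker, per-tracker SD); occasional additive
Poisson overcount bursts, the mechanism by which ratios exceed 1.5 (the
observed overcounts need one, and none is documented); true-step jitter
(20 with probability 0.9, 19/21 with 0.05 each — small execution errors
around the intended 20 steps); an optional systematic off-by-one per
tracker (half steps at the start and end of a walk); whole-tracker
missingness per participant (app failures) and unrecorded
participant-rounds.

`preset_study_like()` encodes the qualitative regimes of the four-tracker
evaluation: a sole sensor that is perfect except for the off-by-one, a
near-perfect knee sensor whose app fails for 9 of 14 raters, a trouser
sensor with a strong step-size-dependent detection limit and an average
crutch-induced decrease of about eight counted steps, and a wrist tracker
with mild condition effects but strong participant heterogeneity (SD 0.5
on the log count scale). Round 1 of participant 1 is unrecorded. **All
distributional values are illustrative**: the source study reports no
device-level distribution parameters, so the preset encodes its
qualitative statements, chosen once and documented here. What the
generator does *not* emulate: within-participant *reproducible* individual
condition profiles (a rater's idiosyncratic but stable gait
interpretation), instructor/assistant variation, ground-truth counting
error, and serial correlation across the protocol sequence. Consequently,
passing tests demonstrate the statistical machinery, not device
properties; in the generator, intra- and inter-rater reproducibility
coincide in expectation, whereas real raters tend to reproduce themselves
better than they match each other.

## Validation problem sizes and numerical choices

The test suite validates, among others: the weight table by exhaustive
clause enumeration; agreement rates against an independently coded naive
loop on 1,000 random pair sets; kappa calibration (|κ| < 0.05 on 10,000
independent band pairs; κ = 1 under exact reproduction); ICC parameter
recovery on a \(\{0.1, 0.3, 0.5\}^2\) grid of (σ_cond, σ_res) with 200
simulated datasets per cell (12 conditions × 6 observations each, mean
estimate within ±0.1 of truth); ZINB recovery of inflation probabilities
(±0.1) and count effects (±2 SE) at 200 simulated participants; and the
calibration of the global condition test under the null (rejection rate
within [2.5%, 8%] at the nominal 5% over 400 simulated datasets of 80
participants × 6 conditions — sizes chosen to be comfortably in the
sandwich estimator's asymptotic regime while keeping the whole suite
fast). Tolerances quoted are the ones asserted in `tests/testthat/`.

Other numerical choices: ratios above 3.0 are flagged but retained
(overcounting is data); missing device counts are encoded as empty fields,
never 0 (a zero count is a measurement); cleaning drops the slipper
conditions (too little data in the evaluation study) and logs every
exclusion; trackers whose ratios show very limited variation (≥ 95% of
ratios within [0.9, 1.1], configurable) are excluded from reproducibility
quantification, which reproduces the sole/knee exclusion on study-like
data without hard-coding device names.

One more inference, flagged as such: the condition letter codes (S, T, Z,
C, W, L) are never expanded in the protocol description; the mapping
(S = straight, T = turn, Z = zigzag, C = circle, W = walking aid,
L = slippers) is inferred from the factor-level ordering and from which
conditions are called "core". `parse_condition()` accepts only the 14
standard codes; `condition_spec()` permits non-standard factor
combinations for protocol extensions but flags them.

## A worked example

```{r example, eval = FALSE}
cfg <- preset_study_like()
trials <- simulate_dataset(cfg, seed = 1)
report <- run_analysis(trials, provenance = "synthetic")
report
report$inter[, c("pat", "inter_kappa", "inter_kappa_label", "inter_icc")]
marginal_means(report$condition_effects$trouser$fit)
```

## Known limitations

* The chance-agreement policy (pair-member vs. pooled marginals) can shift
  inter-rater kappas slightly; both are exposed, neither is certain to
  match the original appendix computation.
* Sandwich-based Wald inference is asymptotic in the number of
  participants; with 14 raters, p-values near the 5% boundary should be
  read cautiously (the suite calibrates the global test at 80 clusters).
* The ICC model treats conditions as exchangeable draws of a random
  effect; with 12 conditions the variance components are estimated with
  considerable uncertainty, which is why suppression rules rather than
  confidence intervals guard interpretation.
* Bootstrap or interval estimates for kappa and ICC are deliberately out
  of scope, as is any modelling of rater characteristics.
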