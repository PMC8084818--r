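---
title: "Expected-gain optimality in risky duration and distance reproduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expected-gain optimality in risky duration and distance reproduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskaim)
```

## The decision problem

A participant reproduces a magnitude — a 750 ms interval by a button press, or
a 55 mm distance by a screen touch. A response inside the symmetric hit
window `[(1 - m) T, (1 + m) T]` around the target `T` (margin `m = 0.3`)
earns `G_hit = 5` points; undershooting the window ("too early" / "too
close") earns `G_early <= 0`, overshooting earns `G_late <= 0`. Across blocks
only the early penalty changes: 0, -5, 0, -30, 0 points in experimental
blocks 1-5, preceded by an unrewarded practice block.

Responses are modeled as Gaussian around an *aim point* `S` with endogenous
noise `sigma`. The expected gain of an aim point is

    EG(S) = G_early * P(X < L) + G_hit * P(L <= X <= U) + G_late * P(X > U),
    X ~ Normal(S, sigma),

a convex combination of the three gains. With zero penalties, `EG` is
symmetric around the window midpoint and the optimum is the target itself,
for any `sigma`. An asymmetric early penalty makes aiming slightly late
worthwhile: the optimal aim `S* = argmax EG(S)` shifts away from the
penalized bound, the more so the larger the penalty and the noisier the
responder. A precise responder can ignore the penalty; a noisy one must trade
hit probability for safety. `reward_surface()` maps `EG` over a grid of
`(sigma, S)` and traces the "optimal ridge" `S*(sigma)`.

```{r}
sch30 <- payoff_scheme(750, gain_early = -30)
optimal_aim(100, sch30)        # a 100-ms-SD responder should aim ~793 ms
max_expected_gain(100, sch30)  # and can expect at most ~4.7 of 5 points
```

## Numerical choices

* **Optimizer.** `optimal_aim()` returns the target analytically when the two
  tail gains are equal (the symmetric case has a closed-form optimum).
  Otherwise a 257-point scan over `[L - 2 sigma, U + 4 sigma]` brackets the
  maximum and `stats::optimize()` refines it to `1e-4 * target` (0.075 ms /
  0.0055 mm) — verified in the tests against an exhaustive 0.1-unit grid
  search.
* **Plateaus.** When `sigma` is tiny relative to the window (or all gains are
  zero), `EG` is flat near its maximum and the maximizer is ill-defined. The
  tie-break returns the plateau point closest to the target (found by
  bisection on `EG >= EG_max - 1e-8 * gain span`), so `S* -> T` as
  `sigma -> 0`.
* **No truncation.** The Gaussian response model formally puts mass below
  zero; it is ignored in `EG` (for the tasks' scales it is below `1e-13`).
  The *generator* does floor simulated responses at 1 ms / 0.1 mm, where the
  truncation probability is equally negligible at default parameters.
* **Hit window closed on both ends.** Boundary responses count as hits; under
  the continuous model exact boundaries have probability zero, so this only
  matters for discretized data.

## Preprocessing

Following the experiment's analysis rule, responses deviating more than 3
*raw* median absolute deviations from the median — pooled over all
experimental trials of one participant and modality — are excluded. The raw
MAD (no 1.4826 consistency constant) is deliberate: the exclusion rule is
stated in plain MAD units. `k = 3` raw MADs is about 2 Gaussian SDs, so on
purely Gaussian data the rule trims ~4-5% of trials; the Gaussian-consistent
variant (`normalize = TRUE`, about 3 SDs) is available. Boundary cases
(`|x - m| = 3 MAD`) are kept. Practice trials enter neither the pooled filter
statistics nor any summary: they earn no points and the analyses cover the
250 experimental trials. If the MAD is zero with non-constant data, only
median-valued responses survive, with a warning.

Block summaries (mean, SD with denominator `n - 1`, realized points) use kept
trials only; a block with fewer than two kept trials is flagged invalid.

## Optimality and efficiency

For each penalty block `b` (2 and 4) of each participant and modality:

* **actual adjustment** = mean response in block `b` minus mean in block 1;
* **optimal adjustment** = `optimal_aim(sd_b, scheme_b)` minus the block-1
  mean, where `sd_b` is the penalty block's own empirical SD (using the
  block-1 SD instead is a config option, `sigma_source = "block1"`);
* **optimality** = actual - optimal: negative means the participant should
  have shifted further (risk-seeking underadjustment), positive means
  over-caution;
* **efficiency** = `100 * points earned / (n_kept * max_expected_gain(sd_b,
  scheme_b))`: realized points relative to the best a responder with that SD
  could expect. Realized points are used (the narrative speaks of received
  points), so lucky risk-seekers can exceed 100%. The denominator counts kept
  trials, for consistency with every other filtered statistic.

`ridge_side_fraction()` reports the percentage of participants with negative
optimality — mean responses on the risky side of the optimal ridge.
`estimate_lambda()` recovers the cohort's adjustment propensity as a
least-squares slope through the origin of actual on optimal adjustment; this
down-weights participants whose required adjustment is near zero (they carry
no information about the propensity) and avoids unstable ratios.

## Cross-modal inference

Whether under-/over-adjustment is a stable trait across modalities is tested
by OLS of timing optimality on distance optimality plus a punishment-level
indicator (5-point level as reference) — the same fixed-effect structure as a
random-intercept mixed model with Bayes-factor selection, which it
deliberately replaces with transparent machinery: confidence intervals come
from resampling participants (the clusters) with replacement, at least 2000
times, under a fixed seed. The default interval is the normal approximation
(estimate ± z × bootstrap SE); with 36 clusters percentile intervals proved
slightly anticonservative in the package's null-calibration check (part of
the acceptance suite), while the normal flavor sat at nominal coverage.
Percentile intervals remain available (`ci_type = "percentile"`). Variables
are left in native units (ms, mm); a z-scored variant (`standardize = TRUE`)
is exposed since the original analysis does not state whether variables were
standardized. Per-modality models of the adjustment on punishment level and
block SD use the same contract.

## The synthetic cohort

`simulate_cohort()` emulates the design: 36 participants, two modalities,
a 50-trial practice block plus 5 experimental blocks of 50 trials, the payoff
schedule above. Ground truth per participant and modality:

* `sigma` — log-normal across participants, median 80 ms (timing) and 4 mm
  (distance), log-SD 0.35: roughly the 10% Weber fraction typical of interval
  reproduction, with a 2-fold spread across the central 95% of timers;
* `bias` — a Gaussian baseline aim bias (SD 30 ms / 2.5 mm, ~4% of the
  target) applied in all no-punishment blocks: participants are not assumed
  to reproduce the target exactly at baseline;
* `lambda` — the adjustment propensity. Penalty-block aims are
  `baseline + lambda * (S*(sigma) - baseline)`: `lambda = 1` lands on the
  expected-gain maximum, `lambda = 0.5` makes half the required shift. The
  default spread (SD 0.4) spans strong underadjusters to overadjusters, the
  heterogeneity the observed cohorts show; the timing and distance lambdas
  correlate with `rho` (default 0.6), the shared cross-modal component;
* 2% of trials are contaminants, uniform over 50-3000 ms / 1-200 mm —
  attention lapses and accidental touches, the kind of gross outliers the MAD
  filter exists for.

An optional scalar-property flag (`scalar_sigma`) lets noise grow
proportionally with the aim; it is off by default because the analysis model
treats each block's SD as a free, empirically measured quantity.

What the generator does *not* emulate: trial-by-trial feedback learning,
sequential effects, drifting attention, or heavy-tailed "regular" noise.
A green recovery test therefore establishes that the pipeline is an unbiased
chain from the stated strategy model to the reported statistics — not that
real data satisfy the model.

The distance margin is never stated numerically in the source experiment's
write-up; by symmetry with the timing task it defaults to 0.3, and it is an
explicit parameter everywhere.

## Known limitations

* With the default distance parameters (sigma median 4 mm against a ±16.5 mm
  window) the early penalty is nearly toothless in the distance task: the
  optimal shift is ~1 mm even under -30 points. Distance optimality scores
  are then dominated by baseline bias and estimation noise, so the
  cross-modal regression has limited power to detect even a strongly shared
  propensity at n = 36 — the package's acceptance suite measures exactly
  this, and the power check under `rho = 0.9` fails at the 90%-of-seeds level
  while the null-calibration check passes. This mirrors the marginal
  significance of the original cross-modal slope and is a property of the
  stated world, not of the estimator: the slope still orders correctly with
  the generating correlation (a tested invariant).
* The pooled MAD filter truncates the late tail of strongly shifted penalty
  blocks for very noisy participants, slightly deflating their measured means
  and SDs; this is inherited from the published analysis rule and is visible
  as a small positive bias of optimality scores at `lambda = 1`.
* Efficiency is undefined (flagged `NA`) when the attainable maximum is not
  positive, e.g. in the practice block.
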