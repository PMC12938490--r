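---
title: "Auditing embedding-based regression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing embedding-based regression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Embedding-based regression predicts a behavioral target (a rating, a
trial-wise neural signal, a binary choice) by regressing it on the
coordinates of text-prompt embeddings with an L2 penalty:

$$\hat{y} = \beta_0 + \sum_{i=1}^{d} \beta_i x_i,$$

where $x \in \mathbb{R}^d$ is the final-layer representation of the prompt
and the $\beta_i$ are estimated by ridge (or logistic ridge) regression
with cross-validated penalty $\lambda$. Because nearby prompts ("This is
number 4" vs. "This is number 5") receive similar embeddings, such models
interpolate extremely well between trained prompt-target pairs. The
question this package operationalizes is whether that predictive success
survives when the *target* of prediction moves outside the training
distribution — the difference between interpolation and extrapolation.

`embedaudit` fits the regression, constructs the hold-out regimes that
separate those two abilities, and quantifies extrapolation failure with
the SD score and ordinal-adequacy verdicts, entirely on synthetic data.

## Hold-out regimes

Three split families cover the audit (module `R/splits.R`):

* **Random out-of-sample (OOS)** — `random_oos()`: a seeded random
  fraction (default 1/3) of rows is held out. Held-out targets lie inside
  the training range, so success requires only interpolation.
* **Target-quantile out-of-distribution (OOD)** — `quantile_ood()`: the
  lowest, central, or top fraction of rows *by target rank* is held out.
  For the top band every test target exceeds every training target;
  success requires extrapolation. The middle band is rank-based (rather
  than value-based) so it stays well defined under ties and skew, and
  ties at a cut are broken by stable row order. Split sizes use
  round-half-away-from-zero, so a 33% cut of 777 rows is exactly 256.
* **Condition hold-out** — `condition_holdout()`: all rows carrying
  designated condition labels are held out (out-of-domain with respect to
  the experimental design).

All three return the same partition structure, and `swap_split()`
exchanges the sides — which is how the SD score's reference model is
expressed.

## The SD score

For a given split, two models are fitted with an identical configuration:
one on the training side (producing test-set predictions) and one on the
test side itself (the train/test exchange, producing an in-sample
reference fit of the same rows). The SD score is

$$\mathrm{SD} = \frac{\sum_j d\!\left(\hat{y}^{\text{train}}_j,\; y_j\right)}
                     {\sum_j d\!\left(\hat{y}^{\text{test}}_j,\; y_j\right)},$$

summing over test rows $j$. The default distance is L1 (the plainest
reading of "summed distances"); L2 is available via `distance = "L2"` and
reported alongside in the report provenance. A score near 1 means the
out-of-split predictions deviate from the data no more than a model that
was allowed to see those rows — model integrity. Scores well above 1
signal extrapolation breakdown; scores below 1 are flagged for inspection
rather than celebrated. Across repeated well-specified evaluations,
log(SD) should center on 0; `log_sd_summary()` reports the mean log score
with a configurable consistency band (default ±0.2, reported as a flag,
never a hard failure).

Two numerical guards matter here. First, the denominator has a tolerance
(`1e-10` relative to the centered target scale): a (near-)perfect
reference fit makes the diagnostic *undefined*, and the package raises a
degenerate-denominator error carrying both raw sums instead of returning
an infinity. Second, the automatic $\lambda$ grid never reaches the
interpolation regime when $p \ge n$ (below), which in practice keeps the
reference fit imperfect for honest reasons — irreducible noise — rather
than by arithmetic accident.

## Ridge estimation and the lambda grid

`ridge_fit()` standardizes every coordinate (centering, population-sd
scaling), leaves the intercept unpenalized, and stores the
standardization with the model, so predictions are invariant under
coordinate rescaling. The continuous path is computed exactly from one
SVD per training fold; the binomial path uses warm-started penalized
IRLS. With `lambda = "auto"` the grid is log-spaced with
$\lambda_{\max} = 100 \cdot \max d_i^2$ ($d_i$ the singular values of the
standardized design) and a floor of $\lambda_{\max} \cdot 10^{-2}$ when
$n < p$ ($10^{-4}$ otherwise), mirroring the documented default grid
policy of the standard ridge tooling in this literature. The floor is
load-bearing: with $p \ge n$ an unbounded grid lets the test-side
reference model interpolate its rows in-sample, which collapses the SD
denominator. Penalty selection is by seeded k-fold cross-validation
(squared error / deviance; default 10 folds), the fold assignment and the
full CV trace are stored on the model, and every fit is reproducible from
its JSON serialization.

Choosing the minimum-CV $\lambda$ (not a one-standard-error rule) is
deliberate: the 1-SE rule over-shrinks small test-side fits and distorts
both SD sides asymmetrically.

## The synthetic encoder

`synthetic_encode()` maps each prompt's concept scalar through
$m = d(1 - f_{\text{distractor}})$ random band-limited basis functions

$$z_k(c) = \sqrt{2}\,\cos(\omega_k c + \varphi_k),\qquad
  \omega_k \sim \mathcal{N}(0, 1/\ell^2),\ \varphi_k \sim U(0, 2\pi),$$

i.e., random Fourier features of a squared-exponential kernel with length
scale $\ell$. The expected cosine similarity of two noiseless rows is
$\exp(-\Delta^2 / 2\ell^2)(1 - f_{\text{distractor}})$ in the concept
distance $\Delta$ — exactly the local-similarity property that makes
embedding regression interpolate but not extrapolate, reproduced without
any pretrained weights. The remaining coordinates are concept-independent
standard-normal distractors, and a small per-entry noise (default sd 0.1
on unit-scale features) models idiosyncratic phrasing variation. Finite
$m$ leaves a ripple of order $1/\sqrt{m}$ on the far-field similarity;
the decay-monotonicity test therefore checks binned averages.

The length scale is always chosen relative to the concept geometry of the
study: well below the level spacing where concept levels must stay
dissociable (rating study), a few trials for trial-index prompts
(matching the reach of the series' autocorrelation), about one
remaining-trial for the horizon task, and about the condition spacing
where a held-out condition should be *interpolable* (the three-condition
sleep study).

## What the generators emulate

* `generate_number_prompts()` — the templated concept grid ("This is
  number 0" ... "This is number 100"), deterministic.
* `generate_level_prompts()` — label-style studies: a handful of coarse
  concept levels, each extended to many unique per-item prompts. This is
  the structure of a rating study in which a few label phrasings stand
  behind hundreds of rated items.
* `generate_linear_target()` / `vshape_transform()` — an injected linear
  concept-target relation with Gaussian noise, and its V-shaped pendant:
  out $= a + b\,|y - \text{pivot}|$ with $(a, b)$ mapping onto the
  original min/max range and pivot defaulting to the sample median. Any
  symmetric, range-preserving V serves the purpose (destroying linear
  recoverability while leaving the target interpolable); the specific
  pivot and scaling are this package's choice and are recorded in
  `study_truth()`.
* `generate_condition_study()` — a between-subjects design (defaults
  mirror a three-condition sleep-deprivation example: means 90/70/50,
  SD 5, N = 20 per condition), with individual per-participant prompts.
* `generate_autocorrelated_series()` — a stationary AR(1) series standing
  in for trial-wise neural activity. AR(1) is the minimal process with
  trial-index-predictable autocorrelation, which is all the trial-prompt
  binding phenomenon requires.
* `generate_horizon_choices()` — explore/exploit choices across horizon
  conditions. The generative model works on the probability scale
  (P(best) grows linearly in elapsed trials within a horizon; the first
  free choice of the shortest horizon is more exploitative by a fixed
  gap) because the two effect-size parameters are defined as probability
  differences; parameters implying probabilities outside (0,1) are
  rejected. The defaults (first-choice P(best) 0.25 in the long horizon,
  growth 0.10 per trial, gap 0.25) keep the long-horizon early choices
  exploration-dominant. That choice is substantive: if every condition's
  P(best) exceeded 0.5, the Bayes-optimal classifier would coincide with
  the majority rule and no embedding model could demonstrate skill above
  baseline; and a training band well below the decision threshold is what
  makes the hold-out failure mode (predicting continued exploration for
  late, exploitative trials) the typical outcome rather than a coin flip.
  Extrapolated predictions for an unseen remaining-trials level still
  amount to very few pseudo-random draws (all rows of a level share one
  concept), so occasional lucky transfer remains possible — the audit
  presets therefore summarize this use case by medians over replicates.

All generators are seeded through a single `with_seed()` scope (no global
RNG state is disturbed), record their generating parameters in
`study_truth()`, and round-trip through a CSV + JSON bundle.

## The frozen study presets

`preset_study()` / `preset_encoder()` pin one configuration per use case,
shared verbatim by the documentation, the test suite and the
command-line runner:

* **usecase1_linear**: 777 prompts over five concept levels
  (0, 25, 50, 75, 100) with centered weights (10/20/40/20/10%), target =
  level + N(0, 5); encoder dim 256, $\ell = 5$, 25% distractors. The
  clustered design is deliberate: a label-prompt study has few distinct
  concept values with many items each, and a centrally concentrated
  target. It is also what makes the middle-band result sharp — the
  central 33% of rows falls inside the modal level, where predictions
  are flat by construction (means right, correlation near zero). With an
  evenly spaced 0-100 grid instead, the smooth similarity ramps at the
  band edges would always induce a spurious middle-band correlation of
  0.4-0.7, which says more about the synthetic geometry than about the
  method under audit.
* **usecase1_vshape**: the same rows with the V-transformed target. Under
  the top hold-out this produces the floor-prediction signature —
  estimates compressed into the trained low band, far below the observed
  test values — rather than a strict two-cluster inversion.
* **trial_prompt / feedback_prompt**: 150-trial AR(1) participants
  (coefficient 0.8); the feedback variant re-prompts the *same* series
  with series-independent binary feedback labels, so any predictive
  success of the trial-prompt variant is attributable to the trial index
  alone.
* **horizon**: 500 games per horizon condition (lengths 1 and 6),
  encoder dim 64, $\ell = 1.5$.

Problem sizes (777 rows, 30 simulated participants, 100 repeated OOS
runs, 500 games per horizon) are the package's chosen study conditions;
they keep every audit preset comfortably reproducible on a laptop while
matching the row counts of the studies they emulate.

## Expected audit pattern

```{r}
library(embedaudit)
res <- run_audit("usecase1_linear", seed = 1)
res$summary
```

Random 33% gives r near 0.98 with SD near 1; the lowest/top 33% bands
give SD above 10 with an ordinal reversal (predicted test means collapse
toward the training mean, landing on the wrong side of the fitted
cluster means); the middle band recovers the test mean almost exactly
while the within-band correlation is near zero — superficial
interpolation. `autoplot()` on any report draws the familiar
observed-vs-predicted panel with cluster-mean overlays.

## Ordinal adequacy

`ordinal_adequacy()` evaluates a-priori ordering assertions ("top bin >
middle bin") on observed and predicted cluster means; a reversal is
recorded only when an assertion that holds in the data is strictly
inverted in the predictions. `run_evaluation()` derives default clusters
from the split: condition labels for condition hold-outs, otherwise
rank bins of the target (one per held-out fraction), with ascending
adjacent-pair assertions. Callers can (and for design-structured studies
should) supply their own clusters and assertions — the horizon preset,
for instance, asserts the monotone remaining-trials ordering.

## Known limitations

* The synthetic encoder emulates one property of real language-model
  embeddings — smooth local similarity in a scalar concept plus
  concept-independent variance — and nothing else. Passing audits here
  show the *pipeline and diagnostics* behave as designed; they say
  nothing about any particular real encoder, whose similarity structure
  is noisier, anisotropic, and confounded with surface features such as
  prompt length.
* Real-encoder adapters are a registration slot (`encoder_external()`):
  pooling choices for transformer hidden states are pinned by the caller
  and are outside the tested surface. An unavailable adapter raises a
  capability error; there is no silent fallback.
* The SD score is a diagnostic ratio, not a test statistic; no p-values
  are attached, and none are claimed.
* Binary-mode SD distances are computed between predicted probabilities
  and 0/1 outcomes; with a well-calibrated reference fit the score is
  1-anchored, but with very few rows per condition the exchange fit can
  be unstable — the presets keep thousands of choice rows for this
  reason.
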