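# embedaudit

Auditing out-of-distribution generalization of embedding-based
regression.

## The problem

A growing class of behavioral analyses predicts human data — severity
ratings, trial-wise neural activity, binary choices — by regressing the
target on text-prompt embeddings with an L2 penalty:

    y_hat = b0 + sum_i b_i * x_i,        b = argmin ||y - Xb||^2 + lambda ||b||^2

Because similar prompts receive similar embeddings, these models
interpolate superbly: random out-of-sample (OOS) cross-validation, the
standard check, reports high correlations. But random OOS only ever asks
the model about targets *inside* the range it was trained on. When the
held-out targets lie outside that range (out-of-distribution, OOD), the
same models can collapse to floor predictions or reverse the ordering of
condition means entirely — while the usual metrics never notice.

`embedaudit` makes that failure measurable. It provides:

* **Hold-out regimes** (`random_oos()`, `quantile_ood()`,
  `condition_holdout()`) separating interpolation from extrapolation.
* **The SD score** (`sd_score()`): for a given split, the ratio of the
  summed distances between test-set predictions and observed targets to
  the summed distances of an in-sample fit of that same test set (the
  train/test exchange). SD near 1 means model integrity; SD well above 1
  means extrapolation breakdown. `log_sd_summary()` checks that log(SD)
  centers on 0 across repeated runs.
* **Ordinal adequacy** (`ordinal_adequacy()`): whether predictions
  reproduce a-priori orderings of cluster/condition means, with an
  explicit reversal flag.
* **Seeded ridge / logistic-ridge fits** (`ridge_fit()`) with stored
  standardization, recorded CV traces and JSON round-trips.
* **Synthetic generators + a synthetic encoder** so the full audit runs
  with no downloads: templated number prompts, label-level rating
  studies, condition designs, AR(1) trial series, horizon-task choices,
  and random-Fourier-feature embeddings whose cosine similarity decays
  smoothly with concept distance.

Everything is a plain tibble in, tibble out; fitted objects have
`tidy()` / `glance()` methods and reports have `autoplot()`.

## Worked example

The flagship preset emulates a rating study: 777 label prompts over five
concept levels (0–100), target = level + N(0, 5), 256-dimensional
synthetic embeddings. Four hold-out regimes, one call:

```r
library(embedaudit)
res <- run_audit("usecase1_linear", seed = 1)
dplyr::select(res$summary, regime, n_test, r, sd_score, reversal)
#>       regime n_test       r sd_score reversal
#> 1 random 33%    259  0.9816     1.20    FALSE
#> 2 lowest 33%    259 -0.2360    11.81     TRUE
#> 3 middle 33%    259 -0.0213     1.14    FALSE
#> 4    top 33%    259  0.1996    12.94     TRUE
```

Read the four rows together: under random OOS the model looks excellent
(r = 0.98, SD = 1.2 — predictions deviate from the data about as much as
an in-sample fit does). Hold out the top third of the target instead and
the same pipeline falls apart: SD = 12.9 — predictions now sit thirteen
times further from the data than a reference fit of those rows — and the
ordinal verdict flags a reversal. The cluster means show why:

```r
rep <- res$reports[[4]]          # top 33%
cluster_means(rep$ordinal)
#>   cluster   n observed_mean predicted_mean
#> 1    bin1 259          18.8           19.8
#> 2    bin2 259          50.4           49.4
#> 3    bin3 259          81.1           35.7
```

The held-out top bin (observed mean 81) is predicted at 36 — *below* the
middle bin's 49: the model extrapolates by similarity to the nearest
trained prompts and lands on the wrong side of the ordering. Meanwhile
the middle-33% regime shows the opposite face of the same coin:
the predicted mean is almost exactly right but the within-band
correlation is zero — interpolation reproduces the coarse location of
the data while resolving none of its structure.

`autoplot(rep)` draws the observed-vs-predicted panel with train/test
colors and cluster-mean overlays.

Other presets (`preset_names()`) cover a three-condition sleep study, an
AR(1) trial-series participant prompted by trial index vs. by feedback
(showing the trial-prompt method "explains" nothing beyond
autocorrelation), and a horizon-task explore/exploit simulation with a
logistic pipeline and condition hold-outs.

A thin CLI over the same functions lives at `inst/cli/audit.R`
(`generate`, `encode`, `evaluate`, `report` verbs, YAML configs,
`--seed`/`--out`/`--regime` overrides).

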