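# Extrapolation diagnostics: the SD score (train/test exchange), log-SD
# consistency summaries, and ordinal-adequacy verdicts.

#' SD score: exchange-based misalignment of test predictions
#'
#' The SD score is the ratio of (i) the summed distances between the
#' test-set predictions of a model trained on the training side and the
#' observed test targets, to (ii) the summed distances between an
#' in-sample fit of the test side itself (the model obtained after
#' exchanging the training set) and the same targets. A score of 1 means
#' the out-of-split predictions deviate from the data no more than a model
#' allowed to see those rows - model integrity. Scores far above 1 signal
#' extrapolation breakdown; scores below 1 warrant inspection (predictions
#' beating the reference fit). The score is scale-free: rescaling targets,
#' predictions and reference fit by a common positive factor leaves it
#' unchanged.
#'
#' @param test_targets Observed targets on the test side.
#' @param predictions_from_train Test-side predictions of the model
#'   trained on the training side.
#' @param reference_fit_on_test In-sample fitted values of a model trained
#'   on the test side (identical regression configuration).
#' @param distance `"L1"` (sum of absolute deviations, default) or `"L2"`
#'   (Euclidean norm of the deviation vector).
#' @return A positive number.
#' @examples
#' sd_score(c(0, 0), c(2, 2), c(1, 1)) # (2+2)/(1+1) = 2
#' @export
sd_score <- function(test_targets, predictions_from_train,
                     reference_fit_on_test, distance = c("L1", "L2")) {
  distance <- match.arg(distance)
  n <- length(test_targets)
  if (n < 2) stop_usage("Need at least 2 test rows for an SD score.")
  if (length(predictions_from_train) != n || length(reference_fit_on_test) != n) {
    stop_usage("All three vectors must have equal length.")
  }
  dist_fun <- if (distance == "L1") {
    function(a, b) sum(abs(a - b))
  } else {
    function(a, b) sqrt(sum((a - b)^2))
  }
  numerator <- dist_fun(predictions_from_train, test_targets)
  denominator <- dist_fun(reference_fit_on_test, test_targets)
  tol <- 1e-10 * max(1, sum(abs(test_targets - mean(test_targets))))
  if (denominator <= tol) {
    abort(
      paste(
        "SD score denominator is degenerate: the reference fit matches the",
        "test targets (near-)perfectly, so the diagnostic is undefined."
      ),
      class = "embedaudit_error_degenerate",
      numerator = numerator, denominator = denominator
    )
  }
  numerator / denominator
}

#' Summarize a collection of SD scores on the log scale
#'
#' For consistent models, log(SD) should be distributed around 0 across
#' repeated evaluations. The summary reports the mean and sd of the log
#' scores, a Shapiro-Wilk normality p-value where computable, and a
#' consistency flag (mean log within `band` of 0).
#'
#' @param scores Positive SD scores (length >= 2).
#' @param band Half-width of the consistency band around 0 (default 0.2).
#' @return A one-row tibble.
#' @export
log_sd_summary <- function(scores, band = 0.2) {
  if (length(scores) < 2) stop_usage("Need at least 2 scores.")
  if (any(!is.finite(scores)) || any(scores <= 0)) {
    abort("SD scores must be positive and finite; an upstream invariant was violated.",
          class = "embedaudit_error_invariant")
  }
  logs <- log(scores)
  shapiro_p <- if (length(logs) >= 3 && length(logs) <= 5000 && sd(logs) > 0) {
    stats::shapiro.test(logs)$p.value
  } else {
    NA_real_
  }
  tibble(
    n = length(scores),
    mean_log = mean(logs),
    sd_log = sd(logs),
    shapiro_p = shapiro_p,
    band = band,
    consistent = abs(mean(logs)) <= band
  )
}

parse_ordering <- function(expected_ordering) {
  if (is.character(expected_ordering)) {
    pairs <- map(expected_ordering, function(s) {
      gt <- strsplit(s, ">", fixed = TRUE)[[1]]
      lt <- strsplit(s, "<", fixed = TRUE)[[1]]
      if (length(gt) == 2) {
        trimws(gt)
      } else if (length(lt) == 2) {
        rev(trimws(lt))
      } else {
        stop_usage(glue("Cannot parse ordering assertion '{s}' (use 'a > b' or 'a < b')."))
      }
    })
  } else if (is.list(expected_ordering)) {
    pairs <- map(expected_ordering, function(p) {
      if (length(p) != 2) stop_usage("Each ordering assertion must name two clusters.")
      as.character(p)
    })
  } else {
    stop_usage("`expected_ordering` must be a character vector or a list of pairs.")
  }
  pairs
}

#' Ordinal adequacy of predictions
#'
#' Evaluates a-priori ordering assertions about cluster means (e.g.
#' "top > middle") on both the observed targets and the predictions. A
#' reversal is flagged when some assertion holds in the observed means but
#' its strict inverse holds in the predicted means - the signature failure
#' of extrapolation from local prompt similarity.
#'
#' @param observed Observed targets.
#' @param predicted Predictions aligned with `observed`.
#' @param cluster_ids Cluster label per row (every referenced cluster must
#'   be nonempty).
#' @param expected_ordering Assertions as strings (`"a > b"` / `"b < a"`)
#'   or a list of `c(higher, lower)` pairs.
#' @return An `ordinal_verdict`: a tibble of per-assertion results with
#'   attributes `reversal` (logical) and `cluster_means`.
#' @examples
#' ordinal_adequacy(
#'   observed = c(1, 1, 5, 5), predicted = c(5, 5, 1, 1),
#'   cluster_ids = c("lo", "lo", "hi", "hi"),
#'   expected_ordering = "hi > lo"
#' )
#' @export
ordinal_adequacy <- function(observed, predicted, cluster_ids, expected_ordering) {
  n <- length(observed)
  if (length(predicted) != n || length(cluster_ids) != n) {
    stop_usage("`observed`, `predicted` and `cluster_ids` must have equal length.")
  }
  cluster_ids <- as.character(cluster_ids)
  counts <- table(cluster_ids)
  if (any(counts == 0)) stop_usage("Every cluster must be nonempty.")
  pairs <- parse_ordering(expected_ordering)
  known <- names(counts)
  referenced <- unique(unlist(pairs))
  missing_clusters <- setdiff(referenced, known)
  if (length(missing_clusters) > 0) {
    stop_usage(glue(
      "Ordering references unknown cluster(s): {paste(missing_clusters, collapse = ', ')}."
    ))
  }
  obs_means <- tapply(observed, cluster_ids, mean)
  pred_means <- tapply(predicted, cluster_ids, mean)

  rows <- map(pairs, function(p) {
    tibble(
      higher = p[1], lower = p[2],
      observed_holds = unname(obs_means[p[1]] > obs_means[p[2]]),
      predicted_holds = unname(pred_means[p[1]] > pred_means[p[2]]),
      reversed = unname(obs_means[p[1]] > obs_means[p[2]] &
                          pred_means[p[1]] < pred_means[p[2]])
    )
  }) |> list_rbind()

  structure(
    rows,
    class = c("ordinal_verdict", class(rows)),
    reversal = any(rows$reversed),
    cluster_means = tibble(
      cluster = names(obs_means),
      n = as.integer(counts[names(obs_means)]),
      observed_mean = as.numeric(obs_means),
      predicted_mean = as.numeric(pred_means[names(obs_means)])
    )
  )
}

#' @export
print.ordinal_verdict <- function(x, ...) {
  cat(sprintf("<ordinal_verdict: reversal = %s>\n", attr(x, "reversal")))
  NextMethod()
}

#' Has an ordinal reversal occurred?
#' @param verdict An `ordinal_verdict`.
#' @return Logical scalar.
#' @export
has_reversal <- function(verdict) isTRUE(attr(verdict, "reversal", exact = TRUE))

#' Cluster means behind an ordinal verdict
#' @param verdict An `ordinal_verdict`.
#' @return A tibble of per-cluster observed and predicted means.
#' @export
cluster_means <- function(verdict) attr(verdict, "cluster_means", exact = TRUE)

# Rank-based bins of a target, ascending; used as default ordinal clusters.
rank_bins <- function(y, k) {
  ranks <- rank(y, ties.method = "first")
  bins <- ceiling(ranks / (length(y) / k))
  bins <- pmin(pmax(bins, 1L), k)
  sprintf("bin%d", bins)
}

realize_split <- function(study, split, master_seed) {
  if (inherits(split, "split_result")) return(split)
  if (!is.list(split) || is.null(split$strategy)) {
    stop_usage("`split` must be a split_result or a list with a `strategy` field.")
  }
  switch(
    split$strategy,
    random = random_oos(
      study, fraction = split$fraction %||% (1 / 3),
      seed = split$seed %||% derive_seed(master_seed, "split")
    ),
    quantile = quantile_ood(
      study, region = split$region %||% "top",
      fraction = split$fraction %||% (1 / 3)
    ),
    condition = condition_holdout(
      study, held_out = split$held_out,
      condition_col = split$condition_col %||% "condition"
    ),
    stop_usage(glue("Unknown split strategy '{split$strategy}'."))
  )
}

#' Run one full evaluation: encode, split, fit, exchange, diagnose
#'
#' Executes the complete audit protocol for one hold-out regime:
#' encode the prompts, split the rows, fit the regression on the training
#' side, predict the held-out test side, fit the identical regression
#' configuration on the test side (the train/test exchange) to obtain the
#' in-sample reference fit, then compute fit metrics, the SD score and an
#' ordinal-adequacy verdict. Every seed and selected lambda is recorded so
#' the report can be reproduced bit for bit.
#'
#' @param study A study tibble.
#' @param encoder An encoder handle, or a precomputed embedding matrix
#'   aligned with `study`.
#' @param split A `split_result`, or a spec list such as
#'   `list(strategy = "random", fraction = 1/3)`,
#'   `list(strategy = "quantile", region = "top", fraction = 1/3)`,
#'   `list(strategy = "condition", held_out = c("remaining_1"))`.
#' @param regression Regression configuration: a list with any of
#'   `lambda`, `k_folds`, `n_lambda`.
#' @param distance Distance for the SD score, `"L1"` or `"L2"`.
#' @param clusters Cluster labels for the ordinal test (one per row), or
#'   `NULL` to use rank-based target bins (`round(1/fraction)` of them)
#'   for random/quantile regimes and the condition column for condition
#'   regimes.
#' @param expected_ordering Ordering assertions; `NULL` derives ascending
#'   assertions between adjacent rank bins (higher bin > lower bin).
#' @param seed Master seed; stage seeds are derived from it. Defaults to
#'   the study's generation seed.
#' @return An `evaluation_report`.
#' @export
run_evaluation <- function(study, encoder, split,
                           regression = list(), distance = c("L1", "L2"),
                           clusters = NULL, expected_ordering = NULL,
                           seed = NULL) {
  distance <- match.arg(distance)
  stopifnot(is.data.frame(study), "target" %in% names(study))
  master_seed <- seed %||% study_seed(study) %||% 1L
  mode <- study_mode(study)
  y <- study$target

  embedding <- if (inherits(encoder, "embedaudit_embedding") || is.matrix(encoder)) {
    if (nrow(encoder) != nrow(study)) {
      stop_usage("Precomputed embeddings must have one row per study row.")
    }
    encoder
  } else {
    encode(study, encoder)
  }

  split <- realize_split(study, split, master_seed)
  tr <- split$train_idx
  te <- split$test_idx

  fit_seed <- derive_seed(master_seed, "fit")
  ref_seed <- derive_seed(master_seed, "fit_exchange")
  reg_args <- function(s) {
    c(list(lambda = regression$lambda %||% "auto",
           k_folds = regression$k_folds %||% 10,
           mode = mode, seed = s),
      if (!is.null(regression$n_lambda)) list(n_lambda = regression$n_lambda))
  }
  model_train <- do.call(ridge_fit, c(list(X = embedding[tr, , drop = FALSE], y = y[tr]),
                                      reg_args(fit_seed)))
  model_ref <- do.call(ridge_fit, c(list(X = embedding[te, , drop = FALSE], y = y[te]),
                                    reg_args(ref_seed)))

  predictions <- predict(model_train, embedding[te, , drop = FALSE])
  reference <- predict(model_ref, embedding[te, , drop = FALSE])
  train_fitted <- predict(model_train, embedding[tr, , drop = FALSE])

  metrics <- score_predictions(predictions, y[te], mode = mode)
  sd_val <- sd_score(y[te], predictions, reference, distance = distance)

  # ordinal verdict on the full table: fitted values on the train side,
  # genuine predictions on the test side
  full_pred <- numeric(nrow(study))
  full_pred[tr] <- train_fitted
  full_pred[te] <- predictions
  if (is.null(clusters)) {
    if (split$spec$strategy == "condition" &&
        (split$spec$condition_col %||% "condition") %in% names(study)) {
      clusters <- study[[split$spec$condition_col %||% "condition"]]
    } else {
      k <- max(2L, min(10L, round(1 / (split$spec$fraction %||% (1 / 3)))))
      clusters <- rank_bins(y, k)
    }
  }
  ordinal <- NULL
  if (is.null(expected_ordering)) {
    lv <- names(sort(tapply(y, clusters, mean)))
    if (length(lv) >= 2) {
      expected_ordering <- sprintf("%s > %s", lv[-1], lv[-length(lv)])
    }
  }
  if (!is.null(expected_ordering) && length(expected_ordering) > 0) {
    ordinal <- ordinal_adequacy(y, full_pred, clusters, expected_ordering)
  }

  structure(
    list(
      regime = split$spec,
      split = split,
      mode = mode,
      test_targets = unname(y[te]),
      predictions_from_train = unname(predictions),
      reference_fit_on_test = unname(reference),
      train_targets = unname(y[tr]),
      train_fitted = unname(train_fitted),
      metrics = metrics,
      sd_score = sd_val,
      log_sd = log(sd_val),
      ordinal = ordinal,
      ids = study$id,
      provenance = list(
        master_seed = master_seed,
        fit_seed = fit_seed,
        ref_seed = ref_seed,
        lambda_train = model_train$lambda,
        lambda_ref = model_ref$lambda,
        k_folds = model_train$k_folds,
        encoder_id = encoder_id(embedding),
        distance = distance
      )
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  lab <- regime_label(x$regime)
  key <- if (x$mode == "continuous") {
    sprintf("r = %.3f", x$metrics$r)
  } else {
    sprintf("accuracy = %.3f", x$metrics$accuracy)
  }
  cat(sprintf(
    "<evaluation_report: %s | n_test = %d | %s | SD = %.3f%s>\n",
    lab, length(x$test_targets), key, x$sd_score,
    if (!is.null(x$ordinal) && has_reversal(x$ordinal)) " | ORDINAL REVERSAL" else ""
  ))
  invisible(x)
}

regime_label <- function(spec) {
  switch(
    spec$strategy,
    random = sprintf("random %.0f%%", 100 * (spec$fraction %||% (1 / 3))),
    quantile = sprintf("%s %.0f%%", spec$region, 100 * (spec$fraction %||% (1 / 3))),
    condition = sprintf("hold out %s", paste(spec$held_out, collapse = "+")),
    spec$strategy
  )
}

#' @rdname run_evaluation
#' @param x An `evaluation_report` (for `tidy()`/`glance()`).
#' @param ... Unused.
#' @export
tidy.evaluation_report <- function(x, ...) {
  te <- x$split$test_idx
  tr <- x$split$train_idx
  tibble(
    id = x$ids[c(tr, te)],
    side = rep(c("train", "test"), c(length(tr), length(te))),
    observed = c(x$train_targets, x$test_targets),
    predicted = c(x$train_fitted, x$predictions_from_train),
    reference = c(rep(NA_real_, length(tr)), x$reference_fit_on_test)
  )
}

#' @rdname run_evaluation
#' @export
glance.evaluation_report <- function(x, ...) {
  out <- tibble(
    regime = regime_label(x$regime),
    strategy = x$regime$strategy,
    mode = x$mode,
    n_train = length(x$train_targets),
    n_test = length(x$test_targets),
    sd_score = x$sd_score,
    log_sd = x$log_sd,
    reversal = if (!is.null(x$ordinal)) has_reversal(x$ordinal) else NA,
    lambda_train = x$provenance$lambda_train,
    lambda_ref = x$provenance$lambda_ref
  )
  dplyr::bind_cols(out, x$metrics[setdiff(names(x$metrics), "mode")])
}

#' @rdname run_evaluation
#' @param object An `evaluation_report` (for `autoplot()`).
#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- tidy(object)
  cm <- if (!is.null(object$ordinal)) cluster_means(object$ordinal) else NULL
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted,
                                        colour = .data$side)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::scale_colour_manual(values = c(train = "#20808D", test = "#E8630A")) +
    ggplot2::labs(
      title = regime_label(object$regime),
      subtitle = sprintf("SD = %.2f%s", object$sd_score,
                         if (!is.null(object$ordinal) && has_reversal(object$ordinal))
                           " (ordinal reversal)" else ""),
      x = "observed target", y = "model estimate"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(cm)) {
    p <- p + ggplot2::geom_point(
      data = cm,
      ggplot2::aes(x = .data$observed_mean, y = .data$predicted_mean),
      inherit.aes = FALSE, shape = 21, size = 4, stroke = 1.2,
      fill = "white", colour = "black"
    )
  }
  p
}
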