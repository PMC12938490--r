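test_that("sd_score matches hand-computed values", {
  # identical prediction profiles anchor the score at exactly 1
  y <- c(3, 1, 4, 1, 5)
  fit <- y + c(0.5, -0.5, 0.2, -0.2, 0.1)
  expect_equal(sd_score(y, fit, fit), 1)

  # hand oracle: (|2-0| + |2-0|) / (|1-0| + |1-0|) = 2
  expect_equal(sd_score(c(0, 0), c(2, 2), c(1, 1), distance = "L1"), 2)

  # perfect predictions against an imperfect reference score below 1
  expect_lt(sd_score(y, y + 1e-6, fit), 1)

  # L2 variant
  expect_equal(sd_score(c(0, 0), c(3, 4), c(0, 1), distance = "L2"), 5)
})

test_that("sd_score is scale-free", {
  set.seed(2)
  y <- rnorm(30); pred <- y + rnorm(30); ref <- y + rnorm(30, sd = 0.5)
  s1 <- sd_score(y, pred, ref)
  for (c in c(0.001, 7, 1e4)) {
    expect_equal(sd_score(c * y, c * pred, c * ref), s1, tolerance = 1e-12)
  }
})

test_that("a near-perfect reference fit is a hard degenerate error", {
  y <- c(1, 2, 3)
  err <- tryCatch(sd_score(y, y + 1, y), error = function(e) e)
  expect_s3_class(err, "embedaudit_error_degenerate")
  # raw sums are attached for inspection
  expect_equal(err$numerator, 3)
  expect_equal(err$denominator, 0)
})

test_that("log-SD summaries behave at the anchors", {
  all_one <- log_sd_summary(rep(1, 10))
  expect_equal(all_one$mean_log, 0)
  expect_equal(all_one$sd_log, 0)
  expect_true(all_one$consistent)

  sym <- log_sd_summary(c(2, 0.5))
  expect_equal(sym$mean_log, 0)

  expect_error(log_sd_summary(c(1, -2)), class = "embedaudit_error_invariant")
  expect_error(log_sd_summary(1), class = "embedaudit_error_usage")
})

test_that("ordinal adequacy flags constructed reversals only", {
  obs <- rep(c(50, 70, 90), each = 10)
  ids <- rep(c("a", "b", "c"), each = 10)
  ordering <- c("c > b", "b > a")

  agree <- ordinal_adequacy(obs, obs, ids, ordering)
  expect_false(has_reversal(agree))
  expect_true(all(agree$observed_holds))
  expect_true(all(agree$predicted_holds))

  inverted <- ordinal_adequacy(obs, rep(c(90, 70, 50), each = 10), ids, ordering)
  expect_true(has_reversal(inverted))
  expect_true(all(inverted$reversed))

  cm <- cluster_means(inverted)
  expect_equal(cm$observed_mean[cm$cluster == "c"], 90)
  expect_equal(cm$predicted_mean[cm$cluster == "c"], 50)

  # flat predictions are inadequate but not reversed
  flat <- ordinal_adequacy(obs, rep(70, 30), ids, ordering)
  expect_false(has_reversal(flat))
  expect_false(any(flat$predicted_holds))
})

test_that("ordinal adequacy validates clusters and assertions", {
  expect_error(ordinal_adequacy(1:4, 1:4, c("a", "a", "b", "b"), "a > zz"),
               class = "embedaudit_error_usage")
  expect_error(ordinal_adequacy(1:4, 1:3, c("a", "a", "b", "b"), "a > b"),
               class = "embedaudit_error_usage")
  # 'a < b' parses to the same assertion as 'b > a'
  v1 <- ordinal_adequacy(1:4, 1:4, c("a", "a", "b", "b"), "a < b")
  v2 <- ordinal_adequacy(1:4, 1:4, c("a", "a", "b", "b"), "b > a")
  expect_equal(v1$higher, v2$higher)
})

test_that("evaluation reports satisfy their structural invariants", {
  st <- tiny_study(seed = 3, step = 2)
  E <- tiny_embedding(st, dim = 64)
  rep <- run_evaluation(st, E, list(strategy = "random", fraction = 1 / 3),
                        seed = 5)
  n_te <- length(rep$test_targets)
  expect_equal(length(rep$predictions_from_train), n_te)
  expect_equal(length(rep$reference_fit_on_test), n_te)
  expect_equal(
    rep$sd_score,
    sd_score(rep$test_targets, rep$predictions_from_train,
             rep$reference_fit_on_test)
  )
  expect_equal(rep$log_sd, log(rep$sd_score))
  expect_equal(rep$provenance$distance, "L1")
  expect_match(rep$provenance$encoder_id, "synthetic")

  td <- tidy(rep)
  expect_equal(nrow(td), nrow(st))
  expect_equal(sum(td$side == "test"), n_te)
  expect_true(all(is.na(td$reference[td$side == "train"])))

  gl <- glance(rep)
  expect_equal(gl$n_test, n_te)
  expect_equal(gl$sd_score, rep$sd_score)
})

test_that("rerunning an evaluation reproduces it bit for bit", {
  st <- tiny_study(seed = 4, step = 2)
  E <- tiny_embedding(st, dim = 32)
  r1 <- run_evaluation(st, E, list(strategy = "quantile", region = "top"),
                       seed = 9)
  r2 <- run_evaluation(st, E, list(strategy = "quantile", region = "top"),
                       seed = 9)
  expect_identical(r1$predictions_from_train, r2$predictions_from_train)
  expect_identical(r1$sd_score, r2$sd_score)
  expect_identical(r1$provenance, r2$provenance)
})

test_that("exchange coherence: swapping sides yields the complementary report", {
  st <- tiny_study(seed = 6, step = 2)
  E <- tiny_embedding(st, dim = 32)
  sp <- random_oos(nrow(st), 0.5, seed = 3)
  fwd <- run_evaluation(st, E, sp, seed = 11)
  bwd <- run_evaluation(st, E, swap_split(sp), seed = 11)
  # each side's denominator is an in-sample fit of its own rows
  expect_equal(bwd$test_targets, st$target[sp$train_idx])
  expect_equal(fwd$test_targets, st$target[sp$test_idx])
  # the two reports cover complementary test sets that tile the study
  expect_setequal(c(fwd$split$test_idx, bwd$split$test_idx), seq_len(nrow(st)))
})

test_that("binary evaluations keep the SD score positive and 1-anchored", {
  hz <- generate_horizon_choices(60, c(1, 6), 0.2, 0.08, 0.35, seed = 2)
  E <- synthetic_encode(hz, dim = 16, length_scale = 1, seed = 3)
  rep <- run_evaluation(hz, E, list(strategy = "random", fraction = 1 / 3),
                        regression = list(k_folds = 5, n_lambda = 15), seed = 7)
  expect_gt(rep$sd_score, 0)
  expect_true(all(rep$predictions_from_train > 0 & rep$predictions_from_train < 1))
  expect_true("accuracy" %in% names(rep$metrics))
  # identical prediction profiles anchor at exactly 1
  expect_equal(
    sd_score(hz$target[1:10], rep(0.5, 10), rep(0.5, 10)), 1
  )
})

test_that("condition regimes use condition labels for the ordinal verdict", {
  sleep <- generate_condition_study(c("none", "moderate", "strong"),
                                    c(90, 70, 50), 5, 20, seed = 2)
  E <- synthetic_encode(sleep, dim = 32, length_scale = 20, seed = 4)
  rep <- run_evaluation(
    sleep, E, list(strategy = "condition", held_out = "moderate"),
    expected_ordering = c("none > moderate", "moderate > strong"),
    regression = list(k_folds = 5), seed = 5
  )
  expect_s3_class(rep$ordinal, "ordinal_verdict")
  cm <- cluster_means(rep$ordinal)
  expect_setequal(cm$cluster, c("none", "moderate", "strong"))
  # the held-out middle condition is interpolable: no reversal expected
  expect_false(has_reversal(rep$ordinal))
})

test_that("autoplot returns a ggplot without error", {
  st <- tiny_study(seed = 8, step = 5)
  E <- tiny_embedding(st, dim = 16)
  rep <- run_evaluation(st, E, list(strategy = "random", fraction = 1 / 3),
                        regression = list(k_folds = 5, n_lambda = 20), seed = 2)
  p <- ggplot2::autoplot(rep)
  expect_s3_class(p, "ggplot")
})
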