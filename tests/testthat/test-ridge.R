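test_that("lambda = 0 on a tall well-conditioned design equals least squares", {
  inst <- random_instance(1, n = 40, p = 5)
  fit <- ridge_fit(inst$X, inst$y, lambda = 0)
  ols <- ridge_oracle(inst$X, inst$y, 0)
  expect_equal(fit$weights, ols$weights, tolerance = 1e-8)
  expect_equal(fit$intercept, ols$intercept, tolerance = 1e-10)
})

test_that("fixed-lambda fits match the independent closed-form oracle", {
  for (seed in 1:10) {
    inst <- random_instance(seed)
    fit <- ridge_fit(inst$X, inst$y, lambda = 1)
    oracle <- ridge_oracle(inst$X, inst$y, 1)
    expect_lt(max(abs(fit$weights - oracle$weights)), 1e-8)
  }
})

test_that("infinite penalty shrinks to the mean prediction", {
  inst <- random_instance(2)
  fit <- ridge_fit(inst$X, inst$y, lambda = 1e12)
  expect_lt(max(abs(fit$weights)), 1e-6)
  preds <- predict(fit, inst$X)
  expect_equal(unname(preds), rep(mean(inst$y), 20), tolerance = 1e-4)
})

test_that("weight norms shrink monotonically in lambda", {
  inst <- random_instance(3, n = 30, p = 10)
  lambdas <- c(0.01, 0.1, 1, 10, 100, 1e4)
  norms <- vapply(lambdas, function(l) {
    sqrt(sum(ridge_fit(inst$X, inst$y, lambda = l)$weights^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("predictions are invariant under coordinate rescaling", {
  inst <- random_instance(4, n = 30, p = 6)
  scales <- c(1, 10, 0.01, 100, 5, 0.5)
  X2 <- sweep(inst$X, 2, scales, "*")
  f1 <- ridge_fit(inst$X, inst$y, lambda = 2)
  f2 <- ridge_fit(X2, inst$y, lambda = 2)
  expect_equal(unname(predict(f1, inst$X)), unname(predict(f2, X2)),
               tolerance = 1e-10)
})

test_that("cross-validated fits are deterministic under the fold seed", {
  st <- tiny_study()
  E <- tiny_embedding(st)
  f1 <- ridge_fit(E, st, seed = 42)
  f2 <- ridge_fit(E, st, seed = 42)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$lambda, f2$lambda)
  expect_true(f1$cv_trace$selected[which.min(f1$cv_trace$loss)])
  # the chosen lambda is the recorded CV minimizer
  expect_equal(f1$lambda, f1$cv_trace$lambda[which.min(f1$cv_trace$loss)])
})

test_that("continuous fits agree with glmnet at matched fixed lambda", {
  skip_if_not_installed("glmnet")
  inst <- random_instance(7, n = 50, p = 8)
  lambda <- 3
  fit <- ridge_fit(inst$X, inst$y, lambda = lambda)
  # glmnet standardizes y internally (population sd), so its objective
  # 1/(2n)||.||^2 + lg/2 ||b||^2 matches (Xs'Xs + lambda I)^-1 Xs'yc on
  # standardized coordinates at lg = lambda / n * sd(y)
  n <- nrow(inst$X)
  sdy <- sqrt(mean((inst$y - mean(inst$y))^2))
  g <- glmnet::glmnet(inst$X, inst$y, alpha = 0, lambda = lambda / n * sdy,
                      standardize = TRUE, thresh = 1e-16, maxit = 1e6)
  beta_orig <- as.numeric(g$beta)
  # convert package weights (standardized scale) to the original scale
  ctr <- colMeans(inst$X)
  sc <- sqrt(colMeans(sweep(inst$X, 2, ctr)^2))
  expect_equal(fit$weights / sc, beta_orig, tolerance = 1e-6)
})

test_that("logistic ridge agrees with glmnet binomial at matched lambda", {
  skip_if_not_installed("glmnet")
  set.seed(11)
  n <- 200; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- rbinom(n, 1, plogis(0.5 + X[, 1] - 0.5 * X[, 2]))
  lambda <- 2
  fit <- ridge_fit(X, y, lambda = lambda, mode = "binary")
  g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0, lambda = lambda / n,
                      standardize = TRUE, thresh = 1e-14, maxit = 1e6)
  sc <- sqrt(colMeans(sweep(X, 2, colMeans(X))^2))
  expect_equal(fit$weights / sc, as.numeric(g$beta), tolerance = 1e-3)
  mu <- predict(fit, X)
  expect_true(all(mu > 0 & mu < 1))
})

test_that("degenerate inputs raise the documented errors", {
  inst <- random_instance(5)
  expect_error(ridge_fit(inst$X, rep(1, 20), mode = "binary"),
               class = "embedaudit_error_degenerate")
  expect_error(ridge_fit(inst$X, inst$y, k_folds = 21),
               class = "embedaudit_error_usage")
  expect_error(ridge_fit(inst$X, inst$y[-1]), class = "embedaudit_error_usage")
  fit <- ridge_fit(inst$X, inst$y, lambda = 1)
  expect_error(predict(fit, inst$X[, 1:3]), class = "embedaudit_error_usage")
})

test_that("score_predictions reports the documented metrics", {
  y <- c(1, 2, 3, 4, 5)
  s <- score_predictions(y, y)
  expect_equal(s$r, 1)
  expect_equal(s$mean_signed_error, 0)
  s_neg <- score_predictions(-(y - mean(y)) + mean(y), y)
  expect_equal(s_neg$r, -1)

  # balanced binary targets against constant 0.5: ties predict positive
  yb <- c(0, 0, 1, 1)
  sb <- score_predictions(rep(0.5, 4), yb, mode = "binary")
  expect_equal(sb$accuracy, 0.5)

  expect_warning(s0 <- score_predictions(rep(1, 5), y), "zero variance")
  expect_true(is.na(s0$r))
})

test_that("binary predictions are probabilities that sum to one over classes", {
  hz <- generate_horizon_choices(30, c(1, 6), 0.15, 0.05, 0.35, seed = 2)
  E <- synthetic_encode(hz, dim = 16, length_scale = 1, seed = 3)
  fit <- ridge_fit(E, hz, lambda = 5)
  p <- predict(fit, E)
  expect_true(all(p > 0 & p < 1))
  expect_equal(unname(p + (1 - p)), rep(1, length(p)))
  expect_equal(fit$mode, "binary")
})

test_that("models round-trip through JSON with full provenance", {
  st <- tiny_study()
  E <- tiny_embedding(st)
  fit <- ridge_fit(E, st, seed = 13)
  path <- file.path(withr::local_tempdir(), "model.json")
  write_ridge_model(fit, path)
  back <- read_ridge_model(path)
  expect_equal(back$weights, fit$weights)
  expect_equal(back$lambda, fit$lambda)
  expect_equal(back$centers, fit$centers)
  expect_equal(back$seed, fit$seed)
  expect_equal(unname(predict(back, E)), unname(predict(fit, E)))
  expect_match(back$encoder_id, "synthetic")
})

test_that("tidy and glance expose coefficients and fit summary", {
  st <- tiny_study()
  E <- tiny_embedding(st, dim = 8)
  fit <- ridge_fit(E, st, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 9) # intercept + 8 weights
  expect_equal(td$term[1], "(Intercept)")
  gl <- glance(fit)
  expect_equal(gl$dim, 8)
  expect_equal(gl$mode, "continuous")
  expect_false(is.na(gl$cv_loss))
})
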