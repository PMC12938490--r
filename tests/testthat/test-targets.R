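test_that("linear targets follow the injected relationship", {
  ps <- generate_number_prompts(0, 100, 1)
  noiseless <- generate_linear_target(ps, slope = 1, intercept = 0,
                                      noise_sd = 0, seed = 7)
  expect_equal(noiseless$target, noiseless$concept)

  noisy <- generate_linear_target(ps, 1, 0, noise_sd = 5, seed = 7)
  n <- nrow(noisy)
  expect_lt(abs(mean(noisy$target - noisy$concept)), 3 * 5 / sqrt(n))

  flipped <- generate_linear_target(ps, -1, 100, noise_sd = 0, seed = 7)
  expect_equal(order(flipped$target), rev(order(flipped$concept)))

  truth <- study_truth(noisy)
  expect_equal(truth$slope, 1)
  expect_equal(truth$noise_sd, 5)
  expect_error(
    generate_linear_target(tibble::tibble(id = "a", prompt = "x"), 1, 0, 0, 1),
    class = "embedaudit_error_usage"
  )
})

test_that("least squares recovers the generating parameters", {
  # parameter recovery: slope/intercept within 3 standard errors
  for (seed in c(1, 2, 3)) {
    st <- generate_number_prompts(0, 100, 2) |>
      generate_linear_target(slope = 0.8, intercept = 12, noise_sd = 6, seed = seed)
    fit <- summary(lm(target ~ concept, data = st))$coefficients
    expect_lt(abs(fit["concept", "Estimate"] - 0.8),
              3 * fit["concept", "Std. Error"])
    expect_lt(abs(fit["(Intercept)", "Estimate"] - 12),
              3 * fit["(Intercept)", "Std. Error"])
  }
})

test_that("vshape transform folds symmetrically about the pivot", {
  st <- tiny_study(noise_sd = 0)
  st$target <- c(0, 50, 100, st$target[-(1:3)])
  v <- vshape_transform(st, pivot = 50)
  expect_equal(v$target[1], v$target[3])
  expect_gt(v$target[1], v$target[2])
  # range preserved
  expect_equal(range(v$target), range(st$target))

  # pivot at the minimum: monotone increasing rescaling of the input
  v_min <- vshape_transform(st, pivot = min(st$target))
  expect_equal(cor(rank(v_min$target), rank(st$target)), 1)

  # "median" resolves to the sample median
  st3 <- st[1:3, ]
  st3$target <- c(20, 30, 40)
  v_med <- vshape_transform(st3, pivot = "median")
  expect_equal(study_truth(v_med)$vshape_pivot, 30)
  expect_equal(v_med$target[1], v_med$target[3])

  # ordering of outputs equals ordering of |y - pivot|
  v50 <- vshape_transform(st, pivot = 50)
  expect_equal(order(v50$target), order(abs(st$target - 50)))
})

test_that("vshape applied twice with pivot at the transformed minimum is rank-equivalent", {
  st <- tiny_study(seed = 5)
  once <- vshape_transform(st, pivot = "median")
  twice <- vshape_transform(once, pivot = min(once$target))
  expect_equal(cor(rank(twice$target), rank(once$target)), 1)
})

test_that("vshape rejects binary targets", {
  hz <- generate_horizon_choices(5, c(1, 2), 0.1, 0.05, 0.4, seed = 1)
  expect_error(vshape_transform(hz), class = "embedaudit_error_usage")
})

test_that("condition studies match their design", {
  st <- generate_condition_study(c("none", "moderate", "strong"), c(90, 70, 50),
                                 within_sd = 5, n_per_condition = 20, seed = 2)
  expect_equal(nrow(st), 60)
  expect_equal(as.integer(table(st$condition)), rep(20L, 3))
  expect_false(anyDuplicated(st$prompt) > 0)

  one <- generate_condition_study("only", 42, within_sd = 0,
                                  n_per_condition = 1, seed = 2)
  expect_equal(nrow(one), 1)
  expect_equal(one$target, 42)

  exact <- generate_condition_study(c("a", "b"), c(10, 20), within_sd = 0,
                                    n_per_condition = 7, seed = 2)
  means <- tapply(exact$target, exact$condition, mean)
  expect_equal(as.numeric(means[c("a", "b")]), c(10, 20))

  expect_error(generate_condition_study(c("a", "b"), 1, 1, 5, 1),
               class = "embedaudit_error_usage")
})

test_that("AR(1) series have the designed autocorrelation", {
  for (seed in c(1, 2, 3)) {
    st <- generate_autocorrelated_series(150, 0.8, 1, seed = seed)
    expect_equal(nrow(st), 150)
    r1 <- cor(st$target[-1], st$target[-150])
    expect_lt(abs(r1 - 0.8), 0.15)
  }
  st <- generate_autocorrelated_series(150, 0.8, 1, seed = 1)
  expect_equal(st$prompt[1], "This is trial 1")
  expect_equal(st$prompt[150], "This is trial 150")
  expect_equal(study_truth(st)$ar_coefficient, 0.8)

  white <- generate_autocorrelated_series(400, 0, 1, seed = 9)
  r1 <- cor(white$target[-1], white$target[-400])
  expect_lt(abs(r1), 2 / sqrt(400))

  expect_error(generate_autocorrelated_series(100, 1, 1, 1),
               class = "embedaudit_error_usage")
  expect_error(generate_autocorrelated_series(100, -1.2, 1, 1),
               class = "embedaudit_error_usage")
})

test_that("horizon choices match the factorial design exactly", {
  hz <- generate_horizon_choices(50, c(1, 6), 0.15, 0.05, 0.30, seed = 4)
  # rows = sum over horizons of horizon length x games
  expect_equal(nrow(hz), 50 * 1 + 50 * 6)
  h6 <- hz[hz$horizon == 6, ]
  per_game <- tapply(h6$remaining, h6$game, function(r) all(sort(r) == 1:6))
  expect_true(all(per_game))
  expect_true(all(hz$target %in% c(0, 1)))
})

test_that("first-choice exploration gap is realized empirically", {
  hz <- generate_horizon_choices(500, c(1, 6), first_choice_explore_gap = 0.15,
                                 exploit_growth = 0.05, p_first_long = 0.30,
                                 seed = 11)
  p_short <- mean(hz$target[hz$horizon == 1])
  p_long_first <- mean(hz$target[hz$horizon == 6 & hz$remaining == 6])
  expect_lt(abs((p_short - p_long_first) - 0.15), 0.06)
})

test_that("zero growth removes the within-horizon trend", {
  hz <- generate_horizon_choices(500, c(1, 6), 0.15, exploit_growth = 0,
                                 p_first_long = 0.4, seed = 5)
  h6 <- hz[hz$horizon == 6, ]
  means <- tapply(h6$target, h6$remaining, mean)
  expect_lt(diff(range(means)), 0.1) # ~4 binomial SEs at n = 500
})

test_that("invalid horizon probabilities raise a parameter error", {
  expect_error(
    generate_horizon_choices(10, c(1, 6), 0.5, 0.2, 0.6, seed = 1),
    class = "embedaudit_error_parameter"
  )
})

test_that("identical seeds give bit-identical studies", {
  gens <- list(
    function(s) tiny_study(seed = s),
    function(s) generate_condition_study(c("a", "b"), c(1, 2), 1, 5, seed = s),
    function(s) generate_autocorrelated_series(50, 0.5, 1, seed = s),
    function(s) generate_horizon_choices(20, c(1, 6), 0.15, 0.05, 0.3, seed = s)
  )
  for (gen in gens) {
    expect_identical(gen(123), gen(123))
    expect_false(identical(gen(123)$target, gen(124)$target))
  }
})

test_that("studies round-trip through the CSV + JSON bundle", {
  st <- tiny_study(seed = 8)
  prefix <- file.path(withr::local_tempdir(), "study")
  write_study(st, prefix)
  back <- read_study(prefix)
  expect_equal(back$target, st$target)
  expect_equal(back$id, st$id)
  expect_equal(study_mode(back), "continuous")
  expect_equal(study_truth(back)$slope, study_truth(st)$slope)
  expect_equal(study_seed(back), study_seed(st))
})
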