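# Study datasets: a prompt set plus a behavioral target, with the
# generating parameters ("truth") and seed attached for parameter-recovery
# tests and exact replay.

new_study <- function(data, mode, truth, seed) {
  stopifnot(mode %in% c("continuous", "binary"))
  data <- as_tibble(data)
  if (mode == "binary" && !all(data$target %in% c(0, 1))) {
    stop_usage("Binary-mode targets must contain only 0/1.")
  }
  structure(
    data,
    class = c("embedaudit_study", class(data)),
    mode = mode,
    truth = truth,
    seed = seed
  )
}

#' @export
print.embedaudit_study <- function(x, ...) {
  cat(sprintf(
    "<embedaudit_study: %d prompts, %s target%s>\n",
    nrow(x), study_mode(x),
    if (!is.null(study_seed(x))) sprintf(", seed %d", study_seed(x)) else ""
  ))
  NextMethod()
}

#' Study metadata accessors
#'
#' `study_truth()` returns the list of generating parameters recorded by a
#' synthetic generator, `study_seed()` the seed it was generated under, and
#' `study_mode()` whether the target is `"continuous"` or `"binary"`.
#'
#' @param study A study tibble produced by one of the `generate_*` functions.
#' @return A list, an integer, or a character scalar respectively.
#' @export
study_truth <- function(study) attr(study, "truth", exact = TRUE)

#' @rdname study_truth
#' @export
study_seed <- function(study) attr(study, "seed", exact = TRUE)

#' @rdname study_truth
#' @export
study_mode <- function(study) {
  attr(study, "mode", exact = TRUE) %||%
    (if (all(study$target %in% c(0, 1))) "binary" else "continuous")
}

#' Attach a linear target to a prompt set
#'
#' Generates `target = intercept + slope * concept + N(0, noise_sd)` for
#' each prompt, reproducibly under `seed`.
#'
#' @param prompt_set A prompt-set tibble with a finite `concept` column.
#' @param slope,intercept Coefficients of the injected linear relationship.
#' @param noise_sd Standard deviation of the Gaussian noise, `>= 0`.
#' @param seed Integer seed.
#' @return A study tibble (`prompt_set` plus a `target` column) carrying the
#'   generating parameters as `study_truth()`.
#' @examples
#' generate_number_prompts(0, 100, 10) |>
#'   generate_linear_target(slope = 1, intercept = 0, noise_sd = 5, seed = 1)
#' @export
generate_linear_target <- function(prompt_set, slope, intercept, noise_sd, seed) {
  data <- validate_prompt_set(prompt_set, require_concept = TRUE)
  check_scalar_number(slope, "slope")
  check_scalar_number(intercept, "intercept")
  check_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stop_usage("`noise_sd` must be >= 0.")
  noise <- with_seed(seed, rnorm(nrow(data), 0, noise_sd))
  data$target <- intercept + slope * data$concept + noise
  new_study(
    data, "continuous",
    truth = list(kind = "linear", slope = slope, intercept = intercept,
                 noise_sd = noise_sd),
    seed = as.integer(seed)
  )
}

#' V-shape transform of a continuous target
#'
#' Replaces the target with a strictly increasing function of its absolute
#' distance from a pivot, rescaled to span the original target range. The
#' transform preserves the ordering of `|target - pivot|`, destroys linear
#' recoverability of the original concept-target relation, and leaves the
#' target interpolable from similar prompts.
#'
#' @param study A continuous-mode study tibble.
#' @param pivot A number, or `"median"` (the default) to pivot at the
#'   sample median of the target.
#' @return The study with its `target` column transformed; `study_truth()`
#'   gains `vshape_pivot`.
#' @export
vshape_transform <- function(study, pivot = "median") {
  if (!is.data.frame(study) || !"target" %in% names(study)) {
    stop_usage("`study` must be a data frame with a `target` column.")
  }
  if (study_mode(study) == "binary") {
    stop_usage("vshape_transform() applies to continuous targets only.")
  }
  y <- study$target
  pivot_value <- if (identical(pivot, "median")) median(y) else {
    check_scalar_number(pivot, "pivot")
    pivot
  }
  d <- abs(y - pivot_value)
  rng <- range(y)
  span <- diff(range(d))
  scaled <- if (span == 0) rep(rng[1], length(d)) else {
    rng[1] + (d - min(d)) / span * diff(rng)
  }
  out <- study
  out$target <- scaled
  truth <- c(study_truth(study) %||% list(), list(vshape_pivot = pivot_value))
  new_study(out, "continuous", truth = truth, seed = study_seed(study))
}

#' Generate a multi-condition study with Gaussian targets
#'
#' Emulates a between-subjects design (e.g. three sleep-deprivation
#' conditions with cognitive performance as the outcome): each condition
#' contributes `n_per_condition` participants whose targets are Gaussian
#' around the condition mean. Every participant receives an individual
#' prompt (the condition phrase plus a distinct stimulus-order token), so
#' prompts are unique but condition-similar.
#'
#' @param condition_names Character vector of condition labels.
#' @param condition_means Numeric vector of per-condition target means.
#' @param within_sd Within-condition standard deviation, `>= 0`.
#' @param n_per_condition Participants per condition, `>= 1`.
#' @param seed Integer seed.
#' @return A study tibble with columns `id`, `prompt`, `concept` (the
#'   condition mean), `condition`, `target`.
#' @examples
#' generate_condition_study(
#'   c("none", "moderate", "strong"), c(90, 70, 50),
#'   within_sd = 5, n_per_condition = 20, seed = 1
#' )
#' @export
generate_condition_study <- function(condition_names, condition_means,
                                     within_sd, n_per_condition, seed) {
  if (length(condition_names) != length(condition_means)) {
    stop_usage("`condition_names` and `condition_means` must have the same length.")
  }
  if (length(condition_names) < 1L) stop_usage("Need at least one condition.")
  check_scalar_number(within_sd, "within_sd")
  if (within_sd < 0) stop_usage("`within_sd` must be >= 0.")
  check_scalar_number(n_per_condition, "n_per_condition")
  if (n_per_condition < 1) stop_usage("`n_per_condition` must be >= 1.")

  k <- length(condition_names)
  data <- with_seed(seed, {
    rows <- map(seq_len(k), function(i) {
      subj <- seq_len(n_per_condition)
      order_token <- sample(1000:9999, n_per_condition)
      tibble(
        id = sprintf("%s_p%02d", condition_names[i], subj),
        prompt = sprintf(
          "Participant saw stimulus order %d under %s deprivation.",
          order_token, condition_names[i]
        ),
        concept = condition_means[i],
        condition = condition_names[i],
        target = rnorm(n_per_condition, condition_means[i], within_sd)
      )
    })
    bind_rows(rows)
  })
  new_study(
    data, "continuous",
    truth = list(kind = "condition", condition_names = condition_names,
                 condition_means = condition_means, within_sd = within_sd,
                 n_per_condition = n_per_condition),
    seed = as.integer(seed)
  )
}

#' Generate a stationary AR(1) trial series with trial prompts
#'
#' Produces a length-`n_trials` stationary AR(1) series standing in for
#' trial-wise neural activity, paired with the trial-prompt grid
#' ("This is trial 1", ..., "This is trial n"). The trial index is the only
#' concept the prompts carry, which is exactly what lets an embedding
#' regression bind the series' autocorrelation.
#'
#' @param n_trials Number of trials, `>= 2`.
#' @param ar_coefficient AR(1) coefficient, strictly inside (-1, 1).
#' @param noise_sd Innovation standard deviation.
#' @param seed Integer seed.
#' @return A study tibble; `study_truth()` records `ar_coefficient`.
#' @export
generate_autocorrelated_series <- function(n_trials, ar_coefficient, noise_sd = 1,
                                           seed = 1) {
  check_scalar_number(n_trials, "n_trials")
  if (n_trials < 2) stop_usage("`n_trials` must be >= 2.")
  check_scalar_number(ar_coefficient, "ar_coefficient")
  if (abs(ar_coefficient) >= 1) {
    stop_usage("`ar_coefficient` must lie strictly inside (-1, 1).")
  }
  check_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stop_usage("`noise_sd` must be >= 0.")

  series <- with_seed(seed, {
    if (ar_coefficient == 0) {
      rnorm(n_trials, 0, noise_sd)
    } else {
      as.numeric(stats::arima.sim(list(ar = ar_coefficient), n_trials, sd = noise_sd))
    }
  })
  prompts <- generate_number_prompts(1, n_trials, 1, template = "This is trial {}")
  prompts$target <- series
  new_study(
    prompts, "continuous",
    truth = list(kind = "ar1", ar_coefficient = ar_coefficient,
                 noise_sd = noise_sd, n_trials = n_trials),
    seed = as.integer(seed)
  )
}

# Per-condition best-choice probabilities of the horizon design. Exposed
# internally so both the generator and its tests derive the same schedule.
horizon_probabilities <- function(horizon_lengths, p_first_long,
                                  first_choice_explore_gap, exploit_growth) {
  h_max <- max(horizon_lengths)
  map(horizon_lengths, function(h) {
    p_first <- if (h_max == 1) p_first_long else {
      p_first_long + first_choice_explore_gap * (1 - (h - 1) / (h_max - 1))
    }
    remaining <- seq(h, 1)
    tibble(
      horizon = h,
      remaining = remaining,
      p_best = p_first + exploit_growth * (h - remaining)
    )
  }) |> list_rbind()
}

#' Simulate horizon-task binary choices
#'
#' Emulates a two-option bandit task in which the number of remaining
#' choices (the horizon) modulates the explore-exploit tradeoff. Each game
#' of horizon length h contributes h choice rows; the binary target is
#' whether the participant chose the option with the higher expected
#' reward. The generating model works on the probability scale:
#' within the longest horizon, P(best) starts at `p_first_long` on the
#' first free choice and grows by `exploit_growth` per elapsed trial;
#' the first free choice of the shortest horizon is more exploitative by
#' `first_choice_explore_gap`.
#'
#' @param n_games Games simulated per horizon condition.
#' @param horizon_lengths Integer vector of horizon lengths (free choices
#'   per game), e.g. `c(1, 6)`.
#' @param first_choice_explore_gap First-free-choice P(best) difference
#'   between the shortest and longest horizon.
#' @param exploit_growth Per-trial increase of P(best) as the remaining
#'   trials decrease.
#' @param p_first_long P(best) on the first free choice of the longest
#'   horizon.
#' @param seed Integer seed.
#' @return A binary-mode study tibble with columns `id`, `prompt`,
#'   `concept` (remaining trials), `condition` (remaining trials as label),
#'   `horizon`, `remaining`, `game`, `target`.
#' @export
generate_horizon_choices <- function(n_games, horizon_lengths = c(1, 6),
                                     first_choice_explore_gap = 0.25,
                                     exploit_growth = 0.10,
                                     p_first_long = 0.25, seed = 1) {
  check_scalar_number(n_games, "n_games")
  if (n_games < 1) stop_usage("`n_games` must be >= 1.")
  if (length(horizon_lengths) < 1L || any(horizon_lengths < 1)) {
    stop_usage("`horizon_lengths` must be a non-empty vector of lengths >= 1.")
  }
  sched <- horizon_probabilities(horizon_lengths, p_first_long,
                                 first_choice_explore_gap, exploit_growth)
  if (any(sched$p_best <= 0 | sched$p_best >= 1)) {
    stop_parameter(glue(
      "Implied P(best) outside (0,1): range [{round(min(sched$p_best), 3)}, ",
      "{round(max(sched$p_best), 3)}]. Adjust the effect-size parameters."
    ))
  }

  data <- with_seed(seed, {
    rows <- map(seq_along(horizon_lengths), function(ih) {
      h <- horizon_lengths[ih]
      per_game <- sched[sched$horizon == h, ]
      game <- rep(seq_len(n_games), each = h)
      remaining <- rep(per_game$remaining, times = n_games)
      p <- rep(per_game$p_best, times = n_games)
      prior_a <- round(runif(n_games * h, 20, 80))
      prior_b <- round(runif(n_games * h, 20, 80))
      tibble(
        id = sprintf("h%d_g%03d_r%d", h, game, remaining),
        prompt = sprintf(
          paste0("Prior samples: option A %d points, option B %d points. ",
                 "%d trial%s left. Choose an option."),
          prior_a, prior_b, remaining, ifelse(remaining == 1, "", "s")
        ),
        concept = as.numeric(remaining),
        condition = sprintf("remaining_%d", remaining),
        horizon = h,
        remaining = remaining,
        game = game,
        target = rbinom(length(p), 1, p)
      )
    })
    bind_rows(rows)
  })
  new_study(
    data, "binary",
    truth = list(kind = "horizon", n_games = n_games,
                 horizon_lengths = horizon_lengths,
                 first_choice_explore_gap = first_choice_explore_gap,
                 exploit_growth = exploit_growth, p_first_long = p_first_long,
                 schedule = sched),
    seed = as.integer(seed)
  )
}

#' Write or read a study as a CSV plus JSON sidecar
#'
#' The CSV holds the per-prompt table (id, prompt, concept, condition,
#' target, and any extra columns); the JSON sidecar holds the generating
#' parameters, seed and target mode so a round-trip preserves provenance.
#'
#' @param study A study tibble.
#' @param path_prefix Path without extension; `<prefix>.csv` and
#'   `<prefix>.json` are written/read.
#' @return `write_study()` returns `path_prefix` invisibly; `read_study()`
#'   returns the study tibble.
#' @export
write_study <- function(study, path_prefix) {
  stopifnot(is.data.frame(study), "target" %in% names(study))
  readr::write_csv(as_tibble(as.data.frame(study)), paste0(path_prefix, ".csv"))
  meta <- list(
    mode = study_mode(study),
    seed = study_seed(study),
    truth = study_truth(study)
  )
  jsonlite::write_json(meta, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path_prefix)
}

#' @rdname write_study
#' @export
read_study <- function(path_prefix) {
  data <- readr::read_csv(paste0(path_prefix, ".csv"), show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path_prefix, ".json"), simplifyVector = TRUE)
  new_study(
    data, meta$mode %||% "continuous",
    truth = meta$truth,
    seed = if (!is.null(meta$seed)) as.integer(meta$seed) else NULL
  )
}
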