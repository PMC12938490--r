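# Study and pipeline presets. Each preset pins the exact generator,
# encoder and hold-out parameters of one worked use case, so that the
# documentation, the test suite and the command-line runner all exercise
# one and the same configuration.

PRESET_NAMES <- c("usecase1_linear", "usecase1_vshape", "sleep_conditions",
                  "trial_prompt", "feedback_prompt", "horizon")

#' Available preset names
#' @return Character vector of preset identifiers.
#' @export
preset_names <- function() PRESET_NAMES

#' Build a preset study
#'
#' * `usecase1_linear` - a severity-rating-style study: 777 label prompts
#'   over five concept levels (0, 25, 50, 75, 100) with centered level
#'   weights (10/20/40/20/10%), and target = level + N(0, 5). Few coarse
#'   prompt levels with many rated items each, and a centrally
#'   concentrated target distribution.
#' * `usecase1_vshape` - the same study with the target sent through the
#'   median-pivot V-shape transform.
#' * `sleep_conditions` - three sleep-deprivation conditions
#'   (none/moderate/strong; means 90/70/50, SD 5, N = 20 per condition).
#' * `trial_prompt` - one simulated participant: a 150-trial stationary
#'   AR(1) series (coefficient 0.8) with "This is trial t" prompts.
#' * `feedback_prompt` - the same AR(1) series, but the prompts encode
#'   only the (random, series-independent) trial feedback, so they carry
#'   no concept correlated with the target.
#' * `horizon` - 500 games per horizon condition (lengths 1 and 6) of
#'   simulated explore/exploit choices.
#'
#' @param name Preset name (see [preset_names()]).
#' @param seed Integer master seed.
#' @return A study tibble.
#' @export
preset_study <- function(name, seed = 1) {
  name <- match.arg(name, PRESET_NAMES)
  dseed <- derive_seed(seed, paste0("dataset_", name))
  switch(
    name,
    usecase1_linear = generate_level_prompts(
      levels = c(0, 25, 50, 75, 100),
      weights = c(0.1, 0.2, 0.4, 0.2, 0.1),
      n_total = 777
    ) |>
      generate_linear_target(slope = 1, intercept = 0, noise_sd = 5,
                             seed = dseed),
    usecase1_vshape = preset_study("usecase1_linear", seed) |>
      vshape_transform(pivot = "median"),
    sleep_conditions = generate_condition_study(
      c("none", "moderate", "strong"), c(90, 70, 50),
      within_sd = 5, n_per_condition = 20, seed = dseed
    ),
    trial_prompt = generate_autocorrelated_series(
      n_trials = 150, ar_coefficient = 0.8, noise_sd = 1, seed = dseed
    ),
    feedback_prompt = {
      # same neural series as trial_prompt: only the prompting differs
      study <- preset_study("trial_prompt", seed)
      feedback <- with_seed(derive_seed(seed, "feedback"),
                            sample(c(0, 1), nrow(study), replace = TRUE))
      study$concept <- as.numeric(feedback)
      study$prompt <- sprintf(
        "Feedback: option %s was rewarded.", ifelse(feedback == 1, "A", "B")
      )
      study
    },
    horizon = generate_horizon_choices(
      n_games = 500, horizon_lengths = c(1, 6),
      first_choice_explore_gap = 0.25, exploit_growth = 0.10,
      p_first_long = 0.25, seed = dseed
    )
  )
}

#' Encoder preset matched to a study preset
#'
#' Length scales are pinned to each preset's concept geometry: well below
#' the level spacing for the rating study (levels stay dissociable, so
#' extrapolation beyond the trained levels fails), a few trials for the
#' trial-series (mirroring the reach of the series' autocorrelation), and
#' one remaining-trial for the horizon task.
#'
#' @param name Preset name.
#' @param seed Integer master seed.
#' @return An encoder handle.
#' @export
preset_encoder <- function(name, seed = 1) {
  name <- match.arg(name, PRESET_NAMES)
  eseed <- derive_seed(seed, paste0("encode_", name))
  switch(
    name,
    usecase1_linear = ,
    usecase1_vshape = encoder_synthetic(dim = 256, length_scale = 5,
                                        distractor_fraction = 0.25,
                                        noise_sd = 0.1, seed = eseed),
    sleep_conditions = encoder_synthetic(dim = 64, length_scale = 20,
                                         distractor_fraction = 0.25,
                                         noise_sd = 0.1, seed = eseed),
    trial_prompt = ,
    feedback_prompt = encoder_synthetic(dim = 128, length_scale = 2,
                                        distractor_fraction = 0.25,
                                        noise_sd = 0.1, seed = eseed),
    horizon = encoder_synthetic(dim = 64, length_scale = 1.5,
                                distractor_fraction = 0.25,
                                noise_sd = 0.1, seed = eseed)
  )
}

# Default hold-out regimes per preset.
preset_splits <- function(name) {
  third <- 1 / 3
  switch(
    name,
    usecase1_linear = ,
    usecase1_vshape = list(
      list(strategy = "random", fraction = third),
      list(strategy = "quantile", region = "lowest", fraction = third),
      list(strategy = "quantile", region = "middle", fraction = third),
      list(strategy = "quantile", region = "top", fraction = third)
    ),
    sleep_conditions = list(
      list(strategy = "random", fraction = third),
      list(strategy = "condition", held_out = "moderate")
    ),
    trial_prompt = ,
    feedback_prompt = list(
      list(strategy = "random", fraction = third),
      list(strategy = "quantile", region = "top", fraction = third)
    ),
    horizon = list(
      list(strategy = "random", fraction = third),
      list(strategy = "condition", held_out = c("remaining_1", "remaining_2", "remaining_3"))
    )
  )
}
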