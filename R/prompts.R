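# Prompt sets: one row per prompt, with optional concept scalar and
# condition label. All generators return plain tibbles so they pipe into
# the rest of the package.

#' Validate a prompt-set data frame
#'
#' A prompt set is a tibble with one row per prompt and columns `id`
#' (unique identifiers), `prompt` (text), and optionally `concept`
#' (a finite real scalar carried by the prompt, such as the n of
#' "This is number n") and `condition` (a categorical label).
#'
#' @param data A data frame to validate.
#' @param require_concept If `TRUE`, error unless a finite `concept`
#'   column is present.
#' @return `data`, invisibly, as a tibble.
#' @export
validate_prompt_set <- function(data, require_concept = FALSE) {
  if (!is.data.frame(data)) {
    stop_usage("A prompt set must be a data frame.")
  }
  data <- as_tibble(data)
  missing_cols <- setdiff(c("id", "prompt"), names(data))
  if (length(missing_cols) > 0) {
    stop_usage(glue("Prompt set is missing column(s): {paste(missing_cols, collapse = ', ')}."))
  }
  if (anyDuplicated(data$id) > 0) {
    stop_usage("Prompt set `id` values must be unique.")
  }
  if (require_concept) {
    if (!"concept" %in% names(data)) {
      stop_usage("This operation needs a `concept` column on the prompt set.")
    }
    if (!is.numeric(data$concept) || any(!is.finite(data$concept))) {
      stop_usage("`concept` must be numeric and finite for every prompt.")
    }
  }
  if ("concept" %in% names(data) && is.numeric(data$concept) &&
      any(!is.finite(data$concept))) {
    stop_usage("`concept`, when present, must be finite for every prompt.")
  }
  invisible(data)
}

# Substitute a single "{}" placeholder. Exactly one placeholder is a
# format contract, not a convenience.
fill_template <- function(template, values) {
  if (!is.character(template) || length(template) != 1L) {
    stop_format("`template` must be a single character string.")
  }
  n_placeholders <- lengths(regmatches(template, gregexpr("\\{\\}", template, perl = TRUE)))
  if (n_placeholders != 1L) {
    stop_format(glue(
      "`template` must contain exactly one '{{}}' placeholder; found {n_placeholders}."
    ))
  }
  vapply(values, function(v) sub("{}", format(v, trim = TRUE, scientific = FALSE), template, fixed = TRUE), character(1))
}

#' Generate templated number prompts over a grid
#'
#' Builds prompts such as "This is number 0", "This is number 10", ...,
#' one per grid value, with the numeric value stored in the `concept`
#' column. Deterministic: no randomness is involved.
#'
#' @param n_min,n_max Integer endpoints of the grid (inclusive).
#' @param step Integer grid step, `>= 1`.
#' @param template Prompt template containing exactly one `{}` placeholder.
#' @return A prompt-set tibble with columns `id`, `prompt`, `concept`.
#' @examples
#' generate_number_prompts(0, 100, 10)
#' @export
generate_number_prompts <- function(n_min, n_max, step = 1,
                                    template = "This is number {}") {
  check_scalar_number(n_min, "n_min")
  check_scalar_number(n_max, "n_max")
  check_scalar_number(step, "step")
  if (n_min > n_max) stop_usage("`n_min` must be <= `n_max`.")
  if (step < 1) stop_usage("`step` must be >= 1.")
  values <- seq(n_min, n_max, by = step)
  tibble(
    id = sprintf("num_%03d", seq_along(values)),
    prompt = fill_template(template, values),
    concept = as.numeric(values)
  )
}

#' Generate label-style prompts with repeated concept levels
#'
#' Emulates studies whose prompts carry a small number of coarse concept
#' levels, each repeated for many items (e.g. a handful of severity-label
#' phrasings extended to hundreds of rated items). Each row receives the
#' level's numeric value as `concept` and a unique per-item suffix so
#' prompts are distinct yet level-similar.
#'
#' @param levels Numeric vector of concept levels.
#' @param weights Non-negative weights, one per level; row counts are
#'   proportional to these (they need not sum to 1).
#' @param n_total Total number of prompts to generate.
#' @param template Template with one `{}` placeholder for the level value.
#' @return A prompt-set tibble with columns `id`, `prompt`, `concept`.
#' @examples
#' generate_level_prompts(c(0, 50, 100), c(1, 2, 1), 20)
#' @export
generate_level_prompts <- function(levels, weights = rep(1, length(levels)),
                                   n_total, template = "This is number {}") {
  if (length(levels) < 1L || !is.numeric(levels) || any(!is.finite(levels))) {
    stop_usage("`levels` must be a non-empty finite numeric vector.")
  }
  if (length(weights) != length(levels) || any(weights < 0) || sum(weights) <= 0) {
    stop_usage("`weights` must be non-negative, match `levels` in length, and not all be zero.")
  }
  check_scalar_number(n_total, "n_total")
  if (n_total < length(levels)) {
    stop_usage("`n_total` must be at least the number of levels.")
  }
  counts <- round_half_away(n_total * weights / sum(weights))
  counts <- pmax(counts, 1)
  # absorb rounding drift into the heaviest level
  counts[which.max(counts)] <- counts[which.max(counts)] + (n_total - sum(counts))
  concept <- rep(as.numeric(levels), counts)
  base <- fill_template(template, rep(levels, counts))
  item <- sequence(counts)
  tibble(
    id = sprintf("lvl%02d_item%03d", rep(seq_along(levels), counts), item),
    prompt = paste0(base, " (item ", item, ")"),
    concept = concept
  )
}
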