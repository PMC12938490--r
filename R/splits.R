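# Hold-out regimes: random out-of-sample, target-quantile
# out-of-distribution (lowest / middle / top), and condition hold-out.
# All of them return the same split_result structure: disjoint, exhaustive,
# nonempty train/test index sets plus the declarative spec that produced
# them.

new_split_result <- function(train_idx, test_idx, spec, y = NULL) {
  train_idx <- sort(as.integer(train_idx))
  test_idx <- sort(as.integer(test_idx))
  n <- length(train_idx) + length(test_idx)
  stopifnot(
    length(train_idx) > 0, length(test_idx) > 0,
    !anyDuplicated(c(train_idx, test_idx)),
    setequal(c(train_idx, test_idx), seq_len(n))
  )
  summary <- if (!is.null(y)) {
    tibble(
      side = c("train", "test"),
      n = c(length(train_idx), length(test_idx)),
      min = c(min(y[train_idx]), min(y[test_idx])),
      mean = c(mean(y[train_idx]), mean(y[test_idx])),
      max = c(max(y[train_idx]), max(y[test_idx]))
    )
  } else {
    NULL
  }
  structure(
    list(train_idx = train_idx, test_idx = test_idx, spec = spec,
         target_summary = summary),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result: %s | train %d, test %d>\n",
              x$spec$strategy, length(x$train_idx), length(x$test_idx)))
  if (!is.null(x$target_summary)) print(x$target_summary)
  invisible(x)
}

resolve_n <- function(x) {
  if (is.data.frame(x)) nrow(x) else {
    check_scalar_number(x, "x")
    as.integer(x)
  }
}

resolve_target <- function(x, target_col) {
  if (is.data.frame(x)) {
    if (!target_col %in% names(x)) {
      stop_usage(glue("Column `{target_col}` not found."))
    }
    x[[target_col]]
  } else {
    if (!is.numeric(x)) stop_usage("Pass a data frame or a numeric target vector.")
    x
  }
}

#' Random out-of-sample split
#'
#' Samples `round(fraction * n)` rows (rounding half away from zero)
#' without replacement as the test set, under the given seed. Because the
#' test targets are drawn from the full observed range, evaluating on this
#' split exercises interpolation only.
#'
#' @param x A data frame (its row count is used) or a single integer `n`.
#' @param fraction Test fraction in (0, 1); default one third.
#' @param seed Integer seed.
#' @param target_col Target column used for the side summaries when `x`
#'   is a data frame.
#' @return A `split_result`.
#' @examples
#' random_oos(100, fraction = 0.33, seed = 1)
#' @export
random_oos <- function(x, fraction = 1 / 3, seed = 1, target_col = "target") {
  n <- resolve_n(x)
  if (n < 4) stop_usage("`n` must be >= 4 for a random split.")
  check_scalar_number(fraction, "fraction")
  if (fraction <= 0 || fraction >= 1) stop_usage("`fraction` must lie in (0, 1).")
  m <- as.integer(round_half_away(fraction * n))
  if (m < 1 || m >= n) {
    stop_usage(glue("Test size {m} is degenerate for n = {n}."))
  }
  test_idx <- with_seed(seed, sample.int(n, m))
  y <- if (is.data.frame(x) && target_col %in% names(x)) x[[target_col]] else NULL
  new_split_result(
    setdiff(seq_len(n), test_idx), test_idx,
    spec = list(strategy = "random", fraction = fraction, seed = as.integer(seed)),
    y = y
  )
}

#' Target-quantile out-of-distribution split
#'
#' Holds out the `fraction` of rows with the lowest, central, or highest
#' target values (by rank; ties broken by stable row order). For
#' `region = "top"` every test target is >= every train target, and
#' symmetrically for `"lowest"`; `"middle"` carves a central band out of
#' the target range so that the training set occupies both flanks.
#' Predicting these test sets requires extrapolation (or, for the middle
#' band, interpolation across a target gap).
#'
#' @param x A data frame with a target column, or a numeric target vector.
#' @param region `"lowest"`, `"middle"` or `"top"`.
#' @param fraction Held-out fraction in (0, 1).
#' @param target_col Target column name when `x` is a data frame.
#' @return A `split_result`.
#' @examples
#' quantile_ood(1:100, "top", 0.33)
#' @export
quantile_ood <- function(x, region = c("lowest", "middle", "top"),
                         fraction = 1 / 3, target_col = "target") {
  region <- match.arg(region)
  y <- resolve_target(x, target_col)
  n <- length(y)
  if (n < 4) stop_usage("Need at least 4 rows.")
  if (length(unique(y)) < 2) {
    abort("All target values are equal; a quantile hold-out is undefined.",
          class = "embedaudit_error_degenerate")
  }
  check_scalar_number(fraction, "fraction")
  if (fraction <= 0 || fraction >= 1) stop_usage("`fraction` must lie in (0, 1).")
  m <- as.integer(round_half_away(fraction * n))
  if (m < 1 || m >= n) stop_usage(glue("Test size {m} is degenerate for n = {n}."))

  ranks <- rank(y, ties.method = "first")
  test_idx <- switch(
    region,
    lowest = which(ranks <= m),
    top = which(ranks > n - m),
    middle = {
      lo <- ceiling((n - m) / 2)
      which(ranks > lo & ranks <= lo + m)
    }
  )
  new_split_result(
    setdiff(seq_len(n), test_idx), test_idx,
    spec = list(strategy = "quantile", region = region, fraction = fraction),
    y = y
  )
}

#' Condition (out-of-domain) hold-out
#'
#' Puts every row whose condition label is in `held_out` into the test
#' set. The held-out labels must be a nonempty proper subset of the
#' observed labels.
#'
#' @param x A data frame with a condition column, or a vector of labels.
#' @param held_out Labels to hold out.
#' @param condition_col Condition column name when `x` is a data frame.
#' @param target_col Target column for side summaries (optional).
#' @return A `split_result`.
#' @export
condition_holdout <- function(x, held_out, condition_col = "condition",
                              target_col = "target") {
  labels <- if (is.data.frame(x)) {
    if (!condition_col %in% names(x)) {
      stop_usage(glue("Column `{condition_col}` not found."))
    }
    x[[condition_col]]
  } else {
    x
  }
  held_out <- unique(held_out)
  if (length(held_out) == 0) stop_usage("`held_out` must be nonempty.")
  observed <- unique(labels)
  unknown <- setdiff(as.character(held_out), as.character(observed))
  if (length(unknown) > 0) {
    stop_usage(glue("Unknown label(s): {paste(unknown, collapse = ', ')}."))
  }
  if (setequal(held_out, observed)) {
    stop_usage("`held_out` covers every observed label; nothing left to train on.")
  }
  test_idx <- which(labels %in% held_out)
  y <- if (is.data.frame(x) && target_col %in% names(x)) x[[target_col]] else NULL
  new_split_result(
    setdiff(seq_along(labels), test_idx), test_idx,
    spec = list(strategy = "condition", held_out = as.character(held_out)),
    y = y
  )
}

#' Swap the sides of a split
#'
#' Exchanging train and test is how the SD score's reference model is
#' expressed: the reference fit is an ordinary fit on the (swapped-in)
#' test side.
#'
#' @param split A `split_result`.
#' @return A `split_result` with the sides exchanged.
#' @export
swap_split <- function(split) {
  stopifnot(inherits(split, "split_result"))
  spec <- split$spec
  spec$swapped <- !isTRUE(spec$swapped)
  out <- new_split_result(split$test_idx, split$train_idx, spec)
  out$target_summary <- if (!is.null(split$target_summary)) {
    split$target_summary[c(2, 1), ] |>
      mutate(side = c("train", "test"))
  } else {
    NULL
  }
  out
}

#' Serialize a split to JSON (and back) for exact replay
#'
#' @param split A `split_result`.
#' @param path JSON path.
#' @return `write_split()` returns `path` invisibly; `read_split()` the
#'   `split_result`.
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "split_result"))
  jsonlite::write_json(
    list(train_idx = split$train_idx, test_idx = split$test_idx,
         spec = split$spec),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_split_result(raw$train_idx, raw$test_idx, as.list(raw$spec))
}
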