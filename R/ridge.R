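# Regularized regression on embedding features: ridge (Gaussian) and
# logistic ridge (binomial), with per-coordinate standardization, an
# unpenalized intercept, and seeded k-fold cross-validation over a
# log-spaced lambda grid.
#
# The Gaussian path is computed exactly from one SVD per training fold
# (weights for every lambda follow by rescaling singular values), the
# binomial path by warm-started penalized IRLS. The automatic grid uses
# lambda_max = 100 * max(d^2) and a floor of lambda_max * 0.01 when
# n < p (1e-4 otherwise); keeping the floor above the interpolation
# regime when p >= n is what keeps in-sample reference fits - and hence
# SD-score denominators - well defined.

standardize_fit <- function(X) {
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers)
  scales <- sqrt(colMeans(Xc^2))
  scales[scales == 0] <- 1
  list(centers = centers, scales = scales,
       Xs = sweep(Xc, 2, scales, "/"))
}

auto_lambda_grid <- function(d2, n, p, n_lambda) {
  lmax <- 100 * max(d2)
  lmin <- lmax * if (n < p) 1e-2 else 1e-4
  10^seq(log10(lmax), log10(lmin), length.out = n_lambda)
}

# Penalized IRLS for logistic ridge; intercept unpenalized.
logistic_ridge_solve <- function(Xs, y, lambda, start = NULL,
                                 maxit = 50, tol = 1e-9) {
  n <- nrow(Xs); p <- ncol(Xs)
  b <- if (is.null(start)) qlogis((sum(y) + 0.5) / (n + 1)) else start$intercept
  w <- if (is.null(start)) rep(0, p) else start$weights
  for (iter in seq_len(maxit)) {
    eta <- b + drop(Xs %*% w)
    mu <- plogis(eta)
    wt <- pmax(mu * (1 - mu), 1e-6)
    z <- eta + (y - mu) / wt
    Xw <- Xs * wt
    A <- rbind(
      c(sum(wt), colSums(Xw)),
      cbind(colSums(Xw), crossprod(Xs, Xw) + diag(lambda, p))
    )
    rhs <- c(sum(wt * z), drop(crossprod(Xs, wt * z)))
    sol <- tryCatch(solve(A, rhs), error = function(e) {
      solve(A + diag(1e-8 * max(diag(A)), p + 1), rhs)
    })
    delta <- max(abs(sol - c(b, w)))
    b <- sol[1]; w <- sol[-1]
    if (delta < tol) break
  }
  list(intercept = b, weights = w)
}

binomial_deviance <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  -2 * mean(y * log(mu) + (1 - y) * log(1 - mu))
}

#' Fit a ridge (or logistic ridge) regression on embedding features
#'
#' Coordinates are standardized (centered, scaled to unit variance) before
#' penalization; the intercept is unpenalized; fitted weights are stored on
#' the standardized scale together with the centers/scales used, so
#' predictions are invariant to coordinate rescaling of the input. With a
#' lambda grid (or `"auto"`), the penalty is chosen by seeded k-fold
#' cross-validation (squared error for continuous targets, deviance for
#' binary ones) and the full CV trace is kept on the model.
#'
#' @param X An embedding matrix (rows aligned with `y`).
#' @param y Numeric target vector, or a study tibble (its `target` column
#'   is used and its mode respected).
#' @param lambda `"auto"` for a data-derived log-spaced grid, a numeric
#'   vector to grid-search, or a single value to fit directly.
#' @param k_folds Folds for cross-validation (default 10).
#' @param mode `"auto"` (binary iff `y` is all 0/1), `"continuous"`, or
#'   `"binary"`.
#' @param seed Integer seed for the fold assignment.
#' @param n_lambda Grid length used when `lambda = "auto"`.
#' @return A `ridge_model` object.
#' @examples
#' ps <- generate_number_prompts(0, 100, 5)
#' st <- generate_linear_target(ps, 1, 0, 5, seed = 1)
#' E <- synthetic_encode(st, dim = 32, length_scale = 5, seed = 2)
#' fit <- ridge_fit(E, st, seed = 3)
#' cor(predict(fit, E), st$target)
#' @export
ridge_fit <- function(X, y, lambda = "auto", k_folds = 10,
                      mode = c("auto", "continuous", "binary"), seed = 1,
                      n_lambda = NULL) {
  mode <- match.arg(mode)
  if (is.data.frame(y)) {
    if (mode == "auto" && !is.null(attr(y, "mode", exact = TRUE))) {
      mode <- study_mode(y)
    }
    y <- y$target
  }
  enc_id <- if (inherits(X, "embedaudit_embedding")) encoder_id(X) else NULL
  X <- unclass(X)
  if (!is.matrix(X)) stop_usage("`X` must be a matrix.")
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_usage("`X` rows and `y` length must match.")
  if (any(!is.finite(y))) stop_usage("`y` must be finite.")
  if (mode == "auto") {
    mode <- if (all(y %in% c(0, 1))) "binary" else "continuous"
  }
  if (mode == "binary") {
    if (!all(y %in% c(0, 1))) stop_usage("Binary mode requires a 0/1 target.")
    if (length(unique(y)) < 2) {
      abort("Binary target is constant; the logistic fit is degenerate.",
            class = "embedaudit_error_degenerate")
    }
  }
  if (n < 2) stop_usage("Need at least 2 rows to fit.")

  std <- standardize_fit(X)
  Xs <- std$Xs
  sv <- svd(Xs)
  d2 <- sv$d^2

  grid_search <- identical(lambda, "auto") || length(lambda) > 1
  lambda_grid <- if (identical(lambda, "auto")) {
    auto_lambda_grid(d2, n, p,
                     n_lambda %||% (if (mode == "continuous") 100L else 30L))
  } else {
    if (!is.numeric(lambda) || any(lambda < 0)) {
      stop_usage("`lambda` must be \"auto\" or non-negative numbers.")
    }
    sort(lambda, decreasing = TRUE)
  }
  if (grid_search && n < k_folds) {
    stop_usage("Cross-validation needs `n >= k_folds`.")
  }

  cv_trace <- NULL
  if (grid_search) {
    folds <- with_seed(seed, sample(rep(seq_len(k_folds), length.out = n)))
    loss <- matrix(NA_real_, length(lambda_grid), k_folds)
    for (f in seq_len(k_folds)) {
      tr <- folds != f
      if (mode == "continuous") {
        ybar_f <- mean(y[tr])
        yc <- y[tr] - ybar_f
        s <- svd(Xs[tr, , drop = FALSE])
        uy <- drop(crossprod(s$u, yc))
        proj <- Xs[!tr, , drop = FALSE] %*% s$v
        for (li in seq_along(lambda_grid)) {
          coef_rot <- uy * s$d / (s$d^2 + lambda_grid[li])
          pred <- drop(proj %*% coef_rot) + ybar_f
          loss[li, f] <- mean((y[!tr] - pred)^2)
        }
      } else {
        warm <- NULL
        Xtr <- Xs[tr, , drop = FALSE]
        Xte <- Xs[!tr, , drop = FALSE]
        for (li in seq_along(lambda_grid)) {
          warm <- logistic_ridge_solve(Xtr, y[tr], lambda_grid[li],
                                       start = warm, maxit = 25, tol = 1e-8)
          mu <- plogis(warm$intercept + drop(Xte %*% warm$weights))
          loss[li, f] <- binomial_deviance(y[!tr], mu)
        }
      }
    }
    mean_loss <- rowMeans(loss)
    se_loss <- apply(loss, 1, sd) / sqrt(k_folds)
    best <- which.min(mean_loss)
    lambda_hat <- lambda_grid[best]
    cv_trace <- tibble(lambda = lambda_grid, loss = mean_loss, se = se_loss,
                       selected = seq_along(lambda_grid) == best)
  } else {
    lambda_hat <- lambda_grid[1]
  }

  if (mode == "continuous") {
    ybar <- mean(y)
    uy <- drop(crossprod(sv$u, y - ybar))
    shrink <- ifelse(sv$d > 0, sv$d / (sv$d^2 + lambda_hat), 0)
    weights <- drop(sv$v %*% (uy * shrink))
    intercept <- ybar
  } else {
    sol <- logistic_ridge_solve(Xs, y, lambda_hat)
    weights <- sol$weights
    intercept <- sol$intercept
  }

  structure(
    list(
      weights = weights,
      intercept = intercept,
      lambda = lambda_hat,
      mode = mode,
      centers = std$centers,
      scales = std$scales,
      cv_trace = cv_trace,
      k_folds = if (grid_search) k_folds else NA_integer_,
      seed = as.integer(seed),
      n = n, dim = p,
      encoder_id = enc_id
    ),
    class = "ridge_model"
  )
}

#' @export
print.ridge_model <- function(x, ...) {
  cat(sprintf(
    "<ridge_model: %s, n = %d, dim = %d, lambda = %.4g%s>\n",
    x$mode, x$n, x$dim, x$lambda,
    if (!is.null(x$cv_trace)) sprintf(" (CV over %d values)", nrow(x$cv_trace)) else ""
  ))
  invisible(x)
}

#' Predict from a fitted ridge model
#'
#' Applies the standardization stored at fit time. Continuous models
#' return real-valued predictions; binary models return probabilities in
#' (0, 1).
#'
#' @param object A `ridge_model`.
#' @param newdata An embedding matrix with the model's dimensionality.
#' @param ... Unused.
#' @return A numeric vector, named by row ids when available.
#' @export
predict.ridge_model <- function(object, newdata, ...) {
  X <- unclass(newdata)
  if (!is.matrix(X)) stop_usage("`newdata` must be a matrix.")
  if (ncol(X) != object$dim) {
    stop_usage(glue("`newdata` has {ncol(X)} columns but the model expects {object$dim}."))
  }
  Xs <- sweep(sweep(X, 2, object$centers), 2, object$scales, "/")
  eta <- object$intercept + drop(Xs %*% object$weights)
  out <- if (object$mode == "binary") plogis(eta) else eta
  names(out) <- rownames(X)
  out
}

#' Score predictions against observed targets
#'
#' Continuous mode reports the Pearson correlation and the mean signed
#' error; binary mode reports accuracy at the 0.5 threshold (ties predict
#' the positive class) and McFadden's deviance-based determination
#' coefficient. A zero-variance side makes the correlation undefined: it
#' is reported as `NA` with a warning, never silently zeroed.
#'
#' @param predictions Numeric predictions (probabilities in binary mode).
#' @param y Observed targets (or a study tibble).
#' @param mode `"auto"`, `"continuous"` or `"binary"`.
#' @return A one-row tibble of metrics.
#' @export
score_predictions <- function(predictions, y, mode = c("auto", "continuous", "binary")) {
  mode <- match.arg(mode)
  if (is.data.frame(y)) {
    if (mode == "auto" && !is.null(attr(y, "mode", exact = TRUE))) mode <- study_mode(y)
    y <- y$target
  }
  if (length(predictions) != length(y)) {
    stop_usage("`predictions` and `y` must have the same length.")
  }
  if (mode == "auto") mode <- if (all(y %in% c(0, 1))) "binary" else "continuous"

  if (mode == "continuous") {
    r <- if (sd(predictions) == 0 || sd(y) == 0) {
      warn("Correlation undefined: zero variance in predictions or targets.")
      NA_real_
    } else {
      cor(predictions, y)
    }
    tibble(mode = "continuous", r = r,
           mean_signed_error = mean(predictions - y))
  } else {
    hard <- as.numeric(predictions >= 0.5)
    null_dev <- binomial_deviance(y, mean(y))
    model_dev <- binomial_deviance(y, predictions)
    tibble(
      mode = "binary",
      accuracy = mean(hard == y),
      r2_deviance = 1 - model_dev / null_dev
    )
  }
}

#' @rdname ridge_fit
#' @param x A `ridge_model` (for `tidy()`/`glance()`).
#' @param ... Unused.
#' @export
tidy.ridge_model <- function(x, ...) {
  tibble(
    term = c("(Intercept)", sprintf("d%03d", seq_along(x$weights))),
    estimate = c(x$intercept, x$weights)
  )
}

#' @rdname ridge_fit
#' @export
glance.ridge_model <- function(x, ...) {
  tibble(
    mode = x$mode, n = x$n, dim = x$dim, lambda = x$lambda,
    k_folds = x$k_folds, seed = x$seed,
    cv_loss = if (!is.null(x$cv_trace)) min(x$cv_trace$loss) else NA_real_
  )
}

#' Save or load a ridge model as JSON
#'
#' The serialization carries everything needed to replay a fit's
#' predictions exactly: weights, intercept, lambda, standardization,
#' mode, seed and encoder id.
#'
#' @param model A `ridge_model`.
#' @param path JSON path.
#' @return `write_ridge_model()` returns `path` invisibly;
#'   `read_ridge_model()` returns the model.
#' @export
write_ridge_model <- function(model, path) {
  stopifnot(inherits(model, "ridge_model"))
  payload <- model
  payload$cv_trace <- if (!is.null(model$cv_trace)) as.list(model$cv_trace) else NULL
  class(payload) <- NULL
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ridge_model
#' @export
read_ridge_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- raw
  model$cv_trace <- if (!is.null(raw$cv_trace)) as_tibble(raw$cv_trace) else NULL
  model$k_folds <- raw$k_folds %||% NA_integer_
  structure(model, class = "ridge_model")
}
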