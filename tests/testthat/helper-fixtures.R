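# Shared fixtures, built in code at test time.

tiny_study <- function(seed = 1, n_max = 100, step = 5, noise_sd = 5) {
  generate_number_prompts(0, n_max, step) |>
    generate_linear_target(slope = 1, intercept = 0, noise_sd = noise_sd,
                           seed = seed)
}

tiny_embedding <- function(study, dim = 32, length_scale = 5, seed = 2, ...) {
  synthetic_encode(study, dim = dim, length_scale = length_scale, seed = seed, ...)
}

# Independent closed-form ridge oracle: standardize columns by their
# population sd, center y, solve (Xs'Xs + lambda I)^-1 Xs' yc directly.
# Deliberately naive (dense solve) and written without reference to the
# package internals.
ridge_oracle <- function(X, y, lambda) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sc <- sqrt(colMeans(Xc^2))
  sc[sc == 0] <- 1
  Xs <- sweep(Xc, 2, sc, "/")
  yc <- y - mean(y)
  p <- ncol(Xs)
  beta <- solve(crossprod(Xs) + diag(lambda, p), crossprod(Xs, yc))
  list(weights = drop(beta), intercept = mean(y))
}

random_instance <- function(seed, n = 20, p = 5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  list(X = X, y = y)
}
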