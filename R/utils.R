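# Internal helpers shared across modules.

# Round half away from zero (round() rounds half to even, which would make
# documented split sizes depend on parity).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. All randomness in the package flows through this.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.", class = "embedaudit_error_usage")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Fans a single master seed out to per-stage seeds by hashing the stage
#' name, so that adding or reordering pipeline stages never perturbs the
#' random stream of another stage. The result is a deterministic integer
#' in `[0, 2^31 - 2]`.
#'
#' @param master Single integer master seed.
#' @param stage Character stage label (e.g. `"split"`, `"fit"`).
#' @return A single integer seed.
#' @examples
#' derive_seed(1, "split")
#' derive_seed(1, "fit")
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  if (!is.numeric(master) || length(master) != 1L || !is.finite(master)) {
    abort("`master` must be a single finite number.", class = "embedaudit_error_usage")
  }
  h <- 0
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((abs(master) + h) %% 2147483647)
}

stop_usage <- function(msg) {
  abort(msg, class = "embedaudit_error_usage")
}

stop_format <- function(msg) {
  abort(msg, class = "embedaudit_error_format")
}

stop_parameter <- function(msg) {
  abort(msg, class = "embedaudit_error_parameter")
}

check_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop_usage(glue("`{name}` must be a single finite number."))
  }
  invisible(x)
}
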