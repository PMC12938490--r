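# Encoders: turn a prompt set into an n x dim embedding matrix. The
# synthetic encoder reproduces the one property downstream arguments rely
# on - embeddings of prompts with nearby concept values are similar, and
# similarity decays smoothly with concept distance - without any
# pretrained weights.

new_embedding <- function(matrix, encoder_id, row_ids) {
  if (any(!is.finite(matrix))) {
    stop_usage("Embedding matrices must not contain non-finite entries.")
  }
  rownames(matrix) <- row_ids
  structure(matrix, encoder_id = encoder_id, class = c("embedaudit_embedding", "matrix", "array"))
}

#' @export
print.embedaudit_embedding <- function(x, ...) {
  cat(sprintf("<embedding: %d prompts x %d dims, encoder '%s'>\n",
              nrow(x), ncol(x), encoder_id(x)))
  invisible(x)
}

#' Encoder id of an embedding matrix
#' @param x An embedding matrix.
#' @return Character scalar.
#' @export
encoder_id <- function(x) attr(x, "encoder_id", exact = TRUE) %||% "unknown"

#' Synthetic local-similarity encoder
#'
#' Encodes each prompt's concept scalar through `dim * (1 -
#' distractor_fraction)` random band-limited basis functions
#' (random Fourier features of a squared-exponential kernel with
#' bandwidth `1 / length_scale`), so that the cosine similarity of
#' noiseless rows decays smoothly with concept distance - the structure
#' that lets a downstream ridge regression interpolate between similar
#' prompts but not extrapolate beyond them. The remaining coordinates are
#' concept-independent standard-normal distractors, and optional
#' per-entry Gaussian noise models idiosyncratic phrasing variation.
#'
#' @param prompt_set A prompt-set tibble with a finite `concept` column.
#' @param dim Embedding dimension, `>= 2`.
#' @param length_scale Concept distance over which similarity decays
#'   (`> 0`), in concept units.
#' @param distractor_fraction Fraction of coordinates carrying no concept
#'   signal, in `[0, 1)`.
#' @param noise_sd Per-entry Gaussian noise sd, `>= 0` (features have unit
#'   scale).
#' @param seed Integer seed; fixes both the basis and the noise.
#' @return An `n x dim` embedding matrix with prompt ids as row names.
#' @examples
#' ps <- generate_number_prompts(0, 100, 10)
#' E <- synthetic_encode(ps, dim = 64, length_scale = 5, seed = 1)
#' @export
synthetic_encode <- function(prompt_set, dim = 256, length_scale = 5,
                             distractor_fraction = 0.25, noise_sd = 0.1,
                             seed = 1) {
  data <- validate_prompt_set(prompt_set, require_concept = TRUE)
  check_scalar_number(dim, "dim")
  if (dim < 2) stop_parameter("`dim` must be >= 2.")
  check_scalar_number(length_scale, "length_scale")
  if (length_scale <= 0) stop_parameter("`length_scale` must be > 0.")
  check_scalar_number(distractor_fraction, "distractor_fraction")
  if (distractor_fraction < 0 || distractor_fraction >= 1) {
    stop_parameter("`distractor_fraction` must lie in [0, 1).")
  }
  check_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stop_parameter("`noise_sd` must be >= 0.")

  concept <- data$concept
  n <- length(concept)
  m_signal <- max(1L, round(dim * (1 - distractor_fraction)))
  m_distract <- dim - m_signal

  X <- with_seed(seed, {
    omega <- rnorm(m_signal, 0, 1 / length_scale)
    phase <- runif(m_signal, 0, 2 * pi)
    signal <- sqrt(2) * cos(outer(concept, omega) +
                              matrix(phase, n, m_signal, byrow = TRUE))
    out <- if (m_distract > 0) {
      cbind(signal, matrix(rnorm(n * m_distract), n, m_distract))
    } else {
      signal
    }
    if (noise_sd > 0) out <- out + matrix(rnorm(n * dim, 0, noise_sd), n, dim)
    out
  })
  new_embedding(X, sprintf("synthetic(dim=%d,ls=%g)", dim, length_scale), data$id)
}

#' Encoder handles
#'
#' `encoder_synthetic()` wraps [synthetic_encode()] parameters into a
#' reusable handle; `encoder_matrix()` wraps a precomputed embedding
#' matrix (or a path to one written by [write_embeddings()]);
#' `encoder_external()` registers a user function
#' (`function(prompt_set) -> matrix`) standing in for a real transformer
#' adapter. Pass any handle to [encode()].
#'
#' @param dim,length_scale,distractor_fraction,noise_sd,seed See
#'   [synthetic_encode()].
#' @return An encoder handle.
#' @export
encoder_synthetic <- function(dim = 256, length_scale = 5,
                              distractor_fraction = 0.25, noise_sd = 0.1,
                              seed = 1) {
  structure(
    list(type = "synthetic", dim = dim, length_scale = length_scale,
         distractor_fraction = distractor_fraction, noise_sd = noise_sd,
         seed = seed),
    class = "embedaudit_encoder"
  )
}

#' @rdname encoder_synthetic
#' @param x A numeric matrix with prompt ids as row names, or a path to a
#'   delimited embedding file.
#' @export
encoder_matrix <- function(x) {
  structure(list(type = "matrix", source = x), class = "embedaudit_encoder")
}

#' @rdname encoder_synthetic
#' @param fun A function taking a prompt set and returning an `n x dim`
#'   numeric matrix (rows in prompt order). `NULL` marks the adapter as
#'   unavailable, which raises a capability error at [encode()] time
#'   rather than silently falling back.
#' @param id Identifier recorded on the resulting embeddings.
#' @export
encoder_external <- function(fun = NULL, id = "external") {
  structure(list(type = "external", fun = fun, id = id),
            class = "embedaudit_encoder")
}

#' Encode a prompt set with a registered encoder
#'
#' Dispatches on the encoder handle and returns an embedding matrix whose
#' rows are aligned (and checked) against the prompt set's ids.
#'
#' @param prompt_set A prompt-set tibble.
#' @param encoder An encoder handle from [encoder_synthetic()],
#'   [encoder_matrix()] or [encoder_external()].
#' @return An embedding matrix with `encoder_id` recorded.
#' @export
encode <- function(prompt_set, encoder) {
  data <- validate_prompt_set(prompt_set)
  if (!inherits(encoder, "embedaudit_encoder")) {
    abort("Unknown encoder: pass a handle created by encoder_synthetic(), encoder_matrix() or encoder_external().",
          class = "embedaudit_error_config")
  }
  switch(
    encoder$type,
    synthetic = synthetic_encode(
      data, dim = encoder$dim, length_scale = encoder$length_scale,
      distractor_fraction = encoder$distractor_fraction,
      noise_sd = encoder$noise_sd, seed = encoder$seed
    ),
    matrix = {
      src <- encoder$source
      E <- if (is.character(src)) read_embeddings(src) else src
      if (is.null(rownames(E))) {
        stop_usage("Matrix encoders need prompt ids as row names.")
      }
      if (!identical(rownames(E), data$id)) {
        stop_usage("Embedding rows do not match the prompt set's ids (same ids, same order, required).")
      }
      new_embedding(unclass(E)[, , drop = FALSE],
                    if (is.character(src)) sprintf("file(%s)", basename(src)) else "matrix",
                    data$id)
    },
    external = {
      if (!is.function(encoder$fun)) {
        abort(
          "External encoder adapter is not available at runtime; supply `fun` or use the synthetic encoder.",
          class = "embedaudit_error_capability"
        )
      }
      E <- encoder$fun(data)
      if (!is.matrix(E) || nrow(E) != nrow(data)) {
        stop_usage("External encoder must return a matrix with one row per prompt.")
      }
      new_embedding(E, encoder$id, data$id)
    },
    abort(glue("Unknown encoder type '{encoder$type}'."),
          class = "embedaudit_error_config")
  )
}

#' Cosine similarity between embedding rows
#'
#' @param x An embedding matrix (or any numeric matrix).
#' @return An `n x n` cosine similarity matrix.
#' @export
cosine_similarity <- function(x) {
  x <- unclass(x)
  norms <- sqrt(rowSums(x^2))
  norms[norms == 0] <- 1
  tcrossprod(x / norms)
}

#' Write or read embeddings as delimited text
#'
#' Rows are prompts; the first column `id` holds the prompt identifier and
#' the remaining columns the embedding coordinates. A `.gz` suffix on the
#' path yields the compressed variant of the same container.
#'
#' @param embedding An embedding matrix with row names.
#' @param path Output/input path (TSV, optionally gzip-compressed).
#' @return `write_embeddings()` returns `path` invisibly;
#'   `read_embeddings()` returns an embedding matrix.
#' @export
write_embeddings <- function(embedding, path) {
  stopifnot(is.matrix(embedding) || inherits(embedding, "embedaudit_embedding"))
  m <- unclass(embedding)
  df <- as_tibble(as.data.frame(m), .name_repair = "minimal")
  names(df) <- sprintf("d%03d", seq_len(ncol(m)))
  df <- dplyr::bind_cols(tibble(id = rownames(m)), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"id" %in% names(df)) stop_format("Embedding file must have an `id` column.")
  m <- as.matrix(df[setdiff(names(df), "id")])
  new_embedding(m, sprintf("file(%s)", basename(path)), as.character(df$id))
}
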