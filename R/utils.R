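# Internal validation and seed-management helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_config(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_config(field, "must be a single positive number")
  as.numeric(x)
}

check_number <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_config(field, "must be a single finite number")
  as.numeric(x)
}

#' Derive a stage seed from a master seed
#'
#' All randomness in the package is routed through a deterministic seed tree:
#' every stage (and every replicate within a stage) derives its own seed from
#' the master seed, so stages can be rerun independently and a full pipeline
#' run is reproducible bit-for-bit from a single integer.
#'
#' The derivation is a multiplicative integer hash of
#' \code{(seed, stage label, index)} reduced modulo 2^31 - 1, so derived seeds
#' always fit in a 32-bit integer.
#'
#' @param seed master seed (single integer).
#' @param stage character stage label, e.g. \code{"crqa"}, \code{"loso"}.
#' @param index replicate index within the stage (default 0).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  seed <- check_count(seed, "seed", min = 0L)
  index <- check_count(index, "index", min = 0L)
  h <- (seed %% 2147483647) + 1
  for (ch in utf8ToInt(as.character(stage))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  h <- (h * 2654435761 + index * 97 + 1) %% 2147483647
  as.integer(h)
}

# Evaluate expr with a locally set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
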