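# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a local RNG seed
#'
#' Runs `code` with the RNG seeded at `seed` and restores the caller's RNG
#' state afterwards, so seeded operations never perturb the global stream.
#' A `NULL` seed leaves the RNG untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# seed fan-out: derive a stage seed < 2^31 from a master seed and a stage tag
derive_seed <- function(master, tag) {
  if (is.null(master)) return(NULL)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(master) * 7919 + h) %% 2147483629L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
    all(abs(x - round(x)) < 1e-8)
}
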