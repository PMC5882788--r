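# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded operations do not disturb the
#' caller's RNG stream.  A `NULL` seed evaluates the expression as-is.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a run-level seed and a string key
#'
#' Stable (platform-independent) hash of the key folded into the parent seed,
#' kept below 2^31 so it is always a valid R integer seed.  Used to give every
#' taxon / gradient / stage its own reproducible RNG stream.
#'
#' @param seed parent integer seed.
#' @param key character scalar (e.g. a taxon id) or integer offset.
#' @return integer seed in `[0, 2^31 - 1]`.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, key) {
  if (is.null(seed)) return(NULL)
  h <- 0
  if (is.character(key)) {
    for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483647
  } else {
    h <- as.numeric(key) %% 2147483647
  }
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

assert_scalar_in <- function(x, lo, hi, name = deparse(substitute(x))) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < lo) || any(x > hi))
    stop(sprintf("`%s` must be numeric in [%g, %g]", name, lo, hi), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
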