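#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, restoring the caller's
#' RNG state afterwards so seeded helpers never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a named substream seed from a master seed
#'
#' One master seed deterministically spawns independent named substreams
#' (e.g. "trials", "population", "choices", "cortisol") so each simulation
#' component can be regenerated on its own. Result is always in
#' `[0, .Machine$integer.max)`.
#'
#' @param seed master integer seed.
#' @param name substream name.
#' @return integer seed for the substream.
#' @export
#' @examples
#' substream_seed(42, "trials")
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.double(seed) * 48271 + h * 7919) %% (.Machine$integer.max - 1))
}

## internal: the three value-parameter names, in canonical order
.par_names <- c("rho", "lam", "mu")

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
}
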