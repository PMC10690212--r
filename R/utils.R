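# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Draw n iteration seeds below .Machine$integer.max, deterministically from a
# master seed. Used so subsampling / CV iterations can be re-run in isolation.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

# Unit L2 normalization; zero vectors pass through unchanged.
unit_l2 <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv > 0) v / nv else v
}

# Deterministic sign convention: flip v so that its largest-|entry| coordinate
# is positive (ties broken by lowest index, which.max's behaviour).
canonical_sign <- function(v) {
  if (all(v == 0)) return(v)
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

msg <- function(...) message("[moccanet] ", sprintf(...))

stop2 <- function(...) stop(sprintf(...), call. = FALSE)

warn2 <- function(...) warning(sprintf(...), call. = FALSE)
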