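# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds, evaluates, restores. All stochastic
#' functions in the package route their `seed` argument through this so that
#' calls are reproducible without clobbering the session RNG.
#'
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Derive a child seed from a parent seed and a stream label, kept < 2^31.
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + sum(utf8ToInt(stream))) %% 2147483579
}

#' Add-one permutation p-value
#'
#' `(1 + #{null >= observed}) / (1 + B)` — never exactly zero, matching the
#' usual recommendation for Monte-Carlo tests.
#'
#' @param observed observed statistic (scalar).
#' @param null numeric vector of null draws.
#' @keywords internal
perm_pvalue <- function(observed, null) {
  (1 + sum(null >= observed)) / (1 + length(null))
}

# Inverse of the trigamma function by Newton iteration on 1/trigamma,
# which is nearly linear; converges in a handful of steps.
trigamma_inverse <- function(y) {
  out <- y
  ok <- is.finite(y) & y > 0
  out[!ok] <- NA_real_
  hi <- ok & y > 1e7
  out[hi] <- 1 / sqrt(y[hi])
  lo <- ok & y < 1e-6
  out[lo] <- 1 / y[lo]
  mid <- ok & !hi & !lo
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (max(abs(dif / x)) < 1e-10) break
    }
    out[mid] <- x
  }
  out
}

# stopifnot with a formatted message
assert_that <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
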