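# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so seeded internals never disturb the
#' caller's random stream. All stochastic operations in the package route
#' through this.
#'
#' @param seed integer seed, or NULL to leave the stream untouched.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
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

# Derive a reproducible vector of sub-seeds from a master seed, each < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Population (1/N) standard deviation.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# Row-wise z-scoring with population sd; errors on constant rows.
zscore_rows <- function(m) {
  t(apply(m, 1L, function(x) {
    s <- pop_sd(x)
    if (s == 0) stop("cannot z-score a constant map")
    (x - mean(x)) / s
  }))
}

# round-half-up to integer (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
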