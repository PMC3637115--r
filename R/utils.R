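#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the current RNG stream" (no save/restore).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Truncated-normal sampler by inverse-CDF; exact for the one-sided and
# two-sided truncations used here (no rejection loop, reproducible draw count).
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) stop("sd must be >= 0")
  if (lower >= upper) stop("lower bound must be below upper bound")
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop("degenerate distribution (sd = 0) with mean outside bounds")
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

clip255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
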