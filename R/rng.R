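# Named random-number streams.
#
# Every stochastic sub-generator draws under a seed derived from the master
# seed and a stream name, so adding or reordering a stream never perturbs the
# draws of another (e.g. applying missingness does not change the simulated
# outcomes).

#' Derive a stream seed from a master seed and a stream name
#'
#' Deterministic 31-bit hash mixing the stream name into the master seed
#' (FNV-style over the name's bytes, then combined with the seed by a
#' Knuth multiplicative step). Stable across platforms and R versions.
#'
#' @param seed integer master seed.
#' @param stream character stream name.
#' @return a non-negative integer below 2^31 - 1.
#' @export
stream_seed <- function(seed, stream) {
  stopifnot(length(stream) == 1L, is.character(stream))
  m <- 2147483647
  h <- 2166136261 %% m
  for (b in utf8ToInt(stream)) h <- (h * 127 + b) %% m
  as.integer((h + (as.numeric(seed) %% m) * 2654435761) %% m)
}

# Run `expr` under the stream's seed, restoring the caller's RNG state.
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(stream_seed(seed, stream))
  expr
}

# Truncated-normal helpers -------------------------------------------------

# Mean of N(mu, sd^2) truncated to [lower, upper].
truncnorm_mean <- function(mu, sd, lower, upper) {
  a <- (lower - mu) / sd
  b <- (upper - mu) / sd
  za <- pnorm(a); zb <- pnorm(b)
  mu + sd * (dnorm(a) - dnorm(b)) / (zb - za)
}

# Solve for the pre-truncation mean mu such that the truncated mean equals
# `target`. Errors when the target is infeasible (at or outside the bounds).
solve_truncnorm_mu <- function(target, sd, lower, upper) {
  if (target <= lower || target >= upper)
    stop("target mean ", target, " infeasible for bounds [",
         lower, ", ", upper, "]")
  f <- function(mu) truncnorm_mean(mu, sd, lower, upper) - target
  stats::uniroot(f, lower = target - 8 * sd, upper = target + 8 * sd,
                 tol = 1e-10)$root
}

# Inverse-CDF sampler of N(mu, sd^2) truncated to [lower, upper].
rtruncnorm <- function(n, mu, sd, lower, upper) {
  pa <- pnorm(lower, mu, sd)
  pb <- pnorm(upper, mu, sd)
  if (pb - pa < 1e-12)
    stop("truncation bounds [", lower, ", ", upper,
         "] carry negligible mass under N(", mu, ", ", sd, "^2)")
  qnorm(pa + runif(n) * (pb - pa), mu, sd)
}
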