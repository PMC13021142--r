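## internal helpers shared across modules

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_finite_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite numeric, not %s.", name,
                  paste(utils::head(x, 3), collapse = ", ")),
          class = "vagusloop_input_error")
  }
  invisible(x)
}

## Fan a single user seed out to independent component streams. Offsets are
## fixed so adding a new stream never perturbs existing ones; the result stays
## inside the 32-bit integer range that set.seed() accepts.
derive_seed <- function(seed, stream) {
  offsets <- c(animal = 101L, anchors = 211L, trial = 307L,
               calibration = 401L, beats = 503L, misc = 601L)
  if (!stream %in% names(offsets)) {
    abort(sprintf("unknown seed stream '%s'", stream))
  }
  as.integer((as.double(seed) * 7919 + offsets[[stream]]) %% 2147483647)
}

## Evaluate expr under a temporary RNG seed without disturbing the caller's
## RNG state; seed = NULL leaves the current stream in place.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Mean of a Normal(mu, sd) truncated to [lo, hi] (closed form).
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- pnorm(b) - pnorm(a)
  mu + sd * (dnorm(a) - dnorm(b)) / z
}

## Location parameter mu such that Normal(mu, sd) truncated to [lo, hi] has
## the requested mean. The paper-reported population means are means of the
## observed (range-limited) samples, so the generator must match the mean of
## the truncated distribution, not of the untruncated parent.
truncnorm_match_mu <- function(target_mean, sd, lo, hi) {
  stopifnot(target_mean > lo, target_mean < hi)
  stats::uniroot(function(mu) truncnorm_mean(mu, sd, lo, hi) - target_mean,
                 interval = c(lo - 4 * sd, hi + 4 * sd), tol = 1e-10)$root
}

## Vectorised rejection sampler for the truncated normal.
rtruncnorm <- function(n, mu, sd, lo, hi) {
  out <- rnorm(n, mu, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mu, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}
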