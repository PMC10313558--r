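# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed errors so drivers (e.g. the voxel loop) can catch specific failures.
stop_ivim <- function(msg, class) {
  stop(structure(
    class = c(class, "ivimprog_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All stochastic operations in the package
# route through this so a master seed gives full reproducibility.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a stage-specific child seed from a master seed
#'
#' Deterministically maps a master seed and a stage label to a positive
#' 32-bit integer seed, so independent simulation stages (parameter draws,
#' survival times, noise) use decorrelated but reproducible streams.
#'
#' @param master Integer master seed.
#' @param stage Character stage label.
#' @return A positive integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  val <- ((abs(master) %% 1000003) * 2017 + h * 7919) %% 2147483562
  as.integer(val) + 1L
}

# Simple FNV-1a string hash, used to stamp run manifests with a config hash.
fnv1a <- function(text) {
  h <- 2166136261
  for (code in utf8ToInt(text)) {
    h <- bitwXor(as.integer(h %% 2^31), code)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Cache for deterministic calibration solves (truncated-normal parent
# parameters, event-time calibration); keyed by the numeric inputs, so
# repeated simulation with the same spec skips the optimisation.
.ivim_cache <- new.env(parent = emptyenv())

memo <- function(key, compute) {
  val <- .ivim_cache[[key]]
  if (is.null(val)) {
    val <- compute()
    .ivim_cache[[key]] <- val
  }
  val
}

# ---- truncated normal machinery (cohort simulation) -------------------------

# Mean and sd of N(mu, sigma^2) truncated to [lower, upper], closed form.
# One-sided truncation uses the log-scale hazard for tail stability; when a
# bounded interval is many sigma away from mu the distribution collapses
# onto the nearer endpoint, which is returned instead of 0/0.
truncnorm_moments <- function(mu, sigma, lower, upper) {
  if (is.infinite(upper)) {
    a <- (lower - mu) / sigma
    lam <- exp(dnorm(a, log = TRUE) -
                 pnorm(a, lower.tail = FALSE, log.p = TRUE))
    m <- mu + sigma * lam
    v <- sigma^2 * (1 + lam * (a - lam))
    return(list(mean = m, sd = sqrt(max(v, 0))))
  }
  # bounded support: integrate on a grid with log-weights re-centered at
  # their maximum, immune to tail underflow for any (mu, sigma)
  x <- seq(lower, upper, length.out = 2001L)
  lw <- dnorm(x, mu, sigma, log = TRUE)
  w <- exp(lw - max(lw))
  W <- sum(w)
  m <- sum(w * x) / W
  v <- sum(w * (x - m)^2) / W
  list(mean = m, sd = sqrt(max(v, 0)))
}

# Inverse-CDF sampler working on upper-tail log-probabilities, so draws
# stay finite even when the support sits many sigma from mu.
rtruncnorm <- function(n, mu, sigma, lower = -Inf, upper = Inf) {
  if (sigma <= 0) return(rep(min(max(mu, lower), upper), n))
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  pmin(pmax(mu + sigma * rtrunc_std(n, a, b), lower), upper)
}

# Standard-normal sampler on [a, b]; reflected so the interval lies toward
# the upper tail, where log-scale tail probabilities are accurate.
rtrunc_std <- function(n, a, b) {
  reflect <- is.finite(b) && (!is.finite(a) || a + b < 0)
  if (reflect) {
    tmp <- a
    a <- -b
    b <- -tmp
  }
  la <- pnorm(a, lower.tail = FALSE, log.p = TRUE)  # log P(Z > a), larger
  lb <- pnorm(b, lower.tail = FALSE, log.p = TRUE)
  u <- runif(n)
  lp <- la + log1p(-u * (1 - exp(lb - la)))
  z <- qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  if (reflect) -z else z
}

# Find (mu, sigma) of the parent normal so the truncated distribution has
# mean exactly `m` and sd as close to `s` as the family permits on the given
# support. The truncated mean is strictly increasing in mu, so for every
# sigma there is a unique mean-matching mu (root-finding); sigma is then
# chosen by 1-D optimisation of the sd mismatch. Printed-table targets whose
# sd exceeds the family's attainable maximum (e.g. sd/mean > 1 with a lower
# bound at 0) keep an exact mean and the closest achievable sd.
solve_truncnorm <- function(m, s, lower = -Inf, upper = Inf) {
  if (!(m > lower && m < upper))
    stop_ivim(sprintf("target mean %g outside truncation bounds (%g, %g)",
                      m, lower, upper), "ivimprog_infeasible_truncation")
  if (s <= 0) return(list(mu = m, sigma = 0, mean = m, sd = 0))
  mu_for_mean <- function(sigma) {
    f <- function(mu) truncnorm_moments(mu, sigma, lower, upper)$mean - m
    span <- 10 * (sigma + s + abs(m) + 1)
    lo <- m - span
    hi <- m + span
    for (i in 1:60) {  # doubling expansion; mu can need to scale as sigma^2
      if (is.finite(f(lo)) && f(lo) < 0) break
      lo <- lo - span
      span <- span * 2
    }
    span <- 10 * (sigma + s + abs(m) + 1)
    for (i in 1:60) {
      if (is.finite(f(hi)) && f(hi) > 0) break
      hi <- hi + span
      span <- span * 2
    }
    uniroot(f, c(lo, hi), tol = 1e-12)$root
  }
  obj <- function(logsig) {
    sigma <- exp(logsig)
    mu <- mu_for_mean(sigma)
    (truncnorm_moments(mu, sigma, lower, upper)$sd - s)^2
  }
  opt <- optimize(obj, interval = log(c(s / 100, 100 * (s + abs(m) + 1))),
                  tol = 1e-12)
  sigma <- exp(opt$minimum)
  mu <- mu_for_mean(sigma)
  mom <- truncnorm_moments(mu, sigma, lower, upper)
  list(mu = mu, sigma = sigma, mean = mom$mean, sd = mom$sd)
}
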