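# Moment utilities and sampling for (singly or doubly) truncated normal
# distributions. Used by the synthetic cohort generator, which matches the
# published cohort mean/SD on the truncated scale, not the parent scale.

tn_phi_terms <- function(mu, sigma, a, b) {
  alpha <- (a - mu) / sigma
  beta <- (b - mu) / sigma
  # work with upper-tail probabilities: stable when the kept region is a
  # far upper tail of the parent (strong lower truncation)
  qa <- stats::pnorm(alpha, lower.tail = FALSE)
  qb <- if (is.finite(b)) stats::pnorm(beta, lower.tail = FALSE) else 0
  da <- stats::dnorm(alpha)
  db <- if (is.finite(b)) stats::dnorm(beta) else 0
  adb <- if (is.finite(b)) beta * db else 0
  ada <- if (is.finite(a)) alpha * da else 0
  z <- qa - qb
  list(z = z, da = da, db = db, ada = ada, adb = adb)
}

tn_mean <- function(mu, sigma, a, b) {
  t <- tn_phi_terms(mu, sigma, a, b)
  mu + sigma * (t$da - t$db) / t$z
}

tn_sd <- function(mu, sigma, a, b) {
  t <- tn_phi_terms(mu, sigma, a, b)
  r <- (t$da - t$db) / t$z
  v <- sigma^2 * (1 + (t$ada - t$adb) / t$z - r^2)
  sqrt(max(v, 0))
}

# Find parent (mu, sigma) so that the truncated distribution on [a, b] has
# the target mean exactly and an SD as close as possible to `sd`. A normal
# truncated from below cannot exceed a coefficient of variation of 1
# (exponential limit), so for targets beyond that bound the closest
# attainable SD is returned; the mean always matches.
tn_match_moments <- function(mean, sd, a = -Inf, b = Inf) {
  stopifnot(sd > 0, mean > a, mean < b)
  mu_for_sigma <- function(sigma) {
    f <- function(mu) tn_mean(mu, sigma, a, b) - mean
    lo <- mean - sigma
    while (f(lo) > 0 && lo > mean - 60 * sigma) lo <- lo - 2 * sigma
    hi <- mean + sigma
    while (f(hi) < 0 && hi < mean + 60 * sigma) hi <- hi + 2 * sigma
    stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  }
  sd_gap <- function(sigma) tn_sd(mu_for_sigma(sigma), sigma, a, b) - sd
  lo <- sd / 10
  hi <- sd * 10
  glo <- sd_gap(lo)
  ghi <- sd_gap(hi)
  sigma <- if (glo * ghi <= 0) {
    stats::uniroot(sd_gap, c(lo, hi), tol = 1e-9)$root
  } else if (abs(glo) < abs(ghi)) lo else hi
  list(mu = mu_for_sigma(sigma), sigma = sigma)
}

# Inverse-CDF sampler, parameterized through whichever tail of the parent
# is smaller so that extreme truncation keeps full double precision.
# `u` may be supplied (Gaussian-copula coupling of attributes).
tn_sample <- function(n, mu, sigma, a = -Inf, b = Inf, u = stats::runif(n)) {
  pa_lower <- if (is.finite(a)) stats::pnorm(a, mu, sigma) else 0
  if (pa_lower < 0.5) {
    pb <- if (is.finite(b)) stats::pnorm(b, mu, sigma) else 1
    stats::qnorm(pa_lower + u * (pb - pa_lower), mu, sigma)
  } else {
    qa <- stats::pnorm(a, mu, sigma, lower.tail = FALSE)
    qb <- if (is.finite(b)) stats::pnorm(b, mu, sigma, lower.tail = FALSE) else 0
    stats::qnorm(qb + u * (qa - qb), mu, sigma, lower.tail = FALSE)
  }
}

# One draw call: n values from the truncated normal whose truncated-scale
# moments match (mean, sd) as far as the family allows.
rtrunc_matched <- function(n, mean, sd, a = -Inf, b = Inf,
                           u = stats::runif(n)) {
  par <- tn_match_moments(mean, sd, a, b)
  tn_sample(n, par$mu, par$sigma, a, b, u)
}
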