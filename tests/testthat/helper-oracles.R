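# Independent oracles, deliberately coded without reusing package internals.

# Beta-binomial log marginal likelihood by numerical integration over the
# study-level probability, one arm at a time.
oracle_log_marglik <- function(mu, M, arms) {
  a <- mu * M
  b <- (1 - mu) * M
  per_arm <- function(x, n) {
    coef <- exp(lgamma(n + 1) - lgamma(x + 1) - lgamma(n - x + 1))
    f <- function(p) {
      coef * p^x * (1 - p)^(n - x) * stats::dbeta(p, a, b)
    }
    log(stats::integrate(f, 0, 1, rel.tol = 1e-12)$value)
  }
  sum(mapply(per_arm, arms$successes, arms$n))
}

# Posterior median of mu by 2-D grid integration over (mu, s) with
# s = 1/(1+M) uniform, matching the sampler's prior.
oracle_posterior_median_mu <- function(arms, n_mu = 300, n_s = 120) {
  mu <- (seq_len(n_mu) - 0.5) / n_mu
  s <- (seq_len(n_s) - 0.5) / n_s
  M <- 1 / s - 1
  ll <- outer(seq_along(mu), seq_along(M), Vectorize(function(i, j) {
    oracle_log_marglik(mu[i], M[j], arms)
  }))
  w <- exp(ll - max(ll))
  marg <- rowSums(w)
  cdf <- cumsum(marg) / sum(marg)
  stats::approx(cdf, mu, xout = 0.5, ties = "ordered")$y
}

# Constraint checker independent of satisfies_constraints().
oracle_satisfies <- function(u, system) {
  ok <- rep(TRUE, nrow(u))
  for (i in seq_len(nrow(system$edges))) {
    ok <- ok & (u[, system$edges$worse[i]] < u[, system$edges$better[i]])
  }
  nonlethal <- setdiff(system$classes, system$lethal)
  if (length(system$lethal) && length(nonlethal)) {
    mins <- apply(u[, nonlethal, drop = FALSE], 1, min)
    maxs <- apply(u[, system$lethal, drop = FALSE], 1, max)
    ok <- ok & (mins >= maxs + system$delta)
  }
  ok
}

# Plain rejection sampling from the uniform distribution on the polytope.
oracle_rejection_sample <- function(system, n, batch = 2e5, max_batches = 200) {
  k <- length(system$classes)
  rows <- list()
  got <- 0L
  for (i in seq_len(max_batches)) {
    u <- matrix(runif(batch * k), batch, k,
                dimnames = list(NULL, system$classes))
    keep <- u[oracle_satisfies(u, system), , drop = FALSE]
    rows[[i]] <- keep
    got <- got + nrow(keep)
    if (got >= n) break
  }
  out <- do.call(rbind, rows)
  stopifnot(nrow(out) >= n)
  out[seq_len(n), , drop = FALSE]
}

# Brute-force argmax preference counting with equal tie splits.
oracle_preference_rates <- function(eu) {
  counts <- numeric(ncol(eu))
  for (i in seq_len(nrow(eu))) {
    top <- which(eu[i, ] == max(eu[i, ]))
    counts[top] <- counts[top] + 1 / length(top)
  }
  setNames(counts / nrow(eu), colnames(eu))
}
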