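#' Log marginal likelihood of the hierarchical beta-binomial model
#'
#' Each study arm has its own improvement probability drawn from
#' `Beta(mu * M, (1 - mu) * M)`; arm counts are binomial given that
#' probability. Integrating the study-level probability out gives, per arm,
#' the beta-binomial marginal
#' `C(n, x) * B(alpha + x, beta + n - x) / B(alpha, beta)` with
#' `alpha = mu * M`, `beta = (1 - mu) * M`. All Beta and binomial-coefficient
#' terms are evaluated through `lgamma` so fractional success counts (39.25
#' of 94; 9.2 of 13) are valid.
#'
#' @param mu Population mean improvement probability, in `(0, 1)`.
#' @param M Concentration (prior sample size), positive.
#' @param arms A data frame of study arms with columns `successes` and `n`.
#' @return The summed log marginal likelihood over arms.
#' @export
#' @examples
#' log_marginal_likelihood(0.3, 2, tibble::tibble(successes = 0, n = 1))
#' # log(0.7): one failure has marginal probability beta / (alpha + beta)
log_marginal_likelihood <- function(mu, M, arms) {
  stopifnot(length(mu) == 1L, length(M) == 1L)
  if (mu <= 0 || mu >= 1 || M <= 0) return(-Inf)
  if (!is.data.frame(arms) || nrow(arms) == 0L) abort("arms must be a non-empty data frame")
  x <- arms$successes
  n <- arms$n
  if (any(n <= 0) || any(x < 0) || any(x > n)) {
    abort("study arms must satisfy n > 0 and 0 <= successes <= n")
  }
  a <- mu * M
  b <- (1 - mu) * M
  lcoef <- lgamma(n + 1) - lgamma(x + 1) - lgamma(n - x + 1)
  sum(lcoef + lbeta(a + x, b + n - x) - lbeta(a, b))
}

# Log posterior on the sampling scale theta = (logit mu, log M).
# Prior: mu uniform on (0,1); 1/(1+M) uniform on (0,1), i.e. p(M) = (1+M)^-2.
# The Jacobian of (mu, M) -> theta contributes mu(1-mu) * M.
log_posterior_theta <- function(theta, arms) {
  mu <- stats::plogis(theta[1])
  M <- exp(theta[2])
  log_marginal_likelihood(mu, M, arms) -
    2 * log1p(M) + log(mu) + log(1 - mu) + log(M)
}

#' Fit the hierarchical beta-binomial model by Metropolis-Hastings
#'
#' Random-walk Metropolis-Hastings on `(logit mu, log M)` targeting the
#' posterior under a weakly-informative prior: `mu` uniform on `(0, 1)` and
#' `1 / (1 + M)` uniform on `(0, 1)` (so `p(M)` is proportional to
#' `(1 + M)^-2`). Gaussian proposal steps, independent per coordinate, with
#' scales chosen so that acceptance falls in the 20-50 % range on the
#' packaged study-arm tables.
#'
#' @param arms Study arms (columns `successes`, `n`); typically one
#'   alternative's rows of [effectiveness_arms()] or [nonserious_arms()].
#' @param n_iter Total chain length (default 55000).
#' @param burn_in Discarded initial iterations (default 5000).
#' @param seed Optional integer seed for the chain's random stream.
#' @param proposal_scale Standard deviations of the Gaussian steps on
#'   `(logit mu, log M)`.
#' @return An object of class `betabin_fit`: post-burn-in draws of `mu` and
#'   `M`, the acceptance rate, and the sampler settings.
#' @export
#' @examples
#' arms <- tibble::tibble(successes = c(5, 7), n = c(10, 12))
#' fit <- fit_beta_binomial(arms, n_iter = 2000, burn_in = 500, seed = 1)
#' median(posterior_draws(fit))
fit_beta_binomial <- function(arms, n_iter = 55000, burn_in = 5000,
                              seed = NULL, proposal_scale = c(0.6, 1.4)) {
  stopifnot(n_iter > burn_in, burn_in >= 0, all(proposal_scale > 0))
  if (!is.data.frame(arms) || nrow(arms) == 0L) {
    abort("arms must be a non-empty data frame")
  }
  if (any(arms$n <= 0) || any(arms$successes < 0) ||
      any(arms$successes > arms$n)) {
    abort("study arms must satisfy n > 0 and 0 <= successes <= n")
  }
  if (!is.null(seed)) set.seed(seed)
  crude <- sum(arms$successes) / sum(arms$n)
  crude <- min(max(crude, 0.02), 0.98)
  theta <- c(stats::qlogis(crude), log(10))
  lp <- log_posterior_theta(theta, arms)
  if (!is.finite(lp)) abort("log-posterior not finite at the starting point")

  draws <- matrix(NA_real_, n_iter, 2L)
  steps <- matrix(stats::rnorm(2L * n_iter, 0, proposal_scale),
                  nrow = 2L)  # column i = proposal step of iteration i
  log_u <- log(runif(n_iter))
  accept <- 0L
  for (i in seq_len(n_iter)) {
    prop <- theta + steps[, i]
    lp_prop <- log_posterior_theta(prop, arms)
    if (lp_prop - lp > log_u[i]) {
      theta <- prop
      lp <- lp_prop
      accept <- accept + 1L
    }
    draws[i, ] <- theta
  }
  kept <- draws[(burn_in + 1L):n_iter, , drop = FALSE]
  structure(
    list(
      draws = tibble::tibble(mu = stats::plogis(kept[, 1]),
                             M = exp(kept[, 2])),
      acceptance_rate = accept / n_iter,
      n_iter = n_iter, burn_in = burn_in, seed = seed,
      proposal_scale = proposal_scale,
      arms = tibble::as_tibble(arms)
    ),
    class = "betabin_fit"
  )
}

#' Posterior draws of the population mean
#'
#' The per-iteration probability values fed to the evaluation stage: the
#' posterior draws of the population mean `mu` (the assessment targets a
#' representative patient of the population, not a new study).
#'
#' @param fit A `betabin_fit`.
#' @return Numeric vector of draws in `(0, 1)`.
#' @export
posterior_draws <- function(fit) {
  stopifnot(inherits(fit, "betabin_fit"))
  fit$draws$mu
}

#' @export
print.betabin_fit <- function(x, ...) {
  cat(sprintf(
    "Hierarchical beta-binomial fit: %d arms, %d draws (burn-in %d), acceptance %.1f%%\n",
    nrow(x$arms), nrow(x$draws), x$burn_in, 100 * x$acceptance_rate))
  cat(sprintf("posterior median mu = %.3f, M = %.1f\n",
              median(x$draws$mu), median(x$draws$M)))
  invisible(x)
}

#' @export
tidy.betabin_fit <- function(x, conf_level = 0.95, ...) {
  lo <- (1 - conf_level) / 2
  purrr::map_dfr(c("mu", "M"), function(p) {
    d <- x$draws[[p]]
    tibble::tibble(term = p, estimate = median(d),
                   conf.low = quantile(d, lo, names = FALSE),
                   conf.high = quantile(d, 1 - lo, names = FALSE))
  })
}

#' @export
glance.betabin_fit <- function(x, ...) {
  tibble::tibble(
    n_arms = nrow(x$arms), n_patients = sum(x$arms$n),
    n_draws = nrow(x$draws), acceptance_rate = x$acceptance_rate,
    mu_median = median(x$draws$mu), M_median = median(x$draws$M)
  )
}

#' Interpolated low-dose non-serious risk
#'
#' The trials give too little information to estimate the non-serious
#' adverse-event risk of low-dose methylprednisolone directly, so it is
#' assumed to lie between the placebo and high-dose risks: each value is
#' sampled uniformly on the interval formed by one paired placebo draw and
#' one paired high-dose draw.
#'
#' @param placebo_draws,high_draws Equal-length vectors of paired posterior
#'   draws.
#' @param seed Optional integer seed.
#' @return A vector of the same length, elementwise uniform on
#'   `[min(a, b), max(a, b)]`.
#' @export
interpolate_low_dose <- function(placebo_draws, high_draws, seed = NULL) {
  if (length(placebo_draws) != length(high_draws)) {
    abort("paired draw vectors must have equal length")
  }
  if (!is.null(seed)) set.seed(seed)
  lo <- pmin(placebo_draws, high_draws)
  hi <- pmax(placebo_draws, high_draws)
  lo + (hi - lo) * runif(length(lo))
}
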