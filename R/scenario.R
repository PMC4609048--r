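#' Fit all five posterior inputs of the evaluation
#'
#' Convenience wrapper fitting the hierarchical beta-binomial model to each
#' alternative's effectiveness arms (high dose, low dose, placebo) and to
#' the non-serious adverse-event arms (high dose, placebo). Placebo arms
#' act as the proxy for the no-treatment alternative; the low-dose
#' non-serious risk is interpolated later from the placebo and high-dose
#' draws. Each fit gets its own named seed stream derived from the master
#' seed.
#'
#' @param seed Master seed.
#' @param n_iter,burn_in Chain settings passed to [fit_beta_binomial()].
#' @return Named list of `betabin_fit` objects: `eff_high`, `eff_low`,
#'   `eff_placebo`, `ns_high`, `ns_placebo`.
#' @export
fit_all_posteriors <- function(seed = 1, n_iter = 55000, burn_in = 5000) {
  eff <- effectiveness_arms()
  ns <- nonserious_arms()
  fit_one <- function(arms, stream) {
    fit_beta_binomial(arms, n_iter = n_iter, burn_in = burn_in,
                      seed = derive_seed(seed, stream))
  }
  list(
    eff_high = fit_one(eff[eff$alternative == "HIGH_DOSE", ], "fit-effectiveness-high"),
    eff_low = fit_one(eff[eff$alternative == "LOW_DOSE", ], "fit-effectiveness-low"),
    eff_placebo = fit_one(eff[eff$alternative == "PLACEBO", ], "fit-effectiveness-placebo"),
    ns_high = fit_one(ns[ns$alternative == "HIGH_DOSE", ], "fit-nonserious-high"),
    ns_placebo = fit_one(ns[ns$alternative == "PLACEBO", ], "fit-nonserious-placebo")
  )
}

as_draw_vector <- function(x) {
  if (inherits(x, "betabin_fit")) posterior_draws(x) else as.numeric(x)
}

# n x k serious-risk matrix for one alternative, columns in `limits` order
sample_risk_matrix <- function(limits_vec, n, family, k_rate) {
  vapply(limits_vec,
         function(L) sample_serious_risk(L, n, family = family, k = k_rate),
         numeric(n))
}

#' Run one probabilistic evaluation scenario
#'
#' Executes the full Monte-Carlo evaluation for one scenario: per
#' iteration, effectiveness and non-serious-risk values are taken from
#' paired posterior draws (pairing across alternatives by iteration
#' index); serious risks are sampled independently per effect-outcome
#' combination and per active alternative from the configured interval
#' distribution, with the no-treatment value derived as the background
#' share of the low/high average; one utility vector is drawn from the
#' constraint polytope; and the expected utility of each alternative is
#' the probability-weighted sum of outcome utilities in the shared
#' decision tree. No-treatment effectiveness and non-serious risk use the
#' placebo posterior.
#'
#' @param posteriors A list as returned by [fit_all_posteriors()] (fits or
#'   raw draw vectors).
#' @param config A [scenario_config()].
#' @param limits Effective risk limits, as [effective_risk_limits()].
#' @param tree Decision tree; defaults to the packaged specification.
#' @param resample Allow sampling posterior draws with replacement when
#'   fewer draws than iterations are available.
#' @return An object of class `msbr_scenario`: `eu` (iterations x 3 matrix
#'   of expected utilities), `preference_rates`, the full draw streams,
#'   the config, tree and per-stage seeds.
#' @export
run_scenario <- function(posteriors, config = scenario_config(),
                         limits = effective_risk_limits(),
                         tree = build_decision_tree(adverse_effect_specs()),
                         resample = FALSE) {
  stopifnot(inherits(config, "scenario_config"), inherits(tree, "msbr_tree"))
  n <- config$iterations
  streams <- purrr::map(posteriors[c("eff_high", "eff_low", "eff_placebo",
                                     "ns_high", "ns_placebo")],
                        as_draw_vector)
  if (any(purrr::map_lgl(streams, is.null))) {
    abort("posteriors must contain eff_high, eff_low, eff_placebo, ns_high, ns_placebo")
  }
  n_avail <- min(lengths(streams))
  if (n > n_avail && !resample) {
    abort(sprintf(
      "%d iterations requested but only %d posterior draws available (set resample = TRUE to recycle)",
      n, n_avail))
  }

  # align the limit rows with the tree's serious-combination order
  serious <- tree[tree$branch == "SERIOUS" & tree$benefit == "REDUCED", ]
  key <- paste(serious$effect, serious$outcome, sep = "/")
  lim <- limits[match(key, paste(limits$effect, limits$outcome, sep = "/")), ]
  if (anyNA(lim$limit_low)) abort("risk limits missing for some tree combinations")

  seeds <- list(
    draws = derive_seed(config$seed, "draws"),
    lowdose = derive_seed(config$seed, "lowdose"),
    risks = derive_seed(config$seed, "risks"),
    utilities = derive_seed(config$seed, "utilities")
  )

  set.seed(seeds$draws)
  idx <- sample.int(n_avail, n, replace = n > n_avail)
  e <- list(HIGH_DOSE = streams$eff_high[idx],
            LOW_DOSE = streams$eff_low[idx],
            NO_TREATMENT = streams$eff_placebo[idx])
  r_high <- streams$ns_high[idx]
  r_placebo <- streams$ns_placebo[idx]
  r <- list(HIGH_DOSE = r_high,
            LOW_DOSE = interpolate_low_dose(r_placebo, r_high,
                                            seed = seeds$lowdose),
            NO_TREATMENT = r_placebo)

  set.seed(seeds$risks)
  q <- list()
  q$LOW_DOSE <- sample_risk_matrix(lim$limit_low, n, config$risk_family, config$k)
  q$HIGH_DOSE <- sample_risk_matrix(lim$limit_high, n, config$risk_family, config$k)
  q$NO_TREATMENT <- background_risk(q$LOW_DOSE, q$HIGH_DOSE,
                                    config$background_proportion)
  q <- q[ALTERNATIVES]
  q <- purrr::map(q, function(m) {
    colnames(m) <- key
    m
  })

  utilities <- sample_utilities(
    build_utility_constraints(config$edss, config$min_utility_difference),
    n, seed = seeds$utilities
  )

  draws <- list(e = e, r = r, q = q, u = utilities$values)
  result <- evaluate_draws(tree, draws)
  structure(
    list(eu = result$eu, preference_rates = result$preference_rates,
         draws = draws, config = config, tree = tree, seeds = seeds,
         fixed = character(0)),
    class = "msbr_scenario"
  )
}

# Expected utilities and preference rates from assembled draw streams.
evaluate_draws <- function(tree, draws) {
  u56 <- draws$u[, tree$utility_class, drop = FALSE]
  eu <- vapply(ALTERNATIVES, function(a) {
    p <- outcome_probability_matrix(draws$e[[a]], draws$r[[a]], draws$q[[a]])
    rowSums(p * u56)
  }, numeric(nrow(draws$u)))
  list(eu = eu, preference_rates = preference_rates(eu))
}

#' Preference rates from expected-utility draws
#'
#' The preference rate of an alternative is the fraction of Monte-Carlo
#' iterations in which it attains the highest expected utility. Exact ties
#' are split equally among the tied alternatives, so the rates always sum
#' to one.
#'
#' @param eu An iterations x alternatives numeric matrix (or data frame)
#'   of expected utilities.
#' @return Named numeric vector of rates summing to 1.
#' @export
preference_rates <- function(eu) {
  eu <- as.matrix(eu)
  stopifnot(nrow(eu) >= 1)
  top <- apply(eu, 1, max)
  is_top <- eu == top
  weights <- is_top / rowSums(is_top)
  colSums(weights) / nrow(eu)
}

#' Per-iteration expected-utility differences for one alternative
#'
#' For each iteration, the difference between the alternative's expected
#' utility and the maximum expected utility of the other alternatives. The
#' fraction of positive differences equals the alternative's preference
#' rate (up to the equal-split handling of exact ties).
#'
#' @param eu An iterations x alternatives matrix of expected utilities.
#' @param alternative Column name or index.
#' @return Numeric vector of differences.
#' @export
eu_differences <- function(eu, alternative) {
  eu <- as.matrix(eu)
  if (is.character(alternative)) {
    alternative <- match(alternative, colnames(eu))
  }
  stopifnot(!is.na(alternative), length(alternative) == 1L)
  others <- eu[, -alternative, drop = FALSE]
  eu[, alternative] - apply(others, 1, max)
}

#' Median-fixation uncertainty attribution
#'
#' Re-evaluates a completed scenario with selected draw streams replaced
#' by their per-variable medians, leaving all other draws untouched. This
#' removes the sampling uncertainty of the fixed variables, revealing how
#' much of the spread in preference rates they account for.
#'
#' @param scenario A completed `msbr_scenario`.
#' @param what `"probabilities"` (all effectiveness, non-serious and
#'   serious-risk streams), `"utilities"`, `"all"`, or any subset of
#'   `c("effectiveness", "nonserious", "serious", "utilities")`.
#' @return A new `msbr_scenario` evaluated on the partially fixed draws.
#' @export
fix_variables <- function(scenario,
                          what = c("probabilities", "utilities", "all")) {
  stopifnot(inherits(scenario, "msbr_scenario"))
  groups <- c("effectiveness", "nonserious", "serious", "utilities")
  if (length(what) == 1L && what %in% c("probabilities", "utilities", "all")) {
    what <- switch(what,
                   probabilities = c("effectiveness", "nonserious", "serious"),
                   utilities = "utilities",
                   all = groups)
  }
  if (any(!what %in% groups)) {
    abort(paste0("unknown variable class: ",
                 paste(setdiff(what, groups), collapse = ", ")))
  }
  draws <- scenario$draws
  fix_vec <- function(v) rep(median(v), length(v))
  fix_mat <- function(m) {
    med <- apply(m, 2, median)
    matrix(med, nrow(m), ncol(m), byrow = TRUE,
           dimnames = dimnames(m))
  }
  if ("effectiveness" %in% what) draws$e <- purrr::map(draws$e, fix_vec)
  if ("nonserious" %in% what) draws$r <- purrr::map(draws$r, fix_vec)
  if ("serious" %in% what) draws$q <- purrr::map(draws$q, fix_mat)
  if ("utilities" %in% what) draws$u <- fix_mat(draws$u)
  result <- evaluate_draws(scenario$tree, draws)
  structure(
    list(eu = result$eu, preference_rates = result$preference_rates,
         draws = draws, config = scenario$config, tree = scenario$tree,
         seeds = scenario$seeds, fixed = sort(unique(c(scenario$fixed, what)))),
    class = "msbr_scenario"
  )
}

#' @export
print.msbr_scenario <- function(x, ...) {
  print(x$config)
  if (length(x$fixed)) {
    cat("fixed at medians:", paste(x$fixed, collapse = ", "), "\n")
  }
  cat("preference rates:\n")
  print(round(x$preference_rates, 3))
  invisible(x)
}

#' @export
tidy.msbr_scenario <- function(x, ...) {
  tibble::tibble(
    alternative = colnames(x$eu),
    preference_rate = unname(x$preference_rates[colnames(x$eu)]),
    eu_median = apply(x$eu, 2, median),
    eu_q025 = apply(x$eu, 2, quantile, 0.025, names = FALSE),
    eu_q975 = apply(x$eu, 2, quantile, 0.975, names = FALSE)
  )
}

#' @export
glance.msbr_scenario <- function(x, ...) {
  best <- names(which.max(x$preference_rates))
  tibble::tibble(
    iterations = x$config$iterations,
    risk_family = x$config$risk_family,
    k = x$config$k,
    background_proportion = x$config$background_proportion,
    min_utility_difference = x$config$min_utility_difference,
    edss = x$config$edss,
    preferred = best,
    max_preference_rate = max(x$preference_rates)
  )
}
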