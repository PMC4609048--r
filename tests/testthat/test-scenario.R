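test_that("preference rates count argmax iterations and split ties", {
  eu <- rbind(c(0.9, 0.8, 0.7), c(0.9, 0.8, 0.7))
  colnames(eu) <- c("HIGH_DOSE", "LOW_DOSE", "NO_TREATMENT")
  expect_equal(preference_rates(eu),
               c(HIGH_DOSE = 1, LOW_DOSE = 0, NO_TREATMENT = 0))

  eu2 <- rbind(c(1, 0, 0), c(0, 1, 0))
  colnames(eu2) <- colnames(eu)
  expect_equal(unname(preference_rates(eu2)), c(0.5, 0.5, 0))

  # exact ties split equally
  eu3 <- rbind(c(0.5, 0.5, 0.1))
  colnames(eu3) <- colnames(eu)
  expect_equal(unname(preference_rates(eu3)), c(0.5, 0.5, 0))

  # random matrices match the brute-force counting oracle, and sum to 1
  set.seed(10)
  for (i in 1:20) {
    m <- matrix(sample(seq(0, 1, 0.1), 30, TRUE), 10, 3,
                dimnames = list(NULL, colnames(eu)))
    expect_equal(preference_rates(m), oracle_preference_rates(m))
    expect_equal(sum(preference_rates(m)), 1, tolerance = 1e-12)
  }
})

test_that("expected-utility differences compare against the best of the others", {
  eu <- rbind(c(0.9, 0.8, 0.7), c(0.7, 0.8, 0.9))
  colnames(eu) <- c("HIGH_DOSE", "LOW_DOSE", "NO_TREATMENT")
  expect_equal(eu_differences(eu, "HIGH_DOSE"), c(0.1, -0.2))
  expect_equal(eu_differences(eu, 3), c(-0.2, 0.1))

  set.seed(11)
  m <- matrix(runif(300), 100, 3, dimnames = list(NULL, colnames(eu)))
  pr <- preference_rates(m)
  for (a in colnames(eu)) {
    expect_equal(mean(eu_differences(m, a) > 0), unname(pr[a]))
  }
})

test_that("a dominant alternative attains preference rate one", {
  post <- list(eff_high = rep(0.9, 500), eff_low = rep(0.5, 500),
               eff_placebo = rep(0.3, 500),
               ns_high = rep(0, 500), ns_placebo = rep(0, 500))
  lim <- effective_risk_limits()
  lim$limit_low <- lim$limit_high <- 0  # no serious risk at all
  cfg <- scenario_config(iterations = 500, seed = 4)
  sc <- run_scenario(post, cfg, limits = lim)
  expect_equal(unname(sc$preference_rates),
               c(1, 0, 0))
  expect_true(all(sc$eu >= 0 & sc$eu <= 1))
})

test_that("scenarios are bit-reproducible from the master seed", {
  post <- test_posteriors()
  cfg <- scenario_config(risk_family = "trunc_exp", k = 50,
                         background_proportion = 0.25,
                         min_utility_difference = 0.3, edss = 5,
                         iterations = 1000, seed = 123)
  s1 <- run_scenario(post, cfg)
  s2 <- run_scenario(post, cfg)
  expect_identical(s1$eu, s2$eu)
  expect_identical(s1$preference_rates, s2$preference_rates)
  # a different master seed gives different draws
  cfg2 <- scenario_config(risk_family = "trunc_exp", k = 50,
                          background_proportion = 0.25,
                          min_utility_difference = 0.3, edss = 5,
                          iterations = 1000, seed = 124)
  expect_false(identical(run_scenario(post, cfg2)$eu, s1$eu))
})

test_that("iteration demand beyond available draws is rejected unless resampling", {
  post <- list(eff_high = runif(100), eff_low = runif(100),
               eff_placebo = runif(100), ns_high = runif(100),
               ns_placebo = runif(100))
  cfg <- scenario_config(iterations = 500, seed = 1)
  expect_error(run_scenario(post, cfg), "resample")
  sc <- run_scenario(post, cfg, resample = TRUE)
  expect_equal(nrow(sc$eu), 500L)
})

test_that("median fixation removes the targeted uncertainty", {
  post <- test_posteriors()
  cfg <- scenario_config(risk_family = "trunc_exp", k = 5,
                         background_proportion = 0.10,
                         min_utility_difference = 0.4, edss = 4,
                         iterations = 2000, seed = 7)
  sc <- run_scenario(post, cfg)

  # fixing everything leaves no randomness: degenerate preference rates
  all_fixed <- fix_variables(sc, "all")
  expect_true(all(apply(all_fixed$eu, 2, function(x) diff(range(x)) == 0)))
  expect_setequal(unique(unname(all_fixed$preference_rates)), c(0, 1))

  # fixing a stream that is already constant is a no-op
  refixed <- fix_variables(all_fixed, "utilities")
  expect_identical(refixed$eu, all_fixed$eu)

  # probability uncertainty dominates utility uncertainty: fixing the
  # probability variables concentrates the preference rates much more
  fix_prob <- fix_variables(sc, "probabilities")
  fix_util <- fix_variables(sc, "utilities")
  expect_gt(max(fix_prob$preference_rates) - max(sc$preference_rates),
            max(fix_util$preference_rates) - max(sc$preference_rates))

  expect_error(fix_variables(sc, "posterior"), "unknown variable class")
})

test_that("scenario summaries expose rates and expected-utility quantiles", {
  post <- test_posteriors()
  sc <- run_scenario(post, scenario_config(iterations = 500, seed = 2))
  td <- tidy(sc)
  expect_identical(td$alternative, c("HIGH_DOSE", "LOW_DOSE", "NO_TREATMENT"))
  expect_equal(sum(td$preference_rate), 1, tolerance = 1e-12)
  expect_true(all(td$eu_q025 <= td$eu_median & td$eu_median <= td$eu_q975))
  gl <- glance(sc)
  expect_equal(gl$iterations, 500L)
  expect_true(gl$preferred %in% td$alternative)
})
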