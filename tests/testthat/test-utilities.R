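test_that("effect-outcome combinations map to their utility classes", {
  expect_equal(assign_utility_class("Psychosis", "PERSISTENT"), "PERS_INT")
  expect_equal(assign_utility_class("Acute severe allergy", "DEATH"), "LETHAL_QUICK")
  expect_equal(assign_utility_class("Osteonecrosis", "PERSISTENT"), "PERS_MILD")
  expect_equal(assign_utility_class("Seizure", "LIFE_THREATENING"), "LIFE_THREAT")
  expect_equal(assign_utility_class("Cardio-pulmonary distress", "DEATH"),
               "LETHAL_PAINFUL")
  # the unassigned lethal group defaults to the painful class, but is
  # exposed as configuration
  expect_equal(assign_utility_class("Diabetes", "DEATH"), "LETHAL_PAINFUL")
  expect_equal(assign_utility_class("Diabetes", "DEATH",
                                    class_map = c("Diabetes/DEATH" = "LETHAL_QUICK")),
               "LETHAL_QUICK")
  expect_error(assign_utility_class("Common cold", "DEATH"), "unknown")
  expect_error(assign_utility_class("Pancreatitis", "PERSISTENT"), "outside")
  # every tree outcome maps to one of the 16 classes
  tree <- build_decision_tree(adverse_effect_specs())
  expect_true(all(tree$utility_class %in% utility_classes()))
  expect_length(utility_classes(), 16L)
})

test_that("constraint systems are acyclic and feasible across the delta range", {
  for (edss in c(4, 5)) {
    for (delta in c(0, 0.4, 0.99)) {
      sys <- build_utility_constraints(edss, delta)
      pt <- feasible_utilities(sys)
      u <- matrix(pt, 1, dimnames = list(NULL, names(pt)))
      expect_true(oracle_satisfies(u, sys),
                  label = sprintf("edss %d delta %.2f", edss, delta))
    }
  }
  # severity-specific diagonals differ
  e4 <- build_utility_constraints(4, 0)$edges
  e5 <- build_utility_constraints(5, 0)$edges
  expect_true(any(e4$worse == "REDUCED:LIFE_THREAT" &
                    e4$better == "STANDARD:NON_SERIOUS"))
  expect_true(any(e5$worse == "REDUCED:PERS_INT" &
                    e5$better == "STANDARD:NON_SERIOUS"))
  expect_false(any(e5$worse == "REDUCED:PERS_SEVERE" &
                     e5$better == "STANDARD:PERS_MILD"))

  expect_error(build_utility_constraints(4, 1.2), "delta")
  # a contradictory edge set is rejected
  expect_error(
    utility_constraint_system(c("a", "b"),
                              tibble::tibble(worse = c("a", "b"),
                                             better = c("b", "a"))),
    "cycle")
})

test_that("Gibbs marginals match analytic triangle means on two classes", {
  chain2 <- utility_constraint_system(
    c("a", "b"), tibble::tibble(worse = "a", better = "b"))
  d <- sample_utilities(chain2, 50000, seed = 21)
  expect_true(all(satisfies_constraints(d, chain2)))
  expect_lt(abs(mean(d$values[, "a"]) - 1 / 3), 0.01)
  expect_lt(abs(mean(d$values[, "b"]) - 2 / 3), 0.01)

  # with a minimum gap of 0.4 the means shift to 0.2 and 0.8
  gap2 <- utility_constraint_system(c("a", "b"), tibble::tibble(worse = "a", better = "b")[0, ],
                                    lethal = "a", delta = 0.4)
  g <- sample_utilities(gap2, 50000, seed = 22)
  expect_lt(abs(mean(g$values[, "a"]) - 0.2), 0.01)
  expect_lt(abs(mean(g$values[, "b"]) - 0.8), 0.01)
})

test_that("Gibbs agrees with rejection sampling on a small system", {
  sys <- utility_constraint_system(
    c("a", "b", "c", "d"),
    tibble::tibble(worse = c("a", "b"), better = c("b", "c")),
    lethal = "d", delta = 0.2)
  n <- 20000
  gibbs <- sample_utilities(sys, n, seed = 33)$values
  set.seed(34)
  rej <- oracle_rejection_sample(sys, n)
  for (cl in sys$classes) {
    ks <- suppressWarnings(stats::ks.test(gibbs[, cl], rej[, cl]))
    expect_lt(unname(ks$statistic), 0.02)
  }
})

test_that("full-system draws satisfy every constraint and known orderings", {
  sys <- build_utility_constraints(4, 0.25)
  d <- sample_utilities(sys, 4000, seed = 41)
  expect_true(all(oracle_satisfies(d$values, sys)))
  expect_true(all(satisfies_constraints(d, sys)))

  # reduced-relapse draws stochastically dominate standard-relapse draws
  for (ae in c("NO_AE", "NON_SERIOUS", "PERS_INT", "LETHAL_PAINFUL")) {
    red <- sort(d$values[, paste0("REDUCED:", ae)])
    std <- sort(d$values[, paste0("STANDARD:", ae)])
    expect_true(all(red >= std))
  }

  # a standard relapse with no adverse event is valued lower when the
  # relapse starts at EDSS 5 than at EDSS 4
  d5 <- sample_utilities(build_utility_constraints(5, 0.25), 4000, seed = 41)
  expect_lt(mean(d5$values[, "STANDARD:NO_AE"]),
            mean(d$values[, "STANDARD:NO_AE"]))
})

test_that("constraint systems round-trip through structured text", {
  sys <- build_utility_constraints(5, 0.4)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_utility_constraints(sys, path)
  back <- read_utility_constraints(path)
  expect_identical(back$classes, sys$classes)
  expect_identical(as.data.frame(back$edges), as.data.frame(sys$edges))
  expect_identical(back$lethal, sys$lethal)
  expect_equal(back$delta, sys$delta)
})

test_that("the gamble interpretation translates delta into a lethal-risk probability", {
  # arithmetic on degenerate draws
  vals <- matrix(0.5, 3, 16, dimnames = list(NULL, utility_classes()))
  vals[, "REDUCED:NO_AE"] <- 1
  vals[, "STANDARD:NO_AE"] <- 0.9
  vals[, "REDUCED:LETHAL_PAINFUL"] <- 0.2
  vals[, "STANDARD:LETHAL_PAINFUL"] <- 0
  fake <- structure(list(values = vals), class = "utility_draws")
  expect_equal(gamble_indifference(fake), 0.1)

  # a stricter lethal gap makes the typical patient more risk-averse
  g05 <- gamble_indifference(
    sample_utilities(build_utility_constraints(4, 0.5), 10000, seed = 5))
  g09 <- gamble_indifference(
    sample_utilities(build_utility_constraints(4, 0.9), 10000, seed = 5))
  expect_lt(abs(g05 - 0.07), 0.03)
  expect_lt(abs(g09 - 0.01), 0.01)
  expect_lt(g09, g05)
})
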