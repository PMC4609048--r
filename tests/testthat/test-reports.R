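mk_reports <- function(...) dplyr::bind_rows(...)

rrow <- function(id, effect, evidence, role = "SUSPECTED",
                 other = FALSE, onset = 30L) {
  tibble::tibble(report_id = id, drug_role = role,
                 other_drug_implicated = other,
                 time_to_onset_days = onset,
                 effect = effect, evidence = evidence)
}

test_that("outcome classification is hierarchical within effect, separate across effects", {
  # persistent + life-threatening evidence for the same effect -> persistent only
  rep1 <- mk_reports(rrow("r1", "Hepatotoxicity", "PERSISTENT"),
                     rrow("r1", "Hepatotoxicity", "LIFE_THREATENING"))
  cl <- classify_report_outcomes(rep1)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$outcome, "PERSISTENT")

  # death dominates everything
  rep2 <- mk_reports(rrow("r2", "Seizure", "LIFE_THREATENING"),
                     rrow("r2", "Seizure", "DEATH"),
                     rrow("r2", "Seizure", "PERSISTENT"))
  expect_equal(classify_report_outcomes(rep2)$outcome, "DEATH")

  # two effects on one report are classified independently
  rep3 <- mk_reports(rrow("r3", "Psychosis", "LIFE_THREATENING"),
                     rrow("r3", "Seizure", "DEATH"))
  cl3 <- classify_report_outcomes(rep3)
  expect_equal(nrow(cl3), 2L)
  expect_setequal(paste(cl3$effect, cl3$outcome),
                  c("Psychosis LIFE_THREATENING", "Seizure DEATH"))

  # only NONE evidence -> empty classification
  rep4 <- rrow("r4", "Diabetes", "NONE")
  expect_equal(nrow(classify_report_outcomes(rep4)), 0L)
})

test_that("the at-least-three-reports rule gates inclusion", {
  counts <- tibble::tibble(
    effect = c("A", "A", "B"),
    outcome = c("DEATH", "PERSISTENT", "DEATH"),
    n_low = c(2, 1, 0),
    n_high = c(0, 2, 5)
  )
  kept <- select_effect_outcomes(counts)
  expect_setequal(paste(kept$effect, kept$outcome), c("A PERSISTENT", "B DEATH"))
  # boundary: (2, 0) excluded, (1, 2) included
  expect_false("A DEATH" %in% paste(kept$effect, kept$outcome))
})

test_that("reporting-ratio upper limits count qualifying reports over all reports", {
  # 3 qualifying carriers among 300 reports -> 0.01
  carriers <- mk_reports(
    rrow("c1", "Psychosis", "PERSISTENT", role = "SUSPECTED"),
    rrow("c2", "Psychosis", "PERSISTENT", role = "INTERACTING"),
    rrow("c3", "Psychosis", "PERSISTENT", role = "CONCOMITANT", other = FALSE)
  )
  filler <- purrr::map_dfr(1:297, function(i) {
    rrow(sprintf("f%d", i), "Diabetes", "NONE", role = "CONCOMITANT", other = TRUE)
  })
  lim <- compute_upper_limit(mk_reports(carriers, filler), "Psychosis", "PERSISTENT")
  expect_equal(lim$limit, 0.01)

  # every report qualifying -> limit 1
  all_in <- purrr::map_dfr(1:5, function(i) rrow(sprintf("a%d", i), "Seizure", "DEATH"))
  expect_equal(compute_upper_limit(all_in, "Seizure", "DEATH")$limit, 1)

  # disqualifiers: concomitant with another drug implicated; onset > 180;
  # missing onset; hierarchy shadowing by a higher outcome
  mixed <- mk_reports(
    rrow("m1", "Myopathy", "PERSISTENT"),                                   # in
    rrow("m2", "Myopathy", "PERSISTENT", role = "CONCOMITANT", other = TRUE),  # out: other drug
    rrow("m3", "Myopathy", "PERSISTENT", onset = 200L),                     # out: late onset
    rrow("m4", "Myopathy", "PERSISTENT", onset = NA_integer_),              # out: unknown onset
    rrow("m5", "Myopathy", "PERSISTENT"),                                   # shadowed ->
    rrow("m5", "Myopathy", "DEATH")                                         # counts as DEATH
  )
  expect_equal(compute_upper_limit(mixed, "Myopathy", "PERSISTENT")$limit, 1 / 5)
  # the onset exemption restores the late and unknown-onset reports
  expect_equal(compute_upper_limit(mixed, "Myopathy", "PERSISTENT",
                                   onset_exempt = TRUE)$limit, 3 / 5)
  expect_error(compute_upper_limit(mixed[0, ], "Myopathy", "PERSISTENT"), "empty")
})

test_that("limits equal an independent filter-count oracle on synthetic collections", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 120L
    reports <- tibble::tibble(
      report_id = sprintf("r%03d", seq_len(n)),
      drug_role = sample(c("SUSPECTED", "INTERACTING", "CONCOMITANT"), n, TRUE),
      other_drug_implicated = sample(c(TRUE, FALSE), n, TRUE),
      time_to_onset_days = sample(c(NA_integer_, 0:400), n, TRUE),
      effect = sample(c("Psychosis", "Seizure"), n, TRUE),
      evidence = sample(c("DEATH", "PERSISTENT", "LIFE_THREATENING", "NONE"), n, TRUE)
    )
    # oracle: explicit per-report loop
    oracle_count <- 0L
    for (id in unique(reports$report_id)) {
      rows <- reports[reports$report_id == id & reports$effect == "Psychosis", ]
      rows <- rows[rows$evidence != "NONE", ]
      if (nrow(rows) == 0) next
      hier <- c("DEATH", "PERSISTENT", "LIFE_THREATENING")
      top <- hier[min(match(rows$evidence, hier))]
      if (top != "PERSISTENT") next
      role <- rows$drug_role[1]
      qualifies <- role %in% c("SUSPECTED", "INTERACTING") ||
        (role == "CONCOMITANT" && !rows$other_drug_implicated[1])
      onset <- rows$time_to_onset_days[1]
      qualifies <- qualifies && !is.na(onset) && onset <= 180
      if (qualifies) oracle_count <- oracle_count + 1L
    }
    lim <- compute_upper_limit(reports, "Psychosis", "PERSISTENT")
    expect_equal(lim$limit, oracle_count / n)
  }
})
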