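#' Simulate beta-binomial study arms
#'
#' Generates study arms from the generative model the meta-analysis
#' assumes: each arm's improvement probability is drawn from
#' `Beta(mu * M, (1 - mu) * M)` and its success count is binomial. Used to
#' validate parameter recovery of the fitter.
#'
#' @param mu True population mean, in `(0, 1)`.
#' @param M True concentration, positive.
#' @param sizes Integer vector of arm sizes.
#' @param seed Optional integer seed.
#' @return A tibble of study arms (`study`, `alternative = "SIMULATED"`,
#'   `successes`, `n`, `p_true`).
#' @export
simulate_study_arms <- function(mu, M, sizes, seed = NULL) {
  stopifnot(mu > 0, mu < 1, M > 0, all(sizes >= 1))
  if (!is.null(seed)) set.seed(seed)
  p <- rbeta(length(sizes), mu * M, (1 - mu) * M)
  tibble::tibble(
    study = paste0("sim-", seq_along(sizes)),
    alternative = "SIMULATED",
    successes = as.numeric(rbinom(length(sizes), sizes, p)),
    n = as.integer(sizes),
    p_true = p
  )
}

#' Simulate a spontaneous case-report collection
#'
#' Generates the reporting regime under which the reporting-ratio bound is
#' conservative: every true case of the effect-outcome combination is
#' reported with the drug suspected and onset within 180 days (subject to
#' the reporting probability), and the collection additionally contains
#' non-case reports that dilute only the denominator (by default
#' concomitant reports implicating another drug, with no serious
#' evidence).
#'
#' @param n_exposed Size of the exposed population.
#' @param incidence True incidence of the combination, in `[0, 1]`.
#' @param effect,outcome The combination the cases carry.
#' @param reporting_prob Probability that a case is reported (default 1).
#' @param n_noncase Either a fixed count of non-case reports or a function
#'   of the case count (e.g. `function(k) 10 * k` for tenfold padding).
#' @param noncase_role,noncase_other_drug Composition of the non-case
#'   reports.
#' @param seed Optional integer seed.
#' @return A reaction-level report tibble (see
#'   [classify_report_outcomes()]), with attributes `n_cases` (true cases)
#'   and `incidence`.
#' @export
simulate_case_reports <- function(n_exposed, incidence,
                                  effect = "Hepatotoxicity",
                                  outcome = "PERSISTENT",
                                  reporting_prob = 1,
                                  n_noncase = function(k) 10L * k,
                                  noncase_role = "CONCOMITANT",
                                  noncase_other_drug = TRUE,
                                  seed = NULL) {
  stopifnot(n_exposed >= 1, incidence >= 0, incidence <= 1,
            reporting_prob >= 0, reporting_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  n_cases <- rbinom(1L, n_exposed, incidence)
  n_reported <- rbinom(1L, n_cases, reporting_prob)
  n_pad <- if (is.function(n_noncase)) n_noncase(n_cases) else n_noncase
  case_rows <- tibble::tibble(
    report_id = sprintf("case-%d", seq_len(n_reported)),
    drug_role = "SUSPECTED",
    other_drug_implicated = FALSE,
    time_to_onset_days = sample.int(181L, n_reported, replace = TRUE) - 1L,
    effect = effect,
    evidence = outcome
  )
  pad_rows <- tibble::tibble(
    report_id = sprintf("noncase-%d", seq_len(n_pad)),
    drug_role = noncase_role,
    other_drug_implicated = noncase_other_drug,
    time_to_onset_days = sample.int(181L, n_pad, replace = TRUE) - 1L,
    effect = effect,
    evidence = "NONE"
  )
  reports <- dplyr::bind_rows(case_rows, pad_rows)
  attr(reports, "n_cases") <- n_cases
  attr(reports, "incidence") <- incidence
  reports
}
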