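#' Classify the serious outcomes of a case-report collection
#'
#' Spontaneous case reports are represented as a flat tibble with one row
#' per reported reaction and report-level fields repeated: `report_id`,
#' `drug_role` (`"SUSPECTED"`, `"INTERACTING"` or `"CONCOMITANT"`),
#' `other_drug_implicated` (logical, meaningful for concomitant reports),
#' `time_to_onset_days` (non-negative integer or `NA`), `effect` and
#' `evidence` (`"DEATH"`, `"PERSISTENT"`, `"LIFE_THREATENING"` or
#' `"NONE"`).
#'
#' Within one report the outcome of a given adverse effect is classified
#' hierarchically: death outranks persistent disability, which outranks a
#' life-threatening reaction, so an effect with both persistent and
#' life-threatening evidence counts only towards persistent disability.
#' Different effects on the same report are classified separately and need
#' not share an outcome.
#'
#' @param reports A reaction-level tibble as described above.
#' @return A tibble with one row per (report, effect) carrying a serious
#'   outcome: `report_id`, `effect`, `outcome`. Effects with only `"NONE"`
#'   evidence are dropped.
#' @export
classify_report_outcomes <- function(reports) {
  stopifnot(is.data.frame(reports),
            all(c("report_id", "effect", "evidence") %in% names(reports)))
  reports |>
    dplyr::filter(.data$evidence %in% SERIOUS_OUTCOMES) |>
    dplyr::mutate(.rank = match(.data$evidence, SERIOUS_OUTCOMES)) |>
    dplyr::group_by(.data$report_id, .data$effect) |>
    dplyr::slice_min(.data$.rank, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$report_id, .data$effect,
                     outcome = SERIOUS_OUTCOMES[.data$.rank])
}

#' Select effect-outcome combinations for inclusion
#'
#' A serious effect-outcome combination enters the assessment only if it
#' was reported at least three times in the two dose groups together.
#'
#' @param counts A tibble with columns `effect`, `outcome`, `n_low`,
#'   `n_high` (report counts per dose group).
#' @param min_reports Inclusion threshold (default 3).
#' @return The included rows, with a `total` column.
#' @export
select_effect_outcomes <- function(counts, min_reports = 3) {
  stopifnot(all(c("effect", "outcome", "n_low", "n_high") %in% names(counts)),
            all(counts$n_low >= 0), all(counts$n_high >= 0))
  counts |>
    dplyr::mutate(total = .data$n_low + .data$n_high) |>
    dplyr::filter(.data$total >= min_reports)
}

# numerator qualification shared by compute_upper_limit and its callers
qualifies_for_numerator <- function(drug_role, other_drug_implicated,
                                    time_to_onset_days, onset_exempt) {
  role_ok <- drug_role %in% c("SUSPECTED", "INTERACTING") |
    (drug_role == "CONCOMITANT" & !other_drug_implicated)
  if (onset_exempt) return(role_ok)
  # missing onset cannot demonstrate onset within 180 days -> excluded
  role_ok & !is.na(time_to_onset_days) & time_to_onset_days <= 180
}

#' Reporting-ratio upper limit on a serious risk
#'
#' Computes the upper limit on the true population risk of one serious
#' effect-outcome combination as a reporting ratio within a collection of
#' case reports for one dose group. The denominator counts all reports,
#' whatever the drug's role. The numerator counts reports that carry the
#' combination after hierarchical outcome classification and that qualify:
#' the drug is suspected or interacting, or concomitant with no other drug
#' implicated, and the time from drug initiation to reaction onset is at
#' most 180 days. The onset requirement is waived when `onset_exempt` is
#' set (used for osteonecrosis, which is hard to date).
#'
#' @param reports A reaction-level report tibble; see
#'   [classify_report_outcomes()].
#' @param effect,outcome The combination to bound.
#' @param onset_exempt Waive the 180-day onset filter.
#' @return One-row tibble: `effect`, `outcome`, `limit` in `[0, 1]`.
#' @export
compute_upper_limit <- function(reports, effect, outcome,
                                onset_exempt = FALSE) {
  total <- dplyr::n_distinct(reports$report_id)
  if (total == 0L) abort("empty report collection: reporting ratio undefined")
  classified <- classify_report_outcomes(reports)
  hits <- classified[classified$effect == effect &
                       classified$outcome == outcome, ]
  report_fields <- reports |>
    dplyr::distinct(.data$report_id, .data$drug_role,
                    .data$other_drug_implicated, .data$time_to_onset_days)
  hits <- dplyr::inner_join(hits, report_fields, by = "report_id")
  ok <- qualifies_for_numerator(hits$drug_role, hits$other_drug_implicated,
                                hits$time_to_onset_days, onset_exempt)
  tibble::tibble(effect = effect, outcome = outcome,
                 limit = sum(ok) / total)
}
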