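#' Packaged input tables
#'
#' The in-package fixtures carry the four inputs of the assessment: the
#' eleven serious adverse effects with their included outcomes, the sixteen
#' effectiveness study arms, the fourteen non-serious adverse-event study
#' arms, and the 26 upper risk limits (in percent) for serious
#' effect-outcome combinations per dose group. Each loader verifies the file
#' against the packaged checksum manifest and validates the printed marginal
#' totals before returning.
#'
#' Two success counts are fractional as printed in the source tables (39.25
#' improved of 94, and 9.2 of 13 with an adverse event); they arise from
#' scale conversions and independence assumptions in the original trial
#' reports and are consumed exactly via gamma-function generalisations of
#' the beta-binomial likelihood.
#'
#' @return A tibble; see each function for columns.
#' @name fixtures
NULL

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "msbr")
  if (!nzchar(path)) abort(paste0("fixture not found: ", file))
  path
}

check_fixture <- function(file) {
  manifest <- utils::read.delim(fixture_path("MANIFEST.tsv"),
                                stringsAsFactors = FALSE)
  expected <- manifest$md5[manifest$file == file]
  if (length(expected) != 1L) abort(paste0("fixture not in manifest: ", file))
  actual <- unname(tools::md5sum(fixture_path(file)))
  if (!identical(actual, expected)) {
    abort(paste0("fixture checksum mismatch for ", file,
                 ": expected ", expected, ", got ", actual))
  }
  invisible(TRUE)
}

read_fixture <- function(file, col_types) {
  check_fixture(file)
  readr::read_tsv(fixture_path(file), col_types = col_types, na = "NA",
                  progress = FALSE)
}

#' @describeIn fixtures The eleven serious adverse effects and which of the
#'   outcomes death / persistent disability / life-threatening reaction are
#'   included for each (26 combinations in total). Columns: `effect`,
#'   `death`, `persistent`, `life_threatening` (logical).
#' @export
adverse_effect_specs <- function() {
  raw <- read_fixture("serious_adverse_effects.tsv", "cccc")
  out <- dplyr::mutate(raw, dplyr::across(-"effect", ~ .x == "yes"))
  stopifnot(nrow(out) == 11L)
  if (sum(out$death) + sum(out$persistent) + sum(out$life_threatening) != 26L) {
    abort("adverse-effect fixture does not contain 26 effect-outcome combinations")
  }
  out
}

validate_arms <- function(arms) {
  if (any(arms$successes < 0 | arms$successes > arms$n)) {
    abort("study arms must satisfy 0 <= successes <= n")
  }
  if (any(arms$n < 1)) abort("study arm sizes must be positive")
  invisible(arms)
}

#' @describeIn fixtures The sixteen effectiveness study arms (fraction of
#'   patients improving at least one EDSS point within 14-28 days).
#'   Columns: `study`, `alternative` (HIGH_DOSE / LOW_DOSE / PLACEBO),
#'   `successes` (possibly fractional), `n`, `route`, `duration_days`,
#'   `assessment_day`.
#' @export
effectiveness_arms <- function() {
  arms <- read_fixture("effectiveness_arms.tsv", "ccdicii")
  validate_arms(arms)
  counts <- table(arms$alternative)[c("HIGH_DOSE", "LOW_DOSE", "PLACEBO")]
  totals <- tapply(arms$n, arms$alternative, sum)[c("HIGH_DOSE", "LOW_DOSE", "PLACEBO")]
  stopifnot(identical(unname(as.integer(counts)), c(8L, 3L, 5L)),
            identical(unname(as.integer(totals)), c(152L, 62L, 156L)))
  arms
}

#' @describeIn fixtures The fourteen study arms for the risk of at least one
#'   non-serious adverse event. Columns: `study`, `alternative` (HIGH_DOSE /
#'   PLACEBO), `successes` (possibly fractional), `n`, `route`, `duration`,
#'   `followup_days`.
#' @export
nonserious_arms <- function() {
  arms <- read_fixture("nonserious_arms.tsv", "ccdicci")
  validate_arms(arms)
  counts <- table(arms$alternative)[c("HIGH_DOSE", "PLACEBO")]
  totals <- tapply(arms$n, arms$alternative, sum)[c("HIGH_DOSE", "PLACEBO")]
  stopifnot(identical(unname(as.integer(counts)), c(11L, 3L)),
            identical(unname(as.integer(totals)), c(301L, 129L)))
  arms
}

#' @describeIn fixtures The 26 upper risk limits in percent for serious
#'   effect-outcome combinations, per dose group. Columns: `effect`,
#'   `outcome`, `low_pct`, `high_pct`, `onset_exempt` (no time-to-onset
#'   requirement applied for osteonecrosis), `use_low_for_high` (a printed
#'   high-dose 0.00 is not a genuine upper limit, so the low-dose limit is
#'   substituted in analyses).
#' @export
risk_limits <- function() {
  lim <- read_fixture("risk_limits.tsv", "ccddcc")
  lim <- dplyr::mutate(lim,
                       onset_exempt = .data$onset_exempt == "yes",
                       use_low_for_high = .data$use_low_for_high == "yes")
  stopifnot(nrow(lim) == 26L,
            all(lim$outcome %in% SERIOUS_OUTCOMES),
            all(lim$low_pct >= 0), all(lim$high_pct >= 0))
  lim
}

#' Effective risk limits as proportions, after footnote substitutions
#'
#' Converts the percent limits of [risk_limits()] to proportions and applies
#' the substitution rule: where the printed high-dose limit is 0.00 (flagged
#' `use_low_for_high`) the low-dose limit is used instead, since a zero
#' reporting ratio clearly is not an upper bound on the true risk.
#'
#' @param limits A tibble as returned by [risk_limits()].
#' @return A tibble with columns `effect`, `outcome`, `onset_exempt`,
#'   `limit_low`, `limit_high` (proportions in `[0, 1]`), ordered by effect
#'   (alphabetical) and outcome severity (death, persistent disability,
#'   life-threatening).
#' @export
effective_risk_limits <- function(limits = risk_limits()) {
  limits |>
    dplyr::mutate(
      limit_low = .data$low_pct / 100,
      limit_high = dplyr::if_else(.data$use_low_for_high,
                                  .data$low_pct / 100,
                                  .data$high_pct / 100),
      outcome = factor(.data$outcome, levels = SERIOUS_OUTCOMES)
    ) |>
    dplyr::arrange(.data$effect, .data$outcome) |>
    dplyr::mutate(outcome = as.character(.data$outcome)) |>
    dplyr::select("effect", "outcome", "onset_exempt", "limit_low", "limit_high")
}
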