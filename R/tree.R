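#' Build the decision tree of clinical outcomes
#'
#' Enumerates the clinical outcomes shared by all three treatment
#' alternatives. Each outcome combines a benefit state (reduced relapse,
#' i.e. improvement of at least one EDSS point, versus standard relapse)
#' with an adverse-effect branch: one of the included serious
#' effect-outcome combinations (assumed mutually exclusive because they are
#' rare), at least one non-serious adverse event, or no adverse event. With
#' `k` included serious combinations the tree therefore has `2 * (k + 2)`
#' outcomes; the packaged specification (11 effects, 26 combinations)
#' yields 56.
#'
#' The ordering is deterministic so that downstream sampling is
#' reproducible: reduced relapse before standard relapse; within a benefit
#' state the serious combinations sorted by effect name (alphabetical) and
#' outcome severity (death, persistent disability, life-threatening), then
#' the non-serious branch, then the no-adverse-event branch.
#'
#' @param effects A tibble with columns `effect`, `death`, `persistent`,
#'   `life_threatening` (logical inclusion flags), as returned by
#'   [adverse_effect_specs()].
#' @param class_map Optional utility-class overrides; see
#'   [assign_utility_class()].
#' @return A tibble of class `msbr_tree` with one row per clinical outcome:
#'   `outcome_id`, `benefit`, `branch` (`"SERIOUS"`, `"NON_SERIOUS"` or
#'   `"NO_AE"`), `effect`, `outcome` (NA outside serious branches) and
#'   `utility_class`.
#' @export
#' @examples
#' tree <- build_decision_tree(adverse_effect_specs())
#' nrow(tree) # 56
build_decision_tree <- function(effects, class_map = NULL) {
  stopifnot(is.data.frame(effects),
            all(c("effect", "death", "persistent", "life_threatening")
                %in% names(effects)))
  if (anyDuplicated(effects$effect)) {
    abort("duplicate adverse-effect names in specification")
  }
  combos <- effects |>
    tidyr::pivot_longer(c("death", "persistent", "life_threatening"),
                        names_to = "outcome", values_to = "included") |>
    dplyr::filter(.data$included) |>
    dplyr::mutate(outcome = factor(
      dplyr::recode(.data$outcome,
                    death = "DEATH",
                    persistent = "PERSISTENT",
                    life_threatening = "LIFE_THREATENING"),
      levels = SERIOUS_OUTCOMES
    )) |>
    dplyr::arrange(.data$effect, .data$outcome) |>
    dplyr::mutate(outcome = as.character(.data$outcome)) |>
    dplyr::select("effect", "outcome")
  if (any(!effects$effect %in% combos$effect)) {
    abort("every adverse effect must include at least one outcome")
  }

  branch_block <- dplyr::bind_rows(
    dplyr::mutate(combos, branch = "SERIOUS"),
    tibble::tibble(effect = NA_character_, outcome = NA_character_,
                   branch = c("NON_SERIOUS", "NO_AE"))
  )
  tree <- tidyr::expand_grid(benefit = BENEFIT_STATES, branch_block)
  ae_class <- tree$branch  # NON_SERIOUS / NO_AE stand for themselves
  serious_rows <- tree$branch == "SERIOUS"
  ae_class[serious_rows] <- assign_utility_class(tree$effect[serious_rows],
                                                 tree$outcome[serious_rows],
                                                 class_map)
  tree <- tree |>
    dplyr::mutate(
      utility_class = paste(.data$benefit, ae_class, sep = ":"),
      outcome_id = paste(
        .data$benefit,
        dplyr::if_else(.data$branch == "SERIOUS",
                       paste(.data$effect, .data$outcome, sep = "/"),
                       .data$branch),
        sep = ":"
      )
    ) |>
    dplyr::select("outcome_id", "benefit", "branch", "effect", "outcome",
                  "utility_class")
  class(tree) <- c("msbr_tree", class(tree))
  tree
}

#' @export
print.msbr_tree <- function(x, ...) {
  k <- sum(x$branch == "SERIOUS") / 2L
  cat(sprintf("Decision tree: %d clinical outcomes (%d serious effect-outcome combinations)\n",
              nrow(x), k))
  NextMethod()
}

#' Per-outcome probabilities for one alternative in one iteration
#'
#' Factorises one alternative's sampled probability variables over the
#' outcomes of the tree. With effectiveness `e`, conditional non-serious
#' risk `r` and serious risks `q` (one per included combination, shared
#' between the two benefit branches):
#' `P(REDUCED, combo j) = e * q_j`,
#' `P(REDUCED, NON_SERIOUS) = e * (1 - sum(q)) * r`,
#' `P(REDUCED, NO_AE) = e * (1 - sum(q)) * (1 - r)`,
#' and analogously with `1 - e` for the standard-relapse branches. The 56
#' probabilities sum to one.
#'
#' @param tree A tree from [build_decision_tree()].
#' @param e Effectiveness (probability of a reduced relapse) in `[0, 1]`.
#' @param r Risk of at least one non-serious adverse event in `[0, 1]`,
#'   conditional on no serious effect.
#' @param q Named numeric vector of serious-risk values, one per serious
#'   combination in the tree; names `"effect/outcome"` or in tree order.
#' @return The tree tibble with a `probability` column appended.
#' @export
outcome_probabilities <- function(tree, e, r, q) {
  stopifnot(inherits(tree, "msbr_tree"), length(e) == 1L, length(r) == 1L)
  serious <- tree$branch == "SERIOUS" & tree$benefit == "REDUCED"
  k <- sum(serious)
  if (length(q) != k) abort(sprintf("expected %d serious-risk values, got %d", k, length(q)))
  keys <- paste(tree$effect[serious], tree$outcome[serious], sep = "/")
  if (!is.null(names(q))) {
    if (!setequal(names(q), keys)) abort("names of q do not match the tree's serious combinations")
    q <- q[keys]
  }
  if (any(e < 0 | e > 1) || any(r < 0 | r > 1) || any(q < 0 | q > 1)) {
    abort("probabilities must lie in [0, 1]")
  }
  if (sum(q) >= 1) abort("serious risks must sum to less than 1")
  prob <- as.numeric(outcome_probability_matrix(e, r, matrix(q, nrow = 1L)))
  dplyr::mutate(tree, probability = prob)
}

# Vectorised core: n iterations at once.
# e, r: length-n vectors; Q: n x k matrix of serious risks in tree order.
# Returns n x (2*(k+2)) matrix with columns in tree row order.
outcome_probability_matrix <- function(e, r, Q) {
  rest <- 1 - rowSums(Q)
  cbind(e * Q, e * rest * r, e * rest * (1 - r),
        (1 - e) * Q, (1 - e) * rest * r, (1 - e) * rest * (1 - r))
}

#' Expected utility of one alternative
#'
#' The probability-weighted sum of outcome utilities,
#' `sum(p_c * u_c)` over all clinical outcomes `c`.
#'
#' @param probabilities A tibble from [outcome_probabilities()] (columns
#'   `outcome_id`, `probability`).
#' @param utilities A data frame with columns `outcome_id` and `utility`
#'   (values in `[0, 1]`), or a numeric vector named by `outcome_id`.
#' @return A scalar in `[0, 1]`.
#' @export
expected_utility <- function(probabilities, utilities) {
  stopifnot(is.data.frame(probabilities),
            all(c("outcome_id", "probability") %in% names(probabilities)))
  if (is.numeric(utilities)) {
    utilities <- tibble::tibble(outcome_id = names(utilities),
                                utility = unname(utilities))
  }
  if (!setequal(probabilities$outcome_id, utilities$outcome_id) ||
      nrow(utilities) != nrow(probabilities)) {
    abort("utility outcomes do not match the probability outcomes")
  }
  u <- utilities$utility[match(probabilities$outcome_id, utilities$outcome_id)]
  if (any(u < 0 | u > 1)) abort("utilities must lie in [0, 1]")
  sum(probabilities$probability * u)
}
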