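#' Default sensitivity grid
#'
#' The full factorial grid over the four varied components: the
#' distribution family over serious-risk intervals (uniform, and truncated
#' exponential with rate multiplier 5, 50 or 500), the background risk
#' proportion (0, 10, 25, 50 %), the minimum utility difference (0 to 0.9
#' in steps of 0.1, plus 0.99) and the relapse severity (EDSS 4 or 5):
#' 4 x 4 x 11 x 2 = 352 cells.
#'
#' @return A tibble with columns `risk_family`, `k`,
#'   `background_proportion`, `min_utility_difference`, `edss`.
#' @export
default_grid <- function() {
  families <- tibble::tibble(
    risk_family = c("uniform", "trunc_exp", "trunc_exp", "trunc_exp"),
    k = c(NA_real_, 5, 50, 500)
  )
  tidyr::expand_grid(
    families,
    background_proportion = c(0, 0.10, 0.25, 0.50),
    min_utility_difference = c(seq(0, 0.9, by = 0.1), 0.99),
    edss = c(4L, 5L)
  )
}

#' Run the sensitivity grid
#'
#' Runs [run_scenario()] once per grid cell with a per-cell seed derived
#' from the base seed and the cell's settings, and collects one summary
#' row per cell: the preference rate and median expected utility of every
#' alternative.
#'
#' @param posteriors As for [run_scenario()] (fitted once, shared by all
#'   cells).
#' @param grid A grid tibble, as [default_grid()].
#' @param n_iter Iterations per cell.
#' @param seed Base seed for deriving per-cell seeds.
#' @param limits,tree Passed through to [run_scenario()].
#' @param resample Passed through to [run_scenario()].
#' @return A tibble of class `msbr_grid`: the grid columns plus
#'   `pref_high`, `pref_low`, `pref_none`, `eu_median_high`,
#'   `eu_median_low`, `eu_median_none` and `cell_seed`.
#' @export
run_sensitivity_grid <- function(posteriors, grid = default_grid(),
                                 n_iter = 2000, seed = 1,
                                 limits = effective_risk_limits(),
                                 tree = build_decision_tree(adverse_effect_specs()),
                                 resample = FALSE) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  out <- purrr::pmap_dfr(
    grid,
    function(risk_family, k, background_proportion,
             min_utility_difference, edss, ...) {
      cell_name <- sprintf("cell-%s-%s-%s-%s-%s", risk_family,
                           ifelse(is.na(k), "NA", k),
                           background_proportion,
                           min_utility_difference, edss)
      cell_seed <- derive_seed(seed, cell_name)
      config <- scenario_config(
        risk_family = risk_family,
        k = ifelse(is.na(k), 5, k),
        background_proportion = background_proportion,
        min_utility_difference = min_utility_difference,
        edss = edss, iterations = n_iter, seed = cell_seed
      )
      sc <- run_scenario(posteriors, config, limits = limits, tree = tree,
                         resample = resample)
      med <- apply(sc$eu, 2, median)
      tibble::tibble(
        risk_family = risk_family, k = k,
        background_proportion = background_proportion,
        min_utility_difference = min_utility_difference, edss = edss,
        pref_high = sc$preference_rates[["HIGH_DOSE"]],
        pref_low = sc$preference_rates[["LOW_DOSE"]],
        pref_none = sc$preference_rates[["NO_TREATMENT"]],
        eu_median_high = med[["HIGH_DOSE"]],
        eu_median_low = med[["LOW_DOSE"]],
        eu_median_none = med[["NO_TREATMENT"]],
        cell_seed = cell_seed
      )
    }
  )
  structure(out, class = c("msbr_grid", class(out)),
            base_config = list(n_iter = n_iter), seed = seed)
}

#' @export
glance.msbr_grid <- function(x, ...) {
  pref <- as.matrix(x[, c("pref_high", "pref_low", "pref_none")])
  winner <- c("HIGH_DOSE", "LOW_DOSE", "NO_TREATMENT")[max.col(pref, "first")]
  tibble::tibble(
    n_cells = nrow(x),
    low_dose_preferred_cells = sum(winner == "LOW_DOSE"),
    max_pref_high = max(x$pref_high),
    max_pref_low = max(x$pref_low),
    max_pref_none = max(x$pref_none)
  )
}
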