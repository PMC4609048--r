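alt_labels <- c(HIGH_DOSE = "High-dose MP", LOW_DOSE = "Low-dose MP",
                NO_TREATMENT = "No treatment")

#' Plot a fitted beta-binomial posterior
#'
#' Density of the posterior draws of the population mean.
#'
#' @param object A `betabin_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.betabin_fit <- function(object, ...) {
  ggplot2::ggplot(object$draws, ggplot2::aes(x = .data$mu)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "population mean probability", y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Plot sampled utilities by class
#'
#' @param object A `utility_draws` object.
#' @param ... Unused.
#' @return A ggplot of per-class utility distributions, faceted by benefit
#'   state.
#' @export
autoplot.utility_draws <- function(object, ...) {
  tidy(object) |>
    dplyr::mutate(ae_class = factor(.data$ae_class, levels = AE_CLASSES)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$ae_class, y = .data$utility)) +
    ggplot2::geom_violin(fill = "grey85", scale = "width") +
    ggplot2::facet_wrap(~ .data$benefit) +
    ggplot2::labs(x = NULL, y = "utility") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a scenario's evaluation results
#'
#' `type = "eu"` shows the expected-utility distributions of the three
#' alternatives; `type = "differences"` shows, per alternative, the
#' histogram of per-iteration differences against the best of the other
#' alternatives — the shaded area right of zero is the preference rate.
#'
#' @param object An `msbr_scenario`.
#' @param type `"eu"` or `"differences"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msbr_scenario <- function(object, type = c("eu", "differences"), ...) {
  type <- match.arg(type)
  eu <- tibble::as_tibble(object$eu) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "alternative",
                        values_to = "expected_utility") |>
    dplyr::mutate(alternative = alt_labels[.data$alternative])
  if (type == "eu") {
    return(
      ggplot2::ggplot(eu, ggplot2::aes(x = .data$expected_utility)) +
        ggplot2::geom_density(fill = "grey80") +
        ggplot2::facet_wrap(~ .data$alternative) +
        ggplot2::labs(x = "expected utility", y = "density") +
        ggplot2::theme_minimal()
    )
  }
  diffs <- purrr::map_dfr(colnames(object$eu), function(a) {
    tibble::tibble(alternative = alt_labels[[a]],
                   difference = eu_differences(object$eu, a))
  })
  ggplot2::ggplot(diffs, ggplot2::aes(x = .data$difference,
                                      fill = .data$difference > 0)) +
    ggplot2::geom_histogram(bins = 60, show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~ .data$alternative) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "steelblue")) +
    ggplot2::labs(x = "expected-utility difference vs best of others",
                  y = "iterations") +
    ggplot2::theme_minimal()
}

#' Plot preference rates across the sensitivity grid
#'
#' Preference rate against the minimum utility difference, one line per
#' alternative, faceted by risk-distribution family (columns) and
#' background proportion (rows), for one relapse severity.
#'
#' @param object An `msbr_grid`.
#' @param edss Which severity level to display (default 4).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msbr_grid <- function(object, edss = 4, ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::filter(.data$edss == !!edss) |>
    dplyr::mutate(family = ifelse(.data$risk_family == "uniform", "uniform",
                                  paste0("trunc exp k=", .data$k))) |>
    tidyr::pivot_longer(c("pref_high", "pref_low", "pref_none"),
                        names_to = "alternative", values_to = "rate") |>
    dplyr::mutate(alternative = dplyr::recode(.data$alternative,
                                              pref_high = alt_labels[["HIGH_DOSE"]],
                                              pref_low = alt_labels[["LOW_DOSE"]],
                                              pref_none = alt_labels[["NO_TREATMENT"]]))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$min_utility_difference,
                                    y = .data$rate,
                                    colour = .data$alternative)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(background_proportion ~ family) +
    ggplot2::labs(x = "minimum utility difference", y = "preference rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
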