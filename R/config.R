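#' Scenario configuration
#'
#' One sensitivity-analysis scenario is defined by the distribution family
#' over the serious-risk intervals, the background risk proportion, the
#' minimum utility difference, the relapse severity, the number of
#' Monte-Carlo iterations and a master seed.
#'
#' @param risk_family `"uniform"` or `"trunc_exp"`.
#' @param k Rate multiplier of the truncated exponential (ignored for the
#'   uniform family).
#' @param background_proportion Share of active-treatment serious risk
#'   attributed to the untreated disease course, in `[0, 0.5]`.
#' @param min_utility_difference Minimum gap between non-lethal and lethal
#'   utilities, in `[0, 0.99]`.
#' @param edss Relapse severity at onset, 4 or 5.
#' @param iterations Monte-Carlo iterations (default 10000).
#' @param seed Master seed; per-stage streams are derived from it with
#'   [derive_seed()].
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(risk_family = "uniform", k = 5,
                            background_proportion = 0,
                            min_utility_difference = 0,
                            edss = 4, iterations = 10000, seed = 1) {
  if (!risk_family %in% c("uniform", "trunc_exp")) {
    abort("risk_family must be \"uniform\" or \"trunc_exp\"")
  }
  if (background_proportion < 0 || background_proportion > 0.5) {
    abort("background_proportion must lie in [0, 0.5]")
  }
  if (min_utility_difference < 0 || min_utility_difference > 0.99) {
    abort("min_utility_difference must lie in [0, 0.99]")
  }
  stopifnot(edss %in% c(4, 5), iterations >= 1, k > 0)
  structure(list(risk_family = risk_family, k = k,
                 background_proportion = background_proportion,
                 min_utility_difference = min_utility_difference,
                 edss = edss, iterations = as.integer(iterations),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  fam <- if (x$risk_family == "uniform") "uniform"
         else sprintf("truncated exponential (k = %g)", x$k)
  cat(sprintf(
    paste0("Scenario: %s serious-risk distributions, background %.0f%%, ",
           "delta %.2f, EDSS %d, %d iterations, seed %d\n"),
    fam, 100 * x$background_proportion, x$min_utility_difference,
    x$edss, x$iterations, x$seed))
  invisible(x)
}

#' Read or write a scenario configuration
#'
#' Configurations are stored as YAML with keys `risk_family`, `k`,
#' `background_proportion`, `min_utility_difference`, `edss`, `iterations`
#' and `seed`. Missing keys take their defaults; unknown keys are rejected.
#' `write_scenario_config()` round-trips exactly.
#'
#' @param path File to read or write.
#' @return `read_scenario_config()` returns a [scenario_config()];
#'   `write_scenario_config()` returns `path` invisibly.
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("risk_family", "k", "background_proportion",
               "min_utility_difference", "edss", "iterations", "seed")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    abort(paste0("unknown configuration keys: ",
                 paste(unknown, collapse = ", ")))
  }
  do.call(scenario_config, raw)
}

#' @rdname read_scenario_config
#' @param config A [scenario_config()].
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Derive a named seed substream from a master seed
#'
#' Stages of the pipeline (effectiveness fits, risk sampling, utility
#' sampling, evaluation, grid cells) draw their seeds deterministically
#' from one master seed and a stage name, so any stage can be re-run
#' bit-identically in isolation. A polynomial rolling hash of the name is
#' combined with the master seed modulo `2^31 - 1`.
#'
#' @param master Integer master seed.
#' @param name Stage name.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, name) {
  p <- 2147483647
  h <- as.double(master %% p)
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% p
  as.integer(h %% (p - 2) + 1)
}

#' Write scenario or grid results to plain-text files
#'
#' Writes the expected-utility draws (scenarios only), the preference
#' rates, the grid summary (grids only) and a YAML run manifest that
#' echoes the configuration, per-stage seeds, package version and fixture
#' checksums, sufficient to regenerate every output bit-identically.
#'
#' @param result An `msbr_scenario` or `msbr_grid` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(paste0("cannot create output directory: ", dir))
  paths <- character(0)
  if (inherits(result, "msbr_scenario")) {
    eu_path <- file.path(dir, "expected_utilities.tsv")
    readr::write_tsv(tibble::as_tibble(result$eu), eu_path)
    pref_path <- file.path(dir, "preference_rates.tsv")
    readr::write_tsv(tidy(result), pref_path)
    paths <- c(eu_path, pref_path)
    config <- result$config
    seeds <- result$seeds
  } else if (inherits(result, "msbr_grid")) {
    grid_path <- file.path(dir, "grid_summary.tsv")
    readr::write_tsv(tibble::as_tibble(result), grid_path)
    paths <- grid_path
    config <- attr(result, "base_config")
    seeds <- list(base_seed = attr(result, "seed"))
  } else {
    abort("write_results expects an msbr_scenario or msbr_grid")
  }
  manifest_path <- file.path(dir, "run_manifest.yaml")
  yaml::write_yaml(run_manifest(config, seeds), manifest_path)
  invisible(c(paths, manifest_path))
}

#' Run manifest
#'
#' @param config Configuration to echo (a [scenario_config()] or plain
#'   list).
#' @param seeds Named list of per-stage seeds.
#' @return A list with the configuration echo, seeds, package version,
#'   fixture checksums and a timestamp.
#' @export
run_manifest <- function(config, seeds) {
  manifest <- utils::read.delim(fixture_path("MANIFEST.tsv"),
                                stringsAsFactors = FALSE)
  list(
    config = unclass(config),
    seeds = seeds,
    package_version = as.character(utils::packageVersion("msbr")),
    fixture_checksums = setNames(as.list(manifest$md5), manifest$file),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}
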