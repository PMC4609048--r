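#' Utility classes of the clinical outcomes
#'
#' To reduce dimensionality the 56 clinical outcomes are grouped at common
#' utility levels: 2 benefit states times 8 adverse-effect classes
#' (`NO_AE`, `NON_SERIOUS`, `LIFE_THREAT`, `PERS_MILD`, `PERS_INT`,
#' `PERS_SEVERE`, `LETHAL_QUICK`, `LETHAL_PAINFUL`), 16 classes in all.
#' Class labels are `"BENEFIT:AE_CLASS"`, e.g. `"REDUCED:NO_AE"`.
#'
#' @return Character vector of the 16 class labels, reduced-relapse block
#'   first, adverse-effect classes from best to worst.
#' @export
utility_classes <- function() {
  as.character(outer(AE_CLASSES, BENEFIT_STATES,
                     function(a, b) paste(b, a, sep = ":")))
}

# default grouping of persistent and lethal outcomes by clinical character
persistent_class_map <- c(
  "Osteonecrosis" = "PERS_MILD",
  "Diabetes" = "PERS_MILD",
  "Cardio-pulmonary distress" = "PERS_SEVERE",
  "Ventricular arrhythmia/cardiac arrest" = "PERS_SEVERE",
  "Seizure" = "PERS_SEVERE",
  "Psychosis" = "PERS_INT",
  "Myopathy" = "PERS_INT",
  "Hepatotoxicity" = "PERS_INT",
  "Gastrointestinal haemorrhage" = "PERS_INT"
)
lethal_class_map <- c(
  "Pancreatitis" = "LETHAL_PAINFUL",
  "Cardio-pulmonary distress" = "LETHAL_PAINFUL",
  "Gastrointestinal haemorrhage" = "LETHAL_PAINFUL",
  "Acute severe allergy" = "LETHAL_QUICK",
  "Ventricular arrhythmia/cardiac arrest" = "LETHAL_QUICK",
  # protracted clinical course: grouped with the painful lethal outcomes
  "Diabetes" = "LETHAL_PAINFUL",
  "Hepatotoxicity" = "LETHAL_PAINFUL",
  "Seizure" = "LETHAL_PAINFUL"
)

#' Map a serious effect-outcome combination to its utility class
#'
#' All life-threatening outcomes share one class. Persistent outcomes fall
#' in three groups: osteonecrosis and diabetes are least undesirable
#' (generally manageable, no life-threatening trigger); persistent
#' cardio-pulmonary distress, ventricular arrhythmia/cardiac arrest and
#' seizures are most severe; the remaining persistent outcomes (psychosis,
#' myopathy, hepatotoxicity, gastrointestinal haemorrhage) are
#' intermediate. Lethal outcomes split into quick deaths with little
#' suffering (anaphylaxis, cardiac arrest) and deaths extended in time and
#' very painful (pancreatitis, cardio-pulmonary distress, gastrointestinal
#' haemorrhage; lethal diabetes, hepatotoxicity and seizure are grouped
#' here too on account of their protracted course — override via
#' `class_map` if preferred).
#'
#' @param effect,outcome Character vectors (recycled) naming the
#'   combination; outcomes are `"DEATH"`, `"PERSISTENT"`,
#'   `"LIFE_THREATENING"`.
#' @param class_map Optional named character vector of overrides, names
#'   `"effect/outcome"`, values adverse-effect classes.
#' @return Character vector of adverse-effect class labels.
#' @export
#' @examples
#' assign_utility_class("Psychosis", "PERSISTENT") # PERS_INT
assign_utility_class <- function(effect, outcome, class_map = NULL) {
  known <- adverse_effect_specs()$effect
  if (any(!effect %in% known)) {
    abort(paste0("unknown adverse effect: ",
                 paste(setdiff(effect, known), collapse = ", ")))
  }
  res <- dplyr::case_when(
    outcome == "LIFE_THREATENING" ~ "LIFE_THREAT",
    outcome == "PERSISTENT" ~ unname(persistent_class_map[effect]),
    outcome == "DEATH" ~ unname(lethal_class_map[effect])
  )
  if (anyNA(res)) abort("combination outside the included effect-outcome set")
  if (!is.null(class_map)) {
    key <- paste(effect, outcome, sep = "/")
    hit <- !is.na(class_map[key])
    res[hit] <- unname(class_map[key][hit])
  }
  res
}

#' Construct a utility constraint system
#'
#' Low-level constructor for an arbitrary system of strict-order
#' constraints (`u[worse] < u[better]`) on utilities in the unit cube,
#' optionally with a minimum difference `delta` between a lethal block and
#' the remaining classes. [build_utility_constraints()] uses this to build
#' the full 16-class clinical system; small custom systems are useful for
#' audit and validation.
#'
#' @param classes Character vector of class labels.
#' @param edges Tibble or data frame with columns `worse`, `better`.
#' @param lethal Labels forming the lethal block (possibly empty).
#' @param delta Minimum difference between the two blocks.
#' @param edss_level Optional severity tag carried along.
#' @return A `utility_constraints` object; errors if the edge relation is
#'   cyclic or refers to unknown classes.
#' @export
utility_constraint_system <- function(classes, edges, lethal = character(0),
                                      delta = 0, edss_level = NA_integer_) {
  stopifnot(is.character(classes), !anyDuplicated(classes),
            all(lethal %in% classes), delta >= 0, delta <= 0.99)
  edges <- tibble::as_tibble(edges)[, c("worse", "better")]
  system <- structure(
    list(classes = classes, edges = edges, lethal = lethal,
         delta = delta, edss_level = edss_level),
    class = "utility_constraints"
  )
  topological_order(system)  # errors on a cycle
  system
}

#' Serialise a constraint system to structured text
#'
#' Writes (or reads back) the class labels, edge pairs, lethal block,
#' `delta` and severity level as YAML for audit.
#'
#' @param system A `utility_constraints` object.
#' @param path File path.
#' @return `write_utility_constraints()` returns `path` invisibly;
#'   `read_utility_constraints()` returns the reconstructed system.
#' @export
write_utility_constraints <- function(system, path) {
  stopifnot(inherits(system, "utility_constraints"))
  yaml::write_yaml(list(
    classes = system$classes,
    edges = purrr::map2(system$edges$worse, system$edges$better,
                        function(w, b) list(worse = w, better = b)),
    lethal = as.list(system$lethal),
    delta = system$delta,
    edss_level = system$edss_level
  ), path)
  invisible(path)
}

#' @rdname write_utility_constraints
#' @export
read_utility_constraints <- function(path) {
  raw <- yaml::read_yaml(path)
  utility_constraint_system(
    classes = unlist(raw$classes),
    edges = purrr::map_dfr(raw$edges, tibble::as_tibble),
    lethal = as.character(unlist(raw$lethal)),
    delta = raw$delta,
    edss_level = if (is.null(raw$edss_level)) NA_integer_ else raw$edss_level
  )
}

#' Build the qualitative utility constraint system
#'
#' Encodes the clinical preference relations among the 16 utility classes
#' as a strict partial order on the unit cube, plus a minimum utility
#' difference between the non-lethal and lethal blocks:
#' \itemize{
#'   \item within each benefit state, the vertical chain
#'     `NO_AE > NON_SERIOUS > LIFE_THREAT > PERS_MILD > PERS_INT >
#'     PERS_SEVERE > LETHAL_QUICK > LETHAL_PAINFUL`;
#'   \item horizontally, a reduced relapse beats a standard relapse at
#'     every adverse-effect class;
#'   \item a reduced relapse with a non-serious adverse event beats a
#'     standard relapse with none (the gained EDSS point outlasts a
#'     transient adverse event);
#'   \item `min(non-lethal utilities) >= max(lethal utilities) + delta`;
#'   \item relapses starting at EDSS 4: remaining at EDSS 4 with a
#'     non-serious event beats improving to EDSS 3 with a life-threatening
#'     event, and EDSS 4 plus a mild persistent disability beats EDSS 3
#'     plus a severe one;
#'   \item relapses starting at EDSS 5: remaining at EDSS 5 with a
#'     non-serious event beats improving to EDSS 4 with an intermediate
#'     persistent disability.
#' }
#'
#' @param edss_level Relapse severity at onset, 4 or 5.
#' @param delta Minimum utility difference between non-lethal and lethal
#'   outcomes, in `[0, 0.99]`; a proxy for risk aversiveness.
#' @return An object of class `utility_constraints`: the class labels, a
#'   tibble of strict edges (`worse`, `better`), the lethal-class labels,
#'   `delta` and `edss_level`. Construction fails if the edge relation has
#'   a cycle.
#' @export
build_utility_constraints <- function(edss_level = 4, delta = 0) {
  stopifnot(edss_level %in% c(4, 5))
  if (delta < 0 || delta > 0.99) {
    abort("delta must lie in [0, 0.99]")
  }
  cls <- function(benefit, ae) paste(benefit, ae, sep = ":")
  chain <- AE_CLASSES
  edges <- dplyr::bind_rows(
    # vertical chains, worse -> better
    purrr::map_dfr(BENEFIT_STATES, function(b) {
      tibble::tibble(worse = cls(b, chain[-1]), better = cls(b, chain[-8]))
    }),
    # reduced beats standard at equal adverse-effect class
    tibble::tibble(worse = cls("STANDARD", chain), better = cls("REDUCED", chain)),
    # reduced + non-serious beats standard + nothing
    tibble::tibble(worse = cls("STANDARD", "NO_AE"),
                   better = cls("REDUCED", "NON_SERIOUS"))
  )
  if (edss_level == 4) {
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      worse = c(cls("REDUCED", "LIFE_THREAT"), cls("REDUCED", "PERS_SEVERE")),
      better = c(cls("STANDARD", "NON_SERIOUS"), cls("STANDARD", "PERS_MILD"))
    ))
  } else {
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      worse = cls("REDUCED", "PERS_INT"),
      better = cls("STANDARD", "NON_SERIOUS")
    ))
  }
  system <- structure(
    list(classes = utility_classes(),
         edges = edges,
         lethal = as.character(outer(LETHAL_CLASSES, BENEFIT_STATES,
                                     function(a, b) paste(b, a, sep = ":"))),
         delta = delta,
         edss_level = edss_level),
    class = "utility_constraints"
  )
  topological_order(system)  # errors on a cycle
  system
}

#' @export
print.utility_constraints <- function(x, ...) {
  cat(sprintf(
    "Utility constraint system: %d classes, %d strict relations, delta = %g, EDSS %d at onset\n",
    length(x$classes), nrow(x$edges), x$delta, x$edss_level))
  invisible(x)
}

# Kahn's algorithm; errors with a diagnostic if the edge relation is cyclic.
topological_order <- function(system) {
  cls <- system$classes
  bad <- setdiff(c(system$edges$worse, system$edges$better), cls)
  if (length(bad)) abort(paste0("edges refer to unknown classes: ",
                                paste(bad, collapse = ", ")))
  edges <- system$edges
  indeg <- setNames(integer(length(cls)), cls)
  tab <- table(edges$better)
  indeg[names(tab)] <- as.integer(tab)
  order <- character(0)
  avail <- names(indeg)[indeg == 0L]
  while (length(avail)) {
    nxt <- sort(avail)[1]  # deterministic tie-break
    order <- c(order, nxt)
    avail <- setdiff(avail, nxt)
    out <- edges$better[edges$worse == nxt]
    indeg[out] <- indeg[out] - 1L
    avail <- union(avail, out[indeg[out] == 0L])
  }
  if (length(order) != length(cls)) {
    abort(paste0("constraint system is infeasible: cycle among ",
                 paste(setdiff(cls, order), collapse = ", ")))
  }
  order
}

#' One feasible utility assignment
#'
#' Returns a point satisfying every constraint: classes are placed in
#' topological order with evenly spaced values, the lethal block compressed
#' below the `delta` gap and the non-lethal block above it.
#'
#' @param system A [build_utility_constraints()] system.
#' @return Named numeric vector over the classes.
#' @export
feasible_utilities <- function(system) {
  stopifnot(inherits(system, "utility_constraints"))
  ord <- topological_order(system)
  lethal <- intersect(ord, system$lethal)
  nonlethal <- setdiff(ord, system$lethal)
  gap_floor <- (1 - system$delta) / 2
  spread <- function(labels, lo, hi) {
    setNames(lo + (hi - lo) * seq_along(labels) / (length(labels) + 1), labels)
  }
  u <- if (length(lethal) == 0L || length(nonlethal) == 0L) {
    spread(ord, 0, 1)
  } else {
    c(spread(lethal, 0, gap_floor),
      spread(nonlethal, gap_floor + system$delta, 1))
  }
  u <- u[system$classes]
  stopifnot(satisfies_constraints(matrix(u, nrow = 1,
                                         dimnames = list(NULL, system$classes)),
                                  system))
  u
}

#' Do utility rows satisfy a constraint system?
#'
#' @param draws Matrix (rows = draws) with columns named by the system's
#'   classes, or a `utility_draws` object.
#' @param system A [build_utility_constraints()] system.
#' @return Logical vector, one entry per row.
#' @export
satisfies_constraints <- function(draws, system) {
  u <- if (inherits(draws, "utility_draws")) draws$values else draws
  u <- u[, system$classes, drop = FALSE]
  ok <- rep(TRUE, nrow(u))
  for (i in seq_len(nrow(system$edges))) {
    ok <- ok & u[, system$edges$worse[i]] < u[, system$edges$better[i]]
  }
  nonlethal <- setdiff(system$classes, system$lethal)
  if (length(system$lethal) && length(nonlethal)) {
    gap <- apply(u[, nonlethal, drop = FALSE], 1, min) -
      apply(u[, system$lethal, drop = FALSE], 1, max)
    ok <- ok & (gap >= system$delta)
  }
  in_cube <- apply(u >= 0 & u <= 1, 1, all)
  ok & in_cube
}

#' Sample utility vectors uniformly from the constraint polytope
#'
#' Each class utility starts as an independent standard uniform variable;
#' conditioning that joint distribution on the qualitative relations gives
#' the uniform distribution on the constraint polytope, which is sampled by
#' coordinate-wise Gibbs updates: every class utility in turn is resampled
#' uniformly on the interval permitted by its neighbours in the order and
#' by the `delta` gap.
#'
#' @param system A [build_utility_constraints()] system.
#' @param n Number of retained draws.
#' @param burn_in Discarded initial sweeps (default 1000).
#' @param thin Keep every `thin`-th sweep (default 5).
#' @param seed Optional integer seed.
#' @return An object of class `utility_draws`: list with `values` (an
#'   `n x 16` matrix, columns named by class), the system, and the sampler
#'   settings.
#' @export
sample_utilities <- function(system, n, burn_in = 1000, thin = 5,
                             seed = NULL) {
  stopifnot(inherits(system, "utility_constraints"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  init <- feasible_utilities(system)
  idx <- setNames(seq_along(system$classes) - 1L, system$classes)
  values <- gibbs_polytope_cpp(
    init = unname(init[system$classes]),
    worse = unname(idx[system$edges$worse]),
    better = unname(idx[system$edges$better]),
    lethal = system$classes %in% system$lethal,
    delta = system$delta,
    n_keep = as.integer(n), burn_in = as.integer(burn_in),
    thin = as.integer(thin)
  )
  colnames(values) <- system$classes
  structure(list(values = values, system = system,
                 burn_in = burn_in, thin = thin, seed = seed),
            class = "utility_draws")
}

#' @export
print.utility_draws <- function(x, ...) {
  cat(sprintf("Utility draws: %d x %d (burn-in %d, thinning %d)\n",
              nrow(x$values), ncol(x$values), x$burn_in, x$thin))
  invisible(x)
}

#' @export
tidy.utility_draws <- function(x, ...) {
  tibble::as_tibble(x$values) |>
    dplyr::mutate(draw = dplyr::row_number()) |>
    tidyr::pivot_longer(-"draw", names_to = "utility_class",
                        values_to = "utility") |>
    tidyr::separate_wider_delim("utility_class", ":",
                                names = c("benefit", "ae_class"),
                                cols_remove = FALSE)
}

#' Gamble interpretation of the minimum utility difference
#'
#' Translates the opaque `delta` parameter into a standard-gamble
#' probability: the chance of the worst outcome at which the typical
#' patient is indifferent between the status quo (standard relapse, no
#' adverse event) and a gamble between the best outcome (reduced relapse,
#' no adverse event) and the worst outcome (a painful lethal event).
#' Computed per draw as `(u_best - u_statusquo) / (u_best - u_worst)` and
#' summarised by the median.
#'
#' @param draws A `utility_draws` object.
#' @return Scalar probability.
#' @export
gamble_indifference <- function(draws) {
  stopifnot(inherits(draws, "utility_draws"))
  u <- draws$values
  best <- u[, "REDUCED:NO_AE"]
  sq <- u[, "STANDARD:NO_AE"]
  worst <- pmin(u[, "REDUCED:LETHAL_PAINFUL"], u[, "STANDARD:LETHAL_PAINFUL"])
  p <- (best - sq) / (best - worst)
  median(p[best > worst])
}
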