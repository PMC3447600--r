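## End-to-end orchestration: calibration on a historical map pair, hold-out
## validation by overlay accuracy, and the three-scenario comparison run.

# derive reproducible per-stage seeds from one top-level seed
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 97L + match(stage, c("sample", "validate",
                                           "natural_development",
                                           "object_orientation",
                                           "ecosystem_priority")) * 1009L) %% 2147483647L
}

#' Calibrate the CA on an observed map pair
#'
#' Runs the full calibration protocol: random cell sampling, the three
#' per-class conversion logits, and the inter-epoch transition matrix. The
#' sampling frame excludes constraint-masked cells (structural
#' non-converters).
#'
#' @param map_t0,map_t1 aligned observed \code{\link{land_grid}}s.
#' @param drivers a \code{\link{driver_stack}}.
#' @param fraction sampling proportion (default 0.2, the published
#'   calibration protocol).
#' @param seed top-level seed; stage seeds are derived from it.
#' @param scheme a \code{\link{class_scheme}}.
#' @param exclude optional binary lattice of cells to keep out of the
#'   sampling frame (e.g. \code{masks$core_area}).
#' @return An object of class \code{"eca_calibration"}: \code{models}
#'   (logit per target class), \code{transition}
#'   (\code{\link{transition_matrix}}), the design-table size and settings.
#' @export
eca_calibrate <- function(map_t0, map_t1, drivers, fraction = 0.2, seed = 1,
                          scheme = default_scheme(), exclude = NULL) {
  design <- sample_cells(map_t0, map_t1, drivers, fraction = fraction,
                         seed = stage_seed(seed, "sample"), scheme = scheme,
                         exclude = exclude)
  models <- lapply(stats::setNames(nm = c("cultivated", "ecological",
                                          "construction")),
                   function(m) fit_logit(design, m, scheme))
  tm <- crosstab(map_t0, map_t1, scheme)
  structure(list(models = models, transition = tm, n_sampled = nrow(design),
                 fraction = fraction, seed = seed, scheme = scheme,
                 drivers = names(drivers$layers)),
            class = "eca_calibration")
}

#' @export
print.eca_calibration <- function(x, ...) {
  cat(sprintf("CA calibration: %d sampled cells (fraction %.2g, seed %d)\n",
              x$n_sampled, x$fraction, x$seed))
  for (m in x$models) print(m)
  invisible(x)
}

#' @export
coef.eca_calibration <- function(object, ...) {
  do.call(rbind, lapply(object$models, stats::coef))
}

#' @export
summary.eca_calibration <- function(object, ...) {
  cat("Fitted conversion-suitability coefficients (rows = target class):\n")
  print(round(coef(object), 4))
  cat("\nTransition matrix (km^2):\n")
  print(round(object$transition$area, 2))
  invisible(object)
}

#' @export
predict.eca_calibration <- function(object, drivers, normalized = TRUE, ...) {
  s <- lapply(object$models, predict_surface, drivers = drivers)
  if (normalized) theil_normalize(s) else s
}

#' Hold-out validation by overlay accuracy
#'
#' Re-simulates the calibration interval (t0 to t1) with macro targets set
#' to the observed t1 areas, then scores the simulated map cell-by-cell
#' against the observed t1 map.
#'
#' @param calibration an \code{\link{eca_calibrate}} result.
#' @param map_t0,map_t1 the observed maps.
#' @param drivers a \code{\link{driver_stack}}.
#' @param masks constraint masks (natural-development recipe is used).
#' @param seed run seed.
#' @param ... passed to \code{\link{scenario_config}}.
#' @return List: \code{accuracy} (proportion of matching cells),
#'   \code{simulation} (the \code{eca_simulation}).
#' @export
eca_validate <- function(calibration, map_t0, map_t1, drivers, masks,
                         seed = 1, ...) {
  at1 <- area_table(map_t1, calibration$scheme)
  targets <- macro_targets(stats::setNames(at1$area_km2, at1$class),
                           provenance = "markov", epoch = "t1",
                           tolerance_floor = 0.001 * sum(at1$area_km2))
  cfg <- scenario_config("natural_development",
                         seed = stage_seed(seed, "validate"), ...)
  sim <- run_scenario(map_t0, drivers, masks, calibration$models, cfg,
                      targets, calibration$scheme)
  list(accuracy = overlay_accuracy(sim$final, map_t1), simulation = sim)
}

#' Macro targets for the three policy scenarios
#'
#' Natural development projects the calibrated Markov matrix forward;
#' object orientation and ecosystem priority apply planning caps. Default
#' caps mirror the stringency of the published planning constraints
#' relative to the trend: the construction increment is capped at 32% of
#' the Markov-projected increment, and cultivated decline at 5.5% (object
#' orientation) or 8% (ecosystem priority, where more farmland returns to
#' forest).
#'
#' @param base area table (or named vector, km^2) at the simulation start
#'   epoch.
#' @param tm calibrated \code{\link{transition_matrix}}.
#' @param steps Markov steps to the target epoch (default 3, i.e. three
#'   five-year monitoring intervals).
#' @param construction_cap_frac planning construction-increment cap as a
#'   fraction of the Markov-projected increment.
#' @param cultivated_decline_oo,cultivated_decline_ep cultivated decline
#'   caps (percent) for the two planning scenarios.
#' @param tolerance_frac stopping-band half width.
#' @return Named list of \code{\link{macro_targets}} per scenario.
#' @export
scenario_targets <- function(base, tm, steps = 3,
                             construction_cap_frac = 0.32,
                             cultivated_decline_oo = 5.5,
                             cultivated_decline_ep = 8,
                             tolerance_frac = 0.01) {
  areas <- if (is.data.frame(base)) stats::setNames(base$area_km2, base$class) else base
  floor <- 0.001 * sum(areas)  # keep bands wider than allocation granularity
  nd <- markov_targets(areas, tm, steps = steps,
                       tolerance_frac = tolerance_frac, epoch = "target",
                       tolerance_floor = floor)
  increment <- max(nd$targets[["construction"]] - areas[["construction"]], 0)
  cap <- construction_cap_frac * increment
  oo <- planning_targets(areas, cap, cultivated_decline_oo,
                         tolerance_frac = tolerance_frac, epoch = "target",
                         tolerance_floor = floor)
  ep <- planning_targets(areas, cap, cultivated_decline_ep,
                         tolerance_frac = tolerance_frac, epoch = "target",
                         tolerance_floor = floor)
  list(natural_development = nd, object_orientation = oo,
       ecosystem_priority = ep)
}

#' Simulate all three policy scenarios and build the comparison report
#'
#' One simulation per scenario from a shared start map and top-level seed,
#' followed by the scenario comparison: per-class areas and changes,
#' ecological-land pattern metrics (LPI, COHESION, SPLIT, AI) and
#' key-ecological-land losses by security level.
#'
#' @param start_map \code{\link{land_grid}} at the simulation start epoch.
#' @param drivers a \code{\link{driver_stack}}.
#' @param masks named list of binary constraint/security lattices.
#' @param calibration an \code{\link{eca_calibrate}} result (or a named
#'   list of logit models plus a transition matrix).
#' @param targets a \code{\link{scenario_targets}} result.
#' @param seed top-level seed; per-scenario seeds derive from it.
#' @param scheme a \code{\link{class_scheme}}.
#' @param ... passed to \code{\link{scenario_config}} (e.g.
#'   \code{p_threshold}, \code{alpha}).
#' @return An object of class \code{"eca_report"}: \code{simulations}
#'   (named list of \code{eca_simulation}), \code{areas} (per-scenario
#'   area tables), \code{changes} (per-scenario
#'   \code{\link{area_change_summary}}), \code{metrics} (ecological-land
#'   pattern indices incl. the start epoch), \code{key_loss} (km^2 by
#'   security level) and \code{converged}.
#' @export
run_all_scenarios <- function(start_map, drivers, masks, calibration,
                              targets, seed = 1, scheme = default_scheme(),
                              ...) {
  models <- if (inherits(calibration, "eca_calibration"))
    calibration$models else calibration
  base_at <- area_table(start_map, scheme)
  base <- stats::setNames(base_at$area_km2, base_at$class)
  sims <- list(); areas <- list(); changes <- list(); metrics <- list()
  key_loss <- list(); converged <- list()
  metrics$status <- pattern_metrics(start_map, "ecological", scheme)
  sec <- masks[grep("^key_ecoland", names(masks))]
  names(sec) <- sub("^key_ecoland_(\\w+)_security$", "\\1", names(sec))
  # key-land masks may have been drawn on an earlier epoch; restrict them to
  # cells still ecological at the simulation start
  eco0 <- start_map$values == scheme$classes[["ecological"]]
  sec <- lapply(sec, function(m) (m > 0 & eco0) * 1L)
  for (sc in names(targets)) {
    cfg <- scenario_config(sc, seed = stage_seed(seed, sc), ...)
    sim <- run_scenario(start_map, drivers, masks, models, cfg,
                        targets[[sc]], scheme)
    sims[[sc]] <- sim
    at <- area_table(sim$final, scheme)
    areas[[sc]] <- at
    changes[[sc]] <- area_change_summary(base,
                                         stats::setNames(at$area_km2, at$class))
    metrics[[sc]] <- pattern_metrics(sim$final, "ecological", scheme)
    if (length(sec))
      key_loss[[sc]] <- key_ecoland_loss(start_map, sim$final, sec, scheme)
    converged[[sc]] <- all(sim$converged)
  }
  structure(list(simulations = sims, base = base_at, areas = areas,
                 changes = changes, metrics = do.call(rbind, metrics),
                 key_loss = key_loss, converged = converged, seed = seed),
            class = "eca_report")
}

#' @export
print.eca_report <- function(x, ...) {
  cat("Scenario comparison report (seed", x$seed, ")\n\n")
  eco <- vapply(x$areas, function(a) a$area_km2[a$class == "ecological"],
                numeric(1))
  cat("Final ecological-land area (km^2):\n")
  print(round(eco, 2))
  cat("\nEcological-land pattern metrics:\n")
  print(round(x$metrics, 3))
  if (length(x$key_loss)) {
    cat("\nKey-ecological-land loss (km^2):\n")
    print(round(do.call(rbind, x$key_loss), 3))
  }
  nc <- names(x$converged)[!unlist(x$converged)]
  if (length(nc)) cat("\nNot converged:", paste(nc, collapse = ", "), "\n")
  invisible(x)
}
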