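#' Cross-tabulate land-use transitions between two epochs
#'
#' Counts cells transitioning from each class at the first epoch (rows) to
#' each class at the second (columns) and converts counts to areas. Row sums
#' equal the first epoch's area table and column sums the second's, exactly.
#'
#' @param map_t0,map_t1 aligned \code{\link{land_grid}}s on the same scheme.
#' @param scheme a \code{\link{class_scheme}}.
#' @return An object of class \code{"transition_matrix"} with elements
#'   \code{cells} (count matrix), \code{area} (km^2 matrix), \code{cell_area}
#'   and \code{epochs}.
#' @export
crosstab <- function(map_t0, map_t1, scheme = default_scheme()) {
  stop_if_misaligned(map_t0, map_t1)
  v0 <- collapse_subclasses(map_t0$values, scheme)
  v1 <- collapse_subclasses(map_t1$values, scheme)
  keep <- v0 != map_t0$nodata & v1 != map_t1$nodata
  codes <- sort(scheme$classes)
  f0 <- factor(v0[keep], levels = codes, labels = names(codes))
  f1 <- factor(v1[keep], levels = codes, labels = names(codes))
  cells <- unclass(table(f0, f1))
  dimnames(cells) <- list(from = names(codes), to = names(codes))
  transition_matrix(cells * cell_area_km2(map_t0),
                    cells = cells, cell_area = cell_area_km2(map_t0),
                    epochs = c(map_t0$epoch %||% "t0", map_t1$epoch %||% "t1"))
}

#' Construct a transition matrix from inter-class areas
#'
#' @param area square numeric matrix of km^2 transitioning from the row
#'   class to the column class; dimnames give the class labels.
#' @param cells optional matching cell-count matrix.
#' @param cell_area cell area in km^2 (used when only one of the two forms
#'   is supplied).
#' @param epochs length-2 character vector of epoch labels.
#' @param step_years years spanned by one transition step.
#' @return An object of class \code{"transition_matrix"}.
#' @export
transition_matrix <- function(area, cells = NULL, cell_area = 0.01,
                              epochs = c("t0", "t1"), step_years = 5) {
  area <- as.matrix(area)
  if (nrow(area) != ncol(area)) stop("transition matrix must be square")
  if (any(area < 0)) stop("transition areas must be non-negative")
  structure(list(area = area, cells = cells, cell_area = cell_area,
                 epochs = epochs, step_years = step_years),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("Land-use transition matrix %s -> %s (km^2):\n",
              x$epochs[1], x$epochs[2]))
  print(round(x$area, 2))
  invisible(x)
}

#' Row-normalize a transition matrix into Markov probability form
#'
#' Each row of the area (or count) form is divided by its row total, giving
#' the probability that a cell of the row class at one epoch belongs to the
#' column class at the next. A class absent at the first epoch (empty row)
#' keeps an identity row and is flagged, never NaN-filled.
#'
#' @param tm a \code{\link{transition_matrix}} or a non-negative square
#'   matrix.
#' @return A row-stochastic matrix with attribute \code{"empty_rows"} naming
#'   any classes absent at the first epoch.
#' @examples
#' bj <- beijing_tables()
#' round(to_probability(bj$transition)["cultivated", ], 4)
#' @export
to_probability <- function(tm) {
  A <- if (inherits(tm, "transition_matrix")) tm$area else as.matrix(tm)
  if (any(A < 0)) stop("transition areas must be non-negative")
  rs <- rowSums(A)
  P <- A
  empty <- rs == 0
  P[!empty, ] <- A[!empty, , drop = FALSE] / rs[!empty]
  if (any(empty)) {
    P[empty, ] <- 0
    P[cbind(which(empty), which(empty))] <- 1
  }
  attr(P, "empty_rows") <- rownames(A)[empty]
  P
}

#' Project class areas forward through a Markov transition matrix
#'
#' @param x named numeric vector of class areas (or cell counts) at the base
#'   epoch.
#' @param P row-stochastic transition probability matrix (one step).
#' @param steps non-negative integer number of steps.
#' @return Projected vector after \code{steps} applications of \code{P};
#'   the total is conserved.
#' @export
project_markov <- function(x, P, steps = 1) {
  P <- if (inherits(P, "transition_matrix")) to_probability(P) else as.matrix(P)
  if (length(x) != nrow(P)) stop("dimension mismatch between state and matrix")
  if (steps < 0) stop("steps must be >= 0")
  y <- as.numeric(x)
  for (k in seq_len(steps)) y <- as.numeric(y %*% P)
  names(y) <- names(x) %||% rownames(P)
  y
}

## ---------------------------------------------------------------------------

#' Macro-scale class-area targets for a simulation
#'
#' Targets are the per-class areas the cellular automaton must reach; the CA
#' stops converting into (and out of) a class once its cell count enters the
#' closed band [target - N, target + N].
#'
#' @param targets named numeric vector of target areas in km^2 for all
#'   classes.
#' @param tolerance_frac band half-width N as a fraction of each class
#'   target (default 0.01).
#' @param tolerance_floor absolute lower bound on N (same units as the
#'   targets); keeps the band wider than the allocation granularity for
#'   tiny classes.
#' @param provenance \code{"markov"} (trend projection) or
#'   \code{"planning"} (policy caps).
#' @param epoch target epoch label.
#' @return An object of class \code{"macro_targets"}.
#' @export
macro_targets <- function(targets, tolerance_frac = 0.01,
                          provenance = c("markov", "planning"),
                          epoch = NULL, tolerance_floor = 0) {
  provenance <- match.arg(provenance)
  if (any(targets < 0)) stop("targets must be non-negative")
  structure(list(targets = targets,
                 tolerance = pmax(tolerance_frac * targets, tolerance_floor, 1e-9),
                 provenance = provenance, epoch = epoch),
            class = "macro_targets")
}

#' @export
print.macro_targets <- function(x, ...) {
  cat(sprintf("Macro area targets (%s%s):\n", x$provenance,
              if (!is.null(x$epoch)) paste0(", epoch ", x$epoch) else ""))
  print(round(x$targets, 2))
  invisible(x)
}

#' Check class counts against the Markov stopping band
#'
#' @param current named numeric vector of current per-class cell counts (or
#'   areas; units must match \code{targets}).
#' @param targets named numeric vector of target values in the same units.
#' @param tolerance band half-width N per class (recycled).
#' @return Character vector over classes: \code{"met"} if
#'   |current - target| <= N (closed band), else \code{"below"} or
#'   \code{"above"}.
#' @export
stop_band_check <- function(current, targets, tolerance) {
  d <- current - targets
  out <- ifelse(abs(d) <= tolerance, "met", ifelse(d < 0, "below", "above"))
  names(out) <- names(targets) %||% names(current)
  out
}

#' Derive planning-constrained macro targets from a base area table
#'
#' Implements the policy-scenario macro prediction: construction land grows
#' by at most a fixed increment, cultivated land declines by at most a fixed
#' percentage, and the ecological + other balance absorbs the remainder so
#' the landscape total is conserved. The ecological/other split preserves
#' their base-epoch ratio.
#'
#' @param base area table (as from \code{\link{area_table}}) for the start
#'   epoch, or a named numeric vector of areas in km^2.
#' @param construction_increment_cap maximum construction-land increment in
#'   km^2.
#' @param cultivated_decline_cap_pct maximum cultivated-land decline in
#'   percent of the base area.
#' @param tolerance_frac stopping-band half width as a fraction of each
#'   target.
#' @param epoch target epoch label.
#' @return A \code{\link{macro_targets}} with provenance \code{"planning"}.
#' @export
planning_targets <- function(base, construction_increment_cap,
                             cultivated_decline_cap_pct,
                             tolerance_frac = 0.01, epoch = NULL,
                             tolerance_floor = 0) {
  areas <- if (is.data.frame(base)) stats::setNames(base$area_km2, base$class) else base
  need <- c("cultivated", "ecological", "construction", "other")
  if (!all(need %in% names(areas))) stop("base must cover the four classes")
  total <- sum(areas)
  tgt <- areas
  tgt["construction"] <- areas["construction"] + construction_increment_cap
  tgt["cultivated"] <- areas["cultivated"] * (1 - cultivated_decline_cap_pct / 100)
  if (any(tgt < 0)) stop("caps produce a negative class target")
  resid <- total - tgt["construction"] - tgt["cultivated"]
  if (resid < 0) stop("caps exceed the landscape total")
  eo <- areas[c("ecological", "other")]
  tgt[c("ecological", "other")] <- resid * eo / sum(eo)
  macro_targets(tgt[need], tolerance_frac = tolerance_frac,
                provenance = "planning", epoch = epoch,
                tolerance_floor = tolerance_floor)
}

#' Trend (Markov) macro targets from an estimated transition matrix
#'
#' @param base area table or named area vector for the start epoch.
#' @param tm estimated \code{\link{transition_matrix}} (one calibration
#'   step).
#' @param steps number of transition steps to project.
#' @param tolerance_frac stopping-band half width as a fraction of each
#'   target.
#' @param epoch target epoch label.
#' @return A \code{\link{macro_targets}} with provenance \code{"markov"}.
#' @export
markov_targets <- function(base, tm, steps = 1, tolerance_frac = 0.01,
                           epoch = NULL, tolerance_floor = 0) {
  areas <- if (is.data.frame(base)) stats::setNames(base$area_km2, base$class) else base
  P <- to_probability(tm)
  areas <- areas[rownames(P)]
  macro_targets(project_markov(areas, P, steps),
                tolerance_frac = tolerance_frac, provenance = "markov",
                epoch = epoch, tolerance_floor = tolerance_floor)
}

#' Write / read a transition matrix as CSV
#'
#' Classes appear as both the header row and the first column.
#' @param tm a \code{\link{transition_matrix}}.
#' @param path CSV path.
#' @return \code{write_transition_csv} returns \code{path} invisibly;
#'   \code{read_transition_csv} returns a \code{transition_matrix}.
#' @export
write_transition_csv <- function(tm, path) {
  utils::write.csv(as.data.frame(tm$area), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_transition_csv
#' @export
read_transition_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  dimnames(m) <- list(from = rownames(m), to = colnames(m))
  transition_matrix(m)
}
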