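## Cellular-automaton micro-evolution engine: composes global suitability,
## neighborhood share, constraint masks and a stochastic disturbance into the
## synthesis conversion probability, then allocates conversions iteratively
## until every class reaches its macro demand band.

# shift a matrix by (di, dj), padding with `fill`
shift_mat <- function(m, di, dj, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- seq_len(nr); ci <- seq_len(nc)
  rs <- ri - di; cs <- ci - dj
  rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
  out[ri[rok], ci[cok]] <- m[rs[rok], cs[cok]]
  out
}

#' Moore-neighborhood share of a class
#'
#' For every cell, the fraction of its in-bounds window neighbors (the cell
#' itself excluded) that belong to class \code{class_m}. With the default
#' 3x3 window an interior cell has 8 neighbors, an edge cell 5 and a corner
#' cell 3; the denominator is always the in-bounds neighbor count.
#'
#' @param grid a \code{\link{land_grid}} or an integer matrix of codes.
#' @param class_m class label or integer code.
#' @param window odd window width >= 3 (default 3).
#' @param cell optional (row, col); if given, the scalar share for that
#'   cell is returned instead of the full lattice.
#' @param scheme a \code{\link{class_scheme}} (used when \code{class_m} is
#'   a label).
#' @return Matrix of shares in [0, 1] (or a scalar if \code{cell} given).
#' @export
neighborhood_share <- function(grid, class_m, window = 3, cell = NULL,
                               scheme = default_scheme()) {
  v <- if (inherits(grid, "land_grid")) grid$values else grid
  code <- if (is.character(class_m)) scheme$classes[[class_m]] else as.integer(class_m)
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  w2 <- (window - 1) / 2
  like <- matrix(0, nrow(v), ncol(v))
  nbrs <- matrix(0, nrow(v), ncol(v))
  ind <- (v == code) * 1L
  ones <- matrix(1L, nrow(v), ncol(v))
  for (di in -w2:w2) for (dj in -w2:w2) {
    if (di == 0 && dj == 0) next
    like <- like + shift_mat(ind, di, dj, 0L)
    nbrs <- nbrs + shift_mat(ones, di, dj, 0L)
  }
  out <- like / nbrs
  if (!is.null(cell)) return(out[cell[1], cell[2]])
  out
}

#' Stochastic disturbance factor
#'
#' Controlled randomness injected into the synthesis conversion probability:
#' R = 1 + (-ln(gamma))^alpha, with gamma a uniform(0, 1) draw and alpha an
#' integer in 1..10 governing the weight of the disturbance. (The published
#' source prints this expression only as a figure; the form implemented here
#' is the standard stochastic-disturbance term of CA land-use models and is
#' documented as reconstructed.)
#'
#' @param gamma draw(s) in the open interval (0, 1).
#' @param alpha integer in 1..10.
#' @return R >= 1, same shape as \code{gamma}.
#' @examples
#' stochastic_factor(exp(-1), 7)   # exactly 2 for every alpha
#' @export
stochastic_factor <- function(gamma, alpha) {
  if (any(gamma <= 0 | gamma >= 1)) stop("gamma must lie in (0, 1)")
  if (alpha < 1 || alpha > 10 || alpha != round(alpha))
    stop("alpha must be an integer in 1..10")
  1 + (-log(gamma))^alpha
}

#' Scenario configuration for a CA run
#'
#' @param name one of \code{"natural_development"} (trend continuation,
#'   only basic farmland protected), \code{"object_orientation"} (planning
#'   caps on construction growth and cultivated decline; water and basic
#'   farmland protected) or \code{"ecosystem_priority"} (core protection
#'   areas inviolable, no construction on steep slopes, no conversion out
#'   of ecological land).
#' @param targets_source \code{"markov"} or \code{"planning"}.
#' @param p_threshold conversion threshold on the normalized synthesis
#'   probability, in (0, 1).
#' @param alpha stochastic-disturbance exponent, integer 1..10.
#' @param tolerance_frac stopping-band half width N as a fraction of each
#'   class target.
#' @param max_iter iteration cap (default 3000; with the default 0.8
#'   threshold each sweep converts only the top slice of candidates, so
#'   realistic demands take on the order of a thousand sweeps).
#' @param seed RNG seed for the run.
#' @param threshold_direction \code{"ge"} (default: cells at or above the
#'   threshold convert) or \code{"lt"} (literal published comparison; kept
#'   as an option because it inverts suitability).
#' @return An object of class \code{"scenario_config"}.
#' @export
scenario_config <- function(name = c("natural_development",
                                     "object_orientation",
                                     "ecosystem_priority"),
                            targets_source = NULL,
                            p_threshold = 0.8, alpha = 1,
                            tolerance_frac = 0.01, max_iter = 3000,
                            seed = 1, threshold_direction = c("ge", "lt")) {
  name <- match.arg(name)
  threshold_direction <- match.arg(threshold_direction)
  if (is.null(targets_source))
    targets_source <- if (name == "natural_development") "markov" else "planning"
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must be in (0, 1)")
  if (alpha < 1 || alpha > 10 || alpha != round(alpha))
    stop("alpha must be an integer in 1..10")
  structure(list(name = name, targets_source = targets_source,
                 p_threshold = p_threshold, alpha = as.integer(alpha),
                 tolerance_frac = tolerance_frac,
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 threshold_direction = threshold_direction),
            class = "scenario_config")
}

#' Read a scenario configuration from YAML
#'
#' The YAML keys mirror \code{\link{scenario_config}} arguments
#' field-for-field.
#' @param path YAML path.
#' @return A \code{scenario_config}.
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(scenario_config, y)
}

#' Build the per-cell constraint mask for a scenario
#'
#' Encodes each scenario's mandatory protections as multiplicative
#' constraints con(i) with 0 = conversion prohibited:
#' \itemize{
#'   \item natural development: basic farmland may not change;
#'   \item object orientation: basic farmland and water may not change;
#'   \item ecosystem priority: core protection areas (basic farmland,
#'     water, first-level water sources, nature reserves, scenic spots,
#'     geological parks, supplied jointly as \code{core_area}) may not
#'     change, cells on slopes above 25 degrees may not convert to
#'     construction, and no cell may convert out of ecological land.
#' }
#'
#' @param config a \code{\link{scenario_config}} (or a scenario name).
#' @param masks named list of binary lattices; requires
#'   \code{basic_farmland}, plus \code{water} (object orientation) or
#'   \code{water}, \code{core_area} and \code{steep_slope} (ecosystem
#'   priority).
#' @return An object of class \code{"constraint_mask"}: logical lattices
#'   \code{block_out} (no conversion at all) and
#'   \code{block_to_construction}, plus \code{protect_ecological} (dynamic
#'   out-conversion ban on ecological cells).
#' @export
build_constraints <- function(config, masks) {
  name <- if (inherits(config, "scenario_config")) config$name else config
  need <- switch(name,
                 natural_development = "basic_farmland",
                 object_orientation = c("basic_farmland", "water"),
                 ecosystem_priority = c("basic_farmland", "water",
                                        "core_area", "steep_slope"),
                 stop("unknown scenario: ", name))
  miss <- setdiff(need, names(masks))
  if (length(miss))
    stop("scenario '", name, "' requires mask(s): ", paste(miss, collapse = ", "))
  as_l <- function(m) m > 0
  block_out <- switch(name,
    natural_development = as_l(masks$basic_farmland),
    object_orientation = as_l(masks$basic_farmland) | as_l(masks$water),
    ecosystem_priority = as_l(masks$basic_farmland) | as_l(masks$water) |
      as_l(masks$core_area))
  block_to_c <- if (name == "ecosystem_priority") as_l(masks$steep_slope)
                else matrix(FALSE, nrow(block_out), ncol(block_out))
  structure(list(block_out = block_out, block_to_construction = block_to_c,
                 protect_ecological = (name == "ecosystem_priority"),
                 scenario = name),
            class = "constraint_mask")
}

#' Synthesis conversion probability
#'
#' The per-cell development probability composed from the global (logistic)
#' suitability, the neighborhood share, the constraint value and the
#' stochastic disturbance: P_T = P_global * Omega * con * R. During
#' simulation the result is subsequently min-max normalized to (0, 1) over
#' the iteration's candidate cells before the threshold comparison.
#'
#' @param p_global global suitability in [0, 1].
#' @param omega neighborhood share in [0, 1].
#' @param con constraint value in [0, 1] (0 prohibits).
#' @param r stochastic factor >= 1.
#' @return P_T (pre-normalization), same shape as the inputs.
#' @export
synthesis_probability <- function(p_global, omega, con, r) {
  p_global * omega * con * r
}

# row-major cell index, used for deterministic tie-breaking
row_major_index <- function(d) {
  m <- matrix(seq_len(d[1] * d[2]), d[1], d[2], byrow = TRUE)
  as.vector(m)
}

#' One CA allocation iteration
#'
#' Phase A (development): unconstrained non-construction cells of surplus
#' classes whose normalized construction synthesis probability passes the
#' threshold convert to construction, highest probability first, capped by
#' the remaining construction demand. Phase B (reallocation): remaining
#' convertible cells evaluate the synthesis probability of each deficit
#' class among {cultivated, ecological} and convert to the
#' maximal-probability class if it passes the threshold, again demand
#' capped. A class accepts conversions only while below its target and
#' releases cells only while above it (per-source release budgets), so
#' every conversion moves both classes involved strictly toward their
#' targets and total imbalance decreases monotonically; the stopping band
#' is evaluated at the run level (\code{\link{run_scenario}}).
#'
#' @param state integer matrix of class codes.
#' @param surfaces \code{\link{theil_normalize}}d suitability surfaces for
#'   cultivated, ecological and construction.
#' @param constraints a \code{\link{build_constraints}} result.
#' @param targets_cells named numeric vector of per-class target cell
#'   counts.
#' @param tolerance_cells named numeric stopping-band half widths in cells.
#' @param config a \code{\link{scenario_config}}.
#' @param scheme a \code{\link{class_scheme}}.
#' @param window neighborhood window width.
#' @param cache optional per-run cache from \code{step_cache} (neighborhood
#'   like-counts maintained incrementally across iterations); built fresh
#'   when NULL.
#' @return List: updated \code{state}, per-class \code{counts},
#'   \code{status} (met/below/above) and \code{converted} (cells changed
#'   this iteration). Uses the current RNG stream (one fresh gamma draw per
#'   cell per iteration).
#' @export
iterate_step <- function(state, surfaces, constraints, targets_cells,
                         tolerance_cells, config, scheme = default_scheme(),
                         window = 3, cache = NULL) {
  codes <- sort(scheme$classes)
  labs <- names(codes)
  d <- dim(state)
  if (is.null(cache)) cache <- step_cache(state, scheme, window)
  counts <- cache$counts[labs]
  status <- stop_band_check(counts, targets_cells[labs],
                            tolerance_cells[labs])
  # per-source release budgets: a class may lose only its excess over target
  release <- pmax(floor(counts - targets_cells[labs]), 0)
  # one fresh disturbance draw per cell per iteration
  r_vec <- stochastic_factor(stats::runif(length(state)), config$alpha)
  rmi <- cache$rmi
  passes <- function(p_norm) {
    if (config$threshold_direction == "ge") p_norm >= config$p_threshold
    else p_norm < config$p_threshold
  }
  ss <- surfaces$surfaces
  # dynamic out-conversion protection of ecological land (scenario III)
  block_out <- constraints$block_out
  if (isTRUE(constraints$protect_ecological))
    block_out <- block_out | (state == scheme$classes[["ecological"]])
  # cells may leave only classes above their target, within release budget
  surplus <- matrix(FALSE, d[1], d[2])
  for (m in labs[release >= 1]) surplus[state == codes[[m]]] <- TRUE
  convertible <- surplus & !block_out
  converted <- 0L

  # min-max normalize over candidates, threshold, enforce release budgets,
  # cap by demand; all arithmetic on the candidate index vector only
  allocate <- function(cand_idx, p_raw, demand) {
    if (!length(cand_idx) || demand < 1) return(integer(0))
    rng <- range(p_raw)
    if (rng[2] <= rng[1]) return(integer(0))
    p_norm <- (p_raw - rng[1]) / (rng[2] - rng[1])
    keep <- passes(p_norm) & p_raw > 0
    sel <- cand_idx[keep]
    if (!length(sel)) return(integer(0))
    ord <- order(-p_norm[keep], rmi[sel])
    sel <- sel[ord]
    src <- match(state[sel], codes)
    within <- stats::ave(seq_along(sel), src, FUN = seq_along) <=
      release[labs[src]]
    sel <- sel[within]
    if (!length(sel)) return(integer(0))
    sel[seq_len(min(length(sel), floor(demand)))]
  }
  apply_conversion <- function(sel, mcode) {
    from <- state[sel]
    for (k in unique(from)) {
      m <- labs[match(k, codes)]
      release[m] <<- release[m] - sum(from == k)
    }
    state[sel] <<- mcode
    convertible[sel] <<- FALSE
    cache_update(cache, sel, from, mcode, d)
    converted <<- converted + length(sel)
  }

  # Phase A: development (conversions into construction)
  ccode <- scheme$classes[["construction"]]
  if (targets_cells[["construction"]] - counts[["construction"]] >= 1) {
    cand_idx <- which(convertible & state != ccode &
                        !constraints$block_to_construction)
    omega <- cache$like[["construction"]][cand_idx] / cache$nbrs[cand_idx]
    p_raw <- synthesis_probability(ss$construction[cand_idx], omega, 1,
                                   r_vec[cand_idx])
    sel <- allocate(cand_idx, p_raw,
                    targets_cells[["construction"]] - counts[["construction"]])
    if (length(sel)) apply_conversion(sel, ccode)
  }

  # Phase B: reallocation among the non-construction classes with fitted
  # suitability (cells never convert INTO construction here, and
  # construction is absorbing: its cells are never surplus candidates once
  # all three scenarios have non-decreasing construction demand)
  for (m in c("cultivated", "ecological")) {
    mcode <- codes[[m]]
    if (targets_cells[[m]] - cache$counts[[m]] < 1) next
    cand_idx <- which(convertible & state != mcode & state != ccode)
    omega <- cache$like[[m]][cand_idx] / cache$nbrs[cand_idx]
    p_raw <- synthesis_probability(ss[[m]][cand_idx], omega, 1,
                                   r_vec[cand_idx])
    sel <- allocate(cand_idx, p_raw, targets_cells[[m]] - cache$counts[[m]])
    if (length(sel)) apply_conversion(sel, mcode)
  }

  counts <- cache$counts[labs]
  list(state = state, counts = counts,
       status = stop_band_check(counts, targets_cells[labs],
                                tolerance_cells[labs]),
       converted = converted)
}

# mutable per-run cache: neighborhood like counts per modeled class, the
# in-bounds neighbor denominator, per-class cell counts and the row-major
# tie-break index
step_cache <- function(state, scheme = default_scheme(), window = 3) {
  e <- new.env(parent = emptyenv())
  d <- dim(state)
  w2 <- (window - 1) / 2
  ones <- matrix(1L, d[1], d[2])
  nbrs <- matrix(0L, d[1], d[2])
  for (di in -w2:w2) for (dj in -w2:w2) {
    if (di == 0 && dj == 0) next
    nbrs <- nbrs + shift_mat(ones, di, dj, 0L)
  }
  e$nbrs <- nbrs
  e$w2 <- w2
  e$like <- lapply(stats::setNames(nm = c("cultivated", "ecological",
                                          "construction")), function(m) {
    code <- scheme$classes[[m]]
    ind <- (state == code) * 1L
    like <- matrix(0L, d[1], d[2])
    for (di in -w2:w2) for (dj in -w2:w2) {
      if (di == 0 && dj == 0) next
      like <- like + shift_mat(ind, di, dj, 0L)
    }
    like
  })
  codes <- sort(scheme$classes)
  cnt <- vapply(codes, function(k) sum(state == k), numeric(1))
  names(cnt) <- names(codes)
  e$counts <- cnt
  e$codes <- codes
  e$rmi <- row_major_index(d)
  e
}

# incremental cache update after converting cells `sel` from `from` to `to`
cache_update <- function(cache, sel, from, to, d) {
  labs <- names(cache$codes)
  nr <- d[1]
  r0 <- (sel - 1L) %% nr + 1L
  c0 <- (sel - 1L) %/% nr + 1L
  w2 <- cache$w2
  touch <- function(m, delta, which_cells) {
    if (!m %in% names(cache$like) || !length(which_cells)) return()
    r <- (which_cells - 1L) %% nr + 1L
    c <- (which_cells - 1L) %/% nr + 1L
    L <- cache$like[[m]]
    for (di in -w2:w2) for (dj in -w2:w2) {
      if (di == 0 && dj == 0) next
      rr <- r + di; cc <- c + dj
      ok <- rr >= 1 & rr <= nr & cc <= ncol(L) & cc >= 1
      idx <- (cc[ok] - 1L) * nr + rr[ok]
      if (length(idx)) {
        tb <- tabulate(idx, nbins = length(L))  # duplicates accumulate
        nzidx <- which(tb > 0L)
        L[nzidx] <- L[nzidx] + delta * tb[nzidx]
      }
    }
    cache$like[[m]] <- L
  }
  for (mcode in unique(from)) {
    m <- labs[match(mcode, cache$codes)]
    cells <- sel[from == mcode]
    touch(m, -1L, cells)
    cache$counts[[m]] <- cache$counts[[m]] - length(cells)
  }
  mto <- labs[match(to, cache$codes)]
  touch(mto, +1L, sel)
  cache$counts[[mto]] <- cache$counts[[mto]] + length(sel)
  invisible(cache)
}

#' Run a full scenario simulation
#'
#' Repeats \code{\link{iterate_step}} until every class's cell count is
#' inside its stopping band or \code{max_iter} is reached. Fully
#' reproducible: the seed in \code{config} initializes the RNG stream.
#'
#' @param map_t0 starting \code{\link{land_grid}}.
#' @param drivers a \code{\link{driver_stack}}.
#' @param masks named list of binary constraint lattices (see
#'   \code{\link{build_constraints}}).
#' @param models named list of fitted \code{\link{fit_logit}} models for
#'   cultivated, ecological and construction.
#' @param config a \code{\link{scenario_config}}.
#' @param targets a \code{\link{macro_targets}} in km^2.
#' @param scheme a \code{\link{class_scheme}}.
#' @param window neighborhood window width (default 3).
#' @return An object of class \code{"eca_simulation"}: \code{final} grid,
#'   \code{trajectory} (per-iteration class counts), \code{iterations},
#'   \code{converged} flag per class, per-class \code{gaps} in cells at
#'   stop, the config and seed. Non-convergence is reported in the object,
#'   never thrown.
#' @export
run_scenario <- function(map_t0, drivers, masks, models, config, targets,
                         scheme = default_scheme(), window = 3) {
  surfaces <- theil_normalize(lapply(models, predict_surface, drivers = drivers))
  constraints <- build_constraints(config, masks)
  ca <- cell_area_km2(map_t0)
  labs <- names(sort(scheme$classes))
  targets_cells <- targets$targets[labs] / ca
  tol_cells <- pmax(targets$tolerance[labs] / ca, 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  state <- map_t0$values
  codes <- sort(scheme$classes)
  counts <- vapply(codes, function(k) sum(state == k), numeric(1))
  traj <- matrix(counts, nrow = 1, dimnames = list(NULL, labs))
  status <- stop_band_check(counts, targets_cells, tol_cells)
  iter <- 0L
  cache <- step_cache(state, scheme, window)
  while (any(status != "met") && iter < config$max_iter) {
    step <- iterate_step(state, surfaces, constraints, targets_cells,
                         tol_cells, config, scheme, window, cache = cache)
    state <- step$state
    status <- step$status
    traj <- rbind(traj, step$counts)
    iter <- iter + 1L
    if (step$converted == 0L && any(status != "met")) break  # stalled
  }
  final <- land_grid(state, cell_size = map_t0$cell_size,
                     origin = map_t0$origin,
                     epoch = targets$epoch %||% "simulated",
                     nodata = map_t0$nodata)
  structure(list(final = final, trajectory = traj, iterations = iter,
                 converged = status == "met",
                 gaps_cells = traj[nrow(traj), ] - targets_cells,
                 targets_cells = targets_cells, tolerance_cells = tol_cells,
                 config = config, seed = config$seed, scheme = scheme),
            class = "eca_simulation")
}

#' @export
print.eca_simulation <- function(x, ...) {
  cat(sprintf("CA scenario simulation: %s (%d iterations, seed %d)\n",
              x$config$name, x$iterations, x$seed))
  cat(sprintf("  converged: %s\n",
              if (all(x$converged)) "yes (all classes in band)"
              else paste("no -", paste(names(x$converged)[!x$converged],
                                       collapse = ", "))))
  print(round(x$trajectory[nrow(x$trajectory), ]))
  invisible(x)
}

#' @export
summary.eca_simulation <- function(object, ...) {
  at <- area_table(object$final, object$scheme)
  cat(sprintf("Scenario %s after %d iterations:\n",
              object$config$name, object$iterations))
  print(at)
  gaps <- object$gaps_cells
  cat("Cell-count gap to target (final - target):\n")
  print(round(gaps, 1))
  invisible(list(area_table = at, gaps_cells = gaps,
                 converged = object$converged))
}

#' @export
plot.eca_simulation <- function(x, ...) {
  v <- x$final$values
  graphics::image(t(v)[, nrow(v):1], col = c("khaki", "darkgreen",
                                             "firebrick", "grey70"),
                  axes = FALSE, main = paste("Scenario:", x$config$name), ...)
  invisible(x)
}
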