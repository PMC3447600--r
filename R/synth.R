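## Synthetic landscape generator: seeded land-use maps at two epochs, driver
## stacks and constraint/security masks with known generating parameters, so
## calibration, simulation and evaluation are all testable against ground
## truth without any proprietary rasters.

#' Specification of a synthetic landscape
#'
#' Defaults describe the study conditions the package emulates: a
#' ~16,800 km^2 urbanizing region on a 100 m lattice with 2005-status class
#' shares (cultivated 25, ecological 56, construction 18, other 1 percent),
#' seven normalized drivers, statutory protection masks, and a true
#' conversion process that is logistic in the drivers with per-class
#' intercepts calibrated so the expected gross conversion intensity into
#' each class over one epoch step matches the published 2000-2005
#' accounting (10.3% of eligible cells into cultivated, 11.3% into
#' ecological, 8.6% into construction).
#'
#' @param shape lattice (rows, cols); default 300 x 300.
#' @param cell_size cell edge in meters.
#' @param seed master seed; every stage derives its stream from it.
#' @param n_towns,n_highways,n_rivers counts of seeded point/line features.
#' @param n_econ_points sample points for the IDW-interpolated
#'   socio-economic layers.
#' @param dem_smooth box-filter width (cells) for the DEM random field.
#' @param class_shares named percentages of the four classes at t0.
#' @param beta_true named list of true slope vectors (one entry per driver)
#'   for the three modeled target classes; intercepts are added by net-rate
#'   calibration (see \code{\link{evolve_true_model}}).
#' @param intensity per-class multiplier on the conversion probability
#'   (1 = pure logistic; 0 = class never gains cells).
#' @param gain_rates target expected fraction of eligible (unmasked,
#'   non-member) cells converting into each modeled class over one step,
#'   used to calibrate the true intercepts; defaults are the published
#'   2000-2005 gross conversion intensities.
#' @param basic_farmland_frac fraction of cultivated cells protected as
#'   basic farmland.
#' @param water_frac fraction of ecological+other cells that are water.
#' @param reserve_frac fraction of ecological cells in nature
#'   reserves/scenic core zones.
#' @param steep_frac fraction of the landscape above the 25-degree slope
#'   cutoff.
#' @param key_low_frac,key_high_frac fractions of ecological cells flagged
#'   as key ecological land at low / high security.
#' @return An object of class \code{"synth_spec"}.
#' @export
synth_spec <- function(shape = c(300, 300), cell_size = 100, seed = 1,
                       n_towns = 6, n_highways = 3, n_rivers = 3,
                       n_econ_points = 25, dem_smooth = 11,
                       class_shares = c(cultivated = 25, ecological = 56,
                                        construction = 18, other = 1),
                       beta_true = list(
                         cultivated = c(dist_town = 1.2, dist_highway = -1.2,
                                        dist_river = -1.5, dem = -2.0,
                                        slope = -2.5, gdp_pc = -1.2,
                                        pop_density = 1.5),
                         ecological = c(dist_town = 1.5, dist_highway = 1.2,
                                        dist_river = -1.2, dem = 2.0,
                                        slope = 1.5, gdp_pc = -1.2,
                                        pop_density = -2.0),
                         construction = c(dist_town = -3.0, dist_highway = -2.0,
                                          dist_river = -1.2, dem = -1.5,
                                          slope = -2.0, gdp_pc = 2.0,
                                          pop_density = 2.5)),
                       intensity = c(cultivated = 1, ecological = 1,
                                     construction = 1),
                       gain_rates = c(cultivated = 0.103,
                                      ecological = 0.113,
                                      construction = 0.086),
                       basic_farmland_frac = 0.30, water_frac = 0.04,
                       reserve_frac = 0.10, steep_frac = 0.05,
                       key_low_frac = 0.15, key_high_frac = 0.35) {
  if (abs(sum(class_shares) - 100) > 1e-6) stop("class shares must sum to 100")
  fr <- c(basic_farmland_frac, water_frac, reserve_frac, steep_frac,
          key_low_frac, key_high_frac)
  if (any(fr < 0 | fr > 1)) stop("mask fractions must lie in [0, 1]")
  if (key_low_frac + key_high_frac > 1)
    stop("security-level fractions jointly infeasible")
  structure(as.list(environment()), class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf("synth_spec: %d x %d cells at %g m, seed %d\n",
              x$shape[1], x$shape[2], x$cell_size, x$seed))
  invisible(x)
}

## -- low-level field builders -----------------------------------------------

# sliding box mean with edge renormalization (separable, cumsum-based)
box_mean_1d <- function(m, w2) {
  nr <- nrow(m)
  cs <- apply(rbind(0, m), 2, cumsum)
  hi <- pmin(seq_len(nr) + w2, nr)
  lo <- pmax(seq_len(nr) - w2, 1)
  (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
}

smooth_box <- function(m, width) {
  w2 <- (width - 1) %/% 2
  t(box_mean_1d(t(box_mean_1d(m, w2)), w2))
}

# Euclidean distance to the nearest feature cell
dist_to_features <- function(nr, nc, cells) {
  if (!length(cells)) stop("degenerate spec: zero features")
  x <- matrix(1, nr, nc)
  x[cells] <- 0
  dm <- EBImage::distmap(x)
  matrix(as.numeric(dm), nr, nc)
}

# momentum random-walk polyline across the lattice, returns cell indices
walk_line <- function(nr, nc) {
  r <- sample.int(nr, 1); c <- 1
  dr <- sample(c(-1, 0, 1), 1); dc <- 1
  cells <- integer(0)
  for (k in seq_len(4 * nc)) {
    cells <- c(cells, (c - 1L) * nr + r)
    if (stats::runif(1) < 0.3) dr <- max(-1, min(1, dr + sample(c(-1, 1), 1)))
    r <- min(max(r + dr, 1), nr)
    c <- c + dc
    if (c > nc) break
  }
  unique(cells)
}

# inverse-distance-weighted (power 2) interpolation of point samples
idw_field <- function(nr, nc, pts_r, pts_c, vals, power = 2) {
  if (!length(vals)) stop("degenerate spec: zero features")
  rr <- rep(seq_len(nr), nc)
  cc <- rep(seq_len(nc), each = nr)
  out <- numeric(nr * nc)
  wsum <- numeric(nr * nc)
  exact <- rep(NA_real_, nr * nc)
  for (k in seq_along(vals)) {
    d2 <- (rr - pts_r[k])^2 + (cc - pts_c[k])^2
    hit <- d2 == 0
    exact[hit] <- vals[k]
    d2[hit] <- Inf
    w <- d2^(-power / 2)   # 1/d^power with d^2 precomputed
    out <- out + w * vals[k]
    wsum <- wsum + w
  }
  v <- out / wsum
  v[!is.na(exact)] <- exact[!is.na(exact)]
  matrix(v, nr, nc)
}

#' Generate the synthetic driver stack
#'
#' Distance layers are Euclidean distance transforms from seeded town
#' points and random-walk highway/river polylines; the DEM is a
#' box-smoothed uniform random field; slope is the finite-difference
#' gradient magnitude of the DEM; per-capita GDP and population density
#' are IDW (power 2) interpolations of seeded point values, with
#' population concentrated near towns. Each layer is standardized to (0, 1)
#' by quantile (rank) normalization: the marginal becomes uniform, which
#' preserves spatial structure and rank order while giving every driver
#' full contrast over the standardized range (smooth fields squeezed
#' through a plain min-max map would concentrate mass mid-range and weaken
#' the identifiability of the conversion coefficients the generator is
#' meant to let the calibration recover).
#'
#' @param spec a \code{\link{synth_spec}}.
#' @return A \code{\link{driver_stack}} with all layers in [0, 1].
#' @export
gen_drivers <- function(spec) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  nr <- spec$shape[1]; nc <- spec$shape[2]
  if (spec$n_towns < 1) stop("degenerate spec: zero features")
  town_cells <- sample.int(nr * nc, spec$n_towns)
  hw <- unlist(lapply(seq_len(spec$n_highways), function(i) walk_line(nr, nc)))
  rv <- unlist(lapply(seq_len(spec$n_rivers), function(i) walk_line(nr, nc)))
  dist_town <- dist_to_features(nr, nc, town_cells)
  dist_highway <- dist_to_features(nr, nc, hw)
  dist_river <- dist_to_features(nr, nc, rv)
  dem <- smooth_box(matrix(stats::runif(nr * nc), nr, nc), spec$dem_smooth)
  gx <- (shift_mat(dem, 0, -1, NA) - shift_mat(dem, 0, 1, NA)) / 2
  gy <- (shift_mat(dem, -1, 0, NA) - shift_mat(dem, 1, 0, NA)) / 2
  gx[is.na(gx)] <- 0; gy[is.na(gy)] <- 0
  slope <- sqrt(gx^2 + gy^2)
  pr <- sample.int(nr, spec$n_econ_points, replace = TRUE)
  pc <- sample.int(nc, spec$n_econ_points, replace = TRUE)
  gdp <- idw_field(nr, nc, pr, pc, stats::runif(spec$n_econ_points))
  # population clusters around towns: values decay with distance to town
  pr2 <- sample.int(nr, spec$n_econ_points, replace = TRUE)
  pc2 <- sample.int(nc, spec$n_econ_points, replace = TRUE)
  popv <- stats::runif(spec$n_econ_points) *
    exp(-dist_town[cbind(pr2, pc2)] / (0.3 * max(dist_town)))
  pop <- idw_field(nr, nc, pr2, pc2, popv)
  rank_unit <- function(m) {
    r <- rank(as.vector(m), ties.method = "average")
    matrix((r - min(r)) / (max(r) - min(r)), nrow(m), ncol(m))
  }
  driver_stack(lapply(list(dist_town = dist_town, dist_highway = dist_highway,
                           dist_river = dist_river, dem = dem, slope = slope,
                           gdp_pc = gdp, pop_density = pop), rank_unit),
               cell_size = spec$cell_size, normalize = FALSE)
}

#' Generate the initial (t0) land-use map
#'
#' Spatially clustered allocation: cells are scored per class from the
#' drivers plus a smoothed noise field (construction favors proximity to
#' towns and high population density, ecological favors high elevation and
#' slope, cultivated favors flat low terrain), then classes are assigned
#' greedily by rank until each reaches its share, so realized shares match
#' the spec exactly up to rounding.
#'
#' @param spec a \code{\link{synth_spec}}.
#' @param drivers a \code{\link{gen_drivers}} result.
#' @param scheme a \code{\link{class_scheme}}.
#' @return A \code{\link{land_grid}} labeled epoch \code{"t0"}.
#' @export
gen_initial_map <- function(spec, drivers, scheme = default_scheme()) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 1L)
  nr <- spec$shape[1]; nc <- spec$shape[2]
  n <- nr * nc
  L <- drivers$layers
  noise <- function() smooth_box(matrix(stats::runif(n), nr, nc), 9)
  score <- list(
    construction = -2 * L$dist_town - L$dist_highway + 1.5 * L$pop_density -
      L$slope + 0.6 * normalize_driver(noise()),
    ecological = 2 * L$dem + L$slope + 0.5 * L$dist_town +
      0.6 * normalize_driver(noise()),
    cultivated = -1.5 * L$dem - 2 * L$slope - 0.5 * L$dist_river +
      0.6 * normalize_driver(noise()))
  shares <- spec$class_shares
  v <- rep(scheme$classes[["other"]], n)
  taken <- logical(n)
  for (m in c("construction", "ecological", "cultivated")) {
    want <- round(shares[[m]] / 100 * n)
    ord <- order(score[[m]], decreasing = TRUE)
    pick <- ord[!taken[ord]][seq_len(min(want, sum(!taken)))]
    v[pick] <- scheme$classes[[m]]
    taken[pick] <- TRUE
  }
  land_grid(matrix(v, nr, nc), cell_size = spec$cell_size, epoch = "t0",
            nodata = scheme$nodata)
}

#' Generate constraint and security masks
#'
#' Basic farmland = flattest fraction of cultivated cells; water = the
#' fraction of ecological/other cells nearest rivers; nature-reserve core
#' zones = highest-elevation ecological cells; steep slope = top slope
#' quantile of the landscape; \code{core_area} is the union of basic
#' farmland, water and reserves. Key-ecological-land security levels
#' partition ecological cells by exposure: the fraction nearest towns is
#' low security, the next band high security. All selections are
#' order-based, so realized fractions are exact up to one-cell rounding and
#' reproducible under the seed.
#'
#' @param spec a \code{\link{synth_spec}}.
#' @param map_t0 the \code{\link{gen_initial_map}} result.
#' @param drivers the \code{\link{gen_drivers}} result.
#' @param scheme a \code{\link{class_scheme}}.
#' @return Named list of 0/1 integer lattices: \code{basic_farmland},
#'   \code{water}, \code{reserve}, \code{core_area}, \code{steep_slope},
#'   \code{key_ecoland_low_security}, \code{key_ecoland_high_security}.
#' @export
gen_masks <- function(spec, map_t0, drivers, scheme = default_scheme()) {
  nr <- spec$shape[1]; nc <- spec$shape[2]
  v <- as.vector(map_t0$values)
  L <- drivers$layers
  zero <- function() matrix(0L, nr, nc)
  pick_frac <- function(eligible, keyvals, frac, decreasing = FALSE) {
    idx <- which(eligible)
    k <- round(frac * length(idx))
    m <- zero()
    if (k > 0)
      m[idx[order(keyvals[idx], decreasing = decreasing)][seq_len(k)]] <- 1L
    m
  }
  cult <- v == scheme$classes[["cultivated"]]
  eco <- v == scheme$classes[["ecological"]]
  ecoother <- eco | v == scheme$classes[["other"]]
  basic_farmland <- pick_frac(cult, as.vector(L$slope),
                              spec$basic_farmland_frac)
  water <- pick_frac(ecoother, as.vector(L$dist_river), spec$water_frac)
  reserve <- pick_frac(eco, as.vector(L$dem), spec$reserve_frac,
                       decreasing = TRUE)
  steep <- pick_frac(rep(TRUE, nr * nc), as.vector(L$slope),
                     spec$steep_frac, decreasing = TRUE)
  core <- (basic_farmland | water | reserve) * 1L
  storage.mode(core) <- "integer"
  # security levels: exposure = proximity to towns, on ecological cells
  n_eco <- sum(eco)
  dt <- as.vector(L$dist_town)
  eco_idx <- which(eco)[order(dt[which(eco)])]
  n_low <- round(spec$key_low_frac * n_eco)
  n_high <- round(spec$key_high_frac * n_eco)
  low <- zero(); high <- zero()
  if (n_low > 0) low[eco_idx[seq_len(n_low)]] <- 1L
  if (n_high > 0) high[eco_idx[n_low + seq_len(n_high)]] <- 1L
  list(basic_farmland = basic_farmland, water = water, reserve = reserve,
       core_area = core, steep_slope = steep,
       key_ecoland_low_security = low, key_ecoland_high_security = high)
}

# calibrate each class intercept so the expected fraction of eligible
# (unmasked, non-member) cells converting into the class equals
# spec$gain_rates; the expected gain is strictly increasing in the
# intercept, so the root is unique
calibrate_intercepts <- function(spec, map_t0, drivers, masks,
                                 scheme = default_scheme()) {
  v <- as.vector(map_t0$values)
  X <- driver_matrix(drivers)
  blocked <- if (!is.null(masks)) as.vector(masks$core_area) > 0
             else rep(FALSE, length(v))
  mods <- names(spec$beta_true)
  out <- numeric(length(mods)); names(out) <- mods
  for (m in mods) {
    if (spec$intensity[[m]] == 0) { out[m] <- 0; next }
    b <- spec$beta_true[[m]]
    eta0 <- as.numeric(X[, names(b), drop = FALSE] %*% b)
    elig <- v != scheme$classes[[m]] & !blocked
    target <- spec$gain_rates[[m]] / spec$intensity[[m]]
    f <- function(d) mean(stats::plogis(eta0[elig] + d)) - target
    out[m] <- stats::uniroot(f, c(-20, 10), tol = 1e-10)$root
  }
  out
}

#' Evolve the true conversion process one step
#'
#' Each unmasked cell converts to modeled class m (m not its current class)
#' with probability intensity_m * plogis(beta*_m . x_i); a single uniform
#' draw per cell allocates among the competing classes (exact marginals
#' whenever the class probabilities sum to at most 1, which holds except on
#' a negligible set of extreme cells where they are rescaled). Masked
#' (core-area) cells never convert. Realized transition counts are recorded
#' as ground truth.
#'
#' @param map_t0 the t0 \code{\link{land_grid}}.
#' @param drivers the \code{\link{driver_stack}}.
#' @param spec a \code{\link{synth_spec}}.
#' @param masks a \code{\link{gen_masks}} result (NULL = no constraint).
#' @param intercepts named per-class intercepts; if NULL they are
#'   calibrated to \code{spec$net_change} (see package vignette).
#' @param scheme a \code{\link{class_scheme}}.
#' @return List: \code{map_t1} (\code{land_grid}, epoch "t1") and
#'   \code{truth} (true beta incl. intercepts, realized transition cell
#'   counts, seed).
#' @export
evolve_true_model <- function(map_t0, drivers, spec, masks = NULL,
                              intercepts = NULL, scheme = default_scheme()) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 2L)
  if (is.null(intercepts))
    intercepts <- calibrate_intercepts(spec, map_t0, drivers, masks, scheme)
  v <- as.vector(map_t0$values)
  X <- driver_matrix(drivers)
  blocked <- if (!is.null(masks)) as.vector(masks$core_area) > 0 else rep(FALSE, length(v))
  mods <- names(spec$beta_true)
  p <- lapply(mods, function(m) {
    b <- spec$beta_true[[m]]
    pm <- spec$intensity[[m]] *
      stats::plogis(as.numeric(X[, names(b), drop = FALSE] %*% b) +
                      intercepts[[m]])
    pm[v == scheme$classes[[m]] | blocked] <- 0
    pm
  })
  names(p) <- mods
  tot <- Reduce(`+`, p)
  over <- tot > 1
  if (any(over)) p <- lapply(p, function(pm) { pm[over] <- pm[over] / tot[over]; pm })
  u <- stats::runif(length(v))
  v1 <- v
  cum <- 0
  for (m in mods) {
    hit <- u >= cum & u < cum + p[[m]]
    v1[hit] <- scheme$classes[[m]]
    cum <- cum + p[[m]]
  }
  map_t1 <- land_grid(matrix(v1, nrow(map_t0$values), ncol(map_t0$values)),
                      cell_size = map_t0$cell_size, origin = map_t0$origin,
                      epoch = "t1", nodata = map_t0$nodata)
  truth_beta <- lapply(mods, function(m)
    c("(Intercept)" = unname(intercepts[[m]]), spec$beta_true[[m]]))
  names(truth_beta) <- mods
  counts <- crosstab(map_t0, map_t1, scheme)$cells
  list(map_t1 = map_t1,
       truth = list(beta = truth_beta, transition_cells = counts,
                    rescaled_cells = sum(over), seed = spec$seed))
}

#' Generate a complete synthetic bundle
#'
#' Drivers, t0 map, masks, t1 map and ground truth, all aligned and fully
#' determined by the spec and its seed.
#'
#' @param spec a \code{\link{synth_spec}}.
#' @param scheme a \code{\link{class_scheme}}.
#' @return An object of class \code{"synth_bundle"} with elements
#'   \code{map_t0}, \code{map_t1}, \code{drivers}, \code{masks},
#'   \code{truth} and \code{spec}.
#' @export
synth_bundle <- function(spec = synth_spec(), scheme = default_scheme()) {
  drivers <- gen_drivers(spec)
  map_t0 <- gen_initial_map(spec, drivers, scheme)
  masks <- gen_masks(spec, map_t0, drivers, scheme)
  ev <- evolve_true_model(map_t0, drivers, spec, masks, scheme = scheme)
  structure(list(map_t0 = map_t0, map_t1 = ev$map_t1, drivers = drivers,
                 masks = masks, truth = ev$truth, spec = spec),
            class = "synth_bundle")
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat(sprintf("synth_bundle: %d x %d cells, seed %d\n",
              x$spec$shape[1], x$spec$shape[2], x$spec$seed))
  cat(sprintf("  %d cells converted t0 -> t1 (%d rescaled)\n",
              sum(x$truth$transition_cells) -
                sum(diag(x$truth$transition_cells)),
              x$truth$rescaled_cells))
  invisible(x)
}

#' Write a synthetic bundle to disk
#'
#' Maps and masks as ESRI ASCII grids, drivers as float ASCII grids, truth
#' (true coefficients, transition counts, seed) as JSON.
#'
#' @param bundle a \code{\link{synth_bundle}}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_landuse_raster(bundle$map_t0, file.path(dir, "map_t0.asc"))
  write_landuse_raster(bundle$map_t1, file.path(dir, "map_t1.asc"))
  cs <- bundle$map_t0$cell_size
  for (nm in names(bundle$drivers$layers))
    write_float_raster(bundle$drivers$layers[[nm]],
                       file.path(dir, paste0("driver_", nm, ".asc")),
                       cell_size = cs)
  for (nm in names(bundle$masks))
    write_float_raster(bundle$masks[[nm]],
                       file.path(dir, paste0("mask_", nm, ".asc")),
                       cell_size = cs)
  jsonlite::write_json(
    list(beta = lapply(bundle$truth$beta, as.list),
         transition_cells = as.data.frame(bundle$truth$transition_cells),
         seed = bundle$truth$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
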