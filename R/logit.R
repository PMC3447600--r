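#' Sample cells and build the conversion-regression design table
#'
#' Draws a uniform random sample (without replacement) of non-nodata cells
#' and records, for each sampled cell, the binary conversion outcomes
#' y_m = 1 iff the cell changed to class m between the two epochs, the
#' cell's class at the first epoch, and its driver values. This is the
#' calibration sample for the per-class suitability logits.
#'
#' @param map_t0,map_t1 aligned \code{\link{land_grid}}s.
#' @param drivers a \code{\link{driver_stack}} aligned with the maps.
#' @param fraction sampling proportion in (0, 1].
#' @param seed integer RNG seed for the sample draw.
#' @param scheme a \code{\link{class_scheme}}.
#' @param exclude optional logical/0-1 lattice; TRUE cells (e.g. cells whose
#'   conversion is prohibited by constraint masks) are left out of the
#'   sample frame, since structural non-converters carry no suitability
#'   information.
#' @return A data frame with columns \code{cell} (1-based column-major
#'   index), \code{class_t0}, one \code{y_<class>} column per modeled class
#'   (cultivated, ecological, construction) and one column per driver layer.
#' @export
sample_cells <- function(map_t0, map_t1, drivers, fraction = 0.2, seed = 1,
                         scheme = default_scheme(), exclude = NULL) {
  stop_if_misaligned(map_t0, map_t1)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  v0 <- as.vector(collapse_subclasses(map_t0$values, scheme))
  v1 <- as.vector(collapse_subclasses(map_t1$values, scheme))
  frame <- which(v0 != map_t0$nodata & v1 != map_t1$nodata)
  if (!is.null(exclude)) frame <- setdiff(frame, which(as.vector(exclude) > 0))
  n <- round(fraction * length(frame))
  if (n < 100) stop("sample smaller than 100 cells; increase fraction")
  if (fraction == 1) {
    idx <- frame
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    idx <- sort(sample(frame, n))
  }
  X <- driver_matrix(drivers)[idx, , drop = FALSE]
  colnames(X) <- names(drivers$layers)
  out <- data.frame(cell = idx, class_t0 = v0[idx])
  for (m in c("cultivated", "ecological", "construction")) {
    code <- scheme$classes[[m]]
    out[[paste0("y_", m)]] <- as.integer(v1[idx] == code & v0[idx] != code)
  }
  cbind(out, as.data.frame(X))
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Fit the conversion-suitability logistic regression for one target class
#'
#' Binary logistic regression (maximum likelihood via IRLS,
#' \code{stats::glm}) of "converted to class m" on the driver covariates,
#' over cells eligible to convert (cells not already in class m at the
#' first epoch). The fitted linear predictor eta = b0 + b . x gives the
#' global conversion probability P(i_m) = exp(eta) / (1 + exp(eta)).
#'
#' @param design design table from \code{\link{sample_cells}}.
#' @param class_m target class label ("cultivated", "ecological" or
#'   "construction").
#' @param scheme a \code{\link{class_scheme}}.
#' @param epsilon IRLS convergence tolerance on deviance.
#' @return An object of class \code{"logit_model"}: coefficients
#'   (intercept + one per driver), the target class, n, a convergence flag
#'   and a separation flag.
#' @export
fit_logit <- function(design, class_m, scheme = default_scheme(),
                      epsilon = 1e-8) {
  ycol <- paste0("y_", class_m)
  if (!ycol %in% names(design)) stop("no outcome column for class ", class_m)
  code <- scheme$classes[[class_m]]
  d <- design[design$class_t0 != code, , drop = FALSE]
  drv <- setdiff(names(design),
                 c("cell", "class_t0", grep("^y_", names(design), value = TRUE)))
  if (length(unique(d[[ycol]])) < 2)
    stop("both outcome levels must be present for class ", class_m)
  f <- stats::as.formula(paste(ycol, "~", paste(drv, collapse = " + ")))
  fit <- stats::glm(f, family = stats::binomial(), data = d,
                    control = stats::glm.control(epsilon = epsilon,
                                                 maxit = 100))
  beta <- stats::coef(fit)
  separated <- any(abs(beta) > 15) || !fit$converged
  if (separated)
    warning("possible separation or non-convergence fitting class ", class_m)
  structure(list(class_m = class_m, coefficients = beta, drivers = drv,
                 n = nrow(d), converged = fit$converged,
                 separation = separated,
                 deviance = fit$deviance, null_deviance = fit$null.deviance),
            class = "logit_model")
}

#' @export
print.logit_model <- function(x, ...) {
  cat(sprintf("Conversion suitability logit: target class '%s' (n = %d%s)\n",
              x$class_m, x$n, if (!x$converged) ", NOT converged" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.logit_model <- function(object, ...) object$coefficients

#' Rasterize a fitted suitability model into a probability surface
#'
#' @param model a \code{\link{fit_logit}} result.
#' @param drivers a \code{\link{driver_stack}} containing every driver the
#'   model was fitted on.
#' @return Numeric matrix of P(i_m) in (0, 1), aligned with the drivers.
#' @export
predict_surface <- function(model, drivers) {
  missing <- setdiff(model$drivers, names(drivers$layers))
  if (length(missing))
    stop("driver layer(s) missing: ", paste(missing, collapse = ", "))
  d <- dim(drivers$layers[[1]])
  eta <- matrix(model$coefficients[["(Intercept)"]], d[1], d[2])
  for (nm in model$drivers)
    eta <- eta + model$coefficients[[nm]] * drivers$layers[[nm]]
  stats::plogis(eta)
}

#' Theil-normalize per-class suitability surfaces into a coherent set
#'
#' Separately fitted binary-logit probabilities do not sum to one across
#' target classes; ratio (Theil) normalization rescales them per cell,
#' P'(i_j) = P(i_j) / sum_k P(i_k), so the per-cell class probabilities form
#' a coherent set. The per-cell argmax class is unchanged (rank invariance).
#' Cells where every surface is zero are flagged and assigned the uniform
#' distribution.
#'
#' @param surfaces named list of per-class probability matrices in [0, 1].
#' @return Object of class \code{"suitability_surfaces"}: the normalized
#'   list plus a \code{degenerate} count of all-zero cells.
#' @export
theil_normalize <- function(surfaces) {
  if (length(surfaces) < 2) stop("need at least two class surfaces")
  tot <- Reduce(`+`, surfaces)
  degenerate <- sum(tot == 0, na.rm = TRUE)
  if (degenerate > 0) {
    u <- 1 / length(surfaces)
    surfaces <- lapply(surfaces, function(s) { s[tot == 0] <- u; s })
    tot[tot == 0] <- 1
  }
  out <- lapply(surfaces, function(s) s / tot)
  structure(list(surfaces = out, normalized = TRUE, degenerate = degenerate),
            class = "suitability_surfaces")
}

#' @export
print.suitability_surfaces <- function(x, ...) {
  cat(sprintf("Normalized suitability surfaces: %s\n",
              paste(names(x$surfaces), collapse = ", ")))
  invisible(x)
}

#' Per-cell candidate target class (maximal normalized suitability)
#'
#' @param surfaces a \code{\link{theil_normalize}} result (or a named list
#'   of matrices).
#' @param scheme a \code{\link{class_scheme}} giving codes for the surface
#'   names.
#' @return Integer matrix of class codes; exact ties go to the lowest class
#'   code (fixed, documented tie-break).
#' @export
argmax_class <- function(surfaces, scheme = default_scheme()) {
  ss <- if (inherits(surfaces, "suitability_surfaces")) surfaces$surfaces else surfaces
  codes <- scheme$classes[names(ss)]
  ord <- order(codes)            # scan in ascending code order; strict > keeps earliest on ties
  best_p <- ss[[ord[1]]]
  best_c <- matrix(codes[ord[1]], nrow(best_p), ncol(best_p))
  for (k in ord[-1]) {
    better <- ss[[k]] > best_p
    best_p[better] <- ss[[k]][better]
    best_c[better] <- codes[k]
  }
  best_c
}

#' Serialize fitted logit models to JSON
#'
#' @param models named list of \code{logit_model} objects.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_models_json <- function(models, path) {
  obj <- lapply(models, function(m)
    list(class_m = m$class_m, coefficients = as.list(m$coefficients),
         n = m$n, converged = m$converged))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_models_json
#' @export
read_models_json <- function(path) {
  obj <- jsonlite::read_json(path)
  lapply(obj, function(m) {
    beta <- unlist(m$coefficients)
    structure(list(class_m = m$class_m, coefficients = beta,
                   drivers = setdiff(names(beta), "(Intercept)"),
                   n = m$n, converged = m$converged, separation = FALSE),
              class = "logit_model")
  })
}
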