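## Class-level landscape pattern metrics (Fragstats conventions): patch
## labeling under 8-connectivity, LPI, COHESION, SPLIT and AI, plus the
## change-accounting and key-ecological-land loss summaries used to compare
## scenarios.

#' Label the patches of one class
#'
#' Connected components of the class-m cells (8-connectivity by default,
#' the Fragstats convention), with per-patch cell counts and perimeters.
#' Perimeter is counted in cell-edge units: every cell edge adjacent to a
#' different class, nodata or the lattice boundary contributes 1.
#'
#' @param grid a \code{\link{land_grid}} or integer code matrix.
#' @param class_m class label or code.
#' @param connectivity 8 (default) or 4.
#' @param scheme a \code{\link{class_scheme}}.
#' @return An object of class \code{"patch_set"}: \code{labels} (integer
#'   matrix, 0 = not class m), \code{area} (cells per patch),
#'   \code{perimeter} (edge units per patch), and \code{A} (non-nodata
#'   landscape cell count).
#' @export
label_patches <- function(grid, class_m, connectivity = 8,
                          scheme = default_scheme()) {
  v <- if (inherits(grid, "land_grid")) grid$values else grid
  nodata <- if (inherits(grid, "land_grid")) grid$nodata else -9999L
  code <- if (is.character(class_m)) scheme$classes[[class_m]] else as.integer(class_m)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  d <- dim(v)
  ind <- v == code
  labels <- matrix(0L, d[1], d[2])
  offs <- if (connectivity == 4) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
          else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                    c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  # iterative BFS with vectorized frontier expansion
  todo <- which(ind)
  lab <- 0L
  nr <- d[1]
  while (length(todo)) {
    lab <- lab + 1L
    frontier <- todo[1]
    labels[frontier] <- lab
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      nxt <- integer(0)
      for (o in offs) {
        rr <- r + o[1]; cc <- c + o[2]
        ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= d[2]
        cand <- (cc[ok] - 1L) * nr + rr[ok]
        cand <- cand[ind[cand] & labels[cand] == 0L]
        if (length(cand)) {
          labels[cand] <- lab
          nxt <- c(nxt, cand)
        }
      }
      frontier <- unique(nxt)
    }
    todo <- todo[labels[todo] == 0L]
  }
  # per-cell perimeter contribution: 4-neighbors not of class m (or out of
  # bounds / nodata) each add one edge
  per_cell <- matrix(0L, d[1], d[2])
  for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    nb <- shift_mat(v, o[1], o[2], fill = nodata)
    per_cell <- per_cell + (ind & nb != code)
  }
  area <- if (lab > 0) tabulate(labels[labels > 0], nbins = lab) else numeric(0)
  peri <- if (lab > 0) as.numeric(tapply(per_cell[labels > 0],
                                         factor(labels[labels > 0],
                                                levels = seq_len(lab)), sum))
          else numeric(0)
  structure(list(labels = labels, area = as.numeric(area),
                 perimeter = peri, A = sum(v != nodata),
                 class_m = class_m, connectivity = connectivity),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("patch_set: class %s, %d patches, %g class cells of %d (%d-connectivity)\n",
              as.character(x$class_m), length(x$area), sum(x$area), x$A,
              x$connectivity))
  invisible(x)
}

#' Largest patch index (LPI)
#'
#' Area of the class's largest patch as a percentage of the landscape.
#' @param patches a \code{\link{label_patches}} result.
#' @return Percent in (0, 100]; an empty class yields 0 with attribute
#'   \code{"empty" = TRUE}.
#' @export
lpi <- function(patches) {
  if (!length(patches$area))
    return(structure(0, empty = TRUE))
  100 * max(patches$area) / patches$A
}

#' Patch cohesion index (COHESION)
#'
#' Connectivity measure from patch perimeters p_i and areas a_i:
#' COHESION = (1 - sum(p_i) / sum(p_i * sqrt(a_i))) *
#' (1 - 1/sqrt(A))^-1 * 100, with A the landscape cell count.
#' @param patches a \code{\link{label_patches}} result.
#' @return Value in [0, 100).
#' @export
cohesion <- function(patches) {
  if (!length(patches$area)) stop("cohesion undefined for an empty class")
  if (patches$A <= 1) stop("cohesion undefined on a single-cell landscape")
  p <- patches$perimeter; a <- patches$area
  (1 - sum(p) / sum(p * sqrt(a))) / (1 - 1 / sqrt(patches$A)) * 100
}

#' Splitting index (SPLIT)
#'
#' Degree of spatial subdivision: SPLIT = A^2 / sum(a_i^2). Equals 1 iff a
#' single patch fills the landscape; grows as the class fragments.
#' @param patches a \code{\link{label_patches}} result.
#' @return Value >= 1.
#' @export
split_index <- function(patches) {
  if (!length(patches$area)) stop("splitting index undefined for an empty class")
  patches$A^2 / sum(patches$area^2)
}

#' Aggregation index (AI)
#'
#' Observed like adjacencies of the class (4-neighbor, single count)
#' relative to their combinatorial maximum for the class area:
#' AI = 100 * g / g_max. With a class cells and n = floor(sqrt(a)),
#' m = a - n^2: g_max = 2n(n-1) if m = 0; 2n(n-1) + 2m - 1 if m <= n;
#' 2n(n-1) + 2m - 2 otherwise.
#'
#' @param grid a \code{\link{land_grid}} or code matrix.
#' @param class_m class label or code.
#' @param scheme a \code{\link{class_scheme}}.
#' @return Percent in [0, 100]. A single-cell class has no possible
#'   adjacency and returns 100 (fully aggregated by convention, flagged
#'   with attribute \code{"degenerate"}).
#' @export
aggregation_index <- function(grid, class_m, scheme = default_scheme()) {
  v <- if (inherits(grid, "land_grid")) grid$values else grid
  code <- if (is.character(class_m)) scheme$classes[[class_m]] else as.integer(class_m)
  ind <- v == code
  a <- sum(ind)
  if (a == 0) stop("aggregation index undefined for an empty class")
  g <- sum(ind[-nrow(ind), ] & ind[-1, ]) + sum(ind[, -ncol(ind)] & ind[, -1])
  n <- floor(sqrt(a)); m <- a - n^2
  gmax <- if (m == 0) 2 * n * (n - 1)
          else if (m <= n) 2 * n * (n - 1) + 2 * m - 1
          else 2 * n * (n - 1) + 2 * m - 2
  if (gmax == 0) return(structure(100, degenerate = TRUE))
  100 * g / gmax
}

#' Class-level pattern metrics report
#'
#' Convenience wrapper computing LPI, COHESION, SPLIT and AI for one class.
#' @param grid a \code{\link{land_grid}}.
#' @param class_m class label (default "ecological", the protected
#'   category the scenario comparison focuses on).
#' @param scheme a \code{\link{class_scheme}}.
#' @return Named numeric vector (lpi, cohesion, split, ai).
#' @export
pattern_metrics <- function(grid, class_m = "ecological",
                            scheme = default_scheme()) {
  ps <- label_patches(grid, class_m, connectivity = 8, scheme = scheme)
  c(lpi = as.numeric(lpi(ps)), cohesion = cohesion(ps),
    split = split_index(ps),
    ai = as.numeric(aggregation_index(grid, class_m, scheme)))
}

#' Per-class area change between two epochs or scenarios
#'
#' @param base,result area tables (from \code{\link{area_table}}) or named
#'   area vectors in km^2 over the same classes.
#' @return Data frame per class: base and result areas, absolute change
#'   (km^2) and percent change relative to base.
#' @examples
#' base <- c(cultivated = 4232.66, ecological = 9237.15,
#'           construction = 2885.32, other = 30.59)
#' res <- c(cultivated = 3798.57, ecological = 8728.13,
#'          construction = 3835.82, other = 23.20)
#' area_change_summary(base, res)
#' @export
area_change_summary <- function(base, result) {
  b <- if (is.data.frame(base)) stats::setNames(base$area_km2, base$class) else base
  r <- if (is.data.frame(result)) stats::setNames(result$area_km2, result$class) else result
  if (!setequal(names(b), names(r))) stop("class sets differ")
  r <- r[names(b)]
  if (any(b == 0)) stop("zero base area: percent change undefined")
  data.frame(class = names(b), base_km2 = unname(b), result_km2 = unname(r),
             change_km2 = unname(r - b),
             change_pct = unname(100 * (r - b) / b),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cell-by-cell overlay accuracy of a simulated map
#'
#' One minus the ratio of cells with inconsistent land type to the total
#' number of (non-nodata) cells.
#' @param simulated,observed aligned \code{\link{land_grid}}s.
#' @return Proportion in [0, 1].
#' @export
overlay_accuracy <- function(simulated, observed) {
  stop_if_misaligned(simulated, observed)
  s <- simulated$values; o <- observed$values
  keep <- s != simulated$nodata & o != observed$nodata
  1 - sum(s[keep] != o[keep]) / sum(keep)
}

#' Loss of key ecological land by security level
#'
#' Area of security-flagged cells that are ecological at the first epoch
#' and no longer ecological at the second, tallied per security level.
#' Mask cells that are not ecological at the first epoch are excluded with
#' a warning.
#'
#' @param map_t0,map_t1 aligned \code{\link{land_grid}}s.
#' @param security_masks named list of binary lattices (e.g.
#'   \code{low}, \code{high}) flagging key ecological cells by security
#'   level at the first epoch.
#' @param scheme a \code{\link{class_scheme}}.
#' @return Named numeric vector of km^2 lost per level.
#' @export
key_ecoland_loss <- function(map_t0, map_t1, security_masks,
                             scheme = default_scheme()) {
  stop_if_misaligned(map_t0, map_t1)
  eco <- scheme$classes[["ecological"]]
  v0 <- collapse_subclasses(map_t0$values, scheme)
  v1 <- collapse_subclasses(map_t1$values, scheme)
  ca <- cell_area_km2(map_t0)
  out <- vapply(security_masks, function(msk) {
    flagged <- msk > 0
    bad <- flagged & v0 != eco
    if (any(bad)) {
      warning(sum(bad), " masked cell(s) not ecological at t0 excluded")
      flagged <- flagged & !bad
    }
    sum(flagged & v1 != eco) * ca
  }, numeric(1))
  names(out) <- names(security_masks)
  out
}
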