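#' Categorical land-use lattice
#'
#' The cellular-automaton state: a 2-D integer lattice of land-use class
#' codes with square cells. Row 1 is the northernmost row (raster file
#' order); \code{origin} is the (x, y) of the lower-left corner in map
#' units (meters).
#'
#' @param values integer matrix of class codes (row 1 = north).
#' @param cell_size cell edge length in meters (default 100).
#' @param origin numeric length-2, (x, y) of the lower-left corner.
#' @param epoch optional epoch label (e.g. "t0", "2005").
#' @param nodata integer nodata code.
#' @param scheme optional \code{\link{class_scheme}} used to validate codes.
#' @return An object of class \code{"land_grid"}.
#' @export
land_grid <- function(values, cell_size = 100, origin = c(0, 0),
                      epoch = NULL, nodata = -9999L, scheme = NULL) {
  if (!is.matrix(values)) stop("values must be a matrix")
  storage.mode(values) <- "integer"
  if (!is.null(scheme)) {
    ok <- values %in% c(scheme$classes, scheme$subclasses, scheme$nodata)
    if (!all(ok))
      stop("unknown class code: ", paste(unique(values[!ok]), collapse = ", "))
    nodata <- scheme$nodata
  }
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin), epoch = epoch,
                 nodata = as.integer(nodata)),
            class = "land_grid")
}

#' @export
print.land_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("land_grid: %d x %d cells, %g m cells", d[1], d[2], x$cell_size))
  if (!is.null(x$epoch)) cat(sprintf(", epoch %s", x$epoch))
  cat("\n")
  tb <- table(x$values[x$values != x$nodata])
  cat("  codes:", paste(sprintf("%s:%d", names(tb), tb), collapse = "  "), "\n")
  invisible(x)
}

#' @export
dim.land_grid <- function(x) dim(x$values)

# cell area in km^2
cell_area_km2 <- function(grid) (grid$cell_size / 1000)^2

#' Test whether two lattices are aligned
#'
#' Two grids are aligned iff they share shape, cell size and origin.
#' @param a,b \code{land_grid} objects (or objects with the same fields).
#' @return Logical scalar.
#' @export
grids_aligned <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stop_if_misaligned <- function(a, b) {
  if (!grids_aligned(a, b)) stop("grids are not aligned")
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## ESRI ASCII Grid I/O. Header rows: ncols, nrows, xllcorner, yllcorner,
## cellsize, NODATA_value; data rows run north -> south. Codes are written as
## plain integers so round trips are bit-exact.

#' Read a categorical raster from an ESRI ASCII grid
#'
#' @param path path to an \code{.asc} file with integer codes.
#' @param scheme a \code{\link{class_scheme}}; values not in the scheme (and
#'   not nodata) raise an error, never a silent remap.
#' @param epoch optional epoch label attached to the grid.
#' @return A \code{\link{land_grid}}.
#' @export
read_landuse_raster <- function(path, scheme = default_scheme(), epoch = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed ASCII grid header")
  nodata <- if (!is.null(hdr$nodata_value)) as.integer(hdr$nodata_value) else -9999L
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = integer(), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) stop("ASCII grid data size mismatch")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$dx) || !is.null(hdr$dy)) stop("non-square cells unsupported")
  grid <- land_grid(m, cell_size = hdr$cellsize,
                    origin = c(hdr$xllcorner %||% 0, hdr$yllcorner %||% 0),
                    epoch = epoch, nodata = nodata)
  if (!is.null(scheme)) {
    ok <- grid$values %in% c(scheme$classes, scheme$subclasses, nodata)
    if (!all(ok))
      stop("unknown class code: ",
           paste(sort(unique(grid$values[!ok])), collapse = ", "))
  }
  grid
}

#' Write a categorical raster as an ESRI ASCII grid
#'
#' Integer codes are written verbatim so that \code{write} then
#' \code{\link{read_landuse_raster}} is the identity on values, cell size,
#' origin and nodata.
#'
#' @param grid a \code{\link{land_grid}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_landuse_raster <- function(grid, path) {
  d <- dim(grid$values)
  hdr <- c(sprintf("ncols %d", d[2]),
           sprintf("nrows %d", d[1]),
           sprintf("xllcorner %.10g", grid$origin[1]),
           sprintf("yllcorner %.10g", grid$origin[2]),
           sprintf("cellsize %.10g", grid$cell_size),
           sprintf("NODATA_value %d", grid$nodata))
  rows <- apply(grid$values, 1, paste, collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, rows), con)
  invisible(path)
}

#' Write a continuous lattice as an ESRI ASCII grid
#'
#' @param values numeric matrix (row 1 = north); NA written as nodata.
#' @param path output path.
#' @param cell_size,origin raster geometry.
#' @param nodata numeric nodata value.
#' @return Invisibly, \code{path}.
#' @export
write_float_raster <- function(values, path, cell_size = 100,
                               origin = c(0, 0), nodata = -9999) {
  d <- dim(values)
  v <- values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", d[2]),
           sprintf("nrows %d", d[1]),
           sprintf("xllcorner %.10g", origin[1]),
           sprintf("yllcorner %.10g", origin[2]),
           sprintf("cellsize %.10g", cell_size),
           sprintf("NODATA_value %.10g", nodata))
  rows <- apply(v, 1, function(r) paste(formatC(r, format = "g", digits = 10),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------

#' Min-max normalize a driver layer to [0, 1]
#'
#' Affine rescaling of a continuous covariate lattice so the finite minimum
#' maps to 0 and the finite maximum to 1; NAs (nodata) propagate. Order is
#' preserved and the map is idempotent on layers already spanning [0, 1].
#'
#' @param layer numeric matrix with at least two distinct finite values.
#' @return Numeric matrix in [0, 1].
#' @export
normalize_driver <- function(layer) {
  fin <- layer[is.finite(layer)]
  if (length(unique(fin)) < 2)
    stop("cannot normalize a constant layer (undefined range)")
  (layer - min(fin)) / (max(fin) - min(fin))
}

#' Aligned stack of continuous driver lattices
#'
#' Drivers are the spatial covariates of the conversion-suitability
#' regressions: distances to the nearest town, highway and river, elevation
#' (DEM), slope, per-capita GDP and population density, each min-max
#' normalized to [0, 1].
#'
#' @param layers named list of numeric matrices of identical dimension.
#' @param cell_size,origin raster geometry shared by all layers.
#' @param normalize if TRUE (default) apply \code{\link{normalize_driver}}
#'   to each layer.
#' @return An object of class \code{"driver_stack"}.
#' @export
driver_stack <- function(layers, cell_size = 100, origin = c(0, 0),
                         normalize = TRUE) {
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop("driver layers must be named")
  d <- dim(layers[[1]])
  for (l in layers) if (!identical(dim(l), d)) stop("driver layers misaligned")
  if (normalize) layers <- lapply(layers, normalize_driver)
  for (nm in names(layers)) {
    fin <- layers[[nm]][is.finite(layers[[nm]])]
    if (length(fin) && (min(fin) < -1e-12 || max(fin) > 1 + 1e-12))
      stop("driver layer '", nm, "' outside [0, 1]; set normalize = TRUE")
  }
  structure(list(layers = layers, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin)),
            class = "driver_stack")
}

#' @export
print.driver_stack <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat(sprintf("driver_stack: %d layers, %d x %d cells\n  %s\n",
              length(x$layers), d[1], d[2],
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

# flatten a driver stack into an n_cells x n_layers design matrix
driver_matrix <- function(drivers) {
  X <- do.call(cbind, lapply(drivers$layers, as.vector))
  colnames(X) <- names(drivers$layers)
  X
}

## ---------------------------------------------------------------------------

#' Per-class area accounting for a land-use grid
#'
#' @param grid a \code{\link{land_grid}}.
#' @param scheme a \code{\link{class_scheme}}.
#' @return A data frame with one row per class: \code{class}, \code{code},
#'   \code{cells}, \code{area_km2} and \code{proportion} (percent of the
#'   non-nodata landscape; sums to 100).
#' @examples
#' g <- land_grid(matrix(c(rep(3L, 25), rep(2L, 75)), 10, 10))
#' area_table(g)
#' @export
area_table <- function(grid, scheme = default_scheme()) {
  v <- collapse_subclasses(grid$values, scheme)
  v <- v[v != grid$nodata]
  codes <- sort(scheme$classes)
  cells <- vapply(codes, function(k) sum(v == k), numeric(1))
  area <- cells * cell_area_km2(grid)
  data.frame(class = names(codes), code = unname(codes),
             cells = unname(cells), area_km2 = unname(area),
             proportion = unname(100 * cells / sum(cells)),
             row.names = NULL, stringsAsFactors = FALSE)
}
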