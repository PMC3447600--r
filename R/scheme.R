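#' Land-use class scheme
#'
#' A class scheme maps integer raster codes to the four aggregate land-use
#' classes used throughout the package: cultivated, ecological, construction
#' and other. Optional subclass codes (e.g. paddy field, forest, wetland,
#' village residential) can be carried and are collapsed onto the four
#' classes before any analysis.
#'
#' @param classes named integer vector of class codes. Names are the class
#'   labels; defaults to \code{c(cultivated = 1, ecological = 2,
#'   construction = 3, other = 4)}.
#' @param subclasses optional named integer vector of subclass codes whose
#'   names are class labels present in \code{classes}; each subclass belongs
#'   to exactly one class.
#' @param nodata integer nodata code, distinct from all class and subclass
#'   codes.
#' @return An object of class \code{"class_scheme"}.
#' @examples
#' sc <- class_scheme()
#' sc$classes[["ecological"]]
#' @export
class_scheme <- function(classes = c(cultivated = 1L, ecological = 2L,
                                     construction = 3L, other = 4L),
                         subclasses = NULL, nodata = -9999L) {
  classes <- vapply(classes, as.integer, integer(1))
  if (is.null(names(classes)) || anyNA(names(classes)) || any(names(classes) == ""))
    stop("class codes must be named")
  if (anyDuplicated(classes)) stop("class codes must be unique")
  nodata <- as.integer(nodata)
  if (nodata %in% classes) stop("nodata code collides with a class code")
  if (!is.null(subclasses)) {
    subclasses <- vapply(subclasses, as.integer, integer(1))
    if (!all(names(subclasses) %in% names(classes)))
      stop("every subclass must map to a known class")
    if (anyDuplicated(subclasses) || any(subclasses %in% classes) ||
        nodata %in% subclasses)
      stop("subclass codes must be unique and distinct from class/nodata codes")
  }
  structure(list(classes = classes, subclasses = subclasses, nodata = nodata),
            class = "class_scheme")
}

#' @export
print.class_scheme <- function(x, ...) {
  cat("Land-use class scheme:\n")
  for (i in seq_along(x$classes))
    cat(sprintf("  %d = %s\n", x$classes[i], names(x$classes)[i]))
  cat(sprintf("  nodata = %d\n", x$nodata))
  if (!is.null(x$subclasses))
    cat(sprintf("  (%d subclass codes mapped)\n", length(x$subclasses)))
  invisible(x)
}

#' @rdname class_scheme
#' @export
default_scheme <- function() class_scheme()

#' Collapse subclass codes onto their aggregate classes
#'
#' @param values integer matrix (or vector) of class/subclass codes.
#' @param scheme a \code{\link{class_scheme}}.
#' @return Values with every subclass code replaced by its class code.
#' @export
collapse_subclasses <- function(values, scheme) {
  if (is.null(scheme$subclasses)) return(values)
  cls <- scheme$classes[names(scheme$subclasses)]
  for (i in seq_along(scheme$subclasses)) {
    values[values == scheme$subclasses[i]] <- cls[i]
  }
  values
}

# labels of classes in code order, internal convenience
class_labels <- function(scheme) names(sort(scheme$classes))

#' Read a class scheme from a YAML file
#'
#' The YAML file has top-level keys \code{classes} (label: code mapping),
#' optional \code{subclasses} and optional \code{nodata}.
#'
#' @param path path to a YAML file.
#' @return A \code{\link{class_scheme}}.
#' @export
read_scheme_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cl <- unlist(y$classes)
  sub <- if (!is.null(y$subclasses)) unlist(y$subclasses) else NULL
  nd <- if (!is.null(y$nodata)) y$nodata else -9999L
  class_scheme(classes = cl, subclasses = sub, nodata = nd)
}
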