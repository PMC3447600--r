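#' Published Beijing land-use accounting tables
#'
#' The worked example shipped with the package: the published 2000-2005
#' inter-class transition matrix (km^2) and the 2005 status plus predicted
#' 2020 class areas under the three policy scenarios for the Beijing
#' region, stored as plain CSV under \code{inst/extdata}. These desk-scale
#' tables drive the arithmetic reproduction checks (transition-probability
#' rows, percent changes, ecological-land deltas) without any raster data.
#'
#' @return A list with \code{transition} (a
#'   \code{\link{transition_matrix}}, epochs 2000/2005) and \code{areas}
#'   (data frame of class areas in km^2: \code{status_2005},
#'   \code{natural_development}, \code{object_orientation},
#'   \code{ecosystem_priority}).
#' @examples
#' bj <- beijing_tables()
#' round(to_probability(bj$transition)["cultivated", ], 4)
#' @export
beijing_tables <- function() {
  tm_path <- system.file("extdata", "beijing_transition_2000_2005.csv",
                         package = "ecolandca", mustWork = TRUE)
  ar_path <- system.file("extdata", "beijing_areas_2020.csv",
                         package = "ecolandca", mustWork = TRUE)
  tm <- read_transition_csv(tm_path)
  tm$epochs <- c("2000", "2005")
  areas <- utils::read.csv(ar_path, stringsAsFactors = FALSE)
  list(transition = tm, areas = areas)
}
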