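#' Specimen geometry
#'
#' Describes the tensile specimen mounted between the two grip tags. Two
#' shapes are supported: `"cylindrical"` (hypocotyls, stems, roots), whose
#' cross-section is \eqn{A = \pi r^2}, and `"prismatic"` (leaves, sepals,
#' epidermal peels), approximated as \eqn{A = thickness \times width}.
#' `gauge_length_um` is the grip-to-grip reference length \eqn{L_0} over
#' which strain is defined.
#'
#' @param shape `"cylindrical"` or `"prismatic"`.
#' @param gauge_length_um Grip-to-grip reference length \eqn{L_0} in um.
#' @param radius_um Radius in um (cylindrical only).
#' @param thickness_um,width_um Section dimensions in um (prismatic only).
#'
#' @return An object of class `specimen_geometry`.
#' @examples
#' geom <- specimen_geometry("cylindrical", gauge_length_um = 5000, radius_um = 100)
#' cross_section_area(geom)
#' @export
specimen_geometry <- function(shape = c("cylindrical", "prismatic"),
                              gauge_length_um,
                              radius_um = NULL,
                              thickness_um = NULL,
                              width_um = NULL) {
  shape <- match.arg(shape)
  if (!is.numeric(gauge_length_um) || length(gauge_length_um) != 1 ||
      !is.finite(gauge_length_um) || gauge_length_um <= 0) {
    stop_microext("`gauge_length_um` must be a single positive number.",
                  "microext_invalid_geometry")
  }
  if (shape == "cylindrical") {
    if (is.null(radius_um) || !is.finite(radius_um) || radius_um <= 0) {
      stop_microext("cylindrical geometry requires `radius_um` > 0.",
                    "microext_invalid_geometry")
    }
  } else {
    ok <- !is.null(thickness_um) && !is.null(width_um) &&
      is.finite(thickness_um) && is.finite(width_um) &&
      thickness_um > 0 && width_um > 0
    if (!ok) {
      stop_microext("prismatic geometry requires `thickness_um` > 0 and `width_um` > 0.",
                    "microext_invalid_geometry")
    }
  }
  structure(
    list(shape = shape, gauge_length_um = gauge_length_um,
         radius_um = radius_um, thickness_um = thickness_um,
         width_um = width_um),
    class = "specimen_geometry"
  )
}

#' Cross-sectional area of a specimen
#'
#' \eqn{A = \pi r^2} for cylindrical specimens, \eqn{A = t \times w} for
#' prismatic ones. The initial area is used throughout the analysis
#' (constant-area assumption; Poisson thinning is not modelled).
#'
#' @param geom A [specimen_geometry()].
#' @return Area in um^2.
#' @export
cross_section_area <- function(geom) {
  stopifnot(inherits(geom, "specimen_geometry"))
  if (geom$shape == "cylindrical") {
    pi * geom$radius_um^2
  } else {
    geom$thickness_um * geom$width_um
  }
}

#' @export
print.specimen_geometry <- function(x, ...) {
  dims <- if (x$shape == "cylindrical") {
    sprintf("r = %g um", x$radius_um)
  } else {
    sprintf("t = %g um, w = %g um", x$thickness_um, x$width_um)
  }
  cat(sprintf("<specimen_geometry> %s, %s, L0 = %g um, A = %.1f um^2\n",
              x$shape, dims, x$gauge_length_um, cross_section_area(x)))
  invisible(x)
}
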