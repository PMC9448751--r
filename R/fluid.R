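#' Fluid properties
#'
#' Container for the Newtonian fluid constants used throughout the analytic
#' flow model. Blood defaults: density 1060 kg/m^3 and dynamic viscosity
#' 3.5e-3 Pa s.
#'
#' @param density mass density in kg/m^3.
#' @param dynamic_viscosity dynamic viscosity in Pa s.
#'
#' @return An object of class \code{fluid_properties} with fields
#'   \code{density}, \code{dynamic_viscosity} and the derived
#'   \code{kinematic_viscosity} (m^2/s).
#' @examples
#' blood <- fluid_properties()
#' blood$kinematic_viscosity   # ~3.302e-6 m^2/s
#' @export
fluid_properties <- function(density = 1060, dynamic_viscosity = 3.5e-3) {
  if (!is.numeric(density) || length(density) != 1L || density <= 0)
    stop("`density` must be a single positive number (kg/m^3)")
  if (!is.numeric(dynamic_viscosity) || length(dynamic_viscosity) != 1L ||
      dynamic_viscosity <= 0)
    stop("`dynamic_viscosity` must be a single positive number (Pa s)")
  structure(
    list(
      density = density,
      dynamic_viscosity = dynamic_viscosity,
      kinematic_viscosity = dynamic_viscosity / density
    ),
    class = "fluid_properties"
  )
}

#' Straight-tube vessel model
#'
#' A rigid circular tube standing in for a vessel segment. The default radius
#' corresponds to a 25 mm-class mid-ascending-aorta diameter; the tube axis
#' runs along y by convention.
#'
#' @param radius lumen radius in m.
#' @param length tube length in m.
#' @param center 3-vector, tube midpoint in m.
#' @param axis unit 3-vector, tube axis direction.
#'
#' @return An object of class \code{vessel_model}.
#' @examples
#' vessel_model(radius = 0.0125)
#' @export
vessel_model <- function(radius = 0.0125, length = 0.05,
                         center = c(0, 0, 0), axis = c(0, 1, 0)) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("`radius` must be a single positive number (m)")
  if (!is.numeric(length) || base::length(length) != 1L || length <= 0)
    stop("`length` must be a single positive number (m)")
  if (base::length(center) != 3L || !is.numeric(center))
    stop("`center` must be a numeric 3-vector (m)")
  nrm <- sqrt(sum(axis^2))
  if (base::length(axis) != 3L || abs(nrm - 1) > 1e-12)
    stop("`axis` must be a unit 3-vector")
  structure(
    list(radius = radius, length = length,
         center = as.numeric(center), axis = as.numeric(axis)),
    class = "vessel_model"
  )
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("Fluid: rho = %g kg/m^3, mu = %g Pa s, nu = %g m^2/s\n",
              x$density, x$dynamic_viscosity, x$kinematic_viscosity))
  invisible(x)
}

#' @export
print.vessel_model <- function(x, ...) {
  cat(sprintf("Straight tube: R = %g m, L = %g m, axis (%g, %g, %g)\n",
              x$radius, x$length, x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}
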