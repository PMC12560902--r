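#' Convert a force coefficient to a force
#'
#' F = 1/2 rho A U^2 C, the inverse of the standard nondimensionalisation of
#' drag/lift/side forces by dynamic pressure and frontal reference area.
#'
#' @param coefficient Dimensionless force coefficient (vectorised).
#' @param fluid A [fluid_properties()].
#' @param geometry A [shark_geometry()]; supplies the reference area.
#' @param speed Free-stream speed U, m/s (>= 0).
#' @return Force in N.
#' @examples
#' coefficient_to_force(0.098, fluid_properties(),
#'                      shark_geometry(2.95, frontal_area = 0.12), 1)
#' @export
coefficient_to_force <- function(coefficient, fluid, geometry, speed) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (!inherits(geometry, "shark_geometry") || is.null(geometry$frontal_area)) {
    abort("`geometry` must be a shark_geometry with a frontal area.",
          class = "tagburden_config_error")
  }
  check_number(coefficient, "coefficient", scalar = FALSE)
  check_number(speed, "speed", nonnegative = TRUE, scalar = FALSE)
  0.5 * fluid$density * geometry$frontal_area * speed^2 * coefficient
}

#' Convert a force to its dimensionless coefficient
#'
#' C = 2 F / (rho A U^2). Exact algebraic inverse of
#' [coefficient_to_force()]; undefined at zero speed.
#'
#' @param force Force, N (vectorised).
#' @inheritParams coefficient_to_force
#' @return Dimensionless coefficient.
#' @export
force_to_coefficient <- function(force, fluid, geometry, speed) {
  stopifnot(inherits(fluid, "fluid_properties"), inherits(geometry, "shark_geometry"))
  check_number(force, "force", scalar = FALSE)
  check_number(speed, "speed", scalar = FALSE)
  if (any(speed <= 0)) {
    abort("Coefficients are undefined at zero speed (zero dynamic pressure).",
          class = "tagburden_domain_error")
  }
  2 * force / (fluid$density * geometry$frontal_area * speed^2)
}

#' Convert a pitching moment to its coefficient
#'
#' C_M = 2 M / (rho A L U^2), with the fork length as moment reference.
#'
#' @param moment Pitching moment about the body's centre of rotation, N m.
#' @inheritParams coefficient_to_force
#' @return Dimensionless moment coefficient.
#' @export
moment_to_coefficient <- function(moment, fluid, geometry, speed) {
  stopifnot(inherits(fluid, "fluid_properties"), inherits(geometry, "shark_geometry"))
  check_number(moment, "moment", scalar = FALSE)
  check_number(speed, "speed", scalar = FALSE)
  if (any(speed <= 0)) {
    abort("Moment coefficients are undefined at zero speed.",
          class = "tagburden_domain_error")
  }
  2 * moment / (fluid$density * geometry$frontal_area * geometry$fork_length * speed^2)
}

#' Percent increase of a tagged quantity over an untagged baseline
#'
#' 100 (tagged - base) / base, the headline tag-burden metric applied to
#' coefficients, forces or energies. May be negative: the packaged archival
#' series dips below the untagged baseline at the highest speeds, within the
#' printing precision of the source coefficients.
#'
#' @param base Baseline (untagged) value, > 0 (vectorised).
#' @param tagged Tagged value, same units.
#' @return Percent change.
#' @examples
#' percent_increase(0.098, 0.118) # fin-mount at cruise: 20.4%
#' @export
percent_increase <- function(base, tagged) {
  check_number(base, "base", scalar = FALSE)
  check_number(tagged, "tagged", scalar = FALSE)
  if (any(base <= 0)) {
    abort("`base` must be strictly positive for a percent increase.",
          class = "tagburden_invalid_input")
  }
  100 * (tagged - base) / base
}
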