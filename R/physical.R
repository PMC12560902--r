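#' Seawater (or other working fluid) properties
#'
#' Bundles the density and dynamic viscosity that every force and Reynolds
#' computation needs. Defaults are seawater at 20 degrees C, the temperature
#' band typical of the pelagic habitat the packaged coefficient tables were
#' computed for.
#'
#' @param density Fluid density rho, kg/m^3. Default 1025 (seawater, 20 C).
#' @param dynamic_viscosity Dynamic viscosity mu, Pa s. Default 0.00109.
#' @return An object of class `fluid_properties`: a list with elements
#'   `density`, `dynamic_viscosity` and the derived `kinematic_viscosity`
#'   (mu/rho, m^2/s).
#' @examples
#' seawater <- fluid_properties()
#' seawater$kinematic_viscosity
#' @export
fluid_properties <- function(density = 1025, dynamic_viscosity = 0.00109) {
  check_number(density, "density", positive = TRUE)
  check_number(dynamic_viscosity, "dynamic_viscosity", positive = TRUE)
  structure(
    list(
      density = density,
      dynamic_viscosity = dynamic_viscosity,
      kinematic_viscosity = dynamic_viscosity / density
    ),
    class = "fluid_properties"
  )
}

#' Shark body geometry
#'
#' Characteristic dimensions of a streamlined pelagic shark body: fork length
#' (snout to caudal-fin fork, the characteristic length for Reynolds numbers)
#' and maximum frontal cross-sectional area (the reference area for force
#' coefficients). When `frontal_area` is not supplied it defaults to the
#' slender-body relation A = c_A * L^2; the default coefficient gives
#' A = 0.12 m^2 at the full adult length of 2.95 m. Frontal area cancels in
#' every ratio metric (percent drag or energy increase), so the default only
#' affects absolute forces and energies.
#'
#' @param fork_length Fork length L, m.
#' @param frontal_area Maximum frontal cross-sectional area A, m^2, or `NULL`
#'   to use `area_coefficient * fork_length^2`.
#' @param mass Body mass, kg, or `NULL` to estimate with [estimate_mass()].
#' @param area_coefficient Dimensionless c_A in the default area relation.
#' @return An object of class `shark_geometry`: a list with `fork_length`,
#'   `frontal_area`, `mass`, `area_coefficient`.
#' @examples
#' adult <- shark_geometry(2.95)
#' juvenile <- scale_geometry(adult, 1)
#' juvenile$mass
#' @export
shark_geometry <- function(fork_length, frontal_area = NULL, mass = NULL,
                           area_coefficient = 0.12 / 2.95^2) {
  check_number(fork_length, "fork_length", positive = TRUE)
  check_number(area_coefficient, "area_coefficient", positive = TRUE)
  if (is.null(frontal_area)) {
    frontal_area <- area_coefficient * fork_length^2
  }
  check_number(frontal_area, "frontal_area", positive = TRUE)
  if (is.null(mass)) {
    mass <- estimate_mass(fork_length)
  }
  check_number(mass, "mass", positive = TRUE)
  structure(
    list(
      fork_length = fork_length,
      frontal_area = frontal_area,
      mass = mass,
      area_coefficient = area_coefficient
    ),
    class = "shark_geometry"
  )
}

#' Uniform isometric scaling of a body geometry
#'
#' Rescales a geometry to a target fork length under geometric similarity:
#' lengths scale by s, areas by s^2, masses by s^3. This mirrors how smaller
#' age classes are represented by uniformly shrinking an adult body model.
#'
#' @param geometry A [shark_geometry()].
#' @param target_fork_length Desired fork length, m.
#' @return A new `shark_geometry` at the target length.
#' @examples
#' adult <- shark_geometry(2.95, frontal_area = 0.12)
#' scale_geometry(adult, 1)$frontal_area # 0.12 * (1 / 2.95)^2
#' @export
scale_geometry <- function(geometry, target_fork_length) {
  stopifnot(inherits(geometry, "shark_geometry"))
  check_number(target_fork_length, "target_fork_length", positive = TRUE)
  s <- target_fork_length / geometry$fork_length
  structure(
    list(
      fork_length = geometry$fork_length * s,
      frontal_area = geometry$frontal_area * s^2,
      mass = geometry$mass * s^3,
      area_coefficient = geometry$area_coefficient
    ),
    class = "shark_geometry"
  )
}

#' Length-mass estimate for a pelagic shark
#'
#' Allometric length-mass model `mass = anchor_mass * (L / anchor_length)^exponent`.
#' The default is isometric (cubic) scaling anchored at 17 kg for a 1 m fork
#' length, the mass used in the weight-ratio worked example for a young mako;
#' both anchor and exponent are overridable for other species or published
#' length-weight fits.
#'
#' @param fork_length Fork length L, m (vectorised).
#' @param anchor_length,anchor_mass Anchor point of the relation (m, kg).
#' @param exponent Allometric exponent; 3 is isometric.
#' @return Estimated mass, kg.
#' @examples
#' estimate_mass(1)   # 17
#' estimate_mass(2)   # 136
#' @export
estimate_mass <- function(fork_length, anchor_length = 1, anchor_mass = 17,
                          exponent = 3) {
  check_number(fork_length, "fork_length", positive = TRUE, scalar = FALSE)
  check_number(anchor_length, "anchor_length", positive = TRUE)
  check_number(anchor_mass, "anchor_mass", positive = TRUE)
  check_number(exponent, "exponent")
  anchor_mass * (fork_length / anchor_length)^exponent
}

#' Reynolds number of the flow around a body
#'
#' Re = rho * U * L / mu, the dimensionless ratio of inertial to viscous
#' forces, with the fork length as characteristic length. Governs whether the
#' boundary layer is laminar or turbulent and indexes the drag-coefficient
#' sweeps.
#'
#' @param fluid A [fluid_properties()].
#' @param geometry A [shark_geometry()].
#' @param speed Free-stream speed U, m/s (vectorised, >= 0).
#' @return Dimensionless Reynolds number, same length as `speed`.
#' @examples
#' reynolds_number(fluid_properties(), shark_geometry(2.95), c(0.5, 9.1))
#' @export
reynolds_number <- function(fluid, geometry, speed) {
  stopifnot(inherits(fluid, "fluid_properties"), inherits(geometry, "shark_geometry"))
  check_number(speed, "speed", nonnegative = TRUE, scalar = FALSE)
  fluid$density * speed * geometry$fork_length / fluid$dynamic_viscosity
}

#' Tag configuration descriptor
#'
#' Identifies a tag attachment scenario: `"none"` (untagged baseline),
#' `"archival_body"` (archival tag pinned along the dorsal musculature, with
#' a placement site 1-4 running anterior to posterior), or `"fin_mount"`
#' (transmitter bolted to the dorsal fin). The packaged coefficient data
#' carry one archival series; placement sites share it, differing only in the
#' localised force balance not tabulated here.
#'
#' @param tag_kind One of `"none"`, `"archival_body"`, `"fin_mount"`.
#' @param placement_site Integer 1-4; only meaningful (and only allowed) for
#'   `"archival_body"`.
#' @param mass_in_air Tag mass in air, kg (>= 0).
#' @return An object of class `tag_config`.
#' @examples
#' tag_config("archival_body", placement_site = 3, mass_in_air = 0.060)
#' @export
tag_config <- function(tag_kind, placement_site = NULL, mass_in_air = 0) {
  tag_kind <- match.arg(tag_kind, tag_config_levels())
  if (!is.null(placement_site)) {
    if (tag_kind != "archival_body") {
      abort("`placement_site` is defined only for archival_body tags.",
            class = "tagburden_invalid_input")
    }
    if (!placement_site %in% 1:4) {
      abort("`placement_site` must be an integer in 1..4.",
            class = "tagburden_invalid_input")
    }
  }
  check_number(mass_in_air, "mass_in_air", nonnegative = TRUE)
  structure(
    list(tag_kind = tag_kind, placement_site = placement_site,
         mass_in_air = mass_in_air),
    class = "tag_config"
  )
}
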