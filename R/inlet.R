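#' Inlet turbulence quantities for an external CFD case
#'
#' Rule-of-thumb inlet/initial values of turbulent kinetic energy k,
#' dissipation rate epsilon and specific dissipation rate omega for a RANS
#' case around a body of fork length L:
#' k = (2/3) (U Ti)^2, epsilon = 0.09^(3/4) k^(3/2) / (0.07 L),
#' omega = epsilon / k. The default free-stream turbulence intensity is 2%,
#' the value used when calibrating the packaged sweeps; it is an assumption
#' for other speeds and can be overridden.
#'
#' @param speed Free-stream speed U, m/s (vectorised, > 0).
#' @param geometry A [shark_geometry()]; only the fork length enters.
#' @param turbulence_intensity Free-stream turbulence intensity Ti as a
#'   fraction in (0, 1). Default 0.02.
#' @return A tibble with columns `speed_m_s`, `turbulence_intensity`,
#'   `k_m2_s2`, `epsilon_m2_s3`, `omega_per_s`.
#' @examples
#' inlet_conditions(9.1, shark_geometry(2.95))
#' @export
inlet_conditions <- function(speed, geometry, turbulence_intensity = 0.02) {
  stopifnot(inherits(geometry, "shark_geometry"))
  check_number(speed, "speed", scalar = FALSE)
  check_number(turbulence_intensity, "turbulence_intensity")
  if (any(speed <= 0) || turbulence_intensity <= 0) {
    abort("Zero speed or turbulence intensity gives an all-zero (degenerate) inlet.",
          class = "tagburden_degenerate_input")
  }
  if (turbulence_intensity >= 1) {
    abort("`turbulence_intensity` is a fraction and must be < 1.",
          class = "tagburden_invalid_input")
  }
  k <- (2 / 3) * (speed * turbulence_intensity)^2
  epsilon <- 0.09^(3 / 4) * k^(3 / 2) / (0.07 * geometry$fork_length)
  tibble(
    speed_m_s = speed,
    turbulence_intensity = turbulence_intensity,
    k_m2_s2 = k,
    epsilon_m2_s3 = epsilon,
    omega_per_s = epsilon / k
  )
}

#' Format inlet turbulence quantities as a flat key-value block
#'
#' Solver-agnostic plain-text rendering (one `key value` pair per line, units
#' in comments) that is trivial to post-process into any solver's boundary
#' dictionary.
#'
#' @param conditions A one-row tibble from [inlet_conditions()].
#' @param path Optional file path; when given the block is also written there.
#' @return The block as a character vector of lines, invisibly when `path`
#'   is given.
#' @export
format_inlet_block <- function(conditions, path = NULL) {
  stopifnot(is.data.frame(conditions), nrow(conditions) == 1L)
  lines <- c(
    "# inlet turbulence quantities (rule-of-thumb initialisation)",
    sprintf("# U = %g m/s, Ti = %g", conditions$speed_m_s,
            conditions$turbulence_intensity),
    sprintf("k %.10g        # m^2/s^2", conditions$k_m2_s2),
    sprintf("epsilon %.10g  # m^2/s^3", conditions$epsilon_m2_s3),
    sprintf("omega %.10g    # 1/s", conditions$omega_per_s)
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
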