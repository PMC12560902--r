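#' Burst-speed reduction at equal propulsive power
#'
#' If the power an untagged shark produces at its burst speed is the ceiling
#' of its capability, a tagged shark must slow down until its power demand
#' matches that ceiling. Two readings of the equal-power condition are
#' implemented:
#'
#' * `"fixed_force"` (default) holds the drag forces at their burst-speed
#'   values and solves `F_tag(v_b) v' = F_untag(v_b) v_b`, giving the closed
#'   form `v' = v_b / (1 + delta)` and a reduction of `delta / (1 + delta)`
#'   where `delta` is the fractional drag increase at `v_b`.
#' * `"cd_interpolated"` re-evaluates the tagged drag coefficient at the
#'   reduced speed and root-finds `v'` such that
#'   `C_D,tag(v') v'^3 = C_D,untag(v_b) v_b^3` on the interpolated table
#'   (bisection bracket `[bracket_min, v_b]`, tolerance 1e-6 m/s). For a
#'   speed-independent coefficient this reduces to
#'   `1 - (1 + delta)^(-1/3)`.
#'
#' The first reading matches how reported speed reductions relate to
#' reported drag increases in tag-burden studies; the second is the
#' physically richer cubic-power solution. Both are returned by
#' `variant = c("fixed_force", "cd_interpolated")`.
#'
#' @param burst_speed Untagged burst speed v_b, m/s, within the table range.
#' @param table A `drag_table` containing both configurations.
#' @param fluid A [fluid_properties()].
#' @param geometry A [shark_geometry()].
#' @param tagged_config Tagged configuration label.
#' @param untagged_config Baseline label. Default `"none"`.
#' @param variant One or both of `"fixed_force"`, `"cd_interpolated"`.
#' @param bracket_min Lower end of the root bracket, m/s. Default 0.5 (the
#'   table's lower speed edge).
#' @param tol Bisection tolerance, m/s.
#' @return A tibble with one row per variant: `variant`, `tag_config`,
#'   `burst_speed`, `reduced_speed`, `pct_reduction`.
#' @examples
#' burst_speed_reduction(9.1, mako_drag_table(), fluid_properties(),
#'                       shark_geometry(2.95), "fin_mount")
#' @export
burst_speed_reduction <- function(burst_speed, table, fluid, geometry,
                                  tagged_config, untagged_config = "none",
                                  variant = c("fixed_force", "cd_interpolated"),
                                  bracket_min = 0.5, tol = 1e-6) {
  variant <- match.arg(variant, several.ok = TRUE)
  check_number(burst_speed, "burst_speed", positive = TRUE)
  cd_un <- lookup_cd(table, geometry$fork_length, burst_speed,
                     config = untagged_config, rule = "strict")
  cd_tag_at_vb <- lookup_cd(table, geometry$fork_length, burst_speed,
                            config = tagged_config, rule = "strict")
  rows <- purrr::map(variant, function(v) {
    if (v == "fixed_force") {
      delta <- cd_tag_at_vb / cd_un - 1
      reduced <- burst_speed / (1 + delta)
    } else {
      target <- cd_un * burst_speed^3
      f <- function(s) {
        lookup_cd(table, geometry$fork_length, s, config = tagged_config,
                  rule = "strict") * s^3 - target
      }
      lo <- bracket_min
      if (f(burst_speed) <= 0) {
        # tagged power at v_b does not exceed the untagged target: no slow-down
        reduced <- burst_speed
      } else {
        if (f(lo) > 0) {
          abort("No equal-power root within the table's speed range.",
                class = "tagburden_range_error")
        }
        reduced <- uniroot(f, lower = lo, upper = burst_speed, tol = tol)$root
      }
    }
    tibble(
      variant = v,
      tag_config = tagged_config,
      burst_speed = burst_speed,
      reduced_speed = reduced,
      pct_reduction = 100 * (1 - reduced / burst_speed)
    )
  })
  dplyr::bind_rows(rows)
}

#' Tag-to-body weight-ratio rule check
#'
#' Evaluates the classical mass-based tagging thresholds: the 3% rule from
#' avian biologging and the stricter 2% rule sometimes adopted for fish.
#' Ratios use the tag's mass in air (the quantity vendors publish); the rule
#' is inclusive at the boundary. Note that hydrodynamic burden is not
#' proportional to this ratio — a 60 g tag can be 0.35% of body mass yet
#' still carry a disproportionate drag cost — which is why the energetic
#' metrics elsewhere in this package are the headline outputs.
#'
#' @param tag_mass_in_air Tag mass in air, kg (>= 0, vectorised).
#' @param body_mass Body mass, kg (> 0).
#' @param threshold Rule threshold(s) in percent. Default `c(2, 3)`.
#' @return A tibble: `tag_mass_in_air_kg`, `body_mass_kg`, `ratio_pct`,
#'   `threshold_pct`, `within_rule` (one row per tag x threshold).
#' @examples
#' weight_ratio(0.060, 17)  # 0.35%, within both rules
#' @export
weight_ratio <- function(tag_mass_in_air, body_mass, threshold = c(2, 3)) {
  check_number(tag_mass_in_air, "tag_mass_in_air", nonnegative = TRUE, scalar = FALSE)
  check_number(body_mass, "body_mass", positive = TRUE)
  check_number(threshold, "threshold", positive = TRUE, scalar = FALSE)
  out <- tidyr::expand_grid(
    tag_mass_in_air_kg = tag_mass_in_air,
    threshold_pct = threshold
  )
  dplyr::mutate(out,
                body_mass_kg = body_mass,
                ratio_pct = 100 * .data$tag_mass_in_air_kg / body_mass,
                within_rule = .data$ratio_pct <= .data$threshold_pct,
                .after = "tag_mass_in_air_kg")
}
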