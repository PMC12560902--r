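# Shared fixtures: standard seawater, the full-size body, and small
# synthetic tables built in code.

std_fluid <- function() fluid_properties(1025, 0.00109)

adult_geometry <- function() shark_geometry(2.95, frontal_area = 0.12)

# Two-configuration table whose tagged column is a constant multiple
# (1 + delta) of the untagged one; cd constant over speed unless a slope
# is requested (cd decays as speed^-slope).
const_delta_table <- function(delta, cd_base = 0.08,
                              speeds = c(0.5, 1, 2, 3.6, 5, 9.1),
                              sizes = 2.95, slope = 0) {
  grid <- expand.grid(speed_m_s = speeds, fork_length_m = sizes)
  base <- cd_base * grid$speed_m_s^(-slope)
  drag_table(rbind(
    data.frame(grid, tag_config = "none", cd = base),
    data.frame(grid, tag_config = "fin_mount", cd = base * (1 + delta))
  ))
}

# Noiseless surrogate untagged/tagged pair on the packaged speed grid.
surrogate_pair <- function(tag_ratio = 0.02, noise_sd = 0, seed = 1L,
                           sizes = 2.95) {
  fl <- std_fluid()
  speeds <- c(0.5, 1, 1.5, 2, 3.6, 5, 7.8, 9.1)
  un <- generate_table(surrogate_params(noise_sd = noise_sd, seed = seed),
                       speeds, sizes, fl)
  tg <- generate_table(surrogate_params(tag_drag_area_ratio = tag_ratio,
                                        noise_sd = noise_sd, seed = seed + 1000L),
                       speeds, sizes, fl, tag_config = "fin_mount")
  drag_table(rbind(un, tg), check_monotone = FALSE)
}
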