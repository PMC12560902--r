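test_that("activity budgets allocate the non-glide, non-burst remainder to cruising", {
  b <- activity_budget(0, burst_speed = 3.6)
  expect_equal(c(b$glide_fraction, b$burst_fraction, b$cruise_fraction),
               c(0.07, 0, 0.93))
  expect_equal(activity_budget(0.20, 9.1)$cruise_fraction, 0.73)
  expect_equal(activity_budget(0.93, 5)$cruise_fraction, 0)
  expect_error(activity_budget(0.95, 5), class = "tagburden_invalid_budget")
  expect_error(activity_budget(0.05, 0.5), class = "tagburden_invalid_input")
})

test_that("daily energy is time x drag x speed with unpowered gliding", {
  fl <- std_fluid()
  g <- adult_geometry()
  tab <- mako_drag_table()
  b <- activity_budget(0, burst_speed = 3.6)
  e <- daily_energy(b, tab, fl, g)
  expect_equal(e$energy_j[e$behaviour == "glide"], 0)
  expect_equal(e$energy_j[e$behaviour == "burst"], 0)
  # hand evaluation: 0.93 * 86400 * (1/2 * 1025 * 0.12 * 1^2 * 0.098) * 1
  expect_equal(e$energy_j[e$behaviour == "cruise"], 0.93 * 86400 * 6.027,
               tolerance = 1e-12)
  expect_equal(sum(e$energy_j), 4.843e5, tolerance = 1e-3)
  # linear in day length
  b2 <- activity_budget(0, burst_speed = 3.6, day_length = 2 * 86400)
  expect_equal(sum(daily_energy(b2, tab, fl, g)$energy_j), 2 * sum(e$energy_j))
})

test_that("energy increase matches the printed coefficient ratios at cruise", {
  fl <- std_fluid()
  g <- adult_geometry()
  tab <- mako_drag_table()
  b <- activity_budget(0, burst_speed = 3.6)
  expect_equal(energy_increase(b, tab, fl, g, "fin_mount"),
               100 * (0.118 / 0.098 - 1), tolerance = 1e-12)
  # archival equals the baseline at 1 m/s in the 3-decimal table
  expect_equal(energy_increase(b, tab, fl, g, "archival_body"), 0)
  expect_identical(energy_increase(b, tab, fl, g, "none"), 0)
  degenerate <- activity_budget(0, burst_speed = 3.6, glide_fraction = 1)
  expect_error(energy_increase(degenerate, tab, fl, g, "fin_mount"),
               class = "tagburden_undefined_ratio")
})

test_that("percent energy increase is invariant to area, density and day length", {
  tab <- mako_drag_table()
  b <- activity_budget(0.10, burst_speed = 9.1)
  base <- energy_increase(b, tab, std_fluid(), adult_geometry(), "fin_mount")
  set.seed(21)
  for (s in runif(5, 0.2, 5)) {
    alt_geom <- shark_geometry(2.95, frontal_area = 0.12 * s)
    alt_fluid <- fluid_properties(1025 * s, 0.00109)
    alt_budget <- activity_budget(0.10, 9.1, day_length = 86400 * s)
    expect_identical(energy_increase(b, tab, std_fluid(), alt_geom, "fin_mount"), base)
    expect_identical(energy_increase(b, tab, alt_fluid, adult_geometry(), "fin_mount"), base)
    expect_identical(energy_increase(alt_budget, tab, std_fluid(), adult_geometry(),
                                     "fin_mount"), base)
  }
})

test_that("scenario grids have product cardinality and saturating fin-mount curves", {
  fl <- std_fluid()
  g <- adult_geometry()
  tab <- mako_drag_table()
  grid <- scenario_grid(tab, fl, g)
  expect_equal(nrow(grid), 2 * 4 * 21)
  expect_equal(nrow(scenario_grid(tab, fl, g, burst_fractions = 0,
                                  tagged_configs = "fin_mount")), 4)
  # fin-mount burden always exceeds archival burden, scenario by scenario
  wide <- tidyr::pivot_wider(grid[c("tag_config", "burst_speed", "burst_fraction",
                                    "pct_increase")],
                             names_from = "tag_config",
                             values_from = "pct_increase")
  expect_true(all(wide$fin_mount > wide$archival_body))
  # monotone non-decreasing in burst fraction, saturating (diminishing marginal)
  fin <- subset(grid, tag_config == "fin_mount")
  for (v in unique(fin$burst_speed)) {
    curve <- fin$pct_increase[fin$burst_speed == v][order(fin$burst_fraction[fin$burst_speed == v])]
    expect_true(all(diff(curve) >= -1e-12))
    marginals <- diff(curve)
    expect_lt(marginals[length(marginals)], marginals[1])
  }
  expect_error(scenario_grid(tab, fl, g, burst_speeds = numeric()),
               class = "tagburden_invalid_input")
})
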