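test_that("surrogate coefficients match hand-evaluated friction-line values", {
  p <- surrogate_params(noise_sd = 0)
  # hand evaluation of 1.15 * 0.074 * Re^(-1/5) * 25
  expect_equal(surrogate_cd(p, 2.52e7), 0.0704, tolerance = 1e-3)
  expect_equal(surrogate_cd(p, 1.39e6), 0.1257, tolerance = 1e-3)
  # additive tag drag area shifts every cell by exactly its ratio
  p_tag <- surrogate_params(tag_drag_area_ratio = 0.02, noise_sd = 0)
  re <- c(1e6, 5e6, 2e7)
  expect_equal(surrogate_cd(p_tag, re), surrogate_cd(p, re) + 0.02)
  expect_error(surrogate_cd(p, -1), class = "tagburden_invalid_input")
  expect_error(surrogate_params(form_factor = 0.9),
               class = "tagburden_invalid_input")
})

test_that("generated tables are deterministic per seed and monotone when noiseless", {
  fl <- std_fluid()
  speeds <- c(0.5, 1, 2, 3.6, 5, 9.1)
  p <- surrogate_params(noise_sd = 0.002, seed = 42L)
  t1 <- generate_table(p, speeds, c(1, 2.95), fl)
  t2 <- generate_table(p, speeds, c(1, 2.95), fl)
  expect_identical(t1, t2)
  t3 <- generate_table(surrogate_params(noise_sd = 0.002, seed = 43L),
                       speeds, c(1, 2.95), fl)
  expect_false(identical(t1$cd, t3$cd))
  # generation must not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_table(p, speeds, 2.95, fl))
  expect_identical(runif(1), before)
  # noiseless tables satisfy the monotone-decay invariant for any valid params
  set.seed(14)
  for (i in 1:10) {
    pr <- surrogate_params(form_factor = runif(1, 1, 1.5),
                           wetted_to_frontal_ratio = runif(1, 5, 40),
                           pressure_cd = runif(1, 0, 0.05),
                           tag_drag_area_ratio = runif(1, 0, 0.05),
                           noise_sd = 0)
    tab <- generate_table(pr, speeds, c(1, 2, 2.95), fl)
    cols <- split(tab, tab$fork_length_m)
    for (col in cols) expect_true(all(diff(col$cd[order(col$speed_m_s)]) < 0))
  }
})

test_that("noiseless tables return their generating parameters to 1e-6 relative", {
  fl <- std_fluid()
  pair <- surrogate_pair(tag_ratio = 0.02, noise_sd = 0)
  fit <- fit_surrogate(pair, fl)
  expect_equal(fit$friction_scale, 1.15 * 25, tolerance = 1e-6)
  expect_equal(fit$pressure_cd, 0, tolerance = 1e-8)
  expect_equal(unname(fit$tag_deltas[["fin_mount"]]), 0.02, tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-10)
})

test_that("friction scale is recovered within 10% in at least 90% of noisy replicates", {
  fl <- std_fluid()
  speeds <- c(0.5, 1, 1.5, 2, 3.6, 5, 7.8, 9.1)
  truth <- 1.15 * 25
  hits <- vapply(1:50, function(seed) {
    tab <- generate_table(surrogate_params(noise_sd = 0.002, seed = seed),
                          speeds, 2.95, fl)
    fit <- fit_surrogate(tab, fl)
    abs(fit$friction_scale / truth - 1) <= 0.10
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("friction-scale bias vanishes as the noise level goes to zero", {
  fl <- std_fluid()
  speeds <- c(0.5, 1, 1.5, 2, 3.6, 5, 7.8, 9.1)
  truth <- 1.15 * 25
  bias <- vapply(c(0, 0.001, 0.002), function(sd) {
    est <- vapply(1:30, function(seed) {
      tab <- generate_table(surrogate_params(noise_sd = sd, seed = seed),
                            speeds, 2.95, fl)
      fit_surrogate(tab, fl)$friction_scale
    }, numeric(1))
    mean(est) / truth - 1
  }, numeric(1))
  expect_equal(bias[1], 0, tolerance = 1e-10)
  # OLS on an unbiased-noise design: the mean estimate stays within the
  # Monte-Carlo standard error band at every noise level
  expect_lt(abs(bias[2]), 0.02)
  expect_lt(abs(bias[3]), 0.02)
})

test_that("the friction line fits the packaged untagged adult column closely", {
  fl <- std_fluid()
  col <- mako_drag_table("none")
  col <- drag_table(col[col$fork_length_m == 2.95, ])
  fit <- fit_surrogate(col, fl)
  expect_lt(fit$max_abs_residual, 0.01)
  expect_equal(nrow(tidy(fit)), 2)
  expect_equal(glance(fit)$nobs, 8)
})

test_that("a generated tagged/untagged pair yields the additive percent increase", {
  fl <- std_fluid()
  pair <- surrogate_pair(tag_ratio = 0.02, noise_sd = 0)
  un <- pair[pair$tag_config == "none", ]
  tg <- pair[pair$tag_config == "fin_mount", ]
  expect_equal(percent_increase(un$cd, tg$cd), 100 * 0.02 / un$cd,
               tolerance = 1e-12)
})

test_that("degenerate or tiny tables are rejected by the fitter", {
  fl <- std_fluid()
  const <- drag_table(data.frame(speed_m_s = c(1, 2, 3, 4), fork_length_m = 2.95,
                                 tag_config = "none", cd = 0.08))
  expect_error(fit_surrogate(const, fl), class = "tagburden_fit_failure")
  small <- drag_table(data.frame(speed_m_s = c(1, 2, 3), fork_length_m = 2.95,
                                 tag_config = "none", cd = c(0.1, 0.09, 0.08)))
  expect_error(fit_surrogate(small, fl), class = "tagburden_fit_failure")
})
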