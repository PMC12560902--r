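#' Parameters of the friction-line drag surrogate
#'
#' The surrogate emulates the statistical structure of a CFD drag sweep with
#' an interpretable three-term model built on the Prandtl turbulent
#' flat-plate friction line `C_f = 0.074 Re^(-1/5)`:
#'
#' `C_D = pressure_cd + form_factor * C_f(Re) * wetted_to_frontal_ratio +
#' tag_drag_area_ratio`
#'
#' where `form_factor` converts flat-plate friction to a three-dimensional
#' body, `wetted_to_frontal_ratio` rescales from wetted-area to
#' frontal-area reference, `pressure_cd` is a speed-independent pressure
#' (form) drag term, and `tag_drag_area_ratio` is the additive drag area of
#' an attached tag over the host's frontal area. Optional Gaussian noise
#' (sd on the coefficient scale, truncated at zero) emulates solver
#' convergence scatter; the default 0.002 is of the order of the printing
#' precision of published coefficient tables.
#'
#' @param form_factor Dimensionless, >= 1. Default 1.15.
#' @param wetted_to_frontal_ratio Wetted area over frontal area, > 0.
#'   Default 25 (slender body).
#' @param pressure_cd Speed-independent drag term, >= 0. Default 0.
#' @param tag_drag_area_ratio Additive tag drag area over frontal area,
#'   >= 0. Default 0 (untagged).
#' @param noise_sd Gaussian noise sd on the coefficient scale, >= 0.
#'   Default 0.002.
#' @param seed Integer seed used by [generate_table()]; no global random
#'   state is touched.
#' @return An object of class `surrogate_params`.
#' @examples
#' surrogate_params(tag_drag_area_ratio = 0.02)
#' @export
surrogate_params <- function(form_factor = 1.15, wetted_to_frontal_ratio = 25,
                             pressure_cd = 0, tag_drag_area_ratio = 0,
                             noise_sd = 0.002, seed = 1L) {
  check_number(form_factor, "form_factor")
  if (form_factor < 1) {
    abort("`form_factor` must be >= 1 (a body cannot have less friction than a flat plate).",
          class = "tagburden_invalid_input")
  }
  check_number(wetted_to_frontal_ratio, "wetted_to_frontal_ratio", positive = TRUE)
  check_number(pressure_cd, "pressure_cd", nonnegative = TRUE)
  check_number(tag_drag_area_ratio, "tag_drag_area_ratio", nonnegative = TRUE)
  check_number(noise_sd, "noise_sd", nonnegative = TRUE)
  check_number(seed, "seed")
  structure(
    list(form_factor = form_factor,
         wetted_to_frontal_ratio = wetted_to_frontal_ratio,
         pressure_cd = pressure_cd,
         tag_drag_area_ratio = tag_drag_area_ratio,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "surrogate_params"
  )
}

#' Surrogate drag coefficient at a Reynolds number
#'
#' Noiseless evaluation of the friction-line surrogate (see
#' [surrogate_params()]); strictly decreasing in Re whenever the friction
#' term is active.
#'
#' @param params A [surrogate_params()].
#' @param re Reynolds number(s), > 0.
#' @return Dimensionless drag coefficient(s).
#' @examples
#' surrogate_cd(surrogate_params(), 2.52e7)
#' @export
surrogate_cd <- function(params, re) {
  stopifnot(inherits(params, "surrogate_params"))
  check_number(re, "re", positive = TRUE, scalar = FALSE)
  params$pressure_cd +
    params$form_factor * 0.074 * re^(-1 / 5) * params$wetted_to_frontal_ratio +
    params$tag_drag_area_ratio
}

# evaluate expr under a private RNG stream, leaving global state untouched
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic drag-coefficient sweep
#'
#' Evaluates the surrogate at the Reynolds number of every (speed, size)
#' grid point and, when `noise_sd > 0`, perturbs each cell with independent
#' Gaussian noise (truncated at zero) drawn from a private RNG stream seeded
#' by `params$seed` — identical parameters always give an identical table.
#'
#' @param params A [surrogate_params()].
#' @param speeds Speed grid, m/s (> 0).
#' @param sizes Fork-length grid, m (> 0).
#' @param fluid A [fluid_properties()].
#' @param tag_config Label to stamp on the rows. Default `"none"`.
#' @return A validated `drag_table`.
#' @examples
#' tab <- generate_table(surrogate_params(noise_sd = 0),
#'                       mako_speeds()$speed_m_s, 2.95, fluid_properties())
#' @export
generate_table <- function(params, speeds, sizes, fluid, tag_config = "none") {
  stopifnot(inherits(params, "surrogate_params"), inherits(fluid, "fluid_properties"))
  check_number(speeds, "speeds", positive = TRUE, scalar = FALSE)
  check_number(sizes, "sizes", positive = TRUE, scalar = FALSE)
  grid <- tidyr::expand_grid(fork_length_m = sort(sizes),
                             speed_m_s = sort(speeds))
  re <- fluid$density * grid$speed_m_s * grid$fork_length_m /
    fluid$dynamic_viscosity
  cd <- surrogate_cd(params, re)
  if (params$noise_sd > 0) {
    cd <- with_private_seed(params$seed,
                            cd + rnorm(length(cd), sd = params$noise_sd))
    cd <- pmax(cd, .Machine$double.eps)
  }
  out <- dplyr::mutate(grid, tag_config = tag_config, cd = cd)
  drag_table(out[c("speed_m_s", "fork_length_m", "tag_config", "cd")],
             check_monotone = params$noise_sd == 0)
}

#' Fit the friction-line surrogate to a drag table
#'
#' Ordinary least squares of the tabulated coefficients on the
#' `0.074 Re^(-1/5)` friction basis. With a single configuration the fitted
#' terms are the combined friction scale (form factor x wetted-to-frontal
#' ratio) and the speed-independent `pressure_cd` intercept. When the table
#' contains a baseline and tagged configuration(s), the tagged columns are
#' fitted jointly with one additive drag-area offset per tagged
#' configuration (`tag_drag_area_ratio`) — the offset and the intercept are
#' only separately identifiable through the shared baseline.
#'
#' @param table A `drag_table` (>= 4 speed knots).
#' @param fluid A [fluid_properties()] fixing the Reynolds numbers.
#' @param baseline_config Which configuration anchors the intercept.
#' @return An object of class `surrogate_fit` with elements
#'   `friction_scale`, `pressure_cd`, `tag_deltas` (named numeric, possibly
#'   empty), `r_squared`, `sigma`, `max_abs_residual`, `n`, `data`
#'   (augmented table with `fitted` and `residual`), and the underlying
#'   `model`. Supports [tidy()], [glance()], [autoplot()].
#' @examples
#' fit <- fit_surrogate(mako_drag_table("none"), fluid_properties())
#' glance(fit)
#' @export
fit_surrogate <- function(table, fluid, baseline_config = "none") {
  table <- drag_table(table, check_monotone = FALSE)
  stopifnot(inherits(fluid, "fluid_properties"))
  configs <- unique(table$tag_config)
  if (!baseline_config %in% configs) baseline_config <- configs[1]
  d <- dplyr::mutate(
    table,
    re = fluid$density * .data$speed_m_s * .data$fork_length_m /
      fluid$dynamic_viscosity,
    basis = 0.074 * .data$re^(-1 / 5),
    config = factor(.data$tag_config,
                    levels = c(baseline_config, setdiff(configs, baseline_config)))
  )
  if (length(unique(d$speed_m_s)) < 4) {
    abort("Need at least 4 speed knots to fit the surrogate.",
          class = "tagburden_fit_failure")
  }
  if (stats::sd(d$basis) < 1e-12 || stats::sd(d$cd) < 1e-12) {
    abort("Degenerate (constant) table: the friction basis cannot be fitted.",
          class = "tagburden_fit_failure")
  }
  model <- if (length(configs) > 1) {
    lm(cd ~ basis + config, data = d)
  } else {
    lm(cd ~ basis, data = d)
  }
  cf <- coef(model)
  deltas <- cf[grep("^config", names(cf))]
  names(deltas) <- sub("^config", "", names(deltas))
  d$fitted <- stats::fitted(model)
  d$residual <- resid(model)
  # suppressed: summary.lm warns on an (expected) perfect fit of noiseless tables
  smry <- suppressWarnings(summary(model))
  structure(
    list(
      friction_scale = unname(cf[["basis"]]),
      pressure_cd = unname(cf[["(Intercept)"]]),
      tag_deltas = deltas,
      r_squared = smry$r.squared,
      sigma = smry$sigma,
      max_abs_residual = max(abs(d$residual)),
      n = nrow(d),
      data = as_tibble(d),
      model = model
    ),
    class = "surrogate_fit"
  )
}

#' @export
print.surrogate_fit <- function(x, ...) {
  cat("Friction-line surrogate fit\n")
  cat(sprintf("  friction scale (form factor x S_w/A): %.4f\n", x$friction_scale))
  cat(sprintf("  pressure_cd (intercept):              %.5f\n", x$pressure_cd))
  if (length(x$tag_deltas)) {
    for (nm in names(x$tag_deltas)) {
      cat(sprintf("  tag drag-area ratio [%s]: %.5f\n", nm, x$tag_deltas[[nm]]))
    }
  }
  cat(sprintf("  n = %d, R^2 = %.4f, max |residual| = %.5f\n",
              x$n, x$r_squared, x$max_abs_residual))
  invisible(x)
}

#' Tidy a surrogate fit
#'
#' @param x A `surrogate_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`; terms are named `pressure_cd`,
#'   `friction_scale`, and `tag_drag_area_ratio:<config>`.
#' @export
tidy.surrogate_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$model))$coefficients
  term <- rownames(s)
  term[term == "(Intercept)"] <- "pressure_cd"
  term[term == "basis"] <- "friction_scale"
  term <- sub("^config", "tag_drag_area_ratio:", term)
  tibble(term = term, estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' Glance at a surrogate fit
#'
#' @param x A `surrogate_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `r.squared`, `sigma`, `max.abs.residual`, `nobs`.
#' @export
glance.surrogate_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, sigma = x$sigma,
         max.abs.residual = x$max_abs_residual, nobs = x$n)
}

#' Plot a surrogate fit
#'
#' Observed table cells and the fitted friction-line curve against speed.
#'
#' @param object A `surrogate_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.surrogate_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$speed_m_s, colour = .data$tag_config)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cd)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$fork_length_m),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "speed (m/s)", y = expression(C[D]),
                  colour = "tag configuration")
}
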