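#' Validate a drag-coefficient table
#'
#' A drag table is a long tibble with columns `speed_m_s`, `fork_length_m`,
#' `tag_config`, `cd`: drag coefficients on a (speed x body size) grid for
#' one or more tag configurations. Validation enforces positive, finite
#' coefficients, recognised configuration labels, and a strictly increasing
#' speed grid within each (size, config) column. Drag coefficients from
#' turbulent sweeps decay with speed; a column that is not non-increasing in
#' speed draws a warning (noisy synthetic sweeps may legitimately wiggle).
#'
#' @param x A data frame with the columns above.
#' @param check_monotone Warn when a (size, config) column increases with
#'   speed anywhere. Default `TRUE`.
#' @return The validated table as a tibble with class `drag_table`.
#' @examples
#' tab <- drag_table(mako_drag_table())
#' @export
drag_table <- function(x, check_monotone = TRUE) {
  stopifnot(is.data.frame(x))
  needed <- c("speed_m_s", "fork_length_m", "tag_config", "cd")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    abort(paste0("Drag table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "tagburden_invalid_input")
  }
  x <- as_tibble(x)[needed]
  bad <- setdiff(unique(x$tag_config), tag_config_levels())
  if (length(bad)) {
    abort(paste0("Unknown tag_config label(s): ", paste(bad, collapse = ", "),
                 ". Expected one of: ",
                 paste(tag_config_levels(), collapse = ", ")),
          class = "tagburden_invalid_input")
  }
  check_number(x$speed_m_s, "speed_m_s", positive = TRUE, scalar = FALSE)
  check_number(x$fork_length_m, "fork_length_m", positive = TRUE, scalar = FALSE)
  check_number(x$cd, "cd", positive = TRUE, scalar = FALSE)
  cols <- dplyr::group_by(x, .data$tag_config, .data$fork_length_m)
  chk <- dplyr::summarise(
    cols,
    increasing_grid = !is.unsorted(.data$speed_m_s, strictly = TRUE),
    monotone_cd = all(diff(.data$cd[order(.data$speed_m_s)]) <= 0),
    .groups = "drop"
  )
  if (!all(chk$increasing_grid)) {
    abort("Each (size, config) column needs a strictly increasing, duplicate-free speed grid.",
          class = "tagburden_invalid_input")
  }
  if (check_monotone && !all(chk$monotone_cd)) {
    warn("Some (size, config) columns have drag coefficients that increase with speed.")
  }
  class(x) <- c("drag_table", class(x))
  x
}

#' Read / write drag-coefficient tables as CSV
#'
#' The CSV dialect is the long form of the table: header
#' `speed_m_s,fork_length_m,tag_config,cd`, dot decimal separator, UTF-8.
#'
#' @param path File path.
#' @param ... Passed to [drag_table()] (e.g. `check_monotone`).
#' @return `read_drag_table()` returns a validated `drag_table`;
#'   `write_drag_table()` returns `path` invisibly.
#' @export
read_drag_table <- function(path, ...) {
  x <- readr::read_csv(path, col_types = readr::cols(
    speed_m_s = readr::col_double(),
    fork_length_m = readr::col_double(),
    tag_config = readr::col_character(),
    cd = readr::col_double()
  ))
  drag_table(x, ...)
}

#' @rdname read_drag_table
#' @param x A drag table.
#' @export
write_drag_table <- function(x, path) {
  x <- drag_table(x, check_monotone = FALSE)
  readr::write_csv(x, path)
  invisible(path)
}

#' Packaged swimming-speed / Reynolds-number table
#'
#' The eight modelled swim speeds for a 2.95 m fork-length lamnid shark, with
#' the Reynolds numbers they correspond to in seawater at 20 C, transcribed
#' from the source sweep. Speeds span cruising (0.5-1 m/s) through burst
#' swimming (3.6-9.1 m/s).
#'
#' @return A tibble with columns `speed_m_s`, `reynolds`.
#' @export
mako_speeds <- function() {
  path <- system.file("extdata", "table1_speeds.csv", package = "tagburden",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = "dd")
}

#' Packaged drag-coefficient table
#'
#' Frontal-area-referenced drag coefficients for untagged and tagged shark
#' bodies over five fork lengths (1, 1.5, 2, 2.5, 2.95 m) and eight speeds
#' (0.5-9.1 m/s), transcribed verbatim (three decimals) from the source CFD
#' sweep. Configurations: `none` (untagged), `archival_body` (dorsal-
#' musculature archival tag; all sizes), `fin_mount` (dorsal-fin transmitter;
#' 2.95 m only).
#'
#' @param configs Configuration labels to keep; default all.
#' @return A validated `drag_table`.
#' @examples
#' mako_drag_table("fin_mount")
#' @export
mako_drag_table <- function(configs = tag_config_levels()) {
  configs <- match.arg(configs, tag_config_levels(), several.ok = TRUE)
  path <- system.file("extdata", "table2_cd.csv", package = "tagburden",
                      mustWork = TRUE)
  x <- read_drag_table(path)
  drag_table(dplyr::filter(x, .data$tag_config %in% configs))
}

# log-log linear interpolation of cd over speed within one column
interp_speed_loglog <- function(speeds, cds, query) {
  ord <- order(speeds)
  exp(stats::approx(log(speeds[ord]), log(cds[ord]), xout = log(query),
                    rule = 1)$y)
}

#' Interpolate a drag coefficient from a table
#'
#' Looks up C_D at arbitrary (fork length, speed) within a table's coverage
#' for one tag configuration. Between speed knots the interpolant is linear
#' in log(C_D) vs log(speed) — drag coefficients follow an approximate power
#' law in Reynolds number, so this is smooth, exact at knots and preserves
#' monotone decay — and linear in fork length between tabulated sizes.
#' Queries outside the grid are clamped to its edge with a warning by
#' default; `rule = "strict"` raises a range error instead.
#'
#' @param table A `drag_table` (or coercible data frame).
#' @param fork_length,speed Query points, m and m/s; recycled to a common
#'   length.
#' @param config Tag configuration label to look up. Default `"none"`.
#' @param rule `"clamp"` (default) or `"strict"` out-of-range behaviour.
#' @return Numeric vector of drag coefficients.
#' @examples
#' lookup_cd(mako_drag_table(), 2.95, 3.6)           # knot: 0.074
#' lookup_cd(mako_drag_table(), 2.95, 2.7)           # between knots
#' @export
lookup_cd <- function(table, fork_length, speed, config = "none",
                      rule = c("clamp", "strict")) {
  rule <- match.arg(rule)
  table <- drag_table(table, check_monotone = FALSE)
  config <- match.arg(config, tag_config_levels())
  sub <- dplyr::filter(table, .data$tag_config == config)
  if (!nrow(sub)) {
    abort(sprintf("Table has no rows for tag_config '%s'.", config),
          class = "tagburden_range_error")
  }
  n <- max(length(fork_length), length(speed))
  fork_length <- rep_len(fork_length, n)
  speed <- rep_len(speed, n)
  sizes <- sort(unique(sub$fork_length_m))
  sp_rng <- range(sub$speed_m_s)
  out_size <- fork_length < min(sizes) | fork_length > max(sizes)
  out_speed <- speed < sp_rng[1] | speed > sp_rng[2]
  if (any(out_size | out_speed)) {
    msg <- sprintf(
      "Query outside table coverage (speed [%g, %g] m/s, size [%g, %g] m) for config '%s'.",
      sp_rng[1], sp_rng[2], min(sizes), max(sizes), config)
    if (rule == "strict") {
      abort(msg, class = "tagburden_range_error")
    }
    warn(paste(msg, "Clamping to the grid edge."))
    fork_length <- pmin(pmax(fork_length, min(sizes)), max(sizes))
    speed <- pmin(pmax(speed, sp_rng[1]), sp_rng[2])
  }
  by_size <- split(sub, sub$fork_length_m)
  vapply(seq_len(n), function(i) {
    L <- fork_length[i]
    u <- speed[i]
    lo <- max(sizes[sizes <= L])
    hi <- min(sizes[sizes >= L])
    v_lo <- interp_speed_loglog(by_size[[as.character(lo)]]$speed_m_s,
                                by_size[[as.character(lo)]]$cd, u)
    if (hi == lo) return(v_lo)
    v_hi <- interp_speed_loglog(by_size[[as.character(hi)]]$speed_m_s,
                                by_size[[as.character(hi)]]$cd, u)
    v_lo + (v_hi - v_lo) * (L - lo) / (hi - lo)
  }, numeric(1))
}

#' Plot a drag-coefficient table
#'
#' Drag coefficient against speed, one line per tag configuration, faceted
#' by fork length; log-log axes mirror the interpolation space.
#'
#' @param object A `drag_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drag_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$speed_m_s, .data$cd,
                                       colour = .data$tag_config)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$fork_length_m),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "speed (m/s)", y = expression(C[D]),
                  colour = "tag configuration")
}
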