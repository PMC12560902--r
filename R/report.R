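#' Tag-impact reference table
#'
#' The assessment product this package exists to generate: one row per
#' (size, speed, tag configuration) combining the drag-side and energy-side
#' burden metrics a tagging-feasibility review needs — untagged and tagged
#' drag coefficients, percent drag increase, percent daily-energy increase
#' under a reference activity budget, and the equal-power burst-speed
#' reduction in both variants. The reference budget glides 7% of the day,
#' cruises at `cruise_speed`, and (when the row's speed exceeds the cruise
#' speed) spends `burst_fraction` of the day bursting at the row's speed;
#' rows at or below the cruise speed use a cruise-only budget at the row's
#' speed. Rows outside the table's coverage are flagged `covered = FALSE`
#' with missing metrics, or raise an error in strict mode.
#'
#' @param table A `drag_table` with an untagged baseline.
#' @param fluid A [fluid_properties()].
#' @param sizes Fork lengths to report, m.
#' @param speeds Speeds to report, m/s.
#' @param configs Tagged configuration labels to report.
#' @param burst_fraction Burst allocation of the reference budget.
#'   Default 0.05.
#' @param cruise_speed,glide_fraction Reference-budget parameters.
#' @param untagged_config Baseline label.
#' @param strict Error on coverage gaps instead of flagging. Default FALSE.
#' @return A tibble ordered by size, speed, config with columns
#'   `fork_length_m`, `speed_m_s`, `tag_config`, `cd_untagged`, `cd_tagged`,
#'   `pct_drag_increase`, `pct_energy_increase`,
#'   `pct_speed_reduction_fixed_force`, `pct_speed_reduction_cd_interpolated`,
#'   `covered`.
#' @examples
#' reference_table(mako_drag_table(), fluid_properties(),
#'                 sizes = 2.95, speeds = c(1, 9.1), configs = "fin_mount")
#' @export
reference_table <- function(table, fluid, sizes, speeds, configs,
                            burst_fraction = 0.05, cruise_speed = 1,
                            glide_fraction = 0.07, untagged_config = "none",
                            strict = FALSE) {
  table <- drag_table(table, check_monotone = FALSE)
  grid <- tidyr::expand_grid(fork_length_m = sort(sizes),
                             speed_m_s = sort(speeds),
                             tag_config = configs)
  if (!nrow(grid)) {
    return(tibble(fork_length_m = numeric(), speed_m_s = numeric(),
                  tag_config = character(), cd_untagged = numeric(),
                  cd_tagged = numeric(), pct_drag_increase = numeric(),
                  pct_energy_increase = numeric(),
                  pct_speed_reduction_fixed_force = numeric(),
                  pct_speed_reduction_cd_interpolated = numeric(),
                  covered = logical()))
  }
  rows <- purrr::pmap(grid, function(fork_length_m, speed_m_s, tag_config) {
    geom <- shark_geometry(fork_length_m)
    metrics <- tryCatch({
      cd_un <- lookup_cd(table, fork_length_m, speed_m_s,
                         config = untagged_config, rule = "strict")
      cd_tag <- lookup_cd(table, fork_length_m, speed_m_s,
                          config = tag_config, rule = "strict")
      budget <- if (speed_m_s > cruise_speed) {
        activity_budget(burst_fraction, speed_m_s, cruise_speed, glide_fraction)
      } else {
        activity_budget(0, cruise_speed, speed_m_s, glide_fraction)
      }
      e_inc <- energy_increase(budget, table, fluid, geom,
                               tagged_config = tag_config,
                               untagged_config = untagged_config,
                               rule = "strict")
      red <- tryCatch(
        burst_speed_reduction(speed_m_s, table, fluid, geom, tag_config,
                              untagged_config = untagged_config),
        error = function(e) NULL
      )
      pick <- function(v) {
        if (is.null(red)) NA_real_ else red$pct_reduction[red$variant == v]
      }
      tibble(cd_untagged = cd_un, cd_tagged = cd_tag,
             pct_drag_increase = percent_increase(cd_un, cd_tag),
             pct_energy_increase = e_inc,
             pct_speed_reduction_fixed_force = pick("fixed_force"),
             pct_speed_reduction_cd_interpolated = pick("cd_interpolated"),
             covered = TRUE)
    }, tagburden_range_error = function(e) {
      if (strict) abort(conditionMessage(e), class = "tagburden_range_error")
      tibble(cd_untagged = NA_real_, cd_tagged = NA_real_,
             pct_drag_increase = NA_real_, pct_energy_increase = NA_real_,
             pct_speed_reduction_fixed_force = NA_real_,
             pct_speed_reduction_cd_interpolated = NA_real_,
             covered = FALSE)
    })
    metrics
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(rows))
}

#' Format a reference table for human reading
#'
#' Rounds coefficients to 3 significant figures and percentages to one
#' decimal (the printing conventions of the field) and renders an aligned
#' text block. The raw-precision tibble remains the machine product.
#'
#' @param x A tibble from [reference_table()].
#' @return Character vector of aligned text lines.
#' @export
format_reference_table <- function(x) {
  fmt <- dplyr::mutate(
    x,
    dplyr::across(dplyr::starts_with("cd_"), ~ signif(.x, 3)),
    dplyr::across(dplyr::starts_with("pct_"), ~ round(.x, 1))
  )
  utils::capture.output(print(as.data.frame(fmt), row.names = FALSE))
}

read_yaml_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "tagburden_config_error")
  }
  yaml::read_yaml(path)
}

config_field <- function(cfg, field, default = NULL) {
  value <- cfg[[field]]
  if (is.null(value)) default else value
}

validate_pipeline_config <- function(cfg) {
  for (block in c("fluid", "geometry")) {
    if (is.null(cfg[[block]])) {
      abort(sprintf("Config is missing the required `%s` block.", block),
            class = "tagburden_config_error")
    }
  }
  for (fld in c("density", "dynamic_viscosity")) {
    if (is.null(cfg$fluid[[fld]]) || !is.numeric(cfg$fluid[[fld]]) ||
        cfg$fluid[[fld]] <= 0) {
      abort(sprintf("Config field `fluid.%s` must be a positive number.", fld),
            class = "tagburden_config_error")
    }
  }
  if (is.null(cfg$geometry$fork_length) || !is.numeric(cfg$geometry$fork_length) ||
      cfg$geometry$fork_length <= 0) {
    abort("Config field `geometry.fork_length` must be a positive number.",
          class = "tagburden_config_error")
  }
  sc <- config_field(cfg, "scenarios", list())
  bad <- setdiff(unlist(config_field(sc, "tagged_configs",
                                     c("archival_body", "fin_mount"))),
                 tag_config_levels())
  if (length(bad)) {
    abort(paste0("Config field `scenarios.tagged_configs` has unknown label(s): ",
                 paste(bad, collapse = ", ")),
          class = "tagburden_config_error")
  }
  rp <- config_field(cfg, "report", list())
  bad <- setdiff(unlist(config_field(rp, "configs", character())),
                 tag_config_levels())
  if (length(bad)) {
    abort(paste0("Config field `report.configs` has unknown label(s): ",
                 paste(bad, collapse = ", ")),
          class = "tagburden_config_error")
  }
  invisible(cfg)
}

parse_fractions <- function(x, default) {
  if (is.null(x)) return(default)
  if (is.list(x) && !is.null(x$from)) {
    return(seq(x$from, x$to, by = x$by))
  }
  unlist(x)
}

#' Run the full tag-burden pipeline from a config file
#'
#' Reads a YAML config (fluid, geometry, optional drag-table path and
#' scenario/report blocks; see `inst/extdata/default_config.yml`), validates
#' it before any computation, then executes the scenario grid, the
#' equal-power burst-speed reductions and the reference table, writing
#' `scenarios.csv`, `speed_reduction.csv`, `reference_table.csv` (raw
#' precision), `reference_table.txt` (rounded, aligned) and `run.log`
#' (config echo, package version, timestamp — the only file carrying a
#' timestamp) into `out_dir`. Every number in the outputs is recomputable by
#' calling the underlying functions with the logged config.
#'
#' @param config_path Path to the YAML config.
#' @param out_dir Output directory; created if needed.
#' @param quiet Suppress progress messages (they go to standard error).
#' @return Invisibly, a named list of the written file paths.
#' @export
run_pipeline <- function(config_path, out_dir, quiet = FALSE) {
  cfg <- validate_pipeline_config(read_yaml_config(config_path))
  say <- function(...) if (!quiet) message(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  fluid <- fluid_properties(cfg$fluid$density, cfg$fluid$dynamic_viscosity)
  geom_args <- cfg$geometry
  geometry <- shark_geometry(
    fork_length = geom_args$fork_length,
    frontal_area = config_field(geom_args, "frontal_area"),
    area_coefficient = config_field(geom_args, "area_coefficient", 0.12 / 2.95^2)
  )
  mm <- config_field(cfg, "mass_model", list())
  geometry$mass <- estimate_mass(
    geometry$fork_length,
    anchor_length = config_field(mm, "anchor_length", 1),
    anchor_mass = config_field(mm, "anchor_mass", 17),
    exponent = config_field(mm, "exponent", 3)
  )
  table <- if (is.null(cfg$drag_table)) {
    mako_drag_table()
  } else {
    read_drag_table(cfg$drag_table)
  }

  sc <- config_field(cfg, "scenarios", list())
  burst_speeds <- unlist(config_field(sc, "burst_speeds", c(3.6, 5, 7.8, 9.1)))
  burst_fractions <- parse_fractions(sc$burst_fractions, seq(0, 0.20, by = 0.01))
  tagged_configs <- unlist(config_field(sc, "tagged_configs",
                                        c("archival_body", "fin_mount")))
  cruise_speed <- config_field(sc, "cruise_speed", 1)
  glide_fraction <- config_field(sc, "glide_fraction", 0.07)

  say("Computing scenario grid (", length(burst_speeds), " burst speeds x ",
      length(burst_fractions), " fractions x ", length(tagged_configs),
      " configs)...")
  scenarios <- scenario_grid(table, fluid, geometry,
                             burst_speeds = burst_speeds,
                             burst_fractions = burst_fractions,
                             tagged_configs = tagged_configs,
                             cruise_speed = cruise_speed,
                             glide_fraction = glide_fraction)
  paths <- list(scenarios = file.path(out_dir, "scenarios.csv"))
  readr::write_csv(scenarios, paths$scenarios)

  say("Computing equal-power burst-speed reductions...")
  reductions <- dplyr::bind_rows(purrr::map(tagged_configs, function(cfg_lab) {
    dplyr::bind_rows(purrr::map(burst_speeds, function(v) {
      burst_speed_reduction(v, table, fluid, geometry, cfg_lab)
    }))
  }))
  paths$speed_reduction <- file.path(out_dir, "speed_reduction.csv")
  readr::write_csv(reductions, paths$speed_reduction)

  rp <- config_field(cfg, "report", list())
  ref <- reference_table(
    table, fluid,
    sizes = unlist(config_field(rp, "sizes", sort(unique(table$fork_length_m)))),
    speeds = unlist(config_field(rp, "speeds", sort(unique(table$speed_m_s)))),
    configs = unlist(config_field(rp, "configs", tagged_configs)),
    cruise_speed = cruise_speed, glide_fraction = glide_fraction
  )
  paths$reference_table <- file.path(out_dir, "reference_table.csv")
  readr::write_csv(ref, paths$reference_table)
  paths$reference_table_txt <- file.path(out_dir, "reference_table.txt")
  writeLines(format_reference_table(ref), paths$reference_table_txt)

  paths$log <- file.path(out_dir, "run.log")
  writeLines(c(
    sprintf("tagburden %s", as.character(packageVersion("tagburden"))),
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    "config:",
    paste0("  ", strsplit(yaml::as.yaml(cfg), "\n")[[1]])
  ), paths$log)
  say("Wrote ", length(paths), " files to ", out_dir)
  invisible(paths)
}
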