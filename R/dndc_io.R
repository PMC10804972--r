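# File-level interface to a daily-time-step soil biogeochemistry model:
# water-table input files, manure amendment schedules, a site parameter
# sheet, annual-output parsing, and a generic calibrate-to-tolerance search.
# The model itself is never invoked; tests use the synthetic generator and
# mock simulators.

#' Write water-table input files for a schedule
#'
#' One two-column text file (`julian_day level`) per simulation year, 365
#' lines each, plus a JSON manifest recording the seed, the source climate
#' year of every simulation year, and the unit. Content is deterministic
#' given the schedule (no timestamps). Levels are written in cm by default;
#' some model versions expect metres, selectable via `unit`.
#'
#' @param schedule A [build_water_input()] result.
#' @param directory Output directory (created if missing).
#' @param unit `"cm"` (default) or `"m"`.
#' @param sep Column separator (default one space).
#' @return Character vector of the year-file paths, invisibly.
#' @export
write_water_table_files <- function(schedule, directory, unit = c("cm", "m"),
                                    sep = " ") {
  stopifnot(inherits(schedule, "water_input_schedule"))
  unit <- match.arg(unit)
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory, call. = FALSE)
  }
  scale <- if (unit == "m") 0.01 else 1
  paths <- character(schedule$n_years)
  for (y in seq_len(schedule$n_years)) {
    paths[y] <- file.path(directory, sprintf("wt_year_%03d.txt", y))
    lines <- paste(seq_len(365L),
                   format(schedule$levels[, y] * scale, trim = TRUE,
                          scientific = FALSE),
                   sep = sep)
    writeLines(lines, paths[y])
  }
  jsonlite::write_json(list(n_years = schedule$n_years,
                            seed = schedule$seed,
                            unit = unit,
                            source_year = schedule$source_year),
                       file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read one written water-table year file
#'
#' Round-trips the dialect written by [write_water_table_files()].
#'
#' @param path Year file path.
#' @param unit Unit the file is in (`"cm"` default, `"m"` converted back).
#' @param sep Column separator used when writing.
#' @return data.frame with `julian_day`, `level_cm`.
#' @export
read_water_table_file <- function(path, unit = c("cm", "m"), sep = " ") {
  unit <- match.arg(unit)
  df <- utils::read.table(path, sep = sep, col.names = c("julian_day", "level"))
  data.frame(julian_day = as.integer(df$julian_day),
             level_cm = df$level * if (unit == "m") 100 else 1)
}

#' Write a manure amendment schedule file
#'
#' CSV with the application day, manure dry matter and nitrogen mass, for
#' manual entry or scripted model setup. A zero-mass schedule produces a
#' header-only file.
#'
#' @param schedule A [field_amendment()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_amendment_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "amendment_schedule"))
  df <- data.frame(application_julian_day = schedule$application_julian_day,
                   manure_dm_kg_ha = schedule$manure_dm_kg_ha,
                   n_fraction = schedule$n_fraction,
                   n_kg_ha = schedule$n_kg_ha)
  if (schedule$manure_dm_kg_ha <= 0) df <- df[0, , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Site parameter sheet
#'
#' Measured initial soil and crop-management parameters of the synthetic
#' study site (rice-wheat rotation, Eastern Indo-Gangetic Plain), as handed
#' to the soil model.
#'
#' @param ... Overrides of the default fields.
#' @return A `site_sheet` list.
#' @export
site_sheet <- function(...) {
  defaults <- list(soc_0_10cm_gC_kg = 5.2,
                   ph = 8.12,
                   bulk_density_Mg_m3 = 1.46,
                   texture_label = "sandy clay",
                   clay_fraction = 0.42,
                   rice_nursery_day = "06-09",
                   wheat_plant_day = "11-23",
                   rice_harvest_day = "10-29",
                   wheat_harvest_day = "04-10",
                   tillage = "two passes; 20 cm (rice), 10 cm (wheat)")
  ov <- list(...)
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown site field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(ov)] <- ov
  assert_fraction(defaults$clay_fraction, "clay_fraction")
  structure(defaults, class = "site_sheet")
}

#' Write the site sheet as key-value text
#'
#' @param sheet A [site_sheet()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_sheet <- function(sheet, path) {
  stopifnot(inherits(sheet, "site_sheet"))
  writeLines(paste(names(sheet), vapply(sheet, format, character(1)),
                   sep = ": "), path)
  invisible(path)
}

#' Parse an annual model-output summary into a soil flux series
#'
#' Maps delimited annual output columns onto the CH4/N2O/SOC series,
#' applying stoichiometric unit conversions where the source reports element
#' masses: CH4-C is converted to CH4 by 16/12 and N2O-N to N2O by 44/28.
#'
#' @param path Delimited annual-summary file (CSV).
#' @param mapping List with entries `year`, `ch4`, `n2o`, `soc_delta` naming
#'   source columns, and optional `ch4_unit` (`"kg_ch4"` default or
#'   `"kg_c"`) and `n2o_unit` (`"kg_n2o"` default or `"kg_n"`).
#' @param pathway,category,residue_returned Metadata for the series.
#' @return A [soil_flux_series()].
#' @export
parse_model_output <- function(path, mapping,
                               pathway = NA_character_,
                               category = NA_character_,
                               residue_returned = NA) {
  need <- c("year", "ch4", "n2o", "soc_delta")
  miss <- setdiff(need, names(mapping))
  if (length(miss) > 0) {
    stop("mapping missing entries: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- unlist(mapping[need], use.names = FALSE)
  absent <- setdiff(cols, names(df))
  if (length(absent) > 0) {
    stop("unmapped column(s) in model output: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  ch4_unit <- if (is.null(mapping$ch4_unit)) "kg_ch4" else mapping$ch4_unit
  n2o_unit <- if (is.null(mapping$n2o_unit)) "kg_n2o" else mapping$n2o_unit
  ch4 <- df[[mapping$ch4]] * switch(ch4_unit, kg_ch4 = 1, kg_c = 16 / 12,
    stop("ch4_unit must be 'kg_ch4' or 'kg_c'", call. = FALSE))
  n2o <- df[[mapping$n2o]] * switch(n2o_unit, kg_n2o = 1, kg_n = 44 / 28,
    stop("n2o_unit must be 'kg_n2o' or 'kg_n'", call. = FALSE))
  year <- as.integer(df[[mapping$year]])
  if (length(year) >= 1 && !identical(year, seq_len(length(year)))) {
    if (identical(year, seq.int(year[1], length.out = length(year)))) {
      year <- seq_len(length(year))
    }
  }
  soil_flux_series(year, ch4, n2o, df[[mapping$soc_delta]],
                   pathway = pathway, category = category,
                   residue_returned = residue_returned)
}

#' Iterative calibration search
#'
#' Generic incremental parameter adjustment against a black-box simulator:
#' steps the parameter (multiplicatively by default) until the simulated
#' observable falls within a relative tolerance of the target, mirroring the
#' manual protocol used to calibrate crop grain-biomass carbon and thermal
#' degree days against observed yields and harvest dates. The step direction
#' is taken from `direction_hint` when given, otherwise inferred from the
#' first two evaluations.
#'
#' @param simulate Function of one numeric parameter returning the
#'   observable.
#' @param target Target observable value (non-zero).
#' @param start Initial parameter value.
#' @param tolerance_fraction Relative tolerance (default 0.10).
#' @param step Step increment: factor for `"multiplicative"` (default 1.1),
#'   addend for `"additive"`.
#' @param step_rule `"multiplicative"` (default) or `"additive"`.
#' @param max_iterations Iteration cap (default 50).
#' @param direction_hint Optional `+1`/`-1` forcing the step direction.
#' @return List `parameter` (calibrated value), `observable`, `iterations`,
#'   `converged`, `trace` (data.frame of every evaluation, with a
#'   `non_monotone` flag set when progress reversed twice).
#' @examples
#' calibration_search(function(p) 2 * p, target = 10, start = 1,
#'                    step = 1.25)$parameter
#' @export
calibration_search <- function(simulate, target, start,
                               tolerance_fraction = 0.10,
                               step = 1.1,
                               step_rule = c("multiplicative", "additive"),
                               max_iterations = 50,
                               direction_hint = NULL) {
  step_rule <- match.arg(step_rule)
  stopifnot(is.function(simulate), is.finite(target), target != 0,
            is.finite(start))
  if (tolerance_fraction <= 0) stop("`tolerance_fraction` must be > 0", call. = FALSE)
  if (max_iterations < 1) stop("`max_iterations` must be >= 1", call. = FALSE)
  if (step_rule == "multiplicative" && (step <= 0 || step == 1)) {
    stop("multiplicative `step` must be positive and != 1", call. = FALSE)
  }
  if (step_rule == "additive" && step == 0) {
    stop("additive `step` must be non-zero", call. = FALSE)
  }

  apply_step <- function(p, dir) {
    if (step_rule == "multiplicative") {
      if (dir > 0) p * step else p / step
    } else {
      if (dir > 0) p + abs(step) else p - abs(step)
    }
  }
  rel_err <- function(obs) abs(obs - target) / abs(target)

  trace <- data.frame(iteration = integer(), parameter = numeric(),
                      observable = numeric(), rel_error = numeric())
  record <- function(it, p, obs) {
    trace[nrow(trace) + 1L, ] <<- list(it, p, obs, rel_err(obs))
  }

  p <- start
  obs <- simulate(p)
  record(0L, p, obs)
  if (rel_err(obs) <= tolerance_fraction) {
    return(list(parameter = p, observable = obs, iterations = 0L,
                converged = TRUE, trace = trace))
  }

  if (is.null(direction_hint)) {
    trial <- apply_step(p, +1)
    obs_trial <- simulate(trial)
    direction <- if (rel_err(obs_trial) < rel_err(obs)) +1 else -1
  } else {
    direction <- sign(direction_hint)
  }

  reversals <- 0L
  prev_err <- rel_err(obs)
  for (it in seq_len(max_iterations)) {
    p <- apply_step(p, direction)
    obs <- simulate(p)
    record(it, p, obs)
    err <- rel_err(obs)
    if (err <= tolerance_fraction) {
      attr(trace, "non_monotone") <- reversals >= 2L
      return(list(parameter = p, observable = obs, iterations = it,
                  converged = TRUE, trace = trace))
    }
    if (err > prev_err) {
      reversals <- reversals + 1L
      if (reversals == 2L) {
        warning("calibration progress reversed twice; response may be ",
                "non-monotone", call. = FALSE)
      }
    }
    prev_err <- err
  }
  attr(trace, "non_monotone") <- reversals >= 2L
  cond <- structure(class = c("ricegas_calibration_error", "error", "condition"),
                    list(message = sprintf(
                      paste0("calibration did not reach tolerance %.3g of ",
                             "target %.6g in %d iterations (last observable ",
                             "%.6g)"),
                      tolerance_fraction, target, max_iterations, obs),
                      call = sys.call(-1), trace = trace))
  stop(cond)
}
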