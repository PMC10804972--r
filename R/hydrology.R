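# Field hydrology: classification of daily water levels, selection of
# dry/median/wet representative fields, and construction of multi-year
# water-table input schedules for a daily-time-step soil model.

RICE_SEASON <- 183:302  # Julian days of the rice-season water-level record
WHEAT_IRRIGATION_DAYS <- c(22L, 340L, 352L)  # days set to 0 cm outside it

#' Construct a field-year of daily water levels
#'
#' @param field_id Field identifier (character or coercible).
#' @param julian_day Integer Julian days (1-based), strictly increasing.
#' @param level_cm Water level in cm relative to the soil surface (positive =
#'   ponded water, negative = water table below surface).
#' @param climate_year Optional calendar year of the observations.
#' @return A `water_level_series` data.frame with columns `julian_day`,
#'   `level_cm` and attributes `field_id`, `climate_year`.
#' @export
water_level_series <- function(field_id, julian_day, level_cm,
                               climate_year = NA_integer_) {
  julian_day <- as.integer(julian_day)
  if (length(julian_day) != length(level_cm) || length(julian_day) == 0) {
    stop("`julian_day` and `level_cm` must be equal-length, non-empty",
         call. = FALSE)
  }
  if (any(diff(julian_day) <= 0)) {
    stop("`julian_day` must be strictly increasing", call. = FALSE)
  }
  if (any(julian_day < 1L | julian_day > 365L)) {
    stop("`julian_day` must lie in 1..365 (365-day calendar)", call. = FALSE)
  }
  if (any(!is.finite(level_cm))) {
    stop("`level_cm` must be finite", call. = FALSE)
  }
  structure(data.frame(julian_day = julian_day, level_cm = as.numeric(level_cm)),
            field_id = as.character(field_id),
            climate_year = as.integer(climate_year),
            class = c("water_level_series", "data.frame"))
}

#' Read long-format daily water-level observations
#'
#' Accepts the field-tube CSV dialect `field_id,date,level_cm` (ISO dates) or
#' `field_id,julian_day,level_cm`. Dates are converted to 1-based Julian days
#' on a fixed 365-day calendar: in leap years February 29 observations are
#' dropped and later days shifted back one, the convention used by
#' daily-time-step soil models.
#'
#' @param path CSV file path.
#' @return Named list of [water_level_series()] objects, one per field.
#' @export
read_water_levels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"field_id" %in% names(df) || !"level_cm" %in% names(df)) {
    stop("water-level CSV must have columns `field_id` and `level_cm`",
         call. = FALSE)
  }
  if ("julian_day" %in% names(df)) {
    df$jd <- as.integer(df$julian_day)
    df$year <- if ("climate_year" %in% names(df)) {
      as.integer(df$climate_year)
    } else NA_integer_
  } else if ("date" %in% names(df)) {
    d <- as.Date(df$date)
    if (any(is.na(d))) stop("unparseable ISO dates in `date` column", call. = FALSE)
    lt <- as.POSIXlt(d)
    jd <- lt$yday + 1L
    yr <- lt$year + 1900L
    leap <- (yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0
    feb29 <- leap & lt$mon == 1L & lt$mday == 29L
    jd[leap & jd > 59L] <- jd[leap & jd > 59L] - 1L  # shift post-Feb days back
    df$jd <- jd
    df$year <- yr
    df <- df[!feb29, , drop = FALSE]
  } else {
    stop("water-level CSV needs a `date` or `julian_day` column", call. = FALSE)
  }
  out <- lapply(split(df, df$field_id), function(g) {
    g <- g[order(g$jd), , drop = FALSE]
    water_level_series(g$field_id[1], g$jd, g$level_cm, g$year[1])
  })
  out[order(names(out))]
}

#' Classify a daily water level into a field water state
#'
#' A day is `flooded` when ponded water stands above the soil surface,
#' `saturated` when there is no ponding but a free water surface lies within
#' the top 15 cm of soil, and `drained` when the free water surface is deeper
#' than 15 cm. A level of exactly 0 cm is classified `saturated` by default;
#' set `flooded_boundary = "inclusive"` to count it as flooded instead (the
#' field convention is not universal, so the boundary is configurable).
#'
#' @param level_cm Numeric vector of water levels (cm, signed).
#' @param flooded_boundary `"exclusive"` (flooded iff level > 0, default) or
#'   `"inclusive"` (flooded iff level >= 0).
#' @return Factor with levels `flooded`, `saturated`, `drained`.
#' @examples
#' classify_day(c(5, 0, -20))  # flooded, saturated, drained
#' @export
classify_day <- function(level_cm, flooded_boundary = c("exclusive", "inclusive")) {
  flooded_boundary <- match.arg(flooded_boundary)
  if (any(!is.finite(level_cm))) stop("`level_cm` must be finite", call. = FALSE)
  flooded <- if (flooded_boundary == "exclusive") level_cm > 0 else level_cm >= 0
  state <- ifelse(flooded, "flooded",
                  ifelse(level_cm >= -15, "saturated", "drained"))
  factor(state, levels = c("flooded", "saturated", "drained"))
}

#' Summarize a field-year by day-state counts
#'
#' Counts flooded, saturated and drained days over the rice season. The
#' series must cover every day of the season; an incomplete record is an
#' error (no gap-filling is attempted).
#'
#' @param series A [water_level_series()].
#' @param season Integer vector of Julian days defining the season (default
#'   days 183--302, the 120-day rice-season record).
#' @param flooded_boundary Passed to [classify_day()].
#' @return A `field_water_summary` list: `field_id`, `flooded_days`,
#'   `saturated_days`, `drained_days`, `season_days`.
#' @export
summarize_field <- function(series, season = RICE_SEASON,
                            flooded_boundary = "exclusive") {
  stopifnot(inherits(series, "water_level_series"))
  missing_days <- setdiff(season, series$julian_day)
  if (length(missing_days) > 0) {
    stop(sprintf("field %s: season coverage incomplete, missing day(s) %s",
                 attr(series, "field_id"),
                 paste(missing_days, collapse = ", ")), call. = FALSE)
  }
  lv <- series$level_cm[match(season, series$julian_day)]
  counts <- table(classify_day(lv, flooded_boundary))
  structure(list(field_id = attr(series, "field_id"),
                 flooded_days = as.integer(counts[["flooded"]]),
                 saturated_days = as.integer(counts[["saturated"]]),
                 drained_days = as.integer(counts[["drained"]]),
                 season_days = length(season)),
            class = "field_water_summary")
}

summaries_to_df <- function(summaries) {
  if (inherits(summaries, "field_water_summary")) summaries <- list(summaries)
  if (is.data.frame(summaries)) {
    stopifnot(all(c("field_id", "flooded_days") %in% names(summaries)))
    return(summaries)
  }
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(field_id = s$field_id, flooded_days = s$flooded_days,
               stringsAsFactors = FALSE)
  }))
}

#' Select dry, median and wet representative fields
#'
#' Fields are characterized by their flooded-day counts. The field whose
#' count sits at the sample median represents the `median` category (with an
#' even field count or ties, the field closest to the median value is taken,
#' remaining ties broken by lexicographic field id). The `dry` and `wet`
#' representatives are drawn uniformly at random (seeded) from the fields at
#' least `sd_multiplier` sample standard deviations below and above the mean
#' count, respectively.
#'
#' @param summaries List of [summarize_field()] results (or a data.frame with
#'   columns `field_id`, `flooded_days`).
#' @param seed Integer seed for the random dry/wet draws.
#' @param sd_multiplier How many SDs from the mean a field must lie to be a
#'   dry/wet candidate (default 1; relax below 1 when a candidate set comes
#'   up empty).
#' @param climate_year Optional year recorded in the result.
#' @return A `category_assignment` list with the three field ids, the seed,
#'   and selection metadata (mean, SD, median count, candidate sets).
#' @export
assign_categories <- function(summaries, seed, sd_multiplier = 1,
                              climate_year = NA_integer_) {
  df <- summaries_to_df(summaries)
  if (nrow(df) < 3) stop("need >= 3 fields to assign categories", call. = FALSE)
  counts <- df$flooded_days
  if (length(unique(counts)) == 1L) {
    stop("all flooded-day counts identical; categories are undefined",
         call. = FALSE)
  }
  m <- mean(counts)
  s <- stats::sd(counts)  # sample (n-1) SD
  med <- stats::median(counts)

  # median representative: count closest to the sample median, ties by id
  dist <- abs(counts - med)
  cand_med <- df$field_id[dist == min(dist)]
  median_field <- sort(cand_med)[1]

  dry_cand <- df$field_id[counts <= m - sd_multiplier * s]
  wet_cand <- df$field_id[counts >= m + sd_multiplier * s]
  dry_cand <- setdiff(dry_cand, median_field)
  wet_cand <- setdiff(wet_cand, median_field)
  if (length(dry_cand) == 0 || length(wet_cand) == 0) {
    stop("empty ", if (length(dry_cand) == 0) "dry" else "wet",
         " candidate set; consider relaxing `sd_multiplier` below ",
         sd_multiplier, call. = FALSE)
  }

  picks <- with_preserved_seed(seed, {
    d <- dry_cand[sample.int(length(dry_cand), 1L)]
    w <- wet_cand[sample.int(length(wet_cand), 1L)]
    c(d, w)
  })

  structure(list(climate_year = as.integer(climate_year),
                 dry_field = picks[1],
                 median_field = median_field,
                 wet_field = picks[2],
                 seed = as.integer(seed),
                 selection_metadata = list(
                   mean_flooded = m, sd_flooded = s, median_flooded = med,
                   sd_multiplier = sd_multiplier,
                   dry_candidates = dry_cand, wet_candidates = wet_cand)),
            class = "category_assignment")
}

#' @export
print.category_assignment <- function(x, ...) {
  cat("<category_assignment>",
      if (!is.na(x$climate_year)) paste0(" year ", x$climate_year), "\n",
      "  dry: ", x$dry_field,
      "  median: ", x$median_field,
      "  wet: ", x$wet_field, "\n",
      "  flooded days: mean ", signif(x$selection_metadata$mean_flooded, 4),
      ", sd ", signif(x$selection_metadata$sd_flooded, 4),
      ", median ", x$selection_metadata$median_flooded,
      " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Build a multi-year water-table input schedule
#'
#' For each simulation year, one source climate year is chosen uniformly at
#' random (seeded) and its rice-season record (days 183--302) is copied
#' verbatim into the simulation year. All remaining days are set to -100 cm,
#' except Julian days 22, 340 and 352 which are set to 0 cm to represent
#' typical wheat-season irrigation events. A fixed 365-day calendar is used.
#'
#' @param category_series Named list mapping climate year to the category's
#'   [water_level_series()] for that year.
#' @param n_years Number of simulation years (e.g. 100).
#' @param seed Integer seed for the source-year draws.
#' @param season Julian days copied from the source (default 183--302).
#' @return A `water_input_schedule`: `levels` is a 365 x `n_years` matrix of
#'   daily water levels (cm), `source_year` records the climate year backing
#'   each simulation year, `seed` the seed used.
#' @export
build_water_input <- function(category_series, n_years, seed,
                              season = RICE_SEASON) {
  if (!is.list(category_series) || length(category_series) < 1) {
    stop("`category_series` must be a non-empty list of water_level_series",
         call. = FALSE)
  }
  if (n_years <= 0) stop("`n_years` must be positive", call. = FALSE)
  n_years <- as.integer(n_years)
  labels <- names(category_series)
  if (is.null(labels) || any(labels == "")) {
    labels <- vapply(category_series, function(s) {
      as.character(attr(s, "climate_year"))
    }, character(1))
  }
  season_levels <- lapply(category_series, function(s) {
    stopifnot(inherits(s, "water_level_series"))
    idx <- match(season, s$julian_day)
    if (any(is.na(idx))) {
      stop("a source series does not cover the full rice season", call. = FALSE)
    }
    s$level_cm[idx]
  })

  pick <- with_preserved_seed(seed,
    sample.int(length(category_series), n_years, replace = TRUE))

  levels <- matrix(-100, nrow = 365L, ncol = n_years)
  levels[WHEAT_IRRIGATION_DAYS, ] <- 0
  for (y in seq_len(n_years)) {
    levels[season, y] <- season_levels[[pick[y]]]
  }
  structure(list(n_years = n_years,
                 levels = levels,
                 source_year = labels[pick],
                 season = season,
                 seed = as.integer(seed)),
            class = "water_input_schedule")
}

#' @export
print.water_input_schedule <- function(x, ...) {
  cat("<water_input_schedule> ", x$n_years, " simulation years, ",
      length(unique(x$source_year)), " source climate year(s), seed ",
      x$seed, "\n", sep = "")
  print(table(x$source_year))
  invisible(x)
}
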