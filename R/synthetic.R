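# Synthetic data: field hydrographs with the cross-field variability the
# category-selection procedure assumes (near-always-drained through
# near-always-flooded), and annual soil-flux series with configured means and
# interannual spread. These emulate the summary statistics of the observed
# and process-model data; they make no claim of biogeochemical realism.

#' Generate synthetic field water-level observations
#'
#' Each field's daily level over the rice season follows an AR(1) process on
#' the level itself. A field's long-run flooded propensity is drawn on the
#' logit scale around the cohort-level `climate_wetness`, with spread
#' `field_sd`, so a cohort spans drained-dominant to flooded-dominant fields.
#' Levels are clipped to a physical range.
#'
#' @param n_fields Number of fields (>= 3).
#' @param climate_wetness Cohort mean flooded-day propensity, in `[0, 1]`.
#' @param field_sd Spread of field propensities on the logit scale (default 1).
#' @param persistence Lag-1 autocorrelation of the daily level, in `[0, 1]`
#'   (default 0.8). At 1 the process is frozen at its initial level.
#' @param seed Integer seed; same seed, same output.
#' @param season Julian days generated (default 183--302).
#' @param level_sd_cm Marginal standard deviation of the daily level, cm.
#' @param clip Physical level range, cm (default `c(-100, 30)`).
#' @param init_level_cm Optional fixed initial level for every field
#'   (otherwise drawn from the field's stationary distribution).
#' @param climate_year Year label recorded on each series.
#' @return Named list of [water_level_series()], fields `"F001"`, `"F002"`, ...
#' @export
gen_water_levels <- function(n_fields = 30, climate_wetness = 0.5,
                             field_sd = 1, persistence = 0.8, seed = 1,
                             season = RICE_SEASON, level_sd_cm = 10,
                             clip = c(-100, 30), init_level_cm = NULL,
                             climate_year = NA_integer_) {
  if (n_fields < 3) stop("`n_fields` must be >= 3", call. = FALSE)
  assert_fraction(climate_wetness, "climate_wetness")
  assert_fraction(persistence, "persistence")
  assert_nonneg(field_sd, "field_sd")
  n_days <- length(season)
  eps <- 1e-6
  with_preserved_seed(seed, {
    z <- stats::rnorm(n_fields)
    base <- stats::qlogis(min(max(climate_wetness, eps), 1 - eps))
    p_field <- stats::plogis(base + field_sd * z)
    p_field <- pmin(pmax(p_field, eps), 1 - eps)
    mu <- level_sd_cm * stats::qnorm(p_field)  # mean level giving P(level>0)=p
    innov_sd <- level_sd_cm * sqrt(1 - persistence^2)
    out <- vector("list", n_fields)
    for (f in seq_len(n_fields)) {
      x <- numeric(n_days)
      x[1] <- if (is.null(init_level_cm)) {
        stats::rnorm(1, mu[f], level_sd_cm)
      } else init_level_cm
      if (n_days > 1) {
        e <- stats::rnorm(n_days - 1, 0, innov_sd)
        for (t in 2:n_days) {
          # at persistence 1 the process degenerates to a (frozen) random walk
          x[t] <- if (persistence == 1) x[t - 1] + e[t - 1] else {
            mu[f] + persistence * (x[t - 1] - mu[f]) + e[t - 1]
          }
        }
      }
      x <- pmin(pmax(x, clip[1]), clip[2])
      out[[f]] <- water_level_series(sprintf("F%03d", f), season, x,
                                     climate_year)
    }
    stats::setNames(out, vapply(out, attr, character(1), "field_id"))
  })
}

#' Default synthetic soil-flux means
#'
#' Category means of annual CH4 flux (Mg/ha/yr) used by
#' [gen_soil_flux_series()]: without residue return `{dry 0.08, median 0.22,
#' wet 0.31}`; residue return adds `{+0.03, +0.10, +0.14}`.
#'
#' @param category `"dry"`, `"median"` or `"wet"`.
#' @param residue_returned Logical.
#' @return Mean annual CH4, Mg/ha/yr.
#' @export
default_ch4_mean <- function(category, residue_returned = FALSE) {
  base <- c(dry = 0.08, median = 0.22, wet = 0.31)
  incr <- c(dry = 0.03, median = 0.10, wet = 0.14)
  if (!category %in% names(base)) {
    stop("`category` must be one of dry/median/wet", call. = FALSE)
  }
  unname(base[category] + if (isTRUE(residue_returned)) incr[category] else 0)
}

#' Generate a synthetic annual soil-flux series
#'
#' Gas fluxes are drawn lognormally with the configured mean and interannual
#' coefficient of variation (so sample means converge to the configured means
#' as the horizon grows); the SOC stock change is drawn normally, since it is
#' signed. Gases are generated independently.
#'
#' @param category Hydrology category: `"dry"`, `"median"`, `"wet"`.
#' @param residue_returned Logical; with the default CH4 mean this applies
#'   the category's residue increment.
#' @param mean_ch4_Mg Mean annual CH4, Mg/ha/yr (default
#'   [default_ch4_mean()]).
#' @param cv_interannual Interannual coefficient of variation (default 0.3).
#' @param mean_n2o_kg Mean annual N2O, kg/ha/yr (default 0.015).
#' @param mean_soc_delta_kgC Mean annual SOC change, kg C/ha/yr (default 50
#'   with residue return, 0 without).
#' @param n_years Horizon length (default 100).
#' @param seed Integer seed.
#' @param pathway Pathway label recorded on the series.
#' @return A [soil_flux_series()].
#' @export
gen_soil_flux_series <- function(category, residue_returned = FALSE,
                                 mean_ch4_Mg = default_ch4_mean(category, residue_returned),
                                 cv_interannual = 0.3,
                                 mean_n2o_kg = 0.015,
                                 mean_soc_delta_kgC = if (isTRUE(residue_returned)) 50 else 0,
                                 n_years = 100, seed = 1,
                                 pathway = NA_character_) {
  assert_nonneg(mean_ch4_Mg, "mean_ch4_Mg")
  assert_nonneg(mean_n2o_kg, "mean_n2o_kg")
  assert_nonneg(cv_interannual, "cv_interannual")
  if (n_years < 1) stop("`n_years` must be >= 1", call. = FALSE)
  n_years <- as.integer(n_years)

  rlnorm_mean <- function(n, m, cv) {
    if (m == 0 || cv == 0) return(rep(m, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  }
  with_preserved_seed(seed, {
    ch4 <- rlnorm_mean(n_years, mean_ch4_Mg * 1000, cv_interannual)
    n2o <- rlnorm_mean(n_years, mean_n2o_kg, cv_interannual)
    soc <- stats::rnorm(n_years, mean_soc_delta_kgC,
                        cv_interannual * abs(mean_soc_delta_kgC))
    soil_flux_series(seq_len(n_years), ch4, n2o, soc,
                     pathway = pathway, category = category,
                     residue_returned = residue_returned)
  })
}
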