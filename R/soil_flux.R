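# Annual soil flux series (CH4, N2O, delta-SOC) from the external process
# model or the synthetic generator, their 100-year season-average net CO2-e,
# and residue-effect statistics.

#' Construct an annual soil flux series
#'
#' @param year Contiguous year indices starting at 1.
#' @param ch4_kg_ha Annual methane flux, kg/ha (>= 0).
#' @param n2o_kg_ha Annual nitrous oxide flux, kg/ha (>= 0).
#' @param soc_delta_kgC_ha Annual change in soil organic carbon stock,
#'   kg C/ha (signed; gains positive).
#' @param pathway Pathway label (e.g. `"incorporation"`).
#' @param category Hydrology category: `"dry"`, `"median"` or `"wet"`.
#' @param residue_returned Logical: were residues returned to the soil?
#' @return A `soil_flux_series` data.frame with metadata attributes.
#' @export
soil_flux_series <- function(year, ch4_kg_ha, n2o_kg_ha, soc_delta_kgC_ha,
                             pathway = NA_character_,
                             category = NA_character_,
                             residue_returned = NA) {
  year <- as.integer(year)
  n <- length(year)
  if (n < 1) stop("series must have >= 1 year", call. = FALSE)
  if (!identical(year, seq_len(n))) {
    stop("year indices must be contiguous from 1", call. = FALSE)
  }
  if (length(ch4_kg_ha) != n || length(n2o_kg_ha) != n ||
      length(soc_delta_kgC_ha) != n) {
    stop("all flux columns must have the same length as `year`", call. = FALSE)
  }
  assert_nonneg(ch4_kg_ha, "ch4_kg_ha")
  assert_nonneg(n2o_kg_ha, "n2o_kg_ha")
  if (any(!is.finite(soc_delta_kgC_ha))) {
    stop("`soc_delta_kgC_ha` must be finite", call. = FALSE)
  }
  if (!is.na(category) && !category %in% HYDRO_CATEGORIES) {
    stop("`category` must be one of dry/median/wet", call. = FALSE)
  }
  structure(data.frame(year = year, ch4_kg_ha = as.numeric(ch4_kg_ha),
                       n2o_kg_ha = as.numeric(n2o_kg_ha),
                       soc_delta_kgC_ha = as.numeric(soc_delta_kgC_ha)),
            pathway = pathway, category = category,
            residue_returned = residue_returned,
            class = c("soil_flux_series", "data.frame"))
}

#' Read an annual soil flux series from CSV
#'
#' Expects columns `year`, `ch4_kg_ha`, `n2o_kg_ha` and either
#' `soc_delta_kgC_ha` (annual change, signed) or `soc_stock_kgC_ha` (stock,
#' auto-detected and first-differenced; the first year's change is taken
#' relative to `initial_soc_kgC_ha` when given, otherwise 0). Units are
#' asserted through the header tokens.
#'
#' @param path CSV file path.
#' @param pathway,category,residue_returned Metadata recorded on the series.
#' @param initial_soc_kgC_ha Optional pre-simulation SOC stock used to
#'   difference the first year of a stock column.
#' @return A [soil_flux_series()].
#' @export
read_soil_flux_series <- function(path, pathway = NA_character_,
                                  category = NA_character_,
                                  residue_returned = NA,
                                  initial_soc_kgC_ha = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("year", "ch4_kg_ha", "n2o_kg_ha")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("soil flux CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if ("soc_delta_kgC_ha" %in% names(df)) {
    soc_delta <- df$soc_delta_kgC_ha
  } else if ("soc_stock_kgC_ha" %in% names(df)) {
    stock <- df$soc_stock_kgC_ha
    first <- if (is.null(initial_soc_kgC_ha)) 0 else stock[1] - initial_soc_kgC_ha
    soc_delta <- c(first, diff(stock))
  } else {
    stop("soil flux CSV missing column(s): soc_delta_kgC_ha (or soc_stock_kgC_ha)",
         call. = FALSE)
  }
  year <- as.integer(df$year)
  if (!identical(year, seq_len(nrow(df)))) {
    # tolerate calendar-style years (e.g. 2001..2100) by re-indexing, but
    # reject non-contiguous or shuffled records outright
    if (nrow(df) >= 1 && identical(year, seq.int(year[1], length.out = nrow(df)))) {
      year <- seq_len(nrow(df))
    } else {
      stop("soil flux years must be contiguous and in order", call. = FALSE)
    }
  }
  soil_flux_series(year, df$ch4_kg_ha, df$n2o_kg_ha, soc_delta,
                   pathway = pathway, category = category,
                   residue_returned = residue_returned)
}

#' Write a soil flux series to CSV
#'
#' @param series A [soil_flux_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_soil_flux_series <- function(series, path) {
  stopifnot(inherits(series, "soil_flux_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Season-average net soil CO2-equivalent
#'
#' Arithmetic means of the annual fluxes over the simulation horizon,
#' combined into a net soil flux: CH4 and N2O through their GWPs, minus the
#' mean annual SOC stock change converted to CO2 (a SOC gain is a negative
#' term). The SOC term can be excluded for sensitivity analysis.
#'
#' @param series A [soil_flux_series()].
#' @param params An [load_params()] object (GWPs and 44/12).
#' @param include_soc Include the SOC term (default `TRUE`).
#' @return A `soil_flux_summary` list: `mean_ch4_Mg_ha`, `mean_n2o_kg_ha`,
#'   `mean_soc_delta_MgC_ha`, `net_soil_MgCO2e`, `n_years`.
#' @export
season_average_soil_co2e <- function(series, params = load_params(),
                                     include_soc = TRUE) {
  stopifnot(inherits(series, "soil_flux_series"),
            inherits(params, "emission_params"))
  if (nrow(series) == 0) stop("empty soil flux series", call. = FALSE)
  mean_ch4_kg <- mean(series$ch4_kg_ha)
  mean_n2o_kg <- mean(series$n2o_kg_ha)
  mean_soc_kg <- mean(series$soc_delta_kgC_ha)
  net <- (mean_ch4_kg * params$gwp_ch4 + mean_n2o_kg * params$gwp_n2o) / 1000
  if (include_soc) net <- net - mean_soc_kg * params$c_to_co2 / 1000
  structure(list(mean_ch4_Mg_ha = mean_ch4_kg / 1000,
                 mean_n2o_kg_ha = mean_n2o_kg,
                 mean_soc_delta_MgC_ha = mean_soc_kg / 1000,
                 net_soil_MgCO2e = net,
                 n_years = nrow(series),
                 pathway = attr(series, "pathway"),
                 category = attr(series, "category")),
            class = "soil_flux_summary")
}

#' @export
print.soil_flux_summary <- function(x, ...) {
  cat("<soil_flux_summary>",
      if (!is.na(x$pathway)) paste0(" ", x$pathway),
      if (!is.na(x$category)) paste0(" / ", x$category),
      " (", x$n_years, " yr)\n",
      sprintf("  mean CH4: %.4f Mg/ha/yr  mean N2O: %.4f kg/ha/yr  mean dSOC: %.4f Mg C/ha/yr\n",
              x$mean_ch4_Mg_ha, x$mean_n2o_kg_ha, x$mean_soc_delta_MgC_ha),
      sprintf("  net soil flux: %.3f Mg CO2-e/ha/yr\n", x$net_soil_MgCO2e),
      sep = "")
  invisible(x)
}

#' Residue-return effect on mean annual flux
#'
#' Compares a with-residue series against its no-residue baseline for the
#' same hydrology category: absolute difference of mean annual fluxes,
#' percent difference relative to the baseline, and their ratio. With a zero
#' baseline the percent and ratio are flagged undefined (`NA`) rather than
#' raising an error.
#'
#' @param no_residue,with_residue Two [soil_flux_series()] of equal length
#'   and hydrology category.
#' @param gas Which flux to compare: `"ch4"` (default, reported in Mg/ha) or
#'   `"n2o"` (kg/ha).
#' @return List `mean_no`, `mean_with`, `abs_diff`, `pct_diff`, `ratio`,
#'   `undefined` (TRUE when the baseline mean is zero).
#' @export
residue_effect_stats <- function(no_residue, with_residue, gas = c("ch4", "n2o")) {
  gas <- match.arg(gas)
  stopifnot(inherits(no_residue, "soil_flux_series"),
            inherits(with_residue, "soil_flux_series"))
  if (nrow(no_residue) != nrow(with_residue)) {
    stop("series must have equal length", call. = FALSE)
  }
  cat_no <- attr(no_residue, "category")
  cat_with <- attr(with_residue, "category")
  if (!is.na(cat_no) && !is.na(cat_with) && cat_no != cat_with) {
    stop("series are from different hydrology categories (",
         cat_no, " vs ", cat_with, ")", call. = FALSE)
  }
  col <- if (gas == "ch4") "ch4_kg_ha" else "n2o_kg_ha"
  scale <- if (gas == "ch4") 1000 else 1  # CH4 reported in Mg
  m0 <- mean(no_residue[[col]]) / scale
  m1 <- mean(with_residue[[col]]) / scale
  undefined <- m0 == 0
  list(mean_no = m0, mean_with = m1,
       abs_diff = m1 - m0,
       pct_diff = if (undefined) NA_real_ else (m1 - m0) / m0 * 100,
       ratio = if (undefined) NA_real_ else m1 / m0,
       undefined = undefined)
}
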