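# CO2-equivalent conversion, component-labelled gas inventories, assembly of
# the 4-pathway x 3-hydrology scenario table, and pathway-vs-reference
# comparisons.

#' Convert gas masses to CO2-equivalent
#'
#' 100-year GWP aggregation: `(ch4 * GWP_CH4 + n2o * GWP_N2O) / 1000`.
#'
#' @param ch4_kg Methane mass, kg.
#' @param n2o_kg Nitrous oxide mass, kg.
#' @param params An [load_params()] object supplying the GWPs (27.9 and 273
#'   by default).
#' @return CO2-equivalent, Mg.
#' @examples
#' co2e(1, 0, load_params())  # 0.0279
#' @export
co2e <- function(ch4_kg, n2o_kg, params = load_params()) {
  stopifnot(inherits(params, "emission_params"))
  assert_nonneg(ch4_kg, "ch4_kg")
  assert_nonneg(n2o_kg, "n2o_kg")
  (ch4_kg * params$gwp_ch4 + n2o_kg * params$gwp_n2o) / 1000
}

#' Component-labelled gas inventory
#'
#' @param components data.frame with columns `label`, `ch4_kg`, `n2o_kg`.
#' @param params An [load_params()] object for the CO2-e conversion.
#' @return A `gas_inventory` list: `components` (with a `co2e_Mg` column),
#'   `total_ch4_kg`, `total_n2o_kg`, `total_co2e_Mg`.
#' @export
gas_inventory <- function(components, params = load_params()) {
  stopifnot(is.data.frame(components),
            all(c("label", "ch4_kg", "n2o_kg") %in% names(components)))
  assert_nonneg(components$ch4_kg, "ch4_kg")
  assert_nonneg(components$n2o_kg, "n2o_kg")
  components$co2e_Mg <- co2e(components$ch4_kg, components$n2o_kg, params)
  structure(list(components = components,
                 total_ch4_kg = sum(components$ch4_kg),
                 total_n2o_kg = sum(components$n2o_kg),
                 total_co2e_Mg = sum(components$co2e_Mg)),
            class = "gas_inventory")
}

#' @export
print.gas_inventory <- function(x, ...) {
  cat("<gas_inventory>\n")
  df <- x$components
  df$ch4_kg <- round(df$ch4_kg, 2)
  df$n2o_kg <- round(df$n2o_kg, 3)
  df$co2e_Mg <- round(df$co2e_Mg, 3)
  print(df, row.names = FALSE)
  cat(sprintf("total: %.2f kg CH4, %.3f kg N2O, %.3f Mg CO2-e\n",
              x$total_ch4_kg, x$total_n2o_kg, x$total_co2e_Mg))
  invisible(x)
}

HYDRO_CATEGORIES <- c("dry", "median", "wet")

#' Assemble the pathway-by-hydrology scenario table
#'
#' Combines season-average soil CO2-e fluxes (per pathway and hydrology
#' category) with each pathway's non-soil flux into total direct GHG fluxes.
#' Credits (biochar, pyrogenic carbon) enter `nonsoil` as negative values so
#' every total is soil + nonsoil. Values are stored unrounded; printing
#' rounds half-away-from-zero to `digits` decimals.
#'
#' @param soil data.frame with columns `pathway`, `category` (dry/median/wet)
#'   and `soil_MgCO2e`; every pathway must have all three categories.
#' @param nonsoil Named numeric vector of non-soil fluxes (Mg CO2-e) per
#'   pathway; pathways without an entry (e.g. in-situ incorporation, which
#'   has none) default to 0.
#' @param digits Display rounding, decimals (default 1).
#' @return A `scenario_table` data.frame with columns `pathway`, `soil_dry`,
#'   `soil_median`, `soil_wet`, `nonsoil`, `total_dry`, `total_median`,
#'   `total_wet`.
#' @export
build_scenario_table <- function(soil, nonsoil = numeric(), digits = 1) {
  stopifnot(is.data.frame(soil),
            all(c("pathway", "category", "soil_MgCO2e") %in% names(soil)))
  bad_cat <- setdiff(unique(soil$category), HYDRO_CATEGORIES)
  if (length(bad_cat) > 0) {
    stop("unknown hydrology category: ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  }
  pathways <- unique(soil$pathway)
  extra <- setdiff(names(nonsoil), pathways)
  if (length(extra) > 0) {
    stop("nonsoil entries for unknown pathway(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(pathways, function(pw) {
    s <- stats::setNames(rep(NA_real_, 3), HYDRO_CATEGORIES)
    sub <- soil[soil$pathway == pw, ]
    s[sub$category] <- sub$soil_MgCO2e
    if (anyNA(s)) {
      stop(sprintf("missing soil flux for pathway '%s', category '%s'",
                   pw, paste(HYDRO_CATEGORIES[is.na(s)], collapse = ", ")),
           call. = FALSE)
    }
    ns <- if (pw %in% names(nonsoil)) unname(nonsoil[[pw]]) else 0
    data.frame(pathway = pw,
               soil_dry = s[["dry"]], soil_median = s[["median"]],
               soil_wet = s[["wet"]], nonsoil = ns,
               total_dry = s[["dry"]] + ns,
               total_median = s[["median"]] + ns,
               total_wet = s[["wet"]] + ns,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), digits = digits,
            class = c("scenario_table", "data.frame"))
}

#' @export
print.scenario_table <- function(x, ...) {
  digits <- attr(x, "digits")
  if (is.null(digits)) digits <- 1
  shown <- x
  num <- vapply(shown, is.numeric, logical(1))
  shown[num] <- lapply(shown[num], round_half_up, digits = digits)
  cat("<scenario_table> Mg CO2-e per ha-yr (display rounded to ",
      digits, " decimal)\n", sep = "")
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}

#' Compare pathway totals against a reference pathway
#'
#' Per-category differences `total_pathway - total_reference`, computed on
#' the unrounded totals (positive values indicate an emission increase over
#' the reference).
#'
#' @param table A [build_scenario_table()] result.
#' @param reference_pathway Pathway label used as the baseline (e.g.
#'   `"burning"`).
#' @return data.frame with columns `pathway`, `delta_dry`, `delta_median`,
#'   `delta_wet`.
#' @export
compare_to_reference <- function(table, reference_pathway) {
  stopifnot(inherits(table, "scenario_table"))
  if (!reference_pathway %in% table$pathway) {
    stop("unknown reference pathway: ", reference_pathway, call. = FALSE)
  }
  ref <- table[table$pathway == reference_pathway, ]
  data.frame(pathway = table$pathway,
             delta_dry = table$total_dry - ref$total_dry,
             delta_median = table$total_median - ref$total_median,
             delta_wet = table$total_wet - ref$total_wet,
             stringsAsFactors = FALSE)
}

#' Serialize / restore a scenario table
#'
#' JSON round-trip with full double precision, so a regenerated report is
#' identical to the original.
#'
#' @param table A `scenario_table`.
#' @param path Output JSON path.
#' @return `path` invisibly (`write_scenario_table`); the restored
#'   `scenario_table` (`read_scenario_table`).
#' @export
write_scenario_table <- function(table, path) {
  stopifnot(inherits(table, "scenario_table"))
  jsonlite::write_json(list(digits = attr(table, "digits"),
                            rows = as.data.frame(unclass(table))),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_scenario_table
#' @export
read_scenario_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(as.data.frame(obj$rows), digits = obj$digits,
            class = c("scenario_table", "data.frame"))
}

#' Published scenario reference values
#'
#' The published farm-scale summary for the four residue pathways across the
#' three hydrology categories: season-average soil fluxes (process-model
#' derived; not recomputable from this package), published non-soil fluxes,
#' and the published totals. These serve as fixed inputs for table assembly
#' and pathway comparisons. Note the published burning non-soil value (0.4)
#' is not reproducible from the burning equations and emission factors, which
#' yield about 1.45 Mg CO2-e net; see the methods vignette.
#'
#' @return List of data.frames `soil` (pathway, category, soil_MgCO2e),
#'   `nonsoil` (pathway, nonsoil_MgCO2e) and `totals` (pathway, dry, median,
#'   wet), all in Mg CO2-e per ha-yr.
#' @export
published_scenario_values <- function() {
  pathways <- c("burning", "incorporation", "livestock", "biochar")
  soil <- data.frame(
    pathway = rep(pathways, each = 3),
    category = rep(HYDRO_CATEGORIES, times = 4),
    soil_MgCO2e = c(2.1, 5.7, 8.3,    # burning
                    2.3, 7.9, 11.8,   # incorporation
                    2.2, 6.0, 8.8,    # livestock fodder + manure return
                    2.1, 5.7, 8.3),   # biochar
    stringsAsFactors = FALSE)
  nonsoil <- data.frame(pathway = pathways,
                        nonsoil_MgCO2e = c(0.4, 0, 2.2, -2.5),
                        stringsAsFactors = FALSE)
  totals <- data.frame(pathway = pathways,
                       dry = c(2.5, 2.3, 4.5, -0.4),
                       median = c(6.1, 7.9, 8.2, 3.2),
                       wet = c(8.7, 11.8, 11.0, 5.8),
                       stringsAsFactors = FALSE)
  list(soil = soil, nonsoil = nonsoil, totals = totals)
}
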