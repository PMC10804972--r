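# Central registry of physical constants, emission factors and conversion
# factors used by the residue-pathway calculators. Each parameter carries its
# unit and a short provenance string so reports can emit a parameter table.

param_registry <- function() {
  p <- function(name, default, unit, class, source) {
    data.frame(name = name, default = default, unit = unit, class = class,
               source = source, stringsAsFactors = FALSE)
  }
  rbind(
    p("grain_yield_t_ha", 3.77, "t/ha fresh grain", "nonneg",
      "mean observed yield, rice-wheat survey, West Champaran 2021"),
    p("straw_ratio_R", 1.5, "dimensionless", "nonneg",
      "crop production to straw ratio, regional residue inventory"),
    p("dm_fraction_D", 0.86, "fraction", "fraction",
      "dry matter fraction of fresh rice straw"),
    p("burn_efficiency_B", 0.89, "fraction", "fraction",
      "open-field burn efficiency, rice straw combustion study"),
    p("straw_energy_Es", 14.08, "MJ/kg DM (HHV)", "nonneg",
      "higher heating value of rice straw"),
    p("methane_energy_ECH4", 55.65, "MJ/kg", "positive",
      "energy content of methane, IPCC 2006 Vol. 4"),
    p("ym_fraction", 0.0474, "fraction of GE", "fraction",
      "herd-weighted enteric methane conversion factor (Tier 2, IGP herd model)"),
    p("digestible_energy_DE", 0.55, "fraction", "fraction",
      "digestible energy, Indian Subcontinent default, IPCC 2019"),
    p("urinary_energy_UE", 0.04, "fraction of GE", "fraction",
      "urinary energy for most ruminants, IPCC 2019"),
    p("ash_fraction_ASH", 0.08, "fraction", "fraction",
      "ash content of cattle manure, IPCC 2019"),
    p("vs_energy_divisor", 18.45, "MJ/kg DM", "positive",
      "dietary gross-energy per kg dry matter, IPCC volatile-solids equation"),
    p("bo_m3_per_kgVS", 0.13, "m3 CH4/kg VS", "nonneg",
      "maximum methane producing capacity, dairy cattle, Indian Subcontinent"),
    p("ch4_density_kg_m3", 0.67, "kg/m3", "positive",
      "methane density at standard conditions"),
    p("mcf", 0.05, "fraction", "fraction",
      "methane conversion factor, solid storage, warm climate"),
    p("nf_fraction", 0.022, "fraction of VS (dry, ash-free)", "fraction",
      "nitrogen fraction of manure, low-intensity systems"),
    p("efn_kgN2ON_per_kgN", 0.01, "kg N2O-N/kg N", "nonneg",
      "direct N2O EF, solid manure storage, IPCC class default"),
    p("cookstove_ef_ch4_kg_TJ", 281, "kg CH4/TJ", "nonneg",
      "dung-fuelled cookstove CH4 EF, IPCC 2006 Vol. 2"),
    p("cookstove_ef_n2o_kg_TJ", 27, "kg N2O/TJ", "nonneg",
      "dung-fuelled cookstove N2O EF, IPCC 2006 Vol. 2"),
    p("dung_ncv_MJ_kg", 17.8, "MJ/kg dry", "nonneg",
      "net caloric value of dry cattle dung"),
    p("fperm", 0.71, "fraction", "fraction",
      "biochar C remaining after 100 yr, medium-T pyrolysis (SE 0.03)"),
    p("lignin_Lf", 0.179, "fraction DM", "fraction",
      "lignin mass fraction of rice residues, Phyllis2 database"),
    p("pyrolysis_T_K", 798.15, "K", "positive",
      "medium pyrolysis temperature (525 C, range 450-600 C)"),
    p("pyc_fraction_Pf", 0.11, "fraction", "fraction",
      "pyrogenic-C fraction after burn (1 - burn efficiency)"),
    p("pyc_retained_Pr", 0.9895, "fraction", "fraction",
      "fraction of pyrogenic C remaining on site"),
    p("burn_ef_ch4_g_kg", 9.59, "g CH4/kg burned", "nonneg",
      "rice residue open-burning CH4 EF, country-specific Tier 2"),
    p("burn_ef_n2o_g_kg", 0.48, "g N2O/kg burned", "nonneg",
      "rice residue open-burning N2O EF, country-specific Tier 2"),
    p("gwp_ch4", 27.9, "kg CO2-e/kg CH4 (100 yr)", "gwp",
      "AR6 100-year global warming potential"),
    p("gwp_n2o", 273, "kg CO2-e/kg N2O (100 yr)", "gwp",
      "AR6 100-year global warming potential"),
    p("c_to_co2", 44 / 12, "kg CO2/kg C", "exact_44_12",
      "molar mass ratio CO2:C"),
    p("n2on_to_n2o", 44 / 28, "kg N2O/kg N2O-N", "exact_44_28",
      "molar mass ratio N2O:N2"),
    p("field_split", 0.5, "fraction of VS to field", "fraction",
      "household manure split: half to field, half to cookstove fuel"),
    p("rice_start_day", 183, "Julian day", "day",
      "first day of the rice season water-level record")
  )
}

validate_param <- function(name, value, class) {
  bad <- function(msg) stop(sprintf("parameter `%s` %s (got %s)",
                                    name, msg, format(value)), call. = FALSE)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    bad("must be a single finite number")
  }
  switch(class,
    fraction = if (value < 0 || value > 1) bad("must be a fraction in [0, 1]"),
    nonneg = if (value < 0) bad("must be >= 0"),
    positive = if (value <= 0) bad("must be > 0"),
    gwp = if (value <= 1) bad("must be > 1 (100-yr GWP of a non-CO2 gas)"),
    exact_44_12 = if (abs(value - 44 / 12) > 1e-12) bad("is fixed at 44/12"),
    exact_44_28 = if (abs(value - 44 / 28) > 1e-12) bad("is fixed at 44/28"),
    day = if (value != as.integer(value) || value < 1 || value > 365) {
      bad("must be an integer Julian day in 1..365")
    }
  )
  invisible(value)
}

#' Load emission parameters
#'
#' Builds the full parameter set used by the pathway calculators: the packaged
#' defaults overlaid with any overrides from a YAML/JSON config file or a
#' named list. Every parameter is validated against its physical class
#' (fraction, non-negative, GWP > 1, fixed stoichiometric ratio) and carries
#' its unit and provenance, retrievable with [params_table()].
#'
#' @param config_source `NULL` for all defaults, a path to a YAML or JSON file
#'   whose keys are a subset of the parameter names, or a named list.
#' @param overrides Named list of additional `key = value` overrides applied
#'   after `config_source` (analogous to command-line `--set key=value`).
#' @return An object of class `emission_params`: a named list of numeric
#'   values with unit/provenance metadata attached.
#' @examples
#' p <- load_params()
#' p$grain_yield_t_ha            # 3.77
#' p2 <- load_params(overrides = list(grain_yield_t_ha = 5))
#' @export
load_params <- function(config_source = NULL, overrides = list()) {
  reg <- param_registry()
  values <- as.list(stats::setNames(reg$default, reg$name))

  cfg <- list()
  if (is.character(config_source) && length(config_source) == 1L) {
    if (!file.exists(config_source)) {
      stop("config file not found: ", config_source, call. = FALSE)
    }
    cfg <- if (grepl("\\.json$", config_source, ignore.case = TRUE)) {
      jsonlite::read_json(config_source, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config_source)
    }
    if (is.null(cfg)) cfg <- list()
  } else if (is.list(config_source)) {
    cfg <- config_source
  } else if (!is.null(config_source)) {
    stop("`config_source` must be NULL, a file path, or a named list",
         call. = FALSE)
  }

  for (ov in list(cfg, overrides)) {
    if (length(ov) == 0) next
    unknown <- setdiff(names(ov), reg$name)
    if (length(unknown) > 0) {
      stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    values[names(ov)] <- lapply(ov, as.numeric)
  }

  for (i in seq_len(nrow(reg))) {
    validate_param(reg$name[i], values[[reg$name[i]]], reg$class[i])
  }

  structure(values,
            units = stats::setNames(reg$unit, reg$name),
            source = stats::setNames(reg$source, reg$name),
            class = "emission_params")
}

#' Parameter table with units and provenance
#'
#' @param params An `emission_params` object from [load_params()].
#' @return A data.frame with columns `parameter`, `value`, `unit`, `source`.
#' @export
params_table <- function(params) {
  stopifnot(inherits(params, "emission_params"))
  data.frame(parameter = names(params),
             value = unlist(params, use.names = FALSE),
             unit = unname(attr(params, "units")[names(params)]),
             source = unname(attr(params, "source")[names(params)]),
             stringsAsFactors = FALSE)
}

#' Write emission parameters to a config file
#'
#' Serializes the numeric values (YAML or JSON by extension); round-tripping
#' through [load_params()] is lossless.
#'
#' @param params An `emission_params` object.
#' @param path Output path ending in `.yml`, `.yaml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "emission_params"))
  values <- unclass(params)
  attributes(values) <- list(names = names(values))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(values, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(values, path, precision = 17)
  }
  invisible(path)
}

#' @export
print.emission_params <- function(x, ...) {
  cat("<emission_params> ", length(x), " parameters\n", sep = "")
  print(utils::head(params_table(x)[, c("parameter", "value", "unit")], 10))
  if (length(x) > 10) cat("... use params_table() for the full set\n")
  invisible(x)
}

#' Representative herd model
#'
#' A herd composition used to weight category-specific enteric methane
#' conversion factors into a single Tier 2 factor.
#'
#' @param label Character vector of livestock category labels.
#' @param herd_fraction Numeric vector of herd composition fractions; must sum
#'   to 1 within 1e-9.
#' @param ym_percent Category methane conversion factors, in percent of gross
#'   energy intake.
#' @return A `herd_model` data.frame.
#' @export
herd_model <- function(label, herd_fraction, ym_percent) {
  stopifnot(length(label) == length(herd_fraction),
            length(label) == length(ym_percent))
  if (length(label) == 0) stop("herd model must have >= 1 category", call. = FALSE)
  assert_nonneg(ym_percent, "ym_percent")
  assert_fraction(herd_fraction, "herd_fraction")
  if (abs(sum(herd_fraction) - 1) > 1e-9) {
    stop("herd fractions must sum to 1 (got ", format(sum(herd_fraction)), ")",
         call. = FALSE)
  }
  structure(data.frame(label = as.character(label),
                       herd_fraction = herd_fraction,
                       ym_percent = ym_percent,
                       stringsAsFactors = FALSE),
            class = c("herd_model", "data.frame"))
}

#' Herd-weighted enteric methane conversion factor
#'
#' Weights each livestock category's methane conversion factor (percent of
#' gross energy) by its share of the herd and returns the composite factor as
#' a fraction, ready for the enteric emission equation.
#'
#' @param herd A [herd_model()] object.
#' @return Weighted mean conversion factor as a dimensionless fraction
#'   (percent / 100).
#' @examples
#' weighted_ym(herd_model("adult", 1, 6))  # 0.06
#' @export
weighted_ym <- function(herd) {
  if (!inherits(herd, "herd_model")) {
    stop("`herd` must be a herd_model object", call. = FALSE)
  }
  sum(herd$herd_fraction * herd$ym_percent) / 100
}

#' Straw yield from grain yield
#'
#' Fresh rice-straw production per hectare from grain yield and the crop
#' production to straw ratio.
#'
#' @param grain_yield_t_ha Fresh grain yield, t/ha.
#' @param ratio_R Production-to-straw ratio (dimensionless).
#' @return Fresh straw yield, t/ha.
#' @examples
#' straw_yield(3.77, 1.5)  # 5.655
#' @export
straw_yield <- function(grain_yield_t_ha, ratio_R) {
  assert_nonneg(grain_yield_t_ha, "grain_yield_t_ha")
  assert_nonneg(ratio_R, "ratio_R")
  grain_yield_t_ha * ratio_R
}

#' Convert fresh biomass to dry matter
#'
#' @param fresh_t_ha Fresh biomass, t/ha.
#' @param dm_fraction Dry matter fraction in `[0, 1]`.
#' @return Dry matter, kg/ha.
#' @examples
#' to_dry_matter(5.655, 0.86)  # 4863.3 kg DM/ha
#' @export
to_dry_matter <- function(fresh_t_ha, dm_fraction) {
  assert_nonneg(fresh_t_ha, "fresh_t_ha")
  assert_fraction(dm_fraction, "dm_fraction")
  fresh_t_ha * 1000 * dm_fraction
}
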