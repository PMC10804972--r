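# Livestock fodder pathway: non-soil emissions from feeding the hectare's
# rice straw to a representative bovine herd -- enteric fermentation, manure
# storage (CH4 and N2O), and dung-fuelled cookstoves -- plus the manure
# field-amendment schedule handed to the soil-model interface.

#' Gross energy of straw consumed
#'
#' @param straw_dm_kg Straw intake, kg dry matter per ha-yr.
#' @param es Energy content of rice straw (HHV), MJ/kg DM.
#' @return Gross energy, MJ per ha-yr.
#' @export
gross_energy <- function(straw_dm_kg, es) {
  assert_nonneg(straw_dm_kg, "straw_dm_kg")
  assert_nonneg(es, "es")
  straw_dm_kg * es
}

#' Enteric methane from straw consumption
#'
#' Tier 2 estimate: a fraction `ym` of the gross energy of the straw consumed
#' is converted to methane, divided by methane's energy content to obtain a
#' mass.
#'
#' @param straw_dm_kg Straw intake, kg DM.
#' @param es Straw energy content, MJ/kg DM.
#' @param ym Methane conversion factor as a fraction of gross energy (herd
#'   weighted; see [weighted_ym()]).
#' @param e_ch4 Energy content of methane, MJ/kg.
#' @return Enteric CH4, kg.
#' @examples
#' enteric_ch4(4863.3, 14.08, 0.0474, 55.65)  # ~58.3 kg CH4
#' @export
enteric_ch4 <- function(straw_dm_kg, es, ym, e_ch4) {
  assert_nonneg(straw_dm_kg, "straw_dm_kg")
  assert_nonneg(es, "es")
  assert_fraction(ym, "ym")
  if (!is.finite(e_ch4) || e_ch4 <= 0) {
    stop("`e_ch4` must be > 0", call. = FALSE)
  }
  ym * straw_dm_kg * es / e_ch4
}

#' Volatile solid excretion
#'
#' IPCC manure-production equation on a dry-organic-matter basis: the
#' undigested fraction of gross energy plus urinary energy, converted to mass
#' through the dietary energy density and corrected for ash.
#'
#' @param ge_MJ Gross energy of feed consumed, MJ.
#' @param de Digestible energy fraction.
#' @param ue Urinary energy as a fraction of gross energy.
#' @param ash Ash content of manure as a fraction of dry matter intake.
#' @param divisor Dietary gross energy per kg dry matter, MJ/kg (18.45).
#' @return Volatile solids excreted, kg (dry, organic).
#' @export
volatile_solids <- function(ge_MJ, de, ue, ash, divisor = 18.45) {
  assert_nonneg(ge_MJ, "ge_MJ")
  assert_fraction(de, "de")
  assert_fraction(ue, "ue")
  assert_fraction(ash, "ash")
  if (!is.finite(divisor) || divisor <= 0) {
    stop("`divisor` must be > 0", call. = FALSE)
  }
  (ge_MJ * (1 - de) + ue * ge_MJ) * (1 - ash) / divisor
}

#' Methane from manure storage
#'
#' @param vs_kg Volatile solids stored, kg.
#' @param bo Maximum methane producing capacity, m3 CH4 per kg VS.
#' @param density Methane density, kg/m3 (0.67).
#' @param mcf Methane conversion factor of the storage system (fraction).
#' @return Storage CH4, kg.
#' @export
manure_storage_ch4 <- function(vs_kg, bo, density = 0.67, mcf) {
  assert_nonneg(vs_kg, "vs_kg")
  assert_nonneg(bo, "bo")
  assert_nonneg(density, "density")
  assert_nonneg(mcf, "mcf")
  vs_kg * bo * density * mcf
}

#' Direct nitrous oxide from manure storage
#'
#' @param vs_kg Volatile solids stored, kg.
#' @param nf Nitrogen fraction of volatile solids (dry, ash-free).
#' @param efn Emission factor, kg N2O-N per kg N.
#' @param n2on_to_n2o Mass conversion N2O-N to N2O (44/28).
#' @return Storage N2O, kg.
#' @export
manure_storage_n2o <- function(vs_kg, nf, efn, n2on_to_n2o = 44 / 28) {
  assert_nonneg(vs_kg, "vs_kg")
  assert_nonneg(nf, "nf")
  assert_nonneg(efn, "efn")
  assert_nonneg(n2on_to_n2o, "n2on_to_n2o")
  nf * vs_kg * efn * n2on_to_n2o
}

#' Cookstove emissions from dung fuel
#'
#' Tier 1 fuel-combustion estimate: the dry dung mass is converted to energy
#' through its net caloric value and multiplied by per-TJ emission factors.
#'
#' @param manure_dm_kg Dry dung burned, kg.
#' @param ncv_MJ_kg Net caloric value of dung, MJ/kg.
#' @param ef_ch4 CH4 emission factor, kg/TJ.
#' @param ef_n2o N2O emission factor, kg/TJ.
#' @return Named list `ch4_kg`, `n2o_kg`, `fuel_TJ`.
#' @export
cookstove_emissions <- function(manure_dm_kg, ncv_MJ_kg, ef_ch4, ef_n2o) {
  assert_nonneg(manure_dm_kg, "manure_dm_kg")
  assert_nonneg(ncv_MJ_kg, "ncv_MJ_kg")
  assert_nonneg(ef_ch4, "ef_ch4")
  assert_nonneg(ef_n2o, "ef_n2o")
  fc_TJ <- manure_dm_kg * ncv_MJ_kg * 1e-6
  list(ch4_kg = fc_TJ * ef_ch4, n2o_kg = fc_TJ * ef_n2o, fuel_TJ = fc_TJ)
}

#' Manure field-amendment schedule
#'
#' The field-bound share of the volatile solids is returned to the field five
#' days before the rice season starts; the remainder is dried for cookstove
#' fuel. The schedule is the hand-off artifact for the soil-model interface.
#'
#' @param vs_total_kg Total volatile solids, kg.
#' @param field_split Fraction of VS applied to the field (default 0.5).
#' @param n_fraction Nitrogen fraction of the manure dry matter (default 0.022).
#' @param rice_start_day Julian day the rice season starts (default 183).
#' @return An `amendment_schedule` list: `application_julian_day`,
#'   `manure_dm_kg_ha`, `n_fraction`, `n_kg_ha`.
#' @export
field_amendment <- function(vs_total_kg, field_split = 0.5, n_fraction = 0.022,
                            rice_start_day = 183L) {
  assert_nonneg(vs_total_kg, "vs_total_kg")
  assert_fraction(field_split, "field_split")
  assert_fraction(n_fraction, "n_fraction")
  if (rice_start_day <= 5) {
    stop("`rice_start_day` must exceed 5 so the amendment day is a valid ",
         "Julian day", call. = FALSE)
  }
  dm <- vs_total_kg * field_split
  structure(list(application_julian_day = as.integer(rice_start_day) - 5L,
                 manure_dm_kg_ha = dm,
                 n_fraction = n_fraction,
                 n_kg_ha = dm * n_fraction),
            class = "amendment_schedule")
}

#' Non-soil emissions of the livestock fodder pathway
#'
#' Chains the hectare's straw yield through the full Tier 2 livestock
#' accounting: gross energy and enteric methane from consumption, volatile
#' solids excretion, storage CH4 and N2O on the full stored VS, and cookstove
#' emissions from the dung share not returned to the field. Returns a
#' component-labelled [gas_inventory()]; the manure [field_amendment()]
#' schedule is attached as attribute `"amendment"` for the soil-model
#' interface (its soil consequences are not computed here).
#'
#' @param params An [load_params()] object.
#' @return A `gas_inventory` with components `enteric`, `manure_storage_ch4`,
#'   `manure_storage_n2o`, `cookstove`.
#' @examples
#' inv <- livestock_pathway(load_params())
#' inv$total_co2e_Mg  # ~2.2 Mg CO2-e/ha/yr
#' @export
livestock_pathway <- function(params = load_params()) {
  stopifnot(inherits(params, "emission_params"))
  straw_dm <- to_dry_matter(
    straw_yield(params$grain_yield_t_ha, params$straw_ratio_R),
    params$dm_fraction_D)
  ge <- gross_energy(straw_dm, params$straw_energy_Es)
  ent <- enteric_ch4(straw_dm, params$straw_energy_Es, params$ym_fraction,
                     params$methane_energy_ECH4)
  vs <- volatile_solids(ge, params$digestible_energy_DE,
                        params$urinary_energy_UE, params$ash_fraction_ASH,
                        params$vs_energy_divisor)
  # manure is stored daily before either end use, so storage emissions apply
  # to the full VS; only the non-field share reaches the cookstove
  st_ch4 <- manure_storage_ch4(vs, params$bo_m3_per_kgVS,
                               params$ch4_density_kg_m3, params$mcf)
  st_n2o <- manure_storage_n2o(vs, params$nf_fraction,
                               params$efn_kgN2ON_per_kgN, params$n2on_to_n2o)
  cook <- cookstove_emissions(vs * (1 - params$field_split),
                              params$dung_ncv_MJ_kg,
                              params$cookstove_ef_ch4_kg_TJ,
                              params$cookstove_ef_n2o_kg_TJ)
  amend <- field_amendment(vs, params$field_split, params$nf_fraction,
                           params$rice_start_day)

  inv <- gas_inventory(
    data.frame(label = c("enteric", "manure_storage_ch4", "manure_storage_n2o",
                         "cookstove"),
               ch4_kg = c(ent, st_ch4, 0, cook$ch4_kg),
               n2o_kg = c(0, 0, st_n2o, cook$n2o_kg),
               stringsAsFactors = FALSE),
    params)
  attr(inv, "amendment") <- amend
  attr(inv, "budget") <- list(gross_energy_MJ = ge, vs_total_kg = vs,
                              vs_to_field_kg = amend$manure_dm_kg_ha,
                              vs_to_cookstove_kg = vs * (1 - params$field_split),
                              field_n_kg = amend$n_kg_ha)
  inv
}
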