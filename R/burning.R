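# Open-burning pathway: combustion CH4/N2O from the mass of residue burned,
# and the small credit for pyrogenic carbon (charred residue) that remains on
# site. CO2 released by combustion is biogenic and not counted; atmospheric
# black carbon exported in smoke is excluded.

#' Mass of rice residue burned
#'
#' @param grain_kg Grain yield, kg/ha.
#' @param ratio_R Production-to-straw ratio.
#' @param dm_fraction Dry matter fraction of fresh straw.
#' @param burn_eff Burn efficiency fraction (share of dry straw combusted).
#' @return Residue burned, kg dry matter.
#' @examples
#' residue_burned_mass(3770, 1.5, 0.86, 0.89)  # ~4328 kg
#' @export
residue_burned_mass <- function(grain_kg, ratio_R, dm_fraction, burn_eff) {
  assert_nonneg(grain_kg, "grain_kg")
  assert_nonneg(ratio_R, "ratio_R")
  assert_fraction(dm_fraction, "dm_fraction")
  assert_fraction(burn_eff, "burn_eff")
  grain_kg * ratio_R * dm_fraction * burn_eff
}

#' Combustion emissions from open burning
#'
#' @param mass_burned_kg Residue burned, kg.
#' @param ef_ch4_g_kg CH4 emission factor, g per kg burned.
#' @param ef_n2o_g_kg N2O emission factor, g per kg burned.
#' @return Named list `ch4_kg`, `n2o_kg`.
#' @export
burning_emissions <- function(mass_burned_kg, ef_ch4_g_kg, ef_n2o_g_kg) {
  assert_nonneg(mass_burned_kg, "mass_burned_kg")
  assert_nonneg(ef_ch4_g_kg, "ef_ch4_g_kg")
  assert_nonneg(ef_n2o_g_kg, "ef_n2o_g_kg")
  list(ch4_kg = mass_burned_kg * ef_ch4_g_kg / 1000,
       n2o_kg = mass_burned_kg * ef_n2o_g_kg / 1000)
}

#' Pyrogenic-carbon credit from incomplete combustion
#'
#' The uncombusted fraction of the straw carbon chars in place; the share
#' retained on site earns the same 100-year permanence credit as biochar
#' carbon: `Mbc = fby * straw * dm * pf * pr`, then converted to CO2-e via
#' the permanence fraction.
#'
#' @param fby Char carbon yield fraction (see [biochar_yield_fraction()]).
#' @param straw_fresh_kg Fresh straw, kg.
#' @param dm_fraction Dry matter fraction.
#' @param pf Pyrogenic carbon fraction after burn (1 - burn efficiency).
#' @param pr Fraction of pyrogenic carbon remaining on site.
#' @param fperm Fraction persisting after 100 years.
#' @return List `mbc_kgC` (pyrogenic C on site) and `credit_MgCO2e`.
#' @export
pyc_credit <- function(fby, straw_fresh_kg, dm_fraction, pf, pr, fperm) {
  assert_fraction(fby, "fby")
  assert_nonneg(straw_fresh_kg, "straw_fresh_kg")
  assert_fraction(dm_fraction, "dm_fraction")
  assert_fraction(pf, "pf")
  assert_fraction(pr, "pr")
  assert_fraction(fperm, "fperm")
  mbc <- fby * straw_fresh_kg * dm_fraction * pf * pr
  list(mbc_kgC = mbc, credit_MgCO2e = net_avoided_ghg(mbc, fperm))
}

#' Non-soil emissions of the open-burning pathway
#'
#' Assumes all available crop residue is burned: combustion CH4 and N2O minus
#' the on-site pyrogenic-carbon credit.
#'
#' @param params An [load_params()] object.
#' @return A `burning_result` list: `mass_burned_kg`, `ch4_kg`, `n2o_kg`,
#'   `combustion_MgCO2e`, `pyc_credit_MgCO2e`, `net_nonsoil_MgCO2e`.
#' @export
burning_pathway <- function(params = load_params()) {
  stopifnot(inherits(params, "emission_params"))
  grain_kg <- params$grain_yield_t_ha * 1000
  straw_fresh_kg <- straw_yield(params$grain_yield_t_ha,
                                params$straw_ratio_R) * 1000
  burned <- residue_burned_mass(grain_kg, params$straw_ratio_R,
                                params$dm_fraction_D, params$burn_efficiency_B)
  em <- burning_emissions(burned, params$burn_ef_ch4_g_kg,
                          params$burn_ef_n2o_g_kg)
  fby <- biochar_yield_fraction(params$lignin_Lf, params$pyrolysis_T_K)
  pyc <- pyc_credit(fby, straw_fresh_kg, params$dm_fraction_D,
                    params$pyc_fraction_Pf, params$pyc_retained_Pr,
                    params$fperm)
  combustion <- co2e(em$ch4_kg, em$n2o_kg, params)
  structure(list(mass_burned_kg = burned,
                 ch4_kg = em$ch4_kg, n2o_kg = em$n2o_kg,
                 combustion_MgCO2e = combustion,
                 pyc_mbc_kgC = pyc$mbc_kgC,
                 pyc_credit_MgCO2e = pyc$credit_MgCO2e,
                 net_nonsoil_MgCO2e = combustion - pyc$credit_MgCO2e),
            class = "burning_result")
}

#' @export
print.burning_result <- function(x, ...) {
  cat("<burning_result>\n",
      sprintf("  residue burned:   %8.1f kg DM/ha\n", x$mass_burned_kg),
      sprintf("  combustion:       %8.2f kg CH4, %.3f kg N2O (%.3f Mg CO2-e)\n",
              x$ch4_kg, x$n2o_kg, x$combustion_MgCO2e),
      sprintf("  on-site PyC:      %8.1f kg C (credit %.3f Mg CO2-e)\n",
              x$pyc_mbc_kgC, x$pyc_credit_MgCO2e),
      sprintf("  net non-soil:     %8.3f Mg CO2-e/ha\n", x$net_nonsoil_MgCO2e),
      sep = "")
  invisible(x)
}
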