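test_that("soil flux CSV round-trips and errors are descriptive", {
  s <- gen_soil_flux_series("median", n_years = 100, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_soil_flux_series(s, path)
  r <- read_soil_flux_series(path, category = "median")
  expect_equal(nrow(r), 100)
  expect_equal(r$ch4_kg_ha, s$ch4_kg_ha, tolerance = 1e-12)

  df <- utils::read.csv(path)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[, setdiff(names(df), "n2o_kg_ha")], path2, row.names = FALSE)
  expect_error(read_soil_flux_series(path2), "n2o_kg_ha")

  shuffled <- df[sample(nrow(df)), ]
  path3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(shuffled, path3, row.names = FALSE)
  expect_error(read_soil_flux_series(path3), "contiguous")

  neg <- df; neg$ch4_kg_ha[3] <- -1
  path4 <- withr::local_tempfile(fileext = ".csv")
  write.csv(neg, path4, row.names = FALSE)
  expect_error(read_soil_flux_series(path4), "ch4")
})

test_that("SOC stock columns are auto-detected and first-differenced", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(year = 1:4, ch4_kg_ha = rep(100, 4),
                       n2o_kg_ha = rep(0.01, 4),
                       soc_stock_kgC_ha = c(10000, 10100, 10150, 10150)),
            path, row.names = FALSE)
  s <- read_soil_flux_series(path)
  expect_equal(s$soc_delta_kgC_ha, c(0, 100, 50, 0))
  s2 <- read_soil_flux_series(path, initial_soc_kgC_ha = 9950)
  expect_equal(s2$soc_delta_kgC_ha, c(50, 100, 50, 0))
})

test_that("season average combines gas GWPs and subtracts SOC gain", {
  p <- load_params()
  # constant 0.1 Mg CH4/yr, nothing else -> 2.79 Mg CO2-e/yr
  s <- constant_flux_series(100, 0, 0, n = 10)
  expect_equal(season_average_soil_co2e(s, p)$net_soil_MgCO2e, 2.79)

  expect_equal(season_average_soil_co2e(constant_flux_series(0, 0, 0), p)$net_soil_MgCO2e, 0)

  # pure SOC gain of 100 kg C/yr -> -0.3667 Mg CO2-e/yr
  soc <- constant_flux_series(0, 0, 100)
  expect_equal(season_average_soil_co2e(soc, p)$net_soil_MgCO2e,
               -100 * 44 / 12 / 1000, tolerance = 1e-12)
  expect_equal(round(season_average_soil_co2e(soc, p)$net_soil_MgCO2e, 4),
               -0.3667)
  # SOC switch excludes the term
  expect_equal(season_average_soil_co2e(soc, p, include_soc = FALSE)$net_soil_MgCO2e, 0)
})

test_that("season average is permutation-invariant and linear in each gas", {
  p <- load_params()
  s <- gen_soil_flux_series("wet", residue_returned = TRUE, n_years = 50,
                            seed = 8)
  perm <- withr::with_seed(9, sample(nrow(s)))
  s_perm <- soil_flux_series(seq_len(nrow(s)), s$ch4_kg_ha[perm],
                             s$n2o_kg_ha[perm], s$soc_delta_kgC_ha[perm],
                             category = "wet")
  expect_equal(season_average_soil_co2e(s_perm, p)$net_soil_MgCO2e,
               season_average_soil_co2e(s, p)$net_soil_MgCO2e,
               tolerance = 1e-12)

  s2 <- soil_flux_series(seq_len(nrow(s)), 2 * s$ch4_kg_ha, s$n2o_kg_ha,
                         s$soc_delta_kgC_ha, category = "wet")
  base <- season_average_soil_co2e(s, p)
  dbl <- season_average_soil_co2e(s2, p)
  expect_equal(dbl$net_soil_MgCO2e - base$net_soil_MgCO2e,
               base$mean_ch4_Mg_ha * 1000 * p$gwp_ch4 / 1000,
               tolerance = 1e-12)
})

test_that("residue effect statistics reproduce the dry-category contrast", {
  no <- constant_flux_series(80, 0, 0, n = 100, category = "dry")
  yes <- constant_flux_series(110, 0, 0, n = 100, category = "dry")
  st <- residue_effect_stats(no, yes)
  expect_equal(st$abs_diff, 0.03)
  expect_equal(st$pct_diff, 37.5)
  expect_equal(st$ratio, 0.11 / 0.08)

  same <- residue_effect_stats(no, no)
  expect_equal(c(same$abs_diff, same$pct_diff), c(0, 0))

  zero <- constant_flux_series(0, 0, 0, n = 100, category = "dry")
  st0 <- residue_effect_stats(zero, yes)
  expect_true(st0$undefined)
  expect_true(is.na(st0$pct_diff) && is.na(st0$ratio))

  wet <- constant_flux_series(110, 0, 0, n = 100, category = "wet")
  expect_error(residue_effect_stats(no, wet), "categories")
  expect_error(residue_effect_stats(no, constant_flux_series(1, n = 5,
                                                             category = "dry")),
               "length")
})

test_that("ratio matches a brute-force mean computation to 1e-12", {
  set.seed(55)
  for (i in 1:10) {
    n <- sample(20:80, 1)
    a <- runif(n, 10, 400); b <- runif(n, 10, 400)
    no <- soil_flux_series(1:n, a, rep(0, n), rep(0, n), category = "median")
    yes <- soil_flux_series(1:n, b, rep(0, n), rep(0, n), category = "median")
    st <- residue_effect_stats(no, yes)
    expect_equal(st$ratio, (sum(b) / n) / (sum(a) / n), tolerance = 1e-12)
  }
})
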