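make_schedule <- function(n_years = 4, seed = 7) {
  yrs <- lapply(2020:2022, function(y) {
    water_level_series(paste0("A", y), 183:302,
                       withr::with_seed(y, round(runif(120, -30, 15), 2)),
                       climate_year = y)
  })
  names(yrs) <- 2020:2022
  build_water_input(yrs, n_years = n_years, seed = seed)
}

test_that("water-table files are written per year and round-trip exactly", {
  sched <- make_schedule(n_years = 4)
  dir <- withr::local_tempdir()
  paths <- write_water_table_files(sched, dir)
  expect_length(paths, 4)
  expect_true(file.exists(file.path(dir, "manifest.json")))

  for (y in seq_along(paths)) {
    back <- read_water_table_file(paths[y])
    expect_equal(nrow(back), 365)
    expect_equal(back$level_cm, unname(sched$levels[, y]), tolerance = 1e-9)
    expect_equal(back$level_cm[22], 0)
    expect_equal(back$level_cm[c(340, 352)], c(0, 0))
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$n_years, 4)
  expect_equal(manifest$source_year, sched$source_year)

  # metre dialect converts and converts back
  dir2 <- withr::local_tempdir()
  paths2 <- write_water_table_files(sched, dir2, unit = "m")
  back2 <- read_water_table_file(paths2[1], unit = "m")
  expect_equal(back2$level_cm, unname(sched$levels[, 1]), tolerance = 1e-9)
})

test_that("file writing is deterministic given the schedule", {
  sched <- make_schedule()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_water_table_files(sched, d1)
  p2 <- write_water_table_files(sched, d2)
  for (i in seq_along(p1)) {
    expect_identical(readLines(p1[i]), readLines(p2[i]))
  }
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
})

test_that("amendment schedule serializes the livestock defaults", {
  am <- field_amendment(1673.0, 0.5, 0.022, 183)
  path <- withr::local_tempfile(fileext = ".csv")
  write_amendment_schedule(am, path)
  df <- utils::read.csv(path)
  expect_equal(df$application_julian_day, 178)
  expect_equal(df$manure_dm_kg_ha, 836.5)
  expect_equal(round(df$n_kg_ha, 2), 18.4)

  # zero split -> header-only file
  empty <- field_amendment(1673.0, 0, 0.022, 183)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_amendment_schedule(empty, path2)
  df2 <- utils::read.csv(path2)
  expect_equal(nrow(df2), 0)
  expect_true(all(c("application_julian_day", "manure_dm_kg_ha", "n_kg_ha")
                  %in% names(df2)))

  # zero N fraction -> zero N mass
  expect_equal(field_amendment(1673, 0.5, 0, 183)$n_kg_ha, 0)
})

test_that("model output parsing applies element-mass conversions", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(yr = 1:3, ch4c = c(75, 30, 0), n2on = c(0.7, 0, 0.35),
                       dsoc = c(10, -5, 0)), path, row.names = FALSE)
  s <- parse_model_output(path, list(year = "yr", ch4 = "ch4c", n2o = "n2on",
                                     soc_delta = "dsoc", ch4_unit = "kg_c",
                                     n2o_unit = "kg_n"))
  expect_equal(s$ch4_kg_ha, c(75, 30, 0) * 16 / 12)
  expect_equal(s$ch4_kg_ha[1], 100)
  expect_equal(s$n2o_kg_ha, c(0.7, 0, 0.35) * 44 / 28)
  expect_equal(s$n2o_kg_ha[1], 1.1)

  expect_error(parse_model_output(path, list(year = "yr", ch4 = "nope",
                                             n2o = "n2on", soc_delta = "dsoc")),
               "unmapped")

  # identity mapping round-trips the synthetic generator's CSV
  synth <- gen_soil_flux_series("dry", n_years = 10, seed = 2)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_soil_flux_series(synth, p2)
  back <- parse_model_output(p2, list(year = "year", ch4 = "ch4_kg_ha",
                                      n2o = "n2o_kg_ha",
                                      soc_delta = "soc_delta_kgC_ha"))
  for (col in c("year", "ch4_kg_ha", "n2o_kg_ha", "soc_delta_kgC_ha")) {
    expect_equal(back[[col]], synth[[col]], tolerance = 1e-12)
  }
})

test_that("site sheet carries measured defaults and writes key-value text", {
  sh <- site_sheet()
  expect_equal(sh$soc_0_10cm_gC_kg, 5.2)
  expect_equal(sh$ph, 8.12)
  expect_equal(sh$bulk_density_Mg_m3, 1.46)
  expect_equal(sh$clay_fraction, 0.42)
  expect_error(site_sheet(not_a_field = 1), "unknown site field")
  path <- withr::local_tempfile(fileext = ".txt")
  write_site_sheet(sh, path)
  expect_true(any(grepl("^ph: 8.12$", readLines(path))))
})

test_that("calibration search converges on the linear example", {
  res <- calibration_search(function(p) 2 * p, target = 10, start = 1,
                            step = 1.25)
  expect_true(res$converged)
  expect_gte(res$parameter, 4.5)
  expect_lte(res$parameter, 5.5)
  expect_lte(abs(res$observable - 10) / 10, 0.10)
  expect_equal(nrow(res$trace), res$iterations + 1)

  # start already within tolerance returns immediately
  quick <- calibration_search(function(p) p, target = 10, start = 9.5)
  expect_equal(quick$iterations, 0L)
  expect_equal(quick$parameter, 9.5)

  # unreachable target exhausts iterations with a trace attached
  err <- tryCatch(
    calibration_search(function(p) 1, target = 10, start = 1,
                       max_iterations = 10),
    ricegas_calibration_error = function(e) e)
  expect_s3_class(err, "ricegas_calibration_error")
  expect_s3_class(err$trace, "data.frame")
  expect_gte(nrow(err$trace), 10)
})

test_that("calibration handles decreasing responses and direction hints", {
  # decreasing simulator: must step the parameter down
  res <- calibration_search(function(p) 100 / p, target = 10, start = 1,
                            step = 1.2)
  expect_true(res$converged)
  expect_lte(abs(res$observable - 10) / 10, 0.10)

  res2 <- calibration_search(function(p) p + 50, target = 100, start = 10,
                             step = 5, step_rule = "additive",
                             direction_hint = +1)
  expect_true(res2$converged)
  expect_lte(abs(res2$observable - 100) / 100, 0.10)
  # trace observable is monotone for a monotone simulator
  expect_true(all(diff(res2$trace$observable) >= 0))
})
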