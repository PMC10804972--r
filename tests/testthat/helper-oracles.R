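# Independent reference implementations used as oracles. These are written
# deliberately naively (explicit loops, base arithmetic) and never call the
# package's own code paths for the quantity they check.

# Brute-force dry/median/wet selection on a data.frame of field_id and
# flooded_days. Mirrors the documented rules with a plain re-derivation.
brute_force_assignment <- function(df, seed, sd_multiplier = 1) {
  counts <- df$flooded_days
  n <- length(counts)
  m <- sum(counts) / n
  s <- sqrt(sum((counts - m)^2) / (n - 1))
  sorted <- sort(counts)
  med <- if (n %% 2 == 1) sorted[(n + 1) / 2] else {
    (sorted[n / 2] + sorted[n / 2 + 1]) / 2
  }
  dmin <- min(abs(counts - med))
  med_field <- sort(df$field_id[abs(counts - med) == dmin])[1]
  dry <- setdiff(df$field_id[counts <= m - sd_multiplier * s], med_field)
  wet <- setdiff(df$field_id[counts >= m + sd_multiplier * s], med_field)
  if (length(dry) == 0 || length(wet) == 0) return(NULL)
  picks <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    c(dry[sample.int(length(dry), 1)], wet[sample.int(length(wet), 1)])
  })
  list(dry = picks[1], median = med_field, wet = picks[2],
       dry_candidates = dry, wet_candidates = wet)
}

# Spreadsheet-style livestock chain, spelled out step by step with literal
# constants rather than through the package functions.
spreadsheet_livestock <- function() {
  straw_fresh_kg <- 3.77 * 1.5 * 1000
  straw_dm <- straw_fresh_kg * 0.86
  ge <- straw_dm * 14.08
  enteric <- 0.0474 * straw_dm * 14.08 / 55.65
  vs <- (ge * (1 - 0.55) + 0.04 * ge) * (1 - 0.08) / 18.45
  st_ch4 <- vs * 0.13 * 0.67 * 0.05
  st_n2o <- 0.022 * vs * 0.01 * 44 / 28
  fc <- vs * 0.5 * 17.8 * 1e-6
  ck_ch4 <- fc * 281
  ck_n2o <- fc * 27
  comp <- c(enteric = enteric * 27.9,
            storage_ch4 = st_ch4 * 27.9,
            storage_n2o = st_n2o * 273,
            cookstove = ck_ch4 * 27.9 + ck_n2o * 273) / 1000
  list(components_Mg = comp, total_Mg = sum(comp), vs = vs, ge = ge)
}

# Constant flux series builder for aggregation tests.
constant_flux_series <- function(ch4_kg, n2o_kg = 0, soc_kg = 0, n = 10,
                                 category = NA_character_) {
  soil_flux_series(seq_len(n), rep(ch4_kg, n), rep(n2o_kg, n), rep(soc_kg, n),
                   category = category)
}
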