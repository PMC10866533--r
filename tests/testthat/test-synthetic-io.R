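test_that("generator collapses to the baseline when all stochastic terms are off", {
  cfg <- synth_config(duration_days = 2, baseline = 120,
                      circadian_amplitude = 0, meal_rate = 0, noise_sd = 0,
                      missing_fraction = 0)
  s <- generate_cgm(cfg)
  expect_length(s$values, 2 * 288)
  expect_true(all(s$values == 120))
  expect_equal(as.numeric(diff(s$timestamps), units = "mins"),
               rep(5, 2 * 288 - 1))
})

test_that("generation is seeded and bitwise reproducible", {
  cfg <- synth_config(duration_days = 3, seed = 77)
  s1 <- generate_cgm(cfg)
  s2 <- generate_cgm(cfg)
  expect_identical(s1$values, s2$values)
  expect_identical(s1$timestamps, s2$timestamps)
  s3 <- generate_cgm(synth_config(duration_days = 3, seed = 78))
  expect_false(identical(s1$values, s3$values))
})

test_that("missing fraction lands inside the binomial 99% band", {
  n_grid <- 7 * 288
  cfg <- synth_config(duration_days = 7, missing_fraction = 0.05, seed = 5)
  s <- generate_cgm(cfg)
  n_missing <- n_grid - length(s$values)
  band <- qbinom(c(0.005, 0.995), n_grid, 0.05)
  expect_gte(n_missing, band[1])
  expect_lte(n_missing, band[2])
})

test_that("generated values respect the CGM dynamic range", {
  cfg <- synth_config(duration_days = 2, baseline = 350, meal_peak = 200,
                      noise_sd = 30, seed = 2)
  s <- generate_cgm(cfg)
  expect_true(all(s$values >= 40 & s$values <= 400))
})

test_that("invalid generator config names the offending field", {
  expect_error(synth_config(missing_fraction = 1.2), "missing_fraction",
               class = "gs_config_error")
  expect_error(synth_config(noise_ar1 = 1), "noise_ar1",
               class = "gs_config_error")
  expect_error(synth_config(duration_days = 0), "duration_days",
               class = "gs_config_error")
})

test_that("CSV round trip reproduces a series exactly, including gaps", {
  path <- withr::local_tempfile(fileext = ".csv")
  s <- generate_cgm(synth_config(duration_days = 1, seed = 3,
                                 missing_fraction = 0))
  s$values[c(5, 40)] <- NA  # sensor dropouts survive the round trip
  s <- glucose_series(s$patient_id, s$timestamps, s$values, role = "train")
  write_cgm_csv(s, path)
  r <- read_cgm_csv(path, patient_id = s$patient_id)
  expect_identical(r$values, s$values)
  expect_equal(as.numeric(r$timestamps), as.numeric(s$timestamps))
})

test_that("CSV reader parses a small fixture and rejects bad rows by line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,glucose_mg_dl",
               "2024-01-01T00:00:00Z,101.5",
               "2024-01-01T00:05:00Z,",
               "2024-01-01T00:10:00Z,99"), path)
  s <- read_cgm_csv(path)
  expect_length(s$values, 3)
  expect_identical(s$values, c(101.5, NA, 99))

  writeLines(c("timestamp,glucose_mg_dl",
               "2024-01-01T00:00:00Z,101.5",
               "2024-01-01T00:05:00Z,abc"), path)
  expect_error(read_cgm_csv(path), "line 3", class = "gs_format_error")
  writeLines(c("not,a,header", "x"), path)
  expect_error(read_cgm_csv(path), "header", class = "gs_format_error")
})

ohio_fixture <- function(events) {
  paste0('<patient id="559"><glucose_level>',
         paste0(sprintf('<event ts="%s" value="%s"/>',
                        names(events), events), collapse = ""),
         "</glucose_level></patient>")
}

test_that("OhioT1DM-style XML is parsed, sorted, and de-duplicated", {
  path <- withr::local_tempfile(fileext = ".xml")
  ev <- c("01-02-2024 00:00:00" = 100, "01-02-2024 00:05:00" = 105,
          "01-02-2024 00:10:00" = 110, "01-02-2024 00:15:00" = 120)
  writeLines(ohio_fixture(ev), path)
  s <- read_ohio_xml(path)
  expect_length(s$values, 4)
  expect_identical(s$patient_id, "559")
  expect_identical(s$values, c(100, 105, 110, 120))

  # out-of-order events come back sorted
  writeLines(ohio_fixture(ev[c(3, 1, 4, 2)]), path)
  s2 <- read_ohio_xml(path)
  expect_identical(s2$values, c(100, 105, 110, 120))

  # duplicate timestamp: first occurrence wins, with a warning
  ev_dup <- c("01-02-2024 00:00:00" = 100, "01-02-2024 00:05:00" = 105,
              "01-02-2024 00:05:00" = 999, "01-02-2024 00:10:00" = 110)
  writeLines(ohio_fixture(ev_dup), path)
  expect_warning(s3 <- read_ohio_xml(path), "duplicate")
  expect_length(s3$values, 3)
  expect_identical(s3$values, c(100, 105, 110))
})

test_that("XML without a glucose_level element is a format error", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines("<patient id=\"1\"><basal/></patient>", path)
  expect_error(read_ohio_xml(path), "glucose_level",
               class = "gs_format_error")
})

test_that("CSV and XML readers agree on equivalent content", {
  csvp <- withr::local_tempfile(fileext = ".csv")
  xmlp <- withr::local_tempfile(fileext = ".xml")
  writeLines(c("timestamp,glucose_mg_dl",
               "2024-02-01T00:00:00Z,100",
               "2024-02-01T00:05:00Z,105"), csvp)
  writeLines(ohio_fixture(c("01-02-2024 00:00:00" = 100,
                            "01-02-2024 00:05:00" = 105)), xmlp)
  a <- read_cgm_csv(csvp)
  b <- read_ohio_xml(xmlp)
  expect_identical(a$values, b$values)
  expect_equal(as.numeric(a$timestamps), as.numeric(b$timestamps))
})
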