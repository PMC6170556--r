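test_that("standard clouds follow the bilateral-constraint identities", {
  # SO2 Lightly Polluted band (150, 475]
  m <- standard_cloud(150, 475, k = 0.1)
  expect_equal(m$ex, 312.5)
  expect_equal(m$en, 325 / 6)
  expect_equal(m$he, 32.5 / 6)
  # NO2 Heavily Polluted band (280, 565]
  m2 <- standard_cloud(280, 565, k = 0.1)
  expect_equal(c(m2$ex, m2$en, m2$he), c(422.5, 47.5, 4.75))
  # unit-entropy case
  expect_equal(unlist(unclass(standard_cloud(0, 6, 0.1))),
               c(ex = 3, en = 1, he = 0.1))
  expect_error(standard_cloud(5, 5), "cmin < cmax")
  expect_warning(standard_cloud(0, 6, k = 0.5), "1/3")
})

test_that("the full standard set satisfies the closed-form identities", {
  expect_equal(nrow(std_set), 7 * 5)
  expect_equal(2 * std_set$ex, std_set$cmin + std_set$cmax)
  expect_equal(6 * std_set$en, std_set$cmax - std_set$cmin)
  expect_equal(std_set$he, 0.1 * std_set$en)
  # expectations strictly increase with severity within each scale
  for (ind in unique(std_set$indicator)) {
    ex <- std_set$ex[std_set$indicator == ind]
    expect_true(all(diff(ex) > 0))
  }
  # shifting every band shifts ex, leaves en unchanged
  shifted <- default_table
  for (ind in names(shifted$indicators))
    shifted$indicators[[ind]]$upper <-
      shifted$indicators[[ind]]$upper + 10
  # bands now start at 10, not 0, for levels >= 2; compare level-3+ cells
  s2 <- build_standard_clouds(shifted)
  l3 <- s2$level >= 2 & s2$indicator != "AQI"
  expect_equal(s2$ex[l3], std_set$ex[std_set$level >= 2 &
                                       std_set$indicator != "AQI"] + 10)
  expect_equal(s2$en[l3], std_set$en[std_set$level >= 2 &
                                       std_set$indicator != "AQI"])
})

test_that("grading tables round-trip through JSON and validate structure", {
  path <- withr::local_tempfile(fileext = ".json")
  write_grading_table(default_table, path)
  back <- read_grading_table(path)
  expect_equal(back$index, default_table$index)
  expect_equal(back$indicators, default_table$indicators)
  # the packaged default JSON equals the built-in table
  pkg <- read_grading_table(system.file("extdata", "grading_gb3095.json",
                                        package = "aircloud"))
  expect_equal(pkg$indicators, default_table$indicators)
  # malformed tables are rejected
  bad <- default_table
  bad$indicators$PM10$upper <- c(50, 40, 250, 350, 420)
  expect_error(validate_grading_table(bad), "increasing")
})

test_that("IAQI interpolates exactly, continuously and monotonically", {
  # breakpoints map to index breakpoints exactly
  expect_equal(iaqi(75, "PM2.5")$value, 100)
  for (ind in names(default_table$indicators)) {
    upper <- default_table$indicators[[ind]]$upper
    for (j in seq_along(upper))
      expect_equal(iaqi(upper[j], ind)$value, default_table$index[j])
    # continuity: approach each breakpoint from both sides
    for (j in seq_along(upper)) {
      eps <- upper[j] * 1e-9
      expect_equal(iaqi(upper[j] - eps, ind)$value,
                   iaqi(upper[j] + eps, ind)$value, tolerance = 1e-6)
    }
    # monotone in concentration
    grid <- seq(0, max(upper) * 1.2, length.out = 101)
    vals <- vapply(grid, function(c_) iaqi(c_, ind)$value, numeric(1))
    expect_true(all(diff(vals) >= 0))
  }
  # hand-interpolated mid-band values
  expect_equal(iaqi(220.2, "PM2.5")$value, 270.2)
  expect_equal(iaqi(274.4, "PM10")$value, 162.2)
  expect_equal(iaqi(0, "SO2")$value, 0)
  # above-scale extrapolation is flagged
  top <- iaqi(300, "PM2.5")
  expect_true(top$above_scale)
  expect_gt(top$value, 300)
  expect_false(iaqi(249, "PM2.5")$above_scale)
  expect_error(iaqi(-5, "PM2.5"), "negative")
  expect_error(iaqi(10, "PM7"), "unknown indicator")
})

test_that("the daily AQI is the maximum IAQI with dominant bookkeeping", {
  # 5 Nov: PM2.5 at 220.2 dominates with IAQI 270.2
  r5 <- aqi_record(nov2016[5, ])
  expect_equal(r5$aqi, 270.2)
  expect_equal(r5$dominant, "PM2.5")
  # 2 Nov: NO2 at 57.8 dominates with IAQI 72.25
  r2 <- aqi_record(nov2016[2, ])
  expect_equal(r2$aqi, 72.25)
  expect_equal(r2$dominant, "NO2")
  expect_true(all(r2$aqi >= r2$iaqi))
  expect_true(r2$aqi %in% r2$iaqi)
  # all-zero record
  zero <- as.list(setNames(rep(0, 6), names(default_table$indicators)))
  expect_equal(aqi_record(zero)$aqi, 0)
  expect_error(aqi_record(zero[-3]), "missing indicator 'SO2'")
  tab <- daily_aqi(nov2016)
  expect_equal(nrow(tab), 30)
  expect_equal(tab$AQI[5], 270.2)
})
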