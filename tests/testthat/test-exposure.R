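test_that("exposure weights halve every half-life and decay monotonically", {
  p <- weightingParams(half_life_days = 35, window_days = 135)
  w <- exposureWeights(p)
  expect_length(w, 135)
  expect_equal(w[1 + 35] / w[1], 0.5, tolerance = 1e-12)
  expect_equal(w[70] / w[35], 0.5, tolerance = 1e-12)
  expect_true(all(diff(w) < 0))
  # arbitrary half-life too
  p2 <- weightingParams(half_life_days = 10, window_days = 50)
  w2 <- exposureWeights(p2)
  expect_equal(w2[25] / w2[15], 0.5, tolerance = 1e-12)
})

test_that("cumulative weighted dose matches closed forms", {
  p <- weightingParams()
  expect_equal(cumulativeWeightedDose(rep(0, 135), p), 0)
  # single dose D at lag 35 contributes D/2
  s <- rep(0, 135); s[35] <- 4
  expect_equal(cumulativeWeightedDose(s, p), 2, tolerance = 1e-12)
  # constant series: geometric series closed form
  r <- exp(-log(2) / 35)
  expect_equal(cumulativeWeightedDose(rep(1, 135), p),
               r * (1 - r^135) / (1 - r), tolerance = 1e-10)
  expect_error(cumulativeWeightedDose(c(rep(1, 134), -1), p), "non-negative")
  expect_error(cumulativeWeightedDose(rep(1, 10), p), "length")
})

test_that("cumulative weighted dose is homogeneous and additive", {
  p <- weightingParams()
  set.seed(42)
  for (i in 1:20) {
    s1 <- runif(135, 0, 6); s2 <- runif(135, 0, 6); c0 <- runif(1, 0, 5)
    expect_equal(cumulativeWeightedDose(c0 * s1, p),
                 c0 * cumulativeWeightedDose(s1, p), tolerance = 1e-10)
    expect_equal(cumulativeWeightedDose(s1 + s2, p),
                 cumulativeWeightedDose(s1, p) +
                   cumulativeWeightedDose(s2, p), tolerance = 1e-10)
  }
})

test_that("OSGB inverse projection hits the true origin and central meridian", {
  o <- osgbToLatLon(400000, -100000)
  expect_equal(o$lat, 49, tolerance = 1e-9)
  expect_equal(o$lon, -2, tolerance = 1e-9)
  # any northing on the central meridian has longitude exactly -2
  o2 <- osgbToLatLon(rep(400000, 4), c(0, 200000, 600000, 1000000))
  expect_equal(o2$lon, rep(-2, 4), tolerance = 1e-9)
  expect_error(osgbToLatLon(5e6, 0), "extent")
})

test_that("projection round-trips against a forward oracle below 1e-6 degrees", {
  set.seed(7)
  lat <- runif(100, 50, 60); lon <- runif(100, -6, 1)
  en <- oracleOsgbForward(lat, lon)
  back <- osgbToLatLon(en$easting, en$northing)
  expect_lt(max(abs(back$lat - lat)), 1e-6)
  expect_lt(max(abs(back$lon - lon)), 1e-6)
})

test_that("WGS84 datum option shifts points by a sub-cell amount", {
  a <- osgbToLatLon(400000, 300000)
  b <- osgbToLatLon(400000, 300000, datum = "WGS84")
  d <- sqrt((a$lat - b$lat)^2 + (a$lon - b$lon)^2)
  expect_gt(d, 1e-4)  # the shift is real...
  expect_lt(d, 0.01)  # ...but far below a quarter-degree cell
})

test_that("grid cell lookup uses half-open lower-left-anchored cells", {
  spec <- GridSpec(lat_min = 50, lon_min = -4, cell_size_deg = 0.25,
                   n_lat = 8, n_lon = 8)
  expect_equal(unlist(latLonToCell(50, -4, spec)[1, c("lat_idx", "lon_idx")]),
               c(lat_idx = 0L, lon_idx = 0L))
  # cell-center point
  expect_equal(latLonToCell(50.375, -3.625, spec)$lat_idx, 1L)
  expect_equal(latLonToCell(50.375, -3.625, spec)$lon_idx, 1L)
  # interior boundary point goes to the higher-index cell
  expect_equal(latLonToCell(50.25, -4, spec)$lat_idx, 1L)
  expect_equal(latLonToCell(50, -3.75, spec)$lon_idx, 1L)
  expect_error(latLonToCell(49.9, -4, spec), "outside")
  expect_error(latLonToCell(52.1, -4, spec), "outside")
})

test_that("daily series extraction imputes interior gaps and flags bad windows", {
  g <- makeConstantGrid(value = 2, n_days = 300)
  p <- weightingParams()
  d0 <- gridDates(g)[1]
  ds <- dailySeries(g, 1, d0 + 200, p)
  expect_equal(ds$n_days_imputed, 0)
  expect_equal(ds$series, rep(2, 135))
  # one interior missing day: linear interpolation between neighbours
  dose <- gridDose(g)
  dose[150, 1] <- NA
  dose[149, 1] <- 1; dose[151, 1] <- 3
  g2 <- DailyDoseGrid(gridSpec(g), gridDates(g), dose)
  ds2 <- dailySeries(g2, 1, d0 + 200, p)
  expect_equal(ds2$n_days_imputed, 1)
  lag_of_150 <- as.integer((d0 + 200) - (d0 + 149))  # date index 150
  expect_equal(ds2$series[lag_of_150], 2)            # midpoint of 1 and 3
  expect_equal(ds2$n_days_observed + ds2$n_days_imputed, 135)
  # window extending before grid start
  expect_error(dailySeries(g, 1, d0 + 100, p), "coverage")
  # too many missing days
  dose3 <- gridDose(g); dose3[120:160, 1] <- NA
  g3 <- DailyDoseGrid(gridSpec(g), gridDates(g), dose3)
  expect_error(dailySeries(g3, 1, d0 + 200, p), "missing")
})

test_that("exposure table is translation-invariant on a constant grid and linear", {
  g <- makeConstantGrid(value = 2, n_days = 400)
  d0 <- gridDates(g)[1]
  res <- data.frame(
    participant_id = c("a", "b"),
    lat = c(50.4, 50.4), lon = c(-3.4, -3.4),
    sample_date = c(d0 + 200, d0 + 235)
  )
  tab <- buildExposureTable(res, g)$exposure
  expect_equal(tab$cwduvb[1], tab$cwduvb[2], tolerance = 1e-12)
  gs <- DailyDoseGrid(gridSpec(g), gridDates(g), gridDose(g) * 3)
  tab3 <- buildExposureTable(res, gs)$exposure
  expect_equal(tab3$cwduvb, 3 * tab$cwduvb, tolerance = 1e-10)
})

test_that("winter-sampled participants get lower exposure than summer-sampled", {
  spec <- GridSpec(lat_min = 50, lon_min = -4, cell_size_deg = 0.25,
                   n_lat = 8, n_lon = 8)
  g <- simulateUvbGrid(spec, seq(as.Date("2009-01-01"),
                                 as.Date("2010-12-31"), by = "day"),
                       cloud_sd = 0)
  res <- data.frame(
    participant_id = c("winter", "summer"),
    lat = 50.9, lon = -3.1,
    sample_date = as.Date(c("2010-01-15", "2010-08-15"))
  )
  tab <- buildExposureTable(res, g)$exposure
  expect_lt(tab$cwduvb[tab$participant_id == "winter"],
            tab$cwduvb[tab$participant_id == "summer"])
})

test_that("exposure is invariant to the coordinate representation", {
  g <- makeConstantGrid(value = 1.5, n_days = 300)
  # pick an OSGB point whose lat/lon lands inside the small grid
  en <- oracleOsgbForward(51.1, -2.7)
  d0 <- gridDates(g)[1]
  r1 <- data.frame(participant_id = "x", easting = en$easting,
                   northing = en$northing, sample_date = d0 + 250)
  ll <- osgbToLatLon(en$easting, en$northing)
  r2 <- data.frame(participant_id = "x", lat = ll$lat, lon = ll$lon,
                   sample_date = d0 + 250)
  expect_equal(buildExposureTable(r1, g)$exposure$cwduvb,
               buildExposureTable(r2, g)$exposure$cwduvb,
               tolerance = 1e-12)
})

test_that("unresolvable residences are reported without aborting the run", {
  g <- makeConstantGrid()
  d0 <- gridDates(g)[1]
  res <- data.frame(
    participant_id = c("ok", "off_grid", "early"),
    lat = c(50.5, 70, 50.5), lon = c(-3.5, -3.5, -3.5),
    sample_date = c(d0 + 300, d0 + 300, d0 + 10)
  )
  out <- buildExposureTable(res, g)
  expect_equal(out$exposure$participant_id, "ok")
  expect_setequal(out$failures$participant_id, c("off_grid", "early"))
})
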