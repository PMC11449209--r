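writeTempCSV <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

test_that("generic reader drops bad rows and reports them", {
  f <- writeTempCSV(c("individual_id,timestamp,lon,lat",
                      "a,2024-06-03T06:00:00Z,36.9,0.29",
                      "a,2024-06-03T06:00:05Z,36.9,",
                      "b,2024-06-03T06:00:00Z,36.91,0.30"))
  fx <- readFixTable(f, "generic")
  expect_equal(nrow(fx), 2)
  rep <- attr(fx, "load_report")
  expect_equal(rep$n_read, 3)
  expect_equal(rep$n_dropped, 1)
  expect_equal(rep$dropped_missing_coord, 1)
})

test_that("reader sorts within individual and handles the Movebank dialect", {
  f <- writeTempCSV(c("individual_id,timestamp,lon,lat",
                      "a,2024-06-03T06:00:10Z,36.9,0.30",
                      "a,2024-06-03T06:00:00Z,36.9,0.29"))
  fx <- readFixTable(f, "generic")
  expect_false(is.unsorted(fx$time))
  m <- writeTempCSV(c("individual-local-identifier,timestamp,location-long,location-lat",
                      "2433,2012-08-05 09:00:00.000,36.9,0.29",
                      "2433,2012-08-05 09:00:01.000,36.901,0.291"))
  mfx <- readFixTable(m, "movebank")
  expect_equal(nrow(mfx), 2)
  expect_equal(mfx$individual_id, c("2433", "2433"))
  expect_equal(diff(mfx$time), 1)
})

test_that("reader errors name the missing column and reject empty files", {
  f <- writeTempCSV(c("individual_id,timestamp,lon", "a,2024-06-03T06:00:00Z,36.9"))
  expect_error(readFixTable(f, "generic"), "lat")
  e <- writeTempCSV("individual_id,timestamp,lon,lat")
  expect_error(readFixTable(e, "generic"), "empty")
  expect_error(readFixTable(tempfile(), "generic"), "not found")
})

test_that("a simulated dataset round-trips through the community store", {
  ds <- simulateTroop(troopConfig(nIndividuals = 2, nDays = 1,
                                  dayStart = "07:00", dayEnd = "07:10"))
  dir <- tempfile()
  writeCommunity(ds, dir)
  back <- readCommunity(dir)
  expect_equal(communityId(back), communityId(ds))
  a <- fixTable(ds); b <- fixTable(back)
  expect_equal(b$individual_id, a$individual_id)
  expect_equal(b$time, a$time)
  expect_equal(b$x, a$x, tolerance = 1e-9)
  expect_equal(b$lat, a$lat, tolerance = 1e-12)
  expect_equal(crsDescriptor(back)$lon0, crsDescriptor(ds)$lon0)
})

test_that("resampling decimates 1-Hz input onto the 5-s grid", {
  t0 <- baseEpoch()
  fx <- data.frame(time = t0 + 0:60, lon = 36.9 + (0:60) * 1e-5,
                   lat = 0.29, x = 100 + 0:60, y = 50)
  out <- resample5s(fx)
  expect_equal(nrow(out), 13)
  expect_equal(out$time, t0 + seq(0, 60, 5))
  expect_equal(out$x, 100 + seq(0, 60, 5))   # originals, not interpolations
})

test_that("resampling interpolates inside the gap bound and not beyond", {
  t0 <- baseEpoch()
  fx <- data.frame(time = t0 + c(0, 10), lon = c(36.9, 36.9),
                   lat = c(0.29, 0.3), x = c(0, 10), y = c(0, 20))
  out <- resample5s(fx, maxGapS = 30)
  expect_equal(out$x, c(0, 5, 10))
  expect_equal(out$y, c(0, 10, 20))          # linear midpoint
  far <- data.frame(time = t0 + c(0, 600), lon = c(36.9, 36.9),
                    lat = c(0.29, 0.3), x = c(0, 100), y = c(0, 0))
  out2 <- resample5s(far, maxGapS = 60)
  expect_equal(out2$time, t0 + c(0, 600))    # nothing bridged in between
  expect_error(resample5s(data.frame(time = c(t0, t0), lon = 1, lat = 1,
                                     x = 0, y = 0)),
               "degenerate")
})

test_that("resampling is idempotent and keeps the first duplicate fix", {
  t0 <- baseEpoch()
  fx <- data.frame(time = t0 + c(0, 3, 3, 8, 14), lon = 36.9, lat = 0.29,
                   x = c(0, 3, 99, 8, 14), y = 0)
  once <- resample5s(fx, maxGapS = 30)
  expect_equal(attr(once, "n_duplicate_fixes_dropped"), 1)
  twice <- resample5s(once, maxGapS = 30)
  expect_equal(as.data.frame(once), as.data.frame(twice), ignore_attr = TRUE)
  # duplicate kept the first value: interpolation between t=0 (x=0) and
  # t=3 (x=3) never sees x=99
  expect_true(all(once$x <= 14))
})

test_that("exclusion rules remove individuals and individual-days with a log", {
  t0 <- baseEpoch()
  df <- do.call(rbind, lapply(sprintf("24%02d", 50:54), function(id)
    rbind(stationaryTrack(id, 100, 100, 4, t0),
          stationaryTrack(id, 100, 100, 4, t0 + 86400))))
  ds <- makeDataset(df)
  rules <- data.frame(individual_id = "2450", date = as.Date(NA), reason = "all")
  out <- applyExclusions(ds, rules)
  expect_equal(length(individuals(out)), 4)
  expect_false("2450" %in% individuals(out))
  dayRule <- data.frame(individual_id = "2451",
                        date = sociospat:::localDate(t0, 3), reason = "one day")
  out2 <- applyExclusions(ds, dayRule)
  expect_true("2451" %in% individuals(out2))
  expect_equal(nrow(trajectory(out2, "2451", sociospat:::localDate(t0, 3))), 0)
  expect_equal(nrow(trajectory(out2, "2451", sociospat:::localDate(t0 + 86400, 3))), 4)
  expect_warning(applyExclusions(ds, data.frame(individual_id = "9999",
                                                date = as.Date(NA),
                                                reason = "unknown")),
                 "unknown")
  log <- datasetMetadata(out)$exclusion_log
  expect_equal(log[[1]]$individual_id, "2450")
  expect_equal(log[[1]]$reason, "all")
})

test_that("the shipped Mpala defaults drop individual 2459 everywhere", {
  rules <- readExclusionRules(mpalaExclusions())
  expect_equal(nrow(rules), 5)
  expect_true(is.na(rules$date[rules$individual_id == "2459"]))
  expect_equal(sort(rules$individual_id),
               c("2432", "2433", "2450", "2452", "2459"))
  # synthetic table carrying the real IDs and dates
  t0 <- as.numeric(as.POSIXct("2012-08-05 06:00:00", tz = "UTC"))
  df <- do.call(rbind, lapply(c("2432", "2433", "2452", "2459", "2440"),
                              function(id)
    rbind(stationaryTrack(id, 100, 100, 4, t0),
          stationaryTrack(id, 100, 100, 4, t0 + 9 * 86400))))
  ds <- makeDataset(df)
  # rules for individuals absent from this small fixture warn, not error
  expect_warning(out <- applyExclusions(ds, rules), "unknown individual")
  expect_false("2459" %in% individuals(out))
  # 2432 loses only 2012-08-05; 2452 loses only 2012-08-14
  expect_equal(nrow(trajectory(out, "2432", "2012-08-05")), 0)
  expect_equal(nrow(trajectory(out, "2432", "2012-08-14")), 4)
  expect_equal(nrow(trajectory(out, "2452", "2012-08-14")), 0)
  expect_equal(nrow(trajectory(out, "2452", "2012-08-05")), 4)
  expect_true("2440" %in% individuals(out))
})

test_that("communityDataset flags and excludes individuals without demographics", {
  t0 <- baseEpoch()
  fx <- data.frame(individual_id = rep(c("a", "b"), each = 3),
                   time = rep(t0 + c(0, 5, 10), 2),
                   lon = 36.9, lat = 0.29)
  demo <- data.frame(individual_id = "a", sex = "female", age = 30)
  expect_warning(ds <- communityDataset(fx, demo), "without demographics")
  expect_equal(individuals(ds), "a")
  expect_equal(datasetMetadata(ds)$excluded_no_demographics, "b")
})
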