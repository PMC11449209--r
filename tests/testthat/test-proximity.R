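test_that("two stationary individuals 100 m apart give constant distances", {
  df <- rbind(stationaryTrack("a", 1000, 1000, 720),
              stationaryTrack("b", 1100, 1000, 720))
  dd <- dyadDistances(makeDataset(df))
  expect_equal(nrow(dd), 720)
  expect_true(all(dd$distance_m == 100))
})

test_that("every possible dyad appears, and only shared epochs contribute", {
  df <- do.call(rbind, lapply(letters[1:5], function(id)
    stationaryTrack(id, runif(1, 0, 100), runif(1, 0, 100), 10)))
  dd <- dyadDistances(makeDataset(df))
  expect_equal(length(unique(paste(dd$individual_i, dd$individual_j))),
               5 * 4 / 2)
  # shift one individual so only half the epochs are shared
  t0 <- baseEpoch()
  df2 <- rbind(stationaryTrack("a", 0, 0, 10, t0),
               stationaryTrack("b", 30, 40, 10, t0 + 25))
  dd2 <- dyadDistances(makeDataset(df2))
  expect_equal(nrow(dd2), 5)
  expect_equal(dd2$time, t0 + seq(25, 45, 5))
  expect_true(all(dd2$distance_m == 50))
})

test_that("distances match a brute-force recomputation on a toy day", {
  set.seed(31)
  df <- do.call(rbind, lapply(c("a", "b", "c"), function(id)
    polylineTrack(id, cumsum(rnorm(30, 0, 12)), cumsum(rnorm(30, 0, 12)))))
  df$x <- df$x + 5000; df$y <- df$y + 5000
  ds <- makeDataset(df)
  got <- dyadDistances(ds)
  want <- bruteDyadDistances(fixTable(ds))
  got <- got[order(got$individual_i, got$individual_j, got$time)]
  want <- want[order(want$individual_i, want$individual_j, want$time), ]
  expect_equal(got$distance_m, want$distance_m, tolerance = 1e-12)
  expect_equal(nrow(got), 3 * 30)
})

test_that("pooled summaries match direct statistics and concatenation", {
  expect_equal(proximitySummary(c(1, 2, 3))$mean_m, 2)
  expect_equal(proximitySummary(c(1, 2, 3))$median_m, 2)
  set.seed(5)
  parts <- list(runif(1000, 0, 50), runif(500, 10, 400), runif(200, 0, 5))
  accs <- lapply(parts, function(p)
    accumulateDistances(proximityAccumulator(), p))
  merged <- Reduce(mergeAccumulators, accs)
  pooled <- proximitySummary(merged)
  all <- unlist(parts)
  expect_equal(pooled$n_samples, length(all))
  expect_equal(pooled$mean_m, mean(all))
  expect_equal(pooled$median_m, median(all))
  expect_equal(pooled$sd_m, sd(all))
  expect_equal(pooled$max_m, max(all))
  expect_error(proximitySummary(numeric()), "no distance samples")
})

test_that("histogram median is exact to one bin width at large n", {
  set.seed(9)
  d <- rexp(50000, 1 / 40)
  acc <- proximityAccumulator(binWidthM = 0.1, exactLimit = 100)
  accumulateDistances(acc, d)
  expect_null(acc$values)
  expect_lt(abs(proximitySummary(acc)$median_m - median(d)), 0.1)
})

test_that("hourly quantiles bin by local hour and respect ordering", {
  # epochs all inside local hour 7 (UTC+3): 04:10 UTC
  t0 <- baseEpoch("04:10:00")
  df <- rbind(stationaryTrack("a", 0, 0, 100, t0),
              stationaryTrack("b", 30, 40, 100, t0))
  hq <- hourlyQuantiles(dyadDistances(makeDataset(df)), utcOffsetHours = 3)
  expect_equal(unique(hq$hour), 7)
  expect_true(all(hq$value_m == 50))
  # quantile values non-decreasing in level within an hour
  ds <- simulateTroop(troopConfig(nIndividuals = 3, nDays = 1))
  hq2 <- hourlyQuantiles(dyadDistances(ds), utcOffsetHours = 3)
  for (h in unique(hq2$hour)) {
    v <- hq2$value_m[hq2$hour == h]
    expect_true(!is.unsorted(v))
  }
  # the 0.5 level equals the summary median of the same samples
  dd <- dyadDistances(ds)
  dd$hourAll <- 0
  q50 <- quantile(dd$distance_m, 0.5, type = 7, names = FALSE)
  expect_equal(proximitySummary(dd)$median_m, q50, tolerance = 1e-9)
})

test_that("dyad distances obey the triangle inequality at shared epochs", {
  ds <- simulateTroop(troopConfig(nIndividuals = 3, nDays = 1,
                                  dayStart = "07:00", dayEnd = "09:00"))
  dd <- dyadDistances(ds)
  wide <- data.table::dcast(data.table::as.data.table(dd), time ~ paste(individual_i, individual_j),
                            value.var = "distance_m")
  expect_true(all(wide$`T01 T03` <= wide$`T01 T02` + wide$`T02 T03` + 1e-9))
  expect_true(all(wide$`T01 T02` <= wide$`T01 T03` + wide$`T02 T03` + 1e-9))
})

test_that("troop hourly medians stay flat while band medians peak at midday", {
  tr <- simulateTroop(troopConfig(nIndividuals = 6, nDays = 1))
  bd <- simulateBand(bandConfig(nIndividuals = 10, nDays = 1))
  hqT <- hourlyQuantiles(dyadDistances(tr), levels = 0.5, utcOffsetHours = 3)
  hqB <- hourlyQuantiles(dyadDistances(bd), levels = 0.5, utcOffsetHours = 3)
  medT <- hqT$value_m
  expect_lt(max(medT) / max(min(medT), 1), 4)  # no strong daily structure
  morning <- hqB$value_m[hqB$hour == 7]
  midday <- hqB$value_m[hqB$hour == 12]
  expect_gt(midday, 10 * morning)              # dispersal at midday
})
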