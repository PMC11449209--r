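test_that("a single stationary fix occupies exactly one cell", {
  r <- rasterizeDay(makeDataset(stationaryTrack("a", 123.4, 567.8, 1))@fixes,
                    gridSpec(10))
  expect_equal(length(r@cells), 1)
  expect_equal(unname(as.matrix(rasterCells(r))[1, ]), c(12, 56))
})

test_that("straight and diagonal segments match the dense-walk oracle", {
  grid <- gridSpec(10)
  # 95 m horizontal segment within one row, starting mid-cell
  tr <- polylineTrack("a", c(3, 98), c(4, 4))
  r <- rasterizeDay(makeDataset(tr)@fixes, grid)
  expect_true(length(r@cells) %in% c(10, 11))
  expect_equal(r@cells, denseWalkCells(c(3, 98), c(4, 4), grid))
  # diagonal across a 5 x 5 block
  tr2 <- polylineTrack("a", c(1, 49), c(2, 47))
  r2 <- rasterizeDay(makeDataset(tr2)@fixes, grid)
  expect_equal(r2@cells, denseWalkCells(c(1, 49), c(2, 47), grid))
})

test_that("random toy paths rasterize exactly as the dense-walk oracle", {
  set.seed(61)
  grid <- gridSpec(10)
  for (k in 1:30) {
    n <- sample(3:8, 1)
    xs <- cumsum(runif(n, -40, 40)) + 200
    ys <- cumsum(runif(n, -40, 40)) + 200
    r <- rasterizeDay(makeDataset(polylineTrack("a", xs, ys))@fixes, grid)
    expect_equal(r@cells, denseWalkCells(xs, ys, grid))
  }
})

test_that("gaps beyond the resampling bound are not bridged", {
  t0 <- baseEpoch()
  df <- data.frame(individual_id = "a", time = t0 + c(0, 5, 3600),
                   x = c(5, 15, 995), y = 5)
  r <- rasterizeDay(makeDataset(df)@fixes, gridSpec(10), maxGapS = 300)
  expect_equal(length(r@cells), 3)   # two adjacent cells plus the far fix
  rBridged <- rasterizeDay(makeDataset(df)@fixes, gridSpec(10), maxGapS = 4000)
  expect_equal(length(rBridged@cells), 100)
  # points mode registers only fix-containing cells
  rp <- rasterizeDay(makeDataset(df)@fixes, gridSpec(10), mode = "points")
  expect_equal(length(rp@cells), 3)
})

test_that("dyad overlap identities hold exactly", {
  ra <- handRaster("i", 0:2)
  expect_equal(dyadOverlap(ra, ra)$fraction_similar, 1)
  expect_equal(dyadOverlap(ra, ra)$fraction_different, 0)
  rb <- handRaster("j", 10:14)
  expect_equal(dyadOverlap(ra, rb)$fraction_similar, 0)
  # {A,B,C} vs {B,C,D,E}
  ri <- handRaster("i", c(0, 1, 2))
  rj <- handRaster("j", c(1, 2, 3, 4))
  ov <- dyadOverlap(ri, rj)
  expect_equal(ov$n_b, 1); expect_equal(ov$n_c, 2)
  expect_equal(ov$n_d, 2); expect_equal(ov$n_e, 5)
  expect_equal(ov$fraction_similar, 0.4)
  expect_equal(ov$fraction_different, 0.6)
  # symmetry: swapping i and j swaps n_b/n_c, fractions unchanged
  vo <- dyadOverlap(rj, ri)
  expect_equal(vo$n_b, ov$n_c); expect_equal(vo$n_c, ov$n_b)
  expect_equal(vo$fraction_similar, ov$fraction_similar)
  expect_equal(ov$fraction_similar + ov$fraction_different, 1)
  expect_error(dyadOverlap(ra, handRaster("k", 0:2, grid = gridSpec(5))),
               "different grids")
})

test_that("overlap table fractions sum to one and bound the shared count", {
  ds <- simulateTroop(troopConfig(nIndividuals = 4, nDays = 1,
                                  dayStart = "07:00", dayEnd = "09:00"))
  ov <- dyadOverlapTable(ds, gridSpec(10))
  expect_equal(nrow(ov), 6)
  expect_true(all(ov$fraction_similar + ov$fraction_different == 1))
  expect_true(all(ov$n_d <= pmin(ov$n_b + ov$n_d, ov$n_c + ov$n_d)))
  expect_true(all(ov$n_e == ov$n_b + ov$n_c + ov$n_d))
})

test_that("exploration curves are monotone with order-invariant endpoints", {
  # identical rasters: no gain after the first individual
  df <- do.call(rbind, lapply(c("a", "b", "c"), function(id)
    polylineTrack(id, seq(5, 995, 10), rep(5, 100))))
  ec <- explorationCurve(makeDataset(df), grid = gridSpec(10))
  expect_equal(unique(ec$cumulative_cells), 100)
  # pairwise-disjoint rasters accumulate additively
  df2 <- rbind(polylineTrack("a", seq(5, 95, 10), rep(5, 10)),
               polylineTrack("b", seq(5, 195, 10), rep(1005, 20)),
               polylineTrack("c", seq(5, 295, 10), rep(2005, 30)))
  for (s in 1:5) {
    ec2 <- explorationCurve(makeDataset(df2), orderSeed = s, grid = gridSpec(10))
    sizes <- c(a = 10, b = 20, c = 30)
    expect_equal(ec2$cumulative_cells, cumsum(unname(sizes[ec2$individual_id])))
    expect_equal(ec2$cumulative_cells[3], 60)
  }
  # final value equals the brute-force union on a random toy day
  set.seed(71)
  df3 <- do.call(rbind, lapply(c("a", "b", "c", "d"), function(id)
    polylineTrack(id, cumsum(runif(20, -30, 30)) + 300,
                  cumsum(runif(20, -30, 30)) + 300)))
  ds3 <- makeDataset(df3)
  vt <- visitationTable(ds3, gridSpec(10))
  ec3 <- explorationCurve(ds3, grid = gridSpec(10))
  expect_true(!is.unsorted(ec3$cumulative_cells))
  expect_equal(ec3$cumulative_cells[4], length(unique(vt$cell)))
})

test_that("sex partition handles pure, identical and unknown-sex cases", {
  df <- rbind(polylineTrack("m1", seq(5, 95, 10), rep(5, 10)),
              polylineTrack("m2", seq(5, 195, 10), rep(105, 20)))
  demoM <- data.frame(individual_id = c("m1", "m2"),
                      sex = "male", age = NA_real_)
  spM <- sexPartition(makeDataset(df, demoM), gridSpec(10))
  expect_equal(c(spM$frac_male_only, spM$frac_female_only, spM$frac_both),
               c(1, 0, 0))
  df2 <- rbind(polylineTrack("m", seq(5, 95, 10), rep(5, 10)),
               polylineTrack("f", seq(5, 95, 10), rep(5, 10)))
  demo2 <- data.frame(individual_id = c("m", "f"),
                      sex = c("male", "female"), age = NA_real_)
  sp2 <- sexPartition(makeDataset(df2, demo2), gridSpec(10))
  expect_equal(sp2$frac_both, 1)
  demo3 <- data.frame(individual_id = c("m", "f"),
                      sex = c("male", NA), age = NA_real_)
  expect_warning(sp3 <- sexPartition(makeDataset(df2, demo3), gridSpec(10)),
                 "unknown sex")
  expect_equal(sp3$frac_male_only, 1)
  expect_equal(sp3$frac_male_only + sp3$frac_female_only + sp3$frac_both, 1)
})

test_that("partition averaging is an unweighted mean, invariant to order", {
  p1 <- data.frame(community_id = "a", n_male_only = 1, n_female_only = 1,
                   n_both = 3, frac_male_only = 0.2, frac_female_only = 0.2,
                   frac_both = 0.6)
  p2 <- data.frame(community_id = "b", n_male_only = 2, n_female_only = 2,
                   n_both = 1, frac_male_only = 0.4, frac_female_only = 0.4,
                   frac_both = 0.2)
  expect_equal(averagePartitions(p1)$frac_both, 0.6)
  avg <- averagePartitions(rbind(p1, p2))
  expect_equal(c(avg$frac_male_only, avg$frac_female_only, avg$frac_both),
               c(0.3, 0.3, 0.4))
  expect_equal(averagePartitions(rbind(p2, p1)), avg)
})

test_that("troop dyads share more landscape than band dyads at every cell size", {
  tr <- simulateTroop(troopConfig(nIndividuals = 6, nDays = 1))
  bd <- simulateBand(bandConfig(nIndividuals = 8, nDays = 1))
  for (cs in c(5, 10, 20)) {
    mT <- median(dyadOverlapTable(tr, gridSpec(cs))$fraction_similar)
    mB <- median(dyadOverlapTable(bd, gridSpec(cs))$fraction_similar)
    expect_gt(mT, mB)
  }
})
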