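# Fixture builders: small CommunityDatasets constructed directly from
# planar coordinates (already on the 5-s grid), bypassing file ingestion.

testCRS <- function() utmCRS(37, TRUE)

baseEpoch <- function(clock = "06:00:00", date = "2024-06-03") {
  as.numeric(as.POSIXct(paste(date, clock), tz = "UTC"))
}

makeDataset <- function(df, demo = NULL, communityId = "test",
                        utcOffsetHours = 3) {
  crs <- testCRS()
  ll <- unprojectPlanar(df$x, df$y, crs)
  fx <- data.frame(individual_id = as.character(df$individual_id),
                   date = sociospat:::localDate(df$time, utcOffsetHours),
                   time = df$time, lon = ll$lon, lat = ll$lat,
                   x = df$x, y = df$y)
  if (is.null(demo))
    demo <- data.frame(individual_id = unique(fx$individual_id),
                       sex = "female", age = NA_real_)
  new("CommunityDataset", communityId = communityId, fixes = fx,
      demographics = demo, crs = crs, utcOffset = utcOffsetHours,
      metadata = list(maxGapS = 300, exclusion_log = list()))
}

# one stationary individual at (x, y) for n epochs starting at t0
stationaryTrack <- function(id, x, y, n, t0 = baseEpoch()) {
  data.frame(individual_id = id, time = t0 + 5 * (seq_len(n) - 1),
             x = x, y = y)
}

# a polyline walked at one vertex per epoch
polylineTrack <- function(id, xs, ys, t0 = baseEpoch()) {
  data.frame(individual_id = id, time = t0 + 5 * (seq_along(xs) - 1),
             x = xs, y = ys)
}

# hand-built visitation raster from integer cell columns (all in row 0
# unless rows given)
handRaster <- function(id, cols, rows = 0, grid = gridSpec(10),
                       date = as.Date("2024-06-03")) {
  keys <- sort(sociospat:::encodeCells(cols, rows))
  new("VisitationRaster", individualId = id, date = date,
      cells = keys, grid = grid)
}

squareTrack <- function(step = 50, side = 250) {
  # closed square, side 250 m, walked anticlockwise at `step` m per epoch
  per <- seq(0, 4 * side, by = step)
  pos <- t(vapply(per, function(s) {
    if (s <= side) c(s, 0)
    else if (s <= 2 * side) c(side, s - side)
    else if (s <= 3 * side) c(3 * side - s, side)
    else c(0, 4 * side - s)
  }, c(0, 0)))
  polylineTrack("sq", pos[, 1] + 1000, pos[, 2] + 1000)
}
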