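# Seeded central-place-forager simulator. Two archetypes:
#   - troop: one cohesive group tracing a smooth closed daily loop with
#     foraging/resting stops, members held near the moving centroid by a
#     smooth mean-reverting offset;
#   - band: a fission-fusion community at a fixed camp, members departing on
#     sex-structured out-and-back trips (solo sinuous male trips, grouped
#     more linear female trips) and re-aggregating by evening.
# Tracks carry an autocorrelated GPS-noise dither, as real 5-s wearable GPS
# does; at this resolution that dither (plus within-group milling) is a
# large share of summed path length, which is why high-frequency day ranges
# read long.
# All randomness flows from one seed; per-individual/per-day substreams are
# derived by stable hashing so output is independent of iteration order.

#' Troop archetype configuration
#'
#' Defaults describe a cohesive baboon-like troop: ~12 h of daylight
#' movement on a closed loop with about five foraging/resting stops,
#' members held within tens of metres of the moving centroid. The default
#' spread (14 m per axis) is the value whose Rayleigh dyad-distance median
#' (`2*sigma*sqrt(ln 2)`) sits near the ~23 m medians reported for cohesive
#' baboon troops; with the default measurement noise the summed day range
#' comes out near 10.5 km.
#'
#' @param nIndividuals number of tracked individuals (>= 2).
#' @param nDays number of simulated days.
#' @param dayStart,dayEnd local clock times ("HH:MM") bounding the recording.
#' @param loopRadiusM base radius of the daily centroid loop, metres; sets
#'   the net excursion scale (summed day range is dominated by milling and
#'   measurement dither at 5-s resolution).
#' @param centroidSpeedMS centroid travel speed while moving, m/s; leftover
#'   time is spent dwelling at the sleep site before departure and after
#'   return.
#' @param nForagingStops number of mid-loop stops; each lasts 30-60 min.
#' @param spreadSigmaM stationary per-axis standard deviation (metres) of
#'   each member's independent offset from the centroid.
#' @param ouRelaxationS relaxation time (seconds) of the offset process.
#' @param offsetNodeS node spacing (seconds) of the offset process; the
#'   mean-reverting offset is simulated at this spacing and interpolated to
#'   the 5-s grid so that tracks stay differentiable at fix scale.
#' @param gpsNoiseSdM,gpsNoiseTauS stationary s.d. (m) and relaxation (s)
#'   of the autocorrelated GPS measurement-noise dither added per axis.
#' @param sleepSite named vector `c(lon=, lat=)` of the sleep site.
#' @param utcOffsetHours fixed UTC offset for local time.
#' @param startDate first simulated local calendar day.
#' @param seed integer seed; identical config + seed gives a bitwise
#'   identical dataset.
#' @return a list of class `"troopConfig"`.
#' @export
troopConfig <- function(nIndividuals = 10, nDays = 3, dayStart = "07:00",
                        dayEnd = "19:00", loopRadiusM = 250,
                        centroidSpeedMS = 0.25, nForagingStops = 5,
                        spreadSigmaM = 14, ouRelaxationS = 600,
                        offsetNodeS = 120, gpsNoiseSdM = 3,
                        gpsNoiseTauS = 120,
                        sleepSite = c(lon = 36.92, lat = 0.29),
                        utcOffsetHours = 3, startDate = "2024-06-03",
                        seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(nIndividuals >= 2, nDays >= 1, loopRadiusM > 0,
            centroidSpeedMS > 0, spreadSigmaM >= 0, ouRelaxationS > 0,
            offsetNodeS >= 5, nForagingStops >= 0, gpsNoiseSdM >= 0,
            clockToSec(dayStart) < clockToSec(dayEnd))
  structure(cfg, class = "troopConfig")
}

#' Band archetype configuration
#'
#' Defaults describe a Hadza-like forager camp: members either stay in camp
#' for the day or leave on out-and-back foraging trips. Male trips are solo,
#' long and sinuous; female trips are taken in small groups, are shorter and
#' more linear. Everyone is in camp at the start and end of the day.
#'
#' @param nIndividuals number of residents (>= 2).
#' @param sexRatio proportion female.
#' @param nDays number of simulated days.
#' @param camp named vector `c(lon=, lat=)` of the camp.
#' @param femaleTrip,maleTrip lists with elements `groupSize` (females;
#'   males are solo), `maxDistanceM` (hard cap on distance from camp),
#'   `sinuosity` (lateral wander as a fraction of trip extent), `departWindow`
#'   and `returnWindow` (each a length-2 character vector of local clock
#'   times).
#' @param inCampJitterM s.d. (metres) of in-camp movement around each
#'   member's hearth.
#' @param pStayInCamp per-individual-day probability of staying in camp.
#' @param dayStart,dayEnd local recording window.
#' @param gpsNoiseSdM,gpsNoiseTauS GPS measurement-noise dither, as in
#'   [troopConfig()].
#' @param utcOffsetHours,startDate,seed as in [troopConfig()].
#' @return a list of class `"bandConfig"`.
#' @export
bandConfig <- function(nIndividuals = 16, sexRatio = 0.5, nDays = 3,
                       camp = c(lon = 35.05, lat = -3.55),
                       femaleTrip = list(groupSize = 3, maxDistanceM = 4000,
                                         sinuosity = 0.15,
                                         departWindow = c("07:30", "09:00"),
                                         returnWindow = c("12:30", "15:00")),
                       maleTrip = list(groupSize = 1, maxDistanceM = 8000,
                                       sinuosity = 0.45,
                                       departWindow = c("07:00", "08:30"),
                                       returnWindow = c("14:30", "17:30")),
                       inCampJitterM = 4, pStayInCamp = 0.25,
                       dayStart = "06:45", dayEnd = "19:00",
                       gpsNoiseSdM = 3, gpsNoiseTauS = 120,
                       utcOffsetHours = 3, startDate = "2024-06-03",
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(nIndividuals >= 2, sexRatio >= 0, sexRatio <= 1, nDays >= 1,
            femaleTrip$maxDistanceM > 0, maleTrip$maxDistanceM > 0,
            inCampJitterM >= 0, pStayInCamp >= 0, pStayInCamp <= 1,
            gpsNoiseSdM >= 0,
            clockToSec(dayStart) < clockToSec(dayEnd))
  for (trip in list(femaleTrip, maleTrip))
    stopifnot(clockToSec(trip$departWindow[2]) < clockToSec(trip$returnWindow[1]))
  structure(cfg, class = "bandConfig")
}

# exact OU update, stationary start
ouSeries <- function(n, sigma, tauS, dt = 5) {
  if (n == 0) return(numeric(0))
  if (sigma == 0) return(numeric(n))
  rho <- exp(-dt / tauS)
  innov <- rnorm(n, sd = sigma * sqrt(1 - rho^2))
  x <- numeric(n)
  x[1] <- rnorm(1, sd = sigma)
  for (i in seq_len(n - 1)) x[i + 1] <- rho * x[i] + innov[i]
  x
}

# OU simulated at coarse nodes, linearly interpolated to target times:
# keeps the stationary marginal (to ~2%) while keeping tracks smooth at
# fix scale.
smoothOU <- function(times, sigma, tauS, nodeS) {
  if (sigma == 0) return(numeric(length(times)))
  nodes <- seq(times[1] - nodeS, times[length(times)] + nodeS, by = nodeS)
  approx(nodes, ouSeries(length(nodes), sigma, tauS, nodeS), xout = times)$y
}

# epochs (UTC seconds, multiples of 5) covering one local day's window
dayEpochs <- function(date, dayStart, dayEnd, utcOffsetHours) {
  base <- as.numeric(as.POSIXct(paste(date, "00:00:00"), tz = "UTC")) -
    utcOffsetHours * 3600
  s0 <- ceiling((base + clockToSec(dayStart)) / 5) * 5
  s1 <- floor((base + clockToSec(dayEnd)) / 5) * 5
  seq(s0, s1, by = 5)
}

# smooth closed loop through the origin: a Fourier-perturbed circle
loopPath <- function(radius, nDense = 4000) {
  ks <- 2:5
  amp <- rnorm(length(ks), sd = 0.06 / sqrt(ks))
  phs <- runif(length(ks), 0, 2 * pi)
  rot <- runif(1, 0, 2 * pi)
  theta <- seq(0, 2 * pi, length.out = nDense)
  rho <- radius * (1 + colSums(amp * sin(outer(ks, theta) + phs)))
  pts <- cbind(rho * cos(theta + rot), rho * sin(theta + rot))
  pts <- sweep(pts, 2, pts[1, ])          # loop starts/ends at the origin
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  list(pts = pts, cumlen = c(0, cumsum(seg)), length = sum(seg))
}

loopAt <- function(loop, s) {
  cbind(approx(loop$cumlen, loop$pts[, 1], xout = s, rule = 2,
               ties = "ordered")$y,
        approx(loop$cumlen, loop$pts[, 2], xout = s, rule = 2,
               ties = "ordered")$y)
}

# centroid arc-length-vs-time profile: sleep-site dwell, travel legs at
# constant speed, and foraging/resting stops of 30-60 min at random arc
# positions
arcProfile <- function(totalS, loopLen, speed, nStops) {
  stopDur <- if (nStops > 0) runif(nStops, 1800, 3600) else numeric()
  travelT <- loopLen / speed
  if (travelT >= totalS) {                # no time for stops or dwell
    return(list(Tk = c(0, totalS), Ak = c(0, loopLen)))
  }
  if (travelT + sum(stopDur) > totalS)
    stopDur <- stopDur * (totalS - travelT) / sum(stopDur)
  dwell <- (totalS - travelT - sum(stopDur)) / 2
  stopAt <- sort(runif(nStops, 0.1, 0.9)) * loopLen
  Tk <- c(0, dwell); Ak <- c(0, 0)
  t <- dwell; a <- 0
  for (k in seq_along(stopAt)) {
    t <- t + (stopAt[k] - a) / speed
    Tk <- c(Tk, t, t + stopDur[k]); Ak <- c(Ak, stopAt[k], stopAt[k])
    t <- t + stopDur[k]; a <- stopAt[k]
  }
  Tk <- c(Tk, t + (loopLen - a) / speed, totalS)
  Ak <- c(Ak, loopLen, loopLen)
  list(Tk = Tk, Ak = Ak)
}

.finishDataset <- function(fixDT, demo, communityId, centreLonLat, utcOffsetHours) {
  crs <- utmCRS(utmZone(centreLonLat["lon"]),
                northern = centreLonLat["lat"] >= 0)
  ll <- unprojectPlanar(fixDT$x, fixDT$y, crs)
  fixDT[, `:=`(lon = ll$lon, lat = ll$lat)]
  fixDT[, date := localDate(time, utcOffsetHours)]
  setorder(fixDT, individual_id, time)
  setcolorder(fixDT, c("individual_id", "date", "time", "lon", "lat", "x", "y"))
  new("CommunityDataset", communityId = communityId,
      fixes = as.data.frame(fixDT), demographics = demo, crs = crs,
      utcOffset = utcOffsetHours,
      metadata = list(maxGapS = 300, simulated = TRUE, exclusion_log = list()))
}

gpsNoise <- function(cfg, d, id, nEp) {
  withSeed(childSeed(cfg$seed, "gps", d, id), {
    cbind(ouSeries(nEp, cfg$gpsNoiseSdM, cfg$gpsNoiseTauS),
          ouSeries(nEp, cfg$gpsNoiseSdM, cfg$gpsNoiseTauS))
  })
}

#' Simulate a cohesive troop
#'
#' Per day, a centroid leaves the sleep site, traverses a smooth closed
#' loop at the configured speed with `nForagingStops` milling stops, and
#' returns, dwelling at the sleep site for leftover time; each member's
#' position is the centroid plus an independent smooth mean-reverting 2-D
#' offset with stationary per-axis s.d. `spreadSigmaM`, plus GPS-noise
#' dither. Fixes lie on the 5-s epoch grid.
#'
#' @param config a [troopConfig()].
#' @return a [CommunityDataset-class]; same config + seed is bitwise
#'   reproducible.
#' @export
simulateTroop <- function(config = troopConfig()) {
  stopifnot(inherits(config, "troopConfig"))
  ids <- sprintf("T%02d", seq_len(config$nIndividuals))
  dates <- seq(as.Date(config$startDate), by = 1, length.out = config$nDays)
  crs <- utmCRS(utmZone(config$sleepSite["lon"]),
                northern = config$sleepSite["lat"] >= 0)
  sleepXY <- projectPlanar(config$sleepSite["lon"], config$sleepSite["lat"], crs)
  days <- lapply(seq_along(dates), function(d) {
    ep <- dayEpochs(dates[d], config$dayStart, config$dayEnd,
                    config$utcOffsetHours)
    cen <- withSeed(childSeed(config$seed, "troop-loop", d), {
      loop <- loopPath(config$loopRadiusM)
      prof <- arcProfile(ep[length(ep)] - ep[1], loop$length,
                         config$centroidSpeedMS, config$nForagingStops)
      loopAt(loop, approx(prof$Tk + ep[1], prof$Ak, xout = ep,
                          ties = "ordered")$y)
    })
    perInd <- lapply(ids, function(id) {
      off <- withSeed(childSeed(config$seed, "troop-off", d, id), {
        cbind(smoothOU(ep, config$spreadSigmaM, config$ouRelaxationS,
                       config$offsetNodeS),
              smoothOU(ep, config$spreadSigmaM, config$ouRelaxationS,
                       config$offsetNodeS))
      })
      noise <- gpsNoise(config, d, id, length(ep))
      data.table(individual_id = id, time = ep,
                 x = sleepXY$x + cen[, 1] + off[, 1] + noise[, 1],
                 y = sleepXY$y + cen[, 2] + off[, 2] + noise[, 2])
    })
    rbindlist(perInd)
  })
  demo <- data.frame(individual_id = ids,
                     sex = rep(c("female", "male"), length.out = length(ids)),
                     age = withSeed(childSeed(config$seed, "troop-age"),
                                    round(runif(length(ids), 4, 22), 1)))
  .finishDataset(rbindlist(days), demo, "troop", config$sleepSite,
                 config$utcOffsetHours)
}

# smooth lateral-wander profile, zero at both ends of the trip
lateralProfile <- function(s, sinuosity, extent) {
  ks <- 1:4
  amp <- rnorm(length(ks), sd = 1 / ks)
  w <- colSums(amp * sin(outer(ks * pi, s)))
  extent * sinuosity * w
}

#' Simulate a fission-fusion band
#'
#' Each individual each day either stays in camp (probability
#' `pStayInCamp`), pottering around their own hearth point, or takes an
#' out-and-back trip: a departure time and outbound heading are drawn
#' (females share the heading and path of their trip group, with small
#' individual jitter; males draw independently), the radial distance
#' follows a smooth out-and-back profile and the lateral wander is scaled
#' by the sex's `sinuosity`; the distance from camp is hard-capped at the
#' sex's `maxDistanceM`. Everyone is in camp before departure and after
#' return.
#'
#' @param config a [bandConfig()].
#' @return a [CommunityDataset-class]; same config + seed is bitwise
#'   reproducible.
#' @export
simulateBand <- function(config = bandConfig()) {
  stopifnot(inherits(config, "bandConfig"))
  n <- config$nIndividuals
  nF <- round(config$sexRatio * n)
  ids <- sprintf("B%02d", seq_len(n))
  sexes <- c(rep("female", nF), rep("male", n - nF))
  dates <- seq(as.Date(config$startDate), by = 1, length.out = config$nDays)
  crs <- utmCRS(utmZone(config$camp["lon"]), northern = config$camp["lat"] >= 0)
  campXY <- projectPlanar(config$camp["lon"], config$camp["lat"], crs)
  hearth <- withSeed(childSeed(config$seed, "hearths"), {
    r <- runif(n, 2, 15); a <- runif(n, 0, 2 * pi)
    cbind(r * cos(a), r * sin(a))
  })
  days <- lapply(seq_along(dates), function(d) {
    ep <- dayEpochs(dates[d], config$dayStart, config$dayEnd,
                    config$utcOffsetHours)
    nEp <- length(ep)
    # who trips today, and the female trip groups
    plan <- withSeed(childSeed(config$seed, "plan", d), {
      trips <- rbinom(n, 1, 1 - config$pStayInCamp) == 1
      fIdx <- sample(which(trips & sexes == "female"))
      groups <- if (length(fIdx))
        split(fIdx, ceiling(seq_along(fIdx) / config$femaleTrip$groupSize))
      else list()
      list(trips = trips, groups = c(groups, as.list(which(trips & sexes == "male"))))
    })
    pos <- vector("list", n)
    # baseline: everyone potters around their hearth all day
    for (i in seq_len(n)) {
      jit <- withSeed(childSeed(config$seed, "camp-jitter", d, ids[i]), {
        cbind(smoothOU(ep, config$inCampJitterM, 600, 60),
              smoothOU(ep, config$inCampJitterM, 600, 60))
      })
      pos[[i]] <- cbind(campXY$x + hearth[i, 1] + jit[, 1],
                        campXY$y + hearth[i, 2] + jit[, 2])
    }
    # overlay trips group by group
    for (g in seq_along(plan$groups)) {
      members <- plan$groups[[g]]
      if (!length(members)) next
      trip <- if (sexes[members[1]] == "female") config$femaleTrip else config$maleTrip
      gkey <- paste(sort(ids[members]), collapse = "+")
      path <- withSeed(childSeed(config$seed, "trip", d, gkey), {
        dep <- runif(1, clockToSec(trip$departWindow[1]),
                     clockToSec(trip$departWindow[2]))
        ret <- runif(1, clockToSec(trip$returnWindow[1]),
                     clockToSec(trip$returnWindow[2]))
        heading <- runif(1, 0, 2 * pi)
        extent <- runif(1, 0.55, 0.95) * trip$maxDistanceM
        localS <- localSecOfDay(ep, config$utcOffsetHours)
        onTrip <- localS >= dep & localS <= ret
        s <- (localS[onTrip] - dep) / (ret - dep)
        radial <- extent * sin(pi * s)^0.8
        lateral <- lateralProfile(s, trip$sinuosity, extent)
        u <- c(cos(heading), sin(heading)); v <- c(-u[2], u[1])
        list(onTrip = onTrip,
             dx = radial * u[1] + lateral * v[1],
             dy = radial * u[2] + lateral * v[2])
      })
      for (i in members) {
        mj <- withSeed(childSeed(config$seed, "member-jitter", d, ids[i]), {
          k <- sum(path$onTrip)
          if (length(members) > 1)
            cbind(smoothOU(ep[path$onTrip], 5, 300, 60),
                  smoothOU(ep[path$onTrip], 5, 300, 60))
          else matrix(0, k, 2)
        })
        px <- hearth[i, 1] + path$dx + mj[, 1]
        py <- hearth[i, 2] + path$dy + mj[, 2]
        rr <- sqrt(px^2 + py^2)         # hard cap incl. hearth/member offsets
        sc <- ifelse(rr > trip$maxDistanceM, trip$maxDistanceM / rr, 1)
        pos[[i]][path$onTrip, 1] <- campXY$x + px * sc
        pos[[i]][path$onTrip, 2] <- campXY$y + py * sc
      }
    }
    rbindlist(lapply(seq_len(n), function(i) {
      noise <- gpsNoise(config, d, ids[i], nEp)
      # noise is capped with the trip so the distance-from-camp bound holds
      rel <- cbind(pos[[i]][, 1] - campXY$x + noise[, 1],
                   pos[[i]][, 2] - campXY$y + noise[, 2])
      lim <- if (sexes[i] == "female") config$femaleTrip$maxDistanceM
             else config$maleTrip$maxDistanceM
      rr <- sqrt(rel[, 1]^2 + rel[, 2]^2)
      sc <- ifelse(rr > lim, lim / rr, 1)
      data.table(individual_id = ids[i], time = ep,
                 x = campXY$x + rel[, 1] * sc, y = campXY$y + rel[, 2] * sc)
    }))
  })
  demo <- data.frame(individual_id = ids, sex = sexes,
                     age = withSeed(childSeed(config$seed, "band-age"),
                                    round(runif(n, 16, 60), 1)))
  .finishDataset(rbindlist(days), demo, "band", config$camp,
                 config$utcOffsetHours)
}
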