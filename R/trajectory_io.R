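# Ingestion: fix-table readers, projection, 5-s resampling, day splitting,
# exclusion rules, and the canonical on-disk community store.

#' Read a GPS fix table
#'
#' Reads a CSV of GPS fixes in either the Movebank dialect
#' (`individual-local-identifier` or `tag-local-identifier`, `timestamp`,
#' `location-long`, `location-lat`) or a generic dialect (`individual_id`,
#' `timestamp` ISO-8601, `lon`, `lat`). Timestamps are taken as UTC. Rows
#' with unparseable timestamps or missing coordinates are dropped and
#' counted in the load report attached as `attr(, "load_report")`.
#'
#' @param path CSV file path.
#' @param dialect `"movebank"` or `"generic"`.
#' @return data.table of fixes (`individual_id`, `time`, `lon`, `lat`),
#'   sorted by individual then time, with a `load_report` attribute
#'   (`n_read`, `n_dropped`, `dropped_bad_timestamp`, `dropped_missing_coord`).
#' @export
readFixTable <- function(path, dialect = c("generic", "movebank")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("fix table not found: ", path)
  raw <- fread(path)
  if (nrow(raw) == 0) stop("empty fix table: ", path)
  cols <- if (dialect == "movebank") {
    idCol <- if ("individual-local-identifier" %in% names(raw))
      "individual-local-identifier" else "tag-local-identifier"
    c(id = idCol, ts = "timestamp", lon = "location-long", lat = "location-lat")
  } else {
    c(id = "individual_id", ts = "timestamp", lon = "lon", lat = "lat")
  }
  missing <- setdiff(unname(cols), names(raw))
  if (length(missing))
    stop("fix table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  fx <- data.table(individual_id = as.character(raw[[cols["id"]]]),
                   time = parseTimestamp(as.character(raw[[cols["ts"]]])),
                   lon = as.numeric(raw[[cols["lon"]]]),
                   lat = as.numeric(raw[[cols["lat"]]]))
  badTs <- is.na(fx$time)
  badCoord <- !badTs & (is.na(fx$lon) | is.na(fx$lat))
  keep <- !(badTs | badCoord)
  out <- fx[keep]
  setorder(out, individual_id, time)
  attr(out, "load_report") <- list(n_read = nrow(raw),
                                   n_dropped = sum(!keep),
                                   dropped_bad_timestamp = sum(badTs),
                                   dropped_missing_coord = sum(badCoord))
  out
}

#' Read a demographics table
#'
#' @param path CSV with columns `individual_id`, `sex` (female/male), and
#'   optionally `age` (years).
#' @return data.frame with those columns.
#' @export
readDemographics <- function(path) {
  dm <- fread(path, colClasses = list(character = "individual_id"))
  need <- c("individual_id", "sex")
  if (!all(need %in% names(dm)))
    stop("demographics table must have columns: ", paste(need, collapse = ", "))
  dm[, individual_id := as.character(individual_id)]
  dm[, sex := tolower(as.character(sex))]
  bad <- !dm$sex %in% c("female", "male")
  if (any(bad)) {
    warning(sum(bad), " demographics row(s) with unknown sex kept as NA")
    dm$sex[bad] <- NA_character_
  }
  if (!"age" %in% names(dm)) dm[, age := NA_real_]
  as.data.frame(dm[, .(individual_id, sex, age = as.numeric(age))])
}

#' Project fixes into a planar frame
#'
#' Fills the `x`, `y` columns (metres) of a fix table by transverse-Mercator
#' projection. With `crs = "auto"` the UTM zone containing the centroid of
#' the fixes is used; fixes spanning more than 6 degrees of longitude then
#' trigger a warning (the centroid zone is still used).
#'
#' @param fixes data.table/data.frame with `lon`, `lat`.
#' @param crs `"auto"` or a CRS from [tmercCRS()]/[utmCRS()].
#' @return the fix table with `x`, `y` columns, the chosen CRS attached as
#'   `attr(, "crs")`.
#' @export
projectToPlanar <- function(fixes, crs = "auto") {
  fx <- as.data.table(fixes)
  if (identical(crs, "auto")) {
    if (diff(range(fx$lon)) > 6)
      warning("fixes span more than 6 degrees of longitude; ",
              "using the UTM zone of their centroid")
    crs <- utmCRS(utmZone(mean(fx$lon)), northern = mean(fx$lat) >= 0)
  }
  xy <- projectPlanar(fx$lon, fx$lat, crs)
  fx[, `:=`(x = xy$x, y = xy$y)]
  data.table::setattr(fx, "crs", crs)
  fx
}

#' Resample one individual-day to the 5-second epoch grid
#'
#' Output timestamps are the multiples of 5 s spanned by the input. At each
#' epoch the fix is (a) the input fix at that instant if one exists, else
#' (b) linearly interpolated between the bracketing fixes when the bracket
#' spans at most `maxGapS` seconds, else (c) absent. Duplicate fixes at one
#' epoch keep the first (deterministic, order-stable). Resampling an already
#' resampled track is a no-op (idempotent).
#'
#' @param fixes fixes for ONE individual on one local day: columns `time`,
#'   `lon`, `lat`, and `x`, `y` if already projected.
#' @param maxGapS maximum bracket span (seconds) across which to
#'   interpolate; default 300.
#' @return data.table on the 5-s grid with a `coverage_hours` attribute.
#' @export
resample5s <- function(fixes, maxGapS = 300) {
  fx <- as.data.table(fixes)
  stopifnot(nrow(fx) >= 2)
  setorder(fx, time)
  nDup <- sum(duplicated(fx$time))
  fx <- fx[!duplicated(fx$time)]
  if (nrow(fx) < 2 || diff(range(fx$time)) == 0)
    stop("degenerate trajectory: all fixes at one instant")
  epochs <- seq(ceiling(fx$time[1] / 5) * 5, floor(fx$time[nrow(fx)] / 5) * 5,
                by = 5)
  idx <- findInterval(epochs, fx$time)
  exact <- fx$time[idx] == epochs
  lo <- idx; hi <- pmin(idx + 1L, nrow(fx))
  span <- fx$time[hi] - fx$time[lo]
  ok <- exact | (span > 0 & span <= maxGapS)
  epochs <- epochs[ok]; lo <- lo[ok]; hi <- hi[ok]
  exact <- exact[ok]; span <- span[ok]
  w <- ifelse(exact, 0, (epochs - fx$time[lo]) / ifelse(span == 0, 1, span))
  interp <- function(col) fx[[col]][lo] * (1 - w) + fx[[col]][hi] * w
  out <- data.table(time = epochs, lon = interp("lon"), lat = interp("lat"))
  if (all(c("x", "y") %in% names(fx)))
    out[, `:=`(x = interp("x"), y = interp("y"))]
  keepCols <- setdiff(names(fx), names(out))
  for (cl in intersect(keepCols, c("individual_id", "date")))
    out[[cl]] <- fx[[cl]][1]
  attr(out, "coverage_hours") <- nrow(out) * 5 / 3600
  attr(out, "n_duplicate_fixes_dropped") <- nDup
  out[]
}

#' Assemble a CommunityDataset from raw fixes
#'
#' The canonical ingestion path: project (if needed), split into local
#' calendar days at the configured fixed UTC offset, resample each
#' individual-day to the 5-s epoch grid, and attach demographics.
#' Individuals without a demographics row are flagged and excluded (with a
#' warning), mirroring standard practice for tracks lacking metadata.
#'
#' @param fixes fix table from [readFixTable()] (or equivalent).
#' @param demographics data.frame (`individual_id`, `sex`, `age`) or `NULL`
#'   to skip the demographics check (sex-partition analyses then refuse to
#'   run).
#' @param communityId label for the community.
#' @param crs `"auto"` or a [tmercCRS()] descriptor.
#' @param utcOffsetHours fixed UTC offset for local day/hour views
#'   (default +3, East Africa Time).
#' @param maxGapS resampling interpolation bound, seconds.
#' @param minFixesPerDay individual-days with fewer raw fixes are dropped
#'   (default 2: a day needs at least two instants to define motion).
#' @return a [CommunityDataset-class].
#' @export
communityDataset <- function(fixes, demographics = NULL,
                             communityId = "community", crs = "auto",
                             utcOffsetHours = 3, maxGapS = 300,
                             minFixesPerDay = 2) {
  fx <- as.data.table(fixes)
  loadReport <- attr(fixes, "load_report")
  if (!all(c("x", "y") %in% names(fx))) {
    fx <- projectToPlanar(fx, crs)
    crs <- attr(fx, "crs")
  } else if (identical(crs, "auto")) {
    crs <- utmCRS(utmZone(mean(fx$lon)), northern = mean(fx$lat) >= 0)
  }
  fx[, date := localDate(time, utcOffsetHours)]
  noDemo <- character()
  if (!is.null(demographics)) {
    noDemo <- setdiff(unique(fx$individual_id), demographics$individual_id)
    if (length(noDemo)) {
      warning("excluding individual(s) without demographics: ",
              paste(noDemo, collapse = ", "))
      fx <- fx[!fx$individual_id %in% noDemo]
    }
  } else {
    demographics <- data.frame(individual_id = character(),
                               sex = character(), age = numeric())
  }
  parts <- split(fx, by = c("individual_id", "date"), drop = TRUE)
  resampled <- lapply(parts, function(p) {
    if (nrow(p) < minFixesPerDay || diff(range(p$time)) == 0) return(NULL)
    resample5s(p, maxGapS = maxGapS)
  })
  res <- rbindlist(resampled[!vapply(resampled, is.null, TRUE)],
                   use.names = TRUE)
  if (nrow(res) == 0) stop("no usable individual-days after resampling")
  setorder(res, individual_id, time)
  setcolorder(res, c("individual_id", "date", "time", "lon", "lat", "x", "y"))
  new("CommunityDataset", communityId = communityId,
      fixes = as.data.frame(res),
      demographics = as.data.frame(demographics), crs = crs,
      utcOffset = utcOffsetHours,
      metadata = list(maxGapS = maxGapS,
                      load_report = loadReport,
                      excluded_no_demographics = noDemo,
                      exclusion_log = list()))
}

#' Read exclusion rules
#'
#' Plain-text config, one rule per line: `id,reason` (all days) or
#' `id,YYYY-MM-DD,reason` (that day only). Blank lines and `#` comments are
#' ignored. The defaults used for the Mpala olive-baboon Movebank release
#' ship with the package:
#' `system.file("extdata", "mpala_exclusions.txt", package = "sociospat")`.
#'
#' @param path config file path.
#' @return data.frame with `individual_id`, `date` (NA = all days), `reason`.
#' @export
readExclusionRules <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(lines, function(ln) {
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed exclusion rule: ", ln)
    maybeDate <- if (length(parts) >= 3)
      tryCatch(as.Date(trimws(parts[2])), error = function(e) as.Date(NA))
    else as.Date(NA)
    if (length(parts) >= 3 && !is.na(maybeDate)) {
      data.frame(individual_id = trimws(parts[1]), date = maybeDate,
                 reason = trimws(paste(parts[-(1:2)], collapse = ",")))
    } else {
      data.frame(individual_id = trimws(parts[1]), date = as.Date(NA),
                 reason = trimws(paste(parts[-1], collapse = ",")))
    }
  })
  do.call(rbind, rows)
}

#' Apply exclusion rules to a dataset
#'
#' Removes whole individuals (rule without a date) or single individual-days
#' (rule with a date). Every removal is recorded, with its reason, in the
#' exclusion log (`datasetMetadata(x)$exclusion_log`). A rule naming an
#' unknown individual warns but does not error.
#'
#' @param dataset a [CommunityDataset-class].
#' @param rules data.frame from [readExclusionRules()], or a path to one.
#' @return the filtered [CommunityDataset-class].
#' @export
applyExclusions <- function(dataset, rules) {
  if (is.character(rules)) rules <- readExclusionRules(rules)
  fx <- fixTable(dataset)
  log <- datasetMetadata(dataset)$exclusion_log %||% list()
  for (k in seq_len(nrow(rules))) {
    id <- rules$individual_id[k]; day <- rules$date[k]
    if (!id %in% fx$individual_id) {
      warning("exclusion rule for unknown individual: ", id)
      next
    }
    drop <- fx$individual_id == id & (is.na(day) | fx$date == day)
    if (any(drop)) {
      log[[length(log) + 1]] <- list(
        individual_id = id,
        date = if (is.na(day)) "all" else format(day),
        n_fixes_removed = sum(drop), reason = rules$reason[k])
      fx <- fx[!drop]
    }
  }
  if (nrow(fx) == 0) stop("all fixes excluded")
  md <- datasetMetadata(dataset)
  md$exclusion_log <- log
  initialize(dataset, fixes = as.data.frame(fx), metadata = md)
}

#' Path to the shipped Mpala exclusion defaults
#' @return file path of the packaged exclusion config.
#' @export
mpalaExclusions <- function() {
  system.file("extdata", "mpala_exclusions.txt", package = "sociospat",
              mustWork = TRUE)
}

#' Write / read the canonical community store
#'
#' `writeCommunity()` writes a per-community directory: `fixes.csv`
#' (generic dialect plus projected x/y), `demographics.csv`, and a
#' `community.json` sidecar recording the CRS, UTC offset, resampling
#' parameters, exclusion log and package version. `readCommunity()` restores
#' the dataset without re-reading raw files.
#'
#' @param dataset a [CommunityDataset-class].
#' @param dir output directory (created if needed).
#' @return `writeCommunity`: the directory, invisibly.
#' @export
writeCommunity <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- fixTable(dataset)
  out <- data.table(individual_id = fx$individual_id,
                    timestamp = formatUTC(fx$time),
                    lon = fx$lon, lat = fx$lat, x = fx$x, y = fx$y)
  fwrite(out, file.path(dir, "fixes.csv"))
  fwrite(as.data.table(demographics(dataset)),
         file.path(dir, "demographics.csv"))
  crs <- crsDescriptor(dataset)
  sidecar <- list(community_id = communityId(dataset),
                  crs = unclass(crs),
                  utc_offset_hours = utcOffset(dataset),
                  resampling = list(epoch_s = 5,
                                    max_gap_s = datasetMetadata(dataset)$maxGapS),
                  exclusion_log = datasetMetadata(dataset)$exclusion_log,
                  package_version = as.character(packageVersion("sociospat")))
  jsonlite::write_json(sidecar, file.path(dir, "community.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname writeCommunity
#' @return `readCommunity`: the restored [CommunityDataset-class].
#' @export
readCommunity <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "community.json"))
  fx <- fread(file.path(dir, "fixes.csv"),
              colClasses = list(character = "individual_id"))
  fx[, time := parseTimestamp(timestamp)]
  fx[, timestamp := NULL]
  fx[, date := localDate(time, sidecar$utc_offset_hours)]
  setcolorder(fx, c("individual_id", "date", "time", "lon", "lat", "x", "y"))
  dmPath <- file.path(dir, "demographics.csv")
  dm <- if (file.exists(dmPath)) readDemographics(dmPath) else
    data.frame(individual_id = character(), sex = character(), age = numeric())
  crs <- tmercCRS(lon0 = sidecar$crs$lon0, k0 = sidecar$crs$k0,
                  falseEasting = sidecar$crs$falseEasting,
                  falseNorthing = sidecar$crs$falseNorthing,
                  name = sidecar$crs$name)
  new("CommunityDataset", communityId = sidecar$community_id,
      fixes = as.data.frame(fx), demographics = dm, crs = crs,
      utcOffset = as.numeric(sidecar$utc_offset_hours),
      metadata = list(maxGapS = sidecar$resampling$max_gap_s %||% 300,
                      exclusion_log = sidecar$exclusion_log %||% list()))
}
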