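# Per-individual-day travel metrics and the community-level radial
# time-at-distance profile.

#' Day metrics for one trajectory
#'
#' Day range (sum of planar step lengths between consecutive present
#' epochs; a recording gap contributes the single straight step between the
#' fixes flanking it), start-end displacement, and maximum distance from the
#' day's first fix. Computed on the 5-s resampled track without smoothing
#' (high-frequency tracks therefore read somewhat long relative to coarse
#' sampling); `medianFilterK` applies an optional odd-width running-median
#' filter to each coordinate first (default off).
#'
#' @param traj one individual-day's fixes ([trajectory()]).
#' @param medianFilterK odd window width for an optional median filter on
#'   x/y before the metrics; 1 (default) disables it.
#' @return data.frame `individual_id`, `date`, `day_range_km`,
#'   `start_end_m`, `max_from_start_m`, `coverage_hours`, `degenerate`.
#' @export
dayMetricsOne <- function(traj, medianFilterK = 1) {
  dt <- as.data.table(traj)
  setorder(dt, time)
  x <- dt$x; y <- dt$y
  if (medianFilterK > 1 && nrow(dt) > medianFilterK) {
    x <- stats::runmed(x, medianFilterK, endrule = "keep")
    y <- stats::runmed(y, medianFilterK, endrule = "keep")
  }
  n <- length(x)
  degenerate <- n < 2
  dr <- if (degenerate) 0 else sum(sqrt(diff(x)^2 + diff(y)^2))
  fromStart <- sqrt((x - x[1])^2 + (y - y[1])^2)
  data.frame(individual_id = dt$individual_id[1] %||% NA_character_,
             date = dt$date[1],
             day_range_km = dr / 1000,
             start_end_m = if (degenerate) 0 else fromStart[n],
             max_from_start_m = if (degenerate) 0 else max(fromStart),
             coverage_hours = n * 5 / 3600,
             degenerate = degenerate)
}

#' Day metrics for every individual-day of a community
#'
#' @param dataset a [CommunityDataset-class].
#' @param medianFilterK see [dayMetricsOne()].
#' @return data.frame, one row per individual-day.
#' @export
dayMetrics <- function(dataset, medianFilterK = 1) {
  fx <- fixTable(dataset)
  parts <- split(fx, by = c("individual_id", "date"), drop = TRUE)
  out <- rbindlist(lapply(parts, dayMetricsOne, medianFilterK = medianFilterK))
  setorder(out, individual_id, date)
  as.data.frame(out)
}

#' Radial time profile: distance from each day's starting point
#'
#' Pools, over all individual-days, the per-epoch planar distance from that
#' day's first fix, and reports the radius containing each requested
#' fraction of total recorded time (the q-quantile of the pooled, hence
#' time-weighted, distribution; level 1 gives the maximum).
#'
#' @param dataset a [CommunityDataset-class].
#' @param levels time fractions.
#' @return list with `radii_m` (named by level), `n_epochs`, and the pooled
#'   distances invisibly omitted.
#' @export
radialTimeProfile <- function(dataset, levels = c(0.25, 0.5, 0.75, 1)) {
  fx <- fixTable(dataset)
  setorder(fx, individual_id, date, time)
  fx[, from_start_m := sqrt((x - x[1])^2 + (y - y[1])^2),
     by = .(individual_id, date)]
  d <- fx$from_start_m
  radii <- vapply(levels, function(q)
    if (q >= 1) max(d) else quantile(d, q, type = 7, names = FALSE), 0)
  names(radii) <- sprintf("%g", levels)
  list(radii_m = radii, n_epochs = length(d))
}
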