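# Synchronized dyadic proximity: per-epoch distances for every possible
# dyad, pooled summaries (streamable accumulator), hourly quantile profiles.

#' Dyadic inter-individual distances every 5 s
#'
#' For every unordered pair of individuals present on a date, the planar
#' Euclidean distance at each epoch where both have a fix (and only those
#' epochs). Dyads with no shared epochs yield no rows and are recorded in
#' the `empty_dyads` attribute.
#'
#' @param dataset a [CommunityDataset-class].
#' @param date one local day, or `NULL` (default) for all days pooled.
#' @return data.table with columns `individual_i`, `individual_j`
#'   (`i < j` in stable sort order), `date`, `time`, `distance_m`.
#' @export
dyadDistances <- function(dataset, date = NULL) {
  fx <- fixTable(dataset)
  days <- if (is.null(date)) observationDates(dataset) else as.Date(date)
  empty <- list()
  out <- lapply(days, function(day) {
    sub <- fx[fx$date == day]
    ids <- sort(unique(sub$individual_id))
    if (length(ids) < 2) return(NULL)
    byId <- split(sub, sub$individual_id)
    pairs <- utils::combn(ids, 2)
    series <- lapply(seq_len(ncol(pairs)), function(p) {
      a <- byId[[pairs[1, p]]]; b <- byId[[pairs[2, p]]]
      m <- match(a$time, b$time)
      ok <- !is.na(m)
      if (!any(ok)) {
        empty[[length(empty) + 1]] <<- c(pairs[, p], format(day))
        return(NULL)
      }
      data.table(individual_i = pairs[1, p], individual_j = pairs[2, p],
                 date = day, time = a$time[ok],
                 distance_m = sqrt((a$x[ok] - b$x[m[ok]])^2 +
                                     (a$y[ok] - b$y[m[ok]])^2))
    })
    rbindlist(series[!vapply(series, is.null, TRUE)])
  })
  res <- rbindlist(out[!vapply(out, is.null, TRUE)])
  attr(res, "empty_dyads") <- empty
  res
}

#' Streaming proximity accumulator
#'
#' A mergeable accumulator for pooled dyad-distance summaries that never
#' needs all samples in memory: exact running moments and max, and a
#' fixed-width histogram (default 0.1 m bins) for the median. Below
#' `exactLimit` samples the raw values are kept and the median is exact;
#' beyond it the histogram median is used (exact to one bin width).
#'
#' @param binWidthM histogram bin width, metres.
#' @param exactLimit sample count up to which raw values are retained.
#' @return an accumulator object (environment); feed with
#'   [accumulateDistances()], merge with [mergeAccumulators()], summarize
#'   with [proximitySummary()].
#' @export
proximityAccumulator <- function(binWidthM = 0.1, exactLimit = 1e6) {
  acc <- new.env(parent = emptyenv())
  acc$n <- 0; acc$sum <- 0; acc$sumsq <- 0; acc$max <- -Inf
  acc$binWidth <- binWidthM; acc$exactLimit <- exactLimit
  acc$values <- numeric()           # kept while n <= exactLimit
  acc$counts <- integer()           # histogram, bin k = [k*w, (k+1)*w)
  class(acc) <- "proximityAccumulator"
  acc
}

#' @param acc a [proximityAccumulator()].
#' @param d numeric vector of distances (metres).
#' @rdname proximityAccumulator
#' @export
accumulateDistances <- function(acc, d) {
  d <- d[is.finite(d)]
  if (!length(d)) return(invisible(acc))
  acc$n <- acc$n + length(d)
  acc$sum <- acc$sum + sum(d)
  acc$sumsq <- acc$sumsq + sum(d^2)
  acc$max <- max(acc$max, max(d))
  bins <- floor(d / acc$binWidth)
  top <- max(bins) + 1
  if (length(acc$counts) < top)
    acc$counts <- c(acc$counts, integer(top - length(acc$counts)))
  tb <- tabulate(bins + 1L, nbins = top)
  acc$counts[seq_len(top)] <- acc$counts[seq_len(top)] + tb
  if (length(acc$values) + length(d) <= acc$exactLimit)
    acc$values <- c(acc$values, d)
  else acc$values <- NULL
  invisible(acc)
}

#' @param a,b accumulators to merge (same bin width).
#' @rdname proximityAccumulator
#' @export
mergeAccumulators <- function(a, b) {
  stopifnot(a$binWidth == b$binWidth)
  out <- proximityAccumulator(a$binWidth, a$exactLimit)
  out$n <- a$n + b$n; out$sum <- a$sum + b$sum
  out$sumsq <- a$sumsq + b$sumsq; out$max <- max(a$max, b$max)
  nb <- max(length(a$counts), length(b$counts))
  pad <- function(v) c(v, integer(nb - length(v)))
  out$counts <- pad(a$counts) + pad(b$counts)
  if (!is.null(a$values) && !is.null(b$values) &&
      length(a$values) + length(b$values) <= out$exactLimit)
    out$values <- c(a$values, b$values)
  else out$values <- NULL
  out
}

accMedian <- function(acc) {
  if (!is.null(acc$values)) return(median(acc$values))
  cum <- cumsum(acc$counts)
  k <- which(cum >= acc$n / 2)[1]
  (k - 0.5) * acc$binWidth      # bin midpoint; exact to binWidth
}

#' Pooled proximity summary
#'
#' Mean, median, s.d. and max of dyadic distances pooled over all dyads and
#' epochs (not per-dyad means of means), with the pooled sample count.
#'
#' @param x a dyad-distance table from [dyadDistances()], a numeric vector
#'   of distances, or a [proximityAccumulator()].
#' @return data.frame with `n_samples`, `mean_m`, `median_m`, `sd_m`, `max_m`.
#' @export
proximitySummary <- function(x) {
  acc <- if (inherits(x, "proximityAccumulator")) x else {
    d <- if (is.numeric(x)) x else x$distance_m
    if (!length(d)) stop("no distance samples to summarize")
    accumulateDistances(proximityAccumulator(), d)
  }
  if (acc$n == 0) stop("no distance samples to summarize")
  data.frame(n_samples = acc$n,
             mean_m = acc$sum / acc$n,
             median_m = accMedian(acc),
             sd_m = if (acc$n > 1)
               sqrt(max(0, (acc$sumsq - acc$sum^2 / acc$n) / (acc$n - 1)))
             else NA_real_,
             max_m = acc$max)
}

#' Hourly quantiles of dyadic distance
#'
#' Each dyad-epoch sample is assigned to the local hour containing its epoch
#' (hour 7 covers 07:00:00-07:59:59); quantiles are computed per hour at the
#' requested levels using the standard linear-interpolation (type-7)
#' definition. Hours with no samples are absent from the output.
#'
#' @param distances a table from [dyadDistances()].
#' @param levels quantile levels.
#' @param utcOffsetHours fixed UTC offset defining local hours.
#' @return data.table `hour`, `level`, `value_m`, `n_samples` (per hour).
#' @export
hourlyQuantiles <- function(distances, levels = c(0.05, 0.25, 0.5, 0.75, 0.95),
                            utcOffsetHours = 3) {
  stopifnot(nrow(distances) > 0)
  dt <- as.data.table(distances)
  dt[, hour := localHour(time, utcOffsetHours)]
  out <- dt[, {
    q <- quantile(distance_m, probs = levels, type = 7, names = FALSE)
    list(level = levels, value_m = q, n_samples = .N)
  }, by = hour]
  setorder(out, hour, level)
  out[]
}
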