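# Optional reporting plots (ggplot2 is in Suggests; all analysis surfaces
# are tabular, plots are conveniences).

#' Plot hourly dyadic-distance quantile profiles
#'
#' One ribbon/line panel of distance quantiles by local hour, the standard
#' way to show daily fission-fusion structure (flat for a cohesive troop,
#' midday-peaked for a dispersing band).
#'
#' @param hq output of [hourlyQuantiles()].
#' @return a ggplot object.
#' @export
plotHourlyQuantiles <- function(hq) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotHourlyQuantiles needs ggplot2")
  hq <- as.data.frame(hq)
  hq$level <- factor(hq$level)
  ggplot2::ggplot(hq, ggplot2::aes(x = hour, y = value_m,
                                   colour = level, group = level)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "local hour", y = "dyadic distance (m)",
                  colour = "quantile") +
    ggplot2::theme_minimal()
}

#' Plot day paths of a community on one date
#'
#' @param dataset a [CommunityDataset-class].
#' @param date local day to draw.
#' @param thinMinutes plot-only thinning interval in minutes (default 0 =
#'   no thinning); computation elsewhere never thins.
#' @return a ggplot object.
#' @export
plotDayPaths <- function(dataset, date, thinMinutes = 0) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotDayPaths needs ggplot2")
  day <- as.Date(date)
  fx <- fixTable(dataset)
  fx <- fx[fx$date == day]
  if (thinMinutes > 0) fx <- fx[fx$time %% (thinMinutes * 60) == 0]
  ggplot2::ggplot(as.data.frame(fx),
                  ggplot2::aes(x = x, y = y, colour = individual_id)) +
    ggplot2::geom_path(alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)", colour = NULL,
                  title = paste(communityId(dataset), format(day))) +
    ggplot2::theme_minimal()
}
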