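#' @import methods
#' @importFrom data.table data.table as.data.table setDT setkey := .N .SD setorder rbindlist fwrite fread copy setnames setcolorder
#' @importFrom stats quantile rnorm runif sd median approx rbinom
#' @importFrom utils head tail packageVersion
#' @useDynLib sociospat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setOldClass("sociospatCRS")

#' GridSpec: the raster grid shared by a comparison
#'
#' Describes the square grid onto which day paths are rasterized: an origin
#' (cell boundaries fall at `origin + k * cellSizeM`), a cell edge length in
#' metres (default 10 m, i.e. 100 m^2 cells), and the planar CRS the grid
#' lives in. Every raster entering a dyadic or group-level comparison must
#' share one GridSpec.
#'
#' @slot originX,originY grid origin in metres (projected frame).
#' @slot cellSizeM cell edge length in metres.
#' @slot crsName name of the planar CRS the grid coordinates refer to.
#' @export
setClass("GridSpec",
         representation(originX = "numeric", originY = "numeric",
                        cellSizeM = "numeric", crsName = "character"),
         prototype(originX = 0, originY = 0, cellSizeM = 10,
                   crsName = "unspecified"))

setValidity("GridSpec", function(object) {
  if (length(object@cellSizeM) != 1 || !is.finite(object@cellSizeM) ||
      object@cellSizeM <= 0)
    return("cellSizeM must be a single positive number")
  if (!is.finite(object@originX) || !is.finite(object@originY))
    return("grid origin must be finite")
  TRUE
})

#' Construct a GridSpec
#'
#' @param cellSizeM cell edge length in metres. The default 10 m reads the
#'   field's "10 m^2 cell" convention as a side length (100 m^2 area); pass
#'   `sqrt(10)` to explore the literal-area reading.
#' @param originX,originY grid anchor in metres; the default (0,0) anchors
#'   cell boundaries at integer multiples of the cell size in the projected
#'   CRS, making cell sets machine-independent. Use [snapGridToData()] for a
#'   data-anchored grid in sensitivity analyses.
#' @param crsName name of the planar CRS (informational; compared for
#'   equality when rasters are combined).
#' @return a [GridSpec-class] object.
#' @export
gridSpec <- function(cellSizeM = 10, originX = 0, originY = 0,
                     crsName = "unspecified") {
  new("GridSpec", originX = originX, originY = originY,
      cellSizeM = cellSizeM, crsName = crsName)
}

#' @param dataset a [CommunityDataset-class]; the grid origin is snapped to
#'   the lower-left corner of its bounding box.
#' @rdname gridSpec
#' @export
snapGridToData <- function(dataset, cellSizeM = 10) {
  fx <- fixTable(dataset)
  gridSpec(cellSizeM = cellSizeM,
           originX = floor(min(fx$x) / cellSizeM) * cellSizeM,
           originY = floor(min(fx$y) / cellSizeM) * cellSizeM,
           crsName = crsDescriptor(dataset)$name)
}

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %g m cells, origin (%g, %g), CRS %s\n",
              object@cellSizeM, object@originX, object@originY,
              object@crsName))
})

#' VisitationRaster: cells touched by one individual-day path
#'
#' The set of grid cells intersected by one individual's path of travel on
#' one day, stored as packed integer cell keys (decode with [rasterCells()]).
#'
#' @slot individualId individual identifier.
#' @slot date the local calendar day.
#' @slot cells numeric vector of packed (col,row) cell keys, sorted, unique.
#' @slot grid the [GridSpec-class] the cells index into.
#' @export
setClass("VisitationRaster",
         representation(individualId = "character", date = "Date",
                        cells = "numeric", grid = "GridSpec"))

setValidity("VisitationRaster", function(object) {
  if (anyDuplicated(object@cells)) return("cell keys must be unique")
  if (is.unsorted(object@cells)) return("cell keys must be sorted")
  TRUE
})

setMethod("show", "VisitationRaster", function(object) {
  cat(sprintf("VisitationRaster: %s on %s, %d cells of %g m\n",
              object@individualId, format(object@date),
              length(object@cells), object@grid@cellSizeM))
})

#' @param x a VisitationRaster.
#' @return `rasterCells`: data.frame of integer `col`, `row` cell indices.
#' @rdname VisitationRaster-class
#' @export
rasterCells <- function(x) decodeCells(x@cells)

#' CommunityDataset: all trajectories of one community
#'
#' The canonical container every analysis stage consumes: the resampled
#' trajectories of one community (camp or troop) on the uniform 5-second
#' epoch grid, their demographics, the planar CRS, and processing metadata.
#' Build one with [communityDataset()] or the simulators
#' ([simulateTroop()], [simulateBand()]).
#'
#' @slot communityId community label.
#' @slot fixes data.frame with columns `individual_id`, `date` (local day),
#'   `time` (numeric seconds since the UNIX epoch, UTC, multiples of 5),
#'   `lon`, `lat`, `x`, `y`.
#' @slot demographics data.frame with `individual_id`, `sex`
#'   (`"female"`/`"male"`), `age`.
#' @slot crs the planar CRS descriptor ([tmercCRS()]).
#' @slot utcOffset fixed UTC offset (hours) used for local days and hours.
#' @slot metadata list: resampling parameters, load report, exclusion log.
#' @export
setClass("CommunityDataset",
         representation(communityId = "character", fixes = "data.frame",
                        demographics = "data.frame", crs = "sociospatCRS",
                        utcOffset = "numeric", metadata = "list"))

setValidity("CommunityDataset", function(object) {
  fx <- object@fixes
  need <- c("individual_id", "date", "time", "lon", "lat", "x", "y")
  if (!all(need %in% names(fx)))
    return(paste("fixes must have columns:", paste(need, collapse = ", ")))
  if (nrow(fx)) {
    if (any(fx$time %% 5 != 0))
      return("fix times must lie on the 5-second epoch grid")
    if (!all(is.finite(fx$x)) || !all(is.finite(fx$y)))
      return("projected coordinates must be finite")
    if (anyDuplicated(fx[, c("individual_id", "time")]))
      return("duplicate (individual_id, time) fixes")
  }
  dm <- object@demographics
  if (!all(c("individual_id", "sex") %in% names(dm)))
    return("demographics must have individual_id and sex columns")
  if (anyDuplicated(dm$individual_id))
    return("demographics must have one row per individual")
  if (length(object@utcOffset) != 1 || !is.finite(object@utcOffset))
    return("utcOffset must be a single finite number")
  TRUE
})

setMethod("show", "CommunityDataset", function(object) {
  fx <- object@fixes
  cat(sprintf("CommunityDataset '%s': %d individuals, %d days, %d fixes\n",
              object@communityId, length(unique(fx$individual_id)),
              length(unique(fx$date)), nrow(fx)))
  cat("  CRS:", object@crs$name,
      sprintf("| UTC offset %+g h | 5-s epoch grid\n", object@utcOffset))
})

#' @param x a [CommunityDataset-class].
#' @rdname CommunityDataset-class
#' @export
communityId <- function(x) x@communityId

#' @return `fixTable`: the fix table as a data.table (copy).
#' @rdname CommunityDataset-class
#' @export
fixTable <- function(x) as.data.table(x@fixes)

#' @rdname CommunityDataset-class
#' @export
demographics <- function(x) x@demographics

#' @rdname CommunityDataset-class
#' @export
crsDescriptor <- function(x) x@crs

#' @rdname CommunityDataset-class
#' @export
utcOffset <- function(x) x@utcOffset

#' @rdname CommunityDataset-class
#' @export
datasetMetadata <- function(x) x@metadata

#' @rdname CommunityDataset-class
#' @export
individuals <- function(x) sort(unique(x@fixes$individual_id))

#' @rdname CommunityDataset-class
#' @export
observationDates <- function(x) sort(unique(x@fixes$date))

#' Extract one individual-day trajectory
#'
#' @param x a [CommunityDataset-class].
#' @param id individual identifier.
#' @param date local calendar day (coerced with [as.Date()]).
#' @return data.table of that individual-day's fixes, time-ordered, with a
#'   `coverage_hours` attribute (epochs present x 5 / 3600).
#' @export
trajectory <- function(x, id, date) {
  day <- as.Date(date)
  fx <- fixTable(x)
  fx <- fx[fx$individual_id == id & fx$date == day]
  setorder(fx, time)
  attr(fx, "coverage_hours") <- nrow(fx) * 5 / 3600
  fx[]
}
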