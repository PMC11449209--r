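# Rasterized landscape visitation: per-individual-day cell sets, dyadic
# shared/different overlap fractions, cumulative exploration curves and the
# sex partition of the visited landscape.

#' Rasterize one individual-day path
#'
#' The visitation raster is the set of grid cells containing any point of
#' the day's path: every cell containing a fix, plus every cell crossed by
#' the straight segment between consecutive present epochs. Epoch gaps
#' longer than the resampling `maxGapS` are not bridged (only the flanking
#' fixes' own cells register). With `mode = "points"` only cells containing
#' fixes register (for sensitivity to the point-rasterization reading).
#'
#' @param traj one individual-day's fixes ([trajectory()]), projected into
#'   the grid's CRS.
#' @param grid a [gridSpec()].
#' @param mode `"path"` (default) or `"points"`.
#' @param maxGapS gap length (seconds) beyond which consecutive fixes are
#'   not joined; default 300, matching the resampling default.
#' @return a [VisitationRaster-class].
#' @export
rasterizeDay <- function(traj, grid = gridSpec(), mode = c("path", "points"),
                         maxGapS = 300) {
  mode <- match.arg(mode)
  dt <- as.data.table(traj)
  stopifnot(nrow(dt) >= 1)
  setorder(dt, time)
  bridge <- if (nrow(dt) > 1 && mode == "path")
    diff(dt$time) <= maxGapS else rep(FALSE, max(nrow(dt) - 1, 0))
  keys <- .supercoverKeys(dt$x, dt$y, bridge,
                          grid@originX, grid@originY, grid@cellSizeM)
  new("VisitationRaster",
      individualId = as.character(dt$individual_id[1] %||% "unknown"),
      date = as.Date(dt$date[1] %||% NA), cells = keys, grid = grid)
}

#' Visitation rasters for every individual-day
#'
#' @param dataset a [CommunityDataset-class].
#' @inheritParams rasterizeDay
#' @return data.table with one row per visited cell: `individual_id`,
#'   `date`, `cell` (packed key). Decode keys with [decodeCellKeys()].
#' @export
visitationTable <- function(dataset, grid = gridSpec(),
                            mode = c("path", "points"),
                            maxGapS = datasetMetadata(dataset)$maxGapS %||% 300) {
  mode <- match.arg(mode)
  fx <- fixTable(dataset)
  parts <- split(fx, by = c("individual_id", "date"), drop = TRUE)
  rbindlist(lapply(parts, function(p) {
    r <- rasterizeDay(p, grid, mode, maxGapS)
    data.table(individual_id = r@individualId, date = r@date, cell = r@cells)
  }))
}

#' @param key packed cell keys (column `cell` of [visitationTable()]).
#' @return `decodeCellKeys`: data.frame of integer `col`, `row`.
#' @rdname visitationTable
#' @export
decodeCellKeys <- function(key) decodeCells(key)

#' Dyadic landscape-visitation overlap
#'
#' Exact set arithmetic on two same-day visitation rasters: `n_b` cells
#' visited only by i, `n_c` only by j, `n_d` by both, `n_e = n_b + n_c +
#' n_d`; `fraction_different = (n_b + n_c) / n_e` and `fraction_similar =
#' n_d / n_e`. Cells visited by neither are never materialized (the
#' landscape is unbounded).
#'
#' @param ri,rj [VisitationRaster-class] objects on the same grid and date.
#' @return one-row data.frame with the counts and fractions.
#' @export
dyadOverlap <- function(ri, rj) {
  if (!identical(ri@grid, rj@grid))
    stop("visitation rasters use different grids")
  nd <- length(intersect(ri@cells, rj@cells))
  nb <- length(ri@cells) - nd
  nc <- length(rj@cells) - nd
  ne <- nb + nc + nd
  data.frame(individual_i = ri@individualId, individual_j = rj@individualId,
             date = ri@date, n_b = nb, n_c = nc, n_d = nd, n_e = ne,
             fraction_similar = nd / ne,
             fraction_different = (nb + nc) / ne)
}

#' Overlap table for every same-day dyad
#'
#' @param dataset a [CommunityDataset-class].
#' @inheritParams rasterizeDay
#' @return data.frame, one row per dyad-day, columns as in [dyadOverlap()]
#'   with `individual_i < individual_j` in stable order.
#' @export
dyadOverlapTable <- function(dataset, grid = gridSpec(),
                             mode = c("path", "points"), maxGapS = 300) {
  mode <- match.arg(mode)
  vt <- visitationTable(dataset, grid, mode, maxGapS)
  out <- lapply(split(vt, by = "date"), function(sub) {
    ids <- sort(unique(sub$individual_id))
    if (length(ids) < 2) return(NULL)
    cellsOf <- lapply(ids, function(id) sub$cell[sub$individual_id == id])
    names(cellsOf) <- ids
    pairs <- utils::combn(ids, 2)
    rbindlist(lapply(seq_len(ncol(pairs)), function(p) {
      ci <- cellsOf[[pairs[1, p]]]; cj <- cellsOf[[pairs[2, p]]]
      nd <- length(intersect(ci, cj))
      nb <- length(ci) - nd; nc <- length(cj) - nd; ne <- nb + nc + nd
      data.table(individual_i = pairs[1, p], individual_j = pairs[2, p],
                 date = sub$date[1], n_b = nb, n_c = nc, n_d = nd, n_e = ne,
                 fraction_similar = nd / ne,
                 fraction_different = (nb + nc) / ne)
    }))
  })
  as.data.frame(rbindlist(out[!vapply(out, is.null, TRUE)]))
}

#' Cumulative group exploration curves
#'
#' For each requested random order of individual IDs (seeded permutations),
#' the cumulative count of unique cells visited after adding the k-th
#' individual's day path, k = 1..N. The final count is the union size and
#' does not depend on the order.
#'
#' @param dataset a [CommunityDataset-class].
#' @param date one local day, or `NULL` for every day.
#' @param orderSeed seed for the permutation(s).
#' @param nOrders number of random orders per day (default 1).
#' @inheritParams rasterizeDay
#' @return data.frame `date`, `order_index`, `k`, `individual_id` (the k-th
#'   added), `cumulative_cells`.
#' @export
explorationCurve <- function(dataset, date = NULL, orderSeed = 42,
                             nOrders = 1, grid = gridSpec(),
                             mode = c("path", "points"), maxGapS = 300) {
  mode <- match.arg(mode)
  vt <- visitationTable(dataset, grid, mode, maxGapS)
  days <- if (is.null(date)) sort(unique(vt$date)) else as.Date(date)
  out <- lapply(days, function(day) {
    sub <- vt[vt$date == day]
    ids <- sort(unique(sub$individual_id))
    cellsOf <- lapply(ids, function(id) sub$cell[sub$individual_id == id])
    names(cellsOf) <- ids
    rbindlist(lapply(seq_len(nOrders), function(o) {
      ord <- withSeed(childSeed(orderSeed, "exploration", format(day), o),
                      sample(ids))
      seen <- unlist(cellsOf[ord], use.names = FALSE)
      newCell <- !duplicated(seen)
      perInd <- rep(seq_along(ord), times = lengths(cellsOf[ord]))
      gained <- tabulate(perInd[newCell], nbins = length(ord))
      data.table(date = day, order_index = o, k = seq_along(ord),
                 individual_id = ord, cumulative_cells = cumsum(gained))
    }))
  })
  as.data.frame(rbindlist(out))
}

#' Sex partition of the visited landscape
#'
#' Unions all male and all female visitation cells across every day of the
#' community, and partitions their combined union into cells visited only
#' by males, only by females, or by both sexes. Individuals with unknown
#' sex are excluded with a warning.
#'
#' @param dataset a [CommunityDataset-class] with demographics.
#' @inheritParams rasterizeDay
#' @return data.frame `community_id`, `n_male_only`, `n_female_only`,
#'   `n_both`, `frac_male_only`, `frac_female_only`, `frac_both`.
#' @export
sexPartition <- function(dataset, grid = gridSpec(),
                         mode = c("path", "points"), maxGapS = 300) {
  mode <- match.arg(mode)
  dm <- demographics(dataset)
  if (nrow(dm) == 0) stop("sexPartition needs demographics")
  vt <- visitationTable(dataset, grid, mode, maxGapS)
  sex <- dm$sex[match(vt$individual_id, dm$individual_id)]
  unknown <- unique(vt$individual_id[is.na(sex)])
  if (length(unknown))
    warning("excluding individual(s) with unknown sex: ",
            paste(unknown, collapse = ", "))
  maleCells <- unique(vt$cell[!is.na(sex) & sex == "male"])
  femaleCells <- unique(vt$cell[!is.na(sex) & sex == "female"])
  both <- length(intersect(maleCells, femaleCells))
  mOnly <- length(maleCells) - both
  fOnly <- length(femaleCells) - both
  tot <- mOnly + fOnly + both
  if (tot == 0) stop("no visited cells with known sex")
  data.frame(community_id = communityId(dataset),
             n_male_only = mOnly, n_female_only = fOnly, n_both = both,
             frac_male_only = mOnly / tot, frac_female_only = fOnly / tot,
             frac_both = both / tot)
}

#' Average sex partitions across communities
#'
#' Unweighted arithmetic mean of the three partition fractions across
#' communities (each community counts equally regardless of its landscape
#' size); re-normalized only if floating-point drift exceeds 1e-9.
#'
#' @param partitions data.frame rbind of [sexPartition()] rows, or a list
#'   of them.
#' @return one-row data.frame `n_communities`, `frac_male_only`,
#'   `frac_female_only`, `frac_both`.
#' @export
averagePartitions <- function(partitions) {
  if (is.list(partitions) && !is.data.frame(partitions))
    partitions <- do.call(rbind, partitions)
  stopifnot(nrow(partitions) >= 1)
  f <- colMeans(partitions[, c("frac_male_only", "frac_female_only",
                               "frac_both")])
  drift <- abs(sum(f) - 1)
  if (drift > 1e-9) f <- f / sum(f)
  data.frame(n_communities = nrow(partitions),
             frac_male_only = f[["frac_male_only"]],
             frac_female_only = f[["frac_female_only"]],
             frac_both = f[["frac_both"]])
}
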