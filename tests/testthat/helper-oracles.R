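# Independent oracles the implementation is validated against.

# Dense point-walker rasterization oracle: sample each segment at `step`
# metre spacing (endpoints included) and collect the cells containing the
# sampled points.
denseWalkCells <- function(xs, ys, grid, step = 0.01) {
  ox <- grid@originX; oy <- grid@originY; cs <- grid@cellSizeM
  keys <- lapply(seq_len(length(xs) - 1), function(i) {
    len <- sqrt((xs[i + 1] - xs[i])^2 + (ys[i + 1] - ys[i])^2)
    tt <- seq(0, 1, length.out = max(2, ceiling(len / step) + 1))
    px <- xs[i] + tt * (xs[i + 1] - xs[i])
    py <- ys[i] + tt * (ys[i + 1] - ys[i])
    sociospat:::encodeCells(floor((px - ox) / cs), floor((py - oy) / cs))
  })
  sort(unique(unlist(keys)))
}

# brute-force pairwise distance recomputation on a fix table
bruteDyadDistances <- function(fx) {
  ids <- sort(unique(fx$individual_id))
  out <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    a <- fx[fx$individual_id == ids[i], ]
    b <- fx[fx$individual_id == ids[j], ]
    common <- intersect(a$time, b$time)
    for (tt in common) {
      pa <- a[a$time == tt, ]; pb <- b[b$time == tt, ]
      out[[length(out) + 1]] <- data.frame(
        individual_i = ids[i], individual_j = ids[j], time = tt,
        distance_m = sqrt((pa$x - pb$x)^2 + (pa$y - pb$y)^2))
    }
  }
  do.call(rbind, out)
}

# Exact segment-vs-cell intersection test (Liang-Barsky clipping + the
# half-open floor convention), used to confirm cells that a finite-step
# walker cannot resolve (clipped for less than one step of arc length).
segmentTouchesCell <- function(x0, y0, x1, y1, col, row, grid) {
  cs <- grid@cellSizeM
  cx <- grid@originX + col * cs; cy <- grid@originY + row * cs
  dx <- x1 - x0; dy <- y1 - y0
  t0 <- 0; t1 <- 1
  p <- c(-dx, dx, -dy, dy)
  q <- c(x0 - cx, cx + cs - x0, y0 - cy, cy + cs - y0)
  for (k in 1:4) {
    if (p[k] == 0) {
      if (q[k] < 0) return(FALSE)
    } else {
      t <- q[k] / p[k]
      if (p[k] < 0) t0 <- max(t0, t) else t1 <- min(t1, t)
    }
  }
  if (t0 > t1) return(FALSE)
  # the closed box is touched; require a point that floors into this cell
  # (half-open convention)
  for (tt in unique(c(t0, (t0 + t1) / 2, t1))) {
    px <- x0 + tt * dx; py <- y0 + tt * dy
    if (floor((px - grid@originX) / cs) == col &&
        floor((py - grid@originY) / cs) == row) return(TRUE)
  }
  FALSE
}

pathTouchesCell <- function(xs, ys, key, grid) {
  cr <- sociospat:::decodeCells(key)
  for (i in seq_len(length(xs) - 1)) {
    if (segmentTouchesCell(xs[i], ys[i], xs[i + 1], ys[i + 1],
                           cr$col, cr$row, grid)) return(TRUE)
  }
  FALSE
}
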