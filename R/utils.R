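# Internal helpers: seeding, local-time arithmetic, cell-key encoding.

# 32-bit FNV-1a over a UTF-8 string, done in two 16-bit halves so every
# intermediate stays below 2^53 (doubles are exact there).
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor64(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
    h <- h %% 4294967296
  }
  h
}

# bitwXor() refuses doubles >= 2^31; split into halves.
bitwXor64 <- function(a, b) {
  alo <- a %% 65536; ahi <- (a - alo) / 65536
  blo <- b %% 65536; bhi <- (b - blo) / 65536
  bitwXor(ahi, bhi) * 65536 + bitwXor(alo, blo)
}

# Stable substream seed: same (seed, tags...) always gives the same value,
# independent of iteration order, and always < 2^31 - 1.
childSeed <- function(seed, ...) {
  tag <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  as.integer(fnv1a32(tag) %% 2147483629)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Times are numeric seconds since the UNIX epoch (UTC). Local views use a
# fixed UTC offset in hours (default +3, East Africa Time).
localSecOfDay <- function(time, utcOffset) (time + utcOffset * 3600) %% 86400

localDate <- function(time, utcOffset) {
  as.Date(floor((time + utcOffset * 3600) / 86400), origin = "1970-01-01")
}

localHour <- function(time, utcOffset) floor(localSecOfDay(time, utcOffset) / 3600)

clockToSec <- function(clock) {
  parts <- as.numeric(strsplit(clock, ":", fixed = TRUE)[[1]])
  if (length(parts) == 2) parts <- c(parts, 0)
  parts[1] * 3600 + parts[2] * 60 + parts[3]
}

formatUTC <- function(time) {
  format(as.POSIXct(time, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%OS3Z")
}

parseTimestamp <- function(x) {
  # Accepts ISO-8601 with "T" or " " separator, optional fractional seconds,
  # optional trailing "Z"; values are taken as UTC. Returns numeric seconds,
  # NA where unparseable.
  x <- sub("Z$", "", sub("T", " ", x, fixed = TRUE))
  out <- suppressWarnings(as.POSIXct(x, tz = "UTC",
                                     tryFormats = c("%Y-%m-%d %H:%M:%OS",
                                                    "%Y-%m-%d %H:%M")))
  as.numeric(out)
}

# Integer (col,row) cell indices packed into one exact double key.
# Supports |index| < 2^25 (more than enough for metre-scale UTM grids).
.cellHalf <- 33554432   # 2^25
.cellBase <- 67108864   # 2^26

encodeCells <- function(col, row) (col + .cellHalf) * .cellBase + (row + .cellHalf)

decodeCells <- function(key) {
  row <- key %% .cellBase - .cellHalf
  col <- (key - (key %% .cellBase)) / .cellBase - .cellHalf
  data.frame(col = col, row = row)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
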