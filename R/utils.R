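# Internal helpers: spherical distance, deterministic counter-based RNG,
# local-clock arithmetic, display rounding.

EARTH_RADIUS_M <- 6371000

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6,371,000 m, the metric used for
#' all geofence containment and report-assignment decisions.
#'
#' @param lat1,lon1 first point, decimal degrees.
#' @param lat2,lon2 second point, decimal degrees.
#' @return distance in meters (vectorised).
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  stopifnot(is.finite(lat1), is.finite(lon1), is.finite(lat2), is.finite(lon2))
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
}

# Counter-based deterministic uniform draw on (0, 1).
#
# Lehmer/Park-Miller generator (Schrage's factorisation) re-seeded from
# (seed, counter) and burnt in for a few steps.  All arithmetic stays below
# 2^31 so it is exact in doubles; independent of R's global RNG state.
counter_unif <- function(seed, counter) {
  m <- 2147483647; a <- 16807; q <- 127773; r <- 2836
  x <- (abs(seed) %% 65536) * 32749 + (abs(counter) %% 65536) * 13007 +
    abs(counter) %/% 65536 + 1
  x <- x %% m
  if (x == 0) x <- 1
  for (i in 1:4) {
    hi <- x %/% q
    lo <- x %% q
    x <- a * lo - r * hi
    if (x <= 0) x <- x + m
  }
  x / m
}

# FNV-1a style hash of a character string, returned as 8 hex digits.
# Used for manifest/parameter fingerprints only (not cryptographic).
fnv1a_hex <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 2^32-modular multiply by 16777619 = 2^24 + 403, exact in doubles
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Minutes past local midnight for a timestamp under tz.
local_minutes <- function(time, tz) {
  lt <- as.POSIXlt(time, tz = tz)
  lt$hour * 60 + lt$min + lt$sec / 60
}

# Local calendar date under tz.
local_date <- function(time, tz) {
  as.Date(format(time, tz = tz, format = "%Y-%m-%d"))
}

# Time-of-day bin index (1..8): 3-hour bins anchored at the active-window
# start so bin 1 covers 08:00-10:59 local by default.
time_bin <- function(time, config) {
  mins <- local_minutes(time, config$tz)
  anchor <- config$active_window[1]
  offset <- (mins - anchor) %% 1440
  as.integer(offset %/% 180) + 1L
}

in_active_window <- function(time, config) {
  mins <- local_minutes(time, config$tz)
  mins >= config$active_window[1] & mins <= config$active_window[2]
}

#' Round half away from zero
#'
#' Display rounding used for report cells (plain `round()` rounds half to
#' even, which does not reproduce printed-table conventions).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_jitai <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "jitai_error")))
}
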