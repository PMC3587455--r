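# Road network: polylines with NOx emissions -> 10 m unit sources.
#
# Coordinates are projected metres (x east, y north). Bearings are degrees
# clockwise from north, folded into [0, 180) since a road axis is undirected.

ROAD_CATEGORIES <- c("open", "typical",
                     "canyon_NS", "canyon_SWNE", "canyon_EW", "canyon_SENW")

# axis bearing represented by each category (deg from north, mod 180);
# open/typical roads have no preferred axis and use 0 by convention
CATEGORY_AXIS <- c(open = 0, typical = 0,
                   canyon_NS = 0, canyon_SWNE = 45,
                   canyon_EW = 90, canyon_SENW = 135)

#' Construct a road link
#'
#' A road link is a polyline carriageway centreline carrying a NOx emission
#' rate (NO2-equivalent mass per km of road per second) and the primary
#' exhaust NO2 fraction of that NOx.
#'
#' @param id link identifier (character)
#' @param xy two-column matrix of vertex coordinates, projected metres
#' @param nox_rate NOx emission rate, g km-1 s-1 (as NO2 mass)
#' @param f_no2 primary exhaust NO2 fraction of NOx (mass basis as NO2),
#'   in [0, 1]
#' @param canyon logical; is the link flanked by a street canyon
#' @param typical logical; for non-canyon links, is the road a "typical"
#'   built-up street (as opposed to an open road such as a motorway)
#' @param canyon_width,canyon_height optional canyon geometry, m
#' @return an object of class `road_link`
#' @export
road_link <- function(id, xy, nox_rate, f_no2, canyon = FALSE,
                      typical = TRUE, canyon_width = 30, canyon_height = 25) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2 || nrow(xy) < 2) {
    stop("link geometry must be a polyline with >= 2 (x, y) vertices")
  }
  seg_len <- sqrt(rowSums(diff(xy)^2))
  if (any(seg_len == 0)) stop("consecutive polyline vertices must be distinct")
  if (nox_rate < 0) stop("nox_rate must be non-negative")
  if (f_no2 < 0 || f_no2 > 1) stop("f_no2 must lie in [0, 1]")
  structure(list(id = as.character(id), xy = xy,
                 nox_rate = nox_rate, f_no2 = f_no2,
                 canyon = isTRUE(canyon), typical = isTRUE(typical),
                 canyon_width = canyon_width, canyon_height = canyon_height),
            class = "road_link")
}

#' @export
print.road_link <- function(x, ...) {
  cat(sprintf("road_link '%s': %d vertices, %.1f m, NOx %.3g g/km/s, f_NO2 %.2f%s\n",
              x$id, nrow(x$xy), link_length(x), x$nox_rate, x$f_no2,
              if (x$canyon) ", canyon" else ""))
  invisible(x)
}

#' Polyline arc length of a road link, metres
#' @param link a `road_link`
#' @export
link_length <- function(link) {
  sum(sqrt(rowSums(diff(link$xy)^2)))
}

# position and local bearing at arc length s along a polyline
point_at_arclength <- function(xy, s) {
  seg <- diff(xy)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  s <- pmin(pmax(s, 0), cum[length(cum)])
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(i, length(seg_len))
  f <- (s - cum[i]) / seg_len[i]
  pos <- xy[i, , drop = FALSE] + seg[i, , drop = FALSE] * f
  bearing <- (atan2(seg[i, 1], seg[i, 2]) * 180 / pi) %% 180
  list(pos = pos, bearing = bearing)
}

#' Split a road link into unit road sources
#'
#' Partitions the polyline arc length into consecutive intervals of at most
#' `target_length` metres (full-length pieces plus one shorter remainder,
#' kept as its own source). Each source takes its midpoint and bearing from
#' the arc-length interval it covers and inherits the link's per-km rates;
#' emitted mass is scaled by the source length at superposition time.
#'
#' @param link a `road_link`
#' @param target_length nominal section length, m (default 10)
#' @return data.frame with one row per source: `link_id`, `x`, `y`
#'   (midpoint), `bearing` (deg in [0, 180)), `length` (m)
#' @export
segment_link <- function(link, target_length = 10) {
  stopifnot(inherits(link, "road_link"), target_length > 0)
  L <- link_length(link)
  if (L <= 0) stop("degenerate polyline: zero arc length")
  n_full <- floor(L / target_length + 1e-9)
  lengths <- rep(target_length, n_full)
  rem <- L - n_full * target_length
  if (rem > 1e-9) lengths <- c(lengths, rem)
  ends <- cumsum(lengths)
  mids <- ends - lengths / 2
  p <- point_at_arclength(link$xy, mids)
  data.frame(link_id = link$id, x = p$pos[, 1], y = p$pos[, 2],
             bearing = p$bearing, length = lengths,
             stringsAsFactors = FALSE)
}

#' Assign a road category from bearing and canyon status
#'
#' Canyon roads are classified by the nearest of the four canyon axis
#' orientations (north-south 0 deg, southwest-northeast 45 deg, east-west
#' 90 deg, southeast-northwest 135 deg), modulo 180. A tie exactly midway
#' between two axes breaks toward the lower axis angle. Non-canyon roads
#' are "typical" (built-up street) or "open" per link metadata.
#'
#' @param bearing road bearing, degrees clockwise from north (any value;
#'   normalised modulo 180)
#' @param canyon logical, vectorised with bearing
#' @param typical logical; used only where `canyon` is FALSE
#' @return character vector of categories
#' @export
classify_category <- function(bearing, canyon, typical = TRUE) {
  bearing <- bearing %% 180
  n <- max(length(bearing), length(canyon))
  bearing <- rep_len(bearing, n)
  canyon <- rep_len(canyon, n)
  typical <- rep_len(typical, n)
  axes <- c(0, 45, 90, 135)
  axis_names <- c("canyon_NS", "canyon_SWNE", "canyon_EW", "canyon_SENW")
  out <- character(n)
  for (k in seq_len(n)) {
    if (canyon[k]) {
      d <- abs(bearing[k] - axes)
      d <- pmin(d, 180 - d)          # circular distance mod 180
      out[k] <- axis_names[which.min(d)]  # which.min: first (lower) axis on tie
    } else {
      out[k] <- if (typical[k]) "typical" else "open"
    }
  }
  out
}

#' Split a NOx emission rate into NO and primary NO2 mass rates
#'
#' NOx is reported as NO2-equivalent mass (the UK inventory convention).
#' The primary NO2 fraction `f_no2` of that mass is emitted as NO2; the
#' remainder is emitted as NO, whose mass rate follows from the molar-mass
#' ratio 30/46 (one mole of NOx-as-NO2 is one mole of NO).
#'
#' @param nox_rate NOx emission rate, g km-1 s-1 as NO2 (vectorised)
#' @param f_no2 primary NO2 fraction in [0, 1] (vectorised)
#' @return list with `no_rate` (g of NO km-1 s-1) and `no2_rate`
#'   (g of NO2 km-1 s-1)
#' @export
split_nox_emission <- function(nox_rate, f_no2) {
  if (any(nox_rate < 0)) stop("nox_rate must be non-negative")
  if (any(f_no2 < 0 | f_no2 > 1)) stop("f_no2 must lie in [0, 1]")
  list(no_rate = (1 - f_no2) * nox_rate * (MOLAR_MASS[["NO"]] / MOLAR_MASS[["NO2"]]),
       no2_rate = f_no2 * nox_rate)
}

#' Construct a temporal emissions profile
#'
#' Hour-of-week (168 values, index 1 = Monday 00:00 UTC) and month factors.
#' Both sets must average to one so the annual emission total is preserved.
#'
#' @param hour_of_week 168 non-negative scaling factors
#' @param month 12 non-negative scaling factors
#' @return an object of class `temporal_profile`
#' @export
temporal_profile <- function(hour_of_week = rep(1, 168), month = rep(1, 12)) {
  stopifnot(length(hour_of_week) == 168, length(month) == 12,
            all(hour_of_week >= 0), all(month >= 0))
  if (abs(mean(hour_of_week) - 1) > 1e-9) {
    stop("hour-of-week factors must average to 1")
  }
  if (abs(mean(month) - 1) > 1e-9) stop("month factors must average to 1")
  structure(list(hour_of_week = as.numeric(hour_of_week),
                 month = as.numeric(month)),
            class = "temporal_profile")
}

# hour-of-week index 1..168 with Monday 00:00 = 1 (UTC)
hour_of_week_index <- function(timestamp) {
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  dow <- (lt$wday + 6L) %% 7L  # Monday = 0
  dow * 24L + lt$hour + 1L
}

#' Scale a base emission rate to a given hour
#'
#' @param base_rate annual-mean emission rate, g km-1 s-1
#' @param profile a [temporal_profile()]
#' @param timestamp POSIXct (UTC)
#' @return scaled rate(s), g km-1 s-1
#' @export
emission_at_hour <- function(base_rate, profile, timestamp) {
  stopifnot(inherits(profile, "temporal_profile"))
  hw <- hour_of_week_index(timestamp)
  mo <- as.POSIXlt(timestamp, tz = "UTC")$mon + 1L
  base_rate * profile$hour_of_week[hw] * profile$month[mo]
}

#' Expand road links into categorised, emission-split road sources
#'
#' Runs [segment_link()], [classify_category()] and [split_nox_emission()]
#' over a list of links.
#'
#' @param links list of [road_link()] objects
#' @param target_length section length, m
#' @return data.frame of road sources: `link_id`, `x`, `y`, `bearing`,
#'   `length`, `category`, `no_rate`, `no2_rate` (rates g km-1 s-1)
#' @export
build_sources <- function(links, target_length = 10) {
  out <- lapply(links, function(link) {
    src <- segment_link(link, target_length)
    src$category <- classify_category(src$bearing, link$canyon, link$typical)
    rates <- split_nox_emission(link$nox_rate, link$f_no2)
    src$no_rate <- rates$no_rate
    src$no2_rate <- rates$no2_rate
    src
  })
  do.call(rbind, out)
}
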