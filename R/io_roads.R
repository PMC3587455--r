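# Road network and temporal profile readers.

#' Read a road network from GeoJSON
#'
#' Expects a FeatureCollection of LineString features with properties
#' `id`, `nox_rate`, `f_no2` and optionally `canyon`, `typical`,
#' `canyon_width`, `canyon_height`. Coordinates must already be in a
#' projected metre CRS; no coordinate transformation is performed.
#'
#' @param path GeoJSON file
#' @return list of [road_link()] objects
#' @export
read_roads_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  lapply(seq_along(gj$features), function(i) {
    ft <- gj$features[[i]]
    if (!identical(ft$geometry$type, "LineString")) {
      stop("feature ", i, " is not a LineString")
    }
    xy <- do.call(rbind, lapply(ft$geometry$coordinates,
                                function(p) c(p[[1]], p[[2]])))
    pr <- ft$properties
    road_link(id = pr$id %||% as.character(i), xy = xy,
              nox_rate = pr$nox_rate, f_no2 = pr$f_no2,
              canyon = isTRUE(pr$canyon),
              typical = if (is.null(pr$typical)) TRUE else isTRUE(pr$typical),
              canyon_width = pr$canyon_width %||% 30,
              canyon_height = pr$canyon_height %||% 25)
  })
}

#' Write a road network to GeoJSON
#'
#' @param links list of [road_link()] objects
#' @param path output file
#' @export
write_roads_geojson <- function(links, path) {
  features <- lapply(links, function(l) {
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(l$xy)),
                                              function(i) as.numeric(l$xy[i, ]))),
         properties = list(id = l$id, nox_rate = l$nox_rate, f_no2 = l$f_no2,
                           canyon = l$canyon, typical = l$typical,
                           canyon_width = l$canyon_width,
                           canyon_height = l$canyon_height))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
}

# minimal WKT LINESTRING parser ("LINESTRING (x1 y1, x2 y2, ...)")
parse_wkt_linestring <- function(wkt) {
  body <- sub("^\\s*LINESTRING\\s*\\(", "", wkt, ignore.case = TRUE)
  if (identical(body, wkt)) stop("not a WKT LINESTRING: ", substr(wkt, 1, 40))
  body <- sub("\\)\\s*$", "", body)
  pts <- strsplit(trimws(strsplit(body, ",")[[1]]), "\\s+")
  do.call(rbind, lapply(pts, function(p) as.numeric(p[1:2])))
}

#' Read a road network from CSV with a WKT geometry column
#'
#' Columns: `id`, `wkt` (LINESTRING, projected metres), `nox_rate`,
#' `f_no2`, optional `canyon`, `typical`, `canyon_width`, `canyon_height`.
#'
#' @param path CSV file
#' @return list of [road_link()] objects
#' @export
read_roads_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    road_link(id = df$id[i], xy = parse_wkt_linestring(df$wkt[i]),
              nox_rate = df$nox_rate[i], f_no2 = df$f_no2[i],
              canyon = if ("canyon" %in% names(df)) isTRUE(as.logical(df$canyon[i])) else FALSE,
              typical = if ("typical" %in% names(df)) isTRUE(as.logical(df$typical[i])) else TRUE,
              canyon_width = if ("canyon_width" %in% names(df)) df$canyon_width[i] else 30,
              canyon_height = if ("canyon_height" %in% names(df)) df$canyon_height[i] else 25)
  })
}

#' Read temporal emission profiles from CSV
#'
#' `hour_path` must hold a 168-row table with column `factor` (rows in
#' hour-of-week order, Monday 00:00 first); `month_path` a 12-row table
#' with column `factor`.
#'
#' @param hour_path,month_path CSV files
#' @return a [temporal_profile()]
#' @export
read_temporal_profiles <- function(hour_path, month_path) {
  hw <- utils::read.csv(hour_path)$factor
  mo <- utils::read.csv(month_path)$factor
  temporal_profile(hour_of_week = hw, month = mo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
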