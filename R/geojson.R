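# Minimal GeoJSON reading/writing on top of jsonlite. Only the feature types
# the environment files use are supported: Point, LineString, Polygon.

#' Read a GeoJSON FeatureCollection
#'
#' @param path file path.
#' @return a list with class `geojson_fc`: `type`, and `features`, each
#'   feature a list with `geometry` (`type`, `coordinates`) and `properties`.
#' @export
read_geojson <- function(path) {
  if (!file.exists(path)) stop_fmt("GeoJSON file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$type) || x$type != "FeatureCollection")
    stop_fmt("%s is not a GeoJSON FeatureCollection", path)
  structure(x, class = "geojson_fc")
}

feature_id <- function(feat, i) {
  id <- feat$properties$id %||% feat$id
  if (is.null(id)) sprintf("<feature %d>", i) else as.character(id)
}

# Extract a data.frame from Point features, checking required properties.
geojson_points <- function(fc, required = character(), what = "feature") {
  feats <- fc$features
  rows <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    if (f$geometry$type != "Point")
      stop_fmt("%s %s: expected Point geometry, got %s",
               what, feature_id(f, i), f$geometry$type)
    for (p in required) {
      if (is.null(f$properties[[p]]))
        stop_fmt("schema error: %s %s lacks required property '%s'",
                 what, feature_id(f, i), p)
    }
    cc <- unlist(f$geometry$coordinates)
    props <- lapply(f$properties[required], function(v) v)
    c(list(x = cc[1], y = cc[2]), props)
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

# LineString features -> list of coordinate matrices (+ optional length prop)
geojson_lines <- function(fc) {
  lapply(seq_along(fc$features), function(i) {
    f <- fc$features[[i]]
    if (f$geometry$type != "LineString")
      stop_fmt("road feature %s: expected LineString geometry", feature_id(f, i))
    m <- do.call(rbind, lapply(f$geometry$coordinates, unlist))
    list(coords = m, length = f$properties$length)
  })
}

# Polygon features -> named list of rings keyed by the `level` property
geojson_polygons <- function(fc) {
  out <- list()
  for (i in seq_along(fc$features)) {
    f <- fc$features[[i]]
    if (f$geometry$type != "Polygon")
      stop_fmt("zone feature %s: expected Polygon geometry", feature_id(f, i))
    lev <- f$properties$level
    if (is.null(lev))
      stop_fmt("schema error: zone feature %s lacks required property 'level'",
               feature_id(f, i))
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    out[[as.character(lev)]] <- ring
  }
  out
}

geojson_feature <- function(geometry, properties) {
  list(type = "Feature", geometry = geometry, properties = properties)
}

write_feature_collection <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Write Point features to GeoJSON
#'
#' @param df data.frame with `x`, `y` and property columns.
#' @param path output path.
#' @param props names of columns written as feature properties.
#' @export
write_geojson_points <- function(df, path, props = setdiff(names(df), c("x", "y"))) {
  feats <- lapply(seq_len(nrow(df)), function(i) {
    geojson_feature(
      geometry = list(type = "Point", coordinates = c(df$x[i], df$y[i])),
      properties = as.list(df[i, props, drop = FALSE])
    )
  })
  write_feature_collection(feats, path)
}

write_geojson_lines <- function(lines, path) {
  feats <- lapply(lines, function(m) {
    coords <- lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
    geojson_feature(list(type = "LineString", coordinates = coords),
                    properties = list())
  })
  write_feature_collection(feats, path)
}

write_geojson_zones <- function(zones, path) {
  feats <- lapply(c("neighborhood", "city"), function(lev) {
    ring <- if (lev == "neighborhood") zones$neighborhood else zones$city
    ring <- close_ring(ring)
    coords <- list(lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2])))
    geojson_feature(list(type = "Polygon", coordinates = coords),
                    properties = list(level = lev))
  })
  write_feature_collection(feats, path)
}
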