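# Minimal GeoJSON (and per-feature WKT) reading/writing for the geometry
# layers this package consumes: Polygon / MultiPolygon / LineString /
# MultiLineString in WGS84 lon/lat. Backed by jsonlite; deliberately not a
# general GIS reader.

geojson_parse_geometry <- function(g) {
  if (is.character(g)) return(wkt_parse(g))
  type <- g$type
  cc <- function(x) do.call(rbind, lapply(x, function(p)
    c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
  switch(type,
    LineString = list(lines = list(cc(g$coordinates)), polys = list()),
    MultiLineString = list(lines = lapply(g$coordinates, cc), polys = list()),
    Polygon = list(lines = list(),
                   polys = list(as_polygon(lapply(g$coordinates, cc)))),
    MultiPolygon = list(lines = list(),
                        polys = lapply(g$coordinates, function(rings)
                          as_polygon(lapply(rings, cc)))),
    stop("unsupported GeoJSON geometry type: ", type, call. = FALSE)
  )
}

# tiny WKT subset: POLYGON, MULTIPOLYGON, LINESTRING, MULTILINESTRING
wkt_parse <- function(s) {
  s <- trimws(s)
  type <- toupper(sub("\\s*\\(.*$", "", s))
  body <- sub("^[A-Za-z ]+\\s*", "", s)
  coords <- function(txt) {
    pts <- strsplit(trimws(txt), "\\s*,\\s*")[[1]]
    do.call(rbind, lapply(pts, function(p)
      as.numeric(strsplit(trimws(p), "\\s+")[[1]][1:2])))
  }
  strip1 <- function(x) sub("^\\s*\\(", "", sub("\\)\\s*$", "", x))
  split_groups <- function(x) {
    # split a "(...),(...)" list at depth-0 commas
    depth <- 0; start <- 1; out <- character(0)
    chars <- strsplit(x, "")[[1]]
    for (i in seq_along(chars)) {
      if (chars[i] == "(") depth <- depth + 1
      if (chars[i] == ")") depth <- depth - 1
      if (chars[i] == "," && depth == 0) {
        out <- c(out, substr(x, start, i - 1)); start <- i + 1
      }
    }
    c(out, substr(x, start, nchar(x)))
  }
  switch(type,
    LINESTRING = list(lines = list(coords(strip1(body))), polys = list()),
    MULTILINESTRING = list(
      lines = lapply(split_groups(strip1(body)),
                     function(g) coords(strip1(g))), polys = list()),
    POLYGON = list(lines = list(), polys = list(as_polygon(
      lapply(split_groups(strip1(body)), function(g) coords(strip1(g)))))),
    MULTIPOLYGON = list(lines = list(), polys = lapply(
      split_groups(strip1(body)), function(pg)
        as_polygon(lapply(split_groups(strip1(pg)),
                          function(g) coords(strip1(g)))))),
    stop("unsupported WKT type: ", type, call. = FALSE)
  )
}

#' Read one geometry layer from a GeoJSON file
#'
#' Accepts a FeatureCollection, a bare geometry, or features whose geometry
#' is a WKT string. Returns the features' polygons, polylines and `type`
#' properties.
#'
#' @param path GeoJSON file.
#' @return list with elements `polys`, `lines`, `props` (list of per-feature
#'   property lists, aligned with polys then lines in file order).
#' @export
read_geojson_layer <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(j$type, "FeatureCollection")) j$features
           else list(list(geometry = j, properties = list()))
  polys <- list(); lines <- list(); props <- list()
  for (f in feats) {
    g <- geojson_parse_geometry(f$geometry)
    for (p in g$polys) { polys[[length(polys) + 1]] <- p
                         props[[length(props) + 1]] <- f$properties }
    for (l in g$lines) { lines[[length(lines) + 1]] <- l
                         props[[length(props) + 1]] <- f$properties }
  }
  list(polys = polys, lines = lines, props = props)
}

geojson_geom <- function(polys = list(), lines = list()) {
  ring_j <- function(r) lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
  feats <- c(
    lapply(polys, function(p) list(
      type = "Feature", properties = list(),
      geometry = list(type = "Polygon", coordinates = lapply(p, ring_j)))),
    lapply(lines, function(l) list(
      type = "Feature", properties = list(),
      geometry = list(type = "LineString", coordinates = ring_j(l)))))
  list(type = "FeatureCollection", features = feats)
}

#' Write a coast model as one GeoJSON file per layer
#'
#' Files are named `<prefix>_land.geojson`, `_coastline`, `_glacier_fronts`,
#' `_fjords`.
#' @param model a [coast_model()].
#' @param prefix path prefix (directory must exist).
#' @return invisibly, the four file paths.
#' @export
write_coast_geojson <- function(model, prefix) {
  paths <- c(land = paste0(prefix, "_land.geojson"),
             coastline = paste0(prefix, "_coastline.geojson"),
             glacier_fronts = paste0(prefix, "_glacier_fronts.geojson"),
             fjords = paste0(prefix, "_fjords.geojson"))
  jsonlite::write_json(geojson_geom(polys = model$land), paths["land"],
                       auto_unbox = TRUE, digits = 10)
  jsonlite::write_json(geojson_geom(lines = model$coastline),
                       paths["coastline"], auto_unbox = TRUE, digits = 10)
  jsonlite::write_json(geojson_geom(lines = model$glacier_fronts),
                       paths["glacier_fronts"], auto_unbox = TRUE, digits = 10)
  jsonlite::write_json(geojson_geom(polys = model$fjords), paths["fjords"],
                       auto_unbox = TRUE, digits = 10)
  invisible(paths)
}

#' Read a coast model from per-layer GeoJSON files
#' @param prefix path prefix as used by [write_coast_geojson()].
#' @param epoch_label label to stamp on the model.
#' @return a [coast_model()].
#' @export
read_coast_geojson <- function(prefix, epoch_label = basename(prefix)) {
  land <- read_geojson_layer(paste0(prefix, "_land.geojson"))$polys
  coastline <- read_geojson_layer(paste0(prefix, "_coastline.geojson"))$lines
  fronts <- read_geojson_layer(paste0(prefix, "_glacier_fronts.geojson"))$lines
  fjords <- read_geojson_layer(paste0(prefix, "_fjords.geojson"))$polys
  coast_model(epoch_label, land = land, coastline = coastline,
              glacier_fronts = fronts, fjords = fjords)
}

#' Write a dated ice field to GeoJSON
#'
#' One feature per typed polygon, with a `type` property from the six-class
#' ice set; file named `ice_YYYYMMDD.geojson`.
#' @param field an ice field (list with `date` and `polygons`, see
#'   [make_ice_fields()]).
#' @param dir output directory.
#' @return invisibly, the file path.
#' @export
write_ice_geojson <- function(field, dir) {
  path <- file.path(dir, sprintf("ice_%s.geojson",
                                 format(field$date, "%Y%m%d")))
  ring_j <- function(r) lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
  feats <- mapply(function(poly, type) list(
    type = "Feature", properties = list(type = type),
    geometry = list(type = "Polygon", coordinates = lapply(poly, ring_j))),
    field$polygons, field$types, SIMPLIFY = FALSE)
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read all `ice_YYYYMMDD.geojson` files from a directory
#' @param dir directory containing ice GeoJSON files.
#' @return list of ice fields (date, polygons, types), sorted by date.
#' @export
read_ice_geojson <- function(dir) {
  files <- sort(list.files(dir, pattern = "^ice_\\d{8}\\.geojson$",
                           full.names = TRUE))
  fields <- lapply(files, function(f) {
    date <- as.Date(sub("^ice_(\\d{8})\\.geojson$", "\\1", basename(f)),
                    format = "%Y%m%d")
    lay <- read_geojson_layer(f)
    types <- vapply(lay$props, function(p)
      if (is.null(p$type)) NA_character_ else p$type, character(1))
    if (any(is.na(types)) || !all(types %in% ICE_TYPES))
      stop("ice feature with missing/unknown `type` in ", f, call. = FALSE)
    list(date = date, polygons = lay$polys, types = types)
  })
  fields
}
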