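# GeoJSON IO. Only the small subset the pipeline needs: a boundary polygon in,
# and Point/Polygon feature collections out. Coordinates on disk are always
# WGS84 lon/lat; everything in memory is planar metres.

#' Read a city boundary from GeoJSON
#'
#' Accepts a Feature, FeatureCollection (first polygonal feature used),
#' Polygon or MultiPolygon (largest polygon used, with its holes) and returns
#' the projected planar window. The projection reference defaults to the mean
#' of the outer ring's vertices.
#'
#' @param path GeoJSON file.
#' @param reference optional lon/lat projection origin.
#' @return a [poly_window()].
#' @export
read_boundary_geojson <- function(path, reference = NULL) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  geom <- extract_polygon_geometry(g)
  if (is.null(geom)) stop("no Polygon/MultiPolygon geometry found in ", path)
  polys <- if (geom$type == "Polygon") list(geom$coordinates) else geom$coordinates
  rings_ll <- lapply(polys, function(poly) {
    lapply(poly, function(ring) {
      m <- do.call(rbind, lapply(ring, function(pt) as.numeric(pt[1:2])))
      colnames(m) <- c("lon", "lat")
      m
    })
  })
  # choose the largest outer ring (MultiPolygon: keep the main landmass)
  outer_areas <- vapply(rings_ll, function(rr) abs(spherical_ring_area(rr[[1]])), 0)
  best <- which.max(outer_areas)
  rings <- rings_ll[[best]]
  if (is.null(reference)) reference <- colMeans(rings[[1]])
  planar <- lapply(rings, geo_to_plane, reference = reference)
  poly_window(planar[[1]], holes = planar[-1], reference = reference)
}

# crude equirectangular ring area in deg^2-ish units; only used for ranking
spherical_ring_area <- function(ring_ll) {
  shoelace_area(cbind(ring_ll[, 1] * cos(mean(ring_ll[, 2]) * pi / 180),
                      ring_ll[, 2]))
}

extract_polygon_geometry <- function(g) {
  if (is.null(g$type)) return(NULL)
  if (g$type %in% c("Polygon", "MultiPolygon")) return(g)
  if (g$type == "Feature") return(extract_polygon_geometry(g$geometry))
  if (g$type == "FeatureCollection") {
    for (f in g$features) {
      geom <- extract_polygon_geometry(f)
      if (!is.null(geom)) return(geom)
    }
  }
  NULL
}

ring_to_coords <- function(ring_xy, reference) {
  ll <- plane_to_geo(ring_xy, reference)
  ll <- rbind(ll, ll[1, ])  # GeoJSON rings are closed
  lapply(seq_len(nrow(ll)), function(i) c(ll[i, 1], ll[i, 2]))
}

geojson_feature <- function(geometry, properties = list()) {
  list(type = "Feature",
       properties = if (length(properties)) properties else structure(list(), names = character()),
       geometry = geometry)
}

geojson_polygon <- function(window) {
  list(type = "Polygon",
       coordinates = lapply(window$rings, ring_to_coords,
                            reference = window$reference))
}

geojson_point <- function(xy, reference) {
  ll <- plane_to_geo(matrix(xy, ncol = 2), reference)
  list(type = "Point", coordinates = c(ll[1, 1], ll[1, 2]))
}

write_feature_collection <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}

#' Write a window boundary to GeoJSON
#'
#' @param window a [poly_window()] carrying a lon/lat reference.
#' @param path output file.
#' @export
write_boundary_geojson <- function(window, path) {
  if (is.null(window$reference)) {
    stop("window has no lon/lat reference; cannot write geographic output")
  }
  write_feature_collection(
    list(geojson_feature(geojson_polygon(window),
                         list(role = "city-boundary",
                              area_m2 = round(window$area, 1)))),
    path)
}
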