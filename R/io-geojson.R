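# Minimal GeoJSON (RFC 7946) reading and writing on top of jsonlite.
#
# RFC 7946 mandates WGS84 coordinates, but the pipeline works in a projected,
# metre-unit CRS; the CRS identifier therefore travels in a sidecar config /
# the `crs` attribute, never inside the GeoJSON itself, and coordinates are
# written as-is.

#' Read polygons from a GeoJSON file
#'
#' Accepts FeatureCollection, Feature, Polygon and MultiPolygon objects.
#' Each feature becomes one element of the returned list: a multipolygon in
#' the package's internal form (list of polygons, each a list of rings, each
#' ring a 2-column matrix), with the feature's properties attached as the
#' \code{properties} attribute.
#'
#' @param path path to a GeoJSON file.
#' @param crs optional CRS identifier (e.g. \code{"EPSG:27700"}) recorded as
#'   an attribute on the result; GeoJSON itself cannot carry a projected CRS.
#' @return list of multipolygons with attributes \code{properties} (per
#'   feature) and \code{crs} (on the list).
#' @export
read_geojson_polygons <- function(path, crs = NULL) {
  if (!file.exists(path)) stop("GeoJSON file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- switch(gj$type,
    FeatureCollection = gj$features,
    Feature = list(gj),
    Polygon = ,
    MultiPolygon = list(list(type = "Feature", geometry = gj, properties = NULL)),
    stop("unsupported GeoJSON type: ", gj$type)
  )
  out <- lapply(feats, function(f) {
    geom <- f$geometry
    poly <- switch(geom$type,
      Polygon = list(lapply(geom$coordinates, coords_to_ring)),
      MultiPolygon = lapply(geom$coordinates, function(p) lapply(p, coords_to_ring)),
      stop("unsupported geometry type: ", geom$type)
    )
    attr(poly, "properties") <- f$properties
    poly
  })
  attr(out, "crs") <- crs
  out
}

# GeoJSON rings repeat the first vertex at the end; internal rings do not.
coords_to_ring <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  if (nrow(m) > 1L && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

ring_to_coords <- function(ring) {
  closed <- rbind(ring, ring[1, ])
  lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1], closed[i, 2]))
}

geometry_json <- function(polygon) {
  polys <- normalize_multipolygon(polygon)
  if (length(polys) == 1L) {
    list(type = "Polygon",
         coordinates = lapply(polys[[1L]], ring_to_coords))
  } else {
    list(type = "MultiPolygon",
         coordinates = lapply(polys, function(rings) lapply(rings, ring_to_coords)))
  }
}

#' Write polygon features to a GeoJSON file
#'
#' @param geoms list of (multi)polygons in internal form.
#' @param properties optional data frame with one row per geometry; columns
#'   become feature properties.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_geojson_polygons <- function(geoms, path, properties = NULL) {
  features <- lapply(seq_along(geoms), function(i) {
    props <- if (is.null(properties)) NULL else as.list(properties[i, , drop = FALSE])
    list(type = "Feature", properties = props, geometry = geometry_json(geoms[[i]]))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write line features (e.g. stream segments) to a GeoJSON file
#'
#' @param lines list of 2-column coordinate matrices.
#' @param properties optional data frame, one row per line.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_geojson_lines <- function(lines, path, properties = NULL) {
  features <- lapply(seq_along(lines), function(i) {
    m <- lines[[i]]
    coords <- lapply(seq_len(nrow(m)), function(k) c(m[k, 1], m[k, 2]))
    props <- if (is.null(properties)) NULL else as.list(properties[i, , drop = FALSE])
    list(type = "Feature", properties = props,
         geometry = list(type = "LineString", coordinates = coords))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
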