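# Still-water site size: polygon areas in hectares and the Ramsar 8 ha
# pond/lake split.

#' Planar polygon area in hectares
#'
#' Shoelace area of the outer ring minus any holes, divided by 10,000.
#' Orientation-independent. Multi-part sites (a list of polygons) sum their
#' parts.
#'
#' @param polygon a ring matrix, a list of rings (first outer, rest holes),
#'   or a multipolygon; coordinates in metres.
#' @return area in hectares.
#' @export
polygon_area_ha <- function(polygon) {
  polys <- normalize_multipolygon(polygon)
  for (rings in polys) {
    for (ring in rings) {
      if (!ring_is_simple(ring))
        stop("polygon ring is self-intersecting")
    }
  }
  polygon_area(polys) / 1e4
}

#' Ramsar size classification of still waterbodies
#'
#' Sites at or below the threshold (default 8 ha, the Ramsar pond/lake
#' convention) are \code{"small"}; larger sites are \code{"large"}. A site of
#' exactly 8 ha is classified small (ties-to-small), configurable via
#' \code{ties}.
#'
#' @param area area(s) in hectares.
#' @param threshold split point in hectares.
#' @param ties \code{"small"} (default) or \code{"large"}: which class
#'   receives an area exactly at the threshold.
#' @return factor with ordered levels \code{small < large}.
#' @export
classify_size <- function(area, threshold = 8, ties = c("small", "large")) {
  ties <- match.arg(ties)
  if (any(is.na(area)) || any(area < 0)) stop("areas must be non-negative")
  large <- if (ties == "small") area > threshold else area >= threshold
  factor(ifelse(large, "large", "small"), levels = c("small", "large"),
         ordered = TRUE)
}

#' Area and size class of still-water sites
#'
#' @param waterbodies list of polygons (as read by
#'   \code{\link{read_geojson_polygons}}); multi-part geometries sum their
#'   parts' areas.
#' @param site_ids optional character vector of ids (defaults to feature
#'   \code{id}/\code{site_id} properties, then a sequence).
#' @param threshold,ties passed to \code{\link{classify_size}}.
#' @return data frame: \code{site_id}, \code{area_ha}, \code{size_class}.
#' @export
still_water_table <- function(waterbodies, site_ids = NULL, threshold = 8,
                              ties = "small") {
  if (is.null(site_ids)) {
    site_ids <- vapply(seq_along(waterbodies), function(i) {
      p <- attr(waterbodies[[i]], "properties")
      id <- p$site_id %||% p$id
      if (is.null(id)) paste0("wb-", i) else as.character(id)
    }, character(1))
  }
  areas <- vapply(waterbodies, polygon_area_ha, numeric(1))
  data.frame(site_id = site_ids, area_ha = areas,
             size_class = classify_size(areas, threshold, ties))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
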