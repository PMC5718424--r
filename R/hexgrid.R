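# Regular hexagonal tessellation of a catchment boundary.
#
# Flat-top hexagons on an axial (q, r) lattice. With edge length s the
# centre of cell (q, r) sits at
#   x = ox + 1.5 * s * q
#   y = oy + sqrt(3) * s * (r + q / 2)
# and each full cell has area (3 * sqrt(3) / 2) * s^2 — for s = 5 km that is
# 64.95 km^2, the "65 km^2" cell of a 5 km grid. Because the tessellation is
# the Voronoi diagram of its centres, point location is nearest-centre
# search, exact up to ties on shared edges.

HEX_AREA_FACTOR <- 3 * sqrt(3) / 2

#' Full (unclipped) area of a hexagon cell
#'
#' @param edge_length hexagon edge length in metres.
#' @return area in km^2: \code{(3 * sqrt(3) / 2) * edge_length^2 / 1e6}.
#' @export
hex_cell_area_km2 <- function(edge_length) {
  HEX_AREA_FACTOR * edge_length^2 / 1e6
}

hex_center <- function(q, r, edge, origin) {
  cbind(x = origin[1] + 1.5 * edge * q,
        y = origin[2] + sqrt(3) * edge * (r + q / 2))
}

#' Vertex ring of one hexagon cell
#'
#' @param cx,cy cell centre.
#' @param edge edge length in metres.
#' @return 6 x 2 matrix of vertices (counter-clockwise, flat-top).
#' @export
hex_polygon <- function(cx, cy, edge) {
  ang <- seq(0, 5) * pi / 3
  cbind(cx + edge * cos(ang), cy + edge * sin(ang))
}

#' Tessellate a catchment boundary with regular hexagons
#'
#' Returns every lattice hexagon whose polygon intersects the boundary with
#' positive area. Cells are not clipped: a cell partially outside the
#' catchment is kept whole, and points falling in it still count towards it.
#'
#' @param boundary catchment outline: a ring matrix, a list of rings (first
#'   outer, rest holes) or a multipolygon (list of such lists); coordinates
#'   in metres.
#' @param edge_length hexagon edge length in metres (default 5000; a 5 km
#'   grid has ~65 km^2 cells).
#' @param origin lattice origin (x, y). Defaults to the lower-left corner of
#'   the boundary's bounding box, which fixes the grid deterministically for
#'   a given boundary.
#' @param crs optional CRS identifier carried as metadata.
#' @return object of class \code{hex_grid}: list with \code{cells} (data
#'   frame q, r, cx, cy), \code{edge_length}, \code{origin},
#'   \code{orientation} (always \code{"flat-top"}) and \code{boundary}.
#' @export
build_hex_grid <- function(boundary, edge_length = 5000, origin = NULL,
                           crs = NULL) {
  stopifnot(edge_length > 0)
  boundary <- normalize_multipolygon(boundary)
  if (polygon_area(boundary) <= 0)
    stop("boundary polygon is degenerate (zero area)")
  bb <- polygon_bbox(boundary)
  if (is.null(origin)) origin <- c(bb["xmin"], bb["ymin"])
  origin <- as.numeric(origin)
  s <- edge_length

  # candidate axial range covering the bounding box plus one cell of slack
  qmin <- floor((bb["xmin"] - origin[1] - s) / (1.5 * s))
  qmax <- ceiling((bb["xmax"] - origin[1] + s) / (1.5 * s))
  area_tol <- 1e-12 * s^2
  cells <- list()
  for (q in qmin:qmax) {
    ry <- (c(bb["ymin"] - s, bb["ymax"] + s) - origin[2]) / (sqrt(3) * s) - q / 2
    for (r in floor(ry[1]):ceiling(ry[2])) {
      ctr <- hex_center(q, r, s, origin)
      hex <- hex_polygon(ctr[1], ctr[2], s)
      if (clip_area_convex(boundary, hex) > area_tol) {
        cells[[length(cells) + 1L]] <- c(q, r, ctr[1], ctr[2])
      }
    }
  }
  if (length(cells) == 0L) stop("no hexagon cell intersects the boundary")
  cells <- do.call(rbind, cells)
  cells <- data.frame(q = as.integer(cells[, 1]), r = as.integer(cells[, 2]),
                      cx = cells[, 3], cy = cells[, 4])
  cells <- cells[order(cells$q, cells$r), , drop = FALSE]
  rownames(cells) <- NULL
  structure(list(cells = cells, edge_length = edge_length, origin = origin,
                 orientation = "flat-top", boundary = boundary, crs = crs),
            class = "hex_grid")
}

#' @export
print.hex_grid <- function(x, ...) {
  cat("Hexagonal grid: ", nrow(x$cells), " cells, edge ",
      x$edge_length / 1000, " km (", round(hex_cell_area_km2(x$edge_length), 2),
      " km^2 per full cell), flat-top\n", sep = "")
  invisible(x)
}

# Axial rounding: nearest lattice centre via cube-coordinate rounding.
hex_round <- function(qf, rf) {
  xf <- qf; zf <- rf; yf <- -xf - zf
  rx <- round(xf); ry <- round(yf); rz <- round(zf)
  dx <- abs(rx - xf); dy <- abs(ry - yf); dz <- abs(rz - zf)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  cbind(q = rx, r = rz)
}

HEX_NEIGHBOURS <- cbind(q = c(0, 1, 1, 0, -1, -1, 0),
                        r = c(0, 0, -1, -1, 0, 1, 1))

#' Locate points on a hexagonal grid
#'
#' Finds, for each point, the axial index of the grid cell containing it.
#' A point on a shared edge or vertex is assigned to the cell with the
#' lexicographically smallest (q, r) among the tied cells, so assignment is
#' deterministic and order-independent. Points whose containing lattice cell
#' is not part of the grid get \code{NA}.
#'
#' @param grid a \code{hex_grid}.
#' @param x,y point coordinates (vectors of equal length).
#' @return data frame with integer columns \code{q}, \code{r} (\code{NA}
#'   where the point falls outside the grid).
#' @export
locate_points <- function(grid, x, y) {
  s <- grid$edge_length
  ox <- grid$origin[1]; oy <- grid$origin[2]
  qf <- (x - ox) * 2 / (3 * s)
  rf <- (y - oy) / (sqrt(3) * s) - qf / 2
  ax <- hex_round(qf, rf)
  tol2 <- (1e-9 * s)^2
  n <- length(x)
  outq <- integer(n); outr <- integer(n)
  key <- paste(grid$cells$q, grid$cells$r)
  for (i in seq_len(n)) {
    cq <- ax[i, 1] + HEX_NEIGHBOURS[, 1]
    cr <- ax[i, 2] + HEX_NEIGHBOURS[, 2]
    ctr <- hex_center(cq, cr, s, grid$origin)
    d2 <- (ctr[, 1] - x[i])^2 + (ctr[, 2] - y[i])^2
    near <- which(d2 <= min(d2) + tol2)
    # tie rule: lexicographically smallest (q, r) among equidistant cells
    pick <- near[order(cq[near], cr[near])][1L]
    outq[i] <- cq[pick]; outr[i] <- cr[pick]
  }
  in_grid <- paste(outq, outr) %in% key
  outq[!in_grid] <- NA_integer_; outr[!in_grid] <- NA_integer_
  data.frame(q = outq, r = outr)
}

#' Polygons of all grid cells
#'
#' @param grid a \code{hex_grid}.
#' @return list of 6 x 2 vertex matrices, one per cell, in the order of
#'   \code{grid$cells}.
#' @export
grid_cell_polygons <- function(grid) {
  lapply(seq_len(nrow(grid$cells)), function(i) {
    hex_polygon(grid$cells$cx[i], grid$cells$cy[i], grid$edge_length)
  })
}

#' Export a hexagonal grid as GeoJSON
#'
#' One Polygon feature per cell with properties \code{q}, \code{r} and
#' \code{area_km2} (the full, unclipped cell area), plus any extra columns
#' supplied in \code{properties}.
#'
#' @param grid a \code{hex_grid}.
#' @param path output path.
#' @param properties optional data frame with one row per cell (aligned with
#'   \code{grid$cells}) of additional per-cell attributes.
#' @return \code{path}, invisibly.
#' @export
write_grid_geojson <- function(grid, path, properties = NULL) {
  props <- data.frame(q = grid$cells$q, r = grid$cells$r,
                      area_km2 = hex_cell_area_km2(grid$edge_length))
  if (!is.null(properties)) props <- cbind(props, properties)
  write_geojson_polygons(grid_cell_polygons(grid), path, props)
}
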