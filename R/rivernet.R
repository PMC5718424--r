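# Drainage analysis on D8 direction rasters: flow accumulation, stream
# extraction at a minimum-accumulation condition, Strahler ordering, and
# site snapping/pooling onto the network.
#
# Accumulation convention: acc(cell) counts upstream cells EXCLUDING the
# cell itself, so headwater cells have 0. The minimum-accumulation stream
# condition (default 50 cells) applies to this count.

# Linear index helpers (column-major over the codes matrix)
d8_downstream_index <- function(d8) {
  nr <- d8$nrow; nc <- d8$ncol
  codes <- d8$codes
  down <- rep(NA_integer_, nr * nc)
  for (k in seq_along(D8_CODES)) {
    sel <- which(!is.na(codes) & codes == D8_CODES[k])
    if (length(sel) == 0L) next
    r <- ((sel - 1L) %% nr) + 1L
    cl <- ((sel - 1L) %/% nr) + 1L
    r2 <- r + D8_DROW[k]
    c2 <- cl + D8_DCOL[k]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    tgt <- rep(NA_integer_, length(sel))
    tgt[ok] <- (c2[ok] - 1L) * nr + r2[ok]
    # flowing into a nodata cell terminates the path, like flowing off-grid
    tgt[!is.na(tgt) & is.na(codes[tgt])] <- NA_integer_
    down[sel] <- tgt
  }
  down
}

#' Flow accumulation from a D8 direction grid
#'
#' Counts, for every cell, the number of distinct upstream cells draining
#' through it (excluding the cell itself); computed in topological order.
#'
#' @param d8 a \code{\link{d8_grid}}.
#' @return object of class \code{flow_accumulation}: list with \code{values}
#'   (integer matrix, \code{NA} at nodata cells) and the grid georeferencing.
#' @export
flow_accumulation <- function(d8) {
  stopifnot(inherits(d8, "d8_grid"))
  nr <- d8$nrow; nc <- d8$ncol
  valid <- which(!is.na(d8$codes))
  down <- d8_downstream_index(d8)
  indeg <- tabulate(down[valid], nbins = nr * nc)
  acc <- integer(nr * nc)
  queue <- integer(length(valid))
  seeds <- valid[indeg[valid] == 0L]
  queue[seq_along(seeds)] <- seeds
  tail <- length(seeds)
  head <- 1L
  n_done <- 0L
  while (head <= tail) {
    u <- queue[head]; head <- head + 1L
    n_done <- n_done + 1L
    v <- down[u]
    if (!is.na(v)) {
      acc[v] <- acc[v] + acc[u] + 1L
      indeg[v] <- indeg[v] - 1L
      if (indeg[v] == 0L) { tail <- tail + 1L; queue[tail] <- v }
    }
  }
  if (n_done < length(valid)) {
    stuck <- setdiff(valid, queue[seq_len(tail)])[1L]
    stop("flow-direction cycle detected at cell (row ",
         ((stuck - 1L) %% nr) + 1L, ", col ", ((stuck - 1L) %/% nr) + 1L, ")")
  }
  m <- matrix(acc, nr, nc)
  m[is.na(d8$codes)] <- NA_integer_
  structure(list(values = m, cellsize = d8$cellsize, xll = d8$xll,
                 yll = d8$yll, nrow = nr, ncol = nc, d8 = d8),
            class = "flow_accumulation")
}

#' @export
print.flow_accumulation <- function(x, ...) {
  cat("Flow accumulation: ", x$nrow, " x ", x$ncol, " cells, max ",
      max(x$values, na.rm = TRUE), " upstream cells\n", sep = "")
  invisible(x)
}

#' Extract a stream network at a minimum-accumulation condition
#'
#' Stream cells are those with accumulation at or above \code{threshold}
#' (default 50 cells). Stream cells are chained into segments broken at
#' confluences (stream cells receiving two or more stream inflows); the
#' confluence cell starts the downstream segment. The result is a forest of
#' trees rooted at outlet segments.
#'
#' @param acc a \code{\link{flow_accumulation}} result.
#' @param threshold minimum upstream-cell count for a stream cell.
#' @return object of class \code{stream_network}: list with \code{segments}
#'   (each with \code{id}, \code{cells} matrix of row/col indices from
#'   upstream to downstream, \code{downstream} id or \code{NA},
#'   \code{order} — \code{NA} until \code{\link{strahler_order}}),
#'   plus raster georeferencing.
#' @export
extract_streams <- function(acc, threshold = 50) {
  stopifnot(inherits(acc, "flow_accumulation"), threshold >= 0)
  d8 <- acc$d8
  nr <- acc$nrow; nc <- acc$ncol
  stream <- !is.na(acc$values) & acc$values >= threshold
  net <- structure(list(segments = list(), cellsize = acc$cellsize,
                        xll = acc$xll, yll = acc$yll, nrow = nr, ncol = nc,
                        threshold = threshold, junctions = NULL),
                   class = "stream_network")
  if (!any(stream)) {
    warning("no cell meets the accumulation threshold (", threshold,
            "); empty network", call. = FALSE)
    return(net)
  }
  down <- d8_downstream_index(d8)
  sidx <- which(stream)
  # stream inflow count per stream cell
  dtarget <- down[sidx]
  on_stream <- !is.na(dtarget) & stream[dtarget]
  indeg <- tabulate(dtarget[on_stream], nbins = nr * nc)
  heads <- sidx[indeg[sidx] != 1L]
  # deterministic segment ids: heads ordered by (row, col)
  hr <- ((heads - 1L) %% nr) + 1L
  hc <- ((heads - 1L) %/% nr) + 1L
  heads <- heads[order(hr, hc)]
  seg_of_head <- seq_along(heads)
  names(seg_of_head) <- heads
  segments <- vector("list", length(heads))
  for (i in seq_along(heads)) {
    path <- heads[i]
    cur <- heads[i]
    repeat {
      nxt <- down[cur]
      if (is.na(nxt) || !stream[nxt] || indeg[nxt] != 1L) break
      path <- c(path, nxt)
      cur <- nxt
    }
    nxt <- down[cur]
    down_id <- if (!is.na(nxt) && stream[nxt])
      unname(seg_of_head[as.character(nxt)]) else NA_integer_
    segments[[i]] <- list(
      id = i,
      cells = cbind(row = ((path - 1L) %% nr) + 1L,
                    col = ((path - 1L) %/% nr) + 1L),
      downstream = down_id,
      order = NA_integer_)
  }
  junc <- sidx[indeg[sidx] >= 2L]
  net$segments <- segments
  net$junctions <- cbind(row = ((junc - 1L) %% nr) + 1L,
                         col = ((junc - 1L) %/% nr) + 1L)
  net
}

#' @export
print.stream_network <- function(x, ...) {
  ncell <- sum(vapply(x$segments, function(s) nrow(s$cells), integer(1)))
  ord <- vapply(x$segments, function(s) s$order, integer(1))
  cat("Stream network: ", length(x$segments), " segments, ", ncell,
      " stream cells", sep = "")
  if (length(ord) > 0 && !all(is.na(ord)))
    cat(", Strahler orders 1-", max(ord, na.rm = TRUE), sep = "")
  cat("\n")
  invisible(x)
}

#' Assign Strahler orders to a stream network
#'
#' Headwater segments get order 1. At a junction the downstream segment's
#' order is the maximum of its inflow orders, incremented by one when that
#' maximum is attained by two or more inflows (generalized Strahler rule for
#' junctions with three or more inflows).
#'
#' @param net a \code{\link{extract_streams}} network.
#' @return the network with segment \code{order} fields filled in.
#' @export
strahler_order <- function(net) {
  stopifnot(inherits(net, "stream_network"))
  n <- length(net$segments)
  if (n == 0L) return(net)
  down <- vapply(net$segments, function(s) s$downstream, integer(1))
  n_up <- tabulate(down[!is.na(down)], nbins = n)
  orders <- rep(NA_integer_, n)
  queue <- which(n_up == 0L)
  orders[queue] <- 1L
  pending <- n_up
  inflows <- vector("list", n)
  head <- 1L
  done <- 0L
  while (head <= length(queue)) {
    u <- queue[head]; head <- head + 1L
    done <- done + 1L
    v <- down[u]
    if (!is.na(v)) {
      inflows[[v]] <- c(inflows[[v]], orders[u])
      pending[v] <- pending[v] - 1L
      if (pending[v] == 0L) {
        o <- inflows[[v]]
        mx <- max(o)
        orders[v] <- if (sum(o == mx) >= 2L) mx + 1L else mx
        queue <- c(queue, v)
      }
    }
  }
  if (done < n) stop("stream network topology is cyclic")
  for (i in seq_len(n)) net$segments[[i]]$order <- orders[i]
  net
}

# All stream cell centres with their segment ids and along-segment position.
network_cell_table <- function(net) {
  if (length(net$segments) == 0L)
    return(data.frame(segment = integer(0), pos = integer(0),
                      row = integer(0), col = integer(0),
                      x = numeric(0), y = numeric(0)))
  parts <- lapply(net$segments, function(s) {
    ctr <- cell_center(net, s$cells[, "row"], s$cells[, "col"])
    data.frame(segment = s$id, pos = seq_len(nrow(s$cells)),
               row = s$cells[, "row"], col = s$cells[, "col"],
               x = ctr[, 1], y = ctr[, 2])
  })
  do.call(rbind, parts)
}

#' Snap points to the nearest stream cell
#'
#' Each point is assigned the nearest stream-cell centre within
#' \code{max_snap} metres; ties are broken by the smallest segment id (then
#' the most upstream cell). Points farther than \code{max_snap} from every
#' stream cell are left unassigned.
#'
#' @param points data frame with columns \code{x}, \code{y} (and optionally
#'   \code{id}).
#' @param net a stream network.
#' @param max_snap maximum snapping distance in metres (default 200).
#' @return data frame with columns \code{segment} (\code{NA} if unsnapped),
#'   \code{pos} (cell index along the segment), \code{snap_x}, \code{snap_y},
#'   \code{snap_dist}.
#' @export
snap_to_stream <- function(points, net, max_snap = 200) {
  stopifnot(inherits(net, "stream_network"))
  tab <- network_cell_table(net)
  n <- nrow(points)
  out <- data.frame(segment = rep(NA_integer_, n), pos = NA_integer_,
                    snap_x = NA_real_, snap_y = NA_real_,
                    snap_dist = NA_real_)
  if (nrow(tab) == 0L || n == 0L) return(out)
  # order so that which.min's first-match tie-break realizes the documented
  # (segment id, upstream position) tie rule
  tab <- tab[order(tab$segment, tab$pos), , drop = FALSE]
  for (i in seq_len(n)) {
    d2 <- (tab$x - points$x[i])^2 + (tab$y - points$y[i])^2
    dmin <- min(d2)
    cand <- which(d2 <= dmin + 1e-9 * max(dmin, 1))
    j <- cand[1L]
    d <- sqrt(d2[j])
    if (d <= max_snap) {
      out$segment[i] <- tab$segment[j]
      out$pos[i] <- tab$pos[j]
      out$snap_x[i] <- tab$x[j]
      out$snap_y[i] <- tab$y[j]
      out$snap_dist[i] <- d
    }
  }
  out
}

# Connected components of a distance graph (edges where dist <= radius) —
# order-independent single-linkage clustering at a fixed cut.
single_linkage_components <- function(x, y, radius) {
  n <- length(x)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq(i + 1L, n)) {
      if ((x[i] - x[j])^2 + (y[i] - y[j])^2 <= radius^2) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

complete_linkage_components <- function(x, y, radius) {
  n <- length(x)
  if (n <= 1L) return(rep(1L, n))
  hc <- stats::hclust(stats::dist(cbind(x, y)), method = "complete")
  stats::cutree(hc, h = radius)
}

#' Pool snapped sampling points into standardized sites
#'
#' Points snapped to the same stream segment are clustered under the stated
#' linkage with a distance cut of \code{radius} metres (default 50) between
#' snapped points, and each cluster becomes one pooled site named
#' \code{"seg<id>-<k>"} with \code{k} running from upstream to downstream.
#' Single linkage (the default) makes pooling order-independent and allows
#' chains; complete linkage is available. Unsnappable points become
#' singleton sites flagged off-network, named \code{"off-<id>"}.
#'
#' @param points data frame with columns \code{id}, \code{x}, \code{y}.
#' @param net a Strahler-ordered stream network.
#' @param radius pooling distance in metres.
#' @param max_snap maximum snapping distance passed to
#'   \code{\link{snap_to_stream}}.
#' @param linkage \code{"single"} or \code{"complete"}.
#' @return data frame of pooled sites: \code{pooled_id}, \code{segment},
#'   \code{order}, \code{x}, \code{y} (centroid of members' snapped points),
#'   \code{n_members}, \code{off_network}, and \code{members} (list column
#'   of member ids).
#' @export
pool_sites <- function(points, net, radius = 50, max_snap = 200,
                       linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(all(c("id", "x", "y") %in% names(points)))
  snapped <- snap_to_stream(points, net, max_snap)
  seg_order <- vapply(net$segments, function(s) s$order, integer(1))
  rows <- list()
  # deterministic iteration regardless of input order
  for (seg in sort(unique(snapped$segment[!is.na(snapped$segment)]))) {
    idx <- which(!is.na(snapped$segment) & snapped$segment == seg)
    idx <- idx[order(snapped$pos[idx], points$id[idx])]
    comp <- if (linkage == "single")
      single_linkage_components(snapped$snap_x[idx], snapped$snap_y[idx], radius)
    else complete_linkage_components(snapped$snap_x[idx], snapped$snap_y[idx], radius)
    # order clusters upstream-to-downstream by their most upstream member
    first_pos <- vapply(split(snapped$pos[idx], comp), min, numeric(1))
    ranks <- rank(first_pos, ties.method = "first")
    for (ci in seq_along(first_pos)) {
      members <- idx[comp == as.integer(names(first_pos)[ci])]
      rows[[length(rows) + 1L]] <- data.frame(
        pooled_id = sprintf("seg%d-%d", seg, ranks[ci]),
        segment = seg,
        order = seg_order[seg],
        x = mean(snapped$snap_x[members]),
        y = mean(snapped$snap_y[members]),
        n_members = length(members),
        off_network = FALSE)
      rows[[length(rows)]]$members <- list(sort(points$id[members]))
    }
  }
  off <- which(is.na(snapped$segment))
  off <- off[order(points$id[off])]
  for (i in off) {
    rows[[length(rows) + 1L]] <- data.frame(
      pooled_id = paste0("off-", points$id[i]),
      segment = NA_integer_, order = NA_integer_,
      x = points$x[i], y = points$y[i],
      n_members = 1L, off_network = TRUE)
    rows[[length(rows)]]$members <- list(points$id[i])
  }
  if (length(rows) == 0L)
    return(data.frame(pooled_id = character(0), segment = integer(0),
                      order = integer(0), x = numeric(0), y = numeric(0),
                      n_members = integer(0), off_network = logical(0)))
  out <- do.call(rbind, rows)
  out[order(out$off_network, out$segment, out$pooled_id), , drop = FALSE]
}

#' Export a stream network as GeoJSON LineStrings
#'
#' One LineString per segment through its cell centres, with properties
#' \code{segment_id} and \code{strahler_order}.
#'
#' @param net a stream network.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_network_geojson <- function(net, path) {
  lines <- lapply(net$segments, function(s)
    cell_center(net, s$cells[, "row"], s$cells[, "col"]))
  props <- data.frame(
    segment_id = vapply(net$segments, function(s) s$id, integer(1)),
    strahler_order = vapply(net$segments, function(s) s$order, integer(1)))
  write_geojson_lines(lines, path, props)
}
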