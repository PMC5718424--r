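# Synthetic catchment, drainage, waterbody and two-actor sampling generator.
#
# The generator emulates the data-generating context of a catchment
# monitored by two actors: a regulatory agency ("EA" by default) that
# samples predefined sites nearly every season with no spatial preference,
# and a citizen-science programme ("FWW") whose sites cluster near urban
# accessibility centres, over-represent order-1 streams and small still
# waters, and are sampled mostly in spring and summer. Terrain is a random
# spanning-tree drainage on the raster (acyclic by construction), so the
# drainage module consumes D8 directions directly; no DEM is involved.

#' Configuration for the synthetic catchment generator
#'
#' All knobs of the generator in one validated object. Defaults encode the
#' study conditions the analysis assumes: a near-complete seasonal sampler
#' versus a spring/summer-heavy one, uniform versus accessibility-biased
#' site placement, and citizen preference for order-1 streams and small
#' still waters.
#'
#' @param seed integer seed fixing every draw.
#' @param nrow,ncol,cellsize raster shape and cell size in metres.
#' @param n_urban number of urban accessibility centres.
#' @param n_still number of still waterbodies to place.
#' @param still_meanlog,still_sdlog log-normal parameters of waterbody areas
#'   in hectares.
#' @param n_ea,n_fww number of sites per actor.
#' @param p_still named fraction of each actor's sites on still waters.
#' @param season_p list of per-actor seasonal sampling probabilities
#'   (spring, summer, autumn, winter).
#' @param order_weights list of per-actor site-placement weights by Strahler
#'   order 1-6 (orders above 6 use the order-6 weight).
#' @param still_weights list of per-actor weights for small vs large still
#'   waterbodies.
#' @param urban_decay named per-actor distance-decay rate (1/m) of placement
#'   probability with distance to the nearest urban centre; 0 disables the
#'   decay.
#' @param activity_periods named per-actor mean length, in consecutive
#'   season-year periods, of a site's activity window. \code{Inf} keeps
#'   every site active over the whole study window (a permanent monitoring
#'   station); a finite value gives each site a contiguous window of that
#'   length starting at a uniformly drawn period, emulating volunteers who
#'   monitor a site for a limited spell (the default 4 periods is about one
#'   year).
#' @param accumulation_threshold minimum-accumulation stream condition.
#' @param size_threshold_ha still-water small/large split in hectares.
#' @param window a \code{\link{study_window}}.
#' @param nitrate list with \code{beta0}, \code{beta_order},
#'   \code{beta_smallstill}, \code{season_offsets} (named length-4) and
#'   \code{sigma}: the log-scale nitrate model
#'   mu = beta0 + beta_order * (order - 1) + beta_smallstill * [small still]
#'   + season offset, value = exp(mu + sigma * epsilon).
#' @param actors labels, \code{c(agency = ..., citizen = ...)}.
#' @return object of class \code{synthetic_catchment_config}.
#' @export
synthetic_catchment_config <- function(
    seed = 1L,
    nrow = 200L, ncol = 200L, cellsize = 500,
    n_urban = 4L,
    n_still = 150L, still_meanlog = -0.5, still_sdlog = 2.0,
    n_ea = 691L, n_fww = 870L,
    p_still = c(EA = 25 / 691, FWW = 156 / 870),
    season_p = list(EA = c(spring = 0.95, summer = 0.95,
                           autumn = 0.95, winter = 0.95),
                    FWW = c(spring = 0.9, summer = 0.9,
                            autumn = 0.2, winter = 0.2)),
    order_weights = list(EA = rep(1, 6), FWW = c(5, 1, 1, 1, 1, 1)),
    still_weights = list(EA = c(small = 1, large = 10),
                         FWW = c(small = 8, large = 1)),
    urban_decay = c(EA = 0, FWW = 1 / 10000),
    activity_periods = c(EA = Inf, FWW = 4),
    accumulation_threshold = 50L,
    size_threshold_ha = 8,
    window = study_window(),
    nitrate = list(beta0 = log(2), beta_order = 0.15,
                   beta_smallstill = -1.5,
                   season_offsets = c(spring = 0.05, summer = -0.15,
                                      autumn = 0.05, winter = 0.15),
                   sigma = 0.5),
    actors = c(agency = "EA", citizen = "FWW")) {
  cfg <- list(seed = as.integer(seed), nrow = as.integer(nrow),
              ncol = as.integer(ncol), cellsize = cellsize,
              n_urban = as.integer(n_urban), n_still = as.integer(n_still),
              still_meanlog = still_meanlog, still_sdlog = still_sdlog,
              n_ea = as.integer(n_ea), n_fww = as.integer(n_fww),
              p_still = p_still, season_p = season_p,
              order_weights = order_weights, still_weights = still_weights,
              urban_decay = urban_decay,
              activity_periods = activity_periods,
              accumulation_threshold = as.integer(accumulation_threshold),
              size_threshold_ha = size_threshold_ha,
              window = window, nitrate = nitrate, actors = actors)
  validate_config(cfg)
  structure(cfg, class = "synthetic_catchment_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$nrow >= 4L, cfg$ncol >= 4L, cfg$cellsize > 0,
            cfg$n_urban >= 1L, cfg$n_still >= 0L, cfg$still_sdlog > 0,
            cfg$n_ea >= 1L, cfg$n_fww >= 1L,
            inherits(cfg$window, "study_window"),
            cfg$nitrate$sigma > 0)
  for (a in names(cfg$season_p)) {
    p <- cfg$season_p[[a]]
    if (length(p) != 4L || any(p < 0) || any(p > 1))
      stop("seasonal probabilities for ", a, " must be 4 values in [0, 1]")
  }
  for (a in names(cfg$order_weights)) {
    w <- cfg$order_weights[[a]]
    if (length(w) != 6L || any(w < 0) || all(w == 0))
      stop("order weights for ", a,
           " must be 6 non-negative values, not all zero")
  }
  for (a in names(cfg$still_weights)) {
    w <- cfg$still_weights[[a]]
    if (any(w < 0) || all(w == 0))
      stop("still-water weights for ", a, " must be non-negative, not all zero")
  }
  if (any(cfg$p_still < 0) || any(cfg$p_still > 1))
    stop("p_still must lie in [0, 1]")
  invisible(cfg)
}

#' @export
print.synthetic_catchment_config <- function(x, ...) {
  cat("Synthetic catchment config: ", x$nrow, "x", x$ncol, " raster at ",
      x$cellsize, " m, seed ", x$seed, "\n  ", x$n_ea, " ", x$actors[["agency"]],
      " sites, ", x$n_fww, " ", x$actors[["citizen"]], " sites, ",
      x$n_still, " still waterbodies\n", sep = "")
  invisible(x)
}

# Random spanning-tree drainage: randomized Prim growth over the
# 8-neighbour grid graph from the outlet. Each newly attached cell's D8 code
# points to the already-drained neighbour it was attached through, so every
# path terminates at the outlet and the raster is acyclic. Prim growth makes
# a dendritic tree (many short branches feeding a backbone), which is what a
# natural drainage looks like; depth-first growth would give one long snake.
random_drainage <- function(nr, nc, cellsize) {
  n <- nr * nc
  codes <- matrix(NA_integer_, nr, nc)
  outlet <- c(nr, max(1L, nc %/% 2L))
  visited <- matrix(FALSE, nr, nc)
  visited[outlet[1], outlet[2]] <- TRUE
  codes[outlet[1], outlet[2]] <- 0L
  # frontier of unvisited cells adjacent to the tree (preallocated;
  # removal is swap-with-last since the pick is uniform anyway)
  fr <- integer(n); fc <- integer(n)
  cnt <- 0L
  in_frontier <- matrix(FALSE, nr, nc)
  add_frontier <- function(r, cl) {
    for (k in seq_len(8L)) {
      r2 <- r + D8_DROW[k]; c2 <- cl + D8_DCOL[k]
      if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc &&
          !visited[r2, c2] && !in_frontier[r2, c2]) {
        cnt <<- cnt + 1L
        fr[cnt] <<- r2
        fc[cnt] <<- c2
        in_frontier[r2, c2] <<- TRUE
      }
    }
  }
  add_frontier(outlet[1], outlet[2])
  while (cnt > 0L) {
    i <- sample.int(cnt, 1L)
    r <- fr[i]; cl <- fc[i]
    fr[i] <- fr[cnt]; fc[i] <- fc[cnt]
    cnt <- cnt - 1L
    in_frontier[r, cl] <- FALSE
    # attach to a random already-drained neighbour
    ks <- sample.int(8L)
    for (k in ks) {
      r2 <- r + D8_DROW[k]; c2 <- cl + D8_DCOL[k]
      if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc && visited[r2, c2]) {
        codes[r, cl] <- D8_CODES[k]
        break
      }
    }
    visited[r, cl] <- TRUE
    add_frontier(r, cl)
  }
  d8_grid(codes, cellsize = cellsize, xll = 0, yll = 0)
}

# Regular n-gon with exact target area (m^2), centred at (cx, cy).
area_polygon <- function(cx, cy, area_m2, nv = 24L) {
  radius <- sqrt(2 * area_m2 / (nv * sin(2 * pi / nv)))
  ang <- seq(0, nv - 1L) * 2 * pi / nv
  cbind(cx + radius * cos(ang), cy + radius * sin(ang))
}

uniform_points_in_polygon <- function(n, boundary, max_tries = 1000L) {
  bb <- polygon_bbox(boundary)
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  for (t in seq_len(max_tries)) {
    if (got >= n) break
    m <- max(4L * (n - got), 16L)
    px <- stats::runif(m, bb["xmin"], bb["xmax"])
    py <- stats::runif(m, bb["ymin"], bb["ymax"])
    keep <- which(point_in_polygon(px, py, boundary))
    take <- keep[seq_len(min(length(keep), n - got))]
    if (length(take) > 0L) {
      out[(got + 1L):(got + length(take)), ] <- cbind(px[take], py[take])
      got <- got + length(take)
    }
  }
  if (got < n) stop("could not place points inside the boundary")
  out
}

#' Generate a synthetic catchment
#'
#' Builds, deterministically for the config's seed: a random spanning-tree
#' D8 drainage with a single outlet, its flow accumulation and
#' Strahler-ordered stream network, a convex-hull catchment boundary, urban
#' accessibility centres, and non-overlapping still waterbody polygons with
#' log-normal areas.
#'
#' @param config a \code{\link{synthetic_catchment_config}}.
#' @return object of class \code{synthetic_catchment}: list with
#'   \code{boundary}, \code{d8}, \code{accumulation}, \code{network},
#'   \code{waterbodies} (data frame: \code{wb_id}, \code{x}, \code{y},
#'   \code{area_ha}, \code{size_class}, plus the \code{polygons} list
#'   attribute), \code{urban} (centre coordinates) and \code{config}.
#' @export
generate_catchment <- function(config) {
  stopifnot(inherits(config, "synthetic_catchment_config"))
  set.seed(config$seed)
  d8 <- random_drainage(config$nrow, config$ncol, config$cellsize)
  acc <- flow_accumulation(d8)
  net <- strahler_order(extract_streams(acc, config$accumulation_threshold))

  ctr <- cell_center(d8, rep(seq_len(config$nrow), config$ncol),
                     rep(seq_len(config$ncol), each = config$nrow))
  hull <- grDevices::chull(ctr)
  boundary <- ctr[hull, , drop = FALSE]

  urban <- uniform_points_in_polygon(config$n_urban, boundary)

  wb_area <- stats::rlnorm(config$n_still, config$still_meanlog,
                           config$still_sdlog)
  wb_radius <- sqrt(wb_area * 1e4 / pi)
  polys <- vector("list", config$n_still)
  cx <- numeric(config$n_still); cy <- numeric(config$n_still)
  placed <- 0L
  tries <- 0L
  max_tries <- 200L * max(config$n_still, 1L)
  bb <- polygon_bbox(boundary)
  while (placed < config$n_still) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place ", config$n_still,
           " non-overlapping waterbodies after ", max_tries, " tries")
    px <- stats::runif(1, bb["xmin"], bb["xmax"])
    py <- stats::runif(1, bb["ymin"], bb["ymax"])
    i <- placed + 1L
    if (!point_in_polygon(px, py, boundary)) next
    if (placed > 0L) {
      d <- sqrt((cx[seq_len(placed)] - px)^2 + (cy[seq_len(placed)] - py)^2)
      if (any(d < wb_radius[seq_len(placed)] + wb_radius[i] + 10)) next
    }
    cx[i] <- px; cy[i] <- py
    polys[[i]] <- area_polygon(px, py, wb_area[i] * 1e4)
    placed <- i
  }
  wb <- data.frame(wb_id = sprintf("wb-%03d", seq_len(config$n_still)),
                   x = cx, y = cy, area_ha = wb_area,
                   size_class = classify_size(wb_area, config$size_threshold_ha))
  attr(wb, "polygons") <- polys
  structure(list(boundary = boundary, d8 = d8, accumulation = acc,
                 network = net, waterbodies = wb, urban = urban,
                 config = config),
            class = "synthetic_catchment")
}

#' @export
print.synthetic_catchment <- function(x, ...) {
  cat("Synthetic catchment (seed ", x$config$seed, "): ",
      nrow(x$boundary), "-vertex boundary, ",
      length(x$network$segments), " stream segments, ",
      nrow(x$waterbodies), " still waterbodies\n", sep = "")
  invisible(x)
}

# Season-year periods intersecting the window, with their date ranges.
window_periods <- function(window) {
  days <- seq(window$start, window$end, by = "day")
  s <- assign_season(days)
  y <- season_year(days)
  key <- paste(s, y)
  idx <- split(seq_along(days), key)
  out <- do.call(rbind, lapply(idx, function(ix) {
    data.frame(season = s[ix[1]], season_year = y[ix[1]],
               first = days[min(ix)], last = days[max(ix)])
  }))
  out <- out[order(out$season_year, match(out$season, SEASONS)), ]
  rownames(out) <- NULL
  out
}

#' Draw nitrate values for a set of site-season draws
#'
#' The log-scale mean is mu = beta0 + beta_order * (order - 1) for running
#' sites (the order term is omitted for still sites), plus
#' beta_smallstill for small still waters and the season offset; values are
#' exp(mu + sigma * epsilon) with standard-normal epsilon. The categorical
#' (field-kit style) reading is the continuous value passed through
#' \code{\link{categorize}}.
#'
#' @param model nitrate model list (see
#'   \code{\link{synthetic_catchment_config}}).
#' @param sites data frame with one row per draw: \code{waterbody_class},
#'   \code{order} (\code{NA} for still sites), \code{small_still} (logical).
#' @param seasons character vector parallel to \code{sites} rows.
#' @param seed integer seed.
#' @param scheme category scheme for the categorical readings.
#' @return data frame with \code{value} (mg/L) and \code{category}.
#' @export
generate_nitrate <- function(model, sites, seasons, seed,
                             scheme = nitrate_scheme()) {
  set.seed(seed)
  n <- nrow(sites)
  ord_term <- ifelse(sites$waterbody_class == "running" & !is.na(sites$order),
                     model$beta_order * (sites$order - 1), 0)
  still_term <- ifelse(sites$small_still, model$beta_smallstill, 0)
  mu <- model$beta0 + ord_term + still_term +
    model$season_offsets[seasons]
  value <- exp(mu + model$sigma * stats::rnorm(n))
  data.frame(value = unname(value),
             category = as.character(categorize(value, scheme)))
}

place_actor_sites <- function(actor_key, cfg, catchment, stream_tab, seg_order) {
  actor <- cfg$actors[[actor_key]]
  n_sites <- if (actor_key == "agency") cfg$n_ea else cfg$n_fww
  p_still <- unname(cfg$p_still[[actor]])
  n_still_sites <- round(n_sites * p_still)
  n_run_sites <- n_sites - n_still_sites
  decay <- unname(cfg$urban_decay[[actor]])
  urban_dist <- function(px, py) {
    d <- outer(px, catchment$urban[, 1], "-")^2 +
      outer(py, catchment$urban[, 2], "-")^2
    sqrt(apply(d, 1, min))
  }

  sites <- list()
  if (n_run_sites > 0L) {
    if (nrow(stream_tab) == 0L)
      stop("no eligible running-water cells for actor ", actor)
    ow <- cfg$order_weights[[actor]]
    w <- ow[pmin(seg_order[stream_tab$segment], 6L)]
    if (decay > 0)
      w <- w * exp(-decay * urban_dist(stream_tab$x, stream_tab$y))
    if (all(w == 0)) stop("all running-water weights are zero for actor ", actor)
    pick <- sample.int(nrow(stream_tab), n_run_sites, replace = TRUE, prob = w)
    jit <- cfg$cellsize / 4
    sites$running <- data.frame(
      site_id = sprintf("%s-R-%04d", actor, seq_len(n_run_sites)),
      x = stream_tab$x[pick] + stats::runif(n_run_sites, -jit, jit),
      y = stream_tab$y[pick] + stats::runif(n_run_sites, -jit, jit),
      waterbody_class = "running",
      order = seg_order[stream_tab$segment[pick]],
      small_still = FALSE, wb_id = NA_character_)
  }
  if (n_still_sites > 0L) {
    wb <- catchment$waterbodies
    if (nrow(wb) == 0L) stop("no still waterbodies for actor ", actor)
    sw <- cfg$still_weights[[actor]]
    w <- unname(sw[as.character(wb$size_class)])
    if (decay > 0) w <- w * exp(-decay * urban_dist(wb$x, wb$y))
    if (all(w == 0)) stop("all still-water weights are zero for actor ", actor)
    replace <- n_still_sites > sum(w > 0)
    pick <- sample.int(nrow(wb), n_still_sites, replace = replace, prob = w)
    sites$still <- data.frame(
      site_id = sprintf("%s-S-%04d", actor, seq_len(n_still_sites)),
      x = wb$x[pick], y = wb$y[pick],
      waterbody_class = "still",
      order = NA_integer_,
      small_still = wb$size_class[pick] == "small",
      wb_id = wb$wb_id[pick])
  }
  out <- do.call(rbind, sites)
  out$actor <- actor
  rownames(out) <- NULL
  out
}

#' Generate two-actor sample records over a synthetic catchment
#'
#' Places each actor's sites (running-water sites on stream cells weighted
#' by Strahler order and, for the citizen actor, by proximity to urban
#' centres; still-water sites on waterbodies weighted by size class), then
#' visits each site in each season-year period of the window with the
#' actor's seasonal probability and draws a nitrate value from the
#' generator's log-normal model. The agency actor reports continuous values;
#' the citizen actor reports categorized readings.
#'
#' @param config a \code{\link{synthetic_catchment_config}}.
#' @param catchment result of \code{\link{generate_catchment}(config)}.
#' @param scheme category scheme for the citizen actor's readings.
#' @return sample data frame in the \code{\link{read_samples}} layout, with
#'   the site attribute table attached as the \code{sites} attribute.
#' @export
generate_sampling <- function(config, catchment, scheme = nitrate_scheme()) {
  stopifnot(inherits(config, "synthetic_catchment_config"),
            inherits(catchment, "synthetic_catchment"))
  set.seed(config$seed + 1L)
  net <- catchment$network
  stream_tab <- network_cell_table(net)
  seg_order <- vapply(net$segments, function(s) s$order, integer(1))

  sites <- rbind(
    place_actor_sites("agency", config, catchment, stream_tab, seg_order),
    place_actor_sites("citizen", config, catchment, stream_tab, seg_order))

  periods <- window_periods(config$window)
  recs <- list()
  for (a in unname(config$actors)) {
    p_season <- config$season_p[[a]]
    asites <- sites[sites$actor == a, , drop = FALSE]
    len <- unname(config$activity_periods[[a]])
    if (is.finite(len)) {
      first_active <- sample.int(nrow(periods), nrow(asites), replace = TRUE)
      last_active <- pmin(first_active + len - 1L, nrow(periods))
    } else {
      first_active <- rep(1L, nrow(asites))
      last_active <- rep(nrow(periods), nrow(asites))
    }
    for (k in seq_len(nrow(periods))) {
      p <- unname(p_season[[periods$season[k]]])
      active <- first_active <= k & k <= last_active
      visit <- active & stats::runif(nrow(asites)) < p
      if (!any(visit)) next
      sub <- asites[visit, , drop = FALSE]
      span <- as.integer(periods$last[k] - periods$first[k])
      dates <- periods$first[k] + sample.int(span + 1L, nrow(sub),
                                             replace = TRUE) - 1L
      recs[[length(recs) + 1L]] <- data.frame(
        actor = sub$actor, site_id = sub$site_id, x = sub$x, y = sub$y,
        timestamp = dates, determinand = "nitrate-N",
        season = periods$season[k],
        order = sub$order, small_still = sub$small_still,
        waterbody_class = sub$waterbody_class)
    }
  }
  recs <- do.call(rbind, recs)
  nit <- generate_nitrate(config$nitrate, recs, recs$season,
                          seed = config$seed + 2L, scheme = scheme)
  citizen <- recs$actor == config$actors[["citizen"]]
  out <- data.frame(
    actor = recs$actor, site_id = recs$site_id, x = recs$x, y = recs$y,
    timestamp = recs$timestamp, determinand = recs$determinand,
    value = ifelse(citizen, NA_real_, nit$value),
    category = ifelse(citizen, nit$category, NA_character_),
    value_kind = ifelse(citizen, "categorical", "continuous"),
    waterbody_class = recs$waterbody_class,
    stringsAsFactors = FALSE)
  ord <- order(out$actor, out$site_id, out$timestamp)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sites") <- sites
  out
}

#' Write a synthetic catchment and its samples to disk
#'
#' Emits exactly the formats the pipeline reads: the sample CSV, boundary
#' and waterbody GeoJSON, the D8 ESRI ASCII grid, and a JSON manifest
#' recording the config and seed.
#'
#' @param catchment a \code{synthetic_catchment}.
#' @param samples sample data frame from \code{\link{generate_sampling}}.
#' @param dir output directory (created if needed).
#' @return named vector of the written paths, invisibly.
#' @export
write_synthetic_inputs <- function(catchment, samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(samples = file.path(dir, "samples.csv"),
             boundary = file.path(dir, "boundary.geojson"),
             waterbodies = file.path(dir, "waterbodies.geojson"),
             d8 = file.path(dir, "flowdir.asc"),
             manifest = file.path(dir, "manifest.json"))
  write_samples(samples, paths["samples"])
  write_geojson_polygons(list(catchment$boundary), paths["boundary"])
  wb <- catchment$waterbodies
  write_geojson_polygons(attr(wb, "polygons"), paths["waterbodies"],
                         data.frame(site_id = wb$wb_id,
                                    area_ha = wb$area_ha))
  write_ascii_grid(catchment$d8, paths["d8"])
  cfg <- catchment$config
  cfg$window <- list(start = format(cfg$window$start),
                     end = format(cfg$window$end))
  jsonlite::write_json(cfg, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(paths)
}
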