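# Pipeline orchestration: from raw inputs (files or the synthetic
# generator) to the coverage/overlap maps, waterbody-size, stream-order and
# nitrate-category association analyses, with stage-level logging of record
# counts.

#' Pipeline run configuration
#'
#' Exactly one of the file-input block (\code{samples}, \code{boundary},
#' \code{d8}, \code{waterbodies} paths) or \code{simulate} (a
#' \code{\link{synthetic_catchment_config}}) must be supplied.
#'
#' @param samples,boundary,d8,waterbodies input file paths (sample CSV,
#'   boundary GeoJSON, D8 ESRI ASCII grid, waterbody GeoJSON).
#' @param simulate a \code{\link{synthetic_catchment_config}}.
#' @param actors actor labels, \code{c(agency = ..., citizen = ...)}; the
#'   agency actor is the overlap reference and the citizen actor the
#'   gap-filling one.
#' @param grid_edge hexagon edge length in metres (default 5000).
#' @param accumulation_threshold minimum-accumulation stream condition
#'   (cells, default 50).
#' @param pooling_radius site-pooling distance in metres (default 50).
#' @param max_snap maximum site-to-stream snapping distance in metres.
#' @param size_threshold_ha still-water small/large split (default 8 ha).
#' @param scheme a \code{\link{nitrate_scheme}}.
#' @param alpha significance level for post-hoc flags.
#' @param window a \code{\link{study_window}}.
#' @param out_dir optional output directory for the report bundle.
#' @param crs optional CRS identifier of the planar coordinates (sidecar
#'   metadata; the pipeline never reprojects).
#' @return object of class \code{run_config}.
#' @export
run_config <- function(samples = NULL, boundary = NULL, d8 = NULL,
                       waterbodies = NULL, simulate = NULL,
                       actors = c(agency = "EA", citizen = "FWW"),
                       grid_edge = 5000, accumulation_threshold = 50,
                       pooling_radius = 50, max_snap = 200,
                       size_threshold_ha = 8, scheme = nitrate_scheme(),
                       alpha = 0.05, window = study_window(),
                       out_dir = NULL, crs = NULL) {
  have_paths <- !is.null(samples)
  have_sim <- !is.null(simulate)
  if (have_paths == have_sim)
    stop("supply exactly one of the input paths or a simulate config")
  if (have_sim) stopifnot(inherits(simulate, "synthetic_catchment_config"))
  stopifnot(grid_edge > 0, accumulation_threshold >= 0, pooling_radius > 0,
            max_snap > 0, size_threshold_ha > 0, alpha > 0, alpha < 1)
  structure(list(samples = samples, boundary = boundary, d8 = d8,
                 waterbodies = waterbodies, simulate = simulate,
                 actors = actors, grid_edge = grid_edge,
                 accumulation_threshold = accumulation_threshold,
                 pooling_radius = pooling_radius, max_snap = max_snap,
                 size_threshold_ha = size_threshold_ha, scheme = scheme,
                 alpha = alpha, window = window, out_dir = out_dir,
                 crs = crs),
            class = "run_config")
}

stage_log <- function(log, stage, ...) {
  line <- paste0("[", stage, "] ", paste0(..., collapse = ""))
  message(line)
  c(log, line)
}

# Run an association on a table that may be degenerate at small scale
# (e.g. one actor contributed no large still waters): keep the table,
# return NULL test/posthoc and a log-able reason instead of aborting.
safe_assoc <- function(tab, alpha) {
  out <- list(table = tab, test = NULL, posthoc = NULL, skipped = NULL)
  res <- tryCatch(list(test = chi_square(tab),
                       posthoc = adjusted_residuals(tab, alpha = alpha)),
                  error = function(e) conditionMessage(e))
  if (is.character(res)) out$skipped <- res
  else { out$test <- res$test; out$posthoc <- res$posthoc }
  out
}

#' Run the complementarity pipeline
#'
#' Executes the full analysis: window filtering and season assignment;
#' hexagonal-grid seasonal coverage, overlap classification and gap-fill
#' detection for both actors; running-water site snapping, pooling and the
#' stream-order association (chi-squared, Cramer's V, adjusted-residual
#' post-hoc); still-water size classification with its 2 x 2 association and
#' a Mann-Whitney test on site areas; and the nitrate-category association.
#' Every stage logs record counts in and out. When \code{out_dir} is set the
#' bundle is also written to disk (GeoJSON grid and network, CSV tables, a
#' plain-text report and \code{run.log}).
#'
#' @param config a \code{\link{run_config}}.
#' @return object of class \code{complementarity_report} (a list of stage
#'   results; see the elements \code{coverage}, \code{stream_order},
#'   \code{still_water}, \code{nitrate}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  agency <- config$actors[["agency"]]
  citizen <- config$actors[["citizen"]]

  # --- inputs ---------------------------------------------------------
  if (!is.null(config$simulate)) {
    log <- stage_log(log, "input", "simulating catchment (seed ",
                     config$simulate$seed, ")")
    catchment <- generate_catchment(config$simulate)
    samples <- generate_sampling(config$simulate, catchment, config$scheme)
    boundary <- catchment$boundary
    d8 <- catchment$d8
    wb_polys <- attr(catchment$waterbodies, "polygons")
    wb_ids <- catchment$waterbodies$wb_id
    acc <- catchment$accumulation
    net <- catchment$network
  } else {
    log <- stage_log(log, "input", "reading ", config$samples)
    samples <- read_samples(config$samples)
    rej <- attr(samples, "rejected")
    if (!is.null(rej) && nrow(rej) > 0L)
      log <- stage_log(log, "input", nrow(rej), " row(s) rejected")
    bset <- read_geojson_polygons(config$boundary, crs = config$crs)
    boundary <- bset[[1L]]
    d8 <- read_ascii_grid(config$d8, as_d8 = TRUE)
    wbs <- if (!is.null(config$waterbodies))
      read_geojson_polygons(config$waterbodies, crs = config$crs) else list()
    wb_polys <- wbs
    wb_ids <- vapply(seq_along(wbs), function(i) {
      p <- attr(wbs[[i]], "properties")
      as.character(p$site_id %||% p$id %||% paste0("wb-", i))
    }, character(1))
    acc <- flow_accumulation(d8)
    net <- strahler_order(extract_streams(acc, config$accumulation_threshold))
  }
  n_in <- nrow(samples)
  samples <- filter_window(samples, config$window)
  log <- stage_log(log, "window", n_in, " records in, ", nrow(samples),
                   " inside ", format(config$window$start), "..",
                   format(config$window$end))
  if (nrow(samples) == 0L) stop("pipeline aborted at stage 'window': ",
                                "no records inside the study window")

  # --- coverage -------------------------------------------------------
  grid <- build_hex_grid(boundary, config$grid_edge, crs = config$crs)
  log <- stage_log(log, "grid", nrow(grid$cells), " hexagon cells of ",
                   round(hex_cell_area_km2(config$grid_edge), 2), " km^2")
  covA <- seasonal_coverage(samples, grid, agency)
  covB <- seasonal_coverage(samples, grid, citizen)
  classes <- classify_overlap(covA, covB)
  cov_summary <- summarize_coverage(covA, covB, classes)
  log <- stage_log(log, "coverage", "complete/partial/none = ",
                   sum(classes$overlap_class == "complete"), "/",
                   sum(classes$overlap_class == "partial"), "/",
                   sum(classes$overlap_class == "none"), ", gap-fill ",
                   sum(classes$gap_fill), " cells")

  # --- running water: stream order -----------------------------------
  running <- samples[samples$waterbody_class == "running", , drop = FALSE]
  stream_order_res <- NULL
  pooled_all <- NULL
  if (nrow(running) > 0L && length(net$segments) > 0L) {
    pooled_by_actor <- list()
    for (a in c(agency, citizen)) {
      pts <- unique(running[running$actor == a,
                            c("site_id", "x", "y"), drop = FALSE])
      names(pts)[1] <- "id"
      pooled <- pool_sites(pts, net, radius = config$pooling_radius,
                           max_snap = config$max_snap)
      n_off <- sum(pooled$off_network)
      log <- stage_log(log, "streamorder", a, ": ", nrow(pts),
                       " raw sites -> ", nrow(pooled), " pooled sites (",
                       n_off, " off-network, excluded from the order table)")
      pooled$actor <- a
      pooled_by_actor[[a]] <- pooled
    }
    pooled_all <- do.call(rbind, pooled_by_actor)
    on_net <- pooled_all[!pooled_all$off_network, , drop = FALSE]
    if (nrow(on_net) > 0L && length(unique(on_net$actor)) == 2L) {
      tab <- contingency_table(on_net$actor, on_net$order,
                               col_levels = sort(unique(on_net$order)))
      colnames(tab) <- paste0("order", colnames(tab))
      stream_order_res <- safe_assoc(tab, config$alpha)
      log <- if (is.null(stream_order_res$skipped))
        stage_log(log, "streamorder",
                  sprintf("X^2 = %.2f, V = %.3f",
                          stream_order_res$test$statistic,
                          stream_order_res$test$cramers_v))
      else stage_log(log, "streamorder", "association skipped: ",
                     stream_order_res$skipped)
    }
  } else {
    log <- stage_log(log, "streamorder", "skipped (no running-water ",
                     "records or empty network)")
  }

  # --- still water: size ----------------------------------------------
  still <- samples[samples$waterbody_class == "still", , drop = FALSE]
  still_res <- NULL
  if (nrow(still) > 0L && length(wb_polys) > 0L) {
    sites <- unique(still[, c("actor", "site_id", "x", "y"), drop = FALSE])
    area_tab <- still_water_table(wb_polys, wb_ids,
                                  threshold = config$size_threshold_ha)
    match_idx <- match_sites_to_waterbodies(sites, wb_polys)
    matched <- !is.na(match_idx)
    log <- stage_log(log, "sizeclass", nrow(sites), " still sites, ",
                     sum(matched), " matched to a waterbody polygon (",
                     sum(!matched), " excluded)")
    sw <- data.frame(actor = sites$actor[matched],
                     site_id = sites$site_id[matched],
                     wb_id = area_tab$site_id[match_idx[matched]],
                     area_ha = area_tab$area_ha[match_idx[matched]],
                     size_class = area_tab$size_class[match_idx[matched]])
    if (length(unique(sw$actor)) == 2L && nrow(sw) >= 4L) {
      tab <- contingency_table(sw$actor, as.character(sw$size_class),
                               col_levels = c("small", "large"))
      colnames(tab) <- paste0(colnames(tab),
                              c("(<=8ha)", "(>8ha)")[seq_len(ncol(tab))])
      mw <- mann_whitney(sw$area_ha[sw$actor == agency],
                         sw$area_ha[sw$actor == citizen])
      still_res <- safe_assoc(tab, config$alpha)
      still_res$sites <- sw
      still_res$mann_whitney <- mw
      log <- if (is.null(still_res$skipped))
        stage_log(log, "sizeclass",
                  sprintf("X^2 = %.2f, U = %g; median areas %s %.2f ha, %s %.2f ha",
                          still_res$test$statistic, mw$U, agency,
                          mw$median1, citizen, mw$median2))
      else stage_log(log, "sizeclass", "association skipped: ",
                     still_res$skipped)
    }
  } else {
    log <- stage_log(log, "sizeclass", "skipped (no still-water records ",
                     "or no waterbody polygons)")
  }

  # --- nitrate categories ---------------------------------------------
  site_summary <- site_nitrate_summary(samples, config$scheme)
  tab <- contingency_table(site_summary$actor, site_summary$site_category,
                           col_levels = config$scheme$labels)
  nitrate_res <- safe_assoc(tab, config$alpha)
  nitrate_res$sites <- site_summary
  nitrate_res$cell_season <- cell_season_medians(samples, grid, config$scheme)
  log <- if (is.null(nitrate_res$skipped))
    stage_log(log, "nitrate", nrow(site_summary), " sites; X^2 = ",
              sprintf("%.2f, V = %.3f", nitrate_res$test$statistic,
                      nitrate_res$test$cramers_v))
  else stage_log(log, "nitrate", "association skipped: ",
                 nitrate_res$skipped)

  report <- structure(list(
    config = config, grid = grid, network = net,
    samples = samples,
    coverage = list(agency = covA, citizen = covB, classes = classes,
                    summary = cov_summary),
    stream_order = stream_order_res,
    pooled_sites = pooled_all,
    still_water = still_res,
    nitrate = nitrate_res,
    log = log), class = "complementarity_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Point-in-polygon site/waterbody matching with a nearest-centroid fallback
# within one polygon "radius" (for sites digitized just off the outline).
match_sites_to_waterbodies <- function(sites, wb_polys) {
  n <- nrow(sites)
  idx <- rep(NA_integer_, n)
  if (length(wb_polys) == 0L || n == 0L) return(idx)
  cents <- t(vapply(wb_polys, function(p) {
    ring_centroid(normalize_multipolygon(p)[[1L]][[1L]])
  }, numeric(2)))
  radii <- vapply(wb_polys, function(p) {
    sqrt(polygon_area(normalize_multipolygon(p)) / pi)
  }, numeric(1))
  for (i in seq_len(n)) {
    inside <- which(vapply(wb_polys, function(p)
      point_in_polygon(sites$x[i], sites$y[i], p), logical(1)))
    if (length(inside) > 0L) { idx[i] <- inside[1L]; next }
    d <- sqrt((cents[, 1] - sites$x[i])^2 + (cents[, 2] - sites$y[i])^2)
    j <- which.min(d)
    if (d[j] <= 2 * radii[j]) idx[i] <- j
  }
  idx
}

#' @export
print.complementarity_report <- function(x, ...) {
  cat("Complementarity report\n")
  cat("======================\n\n")
  print(x$coverage$summary)
  print_assoc <- function(res) {
    print(res$table)
    if (!is.null(res$skipped))
      cat("  association skipped:", res$skipped, "\n")
    if (!is.null(res$test)) print(res$test)
    if (!is.null(res$posthoc)) print(res$posthoc)
  }
  if (!is.null(x$stream_order)) {
    cat("\nRunning-water sites by stream order:\n")
    print_assoc(x$stream_order)
  }
  if (!is.null(x$still_water)) {
    cat("\nStill-water sites by size class:\n")
    print_assoc(x$still_water)
    print(x$still_water$mann_whitney)
  }
  cat("\nSites by nitrate category:\n")
  print_assoc(x$nitrate)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits the coverage grid GeoJSON (per-cell scores, overlap class,
#' gap-fill), the stream-network GeoJSON, the summary and association CSVs,
#' a plain-text report and the run log.
#'
#' @param report a \code{complementarity_report}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  covA <- report$coverage$agency; covB <- report$coverage$citizen
  cls <- report$coverage$classes
  props <- data.frame(score_A = covA$score, score_B = covB$score,
                      overlap_class = as.character(cls$overlap_class),
                      gap_fill = cls$gap_fill)
  names(props)[1:2] <- paste0("score_", c(attr(covA, "actor"),
                                          attr(covB, "actor")))
  write_grid_geojson(report$grid, file.path(dir, "coverage_grid.geojson"),
                     props)
  if (length(report$network$segments) > 0L)
    write_network_geojson(report$network, file.path(dir, "network.geojson"))
  s <- report$coverage$summary
  utils::write.csv(data.frame(
    quantity = c(paste0("pct_all_seasons_", s$actors$actor),
                 paste0("pct_covered_", s$actors$actor),
                 "pct_complete", "pct_partial", "pct_overlap",
                 "pct_gap_fill"),
    value = c(s$actors$pct_all_seasons, s$actors$pct_covered,
              s$pct_complete, s$pct_partial, s$pct_overlap, s$pct_gap_fill),
    rounded = round_half_up(c(s$actors$pct_all_seasons, s$actors$pct_covered,
                              s$pct_complete, s$pct_partial, s$pct_overlap,
                              s$pct_gap_fill))),
    file.path(dir, "coverage_summary.csv"), row.names = FALSE)
  write_assoc_csv <- function(res, stem) {
    if (is.null(res)) return(invisible(NULL))
    utils::write.csv(as.data.frame(res$table),
                     file.path(dir, paste0(stem, "_table.csv")))
    if (is.null(res$test)) return(invisible(NULL))
    t <- res$test
    utils::write.csv(data.frame(chi2 = t$statistic, df = t$df,
                                p = t$p.value, cramers_v = t$cramers_v,
                                N = t$N),
                     file.path(dir, paste0(stem, "_test.csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(res$posthoc$z),
                     file.path(dir, paste0(stem, "_residuals.csv")))
  }
  write_assoc_csv(report$stream_order, "stream_order")
  write_assoc_csv(report$still_water, "still_water")
  write_assoc_csv(report$nitrate, "nitrate")
  if (!is.null(report$nitrate$sites))
    utils::write.csv(report$nitrate$sites,
                     file.path(dir, "site_nitrate.csv"), row.names = FALSE)
  if (!is.null(report$nitrate$cell_season))
    utils::write.csv(report$nitrate$cell_season,
                     file.path(dir, "cell_season_medians.csv"),
                     row.names = FALSE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  writeLines(report$log, file.path(dir, "run.log"))
  invisible(dir)
}
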