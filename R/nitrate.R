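# Nitrate-N category harmonization and site/seasonal medians.
#
# The field-kit scheme is categorical with bin edges 0.2, 0.5, 1, 2, 5 and
# 10 mg/L as N (seven bins); laboratory measurements are continuous and are
# placed into the same bins. Bins are right-closed: a value equal to an
# interior edge falls in the lower bin, consistent with the first label
# "<=0.2".

#' The seven-bin nitrate category scheme
#'
#' @param edges strictly increasing bin edges in mg/L as N.
#' @return object of class \code{category_scheme}: list with \code{edges},
#'   \code{labels} (length \code{length(edges) + 1}) and \code{midpoints}
#'   used when pooling categorical readings with continuous values. The
#'   first bin's midpoint is half its upper edge; the open top bin is
#'   represented by a sentinel at 1.5 times the last edge, which always
#'   exceeds that edge.
#' @export
nitrate_scheme <- function(edges = c(0.2, 0.5, 1, 2, 5, 10)) {
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  k <- length(edges)
  labels <- c(paste0("<=", edges[1]),
              paste0(edges[-k], "-", edges[-1]),
              paste0(">", edges[k]))
  midpoints <- c(edges[1] / 2, (edges[-k] + edges[-1]) / 2, 1.5 * edges[k])
  structure(list(edges = edges, labels = labels, midpoints = midpoints),
            class = "category_scheme")
}

#' @export
print.category_scheme <- function(x, ...) {
  cat("Nitrate category scheme (mg/L as N):",
      paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Place continuous nitrate values into categories
#'
#' Right-closed bins: value in (edge[k-1], edge[k]] gets label k; values at
#' or below the first edge get the first label; values above the last edge
#' get the last.
#'
#' @param value non-negative concentration(s) in mg/L as N.
#' @param scheme a \code{\link{nitrate_scheme}}.
#' @return factor over the scheme's labels (ordered).
#' @export
categorize <- function(value, scheme = nitrate_scheme()) {
  if (any(is.na(value)) || any(value < 0))
    stop("nitrate values must be non-negative")
  idx <- vapply(value, function(v) sum(v > scheme$edges), integer(1)) + 1L
  factor(scheme$labels[idx], levels = scheme$labels, ordered = TRUE)
}

#' Median of one site-season's measurements
#'
#' Standard median (mean of the middle two for even counts).
#'
#' @param values at least one concentration in mg/L.
#' @return the median concentration.
#' @export
seasonal_median <- function(values) {
  if (length(values) == 0L) stop("seasonal_median requires at least one value")
  stats::median(values)
}

# One pooled numeric value per record: continuous records keep their value,
# categorical records are represented by their bin midpoint (the open top
# bin by its sentinel).
pooled_values <- function(records, scheme) {
  v <- records$value
  cat_rows <- records$value_kind == "categorical"
  if (any(cat_rows)) {
    idx <- match(records$category[cat_rows], scheme$labels)
    if (any(is.na(idx)))
      stop("unknown category label(s): ",
           paste(unique(records$category[cat_rows][is.na(idx)]), collapse = ", "))
    v[cat_rows] <- scheme$midpoints[idx]
  }
  v
}

#' Overall nitrate category of one site
#'
#' Median of all the site's window samples, then categorized. Categorical
#' readings are pooled via their bin midpoints; a site mixing continuous and
#' categorical records is flagged in the result's \code{mixed_kinds}
#' attribute (the two actors here never mix kinds, so this path is an
#' extension).
#'
#' @param records the site's sample records (data frame with \code{value},
#'   \code{category}, \code{value_kind}).
#' @param scheme a \code{\link{nitrate_scheme}}.
#' @return the site's category label (factor), with attribute
#'   \code{median_mgL} (\code{NA} when any record is categorical) and
#'   \code{mixed_kinds}.
#' @export
site_category <- function(records, scheme = nitrate_scheme()) {
  if (nrow(records) == 0L) stop("site_category requires at least one record")
  v <- pooled_values(records, scheme)
  med <- stats::median(v)
  out <- categorize(med, scheme)
  kinds <- unique(records$value_kind)
  attr(out, "median_mgL") <- if (all(kinds == "continuous")) med else NA_real_
  attr(out, "mixed_kinds") <- length(kinds) > 1L
  out
}

#' Site-level nitrate summary table
#'
#' One row per site: sample count, overall median (blank for sites with any
#' categorical reading), overall category, and per-season medians and
#' categories.
#'
#' @param samples window-filtered sample data frame.
#' @param scheme a \code{\link{nitrate_scheme}}.
#' @return data frame: \code{site_id}, \code{actor}, \code{waterbody_class},
#'   \code{n_samples}, \code{median_mgL}, \code{site_category},
#'   \code{mixed_kinds}, plus \code{median_<season>} and
#'   \code{category_<season>} columns.
#' @export
site_nitrate_summary <- function(samples, scheme = nitrate_scheme()) {
  ids <- unique(samples$site_id)
  season <- assign_season(samples$timestamp)
  rows <- lapply(ids, function(sid) {
    rec <- samples[samples$site_id == sid, , drop = FALSE]
    sc <- site_category(rec, scheme)
    row <- data.frame(site_id = sid, actor = rec$actor[1L],
                      waterbody_class = rec$waterbody_class[1L],
                      n_samples = nrow(rec),
                      median_mgL = attr(sc, "median_mgL"),
                      site_category = as.character(sc),
                      mixed_kinds = attr(sc, "mixed_kinds"))
    v <- pooled_values(rec, scheme)
    s <- season[samples$site_id == sid]
    for (se in SEASONS) {
      if (any(s == se)) {
        m <- seasonal_median(v[s == se])
        row[[paste0("median_", se)]] <- m
        row[[paste0("category_", se)]] <- as.character(categorize(m, scheme))
      } else {
        row[[paste0("median_", se)]] <- NA_real_
        row[[paste0("category_", se)]] <- NA_character_
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-cell, per-season median nitrate
#'
#' The seasonal-grid-cell aggregation: median of pooled values within each
#' (grid cell, season-year) group, then categorized.
#'
#' @param samples window-filtered sample data frame.
#' @param grid a hexagonal grid.
#' @param scheme a \code{\link{nitrate_scheme}}.
#' @return data frame: \code{q}, \code{r}, \code{season}, \code{season_year},
#'   \code{actor}, \code{n}, \code{median_mgL}, \code{category}.
#' @export
cell_season_medians <- function(samples, grid, scheme = nitrate_scheme()) {
  loc <- locate_points(grid, samples$x, samples$y)
  ok <- !is.na(loc$q)
  sub <- samples[ok, , drop = FALSE]
  if (nrow(sub) == 0L)
    return(data.frame(q = integer(0), r = integer(0), season = character(0),
                      season_year = integer(0), actor = character(0),
                      n = integer(0), median_mgL = numeric(0),
                      category = character(0)))
  v <- pooled_values(sub, scheme)
  g <- data.frame(q = loc$q[ok], r = loc$r[ok],
                  season = assign_season(sub$timestamp),
                  season_year = season_year(sub$timestamp),
                  actor = sub$actor)
  keys <- split(seq_len(nrow(g)), interaction(g, drop = TRUE, lex.order = TRUE))
  rows <- lapply(keys, function(ix) {
    m <- seasonal_median(v[ix])
    cbind(g[ix[1L], , drop = FALSE],
          data.frame(n = length(ix), median_mgL = m,
                     category = as.character(categorize(m, scheme))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
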