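# Per-cell seasonal coverage, actor overlap and coverage summaries.
#
# A cell's coverage score for an actor is the number of distinct
# seasons-of-year (0-4) represented by that actor's samples falling in the
# cell. Counting the 12 season-by-year combinations instead is available via
# `by_year = TRUE` but is not the default: the score scale runs 0 to 4.

#' Seasonal coverage of a grid by one actor
#'
#' @param samples window-filtered sample data frame (see
#'   \code{\link{read_samples}}).
#' @param grid a \code{\link{build_hex_grid}} grid.
#' @param actor actor label to tabulate (e.g. \code{"EA"}).
#' @param by_year if \code{TRUE}, count distinct season-by-year combinations
#'   instead of the four seasons-of-year.
#' @return object of class \code{season_coverage}: a data frame with one row
#'   per grid cell and columns \code{q}, \code{r}, one logical column per
#'   season (\code{spring}..\code{winter}), and \code{score}. Attributes
#'   \code{actor} and \code{grid_key} identify the tabulation.
#' @export
seasonal_coverage <- function(samples, grid, actor, by_year = FALSE) {
  stopifnot(inherits(grid, "hex_grid"))
  sub <- samples[samples$actor == actor, , drop = FALSE]
  if (nrow(sub) == 0L)
    warning("actor '", actor, "' has no samples; coverage is all-empty",
            call. = FALSE)
  cells <- grid$cells
  cov <- matrix(FALSE, nrow(cells), 4L,
                dimnames = list(NULL, SEASONS))
  combos <- character(0)
  if (nrow(sub) > 0L) {
    loc <- locate_points(grid, sub$x, sub$y)
    season <- assign_season(sub$timestamp)
    syear <- season_year(sub$timestamp)
    ok <- !is.na(loc$q)
    if (any(ok)) {
      idx <- match(paste(loc$q[ok], loc$r[ok]), paste(cells$q, cells$r))
      for (k in seq_along(SEASONS)) {
        hit <- season[ok] == SEASONS[k]
        cov[unique(idx[hit]), k] <- TRUE
      }
      combos <- paste(idx, season[ok], syear[ok])
    }
  }
  out <- data.frame(q = cells$q, r = cells$r)
  out <- cbind(out, as.data.frame(cov))
  if (by_year) {
    score <- integer(nrow(cells))
    tab <- table(factor(vapply(strsplit(unique(combos), " "),
                               `[`, character(1), 1L),
                        levels = as.character(seq_len(nrow(cells)))))
    out$score <- as.integer(tab)
  } else {
    out$score <- as.integer(rowSums(cov))
  }
  structure(out, class = c("season_coverage", "data.frame"),
            actor = actor,
            grid_key = grid_key(grid))
}

grid_key <- function(grid) {
  list(edge_length = grid$edge_length, origin = grid$origin,
       n_cells = nrow(grid$cells))
}

season_sets <- function(cov) {
  m <- as.matrix(cov[, SEASONS])
  storage.mode(m) <- "logical"
  m
}

#' Classify per-cell overlap of two actors' coverages
#'
#' A cell is \code{complete} when both actors' season sets contain all four
#' seasons; \code{none} when the sets share no season (including when either
#' is empty); \code{partial} otherwise. A cell is flagged \code{gap_fill}
#' when actor B (conventionally the citizen-science actor) achieved all four
#' seasons but actor A did not.
#'
#' @param covA,covB \code{season_coverage} objects on the same grid; A is the
#'   reference (agency) actor, B the complementing actor.
#' @return data frame with columns \code{q}, \code{r}, \code{overlap_class}
#'   (factor complete/partial/none) and \code{gap_fill} (logical).
#' @export
classify_overlap <- function(covA, covB) {
  keyA <- attr(covA, "grid_key"); keyB <- attr(covB, "grid_key")
  if (!identical(keyA, keyB) || !identical(covA$q, covB$q) ||
      !identical(covA$r, covB$r))
    stop("coverages were computed on different grids")
  a <- season_sets(covA); b <- season_sets(covB)
  both_full <- rowSums(a) == 4L & rowSums(b) == 4L
  shared <- rowSums(a & b) > 0L
  cls <- ifelse(both_full, "complete", ifelse(shared, "partial", "none"))
  data.frame(q = covA$q, r = covA$r,
             overlap_class = factor(cls, levels = c("complete", "partial", "none")),
             gap_fill = rowSums(b) == 4L & rowSums(a) < 4L)
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Summarize coverage and overlap over all grid cells
#'
#' Percentages use the total number of grid cells as denominator and are
#' reported both at full precision and rounded half-up to the integer.
#'
#' @param covA,covB \code{season_coverage} objects on the same grid.
#' @param classes result of \code{\link{classify_overlap}(covA, covB)};
#'   computed if missing.
#' @return object of class \code{coverage_summary}: list with a per-actor
#'   table (\% of cells with score 4, \% with score >= 1), \% complete,
#'   \% partial, \% complete-or-partial overlap, \% gap-fill, and the cell
#'   total.
#' @export
summarize_coverage <- function(covA, covB, classes = NULL) {
  if (is.null(classes)) classes <- classify_overlap(covA, covB)
  n <- nrow(covA)
  pct <- function(k) 100 * k / n
  actors <- data.frame(
    actor = c(attr(covA, "actor"), attr(covB, "actor")),
    pct_all_seasons = pct(c(sum(covA$score == 4L), sum(covB$score == 4L))),
    pct_covered = pct(c(sum(covA$score >= 1L), sum(covB$score >= 1L))))
  out <- list(
    actors = actors,
    pct_complete = pct(sum(classes$overlap_class == "complete")),
    pct_partial = pct(sum(classes$overlap_class == "partial")),
    pct_overlap = pct(sum(classes$overlap_class %in% c("complete", "partial"))),
    pct_gap_fill = pct(sum(classes$gap_fill)),
    n_cells = n)
  structure(out, class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat("Coverage over", x$n_cells, "grid cells\n")
  for (i in seq_len(nrow(x$actors))) {
    cat(sprintf("  %s: %d%% of cells sampled in all four seasons; %d%% covered\n",
                x$actors$actor[i],
                round_half_up(x$actors$pct_all_seasons[i]),
                round_half_up(x$actors$pct_covered[i])))
  }
  cat(sprintf("  Overlap (complete or partial): %d%% of cells\n",
              round_half_up(x$pct_overlap)))
  cat(sprintf("  Gap-fill cells: %d%%\n", round_half_up(x$pct_gap_fill)))
  invisible(x)
}
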