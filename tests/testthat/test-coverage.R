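cov_grid <- function() build_hex_grid(square_ring(0, 0, 20000), 5000)

# coverage object with prescribed season sets, built through the real
# tabulation path by placing dated samples at cell centres
cov_from_sets <- function(grid, sets, actor = "A") {
  season_date <- c(spring = "2013-04-10", summer = "2013-07-10",
                   autumn = "2013-10-10", winter = "2013-12-10")
  rows <- list()
  for (i in seq_along(sets)) {
    for (s in sets[[i]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        actor = actor, site_id = "s", x = grid$cells$cx[i],
        y = grid$cells$cy[i], timestamp = as.Date(season_date[[s]]),
        determinand = "nitrate-N", value = 1, category = NA_character_,
        value_kind = "continuous", waterbody_class = "running")
    }
  }
  df <- if (length(rows) > 0) do.call(rbind, rows) else
    make_sample_df(0)
  suppressWarnings(seasonal_coverage(df, grid, actor))
}

test_that("a cell's score counts distinct seasons of year", {
  g <- cov_grid()
  ctr <- g$cells[1, ]
  df <- make_sample_df(4, x = ctr$cx, y = ctr$cy,
                       dates = as.Date(c("2013-03-15", "2014-06-20",
                                         "2015-09-01", "2013-12-30")))
  cov <- seasonal_coverage(df, g, "EA")
  expect_equal(cov$score[1], 4)
  # ten July samples are still one season
  df2 <- make_sample_df(10, x = ctr$cx, y = ctr$cy,
                        dates = as.Date("2014-07-04"))
  cov2 <- seasonal_coverage(df2, g, "EA")
  expect_equal(cov2$score[1], 1)
  expect_true(all(cov2$score[-1] == 0))
})

test_that("the season-by-year variant counts up to 12 combinations", {
  g <- cov_grid()
  ctr <- g$cells[1, ]
  df <- make_sample_df(3, x = ctr$cx, y = ctr$cy,
                       dates = as.Date(c("2013-04-01", "2014-04-01",
                                         "2014-07-01")))
  cov_default <- seasonal_coverage(df, g, "EA")
  cov_year <- seasonal_coverage(df, g, "EA", by_year = TRUE)
  expect_equal(cov_default$score[1], 2)  # spring + summer
  expect_equal(cov_year$score[1], 3)     # spring 2013, spring 2014, summer 2014
  expect_true(all(cov_year$score[-1] == 0))
})

test_that("an absent actor warns and yields all-empty coverage", {
  g <- cov_grid()
  df <- make_sample_df(3)
  expect_warning(cov <- seasonal_coverage(df, g, "FWW"), "no samples")
  expect_true(all(cov$score == 0))
})

test_that("per-cell scores equal an independent group-by tabulation", {
  set.seed(99)
  g <- cov_grid()
  n <- 400
  df <- make_sample_df(n, x = runif(n, 0, 20000), y = runif(n, 0, 20000),
                       dates = sample(seq(as.Date("2013-03-01"),
                                          as.Date("2015-12-31"), by = "day"),
                                      n, replace = TRUE))
  cov <- seasonal_coverage(df, g, "EA")
  # oracle: locate independently via point-in-polygon, then tapply
  polys <- grid_cell_polygons(g)
  for (i in seq_len(nrow(g$cells))) {
    inside <- fwcomplement:::point_in_ring(df$x, df$y, polys[[i]])
    expect_equal(cov$score[i],
                 length(unique(assign_season(df$timestamp[inside]))))
  }
})

test_that("overlap classification matches the rule on all 256 season-set pairs", {
  g <- build_hex_grid(square_ring(0, 0, 1000), 5000)  # single cell
  all_sets <- unlist(lapply(0:4, function(k)
    combn(c("spring", "summer", "autumn", "winter"), k, simplify = FALSE)),
    recursive = FALSE)
  for (sa in all_sets) for (sb in all_sets) {
    covA <- cov_from_sets(g, list(sa), "A")
    covB <- cov_from_sets(g, list(sb), "B")
    got <- suppressWarnings(classify_overlap(covA, covB))
    expected <- if (length(sa) == 4 && length(sb) == 4) "complete"
    else if (length(intersect(sa, sb)) == 0) "none"
    else "partial"
    expect_equal(as.character(got$overlap_class), expected,
                 info = paste(paste(sa, collapse = "+"), "vs",
                              paste(sb, collapse = "+")))
    expect_equal(got$gap_fill, length(sb) == 4 && length(sa) < 4)
  }
})

test_that("overlap classes are symmetric and partition the grid", {
  set.seed(5)
  g <- cov_grid()
  n <- 300
  mk <- function(actor) make_sample_df(
    n, actor = actor, x = runif(n, 0, 20000), y = runif(n, 0, 20000),
    dates = sample(seq(as.Date("2013-03-01"), as.Date("2015-12-31"),
                       by = "day"), n, replace = TRUE))
  covA <- seasonal_coverage(mk("EA"), g, "EA")
  covB <- seasonal_coverage(mk("FWW"), g, "FWW")
  ab <- classify_overlap(covA, covB)
  ba <- classify_overlap(covB, covA)
  expect_equal(ab$overlap_class, ba$overlap_class)
  s <- summarize_coverage(covA, covB, ab)
  expect_equal(s$pct_complete + s$pct_partial +
                 100 * sum(ab$overlap_class == "none") / s$n_cells, 100)
})

test_that("adding a sample never decreases a score or downgrades overlap", {
  set.seed(8)
  g <- cov_grid()
  n <- 120
  base <- make_sample_df(n, x = runif(n, 0, 20000), y = runif(n, 0, 20000),
                         dates = sample(seq(as.Date("2013-03-01"),
                                            as.Date("2015-12-31"), by = "day"),
                                        n, replace = TRUE))
  covB <- suppressWarnings(seasonal_coverage(base[0, ], g, "FWW"))
  cov1 <- seasonal_coverage(base, g, "EA")
  rank_of <- c(none = 0, partial = 1, complete = 2)
  for (k in 1:20) {
    extra <- make_sample_df(1, x = runif(1, 0, 20000), y = runif(1, 0, 20000),
                            dates = sample(seq(as.Date("2013-03-01"),
                                               as.Date("2015-12-31"),
                                               by = "day"), 1))
    cov2 <- seasonal_coverage(rbind(base, extra), g, "EA")
    expect_true(all(cov2$score >= cov1$score))
    c1 <- classify_overlap(cov1, cov1)
    c2 <- classify_overlap(cov2, cov2)
    expect_true(all(rank_of[as.character(c2$overlap_class)] >=
                      rank_of[as.character(c1$overlap_class)]))
    base <- rbind(base, extra)
    cov1 <- cov2
  }
})

test_that("summary percentages match a brute-force recount", {
  set.seed(13)
  g <- cov_grid()
  n <- 250
  mk <- function(actor) make_sample_df(
    n, actor = actor, x = runif(n, 0, 20000), y = runif(n, 0, 20000),
    dates = sample(seq(as.Date("2013-03-01"), as.Date("2015-12-31"),
                       by = "day"), n, replace = TRUE))
  covA <- seasonal_coverage(mk("EA"), g, "EA")
  covB <- seasonal_coverage(mk("FWW"), g, "FWW")
  s <- summarize_coverage(covA, covB)
  nc <- nrow(g$cells)
  expect_equal(s$actors$pct_all_seasons[1], 100 * sum(covA$score == 4) / nc)
  expect_equal(s$actors$pct_covered[2], 100 * sum(covB$score > 0) / nc)
  cls <- classify_overlap(covA, covB)
  expect_equal(s$pct_overlap,
               100 * mean(cls$overlap_class != "none"))
  expect_equal(s$pct_gap_fill, 100 * mean(cls$gap_fill))
})

test_that("coverages from different grids refuse to combine", {
  g1 <- cov_grid()
  g2 <- build_hex_grid(square_ring(0, 0, 20000), 4000)
  df <- make_sample_df(3)
  covA <- seasonal_coverage(df, g1, "EA")
  covB <- suppressWarnings(seasonal_coverage(df, g2, "FWW"))
  expect_error(classify_overlap(covA, covB), "different grids")
})

test_that("toy percentages come out exact and rounding is half-up", {
  expect_equal(fwcomplement:::round_half_up(59.5), 60)
  expect_equal(fwcomplement:::round_half_up(2.5), 3)
  expect_equal(fwcomplement:::round_half_up(2.4), 2)
})
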