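# A small-raster config keeps the generator tests fast; the full-size
# default (200 x 200) is exercised by the pipeline and acceptance runs.
small_cfg <- function(seed = 1, ...) {
  synthetic_catchment_config(seed = seed, nrow = 40, ncol = 40,
                             n_still = 40, n_ea = 80, n_fww = 80,
                             accumulation_threshold = 20, ...)
}

test_that("identical seeds reproduce the catchment and samples exactly", {
  cfg <- small_cfg(seed = 42)
  c1 <- generate_catchment(cfg)
  c2 <- generate_catchment(cfg)
  expect_identical(c1$d8$codes, c2$d8$codes)
  expect_identical(c1$boundary, c2$boundary)
  expect_identical(c1$waterbodies$area_ha, c2$waterbodies$area_ha)
  s1 <- generate_sampling(cfg, c1)
  s2 <- generate_sampling(cfg, c2)
  expect_identical(s1, s2)
  # and a different seed differs
  s3 <- generate_sampling(small_cfg(seed = 43), generate_catchment(small_cfg(seed = 43)))
  expect_false(identical(s1$timestamp, s3$timestamp))
})

test_that("the emitted D8 is acyclic, single-outlet and conservative", {
  for (seed in 1:5) {
    cfg <- small_cfg(seed = seed)
    catch <- generate_catchment(cfg)
    expect_equal(sum(catch$d8$codes == 0L, na.rm = TRUE), 1)
    acc <- flow_accumulation(catch$d8)  # would error on a cycle
    outlet <- which(catch$d8$codes == 0L)
    expect_equal(acc$values[outlet] + 1L, sum(!is.na(catch$d8$codes)))
  }
})

test_that("waterbody areas follow the configured log-normal", {
  cfg <- synthetic_catchment_config(seed = 3, nrow = 120, ncol = 120,
                                    n_still = 500, still_meanlog = -0.5,
                                    still_sdlog = 1.2)
  catch <- generate_catchment(cfg)
  areas <- catch$waterbodies$area_ha
  expect_length(areas, 500)
  # sample median within 15% of the distribution median exp(-0.5)
  expect_lt(abs(stats::median(areas) - exp(-0.5)) / exp(-0.5), 0.15)
  # the polygons measure the same areas they were drawn with
  polys <- attr(catch$waterbodies, "polygons")
  got <- vapply(polys[1:20], polygon_area_ha, numeric(1))
  expect_equal(got, areas[1:20], tolerance = 1e-9)
  # no two waterbodies overlap (bounding circles are disjoint)
  r <- sqrt(areas * 1e4 / pi)
  d <- as.matrix(stats::dist(catch$waterbodies[, c("x", "y")]))
  sep <- d - outer(r, r, "+")
  diag(sep) <- Inf
  expect_true(all(sep > 0))
})

test_that("records respect the window, the schema and the actor value kinds", {
  cfg <- small_cfg(seed = 9)
  catch <- generate_catchment(cfg)
  samples <- generate_sampling(cfg, catch)
  expect_true(all(samples$timestamp >= cfg$window$start &
                    samples$timestamp <= cfg$window$end))
  expect_true(all(samples$actor %in% c("EA", "FWW")))
  ea <- samples[samples$actor == "EA", ]
  fww <- samples[samples$actor == "FWW", ]
  expect_true(all(ea$value_kind == "continuous") && all(!is.na(ea$value)))
  expect_true(all(fww$value_kind == "categorical") && all(!is.na(fww$category)))
  expect_true(all(samples$waterbody_class %in% c("running", "still")))
  # round-trips through the sample CSV layer
  path <- tempfile(fileext = ".csv")
  write_samples(samples, path)
  back <- read_samples(path)
  expect_equal(nrow(back), nrow(samples))
  expect_equal(back$value, samples$value)
})

test_that("forcing every-season agency sampling fills all its cells", {
  cfg <- small_cfg(
    seed = 5,
    season_p = list(EA = c(spring = 1, summer = 1, autumn = 1, winter = 1),
                    FWW = c(spring = 0.9, summer = 0.9, autumn = 0.2,
                            winter = 0.2)))
  catch <- generate_catchment(cfg)
  samples <- generate_sampling(cfg, catch)
  grid <- build_hex_grid(catch$boundary, 2500)
  cov <- seasonal_coverage(samples, grid, "EA")
  expect_true(all(cov$score[cov$score > 0] == 4))
})

test_that("zero distance decay gives spatially uniform citizen sites", {
  # with no urban decay and flat preferences, FWW stream-cell picks are
  # uniform over stream cells: chi-squared GOF over cell counts
  cfg <- synthetic_catchment_config(
    seed = 8, nrow = 60, ncol = 60, n_still = 10,
    n_ea = 10, n_fww = 1000, p_still = c(EA = 0, FWW = 0),
    order_weights = list(EA = rep(1, 6), FWW = rep(1, 6)),
    urban_decay = c(EA = 0, FWW = 0),
    accumulation_threshold = 20)
  catch <- generate_catchment(cfg)
  samples <- generate_sampling(cfg, catch)
  sites <- attr(samples, "sites")
  fww <- sites[sites$actor == "FWW", ]
  tab <- fwcomplement:::network_cell_table(catch$network)
  # nearest stream cell of each site
  idx <- vapply(seq_len(nrow(fww)), function(i)
    which.min((tab$x - fww$x[i])^2 + (tab$y - fww$y[i])^2), integer(1))
  counts <- tabulate(idx, nbins = nrow(tab))
  # small expected counts are fine here: this is a Monte-Carlo uniformity
  # check, not an inference
  gof <- suppressWarnings(
    stats::chisq.test(counts, p = rep(1 / nrow(tab), nrow(tab))))
  expect_gt(gof$p.value, 0.01)
})

test_that("degenerate nitrate noise recovers the deterministic category", {
  model <- list(beta0 = log(1.5), beta_order = 0, beta_smallstill = 0,
                season_offsets = c(spring = 0, summer = 0, autumn = 0,
                                   winter = 0), sigma = 1e-12)
  sites <- data.frame(waterbody_class = rep("running", 50), order = 1:50 %% 6 + 1,
                      small_still = FALSE)
  out <- generate_nitrate(model, sites, rep("spring", 50), seed = 1)
  expect_equal(out$value, rep(1.5, 50), tolerance = 1e-9)
  expect_true(all(out$category == "1-2"))
})

test_that("a negative small-still effect lowers still-water nitrate", {
  model <- list(beta0 = log(2), beta_order = 0.15, beta_smallstill = -1.5,
                season_offsets = c(spring = 0, summer = 0, autumn = 0,
                                   winter = 0), sigma = 0.5)
  n <- 300
  sites <- data.frame(
    waterbody_class = rep(c("running", "still"), each = n),
    order = c(sample(1:4, n, replace = TRUE), rep(NA_integer_, n)),
    small_still = rep(c(FALSE, TRUE), each = n))
  out <- generate_nitrate(model, sites, rep("summer", 2 * n), seed = 2)
  expect_lt(stats::median(out$value[sites$small_still]),
            stats::median(out$value[!sites$small_still]))
})

test_that("log-values centre on the model mean", {
  model <- list(beta0 = 0.7, beta_order = 0, beta_smallstill = 0,
                season_offsets = c(spring = 0, summer = 0, autumn = 0,
                                   winter = 0), sigma = 0.5)
  n <- 10000
  sites <- data.frame(waterbody_class = rep("running", n), order = 1,
                      small_still = FALSE)
  out <- generate_nitrate(model, sites, rep("winter", n), seed = 3)
  se <- 0.5 / sqrt(n)
  expect_lt(abs(mean(log(out$value)) - 0.7), 3 * se)
})

test_that("spring/summer-heavy seasonal probabilities depress citizen all-season coverage", {
  diffs <- numeric(10)
  for (k in 1:10) {
    cfg <- synthetic_catchment_config(seed = 100 + k, nrow = 60, ncol = 60,
                                      n_still = 40, n_ea = 200, n_fww = 200,
                                      accumulation_threshold = 20)
    catch <- generate_catchment(cfg)
    samples <- generate_sampling(cfg, catch)
    grid <- build_hex_grid(catch$boundary, 2500)
    covA <- seasonal_coverage(samples, grid, "EA")
    covB <- seasonal_coverage(samples, grid, "FWW")
    diffs[k] <- mean(covA$score == 4) - mean(covB$score == 4)
  }
  expect_true(all(diffs > 0))
  expect_gt(mean(diffs), 0.10)
})

test_that("the synthetic inputs round-trip through the file formats", {
  cfg <- small_cfg(seed = 2)
  catch <- generate_catchment(cfg)
  samples <- generate_sampling(cfg, catch)
  dir <- tempfile("synth")
  paths <- write_synthetic_inputs(catch, samples, dir)
  expect_true(all(file.exists(paths)))
  d8 <- read_ascii_grid(paths["d8"], as_d8 = TRUE)
  expect_identical(d8$codes, catch$d8$codes)
  expect_equal(d8$cellsize, catch$d8$cellsize)
  b <- read_geojson_polygons(paths["boundary"])
  expect_equal(b[[1]][[1]][[1]], unname(catch$boundary), tolerance = 1e-12)
  wbs <- read_geojson_polygons(paths["waterbodies"])
  expect_length(wbs, nrow(catch$waterbodies))
  manifest <- jsonlite::fromJSON(paths["manifest"])
  expect_equal(manifest$seed, cfg$seed)
})
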