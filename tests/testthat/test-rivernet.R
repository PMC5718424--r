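test_that("a straight chain accumulates 0..n-1", {
  d8 <- chain_d8(5)
  acc <- flow_accumulation(d8)
  expect_equal(as.vector(acc$values), 0:4)
})

test_that("a Y junction accumulates both branches", {
  d8 <- y_d8()
  acc <- flow_accumulation(d8)
  expect_equal(acc$values[2, 4], 6)
  expect_equal(acc$values[1, 1], 0)
  expect_equal(acc$values[1, 3], 2)
})

test_that("cycles are detected and reported with a cell", {
  codes <- matrix(NA_integer_, 1, 2)
  codes[1, 1] <- 1L   # E
  codes[1, 2] <- 16L  # W -> cycle
  expect_error(flow_accumulation(d8_grid(codes, 100)), "cycle.*row")
})

test_that("accumulation equals the reachability oracle on random rasters", {
  for (seed in 1:100) {
    set.seed(seed)
    d8 <- random_d8(20, 20, n_outlets = sample(1:3, 1))
    acc <- flow_accumulation(d8)
    expect_identical(acc$values, oracle_accumulation(d8))
  }
})

test_that("outlet accumulations conserve the drained cell count", {
  for (seed in 1:20) {
    set.seed(seed)
    d8 <- random_d8(15, 25, n_outlets = 2)
    acc <- flow_accumulation(d8)
    outlets <- which(d8$codes == 0L)
    expect_equal(sum(acc$values[outlets] + 1L), sum(!is.na(d8$codes)))
  }
})

test_that("stream extraction keeps exactly the cells at the threshold", {
  d8 <- chain_d8(60)
  acc <- flow_accumulation(d8)
  net <- extract_streams(acc, threshold = 50)
  expect_length(net$segments, 1)
  expect_equal(nrow(net$segments[[1]]$cells), 10)
  expect_equal(net$segments[[1]]$cells[, "col"], 51:60)
  # threshold 0 keeps every cell
  net0 <- extract_streams(acc, threshold = 0)
  expect_equal(sum(vapply(net0$segments, function(s) nrow(s$cells),
                          integer(1))), 60)
  # nothing reaches an impossible threshold
  expect_warning(net_empty <- extract_streams(acc, threshold = 1000),
                 "no cell")
  expect_length(net_empty$segments, 0)
})

test_that("segments and junctions match a brute-force mask oracle", {
  for (seed in 1:25) {
    set.seed(seed)
    d8 <- random_d8(20, 20)
    acc <- flow_accumulation(d8)
    thr <- sample(c(5, 15, 30), 1)
    net <- extract_streams(acc, thr)
    mask <- !is.na(acc$values) & acc$values >= thr
    # every segment cell is a mask cell and together they cover the mask
    seg_cells <- do.call(rbind, lapply(net$segments, function(s) s$cells))
    expect_equal(sum(mask), nrow(seg_cells))
    expect_true(all(mask[seg_cells]))
    # oracle junctions: mask cells with >= 2 mask inflows
    down <- fwcomplement:::d8_downstream_index(d8)
    midx <- which(mask)
    inflow <- table(down[midx][!is.na(down[midx]) & mask[down[midx]]])
    oracle_junc <- sort(as.integer(names(inflow)[inflow >= 2]))
    got_junc <- sort((net$junctions[, "col"] - 1L) * nrow(mask) +
                       net$junctions[, "row"])
    expect_equal(got_junc, oracle_junc)
  }
})

test_that("Strahler examples follow the textbook rule", {
  # two order-1 branches joining give order 2
  d8 <- y_d8()
  net <- strahler_order(extract_streams(flow_accumulation(d8), threshold = 1))
  ords <- vapply(net$segments, function(s) s$order, integer(1))
  down <- vapply(net$segments, function(s) s$downstream, integer(1))
  expect_equal(sort(ords), c(1, 1, 2))
  expect_equal(ords[!is.na(down)], c(1, 1))
})

test_that("Strahler orders equal the recursive oracle on random forests", {
  for (seed in 1:40) {
    set.seed(seed)
    d8 <- random_d8(20, 20, n_outlets = sample(1:2, 1))
    net <- strahler_order(extract_streams(flow_accumulation(d8),
                                          threshold = sample(3:10, 1)))
    if (length(net$segments) == 0) next
    down <- vapply(net$segments, function(s) s$downstream, integer(1))
    got <- vapply(net$segments, function(s) s$order, integer(1))
    expect_equal(got, oracle_strahler(down))
    # order bound: <= ceil(log2(#headwaters)) + 1
    n_heads <- sum(!seq_along(down) %in% down)
    expect_true(max(got) <= ceiling(log2(max(n_heads, 1))) + 1)
  }
})

test_that("snapping finds the nearest stream cell within range", {
  d8 <- chain_d8(60, cellsize = 100)
  net <- strahler_order(extract_streams(flow_accumulation(d8), 50))
  # centre of the 55th cell is at x = 5450, y = 50
  hit <- snap_to_stream(data.frame(x = 5460, y = 70), net, max_snap = 200)
  expect_equal(hit$segment, 1L)
  expect_equal(hit$snap_x, 5450)
  expect_equal(hit$snap_dist, sqrt(10^2 + 20^2))
  miss <- snap_to_stream(data.frame(x = 100, y = 5000), net, max_snap = 200)
  expect_true(is.na(miss$segment))
})

test_that("snapping matches exhaustive nearest-neighbour search", {
  set.seed(77)
  d8 <- random_d8(20, 20, cellsize = 100)
  net <- strahler_order(extract_streams(flow_accumulation(d8), 5))
  tab <- fwcomplement:::network_cell_table(net)
  pts <- data.frame(x = runif(500, -200, 2200), y = runif(500, -200, 2200))
  got <- snap_to_stream(pts, net, max_snap = 300)
  for (i in seq_len(500)) {
    d <- sqrt((tab$x - pts$x[i])^2 + (tab$y - pts$y[i])^2)
    if (min(d) > 300) {
      expect_true(is.na(got$segment[i]))
    } else {
      expect_equal(got$snap_dist[i], min(d), tolerance = 1e-9)
    }
  }
})

test_that("pooling respects the 50 m rule with single-linkage chaining", {
  # fine raster so snapped points can be metres apart
  d8 <- chain_d8(300, cellsize = 10)
  net <- strahler_order(extract_streams(flow_accumulation(d8), 50))
  on_seg <- function(m) data.frame(id = sprintf("p%d", seq_along(m)),
                                   x = 1000 + m, y = 5)
  # 30 m apart -> one site
  expect_equal(nrow(pool_sites(on_seg(c(0, 30)), net, radius = 50)), 1)
  # 60 m apart -> two sites
  expect_equal(nrow(pool_sites(on_seg(c(0, 60)), net, radius = 50)), 2)
  # 0, 40, 80 m chain -> one site under single linkage
  p <- pool_sites(on_seg(c(0, 40, 80)), net, radius = 50)
  expect_equal(nrow(p), 1)
  expect_equal(p$n_members, 3)
  # but two sites under complete linkage
  expect_equal(nrow(pool_sites(on_seg(c(0, 40, 80)), net, radius = 50,
                               linkage = "complete")), 2)
})

test_that("pooled clusters equal the explicit single-linkage oracle", {
  set.seed(31)
  d8 <- chain_d8(500, cellsize = 10)
  net <- strahler_order(extract_streams(flow_accumulation(d8), 50))
  for (rep in 1:10) {
    m <- sort(runif(30, 0, 4000))
    pts <- data.frame(id = sprintf("p%02d", 1:30), x = 600 + m, y = 3)
    pooled <- pool_sites(pts, net, radius = 50)
    snapped <- snap_to_stream(pts, net, 200)
    oracle <- oracle_single_linkage(snapped$snap_x, snapped$snap_y, 50)
    expect_equal(nrow(pooled), length(unique(oracle)))
    # membership partitions agree
    got_part <- lapply(pooled$members, sort)
    orc_part <- lapply(split(pts$id, oracle), sort)
    expect_setequal(vapply(got_part, paste, "", collapse = ","),
                    vapply(orc_part, paste, "", collapse = ","))
  }
})

test_that("pooling is invariant under input permutation", {
  set.seed(55)
  d8 <- random_d8(20, 20, cellsize = 20)
  net <- strahler_order(extract_streams(flow_accumulation(d8), 5))
  pts <- data.frame(id = sprintf("p%02d", 1:40),
                    x = runif(40, 0, 400), y = runif(40, 0, 400))
  p1 <- pool_sites(pts, net, radius = 50, max_snap = 100)
  p2 <- pool_sites(pts[sample(40), ], net, radius = 50, max_snap = 100)
  rownames(p1) <- rownames(p2) <- NULL
  expect_equal(p1, p2)
  # unsnappable points become flagged singletons
  far <- data.frame(id = "far", x = 1e6, y = 1e6)
  pf <- pool_sites(far, net, radius = 50, max_snap = 100)
  expect_true(pf$off_network)
  expect_equal(pf$pooled_id, "off-far")
})

test_that("pooled site names run upstream to downstream", {
  d8 <- chain_d8(300, cellsize = 10)
  net <- strahler_order(extract_streams(flow_accumulation(d8), 50))
  pts <- data.frame(id = c("down", "up"), x = c(2500, 700), y = c(5, 5))
  p <- pool_sites(pts, net, radius = 50)
  expect_equal(p$pooled_id, c("seg1-1", "seg1-2"))
  expect_equal(unlist(p$members), c("up", "down"))
})
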