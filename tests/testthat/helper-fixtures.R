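# Fixture builders and independent brute-force oracles shared by the tests.
# Oracles deliberately avoid the code paths they check.

make_sample_df <- function(n = 5, actor = "EA", x = 1000, y = 1000,
                           dates = as.Date("2014-06-15"),
                           value = 1.5, wclass = "running") {
  data.frame(actor = rep_len(actor, n), site_id = sprintf("s%02d", seq_len(n)),
             x = rep_len(x, n), y = rep_len(y, n),
             timestamp = rep_len(as.Date(dates), n),
             determinand = rep_len("nitrate-N", n),
             value = rep_len(value, n),
             category = rep_len(NA_character_, n),
             value_kind = rep_len("continuous", n),
             waterbody_class = rep_len(wclass, n),
             stringsAsFactors = FALSE)
}

write_sample_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# A square boundary ring (counter-clockwise)
square_ring <- function(x0, y0, side) {
  cbind(c(x0, x0 + side, x0 + side, x0),
        c(y0, y0, y0 + side, y0 + side))
}

# --- D8 fixtures ------------------------------------------------------

# straight west-to-east chain in one row of an nr x nc raster
chain_d8 <- function(len, cellsize = 100) {
  codes <- matrix(NA_integer_, 1, len)
  codes[1, seq_len(len - 1)] <- 1L  # E
  codes[1, len] <- 0L
  d8_grid(codes, cellsize = cellsize)
}

# Y-shape: two 3-cell branches joining into one junction cell
y_d8 <- function(cellsize = 100) {
  codes <- matrix(NA_integer_, 4, 4)
  # branch A: (1,1)->(1,2)->(1,3); branch B: (3,1)->(3,2)->(3,3);
  # both drain into the junction cell (2,4)
  codes[1, 1] <- 1L; codes[1, 2] <- 1L; codes[1, 3] <- 2L  # E, E, SE
  codes[3, 1] <- 1L; codes[3, 2] <- 1L; codes[3, 3] <- 128L  # E, E, NE
  codes[2, 4] <- 0L
  d8_grid(codes, cellsize = cellsize)
}

# random acyclic D8 raster: random spanning forest via randomized Prim from
# several outlet roots (independent of the package's generator internals)
random_d8 <- function(nr, nc, n_outlets = 1, cellsize = 100) {
  drow <- c(0, 1, 1, 1, 0, -1, -1, -1)
  dcol <- c(1, 1, 0, -1, -1, -1, 0, 1)
  codes <- matrix(NA_integer_, nr, nc)
  visited <- matrix(FALSE, nr, nc)
  roots <- cbind(sample.int(nr, n_outlets, replace = TRUE),
                 sample.int(nc, n_outlets, replace = TRUE))
  frontier <- list()
  for (i in seq_len(nrow(roots))) {
    r <- roots[i, 1]; cl <- roots[i, 2]
    if (visited[r, cl]) next
    visited[r, cl] <- TRUE
    codes[r, cl] <- 0L
    frontier[[length(frontier) + 1L]] <- c(r, cl)
  }
  while (length(frontier) > 0L) {
    i <- sample.int(length(frontier), 1L)
    cell <- frontier[[i]]
    frontier[[i]] <- NULL
    for (k in sample.int(8L)) {
      r2 <- cell[1] + drow[k]; c2 <- cell[2] + dcol[k]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && !visited[r2, c2]) {
        visited[r2, c2] <- TRUE
        # new cell drains back toward `cell`: opposite of direction k
        codes[r2, c2] <- c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L)[(k + 3L) %% 8L + 1L]
        frontier[[length(frontier) + 1L]] <- c(r2, c2)
      }
    }
  }
  d8_grid(codes, cellsize = cellsize)
}

# --- oracles ----------------------------------------------------------

# upstream-set size per cell by explicit reachability: walk every cell's
# full downstream path and credit each visited cell
oracle_accumulation <- function(d8) {
  drow <- c(0, 1, 1, 1, 0, -1, -1, -1)
  dcol <- c(1, 1, 0, -1, -1, -1, 0, 1)
  codes <- c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L)
  nr <- nrow(d8$codes); nc <- ncol(d8$codes)
  acc <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    if (is.na(d8$codes[r, cl])) next
    cr <- r; cc <- cl
    repeat {
      k <- match(d8$codes[cr, cc], codes)
      if (is.na(k)) break
      cr2 <- cr + drow[k]; cc2 <- cc + dcol[k]
      if (cr2 < 1 || cr2 > nr || cc2 < 1 || cc2 > nc ||
          is.na(d8$codes[cr2, cc2])) break
      acc[cr2, cc2] <- acc[cr2, cc2] + 1L
      cr <- cr2; cc <- cc2
    }
  }
  acc[is.na(d8$codes)] <- NA_integer_
  acc
}

# recursive Strahler evaluation on an upstream-adjacency list
oracle_strahler <- function(downstream) {
  n <- length(downstream)
  ups <- lapply(seq_len(n), function(i) which(!is.na(downstream) & downstream == i))
  ord <- rep(NA_integer_, n)
  eval_seg <- function(i) {
    if (!is.na(ord[i])) return(ord[i])
    if (length(ups[[i]]) == 0L) { ord[i] <<- 1L; return(1L) }
    o <- vapply(ups[[i]], eval_seg, integer(1))
    mx <- max(o)
    ord[i] <<- if (sum(o == mx) >= 2L) mx + 1L else mx
    ord[i]
  }
  for (i in seq_len(n)) eval_seg(i)
  ord
}

# chi-squared by direct double-loop evaluation of the formula
oracle_chisq <- function(tab) {
  N <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    E <- sum(tab[i, ]) * sum(tab[, j]) / N
    if (E > 0) stat <- stat + (tab[i, j] - E)^2 / E
  }
  stat
}

# adjusted residuals by direct per-cell evaluation
oracle_adjusted_residuals <- function(tab) {
  N <- sum(tab)
  z <- matrix(0, nrow(tab), ncol(tab))
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    E <- sum(tab[i, ]) * sum(tab[, j]) / N
    den <- sqrt(E * (1 - sum(tab[i, ]) / N) * (1 - sum(tab[, j]) / N))
    z[i, j] <- if (den > 0) (tab[i, j] - E) / den else 0
  }
  z
}

# Mann-Whitney U by brute-force pair counting: U1 counts (x_i < y_j) pairs
# plus half-ties
oracle_u <- function(x, y) {
  u1 <- 0
  for (xi in x) for (yj in y) {
    u1 <- u1 + (xi < yj) + 0.5 * (xi == yj)
  }
  u1
}

# fan-triangulation area of a convex polygon ring (m^2)
oracle_convex_area <- function(ring) {
  a <- 0
  for (i in 2:(nrow(ring) - 1)) {
    v1 <- ring[i, ] - ring[1, ]
    v2 <- ring[i + 1, ] - ring[1, ]
    a <- a + abs(v1[1] * v2[2] - v1[2] * v2[1]) / 2
  }
  a
}

# single-linkage clusters as connected components, via explicit BFS over the
# threshold graph
oracle_single_linkage <- function(x, y, radius) {
  n <- length(x)
  adj <- outer(x, x, "-")^2 + outer(y, y, "-")^2 <= radius^2
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    q <- s
    while (length(q) > 0L) {
      v <- q[1]; q <- q[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      q <- c(q, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}
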