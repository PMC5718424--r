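# ESRI ASCII grid reader/writer and the D8 direction-raster container.
#
# Raster convention: row 1 of the matrix is the northernmost row; cell
# (row, col) is 1-based; the centre of cell (row, col) is at
#   x = xllcorner + (col - 0.5) * cellsize
#   y = yllcorner + (nrow - row + 0.5) * cellsize.
# D8 direction codes follow the ESRI convention, clockwise from East:
# 1 = E, 2 = SE, 4 = S, 8 = SW, 16 = W, 32 = NW, 64 = N, 128 = NE;
# 0 marks an outlet (no downstream cell).

D8_CODES <- c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L)
D8_DROW  <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
D8_DCOL  <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)

#' Construct a D8 flow-direction grid
#'
#' @param codes integer matrix of ESRI D8 direction codes (row 1 = north);
#'   0 marks outlets, \code{NA} marks nodata.
#' @param cellsize cell size in metres.
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param crs optional CRS identifier carried as metadata.
#' @return object of class \code{d8_grid}.
#' @export
d8_grid <- function(codes, cellsize, xll = 0, yll = 0, crs = NULL) {
  stopifnot(is.matrix(codes), cellsize > 0)
  bad <- !is.na(codes) & !(codes %in% c(0L, D8_CODES))
  if (any(bad)) stop("invalid D8 direction code(s): ",
                     paste(unique(codes[bad]), collapse = ", "))
  structure(list(codes = codes, cellsize = cellsize, xll = xll, yll = yll,
                 nrow = nrow(codes), ncol = ncol(codes), crs = crs),
            class = "d8_grid")
}

#' @export
print.d8_grid <- function(x, ...) {
  cat("D8 flow-direction grid: ", x$nrow, " x ", x$ncol,
      " cells of ", x$cellsize, " m (",
      sum(!is.na(x$codes)), " valid cells)\n", sep = "")
  invisible(x)
}

#' Centre coordinates of raster cells
#'
#' @param grid a \code{d8_grid} (or any list with nrow/ncol/cellsize/xll/yll).
#' @param row,col 1-based cell indices (vectors of equal length).
#' @return two-column matrix of x, y centre coordinates.
#' @export
cell_center <- function(grid, row, col) {
  cbind(x = grid$xll + (col - 0.5) * grid$cellsize,
        y = grid$yll + (grid$nrow - row + 0.5) * grid$cellsize)
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard six-line header (ncols, nrows, xllcorner, yllcorner,
#' cellsize, NODATA_value; the nodata line is optional) followed by
#' whitespace-separated values, north row first.
#'
#' @param path path to an .asc file.
#' @param as_d8 if \code{TRUE}, wrap the matrix in a \code{\link{d8_grid}}.
#' @return a list with elements \code{values} (matrix), \code{cellsize},
#'   \code{xll}, \code{yll}, \code{nodata}, or a \code{d8_grid}.
#' @export
read_ascii_grid <- function(path, as_d8 = FALSE) {
  if (!file.exists(path)) stop("ASCII grid not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[key]])) stop("ASCII grid header missing field: ", key)
  }
  vals <- as.numeric(unlist(strsplit(trimws(lines[i:length(lines)]), "\\s+")))
  vals <- vals[!is.na(vals) | TRUE]
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("ASCII grid has ", length(vals), " values; expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  if (as_d8) {
    d8_grid(matrix(as.integer(m), nr, nc), cellsize = hdr$cellsize,
            xll = hdr$xllcorner, yll = hdr$yllcorner)
  } else {
    list(values = m, cellsize = hdr$cellsize, xll = hdr$xllcorner,
         yll = hdr$yllcorner, nodata = hdr$nodata_value)
  }
}

#' Write a matrix (or d8_grid) as an ESRI ASCII grid
#'
#' @param x a matrix, or a \code{d8_grid}.
#' @param path output path.
#' @param cellsize,xll,yll grid georeferencing (taken from \code{x} when it
#'   is a \code{d8_grid}).
#' @param nodata value written for \code{NA} cells.
#' @return \code{path}, invisibly.
#' @export
write_ascii_grid <- function(x, path, cellsize = 1, xll = 0, yll = 0,
                             nodata = -9999) {
  if (inherits(x, "d8_grid")) {
    cellsize <- x$cellsize; xll <- x$xll; yll <- x$yll
    x <- x$codes
  }
  m <- x
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", format(xll, scientific = FALSE)),
    paste("yllcorner", format(yll, scientific = FALSE)),
    paste("cellsize", format(cellsize, scientific = FALSE)),
    paste("NODATA_value", nodata)
  ), con)
  writeLines(apply(m, 1, paste, collapse = " "), con)
  invisible(path)
}
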