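#' Regular planar grid raster
#'
#' A minimal in-memory container for a regular planar grid of cell-centre
#' values, used for synthetic environmental covariates (MCWD- and WTD-like
#' fields), interpolated community-weighted \eqn{\Psi_{50}} surfaces and MESS
#' layers. Coordinates are planar (km); cell \code{[i, j]} is centred at
#' \code{(xmin + (j - 0.5) * cell, ymin + (i - 0.5) * cell)}, with row 1 at
#' the bottom (south) edge.
#'
#' @param values numeric matrix of cell values (rows = south to north).
#' @param xmin,ymin coordinates of the lower-left corner of the grid (km).
#' @param cell cell size (km), strictly positive.
#' @return An object of class \code{grid_raster}: a list with elements
#'   \code{values}, \code{xmin}, \code{ymin}, \code{cell}, \code{nrow},
#'   \code{ncol}.
#' @examples
#' g <- grid_raster(matrix(1:12, 3, 4), xmin = 0, ymin = 0, cell = 10)
#' grid_coords(g)[1, ]
#' @export
grid_raster <- function(values, xmin = 0, ymin = 0, cell = 1) {
  if (!is.matrix(values) || !is.numeric(cell) || cell <= 0)
    stop("'values' must be a matrix and 'cell' > 0", call. = FALSE)
  structure(list(values = values, xmin = xmin, ymin = ymin, cell = cell,
                 nrow = nrow(values), ncol = ncol(values)),
            class = "grid_raster")
}

#' Build an empty grid covering a bounding box
#'
#' @param extent numeric length-4 vector \code{c(xmin, xmax, ymin, ymax)} (km).
#' @param cell cell size (km).
#' @return A \code{grid_raster} of \code{NA} values whose cells cover the
#'   extent (the last row/column may overshoot \code{xmax}/\code{ymax} by less
#'   than one cell).
#' @export
grid_skeleton <- function(extent, cell) {
  stopifnot(length(extent) == 4, cell > 0,
            extent[2] > extent[1], extent[4] > extent[3])
  nc <- ceiling((extent[2] - extent[1]) / cell)
  nr <- ceiling((extent[4] - extent[3]) / cell)
  grid_raster(matrix(NA_real_, nr, nc), xmin = extent[1], ymin = extent[3],
              cell = cell)
}

#' Cell-centre coordinates of a grid
#'
#' @param g a \code{grid_raster}.
#' @return A two-column matrix (x, y) of all cell centres in column-major
#'   order matching \code{as.vector(g$values)}.
#' @export
grid_coords <- function(g) {
  xs <- g$xmin + (seq_len(g$ncol) - 0.5) * g$cell
  ys <- g$ymin + (seq_len(g$nrow) - 0.5) * g$cell
  cbind(x = rep(xs, each = g$nrow), y = rep(ys, times = g$ncol))
}

#' Extract grid values at point locations (nearest cell)
#'
#' @param g a \code{grid_raster}.
#' @param x,y point coordinates (km).
#' @return Numeric vector of cell values; points outside the grid get the
#'   nearest edge cell.
#' @export
grid_extract <- function(g, x, y) {
  j <- pmin(pmax(ceiling((x - g$xmin) / g$cell), 1L), g$ncol)
  i <- pmin(pmax(ceiling((y - g$ymin) / g$cell), 1L), g$nrow)
  g$values[cbind(i, j)]
}

#' Mean convolution filter with truncated edge windows
#'
#' Smooths a matrix with a \code{window} x \code{window} moving-average
#' filter. At the edges the window is truncated to the cells that exist, so
#' no values outside the domain are invented. \code{window = 1} is the
#' identity.
#'
#' @param m numeric matrix.
#' @param window odd positive integer window side length.
#' @return Matrix of the same dimension.
#' @export
mean_filter <- function(m, window = 9) {
  stopifnot(is.matrix(m), window >= 1, window %% 2 == 1)
  if (window == 1) return(m)
  h <- (window - 1) / 2
  nr <- nrow(m); nc <- ncol(m)
  # summed-area table with a zero border row/column
  S <- matrix(0, nr + 1, nc + 1)
  S[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  i1 <- pmax(seq_len(nr) - h, 1); i2 <- pmin(seq_len(nr) + h, nr)
  j1 <- pmax(seq_len(nc) - h, 1); j2 <- pmin(seq_len(nc) + h, nc)
  # block sum via inclusion-exclusion on the summed-area table
  out <- S[i2 + 1, j2 + 1, drop = FALSE] - S[i1, j2 + 1, drop = FALSE] -
    S[i2 + 1, j1, drop = FALSE] + S[i1, j1, drop = FALSE]
  counts <- outer(i2 - i1 + 1, j2 - j1 + 1)
  out / counts
}

#' Write a grid as an ESRI ASCII raster
#'
#' @param g a \code{grid_raster}.
#' @param path output file path.
#' @param nodata value used for \code{NA} cells.
#' @return \code{path}, invisibly.
#' @export
write_esri_ascii <- function(g, path, nodata = -9999) {
  hdr <- c(sprintf("ncols %d", g$ncol), sprintf("nrows %d", g$nrow),
           sprintf("xllcorner %.10g", g$xmin), sprintf("yllcorner %.10g", g$ymin),
           sprintf("cellsize %.10g", g$cell), sprintf("NODATA_value %.10g", nodata))
  v <- g$values
  v[is.na(v)] <- nodata
  rows <- apply(v[rev(seq_len(g$nrow)), , drop = FALSE], 1,
                function(r) paste(format(r, trim = TRUE, digits = 10), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path file path.
#' @return A \code{grid_raster}.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- as.numeric(kv[, 2]); names(vals) <- tolower(kv[, 1])
  body <- strsplit(trimws(lines[-(1:6)]), "\\s+")
  m <- do.call(rbind, lapply(body, as.numeric))
  m[m == vals[["nodata_value"]]] <- NA_real_
  grid_raster(m[rev(seq_len(nrow(m))), , drop = FALSE],
              xmin = vals[["xllcorner"]], ymin = vals[["yllcorner"]],
              cell = vals[["cellsize"]])
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("grid_raster: %d x %d cells of %.3g km, origin (%.4g, %.4g)\n",
              x$nrow, x$ncol, x$cell, x$xmin, x$ymin))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values in [%.4g, %.4g], %d NA\n", rng[1], rng[2],
              sum(is.na(x$values))))
  invisible(x)
}
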