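#' Lightweight planar raster
#'
#' A `grid_raster` is a numeric or integer matrix anchored in planar
#' (metric) coordinates. Row 1 is the northernmost row; cell `(i, j)`
#' covers the half-open square
#' `[xmin + (j-1)*cs, xmin + j*cs) x [ymax - i*cs, ymax - (i-1)*cs)`
#' with `cs` the cell size in meters. `NA` cells are nodata.
#'
#' All landscape layers in the package (habitat cover, chlorophyll, edge
#' area, HRI) are `grid_raster`s; there is deliberately no geographic CRS
#' handling — inputs must already be projected to planar meters.
#'
#' @param values numeric/integer matrix (row 1 = north).
#' @param xmin,ymin coordinates of the lower-left corner (m).
#' @param cellsize cell edge length in meters (> 0).
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, xmin = 0, ymin = 0, cellsize = 10) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("`cellsize` must be a single positive number")
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 cellsize = cellsize),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid_raster> %d x %d cells, %g m, extent x [%g, %g] y [%g, %g]\n",
              nrow(v), ncol(v), x$cellsize,
              x$xmin, raster_xmax(x), x$ymin, raster_ymax(x)))
  cat(sprintf("  values: %s, %d nodata\n",
              if (is.null(attr(v, "levels"))) typeof(v) else
                paste(attr(v, "levels"), collapse = "/"),
              sum(is.na(v))))
  invisible(x)
}

raster_xmax <- function(r) r$xmin + ncol(r$values) * r$cellsize
raster_ymax <- function(r) r$ymin + nrow(r$values) * r$cellsize

#' Raster extent
#' @param r a [grid_raster()].
#' @return named numeric `c(xmin, xmax, ymin, ymax)`.
#' @export
raster_extent <- function(r) {
  c(xmin = r$xmin, xmax = raster_xmax(r), ymin = r$ymin, ymax = raster_ymax(r))
}

#' Cell center coordinates
#' @param r a [grid_raster()].
#' @param rows,cols integer indices (recycled together).
#' @return two-column matrix of x, y centers.
#' @export
cell_center <- function(r, rows, cols) {
  cs <- r$cellsize
  cbind(x = r$xmin + (cols - 0.5) * cs,
        y = raster_ymax(r) - (rows - 0.5) * cs)
}

# Map points to row/col under the half-open convention. Points on the top
# or right outer edge fall outside (consistent with [x0, x1) x [y0, y1)).
xy_to_rowcol <- function(r, x, y) {
  cs <- r$cellsize
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((x - r$xmin) / cs) + 1
  rowb <- floor((y - r$ymin) / cs) + 1      # 1 = bottom row
  row <- nr - rowb + 1
  bad <- !is.finite(col) | !is.finite(row) |
    col < 1 | col > nc | row < 1 | row > nr
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at points
#'
#' Values of the cell containing each point; points outside the extent
#' (or on its half-open top/right edge) return `NA` with an attribute
#' `n_outside` counting them. Nodata cells also return `NA`.
#'
#' @param r a [grid_raster()].
#' @param x,y point coordinates (m).
#' @return numeric vector, one value per point.
#' @export
raster_extract <- function(r, x, y) {
  rc <- xy_to_rowcol(r, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc[, 1L])
  out[ok] <- r$values[rc[ok, , drop = FALSE]]
  structure(out, n_outside = sum(!ok))
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Write / read Esri ASCII grid
#'
#' Plain-text raster exchange format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows north to south),
#' readable by standard GIS software.
#'
#' @param r a [grid_raster()].
#' @param path file path.
#' @param nodata value standing in for `NA` on disk.
#' @return `write_ascii_grid` returns `path` invisibly;
#'   `read_ascii_grid` returns a [grid_raster()].
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  v <- r$values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", r$xmin),
           sprintf("yllcorner %.10g", r$ymin),
           sprintf("cellsize %.10g", r$cellsize),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(v, 1L, function(row) paste(format(row, trim = TRUE,
                                                  digits = 10),
                                           collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2L]), tolower(kv[, 1L]))
  vals <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])))
  vals[vals == h[["nodata_value"]]] <- NA_real_
  grid_raster(vals, xmin = h[["xllcorner"]], ymin = h[["yllcorner"]],
              cellsize = h[["cellsize"]])
}
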