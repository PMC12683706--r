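# E-scape construction. Three resource-producing habitat layers stand in
# for the basal sources: marsh cover (marsh grass), marsh-water edge
# (benthic algae) and water weighted by relative chlorophyll
# (phytoplankton). IEI_i = fsource_i / fhabitat_i is calibrated at random
# buffer samples; HRI_x = sum_i median(IEI_i) * fhabitat_{i,x} on
# landscape foraging units.

#' Aggregate raw cover classes to marsh/water/other
#'
#' @param raw integer-coded [grid_raster()] of raw cover classes.
#' @param mapping named character vector, names = raw class codes (as
#'   character), values in `c("marsh", "water", "other")`. Every raw
#'   class present must be mapped.
#' @return habitat [grid_raster()] coded 1 = marsh, 2 = water, 3 = other
#'   with a `levels` attribute; geometry preserved.
#' @export
aggregate_cover <- function(raw, mapping) {
  stopifnot(inherits(raw, "grid_raster"))
  if (!all(mapping %in% HAB_LEVELS))
    stop("mapping values must be marsh, water or other")
  present <- unique(stats::na.omit(as.vector(raw$values)))
  unmapped <- setdiff(as.character(present), names(mapping))
  if (length(unmapped))
    stop("unmapped raw classes: ", paste(unmapped, collapse = ", "))
  codes <- match(mapping, HAB_LEVELS)
  v <- matrix(codes[match(as.character(raw$values), names(mapping))],
              nrow(raw$values), ncol(raw$values))
  attr(v, "levels") <- HAB_LEVELS
  grid_raster(v, xmin = raw$xmin, ymin = raw$ymin,
              cellsize = raw$cellsize)
}

#' Marsh-water edge area per cell
#'
#' Counts 4-neighbour (rook) marsh-water adjacencies — the linear
#' boundary between the classes — and converts each shared cell edge to
#' an area: `cellsize * width` square meters, accumulated on the
#' `side` cell of the adjacency (default water, where benthic algae
#' production is assigned). Total edge area is identical for either side.
#'
#' @param hab habitat [grid_raster()] (codes 1/2/3).
#' @param width buffer width of the edge strip (m); default 10.
#' @param side `"water"` or `"marsh"`: which side of the boundary
#'   accumulates the area.
#' @return [grid_raster()] of edge area (m^2 per cell); `NA` where the
#'   habitat is nodata.
#' @export
edge_area <- function(hab, width = 10, side = c("water", "marsh")) {
  side <- match.arg(side)
  v <- hab$values
  M <- !is.na(v) & v == HAB_MARSH
  W <- !is.na(v) & v == HAB_WATER
  tgt <- if (side == "water") W else M
  oth <- if (side == "water") M else W
  nr <- nrow(v); nc <- ncol(v)
  cnt <- matrix(0, nr, nc)
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
    cnt <- cnt + (tgt & shift(oth, d[1], d[2]))
  area <- cnt * hab$cellsize * width
  area[is.na(v)] <- NA_real_
  grid_raster(area, xmin = hab$xmin, ymin = hab$ymin,
              cellsize = hab$cellsize)
}

#' Relative chlorophyll over a multi-year window
#'
#' Cellwise mean over the window rasters divided by the maximum mean
#' over valid cells, so output lies in `[0, 1]` with max 1.
#'
#' @param stack list of aligned chlorophyll [grid_raster()]s (one per
#'   year of the window).
#' @return relative chlorophyll [grid_raster()].
#' @export
relative_chl <- function(stack) {
  if (length(stack) < 1L) stop("need at least one raster")
  ref <- stack[[1L]]
  for (r in stack)
    if (!same_geometry(ref, r)) stop("chlorophyll rasters are misaligned")
  arr <- vapply(stack, function(r) r$values,
                matrix(0, nrow(ref$values), ncol(ref$values)))
  m <- apply(arr, c(1, 2), function(z)
    if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE))
  mx <- max(m, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) stop("no positive chlorophyll values")
  grid_raster(m / mx, xmin = ref$xmin, ymin = ref$ymin,
              cellsize = ref$cellsize)
}

# disk row/col offsets for a center-in-circle buffer
disk_offsets <- function(radius, cellsize) {
  half <- floor(radius / cellsize)
  d <- expand.grid(dr = -half:half, dc = -half:half)
  keep <- (d$dr^2 + d$dc^2) * cellsize^2 <= radius^2
  as.matrix(d[keep, , drop = FALSE])
}

# fractions over a set of (row, col) cells; shared by buffers and units
fractions_from_cells <- function(hab, chl, edge, rows, cols) {
  idx <- cbind(rows, cols)
  h <- hab$values[idx]
  valid <- !is.na(h)
  n <- sum(valid)
  if (n == 0L) return(NULL)
  h <- h[valid]
  cellarea <- hab$cellsize^2
  chlv <- chl$values[idx][valid]
  chlv[is.na(chlv) | h != HAB_WATER] <- 0
  edgev <- edge$values[idx][valid]
  edgev[is.na(edgev)] <- 0
  c(phyto = sum(chlv) / n,
    edge = sum(edgev) / (n * cellarea),
    marsh = sum(h == HAB_MARSH) / n,
    area = n * cellarea, n_cells = n)
}

#' Habitat fractions within a circular buffer
#'
#' Cells belong to the buffer when their center lies within `radius` of
#' `center` (center-in-circle rule). `f_marsh` is areal marsh fraction,
#' `f_edge` edge area over buffer area, `f_phyto` the mean of
#' water-cell relative chlorophyll over the buffer (non-water cells
#' contribute 0).
#'
#' @param hab,chl,edge aligned [grid_raster()]s (habitat codes, relative
#'   chlorophyll, edge area).
#' @param center length-2 `(x, y)` (m).
#' @param radius buffer radius (m); default 500, the foraging scale.
#' @return named numeric: `phyto`, `edge`, `marsh`, `area` (m^2),
#'   `n_cells`.
#' @export
habitat_fractions <- function(hab, chl, edge, center, radius = 500) {
  stopifnot(same_geometry(hab, chl), same_geometry(hab, edge))
  rc <- xy_to_rowcol(hab, center[1], center[2])
  offs <- disk_offsets(radius, hab$cellsize)
  if (is.na(rc[1, 1])) stop("buffer center lies outside the raster")
  rows <- rc[1, 1] + offs[, "dr"]
  cols <- rc[1, 2] + offs[, "dc"]
  inb <- rows >= 1 & rows <= nrow(hab$values) &
    cols >= 1 & cols <= ncol(hab$values)
  fr <- fractions_from_cells(hab, chl, edge, rows[inb], cols[inb])
  if (is.null(fr)) stop("buffer contains no valid cells")
  fr
}

#' Calibrate the index of energetic importance (IEI)
#'
#' Samples `n_points` random valid cells, computes habitat fractions in
#' a `radius` buffer at each, and forms `IEI_i = fsource_i / fhabitat_i`
#' per source/habitat pair (phytoplankton <-> chlorophyll-weighted
#' water, benthic algae <-> edge, marsh grass <-> marsh). Points whose
#' buffer lacks habitat `i` are excluded for source `i` (never assigned
#' infinite IEI); the dropped count is reported.
#'
#' @param hab,chl,edge aligned layers as in [habitat_fractions()].
#' @param fsource 3-simplex of posterior median source contributions
#'   (phytoplankton, benthic, marsh).
#' @param n_points number of random calibration points; default 1000.
#' @param radius buffer radius (m).
#' @param mask optional logical matrix (same dim as the raster); only
#'   `TRUE` cells are sampled.
#' @param seed RNG seed.
#' @return an `iei_table` data.frame (source, habitat, median, q25, q75,
#'   n, n_dropped) with the per-point values in attribute `points`.
#' @export
compute_iei <- function(hab, chl, edge, fsource, n_points = 1000,
                        radius = 500, mask = NULL, seed = 1L) {
  if (n_points < 1) stop("n_points must be >= 1")
  if (abs(sum(fsource) - 1) > 1e-9 || any(fsource < -1e-12))
    stop("fsource must lie on the 3-simplex")
  valid <- !is.na(hab$values)
  if (!is.null(mask)) valid <- valid & mask
  cand <- which(valid)
  if (length(cand) < 1L) stop("no samplable cells in region")
  set.seed(seed)
  pick <- if (length(cand) >= n_points)
    sample(cand, n_points) else sample(cand, n_points, replace = TRUE)
  nr <- nrow(hab$values)
  rows0 <- ((pick - 1L) %% nr) + 1L
  cols0 <- ((pick - 1L) %/% nr) + 1L
  offs <- disk_offsets(radius, hab$cellsize)
  pts <- matrix(NA_real_, n_points, 3L,
                dimnames = list(NULL, c("phyto", "edge", "marsh")))
  for (i in seq_len(n_points)) {
    rows <- rows0[i] + offs[, "dr"]
    cols <- cols0[i] + offs[, "dc"]
    inb <- rows >= 1 & rows <= nr & cols >= 1 & cols <= ncol(hab$values)
    fr <- fractions_from_cells(hab, chl, edge, rows[inb], cols[inb])
    if (!is.null(fr)) pts[i, ] <- fr[c("phyto", "edge", "marsh")]
  }
  iei_pts <- sweep(1 / pts, 2L, fsource, `*`)
  iei_pts[!is.finite(iei_pts)] <- NA_real_   # fhabitat = 0 -> dropped
  safe <- function(f) apply(iei_pts, 2L, function(z) {
    z <- z[is.finite(z)]
    if (!length(z)) NA_real_ else f(z)
  })
  tab <- data.frame(source = SOURCE_NAMES,
                    habitat = c("water_chl", "edge", "marsh"),
                    median = safe(stats::median),
                    q25 = safe(function(z) stats::quantile(z, 0.25,
                                                           names = FALSE)),
                    q75 = safe(function(z) stats::quantile(z, 0.75,
                                                           names = FALSE)),
                    n = colSums(!is.na(iei_pts)),
                    n_dropped = colSums(is.na(iei_pts)),
                    row.names = NULL)
  structure(tab, points = iei_pts, class = c("iei_table", "data.frame"))
}

#' Map the habitat resource index (HRI) on landscape units
#'
#' Tiles the raster into `unit` x `unit` landscape foraging units
#' (anchored at the raster origin) and computes
#' `HRI_x = sum_i median(IEI_i) * fhabitat_{i,x}` per unit. A unit whose
#' fraction is zero contributes nothing for that source even when the
#' source's IEI median is undefined; units with no valid cells are
#' nodata. An HRI of 1 corresponds to landscape-average resource
#' production for the consumer.
#'
#' @param hab,chl,edge aligned layers as in [habitat_fractions()].
#' @param iei an [compute_iei()] result.
#' @param unit landscape unit edge (m); must be a positive multiple of
#'   the cell size. Default 1000 (1 km).
#' @param year optional provenance label.
#' @return an `escape` object: `hri` (coarse [grid_raster()]), `iei`,
#'   `unit`, `year`.
#' @export
compute_hri <- function(hab, chl, edge, iei, unit = 1000, year = NULL) {
  cs <- hab$cellsize
  k <- unit / cs
  if (unit < cs || abs(k - round(k)) > 1e-9)
    stop("unit must be a positive multiple of the cell size")
  k <- as.integer(round(k))
  med <- iei$median
  nr <- nrow(hab$values); nc <- ncol(hab$values)
  nbr <- ceiling(nr / k); nbc <- ceiling(nc / k)
  hri <- matrix(NA_real_, nbr, nbc)
  for (bi in seq_len(nbr)) {
    rows <- ((bi - 1L) * k + 1L):min(bi * k, nr)
    for (bj in seq_len(nbc)) {
      cols <- ((bj - 1L) * k + 1L):min(bj * k, nc)
      grid <- expand.grid(r = rows, cl = cols)
      fr <- fractions_from_cells(hab, chl, edge, grid$r, grid$cl)
      if (is.null(fr)) next
      f <- fr[c("phyto", "edge", "marsh")]
      contrib <- ifelse(f == 0, 0, med * f)
      hri[bi, bj] <- if (any(is.na(contrib))) NA_real_ else sum(contrib)
    }
  }
  # coarse grid anchored at the fine raster's top-left origin
  ymin_coarse <- raster_ymax(hab) - nbr * unit
  structure(list(hri = grid_raster(hri, xmin = hab$xmin,
                                   ymin = ymin_coarse, cellsize = unit),
                 iei = iei, unit = unit, year = year),
            class = "escape")
}

#' @export
print.escape <- function(x, ...) {
  cat(sprintf("<escape> %d x %d landscape units of %g m%s\n",
              nrow(x$hri$values), ncol(x$hri$values), x$unit,
              if (is.null(x$year)) "" else paste0(", year ", x$year)))
  cat("IEI medians:", paste(sprintf("%s %.3g", x$iei$source,
                                    x$iei$median), collapse = ", "), "\n")
  invisible(x)
}

#' Sample HRI values at points
#'
#' Value of the landscape unit containing each point (half-open cell
#' convention); points in nodata units or outside the extent return
#' `NA`, never silently 0. The count of outside points is attached as
#' attribute `n_outside`.
#'
#' @param escape an [compute_hri()] result.
#' @param x,y point coordinates (m).
#' @return numeric HRI values.
#' @export
sample_hri <- function(escape, x, y) {
  stopifnot(inherits(escape, "escape"))
  raster_extract(escape$hri, x, y)
}
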