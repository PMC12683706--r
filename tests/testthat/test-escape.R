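test_that("cover aggregation maps subclasses and conserves cell counts", {
  set.seed(1)
  raw <- grid_raster(matrix(sample(c(11:14, 20, 31, 32), 400,
                                   replace = TRUE), 20, 20),
                     cellsize = 10)
  mapping <- c(`11` = "marsh", `12` = "marsh", `13` = "marsh",
               `14` = "marsh", `20` = "water", `31` = "other",
               `32` = "other")
  hab <- aggregate_cover(raw, mapping)
  expect_equal(sum(hab$values == 1L),
               sum(raw$values %in% 11:14))     # marsh conserved
  expect_equal(sum(hab$values == 2L), sum(raw$values == 20))
  expect_equal(hab$cellsize, raw$cellsize)
  # identity mapping on an already 3-class raster is a no-op
  hab2 <- aggregate_cover(hab, c(`1` = "marsh", `2` = "water",
                                 `3` = "other"))
  expect_equal(hab2$values[, ], hab$values[, ], ignore_attr = TRUE)
  expect_error(aggregate_cover(raw, mapping[-1]), "unmapped")
})

test_that("a single marsh cell in open water has exactly 400 m2 of edge", {
  v <- matrix(2L, 9, 9)
  v[5, 5] <- 1L
  hab <- grid_raster(v, cellsize = 10)
  e <- edge_area(hab)
  expect_equal(sum(e$values), 4 * 10 * 10)
  # accumulated on the water side by default
  expect_equal(e$values[5, 5], 0)
  expect_equal(e$values[4, 5], 100)
})

test_that("edge areas match a brute-force adjacency count on random rasters", {
  for (seed in 1:4) {
    set.seed(seed)
    v <- matrix(sample(1:3, 2500, replace = TRUE,
                       prob = c(0.4, 0.5, 0.1)), 50, 50)
    hab <- grid_raster(v, cellsize = 10)
    expect_identical(sum(edge_area(hab, side = "water")$values),
                     brute_edge_total(hab))
    # symmetric: identical total on the marsh side
    expect_identical(sum(edge_area(hab, side = "marsh")$values),
                     brute_edge_total(hab))
  }
})

test_that("relative chlorophyll normalizes the window mean to max 1", {
  r1 <- grid_raster(matrix(c(2, 4, 8, NA), 2, 2), cellsize = 10)
  out <- relative_chl(list(r1))
  expect_equal(sort(as.vector(out$values)), c(0.25, 0.5, 1.0))
  # constant raster maps to 1 everywhere
  rc <- grid_raster(matrix(0.37, 3, 3), cellsize = 10)
  expect_true(all(relative_chl(list(rc))$values == 1))
  # multi-year mean
  r2 <- grid_raster(matrix(c(4, 4, 8, NA), 2, 2), cellsize = 10)
  m <- relative_chl(list(r1, r2))
  expect_equal(m$values[1, 1], 3 / 8)
  bad <- grid_raster(matrix(1, 3, 3), cellsize = 20)
  expect_error(relative_chl(list(r1, bad)), "misaligned")
})

test_that("buffer fractions are exact on constructed landscapes", {
  # all-water buffer with constant relative chlorophyll 0.5
  hab <- grid_raster(matrix(2L, 120, 120), cellsize = 10)
  chl <- grid_raster(matrix(0.5, 120, 120), cellsize = 10)
  edge <- edge_area(hab)
  fr <- habitat_fractions(hab, chl, edge, center = c(600, 600),
                          radius = 500)
  expect_equal(unname(fr["phyto"]), 0.5)
  expect_equal(unname(fr["marsh"]), 0)
  expect_equal(unname(fr["edge"]), 0)
  expect_equal(unname(fr["area"]), unname(fr["n_cells"]) * 100)
  # all-marsh buffer
  habm <- grid_raster(matrix(1L, 120, 120), cellsize = 10)
  frm <- habitat_fractions(habm, chl, edge_area(habm),
                           center = c(600, 600), radius = 500)
  expect_equal(unname(frm["marsh"]), 1)
  # buffer of nodata fails loudly
  habna <- grid_raster(matrix(NA_integer_, 120, 120), cellsize = 10)
  expect_error(habitat_fractions(habna, chl, edge, c(600, 600)),
               "valid cells|outside")
})

test_that("IEI is the ratio of source use to habitat availability", {
  # homogeneous all-water landscape, chl 0.34, phyto share 0.68 -> IEI 2
  hab <- grid_raster(matrix(2L, 150, 150), cellsize = 10)
  chl <- grid_raster(matrix(0.34, 150, 150), cellsize = 10)
  edge <- edge_area(hab)
  iei <- compute_iei(hab, chl, edge, c(0.68, 0.23, 0.09),
                     n_points = 50, radius = 500, seed = 1)
  expect_equal(iei$median[1], 2, tolerance = 1e-12)
  expect_equal(iei$q25[1], 2, tolerance = 1e-12)
  # edge and marsh absent everywhere: all points dropped for them
  expect_equal(iei$n[2:3], c(0L, 0L))
  expect_equal(iei$n_dropped[2:3], c(50L, 50L))
  expect_error(compute_iei(hab, chl, edge, c(0.68, 0.23, 0.09),
                           n_points = 0), "n_points")
  # fixed seed reproduces medians exactly
  layers <- fixture_escape_layers()
  i1 <- compute_iei(layers$hab, layers$chl, layers$edge,
                    c(0.68, 0.23, 0.09), n_points = 100, seed = 5)
  i2 <- compute_iei(layers$hab, layers$chl, layers$edge,
                    c(0.68, 0.23, 0.09), n_points = 100, seed = 5)
  expect_identical(i1$median, i2$median)
})

test_that("HRI is the IEI-weighted sum of unit habitat fractions", {
  # hand-built unit: fractions (phyto, edge, marsh) = (0.10, 0.05, 0.20)
  # with IEI medians (6.2, 3.9, 0.5) -> HRI = 0.915
  n <- 10                                   # one 100 m unit of 10 m cells
  v <- matrix(2L, n, n)
  v[1:2, ] <- 1L                            # 20 marsh cells of 100
  hab <- grid_raster(v, cellsize = 10)
  chl <- grid_raster(matrix(NA_real_, n, n), cellsize = 10)
  chl$values[v == 2L] <- 0.125              # 80 cells * 0.125 / 100 = 0.10
  edgev <- matrix(0, n, n)
  edgev[5, 5] <- 0.05 * n * n * 100         # 5% of unit area
  edge <- grid_raster(edgev, cellsize = 10)
  iei <- structure(data.frame(source = c("phytoplankton", "benthic",
                                         "marsh"),
                              habitat = c("water_chl", "edge", "marsh"),
                              median = c(6.2, 3.9, 0.5),
                              q25 = NA, q75 = NA, n = 1, n_dropped = 0),
                   class = c("iei_table", "data.frame"))
  esc <- compute_hri(hab, chl, edge, iei, unit = 100)
  expect_equal(esc$hri$values[1, 1],
               6.2 * 0.10 + 3.9 * 0.05 + 0.5 * 0.20)
  # all-"other" unit has zero fractions -> HRI 0
  hab3 <- grid_raster(matrix(3L, n, n), cellsize = 10)
  esc3 <- compute_hri(hab3, chl, edge_area(hab3), iei, unit = 100)
  expect_equal(esc3$hri$values[1, 1], 0)
  expect_error(compute_hri(hab, chl, edge, iei, unit = 15), "multiple")
})

test_that("doubling a source's IEI median doubles its HRI contribution", {
  layers <- fixture_escape_layers()
  fs <- c(0.68, 0.23, 0.09)
  iei <- compute_iei(layers$hab, layers$chl, layers$edge, fs,
                     n_points = 100, seed = 5)
  esc1 <- compute_hri(layers$hab, layers$chl, layers$edge, iei,
                      unit = 200)
  iei2 <- iei
  iei2$median[3] <- 2 * iei$median[3]
  esc2 <- compute_hri(layers$hab, layers$chl, layers$edge, iei2,
                      unit = 200)
  # difference per unit equals median_marsh * f_marsh per unit
  diff_hri <- esc2$hri$values - esc1$hri$values
  iei0 <- iei
  iei0$median <- c(0, 0, iei$median[3])
  marsh_part <- compute_hri(layers$hab, layers$chl, layers$edge, iei0,
                            unit = 200)
  expect_equal(diff_hri, marsh_part$hri$values, tolerance = 1e-12)
})

test_that("whole-cell translation leaves IEI and HRI values unchanged", {
  layers <- fixture_escape_layers()
  hab2 <- layers$hab; hab2$xmin <- hab2$xmin + 500; hab2$ymin <- hab2$ymin + 700
  chl2 <- layers$chl; chl2$xmin <- chl2$xmin + 500; chl2$ymin <- chl2$ymin + 700
  edge2 <- layers$edge; edge2$xmin <- edge2$xmin + 500; edge2$ymin <- edge2$ymin + 700
  fs <- c(0.68, 0.23, 0.09)
  i1 <- compute_iei(layers$hab, layers$chl, layers$edge, fs,
                    n_points = 80, seed = 9)
  i2 <- compute_iei(hab2, chl2, edge2, fs, n_points = 80, seed = 9)
  expect_equal(i1$median, i2$median)
  e1 <- compute_hri(layers$hab, layers$chl, layers$edge, i1, unit = 200)
  e2 <- compute_hri(hab2, chl2, edge2, i2, unit = 200)
  expect_equal(e1$hri$values, e2$hri$values)
})

test_that("HRI sampling honors cell membership and missingness", {
  m <- matrix(c(1.5, NA, 0.75, 2.5), 2, 2)
  esc <- escape_from_matrix(m, unit = 1000)
  # centroid of each unit returns that unit's value
  expect_equal(as.numeric(sample_hri(esc, 500, 1500)), m[1, 1])
  expect_equal(as.numeric(sample_hri(esc, 1500, 500)), m[2, 2])
  # shared boundary belongs to the upper-right unit (half-open cells)
  expect_equal(as.numeric(sample_hri(esc, 1000, 1000)), m[1, 2])
  # nodata cells and outside points are NA, never 0
  expect_true(is.na(as.numeric(sample_hri(esc, 500, 500))))
  out <- sample_hri(esc, -10, 500)
  expect_true(is.na(as.numeric(out)))
  expect_equal(attr(out, "n_outside"), 1L)
})
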