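# Shared synthetic fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# patchy marsh/water landscape with calibrated E-scape at movement scale
# (200 m cells, 60 km arena) -- used by the iSSF and HMM recovery tests
fixture_escape <- function() {
  if (!is.null(.fixture_env$esc)) return(.fixture_env$esc)
  cfg <- landscape_config(width = 300, height = 300, cell_size = 200,
                          patch_scale = 5, marsh_fraction = 0.3, seed = 2)
  land <- make_landscape(cfg)
  edge <- edge_area(land$habitat)
  chl <- relative_chl(list(land$chl))
  iei <- compute_iei(land$habitat, chl, edge, c(0.68, 0.23, 0.09),
                     n_points = 300, seed = 3)
  esc <- compute_hri(land$habitat, chl, edge, iei, unit = 1000)
  .fixture_env$esc <- esc
  esc
}

fixture_landscape <- function() {
  if (is.null(.fixture_env$land)) fixture_escape_layers()
  .fixture_env$land
}

fixture_escape_layers <- function() {
  if (is.null(.fixture_env$layers)) {
    cfg <- landscape_config(width = 120, height = 120, cell_size = 10,
                            patch_scale = 4, marsh_fraction = 0.35,
                            seed = 7)
    land <- make_landscape(cfg)
    .fixture_env$land <- land
    .fixture_env$layers <- list(hab = land$habitat,
                                chl = relative_chl(list(land$chl)),
                                edge = edge_area(land$habitat))
  }
  .fixture_env$layers
}

# uniform-HRI escape over an n x n unit grid
flat_escape <- function(hri = 1, n = 60, unit = 1000) {
  structure(list(hri = grid_raster(matrix(hri, n, n), cellsize = unit),
                 iei = NULL, unit = unit),
            class = "escape")
}

# hand-built escape from an HRI matrix
escape_from_matrix <- function(m, unit = 1000, xmin = 0, ymin = 0) {
  structure(list(hri = grid_raster(m, xmin = xmin, ymin = ymin,
                                   cellsize = unit),
                 iei = NULL, unit = unit),
            class = "escape")
}
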