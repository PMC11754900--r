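# Shared fixtures, generated in code (no stored data). The reference
# landscape is built once per test run and memoised.

small_landscape <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- gen_landscape(synthetic_config(
        seed = 7, nrows = 80, ncols = 80, n_colonies = 8,
        offshore_km = c(2), lake_diameters = c(200, 80, 79)))
    cache
  }
})

# a half-plane land mask (left `land_cols` columns land) on an
# nr x nc grid with 100 m cells; coastline is a straight vertical line
halfplane_land <- function(nr = 60, nc = 60, land_cols = 30) {
  grid <- grid_spec(nr, nc, 100)
  land <- matrix(FALSE, nr, nc)
  land[, seq_len(land_cols)] <- TRUE
  list(grid = grid, land = land,
       # x coordinate of the outer edge of the last land column
       coast_x = grid$xmin + land_cols * grid$cell_size)
}

ref_loadings_path <- function() {
  system.file("extdata", "tier1_reference_loadings.csv",
              package = "icefacets")
}
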