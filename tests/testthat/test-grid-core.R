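test_that("grid specification validates its geometry", {
  g <- grid_spec(10, 20, 100)
  expect_equal(g$cell_size^2, 1e4)   # 1 ha pixels at 100 m
  expect_error(grid_spec(0, 5), "dimensions")
  expect_error(grid_spec(5, 5, cell_size = -1), "cell_size")
  expect_error(raster_layer(g, matrix(0, 5, 5)), "dimensions")
  expect_error(label_grid(g, matrix(2L, 10, 20), legend = c("1" = "A")),
               "missing from legend")
})

test_that("fractional coverage is exact on analytic shapes", {
  g <- grid_spec(3, 3, 100)
  # polygon exactly covering the center pixel
  sq <- make_rect(100, 200, 100, 200)
  cov <- rasterize_coverage(sq, g)$values
  expect_equal(cov[2, 2], 1)
  expect_equal(sum(cov), 1)
  # rectangle covering the left half of the center pixel
  half <- make_rect(100, 150, 100, 200)
  expect_equal(rasterize_coverage(half, g)$values[2, 2], 0.5)
  # circle of diameter 80 m centered in a pixel: pi * 40^2 / 10^4
  circ <- make_circle(150, 150, 40, n = 2048)
  got <- rasterize_coverage(circ, g)$values[2, 2]
  expect_equal(got, pi * 40^2 / 1e4, tolerance = 1e-4)
  # cross-check against the dense-subsampling oracle
  expect_equal(got, oracle_pixel_coverage(circ, 100, 200, 100, 200,
                                          sub = 200),
               tolerance = 5e-3)
})

test_that("coverage conserves polygon area and matches touch support", {
  g <- grid_spec(6, 6, 50, xmin = 0, ymin = 0)
  set.seed(11)
  for (rep in 1:40) {
    poly <- polygon_set(list(random_convex_poly(c(20, 280), c(20, 280))))
    cov <- rasterize_coverage(poly, g)
    expect_equal(sum(cov$values) * 50^2, polygon_set_area(poly),
                 tolerance = 1e-6 * polygon_set_area(poly))
    touch <- rasterize_touch(poly, g)
    expect_identical(touch$values > 0, cov$values > 1e-12)
  }
})

test_that("holes subtract from coverage", {
  g <- grid_spec(2, 2, 100)
  outer <- cbind(c(20, 180, 180, 20), c(20, 20, 180, 180))
  hole <- cbind(c(60, 140, 140, 60), c(60, 60, 140, 140))
  ps <- polygon_set(list(list(rings = list(outer, hole))))
  cov <- rasterize_coverage(ps, g)
  expect_equal(sum(cov$values) * 1e4, 160^2 - 80^2, tolerance = 1e-8)
})

test_that("touch rasterization follows the any-intersection rule", {
  g <- grid_spec(4, 4, 100)
  # tiny circle strictly inside one pixel
  tiny <- make_circle(150, 250, 5)
  t1 <- rasterize_touch(tiny, g)$values
  expect_equal(sum(t1), 1)
  expect_equal(t1[2, 2], 1)   # y = 250 falls in row 2
  # circle centered on a 4-pixel corner touches all four
  corner <- make_circle(200, 200, 10)
  t2 <- rasterize_touch(corner, g)$values
  expect_equal(sum(t2), 4)
  expect_true(all(t2[2:3, 2:3] == 1))
  # empty polygon set: nothing touched
  expect_equal(sum(rasterize_touch(polygon_set(), g)$values), 0)
})

test_that("connected components match a BFS oracle on random masks", {
  # fixed small cases for both connectivities
  m <- matrix(FALSE, 3, 3); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(max(connected_components(m, 4)$codes), 2)
  expect_equal(max(connected_components(m, 8)$codes), 1)
  set.seed(21)
  for (rep in 1:60) {
    mask <- matrix(runif(400) < 0.45, 20, 20)
    conn <- if (rep %% 2) 4 else 8
    got <- connected_components(mask, conn)$codes
    want <- oracle_components_bfs(mask, conn)
    # identical partitions up to label permutation
    expect_equal(got != 0, want != 0)
    if (any(mask)) expect_equal(ari(got[mask], want[mask]), 1)
    expect_equal(max(got), max(want))
  }
})

test_that("adjacency fractions match the exhaustive scan oracle", {
  g <- grid_spec(1, 4)
  lab <- label_grid(g, matrix(c(1L, 1L, 2L, 2L), 1))
  expect_equal(adjacency_fractions(lab, 1, 4), c("2" = 0.5))
  # isolated unit: no neighbours of other units
  g2 <- grid_spec(5, 5)
  codes <- matrix(0L, 5, 5); codes[3, 3] <- 1L; codes[1, 1] <- 2L
  expect_length(adjacency_fractions(label_grid(g2, codes), 1, 4), 0)
  expect_error(adjacency_fractions(lab, 9), "not present")
  set.seed(31)
  for (rep in 1:60) {
    codes <- matrix(sample(0:3, 15 * 15, replace = TRUE), 15, 15)
    lab <- label_grid(grid_spec(15, 15), codes)
    conn <- if (rep %% 2) 4 else 8
    for (unit in setdiff(unique(as.vector(codes)), 0)) {
      got <- adjacency_fractions(lab, unit, conn)
      want <- oracle_adjacency(codes, unit, conn)
      expect_equal(got[order(as.integer(names(got)))], want)
    }
  }
})

test_that("raster round-trips preserve grid, values, and nodata", {
  dir <- withr::local_tempdir()
  g <- grid_spec(10, 10, 100, xmin = 12345.5, ymin = -6789.25)
  codes <- matrix(sample(0:5, 100, replace = TRUE), 10, 10)
  lab <- label_grid(g, codes)
  p <- file.path(dir, "lab.asc")
  write_raster(lab, p)
  back <- read_raster(p, as_labels = TRUE)
  expect_identical(back$codes, lab$codes)
  expect_equal(back$grid, g)

  vals <- matrix(rnorm(100), 10, 10)
  vals[c(3, 50, 99)] <- NA
  lay <- raster_layer(g, vals)
  p2 <- file.path(dir, "layer.asc")
  write_raster(lay, p2)
  back2 <- read_raster(p2)
  expect_equal(back2$values, vals)
  expect_identical(is.na(back2$values), is.na(vals))

  writeLines(c("ncols ten", "nrows 2"), file.path(dir, "bad.asc"))
  expect_error(read_raster(file.path(dir, "bad.asc")), "ncols")
})

test_that("GeoJSON polygon round-trip preserves rings and attributes", {
  dir <- withr::local_tempdir()
  outer <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
  hole <- cbind(c(40, 60, 60, 40), c(40, 40, 60, 60))
  ps <- polygon_set(list(list(rings = list(outer, hole), id = "a",
                              attributes = list(kind = "lake"))))
  p <- file.path(dir, "polys.geojson")
  write_polygons(ps, p)
  back <- read_polygons(p)
  expect_equal(polygon_set_area(back), polygon_set_area(ps))
  expect_equal(back$features[[1]]$attributes$kind, "lake")
  expect_equal(back$features[[1]]$id, "a")
})

test_that("convex clipping halves a disc on a straight boundary", {
  disc <- make_circle(0, 0, 50, n = 1024)
  halfplane <- make_rect(0, 1000, -1000, 1000)
  clipped <- clip_polygons_convex(disc, halfplane)
  expect_equal(polygon_set_area(clipped), pi * 50^2 / 2, tolerance = 1e-3)
  notch <- polygon_set(list(cbind(c(0, 10, 10, 5, 0),
                                  c(0, 0, 10, 2, 10))))
  expect_error(clip_polygons_convex(disc, notch), "convex")
})
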