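test_that("geothermal categorization applies the age thresholds", {
  rec <- function(yrs = NA, fum = FALSE, rad = FALSE, prox = FALSE)
    list(years_since_last_eruption = yrs, fumaroles_or_heat_source = fum,
         radiogenic = rad, proximity_override = prox)
  expect_equal(categorize_geothermal(rec(500)), "active")
  expect_equal(categorize_geothermal(rec(999)), "active")
  expect_equal(categorize_geothermal(rec(1000)), "dormant")
  expect_equal(categorize_geothermal(rec(50000)), "dormant")
  expect_equal(categorize_geothermal(rec(100000)), "dormant")
  expect_equal(categorize_geothermal(rec(100001)), "inactive")
  expect_equal(categorize_geothermal(rec(NA)), "inactive")  # unknown
  expect_equal(categorize_geothermal(rec(150000, fum = TRUE)), "active")
  expect_equal(categorize_geothermal(rec(150000, prox = TRUE)), "active")
  expect_equal(categorize_geothermal(rec(500, rad = TRUE)), "radiogenic")
  expect_error(categorize_geothermal(rec(-5)), "non-negative")
})

test_that("colony cleaning applies the distance rules with a log", {
  hp <- halfplane_land()
  # pixel-center distances: the nearest land centers sit 50 m inside
  # the coast line, so place points relative to the last land center
  edge_x <- hp$coast_x - 50   # x of the outermost land pixel centers
  y <- 3000
  colonies <- data.frame(
    id = c("far", "mid", "near", "home"),
    species = "gentoo",
    x = c(edge_x + 5000, edge_x + 3500, edge_x + 2000, edge_x - 300),
    y = y)
  res <- clean_colony_locations(colonies, hp$land, hp$grid)
  log <- res$log
  expect_equal(log$action[log$id == "far"], "removed")
  expect_false("far" %in% res$colonies$id)
  expect_equal(log$action[log$id == "mid"], "snapped")
  expect_equal(log$flag[log$id == "mid"], "manual-review")
  expect_equal(log$action[log$id == "near"], "snapped")
  expect_equal(log$flag[log$id == "near"], "")
  expect_equal(log$action[log$id == "home"], "kept")
  # snapped colonies now sit on coastline pixel centers
  snapped <- res$colonies[res$colonies$id %in% c("mid", "near"), ]
  expect_true(all(snapped$x == edge_x))
  expect_equal(res$colonies$x[res$colonies$id == "home"], edge_x - 300)
})

test_that("species ratios use yearly pairs with a colony-average fallback", {
  obs <- data.frame(
    id = c("a", "a", "a", "b", "b", "c", "c", "c"),
    species = c(rep("gentoo", 5), rep("chinstrap", 3)),
    x = 0, y = 0,
    year = c(2019, 2019, 2019, 2020, 2020, 2019, 2020, 2020),
    count_type = c("nests", "chicks", "adults", "nests", "chicks",
                   "nests", "adults", "chicks"),
    value = c(100, 150, 210, 100, 250, 100, 200, 240))
  r <- estimate_species_ratios(obs)
  g <- r[r$species == "gentoo" & r$ratio == "chicks_per_nest", ]
  expect_equal(g$value, 2)   # mean of 1.5 and 2.5
  expect_equal(g$provenance, "yearly_paired")
  expect_equal(r$value[r$species == "gentoo" &
                         r$ratio == "adults_per_nest"], 2.1)
  # chinstrap adults observed only in a year with no nest count:
  # computed from per-colony all-year averages instead
  cs <- r[r$species == "chinstrap" & r$ratio == "adults_per_nest", ]
  expect_equal(cs$provenance, "colony_average")
  expect_equal(cs$value, 200 / 100)   # colony means: adults 200, nests 100
  expect_error(estimate_species_ratios(
    data.frame(id = "x", species = "adelie", x = 0, y = 0, year = 2019,
               count_type = "adults", value = 10)), "adelie")
})

test_that("breeding pairs come from nests, else ratio-scaled counts", {
  ratios <- data.frame(
    species = rep("gentoo", 2),
    ratio = c("adults_per_nest", "chicks_per_nest"),
    value = c(2, 1.5), provenance = "yearly_paired", n = 5)
  ob <- function(types, values)
    data.frame(id = "c", species = "gentoo", x = 0, y = 0,
               year = 2019, count_type = types, value = values)
  expect_equal(estimate_breeding_pairs(
    ob(c("nests", "adults"), c(120, 999)), ratios), 120)
  expect_equal(estimate_breeding_pairs(
    ob("adults", 300), ratios), 150)
  expect_equal(estimate_breeding_pairs(
    ob(c("adults", "chicks"), c(300, 150)), ratios), mean(c(150, 100)))
  # counts averaged per type over years first
  two_years <- rbind(ob("nests", 100), ob("nests", 200))
  expect_equal(estimate_breeding_pairs(two_years, ratios), 150)
  expect_error(estimate_breeding_pairs(ob("nests", 1)[0, ], ratios),
               "no usable")
})

test_that("the area calibration is an ordinary least-squares line", {
  calib <- data.frame(pairs = c(10, 100, 1000, 5000),
                      area_m2 = 10 + 2 * c(10, 100, 1000, 5000))
  m <- fit_area_model(calib)
  expect_equal(m$intercept, 10)
  expect_equal(m$slope, 2)
  expect_equal(m$r_squared, 1)
  set.seed(60)
  pairs <- exp(runif(30, log(50), log(50000)))
  noisy <- data.frame(pairs = pairs,
                      area_m2 = 50 + 2 * pairs * (1 + rnorm(30, sd = .05)))
  m2 <- fit_area_model(noisy)
  expect_lt(abs(m2$slope - 2) / 2, 0.1)
  expect_error(fit_area_model(data.frame(pairs = c(5, 5, 5),
                                         area_m2 = 1:3)), "singular")
  m3 <- fit_area_model(data.frame(pairs = c(100, 1000, 4000),
                                  area_m2 = c(50, 2000, 8000)))
  expect_warning(a <- predict_area(m3, 0), "floored")
  expect_equal(a, 100)
})

test_that("footprint radius doubles the equivalent-area disc", {
  expect_equal(colony_footprint(0, 0, pi)$radius, 2)
  fp <- colony_footprint(0, 0, 10000)
  expect_equal(fp$radius, 112.8379, tolerance = 1e-6)
  # unclipped footprint has the full 4a disc area
  expect_equal(polygon_set_area(fp$polygon), 4 * 10000, tolerance = 1e-3)
  expect_error(colony_footprint(0, 0, -3), "positive")
})

test_that("a straight coastline halves the footprint to 2a", {
  a <- 25000
  land <- make_rect(-1e6, 0, -1e6, 1e6)   # land is x <= 0
  fp <- colony_footprint(0, 0, a, land = land)
  expect_equal(polygon_set_area(fp$polygon), 2 * a,
               tolerance = 0.02 * 2 * a)
})

test_that("the lake rule needs half-pixel coverage at 100 m", {
  g <- grid_spec(3, 3, 100)
  pass <- make_circle(150, 150, 40, n = 1024)    # 80 m diameter
  fail <- make_circle(150, 150, 39.5, n = 1024)  # 79 m diameter
  expect_equal(build_lake_raster(pass, g)$values[2, 2], 1)
  expect_equal(build_lake_raster(fail, g)$values[2, 2], 0)
  big <- make_rect(0, 200, 100, 200)   # fully covers two pixels
  expect_equal(sum(build_lake_raster(big, g)$values), 2)
})

test_that("overlay assembly follows the fixed precedence", {
  g <- grid_spec(4, 4, 100)
  base <- label_grid(g, matrix(1L, 4, 4), legend = c("1" = "E1B1"))
  geo <- list(dormant = make_rect(0, 200, 0, 400),     # columns 1-2
              active = make_rect(200, 300, 300, 400))  # row 1, col 3
  colony <- colony_footprint(50, 350, 100)             # pixel (1,1)
  lakes <- raster_layer(g, {
    m <- matrix(0, 4, 4); m[1, 2] <- 1; m })           # pixel (1,2)
  res <- assemble_overlays(base, geothermal = geo,
                           colonies = list(colony), lakes = lakes)
  lg <- res$labels
  lab_of <- function(i, j) unname(lg$legend[as.character(lg$codes[i, j])])
  expect_equal(lab_of(1, 2), "L1")     # lake over colony/geothermal
  expect_equal(lab_of(1, 1), "E1B2")   # colony over dormant geothermal
  expect_equal(lab_of(2, 1), "G2")     # dormant geothermal polygon
  expect_equal(lab_of(1, 3), "G1")     # active geothermal polygon
  expect_equal(lab_of(3, 4), "E1B1")   # untouched base pixel
  # re-applying the same overlays with the colony label pinned is
  # exactly idempotent
  res2 <- assemble_overlays(res$labels, geothermal = geo,
                            colonies = list(colony), lakes = lakes,
                            colony_label = "E1B2")
  expect_identical(res2$labels$codes, res$labels$codes)
  expect_identical(res2$labels$legend, res$labels$legend)
})

test_that("colony footprints rasterize with the touch rule", {
  g <- grid_spec(4, 4, 100)
  base <- label_grid(g, matrix(1L, 4, 4), legend = c("1" = "E2B1"))
  # small colony overlapping the corner of four pixels
  colony <- colony_footprint(200, 200, 400)  # r ~ 22.6 m at a corner
  res <- assemble_overlays(base, colonies = list(colony))
  code <- res$overlay_units$code[res$overlay_units$tier1 == "E1"]
  expect_equal(sum(res$labels$codes == code), 4)
})
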