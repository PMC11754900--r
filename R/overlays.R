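#' Geothermal category of a volcano / heat-source record
#'
#' Rule-based categorization of geothermal records:
#' * `radiogenic` - flagged radiogenic heat sources (their own class);
#' * `active` - erupted within the last 1,000 years, observed fumaroles
#'   or heat source, or an explicit proximity override (neighbours of an
#'   active volcano whose eruptions likely affected them);
#' * `dormant` - last eruption between 1,000 and 100,000 years ago;
#' * `inactive` - older than 100,000 years or unknown history. Inactive
#'   records are excluded from the overlay so their pixels stay with the
#'   factor-analysis classification.
#'
#' @param rec A list/one-row data frame with fields
#'   `years_since_last_eruption` (non-negative or `NA` = unknown),
#'   `fumaroles_or_heat_source`, `radiogenic`, `proximity_override`
#'   (logicals, missing treated as `FALSE`).
#' @return One of `"active"`, `"dormant"`, `"inactive"`, `"radiogenic"`.
#' @export
categorize_geothermal <- function(rec) {
  yrs <- rec$years_since_last_eruption
  if (length(yrs) && !is.na(yrs) && yrs < 0)
    stop("years_since_last_eruption must be non-negative")
  flag <- function(f) isTRUE(as.logical(rec[[f]]))
  if (flag("radiogenic")) return("radiogenic")
  if (flag("proximity_override") || flag("fumaroles_or_heat_source"))
    return("active")
  if (!length(yrs) || is.na(yrs)) return("inactive")
  if (yrs < 1000) "active"
  else if (yrs <= 100000) "dormant"
  else "inactive"
}

#' Derive coastline pixels from a land mask
#'
#' The coastline is discretized as the centers of land pixels having at
#' least one non-land neighbour (queen neighbourhood), the grid-native
#' analogue of the coastline curve.
#'
#' @param land_mask Logical matrix.
#' @param grid A [grid_spec()].
#' @return Matrix of x, y coastline point coordinates.
#' @export
coastline_points <- function(land_mask, grid) {
  storage.mode(land_mask) <- "logical"
  off <- neighbour_offsets(8)
  notland <- !land_mask
  boundary <- matrix(FALSE, nrow(land_mask), ncol(land_mask))
  for (d in seq_along(off$dr)) {
    shifted <- shift_matrix(notland, off$dr[d], off$dc[d], fill = TRUE)
    boundary <- boundary | (land_mask & shifted)
  }
  idx <- which(boundary)
  rows <- (idx - 1L) %% nrow(land_mask) + 1L
  cols <- (idx - 1L) %/% nrow(land_mask) + 1L
  pixel_centers(grid, rows, cols)
}

#' Clean colony locations against the land mask
#'
#' Applies the distance rules used to reconcile colony point records
#' with mapped land: records more than 4 km off land are removed;
#' records 3-4 km off are snapped to the nearest coastline point and
#' flagged for manual review; records up to 3 km off are snapped to the
#' nearest coastline point; on-land records are unchanged. Colonies
#' above `large_colony_pairs` estimated breeding pairs are additionally
#' flagged for manual review (no automatic adjustment). Every action is
#' logged.
#'
#' @param colonies Data frame with at least `id`, `x`, `y` (one row per
#'   colony; use [colony_table()] to collapse observation rows).
#' @param land_mask Logical matrix of land pixels.
#' @param grid A [grid_spec()].
#' @param max_land_km,snap_flag_km Distance thresholds (km), defaults 4
#'   and 3.
#' @return List with `colonies` (cleaned data frame) and `log` (one
#'   action row per colony: kept / snapped / snapped-flagged /
#'   removed).
#' @export
clean_colony_locations <- function(colonies, land_mask, grid,
                                   max_land_km = 4, snap_flag_km = 3) {
  storage.mode(land_mask) <- "logical"
  land_idx <- which(land_mask)
  if (!length(land_idx)) stop("land mask is empty")
  lr <- (land_idx - 1L) %% nrow(land_mask) + 1L
  lc <- (land_idx - 1L) %/% nrow(land_mask) + 1L
  land_xy <- pixel_centers(grid, lr, lc)
  coast_xy <- coastline_points(land_mask, grid)
  cs <- grid$cell_size

  out <- colonies
  log <- data.frame(id = colonies$id, action = NA_character_,
                    distance_km = NA_real_, flag = "",
                    stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(colonies))
  for (i in seq_len(nrow(colonies))) {
    x <- colonies$x[i]; y <- colonies$y[i]
    col_j <- floor((x - grid$xmin) / cs) + 1
    row_i <- floor((grid_ymax(grid) - y) / cs) + 1
    on_land <- row_i >= 1 && row_i <= grid$nrows &&
      col_j >= 1 && col_j <= grid$ncols && land_mask[row_i, col_j]
    if (on_land) {
      log$action[i] <- "kept"
      log$distance_km[i] <- 0
      next
    }
    d <- sqrt((land_xy[, 1] - x)^2 + (land_xy[, 2] - y)^2)
    dmin_km <- min(d) / 1000
    log$distance_km[i] <- dmin_km
    if (dmin_km > max_land_km) {
      keep[i] <- FALSE
      log$action[i] <- "removed"
      next
    }
    dc <- sqrt((coast_xy[, 1] - x)^2 + (coast_xy[, 2] - y)^2)
    j <- which.min(dc)
    out$x[i] <- coast_xy[j, 1]
    out$y[i] <- coast_xy[j, 2]
    if (dmin_km > snap_flag_km) {
      log$action[i] <- "snapped"
      log$flag[i] <- "manual-review"
    } else log$action[i] <- "snapped"
  }
  list(colonies = out[keep, , drop = FALSE], log = log)
}

#' Collapse colony observation rows to one row per colony
#'
#' @param observations Data frame with columns `id`, `species`, `x`,
#'   `y`, `year`, `count_type` (`nests`/`adults`/`chicks`), `value`.
#' @return Data frame with one row per colony id.
#' @export
colony_table <- function(observations) {
  ids <- unique(observations$id)
  do.call(rbind, lapply(ids, function(i) {
    rows <- observations[observations$id == i, ]
    data.frame(id = i, species = rows$species[1],
               x = rows$x[1], y = rows$y[1], stringsAsFactors = FALSE)
  }))
}

#' Species count-conversion ratios
#'
#' Mean chicks:nests and adults:nests ratios per species, computed over
#' colony-years where both count types were observed at the same colony
#' in the same year. When no same-year pairs exist for a species/ratio,
#' the ratio is computed from per-colony averages over all observed
#' years and the provenance flagged `colony_average`.
#'
#' @param observations Observation data frame (see [colony_table()]).
#' @param on_missing `"error"` (default): fail when a species has no
#'   paired counts for a ratio at either resolution; `"skip"`: omit
#'   that ratio row (pair estimation then relies on the other count
#'   type for the affected colonies).
#' @return Data frame with one row per species x ratio:
#'   `species`, `ratio` (`adults_per_nest` / `chicks_per_nest`),
#'   `value`, `provenance`, `n` (colony-years or colonies used).
#' @export
estimate_species_ratios <- function(observations,
                                    on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  species <- unique(observations$species)
  rows <- list()
  for (sp in species) {
    obs <- observations[observations$species == sp, ]
    for (rt in c("adults_per_nest", "chicks_per_nest")) {
      numer_type <- if (rt == "adults_per_nest") "adults" else "chicks"
      # yearly-paired: same colony, same year
      key <- paste(obs$id, obs$year)
      nests <- obs[obs$count_type == "nests", ]
      numer <- obs[obs$count_type == numer_type, ]
      kn <- paste(nests$id, nests$year)
      ku <- paste(numer$id, numer$year)
      common <- intersect(kn[nests$value > 0], ku)
      if (length(common)) {
        rvals <- vapply(common, function(k) {
          mean(numer$value[ku == k]) / mean(nests$value[kn == k])
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, ratio = rt, value = mean(rvals),
          provenance = "yearly_paired", n = length(common),
          stringsAsFactors = FALSE)
        next
      }
      # fallback: per-colony all-year averages
      ids <- intersect(unique(nests$id[nests$value > 0]),
                       unique(numer$id))
      if (length(ids)) {
        rvals <- vapply(ids, function(i) {
          mean(numer$value[numer$id == i]) /
            mean(nests$value[nests$id == i])
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, ratio = rt, value = mean(rvals),
          provenance = "colony_average", n = length(ids),
          stringsAsFactors = FALSE)
      } else if (on_missing == "error") {
        stop("no paired counts to estimate ", rt, " for species ", sp)
      }
    }
  }
  do.call(rbind, rows)
}

#' Estimate breeding pairs for one colony
#'
#' Counts are first averaged per count type over years. Nest counts are
#' equated with breeding pairs; where no nest count exists, adult and/or
#' chick counts are divided by the species ratios and the available
#' ratio-derived estimates averaged.
#'
#' @param colony_obs Observation rows for one colony.
#' @param ratios Ratio table from [estimate_species_ratios()].
#' @return Estimated breeding pairs (positive number).
#' @export
estimate_breeding_pairs <- function(colony_obs, ratios) {
  sp <- colony_obs$species[1]
  means <- vapply(c("nests", "adults", "chicks"), function(tp) {
    v <- colony_obs$value[colony_obs$count_type == tp]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  if (!is.na(means["nests"])) return(unname(means["nests"]))
  get_ratio <- function(rt) {
    v <- ratios$value[ratios$species == sp & ratios$ratio == rt]
    if (length(v)) v[1] else NA_real_
  }
  ests <- c(
    if (!is.na(means["adults"])) means["adults"] / get_ratio("adults_per_nest"),
    if (!is.na(means["chicks"])) means["chicks"] / get_ratio("chicks_per_nest"))
  ests <- ests[is.finite(ests)]
  if (!length(ests)) stop("colony has no usable counts")
  mean(ests)
}

#' Fit the breeding-pairs to colony-area calibration
#'
#' Ordinary least squares of colony area (m^2) on breeding pairs.
#'
#' @param calibration Data frame with columns `pairs` and `area_m2`
#'   (>= 3 rows, non-constant pairs).
#' @return An object of class `area_model` with `intercept`, `slope`,
#'   `r_squared` and the underlying `lm` fit.
#' @export
fit_area_model <- function(calibration) {
  if (nrow(calibration) < 3) stop("need >= 3 calibration points")
  if (stats::sd(calibration$pairs) == 0)
    stop("singular fit: pairs are constant")
  fit <- stats::lm(area_m2 ~ pairs, data = calibration)
  if (stats::coef(fit)[["pairs"]] <= 0)
    warning("calibration slope is not positive")
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[["pairs"]]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 fit = fit),
            class = "area_model")
}

#' @export
print.area_model <- function(x, ...) {
  cat(sprintf("<area_model> area = %.4g + %.4g * pairs (R^2 = %.4f)\n",
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' Predict colony area from breeding pairs
#'
#' Predictions are floored at `min_area` (default 100 m^2, one
#' hundredth of a 100 m pixel) with a warning, guarding against
#' negative or null predictions for very small colonies.
#'
#' @param model An `area_model`.
#' @param pairs Breeding-pair estimates.
#' @param min_area Floor in m^2.
#' @return Predicted areas in m^2.
#' @export
predict_area <- function(model, pairs, min_area = 100) {
  a <- model$intercept + model$slope * pairs
  if (any(a < min_area)) {
    warning(sum(a < min_area), " area prediction(s) floored at ",
            min_area, " m^2")
    a <- pmax(a, min_area)
  }
  a
}

#' Circular colony footprint clipped to land
#'
#' The buffer radius is `r = 2 * sqrt(a / pi)`: the disc of the colony's
#' estimated area, doubled in radius because most colonies sit against
#' the coastline (losing about half the disc over a straight coast) and
#' because nutrient influence extends beyond the nest area itself.
#'
#' @param x,y Colony location.
#' @param a Estimated colony area in m^2 (> 0).
#' @param land Optional land [polygon_set()] (must be convex) to clip
#'   the footprint against; raster workflows clip against the land mask
#'   at rasterization instead.
#' @param n Vertices of the disc polygon.
#' @return List of class `colony_footprint`: `x`, `y`, `area`,
#'   `radius`, `polygon` (clipped [polygon_set()]).
#' @export
colony_footprint <- function(x, y, a, land = NULL, n = 720L) {
  if (!is.finite(a) || a <= 0) stop("colony area must be positive")
  r <- 2 * sqrt(a / pi)
  disc <- make_circle(x, y, r, n = n)
  poly <- if (is.null(land)) disc else clip_polygons_convex(disc, land)
  structure(list(x = x, y = y, area = a, radius = r, polygon = poly),
            class = "colony_footprint")
}

#' Binary lake raster from lake polygons
#'
#' A pixel is a lake when at least `threshold` (default 50%) of its
#' area is covered by lake polygons; at 100 m resolution this implies a
#' minimum mappable lake of ~5,000 m^2 (half a pixel).
#'
#' @param lakes A [polygon_set()].
#' @param grid A [grid_spec()].
#' @param threshold Coverage fraction, default 0.5.
#' @return A [raster_layer()] with values 0/1.
#' @export
build_lake_raster <- function(lakes, grid, threshold = 0.5) {
  cov <- rasterize_coverage(lakes, grid)
  raster_layer(grid, (cov$values >= threshold) * 1)
}

#' Assemble distinct overlay ecosystems onto the Tier 2 map
#'
#' Overlays are stacked in fixed precedence, uppermost wins:
#' lakes (`L1`) > penguin colonies (a Habitat Complex within the first
#' Major Environmental Unit, `E1`) > geothermal (`G1` active, `G2`
#' dormant, `G3` radiogenic) > the factor-analysis base map. Colony
#' footprints are rasterized with the touch rule; geothermal polygons
#' with the touch rule; lakes arrive as an already-thresholded raster.
#' All overlay pixels are restricted to the land mask.
#'
#' @param base A [label_grid()] of Tier 2 Habitat Complexes.
#' @param geothermal Named list of [polygon_set()]s by category
#'   (`active`, `dormant`, `radiogenic`); `inactive` entries are
#'   ignored. May be `NULL`.
#' @param colonies List of `colony_footprint`s (or a [polygon_set()]).
#'   May be `NULL`.
#' @param lakes A 0/1 [raster_layer()] from [build_lake_raster()], or
#'   `NULL`.
#' @param land_mask Logical matrix; overlay codes are only written on
#'   land pixels.
#' @param colony_label Label for the colony Habitat Complex; `NULL`
#'   (default) allocates the next free `B` index within `E1`. Pinning
#'   the label (e.g. when re-applying overlays to an already assembled
#'   map) makes the assembly exactly idempotent.
#' @return List with `labels` (the recoded [label_grid()]) and
#'   `overlay_units` (data frame of the overlay codes added).
#' @export
assemble_overlays <- function(base, geothermal = NULL, colonies = NULL,
                              lakes = NULL, land_mask = NULL,
                              colony_label = NULL) {
  grid <- base$grid
  if (is.null(land_mask)) land_mask <- matrix(TRUE, grid$nrows, grid$ncols)
  storage.mode(land_mask) <- "logical"
  codes <- base$codes
  legend <- base$legend
  next_code <- if (length(legend)) max(as.integer(names(legend))) else 0L
  units <- list()
  add_unit <- function(label, tier1, tier2) {
    # reuse an existing legend entry (e.g. G1/L1 on re-assembly), so
    # overlay application is idempotent for the fixed-label overlays
    hit <- which(legend == label)
    if (length(hit)) return(as.integer(names(legend)[hit[1]]))
    next_code <<- next_code + 1L
    legend[as.character(next_code)] <<- label
    units[[length(units) + 1L]] <<- data.frame(
      code = next_code, label = label, tier1 = tier1, tier2 = tier2,
      stringsAsFactors = FALSE)
    next_code
  }
  paint <- function(mask, code) {
    sel <- mask & land_mask
    codes[sel] <<- code
  }

  # geothermal first (lowest of the overlays)
  if (!is.null(geothermal)) {
    geo_codes <- c(active = "G1", dormant = "G2", radiogenic = "G3")
    for (cat in names(geo_codes)) {
      polys <- geothermal[[cat]]
      if (is.null(polys) || !length(polys$features)) next
      code <- add_unit(geo_codes[[cat]], geo_codes[[cat]], "")
      touch <- rasterize_touch(polys, grid)$values > 0
      paint(touch, code)
    }
  }

  # penguin colonies: one Habitat Complex within E1
  if (!is.null(colonies) &&
      ((inherits(colonies, "polygon_set") && length(colonies$features)) ||
       (is.list(colonies) && length(colonies)))) {
    polys <- if (inherits(colonies, "polygon_set")) colonies else {
      feats <- unlist(lapply(colonies, function(f) f$polygon$features),
                      recursive = FALSE)
      polygon_set(feats)
    }
    if (length(polys$features)) {
      if (is.null(colony_label)) {
        e1_b <- grep("^E1B", legend, value = TRUE)
        b_idx <- if (length(e1_b))
          max(as.integer(sub("^E1B", "", e1_b))) + 1L else 1L
        colony_label <- paste0("E1B", b_idx)
      }
      code <- add_unit(colony_label, "E1",
                       sub("^E1", "", colony_label))
      touch <- rasterize_touch(polys, grid)$values > 0
      paint(touch, code)
    }
  }

  # lakes on top
  if (!is.null(lakes)) {
    code <- add_unit("L1", "L1", "")
    paint(lakes$values > 0, code)
  }

  list(labels = label_grid(grid, codes, legend = legend),
       overlay_units = if (length(units)) do.call(rbind, units) else NULL)
}
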