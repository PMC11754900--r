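#' Pipeline configuration
#'
#' Collects every setting of the staged workflow. All stages read their
#' inputs from, and write their outputs to, `out_dir`, so any stage can
#' be re-run independently against the artifacts already on disk.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Global seed; seeds the generator and parallel analysis.
#' @param synthetic A [synthetic_config()] for the simulate stage
#'   (defaults to `synthetic_config(seed = seed)`).
#' @param tier1_k,tier2_k Facet counts (or `"auto"`).
#' @param pa_replicates,pa_quantile Parallel-analysis settings.
#' @param rotation,scoring Factor-model settings.
#' @param transform Tier 2 transform (`"double_log"` default).
#' @param small_unit Tier 2 small-unit action (`"single"`: an
#'   undersized unit becomes one complex instead of aborting the run).
#' @param min_pixels,adjacency_threshold,connectivity Amalgamation
#'   parameters.
#' @param lake_threshold Lake coverage threshold.
#' @param geothermal_buffer_m Synthetic geothermal footprint radius.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, synthetic = NULL,
                            tier1_k = 5, tier2_k = 2,
                            pa_replicates = 100, pa_quantile = 0.95,
                            rotation = "promax", scoring = "regression",
                            transform = "double_log",
                            small_unit = "single",
                            min_pixels = 100, adjacency_threshold = 0.05,
                            connectivity = 8, lake_threshold = 0.5,
                            geothermal_buffer_m = 500) {
  if (is.null(synthetic)) synthetic <- synthetic_config(seed = seed)
  structure(as.list(environment()), class = "pipeline_config")
}

plog <- function(config, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  cat(line, "\n", file = file.path(config$out_dir, "pipeline.log"),
      append = TRUE)
  message(line)
}

# small polynomial rolling hash of the deparsed config for provenance
config_hash <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), "out_dir")]),
             collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_metadata <- function(config, stage) {
  path <- file.path(config$out_dir, "metadata.json")
  meta <- list(config_hash = config_hash(config), seed = config$seed,
               last_stage = stage,
               written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE)
}

#' Run the tiered classification pipeline
#'
#' Executes the requested stages in order (`simulate`, `tier1`,
#' `tier2`, `overlays`, `tier3`, `confidence`, `report`), each stage
#' persisting its outputs before the next begins. Re-running a single
#' stage reuses the artifacts of earlier stages unchanged. The run is
#' deterministic given the configuration.
#'
#' @param config A [pipeline_config()].
#' @param stages Which stages to run (default: all, in order).
#' @return The run report (invisible for non-report stages): per-tier
#'   unit counts, areas, unclassified fraction and dominance summaries.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "tier1", "tier2",
                                    "overlays", "tier3", "confidence",
                                    "report")) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  known <- c("simulate", "tier1", "tier2", "overlays", "tier3",
             "confidence", "report")
  stages <- match.arg(stages, known, several.ok = TRUE)
  report <- NULL
  for (st in known[known %in% stages]) {
    result <- tryCatch(
      switch(st,
             simulate = stage_simulate(config),
             tier1 = stage_tier1(config),
             tier2 = stage_tier2(config),
             overlays = stage_overlays(config),
             tier3 = stage_tier3(config),
             confidence = stage_confidence(config),
             report = stage_report(config)),
      error = function(e)
        stop("pipeline stage '", st, "' failed: ", conditionMessage(e),
             call. = FALSE))
    if (st == "report") report <- result
    write_metadata(config, st)
  }
  invisible(report)
}

op <- function(config, ...) file.path(config$out_dir, ...)

stage_simulate <- function(config) {
  plog(config, "simulate", paste("generating landscape, seed",
                                 config$synthetic$seed))
  land <- gen_landscape(config$synthetic)
  dir.create(op(config, "abiotic"), showWarnings = FALSE)
  dir.create(op(config, "suitability"), showWarnings = FALSE)
  grid <- land$abiotic$grid
  for (v in names(land$abiotic$layers))
    write_raster(raster_layer(grid, land$abiotic$layers[[v]]),
                 op(config, "abiotic", paste0(v, ".asc")))
  for (v in names(land$suitability$layers))
    write_raster(raster_layer(grid, land$suitability$layers[[v]]),
                 op(config, "suitability", paste0(v, ".asc")))
  write_raster(raster_layer(grid, land$abiotic$land_mask * 1),
               op(config, "land_mask.asc"))
  write_raster(land$bioregions, op(config, "bioregions.asc"))
  write_table(data.frame(code = names(land$bioregions$legend),
                         abbrev = unname(land$bioregions$legend)),
              op(config, "bioregions_legend.csv"))
  write_polygons(land$lakes, op(config, "lakes.geojson"))
  write_table(land$colonies$observations, op(config, "colonies.csv"))
  write_table(land$colonies$calibration, op(config, "calibration.csv"))
  write_table(land$volcanoes, op(config, "volcanoes.csv"))
  write_raster(land$truth$tier1_labels, op(config, "truth_tier1.asc"))
  write_raster(land$truth$tier2_group, op(config, "truth_tier2_group.asc"))
  plog(config, "simulate", sprintf("%d land pixels, %d colonies, %d lakes",
                                   sum(land$abiotic$land_mask),
                                   nrow(land$colonies$table),
                                   length(land$lakes$features)))
  invisible(NULL)
}

load_stack <- function(config, subdir) {
  files <- sort(list.files(op(config, subdir), pattern = "\\.asc$",
                           full.names = TRUE))
  land <- read_raster(op(config, "land_mask.asc"))
  layers <- lapply(files, function(f) read_raster(f)$values)
  names(layers) <- sub("\\.asc$", "", basename(files))
  raster_stack(land$grid, layers,
               land_mask = !is.na(land$values) & land$values > 0)
}

stage_tier1 <- function(config) {
  abiotic <- load_stack(config, "abiotic")
  plog(config, "tier1", sprintf("classifying %d land pixels (k = %s)",
                                sum(abiotic$land_mask),
                                as.character(config$tier1_k)))
  res <- classify_tier1(abiotic, k = config$tier1_k,
                        rotation = config$rotation,
                        scoring = config$scoring,
                        pa_replicates = config$pa_replicates,
                        pa_quantile = config$pa_quantile,
                        pa_seed = config$seed)
  write_raster(res$labels, op(config, "tier1_labels.asc"))
  write_table(data.frame(code = names(res$labels$legend),
                         label = unname(res$labels$legend)),
              op(config, "tier1_legend.csv"))
  write_factor_model(res$model, op(config, "tier1_loadings.csv"))
  for (nm in names(res$scores$scores))
    write_raster(raster_layer(res$labels$grid, res$scores$scores[[nm]]),
                 op(config, paste0("tier1_scores_", nm, ".asc")))
  if (!is.null(res$eigen))
    write_table(data.frame(
      rank = seq_along(res$eigen$observed_eigenvalues),
      observed = res$eigen$observed_eigenvalues,
      null_quantile = res$eigen$null_eigenvalue_quantiles),
      op(config, "tier1_eigen.csv"))
  plog(config, "tier1", sprintf("%d Major Environmental Units",
                                res$model$k))
  invisible(NULL)
}

stage_tier2 <- function(config) {
  suit <- load_stack(config, "suitability")
  t1 <- read_raster(op(config, "tier1_labels.asc"), as_labels = TRUE)
  leg <- read_table(op(config, "tier1_legend.csv"))
  t1$legend <- stats::setNames(leg$label, leg$code)
  plog(config, "tier2", "subdividing units into Habitat Complexes")
  res <- classify_tier2(suit, t1, k = config$tier2_k,
                        transform = config$transform,
                        small_unit = config$small_unit,
                        rotation = config$rotation,
                        scoring = config$scoring,
                        pa_replicates = config$pa_replicates,
                        pa_quantile = config$pa_quantile,
                        pa_seed = config$seed)
  filled <- nibble_fill(res$labels, t1, suit$land_mask,
                        connectivity = config$connectivity)
  write_raster(filled, op(config, "tier2_labels.asc"))
  write_table(res$units, op(config, "tier2_legend.csv"))
  for (u in names(res$results)) {
    write_factor_model(res$results[[u]]$model,
                       op(config, paste0("tier2_loadings_", u, ".csv")))
    sc <- res$results[[u]]$scores
    for (nm in names(sc$scores))
      write_raster(raster_layer(filled$grid, sc$scores[[nm]]),
                   op(config, paste0("tier2_scores_", nm, ".asc")))
  }
  unfilled <- sum(res$labels$codes == 0L & suit$land_mask)
  still <- sum(filled$codes == 0L & suit$land_mask)
  plog(config, "tier2",
       sprintf("%d complexes; nibble filled %d pixels, %d left unclassified",
               nrow(res$units), unfilled - still, still))
  invisible(NULL)
}

stage_overlays <- function(config) {
  t2 <- read_raster(op(config, "tier2_labels.asc"), as_labels = TRUE)
  units <- read_table(op(config, "tier2_legend.csv"))
  t2$legend <- stats::setNames(units$label, units$code)
  land <- read_raster(op(config, "land_mask.asc"))
  land_mask <- !is.na(land$values) & land$values > 0
  grid <- t2$grid

  # geothermal: categorize and buffer the point records
  volcanoes <- read_table(op(config, "volcanoes.csv"))
  volcanoes$category <- vapply(seq_len(nrow(volcanoes)), function(i)
    categorize_geothermal(volcanoes[i, ]), character(1))
  write_table(volcanoes, op(config, "volcanoes_categorized.csv"))
  geo <- list()
  for (cat in c("active", "dormant", "radiogenic")) {
    sel <- volcanoes[volcanoes$category == cat, ]
    if (!nrow(sel)) next
    feats <- lapply(seq_len(nrow(sel)), function(i)
      make_circle(sel$x[i], sel$y[i], config$geothermal_buffer_m,
                  n = 128L)$features[[1]])
    geo[[cat]] <- polygon_set(feats)
  }

  # colonies: clean, standardize counts, footprint
  obs <- read_table(op(config, "colonies.csv"))
  tab <- colony_table(obs)
  cleaned <- clean_colony_locations(tab, land_mask, grid)
  write_table(cleaned$log, op(config, "colony_cleaning_log.csv"))
  ratios <- estimate_species_ratios(obs, on_missing = "skip")
  write_table(ratios, op(config, "species_ratios.csv"))
  calibration <- read_table(op(config, "calibration.csv"))
  amodel <- fit_area_model(calibration)
  kept <- cleaned$colonies
  footprints <- list()
  pairs_log <- list()
  for (i in seq_len(nrow(kept))) {
    cobs <- obs[obs$id == kept$id[i], ]
    pairs <- estimate_breeding_pairs(cobs, ratios)
    a <- suppressWarnings(predict_area(amodel, pairs))
    footprints[[i]] <- colony_footprint(kept$x[i], kept$y[i], a)
    pairs_log[[i]] <- data.frame(
      id = kept$id[i], pairs = pairs, area_m2 = a,
      radius_m = footprints[[i]]$radius,
      flag = if (pairs > 80000) "manual-review-large" else "",
      stringsAsFactors = FALSE)
  }
  write_table(do.call(rbind, pairs_log), op(config, "colony_pairs.csv"))

  lakes <- read_polygons(op(config, "lakes.geojson"))
  lake_raster <- build_lake_raster(lakes, grid,
                                   threshold = config$lake_threshold)

  res <- assemble_overlays(t2, geothermal = geo, colonies = footprints,
                           lakes = lake_raster, land_mask = land_mask)
  write_raster(res$labels, op(config, "tier2_final_labels.asc"))
  all_units <- rbind(units[, c("code", "label", "tier1", "tier2")],
                     res$overlay_units)
  write_table(all_units, op(config, "tier2_final_legend.csv"))
  plog(config, "overlays",
       sprintf("added %d overlay units (%d colonies kept)",
               if (is.null(res$overlay_units)) 0L
               else nrow(res$overlay_units), nrow(kept)))
  invisible(NULL)
}

stage_tier3 <- function(config) {
  t2 <- read_raster(op(config, "tier2_final_labels.asc"), as_labels = TRUE)
  units <- read_table(op(config, "tier2_final_legend.csv"))
  units$tier2[is.na(units$tier2)] <- ""
  t2$legend <- stats::setNames(units$label, units$code)
  br <- read_raster(op(config, "bioregions.asc"), as_labels = TRUE)
  leg <- read_table(op(config, "bioregions_legend.csv"))
  br$legend <- stats::setNames(leg$abbrev, leg$code)
  cand <- intersect_bioregions(t2, br, units = units)
  plog(config, "tier3", sprintf("%d candidate units", nrow(cand$units)))
  final <- amalgamate(cand, min_pixels = config$min_pixels,
                      adjacency_threshold = config$adjacency_threshold,
                      connectivity = config$connectivity)
  write_raster(final$labels, op(config, "tier3_labels.asc"))
  write_table(final$units, op(config, "tier3_units.csv"))
  write_table(final$log, op(config, "amalgamation_log.csv"))
  plog(config, "tier3", sprintf("%d final Bioregional Ecosystem Types",
                                nrow(final$units)))
  invisible(NULL)
}

read_score_stack <- function(config, pattern) {
  files <- sort(list.files(config$out_dir, pattern = pattern,
                           full.names = TRUE))
  if (!length(files)) stop("no score rasters matching ", pattern)
  layers <- lapply(files, function(f) read_raster(f)$values)
  names(layers) <- sub("^.*scores_(.*)\\.asc$", "\\1", files)
  grid <- read_raster(files[1])$grid
  structure(list(grid = grid, scores = layers), class = "score_stack")
}

stage_confidence <- function(config) {
  s1 <- read_score_stack(config, "^tier1_scores_.*\\.asc$")
  d1 <- dominance_from_scores(s1)
  write_raster(raster_layer(d1$grid, d1$values),
               op(config, "tier1_dominance.asc"))

  # tier 2 dominance: per parent unit, over that unit's facet scores
  units <- read_table(op(config, "tier2_legend.csv"))
  s2files <- list.files(config$out_dir,
                        pattern = "^tier2_scores_.*\\.asc$",
                        full.names = TRUE)
  grid <- d1$grid
  d2 <- matrix(NA_real_, grid$nrows, grid$ncols)
  for (parent in unique(units$tier1)) {
    f <- sort(s2files[grepl(paste0("^tier2_scores_", parent, "B"),
                            basename(s2files))])
    if (length(f) < 2) next   # single-complex unit: no contrast
    layers <- lapply(f, function(p) read_raster(p)$values)
    names(layers) <- sub("\\.asc$", "", basename(f))
    du <- dominance_from_scores(
      structure(list(grid = grid, scores = layers),
                class = "score_stack"))
    sel <- !is.na(du$values)
    d2[sel] <- du$values[sel]
  }
  write_raster(raster_layer(grid, d2), op(config, "tier2_dominance.asc"))
  plog(config, "confidence", "dominance grids written for tiers 1-2")
  invisible(NULL)
}

stage_report <- function(config) {
  t1 <- read_raster(op(config, "tier1_labels.asc"), as_labels = TRUE)
  t2 <- read_raster(op(config, "tier2_final_labels.asc"), as_labels = TRUE)
  t3units <- read_table(op(config, "tier3_units.csv"))
  land <- read_raster(op(config, "land_mask.asc"))
  land_mask <- !is.na(land$values) & land$values > 0
  n_land <- sum(land_mask)
  px_area_km2 <- (t1$grid$cell_size / 1000)^2

  dom_summary <- function(path) {
    d <- read_raster(path)
    summarize_dominance(structure(list(grid = d$grid, values = d$values),
                                  class = "dominance_grid"))
  }
  d1 <- dom_summary(op(config, "tier1_dominance.asc"))
  d2 <- dom_summary(op(config, "tier2_dominance.asc"))

  report <- list(
    n_land_pixels = n_land,
    area_km2 = n_land * px_area_km2,
    tier1_units = length(setdiff(unique(as.vector(t1$codes)), 0L)),
    tier2_units = length(setdiff(unique(as.vector(t2$codes)), 0L)),
    tier3_units = nrow(t3units),
    frac_unclassified = sum(t2$codes == 0L & land_mask) / n_land,
    tier3_table = data.frame(
      code = t3units$code, pixel_count = t3units$pixel_count,
      area_km2 = t3units$pixel_count * px_area_km2,
      amalgamated = t3units$amalgamated),
    dominance = list(
      tier1 = list(frac_ge_0.2 = d1$frac_ge_0.2,
                   frac_lt_0.1 = d1$frac_lt_0.1),
      tier2 = list(frac_ge_0.2 = d2$frac_ge_0.2,
                   frac_lt_0.1 = d2$frac_lt_0.1)),
    provenance = list(seed = config$seed,
                      config_hash = config_hash(config)))
  jsonlite::write_json(report, op(config, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_table(report$tier3_table, op(config, "report_tier3_units.csv"))
  plog(config, "report",
       sprintf("%d/%d/%d units, %.1f%% unclassified, tier1 dom>=0.2: %.0f%%",
               report$tier1_units, report$tier2_units, report$tier3_units,
               100 * report$frac_unclassified,
               100 * report$dominance$tier1$frac_ge_0.2))
  report
}
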