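#' Raster and table input/output
#'
#' Rasters are written as ESRI ASCII grids (`.asc`): a plain-text,
#' GIS-standard single-band format holding the grid geometry in its
#' header. Integer label grids round-trip exactly; continuous layers are
#' written at full double precision. Tables are CSV with a header row;
#' polygons are GeoJSON in planar coordinates.
#'
#' @param layer A [raster_layer()] or [label_grid()].
#' @param path File path.
#' @param nodata Value used to encode `NA`/unclassified in the file.
#' @name raster_io
NULL

#' @rdname raster_io
#' @export
write_raster <- function(layer, path, nodata = -9999) {
  if (inherits(layer, "label_grid")) {
    grid <- layer$grid
    vals <- layer$codes
    fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
  } else if (inherits(layer, "raster_layer")) {
    grid <- layer$grid
    vals <- layer$values
    fmt <- function(v) formatC(v, format = "g", digits = 17)
  } else stop("layer must be a raster_layer or label_grid")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$ncols),
    paste("nrows", grid$nrows),
    paste("xllcorner", formatC(grid$xmin, format = "g", digits = 17)),
    paste("yllcorner", formatC(grid$ymin, format = "g", digits = 17)),
    paste("cellsize", formatC(grid$cell_size, format = "g", digits = 17)),
    paste("NODATA_value", nodata)), con)
  v <- vals
  v[is.na(v)] <- nodata
  for (i in seq_len(grid$nrows))
    writeLines(paste(fmt(v[i, ]), collapse = " "), con)
  invisible(path)
}

#' @rdname raster_io
#' @param as_labels Read the file as a [label_grid()] of integer codes.
#' @export
read_raster <- function(path, as_labels = FALSE) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^[A-Za-z_]+\\s", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2L)
      stop("malformed raster header line: '", lines[i], "'")
    hdr[[tolower(parts[1])]] <- suppressWarnings(as.numeric(parts[2]))
    i <- i + 1L
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]]) || is.na(hdr[[k]]))
      stop("malformed raster file: missing or invalid header field '", k, "'")
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  grid <- grid_spec(hdr$nrows, hdr$ncols, hdr$cellsize,
                    xmin = hdr$xllcorner, ymin = hdr$yllcorner)
  body <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(body) != grid$nrows * grid$ncols)
    stop("malformed raster file: expected ", grid$nrows * grid$ncols,
         " values in field 'data', got ", length(body))
  m <- matrix(body, grid$nrows, grid$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  if (as_labels) {
    m[is.na(m)] <- 0
    label_grid(grid, m)
  } else raster_layer(grid, m)
}

#' @rdname raster_io
#' @param table A data frame.
#' @export
write_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname raster_io
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read / write polygon sets as GeoJSON
#'
#' Planar-coordinate GeoJSON FeatureCollections with Polygon or
#' MultiPolygon geometries. Feature properties round-trip through the
#' `attributes` field.
#'
#' @param polys A [polygon_set()].
#' @param path File path.
#' @export
write_polygons <- function(polys, path) {
  feats <- lapply(polys$features, function(f) {
    coords <- lapply(f$rings, function(r) {
      rc <- rbind(r, r[1, , drop = FALSE])   # GeoJSON rings are closed
      lapply(seq_len(nrow(rc)), function(i) c(rc[i, 1], rc[i, 2]))
    })
    list(type = "Feature",
         properties = c(list(id = f$id), f$attributes),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polygons
#' @export
read_polygons <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$type) || obj$type != "FeatureCollection")
    stop("malformed GeoJSON: field 'type' is not FeatureCollection")
  feats <- list()
  for (f in obj$features) {
    g <- f$geometry
    if (is.null(g$type)) stop("malformed GeoJSON: feature missing 'geometry'")
    poly_list <- switch(g$type,
      Polygon = list(g$coordinates),
      MultiPolygon = g$coordinates,
      stop("malformed GeoJSON: unsupported geometry type '", g$type, "'"))
    for (p in poly_list) {
      rings <- lapply(p, function(ring) {
        m <- do.call(rbind, lapply(ring, function(pt)
          c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
        m
      })
      props <- f$properties
      id <- if (!is.null(props$id)) props$id else length(feats) + 1L
      props$id <- NULL
      feats[[length(feats) + 1L]] <-
        list(rings = rings, id = id, attributes = props)
    }
  }
  polygon_set(feats)
}
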