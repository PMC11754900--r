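#' Grid specification for a co-registered raster analysis
#'
#' Defines a regular planar grid: row-major, origin at the upper-left
#' corner, 0-based pixel offsets internally exposed through 1-based R
#' indices. All geometry is planar (the workflows this package supports
#' operate in a polar stereographic plane); no geodesic corrections are
#' applied. At the default 100 m cell size one pixel is 1 ha.
#'
#' @param nrows,ncols Grid dimensions (>= 1).
#' @param cell_size Pixel edge length in metres (> 0), default 100.
#' @param xmin,ymin Planar coordinates of the lower-left grid corner.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(nrows, ncols, cell_size = 100, xmin = 0, ymin = 0) {
  nrows <- as.integer(nrows); ncols <- as.integer(ncols)
  if (is.na(nrows) || is.na(ncols) || nrows < 1L || ncols < 1L)
    stop("grid dimensions must be >= 1")
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be a positive length")
  structure(
    list(nrows = nrows, ncols = ncols, cell_size = as.numeric(cell_size),
         xmin = as.numeric(xmin), ymin = as.numeric(ymin)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d pixels, cell %g m, origin UL (%g, %g)\n",
              x$nrows, x$ncols, x$cell_size, x$xmin, grid_ymax(x)))
  invisible(x)
}

grid_ymax <- function(grid) grid$ymin + grid$nrows * grid$cell_size
grid_xmax <- function(grid) grid$xmin + grid$ncols * grid$cell_size

same_grid <- function(a, b, tol = 1e-9) {
  a$nrows == b$nrows && a$ncols == b$ncols &&
    abs(a$cell_size - b$cell_size) < tol &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("inputs are not co-registered: grids differ")
}

#' Pixel-center coordinates
#'
#' @param grid A [grid_spec()].
#' @param rows,cols 1-based row/column indices (row 1 is the top row).
#' @return A two-column matrix of x, y center coordinates.
#' @export
pixel_centers <- function(grid, rows, cols) {
  cs <- grid$cell_size
  cbind(x = grid$xmin + (cols - 0.5) * cs,
        y = grid_ymax(grid) - (rows - 0.5) * cs)
}

#' A single raster layer
#'
#' Values are stored as an `nrows x ncols` numeric matrix; `NA` encodes
#' nodata. Row 1 of the matrix is the northernmost row.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix matching the grid, `NA` = nodata.
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(grid, values) {
  values <- as.matrix(values)
  if (!identical(dim(values), c(grid$nrows, grid$ncols)))
    stop("values matrix does not match grid dimensions")
  if (any(is.infinite(values)))
    stop("raster values must be finite where not nodata")
  structure(list(grid = grid, values = values), class = "raster_layer")
}

#' A stack of co-registered raster layers with a land mask
#'
#' @param grid A [grid_spec()].
#' @param layers Named list of value matrices (or `raster_layer`s).
#' @param land_mask Logical matrix; `TRUE` marks analysis (ice-free land)
#'   pixels. Defaults to all `TRUE`.
#' @return An object of class `raster_stack`.
#' @export
raster_stack <- function(grid, layers, land_mask = NULL) {
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("all layers must be named")
  layers <- lapply(layers, function(l) {
    v <- if (inherits(l, "raster_layer")) l$values else as.matrix(l)
    if (!identical(dim(v), c(grid$nrows, grid$ncols)))
      stop("all layers must share the stack grid")
    v
  })
  if (is.null(land_mask))
    land_mask <- matrix(TRUE, grid$nrows, grid$ncols)
  storage.mode(land_mask) <- "logical"
  if (!identical(dim(land_mask), c(grid$nrows, grid$ncols)))
    stop("land_mask must match the grid")
  structure(list(grid = grid, layers = layers, land_mask = land_mask),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("<raster_stack> %d layers on %d x %d grid (%d land pixels)\n",
              length(x$layers), x$grid$nrows, x$grid$ncols,
              sum(x$land_mask)))
  cat(" layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Integer label raster with a legend
#'
#' Code 0 marks unclassified or nodata pixels; every nonzero code in use
#' must appear in the legend.
#'
#' @param grid A [grid_spec()].
#' @param codes Integer matrix of class codes (0 = unclassified).
#' @param legend Named character vector mapping code (as name) to a
#'   semantic label, e.g. `c("1" = "E1")`.
#' @return An object of class `label_grid`.
#' @export
label_grid <- function(grid, codes, legend = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (!identical(dim(codes), c(grid$nrows, grid$ncols)))
    stop("codes matrix does not match grid dimensions")
  codes[is.na(codes)] <- 0L
  if (any(codes < 0L)) stop("label codes must be non-negative")
  used <- setdiff(sort(unique(as.vector(codes))), 0L)
  if (is.null(legend)) {
    legend <- stats::setNames(as.character(used), as.character(used))
  } else {
    legend <- stats::setNames(as.character(legend), names(legend))
    missing <- setdiff(as.character(used), names(legend))
    if (length(missing))
      stop("codes missing from legend: ", paste(missing, collapse = ", "))
  }
  structure(list(grid = grid, codes = codes, legend = legend),
            class = "label_grid")
}

#' @export
print.label_grid <- function(x, ...) {
  used <- setdiff(unique(as.vector(x$codes)), 0L)
  cat(sprintf("<label_grid> %d x %d, %d classes in use\n",
              x$grid$nrows, x$grid$ncols, length(used)))
  invisible(x)
}

## ---- connectivity -------------------------------------------------------

neighbour_offsets <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 (rook) or 8 (queen)")
  if (connectivity == 4L)
    list(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  else
    list(dr = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
         dc = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
}

#' Connected components of a boolean raster
#'
#' Labels each maximal connected region of `TRUE` pixels with a distinct
#' positive integer (in order of first raster scan encounter); `FALSE`
#' and `NA` pixels get 0. Uses union-find over a single raster scan.
#'
#' @param mask Logical matrix or `raster_layer` with 0/1 values.
#' @param connectivity 4 (rook) or 8 (queen, default).
#' @return A [label_grid()] of component ids.
#' @export
connected_components <- function(mask, connectivity = 8) {
  if (inherits(mask, "raster_layer")) {
    grid <- mask$grid
    m <- mask$values > 0 & !is.na(mask$values)
  } else {
    m <- mask
    storage.mode(m) <- "logical"
    m[is.na(m)] <- FALSE
    grid <- grid_spec(nrow(m), ncol(m))
  }
  off <- neighbour_offsets(connectivity)
  # keep only "previous" neighbours for the forward scan (column-major:
  # up, and for queen also the column to the left)
  prev <- if (connectivity == 8)
    list(dr = c(-1L, -1L, 0L, 1L), dc = c(0L, -1L, -1L, -1L))
  else
    list(dr = c(-1L, 0L), dc = c(0L, -1L))

  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!m[i, j]) next
    neigh <- integer(0)
    for (d in seq_along(prev$dr)) {
      ii <- i + prev$dr[d]; jj <- j + prev$dc[d]
      if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc && lab[ii, jj] > 0L)
        neigh <- c(neigh, lab[ii, jj])
    }
    if (!length(neigh)) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[i, j] <- nxt
    } else {
      r <- min(vapply(neigh, find, integer(1)))
      lab[i, j] <- r
      for (n in neigh) parent[find(n)] <- r
    }
  }
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    # renumber roots in order of first appearance along the scan
    remap <- integer(nxt)
    k <- 0L
    for (j in seq_len(nc)) for (i in seq_len(nr)) {
      if (lab[i, j] > 0L) {
        r <- roots[lab[i, j]]
        if (remap[r] == 0L) { k <- k + 1L; remap[r] <- k }
      }
    }
    pos <- lab > 0L
    lab[pos] <- remap[roots[lab[pos]]]
  }
  label_grid(grid, lab)
}

#' Fractions of a unit's pixels adjacent to each other unit
#'
#' For the candidate unit `unit`, returns for every other code `u` the
#' share of `unit`'s pixels that have at least one neighbour labelled
#' `u`. This is the adjacency measure used by the amalgamation decision
#' rules (a unit counts as "adjacent" to another when the share reaches
#' a threshold, 5% by default there).
#'
#' @param labels A [label_grid()].
#' @param unit Code of the unit of interest (must be present).
#' @param connectivity 4 or 8 (default).
#' @return Named numeric vector of fractions (codes as names); units
#'   with no contact are omitted.
#' @export
adjacency_fractions <- function(labels, unit, connectivity = 8) {
  codes <- labels$codes
  unit <- as.integer(unit)
  sel <- codes == unit
  n_unit <- sum(sel)
  if (n_unit == 0L) stop("unit ", unit, " not present in labels")
  off <- neighbour_offsets(connectivity)
  nr <- nrow(codes); nc <- ncol(codes)
  touched <- list()
  for (d in seq_along(off$dr)) {
    shifted <- shift_matrix(codes, off$dr[d], off$dc[d], fill = 0L)
    touched[[d]] <- shifted
  }
  others <- setdiff(sort(unique(as.vector(codes))), c(0L, unit))
  out <- numeric(0)
  for (u in others) {
    has <- matrix(FALSE, nr, nc)
    for (d in seq_along(touched)) has <- has | (touched[[d]] == u)
    f <- sum(has & sel) / n_unit
    if (f > 0) out[as.character(u)] <- f
  }
  out
}

# shift a matrix by (dr, dc): value at (i,j) becomes the original value at
# (i+dr, j+dc); out-of-range positions take `fill`
shift_matrix <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r0 <- max(1L, 1L - dr); r1 <- min(nr, nr - dr)
  c0 <- max(1L, 1L - dc); c1 <- min(nc, nc - dc)
  if (r0 <= r1 && c0 <= c1)
    out[r0:r1, c0:c1] <- m[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc)]
  out
}
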