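#' Tier 1 classification: Major Environmental Units
#'
#' Runs the full facet workflow on the abiotic stack: standardize over
#' land pixels, select the factor count by parallel analysis (when
#' `k = "auto"`), fit the factor model, score every pixel, and classify
#' each to its highest-scoring facet. Legend codes are `E1..Ek`, ordered
#' by explained variance.
#'
#' @param abiotic A [raster_stack()] of abiotic variables.
#' @param k Number of facets, or `"auto"` for parallel-analysis
#'   selection. Default 5.
#' @param variables Layer names to use (default all).
#' @param rotation,scoring Passed to [fit_factors()].
#' @param pa_replicates,pa_quantile,pa_seed Parallel-analysis settings.
#' @param model Optional pre-built [factor_model()] (e.g. published
#'   loadings); skips fitting and scores/classifies with it directly.
#' @return An object of class `tier_result`: `labels`, `scores`,
#'   `model`, `eigen` (NULL unless auto), `tier = 1`.
#' @export
classify_tier1 <- function(abiotic, k = 5, variables = names(abiotic$layers),
                           rotation = "promax", scoring = "regression",
                           pa_replicates = 100, pa_quantile = 0.95,
                           pa_seed = 1, model = NULL) {
  eig <- NULL
  if (is.null(model)) {
    std <- standardize(abiotic, variables)
    if (identical(k, "auto")) {
      eig <- parallel_analysis(std$z, n_replicates = pa_replicates,
                               quantile = pa_quantile, seed = pa_seed)
      k <- max(eig$retained_k, 1L)
    }
    model <- fit_factors(std, k = k, rotation = rotation, scoring = scoring)
  }
  scores <- compute_scores(model, abiotic)
  labels <- classify_max_score(scores,
                               legend = paste0("E", seq_len(model$k)))
  structure(list(labels = labels, scores = scores, model = model,
                 eigen = eig, tier = 1L, parent_unit = NULL),
            class = "tier_result")
}

#' @export
print.tier_result <- function(x, ...) {
  cat(sprintf("<tier_result> tier %d%s: %d classes on %d x %d grid\n",
              x$tier,
              if (is.null(x$parent_unit)) "" else
                paste0(" (within unit ", x$parent_unit, ")"),
              x$model$k, x$labels$grid$nrows, x$labels$grid$ncols))
  invisible(x)
}

#' Double-log transform of habitat-suitability columns
#'
#' Habitat-suitability surfaces are strongly skewed toward small values
#' and share a common mild-conditions trend; a single log is not enough
#' to separate biotic groupings. The transform applied per taxon column
#' is: log, then range-normalize to `[1, 100]`, then log again, giving
#' values in `[0, log(100)]`. Natural logarithms throughout (the
#' classification is invariant to the base of the outer log only up to
#' the interleaved normalization, so the base is fixed and documented).
#' Zeros and negative values are floored at half the smallest positive
#' value of the column before the first log. A constant column is
#' mapped to all zeros with a warning. Within-column ranks are
#' preserved exactly.
#'
#' @param x Numeric matrix (pixels x taxa).
#' @param order `"log_first"` (default: log, normalize, log) or
#'   `"normalize_first"` (normalize raw values, then log twice).
#' @return Transformed matrix, same dimensions.
#' @export
double_log_transform <- function(x, order = c("log_first",
                                              "normalize_first")) {
  order <- match.arg(order)
  x <- as.matrix(x)
  out <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    v1 <- if (order == "log_first") log_with_floor(col) else col
    lo <- min(v1); hi <- max(v1)
    if (hi == lo) {
      warning("degenerate normalization: column ",
              if (!is.null(colnames(x))) colnames(x)[j] else j,
              " is constant; mapped to 0")
      out[, j] <- 0
      next
    }
    v2 <- 1 + 99 * (v1 - lo) / (hi - lo)   # range-normalize to [1, 100]
    out[, j] <- if (order == "log_first") log(v2)
                else log_with_floor(log(v2))  # log twice, floored inner 0
  }
  out
}

log_with_floor <- function(col) {
  pos <- col[col > 0]
  if (!length(pos)) return(rep(0, length(col)))
  floor_val <- min(pos) / 2
  log(pmax(col, floor_val))
}

#' Single-log transform (ablation comparator)
#'
#' One log with the same positivity floor as [double_log_transform()];
#' used to demonstrate why the double-log version is needed on
#' wedge-shaped suitability data.
#'
#' @param x Numeric matrix (pixels x taxa).
#' @return Transformed matrix.
#' @export
single_log_transform <- function(x) {
  x <- as.matrix(x)
  for (j in seq_len(ncol(x))) x[, j] <- log_with_floor(x[, j])
  x
}

#' Tier 2 classification: Habitat Complexes within each unit
#'
#' Subdivides every Tier 1 Major Environmental Unit independently: its
#' land pixels' suitability values are double-log transformed (per
#' taxon, within the unit), a factor model is fitted, pixels are scored
#' and classified to the highest-scoring biotic facet. Loadings are
#' expected all-positive (classification by predicted presence); the
#' orientation convention in [fit_factors()] enforces positive
#' alignment. Legend codes are `E<i>B<j>`.
#'
#' @param suitability A [raster_stack()] of habitat-suitability layers.
#' @param tier1 A `tier_result` from [classify_tier1()] (or a
#'   [label_grid()] of Tier 1 units).
#' @param k Facet count per unit: a single count, `"auto"`, or a named
#'   list keyed by unit code. Default 2.
#' @param transform `"double_log"` (default), `"single_log"`, or
#'   `"none"`.
#' @param min_unit_pixels Units with fewer pixels than this (default
#'   `max(25, n_taxa + 1)`) trigger the small-unit action.
#' @param small_unit `"error"` (default) or `"single"`: assign all of a
#'   too-small unit's pixels to a single complex B1 instead of failing.
#' @param rotation,scoring,pa_replicates,pa_quantile,pa_seed As in
#'   [classify_tier1()].
#' @return List with `labels` (combined [label_grid()], legend
#'   `E<i>B<j>`), `units` (data frame mapping code to tier1/tier2), and
#'   `results` (per-unit `tier_result`s, named by parent unit code).
#' @export
classify_tier2 <- function(suitability, tier1, k = 2,
                           transform = c("double_log", "single_log", "none"),
                           min_unit_pixels = NULL,
                           small_unit = c("error", "single"),
                           rotation = "promax", scoring = "regression",
                           pa_replicates = 100, pa_quantile = 0.95,
                           pa_seed = 1) {
  transform <- match.arg(transform)
  small_unit <- match.arg(small_unit)
  t1_labels <- if (inherits(tier1, "tier_result")) tier1$labels else tier1
  grid <- suitability$grid
  stopifnot_same_grid(grid, t1_labels$grid)
  taxa <- names(suitability$layers)
  if (is.null(min_unit_pixels)) min_unit_pixels <- max(25L, length(taxa) + 1L)

  land <- which(suitability$land_mask)
  raw <- vapply(taxa, function(v) suitability$layers[[v]][land],
                numeric(length(land)))
  ok <- stats::complete.cases(raw)
  t1_codes <- t1_labels$codes[land]

  units <- setdiff(sort(unique(t1_codes[ok])), 0L)
  codes_out <- matrix(0L, grid$nrows, grid$ncols)
  legend <- character(0)
  unit_rows <- list()
  results <- list()
  next_code <- 0L

  for (u in units) {
    uname <- unname(t1_labels$legend[as.character(u)])
    sel <- ok & t1_codes == u
    n_u <- sum(sel)
    if (n_u < min_unit_pixels) {
      if (small_unit == "error")
        stop("unit ", uname, " has only ", n_u,
             " classifiable pixels (< ", min_unit_pixels, ")")
      next_code <- next_code + 1L
      codes_out[land[sel]] <- next_code
      legend[as.character(next_code)] <- paste0(uname, "B1")
      unit_rows[[length(unit_rows) + 1L]] <- data.frame(
        code = next_code, label = paste0(uname, "B1"),
        tier1 = uname, tier2 = "B1", stringsAsFactors = FALSE)
      next
    }
    x <- raw[sel, , drop = FALSE]
    tx <- switch(transform,
                 double_log = suppressWarnings(double_log_transform(x)),
                 single_log = single_log_transform(x),
                 none = x)
    keep <- apply(tx, 2, function(c) stats::sd(c) > 0)
    tx <- tx[, keep, drop = FALSE]
    if (ncol(tx) < 2L) {
      # one shared suitability profile: a single complex, no analysis
      next_code <- next_code + 1L
      codes_out[land[sel]] <- next_code
      legend[as.character(next_code)] <- paste0(uname, "B1")
      unit_rows[[length(unit_rows) + 1L]] <- data.frame(
        code = next_code, label = paste0(uname, "B1"),
        tier1 = uname, tier2 = "B1", stringsAsFactors = FALSE)
      next
    }
    k_u <- if (is.list(k)) {
      if (!is.null(k[[uname]])) k[[uname]] else 2L
    } else k
    eig <- NULL
    if (identical(k_u, "auto")) {
      eig <- parallel_analysis(tx, n_replicates = pa_replicates,
                               quantile = pa_quantile, seed = pa_seed)
      k_u <- max(eig$retained_k, 1L)
    }
    k_u <- min(as.integer(k_u), ncol(tx))
    std <- standardize_matrix(tx)
    model <- fit_factors(std$z, k = k_u, rotation = rotation,
                         scoring = scoring)
    s <- score_z(model, std$z)
    b <- max.col(s, ties.method = "first")
    codes_u <- next_code + b
    codes_out[land[sel]] <- codes_u
    for (j in seq_len(k_u)) {
      legend[as.character(next_code + j)] <- paste0(uname, "B", j)
      unit_rows[[length(unit_rows) + 1L]] <- data.frame(
        code = next_code + j, label = paste0(uname, "B", j),
        tier1 = uname, tier2 = paste0("B", j), stringsAsFactors = FALSE)
    }
    score_mats <- lapply(seq_len(k_u), function(j) {
      m <- matrix(NA_real_, grid$nrows, grid$ncols)
      m[land[sel]] <- s[, j]
      m
    })
    names(score_mats) <- paste0(uname, "B", seq_len(k_u))
    results[[uname]] <- structure(
      list(labels = NULL,
           scores = structure(list(grid = grid, scores = score_mats),
                              class = "score_stack"),
           model = model, eigen = eig, tier = 2L, parent_unit = uname),
      class = "tier_result")
    next_code <- next_code + k_u
  }

  labels <- label_grid(grid, codes_out, legend = legend)
  list(labels = labels,
       units = do.call(rbind, unit_rows),
       results = results)
}

#' Nibble fill of unclassified pixels
#'
#' Assigns each unclassified land pixel the Tier 2 label of its nearest
#' classified pixel (Euclidean distance between pixel centers) that
#' lies in the same Tier 1 unit and shares a contiguous ice-free patch
#' with it. Pixels with no such donor (e.g. an isolated patch with no
#' classified pixel in the same unit) remain unclassified. Already
#' classified pixels are never altered, and no fill crosses a Tier 1
#' unit boundary. Equidistant donors break by row-major pixel order.
#'
#' @param labels A [label_grid()] of Tier 2 labels (0 = unclassified).
#' @param tier1 A [label_grid()] of Tier 1 units.
#' @param land_mask Logical matrix of in-scope pixels.
#' @param connectivity Patch connectivity, 4 or 8 (default).
#' @return A filled [label_grid()].
#' @export
nibble_fill <- function(labels, tier1, land_mask, connectivity = 8) {
  stopifnot_same_grid(labels$grid, tier1$grid)
  grid <- labels$grid
  storage.mode(land_mask) <- "logical"
  patches <- connected_components(land_mask, connectivity)$codes
  codes <- labels$codes
  nr <- grid$nrows
  # row-major linear order index for deterministic tie-breaks
  rowmajor <- function(idx) {
    r <- (idx - 1L) %% nr + 1L
    c <- (idx - 1L) %/% nr + 1L
    (r - 1L) * grid$ncols + c
  }
  todo <- which(land_mask & codes == 0L & tier1$codes > 0L)
  if (!length(todo)) return(labels)
  donors_all <- which(codes > 0L)
  if (!length(donors_all)) return(labels)
  key_todo <- paste(tier1$codes[todo], patches[todo])
  key_don <- paste(tier1$codes[donors_all], patches[donors_all])
  filled <- codes
  for (key in unique(key_todo)) {
    u_idx <- todo[key_todo == key]
    d_idx <- donors_all[key_don == key]
    if (!length(d_idx)) next
    d_idx <- d_idx[order(rowmajor(d_idx))]
    ur <- (u_idx - 1L) %% nr + 1L; uc <- (u_idx - 1L) %/% nr + 1L
    dr <- (d_idx - 1L) %% nr + 1L; dc <- (d_idx - 1L) %/% nr + 1L
    # squared center distances in cell units are exact integers,
    # so equidistance ties are exact and which.min takes the first
    # donor in row-major order
    d2 <- outer(ur, dr, "-")^2 + outer(uc, dc, "-")^2
    nearest <- apply(d2, 1, which.min)
    filled[u_idx] <- codes[d_idx[nearest]]
  }
  label_grid(grid, filled, legend = labels$legend)
}
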