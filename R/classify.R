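#' Deterministic maximum-score classification
#'
#' Assigns each pixel to the facet with the highest score (1-based facet
#' index). Exact ties break to the lowest facet index, so the solution
#' is fully deterministic. Pixels with nodata scores stay unclassified
#' (code 0). High negative scores are not split into separate classes:
#' classification is by best fit only.
#'
#' @param scores A `score_stack` from [compute_scores()].
#' @param legend Optional character vector of facet names (defaults to
#'   the score layer names).
#' @return A [label_grid()].
#' @export
classify_max_score <- function(scores, legend = NULL) {
  k <- length(scores$scores)
  grid <- scores$grid
  n <- grid$nrows * grid$ncols
  smat <- matrix(vapply(scores$scores, as.vector, numeric(n)), nrow = n)
  codes <- rep(0L, n)
  ok <- stats::complete.cases(smat)
  if (any(ok))
    codes[ok] <- max.col(smat[ok, , drop = FALSE], ties.method = "first")
  if (is.null(legend)) legend <- names(scores$scores)
  if (is.null(legend)) legend <- paste0("F", seq_len(k))
  label_grid(grid, matrix(codes, grid$nrows, grid$ncols),
             legend = stats::setNames(legend, seq_len(k)))
}

#' Dominance of the best-fitting class
#'
#' The classification-confidence index for one pixel: the difference
#' between the best and second-best fit divided by the total range of
#' fits, `d = (best - second) / (max - min)`. `d = 1` means the winning
#' class is the only plausible candidate; `d = 0` means two or more
#' classes fit equally well (including the all-equal case).
#'
#' @param fits Numeric vector of at least two non-negative fit values.
#' @return A number in `[0, 1]`.
#' @examples
#' dominance_index(c(1, 2, 3, 4, 5, 6))  # 0.2
#' dominance_index(c(1, 2, 4, 8, 16))    # 0.533...
#' @export
dominance_index <- function(fits) {
  fits <- as.numeric(fits)
  if (length(fits) < 2) stop("dominance needs at least 2 fit values")
  if (any(!is.finite(fits))) stop("fits must be finite")
  rng <- max(fits) - min(fits)
  if (rng == 0) return(0)
  srt <- sort(fits, decreasing = TRUE)
  (srt[1] - srt[2]) / rng
}

#' Per-pixel dominance from facet scores
#'
#' Scores are exponentiated first to map them to a positive range (and
#' damp the influence of strongly negative scores, which do not form
#' separate classes); the dominance index is then computed per pixel.
#' The exponential preserves score order but not differences, so the
#' result is not invariant to adding a constant to a pixel's scores.
#'
#' @param scores A `score_stack`.
#' @return An object of class `dominance_grid`: list with `grid` and
#'   `values` (matrix in `[0, 1]`, `NA` on unclassified pixels).
#' @export
dominance_from_scores <- function(scores) {
  grid <- scores$grid
  n <- grid$nrows * grid$ncols
  smat <- matrix(vapply(scores$scores, as.vector, numeric(n)), nrow = n)
  out <- rep(NA_real_, n)
  ok <- stats::complete.cases(smat)
  if (any(ok)) {
    e <- exp(smat[ok, , drop = FALSE])
    mx <- apply(e, 1, max)
    mn <- apply(e, 1, min)
    # second best: max after masking each row's first maximum
    second <- vapply(seq_len(nrow(e)), function(i) {
      r <- e[i, ]
      r[which.max(r)] <- -Inf
      max(r)
    }, numeric(1))
    rng <- mx - mn
    d <- ifelse(rng == 0, 0, (mx - second) / rng)
    out[ok] <- d
  }
  structure(list(grid = grid,
                 values = matrix(out, grid$nrows, grid$ncols)),
            class = "dominance_grid")
}

#' Summaries of a dominance grid
#'
#' Reports the fraction of classified pixels with dominance at or above
#' 0.2, the fraction below 0.1, and a histogram on fixed bin edges
#' 0 to 1 in steps of 0.05.
#'
#' @param dom A `dominance_grid` from [dominance_from_scores()].
#' @return List with `frac_ge_0.2`, `frac_lt_0.1`, and `histogram`
#'   (named vector of counts per bin).
#' @export
summarize_dominance <- function(dom) {
  v <- dom$values[!is.na(dom$values)]
  if (!length(v)) stop("dominance grid has no classified pixels")
  edges <- seq(0, 1, by = 0.05)
  bins <- pmin(findInterval(v, edges), 20L)   # d = 1 joins the top bin
  counts <- stats::setNames(tabulate(bins, nbins = 20L),
    paste0("[", utils::head(edges, -1), ",", edges[-1], ")"))
  list(frac_ge_0.2 = mean(v >= 0.2),
       frac_lt_0.1 = mean(v < 0.1),
       histogram = counts)
}
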