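#' Standardize stack variables over land pixels
#'
#' Extracts the named layers at land pixels and converts each to a
#' z-score (mean 0, sd 1 over the land pixels used). Pixels with any
#' missing value among the requested variables are dropped from the
#' returned matrix but recorded in the index.
#'
#' @param stack A [raster_stack()].
#' @param variables Character vector of layer names (default: all).
#' @return A list with `z` (n x p matrix), `means`, `sds` (named), and
#'   `index` (linear pixel indices of the rows of `z`).
#' @export
standardize <- function(stack, variables = names(stack$layers)) {
  missing <- setdiff(variables, names(stack$layers))
  if (length(missing))
    stop("stack is missing variable(s): ", paste(missing, collapse = ", "))
  land <- which(stack$land_mask)
  raw <- vapply(variables, function(v) stack$layers[[v]][land],
                numeric(length(land)))
  ok <- stats::complete.cases(raw)
  raw <- raw[ok, , drop = FALSE]
  z <- standardize_matrix(raw)
  list(z = z$z, means = z$means, sds = z$sds, index = land[ok])
}

# column-wise z-scoring with a degenerate-column guard
standardize_matrix <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  bad <- which(!is.finite(sd) | sd <= 0)
  if (length(bad))
    stop("degenerate (constant) variable(s): ",
         paste(colnames(x)[bad], collapse = ", "))
  list(z = sweep(sweep(x, 2, mu), 2, sd, "/"), means = mu, sds = sd)
}

#' Factor-count selection by parallel analysis
#'
#' Compares the eigenvalues of the data correlation matrix against the
#' eigenvalue distribution of null datasets obtained by independently
#' permuting each column (which preserves marginals while destroying
#' inter-variable correlation). The retained count is the number of
#' leading observed eigenvalues exceeding the chosen quantile of the
#' null eigenvalue at the same rank, stopping at the first failure.
#'
#' @param z Numeric data matrix (n x p), typically standardized.
#' @param n_replicates Number of permutation replicates (default 100).
#' @param quantile Null quantile to beat (default 0.95).
#' @param seed Integer seed; fixes the permutations.
#' @return An object of class `eigen_report`: observed eigenvalues, the
#'   null quantiles, and `retained_k`.
#' @export
parallel_analysis <- function(z, n_replicates = 100, quantile = 0.95,
                              seed = 1) {
  z <- as.matrix(z)
  n <- nrow(z); p <- ncol(z)
  if (p < 2) stop("parallel analysis needs at least 2 variables")
  if (n < p) stop("parallel analysis needs n >= p")
  obs <- eigen(stats::cor(z), symmetric = TRUE, only.values = TRUE)$values
  null_eigs <- matrix(NA_real_, n_replicates, p)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  for (r in seq_len(n_replicates)) {
    perm <- apply(z, 2, sample)
    null_eigs[r, ] <- eigen(stats::cor(perm), symmetric = TRUE,
                            only.values = TRUE)$values
  }
  qs <- apply(null_eigs, 2, stats::quantile, probs = quantile, names = FALSE)
  exceeds <- obs > qs
  retained <- if (exceeds[1]) {
    runs <- rle(exceeds)
    if (runs$values[1]) runs$lengths[1] else 0L
  } else 0L
  structure(list(observed_eigenvalues = obs,
                 null_eigenvalue_quantiles = qs,
                 retained_k = as.integer(retained),
                 n_replicates = n_replicates,
                 quantile = quantile, seed = seed),
            class = "eigen_report")
}

#' @export
print.eigen_report <- function(x, ...) {
  cat(sprintf("<eigen_report> retained_k = %d (%d replicates, q = %g)\n",
              x$retained_k, x$n_replicates, x$quantile))
  cat(" observed:", paste(sprintf("%.3f", utils::head(x$observed_eigenvalues, 8)),
                          collapse = " "), "...\n")
  invisible(x)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Fit a factor model by principal-axis extraction
#'
#' Iterated principal-axis factoring: the correlation matrix with
#' squared multiple correlations as initial communalities is
#' eigendecomposed, communalities updated from the loading rows, and the
#' process repeated to convergence. The unrotated solution is then
#' rotated (varimax, or promax for an oblique solution, the default,
#' since the latent facets need not be orthogonal). Each factor is
#' oriented so that its largest-magnitude loading is positive, and
#' factors are ordered by explained variance. Regression (Thurstone)
#' score weights are computed as `W = R^-1 (Lambda Phi)`, which reduces
#' to `R^-1 Lambda` for orthogonal solutions.
#'
#' @param z Standardized data matrix (n x p), or a list as returned by
#'   [standardize()].
#' @param k Number of factors (>= 1).
#' @param rotation One of `"promax"`, `"varimax"`, `"none"`.
#' @param scoring `"regression"` (default) or `"structure"` (score
#'   weights equal to the loadings, for use with published loadings).
#' @param max_iter,tol Convergence controls for the communality
#'   iteration (defaults 200 iterations at 1e-3, the customary
#'   stopping rule for principal-axis refinement).
#' @return An object of class `factor_model`.
#' @export
fit_factors <- function(z, k, rotation = c("promax", "varimax", "none"),
                        scoring = c("regression", "structure"),
                        max_iter = 200, tol = 1e-3) {
  rotation <- match.arg(rotation)
  scoring <- match.arg(scoring)
  means <- NULL; sds <- NULL
  if (is.list(z) && !is.null(z$z)) { means <- z$means; sds <- z$sds; z <- z$z }
  z <- as.matrix(z)
  n <- nrow(z); p <- ncol(z)
  if (k < 1) stop("k must be >= 1")
  if (n <= p) stop("need more observations than variables")
  vn <- colnames(z)
  if (is.null(vn)) vn <- paste0("V", seq_len(p))
  R <- stats::cor(z)

  # initial communalities: squared multiple correlations
  Rinv <- tryCatch(solve(R), error = function(e)
    solve(R + diag(1e-8, p)))
  h2 <- 1 - 1 / diag(Rinv)
  h2 <- pmin(pmax(h2, 0.05), 0.995)
  L <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Rh <- R
    diag(Rh) <- h2
    e <- eigen(Rh, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(k)], 0)
    L <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k)
    h2_new <- pmin(rowSums(L^2), 0.9999)
    if (max(abs(h2_new - h2)) < tol) { h2 <- h2_new; converged <- TRUE; break }
    h2 <- h2_new
  }
  if (!converged)
    stop("principal-axis extraction did not converge in ", max_iter,
         " iterations")

  Phi <- diag(k)
  if (k > 1 && rotation == "varimax") {
    L <- varimax_multistart(L)
  } else if (k > 1 && rotation == "promax") {
    # promax is an oblique relaxation of the varimax solution
    r <- stats::promax(varimax_multistart(L), m = 4)
    L <- unclass(r$loadings)
    # factor correlations: Phi = (Q'Q)^-1 normalized, Q the oblique
    # part of the rotation (the varimax part is orthogonal)
    Q <- r$rotmat
    U <- solve(t(Q) %*% Q)
    d <- sqrt(diag(U))
    Phi <- U / tcrossprod(d)
    # rescale loadings consistently with unit-variance factors
    L <- L %*% diag(d, k)
  }

  # orientation: largest-magnitude loading of each factor positive
  flips <- vapply(seq_len(k), function(j) {
    sign(L[which.max(abs(L[, j])), j])
  }, numeric(1))
  flips[flips == 0] <- 1
  L <- L %*% diag(flips, k)
  Phi <- diag(flips, k) %*% Phi %*% diag(flips, k)

  # order factors by explained variance (sum of squared loadings)
  ord <- order(colSums(L^2), decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  Phi <- Phi[ord, ord, drop = FALSE]

  dimnames(L) <- list(vn, paste0("F", seq_len(k)))
  dimnames(Phi) <- list(colnames(L), colnames(L))
  W <- if (scoring == "regression") Rinv %*% L %*% Phi else L
  dimnames(W) <- dimnames(L)

  factor_model(variable_names = vn, loadings = L, factor_correlations = Phi,
               score_weights = W, means = means, sds = sds,
               extraction = "principal-axis", rotation = rotation,
               scoring = scoring)
}

# varimax from several fixed starting rotations, keeping the best by
# the varimax criterion: the identity start is a zero-gradient saddle
# for symmetric loading patterns, so single-start varimax can stall
varimax_multistart <- function(L) {
  k <- ncol(L)
  givens <- function(theta, i, j) {
    G <- diag(k)
    G[i, i] <- cos(theta); G[j, j] <- cos(theta)
    G[i, j] <- -sin(theta); G[j, i] <- sin(theta)
    G
  }
  starts <- list(diag(k))
  for (theta in pi * seq(1 / 16, 7 / 16, length.out = 7)) {
    S <- diag(k)
    for (i in seq_len(k - 1)) S <- S %*% givens(theta, i, i + 1)
    starts[[length(starts) + 1L]] <- S
  }
  crit <- function(A) {
    # Kaiser-normalized varimax criterion
    h <- sqrt(rowSums(A^2)); h[h == 0] <- 1
    B <- (A / h)^2
    sum(apply(B, 2, stats::var))
  }
  best <- NULL; best_c <- -Inf
  for (S in starts) {
    r <- tryCatch(stats::varimax(L %*% S, eps = 1e-8),
                  error = function(e) NULL)
    if (is.null(r)) next
    A <- unclass(r$loadings)
    cc <- crit(A)
    if (cc > best_c) { best_c <- cc; best <- A }
  }
  if (is.null(best)) stop("varimax rotation failed")
  # polish: re-run from the incumbent until the criterion stops moving
  for (i in 1:5) {
    r <- tryCatch(stats::varimax(best, eps = 1e-8),
                  error = function(e) NULL)
    if (is.null(r)) break
    A <- unclass(r$loadings)
    cc <- crit(A)
    if (cc <= best_c + 1e-10) break
    best <- A; best_c <- cc
  }
  best
}

#' Construct a factor model
#'
#' @param variable_names Character vector of the p input variables.
#' @param loadings p x k loading matrix.
#' @param factor_correlations k x k factor correlation matrix (identity
#'   for orthogonal solutions).
#' @param score_weights p x k score-weight matrix; defaults to the
#'   loadings (structure weighting).
#' @param means,sds Optional named standardization constants.
#' @param extraction,rotation,scoring Method tags.
#' @return An object of class `factor_model`.
#' @export
factor_model <- function(variable_names, loadings, factor_correlations = NULL,
                         score_weights = NULL, means = NULL, sds = NULL,
                         extraction = "given", rotation = "given",
                         scoring = "structure") {
  L <- as.matrix(loadings)
  p <- nrow(L); k <- ncol(L)
  if (length(variable_names) != p)
    stop("variable_names length does not match loadings")
  if (is.null(factor_correlations)) factor_correlations <- diag(k)
  Phi <- as.matrix(factor_correlations)
  # orthogonal loadings are correlations, bounded near 1; oblique
  # pattern coefficients are regression weights and may exceed 1
  oblique <- k > 1 && max(abs(Phi - diag(k))) > 1e-8
  if (max(abs(L)) > (if (oblique) 1.5 else 1.05))
    stop("implausible loadings (|loading| > ",
         if (oblique) 1.5 else 1.05, ")")
  if (!isTRUE(all.equal(Phi, t(Phi), tolerance = 1e-8)))
    stop("factor correlation matrix must be symmetric")
  if (min(eigen(Phi, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("factor correlation matrix must be positive definite")
  if (is.null(score_weights)) score_weights <- L
  W <- as.matrix(score_weights)
  if (!identical(dim(W), dim(L))) stop("score_weights must be p x k")
  if (!is.null(sds) && any(sds <= 0)) stop("sds must be positive")
  rownames(L) <- variable_names
  if (is.null(colnames(L))) colnames(L) <- paste0("F", seq_len(k))
  dimnames(W) <- dimnames(L)
  structure(list(variable_names = variable_names, k = k, loadings = L,
                 factor_correlations = Phi, score_weights = W,
                 means = means, sds = sds,
                 extraction = extraction, rotation = rotation,
                 scoring = scoring),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> %d variables, %d factors (%s, %s, %s scores)\n",
              length(x$variable_names), x$k, x$extraction, x$rotation,
              x$scoring))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Serialize a factor model to a CSV pair
#'
#' Writes `<path>` with the loading table (variable, then one column per
#' factor) and `<path base>_meta.csv` with standardization constants and
#' method tags, so published loading tables can be stored and reloaded
#' verbatim for scoring.
#'
#' @param model A [factor_model()].
#' @param path CSV path for the loadings table.
#' @export
write_factor_model <- function(model, path) {
  ld <- data.frame(variable = model$variable_names,
                   model$loadings, check.names = FALSE)
  write_table(ld, path)
  meta <- data.frame(
    variable = model$variable_names,
    mean = if (is.null(model$means)) NA_real_ else as.numeric(model$means),
    sd = if (is.null(model$sds)) NA_real_ else as.numeric(model$sds),
    extraction = model$extraction, rotation = model$rotation,
    scoring = model$scoring)
  write_table(meta, sub("\\.csv$", "_meta.csv", path))
  invisible(path)
}

#' @rdname write_factor_model
#' @param scoring Scoring mode to attach on load, default `"structure"`
#'   (published tables print loadings, not score weights).
#' @export
read_factor_model <- function(path, scoring = "structure") {
  ld <- read_table(path)
  vn <- ld$variable
  L <- as.matrix(ld[, setdiff(names(ld), "variable"), drop = FALSE])
  rownames(L) <- vn
  meta_path <- sub("\\.csv$", "_meta.csv", path)
  means <- NULL; sds <- NULL
  if (file.exists(meta_path)) {
    meta <- read_table(meta_path)
    if (!all(is.na(meta$mean))) means <- stats::setNames(meta$mean, meta$variable)
    if (!all(is.na(meta$sd))) sds <- stats::setNames(meta$sd, meta$variable)
  }
  factor_model(vn, L, means = means, sds = sds, scoring = scoring)
}

#' Score a z-matrix with a factor model
#'
#' @param model A [factor_model()].
#' @param z n x p matrix of standardized values, columns matching the
#'   model's variables (matched by name when named).
#' @return n x k matrix of factor scores `s = z W`.
#' @export
score_z <- function(model, z) {
  z <- as.matrix(z)
  if (!is.null(colnames(z))) {
    missing <- setdiff(model$variable_names, colnames(z))
    if (length(missing))
      stop("missing variable(s): ", paste(missing, collapse = ", "))
    z <- z[, model$variable_names, drop = FALSE]
  } else if (ncol(z) != length(model$variable_names))
    stop("z has ", ncol(z), " columns; model expects ",
         length(model$variable_names))
  z %*% model$score_weights
}

#' Compute per-pixel facet scores for a raster stack
#'
#' Standardizes each model variable with the model's stored means/sds
#' (or the stack's own land-pixel statistics when the model carries
#' none) and applies the score weights. Pixels off the land mask or with
#' any missing variable get nodata scores.
#'
#' @param model A [factor_model()].
#' @param stack A [raster_stack()] containing all model variables.
#' @return An object of class `score_stack`: list with `grid` and
#'   `scores`, a named list of k score matrices.
#' @export
compute_scores <- function(model, stack) {
  missing <- setdiff(model$variable_names, names(stack$layers))
  if (length(missing))
    stop("stack is missing variable(s): ", paste(missing, collapse = ", "))
  land <- which(stack$land_mask)
  raw <- vapply(model$variable_names, function(v) stack$layers[[v]][land],
                numeric(length(land)))
  ok <- stats::complete.cases(raw)
  if (is.null(model$means) || is.null(model$sds)) {
    zz <- standardize_matrix(raw[ok, , drop = FALSE])
    z <- zz$z
  } else {
    mu <- model$means[model$variable_names]
    sd <- model$sds[model$variable_names]
    z <- sweep(sweep(raw[ok, , drop = FALSE], 2, mu), 2, sd, "/")
  }
  s <- score_z(model, z)
  grid <- stack$grid
  mats <- lapply(seq_len(model$k), function(j) {
    m <- matrix(NA_real_, grid$nrows, grid$ncols)
    m[land[ok]] <- s[, j]
    m
  })
  names(mats) <- colnames(model$loadings)
  structure(list(grid = grid, scores = mats), class = "score_stack")
}

#' @export
print.score_stack <- function(x, ...) {
  cat(sprintf("<score_stack> %d facet score layers on %d x %d grid\n",
              length(x$scores), x$grid$nrows, x$grid$ncols))
  invisible(x)
}
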