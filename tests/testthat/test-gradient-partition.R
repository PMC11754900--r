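test_that("standardization centers, scales, and flags degenerate input", {
  g <- grid_spec(1, 3)
  st <- raster_stack(g, list(a = matrix(c(1, 2, 3), 1),
                             b = matrix(c(5, 5, 5), 1)))
  out <- standardize(st, "a")
  expect_equal(mean(out$z[, "a"]), 0)
  expect_equal(sd(out$z[, "a"]), 1)
  expect_error(standardize(st, c("a", "b")), "\\bb\\b")
  expect_error(standardize(st, "missing"), "missing")
  # idempotence: standardizing z-scores changes nothing
  st2 <- raster_stack(g, list(a = matrix(out$z[, "a"], 1)))
  expect_equal(standardize(st2, "a")$z, out$z)
})

test_that("parallel analysis retains planted factors and rejects noise", {
  retained <- vapply(1:10, function(s) {
    set.seed(s + 1000)
    n <- 2000; p <- 25; k <- 3
    L <- matrix(0, p, k)
    for (j in 1:k) L[((j - 1) * 8 + 1):min(j * 8 + 1, p), j] <- 0.7
    X <- matrix(rnorm(n * k), n, k) %*% t(L) +
      matrix(rnorm(n * p, sd = sqrt(1 - 0.49)), n, p)
    parallel_analysis(X, 100, 0.95, seed = s)$retained_k
  }, integer(1))
  expect_gte(sum(retained == 3L), 9)

  null_retained <- vapply(1:10, function(s) {
    set.seed(s + 2000)
    parallel_analysis(matrix(rnorm(2000 * 10), 2000, 10),
                      100, 0.95, seed = s)$retained_k
  }, integer(1))
  expect_gte(sum(null_retained == 0L), 8)

  expect_error(parallel_analysis(matrix(rnorm(10), 10, 1)), "2 variables")
})

test_that("doubling the replicate count does not change the retention", {
  set.seed(1001)
  n <- 2000; p <- 25; k <- 3
  L <- matrix(0, p, k)
  for (j in 1:k) L[((j - 1) * 8 + 1):min(j * 8 + 1, p), j] <- 0.7
  X <- matrix(rnorm(n * k), n, k) %*% t(L) +
    matrix(rnorm(n * p, sd = sqrt(1 - 0.49)), n, p)
  k100 <- parallel_analysis(X, 100, 0.95, seed = 1)$retained_k
  k200 <- parallel_analysis(X, 200, 0.95, seed = 1)$retained_k
  expect_identical(k100, k200)
})

test_that("factor extraction recovers planted loadings", {
  set.seed(5)
  n <- 10000; p <- 8
  L_true <- cbind(c(.9, .8, .85, .75, 0, 0, 0, 0),
                  c(0, 0, 0, 0, .9, .8, .85, .75))
  Fm <- qr.Q(qr(matrix(rnorm(n * 2), n, 2))) * sqrt(n - 1)  # exactly orthogonal
  X <- Fm %*% t(L_true) +
    sweep(matrix(rnorm(n * p), n, p), 2, sqrt(1 - rowSums(L_true^2)), "*")
  m <- fit_factors(scale(X), 2, rotation = "varimax")
  # align columns to the plant by absolute correlation
  perm <- apply(abs(cor(m$loadings, L_true)), 2, which.max)
  expect_equal(unname(m$loadings[, perm]), L_true, tolerance = 0.05)

  # independent cross-check against maximum-likelihood extraction:
  # the reduced covariance Lambda Lambda' is rotation-invariant, so it
  # compares the fitted factor spaces without tying the two rotations
  fa <- stats::factanal(covmat = cor(X), factors = 2, rotation = "none")
  La <- unclass(fa$loadings)
  expect_equal(La %*% t(La), m$loadings %*% t(m$loadings),
               tolerance = 0.05, ignore_attr = TRUE)
})

test_that("rank-1 structure yields a single proportional factor", {
  set.seed(6)
  v <- c(.9, .7, .8, .6, .85)
  X <- rnorm(3000) %*% t(v) +
    sweep(matrix(rnorm(3000 * 5), 3000, 5), 2, sqrt(1 - v^2), "*")
  m <- fit_factors(scale(X), 1)
  r <- m$loadings[, 1] / v
  expect_lt(max(abs(r - mean(r))), 0.05)
})

test_that("the oblique model reconstructs the correlation matrix", {
  set.seed(7)
  n <- 4000
  Phi <- matrix(c(1, .4, .4, 1), 2)
  Fm <- matrix(rnorm(n * 2), n, 2) %*% chol(Phi)
  L <- cbind(c(.8, .7, .75, .65, 0, 0, 0, 0),
             c(0, 0, 0, 0, .8, .7, .75, .65))
  X <- Fm %*% t(L) + matrix(rnorm(n * 8, sd = .5), n, 8)
  m <- fit_factors(scale(X), 2, rotation = "promax")
  R <- cor(X)
  recon <- m$loadings %*% m$factor_correlations %*% t(m$loadings)
  Rhat <- recon + diag(diag(R) - diag(recon))
  expect_lt(max(abs(Rhat - R)), 0.05)
  expect_gt(m$factor_correlations[1, 2], 0.2)   # obliqueness recovered
})

test_that("non-convergence is reported with the iteration count", {
  set.seed(8)
  X <- matrix(rnorm(400), 100, 4)
  expect_error(fit_factors(X, 2, max_iter = 1, tol = 1e-12), "1 iteration")
})

test_that("published loadings drive structure-weight scoring", {
  model <- read_factor_model(ref_loadings_path())
  expect_equal(model$k, 5)
  expect_equal(model$scoring, "structure")
  # +2 SD on total precipitation only: twice its loading row
  z <- matrix(0, 1, 10, dimnames = list(NULL, model$variable_names))
  z[, "totPrecip"] <- 2
  s <- score_z(model, z)
  expect_equal(as.vector(s), 2 * c(0.071, 0.947, 0.101, 0.140, 0.253))
  expect_equal(which.max(s), 2L)   # E2
  # +2 SD on elevation only: best score is E4 (2 * 0.138 = 0.276)
  z2 <- matrix(0, 1, 10, dimnames = list(NULL, model$variable_names))
  z2[, "elevation"] <- 2
  s2 <- score_z(model, z2)
  expect_equal(which.max(s2), 4L)
  expect_equal(s2[4], 0.276)
  expect_error(score_z(model, z[, 1:9, drop = FALSE]), "missing")
})

test_that("zero z-scores produce zero scores and nodata propagates", {
  model <- read_factor_model(ref_loadings_path())
  g <- grid_spec(2, 2)
  layers <- lapply(model$variable_names, function(v) matrix(0, 2, 2))
  names(layers) <- model$variable_names
  layers[[1]][2, 2] <- NA
  model$means <- stats::setNames(rep(0, 10), model$variable_names)
  model$sds <- stats::setNames(rep(1, 10), model$variable_names)
  sc <- compute_scores(model, raster_stack(g, layers))
  expect_equal(sc$scores[[1]][1, 1], 0)
  expect_true(is.na(sc$scores[[1]][2, 2]))   # missing variable -> nodata
})

test_that("factor model serialization round-trips", {
  dir <- withr::local_tempdir()
  set.seed(9)
  X <- matrix(rnorm(2000 * 6), 2000, 6) %*%
    matrix(rnorm(36, sd = .5), 6, 6)
  colnames(X) <- letters[1:6]
  st <- list(z = scale(X), means = colMeans(X), sds = apply(X, 2, sd))
  m <- fit_factors(st, 2, rotation = "varimax")
  p <- file.path(dir, "model.csv")
  write_factor_model(m, p)
  back <- read_factor_model(p)
  expect_equal(unclass(back$loadings), unclass(m$loadings),
               tolerance = 1e-10)
  expect_equal(back$means, m$means)
})

test_that("max-score classification is deterministic with tie-breaks", {
  g <- grid_spec(1, 2)
  sc <- structure(list(grid = g, scores = list(
    F1 = matrix(c(1, 0), 1), F2 = matrix(c(0, 1), 1))),
    class = "score_stack")
  lab <- classify_max_score(sc)
  expect_equal(as.vector(lab$codes), c(1L, 2L))
  # exact tie: lowest facet index wins
  tied <- structure(list(grid = grid_spec(1, 1), scores = list(
    F1 = matrix(0.7), F2 = matrix(0.7))), class = "score_stack")
  expect_equal(as.vector(classify_max_score(tied)$codes), 1L)

  set.seed(12)
  smat <- matrix(rnorm(1000 * 5), 1000, 5)
  smat[sample(5000, 40)] <- rep(smat[1, 1], 40)  # force some ties
  sc2 <- structure(list(grid = grid_spec(1000, 1),
                        scores = lapply(1:5, function(j)
                          matrix(smat[, j], 1000, 1))),
                   class = "score_stack")
  expect_equal(as.vector(classify_max_score(sc2)$codes),
               oracle_max_col(smat))
})

test_that("dominance index matches its published worked examples", {
  expect_equal(dominance_index(c(1, 2, 3, 4, 5, 6)), 0.2)
  expect_equal(round(dominance_index(c(1, 2, 4, 8, 16)), 2), 0.53)
  expect_equal(dominance_index(c(3, 3, 3)), 0)
  expect_error(dominance_index(5), "at least 2")
  # scale invariance and bounds on random inputs
  set.seed(13)
  for (rep in 1:200) {
    fits <- runif(sample(2:8, 1), 0, 10)
    d <- dominance_index(fits)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(dominance_index(fits * runif(1, .1, 50)), d)
  }
})

test_that("per-pixel dominance exponentiates scores first", {
  g <- grid_spec(1, 2)
  sc <- structure(list(grid = g, scores = list(
    F1 = matrix(c(0, 1), 1), F2 = matrix(c(log(2), 1), 1),
    F3 = matrix(c(log(4), 1), 1), F4 = matrix(c(log(8), 1), 1),
    F5 = matrix(c(log(16), 1), 1))), class = "score_stack")
  d <- dominance_from_scores(sc)
  expect_equal(d$values[1, 1], 8 / 15, tolerance = 1e-12) # the 0.53 case
  expect_equal(d$values[1, 2], 0)                         # all equal
  set.seed(14)
  smat <- matrix(rnorm(1e4 * 4), 1e4, 4)
  sc2 <- structure(list(grid = grid_spec(1e4, 1),
                        scores = lapply(1:4, function(j)
                          matrix(smat[, j], 1e4, 1))),
                   class = "score_stack")
  dv <- dominance_from_scores(sc2)$values
  expect_true(all(dv >= 0 & dv <= 1))
})

test_that("dominance summaries match a direct counting oracle", {
  g <- grid_spec(10, 10)
  d <- structure(list(grid = g, values = matrix(0.5, 10, 10)),
                 class = "dominance_grid")
  s <- summarize_dominance(d)
  expect_equal(s$frac_ge_0.2, 1); expect_equal(s$frac_lt_0.1, 0)
  half <- matrix(c(rep(0.05, 50), rep(0.25, 50)), 10, 10)
  s2 <- summarize_dominance(structure(list(grid = g, values = half),
                                      class = "dominance_grid"))
  expect_equal(s2$frac_ge_0.2, 0.5); expect_equal(s2$frac_lt_0.1, 0.5)
  set.seed(15)
  v <- matrix(runif(100), 10, 10); v[1:5] <- NA
  s3 <- summarize_dominance(structure(list(grid = g, values = v),
                                      class = "dominance_grid"))
  vv <- v[!is.na(v)]
  expect_equal(s3$frac_ge_0.2, mean(vv >= 0.2))
  expect_equal(s3$frac_lt_0.1, mean(vv < 0.1))
  expect_equal(sum(s3$histogram), length(vv))
})

test_that("classification is equivariant under facet permutation", {
  set.seed(16)
  smat <- matrix(rnorm(500 * 4), 500, 4)
  mk <- function(m) structure(
    list(grid = grid_spec(500, 1),
         scores = lapply(seq_len(ncol(m)), function(j)
           matrix(m[, j], 500, 1))), class = "score_stack")
  base <- classify_max_score(mk(smat))$codes
  perm <- c(3, 1, 4, 2)
  permuted <- classify_max_score(mk(smat[, perm]))$codes
  expect_equal(perm[permuted], as.vector(base))
})
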