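# Independent brute-force oracles used to cross-check the package's
# grid operations on randomized instances.

# breadth-first-search flood fill, label order = scan order
oracle_components_bfs <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  off <- if (connectivity == 4)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in seq_len(nrow(off))) {
        ii <- p[1] + off[d, 1]; jj <- p[2] + off[d, 2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- nxt
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# exhaustive neighbourhood scan for adjacency fractions
oracle_adjacency <- function(codes, unit, connectivity = 8) {
  nr <- nrow(codes); nc <- ncol(codes)
  off <- if (connectivity == 4)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  cells <- which(codes == unit, arr.ind = TRUE)
  counts <- list()
  for (r in seq_len(nrow(cells))) {
    seen <- integer(0)
    for (d in seq_len(nrow(off))) {
      ii <- cells[r, 1] + off[d, 1]; jj <- cells[r, 2] + off[d, 2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
        v <- codes[ii, jj]
        if (v > 0 && v != unit) seen <- union(seen, v)
      }
    }
    for (v in seen) {
      key <- as.character(v)
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  out <- vapply(counts, function(x) x / nrow(cells), numeric(1))
  out[order(as.integer(names(out)))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-row exhaustive argmax with first-wins tie-break
oracle_max_col <- function(m) {
  apply(m, 1, function(r) {
    best <- 1L
    for (j in seq_along(r)) if (r[j] > r[best]) best <- j
    best
  })
}

# exhaustive nearest-donor search replicating the nibble contract
oracle_nibble <- function(labels, tier1, land, connectivity = 8) {
  nr <- nrow(labels)
  patches <- oracle_components_bfs(land, connectivity)
  out <- labels
  for (j in seq_len(ncol(labels))) for (i in seq_len(nr)) {
    if (!land[i, j] || labels[i, j] != 0L || tier1[i, j] == 0L) next
    best <- NULL; bestd <- Inf
    for (jj in seq_len(ncol(labels))) for (ii in seq_len(nr)) {
      if (labels[ii, jj] == 0L) next
      if (tier1[ii, jj] != tier1[i, j]) next
      if (patches[ii, jj] != patches[i, j]) next
      d <- (ii - i)^2 + (jj - j)^2
      rm_order <- (ii - 1) * ncol(labels) + jj
      if (d < bestd ||
          (d == bestd && rm_order < best$rm)) {
        bestd <- d
        best <- list(lab = labels[ii, jj], rm = rm_order)
      }
    }
    if (!is.null(best)) out[i, j] <- best$lab
  }
  out
}

# even-odd point-in-polygon test for one ring (vectorized over points)
points_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  xj <- ring[n, 1]; yj <- ring[n, 2]
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    xj <- xi; yj <- yi
  }
  inside
}

# dense-subsampling coverage oracle for one pixel
oracle_pixel_coverage <- function(polys, x0, x1, y0, y1, sub = 60) {
  gx <- seq(x0, x1, length.out = sub + 1)[-1] - (x1 - x0) / (2 * sub)
  gy <- seq(y0, y1, length.out = sub + 1)[-1] - (y1 - y0) / (2 * sub)
  pts <- expand.grid(x = gx, y = gy)
  inside <- rep(FALSE, nrow(pts))
  for (f in polys$features) {
    fin <- points_in_ring(pts$x, pts$y, f$rings[[1]])
    if (length(f$rings) > 1)
      for (h in f$rings[-1])
        fin <- fin & !points_in_ring(pts$x, pts$y, h)
    inside <- inside | fin
  }
  mean(inside)
}

# random convex polygon (convex hull of random points)
random_convex_poly <- function(xr, yr, n = 8) {
  x <- runif(n, xr[1], xr[2]); y <- runif(n, yr[1], yr[2])
  h <- chull(x, y)
  cbind(x[h], y[h])
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
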