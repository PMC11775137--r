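# Independent oracles used across test files. Each deliberately takes a
# different computational route than the implementation it checks.

# OLS via the normal equations, solved directly.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% beta
  list(coef = as.vector(beta), sigma = sqrt(sum(res^2) / (length(y) - 2)))
}

# Logistic MLE by coarse-to-fine grid search over (intercept, slope). The
# log-likelihood is concave, so zooming on the grid maximum is safe.
oracle_logistic_grid <- function(y, x, r0 = 25, levels = 7, n_grid = 41) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
  }
  c0 <- 0; c1 <- 0; r <- r0
  for (lev in seq_len(levels)) {
    g0 <- seq(c0 - r, c0 + r, length.out = n_grid)
    g1 <- seq(c1 - r, c1 + r, length.out = n_grid)
    vals <- outer(g0, g1, Vectorize(ll))
    best <- arrayInd(which.max(vals), dim(vals))
    c0 <- g0[best[1]]; c1 <- g1[best[2]]
    r <- 2 * (g0[2] - g0[1])
  }
  c(intercept = c0, slope = c1)
}

# EOO oracle: rasterize the closed convex hull (interior at 1 km pitch, the
# boundary -- a 1-D feature -- at 1 m pitch) and collect the cells holding
# at least one raster point. Point-in-polygon comes from mgcv, not from the
# package's own predicates.
oracle_eoo_cells <- function(occupied, grid, projected) {
  idx <- match(occupied, projected$lake_id)
  x <- projected$x[idx]; y <- projected$y[idx]
  key <- function(px, py) {
    ix <- pmax(1L, as.integer(ceiling((px - grid$origin[["x"]]) / grid$side)))
    iy <- pmax(1L, as.integer(ceiling((py - grid$origin[["y"]]) / grid$side)))
    unique(paste(ix, iy, sep = ":"))
  }
  if (length(x) == 1) return(key(x, y))
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  dense_edges <- function(px, py) {
    n <- length(px)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      len <- sqrt((px[j] - px[i])^2 + (py[j] - py[i])^2)
      t <- seq(0, 1, length.out = max(2L, ceiling(len) + 1L))  # ~1 m pitch
      out[[i]] <- cbind(px[i] + t * (px[j] - px[i]),
                        py[i] + t * (py[j] - py[i]))
    }
    do.call(rbind, out)
  }
  if (length(hx) < 3) {  # collinear: the hull is a segment between extremes
    d <- as.matrix(dist(cbind(x, y)))
    ext <- arrayInd(which.max(d), dim(d))
    e <- dense_edges(c(x[ext[1]], x[ext[2]]), c(y[ext[1]], y[ext[2]]))
    return(key(e[, 1], e[, 2]))
  }
  gx <- seq(min(hx), max(hx), by = 1000)
  gy <- seq(min(hy), max(hy), by = 1000)
  pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  inside <- mgcv::in.out(cbind(c(hx, hx[1]), c(hy, hy[1])), pts)
  interior <- pts[inside, , drop = FALSE]
  e <- dense_edges(hx, hy)
  key(c(interior[, 1], e[, 1]), c(interior[, 2], e[, 2]))
}

# Two-site Jaccard turnover by direct set arithmetic.
oracle_two_site_turnover <- function(taxa1, taxa2) {
  a <- length(intersect(taxa1, taxa2))
  b12 <- length(setdiff(taxa1, taxa2))
  b21 <- length(setdiff(taxa2, taxa1))
  if (min(b12, b21) == 0 && a + b12 + b21 == 0) return(0)
  den <- a + 2 * min(b12, b21)
  if (den == 0) 0 else 2 * min(b12, b21) / den
}

# Newman-Girvan modularity from the adjacency matrix, straight from the
# definition: Q = sum_c [ e_c / m - (d_c / 2m)^2 ].
oracle_modularity <- function(adj, membership) {
  m <- sum(adj) / 2
  q <- 0
  for (cm in unique(membership)) {
    v <- membership == cm
    e_c <- sum(adj[v, v, drop = FALSE]) / 2
    d_c <- sum(adj[v, , drop = FALSE])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# Exhaustive maximum-modularity search over all set partitions, generated as
# restricted growth strings by an iterative successor rule.
oracle_best_partition <- function(adj) {
  n <- nrow(adj)
  a <- rep(1L, n)
  best_q <- -Inf; best <- a
  repeat {
    q <- oracle_modularity(adj, a)
    if (q > best_q) { best_q <- q; best <- a }
    # successor of restricted growth string
    i <- n
    while (i > 1) {
      maxprev <- max(a[seq_len(i - 1L)])
      if (a[i] <= maxprev) break
      i <- i - 1L
    }
    if (i == 1) break
    a[i] <- a[i] + 1L
    if (i < n) a[(i + 1L):n] <- 1L
  }
  list(modularity = best_q, membership = best)
}

# Benjamini-Hochberg step-up, written out directly.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
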