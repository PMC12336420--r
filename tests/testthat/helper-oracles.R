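# Independent oracles and small fixtures used across the suite.

# Effective resistance by dense Laplacian pseudoinverse, built by an
# explicit double loop (independent of the package's graph/Laplacian code).
# `groups` optionally maps node -> supernode id before solving.
oracle_resistance <- function(edges, a, b, n, groups = NULL) {
  if (is.null(groups)) groups <- seq_len(n)
  ids <- sort(unique(groups))
  relabel <- match(groups, ids)
  m <- length(ids)
  L <- matrix(0, m, m)
  for (i in seq_len(nrow(edges))) {
    u <- relabel[edges$from[i]]
    v <- relabel[edges$to[i]]
    w <- edges$conductance[i]
    if (u == v) next
    L[u, v] <- L[u, v] - w
    L[v, u] <- L[v, u] - w
    L[u, u] <- L[u, u] + w
    L[v, v] <- L[v, v] + w
  }
  Lp <- MASS::ginv(L)
  d <- numeric(m)
  d[relabel[a]] <- 1
  d[relabel[b]] <- -1
  drop(t(d) %*% Lp %*% d)
}

# random connected weighted graph: a random spanning tree plus extra edges
random_connected_graph <- function(n, extra = n, seed = 1) {
  set.seed(seed)
  from <- integer(0); to <- integer(0)
  for (i in 2:n) {
    from <- c(from, i)
    to <- c(to, sample.int(i - 1, 1))
  }
  if (extra > 0) {
    f2 <- sample.int(n, extra, replace = TRUE)
    t2 <- sample.int(n, extra, replace = TRUE)
    keep <- f2 != t2
    from <- c(from, f2[keep]); to <- c(to, t2[keep])
  }
  edges <- tibble::tibble(from = from, to = to,
                          conductance = runif(length(from), 0.2, 2))
  list(nodes = tibble::tibble(node = seq_len(n)), edges = edges)
}

random_conductance_raster <- function(nr, nc, seed = 1, cellsize = 100,
                                      p_zero = 0) {
  set.seed(seed)
  v <- matrix(runif(nr * nc, 0.05, 1), nr, nc)
  if (p_zero > 0) v[runif(nr * nc) < p_zero] <- 0
  scape_raster(v, cellsize = cellsize)
}

# minimal detection tibble builder
det_tbl <- function(recorder, site, syllable, count = 1L) {
  tibble::tibble(recorder = recorder, site = site, syllable = syllable,
                 count = as.integer(count))
}

tiny_config <- function(seed = 1, ...) {
  scenario_config(seed = seed, grid = c(20L, 20L), cellsize = 1000,
                  n_sites = 3L, n_syllables = 60L, site_radius = 2000,
                  ...)
}

# random symmetric finite resistance-like matrix with zero diagonal
random_resistance <- function(n, seed = 1, lo = 0.2, hi = 3) {
  set.seed(seed)
  pts <- matrix(runif(n * 3), n, 3)       # points in a cube -> metric
  r <- as.matrix(dist(pts)) / sqrt(3) * (hi - lo) + lo
  diag(r) <- 0
  dimnames(r) <- list(paste0("site_", 1:n), paste0("site_", 1:n))
  r
}
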