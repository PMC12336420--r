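#' Convert a conductance raster to a resistor network
#'
#' Every cell with positive, defined conductance becomes a node. Orthogonal
#' neighbors are joined by an edge whose conductance is the mean of the two
#' cell conductances; with the 8-neighborhood, diagonal neighbors are joined
#' with that mean divided by sqrt(2), reflecting the longer center-to-center
#' span. Cells with zero or nodata conductance carry no current.
#'
#' @param conductance A conductance [scape_raster()] (values in `[0, 1]`).
#' @param neighborhood 4 (rook) or 8 (queen; default, the convention of the
#'   circuit-theory tools this solver mirrors).
#' @return An object of class `resistance_graph`: node table (`node`, `row`,
#'   `col`), edge table (`from`, `to`, `conductance`) and the cell-to-node
#'   index matrix.
#' @export
raster_to_graph <- function(conductance, neighborhood = 8) {
  stopifnot(inherits(conductance, "scape_raster"))
  if (!neighborhood %in% c(4, 8)) {
    stop("`neighborhood` must be 4 or 8", call. = FALSE)
  }
  v <- conductance$values
  live <- which(!is.na(v) & v > 0, arr.ind = TRUE)
  if (nrow(live) == 0) {
    stop("conductance raster has no cell with positive conductance",
         call. = FALSE)
  }
  node_of <- matrix(NA_integer_, nrow(v), ncol(v))
  node_of[live] <- seq_len(nrow(live))
  offsets <- list(c(0L, 1L), c(1L, 0L))
  if (neighborhood == 8) offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  edges <- purrr::map_dfr(offsets, function(off) {
    r2 <- live[, 1] + off[1]; c2 <- live[, 2] + off[2]
    ok <- r2 >= 1 & r2 <= nrow(v) & c2 >= 1 & c2 <= ncol(v)
    ok[ok] <- !is.na(node_of[cbind(r2[ok], c2[ok])])
    if (!any(ok)) return(NULL)
    g <- (v[live[ok, , drop = FALSE]] + v[cbind(r2[ok], c2[ok])]) / 2
    if (all(off != 0)) g <- g / sqrt(2)
    tibble::tibble(from = node_of[live[ok, , drop = FALSE]],
                   to = node_of[cbind(r2[ok], c2[ok])],
                   conductance = g)
  })
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble::tibble(from = integer(), to = integer(),
                            conductance = numeric())
  }
  structure(
    list(nodes = tibble::tibble(node = seq_len(nrow(live)),
                                row = live[, 1], col = live[, 2]),
         edges = edges, node_of = node_of,
         raster = conductance, neighborhood = neighborhood),
    class = "resistance_graph"
  )
}

#' @export
print.resistance_graph <- function(x, ...) {
  cat(sprintf("<resistance_graph> %d nodes, %d edges (%d-neighborhood)\n",
              nrow(x$nodes), nrow(x$edges), x$neighborhood))
  invisible(x)
}

# build the (contracted) weighted Laplacian: `group` maps each node to a
# supernode id; returns sparse symmetric Laplacian over supernodes
contracted_laplacian <- function(edges, group, n_groups) {
  gf <- group[edges$from]; gt <- group[edges$to]
  keep <- gf != gt                      # edges inside a supernode vanish
  gf <- gf[keep]; gt <- gt[keep]; w <- edges$conductance[keep]
  A <- Matrix::sparseMatrix(i = c(gf, gt), j = c(gt, gf), x = c(w, w),
                            dims = c(n_groups, n_groups))
  Matrix::Diagonal(x = Matrix::rowSums(A)) - A
}

#' Effective resistance between two node sets
#'
#' Collapses each focal region to a single supernode (zero internal
#' resistance), injects unit current into region A and withdraws it at
#' region B, solves the reduced Laplacian system, and returns the potential
#' difference — the effective (all-paths) resistance of the network between
#' the two regions. Returns `Inf` with a warning when the regions lie in
#' different connected components.
#'
#' @param graph A [raster_to_graph()] result, or any list with an `edges`
#'   tibble (`from`, `to`, `conductance`) and a `nodes` table.
#' @param region_a,region_b Disjoint, non-empty integer vectors of node ids.
#' @return Effective resistance (dimensionless conductance^-1).
#' @export
effective_resistance <- function(graph, region_a, region_b) {
  region_a <- unique(as.integer(region_a))
  region_b <- unique(as.integer(region_b))
  if (length(region_a) == 0 || length(region_b) == 0) {
    stop("both regions must be non-empty", call. = FALSE)
  }
  if (length(intersect(region_a, region_b)) > 0) {
    stop("regions must be disjoint", call. = FALSE)
  }
  n <- nrow(graph$nodes)
  stopifnot(all(c(region_a, region_b) >= 1), all(c(region_a, region_b) <= n))
  group <- rep(NA_integer_, n)
  group[region_a] <- 1L
  group[region_b] <- 2L
  free <- which(is.na(group))
  group[free] <- seq_along(free) + 2L
  ng <- length(free) + 2L
  L <- contracted_laplacian(graph$edges, group, ng)
  # connectivity check on the contracted graph
  gr <- igraph::graph_from_edgelist(
    cbind(group[graph$edges$from], group[graph$edges$to]), directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0, ng - igraph::vcount(gr)))
  comp <- igraph::components(gr)$membership
  if (comp[1] != comp[2]) {
    warning("regions are in different connected components; resistance is Inf",
            call. = FALSE)
    return(Inf)
  }
  # ground supernode B (id 2): solve L[-2,-2] v = e_A; R = v[A]
  keep <- setdiff(seq_len(ng), 2L)
  same <- which(comp[keep] == comp[1])   # restrict to B's component
  keep <- keep[same]
  rhs <- numeric(length(keep))
  rhs[match(1L, keep)] <- 1
  sol <- Matrix::solve(L[keep, keep, drop = FALSE], rhs)
  as.numeric(sol[match(1L, keep)])
}

#' Dense pseudoinverse effective resistance (reference route)
#'
#' Computes `R = (e_A - e_B)' L^+ (e_A - e_B)` on the contracted Laplacian
#' via eigendecomposition. Exact but dense; intended for small networks and
#' as an independent check of [effective_resistance()].
#'
#' @inheritParams effective_resistance
#' @return Effective resistance.
#' @export
effective_resistance_pinv <- function(graph, region_a, region_b) {
  region_a <- unique(as.integer(region_a))
  region_b <- unique(as.integer(region_b))
  n <- nrow(graph$nodes)
  group <- rep(NA_integer_, n)
  group[region_a] <- 1L
  group[region_b] <- 2L
  free <- which(is.na(group))
  group[free] <- seq_along(free) + 2L
  ng <- length(free) + 2L
  L <- as.matrix(contracted_laplacian(graph$edges, group, ng))
  e <- eigen(L, symmetric = TRUE)
  pos <- e$values > max(e$values, 1) * 1e-12
  Lp <- e$vectors[, pos, drop = FALSE] %*%
    ((1 / e$values[pos]) * t(e$vectors[, pos, drop = FALSE]))
  d <- numeric(ng); d[1] <- 1; d[2] <- -1
  r <- drop(t(d) %*% Lp %*% d)
  # pseudoinverse gives a finite number even across components; detect
  gr <- igraph::graph_from_edgelist(
    cbind(group[graph$edges$from], group[graph$edges$to]), directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0, ng - igraph::vcount(gr)))
  comp <- igraph::components(gr)$membership
  if (comp[1] != comp[2]) return(Inf)
  r
}

#' Pairwise effective resistance among focal regions
#'
#' Rasterizes each focal region onto the conductance grid, treats each as a
#' zero-resistance supernode, and solves one linear system per unordered
#' pair — the "pairwise mode" of circuit-theory connectivity tools.
#'
#' @param conductance A conductance [scape_raster()].
#' @param regions A `focal_regions` object (see [delimit_sites()]) or a named
#'   list of integer node-id vectors.
#' @param neighborhood 4 or 8 (see [raster_to_graph()]).
#' @return Symmetric matrix of class `resistance_matrix` with zero diagonal;
#'   `Inf` marks disconnected pairs.
#' @export
pairwise_resistance <- function(conductance, regions, neighborhood = 8) {
  graph <- raster_to_graph(conductance, neighborhood)
  if (inherits(regions, "focal_regions")) {
    node_sets <- region_nodes(regions, graph)
  } else {
    node_sets <- regions
  }
  k <- length(node_sets)
  if (k < 2) stop("need at least 2 regions", call. = FALSE)
  labs <- names(node_sets) %||% paste0("region_", seq_len(k))
  empty <- labs[lengths(node_sets) == 0]
  if (length(empty) > 0) {
    stop("region(s) with no positive-conductance cell: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  out <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    out[i, j] <- out[j, i] <-
      effective_resistance(graph, node_sets[[i]], node_sets[[j]])
  }
  class(out) <- c("resistance_matrix", class(out))
  out
}

# node ids of a graph whose cell centers fall inside each focal region
region_nodes <- function(regions, graph) {
  cc <- cell_center(graph$raster, graph$nodes$row, graph$nodes$col)
  setNames(lapply(regions, function(rg) {
    graph$nodes$node[region_contains(rg, cc[, 1], cc[, 2])]
  }), names(regions))
}

#' Turn a symmetric pairwise matrix into a tidy pair table
#'
#' @param m Symmetric matrix with row/column names.
#' @param value Name for the value column.
#' @return Tibble with one row per unordered pair (`site_a`, `site_b`, value).
#' @export
pairs_tbl <- function(m, value = "value") {
  m <- as.matrix(m)
  labs <- rownames(m) %||% paste0("site_", seq_len(nrow(m)))
  ut <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(site_a = labs[ut[, 1]], site_b = labs[ut[, 2]],
                 !!value := m[ut])
}
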