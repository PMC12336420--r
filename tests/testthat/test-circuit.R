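test_that("a uniform 1x3 raster yields two unit edges under rook adjacency", {
  r <- scape_raster(matrix(1, 1, 3), 1)
  g <- raster_to_graph(r, 4)
  expect_equal(nrow(g$nodes), 3)
  expect_equal(nrow(g$edges), 2)
  expect_equal(g$edges$conductance, c(1, 1))
})

test_that("queen adjacency adds diagonal edges scaled by 1/sqrt(2)", {
  r <- scape_raster(matrix(1, 2, 2), 1)
  g <- raster_to_graph(r, 8)
  expect_equal(nrow(g$edges), 6)  # 4 orthogonal + 2 diagonal
  expect_equal(sort(unique(round(g$edges$conductance, 10))),
               sort(round(c(1 / sqrt(2), 1), 10)))
  expect_equal(sum(abs(g$edges$conductance - 1 / sqrt(2)) < 1e-12), 2)
})

test_that("edge lists match an independent double-loop construction", {
  r <- random_conductance_raster(6, 6, seed = 2, p_zero = 0.2)
  for (nb in c(4, 8)) {
    g <- raster_to_graph(r, nb)
    v <- r$values
    expected <- list()
    for (i in 1:6) for (j in 1:6) {
      if (is.na(v[i, j]) || v[i, j] <= 0) next
      offs <- list(c(0, 1), c(1, 0))
      if (nb == 8) offs <- c(offs, list(c(1, 1), c(1, -1)))
      for (off in offs) {
        i2 <- i + off[1]; j2 <- j + off[2]
        if (i2 < 1 || i2 > 6 || j2 < 1 || j2 > 6) next
        if (is.na(v[i2, j2]) || v[i2, j2] <= 0) next
        w <- (v[i, j] + v[i2, j2]) / 2
        if (all(off != 0)) w <- w / sqrt(2)
        expected[[length(expected) + 1]] <-
          c(sort(c(i * 100 + j, i2 * 100 + j2)), w)
      }
    }
    expected <- do.call(rbind, expected)
    expected <- expected[order(expected[, 1], expected[, 2]), ]
    got <- cbind(
      key_a = pmin(g$nodes$row[g$edges$from] * 100 + g$nodes$col[g$edges$from],
                   g$nodes$row[g$edges$to] * 100 + g$nodes$col[g$edges$to]),
      key_b = pmax(g$nodes$row[g$edges$from] * 100 + g$nodes$col[g$edges$from],
                   g$nodes$row[g$edges$to] * 100 + g$nodes$col[g$edges$to]),
      w = g$edges$conductance)
    got <- got[order(got[, 1], got[, 2]), ]
    expect_equal(unname(got), unname(expected), tolerance = 1e-12)
  }
})

test_that("an all-zero raster is rejected", {
  expect_error(raster_to_graph(scape_raster(matrix(0, 3, 3), 1)),
               "positive conductance")
})

test_that("series and parallel resistor laws hold exactly", {
  # single resistor of conductance 2 -> R = 1/2
  g1 <- list(nodes = tibble::tibble(node = 1:2),
             edges = tibble::tibble(from = 1, to = 2, conductance = 2))
  expect_equal(effective_resistance(g1, 1, 2), 0.5, tolerance = 1e-12)
  # chain of 3, both edges conductance 2 -> series: 0.5 + 0.5 = 1
  g2 <- list(nodes = tibble::tibble(node = 1:3),
             edges = tibble::tibble(from = c(1, 2), to = c(2, 3),
                                    conductance = c(2, 2)))
  expect_equal(effective_resistance(g2, 1, 3), 1.0, tolerance = 1e-12)
  # two disjoint 2-edge paths of resistance 2 each -> parallel: 1
  g3 <- list(nodes = tibble::tibble(node = 1:4),
             edges = tibble::tibble(from = c(1, 2, 1, 3), to = c(2, 4, 3, 4),
                                    conductance = c(1, 1, 1, 1)))
  expect_equal(effective_resistance(g3, 1, 4), 1.0, tolerance = 1e-12)
})

test_that("solver matches the pseudoinverse oracle on random graphs", {
  for (s in 1:20) {
    n <- sample(5:100, 1)
    g <- random_connected_graph(n, extra = n, seed = s)
    ab <- sample.int(n, 2)
    got <- effective_resistance(g, ab[1], ab[2])
    exp_r <- oracle_resistance(g$edges, ab[1], ab[2], n)
    expect_equal(got, exp_r, tolerance = 1e-6)
    # the package's own dense route agrees too
    expect_equal(effective_resistance_pinv(g, ab[1], ab[2]), exp_r,
                 tolerance = 1e-6)
  }
})

test_that("supernode regions match the contracted pseudoinverse oracle", {
  g <- random_connected_graph(40, extra = 50, seed = 9)
  ra <- 1:4; rb <- 10:12
  groups <- seq_len(40)
  groups[ra] <- 1L; groups[rb] <- 10L
  expect_equal(effective_resistance(g, ra, rb),
               oracle_resistance(g$edges, 1, 10, 40, groups = groups),
               tolerance = 1e-8)
})

test_that("disjoint and overlapping regions are handled explicitly", {
  g <- random_connected_graph(10, seed = 1)
  expect_error(effective_resistance(g, 1:3, 3:5), "disjoint")
  expect_error(effective_resistance(g, integer(0), 1:2), "non-empty")
  # two components -> Inf with a warning
  g2 <- list(nodes = tibble::tibble(node = 1:4),
             edges = tibble::tibble(from = c(1, 3), to = c(2, 4),
                                    conductance = c(1, 1)))
  expect_warning(r <- effective_resistance(g2, 1, 4), "components")
  expect_identical(r, Inf)
})

test_that("pairwise resistance is symmetric and scales as 1/conductance", {
  r <- random_conductance_raster(8, 8, seed = 5)
  regions <- list(a = 1:2, b = 30:31, c = 60:62)
  m <- pairwise_resistance(r, regions)
  expect_equal(unclass(m), t(unclass(m)))
  expect_true(all(diag(m) == 0))
  expect_true(all(m[upper.tri(m)] > 0))
  r2 <- r; r2$values <- r$values * 4
  m2 <- pairwise_resistance(r2, regions)
  expect_equal(unclass(m2), unclass(m) / 4, tolerance = 1e-9)
})

test_that("pairwise regions on a raster match the oracle exactly", {
  r <- random_conductance_raster(10, 10, seed = 6)
  g <- raster_to_graph(r, 8)
  node_sets <- list(a = 1:3, b = 45:47, c = 90:92)
  m <- pairwise_resistance(r, node_sets)
  for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
    groups <- g$nodes$node
    groups[node_sets[[pr[1]]]] <- node_sets[[pr[1]]][1]
    groups[node_sets[[pr[2]]]] <- node_sets[[pr[2]]][1]
    exp_r <- oracle_resistance(g$edges, node_sets[[pr[1]]][1],
                               node_sets[[pr[2]]][1], nrow(g$nodes),
                               groups = groups)
    expect_equal(m[pr[1], pr[2]], exp_r, tolerance = 1e-6)
  }
})

test_that("effective resistance is a metric and Rayleigh-monotone", {
  for (s in 1:10) {
    n <- 20
    g <- random_connected_graph(n, extra = 15, seed = 100 + s)
    trip <- sample.int(n, 3)
    rab <- effective_resistance(g, trip[1], trip[2])
    rbc <- effective_resistance(g, trip[2], trip[3])
    rac <- effective_resistance(g, trip[1], trip[3])
    expect_lte(rac, rab + rbc + 1e-10)
    # raise one edge's conductance: no pairwise resistance may increase
    g2 <- g
    k <- sample.int(nrow(g$edges), 1)
    g2$edges$conductance[k] <- g$edges$conductance[k] * 3
    expect_lte(effective_resistance(g2, trip[1], trip[2]), rab + 1e-10)
    expect_lte(effective_resistance(g2, trip[1], trip[3]), rac + 1e-10)
  }
})

test_that("effective resistance is bounded by the best single path", {
  for (s in 1:5) {
    n <- 15
    g <- random_connected_graph(n, extra = 10, seed = 200 + s)
    ig <- igraph::graph_from_edgelist(cbind(g$edges$from, g$edges$to),
                                      directed = FALSE)
    sp <- igraph::distances(ig, weights = 1 / g$edges$conductance)
    ab <- sample.int(n, 2)
    expect_lte(effective_resistance(g, ab[1], ab[2]),
               sp[ab[1], ab[2]] + 1e-10)
  }
})

test_that("a region internally tied by huge conductances converges to the supernode answer", {
  g <- random_connected_graph(15, extra = 10, seed = 3)
  ra <- c(1, 2, 3); rb <- c(9, 10)
  super <- effective_resistance(g, ra, rb)
  g2 <- g
  tie <- function(nodes) {
    tibble::tibble(from = nodes[-length(nodes)], to = nodes[-1],
                   conductance = 1e9)
  }
  g2$edges <- dplyr::bind_rows(g$edges, tie(ra), tie(rb))
  merged <- effective_resistance(g2, ra[1], rb[1])
  expect_equal(merged, super, tolerance = 1e-5)
})
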