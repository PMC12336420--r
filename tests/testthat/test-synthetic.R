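test_that("elevation equals the per-cell cone maximum (brute-force check)", {
  cones <- data.frame(x = c(3000, 7000), y = c(3000, 6000),
                      peak = c(2000, 1500), radius = c(4000, 3500))
  cfg <- scenario_config(seed = 1, grid = c(10, 10), cellsize = 1000,
                         cones = cones)
  elev <- generate_elevation(cfg)
  tb <- raster_tbl(elev)
  expected <- mapply(function(x, y) {
    max(vapply(seq_len(nrow(cones)), function(k) {
      d <- sqrt((x - cones$x[k])^2 + (y - cones$y[k])^2)
      cones$peak[k] * max(0, 1 - d / cones$radius[k])
    }, numeric(1)))
  }, tb$x, tb$y)
  expect_equal(tb$value, expected, tolerance = 1e-12)
  expect_true(all(tb$value >= 0))
})

test_that("a cone center sits at its peak and far cells are clamped to sea level", {
  cones <- data.frame(x = 5500, y = 5500, peak = 2000, radius = 2000)
  cfg <- scenario_config(seed = 1, grid = c(11, 11), cellsize = 1000,
                         cones = cones)
  elev <- generate_elevation(cfg)
  expect_equal(elev$values[6, 6], 2000)        # center cell (5500, 5500)
  expect_equal(elev$values[1, 1], 0)           # far corner, beyond radius
  expect_error(scenario_config(cones = data.frame(x = 0, y = 0, peak = 1,
                                                  radius = 0)),
               "radius")
})

test_that("land cover is elevation-banded, deterministic, and noise-mixed", {
  cfg0 <- tiny_config(seed = 3, class_noise = 0)
  elev <- generate_elevation(cfg0)
  lc0 <- generate_landcover(cfg0, elev)
  # zero noise: class is a pure function of the elevation band
  k <- cfg0$n_landcover_classes
  breaks <- seq(0, max(elev$values), length.out = k + 1)
  expected <- matrix(as.integer(cut(elev$values, breaks, include.lowest = TRUE,
                                    labels = FALSE)), nrow(elev$values))
  expect_equal(lc0$values, expected + 0)
  # determinism
  cfg <- tiny_config(seed = 3, class_noise = 0.3)
  expect_identical(generate_landcover(cfg, elev)$values,
                   generate_landcover(cfg, elev)$values)
  # emitted classes stay within the configured code set
  expect_true(all(generate_landcover(cfg, elev)$values %in% seq_len(k)))
})

test_that("patch-noise proportion matches its Monte-Carlo expectation", {
  # with noise q, a cell keeps its band class w.p. (1-q) + q/k
  q <- 0.3
  flips <- vapply(1:10, function(s) {
    cfg <- tiny_config(seed = s, class_noise = q)
    elev <- generate_elevation(cfg)
    base <- generate_landcover(tiny_config(seed = s, class_noise = 0), elev)
    noisy <- generate_landcover(cfg, elev)
    mean(noisy$values != base$values)
  }, numeric(1))
  k <- tiny_config()$n_landcover_classes
  expected <- q * (1 - 1 / k)
  n <- prod(tiny_config()$grid) * 10
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(mean(flips) - expected), 4 * se)
})

test_that("expert tables aggregate their own stored draws", {
  cfg <- tiny_config(seed = 11, n_experts = 9)
  tabs <- generate_expert_tables(cfg)
  expect_true(all(tabs$permeability$mean >= 0 & tabs$permeability$mean <= 1))
  expect_true(all(tabs$permeability$sd >= 0))
  expect_setequal(tabs$malaria$band, c("year_round", "seasonal", "absent"))
  recomputed <- dplyr::summarise(
    dplyr::group_by(tabs$draws$permeability, class),
    m = mean(value), s = sd(value), .groups = "drop")
  expect_equal(tabs$permeability$mean[order(tabs$permeability$class)],
               recomputed$m[order(recomputed$class)], tolerance = 1e-12)
  expect_equal(tabs$permeability$sd[order(tabs$permeability$class)],
               recomputed$s[order(recomputed$class)], tolerance = 1e-12)
  # determinism
  expect_identical(generate_expert_tables(cfg)$permeability,
                   tabs$permeability)
  expect_error(generate_expert_tables(tiny_config(n_experts = 2)), NA)
})

test_that("recorders respect separation, site membership and determinism", {
  cfg <- scenario_config(seed = 5, grid = c(30, 30), cellsize = 1000,
                         n_sites = 2, recorders_per_site = 6,
                         site_radius = 3000, min_separation = 1000)
  rec <- generate_recorders(cfg)
  expect_equal(nrow(rec), 12)
  for (s in unique(rec$site)) {
    pts <- as.matrix(rec[rec$site == s, c("x", "y")])
    d <- as.matrix(dist(pts))
    expect_true(all(d[upper.tri(d)] >= 1000))
  }
  expect_identical(generate_recorders(cfg), rec)
  # recorders fall inside their buffered site region (point-in-polygon)
  regions <- delimit_sites(rec, buffer_radius_m = 500)
  for (s in unique(rec$site)) {
    pts <- rec[rec$site == s, ]
    expect_true(all(region_contains(regions[[s]], pts$x, pts$y)))
  }
})

test_that("impossible separation constraints fail explicitly", {
  cfg <- scenario_config(seed = 5, grid = c(30, 30), cellsize = 1000,
                         n_sites = 2, recorders_per_site = 40,
                         site_radius = 1000, min_separation = 2500)
  expect_error(generate_recorders(cfg), "separation")
})

test_that("independent sites with p = 0.5 give expected Sorensen 0.5", {
  # analytic independence limit of the latent model
  expect_equal(expected_sorensen(0, 0.5), 0.5, tolerance = 1e-9)
  expect_equal(expected_sorensen(0, 0.3), 0.7, tolerance = 1e-9)
  # realized repertoires, decay -> infinity
  cfg <- scenario_config(seed = 21, n_sites = 4, n_syllables = 400,
                         occupancy = 0.5, decay = 1e6, noise_sd = 0,
                         detect_prob = 1)
  r <- random_resistance(4, seed = 21)
  rep <- generate_repertoires(cfg, r)
  sm <- suppressWarnings(aggregate_by_site(rep$unit_matrix))
  d <- dissimilarity_matrix(sm)
  expect_lt(abs(attr(d, "average") - 0.5), 0.05)
  expect_equal(max(abs(rep$truth$expected_sorensen[upper.tri(r)] - 0.5)), 0,
               tolerance = 1e-6)
})

test_that("zero decay and no noise make all site repertoires identical", {
  cfg <- scenario_config(seed = 9, n_sites = 4, n_syllables = 100,
                         decay = 0, noise_sd = 0, detect_prob = 1)
  # decay 0 makes the latent correlation matrix singular (all ones); the
  # generator repairs it with a warning by design
  rep <- suppressWarnings(generate_repertoires(cfg, random_resistance(4, seed = 9)))
  sm <- suppressWarnings(aggregate_by_site(rep$unit_matrix))
  d <- dissimilarity_matrix(sm)
  expect_equal(max(d), 0)
})

test_that("site-level occupancy is calibrated to p", {
  p <- 0.4
  cfg <- scenario_config(seed = 13, n_sites = 5, n_syllables = 500,
                         occupancy = p, decay = 2, detect_prob = 1)
  rep <- generate_repertoires(cfg, random_resistance(5, seed = 13))
  sm <- suppressWarnings(aggregate_by_site(rep$unit_matrix))
  # realized occupancy per site vs binomial SE (500 syllables)
  occ <- rowSums(sm) / cfg$n_syllables
  se <- sqrt(p * (1 - p) / cfg$n_syllables)
  expect_true(all(abs(occ - p) <= 3.5 * se))
})

test_that("expected Sorensen is non-decreasing in resistance when decay > 0", {
  cfg <- scenario_config(seed = 1, decay = 1.5)
  r <- random_resistance(5, seed = 2)
  rep <- generate_repertoires(cfg, r)
  ut <- upper.tri(r)
  ord <- order(r[ut])
  es <- rep$truth$expected_sorensen[ut][ord]
  expect_true(all(diff(es) >= -1e-10))
})

test_that("realized Sorensen correlates positively with resistance", {
  # strong-decay scenario; Spearman correlation positive in >= 95/100 seeds
  hits <- vapply(1:100, function(s) {
    cfg <- scenario_config(seed = s, n_sites = 5, n_syllables = 150,
                           occupancy = 0.4, decay = 1.2, noise_sd = 0.3)
    r <- random_resistance(5, seed = 1000 + s)
    rep <- generate_repertoires(cfg, r)
    sm <- suppressWarnings(aggregate_by_site(rep$unit_matrix))
    d <- dissimilarity_matrix(sm)
    ut <- upper.tri(r)
    cor(d[ut], r[ut], method = "spearman") > 0
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("generators are bit-identical under the same seed and config", {
  cfg <- tiny_config(seed = 77)
  r <- random_resistance(3, seed = 3)
  a <- generate_repertoires(cfg, r)
  b <- generate_repertoires(cfg, r)
  expect_identical(a$detections, b$detections)
  expect_identical(a$unit_matrix, b$unit_matrix)
})

test_that("non-PD correlation matrices are repaired with a warning", {
  # a non-metric 'resistance' engineered so exp(-lambda R) is not PD
  r <- matrix(c(0, 0.01, 4, 0.01, 0, 0.01, 4, 0.01, 0), 3, 3)
  cfg <- scenario_config(seed = 2, n_sites = 3, decay = 2, noise_sd = 0)
  expect_warning(generate_repertoires(cfg, r), "positive definite")
})

test_that("scenario configs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 4", "grid: [15, 18]", "n_sites: 3",
               "occupancy: 0.35", "decay: 0.8"), path)
  cfg <- read_scenario_config(path)
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$grid, c(15L, 18L))
  expect_equal(cfg$occupancy, 0.35)
})
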