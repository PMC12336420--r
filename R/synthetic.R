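#' Scenario configuration for synthetic study landscapes
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the study design the package targets: a volcanic island whose land covers
#' are zoned by elevation, five focal landscapes sampled by six autonomous
#' recorders each (at least 1 km apart), coefficient tables elicited from
#' nine experts, and syllable repertoires whose between-site sharing decays
#' with effective landscape resistance.
#'
#' @param seed Integer seed; every generator derives its own substream from it.
#' @param grid `c(rows, cols)` of the raster grid (each >= 2).
#' @param cellsize Cell edge length in meters.
#' @param cones Data frame of volcano cones with columns `x`, `y` (center,
#'   meters), `peak` (summit elevation, m) and `radius` (base radius, m).
#'   `NULL` uses five cones scaled to the grid extent, mimicking a Big-Island
#'   style shield-volcano profile.
#' @param n_landcover_classes Number of land-cover classes (>= 2).
#' @param class_noise Probability that a cell's elevation-band class is
#'   replaced by a uniformly random class (patchiness).
#' @param n_sites Number of focal landscapes (>= 2).
#' @param recorders_per_site Recorders per site (study design: 6).
#' @param n_experts Experts scoring each coefficient (study design: 9).
#' @param n_syllables Size M of the island-wide syllable pool.
#' @param occupancy Marginal probability p that a pool syllable is present at
#'   a given site.
#' @param decay Correlation decay rate lambda per unit effective resistance:
#'   latent cross-site correlation is `exp(-decay * R)`.
#' @param noise_sd SD of the independent per-site latent noise added on top
#'   of the shared field (dilutes cross-site correlation).
#' @param detect_prob Probability a syllable present at a site is detected by
#'   any single recorder there.
#' @param site_radius Radius (m) of the disk around a site center in which
#'   its recorders are placed.
#' @param buffer_radius Recorder buffer radius (m) used when delimiting
#'   focal regions (the species' maximum distance moved); site centers are
#'   separated far enough that buffered regions of distinct sites stay
#'   disjoint.
#' @param min_separation Minimum distance (m) between recorders of a site.
#' @param species Species label attached to generated tables.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            grid = c(60L, 60L),
                            cellsize = 1000,
                            cones = NULL,
                            n_landcover_classes = 6L,
                            class_noise = 0.15,
                            n_sites = 5L,
                            recorders_per_site = 6L,
                            n_experts = 9L,
                            n_syllables = 200L,
                            occupancy = 0.4,
                            decay = 1.0,
                            noise_sd = 0.3,
                            detect_prob = 0.7,
                            site_radius = 3000,
                            buffer_radius = 1500,
                            min_separation = 1000,
                            species = "synthetic_species") {
  stopifnot(length(grid) == 2, all(grid >= 2), cellsize > 0,
            n_landcover_classes >= 2, n_sites >= 2, recorders_per_site >= 1,
            n_experts >= 2, n_syllables >= 1)
  probs <- c(class_noise = class_noise, occupancy = occupancy,
             detect_prob = detect_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities (`class_noise`, `occupancy`, `detect_prob`) must lie in [0, 1]",
         call. = FALSE)
  }
  if (decay < 0) stop("`decay` must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  ext_x <- grid[2] * cellsize
  ext_y <- grid[1] * cellsize
  if (is.null(cones)) {
    # five shield volcanoes: two giants, three flank cones
    cones <- data.frame(
      x = c(0.55, 0.35, 0.22, 0.20, 0.72) * ext_x,
      y = c(0.45, 0.68, 0.30, 0.85, 0.28) * ext_y,
      peak = c(4100, 4200, 2500, 1700, 1250),
      radius = c(0.55, 0.45, 0.28, 0.22, 0.25) * max(ext_x, ext_y)
    )
  }
  cones <- as.data.frame(cones)
  stopifnot(all(c("x", "y", "peak", "radius") %in% names(cones)),
            nrow(cones) >= 1)
  if (any(cones$radius <= 0)) stop("cone base radius must be > 0", call. = FALSE)
  if (any(cones$peak < 0)) stop("cone peak elevation must be >= 0", call. = FALSE)
  structure(
    list(seed = as.integer(seed), grid = as.integer(grid),
         cellsize = cellsize, cones = cones,
         n_landcover_classes = as.integer(n_landcover_classes),
         class_noise = class_noise, n_sites = as.integer(n_sites),
         recorders_per_site = as.integer(recorders_per_site),
         n_experts = as.integer(n_experts),
         n_syllables = as.integer(n_syllables), occupancy = occupancy,
         decay = decay, noise_sd = noise_sd, detect_prob = detect_prob,
         site_radius = site_radius, buffer_radius = buffer_radius,
         min_separation = min_separation,
         species = species),
    class = "scenario_config"
  )
}

#' Generate a cone-model elevation raster
#'
#' Each cell's elevation is the pointwise maximum over all volcano cones of
#' `peak * max(0, 1 - dist/radius)`; cells beyond every base radius sit at
#' sea level (0 m).
#'
#' @param config A [scenario_config()].
#' @return A [scape_raster()] of elevations in meters.
#' @export
generate_elevation <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  nr <- config$grid[1]; nc <- config$grid[2]
  template <- scape_raster(matrix(0, nr, nc), cellsize = config$cellsize)
  idx <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  cc <- cell_center(template, idx$row, idx$col)
  elev <- rep(0, nrow(cc))
  for (k in seq_len(nrow(config$cones))) {
    cone <- config$cones[k, ]
    d <- sqrt((cc[, 1] - cone$x)^2 + (cc[, 2] - cone$y)^2)
    elev <- pmax(elev, cone$peak * pmax(0, 1 - d / cone$radius))
  }
  m <- matrix(0, nr, nc)
  m[cbind(idx$row, idx$col)] <- elev
  scape_raster(m, cellsize = config$cellsize)
}

#' Generate an elevation-zoned land-cover raster
#'
#' Base classes are contiguous elevation bands (class 1 = lowest); with
#' probability `class_noise` a cell is replaced by a uniformly random class,
#' producing patchiness. Deterministic given `config$seed`.
#'
#' @param config A [scenario_config()].
#' @param elevation Elevation raster from [generate_elevation()].
#' @return A [scape_raster()] of integer class codes `1..n_landcover_classes`.
#' @export
generate_landcover <- function(config, elevation) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(elevation, "scape_raster"))
  if (!identical(dim(elevation$values), as.integer(config$grid))) {
    stop("elevation raster is not aligned to the configured grid", call. = FALSE)
  }
  k <- config$n_landcover_classes
  top <- max(elevation$values, na.rm = TRUE)
  breaks <- seq(0, max(top, 1), length.out = k + 1)
  cls <- matrix(
    as.integer(cut(elevation$values, breaks = breaks, include.lowest = TRUE,
                   labels = FALSE)),
    nrow = nrow(elevation$values)
  )
  old <- set_local_seed(substream(config$seed, "landcover"))
  on.exit(restore_seed(old))
  n <- length(cls)
  flip <- runif(n) < config$class_noise
  cls[flip] <- sample.int(k, sum(flip), replace = TRUE)
  scape_raster(cls, cellsize = elevation$cellsize,
               xll = elevation$xll, yll = elevation$yll)
}

#' Generate expert-elicited coefficient tables
#'
#' Emulates a panel of experts scoring (a) the permeability of each
#' land-cover class for the species, in `[0, 1]`, and (b) the species'
#' malaria survival in each elevation band (`year_round`, `seasonal`,
#' `absent`). Each expert's answer is a Beta draw around a per-class
#' archetype mean; the aggregated mean and SD are what downstream
#' conductance modelling consumes.
#'
#' @param config A [scenario_config()].
#' @return A list of class `expert_tables` with tibbles `permeability`
#'   (species, class, mean, sd), `malaria` (species, band, mean, sd) and the
#'   raw per-expert `draws`.
#' @export
generate_expert_tables <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$n_experts < 2) stop("need at least 2 experts", call. = FALSE)
  old <- set_local_seed(substream(config$seed, "experts"))
  on.exit(restore_seed(old))
  k <- config$n_landcover_classes
  concentration <- 25
  # higher classes sit higher on the mountain: closer to native forest,
  # hence more permeable for forest honeycreepers
  class_arche <- 0.1 + 0.8 * (seq_len(k) - 1) / (k - 1)
  band_arche <- c(year_round = 0.15, seasonal = 0.55, absent = 0.95)
  draw <- function(m) rbeta(config$n_experts, m * concentration,
                            (1 - m) * concentration)
  perm_draws <- purrr::map_dfr(seq_len(k), function(cl) {
    tibble::tibble(species = config$species, class = cl,
                   expert = seq_len(config$n_experts),
                   value = draw(class_arche[cl]))
  })
  mal_draws <- purrr::map_dfr(names(band_arche), function(b) {
    tibble::tibble(species = config$species, band = b,
                   expert = seq_len(config$n_experts),
                   value = draw(band_arche[[b]]))
  })
  agg <- function(d, key) {
    dplyr::summarise(dplyr::group_by(d, .data$species, .data[[key]]),
                     mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")
  }
  structure(
    list(permeability = agg(perm_draws, "class"),
         malaria = dplyr::mutate(
           agg(mal_draws, "band"),
           band = factor(.data$band, levels = names(band_arche))
         ) |> dplyr::arrange(.data$band) |>
           dplyr::mutate(band = as.character(.data$band)),
         draws = list(permeability = perm_draws, malaria = mal_draws)),
    class = "expert_tables"
  )
}

#' Generate recorder positions
#'
#' Places `n_sites` site centers well inside the grid (mutually separated),
#' then `recorders_per_site` recorders uniformly within each site's disk of
#' radius `site_radius`, enforcing the minimum between-recorder separation by
#' bounded rejection sampling.
#'
#' @param config A [scenario_config()].
#' @param regions_hint Optional tibble with columns `site`, `x`, `y` fixing
#'   the site centers.
#' @return Tibble with columns `recorder`, `site`, `x`, `y` (meters).
#' @export
generate_recorders <- function(config, regions_hint = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  old <- set_local_seed(substream(config$seed, "recorders"))
  on.exit(restore_seed(old))
  ext_x <- config$grid[2] * config$cellsize
  ext_y <- config$grid[1] * config$cellsize
  r <- config$site_radius
  if (is.null(regions_hint)) {
    # keep buffered focal regions of distinct sites disjoint (one cell slack)
    sep_sites <- 2 * (r + config$buffer_radius) + config$cellsize
    centers <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(centers) < config$n_sites && tries < 5000) {
      tries <- tries + 1
      cand <- c(runif(1, r, ext_x - r), runif(1, r, ext_y - r))
      if (nrow(centers) == 0 ||
          all(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                             byrow = TRUE))^2)) >= sep_sites)) {
        centers <- rbind(centers, cand)
      }
    }
    if (nrow(centers) < config$n_sites) {
      stop("could not place ", config$n_sites,
           " mutually separated site centers in the grid extent", call. = FALSE)
    }
    hint <- tibble::tibble(site = paste0("site_", seq_len(config$n_sites)),
                           x = centers[, 1], y = centers[, 2])
  } else {
    hint <- tibble::as_tibble(regions_hint)
    stopifnot(all(c("site", "x", "y") %in% names(hint)))
  }
  place_site <- function(cx, cy) {
    for (attempt in 1:200) {
      pts <- matrix(NA_real_, 0, 2)
      ok <- TRUE
      for (i in seq_len(config$recorders_per_site)) {
        placed <- FALSE
        for (t in 1:200) {
          ang <- runif(1, 0, 2 * pi); rad <- r * sqrt(runif(1))
          p <- c(cx + rad * cos(ang), cy + rad * sin(ang))
          if (nrow(pts) == 0 ||
              all(sqrt(rowSums((pts - matrix(p, nrow(pts), 2,
                                             byrow = TRUE))^2)) >=
                  config$min_separation)) {
            pts <- rbind(pts, p); placed <- TRUE; break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) return(pts)
    }
    stop("could not satisfy the recorder separation constraint (",
         config$min_separation, " m) within the site disk", call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(hint)), function(s) {
    pts <- place_site(hint$x[s], hint$y[s])
    tibble::tibble(
      recorder = paste0(hint$site[s], "_r", seq_len(nrow(pts))),
      site = hint$site[s], x = pts[, 1], y = pts[, 2]
    )
  })
}

# P(Z1 > t, Z2 > t) for standard bivariate normal with correlation rho
bvn_upper_orthant <- function(rho, t) {
  p <- pnorm(t, lower.tail = FALSE)
  if (abs(rho) < 1e-12) return(p^2)
  if (rho > 1 - 1e-10) return(p)
  if (rho < -1 + 1e-10) return(max(0, 1 - 2 * pnorm(t)))
  f <- function(z) dnorm(z) * pnorm((rho * z - t) / sqrt(1 - rho^2))
  integrate(f, t, Inf, rel.tol = 1e-10)$value
}

#' Analytic expected Sorensen dissimilarity of the latent sharing model
#'
#' For two sites whose latent fields have correlation `rho` and marginal
#' occupancy `p`, the expected shared count is `M * P(both present)` and each
#' expected richness is `M * p`, giving (in the ratio-of-expectations
#' approximation, exact as M grows) `D = 1 - P(both)/p`. Under independence
#' this is `1 - p`.
#'
#' @param rho Latent cross-site correlation in `[-1, 1]`.
#' @param p Marginal occupancy in `(0, 1)`.
#' @return Expected Sorensen dissimilarity.
#' @export
expected_sorensen <- function(rho, p) {
  stopifnot(p > 0, p < 1, abs(rho) <= 1)
  t <- qnorm(1 - p)
  1 - bvn_upper_orthant(rho, t) / p
}

# eigenvalue-clipping nearest-PD repair; exp(-lambda*R) on a metric need not
# be PD for every lambda
nearest_pd <- function(m, eps = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= eps) return(m)
  warning("correlation matrix not positive definite; eigenvalues clipped at ",
          eps, call. = FALSE)
  v <- pmax(e$values, eps)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  (out + t(out)) / 2
}

#' Generate syllable repertoires whose sharing decays with resistance
#'
#' For each of the `n_syllables` pool syllables a zero-mean latent Gaussian
#' vector across sites is drawn with cross-site correlation
#' `exp(-decay * R) / (1 + noise_sd^2)` (a shared field plus independent
#' per-site noise); a syllable is present at a site when its latent value
#' exceeds the threshold fixing marginal occupancy at `occupancy`. Each
#' recorder then detects each locally present syllable independently with
#' probability `detect_prob`, and detected syllables receive a positive
#' count. Singletons (syllables detected exactly once in the whole study)
#' arise naturally.
#'
#' @param config A [scenario_config()].
#' @param resistance Symmetric, finite pairwise resistance matrix among
#'   sites (diagonal 0). Row/column names, if present, become site labels.
#' @return A list of class `synthetic_repertoires`:
#'   * `detections`: tibble `recorder`, `site`, `syllable`, `count`;
#'   * `unit_matrix`: binary recorders x syllables matrix (attribute `site`);
#'   * `truth`: list with the resistance matrix, the effective latent
#'     correlation matrix, `decay`, `occupancy` and the analytic expected
#'     pairwise Sorensen matrix.
#' @export
generate_repertoires <- function(config, resistance) {
  stopifnot(inherits(config, "scenario_config"))
  resistance <- as.matrix(resistance)
  if (!isSymmetric(unname(resistance), tol = 1e-8)) {
    stop("`resistance` must be symmetric", call. = FALSE)
  }
  if (any(!is.finite(resistance))) {
    stop("`resistance` must be finite", call. = FALSE)
  }
  n <- nrow(resistance)
  sites <- rownames(resistance) %||% paste0("site_", seq_len(n))
  old <- set_local_seed(substream(config$seed, "repertoires"))
  on.exit(restore_seed(old))

  shrink <- 1 / (1 + config$noise_sd^2)
  rho <- exp(-config$decay * resistance) * shrink
  diag(rho) <- 1
  rho <- nearest_pd(rho)
  L <- t(chol(rho))
  M <- config$n_syllables
  z <- L %*% matrix(rnorm(n * M), n, M)
  thr <- qnorm(1 - config$occupancy)
  presence <- z > thr                      # sites x syllables

  n_rec <- config$recorders_per_site
  unit_site <- rep(sites, each = n_rec)
  unit_ids <- paste0(unit_site, "_r", rep(seq_len(n_rec), n))
  det <- matrix(0L, n * n_rec, M, dimnames = list(unit_ids, paste0("syl_", seq_len(M))))
  for (s in seq_len(n)) {
    rows <- (s - 1) * n_rec + seq_len(n_rec)
    hit <- matrix(rbinom(n_rec * M, 1, config$detect_prob), n_rec, M)
    det[rows, ] <- hit * matrix(rep(as.integer(presence[s, ]), each = n_rec),
                                n_rec, M)
  }
  idx <- which(det == 1L, arr.ind = TRUE)
  detections <- tibble::tibble(
    recorder = rownames(det)[idx[, 1]],
    site = unit_site[idx[, 1]],
    syllable = colnames(det)[idx[, 2]],
    count = 1L + rpois(nrow(idx), 0.8)
  ) |> dplyr::arrange(.data$recorder, .data$syllable)

  exp_sor <- matrix(0, n, n, dimnames = list(sites, sites))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    exp_sor[i, j] <- exp_sor[j, i] <- expected_sorensen(rho[i, j],
                                                        config$occupancy)
  }
  dimnames(resistance) <- list(sites, sites)
  structure(
    list(detections = detections,
         unit_matrix = structure(det, site = unit_site),
         truth = list(resistance = resistance, correlation = rho,
                      decay = config$decay, occupancy = config$occupancy,
                      expected_sorensen = exp_sor)),
    class = "synthetic_repertoires"
  )
}

#' Resistance matrix along a connectivity gradient
#'
#' Builds a pairwise resistance matrix for the parameter-recovery scenario:
#' sites sit at random positions along a one-dimensional connectivity
#' gradient (rescaled to span it fully), and resistance is the gradient
#' separation scaled to `[min_resistance, min_resistance + span]`. Because
#' the gradient is independent of any geographic layout, resistance is
#' decorrelated from geographic distance by construction.
#'
#' @param n_sites Number of sites (>= 3).
#' @param seed Integer seed for the site positions.
#' @param span Resistance range covered by the gradient.
#' @param min_resistance Offset added to every off-diagonal entry.
#' @return Symmetric matrix with zero diagonal and site names.
#' @export
gradient_resistance <- function(n_sites, seed = 1L, span = 4,
                                min_resistance = 0.2) {
  stopifnot(n_sites >= 3, span > 0, min_resistance >= 0)
  old <- set_local_seed(substream(seed, "misc"))
  on.exit(restore_seed(old))
  u <- sort(runif(n_sites))
  u <- (u - min(u)) / (max(u) - min(u))
  r <- as.matrix(dist(u)) * span + min_resistance
  diag(r) <- 0
  dimnames(r) <- list(paste0("site_", seq_len(n_sites)),
                      paste0("site_", seq_len(n_sites)))
  r
}

# seed handling: save/restore .Random.seed so generators are reproducible
# without clobbering the caller's RNG stream
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
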