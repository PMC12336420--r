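#' Delimit focal study landscapes from recorder positions
#'
#' Buffers every recorder by `buffer_radius_m` and merges overlapping buffers
#' of the same site, yielding one (possibly multi-part) focal region per
#' site — the study-landscape polygons that later serve both as circuit
#' terminals and as sampling frames. Regions are represented exactly as disk
#' unions: merged parts are connected components of the "disks overlap"
#' graph.
#'
#' @param recorders Tibble with columns `recorder`, `site`, `x`, `y`
#'   (projected meters); recorder ids must be unique.
#' @param buffer_radius_m Buffer radius in meters (> 0). In the field this
#'   is the species' maximum distance moved.
#' @return A `focal_regions` object: a named list of regions, each with the
#'   disk centers, radius, part memberships and area (m^2).
#' @export
delimit_sites <- function(recorders, buffer_radius_m) {
  recorders <- tibble::as_tibble(recorders)
  stopifnot(all(c("recorder", "site", "x", "y") %in% names(recorders)))
  if (anyDuplicated(recorders$recorder)) {
    stop("duplicate recorder ids", call. = FALSE)
  }
  if (!is.numeric(buffer_radius_m) || buffer_radius_m <= 0) {
    stop("`buffer_radius_m` must be > 0", call. = FALSE)
  }
  if (any(!is.finite(recorders$x)) || any(!is.finite(recorders$y))) {
    stop("recorder coordinates must be finite", call. = FALSE)
  }
  sites <- unique(recorders$site)
  regions <- lapply(sites, function(s) {
    rec <- recorders[recorders$site == s, ]
    centers <- cbind(rec$x, rec$y)
    disk_region(s, centers, buffer_radius_m)
  })
  names(regions) <- sites
  out <- structure(regions, class = "focal_regions")
  ov <- overlapping_site_pairs(out)
  if (nrow(ov) > 0) {
    warning("regions of distinct sites overlap: ",
            paste(paste(ov$site_a, ov$site_b, sep = "/"), collapse = ", "),
            call. = FALSE)
  }
  out
}

# a focal region as a union of equal-radius disks
disk_region <- function(site, centers, radius) {
  centers <- matrix(as.numeric(centers), ncol = 2)
  parts <- disk_components(centers, radius)
  rg <- structure(
    list(site = site, type = "disks", centers = centers, radius = radius,
         part = parts, area_m2 = NA_real_),
    class = "focal_region"
  )
  rg$area_m2 <- region_area(rg)
  rg
}

#' Construct a focal region from explicit polygon rings
#'
#' For regions not built from recorder buffers (e.g., digitized landscape
#' outlines). Rings are closed implicitly; holes are not supported.
#'
#' @param site Site label.
#' @param rings A two-column coordinate matrix, or a list of them (one per
#'   part), in projected meters.
#' @return A `focal_region`.
#' @export
polygon_region <- function(site, rings) {
  if (is.matrix(rings)) rings <- list(rings)
  rings <- lapply(rings, function(r) matrix(as.numeric(r), ncol = 2))
  rg <- structure(
    list(site = site, type = "polygon", rings = rings,
         part = seq_along(rings), area_m2 = NA_real_),
    class = "focal_region"
  )
  rg$area_m2 <- region_area(rg)
  rg
}

# connected components of the disk-overlap graph (union by center distance
# < 2r; tangent disks count as merged)
disk_components <- function(centers, radius) {
  n <- nrow(centers)
  if (n == 1) return(1L)
  d <- as.matrix(dist(centers))
  adj <- d <= 2 * radius
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  as.integer(igraph::components(g)$membership)
}

#' Region area
#'
#' Disk-union parts consisting of a single disk are exact (`pi r^2`); merged
#' parts are integrated on a fine grid (step `radius/128`). Polygon parts
#' use the shoelace formula.
#'
#' @param region A `focal_region`.
#' @return Area in m^2.
#' @export
region_area <- function(region) {
  if (region$type == "polygon") {
    return(sum(vapply(region$rings, shoelace_area, numeric(1))))
  }
  total <- 0
  for (p in unique(region$part)) {
    centers <- region$centers[region$part == p, , drop = FALSE]
    if (nrow(centers) == 1) {
      total <- total + pi * region$radius^2
    } else {
      total <- total + grid_union_area(centers, region$radius)
    }
  }
  total
}

shoelace_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

grid_union_area <- function(centers, radius, step = radius / 128) {
  xr <- range(centers[, 1]) + c(-radius, radius)
  yr <- range(centers[, 2]) + c(-radius, radius)
  xs <- seq(xr[1] + step / 2, xr[2], by = step)
  ys <- seq(yr[1] + step / 2, yr[2], by = step)
  inside <- matrix(FALSE, length(xs), length(ys))
  for (k in seq_len(nrow(centers))) {
    dx2 <- (xs - centers[k, 1])^2
    dy2 <- (ys - centers[k, 2])^2
    inside <- inside | outer(dx2, dy2, "+") <= radius^2
  }
  sum(inside) * step^2
}

#' Point-in-region test
#'
#' @param region A `focal_region`.
#' @param x,y Coordinate vectors (meters).
#' @return Logical vector.
#' @export
region_contains <- function(region, x, y) {
  if (region$type == "disks") {
    out <- rep(FALSE, length(x))
    for (k in seq_len(nrow(region$centers))) {
      out <- out | ((x - region$centers[k, 1])^2 +
                      (y - region$centers[k, 2])^2 <= region$radius^2)
    }
    return(out)
  }
  Reduce(`|`, lapply(region$rings, point_in_ring, x = x, y = y))
}

# even-odd ray casting
point_in_ring <- function(ring, x, y) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Pairwise distances among focal regions
#'
#' `edge` mode returns the minimum boundary-to-boundary Euclidean distance
#' (exact for disk-union regions; segment-to-segment for polygons);
#' `centroid` mode the centroid-to-centroid distance. Overlapping regions
#' get edge distance 0 with a warning.
#'
#' @param regions A `focal_regions` object (or list of `focal_region`s).
#' @param mode `"edge"` (default) or `"centroid"`.
#' @return Symmetric matrix of distances in km, zero diagonal.
#' @export
pairwise_distance <- function(regions, mode = c("edge", "centroid")) {
  mode <- match.arg(mode)
  k <- length(regions)
  if (k < 2) stop("need at least 2 regions", call. = FALSE)
  labs <- names(regions) %||%
    vapply(regions, function(r) r$site, character(1))
  out <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    d <- if (mode == "edge") {
      region_edge_distance(regions[[i]], regions[[j]])
    } else {
      cs <- rbind(region_centroid(regions[[i]]), region_centroid(regions[[j]]))
      sqrt(sum((cs[1, ] - cs[2, ])^2))
    }
    out[i, j] <- out[j, i] <- d / 1000
  }
  if (mode == "edge" && any(out[upper.tri(out)] == 0)) {
    warning("some regions overlap or touch; edge distance 0", call. = FALSE)
  }
  out
}

region_edge_distance <- function(a, b) {
  if (a$type == "disks" && b$type == "disks") {
    dmin <- Inf
    for (i in seq_len(nrow(a$centers))) {
      d <- sqrt((b$centers[, 1] - a$centers[i, 1])^2 +
                  (b$centers[, 2] - a$centers[i, 2])^2)
      dmin <- min(dmin, min(d) - a$radius - b$radius)
    }
    return(max(0, dmin))
  }
  segs_a <- region_segments(a); segs_b <- region_segments(b)
  if (a$type == "disks") return(max(0, segs_disk_dist(segs_b, a)))
  if (b$type == "disks") return(max(0, segs_disk_dist(segs_a, b)))
  # check containment: one polygon fully inside the other
  if (any(region_contains(a, segs_b$x1, segs_b$y1)) ||
      any(region_contains(b, segs_a$x1, segs_a$y1))) {
    return(0)
  }
  dmin <- Inf
  for (i in seq_len(nrow(segs_a))) {
    dmin <- min(dmin, min(segment_segment_dist(
      segs_a$x1[i], segs_a$y1[i], segs_a$x2[i], segs_a$y2[i],
      segs_b$x1, segs_b$y1, segs_b$x2, segs_b$y2)))
  }
  max(0, dmin)
}

region_segments <- function(region) {
  rings <- if (region$type == "polygon") region$rings else
    lapply(seq_len(nrow(region$centers)), function(k) {
      circle_ring(region$centers[k, ], region$radius)
    })
  purrr::map_dfr(rings, function(r) {
    n <- nrow(r)
    nxt <- c(seq_len(n)[-1], 1)
    tibble::tibble(x1 = r[, 1], y1 = r[, 2], x2 = r[nxt, 1], y2 = r[nxt, 2])
  })
}

circle_ring <- function(center, radius, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

segs_disk_dist <- function(segs, disk) {
  dmin <- Inf
  for (k in seq_len(nrow(disk$centers))) {
    d <- point_segment_dist(disk$centers[k, 1], disk$centers[k, 2],
                            segs$x1, segs$y1, segs$x2, segs$y2)
    dmin <- min(dmin, min(d) - disk$radius)
  }
  dmin
}

point_segment_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- ifelse(len2 == 0, 0, pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2)))
  sqrt((x1 + t * dx - px)^2 + (y1 + t * dy - py)^2)
}

# min distance between segment (x1,y1)-(x2,y2) and each segment in vectors
segment_segment_dist <- function(ax1, ay1, ax2, ay2, bx1, by1, bx2, by2) {
  pmin(
    point_segment_dist(ax1, ay1, bx1, by1, bx2, by2),
    point_segment_dist(ax2, ay2, bx1, by1, bx2, by2),
    point_segment_dist(bx1, by1, ax1, ay1, ax2, ay2),
    point_segment_dist(bx2, by2, ax1, ay1, ax2, ay2)
  )
}

#' Region centroid
#'
#' Area centroid; exact for single disks, grid-integrated for merged
#' disk-union parts, shoelace for polygons.
#'
#' @param region A `focal_region`.
#' @return Length-2 numeric `(x, y)` in meters.
#' @export
region_centroid <- function(region) {
  if (region$type == "polygon") {
    cs <- t(vapply(region$rings, ring_centroid_area, numeric(3)))
    w <- cs[, 3] / sum(cs[, 3])
    return(c(sum(cs[, 1] * w), sum(cs[, 2] * w)))
  }
  step <- region$radius / 64
  xr <- range(region$centers[, 1]) + c(-1, 1) * region$radius
  yr <- range(region$centers[, 2]) + c(-1, 1) * region$radius
  xs <- seq(xr[1] + step / 2, xr[2], by = step)
  ys <- seq(yr[1] + step / 2, yr[2], by = step)
  gg <- expand.grid(x = xs, y = ys)
  inside <- region_contains(region, gg$x, gg$y)
  c(mean(gg$x[inside]), mean(gg$y[inside]))
}

ring_centroid_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  cx <- sum((x + x[j]) * cr) / (6 * a)
  cy <- sum((y + y[j]) * cr) / (6 * a)
  c(cx, cy, abs(a))
}

overlapping_site_pairs <- function(regions) {
  k <- length(regions)
  out <- tibble::tibble(site_a = character(), site_b = character())
  if (k < 2) return(out)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (region_edge_distance(regions[[i]], regions[[j]]) <= 0) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        site_a = regions[[i]]$site, site_b = regions[[j]]$site))
    }
  }
  out
}

#' Rasterize focal regions to a site-ID mask
#'
#' @param regions A `focal_regions` object.
#' @param template A [scape_raster()] defining the grid.
#' @return A [scape_raster()] whose cells hold the 1-based region index, `NA`
#'   outside all regions.
#' @export
site_mask <- function(regions, template) {
  d <- dim(template$values)
  m <- matrix(NA_real_, d[1], d[2])
  idx <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  cc <- cell_center(template, idx$row, idx$col)
  for (k in seq_along(regions)) {
    hit <- region_contains(regions[[k]], cc[, 1], cc[, 2])
    cur <- m[cbind(idx$row, idx$col)]
    m[cbind(idx$row[hit], idx$col[hit])] <-
      ifelse(is.na(cur[hit]), k, cur[hit])
  }
  scape_raster(m, cellsize = template$cellsize, xll = template$xll,
               yll = template$yll)
}

#' Summarise focal regions as a tibble
#'
#' @param x A `focal_regions` object.
#' @param ... Unused.
#' @return Tibble with `site`, `n_parts`, `area_km2`.
#' @method tidy focal_regions
#' @export
tidy.focal_regions <- function(x, ...) {
  tibble::tibble(
    site = unname(vapply(x, function(r) r$site, character(1))),
    n_parts = unname(vapply(x, function(r) length(unique(r$part)), integer(1))),
    area_km2 = unname(vapply(x, function(r) r$area_m2 / 1e6, numeric(1)))
  )
}

#' @export
print.focal_regions <- function(x, ...) {
  cat("<focal_regions>\n")
  print(tidy.focal_regions(x))
  invisible(x)
}

#' Write focal regions as GeoJSON
#'
#' Disk-union regions are discretized as 64-vertex circles; the geometry is
#' a MultiPolygon per region (overlapping member disks are written as-is).
#'
#' @param regions A `focal_regions` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_geojson <- function(regions, path) {
  feats <- lapply(regions, function(rg) {
    rings <- if (rg$type == "polygon") rg$rings else
      lapply(seq_len(nrow(rg$centers)), function(k) {
        circle_ring(rg$centers[k, ], rg$radius)
      })
    polys <- lapply(rings, function(r) {
      r <- rbind(r, r[1, , drop = FALSE])
      list(lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2])))
    })
    list(type = "Feature",
         properties = list(site = rg$site, area_m2 = rg$area_m2),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection",
                            features = unname(feats)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
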