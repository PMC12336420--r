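#' Load a scenario configuration from YAML or JSON
#'
#' The file holds named [scenario_config()] arguments; `cones` may be given
#' as a list of `{x, y, peak, radius}` records.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  args <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(args$cones)) args$cones <- as.data.frame(args$cones)
  if (!is.null(args$grid)) args$grid <- as.integer(unlist(args$grid))
  do.call(scenario_config, args)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full synthetic-scenario pipeline
#'
#' Sequences every stage of the analysis on a generated scenario: landscape
#' (elevation, land cover, expert coefficient tables) -> recorders and focal
#' regions -> conductance surfaces (three sensitivity variants) -> pairwise
#' effective resistance -> repertoire generation, singleton filtering and
#' site aggregation -> Sorensen dissimilarity -> pairwise community tests ->
#' isolation-by-resistance vs. isolation-by-distance regressions. All
#' randomness derives from `config$seed`, substreamed per stage, so any
#' stage re-runs reproducibly.
#'
#' @param config A [scenario_config()].
#' @param buffer_radius_m Recorder buffer radius used to delimit focal
#'   regions (defaults to the scenario's `buffer_radius`; in the field, the
#'   species' maximum distance moved).
#' @param neighborhood Circuit neighborhood, 4 or 8.
#' @param n_perm Permutations for the community tests.
#' @param distance_mode `"edge"` or `"centroid"` (see [pairwise_distance()]).
#' @param output_dir Optional directory; when given, every artifact is
#'   written there (ESRI ASCII rasters, CSV tables and matrices, GeoJSON
#'   regions, `truth.json`, `manifest.json`).
#' @return A list of class `songscape_run` with all intermediate and final
#'   artifacts plus a `manifest` (settings, seed, content hashes).
#' @export
run_pipeline <- function(config, buffer_radius_m = config$buffer_radius,
                         neighborhood = 8, n_perm = 199,
                         distance_mode = "edge", output_dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  elevation <- run_stage("elevation", generate_elevation(config))
  landcover <- run_stage("landcover", generate_landcover(config, elevation))
  tables <- run_stage("expert_tables", generate_expert_tables(config))
  recorders <- run_stage("recorders", generate_recorders(config))
  regions <- run_stage("regions", delimit_sites(recorders, buffer_radius_m))
  distances <- run_stage("distances", pairwise_distance(regions, distance_mode))
  conductance <- run_stage("conductance", conductance_variants(
    landcover, elevation, tables$permeability, tables$malaria,
    config$species))
  resistance <- run_stage("resistance", lapply(conductance, function(cd) {
    pairwise_resistance(cd, regions, neighborhood)
  }))
  rep_data <- run_stage("repertoires",
                        generate_repertoires(config, resistance$mean))
  detections <- run_stage("filtering", filter_singletons(rep_data$detections))
  unit_matrix <- run_stage("unit_matrix", detection_matrix(detections))
  site_matrix <- run_stage("site_aggregation", aggregate_by_site(unit_matrix))
  dissim <- run_stage("dissimilarity", dissimilarity_matrix(site_matrix))
  summary_tbl <- run_stage("summary", repertoire_summary(site_matrix, dissim))
  community <- run_stage("community_tests", community_test_table(
    unit_matrix, n_perm = n_perm, seed = substream(config$seed, "community")))
  linkage <- if (choose(config$n_sites, 2) >= 3) {
    run_stage("linkage", sensitivity_suite(dissim, resistance, distances))
  } else {
    message("fewer than 3 site pairs; linkage regressions skipped")
    NULL
  }
  ordination <- run_stage("ordination", ordinate(site_matrix))

  run <- structure(
    list(config = config, elevation = elevation, landcover = landcover,
         tables = tables, recorders = recorders, regions = regions,
         distances = distances, conductance = conductance,
         resistance = resistance, repertoires = rep_data,
         detections = detections, unit_matrix = unit_matrix,
         site_matrix = site_matrix, dissimilarity = dissim,
         summary = summary_tbl, community = community, linkage = linkage,
         ordination = ordination),
    class = "songscape_run"
  )
  run$manifest <- build_manifest(run, buffer_radius_m, neighborhood, n_perm,
                                 distance_mode)
  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

build_manifest <- function(run, buffer_radius_m, neighborhood, n_perm,
                           distance_mode) {
  hashes <- lapply(
    list(elevation = run$elevation$values, landcover = run$landcover$values,
         permeability = run$tables$permeability,
         malaria = run$tables$malaria, recorders = run$recorders,
         distances = run$distances,
         resistance = lapply(run$resistance, unclass),
         detections = run$detections,
         site_matrix = unclass(run$site_matrix),
         dissimilarity = unclass(run$dissimilarity),
         community = run$community, linkage = as.data.frame(run$linkage)),
    rlang::hash)
  list(
    package_version = as.character(utils::packageVersion("songscape")),
    seed = run$config$seed,
    settings = list(
      buffer_radius_m = buffer_radius_m, neighborhood = neighborhood,
      n_perm = n_perm, distance_mode = distance_mode,
      edge_weight = "mean cell conductance (diagonal / sqrt(2))",
      coefficient_composition = "permeability * malaria survival",
      sorensen = "total site richness (classical)",
      variant_rule = "mean -/+ 1 SD, clipped to [0, 1]"
    ),
    config = unclass(run$config)[setdiff(names(unclass(run$config)), "cones")],
    hashes = hashes
  )
}

#' Write every artifact of a pipeline run to disk
#'
#' @param run A `songscape_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_ascii_grid(run$elevation, p("elevation.asc"))
  write_ascii_grid(run$landcover, p("landcover.asc"))
  for (v in names(run$conductance)) {
    write_ascii_grid(run$conductance[[v]], p(paste0("conductance_", v, ".asc")))
  }
  write.csv(run$tables$permeability, p("permeability.csv"), row.names = FALSE)
  write.csv(run$tables$malaria, p("malaria.csv"), row.names = FALSE)
  write.csv(run$recorders, p("recorders.csv"), row.names = FALSE)
  write_regions_geojson(run$regions, p("regions.geojson"))
  write.csv(as.data.frame(as.matrix(run$distances)), p("distances_km.csv"))
  for (v in names(run$resistance)) {
    write.csv(as.data.frame(as.matrix(run$resistance[[v]])),
              p(paste0("resistance_", v, ".csv")))
  }
  write.csv(run$detections, p("detections.csv"), row.names = FALSE)
  sm <- as.data.frame(unclass(run$site_matrix))
  sm <- cbind(site = rownames(run$site_matrix), sm)
  write.csv(sm, p("site_matrix.csv"), row.names = FALSE)
  write.csv(as.data.frame(unclass(run$dissimilarity)), p("dissimilarity.csv"))
  write.csv(run$summary, p("summary.csv"), row.names = FALSE)
  write.csv(run$community, p("community_tests.csv"), row.names = FALSE)
  if (!is.null(run$linkage)) {
    write.csv(as.data.frame(run$linkage), p("linkage.csv"), row.names = FALSE)
  }
  truth <- run$repertoires$truth
  jsonlite::write_json(
    list(resistance = unname(as.matrix(truth$resistance)),
         correlation = unname(truth$correlation),
         expected_sorensen = unname(truth$expected_sorensen),
         decay = truth$decay, occupancy = truth$occupancy),
    p("truth.json"), digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(run$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @export
print.songscape_run <- function(x, ...) {
  cat("<songscape_run> seed", x$config$seed, "\n")
  cat("  sites:", x$config$n_sites, " recorders/site:",
      x$config$recorders_per_site, "\n")
  cat("  repertoire summary:\n")
  print(x$summary)
  cat("  linkage (sensitivity suite):\n")
  print(x$linkage)
  invisible(x)
}
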