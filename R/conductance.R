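#' Sensitivity variant of an elicited coefficient
#'
#' The sensitivity analysis runs the connectivity model three times: with the
#' panel mean of each coefficient, and with the mean minus / plus one
#' standard deviation, clipped to the valid `[0, 1]` range.
#'
#' @param mean Panel mean coefficient(s) in `[0, 1]` (vectorized).
#' @param sd Panel standard deviation(s), `>= 0`.
#' @param which One of `"mean"`, `"min"`, `"max"`.
#' @return Coefficient(s) in `[0, 1]`.
#' @examples
#' coefficient_variant(0.5, 0.2, "min") # 0.3
#' coefficient_variant(0.8, 0.3, "max") # 1 (clipped)
#' @export
coefficient_variant <- function(mean, sd, which = c("mean", "min", "max")) {
  which <- match.arg(which)
  if (any(mean < 0 | mean > 1, na.rm = TRUE)) {
    stop("coefficient means must lie in [0, 1]", call. = FALSE)
  }
  if (any(sd < 0, na.rm = TRUE)) stop("coefficient SDs must be >= 0", call. = FALSE)
  out <- switch(which,
                mean = mean,
                min = mean - sd,
                max = mean + sd)
  pmin(1, pmax(0, out))
}

#' Malaria-risk elevation band
#'
#' Hawaiian forest birds face avian malaria year-round below 900 m, only in
#' the warm season between 900 and 1500 m, and essentially not at all above
#' 1500 m. Band boundaries are `[0, 900)` year-round, `[900, 1500]` seasonal
#' and `(1500, Inf)` absent.
#'
#' @param elevation_m Elevation(s) in meters, `>= 0`.
#' @return Character vector in `{"year_round", "seasonal", "absent"}` (`NA`
#'   passes through).
#' @export
malaria_band <- function(elevation_m) {
  if (any(elevation_m < 0, na.rm = TRUE)) {
    stop("elevation must be >= 0", call. = FALSE)
  }
  out <- ifelse(elevation_m < 900, "year_round",
                ifelse(elevation_m <= 1500, "seasonal", "absent"))
  out[is.na(elevation_m)] <- NA_character_
  out
}

#' Build a species conductance raster
#'
#' Each cell's conductance is the product of the land-cover permeability
#' coefficient and the malaria survival coefficient of the cell's elevation
#' band, both taken at the requested sensitivity variant. Both coefficients
#' are `[0, 1]` survival-like probabilities, so the product keeps the
#' annihilator semantics: an impermeable cover or total malaria mortality
#' zeroes the cell. Nodata in either input propagates.
#'
#' @param landcover Integer-class land-cover [scape_raster()].
#' @param elevation Elevation [scape_raster()], aligned with `landcover`.
#' @param permeability Tibble with columns `species`, `class`, `mean`, `sd`.
#' @param malaria Tibble with columns `species`, `band`, `mean`, `sd`
#'   (bands `year_round`, `seasonal`, `absent`).
#' @param species Species to look up in the tables.
#' @param variant `"mean"`, `"min"` or `"max"` (see [coefficient_variant()]).
#' @return A conductance [scape_raster()] with values in `[0, 1]`.
#' @export
build_conductance <- function(landcover, elevation, permeability, malaria,
                              species, variant = c("mean", "min", "max")) {
  variant <- match.arg(variant)
  assert_aligned(landcover, elevation)
  perm <- dplyr::filter(tibble::as_tibble(permeability),
                        .data$species == !!species)
  mal <- dplyr::filter(tibble::as_tibble(malaria), .data$species == !!species)
  if (nrow(perm) == 0 || nrow(mal) == 0) {
    stop("no coefficient rows for species '", species, "'", call. = FALSE)
  }
  bands <- c("year_round", "seasonal", "absent")
  if (!setequal(mal$band, bands)) {
    stop("malaria table must have exactly the bands ",
         paste(bands, collapse = ", "), call. = FALSE)
  }
  cls <- as.vector(landcover$values)
  seen <- unique(cls[!is.na(cls)])
  missing_cls <- setdiff(seen, perm$class)
  if (length(missing_cls) > 0) {
    stop("land-cover class code(s) without a permeability row: ",
         paste(sort(missing_cls), collapse = ", "), call. = FALSE)
  }
  perm_coef <- setNames(coefficient_variant(perm$mean, perm$sd, variant),
                        perm$class)
  mal_coef <- setNames(coefficient_variant(mal$mean, mal$sd, variant),
                       mal$band)
  band <- malaria_band(as.vector(elevation$values))
  cond <- unname(perm_coef[as.character(cls)]) * unname(mal_coef[band])
  m <- matrix(cond, nrow = nrow(landcover$values))
  scape_raster(m, cellsize = landcover$cellsize,
               xll = landcover$xll, yll = landcover$yll)
}

#' Conductance rasters for all three sensitivity variants
#'
#' @inheritParams build_conductance
#' @return Named list of [scape_raster()] objects (`mean`, `min`, `max`).
#' @export
conductance_variants <- function(landcover, elevation, permeability, malaria,
                                 species) {
  vs <- c("mean", "min", "max")
  setNames(lapply(vs, function(v) {
    build_conductance(landcover, elevation, permeability, malaria, species, v)
  }), vs)
}
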