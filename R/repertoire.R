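#' Drop study-wide singleton syllables
#'
#' Syllables detected exactly once across the entire study (total detection
#' count 1, summed over all recorders) are removed; such one-off detections
#' are as likely to be classification noise as real repertoire elements.
#'
#' @param detections Tibble with columns `recorder`, `site`, `syllable`,
#'   `count` (positive integers).
#' @return The filtered detection tibble.
#' @export
filter_singletons <- function(detections) {
  detections <- tibble::as_tibble(detections)
  stopifnot(all(c("recorder", "site", "syllable", "count") %in%
                  names(detections)))
  if (any(detections$count < 1 | detections$count != round(detections$count))) {
    stop("detection counts must be positive integers", call. = FALSE)
  }
  totals <- dplyr::summarise(dplyr::group_by(detections, .data$syllable),
                             total = sum(.data$count), .groups = "drop")
  keep <- totals$syllable[totals$total >= 2]
  dplyr::filter(detections, .data$syllable %in% keep)
}

#' Detection table to binary recorder-level syllable matrix
#'
#' @param detections Tibble with `recorder`, `site`, `syllable`, `count`.
#' @return Binary matrix (rows = recorders, columns = syllables) with a
#'   `site` attribute giving each row's site, level tag `"unit"`.
#' @export
detection_matrix <- function(detections) {
  detections <- tibble::as_tibble(detections)
  recs <- unique(detections[, c("recorder", "site")])
  if (anyDuplicated(recs$recorder)) {
    stop("a recorder is assigned to more than one site", call. = FALSE)
  }
  syls <- sort(unique(detections$syllable))
  m <- matrix(0L, nrow(recs), length(syls),
              dimnames = list(recs$recorder, syls))
  m[cbind(match(detections$recorder, recs$recorder),
          match(detections$syllable, syls))] <- 1L
  structure(m, site = recs$site, level = "unit")
}

#' Aggregate a recorder-level matrix to site presence/absence
#'
#' Site presence is the logical OR over the site's recorders. Syllables
#' absent everywhere after aggregation are dropped with a warning.
#'
#' @param unit_matrix Binary recorder x syllable matrix with a `site`
#'   attribute (see [detection_matrix()]).
#' @return Binary site x syllable matrix, level tag `"site"`.
#' @export
aggregate_by_site <- function(unit_matrix) {
  site <- attr(unit_matrix, "site")
  if (is.null(site)) stop("`unit_matrix` lacks a `site` attribute", call. = FALSE)
  sites <- unique(site)
  m <- do.call(rbind, lapply(sites, function(s) {
    as.integer(colSums(unit_matrix[site == s, , drop = FALSE]) > 0)
  }))
  dimnames(m) <- list(sites, colnames(unit_matrix))
  empty <- colSums(m) == 0
  if (any(empty)) {
    warning(sum(empty), " syllable(s) absent from every site dropped",
            call. = FALSE)
    m <- m[, !empty, drop = FALSE]
  }
  structure(m, level = "site")
}

#' Sorensen dissimilarity between two repertoires
#'
#' `D = (S_k + S_l - 2J) / (S_k + S_l)`, where `S_k`, `S_l` are the total
#' syllable richness of the two sites and `J` the number of shared
#' syllables: 0 for identical repertoires, 1 for fully disjoint ones.
#' `literal_exclusive = TRUE` instead plugs the per-site *exclusive* counts
#' into the same expression (a non-standard reading kept for comparison; it
#' can leave `[0, 1]`).
#'
#' @param set_k,set_l Character vectors of syllable ids (or logical/0-1
#'   vectors over a common pool).
#' @param literal_exclusive Use exclusive counts instead of total richness.
#' @return Dissimilarity value.
#' @examples
#' sorensen_pair(c("a", "b", "c"), c("a", "b", "d", "e", "f")) # J=2 -> 0.5
#' @export
sorensen_pair <- function(set_k, set_l, literal_exclusive = FALSE) {
  if (!is.character(set_k)) set_k <- which(as.logical(set_k))
  if (!is.character(set_l)) set_l <- which(as.logical(set_l))
  sk <- length(unique(set_k)); sl <- length(unique(set_l))
  if (sk + sl == 0) {
    stop("both repertoires are empty; dissimilarity undefined", call. = FALSE)
  }
  j <- length(intersect(set_k, set_l))
  if (literal_exclusive) {
    ek <- sk - j; el <- sl - j
    return((ek + el - 2 * j) / (ek + el))
  }
  (sk + sl - 2 * j) / (sk + sl)
}

#' Pairwise Sorensen dissimilarity matrix
#'
#' @param site_matrix Binary site x syllable matrix (see
#'   [aggregate_by_site()]).
#' @return Symmetric matrix of class `dissimilarity_matrix` with attribute
#'   `average` = mean of the off-diagonal upper triangle.
#' @export
dissimilarity_matrix <- function(site_matrix) {
  n <- nrow(site_matrix)
  labs <- rownames(site_matrix) %||% paste0("site_", seq_len(n))
  out <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    out[i, j] <- out[j, i] <- sorensen_pair(site_matrix[i, ] > 0,
                                            site_matrix[j, ] > 0)
  }
  structure(out, average = mean(out[upper.tri(out)]),
            class = c("dissimilarity_matrix", "matrix", "array"))
}

#' Repertoire summary
#'
#' The per-species summary row of the study: total distinct syllables,
#' per-site richness range, count and percentage of syllables exclusive to a
#' single site (percentage to 1 decimal), and average pairwise
#' dissimilarity.
#'
#' @param site_matrix Binary site x syllable matrix.
#' @param dissim Optional [dissimilarity_matrix()] (computed if missing).
#' @return One-row tibble.
#' @export
repertoire_summary <- function(site_matrix, dissim = NULL) {
  if (is.null(dissim)) dissim <- dissimilarity_matrix(site_matrix)
  occ <- colSums(site_matrix > 0)
  total <- sum(occ > 0)
  exclusive <- sum(occ == 1)
  rich <- rowSums(site_matrix > 0)
  tibble::tibble(
    n_sites = nrow(site_matrix),
    total_syllables = total,
    richness_min = min(rich),
    richness_max = max(rich),
    exclusive = exclusive,
    exclusive_pct = exclusive_percentage(exclusive, total),
    average_dissimilarity = attr(dissim, "average")
  )
}

#' Percentage of exclusive syllables, rounded half-up to one decimal
#'
#' @param exclusive Number of syllables found at exactly one site.
#' @param total Total number of distinct syllables.
#' @return Percentage with one decimal (e.g. 35 of 52 -> 67.3).
#' @export
exclusive_percentage <- function(exclusive, total) {
  stopifnot(total > 0, exclusive >= 0, exclusive <= total)
  floor(1000 * exclusive / total + 0.5) / 10
}
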