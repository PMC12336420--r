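#' Per-syllable binomial deviance between two groups of recorders
#'
#' Likelihood-ratio statistic comparing a Bernoulli occurrence model with
#' group-specific probabilities against a pooled one, computed in closed
#' form from the 2x2 occurrence table (`0 * log 0 = 0`). This is the
#' single-syllable building block of the multivariate repertoire comparison:
#' one GLM per syllable, group as the only predictor.
#'
#' @param presence_a,presence_b Binary vectors: the syllable's detection
#'   indicator across the recorders of each group.
#' @return Deviance (`>= 0`).
#' @examples
#' syllable_deviance(c(1, 1, 1, 1), c(0, 0, 0, 0)) # 16 log 2
#' @export
syllable_deviance <- function(presence_a, presence_b) {
  ka <- sum(presence_a > 0); na <- length(presence_a)
  kb <- sum(presence_b > 0); nb <- length(presence_b)
  if (na == 0 || nb == 0) stop("both groups must be non-empty", call. = FALSE)
  binom_ll(ka, na) + binom_ll(kb, nb) - binom_ll(ka + kb, na + nb)
}

# 2 * maximized Bernoulli log-likelihood of k successes in n trials
binom_ll <- function(k, n) {
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  2 * (xlogx(k) + xlogx(n - k) - xlogx(n))
}

# total deviance over all syllable columns, vectorized over permutations:
# `lab` is a logical vector (TRUE = group a) over rows of `m`
community_stat <- function(m, lab) {
  na <- sum(lab); nb <- sum(!lab)
  ka <- colSums(m[lab, , drop = FALSE] > 0)
  kb <- colSums(m[!lab, , drop = FALSE] > 0)
  sum(binom_ll(ka, na) + binom_ll(kb, nb) - binom_ll(ka + kb, na + nb))
}

#' Permutation test of repertoire composition between two site groups
#'
#' Test statistic: the sum over syllables of the per-syllable binomial
#' deviance (see [syllable_deviance()]). The null distribution is built by
#' permuting recorder-to-group labels; the p-value uses the add-one
#' convention `p = (1 + #{perm >= obs}) / (1 + n_perm)`, so it is never 0.
#'
#' @param units_a,units_b Binary recorder x syllable matrices over the same
#'   syllable columns (>= 2 rows each).
#' @param n_perm Number of label permutations (>= 99).
#' @param seed Integer seed for the permutation stream.
#' @return One-row tibble of class `community_test`: `statistic`, `p_value`,
#'   `n_perm`, `seed`, `n_units_a`, `n_units_b`.
#' @export
pairwise_community_test <- function(units_a, units_b, n_perm = 999,
                                    seed = 1L) {
  units_a <- as.matrix(units_a); units_b <- as.matrix(units_b)
  if (nrow(units_a) < 2 || nrow(units_b) < 2) {
    stop("need at least 2 sampling units per group", call. = FALSE)
  }
  if (ncol(units_a) != ncol(units_b)) {
    stop("groups must share the same syllable columns", call. = FALSE)
  }
  if (n_perm < 99) stop("`n_perm` must be >= 99", call. = FALSE)
  m <- rbind(units_a, units_b)
  lab <- rep(c(TRUE, FALSE), c(nrow(units_a), nrow(units_b)))
  obs <- community_stat(m, lab)
  old <- set_local_seed(substream(seed, "community"))
  on.exit(restore_seed(old))
  n <- nrow(m)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    if (community_stat(m, lab[perm]) >= obs - 1e-12) exceed <- exceed + 1L
  }
  structure(
    tibble::tibble(statistic = obs,
                   p_value = (1 + exceed) / (1 + n_perm),
                   n_perm = as.integer(n_perm), seed = as.integer(seed),
                   n_units_a = nrow(units_a), n_units_b = nrow(units_b)),
    class = c("community_test", class(tibble::tibble()))
  )
}

#' All pairwise community tests among sites
#'
#' @param unit_matrix Binary recorder x syllable matrix with `site`
#'   attribute (see [detection_matrix()]).
#' @param n_perm,seed Passed to [pairwise_community_test()].
#' @return Tibble with one row per unordered site pair.
#' @export
community_test_table <- function(unit_matrix, n_perm = 999, seed = 1L) {
  site <- attr(unit_matrix, "site")
  sites <- unique(site)
  purrr::map_dfr(utils::combn(seq_along(sites), 2, simplify = FALSE),
                 function(pr) {
    res <- pairwise_community_test(
      unit_matrix[site == sites[pr[1]], , drop = FALSE],
      unit_matrix[site == sites[pr[2]], , drop = FALSE],
      n_perm = n_perm, seed = seed + pr[1] * 131L + pr[2])
    dplyr::bind_cols(tibble::tibble(site_a = sites[pr[1]],
                                    site_b = sites[pr[2]]), res)
  })
}

#' Principal-component ordination of site repertoires
#'
#' Column-centered PCA of the binary site x syllable matrix (no scaling):
#' sites close in the ordination share syllables.
#'
#' @param site_matrix Binary site x syllable matrix.
#' @return Object of class `repertoire_ordination`: `scores` tibble (site +
#'   axes), `variance_explained` (per-axis proportions), the `prcomp` fit.
#' @export
ordinate <- function(site_matrix) {
  m <- as.matrix(site_matrix)
  fit <- prcomp(m, center = TRUE, scale. = FALSE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- tibble::as_tibble(fit$x, .name_repair = "minimal")
  scores <- dplyr::bind_cols(
    tibble::tibble(site = rownames(m) %||% paste0("site_", seq_len(nrow(m)))),
    scores)
  structure(list(scores = scores, variance_explained = ve, fit = fit),
            class = "repertoire_ordination")
}

#' @export
print.repertoire_ordination <- function(x, ...) {
  cat("<repertoire_ordination>\n")
  ve <- x$variance_explained
  cat(sprintf("  axis 1: %.1f%%  axis 2: %.1f%% of variance\n",
              100 * ve[1], if (length(ve) > 1) 100 * ve[2] else 0))
  invisible(x)
}

#' @rdname ordinate
#' @param x A `repertoire_ordination`.
#' @param ... Unused.
#' @method tidy repertoire_ordination
#' @export
tidy.repertoire_ordination <- function(x, ...) x$scores

#' @rdname ordinate
#' @param object A `repertoire_ordination`.
#' @param ... Unused.
#' @method autoplot repertoire_ordination
#' @export
autoplot.repertoire_ordination <- function(object, ...) {
  ve <- object$variance_explained
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               label = .data$site)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ve[2])
    ) +
    ggplot2::theme_minimal()
}
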