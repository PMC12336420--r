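#' Gaussian one-predictor regression of beta-diversity on a pairwise predictor
#'
#' Ordinary least squares with intercept (the Gaussian identity-link GLM),
#' implemented in closed form from the normal equations; the slope is tested
#' two-sided against zero with a t statistic on `n - 2` degrees of freedom.
#' Non-finite predictor values (disconnected pairs with infinite resistance)
#' are dropped with a warning; the number of pairs actually used is
#' reported.
#'
#' @param dissim_pairs Numeric vector of pairwise dissimilarities (response).
#' @param predictor_pairs Numeric vector of pairwise resistance or distance
#'   values, same length and pair order.
#' @param predictor Label stored with the fit (`"resistance"`,
#'   `"distance"`, ...).
#' @param variant Sensitivity-variant label stored with the fit.
#' @return Object of class `linkage_fit` with `slope`, `intercept`,
#'   `p_value`, `r_squared`, `n_pairs`, standard errors and the data used.
#' @examples
#' fit_linkage(0.1 + 0.02 * (1:5), 1:5) # slope 0.02, R^2 = 1
#' @export
fit_linkage <- function(dissim_pairs, predictor_pairs,
                        predictor = "resistance", variant = "mean") {
  stopifnot(length(dissim_pairs) == length(predictor_pairs))
  ok <- is.finite(predictor_pairs) & is.finite(dissim_pairs)
  if (any(!ok)) {
    warning(sum(!ok), " pair(s) with non-finite values dropped", call. = FALSE)
  }
  y <- dissim_pairs[ok]; x <- predictor_pairs[ok]
  n <- length(y)
  if (n < 3) stop("need at least 3 finite pairs", call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("predictor has zero variance", call. = FALSE)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - 2)
  se_slope <- sqrt(sigma2 / sxx)
  se_int <- sqrt(sigma2 * (1 / n + mean(x)^2 / sxx))
  tstat <- if (se_slope > 0) slope / se_slope else Inf * sign(slope)
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  structure(
    list(predictor = predictor, variant = variant, slope = slope,
         intercept = intercept, se_slope = se_slope, se_intercept = se_int,
         t_statistic = tstat, p_value = p, r_squared = r2,
         n_pairs = n, n_dropped = sum(!ok),
         data = tibble::tibble(predictor_value = x, dissimilarity = y)),
    class = "linkage_fit"
  )
}

#' @export
print.linkage_fit <- function(x, ...) {
  cat(sprintf(
    "<linkage_fit> dissimilarity ~ %s (%s variant)\n  slope %.4g (p = %.3g), R^2 = %.3f, n = %d pairs\n",
    x$predictor, x$variant, x$slope, x$p_value, x$r_squared, x$n_pairs))
  invisible(x)
}

#' Broom-style accessors for linkage fits
#'
#' @param x,object A `linkage_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient; `glance()`: one-row model
#'   summary (`r_squared`, `p_value`, `n_pairs`, labels).
#' @method tidy linkage_fit
#' @export
tidy.linkage_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$predictor),
    estimate = c(x$intercept, x$slope),
    std_error = c(x$se_intercept, x$se_slope),
    statistic = c(x$intercept / x$se_intercept, x$t_statistic),
    p_value = c(2 * pt(abs(x$intercept / x$se_intercept),
                       df = x$n_pairs - 2, lower.tail = FALSE), x$p_value)
  )
}

#' @rdname tidy.linkage_fit
#' @method glance linkage_fit
#' @export
glance.linkage_fit <- function(x, ...) {
  tibble::tibble(predictor = x$predictor, variant = x$variant,
                 slope = x$slope, p_value = x$p_value,
                 r_squared = x$r_squared, n_pairs = x$n_pairs)
}

#' @rdname tidy.linkage_fit
#' @method autoplot linkage_fit
#' @export
autoplot.linkage_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$predictor_value,
                               y = .data$dissimilarity)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         color = "steelblue") +
    ggplot2::labs(
      x = object$predictor,
      y = "Sorensen dissimilarity",
      subtitle = sprintf("slope %.3g, p = %.3g, R² = %.2f",
                         object$slope, object$p_value, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Mantel-style permutation p-value for a linkage fit
#'
#' Permutes site identities (rows/columns of both matrices jointly for the
#' response) and refits, respecting the non-independence of the
#' `choose(n, 2)` pairs. A robustness diagnostic complementing the
#' parametric t test; not part of the headline analysis.
#'
#' @param dissim Site x site dissimilarity matrix.
#' @param predictor_m Site x site predictor matrix.
#' @param n_perm Number of site-identity permutations.
#' @param seed Integer seed.
#' @return Two-sided permutation p-value for the slope.
#' @export
mantel_p <- function(dissim, predictor_m, n_perm = 999, seed = 1L) {
  dissim <- as.matrix(dissim); predictor_m <- as.matrix(predictor_m)
  n <- nrow(dissim)
  ut <- upper.tri(dissim)
  obs <- fit_linkage(dissim[ut], predictor_m[ut])$slope
  old <- set_local_seed(substream(seed, "misc"))
  on.exit(restore_seed(old))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    s <- fit_linkage(dissim[p, p][ut], predictor_m[ut])$slope
    if (abs(s) >= abs(obs) - 1e-15) exceed <- exceed + 1L
  }
  (1 + exceed) / (1 + n_perm)
}

#' Sensitivity suite: beta-diversity against every predictor variant
#'
#' Fits the dissimilarity ~ resistance regression for each conductance
#' sensitivity variant (`mean`, `min`, `max`) and the dissimilarity ~
#' distance regression, and flags whether the significance conclusion for
#' resistance is stable across variants.
#'
#' @param dissim Site x site [dissimilarity_matrix()].
#' @param resistances Named list of resistance matrices (any subset of
#'   `mean`, `min`, `max`).
#' @param distances Site x site geographic distance matrix (km), or `NULL`.
#' @param alpha Significance level for the concordance flag.
#' @return Tibble with one row per predictor x variant (`slope`, `p_value`,
#'   `r_squared`, `n_pairs`, `significant`) and attribute
#'   `concordant` (logical).
#' @export
sensitivity_suite <- function(dissim, resistances, distances = NULL,
                              alpha = 0.05) {
  ut <- upper.tri(as.matrix(dissim))
  d <- as.matrix(dissim)[ut]
  rows <- purrr::map_dfr(names(resistances), function(v) {
    glance(fit_linkage(d, as.matrix(resistances[[v]])[ut],
                       predictor = "resistance", variant = v))
  })
  if (!is.null(distances)) {
    rows <- dplyr::bind_rows(
      rows,
      glance(fit_linkage(d, as.matrix(distances)[ut],
                         predictor = "distance", variant = "n/a")))
  }
  rows <- dplyr::mutate(rows, significant = .data$p_value < alpha)
  res_sig <- rows$significant[rows$predictor == "resistance"]
  attr(rows, "concordant") <- length(unique(res_sig)) <= 1
  rows
}
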