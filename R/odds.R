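#' Odds ratios of class membership by covariate
#'
#' Exponentiates the (pooled) covariate coefficients of the membership model
#' into odds ratios of being in each non-reference class versus the
#' reference (healthy-type) class, with Wald 95% confidence intervals
#' `exp(beta +/- 1.96 sqrt(T))` from the total (Rubin) variances.
#'
#' @param pooled An `lca_pooled` (uses its total-variance matrix `T`) or an
#'   `lca_fit` (then `covariance` must be given).
#' @param covariance Optional covariance matrix of the structural
#'   coefficients overriding the one in `pooled`, e.g. from
#'   [cluster_robust_covariance()].
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with one row per (contrast, class[, group]):
#'   `contrast`, `class`, `group`, `log_or`, `or`, `conf_low`, `conf_high`,
#'   `has_ci`. Missing variances leave the interval `NA` with
#'   `has_ci = FALSE`.
#' @export
odds_ratio_table <- function(pooled, covariance = NULL, conf_level = 0.95) {
  if (inherits(pooled, "lca_pooled")) {
    spec <- pooled$spec
    theta <- pooled$theta
    V <- covariance %||% pooled$T
    params <- pooled$params
  } else if (inherits(pooled, "lca_fit")) {
    spec <- pooled$spec
    theta <- structural_vector(pooled$params, spec)
    V <- covariance
    params <- pooled$params
  } else {
    abort_config("pass an lca_pooled or lca_fit")
  }
  b <- params$beta
  db <- dim(b)
  nr <- nonref_classes(spec)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  na <- length(params$alpha)
  rows <- list()
  k <- 0L
  for (idx in seq_along(nr)) {
    for (p in seq_len(db[2])) {
      for (g in seq_len(db[1])) {
        k <- k + 1L
        # index of beta[g, p, idx] in the structural vector
        pos <- na + (idx - 1L) * db[1] * db[2] + (p - 1L) * db[1] + g
        est <- b[g, p, idx]
        tv <- if (is.null(V)) NA_real_ else V[pos, pos]
        has_ci <- is.finite(tv)
        rows[[k]] <- tibble::tibble(
          contrast = spec$dummies[p],
          class = nr[idx],
          group = if (db[1] > 1L) g else NA_integer_,
          log_or = est,
          or = exp(est),
          conf_low = if (has_ci) exp(est - z * sqrt(tv)) else NA_real_,
          conf_high = if (has_ci) exp(est + z * sqrt(tv)) else NA_real_,
          has_ci = has_ci
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
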