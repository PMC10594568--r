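#' Pool aligned fits across multiply imputed datasets
#'
#' Conditional response probabilities are pooled by arithmetic mean and each
#' simplex renormalised. The structural coefficients (membership intercepts
#' and covariate effects) are pooled by Rubin's rules: point estimate = mean
#' across imputations; within-imputation variance W = mean of the supplied
#' covariance matrices; between-imputation variance B = sample covariance of
#' the per-imputation estimates; total variance T = W + (1 + 1/m) B.
#'
#' All fits must share the same specification and be aligned to the first
#' (see [align_to_reference()]); a warning is raised when a fit's CRPs sit
#' far from the first fit's, which usually means alignment was skipped.
#'
#' @param fits List of `lca_fit` objects, one per imputed dataset.
#' @param covariances Optional list of covariance matrices of the structural
#'   coefficients (e.g. from [cluster_robust_covariance()]), same length as
#'   `fits`. Without them W (and hence T) is `NA`.
#' @param alignment_warn_threshold Mean absolute CRP distance per cell above
#'   which the unaligned-input warning fires.
#' @return An `lca_pooled`: pooled `params`, structural estimates `theta`,
#'   matrices `W`, `B`, `T`, and `m`.
#' @export
pool_mi_fits <- function(fits, covariances = NULL, alignment_warn_threshold = 0.25) {
  stopifnot(length(fits) >= 1)
  spec <- fits[[1]]$spec
  cb <- fits[[1]]$codebook
  m <- length(fits)
  for (f in fits[-1]) {
    if (!identical(f$spec[c("K", "constraint", "covariate_effects", "G")],
                   spec[c("K", "constraint", "covariate_effects", "G")])) {
      abort_config("all fits must share the same spec")
    }
  }
  if (m > 1) {
    ncell <- sum(vapply(fits[[1]]$params$rho, length, 0))
    for (f in fits[-1]) {
      d <- class_distance_matrix(fits[[1]]$params, f$params, spec$indicators)
      if (min(diag(d)) / (ncell / spec$K) > alignment_warn_threshold) {
        rlang::warn("fits appear unaligned; run align_to_reference() before pooling",
                    class = "lcat_unaligned")
        break
      }
    }
  }
  rho <- fits[[1]]$params$rho
  for (j in spec$indicators) {
    arr <- Reduce(`+`, lapply(fits, function(f) f$params$rho[[j]])) / m
    s <- apply(arr, c(1, 2), sum)
    rho[[j]] <- sweep(arr, c(1, 2), s, "/")
  }
  thetas <- vapply(fits, function(f) structural_vector(f$params, spec),
                   structural_vector(fits[[1]]$params, spec))
  thetas <- matrix(thetas, ncol = m,
                   dimnames = list(names(structural_vector(fits[[1]]$params, spec)), NULL))
  point <- rowMeans(thetas)
  d <- length(point)
  W <- if (is.null(covariances)) matrix(NA_real_, d, d) else {
    stopifnot(length(covariances) == m)
    Reduce(`+`, covariances) / m
  }
  if (m >= 2) {
    B <- stats::cov(t(thetas))
    Tt <- W + (1 + 1 / m) * B
  } else {
    rlang::warn("m = 1: between-imputation variance undefined; T = W",
                class = "lcat_single_imputation")
    B <- matrix(NA_real_, d, d)
    Tt <- W
  }
  dimnames(W) <- dimnames(B) <- dimnames(Tt) <- list(names(point), names(point))
  pooled_params <- set_structural_vector(new_params(spec, rho,
                                                    fits[[1]]$params$alpha,
                                                    fits[[1]]$params$beta),
                                         spec, point)
  structure(list(
    spec = spec, codebook = cb, params = pooled_params, theta = point,
    W = W, B = B, T = Tt, m = m,
    group_levels = fits[[1]]$group_levels
  ), class = "lca_pooled")
}

#' @export
print.lca_pooled <- function(x, ...) {
  cat("<lca_pooled> K=", x$spec$K, ", pooled over m=", x$m, " imputations\n", sep = "")
  invisible(x)
}
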