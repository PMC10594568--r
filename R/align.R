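# Label-switching repair: class labels in a mixture are arbitrary, so fits
# from different starts or imputations must be permuted onto a common
# labelling before parameters can be compared or averaged.

# total absolute CRP distance between class `a` of `ref` and class `b` of `fit`
class_distance_matrix <- function(ref, fit_params, indicators) {
  K <- dim(ref$rho[[indicators[1]]])[2]
  D <- matrix(0, K, K)
  for (j in indicators) {
    ra <- ref$rho[[j]]; rb <- fit_params$rho[[j]]
    for (a in seq_len(K)) for (b in seq_len(K)) {
      D[a, b] <- D[a, b] + sum(abs(ra[, a, ] - rb[, b, ]))
    }
  }
  D
}

all_permutations <- function(K) {
  if (K == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(K)) {
    for (p in all_permutations(K - 1L)) {
      q <- integer(K); q[1] <- i; q[-1] <- setdiff(seq_len(K), i)[p]
      out[[length(out) + 1L]] <- q
    }
  }
  out
}

#' Align a fit's class labels to a reference parameter set
#'
#' Finds the class permutation minimising the total absolute difference
#' between the fit's conditional response probabilities and the reference's
#' (assignment over all `K!` permutations; ties broken toward the lowest
#' class indices). The relabelled fit has an identical log-likelihood.
#'
#' @param reference An `lca_params` (e.g. generator truth, or the first
#'   imputation's fit parameters).
#' @param fit An `lca_fit` (or bare `lca_params` with `spec` supplied).
#' @param spec Required when `fit` is a bare parameter set.
#' @return The input with classes permuted; for an `lca_fit` the
#'   chosen permutation is attached as attribute `"permutation"` (new class
#'   `c` is old class `perm[c]`).
#' @export
align_to_reference <- function(reference, fit, spec = NULL) {
  is_fit <- inherits(fit, "lca_fit")
  params <- if (is_fit) fit$params else fit
  if (is_fit) spec <- fit$spec
  if (is.null(spec)) abort_config("supply `spec` when aligning a bare parameter set")
  j1 <- spec$indicators[1]
  if (!identical(dim(reference$rho[[j1]]), dim(params$rho[[j1]]))) {
    abort_config("reference and fit parameter shapes differ")
  }
  D <- class_distance_matrix(reference, params, spec$indicators)
  K <- spec$K
  best_perm <- seq_len(K); best_cost <- Inf
  for (p in all_permutations(K)) {
    cost <- sum(D[cbind(seq_len(K), p)])
    if (cost < best_cost - 1e-12) { best_cost <- cost; best_perm <- p }
  }
  out_params <- permute_classes(params, best_perm, spec)
  if (!is_fit) return(out_params)
  fit$params <- out_params
  attr(fit, "permutation") <- best_perm
  fit
}
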