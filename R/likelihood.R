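# Observed-data weighted log-pseudo-likelihood and posterior class
# probabilities. Missing indicator entries are dropped from the likelihood
# product (full-information handling under MAR); missing covariates are not
# allowed here — they must be multiply imputed upstream.

# n x K matrix of membership logits (reference class column = 0)
membership_eta <- function(params, spec, enc) {
  n <- enc$n; K <- spec$K
  eta <- matrix(0, n, K)
  if (K == 1L) return(eta)
  p_x <- length(spec$dummies)
  if (p_x > 0 && anyNA(enc$Xcov)) {
    rlang::abort("missing covariate values present; run impute_covariates() first",
                 class = "lcat_missing_covariate")
  }
  ga <- if (n_groups_alpha(spec) == 1L) rep(1L, n) else enc$group
  gb <- if (n_groups_beta(spec) == 1L) rep(1L, n) else enc$group
  nr <- nonref_classes(spec)
  for (idx in seq_along(nr)) {
    e <- params$alpha[cbind(ga, idx)]
    if (p_x > 0) {
      B <- params$beta[, , idx, drop = FALSE]
      dim(B) <- dim(params$beta)[1:2]
      e <- e + rowSums(enc$Xcov * B[gb, , drop = FALSE])
    }
    eta[, nr[idx]] <- e
  }
  eta
}

# Per-indicator linear-index cache into the rho arrays: for each indicator,
# the rows where it is observed and an (n_obs x K) matrix of linear indices
# into the (G_rho, K, m_j) array. Depends only on (data, spec shape), so it
# is built once per fit and reused every E-step.
make_mcache <- function(enc, spec) {
  n <- enc$n; K <- spec$K
  if (any(rowSums(!is.na(enc$Y)) == 0)) {
    rlang::abort("row(s) with all indicators missing", class = "lcat_all_missing")
  }
  G_rho <- n_groups_rho(spec)
  gr <- if (G_rho == 1L) rep(1L, n) else enc$group
  lapply(spec$indicators, function(j) {
    y <- enc$Y[, j]
    obs <- which(!is.na(y))
    base <- gr[obs] + (y[obs] - 1L) * (G_rho * K)
    lin <- matrix(0L, length(obs), K)
    for (c in seq_len(K)) lin[, c] <- base + (c - 1L) * G_rho
    # cell index (group, category) used by the M-step cross-tabs
    m_j <- spec$ncat[[j]]
    list(obs = obs, lin = lin, cell = (gr[obs] - 1L) * m_j + y[obs])
  }) |> stats::setNames(spec$indicators)
}

# n x K matrix of per-row log measurement probabilities given class
log_measurement <- function(params, spec, enc, mcache = NULL) {
  if (is.null(mcache)) mcache <- make_mcache(enc, spec)
  lm_ <- matrix(0, enc$n, spec$K)
  for (j in spec$indicators) {
    mc <- mcache[[j]]
    lr <- log(params$rho[[j]])
    v <- lr[as.vector(mc$lin)]   # vector indexing (a matrix index would be
    dim(v) <- dim(mc$lin)        # read as array coordinates)
    lm_[mc$obs, ] <- lm_[mc$obs, ] + v
  }
  lm_
}

# internal: per-row log-likelihood vector (unweighted)
row_loglik <- function(params, spec, enc, mcache = NULL) {
  ll <- membership_eta(params, spec, enc)
  lp <- ll - row_logsumexp(ll)          # log membership probabilities
  row_logsumexp(lp + log_measurement(params, spec, enc, mcache))
}

posterior_matrix <- function(params, spec, enc, mcache = NULL) {
  eta <- membership_eta(params, spec, enc)
  lp <- eta - row_logsumexp(eta)
  joint <- lp + log_measurement(params, spec, enc, mcache)
  softmax_rows(joint)
}

#' Weighted observed-data log-likelihood of a multi-group latent class model
#'
#' Computes \eqn{\sum_i w_i \log \sum_c \pi_c(x_i, g_i) \prod_j
#' \rho_{j g_i c y_{ij}}}{sum_i w_i log sum_c pi_c prod_j rho} over the
#' observed indicator entries, where the membership probabilities
#' \eqn{\pi_c} come from a multinomial logit on the covariate dummies with
#' group-specific intercepts. Weights are normalised to mean 1 so that
#' likelihoods (and the adjusted BIC) are comparable across specifications.
#'
#' @param data Dataset tibble (see [read_lca_data()]).
#' @param cb A [codebook()].
#' @param spec An [lca_spec()].
#' @param params An `lca_params` parameter set.
#' @param normalise_weights Rescale weights to mean 1 (the default used
#'   throughout fitting); set `FALSE` for raw-weight likelihoods, e.g. to
#'   compare against a row-expanded dataset.
#' @return A single number (nats).
#' @export
observed_loglik <- function(data, cb, spec, params, normalise_weights = TRUE) {
  enc <- encode_lca_data(data, cb, normalise_weights = normalise_weights)
  sum(enc$w * row_loglik(params, spec, enc))
}

#' Posterior class membership probabilities
#'
#' E-step quantity: `p[i, c]` proportional to the membership probability
#' times the conditional response probabilities of row `i`'s observed
#' indicators, normalised across classes.
#'
#' @inheritParams observed_loglik
#' @return A tibble with one row per data row and columns `class_1` ...
#'   `class_K`; each row sums to 1.
#' @export
posterior_probabilities <- function(data, cb, spec, params) {
  enc <- encode_lca_data(data, cb)
  p <- posterior_matrix(params, spec, enc)
  colnames(p) <- paste0("class_", seq_len(spec$K))
  tibble::as_tibble(p)
}
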