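#' Cluster-robust covariance of the structural coefficients
#'
#' Survey-weighted pseudo-likelihood sandwich \eqn{A^{-1} B A^{-1}}
#' restricted to the membership model's intercepts and covariate
#' coefficients, with the conditional response probabilities held at their
#' estimates. `A` is the negative numerical Hessian of the weighted
#' observed-data log-likelihood; `B` sums the outer products of per-cluster
#' score totals (cluster = primary sampling unit, e.g. school), so the
#' variance respects both the weights and the within-school correlation.
#' Derivatives use central differences with step `1e-5` per coefficient.
#' When every row is its own cluster this reduces to the ordinary
#' heteroskedasticity-robust sandwich.
#'
#' @param fit A converged `lca_fit`.
#' @param data The dataset the fit used.
#' @param cb Codebook; defaults to the one stored in `fit`.
#' @param step Central-difference step.
#' @return Symmetric PSD covariance matrix named like
#'   `structural_vector()` entries (`alpha[g,c]`, `beta[g,dummy,c]`).
#' @export
cluster_robust_covariance <- function(fit, data, cb = fit$codebook, step = 1e-5) {
  spec <- fit$spec
  enc <- encode_lca_data(data, cb)
  if (length(unique(enc$cluster)) < 2) {
    rlang::abort("need at least 2 clusters for cluster-robust variance",
                 class = "lcat_too_few_clusters")
  }
  theta0 <- structural_vector(fit$params, spec)
  d <- length(theta0)
  mcache <- make_mcache(enc, spec)
  lm_fixed <- log_measurement(fit$params, spec, enc, mcache)  # rho held fixed
  rl_at <- function(theta) {
    p <- set_structural_vector(fit$params, spec, theta)
    eta <- membership_eta(p, spec, enc)
    lp <- eta - row_logsumexp(eta)
    row_logsumexp(lp + lm_fixed)
  }
  # per-row numerical scores (n x d), weighted
  S <- matrix(0, enc$n, d)
  for (k in seq_len(d)) {
    tp <- theta0; tp[k] <- tp[k] + step
    tm <- theta0; tm[k] <- tm[k] - step
    S[, k] <- enc$w * (rl_at(tp) - rl_at(tm)) / (2 * step)
  }
  Sc <- rowsum(S, enc$cluster)
  B <- crossprod(Sc)
  # negative numerical Hessian of the total weighted log-likelihood
  L_at <- function(theta) sum(enc$w * rl_at(theta))
  A <- matrix(0, d, d)
  L0 <- L_at(theta0)
  for (k in seq_len(d)) {
    ek <- theta0; ek[k] <- ek[k] + step
    mk <- theta0; mk[k] <- mk[k] - step
    A[k, k] <- -(L_at(ek) - 2 * L0 + L_at(mk)) / step^2
    if (k < d) for (l in seq((k + 1L), d)) {
      pp <- theta0; pp[k] <- pp[k] + step; pp[l] <- pp[l] + step
      pm <- theta0; pm[k] <- pm[k] + step; pm[l] <- pm[l] - step
      mp <- theta0; mp[k] <- mp[k] - step; mp[l] <- mp[l] + step
      mm <- theta0; mm[k] <- mm[k] - step; mm[l] <- mm[l] - step
      A[k, l] <- A[l, k] <- -(L_at(pp) - L_at(pm) - L_at(mp) + L_at(mm)) / (4 * step^2)
    }
  }
  Ainv <- tryCatch(solve(A), error = function(e) {
    rlang::warn("singular Hessian; using pseudo-inverse", class = "lcat_singular_hessian")
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-10
    sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  })
  V <- Ainv %*% B %*% t(Ainv)
  V <- (V + t(V)) / 2
  dimnames(V) <- list(names(theta0), names(theta0))
  V
}
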