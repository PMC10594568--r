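# EM machinery: M-step, random initialisation, single-start fitter.
#
# The M-step for (alpha, beta) is a weighted multinomial logit of the
# posterior class probabilities on the membership design (group intercepts
# plus covariate dummies, with group interactions under by_group effects),
# run for a few damped Newton iterations from the current values. Partial
# inner maximisation still increases the EM minorant (generalized EM), so
# the observed-data likelihood is monotone up to the rho smoothing floor.

DEGENERATE_TOL <- 1e-6

# design matrix for the structural model; column layout matches
# c(alpha[, idx], as.vector(beta[, , idx])) per non-reference class
make_structural_design <- function(spec, enc) {
  n <- enc$n
  Za <- if (n_groups_alpha(spec) == 1L) matrix(1, n, 1L) else {
    Z <- matrix(0, n, spec$G)
    Z[cbind(seq_len(n), enc$group)] <- 1
    Z
  }
  p_x <- length(spec$dummies)
  if (p_x == 0L) return(Za)
  if (n_groups_beta(spec) == 1L) {
    Zb <- enc$Xcov
  } else {
    Zb <- matrix(0, n, p_x * spec$G)
    k <- 0L
    for (p in seq_len(p_x)) {
      for (g in seq_len(spec$G)) {
        k <- k + 1L
        Zb[, k] <- enc$Xcov[, p] * (enc$group == g)
      }
    }
  }
  cbind(Za, Zb)
}

params_to_theta <- function(params, spec) {
  K <- spec$K
  if (K == 1L) return(matrix(0, 0, 0))
  d <- nrow(params$alpha) + length(params$beta[, , 1])
  matrix(vapply(seq_len(K - 1L),
                function(idx) c(params$alpha[, idx], as.vector(params$beta[, , idx])),
                numeric(d)),
         nrow = d)
}

theta_to_params <- function(theta, params, spec) {
  ga <- n_groups_alpha(spec)
  for (idx in seq_len(spec$K - 1L)) {
    params$alpha[, idx] <- theta[seq_len(ga), idx]
    if (length(spec$dummies)) params$beta[, , idx] <- theta[-seq_len(ga), idx]
  }
  params
}

# weighted fractional-response multinomial logit objective
struct_objective <- function(theta, Z, P, w, spec) {
  eta <- matrix(0, nrow(Z), spec$K)
  eta[, nonref_classes(spec)] <- Z %*% theta
  lp <- eta - row_logsumexp(eta)
  sum(w * rowSums(P * lp))
}

# a few safeguarded Newton steps on (alpha, beta), warm-started at `theta`
newton_struct <- function(theta, Z, P, w, spec, n_iter = 5L, ridge = 1e-8) {
  Km1 <- spec$K - 1L
  d <- nrow(theta)
  nr <- nonref_classes(spec)
  obj <- struct_objective(theta, Z, P, w, spec)
  for (it in seq_len(n_iter)) {
    eta <- matrix(0, nrow(Z), spec$K)
    eta[, nr] <- Z %*% theta
    Pi <- softmax_rows(eta)
    grad <- matrix(0, d, Km1)
    H <- matrix(0, d * Km1, d * Km1)
    for (a in seq_len(Km1)) {
      grad[, a] <- crossprod(Z, w * (P[, nr[a]] - Pi[, nr[a]]))
      for (b in seq_len(a)) {
        wab <- w * Pi[, nr[a]] * ((a == b) - Pi[, nr[b]])
        Hab <- crossprod(Z, Z * wab)
        ia <- (a - 1L) * d + seq_len(d); ib <- (b - 1L) * d + seq_len(d)
        H[ia, ib] <- Hab
        if (a != b) H[ib, ia] <- t(Hab)
      }
    }
    step <- tryCatch(solve(H + diag(ridge, d * Km1), as.vector(grad)),
                     error = function(e) as.vector(grad) / max(diag(H), 1))
    step <- matrix(step, d, Km1)
    lambda <- 1
    repeat {
      cand <- theta + lambda * step
      cand_obj <- struct_objective(cand, Z, P, w, spec)
      if (is.finite(cand_obj) && cand_obj >= obj - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-6) { cand <- theta; cand_obj <- obj; break }
    }
    if (abs(cand_obj - obj) < 1e-12 * (abs(obj) + 1)) { theta <- cand; break }
    theta <- cand; obj <- cand_obj
  }
  theta
}

# internal M-step on encoded data
m_step <- function(P, enc, spec, current, Z = NULL, mcache = NULL) {
  wP <- enc$w * P
  cls_mass <- colSums(wP)
  if (any(cls_mass < DEGENERATE_TOL)) {
    bad <- which(cls_mass < DEGENERATE_TOL)[1]
    rlang::abort(paste0("class ", bad, " has (near-)zero posterior mass"),
                 class = "lcat_degenerate_class", class_index = bad)
  }
  if (is.null(mcache)) mcache <- make_mcache(enc, spec)
  G_rho <- n_groups_rho(spec)
  rho <- current$rho
  for (j in spec$indicators) {
    mc <- mcache[[j]]
    m_j <- spec$ncat[[j]]
    num <- rowsum(wP[mc$obs, , drop = FALSE], mc$cell)   # (cells present) x K
    full <- matrix(0, G_rho * m_j, spec$K)
    full[as.integer(rownames(num)), ] <- num
    arr <- array(0, c(G_rho, spec$K, m_j))
    # row block for group g holds its m_j category rows
    for (g in seq_len(G_rho)) for (m in seq_len(m_j)) arr[g, , m] <- full[(g - 1L) * m_j + m, ]
    rho[[j]] <- clip_rho(arr)
  }
  params <- new_params(spec, rho, current$alpha, current$beta)
  if (spec$K > 1L) {
    if (is.null(Z)) Z <- make_structural_design(spec, enc)
    theta <- newton_struct(params_to_theta(current, spec), Z, P, enc$w, spec)
    params <- theta_to_params(theta, params, spec)
  }
  params
}

#' One M-step update of the model parameters
#'
#' Given posterior class probabilities, re-estimates the conditional response
#' probabilities as posterior-weighted category frequencies (pooled across
#' groups under the semi/fully constrained regimes, then clipped to the
#' smoothing floor and renormalised) and updates the membership intercepts
#' and covariate coefficients by a warm-started damped-Newton multinomial
#' logit on the posteriors.
#'
#' @param posteriors Tibble or matrix of posterior probabilities
#'   (rows x classes), e.g. from [posterior_probabilities()].
#' @inheritParams observed_loglik
#' @param current Current `lca_params` (Newton warm start).
#' @return An updated `lca_params`.
#' @export
update_parameters <- function(posteriors, data, cb, spec, current) {
  P <- as.matrix(posteriors)
  enc <- encode_lca_data(data, cb)
  stopifnot(nrow(P) == enc$n, ncol(P) == spec$K)
  m_step(P, enc, spec, current)
}

#' Draw a random starting parameter set
#'
#' Each conditional-response simplex is drawn uniformly (flat Dirichlet);
#' membership intercepts and covariate coefficients are drawn uniformly on
#' (-1, 1). The same seed always reproduces the same start.
#'
#' @inheritParams n_free_parameters
#' @param seed Integer seed for this start.
#' @return An `lca_params`.
#' @export
random_initial_params <- function(spec, cb, seed) {
  with_seed(seed, {
    rho <- list()
    for (j in spec$indicators) {
      m_j <- spec$ncat[[j]]
      arr <- array(stats::rgamma(n_groups_rho(spec) * spec$K * m_j, shape = 1),
                   c(n_groups_rho(spec), spec$K, m_j))
      rho[[j]] <- clip_rho(arr)
    }
    if (spec$K > 1L) {
      alpha <- matrix(stats::runif(n_groups_alpha(spec) * (spec$K - 1L), -1, 1),
                      n_groups_alpha(spec), spec$K - 1L)
      beta <- array(stats::runif(n_groups_beta(spec) * length(spec$dummies) * (spec$K - 1L), -1, 1),
                    c(n_groups_beta(spec), length(spec$dummies), spec$K - 1L))
      new_params(spec, rho, alpha, beta)
    } else new_params(spec, rho)
  })
}

# internal EM loop on encoded data; `state` carries reusable caches
fit_em <- function(enc, spec, init, tol = 1e-7, max_iter = 2000L, state = NULL) {
  if (is.null(state)) state <- em_state(enc, spec)
  params <- init
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  trace <- numeric(0)
  repeat {
    it <- it + 1L
    eta <- membership_eta(params, spec, enc)
    lp <- eta - row_logsumexp(eta)
    joint <- lp + log_measurement(params, spec, enc, state$mcache)
    rl <- row_logsumexp(joint)
    ll <- sum(enc$w * rl)
    trace[it] <- ll
    P <- exp(joint - rl)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    if (it > max_iter) break
    params <- m_step(P, enc, spec, params, state$Z, state$mcache)
    ll_old <- ll
  }
  list(params = params, loglik = ll, n_iter = it, converged = converged,
       loglik_trace = trace)
}

em_state <- function(enc, spec) {
  list(Z = if (spec$K > 1L) make_structural_design(spec, enc) else NULL,
       mcache = make_mcache(enc, spec))
}

new_lca_fit <- function(spec, cb, params, loglik, n_iter, converged, enc) {
  structure(list(
    spec = spec, codebook = cb, params = params, loglik = loglik,
    n_iter = n_iter, converged = converged,
    n_free_params = n_free_parameters(spec, cb),
    n_effective = sum(enc$w), group_levels = enc$group_levels
  ), class = "lca_fit")
}

#' Fit the model by EM from one starting point
#'
#' Alternates the posterior (E) step and the parameter (M) step until the
#' relative change in the weighted observed-data log-likelihood falls below
#' `tol` or `max_iter` is reached. The reported log-likelihood is evaluated
#' at the returned parameters.
#'
#' @inheritParams observed_loglik
#' @param init Starting `lca_params`, e.g. [random_initial_params()].
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @return An `lca_fit` object: `spec`, `params`, `loglik`, `n_iter`,
#'   `converged`, `n_free_params`, `n_effective`.
#' @export
fit_single_start <- function(data, cb, spec, init, tol = 1e-7, max_iter = 2000L) {
  enc <- encode_lca_data(data, cb)
  if (spec$G != length(enc$group_levels)) {
    abort_config(paste0("spec has G=", spec$G, " but data has ",
                        length(enc$group_levels), " groups"))
  }
  res <- fit_em(enc, spec, init, tol, max_iter)
  fit <- new_lca_fit(spec, cb, res$params, res$loglik, res$n_iter, res$converged, enc)
  fit$loglik_trace <- res$loglik_trace
  fit
}

#' @export
print.lca_fit <- function(x, ...) {
  cat("<lca_fit> K=", x$spec$K, " (", x$spec$constraint, ", ",
      x$spec$covariate_effects, " effects), loglik=", format(x$loglik),
      ", ", x$n_iter, " EM iterations",
      if (!x$converged) " [not converged]", "\n", sep = "")
  invisible(x)
}
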