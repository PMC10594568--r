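#' Multistart EM estimation
#'
#' Runs EM from `n_starts` random initialisations and returns the best
#' solution. Start seeds derive from the single master `seed` through a
#' stream split, so results do not depend on execution order. By default the
#' search is two-stage in the style of mainstream mixture software: every
#' start gets a short EM burn-in (`burn_in` iterations), then the
#' `refine_top` most promising starts are run to full convergence. Setting
#' `refine_top = n_starts` runs every start to convergence (single-stage).
#'
#' The replication count — how many fully converged starts land within
#' `1e-4` of the best log-likelihood — is the usual local-maximum
#' diagnostic; a warning is raised when the best solution was not replicated.
#'
#' In multi-group models with group-specific response probabilities, random
#' starts often converge to local maxima in which class labels "cross"
#' between groups. With `anchor = TRUE` (default) the search therefore adds
#' a constraint-ladder warm start: the next more constrained regime
#' (unconstrained is anchored by semi, semi by fully) is itself fitted by
#' multistart, its solution expanded to the current regime's shape and
#' refined alongside the top random starts. This also guarantees that the
#' best log-likelihoods respect the nesting fully <= semi <= unconstrained.
#'
#' @inheritParams fit_single_start
#' @param n_starts Number of random starts.
#' @param seed Master seed.
#' @param burn_in Burn-in EM iterations for stage one.
#' @param refine_top Number of top starts refined to convergence.
#' @param anchor Add the constraint-ladder warm start (see Details).
#' @return An `lca_multistart`: `best` (an `lca_fit`), `logliks` (sorted,
#'   refined starts), `all_logliks` (burn-in values, all starts),
#'   `replication` count, `n_failed`, `seed`.
#' @export
fit_multistart <- function(data, cb, spec, n_starts = 1000L, seed = 1L,
                           tol = 1e-7, max_iter = 2000L,
                           burn_in = 25L, refine_top = 5L, anchor = TRUE) {
  enc <- encode_lca_data(data, cb)
  if (spec$G != length(enc$group_levels)) {
    abort_config(paste0("spec has G=", spec$G, " but data has ",
                        length(enc$group_levels), " groups"))
  }
  start_seeds <- split_seeds(seed, n_starts)
  refine_top <- min(refine_top, n_starts)
  state <- em_state(enc, spec)
  stage1 <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    init <- random_initial_params(spec, cb, start_seeds[s])
    stage1[[s]] <- tryCatch(
      fit_em(enc, spec, init, tol, max_iter = min(burn_in, max_iter), state = state),
      lcat_degenerate_class = function(e) NULL)
  }
  ok <- which(!vapply(stage1, is.null, TRUE))
  if (!length(ok)) rlang::abort("all starts failed", class = "lcat_estimation_failure")
  ll1 <- vapply(stage1[ok], function(r) r$loglik, 0)
  top <- ok[order(ll1, decreasing = TRUE)][seq_len(min(refine_top, length(ok)))]
  inits <- lapply(stage1[top], function(r) r$params)
  if (anchor) {
    parent <- anchor_init(data, cb, spec, n_starts, seed, tol, max_iter,
                          burn_in, refine_top)
    if (!is.null(parent)) inits <- c(inits, list(parent))
  }
  refined <- vector("list", length(inits))
  for (t in seq_along(inits)) {
    refined[[t]] <- tryCatch(
      fit_em(enc, spec, inits[[t]], tol, max_iter, state = state),
      lcat_degenerate_class = function(e) NULL)
  }
  rok <- which(!vapply(refined, is.null, TRUE))
  if (!length(rok)) rlang::abort("all refined starts failed", class = "lcat_estimation_failure")
  llr <- vapply(refined[rok], function(r) r$loglik, 0)
  bi <- rok[which.max(llr)]
  best <- refined[[bi]]
  replication <- sum(llr >= max(llr) - 1e-4)
  if (replication < 2) {
    rlang::warn("best log-likelihood was not replicated across starts; increase n_starts",
                class = "lcat_no_replication")
  }
  structure(list(
    best = new_lca_fit(spec, cb, best$params, best$loglik, best$n_iter,
                       best$converged, enc),
    logliks = sort(llr, decreasing = TRUE),
    all_logliks = sort(ll1, decreasing = TRUE),
    replication = replication,
    n_failed = (n_starts - length(ok)) + (length(inits) - length(rok)),
    seed = seed
  ), class = "lca_multistart")
}

# warm-start parameters from the next more constrained regime, expanded to
# the current regime's shape; NULL when no anchor applies
anchor_init <- function(data, cb, spec, n_starts, seed, tol, max_iter,
                        burn_in, refine_top) {
  if (spec$K == 1L || spec$G == 1L) return(NULL)
  parent_constraint <- switch(spec$constraint,
                              unconstrained = "semi", semi = "fully", NULL)
  if (is.null(parent_constraint)) return(NULL)
  pspec <- lca_spec(cb, spec$K, parent_constraint, spec$covariate_effects,
                    G = spec$G, reference_class = spec$reference_class)
  pms <- tryCatch(
    suppressWarnings(fit_multistart(data, cb, pspec, n_starts, seed, tol,
                                    max_iter, burn_in, refine_top, anchor = TRUE)),
    lcat_estimation_failure = function(e) NULL)
  if (is.null(pms)) return(NULL)
  p <- pms$best$params
  rho <- if (n_groups_rho(spec) > n_groups_rho(pspec)) {
    lapply(p$rho, function(a) {
      out <- array(0, c(spec$G, dim(a)[2], dim(a)[3]))
      for (g in seq_len(spec$G)) out[g, , ] <- a[1, , ]
      out
    })
  } else p$rho
  alpha <- if (n_groups_alpha(spec) > n_groups_alpha(pspec)) {
    matrix(rep(p$alpha[1, ], each = spec$G), spec$G, spec$K - 1L)
  } else p$alpha
  new_params(spec, rho, alpha, p$beta)
}

#' @export
print.lca_multistart <- function(x, ...) {
  cat("<lca_multistart> best loglik ", format(x$best$loglik),
      ", replicated ", x$replication, "x, ", x$n_failed, " failed starts\n", sep = "")
  invisible(x)
}

#' Sample-size-adjusted BIC
#'
#' \eqn{-2\ell + p \log((n^* + 2)/24)} with \eqn{n^*} the effective sample
#' size (sum of normalised weights) — the Sclove adjustment used for latent
#' class enumeration.
#'
#' @param loglik Log-likelihood (nats).
#' @param n_free_params Free parameter count, see [n_free_parameters()].
#' @param n_effective Effective sample size (> 0).
#' @return The adjusted BIC (smaller is better).
#' @examples
#' adjusted_bic(-1000, 10, 1000)  # 2037.317
#' @export
adjusted_bic <- function(loglik, n_free_params, n_effective) {
  stopifnot(n_effective > 0)
  -2 * loglik + n_free_params * log((n_effective + 2) / 24)
}

selection_row <- function(label, spec, ms, cb) {
  tibble::tibble(
    label = label, K = spec$K, constraint = spec$constraint,
    covariate_effects = spec$covariate_effects,
    loglik = ms$best$loglik, n_free_params = ms$best$n_free_params,
    abic = adjusted_bic(ms$best$loglik, ms$best$n_free_params, ms$best$n_effective),
    replication = ms$replication
  )
}

finish_selection <- function(rows, fits) {
  tab <- dplyr::bind_rows(rows)
  sel <- rep(FALSE, nrow(tab))
  ok <- which(!is.na(tab$abic))
  if (length(ok)) sel[ok[which.min(tab$abic[ok])]] <- TRUE   # ties: first (smallest K) wins
  tab$selected <- sel
  attr(tab, "fits") <- fits
  class(tab) <- c("lca_selection", class(tab))
  tab
}

#' Scan over class counts with the adjusted BIC
#'
#' Fits the model for each `K` in `k_range` by [fit_multistart()] and
#' tabulates log-likelihood, free-parameter count and adjusted BIC; the row
#' with the smallest aBIC is flagged (`selected`), ties going to the
#' smallest K. Estimation failures become `NA` rows rather than aborting the
#' scan. The fitted `lca_multistart` objects are attached as the `"fits"`
#' attribute.
#'
#' @inheritParams fit_multistart
#' @param k_range Integer vector of class counts to try.
#' @param constraint,covariate_effects Passed to [lca_spec()].
#' @return An `lca_selection` tibble.
#' @export
scan_classes <- function(data, cb, k_range, n_starts = 100L, seed = 1L,
                         constraint = "unconstrained",
                         covariate_effects = "constant", ...) {
  stopifnot(length(k_range) > 0)
  enc <- encode_lca_data(data, cb)
  G <- length(enc$group_levels)
  seeds <- split_seeds(seed, length(k_range))
  rows <- list(); fits <- list()
  for (i in seq_along(k_range)) {
    K <- k_range[i]
    spec <- lca_spec(cb, K, constraint, covariate_effects, G = G)
    ms <- tryCatch(
      suppressWarnings(fit_multistart(data, cb, spec, n_starts, seeds[i], ...)),
      lcat_estimation_failure = function(e) NULL)
    lbl <- paste0("K=", K)
    if (is.null(ms)) {
      rows[[i]] <- tibble::tibble(label = lbl, K = K, constraint = constraint,
                                  covariate_effects = covariate_effects,
                                  loglik = NA_real_, n_free_params = NA_integer_,
                                  abic = NA_real_, replication = NA_integer_)
    } else {
      rows[[i]] <- selection_row(lbl, spec, ms, cb)
      fits[[lbl]] <- ms
    }
  }
  finish_selection(rows, fits)
}

#' Compare measurement-invariance regimes at a fixed class count
#'
#' Fits the three constraint regimes (unconstrained / semi / fully, with
#' covariate effects held constant across groups), then refits the
#' aBIC-best of those with group-varying covariate effects, and flags the
#' overall aBIC minimum — the model-specification ladder used for multi-group
#' LCA invariance testing.
#'
#' @inheritParams scan_classes
#' @param K Class count (>= 2).
#' @return An `lca_selection` tibble with four rows.
#' @export
scan_constraints <- function(data, cb, K, n_starts = 100L, seed = 1L, ...) {
  stopifnot(K >= 2)
  enc <- encode_lca_data(data, cb)
  G <- length(enc$group_levels)
  regimes <- c("unconstrained", "semi", "fully")
  seeds <- split_seeds(seed, length(regimes) + 1L)
  rows <- list(); fits <- list()
  for (i in seq_along(regimes)) {
    spec <- lca_spec(cb, K, regimes[i], "constant", G = G)
    ms <- tryCatch(
      suppressWarnings(fit_multistart(data, cb, spec, n_starts, seeds[i], ...)),
      lcat_estimation_failure = function(e) NULL)
    lbl <- paste0(regimes[i], "/constant")
    if (is.null(ms)) {
      rows[[i]] <- tibble::tibble(label = lbl, K = K, constraint = regimes[i],
                                  covariate_effects = "constant",
                                  loglik = NA_real_, n_free_params = NA_integer_,
                                  abic = NA_real_, replication = NA_integer_)
    } else {
      rows[[i]] <- selection_row(lbl, spec, ms, cb)
      fits[[lbl]] <- ms
    }
  }
  tab3 <- dplyr::bind_rows(rows)
  best_regime <- regimes[which.min(tab3$abic)]
  spec4 <- lca_spec(cb, K, best_regime, "by_group", G = G)
  ms4 <- tryCatch(
    suppressWarnings(fit_multistart(data, cb, spec4, n_starts, seeds[4], ...)),
    lcat_estimation_failure = function(e) NULL)
  lbl4 <- paste0(best_regime, "/by_group")
  rows[[4]] <- if (is.null(ms4)) {
    tibble::tibble(label = lbl4, K = K, constraint = best_regime,
                   covariate_effects = "by_group", loglik = NA_real_,
                   n_free_params = NA_integer_, abic = NA_real_,
                   replication = NA_integer_)
  } else {
    fits[[lbl4]] <- ms4
    selection_row(lbl4, spec4, ms4, cb)
  }
  finish_selection(rows, fits)
}
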