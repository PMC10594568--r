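#' Multiply impute missing covariate values
#'
#' Chained-equation multiple imputation of the categorical covariates (e.g.
#' sex and family affluence), using all health/wellbeing indicators plus the
#' other covariate as predictors. Missing cells are initialised by
#' survey-weighted marginal draws; each cycle refits, per covariate, a
#' multinomial (or binomial) logit on a bootstrap resample of the rows where
#' that covariate is observed — the bootstrap propagates parameter
#' uncertainty, approximating proper imputation — and redraws the missing
#' cells from the predicted category probabilities. Indicators enter as
#' dummies with an extra "missing" level, so incomplete indicators never
#' block the imputation model. Indicator cells are never touched, and the
#' survey weights are not used in the imputation models themselves.
#'
#' @param data Dataset tibble with (possibly) missing covariate cells.
#' @param cb A [codebook()].
#' @param m Number of imputed datasets (full survey-scale default 50).
#' @param cycles Chained-equation cycles per imputation.
#' @param seed Master seed; each imputation runs on its own seed stream.
#' @return An `lca_imputation`: `datasets` (list of m completed tibbles),
#'   `m`, `cycles`, `seed`, `missing_counts` (per variable, pre-imputation).
#' @export
impute_covariates <- function(data, cb, m = 50L, cycles = 10L, seed = 1L) {
  m <- as.integer(m)
  if (m < 1L) abort_config("m must be >= 1")
  if (m < 2L) rlang::warn("m < 2: Rubin between-imputation variance is undefined",
                          class = "lcat_small_m")
  covs <- covariate_names(cb)
  missing_counts <- vapply(cb$name, function(v) sum(is.na(data[[v]])), 0L)
  for (cv in covs) {
    if (all(is.na(data[[cv]]))) {
      rlang::abort(paste0("covariate ", cv, " has no complete cases; cannot impute"),
                   class = "lcat_unimputable")
    }
  }
  need <- covs[vapply(covs, function(cv) anyNA(data[[cv]]), TRUE)]
  if (!length(need)) {
    return(structure(list(datasets = replicate(m, data, simplify = FALSE),
                          m = m, cycles = cycles, seed = seed,
                          missing_counts = missing_counts),
                     class = "lca_imputation"))
  }
  # fixed predictor block: indicator dummies with an explicit missing level
  inds <- indicator_names(cb)
  Dind <- do.call(cbind, lapply(inds, function(j) {
    cats <- indicator_categories(cb, j)
    v <- data[[j]]
    cols <- vapply(c(cats[-1], NA), function(l) {
      if (is.na(l)) as.numeric(is.na(v)) else as.numeric(!is.na(v) & v == l)
    }, numeric(nrow(data)))
    colnames(cols) <- paste0(j, ".", c(cats[-1], "missing"))
    cols
  }))
  wn <- weight_name(cb)
  w <- if (is.null(wn)) rep(1, nrow(data)) else data[[wn]]
  seeds <- split_seeds(seed, m)
  datasets <- vector("list", m)
  for (i in seq_len(m)) {
    datasets[[i]] <- with_seed(seeds[i], impute_once(data, cb, covs, need, Dind, w, cycles))
  }
  structure(list(datasets = datasets, m = m, cycles = cycles, seed = seed,
                 missing_counts = missing_counts),
            class = "lca_imputation")
}

# one chained-equation pass (runs inside its own seeded RNG stream)
impute_once <- function(data, cb, covs, need, Dind, w, cycles) {
  cur <- data
  for (cv in need) {
    cats <- indicator_categories(cb, cv)
    obs <- !is.na(data[[cv]])
    marg <- vapply(cats, function(l) sum(w[obs & data[[cv]] == l]), 0)
    miss <- which(!obs)
    cur[[cv]][miss] <- sample(cats, length(miss), replace = TRUE, prob = marg / sum(marg))
  }
  for (cy in seq_len(cycles)) {
    for (cv in need) {
      cats <- indicator_categories(cb, cv)
      obs <- which(!is.na(data[[cv]]))
      miss <- which(is.na(data[[cv]]))
      others <- setdiff(covs, cv)
      Doth <- if (length(others)) do.call(cbind, lapply(others, function(o) {
        oc <- indicator_categories(cb, o)
        cols <- vapply(oc[-1], function(l) as.numeric(cur[[o]] == l), numeric(nrow(cur)))
        colnames(cols) <- paste0(o, ".", oc[-1])
        cols
      })) else NULL
      X <- cbind(Dind, Doth)
      y <- factor(data[[cv]][obs], levels = cats)
      # bootstrap resample of the observed rows; keep every response level
      boot <- NULL
      for (try in 1:20) {
        cand <- sample(obs, length(obs), replace = TRUE)
        if (all(cats %in% data[[cv]][cand])) { boot <- cand; break }
      }
      if (is.null(boot)) boot <- obs
      yb <- factor(data[[cv]][boot], levels = cats)
      pm <- fit_and_predict(X[boot, , drop = FALSE], yb, X[miss, , drop = FALSE], cats)
      u <- stats::runif(length(miss))
      cum <- t(apply(pm, 1, cumsum))
      cur[[cv]][miss] <- cats[rowSums(u > cum) + 1L]
    }
  }
  cur
}

# binomial logit for 2 categories, multinomial otherwise; returns a
# (rows x categories) probability matrix for `Xnew`
fit_and_predict <- function(X, y, Xnew, cats) {
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  X <- X[, keep, drop = FALSE]; Xnew <- Xnew[, keep, drop = FALSE]
  if (length(cats) == 2L) {
    fit <- suppressWarnings(stats::glm.fit(cbind(1, X), as.numeric(y == cats[2]),
                                           family = stats::binomial()))
    cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    p2 <- stats::plogis(drop(cbind(1, Xnew) %*% cf))
    cbind(1 - p2, p2)
  } else {
    df <- data.frame(.y = y, X, check.names = TRUE)
    nd <- data.frame(Xnew, check.names = TRUE)
    colnames(nd) <- colnames(df)[-1]
    fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 200, MaxNWts = 5000)
    pm <- stats::predict(fit, newdata = nd, type = "probs")
    if (is.null(dim(pm))) pm <- matrix(pm, nrow = 1)
    # multinom drops empty levels only if present; map back to full set
    cn <- colnames(pm) %||% cats
    out <- matrix(0, nrow(Xnew), length(cats), dimnames = list(NULL, cats))
    out[, cn] <- pm
    out
  }
}

#' @export
print.lca_imputation <- function(x, ...) {
  cat("<lca_imputation> m=", x$m, " completed datasets (", x$cycles,
      " cycles, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Write an imputation set to disk
#'
#' One CSV per completed dataset (`_imp001.csv`, ...) plus a manifest JSON
#' recording seed, m, cycles and the pre-imputation missing counts.
#'
#' @param imp An `lca_imputation`.
#' @param dir Output directory.
#' @param stem File-name stem.
#' @return `dir`, invisibly.
#' @export
write_imputation <- function(imp, dir, stem = "dataset") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(imp$m)) {
    write_lca_data(imp$datasets[[i]],
                   file.path(dir, sprintf("%s_imp%03d.csv", stem, i)))
  }
  jsonlite::write_json(list(seed = imp$seed, m = imp$m, cycles = imp$cycles,
                            missing_counts = as.list(imp$missing_counts)),
                       file.path(dir, paste0(stem, "_imputation_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
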