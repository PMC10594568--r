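# Synthetic cohort generation from a known multi-group LCA truth.

# enumerate the joint covariate cells: returns list(prob, X) with one row
# per cell of the covariate cross-classification
covariate_cells <- function(cb, marginals) {
  covs <- covariate_names(cb)
  if (!length(covs)) {
    return(list(cells = data.frame(row.names = 1), prob = 1,
                X = matrix(0, 1, 0)))
  }
  grids <- lapply(covs, function(cv) indicator_categories(cb, cv))
  cells <- expand.grid(grids, stringsAsFactors = FALSE)
  names(cells) <- covs
  prob <- rep(1, nrow(cells))
  for (cv in covs) prob <- prob * marginals[[cv]][cells[[cv]]]
  dn <- covariate_dummy_names(cb)
  X <- matrix(0, nrow(cells), length(dn), dimnames = list(NULL, dn))
  k <- 0L
  for (cv in covs) {
    lv <- setdiff(indicator_categories(cb, cv), covariate_reference(cb, cv))
    for (l in lv) { k <- k + 1L; X[, k] <- as.numeric(cells[[cv]] == l) }
  }
  list(cells = cells, prob = unname(prob), X = X)
}

# solve group intercepts so the covariate-averaged membership equals the
# target marginal (iterative proportional fitting on the logit scale)
calibrate_intercepts <- function(target, beta, cells, max_iter = 200L, tol = 1e-12) {
  K <- length(target)
  eta_x <- cells$X %*% beta                  # cells x (K-1)
  alpha <- log(target[-K] / target[K])
  for (it in seq_len(max_iter)) {
    eta <- cbind(sweep(eta_x, 2, alpha, "+"), 0)
    pim <- softmax_rows(eta)
    marg <- colSums(cells$prob * pim)
    if (max(abs(marg - target)) < tol) break
    alpha <- alpha + (log(target[-K] / marg[-K]) - log(target[K] / marg[K]))
  }
  alpha
}

# truth ParameterSet in the unconstrained/constant spec shape
scenario_truth_params <- function(scenario, spec) {
  G <- length(scenario$n_per_group)
  K <- ncol(scenario$membership)
  cells <- covariate_cells(scenario$codebook, scenario$covariate_marginals)
  beta_mat <- log(scenario$covariate_or)     # dummies x (K-1)
  alpha <- t(vapply(seq_len(G), function(g) {
    calibrate_intercepts(scenario$membership[g, ], beta_mat, cells)
  }, numeric(K - 1L)))
  beta <- array(0, c(1L, nrow(beta_mat), K - 1L))
  for (idx in seq_len(K - 1L)) beta[1, , idx] <- beta_mat[, idx]
  new_params(spec, scenario$rho, alpha, beta)
}

#' Generate a synthetic cohort from a scenario
#'
#' Draws, per row: covariates from their marginals, a school cluster, a
#' latent class from the multinomial-logit membership model (calibrated wave
#' intercept + covariate effects + normal cluster random intercept), each
#' indicator from the truth CRPs, and a lognormal survey weight normalised
#' to mean 1. No missingness is applied — see [inject_missingness()].
#'
#' @param scenario An [lca_scenario()], e.g. [default_scenario()].
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return An `lca_sim` list: `data` (labelled tibble), `true_class`
#'   (integer vector), `truth` (the generating `lca_params`, unconstrained
#'   shape, usable as an alignment reference), `spec` (matching
#'   [lca_spec()]), and the `scenario`.
#' @export
generate_dataset <- function(scenario, seed = 1L) {
  if (!inherits(scenario, "lca_scenario")) abort_config("scenario must be an lca_scenario")
  cb <- scenario$codebook
  G <- length(scenario$n_per_group)
  K <- ncol(scenario$membership)
  spec <- lca_spec(cb, K, "unconstrained", "constant", G = G)
  truth <- scenario_truth_params(scenario, spec)
  covs <- covariate_names(cb)
  inds <- indicator_names(cb)
  ncat <- indicator_ncat(cb)
  with_seed(seed, {
    rows <- list()
    true_class_all <- integer(0)
    for (g in seq_len(G)) {
      n_g <- scenario$n_per_group[g]
      df <- tibble::tibble(.rows = n_g)
      X <- matrix(0, n_g, length(spec$dummies))
      k <- 0L
      for (cv in covs) {
        cats <- indicator_categories(cb, cv)
        v <- sample(cats, n_g, replace = TRUE, prob = scenario$covariate_marginals[[cv]])
        df[[cv]] <- v
        for (l in setdiff(cats, covariate_reference(cb, cv))) {
          k <- k + 1L
          X[, k] <- as.numeric(v == l)
        }
      }
      cl_id <- sample.int(scenario$clusters_per_group, n_g, replace = TRUE)
      re <- matrix(stats::rnorm(scenario$clusters_per_group * (K - 1L),
                                sd = scenario$cluster_sd),
                   scenario$clusters_per_group, K - 1L)
      beta_mat <- log(scenario$covariate_or)
      eta <- sweep(X %*% beta_mat, 2, truth$alpha[g, ], "+") + re[cl_id, , drop = FALSE]
      pim <- softmax_rows(cbind(eta, 0))
      # draw class by inverse CDF (vectorised)
      u <- stats::runif(n_g)
      cum <- t(apply(pim, 1, cumsum))
      cls <- rowSums(u > cum) + 1L
      for (j in inds) {
        m_j <- ncat[[j]]
        yj <- integer(n_g)
        for (c in seq_len(K)) {
          idx <- which(cls == c)
          if (length(idx)) {
            yj[idx] <- sample.int(m_j, length(idx), replace = TRUE,
                                  prob = scenario$rho[[j]][g, c, ])
          }
        }
        df[[j]] <- indicator_categories(cb, j)[yj]
      }
      if (!is.null(weight_name(cb))) {
        df[[weight_name(cb)]] <- stats::rlnorm(n_g, 0, scenario$weight_sdlog)
      }
      if (!is.null(cluster_name(cb))) {
        df[[cluster_name(cb)]] <- sprintf("g%d_c%02d", g, cl_id)
      }
      if (!is.null(group_name(cb))) {
        df[[group_name(cb)]] <- scenario$group_labels[g]
      }
      rows[[g]] <- df
      true_class_all <- c(true_class_all, cls)
    }
    data <- dplyr::bind_rows(rows)[, cb$name]
    wn <- weight_name(cb)
    if (!is.null(wn)) data[[wn]] <- data[[wn]] / mean(data[[wn]])
    structure(list(data = data, true_class = true_class_all, truth = truth,
                   spec = spec, scenario = scenario, seed = seed),
              class = "lca_sim")
  })
}

#' @export
print.lca_sim <- function(x, ...) {
  cat("<lca_sim> n=", nrow(x$data), " rows across ",
      length(x$scenario$n_per_group), " waves (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Inject missingness into a dataset
#'
#' By default each targeted cell is set to missing independently with its
#' variable's rate (MCAR). A row that would lose every indicator is
#' re-drawn once; if it again loses all indicators, one randomly chosen
#' indicator is restored so the row stays usable.
#'
#' An optional MAR mode makes *covariate* missingness depend on one
#' observed indicator: rows whose `mar$indicator` equals `mar$category`
#' have their covariate missingness rates multiplied by `mar$multiplier`
#' (capped at 1), e.g. making affluence more often missing among weekly
#' drinkers.
#'
#' @param data Dataset tibble.
#' @param cb A [codebook()].
#' @param rates Named vector of per-variable missingness rates in \[0, 1\].
#' @param seed Integer seed.
#' @param mar Optional list `(indicator, category, multiplier)` switching on
#'   the MAR mechanism for covariate cells.
#' @return The dataset with `NA`s injected.
#' @export
inject_missingness <- function(data, cb, rates, seed = 1L, mar = NULL) {
  if (any(rates < 0 | rates > 1)) abort_config("rates must lie in [0,1]")
  bad <- setdiff(names(rates), cb$name)
  if (length(bad)) abort_config(paste0("rates name unknown variables: ",
                                       paste(bad, collapse = ", ")))
  rated_inds <- intersect(names(rates), indicator_names(cb))
  all_inds <- indicator_names(cb)
  covs <- covariate_names(cb)
  if (!is.null(mar)) {
    stopifnot(all(c("indicator", "category", "multiplier") %in% names(mar)))
    if (!mar$indicator %in% all_inds) abort_config("mar$indicator must be an indicator")
  }
  out <- data
  with_seed(seed, {
    draw_mask <- function() {
      mk <- list()
      for (v in names(rates)) {
        p <- rep(rates[[v]], nrow(data))
        if (!is.null(mar) && v %in% covs) {
          hit <- !is.na(data[[mar$indicator]]) &
            data[[mar$indicator]] == mar$category
          p[hit] <- pmin(1, p[hit] * mar$multiplier)
        }
        mk[[v]] <- stats::runif(nrow(data)) < p
      }
      mk
    }
    mask <- draw_mask()
    if (length(rated_inds)) {
      # a row is lost when every indicator column ends up missing
      all_ind_missing <- function(mk) {
        m <- vapply(all_inds, function(j) {
          base <- is.na(data[[j]])
          if (j %in% names(mk)) base | mk[[j]] else base
        }, logical(nrow(data)))
        rowSums(!m) == 0
      }
      lost <- which(all_ind_missing(mask))
      if (length(lost)) {
        redraw <- draw_mask()
        for (v in names(rates)) mask[[v]][lost] <- redraw[[v]][lost]
        still <- which(all_ind_missing(mask))
        for (i in still) {
          cand <- rated_inds[!is.na(as.matrix(data[i, rated_inds]))]
          keep <- cand[sample.int(length(cand), 1L)]
          mask[[keep]][i] <- FALSE
        }
      }
    }
    for (v in names(rates)) out[[v]][mask[[v]]] <- NA
  })
  out
}

#' Write a simulated cohort and its replay information to disk
#'
#' Emits the dataset CSV, the codebook JSON and a truth JSON (scenario echo,
#' seed and true class labels) so that any simulated run can be replayed.
#'
#' @param sim An `lca_sim` from [generate_dataset()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_lca_data(sim$data, file.path(dir, "dataset.csv"))
  write_codebook(sim$scenario$codebook, file.path(dir, "codebook.json"))
  sc <- sim$scenario
  truth <- list(
    seed = sim$seed,
    n_per_group = sc$n_per_group,
    group_labels = sc$group_labels,
    class_labels = sc$class_labels,
    membership = apply(sc$membership, 1, as.list),
    covariate_or = as.data.frame(sc$covariate_or),
    cluster_sd = sc$cluster_sd,
    clusters_per_group = sc$clusters_per_group,
    weight_sdlog = sc$weight_sdlog,
    missingness = as.list(sc$missingness),
    true_class = sim$true_class
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
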