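# Shared fixtures: tiny codebooks, toy datasets and independent oracles.

# codebook with `n_bin` binary indicators, optional covariate/weight/cluster/
# group columns
toy_codebook <- function(n_bin = 2, covariate = FALSE, weight = TRUE,
                         cluster = FALSE, group = TRUE) {
  nm <- paste0("ind", seq_len(n_bin))
  v <- tibble::tibble(
    name = nm, role = "indicator",
    categories = replicate(n_bin, c("no", "yes"), simplify = FALSE),
    reference = NA_character_
  )
  if (covariate) {
    v <- dplyr::bind_rows(v, tibble::tibble(
      name = "sex", role = "covariate",
      categories = list(c("male", "female")), reference = "male"))
  }
  if (weight) v <- dplyr::bind_rows(v, tibble::tibble(
    name = "w", role = "weight", categories = list(NULL), reference = NA))
  if (cluster) v <- dplyr::bind_rows(v, tibble::tibble(
    name = "clus", role = "cluster", categories = list(NULL), reference = NA))
  if (group) v <- dplyr::bind_rows(v, tibble::tibble(
    name = "grp", role = "group", categories = list(NULL), reference = NA))
  codebook(v)
}

# hand-assembled parameter set for a toy spec: `yes_prob` is a K-vector (or
# G x K matrix) of P(yes) shared by all indicators unless `per_indicator`
toy_params <- function(spec, yes_prob, alpha = NULL, beta = NULL) {
  G_rho <- if (spec$constraint == "unconstrained") spec$G else 1L
  rho <- list()
  for (j in spec$indicators) {
    arr <- array(0, c(G_rho, spec$K, 2L))
    yp <- if (is.matrix(yes_prob)) yes_prob else
      matrix(rep(yes_prob, each = G_rho), G_rho, spec$K)
    arr[, , 2] <- yp
    arr[, , 1] <- 1 - yp
    rho[[j]] <- arr
  }
  lcatrends:::new_params(spec, rho, alpha, beta)
}

# independent brute-force observed-data log-likelihood: explicit enumeration
# over classes, written without touching package internals
oracle_loglik <- function(data, cb, spec, params, normalise_weights = TRUE) {
  inds <- indicator_names(cb)
  wn <- weight_name(cb)
  w <- if (is.null(wn)) rep(1, nrow(data)) else data[[wn]]
  if (normalise_weights) w <- w / mean(w)
  gn <- group_name(cb)
  gl <- if (is.null(gn)) rep(1L, nrow(data)) else
    match(data[[gn]], sort(unique(data[[gn]])))
  dummies <- lcatrends:::covariate_dummy_names(cb)
  total <- 0
  for (i in seq_len(nrow(data))) {
    g <- gl[i]
    # membership probabilities
    if (spec$K == 1L) {
      pim <- 1
    } else {
      ga <- if (spec$constraint == "fully") 1L else g
      eta <- rep(0, spec$K)
      nr <- setdiff(seq_len(spec$K), spec$reference_class)
      for (idx in seq_along(nr)) {
        e <- params$alpha[ga, idx]
        if (length(dummies)) {
          x <- numeric(length(dummies))
          k <- 0
          for (cv in covariate_names(cb)) {
            cats <- cb$categories[[match(cv, cb$name)]]
            ref <- cb$reference[[match(cv, cb$name)]]
            for (l in setdiff(cats, ref)) {
              k <- k + 1
              x[k] <- as.numeric(data[[cv]][i] == l)
            }
          }
          gb <- if (spec$covariate_effects == "by_group") g else 1L
          e <- e + sum(x * params$beta[gb, , idx])
        }
        eta[nr[idx]] <- e
      }
      pim <- exp(eta) / sum(exp(eta))
    }
    gr <- if (spec$constraint == "unconstrained") g else 1L
    lik <- 0
    for (c in seq_len(spec$K)) {
      prod_j <- 1
      for (j in inds) {
        val <- data[[j]][i]
        if (!is.na(val)) {
          cats <- cb$categories[[match(j, cb$name)]]
          prod_j <- prod_j * params$rho[[j]][gr, c, match(val, cats)]
        }
      }
      lik <- lik + pim[c] * prod_j
    }
    total <- total + w[i] * log(lik)
  }
  total
}

# dense grid search over (pi, rho) for K=2, two binary indicators, no
# covariates, single group: independent maximiser of the mixture likelihood
grid_search_loglik <- function(data, cb, grid = seq(0.05, 0.95, by = 0.05)) {
  y1 <- as.numeric(data$ind1 == "yes")
  y2 <- as.numeric(data$ind2 == "yes")
  pat <- interaction(y1, y2)
  cnt <- table(pat)
  pats <- do.call(rbind, strsplit(names(cnt), ".", fixed = TRUE))
  storage.mode(pats) <- "numeric"
  g <- expand.grid(pi = grid, r11 = grid, r12 = grid, r21 = grid, r22 = grid)
  ll <- 0
  for (p in seq_along(cnt)) {
    a <- g$r11^pats[p, 1] * (1 - g$r11)^(1 - pats[p, 1]) *
      g$r12^pats[p, 2] * (1 - g$r12)^(1 - pats[p, 2])
    b <- g$r21^pats[p, 1] * (1 - g$r21)^(1 - pats[p, 1]) *
      g$r22^pats[p, 2] * (1 - g$r22)^(1 - pats[p, 2])
    ll <- ll + as.numeric(cnt[p]) * log(g$pi * a + (1 - g$pi) * b)
  }
  max(ll)
}

# small random dataset over a toy codebook (2 groups, weights, no covariates)
random_toy_data <- function(n = 120, n_bin = 3, seed = 1) {
  cbk <- toy_codebook(n_bin = n_bin)
  withr::with_seed(seed, {
    d <- tibble::as_tibble(stats::setNames(
      lapply(seq_len(n_bin), function(j) sample(c("no", "yes"), n, TRUE)),
      paste0("ind", seq_len(n_bin))))
    d$w <- stats::runif(n, 0.5, 2)
    d$grp <- sample(c("g1", "g2"), n, TRUE)
    list(data = d, cb = cbk)
  })
}

# shrunk copy of the default scenario (smaller waves; same truth otherwise)
scaled_default_scenario <- function(n_per_wave) {
  sc <- default_scenario()
  sc$n_per_group <- rep(as.integer(n_per_wave), 4)
  sc
}

# report every failing expectation rather than stopping the run at ten
options(testthat.progress.max_fails = 1000L)
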