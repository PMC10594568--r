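#' Scenario configurations for the synthetic cohort generator
#'
#' A scenario is the full generative truth for a multi-wave categorical
#' cohort: per-wave sample sizes, marginal class membership probabilities,
#' covariate marginals and their effects (odds ratios) on membership,
#' conditional response probabilities per (indicator, wave, class), school
#' clustering, survey-weight dispersion and per-variable missingness rates.
#'
#' @param codebook A [codebook()].
#' @param n_per_group Integer vector of per-wave sample sizes.
#' @param group_labels Character wave labels.
#' @param membership G x K matrix of *population-marginal* class membership
#'   probabilities per wave (rows sum to 1). The generator calibrates the
#'   wave intercepts so the covariate-averaged membership matches these.
#' @param class_labels Length-K character labels; the last class is the
#'   membership-logit reference.
#' @param covariate_marginals Named list of probability vectors over each
#'   covariate's categories.
#' @param covariate_or Matrix (covariate dummies x non-reference classes) of
#'   odds ratios on membership vs the reference class.
#' @param rho Named list of G x K x m_j truth CRP arrays.
#' @param clusters_per_group Number of school clusters per wave.
#' @param cluster_sd SD of the normal cluster random intercept added to each
#'   non-reference membership logit.
#' @param weight_sdlog Log-SD of the lognormal survey weights (normalised to
#'   mean 1).
#' @param missingness Named vector of MCAR missingness rates per variable.
#' @return An `lca_scenario` list.
#' @export
lca_scenario <- function(codebook, n_per_group, group_labels, membership,
                         class_labels, covariate_marginals, covariate_or,
                         rho, clusters_per_group = 30L, cluster_sd = 0.3,
                         weight_sdlog = 0.3, missingness = NULL) {
  G <- length(n_per_group)
  K <- ncol(membership)
  if (any(n_per_group < 1)) abort_config("n_per_group must be >= 1")
  if (nrow(membership) != G) abort_config("membership must have one row per group")
  if (any(abs(rowSums(membership) - 1) > 1e-8)) {
    abort_config("membership rows must sum to 1")
  }
  dn <- covariate_dummy_names(codebook)
  if (nrow(covariate_or) != length(dn) || ncol(covariate_or) != K - 1L) {
    abort_config("covariate_or must be (dummies) x (K-1)")
  }
  if (any(covariate_or <= 0)) abort_config("odds ratios must be positive")
  for (j in indicator_names(codebook)) {
    arr <- rho[[j]]
    if (is.null(arr) || !identical(dim(arr), c(G, K, unname(indicator_ncat(codebook)[j])))) {
      abort_config(paste0("rho truth for ", j, " missing or mis-shaped"))
    }
    if (any(abs(apply(arr, c(1, 2), sum) - 1) > 1e-8)) {
      abort_config(paste0("rho truth rows for ", j, " must sum to 1"))
    }
  }
  for (cv in covariate_names(codebook)) {
    p <- covariate_marginals[[cv]]
    if (is.null(p) || length(p) != length(indicator_categories(codebook, cv)) ||
        abs(sum(p) - 1) > 1e-8) {
      abort_config(paste0("covariate marginal for ", cv, " missing or invalid"))
    }
  }
  missingness <- missingness %||% stats::setNames(numeric(0), character(0))
  if (any(missingness < 0 | missingness > 1)) abort_config("missingness rates must be in [0,1]")
  structure(list(
    codebook = codebook, n_per_group = as.integer(n_per_group),
    group_labels = group_labels, membership = membership,
    class_labels = class_labels, covariate_marginals = covariate_marginals,
    covariate_or = covariate_or, rho = rho,
    clusters_per_group = as.integer(clusters_per_group),
    cluster_sd = cluster_sd, weight_sdlog = weight_sdlog,
    missingness = missingness
  ), class = "lca_scenario")
}

#' @export
print.lca_scenario <- function(x, ...) {
  cat("<lca_scenario> ", length(x$n_per_group), " waves (n=",
      paste(x$n_per_group, collapse = "/"), "), K=", ncol(x$membership),
      ", ", length(indicator_names(x$codebook)), " indicators\n", sep = "")
  invisible(x)
}

# linear interpolation of risky-category CRPs across waves, with the
# remaining mass split over the other categories in class-specific shares
build_rho_truth <- function(cb, anchors, rest_shares, G = 4L, K = 3L) {
  rho <- list()
  for (j in indicator_names(cb)) {
    m_j <- unname(indicator_ncat(cb)[j])
    a <- anchors[[j]]
    risky <- a$risky
    arr <- array(0, c(G, K, m_j))
    for (c in seq_len(K)) {
      series <- seq(a$w1[c], a$w4[c], length.out = G)
      for (g in seq_len(G)) {
        arr[g, c, risky] <- series[g]
        rest <- setdiff(seq_len(m_j), risky)
        if (m_j == 2L) {
          arr[g, c, rest] <- 1 - series[g]
        } else {
          arr[g, c, rest] <- (1 - series[g]) * rest_shares[[c]]
        }
      }
    }
    rho[[j]] <- arr
  }
  rho
}

#' The packaged default scenario: English adolescent health, four waves
#'
#' The calibrated truth for a 5,942-adolescent, four-wave (2001/02-2013/14)
#' cohort with three classes — an *overall unhealthy* type, a *substance
#' abstainer with behavioural risk indicators* type, and an *overall
#' healthy* reference type. Published quantities are wired in directly:
#' wave-1 marginal memberships (0.39, 0.40, 0.21) and wave-4
#' (0.18, 0.41, 0.41); weekly-drinking CRPs falling 0.71 to 0.28, 0.21 to
#' 0.02 and 0.49 to 0.06 across waves in the three classes; wave-1 smoking
#' 0.74/0.06/0.06, sexual activity 0.69/0.14/0.29, cannabis 0.05 and 0.25
#' in the abstainer and healthy classes; membership odds ratios 1.74/1.88
#' (female), 0.35/0.43 (middle family affluence) and 0.18/0.14 (high
#' affluence) versus the healthy class; indicator missingness rates equal to
#' the published missing counts over 5,942. All remaining CRPs, the
#' intermediate-wave memberships, the covariate marginals and the covariate
#' missingness rates are unpublished and are invented package defaults,
#' chosen to keep the classes separable and the waves smoothly
#' interpolated; they are tabulated in the methods vignette.
#'
#' @return An `lca_scenario`.
#' @export
default_scenario <- function() {
  cb <- default_codebook()
  membership <- rbind(
    c(0.39, 0.40, 0.21),   # 2001/02, published
    c(0.25, 0.40, 0.35),   # 2005/06, interpolated (invented)
    c(0.21, 0.40, 0.39),   # 2009/10, interpolated (invented)
    c(0.18, 0.41, 0.41)    # 2013/14, published
  )
  # risky-category CRP anchors per class (unhealthy, abstainer, healthy);
  # w1/w4 published where stated, otherwise invented
  anchors <- list(
    alcohol_weekly    = list(risky = 2L, w1 = c(0.71, 0.21, 0.49), w4 = c(0.28, 0.02, 0.06)),
    smoking           = list(risky = 2L, w1 = c(0.74, 0.06, 0.06), w4 = c(0.45, 0.02, 0.03)),
    cannabis          = list(risky = 2L, w1 = c(0.65, 0.05, 0.25), w4 = c(0.45, 0.03, 0.08)),
    sexual_activity   = list(risky = 2L, w1 = c(0.69, 0.14, 0.29), w4 = c(0.48, 0.08, 0.12)),
    emedia_daily      = list(risky = 2L, w1 = c(0.55, 0.40, 0.42), w4 = c(0.85, 0.72, 0.74)),
    parent_comm_hard  = list(risky = 2L, w1 = c(0.62, 0.58, 0.30), w4 = c(0.56, 0.52, 0.26)),
    exercise          = list(risky = 1L, w1 = c(0.35, 0.33, 0.14), w4 = c(0.36, 0.34, 0.15)),
    fruit_veg         = list(risky = 1L, w1 = c(0.42, 0.30, 0.12), w4 = c(0.40, 0.28, 0.11)),
    achievement       = list(risky = 1L, w1 = c(0.20, 0.08, 0.02), w4 = c(0.20, 0.08, 0.02)),
    school_pressure   = list(risky = 1L, w1 = c(0.42, 0.40, 0.18), w4 = c(0.42, 0.40, 0.20)),
    classmate_support = list(risky = 1L, w1 = c(0.35, 0.33, 0.12), w4 = c(0.34, 0.32, 0.12)),
    life_satisfaction = list(risky = 1L, w1 = c(0.45, 0.25, 0.06), w4 = c(0.45, 0.38, 0.13))
  )
  # how each class spreads the non-risky mass of 4-level items (worse -> best)
  rest_shares <- list(c(0.45, 0.35, 0.20), c(0.35, 0.35, 0.30), c(0.15, 0.30, 0.55))
  rho <- build_rho_truth(cb, anchors, rest_shares)
  covariate_or <- matrix(c(1.74, 1.88,   # sex:female, published
                           0.35, 0.43,   # fas:middle, published
                           0.18, 0.14),  # fas:high, published
                         nrow = 3, byrow = TRUE,
                         dimnames = list(covariate_dummy_names(cb), NULL))
  miss_counts <- c(alcohol_weekly = 68, smoking = 41, sexual_activity = 266,
                   cannabis = 173, achievement = 143, school_pressure = 131,
                   classmate_support = 127, emedia_daily = 226,
                   parent_comm_hard = 164, exercise = 134, fruit_veg = 45,
                   life_satisfaction = 161)
  missingness <- c(miss_counts / 5942, sex = 0.01, fas = 0.05)
  lca_scenario(
    codebook = cb,
    n_per_group = c(1486L, 1486L, 1485L, 1485L),   # total 5,942
    group_labels = c("2001/02", "2005/06", "2009/10", "2013/14"),
    membership = membership,
    class_labels = c("overall_unhealthy", "abstainers_bri", "overall_healthy"),
    covariate_marginals = list(sex = c(male = 0.5, female = 0.5),
                               fas = c(low = 0.15, middle = 0.45, high = 0.40)),
    covariate_or = covariate_or,
    rho = rho,
    missingness = missingness
  )
}
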