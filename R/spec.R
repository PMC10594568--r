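#' Specify a multi-group latent class model
#'
#' Defines the class count, the measurement-invariance regime across groups
#' (survey waves) and how covariates enter the membership model.
#'
#' The three constraint regimes are the standard multi-group LCA ladder:
#' * `"unconstrained"` — conditional response probabilities (CRPs) *and*
#'   class membership vary freely across groups;
#' * `"semi"` — CRPs are equal across groups, class membership varies;
#' * `"fully"` — both CRPs and class membership are equal across groups.
#'
#' Covariates act on the membership log-odds (multinomial logit against the
#' reference class). With `covariate_effects = "constant"` one coefficient
#' per covariate dummy and class is shared across groups; `"by_group"` lets
#' each group have its own coefficients.
#'
#' @param cb A [codebook()].
#' @param K Number of latent classes (>= 1).
#' @param constraint One of `"unconstrained"`, `"semi"`, `"fully"`.
#' @param covariate_effects `"constant"` (default) or `"by_group"`.
#' @param G Number of groups (defaults to the number observed in data when
#'   fitting; must be supplied here for standalone parameter counting).
#' @param reference_class Class used as the logit reference; default the last
#'   class `K` (by convention the healthy-type class after alignment).
#' @return An `lca_spec` list.
#' @export
lca_spec <- function(cb, K, constraint = c("unconstrained", "semi", "fully"),
                     covariate_effects = c("constant", "by_group"),
                     G = 1L, reference_class = K) {
  constraint <- match.arg(constraint)
  covariate_effects <- match.arg(covariate_effects)
  K <- as.integer(K); G <- as.integer(G)
  if (K < 1) abort_config("K must be >= 1")
  if (G < 1) abort_config("G must be >= 1")
  if (reference_class < 1 || reference_class > K) {
    abort_config("reference_class must lie in 1..K")
  }
  structure(list(
    K = K, constraint = constraint, covariate_effects = covariate_effects,
    G = G, reference_class = as.integer(reference_class),
    indicators = indicator_names(cb), ncat = indicator_ncat(cb),
    dummies = covariate_dummy_names(cb)
  ), class = "lca_spec")
}

#' @export
print.lca_spec <- function(x, ...) {
  cat("<lca_spec> K=", x$K, ", ", x$constraint, " constraint, ",
      x$covariate_effects, " covariate effects, G=", x$G, "\n", sep = "")
  invisible(x)
}

# number of distinct rho group slices / alpha group slices under the regime
n_groups_rho <- function(spec) if (spec$constraint == "unconstrained") spec$G else 1L
n_groups_alpha <- function(spec) if (spec$constraint == "fully") 1L else spec$G
n_groups_beta <- function(spec) if (spec$covariate_effects == "by_group") spec$G else 1L

#' Count the free parameters of a model specification
#'
#' Sums the free cells of the CRP simplices, the membership intercepts and
#' the covariate coefficients under the spec's invariance regime. Feeds the
#' sample-size-adjusted BIC. With `K = 1` there is no membership model, so
#' neither intercepts nor covariate coefficients are counted.
#'
#' @param spec An [lca_spec()].
#' @param cb The [codebook()] the spec was built from.
#' @return Integer count.
#' @examples
#' cb <- default_codebook()
#' n_free_parameters(lca_spec(cb, K = 3, "unconstrained", G = 4))  # 302
#' @export
n_free_parameters <- function(spec, cb) {
  if (!all(spec$indicators %in% indicator_names(cb))) {
    abort_config("spec indicators not all present in codebook")
  }
  m <- indicator_ncat(cb)[spec$indicators]
  rho_n <- spec$K * n_groups_rho(spec) * sum(m - 1L)
  if (spec$K == 1L) return(as.integer(rho_n))
  alpha_n <- n_groups_alpha(spec) * (spec$K - 1L)
  beta_n <- length(spec$dummies) * (spec$K - 1L) * n_groups_beta(spec)
  as.integer(rho_n + alpha_n + beta_n)
}
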