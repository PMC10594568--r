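# ParameterSet representation
#
# params$rho   : named list, one entry per indicator j, array [G_rho, K, m_j]
#                (G_rho = G when unconstrained, 1 otherwise)
# params$alpha : matrix [G_alpha, K-1] membership intercepts for the
#                non-reference classes (column order = class index with the
#                reference class dropped); G_alpha = 1 under "fully"
# params$beta  : array [G_beta, p_x, K-1] covariate coefficients on the
#                membership log-odds; G_beta = G only for by_group effects
#
# The smoothing floor keeps every rho cell in [RHO_FLOOR, 1 - RHO_FLOOR],
# a deliberate (documented) deviation from the unpenalised MLE that prevents
# log(0) and boundary cycling in EM.

RHO_FLOOR <- 1e-6

nonref_classes <- function(spec) setdiff(seq_len(spec$K), spec$reference_class)

new_params <- function(spec, rho, alpha = NULL, beta = NULL) {
  K <- spec$K
  if (K > 1L) {
    if (is.null(alpha)) alpha <- matrix(0, n_groups_alpha(spec), K - 1L)
    if (is.null(beta)) beta <- array(0, c(n_groups_beta(spec), length(spec$dummies), K - 1L))
  } else {
    alpha <- matrix(0, 1L, 0L)
    beta <- array(0, c(1L, length(spec$dummies), 0L))
  }
  structure(list(rho = rho, alpha = alpha, beta = beta),
            class = "lca_params")
}

# normalise each (g, c) simplex of a nonnegative array, clip to the
# smoothing floor, renormalise (zero-mass slices become uniform)
clip_rho <- function(arr) {
  s <- apply(arr, c(1, 2), sum)
  s[s == 0] <- 1
  arr <- sweep(arr, c(1, 2), s, "/")
  arr <- pmin(pmax(arr, RHO_FLOOR), 1 - RHO_FLOOR)
  s2 <- apply(arr, c(1, 2), sum)
  sweep(arr, c(1, 2), s2, "/")
}

validate_params <- function(params, spec, tol = 1e-8) {
  for (j in spec$indicators) {
    arr <- params$rho[[j]]
    if (is.null(arr)) abort_config(paste0("rho missing indicator ", j))
    d <- dim(arr)
    if (d[1] != n_groups_rho(spec) || d[2] != spec$K || d[3] != spec$ncat[[j]]) {
      abort_config(paste0("rho for ", j, " has wrong shape"))
    }
    s <- apply(arr, c(1, 2), sum)
    if (any(abs(s - 1) > tol)) abort_config(paste0("rho rows for ", j, " do not sum to 1"))
    if (any(arr < 0) || any(arr > 1)) abort_config("rho outside [0,1]")
  }
  if (!all(is.finite(params$alpha)) || !all(is.finite(params$beta))) {
    abort_config("alpha/beta must be finite")
  }
  invisible(params)
}

# Relabel classes: new class c takes the role of old class perm[c].
# Membership logits are re-expressed against the (relocated) reference class.
permute_classes <- function(params, perm, spec) {
  K <- spec$K
  stopifnot(length(perm) == K, sort(perm) == seq_len(K))
  rho <- lapply(params$rho, function(arr) arr[, perm, , drop = FALSE])
  if (K == 1L) return(new_params(spec, rho))
  # full K-column logit matrices (reference column = 0), permute, re-reference
  nr <- nonref_classes(spec)
  full_alpha <- matrix(0, nrow(params$alpha), K)
  full_alpha[, nr] <- params$alpha
  fa <- full_alpha[, perm, drop = FALSE]
  alpha <- fa[, nr, drop = FALSE] - fa[, spec$reference_class]
  db <- dim(params$beta)
  full_beta <- array(0, c(db[1], db[2], K))
  full_beta[, , nr] <- params$beta
  fb <- full_beta[, , perm, drop = FALSE]
  beta <- array(0, db)
  for (idx in seq_along(nr)) beta[, , idx] <- fb[, , nr[idx]] - fb[, , spec$reference_class]
  new_params(spec, rho, alpha, beta)
}

# flatten the structural (alpha, beta) block to a named vector and back;
# used for Rubin pooling and the numerical sandwich
structural_vector <- function(params, spec) {
  nr <- nonref_classes(spec)
  a <- params$alpha
  av <- as.vector(a)
  names(av) <- paste0("alpha[g", rep(seq_len(nrow(a)), times = ncol(a)),
                      ",c", rep(nr, each = nrow(a)), "]")
  b <- params$beta
  db <- dim(b)
  bv <- as.vector(b)
  if (length(bv)) {
    names(bv) <- paste0("beta[g", rep(seq_len(db[1]), times = db[2] * db[3]),
                        ",", rep(rep(spec$dummies, each = db[1]), times = db[3]),
                        ",c", rep(nr, each = db[1] * db[2]), "]")
  }
  c(av, bv)
}

set_structural_vector <- function(params, spec, theta) {
  na <- length(params$alpha)
  params$alpha[] <- theta[seq_len(na)]
  if (length(theta) > na) params$beta[] <- theta[-seq_len(na)]
  params
}

#' @export
print.lca_params <- function(x, ...) {
  cat("<lca_params> ", length(x$rho), " indicators, K=",
      dim(x$rho[[1]])[2], ", ", dim(x$rho[[1]])[1], " rho group slice(s)\n", sep = "")
  invisible(x)
}
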