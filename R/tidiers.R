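#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted latent class model
#'
#' `effects = "measurement"` returns the conditional response probabilities
#' in long form (one row per indicator/wave/class/category);
#' `effects = "structural"` returns the membership intercepts and covariate
#' coefficients as `term`/`estimate` pairs.
#'
#' @param x An `lca_fit`.
#' @param effects `"measurement"` (default) or `"structural"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lca_fit <- function(x, effects = c("measurement", "structural"), ...) {
  effects <- match.arg(effects)
  if (effects == "measurement") {
    crp_table(x, x$codebook)
  } else {
    th <- structural_vector(x$params, x$spec)
    tibble::tibble(term = names(th), estimate = unname(th))
  }
}

#' @rdname tidy.lca_fit
#' @export
glance.lca_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik,
    n_free_params = x$n_free_params,
    abic = adjusted_bic(x$loglik, x$n_free_params, x$n_effective),
    n_iter = x$n_iter,
    converged = x$converged,
    n_effective = x$n_effective,
    K = x$spec$K,
    constraint = x$spec$constraint,
    covariate_effects = x$spec$covariate_effects
  )
}

#' Tidy a pooled multi-imputation result
#'
#' Structural coefficients with Rubin total-variance standard errors and
#' Wald confidence limits.
#'
#' @param x An `lca_pooled`.
#' @param conf_level Confidence level.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `std.error`, `conf.low`, `conf.high`.
#' @export
tidy.lca_pooled <- function(x, conf_level = 0.95, ...) {
  se <- sqrt(diag(x$T))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = names(x$theta), estimate = unname(x$theta),
    std.error = unname(se),
    conf.low = unname(x$theta - z * se),
    conf.high = unname(x$theta + z * se)
  )
}

#' @rdname tidy.lca_pooled
#' @export
glance.lca_pooled <- function(x, ...) {
  tibble::tibble(m = x$m, K = x$spec$K, constraint = x$spec$constraint,
                 covariate_effects = x$spec$covariate_effects)
}

#' Plot class profiles as risky-category probabilities over waves
#'
#' @param object An `lca_fit` or `lca_pooled`.
#' @param risky_map See [default_risky_map()].
#' @param ... Unused.
#' @return A ggplot object: one panel per class, one line per indicator.
#' @export
autoplot.lca_fit <- function(object, risky_map = default_risky_map(), ...) {
  ser <- risky_category_series(crp_table(object, object$codebook), risky_map)
  ggplot2::ggplot(ser, ggplot2::aes(x = .data$group, y = .data$probability,
                                    colour = .data$indicator)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~class, labeller = ggplot2::label_both) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "survey wave", y = "P(risky category | class)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.lca_fit
#' @export
autoplot.lca_pooled <- autoplot.lca_fit

#' Plot class membership probabilities over waves
#'
#' @param membership A tibble from [class_membership_by_group()].
#' @return A ggplot object.
#' @export
plot_membership_trends <- function(membership) {
  ggplot2::ggplot(membership,
                  ggplot2::aes(x = .data$group_label, y = .data$probability,
                               colour = factor(.data$class),
                               group = factor(.data$class))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "survey wave", y = "P(class)", colour = "class") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
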