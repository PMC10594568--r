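# Reporting surfaces: membership-by-wave, CRP tables, risky-category series.

params_of <- function(x) {
  if (inherits(x, "lca_fit") || inherits(x, "lca_pooled")) x$params
  else if (inherits(x, "lca_params")) x
  else abort_config("expected an lca_fit, lca_pooled or lca_params")
}

spec_of <- function(x, spec = NULL) {
  if (inherits(x, "lca_fit") || inherits(x, "lca_pooled")) x$spec
  else spec %||% abort_config("supply `spec` with a bare parameter set")
}

#' Class membership probabilities by group (survey wave)
#'
#' The survey-weighted mean of the per-row posterior class probabilities
#' within each wave — the estimated-model analogue of per-wave class counts.
#' Set `type = "prior"` for the model-implied average membership (covariate
#' profile averaged, no indicator information).
#'
#' @param object An `lca_fit`, `lca_pooled` or bare `lca_params`.
#' @param data Covariate-complete dataset tibble.
#' @param cb A [codebook()].
#' @param spec Needed only with a bare parameter set.
#' @param type `"posterior"` (default) or `"prior"`.
#' @return A tibble `group`, `group_label`, `class`, `probability`; the
#'   probabilities sum to 1 within each wave.
#' @export
class_membership_by_group <- function(object, data, cb, spec = NULL,
                                      type = c("posterior", "prior")) {
  type <- match.arg(type)
  spec <- spec_of(object, spec)
  params <- params_of(object)
  enc <- encode_lca_data(data, cb)
  if (any(tabulate(enc$group, length(enc$group_levels)) == 0)) {
    abort_config("empty group in data")
  }
  P <- if (type == "posterior") posterior_matrix(params, spec, enc) else {
    eta <- membership_eta(params, spec, enc)
    softmax_rows(eta)
  }
  wP <- enc$w * P
  num <- rowsum(wP, enc$group)
  den <- rowsum(enc$w, enc$group)
  tab <- sweep(num, 1, den, "/")
  tibble::tibble(
    group = rep(seq_len(nrow(tab)), each = spec$K),
    group_label = rep(enc$group_levels, each = spec$K),
    class = rep(seq_len(spec$K), times = nrow(tab)),
    probability = as.vector(t(tab))
  )
}

#' Long-format table of conditional response probabilities
#'
#' Tabulates rho as (indicator, group, class, category, probability). Under
#' the semi/fully constrained regimes the shared slice is repeated for every
#' group so downstream plotting is uniform.
#'
#' @inheritParams class_membership_by_group
#' @param group_labels Optional wave labels (defaults to `1..G` or the
#'   labels stored on a fit).
#' @return A tibble with columns `indicator`, `group`, `group_label`,
#'   `class`, `category`, `probability`.
#' @export
crp_table <- function(object, cb, spec = NULL, group_labels = NULL) {
  spec <- spec_of(object, spec)
  params <- params_of(object)
  if (is.null(group_labels)) {
    group_labels <- if (inherits(object, c("lca_fit", "lca_pooled")))
      object$group_levels else as.character(seq_len(spec$G))
  }
  rows <- list()
  for (j in spec$indicators) {
    arr <- params$rho[[j]]
    cats <- indicator_categories(cb, j)
    G_rho <- dim(arr)[1]
    for (g in seq_len(spec$G)) {
      gs <- if (G_rho == 1L) 1L else g
      for (c in seq_len(spec$K)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          indicator = j, group = g, group_label = group_labels[g],
          class = c, category = cats, probability = arr[gs, c, ]
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Default risky/unhealthy category per indicator
#'
#' Binary indicators map to their affirmative risk level (weekly drinker,
#' smoker, any cannabis use, had intercourse, daily e-media use, no parent
#' easy to talk to). For the four-level items there is no unambiguous risky
#' category, so interpretable defaults are shipped — lowest exercise band,
#' lowest fruit/veg band, below-average perceived achievement, "a lot" of
#' schoolwork pressure, lowest classmate support and lowest life
#' satisfaction — and can be overridden wholesale.
#'
#' @param cb A [codebook()] (defaults to [default_codebook()]).
#' @return Named list mapping indicator name to risky category label.
#' @export
default_risky_map <- function(cb = default_codebook()) {
  list(
    alcohol_weekly = "weekly", smoking = "smoker", cannabis = "any_use",
    sexual_activity = "had_intercourse", emedia_daily = "daily",
    parent_comm_hard = "none_easy",
    exercise = "low", fruit_veg = "low", achievement = "below_average",
    school_pressure = "a_lot", classmate_support = "low",
    life_satisfaction = "low"
  )
}

#' Risky-category probability series
#'
#' Filters a [crp_table()] down to the designated most-risky category of
#' each indicator — the series shown when plotting class profiles over time.
#'
#' @param crp A tibble from [crp_table()].
#' @param risky_map Named list mapping each indicator to its risky category
#'   label; see [default_risky_map()].
#' @return Tibble `indicator`, `group`, `group_label`, `class`,
#'   `probability` (one row per indicator/wave/class).
#' @export
risky_category_series <- function(crp, risky_map = default_risky_map()) {
  inds <- unique(crp$indicator)
  unmapped <- setdiff(inds, names(risky_map))
  if (length(unmapped)) {
    abort_config(paste0("no risky category mapped for: ",
                        paste(unmapped, collapse = ", ")))
  }
  map_tbl <- tibble::tibble(indicator = names(risky_map),
                            category = unlist(risky_map, use.names = FALSE))
  bad <- dplyr::anti_join(map_tbl[map_tbl$indicator %in% inds, ],
                          dplyr::distinct(crp, .data$indicator, .data$category),
                          by = c("indicator", "category"))
  if (nrow(bad)) {
    abort_config(paste0("risky category not a category of its indicator: ",
                        paste(bad$indicator, collapse = ", ")))
  }
  dplyr::inner_join(crp, map_tbl, by = c("indicator", "category")) |>
    dplyr::select("indicator", "group", "group_label", "class", "probability")
}

#' Weighted descriptive table of indicators by wave
#'
#' For each indicator and wave: the unweighted respondent count and the
#' survey-weighted percentage per category, plus the overall missing count
#' per indicator — the standard descriptive layout for repeat
#' cross-sectional health surveys.
#'
#' @inheritParams class_membership_by_group
#' @return Tibble `indicator`, `category`, `group_label`, `n`, `pct`,
#'   `n_missing`.
#' @export
indicator_descriptives <- function(data, cb) {
  wn <- weight_name(cb)
  gn <- group_name(cb)
  w <- if (is.null(wn)) rep(1, nrow(data)) else data[[wn]]
  g <- if (is.null(gn)) rep("all", nrow(data)) else as.character(data[[gn]])
  rows <- list()
  for (j in indicator_names(cb)) {
    v <- data[[j]]
    n_missing <- sum(is.na(v))
    for (gl in sort(unique(g))) {
      sel <- g == gl & !is.na(v)
      wtot <- sum(w[sel])
      for (cat in indicator_categories(cb, j)) {
        s <- sel & v == cat
        rows[[length(rows) + 1L]] <- tibble::tibble(
          indicator = j, category = cat, group_label = gl,
          n = sum(s), pct = 100 * sum(w[s]) / wtot, n_missing = n_missing
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
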