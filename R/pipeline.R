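#' Configure the four-stage analysis pipeline
#'
#' Exactly one input mode must be given: an in-memory dataset + codebook, a
#' CSV/JSON path pair, or a synthetic `scenario`. The pipeline then runs
#' descriptives, covariate imputation, model selection (class-count scan and
#' invariance-regime scan), the final per-imputation fits with alignment and
#' Rubin pooling, cluster-robust covariate inference, and the reporting
#' tables; optional sensitivity variants re-run the final stage with a
#' swapped indicator roster.
#'
#' @param data,codebook In-memory dataset tibble and [codebook()].
#' @param data_path,codebook_path CSV dataset + JSON codebook paths.
#' @param scenario An [lca_scenario()] for synthetic mode.
#' @param roster Indicator subset for the primary analysis (default: all
#'   indicators in the codebook).
#' @param k_range Class counts for the aBIC scan.
#' @param m,cycles Imputation count and chained-equation cycles.
#' @param n_starts Random starts for each multistart fit.
#' @param seed Master seed for every stochastic stage.
#' @param out_dir Output directory (optional; tables also return in-memory).
#' @param risky_map See [default_risky_map()]; defaults per codebook.
#' @param sensitivity Named list of alternative indicator rosters; each
#'   re-runs the final model only.
#' @param apply_missingness In synthetic mode, inject the scenario's
#'   missingness rates before imputation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(data = NULL, codebook = NULL,
                            data_path = NULL, codebook_path = NULL,
                            scenario = NULL, roster = NULL,
                            k_range = 2:4, m = 5L, cycles = 10L,
                            n_starts = 50L, seed = 1L, out_dir = NULL,
                            risky_map = NULL, sensitivity = list(),
                            apply_missingness = TRUE) {
  modes <- c(!is.null(data), !is.null(data_path), !is.null(scenario))
  if (sum(modes) != 1L) abort_config("give exactly one of data, data_path or scenario")
  if (!is.null(data) && is.null(codebook)) abort_config("codebook required with data")
  if (!is.null(data_path) && is.null(codebook_path)) abort_config("codebook_path required with data_path")
  structure(list(data = data, codebook = codebook, data_path = data_path,
                 codebook_path = codebook_path, scenario = scenario,
                 roster = roster, k_range = k_range, m = as.integer(m),
                 cycles = as.integer(cycles), n_starts = as.integer(n_starts),
                 seed = as.integer(seed), out_dir = out_dir,
                 risky_map = risky_map, sensitivity = sensitivity,
                 apply_missingness = isTRUE(apply_missingness)),
            class = "pipeline_config")
}

# codebook restricted to an indicator roster (non-indicator columns kept)
subset_codebook <- function(cb, roster) {
  missing_ind <- setdiff(roster, indicator_names(cb))
  if (length(missing_ind)) {
    abort_config(paste0("roster indicators not in codebook: ",
                        paste(missing_ind, collapse = ", ")))
  }
  keep <- cb$role != "indicator" | cb$name %in% roster
  codebook(tibble::as_tibble(cb)[keep, ])
}

#' Serialise fitted/pooled parameters to JSON
#'
#' Conditional response probabilities in long form (indicator, group, class,
#' category, probability) plus the structural coefficient vector.
#'
#' @param object `lca_fit`, `lca_pooled` or `lca_params`.
#' @param cb A [codebook()].
#' @param path Output path.
#' @param spec Needed for a bare parameter set.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(object, cb, path, spec = NULL) {
  spec <- spec_of(object, spec)
  params <- params_of(object)
  crp <- crp_table(object, cb, spec = spec)
  th <- structural_vector(params, spec)
  jsonlite::write_json(list(
    spec = list(K = spec$K, constraint = spec$constraint,
                covariate_effects = spec$covariate_effects, G = spec$G,
                reference_class = spec$reference_class),
    crp = crp,
    structural = as.list(th)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
                 class = "lcat_stage_error", parent = e)
  })
}

# fit the final spec to each completed dataset: multistart on the first,
# warm-started single runs on the rest, all aligned to the first
fit_imputations <- function(datasets, cb, spec, n_starts, seed, ...) {
  ms1 <- suppressWarnings(fit_multistart(datasets[[1]], cb, spec,
                                         n_starts = n_starts, seed = seed, ...))
  fits <- vector("list", length(datasets))
  fits[[1]] <- ms1$best
  if (length(datasets) > 1) {
    for (i in 2:length(datasets)) {
      f <- fit_single_start(datasets[[i]], cb, spec, init = ms1$best$params)
      fits[[i]] <- align_to_reference(fits[[1]]$params, f)
    }
  }
  fits
}

#' Run the full four-stage pipeline
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress to stderr.
#' @return An `lca_report` bundle: `descriptives`, `imputation`,
#'   `selection_classes`, `selection_constraints`, `final_spec`, `fits`,
#'   `pooled`, `odds_ratios`, `membership`, `crp`, `risky`, `sensitivity`
#'   and the reproducibility `manifest`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  say <- function(...) if (verbose) message("[lcatrends] ", ...)
  seeds <- split_seeds(config$seed, 6L)
  # --- input -----------------------------------------------------------
  if (!is.null(config$scenario)) {
    say("simulating cohort")
    sim <- generate_dataset(config$scenario, seed = seeds[1])
    data <- sim$data
    cb <- config$scenario$codebook
    if (config$apply_missingness && length(config$scenario$missingness)) {
      data <- inject_missingness(data, cb, config$scenario$missingness, seed = seeds[2])
    }
  } else if (!is.null(config$data_path)) {
    cb <- read_codebook(config$codebook_path)
    data <- read_lca_data(config$data_path, cb)
  } else {
    cb <- config$codebook
    data <- validate_lca_data(config$data, cb)
  }
  roster <- config$roster %||% indicator_names(cb)
  cb_run <- subset_codebook(cb, roster)
  out_dir <- config$out_dir
  emit <- function(tbl, file) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(tbl, file.path(out_dir, file), row.names = FALSE)
    }
  }
  # --- stage 1: descriptives ------------------------------------------
  say("stage 1: descriptives")
  desc <- stage("descriptives", indicator_descriptives(data, cb_run))
  emit(desc, "descriptives.csv")
  # --- stage 2: imputation --------------------------------------------
  say("stage 2: multiple imputation")
  imp <- stage("imputation",
               suppressWarnings(impute_covariates(data, cb_run, m = config$m,
                                                  cycles = config$cycles,
                                                  seed = seeds[3])))
  # --- stage 3: model selection ---------------------------------------
  say("stage 3: model selection")
  sel_k <- stage("scan_classes",
                 scan_classes(imp$datasets[[1]], cb_run, config$k_range,
                              n_starts = config$n_starts, seed = seeds[4]))
  emit(dplyr::select(sel_k, -dplyr::any_of("fits")), "selection_classes.csv")
  K_sel <- sel_k$K[sel_k$selected][1]
  sel_c <- stage("scan_constraints",
                 scan_constraints(imp$datasets[[1]], cb_run, K = K_sel,
                                  n_starts = config$n_starts, seed = seeds[5]))
  emit(dplyr::select(sel_c, -dplyr::any_of("fits")), "selection_constraints.csv")
  final_row <- sel_c[sel_c$selected, ][1, ]
  enc_groups <- length(unique(data[[group_name(cb_run)]]))
  final_spec <- lca_spec(cb_run, K_sel, final_row$constraint,
                         final_row$covariate_effects, G = enc_groups)
  # --- stage 4: final fits, pooling, inference ------------------------
  say("stage 4: final estimation (", config$m, " imputations)")
  fits <- stage("final_fits",
                fit_imputations(imp$datasets, cb_run, final_spec,
                                n_starts = config$n_starts, seed = seeds[6]))
  covs <- stage("robust_covariance",
                lapply(seq_along(fits), function(i)
                  cluster_robust_covariance(fits[[i]], imp$datasets[[i]], cb_run)))
  pooled <- stage("pooling", suppressWarnings(pool_mi_fits(fits, covs)))
  ors <- stage("odds_ratios", odds_ratio_table(pooled))
  risky_map <- config$risky_map %||% default_risky_map(cb_run)
  risky_map <- risky_map[intersect(names(risky_map), roster)]
  membership <- class_membership_by_group(pooled, imp$datasets[[1]], cb_run)
  crp <- crp_table(pooled, cb_run)
  risky <- risky_category_series(crp, risky_map)
  emit(ors, "odds_ratios.csv"); emit(membership, "membership.csv")
  emit(crp, "crp.csv"); emit(risky, "risky.csv")
  if (!is.null(out_dir)) {
    write_params_json(pooled, cb_run, file.path(out_dir, "pooled_params.json"))
  }
  # --- sensitivity variants -------------------------------------------
  sens <- list()
  for (nm in names(config$sensitivity)) {
    say("sensitivity variant: ", nm)
    ros <- config$sensitivity[[nm]]
    cb_s <- subset_codebook(cb, ros)
    imp_s <- suppressWarnings(impute_covariates(data, cb_s, m = config$m,
                                                cycles = config$cycles,
                                                seed = seeds[3]))
    spec_s <- lca_spec(cb_s, K_sel, final_row$constraint,
                       final_row$covariate_effects, G = enc_groups)
    fits_s <- fit_imputations(imp_s$datasets, cb_s, spec_s,
                              n_starts = config$n_starts, seed = seeds[6])
    pooled_s <- suppressWarnings(pool_mi_fits(fits_s))
    rm_s <- default_risky_map(cb_s)
    rm_s <- utils::modifyList(rm_s[intersect(names(rm_s), ros)],
                              (config$risky_map %||% list())[intersect(names(config$risky_map %||% list()), ros)])
    crp_s <- crp_table(pooled_s, cb_s)
    sens[[nm]] <- list(pooled = pooled_s, crp = crp_s,
                       risky = risky_category_series(crp_s, rm_s),
                       odds_ratios = odds_ratio_table(pooled_s))
    emit(crp_s, paste0("crp_", nm, ".csv"))
    emit(sens[[nm]]$risky, paste0("risky_", nm, ".csv"))
  }
  manifest <- list(
    seed = config$seed, stage_seeds = as.list(seeds),
    m = config$m, cycles = config$cycles, n_starts = config$n_starts,
    k_range = config$k_range, roster = roster,
    selected_K = K_sel, final_constraint = final_row$constraint,
    final_covariate_effects = final_row$covariate_effects,
    sensitivity = lapply(config$sensitivity, identity),
    mode = if (!is.null(config$scenario)) "synthetic" else "file"
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(list(
    descriptives = desc, imputation = imp, selection_classes = sel_k,
    selection_constraints = sel_c, final_spec = final_spec, fits = fits,
    pooled = pooled, odds_ratios = ors, membership = membership,
    crp = crp, risky = risky, sensitivity = sens, manifest = manifest
  ), class = "lca_report")
}

#' @export
print.lca_report <- function(x, ...) {
  cat("<lca_report> K=", x$final_spec$K, " (", x$final_spec$constraint, ", ",
      x$final_spec$covariate_effects, " effects), m=", x$pooled$m,
      " imputations, ", length(x$sensitivity), " sensitivity variant(s)\n", sep = "")
  invisible(x)
}
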