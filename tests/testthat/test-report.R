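test_that("membership-by-wave at the truth tracks the configured marginals", {
  sc <- scaled_default_scenario(4000)
  sc$cluster_sd <- 0    # school noise does not shrink with n; drop it here
  sim <- generate_dataset(sc, seed = 19)
  mem <- class_membership_by_group(sim$truth, sim$data, sc$codebook,
                                   spec = sim$spec)
  wave1 <- mem$probability[mem$group == 1]
  expect_lt(max(abs(wave1 - c(0.39, 0.40, 0.21))), 0.02)
  # per-wave probabilities sum to one
  sums <- tapply(mem$probability, mem$group, sum)
  expect_true(all(abs(sums - 1) < 1e-10))
})

test_that("a flat membership model reports 1/K everywhere", {
  td <- random_toy_data(n = 100, n_bin = 2, seed = 23)
  spec <- lca_spec(td$cb, 2, "unconstrained", G = 2)
  params <- toy_params(spec, yes_prob = matrix(0.5, 2, 2))
  mem <- class_membership_by_group(params, td$data, td$cb, spec = spec,
                                   type = "prior")
  expect_equal(mem$probability, rep(0.5, 4))
})

test_that("the CRP table tabulates rho losslessly and repeats shared slices", {
  cb <- default_codebook()
  spec_semi <- lca_spec(cb, 3, "semi", "constant", G = 4)
  params <- random_initial_params(spec_semi, cb, 3)
  crp <- crp_table(params, cb, spec = spec_semi)
  # per (indicator, wave, class) sums to one
  sums <- dplyr::summarise(dplyr::group_by(crp, indicator, group, class),
                           s = sum(probability), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-10))
  # shared slice repeated identically across waves
  w1 <- dplyr::filter(crp, group == 1)
  for (g in 2:4) {
    wg <- dplyr::filter(crp, group == g)
    expect_equal(w1$probability, wg$probability)
  }
  # round-trip back to the parameter arrays
  for (j in spec_semi$indicators) {
    sub <- dplyr::filter(w1, indicator == j)
    expect_equal(sub$probability,
                 as.vector(t(params$rho[[j]][1, , ])), tolerance = 1e-12)
  }
})

test_that("risky-category series picks the mapped category", {
  sc <- default_scenario()
  spec <- lca_spec(sc$codebook, 3, "unconstrained", "constant", G = 4)
  truth <- lcatrends:::scenario_truth_params(sc, spec)
  crp <- crp_table(truth, sc$codebook, spec = spec)
  ser <- risky_category_series(crp)
  # weekly drinking, unhealthy class, wave 1: the published 0.71
  v <- ser$probability[ser$indicator == "alcohol_weekly" &
                         ser$group == 1 & ser$class == 1]
  expect_equal(v, 0.71)
  # remapping one 4-level indicator changes only that indicator's rows
  alt_map <- default_risky_map()
  alt_map$life_satisfaction <- "high"
  ser2 <- risky_category_series(crp, alt_map)
  changed <- ser$probability != ser2$probability
  expect_true(all(ser$indicator[changed] == "life_satisfaction"))
  # unmapped indicator errors by name
  expect_error(risky_category_series(crp, alt_map[-1]),
               regexp = "alcohol_weekly", class = "lcat_config_error")
  # a map entry that is not a category of its indicator errors
  bad_map <- default_risky_map(); bad_map$smoking <- "never"
  expect_error(risky_category_series(crp, bad_map), class = "lcat_config_error")
})

test_that("degenerate rho concentrated on the risky category gives a series of 1", {
  cb <- toy_codebook(n_bin = 2, group = FALSE)
  spec <- lca_spec(cb, 2, G = 1)
  params <- toy_params(spec, yes_prob = c(1 - 1e-12, 1 - 1e-12))
  crp <- crp_table(params, cb, spec = spec)
  ser <- risky_category_series(crp, list(ind1 = "yes", ind2 = "yes"))
  expect_equal(ser$probability, rep(1, 4), tolerance = 1e-9)
})

test_that("weighted descriptives reproduce hand-computed percentages", {
  cb <- toy_codebook(n_bin = 1)
  d <- tibble::tibble(ind1 = c("yes", "yes", "no", NA),
                      w = c(2, 1, 1, 5), grp = "w1")
  desc <- indicator_descriptives(d, cb)
  yes_row <- desc[desc$category == "yes", ]
  expect_equal(yes_row$n, 2L)
  expect_equal(yes_row$pct, 100 * 3 / 4)   # weighted among non-missing
  expect_equal(yes_row$n_missing, 1L)
})

test_that("tidiers return the documented shapes", {
  td <- random_toy_data(n = 120, n_bin = 3, seed = 27)
  spec <- lca_spec(td$cb, 2, "unconstrained", G = 2)
  fit <- fit_single_start(td$data, td$cb, spec,
                          init = random_initial_params(spec, td$cb, 1))
  g <- glance(fit)
  expect_named(g, c("loglik", "n_free_params", "abic", "n_iter", "converged",
                    "n_effective", "K", "constraint", "covariate_effects"))
  expect_equal(g$abic, adjusted_bic(fit$loglik, fit$n_free_params, fit$n_effective))
  tm <- tidy(fit)
  expect_true(all(c("indicator", "group", "class", "category", "probability")
                  %in% names(tm)))
  ts <- tidy(fit, effects = "structural")
  expect_equal(nrow(ts), length(lcatrends:::structural_vector(fit$params, spec)))
  expect_s3_class(autoplot(fit, risky_map = list(ind1 = "yes", ind2 = "yes",
                                                 ind3 = "yes")), "ggplot")
})
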