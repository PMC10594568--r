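test_that("multistart is deterministic in (data, seed) and returns the max", {
  td <- random_toy_data(n = 150, n_bin = 3, seed = 21)
  spec <- lca_spec(td$cb, 2, "unconstrained", G = 2)
  ms1 <- suppressWarnings(fit_multistart(td$data, td$cb, spec, n_starts = 15, seed = 3))
  ms2 <- suppressWarnings(fit_multistart(td$data, td$cb, spec, n_starts = 15, seed = 3))
  expect_identical(ms1$best$loglik, ms2$best$loglik)
  expect_identical(ms1$best$params, ms2$best$params)
  expect_true(all(ms1$best$loglik >= ms1$logliks - 1e-10))
  expect_gte(ms1$replication, 1)
})

test_that("an easy well-separated problem replicates the best solution", {
  sc <- lca_scenario(
    codebook = toy_codebook(n_bin = 4, weight = TRUE, group = TRUE),
    n_per_group = 2000L, group_labels = "w1",
    membership = matrix(c(0.5, 0.5), 1),
    class_labels = c("a", "b"),
    covariate_marginals = list(),
    covariate_or = matrix(numeric(0), 0, 1),
    rho = {
      arr1 <- array(c(0.9, 0.1, 0.1, 0.9), c(1, 2, 2))
      list(ind1 = arr1, ind2 = arr1, ind3 = arr1, ind4 = arr1)
    },
    clusters_per_group = 10L, cluster_sd = 0, weight_sdlog = 0)
  sim <- generate_dataset(sc, seed = 5)
  spec <- lca_spec(sc$codebook, 2, G = 1)
  ms <- fit_multistart(sim$data, sc$codebook, spec, n_starts = 100, seed = 9,
                       refine_top = 100)
  expect_gte(ms$replication, 50)
})

test_that("adjusted BIC matches hand evaluations of the formula", {
  expect_equal(adjusted_bic(-1000, 10, 1000), 2000 + 10 * log(1002 / 24),
               tolerance = 1e-9)
  expect_equal(adjusted_bic(-1000, 10, 1000), 2037.317, tolerance = 1e-3)
  expect_identical(adjusted_bic(-123.4, 0, 50), 246.8)
  # one extra parameter at n = 1000 costs ln(1002/24)
  expect_equal(adjusted_bic(-1000, 11, 1000) - adjusted_bic(-1000, 10, 1000),
               log(1002 / 24), tolerance = 1e-12)
  expect_equal(log(1002 / 24), 3.732, tolerance = 1e-3)
})

test_that("class scan tabulates consistent counts and respects nesting in K", {
  td <- random_toy_data(n = 200, n_bin = 3, seed = 31)
  tab <- suppressWarnings(scan_classes(td$data, td$cb, 1:3, n_starts = 10,
                                       seed = 4, refine_top = 3))
  cb <- td$cb
  for (i in seq_len(nrow(tab))) {
    spec_i <- lca_spec(cb, tab$K[i], tab$constraint[i],
                       tab$covariate_effects[i], G = 2)
    expect_identical(tab$n_free_params[i], n_free_parameters(spec_i, cb))
  }
  expect_true(all(diff(tab$loglik) > -1e-6))   # loglik non-decreasing in K
  expect_identical(sum(tab$selected), 1L)
  expect_identical(tab$abic[tab$selected], min(tab$abic))
})

test_that("degenerate single-pattern data selects the smallest K", {
  cb <- toy_codebook(n_bin = 2, group = FALSE)
  d <- tibble::tibble(ind1 = rep("yes", 80), ind2 = rep("no", 80), w = 1)
  tab <- suppressWarnings(scan_classes(d, cb, 1:3, n_starts = 8, seed = 2,
                                       refine_top = 2))
  expect_identical(tab$K[tab$selected], 1L)
})

test_that("constraint scan reports the four-regime ladder coherently", {
  sc <- scaled_default_scenario(250)
  sim <- generate_dataset(sc, seed = 3)
  tab <- suppressWarnings(scan_constraints(sim$data, sc$codebook, K = 3,
                                           n_starts = 8, seed = 6,
                                           burn_in = 15, refine_top = 2))
  expect_identical(nrow(tab), 4L)
  expect_setequal(tab$covariate_effects, c("constant", "by_group"))
  for (i in seq_len(nrow(tab))) {
    spec_i <- lca_spec(sc$codebook, 3, tab$constraint[i],
                       tab$covariate_effects[i], G = 4)
    expect_identical(tab$n_free_params[i], n_free_parameters(spec_i, sc$codebook))
  }
  cons <- tab[tab$covariate_effects == "constant", ]
  ll <- stats::setNames(cons$loglik, cons$constraint)
  expect_true(ll["fully"] <= ll["semi"] + 1e-6)
  expect_true(ll["semi"] <= ll["unconstrained"] + 1e-6)
  expect_identical(sum(tab$selected), 1L)
})
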