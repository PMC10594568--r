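test_that("observed_loglik matches closed forms on hand-worked cases", {
  # single class, one binary indicator, rho = (0.5, 0.5), 4 rows
  cb1 <- toy_codebook(n_bin = 1, weight = TRUE, group = FALSE)
  spec1 <- lca_spec(cb1, 1, G = 1)
  p1 <- toy_params(spec1, yes_prob = matrix(0.5, 1, 1))
  d1 <- tibble::tibble(ind1 = c("yes", "no", "yes", "no"), w = 1)
  expect_equal(observed_loglik(d1, cb1, spec1, p1), 4 * log(0.5), tolerance = 1e-12)

  # two equal classes, two binary indicators, (0.9, 0.9) vs (0.1, 0.1)
  cb2 <- toy_codebook(n_bin = 2, group = FALSE)
  spec2 <- lca_spec(cb2, 2, G = 1)
  p2 <- toy_params(spec2, yes_prob = c(0.9, 0.1))
  d_yy <- tibble::tibble(ind1 = "yes", ind2 = "yes", w = 1)
  expect_equal(observed_loglik(d_yy, cb2, spec2, p2), log(0.41), tolerance = 1e-12)

  # missing item dropped from the product
  d_ym <- tibble::tibble(ind1 = "yes", ind2 = NA_character_, w = 1)
  expect_equal(observed_loglik(d_ym, cb2, spec2, p2), log(0.5), tolerance = 1e-12)
})

test_that("observed_loglik equals brute-force class enumeration on toy cases", {
  for (seed in 1:6) {
    td <- random_toy_data(n = 8, n_bin = 2, seed = seed)
    spec <- lca_spec(td$cb, 2, "unconstrained", G = 2)
    params <- random_initial_params(spec, td$cb, seed + 100)
    expect_equal(observed_loglik(td$data, td$cb, spec, params),
                 oracle_loglik(td$data, td$cb, spec, params),
                 tolerance = 1e-12)
    # and with some missingness on one indicator
    d2 <- td$data
    d2$ind2[1:3] <- NA
    expect_equal(observed_loglik(d2, td$cb, spec, params),
                 oracle_loglik(d2, td$cb, spec, params),
                 tolerance = 1e-12)
  }
})

test_that("posterior probabilities follow Bayes rule and its degenerate cases", {
  cb2 <- toy_codebook(n_bin = 2, group = FALSE)
  spec2 <- lca_spec(cb2, 2, G = 1)
  p2 <- toy_params(spec2, yes_prob = c(0.9, 0.1))
  d_yy <- tibble::tibble(ind1 = "yes", ind2 = "yes", w = 1)
  post <- posterior_probabilities(d_yy, cb2, spec2, p2)
  expect_equal(post$class_1, 0.405 / 0.41, tolerance = 1e-12)

  # identical classes: uniform posteriors everywhere
  p_same <- toy_params(spec2, yes_prob = c(0.7, 0.7))
  d <- tibble::tibble(ind1 = c("yes", "no"), ind2 = c("no", "no"), w = 1)
  post2 <- posterior_probabilities(d, cb2, spec2, p_same)
  expect_equal(unlist(post2), rep(0.5, 4), ignore_attr = TRUE)

  # K = 1: all posteriors exactly 1
  cb1 <- toy_codebook(n_bin = 1, group = FALSE)
  spec1 <- lca_spec(cb1, 1, G = 1)
  post3 <- posterior_probabilities(tibble::tibble(ind1 = c("yes", "no"), w = 1),
                                   cb1, spec1, toy_params(spec1, matrix(0.3, 1, 1)))
  expect_identical(unname(unlist(post3)), c(1, 1))
})

test_that("posterior rows sum to one on random parameter sets", {
  td <- random_toy_data(n = 60, n_bin = 3, seed = 4)
  spec <- lca_spec(td$cb, 3, "unconstrained", G = 2)
  for (s in 1:5) {
    params <- random_initial_params(spec, td$cb, s)
    post <- posterior_probabilities(td$data, td$cb, spec, params)
    expect_true(all(abs(rowSums(as.matrix(post)) - 1) < 1e-10))
    expect_true(all(as.matrix(post) >= 0 & as.matrix(post) <= 1))
  }
})

test_that("relabelling classes leaves the likelihood unchanged exactly", {
  td <- random_toy_data(n = 50, n_bin = 3, seed = 9)
  spec <- lca_spec(td$cb, 3, "unconstrained", G = 2)
  params <- random_initial_params(spec, td$cb, 42)
  ll <- observed_loglik(td$data, td$cb, spec, params)
  for (perm in list(c(2, 1, 3), c(3, 1, 2), c(1, 3, 2))) {
    pp <- lcatrends:::permute_classes(params, perm, spec)
    expect_equal(observed_loglik(td$data, td$cb, spec, pp), ll, tolerance = 1e-10)
  }
})

test_that("integer weights reproduce the row-expanded likelihood exactly", {
  td <- random_toy_data(n = 20, n_bin = 2, seed = 3)
  d <- td$data
  d$w <- sample(1:3, nrow(d), replace = TRUE)
  expanded <- d[rep(seq_len(nrow(d)), d$w), ]
  expanded$w <- 1
  spec <- lca_spec(td$cb, 2, "unconstrained", G = 2)
  params <- random_initial_params(spec, td$cb, 5)
  expect_equal(
    observed_loglik(d, td$cb, spec, params, normalise_weights = FALSE),
    observed_loglik(expanded, td$cb, spec, params, normalise_weights = FALSE),
    tolerance = 1e-10)
})

test_that("missing covariates and all-missing rows are refused", {
  cb <- toy_codebook(n_bin = 2, covariate = TRUE, group = FALSE)
  spec <- lca_spec(cb, 2, G = 1)
  params <- toy_params(spec, yes_prob = c(0.8, 0.2),
                       beta = array(0.5, c(1, 1, 1)))
  d <- tibble::tibble(ind1 = c("yes", "no"), ind2 = c("no", "no"),
                      sex = c("male", NA), w = 1)
  expect_error(observed_loglik(d, cb, spec, params),
               class = "lcat_missing_covariate")
  d2 <- tibble::tibble(ind1 = c("yes", NA), ind2 = c("no", NA),
                       sex = "male", w = 1)
  expect_error(observed_loglik(d2, cb, spec, params), class = "lcat_all_missing")
})
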