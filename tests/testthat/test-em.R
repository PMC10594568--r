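test_that("M-step with hard posteriors equals weighted category frequencies", {
  td <- random_toy_data(n = 40, n_bin = 2, seed = 7)
  spec <- lca_spec(td$cb, 2, "unconstrained", G = 2)
  cur <- random_initial_params(spec, td$cb, 1)
  P <- matrix(0, 40, 2)
  assign <- rep(c(1L, 2L), 20)
  P[cbind(1:40, assign)] <- 1
  up <- update_parameters(P, td$data, td$cb, spec, cur)
  d <- td$data
  w <- d$w / mean(d$w)
  g <- match(d$grp, sort(unique(d$grp)))
  for (gg in 1:2) for (cc in 1:2) {
    sel <- g == gg & assign == cc
    freq <- sum(w[sel & d$ind1 == "yes"]) / sum(w[sel])
    expect_equal(up$rho$ind1[gg, cc, 2], freq, tolerance = 1e-5)
  }
})

test_that("M-step with uniform posteriors pools all classes identically", {
  td <- random_toy_data(n = 30, n_bin = 2, seed = 8)
  spec <- lca_spec(td$cb, 3, "unconstrained", G = 2)
  cur <- random_initial_params(spec, td$cb, 2)
  P <- matrix(1 / 3, 30, 3)
  up <- update_parameters(P, td$data, td$cb, spec, cur)
  # every class's rho equals the pooled weighted frequencies
  expect_equal(up$rho$ind1[, 1, ], up$rho$ind1[, 2, ], tolerance = 1e-9)
  expect_equal(up$rho$ind1[, 2, ], up$rho$ind1[, 3, ], tolerance = 1e-9)
})

test_that("doubling a row's weight equals duplicating the row in the M-step", {
  cb <- toy_codebook(n_bin = 2, group = FALSE)
  spec <- lca_spec(cb, 2, G = 1)
  cur <- random_initial_params(spec, cb, 3)
  d3 <- tibble::tibble(ind1 = c("yes", "no", "yes"), ind2 = c("no", "no", "yes"),
                       w = c(2, 1, 1))
  d4 <- tibble::tibble(ind1 = c("yes", "yes", "no", "yes"),
                       ind2 = c("no", "no", "no", "yes"), w = 1)
  P3 <- matrix(c(0.8, 0.3, 0.6, 0.2, 0.7, 0.4), 3, 2)
  P4 <- P3[c(1, 1, 2, 3), ]
  u3 <- update_parameters(P3, d3, cb, spec, cur)
  u4 <- update_parameters(P4, d4, cb, spec, cur)
  expect_equal(u3$rho, u4$rho, tolerance = 1e-9)
  expect_equal(u3$alpha, u4$alpha, tolerance = 1e-6)
})

test_that("M-step flags a class with no posterior mass", {
  td <- random_toy_data(n = 20, n_bin = 2, seed = 10)
  spec <- lca_spec(td$cb, 2, "unconstrained", G = 2)
  cur <- random_initial_params(spec, td$cb, 4)
  P <- cbind(rep(1, 20), rep(0, 20))
  err <- tryCatch(update_parameters(P, td$data, td$cb, spec, cur),
                  lcat_degenerate_class = function(e) e)
  expect_s3_class(err, "lcat_degenerate_class")
  expect_identical(err$class_index, 2L)
})

test_that("random starts are seed-deterministic and valid simplices", {
  cb <- default_codebook()
  spec <- lca_spec(cb, 3, "unconstrained", G = 4)
  a <- random_initial_params(spec, cb, 7)
  b <- random_initial_params(spec, cb, 7)
  expect_identical(a, b)
  c_ <- random_initial_params(spec, cb, 8)
  expect_false(identical(a, c_))
  for (j in spec$indicators) {
    sums <- apply(a$rho[[j]], c(1, 2), sum)
    expect_true(all(abs(sums - 1) < 1e-12))
  }
})

test_that("K = 1 EM converges immediately to weighted category frequencies", {
  cb <- toy_codebook(n_bin = 1, group = FALSE)
  spec <- lca_spec(cb, 1, G = 1)
  d <- tibble::tibble(ind1 = c("yes", "yes", "no", "no", "no"),
                      w = c(2, 1, 1, 1, 1))
  fit <- fit_single_start(d, cb, spec, init = toy_params(spec, matrix(0.5, 1, 1)))
  expect_lte(fit$n_iter, 3)
  freq <- 3 / 6  # weighted: (2+1)/(2+1+1+1+1)
  expect_equal(fit$params$rho$ind1[1, 1, 2], freq, tolerance = 1e-6)
  # loglik equals the closed-form single-class value
  w <- d$w / mean(d$w)
  ll <- sum(w * ifelse(d$ind1 == "yes", log(freq), log(1 - freq)))
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
})

test_that("EM attains the grid-search optimum on a tiny two-class problem", {
  cb <- toy_codebook(n_bin = 2, weight = TRUE, group = FALSE)
  d <- tibble::tibble(
    ind1 = c("yes", "yes", "yes", "no", "no", "no", "yes", "no"),
    ind2 = c("yes", "yes", "no", "no", "no", "yes", "yes", "no"),
    w = 1)
  spec <- lca_spec(cb, 2, G = 1)
  ms <- suppressWarnings(fit_multistart(d, cb, spec, n_starts = 30, seed = 5,
                                        refine_top = 30))
  expect_gte(ms$best$loglik, grid_search_loglik(d, cb) - 1e-3)
})

test_that("perfectly separated patterns drive rho to the floor and pure posteriors", {
  cb <- toy_codebook(n_bin = 2, group = FALSE)
  d <- tibble::tibble(ind1 = rep(c("yes", "no"), each = 10),
                      ind2 = rep(c("yes", "no"), each = 10), w = 1)
  spec <- lca_spec(cb, 2, G = 1)
  ms <- suppressWarnings(fit_multistart(d, cb, spec, n_starts = 20, seed = 2,
                                        refine_top = 20))
  fit <- ms$best
  yes_prob <- sort(c(fit$params$rho$ind1[1, , 2]))
  expect_lt(yes_prob[1], 1e-4)
  expect_gt(yes_prob[2], 1 - 1e-4)
  post <- posterior_probabilities(d, cb, spec, fit$params)
  expect_true(all(pmax(post$class_1, post$class_2) > 1 - 1e-6))
})

test_that("EM log-likelihood is monotone on random data", {
  for (seed in 1:4) {
    td <- random_toy_data(n = 150, n_bin = 3, seed = seed)
    spec <- lca_spec(td$cb, 2, "unconstrained", G = 2)
    fit <- fit_single_start(td$data, td$cb, spec,
                            init = random_initial_params(spec, td$cb, seed))
    steps <- diff(fit$loglik_trace)
    expect_true(all(steps > -1e-8 * (abs(fit$loglik) + 1)))
  }
})
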