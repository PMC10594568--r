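test_that("generation is deterministic and has the configured shape", {
  sc <- scaled_default_scenario(200)
  s1 <- generate_dataset(sc, seed = 42)
  s2 <- generate_dataset(sc, seed = 42)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$true_class, s2$true_class)
  s3 <- generate_dataset(sc, seed = 43)
  expect_false(identical(s1$data, s3$data))
  # row counts per wave
  expect_equal(unname(table(s1$data$wave)), rep(200L, 4), ignore_attr = TRUE)
  expect_false(anyNA(s1$data))
  expect_equal(mean(s1$data$weight), 1, tolerance = 1e-12)
})

test_that("a degenerate one-class concentrated scenario yields constant codes", {
  cbk <- toy_codebook(n_bin = 2, weight = TRUE, group = TRUE)
  arr <- array(0, c(1, 1, 2)); arr[, , 1] <- 1   # all mass on "no"
  sc <- lca_scenario(cbk, n_per_group = 50L, group_labels = "w1",
                     membership = matrix(1, 1, 1), class_labels = "only",
                     covariate_marginals = list(),
                     covariate_or = matrix(numeric(0), 0, 0),
                     rho = list(ind1 = arr, ind2 = arr),
                     cluster_sd = 0, weight_sdlog = 0)
  sim <- generate_dataset(sc, seed = 1)
  expect_true(all(sim$data$ind1 == "no"))
  expect_true(all(sim$data$ind2 == "no"))
  expect_true(all(sim$true_class == 1L))
})

test_that("empirical category frequencies match the truth CRPs at large n", {
  sc <- default_scenario()
  sc$n_per_group <- 100000L
  sc$group_labels <- sc$group_labels[1]
  sc$membership <- sc$membership[1, , drop = FALSE]
  sc$rho <- lapply(sc$rho, function(a) a[1, , , drop = FALSE])
  sc$cluster_sd <- 0
  sim <- generate_dataset(sc, seed = 7)
  for (j in c("alcohol_weekly", "life_satisfaction")) {
    cats <- sc$codebook$categories[[match(j, sc$codebook$name)]]
    for (cl in 1:3) {
      emp <- prop.table(table(factor(sim$data[[j]][sim$true_class == cl],
                                     levels = cats)))
      expect_lt(max(abs(as.numeric(emp) - sc$rho[[j]][1, cl, ])), 0.01)
    }
  }
})

test_that("per-wave true-class shares stay within three binomial SDs", {
  sc <- scaled_default_scenario(1200)
  sc$cluster_sd <- 0    # binomial bound applies to the pure multinomial draw
  sim <- generate_dataset(sc, seed = 11)
  g <- match(sim$data$wave, sc$group_labels)
  for (gg in 1:4) {
    shares <- prop.table(table(factor(sim$true_class[g == gg], levels = 1:3)))
    p <- sc$membership[gg, ]
    bound <- 3 * sqrt(p * (1 - p) / 1200)
    expect_true(all(abs(as.numeric(shares) - p) <= bound))
  }
})

test_that("covariate effects on membership are generated at their truth", {
  sc <- default_scenario()
  sc$n_per_group <- c(60000L, 100L, 100L, 100L)
  sc$cluster_sd <- 0
  sim <- generate_dataset(sc, seed = 13)
  keep <- sim$data$wave == "2001/02" & sim$true_class %in% c(1, 3)
  d <- sim$data[keep, ]
  y <- as.numeric(sim$true_class[keep] == 1)
  fit <- stats::glm(y ~ I(sex == "female") + I(fas == "middle") + I(fas == "high"),
                    data = d, family = stats::binomial())
  expect_equal(unname(fit$coefficients[2]), log(1.74), tolerance = 0.1)
  expect_equal(unname(fit$coefficients[4]), log(0.18), tolerance = 0.1)
})

test_that("missingness injection respects rates and never empties a row", {
  sc <- scaled_default_scenario(1486)   # n = 5944, close to the study size
  sim <- generate_dataset(sc, seed = 3)
  # zero rates: unchanged
  expect_identical(inject_missingness(sim$data, sc$codebook,
                                      c(sex = 0, alcohol_weekly = 0), seed = 1),
                   sim$data)
  # rate 1 on a covariate: all missing
  d1 <- inject_missingness(sim$data, sc$codebook, c(sex = 1), seed = 1)
  expect_true(all(is.na(d1$sex)))
  # published-rate binomial band for sexual activity (266 of 5,942)
  rate <- 266 / 5942
  d2 <- inject_missingness(sim$data, sc$codebook,
                           c(sexual_activity = rate), seed = 9)
  n <- nrow(sim$data)
  expect_lt(abs(sum(is.na(d2$sexual_activity)) - n * rate),
            3 * sqrt(n * rate * (1 - rate)))
  # full default missingness never wipes out a row's indicators
  d3 <- inject_missingness(sim$data, sc$codebook, sc$missingness, seed = 5)
  ind <- as.matrix(d3[indicator_names(sc$codebook)])
  expect_true(all(rowSums(!is.na(ind)) >= 1))
  # deterministic
  expect_identical(d3, inject_missingness(sim$data, sc$codebook,
                                          sc$missingness, seed = 5))
  # MAR mode: covariate missingness concentrates on the conditioning rows
  d4 <- inject_missingness(sim$data, sc$codebook, c(fas = 0.1), seed = 7,
                           mar = list(indicator = "alcohol_weekly",
                                      category = "weekly", multiplier = 3))
  drinker <- sim$data$alcohol_weekly == "weekly"
  rate_drinker <- mean(is.na(d4$fas[drinker]))
  rate_other <- mean(is.na(d4$fas[!drinker]))
  expect_gt(rate_drinker, 2 * rate_other)
})

test_that("simulation bundles round-trip to disk", {
  sc <- scaled_default_scenario(80)
  sim <- generate_dataset(sc, seed = 2)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_true(file.exists(file.path(dir, "dataset.csv")))
  cb2 <- read_codebook(file.path(dir, "codebook.json"))
  d2 <- read_lca_data(file.path(dir, "dataset.csv"), cb2)
  expect_equal(nrow(d2), nrow(sim$data))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$seed, 2)
  expect_equal(truth$true_class, sim$true_class)
})
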