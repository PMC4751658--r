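test_that("fit_probit validates inputs and is seed-deterministic", {
  sim <- simulate_population(K = 1, n_per_class = 60, m = 40, F = 0.1, seed = 51)
  tr <- simulate_liability_trait(sim$genotypes, h2 = 0.5, seed = 52)
  Z <- center_markers(sim$genotypes)$M
  expect_error(fit_probit(rep(1, 60), Z), "degenerate")
  expect_error(fit_probit(c(2, tr$y[-1]), Z), "binary")
  Zbad <- Z; Zbad[1, 1] <- NA
  expect_error(fit_probit(tr$y, Zbad), "non-finite")
  f1 <- fit_probit(tr$y, Z, spec = reduced_spec(seed = 9))
  f2 <- fit_probit(tr$y, Z, spec = reduced_spec(seed = 9))
  expect_identical(f1$u, f2$u)
  expect_identical(f1$sigma2_u, f2$sigma2_u)
  f3 <- fit_probit(tr$y, Z, spec = reduced_spec(seed = 10))
  expect_false(identical(f1$sigma2_u, f3$sigma2_u))
  expect_equal(f1$n_kept, 1000L)
})

test_that("all three priors run and produce stationary variance chains", {
  sim <- simulate_population(K = 1, n_per_class = 120, m = 80, F = 0.1, seed = 53)
  tr <- simulate_liability_trait(sim$genotypes, h2 = 0.6, seed = 54)
  Z <- center_markers(sim$genotypes)$M
  for (prior in c("ridge", "bayes_a", "bayes_c_pi")) {
    fit <- fit_probit(tr$y, Z, spec = reduced_spec(prior, seed = 55,
                                                   n_iter = 3000, burn_in = 1000))
    expect_s3_class(fit, "probit_fit")
    expect_lt(abs(geweke_z(fit$sigma2_u)), 3)
    if (prior == "bayes_c_pi") {
      expect_true(all(fit$pi >= 0 & fit$pi <= 1))
      expect_true(all(fit$incl_prob >= 0 & fit$incl_prob <= 1))
    }
  }
})

test_that("predictive probability is Phi(0) = 0.5 for a null sample under a null fit", {
  # balanced response, zero features: intercept posterior centred at 0
  set.seed(56)
  y <- rep(c(0L, 1L), 30)
  Z <- matrix(rnorm(60), ncol = 1)
  fit <- fit_probit(y, Z, spec = reduced_spec(seed = 57, n_iter = 4000, burn_in = 1000))
  p0 <- predict_prob(fit, matrix(0, 1, 1))
  expect_equal(p0, 0.5, tolerance = 0.05)
  # duplicated rows get identical probabilities
  p2 <- predict_prob(fit, rbind(Z[1, , drop = FALSE], Z[1, , drop = FALSE]))
  expect_equal(p2[1], p2[2])
  expect_error(predict_prob(fit, matrix(0, 1, 3)), "mismatch")
})

test_that("strong single-feature signal yields confident, well-ordered predictions", {
  set.seed(58)
  z <- c(runif(40, -4, -1), runif(40, 1, 4)) # separated with a clear margin
  y <- as.integer(z > 0)
  fit <- fit_probit(y, matrix(z, ncol = 1),
                    spec = reduced_spec(seed = 59, n_iter = 4000, burn_in = 1000))
  p <- predict_prob(fit, matrix(z, ncol = 1))
  # every training point confidently correct; stronger at larger margins
  expect_true(all(p[y == 1] >= 0.9) && all(p[y == 0] <= 0.1))
  expect_true(all(p[y == 1 & abs(z) >= 2] >= 0.95))
  expect_true(all(p[y == 0 & abs(z) >= 2] <= 0.05))
})

test_that("null features give predictive probabilities near the class frequency", {
  sim <- simulate_population(K = 1, n_per_class = 150, m = 60, F = 0.1, seed = 60)
  Z <- center_markers(sim$genotypes)$M
  set.seed(61)
  y <- rbinom(150, 1, 0.5) # independent of genotypes
  fit <- fit_probit(y, Z, spec = reduced_spec(seed = 62, n_iter = 4000, burn_in = 1500))
  p <- predict_prob(fit, Z)
  # no individual confidently classified, probabilities centred on base rate
  expect_true(all(p > 0.05 & p < 0.95))
  expect_lt(mean(abs(p - mean(y))), 0.15)
  expect_lt(abs(mean(p) - mean(y)), 0.05)
})

test_that("posterior predictions correlate with true liabilities under strong signal", {
  sim <- simulate_population(K = 1, n_per_class = 200, m = 100, F = 0.1, seed = 63)
  tr <- simulate_liability_trait(sim$genotypes, h2 = 0.9, seed = 64)
  Z <- center_markers(sim$genotypes)$M
  fit <- fit_probit(tr$y, Z, spec = reduced_spec(seed = 65, n_iter = 3000, burn_in = 1000))
  p <- predict_prob(fit, Z)
  expect_gt(cor(p, tr$liability), 0.8)
})

test_that("heritability transforms the variance component correctly", {
  fit <- structure(list(var_g = c(1, 1), sigma2_u = c(3, 3)),
                   class = "probit_fit")
  expect_equal(heritability_from_fit(fit, "marker")$h2_mean, 0.5)
  expect_equal(heritability_from_fit(fit, "relationship")$h2_mean, 0.75)
  expect_equal(heritability_from_fit(fit, "pedigree")$h2_mean, 0.75)
})

test_that("tidy and glance return well-formed summaries", {
  sim <- simulate_population(K = 1, n_per_class = 50, m = 20, F = 0.1, seed = 66)
  tr <- simulate_liability_trait(sim$genotypes, h2 = 0.5, seed = 67)
  fit <- fit_probit(tr$y, center_markers(sim$genotypes)$M,
                    spec = reduced_spec(seed = 68))
  td <- tidy(fit)
  expect_equal(nrow(td), 20L)
  expect_named(td, c("term", "estimate", "std.error", "incl_prob"))
  gl <- glance(fit)
  expect_equal(gl$prior, "ridge")
  expect_equal(gl$n, 50L)
})

test_that("fit results persist to a directory of plain-text chains", {
  sim <- simulate_population(K = 1, n_per_class = 30, m = 10, F = 0.1, seed = 69)
  tr <- simulate_liability_trait(sim$genotypes, h2 = 0.5, seed = 70)
  fit <- fit_probit(tr$y, center_markers(sim$genotypes)$M,
                    spec = reduced_spec(seed = 71, n_iter = 600, burn_in = 100))
  dir <- withr::local_tempdir()
  write_fit(fit, dir)
  expect_true(all(file.exists(file.path(dir,
    c("chain_b.tsv", "chain_u.tsv", "chain_scalars.tsv", "fit_meta.json")))))
  meta <- jsonlite::read_json(file.path(dir, "fit_meta.json"))
  expect_equal(meta$n_kept, fit$n_kept)
  u <- as.matrix(utils::read.table(file.path(dir, "chain_u.tsv")))
  expect_equal(dim(u), dim(fit$u))
})
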