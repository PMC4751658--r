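test_that("OVA normalization divides by the sum and is scale-invariant", {
  expect_equal(unname(normalize_ova(c(0.5, 0.5, 0.5, 0.5))), rep(0.25, 4))
  expect_equal(unname(normalize_ova(c(0.9, 0.3, 0.3, 0.3))),
               c(0.5, 1/6, 1/6, 1/6))
  expect_equal(unname(normalize_ova(c(0.8, 0.2))), c(0.8, 0.2))
  set.seed(71)
  for (i in 1:20) {
    v <- runif(sample(2:6, 1), 0.01, 0.99)
    expect_equal(normalize_ova(0.37 * v), normalize_ova(v), tolerance = 1e-12)
  }
})

test_that("pairwise table enforces complementarity and interior clipping", {
  P <- matrix(c(NA, 0.8, 0.2, NA), 2, 2, byrow = TRUE)
  pt <- pairwise_prob_table(P)
  expect_equal(pt$p[2, 1], 1 - pt$p[1, 2])
  P2 <- matrix(c(NA, 1, 0, NA), 2, 2, byrow = TRUE)
  pt2 <- pairwise_prob_table(P2)
  expect_true(all(pt2$p[!is.na(pt2$p)] > 0 & pt2$p[!is.na(pt2$p)] < 1))
})

test_that("OVO voting follows the counting measure and breaks ties low", {
  # class 2 of 4 wins all three pairings: p_2 = 3 * 2/12 = 0.5
  P <- matrix(0.4, 4, 4)
  P[2, ] <- 0.9; P[, 2] <- 0.1; diag(P) <- NA
  v <- vote_ovo(pairwise_prob_table(P))
  expect_equal(unname(v$p[2]), 0.5)
  expect_equal(v$class, "C2")
  # K=2 with p_12 = 0.7: class 1 takes all mass
  v2 <- vote_ovo(pairwise_prob_table(matrix(c(NA, 0.7, 0.3, NA), 2, 2, byrow = TRUE)))
  expect_equal(unname(v2$p), c(1, 0))
  # cyclic wins: uniform measure, tie broken to class 1 with a warning
  P3 <- matrix(NA, 3, 3)
  P3[1, 2] <- 0.6; P3[2, 3] <- 0.6; P3[3, 1] <- 0.6
  P3[2, 1] <- 0.4; P3[3, 2] <- 0.4; P3[1, 3] <- 0.4
  expect_warning(v3 <- vote_ovo(pairwise_prob_table(P3)), "tie")
  expect_equal(unname(v3$p), rep(1/3, 3))
  expect_equal(v3$class, "C1")
})

test_that("pairwise coupling solves the toy fixed points", {
  p2 <- couple_ovo(pairwise_prob_table(matrix(c(NA, 0.8, 0.2, NA), 2, 2, byrow = TRUE)))
  expect_equal(unname(p2), c(0.8, 0.2), tolerance = 1e-10)
  p3 <- couple_ovo(pairwise_prob_table(matrix(0.5, 3, 3)))
  expect_equal(unname(p3), rep(1/3, 3), tolerance = 1e-10)
  # table generated from p = (0.5, 0.3, 0.2)
  P <- consistent_pair_table(c(0.5, 0.3, 0.2))
  expect_equal(unname(couple_ovo(pairwise_prob_table(P))), c(0.5, 0.3, 0.2),
               tolerance = 1e-8)
})

test_that("coupling inverts the consistent-table map and matches the oracle", {
  set.seed(72)
  for (i in 1:40) {
    K <- sample(2:6, 1)
    p <- rgamma(K, 1) + 0.02
    p <- p / sum(p)
    P <- consistent_pair_table(p)
    rec <- couple_ovo(pairwise_prob_table(P))
    expect_lt(max(abs(rec - p)), 1e-8)
  }
  # independent solver agreement on an inconsistent (noisy) table
  set.seed(73)
  p <- c(0.4, 0.35, 0.25)
  P <- consistent_pair_table(p)
  P[1, 2] <- min(max(P[1, 2] + 0.05, 0.01), 0.99); P[2, 1] <- 1 - P[1, 2]
  rec <- couple_ovo(pairwise_prob_table(P))
  ora <- couple_oracle(P)
  expect_lt(max(abs(rec - ora)), 0.02)
})

test_that("coupling and voting agree on the argmax for a dominant class", {
  set.seed(74)
  for (i in 1:10) {
    K <- sample(3:5, 1)
    P <- matrix(runif(K * K, 0.2, 0.8), K, K)
    win <- sample(K, 1)
    P[win, ] <- runif(K, 0.55, 0.95) # dominant class wins every pairing
    for (a in 1:(K-1)) for (b in (a+1):K) P[b, a] <- 1 - P[a, b]
    P[win, ] <- pmax(P[win, ], 0.55); P[, win] <- 1 - P[win, ]
    diag(P) <- NA
    pt <- pairwise_prob_table(P)
    expect_equal(classify(couple_ovo(pt)), vote_ovo(pt)$class)
  }
})

test_that("classify picks the argmax and warns on ties", {
  expect_equal(classify(c(a = 0.1, b = 0.7, c = 0.2)), "b")
  expect_warning(out <- classify(c(a = 0.5, b = 0.5)), "tie")
  expect_equal(out, "a")
})

test_that("OVA and OVO training produce the right number and kind of fits", {
  sim <- simulate_population(K = 4, n_per_class = 10, m = 60, F = 0.3, seed = 75)
  X <- feature_source(sim$genotypes, "markers")
  suppressWarnings({
    ova <- train_ova(X, sim$labels$class, spec = reduced_spec(n_iter = 300, burn_in = 100))
    ovo <- train_ovo(X, sim$labels$class, spec = reduced_spec(n_iter = 300, burn_in = 100))
  })
  expect_length(ova$fits, 4L)
  expect_length(ovo$fits, 6L)
  expect_error(train_ova(X, factor(rep("A", 40))), "2 classes")
  # K = 2: the two OVA fits see complementary labels
  sim2 <- simulate_population(K = 2, n_per_class = 10, m = 40, F = 0.3, seed = 76)
  X2 <- feature_source(sim2$genotypes, "markers")
  ova2 <- train_ova(X2, sim2$labels$class, spec = reduced_spec(n_iter = 300, burn_in = 100))
  expect_length(ova2$fits, 2L)
  expect_equal(ova2$fits[[1]]$success_rate, 1 - ova2$fits[[2]]$success_rate)
})

test_that("well-trained OVA model classifies its own training points", {
  sim <- simulate_population(K = 3, n_per_class = 12, m = 200, F = 0.25, seed = 77)
  X <- feature_source(sim$genotypes, "markers")
  ova <- train_ova(X, sim$labels$class, spec = reduced_spec(n_iter = 1000, burn_in = 300))
  pred <- predict(ova, X)
  expect_gt(accuracy(pred$predicted_class, sim$labels$class), 0.95)
  probs <- as.matrix(pred[, paste0("p_", ova$classes)])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-9)
})

test_that("multiclass schemes are backend-agnostic", {
  # two stub backends returning identical deterministic probabilities
  stub <- function(shift) list(
    train = function(X, y, seed, ...) list(w = colMeans(X * y) - colMeans(X * (1 - y))),
    predict_prob = function(model, X_new)
      pmin(pmax(pnorm(as.numeric(X_new %*% model$w)), 1e-6), 1 - 1e-6))
  register_backend("stub_a", stub(0))
  register_backend("stub_b", stub(0))
  withr::defer(genoclass:::register_builtin_backends())
  sim <- simulate_population(K = 3, n_per_class = 8, m = 50, F = 0.3, seed = 78)
  X <- feature_source(sim$genotypes, "markers")
  m1 <- suppressWarnings(train_ova(X, sim$labels$class, backend = "stub_a"))
  m2 <- suppressWarnings(train_ova(X, sim$labels$class, backend = "stub_b"))
  expect_equal(predict(m1, X)[, -1], predict(m2, X)[, -1])
})

test_that("breeding values reduce to uniform at base frequencies and sum to zero", {
  sim <- simulate_population(K = 3, n_per_class = 12, m = 100, F = 0.3, seed = 79)
  X <- center_markers(sim$genotypes)$M
  ova <- train_ova(X, sim$labels$class, spec = reduced_spec(n_iter = 800, burn_in = 200))
  f <- pmin(pmax(sim$genotypes$freq, 0.01), 0.99)
  p0 <- rep(1/3, 3)
  # candidate at twice the base frequencies with zeroed fixed effects
  ova0 <- ova
  for (k in 1:3) {
    ova0$fits[[k]]$b[] <- 0
    ova0$fits[[k]]$post_mean_b[] <- 0
  }
  bv0 <- breeding_values(2 * f, f, ova0, p0)
  expect_equal(as.numeric(bv0[1, paste0("p_", ova$classes)]), rep(1/3, 3),
               tolerance = 1e-12)
  # g_n sums to zero for arbitrary candidates
  bv <- breeding_values(sim$genotypes$dosage[1:4, ], f, ova, p0)
  gsum <- rowSums(as.matrix(bv[, paste0("g_", ova$classes)]))
  expect_equal(unname(gsum), rep(0, 4), tolerance = 1e-12)
  expect_error(breeding_values(rep(1, 5), f, ova, p0), "marker mismatch")
})

test_that("a class-typical homozygous candidate gets its class's top offspring fraction", {
  sim <- simulate_population(K = 2, n_per_class = 25, m = 300, F = 0.4, seed = 80)
  X <- center_markers(sim$genotypes)$M
  ova <- train_ova(X, sim$labels$class, spec = reduced_spec(n_iter = 1000, burn_in = 300))
  f <- pmin(pmax(sim$genotypes$freq, 0.01), 0.99)
  # candidate homozygous for pop1-enriched alleles
  enriched <- sim$truth$p_sub[, 1] > sim$truth$p_sub[, 2]
  z <- ifelse(enriched, 2, 0)
  bv <- breeding_values(z, f, ova, p_0 = c(0.5, 0.5))
  expect_equal(classify(setNames(as.numeric(bv[1, c("p_pop1", "p_pop2")]),
                                 c("pop1", "pop2"))), "pop1")
})
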