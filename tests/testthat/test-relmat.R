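test_that("marker centering matches hand arithmetic and rejects degenerate f", {
  g <- genotype_matrix(matrix(c(0, 1, 2), ncol = 1,
                              dimnames = list(c("a", "b", "c"), "m1")))
  cm <- center_markers(g, f = 0.5)
  expect_equal(unname(cm$M[, 1]), c(-1, 0, 1))
  expect_equal(cm$denom, 0.5)
  expect_error(center_markers(g, f = 1), "degenerate")
  # training frequencies applied to a held-out genotype
  expect_equal(unname(2 - 2 * 0.5), 1)
  # monomorphic marker under sample frequencies contributes zeros
  g2 <- genotype_matrix(cbind(m1 = c(0, 0, 0), m2 = c(0, 1, 2)))
  cm2 <- center_markers(g2)
  expect_equal(unname(cm2$M[, 1]), c(0, 0, 0))
  expect_equal(cm2$denom, 2 * 0.5 * 0.5)
})

test_that("GRM reproduces the VanRaden hand example and is symmetric", {
  g <- toy_genotypes()
  G <- grm(center_markers(g, f = c(0.5, 0.5)))
  expect_equal(unname(G$values),
               matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3, 3))
  expect_equal(G$values, t(G$values))
  # duplicated individuals give equal rows
  g2 <- genotype_matrix(rbind(a = c(0, 2), b = c(0, 2), c = c(2, 0)))
  G2 <- grm(g2)
  expect_equal(G2$values[1, ], G2$values[2, ], ignore_attr = TRUE)
})

test_that("own-sample centering makes off-diagonal G negative on average", {
  sim <- simulate_population(K = 2, n_per_class = 25, m = 400, F = 0.1, seed = 31)
  G <- grm(sim$genotypes)
  off <- G$values[lower.tri(G$values)]
  expect_lt(mean(off), 0)
})

test_that("pedigree A matches the tabular base cases", {
  ped <- tibble::tibble(id = c("S", "O"), sire = c(NA, "S"), dam = c(NA, NA))
  A <- nrm(ped)
  expect_equal(A$values["S", "O"], 0.5)
  expect_equal(A$values["O", "O"], 1)
  # full sibs share 0.5
  ped2 <- tibble::tibble(id = c("S", "D", "o1", "o2"),
                         sire = c(NA, NA, "S", "S"),
                         dam = c(NA, NA, "D", "D"))
  expect_equal(nrm(ped2)$values["o1", "o2"], 0.5)
  # offspring of half sibs: inbreeding 0.125, diagonal 1.125
  ped3 <- tibble::tibble(id = c("S", "h1", "h2", "X"),
                         sire = c(NA, "S", "S", "h1"),
                         dam = c(NA, NA, NA, "h2"))
  expect_equal(nrm(ped3)$values["X", "X"], 1.125)
})

test_that("pedigree A equals the recursive-kinship oracle on a random pedigree", {
  set.seed(41)
  n <- 20
  ids <- paste0("i", 1:n)
  sire <- dam <- rep(NA_character_, n)
  for (i in 5:n) { # first 4 founders; parents drawn from earlier individuals
    pick <- sample(seq_len(i - 1L), 2)
    sire[i] <- ids[pick[1]]; dam[i] <- ids[pick[2]]
  }
  ped <- tibble::tibble(id = ids, sire = sire, dam = dam)
  A <- nrm(ped)
  O <- kinship_oracle(ped)
  expect_equal(A$values[ids, ids], O, tolerance = 1e-12)
})

test_that("pedigree cycles are detected", {
  ped <- tibble::tibble(id = c("a", "b"), sire = c("b", "a"),
                        dam = c(NA, NA))
  expect_error(nrm(ped), "cycle")
})

test_that("eigendecomposition orders, reconstructs and accumulates variance", {
  Rid <- genoclass:::new_relmat(diag(3), "genomic", c("a", "b", "c"))
  ev <- relmat_eigen(Rid)
  expect_equal(ev$d, rep(1, 3))
  expect_equal(ev$cumvar, c(1, 2, 3) / 3)
  # rank-1 matrix: all variance on the first component
  v <- c(1, -1, 2)
  R1 <- genoclass:::new_relmat(outer(v, v), "genomic", c("a", "b", "c"))
  expect_equal(relmat_eigen(R1)$cumvar, rep(1, 3))
  # reconstruction on a simulated G
  sim <- simulate_population(K = 2, n_per_class = 15, m = 300, F = 0.2, seed = 42)
  G <- grm(sim$genotypes)
  ev2 <- relmat_eigen(G)
  expect_lt(norm(ev2$U %*% diag(ev2$d) %*% t(ev2$U) - G$values, "F"), 1e-8)
  # first eigenvector separates two diverged populations by sign
  cls <- sim$labels$class
  s1 <- sign(ev2$U[cls == "pop1", 1])
  s2 <- sign(ev2$U[cls == "pop2", 1])
  expect_true(all(s1 == s1[1]) && all(s2 == s2[1]) && s1[1] != s2[1])
})

test_that("Cholesky factor reproduces the matrix and the 2x2 closed form", {
  A <- genoclass:::new_relmat(matrix(c(1, 0.5, 0.5, 1), 2), "pedigree", c("a", "b"))
  L <- chol_lower(A)
  expect_equal(unname(L), matrix(c(1, 0.5, 0, sqrt(0.75)), 2))
  ped <- tibble::tibble(id = c("S", "O"), sire = c(NA, "S"), dam = c(NA, NA))
  Ap <- nrm(ped)
  Lp <- chol_lower(Ap)
  expect_lt(max(abs(Lp %*% t(Lp) - Ap$values)), 1e-10)
  expect_equal(unname(chol_lower(genoclass:::new_relmat(diag(4), "genomic",
                                                        paste0("s", 1:4)))),
               diag(4))
})

test_that("relationship summary recovers block structure and flags singletons", {
  n <- 6
  V <- matrix(0, n, n)
  V[1:3, 1:3] <- 0.1; diag(V) <- 1
  R <- genoclass:::new_relmat(V, "genomic", paste0("s", 1:n))
  lab <- toy_labels(paste0("s", 1:n), rep(c("A", "B"), each = 3))
  sm <- relationship_summary(R, lab)
  expect_equal(dplyr::filter(sm, class_a == "A", class_b == "A")$mean, 0.1)
  expect_equal(dplyr::filter(sm, class_a == "A", class_b == "B")$mean, 0)
  expect_equal(dplyr::filter(sm, class_a == "B", class_b == "B")$sd,
               0)
  # singleton class: within-class summary missing, between defined
  lab2 <- toy_labels(paste0("s", 1:n), c(rep("A", 5), "B"))
  sm2 <- relationship_summary(R, lab2)
  expect_true(is.na(dplyr::filter(sm2, class_a == "B", class_b == "B")$mean))
  expect_false(is.na(dplyr::filter(sm2, class_a == "A", class_b == "B")$mean))
})

test_that("within-class relationships exceed between-class in diverged simulations", {
  sim <- simulate_population(K = 2, n_per_class = 30, m = 500, F = 0.2, seed = 43)
  sm <- relationship_summary(grm(sim$genotypes), sim$labels)
  within <- dplyr::filter(sm, class_a == class_b)$mean
  between <- dplyr::filter(sm, class_a != class_b)$mean
  expect_true(all(within > between))
})
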