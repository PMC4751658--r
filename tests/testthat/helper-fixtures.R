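# shared fixtures, all generated in code

toy_genotypes <- function() {
  genotype_matrix(matrix(c(0, 2, 1, 1, 2, 0), nrow = 3, byrow = TRUE,
                         dimnames = list(c("a", "b", "c"), c("m1", "m2"))))
}

toy_labels <- function(samples, classes) {
  tibble::tibble(sample_id = samples,
                 class = factor(classes, levels = unique(classes)))
}

# small VCF written as text: 5 records, one multiallelic
write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\tv2\tC\tT\t.\tPASS\t.\tGT\t0/1\t0/1\t0/0",
    "1\t300\tv3\tG\tA,C\t.\tPASS\t.\tGT\t0/1\t0/2\t1/1",
    "2\t400\tv4\tT\tC\t.\tPASS\t.\tGT\t1/1\t./.\t0/0",
    "2\t500\tv5\tA\tT\t.\tPASS\t.\tGT\t0|1\t1|1\t0|0"), path)
  path
}

# independent recursive-kinship oracle: a(i,j) = 2*kinship
kinship_oracle <- function(ped) {
  ids <- ped$id
  sire <- ped$sire; dam <- ped$dam
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    ii <- match(i, ids); jj <- match(j, ids)
    if (is.na(ii) || is.na(jj)) return(0)
    if (i == j)
      return(0.5 * (1 + phi(sire[ii], dam[ii])))
    # recurse on the later individual (parents appear earlier)
    if (jj > ii) return(0.5 * (phi(i, sire[jj]) + phi(i, dam[jj])))
    0.5 * (phi(j, sire[ii]) + phi(j, dam[ii]))
  }
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(i))
    A[i, j] <- A[j, i] <- 2 * phi(ids[i], ids[j])
  A
}

# consistent pairwise table from a simplex vector via p_kk' = p_k/(p_k+p_k')
consistent_pair_table <- function(p) {
  P <- outer(p, p, function(a, b) a / (a + b))
  diag(P) <- NA_real_
  P
}

# independent coupling oracle: minimize the determining-system residual over
# the simplex via softmax-parameterized BFGS
couple_oracle <- function(P) {
  K <- nrow(P)
  obj <- function(theta) {
    p <- exp(c(theta, 0)); p <- p / sum(p)
    r <- 0
    for (k in 1:K) for (kp in 1:K) if (k != kp)
      r <- r + (P[k, kp] - p[k] / (p[k] + p[kp]))^2
    r
  }
  opt <- stats::optim(rep(0, K - 1), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  p <- exp(c(opt$par, 0)); p / sum(p)
}

reduced_spec <- function(prior = "ridge", seed = 1, n_iter = 1500, burn_in = 500)
  threshold_model_spec(prior, n_iter = n_iter, burn_in = burn_in, seed = seed)
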