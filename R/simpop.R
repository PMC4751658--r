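#' Simulate a structured multi-subpopulation SNP dataset
#'
#' Generates K diverged subpopulations under the Balding-Nichols model:
#' ancestral allele frequencies are drawn uniformly on `ancestral_freq_range`
#' and each subpopulation's per-marker frequency from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, so that the expected per-marker
#' between-population variance is `F p (1-p)`.  Markers are simulated
#' unlinked.  Optional half-sib family structure is built by drawing sires
#' per class and sampling offspring gametes from a genotyped sire and a
#' fresh population dam (dams are unique per offspring).  Optional admixture
#' turns a fraction `lambda` of one class into individuals whose alleles
#' come from either of two parent subpopulations according to an ancestry
#' mix.
#'
#' @param K number of subpopulations (classes).
#' @param n_per_class integer count per class (scalar recycled, or length K).
#' @param m number of markers.
#' @param F Balding-Nichols divergence parameter, scalar or per class;
#'   clamped below at 1e-6.
#' @param ancestral_freq_range interval for ancestral frequencies
#'   (default c(0.05, 0.95)).
#' @param admixture optional list with `classes` (length-2 character or
#'   index vector: donor, target), `lambda` (fraction of the target class
#'   that is admixed) and `mix` (probability an admixed allele comes from
#'   the donor population; default 0.5).
#' @param n_sires sires per class (0 = unrelated individuals, no pedigree
#'   families).
#' @param offspring_per_sire offspring per sire; sires are recycled until
#'   the class is filled.
#' @param seed integer seed; output is fully deterministic given the seed.
#' @return list with `genotypes` (a [genotype_matrix()]), `labels` (tibble
#'   `sample_id`, `class`), `pedigree` (tibble `id`, `sire`, `dam`), and
#'   `truth` (ancestral and subpopulation frequencies, F, ancestry of
#'   admixed individuals).
#' @export
simulate_population <- function(K = 2, n_per_class = 50, m = 1000, F = 0.1,
                                ancestral_freq_range = c(0.05, 0.95),
                                admixture = NULL, n_sires = 0,
                                offspring_per_sire = 10, seed = 1) {
  stopifnot(K >= 1, m >= 1, all(n_per_class >= 1))
  n_per_class <- rep_len(as.integer(n_per_class), K)
  F <- pmax(rep_len(F, K), 1e-6)
  if (any(F >= 1)) stop("F must be in (0, 1)")
  set.seed(as.integer(seed))
  classes <- paste0("pop", seq_len(K))
  p_anc <- runif(m, ancestral_freq_range[1], ancestral_freq_range[2])
  p_sub <- vapply(seq_len(K), function(k) {
    a <- p_anc * (1 - F[k]) / F[k]
    b <- (1 - p_anc) * (1 - F[k]) / F[k]
    rbeta(m, a, b)
  }, numeric(m)) # m x K
  markers <- paste0("M", seq_len(m))

  draw_founder <- function(k) rbinom(m, 2L, p_sub[, k])
  gamete <- function(geno) { # one allele per marker from a diploid genotype
    het <- geno == 1L
    al <- integer(m)
    al[geno == 2L] <- 1L
    al[het] <- rbinom(sum(het), 1L, 0.5)
    al
  }

  dosage <- matrix(0L, sum(n_per_class), m)
  sample_ids <- character(sum(n_per_class))
  class_vec <- character(sum(n_per_class))
  ped <- list()
  row <- 0L
  for (k in seq_len(K)) {
    nk <- n_per_class[k]
    if (n_sires > 0) {
      sire_ids <- paste0(classes[k], "_sire", seq_len(n_sires))
      sire_geno <- vapply(seq_len(n_sires), function(s) draw_founder(k), numeric(m))
      ped[[length(ped) + 1L]] <- tibble::tibble(
        id = sire_ids, sire = NA_character_, dam = NA_character_)
      assigned_sire <- rep(seq_len(n_sires),
                           each = offspring_per_sire, length.out = nk)
      for (i in seq_len(nk)) {
        row <- row + 1L
        id <- paste0(classes[k], "_", i)
        s <- assigned_sire[i]
        dam_id <- paste0(classes[k], "_dam", i) # dams unique per offspring
        dam_geno <- draw_founder(k)
        dosage[row, ] <- gamete(sire_geno[, s]) + gamete(dam_geno)
        sample_ids[row] <- id
        class_vec[row] <- classes[k]
        ped[[length(ped) + 1L]] <- tibble::tibble(
          id = c(dam_id, id),
          sire = c(NA_character_, sire_ids[s]),
          dam = c(NA_character_, dam_id))
      }
    } else {
      for (i in seq_len(nk)) {
        row <- row + 1L
        dosage[row, ] <- draw_founder(k)
        sample_ids[row] <- paste0(classes[k], "_", i)
        class_vec[row] <- classes[k]
        ped[[length(ped) + 1L]] <- tibble::tibble(
          id = sample_ids[row], sire = NA_character_, dam = NA_character_)
      }
    }
  }

  ancestry <- NULL
  if (!is.null(admixture)) {
    cls <- admixture$classes
    if (is.numeric(cls)) cls <- classes[cls]
    donor <- match(cls[1], classes); target <- match(cls[2], classes)
    if (is.na(donor) || is.na(target)) stop("unknown admixture class")
    mix <- admixture$mix %||% 0.5
    lambda <- admixture$lambda
    stopifnot(lambda >= 0, lambda <= 1)
    target_rows <- which(class_vec == classes[target])
    n_adm <- round(lambda * length(target_rows))
    adm_rows <- target_rows[seq_len(n_adm)]
    for (r in adm_rows) {
      # each of the two allele draws picks its source population
      src1 <- runif(m) < mix
      src2 <- runif(m) < mix
      p1 <- ifelse(src1, p_sub[, donor], p_sub[, target])
      p2 <- ifelse(src2, p_sub[, donor], p_sub[, target])
      dosage[r, ] <- rbinom(m, 1L, p1) + rbinom(m, 1L, p2)
    }
    ancestry <- tibble::tibble(sample_id = sample_ids[adm_rows],
                               donor = classes[donor],
                               target = classes[target], mix = mix)
  }

  g <- genotype_matrix(dosage, samples = sample_ids, markers = markers)
  list(genotypes = g,
       labels = tibble::tibble(sample_id = sample_ids,
                               class = factor(class_vec, levels = classes)),
       pedigree = dplyr::bind_rows(ped),
       truth = list(p_ancestral = p_anc, p_sub = p_sub, F = F,
                    classes = classes, ancestry = ancestry, seed = seed))
}

#' Simulate a binary trait from a liability model
#'
#' Marker effects are drawn Gaussian and rescaled so the realized genetic
#' variance satisfies `var(Zu) / (var(Zu) + 1) = h2` in-sample; the
#' liability is `Zu + N(0, 1)` and labels are its sign.  This is the
#' generative direction of the probit threshold model with residual
#' variance 1.
#'
#' @param g a [genotype_matrix()].
#' @param h2 liability-scale heritability in \[0, 1).
#' @param seed integer seed.
#' @return list with `y` (integer 0/1 labels), `liability`, `u` (true marker
#'   effects on centered dosages), `h2`.
#' @export
simulate_liability_trait <- function(g, h2, seed = 1) {
  stopifnot(inherits(g, "genotype_matrix"), h2 >= 0, h2 < 1)
  set.seed(as.integer(seed))
  Z <- center_markers(g)$M
  u <- rnorm(ncol(Z))
  gval <- as.numeric(Z %*% u)
  vg <- var(gval) * (length(gval) - 1) / length(gval)
  target <- h2 / (1 - h2)
  scale <- if (vg > 0 && target > 0) sqrt(target / vg) else 0
  u <- u * scale
  gval <- gval * scale
  liability <- gval + rnorm(length(gval))
  list(y = as.integer(liability > 0), liability = liability, u = u, h2 = h2)
}
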