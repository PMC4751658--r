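# Weir & Cockerham (1984) allele-count moment components for two classes,
# vectorized over markers: MSP (between-class mean square), MSG
# (within-class), n_c (effective allele count). Inputs are per-marker class
# frequencies and non-missing allele counts.
wc_components <- function(fk, fkp, mk, mkp) {
  msum <- mk + mkp
  nc <- msum - (mk^2 + mkp^2) / msum # r - 1 = 1
  pbar <- (mk * fk + mkp * fkp) / msum
  MSP <- mk * (fk - pbar)^2 + mkp * (fkp - pbar)^2
  MSG <- (mk * fk * (1 - fk) + mkp * fkp * (1 - fkp)) / (msum - 2)
  list(MSP = MSP, MSG = MSG, nc = nc, pbar = pbar)
}

#' Pairwise F_ST between two classes
#'
#' Per-marker fixation indices from moment components: the default
#' `convention = "wc"` uses Weir-Cockerham allele-count moments,
#' `theta = (MSP - MSG) / (MSP + (n_c - 1) MSG)`, which equals 1 at opposing
#' fixation, ~0 at equal class frequencies, and recovers the generative
#' divergence parameter without bias under the Balding-Nichols model.
#' `convention = "wright"` instead reports the plain ratio of the
#' sample-size-weighted between-class frequency variance to the binomial
#' variance `pbar (1 - pbar)` at the pooled frequency.
#'
#' The canonical dataset-level `estimate` under `"wc"` is the multilocus
#' ratio of sums `sum(MSP - MSG) / sum(MSP + (n_c - 1) MSG)`; `mean` and
#' `sd` summarize the per-marker values.
#'
#' @param g a [genotype_matrix()].
#' @param labels tibble with `sample_id`, `class`.
#' @param class_k,class_kp the two class labels to contrast.
#' @param convention `"wc"` (default) or `"wright"`.
#' @return object of class `fst_result`: tibble `per_marker` (`marker`,
#'   `sigma2_alpha`, `sigma2_eps`, `fst`), `mean`, `sd`, `estimate`,
#'   `scope`, `convention`.  Markers monomorphic across both classes are
#'   reported as `NA`.
#' @export
fst_pairwise <- function(g, labels, class_k, class_kp,
                         convention = c("wc", "wright")) {
  convention <- match.arg(convention)
  al <- align_labels(g, labels)
  sel_k <- al$idx[al$class == class_k]
  sel_kp <- al$idx[al$class == class_kp]
  if (!length(sel_k) || !length(sel_kp)) stop("empty class in pairwise F_ST")
  fk <- allele_freq(g$dosage[sel_k, , drop = FALSE])
  fkp <- allele_freq(g$dosage[sel_kp, , drop = FALSE])
  nk <- colSums(!is.na(g$dosage[sel_k, , drop = FALSE]))
  nkp <- colSums(!is.na(g$dosage[sel_kp, , drop = FALSE]))
  if (convention == "wc") {
    wc <- wc_components(fk, fkp, 2 * nk, 2 * nkp)
    num <- wc$MSP - wc$MSG
    den <- wc$MSP + (wc$nc - 1) * wc$MSG
    fst <- ifelse(den > 0, pmax(num / den, 0), NA_real_)
    est <- sum(num[den > 0]) / sum(den[den > 0])
    s2a <- wc$MSP; s2e <- wc$MSG
  } else {
    w <- length(sel_k) / (length(sel_k) + length(sel_kp))
    pbar <- w * fk + (1 - w) * fkp
    s2a <- w * (fk - pbar)^2 + (1 - w) * (fkp - pbar)^2
    s2e <- pbar * (1 - pbar)
    fst <- ifelse(s2e > 0, s2a / s2e, 0) # pooled-fixed markers carry no signal
    est <- mean(fst, na.rm = TRUE)
  }
  new_fst_result(g$markers, s2a, s2e, fst, est,
                 scope = paste0("pairwise(", class_k, ",", class_kp, ")"),
                 convention = convention)
}

new_fst_result <- function(markers, s2a, s2e, fst, estimate, scope, convention) {
  per_marker <- tibble::tibble(marker = markers,
                               sigma2_alpha = as.numeric(s2a),
                               sigma2_eps = as.numeric(s2e),
                               fst = as.numeric(fst))
  structure(list(per_marker = per_marker,
                 mean = mean(per_marker$fst, na.rm = TRUE),
                 sd = sd(per_marker$fst, na.rm = TRUE),
                 estimate = estimate, scope = scope, convention = convention),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("<fst_result> scope=", x$scope, ", convention=", x$convention, "\n",
      "  markers: ", nrow(x$per_marker),
      ", mean=", sprintf("%.4f", x$mean),
      " (sd ", sprintf("%.4f", x$sd), ")",
      ", multilocus estimate=", sprintf("%.4f", x$estimate), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.fst_result <- function(x, ...) x$per_marker

#' @export
glance.fst_result <- function(x, ...) {
  tibble::tibble(scope = x$scope, convention = x$convention,
                 n_markers = nrow(x$per_marker), mean = x$mean, sd = x$sd,
                 estimate = x$estimate)
}

#' Global F_ST across all classes from a per-marker mixed model
#'
#' Per marker, gene content is modelled as an intercept plus a random
#' subpopulation effect plus residual (REML via lme4).  The reported
#' fixation index is the ratio of the between-subpopulation variance in
#' allele frequencies to the total variance on the allele-frequency scale:
#' gene content is the sum of two alleles, so its between-class variance is
#' `4 Var(p)` while its residual is twice the per-allele sampling variance,
#' giving `F_ST = sigma2_alpha / (sigma2_alpha + 2 sigma2_eps)`.
#' Monomorphic markers are excluded with a warning; non-converging markers
#' are flagged with `NA`.
#'
#' @param g a [genotype_matrix()].
#' @param labels tibble with `sample_id`, `class` (K >= 2 classes).
#' @return an `fst_result` with scope `"global"`.
#' @export
fst_global <- function(g, labels) {
  al <- align_labels(g, labels)
  cls <- al$class
  dos <- g$dosage[al$idx, , drop = FALSE]
  mono <- apply(dos, 2L, function(x) var(x, na.rm = TRUE) == 0 || all(is.na(x)))
  if (any(mono))
    warning(sum(mono), " monomorphic marker(s) excluded from global F_ST")
  idx <- which(!mono)
  res <- vapply(idx, function(j) {
    ok <- !is.na(dos[, j])
    df <- data.frame(y = dos[ok, j], cls = cls[ok])
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(y ~ (1 | cls), data = df,
                   control = lme4::lmerControl(check.conv.singular = "ignore")))),
      error = function(e) NULL)
    if (is.null(fit)) return(c(NA_real_, NA_real_))
    vc <- as.data.frame(lme4::VarCorr(fit))
    s2a <- vc$vcov[vc$grp != "Residual"][1]
    s2e <- vc$vcov[vc$grp == "Residual"][1]
    c(s2a, s2e)
  }, numeric(2))
  s2a <- rep(NA_real_, ncol(dos)); s2e <- rep(NA_real_, ncol(dos))
  s2a[idx] <- res[1L, ]; s2e[idx] <- res[2L, ]
  fst <- s2a / (s2a + 2 * s2e) # gene content -> allele-frequency scale
  est <- mean(fst, na.rm = TRUE)
  new_fst_result(g$markers, s2a, s2e, fst, est, scope = "global",
                 convention = "mixed_model")
}

#' Eigenvector-inclusion analysis of divergence between two classes
#'
#' Eigendecomposes the genomic relationship matrix of the two classes and
#' fits a BayesC-pi probit threshold model with the eigenvectors (dropping
#' the last; the centered G has rank N-1) as random-effect covariates and
#' class membership as the response.  The posterior mean of the inclusion
#' proportion `pi` is reported as pEV, the expected number of eigenvectors
#' with nonzero effect as `nEV = pEV * (N - 1)`.  Low pEV means few
#' eigenvectors separate the classes — strong divergence; high pEV means a
#' complex relationship — low divergence.
#'
#' By default the orthonormal eigenvectors enter unscaled
#' (`scaling = "none"`), which keeps every indicator identifiable (all
#' columns have unit norm, so exclusion is a real statement about the data).
#' `scaling = "sqrt_eigenvalue"` multiplies each column by the square root
#' of its eigenvalue, putting coefficients on the genetic-value scale; note
#' that near-null eigenvalues then make their indicators unidentifiable and
#' pull the posterior of `pi` toward its prior.
#'
#' @param G a genomic `relationship_matrix` computed on exactly the samples
#'   of the two classes, or a [genotype_matrix()] (G computed internally).
#' @param labels tibble with `sample_id`, `class`; exactly two classes among
#'   the samples of `G`.
#' @param spec a [threshold_model_spec()]; default BayesC-pi with 60000
#'   iterations, 20000 burn-in.
#' @param scaling `"none"` (default) or `"sqrt_eigenvalue"`.
#' @return object of class `pev_result`: `pev`, `nev`, `n`, tibble
#'   `inclusion` (per-eigenvector inclusion probability), `pi_chain`
#'   diagnostics (Geweke z).
#' @export
pev_analysis <- function(G, labels, spec = NULL,
                         scaling = c("none", "sqrt_eigenvalue")) {
  scaling <- match.arg(scaling)
  labels <- tibble::as_tibble(labels)
  if (inherits(G, "genotype_matrix")) {
    G <- subset_samples(G, labels$sample_id)
    G <- grm(center_markers(G))
  }
  stopifnot(inherits(G, "relationship_matrix"))
  labels <- labels[match(G$samples, labels$sample_id), ]
  cls <- droplevels(factor(labels$class))
  if (nlevels(cls) != 2L) stop("pEV analysis needs exactly two classes")
  N <- length(G$samples)
  if (N < 4L) stop("need at least 4 samples")
  ev <- relmat_eigen(G)
  keep <- seq_len(N - 1L) # centered G has rank N-1; drop the last
  pos <- pmax(ev$d[keep], 0)
  low_rank <- pos <= 1e-10 * max(pos)
  if (any(low_rank)) {
    message(sum(low_rank), " near-null eigenvector(s) dropped")
    keep <- keep[!low_rank]
    pos <- pos[!low_rank]
  }
  Z <- ev$U[, keep, drop = FALSE]
  if (scaling == "sqrt_eigenvalue")
    Z <- Z %*% diag(sqrt(pos), length(keep))
  if (is.null(spec))
    spec <- threshold_model_spec(prior = "bayes_c_pi",
                                 n_iter = 60000, burn_in = 20000)
  spec$prior <- "bayes_c_pi"
  y <- as.integer(cls) - 1L
  fit <- fit_probit(y, Z = Z, spec = spec, save_effects = FALSE)
  pev <- mean(fit$pi)
  structure(list(pev = pev, nev = pev * (N - 1), n = N,
                 inclusion = tibble::tibble(eigenvector = keep,
                                            eigenvalue = ev$d[keep],
                                            incl_prob = as.numeric(fit$incl_prob)),
                 pi_chain = fit$pi,
                 geweke_z_pi = geweke_z(fit$pi),
                 classes = levels(cls),
                 scaling = scaling),
            class = "pev_result")
}

#' @export
print.pev_result <- function(x, ...) {
  cat("<pev_result> classes ", paste(x$classes, collapse = " vs "),
      " (N=", x$n, ")\n", sep = "")
  cat("  pEV=", sprintf("%.4f", x$pev), "  nEV=", sprintf("%.4f", x$nev),
      "  top inclusion=", sprintf("%.3f", max(x$inclusion$incl_prob)), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.pev_result <- function(x, ...) x$inclusion

#' @export
glance.pev_result <- function(x, ...) {
  tibble::tibble(pev = x$pev, nev = x$nev, n = x$n,
                 top_incl = max(x$inclusion$incl_prob),
                 geweke_z_pi = x$geweke_z_pi)
}

#' Inclusion probabilities of eigenvectors
#'
#' @param object a `pev_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pev_result <- function(object, ...) {
  ggplot2::ggplot(object$inclusion,
                  ggplot2::aes(x = .data$eigenvector, y = .data$incl_prob)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Eigenvector", y = "Posterior inclusion probability",
                  title = paste0("pEV = ", sprintf("%.4f", object$pev),
                                 ", nEV = ", sprintf("%.2f", object$nev)))
}

#' Liability-scale heritability of subpopulation assignment
#'
#' Fits a probit animal model for the binary trait "assignment to one of two
#' subpopulations", using the Cholesky factorization of either the genomic
#' (`mode = "marker"`) or the pedigree (`mode = "pedigree"`) relationship
#' matrix of the two classes as the random-effect design.  With the residual
#' variance fixed at 1, `h2 = sigma2_a / (sigma2_a + 1)`.
#'
#' @param g a [genotype_matrix()] (marker mode) — or `NULL` if `A` given.
#' @param labels tibble with `sample_id`, `class`.
#' @param class_k,class_kp the two classes.
#' @param mode `"marker"` or `"pedigree"`.
#' @param ped pedigree tibble (pedigree mode).
#' @param spec a [threshold_model_spec()]; default ridge with 60000/20000
#'   chains.
#' @return tibble with `h2_mean`, `h2_sd`, `sigma2_a_mean`, `mode`.
#' @export
h2_subpop <- function(g, labels, class_k, class_kp,
                      mode = c("marker", "pedigree"), ped = NULL, spec = NULL) {
  mode <- match.arg(mode)
  labels <- tibble::as_tibble(labels)
  labels <- dplyr::filter(labels, .data$class %in% c(class_k, class_kp))
  R <- if (mode == "marker") {
    grm(center_markers(subset_samples(g, labels$sample_id)))
  } else {
    if (is.null(ped)) stop("pedigree mode needs a pedigree")
    subset_relmat(nrm(ped), labels$sample_id)
  }
  L <- chol_lower(R, eps = 1e-6)
  y <- as.integer(labels$class == class_k)
  if (is.null(spec))
    spec <- threshold_model_spec(prior = "ridge", n_iter = 60000, burn_in = 20000)
  fit <- fit_probit(y, Z = L, spec = spec, save_effects = FALSE)
  heritability_from_fit(fit, mode = "relationship")
}
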