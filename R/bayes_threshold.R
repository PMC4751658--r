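#' Specify a binary probit threshold model
#'
#' The probit threshold model relates a binary response to a latent liability
#' `l = W b + Z u + e`, `e ~ N(0, I)`, via `Pr(y = 1) = Phi(W b + Z u - delta)`.
#' For identifiability the threshold `delta` is fixed at 0 and an intercept
#' column is included in `W`; the residual variance is fixed at 1, so
#' variance components are on the liability scale.
#'
#' @param prior one of `"ridge"` (Gaussian marker effects, common variance;
#'   the GBLUP-equivalent model), `"bayes_a"` (per-marker variances, a
#'   marginal scaled-t prior) or `"bayes_c_pi"` (spike-slab with estimated
#'   inclusion proportion `pi`).
#' @param n_iter,burn_in,thin Gibbs chain control; defaults 30000 / 15000 / 1.
#' @param seed integer seed; every fit is bit-reproducible given the seed.
#' @param df_u prior degrees of freedom of the scaled-inverse-chi-square
#'   variance-component prior (default 5).
#' @param r2 expected proportion of liability variance captured by the
#'   features, used to set the prior scale so that the prior mode of the
#'   genetic variance matches `r2/(1-r2)` given the observed feature
#'   variances (default 0.5).
#' @param scale_u optional explicit prior scale, overriding the `r2`
#'   heuristic.
#' @param pi_a,pi_b Beta prior for `pi` (BayesC-pi only; default Beta(1,1)).
#' @return an object of class `threshold_model_spec`.
#' @export
threshold_model_spec <- function(prior = c("ridge", "bayes_a", "bayes_c_pi"),
                                 n_iter = 30000, burn_in = 15000, thin = 1,
                                 seed = 1, df_u = 5, r2 = 0.5,
                                 scale_u = NULL, pi_a = 1, pi_b = 1) {
  prior <- match.arg(prior)
  stopifnot(burn_in < n_iter, df_u > 0, thin >= 1, r2 > 0, r2 < 1)
  structure(list(prior = prior, n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), df_u = df_u, r2 = r2,
                 scale_u = scale_u, pi_a = pi_a, pi_b = pi_b),
            class = "threshold_model_spec")
}

prior_code <- function(prior)
  match(prior, c("ridge", "bayes_a", "bayes_c_pi")) - 1L

# prior scale from the R2 heuristic: mode of scaled-inv-chisq(df, S) is
# df*S/(df+2); match it to r2/(1-r2)/MSx, where MSx is the summed feature
# variance. BayesC-pi spreads the slab over an expected half of the features.
resolve_scale <- function(spec, Z) {
  if (!is.null(spec$scale_u)) return(spec$scale_u)
  msx <- sum(apply(Z, 2L, var))
  if (msx <= 0) msx <- sum(colMeans(Z^2)) # constant columns only
  if (msx <= 0) msx <- 1
  target <- spec$r2 / (1 - spec$r2) / msx
  if (spec$prior == "bayes_c_pi") target <- target / 0.5
  target * (spec$df_u + 2) / spec$df_u
}

#' Fit a binary probit threshold model by Gibbs sampling
#'
#' Data-augmentation Gibbs sampler: liabilities are drawn from normals
#' truncated at the threshold by class (inverse-CDF sampling, clamped at 8
#' standard units), location effects from their Gaussian full conditionals,
#' and variance components from scaled-inverse-chi-square full conditionals.
#' BayesA samples a variance per feature; BayesC-pi samples per-feature
#' Bernoulli inclusion indicators with the effect integrated out of the
#' likelihood ratio, and `pi` from its Beta full conditional.
#'
#' @param y binary response in \{0, 1\} (or a two-level factor; the second
#'   level is the success); both classes must be present.
#' @param Z feature matrix (n x m): centered marker covariates, relationship
#'   eigenvectors, or a Cholesky factor of a relationship matrix.
#' @param W fixed-effect design matrix; default a single intercept column.
#' @param spec a [threshold_model_spec()].
#' @param save_effects keep the full chain of feature effects (needed by
#'   [predict_prob()]; default `TRUE`).
#' @return object of class `probit_fit` with posterior chains (`b`, `u`,
#'   `sigma2_u`, `pi`, `var_g`), posterior means, inclusion probabilities
#'   (BayesC-pi), and the model metadata.
#' @export
fit_probit <- function(y, Z, W = NULL, spec = threshold_model_spec(),
                       save_effects = TRUE) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("response must be binary 0/1")
  if (length(unique(y)) < 2L)
    stop("degenerate response: both classes must be present")
  Z <- as.matrix(Z)
  if (!all(is.finite(Z))) stop("non-finite feature values")
  if (nrow(Z) != length(y)) stop("rows of Z must align with y")
  if (is.null(W)) W <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  W <- as.matrix(W)
  if (nrow(W) != length(y)) stop("rows of W must align with y")
  scale_u <- resolve_scale(spec, Z)
  if (spec$prior == "ridge") {
    # thin SVD drives the joint block update of the effect vector
    sv <- svd(Z)
    Us <- sv$u; d <- sv$d; V <- sv$v
  } else {
    Us <- matrix(0, 1, 1); d <- 0; V <- matrix(0, 1, 1)
  }
  set.seed(spec$seed)
  res <- gibbs_probit_cpp(y, W, Z, prior_code(spec$prior),
                          spec$n_iter, spec$burn_in, spec$thin,
                          spec$df_u, scale_u, spec$pi_a, spec$pi_b,
                          save_effects, Us, d, V)
  structure(c(res, list(spec = spec, scale_u = scale_u,
                        n = length(y), p = ncol(W), m = ncol(Z),
                        feature_names = colnames(Z),
                        success_rate = mean(y))),
            class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  cat("<probit_fit> prior=", x$spec$prior, ", n=", x$n, ", features=", x$m,
      ", kept samples=", x$n_kept, "\n", sep = "")
  cat("  posterior mean sigma2_u: ", sprintf("%.4f", mean(x$sigma2_u)), "\n", sep = "")
  if (x$spec$prior == "bayes_c_pi")
    cat("  posterior mean pi: ", sprintf("%.4f", mean(x$pi)), "\n", sep = "")
  invisible(x)
}

#' @export
glance.probit_fit <- function(x, ...) {
  tibble::tibble(prior = x$spec$prior, n = x$n, m = x$m,
                 n_kept = x$n_kept,
                 sigma2_u = mean(x$sigma2_u),
                 var_g = mean(x$var_g),
                 pi = if (x$spec$prior == "bayes_c_pi") mean(x$pi) else NA_real_)
}

#' @export
tidy.probit_fit <- function(x, ...) {
  if (is.null(x$u)) {
    est <- x$post_mean_u; se <- rep(NA_real_, length(est))
  } else {
    est <- colMeans(x$u); se <- apply(x$u, 2L, sd)
  }
  tibble::tibble(
    term = x$feature_names %||% paste0("f", seq_along(est)),
    estimate = est, std.error = se,
    incl_prob = if (x$spec$prior == "bayes_c_pi") as.numeric(x$incl_prob) else NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Posterior predictive success probabilities
#'
#' Monte-Carlo average over the kept posterior samples of
#' `Phi(w' b + z' u - delta)` — the full posterior predictive probability,
#' not `Phi` at the posterior-mean linear predictor.
#'
#' @param fit a `probit_fit` fitted with `save_effects = TRUE`.
#' @param Z_new feature matrix of new samples (columns as in training).
#' @param W_new fixed-effect matrix; default intercept-only.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_prob <- function(fit, Z_new, W_new = NULL) {
  stopifnot(inherits(fit, "probit_fit"))
  Z_new <- as.matrix(Z_new)
  if (ncol(Z_new) != fit$m)
    stop("feature count mismatch: ", ncol(Z_new), " vs ", fit$m, " in training")
  if (is.null(W_new)) W_new <- matrix(1, nrow(Z_new), fit$p)
  W_new <- as.matrix(W_new)
  if (ncol(W_new) != fit$p) stop("fixed-effect column mismatch")
  if (is.null(fit$u)) stop("fit was run with save_effects = FALSE")
  eta <- W_new %*% t(fit$b) + Z_new %*% t(fit$u) # n_new x kept
  as.numeric(rowMeans(pnorm(eta)))
}

#' Liability-scale heritability from a fitted threshold model
#'
#' With the residual variance fixed at 1, `h2 = sigma2_a / (sigma2_a + 1)`.
#' In `"relationship"` mode the genetic variance is the variance component
#' `sigma2_u` itself (valid when the features are a factorization L of a
#' relationship matrix with L L' = G or A, so that var(Zu) has covariance
#' structure G sigma2_u).  In `"marker"` mode the realized genetic variance
#' `var(Z u)` across samples is used, computed per posterior draw.
#'
#' @param fit a `probit_fit`.
#' @param mode `"marker"` (realized var(Zu) per draw) or `"relationship"`
#'   (the sampled variance component; alias `"pedigree"`).
#' @return tibble with `h2_mean`, `h2_sd`, `sigma2_a_mean`, `mode`.
#' @export
heritability_from_fit <- function(fit, mode = c("marker", "relationship", "pedigree")) {
  stopifnot(inherits(fit, "probit_fit"))
  mode <- match.arg(mode)
  if (mode == "pedigree") mode <- "relationship"
  s2 <- if (mode == "marker") fit$var_g else fit$sigma2_u
  h2 <- s2 / (s2 + 1)
  tibble::tibble(h2_mean = mean(h2), h2_sd = sd(h2),
                 sigma2_a_mean = mean(s2), mode = mode)
}

#' Geweke-style stationarity z-score for a chain
#'
#' Compares the means of the first `frac1` and last `frac2` fractions of a
#' chain, standardized by their spectral-density-free standard errors
#' (simple batch variance); |z| well above 3 flags non-stationarity.
#'
#' @param x numeric chain.
#' @param frac1,frac2 fractions of the chain to compare.
#' @return the z statistic.
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(floor(frac1 * n))]
  b <- x[seq.int(n - floor(frac2 * n) + 1L, n)]
  (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
}

#' Persist / restore a fitted threshold model as plain text
#'
#' Chains are written as TSV files plus a JSON metadata file into `dir`.
#'
#' @param fit a `probit_fit`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(fit$b, file.path(dir, "chain_b.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(fit$u))
    utils::write.table(fit$u, file.path(dir, "chain_u.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  scalars <- data.frame(sigma2_u = fit$sigma2_u, pi = fit$pi,
                        n_included = fit$n_included, var_g = fit$var_g)
  utils::write.table(scalars, file.path(dir, "chain_scalars.tsv"), sep = "\t",
                     row.names = FALSE)
  meta <- list(format_version = 1L, prior = fit$spec$prior, n = fit$n,
               p = fit$p, m = fit$m, n_kept = fit$n_kept,
               seed = fit$spec$seed, n_iter = fit$spec$n_iter,
               burn_in = fit$spec$burn_in, thin = fit$spec$thin,
               scale_u = fit$scale_u, df_u = fit$spec$df_u)
  jsonlite::write_json(meta, file.path(dir, "fit_meta.json"), auto_unbox = TRUE)
  invisible(dir)
}
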