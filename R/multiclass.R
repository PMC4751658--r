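#' Train one-vs-all binary classifiers
#'
#' For each of the K classes a binary classifier is trained on all samples
#' with `y = 1` for that class and `y = 0` for the complement.  OVA
#' contrasts are almost always unbalanced; a warning is emitted when the
#' positive class is below 20 % of the data.
#'
#' @param X feature matrix (samples in rows), e.g. from [feature_source()].
#' @param class factor of class labels aligned with the rows of `X`.
#' @param backend backend name (see [register_backend()]); must provide
#'   probabilities.
#' @param spec optional [threshold_model_spec()] passed to Bayesian backends.
#' @param seed base seed; fit k uses `seed + k`.
#' @return object of class `ova_model`: list of K fits plus metadata.
#' @export
train_ova <- function(X, class, backend = "ridge", spec = NULL, seed = 1) {
  class <- droplevels(as.factor(class))
  lev <- levels(class)
  if (length(lev) < 2L) stop("need at least 2 classes")
  if (any(table(class) == 0L)) stop("empty class")
  be <- get_backend(backend)
  X <- as.matrix(X)
  fits <- lapply(seq_along(lev), function(k) {
    y <- as.integer(class == lev[k])
    if (mean(y) < 0.2)
      warning("unbalanced OVA contrast for class ", lev[k],
              " (", sum(y), "/", length(y), " positives)", call. = FALSE)
    be$train(X, y, seed = seed + k, spec = spec)
  })
  structure(list(fits = fits, classes = lev, backend = backend,
                 scheme = "ova"), class = "ova_model")
}

#' Train one-vs-one binary classifiers
#'
#' One classifier per unordered class pair (K(K-1)/2 in total), each trained
#' only on the samples of its two classes, with `y = 1` for the first class
#' of the pair.
#'
#' @inheritParams train_ova
#' @return object of class `ovo_model`: list of pairwise fits plus metadata.
#' @export
train_ovo <- function(X, class, backend = "ridge", spec = NULL, seed = 1) {
  class <- droplevels(as.factor(class))
  lev <- levels(class)
  if (length(lev) < 2L) stop("need at least 2 classes")
  if (any(table(class) == 0L)) stop("empty class")
  be <- get_backend(backend)
  X <- as.matrix(X)
  pairs <- utils::combn(seq_along(lev), 2L)
  fits <- lapply(seq_len(ncol(pairs)), function(q) {
    k <- pairs[1L, q]; kp <- pairs[2L, q]
    sel <- class %in% lev[c(k, kp)]
    if (sum(class == lev[k]) < 2L || sum(class == lev[kp]) < 2L)
      warning("very small class in pairing ", lev[k], " vs ", lev[kp], call. = FALSE)
    y <- as.integer(class[sel] == lev[k])
    list(k = k, kp = kp,
         fit = be$train(X[sel, , drop = FALSE], y, seed = seed + q, spec = spec))
  })
  structure(list(fits = fits, classes = lev, backend = backend,
                 scheme = "ovo"), class = "ovo_model")
}

#' Pairwise probability table
#'
#' K x K matrix with entries `p_kk' = Pr(class = k | class in {k, k'})`;
#' complementarity `p_kk' + p_k'k = 1` is enforced on construction and all
#' entries are clipped to the interior `[clip, 1 - clip]` as required by the
#' coupling fixed-point system.
#'
#' @param p K x K numeric matrix (upper triangle read; diagonal unused) or
#'   the full matrix.
#' @param classes class labels.
#' @param clip interior clipping bound (default 1e-6).
#' @return object of class `pairwise_prob_table`.
#' @export
pairwise_prob_table <- function(p, classes = rownames(p), clip = 1e-6) {
  p <- as.matrix(p)
  K <- nrow(p)
  stopifnot(ncol(p) == K, K >= 2)
  if (is.null(classes)) classes <- paste0("C", seq_len(K))
  p <- pmin(pmax(p, clip), 1 - clip)
  for (k in seq_len(K - 1L)) for (kp in (k + 1L):K) p[kp, k] <- 1 - p[k, kp]
  diag(p) <- NA_real_
  dimnames(p) <- list(classes, classes)
  structure(list(p = p, classes = classes), class = "pairwise_prob_table")
}

#' Normalize one-vs-all probabilities to class probabilities
#'
#' `p_k = Pr_k / sum_l Pr_l` over the K one-vs-all success probabilities.
#' The operation is invariant to common positive scaling of the inputs.
#'
#' @param binary_probs K-vector of OVA success probabilities.
#' @param classes optional class labels.
#' @param clip entries are clipped to `[clip, 1 - clip]` first.
#' @return named probability vector on the K-simplex.
#' @export
normalize_ova <- function(binary_probs, classes = names(binary_probs),
                          clip = 1e-6) {
  v <- pmin(pmax(as.numeric(binary_probs), clip), 1 - clip)
  p <- v / sum(v)
  names(p) <- classes
  p
}

#' Class probabilities from one-vs-one voting
#'
#' The counting measure `p_k = 2/(K(K-1)) * sum_{k' != k} c_kk'` with
#' `c_kk' = 1` when `p_kk' > p_k'k`.  Ties in the final argmax break to the
#' lowest class index with a warning.
#'
#' @param pp a [pairwise_prob_table()].
#' @return list with `p` (probability vector summing to 1 at most; the
#'   counting measure need not reach 1 under cyclic wins) and `class`
#'   (predicted label).
#' @export
vote_ovo <- function(pp) {
  stopifnot(inherits(pp, "pairwise_prob_table"))
  K <- length(pp$classes)
  wins <- vapply(seq_len(K), function(k) {
    sum(pp$p[k, -k] > pp$p[-k, k])
  }, numeric(1))
  p <- 2 / (K * (K - 1)) * wins
  names(p) <- pp$classes
  top <- which(p == max(p))
  if (length(top) > 1L)
    warning("vote tie between ", paste(pp$classes[top], collapse = ", "),
            "; breaking to lowest index", call. = FALSE)
  list(p = p, class = pp$classes[top[1L]])
}

#' Class probabilities by pairwise coupling
#'
#' Reconstructs the K-class probability vector from pairwise conditional
#' probabilities by solving the stationarity system `p = Q p` with
#' `Q_kk' = p_kk'/(K-1)` off the diagonal and `Q_kk = sum_{l != k} p_kl/(K-1)`,
#' under `p > 0`, `sum(p) = 1`.  When the table is consistent with some `p`
#' via `p_kk' = p_k/(p_k + p_k')`, that `p` is recovered exactly.  Solved by
#' a direct normalized linear solve with a power-iteration fallback.
#'
#' @param pp a [pairwise_prob_table()] (or a K x K matrix, converted).
#' @param tol convergence tolerance of the fallback power iteration.
#' @param max_iter iteration cap of the fallback.
#' @return named probability vector on the K-simplex.
#' @export
couple_ovo <- function(pp, tol = 1e-10, max_iter = 10000) {
  if (!inherits(pp, "pairwise_prob_table")) pp <- pairwise_prob_table(pp)
  K <- length(pp$classes)
  Q <- pp$p / (K - 1)
  for (k in seq_len(K)) Q[k, k] <- sum(pp$p[k, -k]) / (K - 1)
  # direct solve: stationary p satisfies (Q - I) p = 0, 1'p = 1
  A <- rbind(Q - diag(K), rep(1, K))
  rhs <- c(rep(0, K), 1)
  p <- tryCatch(qr.solve(A, rhs), error = function(e) NULL)
  if (is.null(p) || any(!is.finite(p)) || any(p <= 0)) {
    # power iteration on the stochastic-like system
    p <- rep(1 / K, K)
    for (it in seq_len(max_iter)) {
      pn <- as.numeric(Q %*% p)
      pn <- pn / sum(pn)
      if (max(abs(pn - p)) < tol) { p <- pn; break }
      p <- pn
    }
    resid <- max(abs(as.numeric(Q %*% p) - p))
    if (resid > 1e-6)
      stop("pairwise coupling did not converge; residual ", format(resid))
  }
  p <- pmax(p, 0)
  p <- p / sum(p)
  names(p) <- pp$classes
  p
}

#' Pick the class with maximal probability
#'
#' Ties break to the lowest class index with a warning.
#'
#' @param p probability vector (named by class if available).
#' @return the predicted class label (name of the argmax entry).
#' @export
classify <- function(p) {
  if (is.null(names(p))) names(p) <- paste0("C", seq_along(p))
  top <- which(p == max(p))
  if (length(top) > 1L)
    warning("probability tie between ", paste(names(p)[top], collapse = ", "),
            "; breaking to lowest index", call. = FALSE)
  names(p)[top[1L]]
}

# pairwise table of predictive probabilities for one sample from an OVO model
ovo_pair_probs <- function(model, X_new, row) {
  K <- length(model$classes)
  P <- matrix(NA_real_, K, K, dimnames = list(model$classes, model$classes))
  be <- get_backend(model$backend)
  for (f in model$fits) {
    pr <- if (!is.null(be$predict_prob))
      be$predict_prob(f$fit, X_new[row, , drop = FALSE])
    else # label-only backend: degenerate 0/1 probability, clipped later
      as.numeric(be$predict_label(f$fit, X_new[row, , drop = FALSE]))
    P[f$k, f$kp] <- pr
    P[f$kp, f$k] <- 1 - pr
  }
  pairwise_prob_table(P, classes = model$classes)
}

#' Predict class probabilities from a trained multiclass model
#'
#' For `ova_model`s the one-vs-all probabilities are normalized; for
#' `ovo_model`s the pairwise probabilities are combined either by coupling
#' (`method = "couple"`, default) or voting (`method = "vote"`).
#'
#' @param object an `ova_model` or `ovo_model`.
#' @param X_new feature matrix of samples to score.
#' @param method OVO combination rule: `"couple"` or `"vote"`.
#' @param ... unused.
#' @return tibble with one row per sample: `sample`, one `p_<class>` column
#'   per class, and `predicted_class`.
#' @export
predict.ova_model <- function(object, X_new, ...) {
  X_new <- as.matrix(X_new)
  be <- get_backend(object$backend)
  if (is.null(be$predict_prob))
    stop("OVA normalization needs a probabilistic backend")
  raw <- vapply(object$fits, function(f) be$predict_prob(f, X_new),
                numeric(nrow(X_new)))
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1L)
  probs <- t(apply(raw, 1L, normalize_ova, classes = object$classes))
  finish_prediction(probs, object$classes, rownames(X_new))
}

#' @rdname predict.ova_model
#' @export
predict.ovo_model <- function(object, X_new, method = c("couple", "vote"), ...) {
  method <- match.arg(method)
  X_new <- as.matrix(X_new)
  be <- get_backend(object$backend)
  if (method == "couple" && is.null(be$predict_prob))
    stop("pairwise coupling needs a probabilistic backend; use method = \"vote\"")
  probs <- t(vapply(seq_len(nrow(X_new)), function(i) {
    pp <- ovo_pair_probs(object, X_new, i)
    if (method == "couple") couple_ovo(pp) else vote_ovo(pp)$p
  }, numeric(length(object$classes))))
  finish_prediction(probs, object$classes, rownames(X_new))
}

finish_prediction <- function(probs, classes, sample_ids = NULL) {
  colnames(probs) <- classes
  pred <- apply(probs, 1L, function(p) classify(stats::setNames(p, classes)))
  out <- tibble::as_tibble(probs, .name_repair = ~ paste0("p_", classes))
  dplyr::bind_cols(
    tibble::tibble(sample = sample_ids %||% seq_len(nrow(probs))),
    out,
    tibble::tibble(predicted_class = factor(pred, levels = classes)))
}

#' Multinomial breeding values from one-vs-all threshold models
#'
#' The expected fraction of a candidate's offspring in class k is
#' `p_nk = Phi(wbar' b_k + 0.5 (z_n - 2 f)' u_k - delta_k)` normalized over
#' the K classes: the candidate transmits half its centered genotype to
#' offspring out of a base population with allele frequencies `f`.  Effect
#' vectors enter at their posterior means.  The breeding value is
#' `g_n = p_n - p_0` against the base-population class fractions `p_0`,
#' so `sum(g_n) = 0`.
#'
#' @param z_n matrix of candidate gene content (candidates in rows), or a
#'   vector for a single candidate.
#' @param f base-population allele frequencies in (0, 1), one per marker.
#' @param ova_model an `ova_model` trained with a Bayesian backend on
#'   centered markers over the same marker set.
#' @param p_0 base-population class fractions on the simplex.
#' @param w_bar average fixed-effect covariate vector (default intercept 1).
#' @return tibble with one row per candidate: `candidate`, `p_<class>`
#'   (expected offspring fractions) and `g_<class>` (deviations from `p_0`).
#' @export
breeding_values <- function(z_n, f, ova_model, p_0, w_bar = NULL) {
  stopifnot(inherits(ova_model, "ova_model"))
  if (is.null(dim(z_n))) z_n <- matrix(z_n, nrow = 1L)
  K <- length(ova_model$classes)
  if (length(p_0) != K || abs(sum(p_0) - 1) > 1e-8)
    stop("p_0 must be a K-simplex vector")
  if (any(f <= 0 | f >= 1)) stop("base frequencies must be in (0, 1)")
  fits <- ova_model$fits
  if (!inherits(fits[[1L]], "probit_fit"))
    stop("breeding values need the Bayesian probit backend")
  m <- fits[[1L]]$m
  if (ncol(z_n) != m) stop("marker mismatch: ", ncol(z_n), " vs ", m)
  if (is.null(w_bar)) w_bar <- rep(1, fits[[1L]]$p)
  centered_half <- 0.5 * sweep(z_n, 2L, 2 * f, "-")
  eta <- vapply(fits, function(fit) {
    b_k <- if (is.null(fit$b)) fit$post_mean_b else colMeans(fit$b)
    u_k <- if (is.null(fit$u)) fit$post_mean_u else colMeans(fit$u)
    as.numeric(sum(w_bar * b_k) + centered_half %*% u_k)
  }, numeric(nrow(z_n)))
  if (is.null(dim(eta))) eta <- matrix(eta, nrow = 1L)
  num <- pnorm(eta)
  p_n <- num / rowSums(num)
  g_n <- sweep(p_n, 2L, p_0, "-")
  colnames(p_n) <- paste0("p_", ova_model$classes)
  colnames(g_n) <- paste0("g_", ova_model$classes)
  dplyr::bind_cols(
    tibble::tibble(candidate = rownames(z_n) %||% seq_len(nrow(z_n))),
    tibble::as_tibble(p_n), tibble::as_tibble(g_n))
}
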