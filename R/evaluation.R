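#' Classification accuracy
#'
#' Number of correct classifications over the total number of
#' classifications.
#'
#' @param preds predicted class labels.
#' @param truths observed class labels, same length.
#' @return a fraction in \[0, 1\].
#' @export
accuracy <- function(preds, truths) {
  stopifnot(length(preds) == length(truths))
  mean(as.character(preds) == as.character(truths))
}

#' Multiclass Brier score
#'
#' `BS = N^{-1} sum_i sum_j (p_ij - [y_i = j])^2` over predicted class
#' probabilities; ranges from 0 (perfect) to 2 (confident and always wrong).
#'
#' @param probs n x K matrix of class probabilities; rows on the simplex
#'   (tolerance 1e-6); columns named by class (or in `levels(truths)` order).
#' @param truths observed class labels.
#' @return list with `total` and tibble `per_class` (mean score over the
#'   samples whose true class is that class).
#' @export
brier <- function(probs, truths) {
  probs <- as.matrix(probs)
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probability rows must lie on the simplex")
  classes <- colnames(probs)
  if (is.null(classes)) {
    classes <- if (is.factor(truths)) levels(truths) else sort(unique(as.character(truths)))
    colnames(probs) <- classes
  }
  truths <- as.character(truths)
  if (!all(truths %in% classes)) stop("true class absent from probability columns")
  onehot <- outer(truths, classes, "==") * 1
  per_sample <- rowSums((probs - onehot)^2)
  per_class <- tibble::tibble(
    class = classes,
    brier = vapply(classes, function(k) {
      sel <- truths == k
      if (any(sel)) mean(per_sample[sel]) else NA_real_
    }, numeric(1)),
    n = vapply(classes, function(k) sum(truths == k), numeric(1)))
  list(total = mean(per_sample), per_class = per_class,
       per_sample = per_sample)
}

#' Scaled Brier score
#'
#' `sBS = 1 - BS / BS_baseline`, with the baseline model assigning equal
#' probability `1/K` to every class (so its Brier score is exactly
#' `(K-1)/K` on every sample set).  0 means no better than uniform random
#' assignment; 1 means perfect prediction; negative values mean worse than
#' the uniform baseline.  `baseline = "frequency"` instead uses observed
#' class frequencies of the evaluated samples as the baseline probabilities.
#'
#' @inheritParams brier
#' @param K number of classes (default: columns of `probs`).
#' @param baseline `"uniform"` (default) or `"frequency"`.
#' @return list with `total` and tibble `per_class` (same uniform baseline
#'   restricted to each class's samples).
#' @export
scaled_brier <- function(probs, truths, K = ncol(as.matrix(probs)),
                         baseline = c("uniform", "frequency")) {
  baseline <- match.arg(baseline)
  probs <- as.matrix(probs)
  bs <- brier(probs, truths)
  classes <- colnames(probs) %||% unique(as.character(truths))
  base_probs <- if (baseline == "uniform") {
    matrix(1 / K, nrow(probs), K, dimnames = list(NULL, classes))
  } else {
    fr <- as.numeric(table(factor(as.character(truths), levels = classes))) / length(truths)
    matrix(fr, nrow(probs), K, byrow = TRUE, dimnames = list(NULL, classes))
  }
  bs0 <- brier(base_probs, truths)
  per_class <- dplyr::mutate(
    dplyr::left_join(bs$per_class,
                     dplyr::rename(bs0$per_class, brier0 = "brier", n0 = "n"),
                     by = "class"),
    sbs = 1 - .data$brier / .data$brier0)
  list(total = 1 - bs$total / bs0$total,
       per_class = per_class[, c("class", "sbs", "n")])
}

#' Leave-one-out cross-validation of multinomial genomic classification
#'
#' For every sample: the classifiers are retrained on the remaining samples
#' (marker centering frequencies recomputed on the training set only, to
#' avoid leakage), the held-out sample is scored, and its class probability
#' vector and predicted class recorded.  Aggregates are accuracy, Brier
#' score and scaled Brier score, per class and total.
#'
#' By default CV uses reduced chains (2000 iterations, 500 burn-in) for
#' desk-scale feasibility; pass a full-length `spec` to override.
#'
#' @param g a [genotype_matrix()] (already QC-filtered).
#' @param labels tibble with `sample_id`, `class`.
#' @param scheme `"ova"`, `"ovo_couple"` or `"ovo_vote"`.
#' @param backend binary classifier backend name.
#' @param spec optional [threshold_model_spec()]; default reduced CV chains.
#' @param include_classes,exclude_classes optional class subsets (the
#'   excluded classes are dropped from both training and testing, mirroring
#'   a leave-a-breed-out design).
#' @param feature_mode passed to [feature_source()].
#' @param ped pedigree (for `feature_mode = "chol_A"`).
#' @param seed base seed; fold i derives its seeds from `seed` and `i`.
#' @return object of class `cv_result`: `predictions` tibble (per sample),
#'   `summary` tibble (per class + Total rows of accuracy, Brier, sBS),
#'   `scheme`, `classes`.
#' @export
loo_cv <- function(g, labels, scheme = c("ova", "ovo_couple", "ovo_vote"),
                   backend = "ridge", spec = NULL,
                   include_classes = NULL, exclude_classes = NULL,
                   feature_mode = "markers", ped = NULL, seed = 1) {
  scheme <- match.arg(scheme)
  labels <- tibble::as_tibble(labels)
  if (!is.null(include_classes))
    labels <- dplyr::filter(labels, .data$class %in% include_classes)
  if (!is.null(exclude_classes))
    labels <- dplyr::filter(labels, !.data$class %in% exclude_classes)
  labels$class <- droplevels(factor(labels$class,
    levels = if (is.factor(labels$class)) levels(labels$class) else unique(labels$class)))
  sizes <- table(labels$class)
  if (any(sizes < 2L))
    stop("class(es) of size 1 cannot be both trained and tested: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  if (is.null(spec) && backend %in% c("ridge", "bayes_a", "bayes_c_pi"))
    spec <- threshold_model_spec(prior = backend, n_iter = 2000, burn_in = 500)
  g <- subset_samples(g, labels$sample_id)
  n <- nrow(labels)
  K <- nlevels(labels$class)
  lev <- levels(labels$class)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    g_tr <- subset_samples(g, tr)
    f_tr <- g_tr$freq
    f_safe <- pmin(pmax(f_tr, 1e-6), 1 - 1e-6) # held-out centering needs interior f
    X_tr <- feature_source(g_tr, mode = feature_mode, ped = ped)
    X_te <- switch(feature_mode,
      markers = sweep(g$dosage[i, , drop = FALSE], 2L, 2 * f_safe, "-"),
      stop("leave-one-out supports feature_mode = \"markers\""))
    cls_tr <- droplevels(labels$class[tr])
    if (nlevels(cls_tr) < K)
      stop("held-out sample ", labels$sample_id[i], " empties its class")
    fold_seed <- (seed * 1000L + i) %% .Machine$integer.max
    model <- if (scheme == "ova")
      train_ova(X_tr, cls_tr, backend = backend, spec = spec, seed = fold_seed)
    else
      train_ovo(X_tr, cls_tr, backend = backend, spec = spec, seed = fold_seed)
    pred <- switch(scheme,
      ova = predict(model, X_te),
      ovo_couple = predict(model, X_te, method = "couple"),
      ovo_vote = predict(model, X_te, method = "vote"))
    pred$sample <- labels$sample_id[i]
    pred$true_class <- as.character(labels$class[i])
    rows[[i]] <- pred
  }
  predictions <- dplyr::bind_rows(rows)
  probs <- as.matrix(predictions[, paste0("p_", lev)])
  colnames(probs) <- lev
  if (scheme == "ovo_vote") { # voting measures need not sum to 1 under cycles
    rs <- rowSums(probs)
    rs[rs == 0] <- 1
    probs <- probs / rs
  }
  truths <- predictions$true_class
  preds <- as.character(predictions$predicted_class)
  bs <- brier(probs, truths)
  sbs <- scaled_brier(probs, truths, K = K)
  per_class <- tibble::tibble(
    class = lev,
    n = as.integer(table(factor(truths, levels = lev))),
    accuracy = vapply(lev, function(k)
      accuracy(preds[truths == k], truths[truths == k]), numeric(1)),
    brier = bs$per_class$brier,
    sbs = sbs$per_class$sbs)
  summary <- dplyr::bind_rows(per_class, tibble::tibble(
    class = "Total", n = length(truths),
    accuracy = accuracy(preds, truths), brier = bs$total, sbs = sbs$total))
  structure(list(predictions = predictions, summary = summary,
                 scheme = scheme, backend = backend, classes = lev,
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> leave-one-out, scheme=", x$scheme, ", backend=", x$backend,
      "\n", sep = "")
  print(as.data.frame(x$summary), digits = 3)
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$summary

#' @export
glance.cv_result <- function(x, ...) {
  tot <- dplyr::filter(x$summary, .data$class == "Total")
  tibble::tibble(scheme = x$scheme, backend = x$backend, n = tot$n,
                 accuracy = tot$accuracy, brier = tot$brier, sbs = tot$sbs)
}

#' Bar chart of per-class cross-validation accuracy and sBS
#'
#' @param object a `cv_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$summary, c("accuracy", "sbs"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Leave-one-out CV (", object$scheme, ", ",
                                 object$backend, ")"))
}
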