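#' Center marker covariates
#'
#' Produces the centered gene-content matrix `M = dosage - 2 f` used by the
#' VanRaden genomic relationship matrix and by marker regressions, together
#' with the scaling denominator `sum(2 f (1 - f))`.  Centering frequencies
#' default to the sample frequencies of `g`; cross-validation callers pass
#' training-only frequencies via `f` to avoid leakage.
#'
#' @param g a [genotype_matrix()].
#' @param f optional external per-marker centering frequencies in (0, 1);
#'   markers with external `f` of exactly 0 or 1 are rejected.
#' @return object of class `centered_markers` with elements `M`, `f`,
#'   `denom`.  Markers monomorphic under sample-based centering contribute
#'   zero columns and are excluded from `denom`.
#' @export
center_markers <- function(g, f = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  external <- !is.null(f)
  if (external) {
    if (length(f) != length(g$markers))
      stop("external frequencies must have one entry per marker")
    if (any(f <= 0 | f >= 1))
      stop("degenerate external centering frequency (0 or 1)")
  } else {
    f <- g$freq
  }
  dos <- g$dosage
  if (anyNA(dos)) { # mean-imputation contributes zero after centering
    na_idx <- which(is.na(dos), arr.ind = TRUE)
    dos[na_idx] <- 2 * f[na_idx[, 2L]]
  }
  M <- sweep(dos, 2L, 2 * f, "-")
  poly <- f > 0 & f < 1
  if (!any(poly)) stop("all markers monomorphic: zero scaling denominator")
  denom <- sum(2 * f[poly] * (1 - f[poly]))
  structure(list(M = M, f = f, denom = denom, markers = g$markers,
                 samples = g$samples),
            class = "centered_markers")
}

new_relmat <- function(values, kind, samples) {
  dimnames(values) <- list(samples, samples)
  structure(list(values = values, kind = kind, samples = samples),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat("<relationship_matrix> kind=", x$kind, ", order ", nrow(x$values),
      ", mean diag ", sprintf("%.3f", mean(diag(x$values))), "\n", sep = "")
  invisible(x)
}

#' VanRaden genomic relationship matrix
#'
#' `G = M M' / sum(2 f (1 - f))` from centered gene content.
#'
#' @param x a `centered_markers` object from [center_markers()], or a
#'   [genotype_matrix()] (centered on its own sample frequencies).
#' @return a `relationship_matrix` of kind `"genomic"`.
#' @export
grm <- function(x) {
  if (inherits(x, "genotype_matrix")) x <- center_markers(x)
  stopifnot(inherits(x, "centered_markers"))
  if (x$denom <= 0) stop("degenerate scaling denominator")
  G <- tcrossprod(x$M) / x$denom
  G <- (G + t(G)) / 2
  new_relmat(G, "genomic", x$samples)
}

#' Pedigree numerator relationship matrix
#'
#' Builds A (twice the kinship matrix) by the tabular method in topological
#' order; founders take diagonal 1, parents unknown are treated as unrelated
#' base individuals.
#'
#' @param ped tibble with columns `id`, `sire`, `dam` (`NA` = unknown).
#' @return a `relationship_matrix` of kind `"pedigree"` covering every
#'   pedigree individual, in topological order.
#' @export
nrm <- function(ped) {
  ped <- tibble::as_tibble(ped)
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  ids <- ped$id
  if (anyDuplicated(ids)) stop("pedigree IDs must be unique")
  # include parents that lack their own record as founders
  parents <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ids)
  if (length(parents))
    ped <- dplyr::bind_rows(
      tibble::tibble(id = parents, sire = NA_character_, dam = NA_character_), ped)
  n <- nrow(ped)
  # topological sort (Kahn); cycle detection
  sire_i <- match(ped$sire, ped$id)
  dam_i <- match(ped$dam, ped$id)
  placed <- rep(FALSE, n)
  order <- integer(0)
  parent_done <- function(ix) is.na(ix) | placed[replace(ix, is.na(ix), 1L)]
  repeat {
    ready <- which(!placed & parent_done(sire_i) & parent_done(dam_i))
    if (!length(ready)) break
    placed[ready] <- TRUE
    order <- c(order, ready)
  }
  if (length(order) < n)
    stop("pedigree cycle detected involving: ",
         paste(ped$id[!placed][1], collapse = ", "))
  ped <- ped[order, ]
  sire_i <- match(ped$sire, ped$id)
  dam_i <- match(ped$dam, ped$id)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sire_i[i]; d <- dam_i[i]
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        a <- 0
        if (!is.na(s)) a <- a + 0.5 * A[j, s]
        if (!is.na(d)) a <- a + 0.5 * A[j, d]
        A[i, j] <- A[j, i] <- a
      }
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  new_relmat(A, "pedigree", ped$id)
}

# subset a relationship matrix to given sample IDs (in that order)
subset_relmat <- function(R, ids) {
  idx <- match(ids, R$samples)
  if (anyNA(idx)) stop("sample(s) not in relationship matrix: ",
                       paste(head(ids[is.na(idx)], 5), collapse = ", "))
  new_relmat(R$values[idx, idx, drop = FALSE], R$kind, ids)
}

#' Eigendecomposition of a relationship matrix
#'
#' Eigenvalues are returned in decreasing order with the cumulative
#' proportion of explained variance computed over nonnegative eigenvalues
#' (negative numerical eigenvalues are clipped to zero for the variance
#' totals).
#'
#' @param R a `relationship_matrix`.
#' @return object of class `eigen_basis` with elements `U` (eigenvectors in
#'   columns), `d` (eigenvalues, decreasing), `cumvar`, `samples`.
#' @export
relmat_eigen <- function(R) {
  stopifnot(inherits(R, "relationship_matrix"))
  ev <- eigen(R$values, symmetric = TRUE)
  d <- ev$values
  pos <- pmax(d, 0)
  structure(list(U = ev$vectors, d = d,
                 cumvar = cumsum(pos) / sum(pos), samples = R$samples),
            class = "eigen_basis")
}

#' @export
tidy.eigen_basis <- function(x, ...) {
  tibble::tibble(component = seq_along(x$d), eigenvalue = x$d,
                 cum_var = x$cumvar)
}

#' Lower Cholesky factor of a relationship matrix
#'
#' Returns L with `L L' = A`, usable as a feature matrix for regression over
#' the pedigree (or over genomic relationships).  If the matrix is not
#' positive definite, a jitter `eps * I` is added (with a message) before
#' retrying.
#'
#' @param R a `relationship_matrix`.
#' @param eps jitter added to the diagonal if the first factorization fails.
#' @return n x n lower-triangular matrix with sample IDs as rownames.
#' @export
chol_lower <- function(R, eps = 1e-8) {
  stopifnot(inherits(R, "relationship_matrix"))
  L <- tryCatch(t(chol(R$values)), error = function(e) NULL)
  if (is.null(L)) {
    message("relationship matrix not positive definite; adding jitter ", eps)
    L <- tryCatch(t(chol(R$values + diag(eps, nrow(R$values)))),
                  error = function(e)
                    stop("factorization failed even with jitter ", eps))
  }
  rownames(L) <- R$samples
  L
}

#' Summarize relationships within and between classes
#'
#' Mean and SD of the pairwise relationship entries for every ordered class
#' pair, diagonals excluded.  Within-class cells with fewer than two samples
#' have no pairs and report `NA`.
#'
#' @param R a `relationship_matrix`.
#' @param labels tibble with `sample_id`, `class`.
#' @return tibble with columns `class_a`, `class_b`, `mean`, `sd`, `n_pairs`.
#' @export
relationship_summary <- function(R, labels) {
  stopifnot(inherits(R, "relationship_matrix"))
  labels <- tibble::as_tibble(labels)
  idx <- match(labels$sample_id, R$samples)
  if (anyNA(idx)) stop("labelled sample(s) not in relationship matrix")
  cls <- labels$class
  if (!is.factor(cls)) cls <- factor(cls, levels = unique(cls))
  lev <- levels(cls)
  V <- R$values[idx, idx, drop = FALSE]
  out <- tidyr::expand_grid(class_a = lev, class_b = lev)
  out <- dplyr::filter(out, match(.data$class_a, lev) <= match(.data$class_b, lev))
  res <- purrr::pmap(out, function(class_a, class_b) {
    ia <- which(cls == class_a); ib <- which(cls == class_b)
    block <- V[ia, ib, drop = FALSE]
    vals <- if (class_a == class_b)
      block[lower.tri(block)] else as.vector(block)
    tibble::tibble(mean = if (length(vals)) mean(vals) else NA_real_,
                   sd = if (length(vals) > 1) sd(vals) else NA_real_,
                   n_pairs = length(vals))
  })
  dplyr::bind_cols(out, dplyr::bind_rows(res))
}

#' Scatterplot of the leading eigenvectors of a relationship matrix
#'
#' @param object an `eigen_basis`.
#' @param labels optional tibble with `sample_id`, `class` for coloring.
#' @param dims which two components to plot.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.eigen_basis <- function(object, labels = NULL, dims = c(1, 2), ...) {
  df <- tibble::tibble(sample_id = object$samples,
                       x = object$U[, dims[1]], y = object$U[, dims[2]])
  if (!is.null(labels))
    df <- dplyr::left_join(df, tibble::as_tibble(labels), by = "sample_id")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(x = paste0("Eigenvector ", dims[1]),
                  y = paste0("Eigenvector ", dims[2]))
  if (!is.null(labels))
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$class))
  else p + ggplot2::geom_point()
}
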