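#' Binary classifier backends
#'
#' Every multiclass scheme in the package is backend-agnostic: a backend is
#' a named entry in a registry providing `train(X, y, seed, ...)` returning
#' a model object, plus either `predict_prob(model, X_new)` returning
#' success probabilities in (0, 1) or `predict_label(model, X_new)`
#' returning \{0, 1\} labels.  Probability-free backends (such as the
#' max-margin adapter) can participate in one-vs-one voting only.
#'
#' Built-in backends: `"ridge"`, `"bayes_a"`, `"bayes_c_pi"` (the native
#' Bayesian probit threshold models) and `"svm"` (a thin adapter over the
#' libsvm-backed implementation in e1071, run with library-default tuning
#' and linear kernel, emitting discrete labels only).
#'
#' @param name unique backend name.
#' @param backend list with elements `train`, and `predict_prob` and/or
#'   `predict_label`.
#' @return `register_backend` returns the name invisibly;
#'   `get_backend` returns the backend list; `list_backends` the names.
#' @export
register_backend <- function(name, backend) {
  stopifnot(is.character(name), length(name) == 1L, is.list(backend),
            is.function(backend$train))
  if (is.null(backend$predict_prob) && is.null(backend$predict_label))
    stop("backend must provide predict_prob or predict_label")
  if (name %in% names(the$backends))
    stop("backend already registered: ", name)
  the$backends[[name]] <- backend
  invisible(name)
}

#' @rdname register_backend
#' @export
get_backend <- function(name) {
  b <- the$backends[[name]]
  if (is.null(b)) stop("unknown backend: ", name,
                       " (registered: ", paste(list_backends(), collapse = ", "), ")")
  b
}

#' @rdname register_backend
#' @export
list_backends <- function() names(the$backends)

bayes_backend <- function(prior) {
  force(prior)
  list(
    train = function(X, y, seed, spec = NULL, ...) {
      if (is.null(spec)) spec <- threshold_model_spec(prior = prior)
      spec$prior <- prior
      spec$seed <- as.integer(seed)
      fit_probit(y, Z = X, spec = spec)
    },
    predict_prob = function(model, X_new) predict_prob(model, X_new))
}

svm_backend <- function() {
  list(
    train = function(X, y, seed, ...) {
      set.seed(seed)
      e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                 kernel = "linear", scale = FALSE)
    },
    predict_label = function(model, X_new)
      as.integer(as.character(predict(model, X_new))))
}

register_builtin_backends <- function() {
  the$backends <- list()
  register_backend("ridge", bayes_backend("ridge"))
  register_backend("bayes_a", bayes_backend("bayes_a"))
  register_backend("bayes_c_pi", bayes_backend("bayes_c_pi"))
  register_backend("svm", svm_backend())
}

.onLoad <- function(libname, pkgname) register_builtin_backends()

#' Build a feature matrix for classification
#'
#' @param g a [genotype_matrix()] (required for `"markers"` and
#'   `"grm_rows"`).
#' @param mode `"markers"` — centered gene content; `"chol_A"` — lower
#'   Cholesky factor of the pedigree numerator relationship matrix,
#'   restricted to the genotyped samples; `"grm_rows"` — each sample's row
#'   of the VanRaden G as its feature vector.
#' @param ped pedigree tibble (required for `"chol_A"`).
#' @param f optional centering frequencies for `"markers"`.
#' @return numeric feature matrix with samples in rows and attribute
#'   `"feature_mode"`.
#' @export
feature_source <- function(g, mode = c("markers", "chol_A", "grm_rows"),
                           ped = NULL, f = NULL) {
  mode <- match.arg(mode)
  X <- switch(mode,
    markers = center_markers(g, f = f)$M,
    chol_A = {
      if (is.null(ped)) stop("chol_A mode needs a pedigree")
      A <- subset_relmat(nrm(ped), g$samples)
      chol_lower(A)
    },
    grm_rows = grm(center_markers(g, f = f))$values)
  attr(X, "feature_mode") <- mode
  X
}
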