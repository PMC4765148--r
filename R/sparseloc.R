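# Multi-label sparse regression for subcellular localization: one-vs-rest
# LASSO / elastic-net fits, essential-term selection, refit on the reduced
# space, scoring and the multi-label decision scheme.

#' Transform label sets to a +/-1 label matrix
#'
#' One-vs-rest encoding: entry (i, m) is +1 when location m belongs to
#' protein i's label set and -1 otherwise. Every protein must have at
#' least one location.
#'
#' @param label_sets list of non-empty integer sets with elements in 1..M.
#' @param M number of locations.
#' @return N x M matrix with entries in \{-1, +1\}.
#' @export
transform_labels <- function(label_sets, M) {
  if (any(lengths(label_sets) == 0L)) stop("empty label set")
  labs <- unlist(label_sets)
  if (any(labs < 1L) || any(labs > M)) stop("label outside 1..M")
  y <- matrix(-1, length(label_sets), M)
  for (i in seq_along(label_sets)) y[i, label_sets[[i]]] <- 1
  rownames(y) <- names(label_sets)
  y
}

# accept either a list of label sets or a +/-1 matrix
as_label_matrix <- function(labels, M = NULL) {
  if (is.matrix(labels)) {
    if (!all(labels %in% c(-1, 1))) stop("label matrix entries must be -1/+1")
    if (any(rowSums(labels == 1) == 0L)) stop("every row needs >= 1 positive label")
    labels
  } else {
    if (is.null(M)) M <- max(unlist(labels))
    transform_labels(labels, M)
  }
}

label_matrix_to_sets <- function(y) {
  apply(y, 1L, function(r) which(r > 0), simplify = FALSE)
}

#' One-vs-rest sparse selection fits
#'
#' Fits M independent binary one-vs-rest regressions of the transformed
#' labels on the GO frequency matrix: class m minimizes
#' \eqn{\sum_i (y_{i,m} - \beta_m^\top x_i)^2 + \lambda_m \|\beta_m\|_1}
#' (mode `"mlasso"`), with the additional ridge term
#' \eqn{\gamma_m \|\beta_m\|_2^2} for mode `"men"`. Penalties may be given
#' per class, recycled, or chosen by per-class cross-validation
#' ([cv_penalty()]) when `lambda` is `NULL`. The same fold assignment is
#' used for every class, so permuting class order permutes the fitted
#' components consistently.
#'
#' @param x N x T numeric matrix of GO term frequencies.
#' @param labels list of label sets, or an N x M matrix of -1/+1 labels.
#' @param mode `"mlasso"` (L1) or `"men"` (L1 + L2).
#' @param lambda per-class L1 penalties (recycled), or `NULL` for CV.
#' @param gamma per-class L2 penalties for `"men"` (recycled); when
#'   `lambda` is `NULL` a vector of candidate gammas for the CV grid
#'   (default `c(0.01, 0.1, 1)`).
#' @param nfolds,nlambda,lambda_min_ratio CV grid controls, see
#'   [cv_penalty()].
#' @param standardize,intercept passed to the solver.
#' @return list of class `"selection_fits"`: M `"sparse_fit"` objects plus
#'   the mode and the penalties used.
#' @export
fit_feature_selection <- function(x, labels, mode = c("mlasso", "men"),
                                  lambda = NULL, gamma = NULL,
                                  nfolds = 5L, nlambda = 20L,
                                  lambda_min_ratio = 0.01,
                                  standardize = TRUE, intercept = TRUE) {
  mode <- match.arg(mode)
  y <- as_label_matrix(labels)
  M <- ncol(y)
  if (nrow(y) != nrow(x)) stop("labels and design disagree on N")
  if (mode == "mlasso") {
    gamma_fixed <- rep(0, M)
    gamma_grid <- 0
  } else if (!is.null(lambda)) {
    if (is.null(gamma)) gamma <- 0.1
    gamma_fixed <- rep_len(gamma, M)
  } else {
    gamma_grid <- if (is.null(gamma)) c(0.01, 0.1, 1) else gamma
  }
  lambda_fixed <- if (!is.null(lambda)) rep_len(lambda, M) else NULL
  folds <- sample(rep(seq_len(nfolds), length.out = nrow(x)))
  fits <- vector("list", M)
  lam_used <- numeric(M)
  gam_used <- numeric(M)
  for (m in seq_len(M)) {
    lam_m <- lambda_fixed[m]
    if (is.null(lambda_fixed)) {
      cv <- tryCatch(
        cv_penalty(x, y[, m], gamma = gamma_grid, nfolds = nfolds,
                   nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
                   standardize = standardize, intercept = intercept,
                   folds = folds),
        error = function(e) stop(sprintf("class %d: %s", m, conditionMessage(e)),
                                 call. = FALSE))
      lam_m <- cv$lambda
      gam_m <- cv$gamma
    } else {
      gam_m <- if (mode == "mlasso") 0 else gamma_fixed[m]
    }
    fits[[m]] <- tryCatch(
      if (gam_m == 0) fit_lasso(x, y[, m], lam_m, standardize, intercept)
      else fit_elastic_net(x, y[, m], lam_m, gam_m, standardize, intercept),
      error = function(e) stop(sprintf("class %d: %s", m, conditionMessage(e)),
                               call. = FALSE))
    lam_used[m] <- lam_m
    gam_used[m] <- gam_m
  }
  structure(list(fits = fits, mode = mode, lambda = lam_used,
                 gamma = gam_used, M = M, T = ncol(x)),
            class = "selection_fits")
}

#' Essential GO terms of a selection model
#'
#' The essential terms are the union, over the M one-vs-rest fits, of the
#' features whose weights are non-zero in at least one class, kept in
#' vocabulary order. They define the reduced feature space on which the
#' final classifiers are refit.
#'
#' @param selection a `"selection_fits"` object (or a plain list of
#'   `"sparse_fit"`).
#' @param vocab a `"go_vocabulary"`, or a character vector of column names;
#'   `NULL` yields indices only.
#' @return class `"essential_terms"`: sorted integer `indices` into the
#'   vocabulary, the corresponding `terms`, size `S`, and the per-class
#'   supports.
#' @export
select_essential_terms <- function(selection, vocab = NULL) {
  fits <- if (inherits(selection, "selection_fits")) selection$fits else selection
  supports <- lapply(fits, function(f) f$active)
  idx <- sort(unique(unlist(supports)))
  terms <- if (is.null(vocab)) {
    NULL
  } else if (inherits(vocab, "go_vocabulary")) {
    vocab$terms[idx]
  } else {
    vocab[idx]
  }
  structure(list(indices = idx, terms = terms, S = length(idx),
                 per_class = supports),
            class = "essential_terms")
}

#' @export
print.essential_terms <- function(x, ...) {
  cat(sprintf("essential terms: S = %d (per-class supports: %s)\n", x$S,
              paste(lengths(x$per_class), collapse = ", ")))
  invisible(x)
}

#' Project a feature matrix onto the essential terms
#'
#' @param x N x T matrix in vocabulary space.
#' @param essential an `"essential_terms"` object or integer indices.
#' @return N x S matrix of the essential columns, in vocabulary order.
#' @export
project_features <- function(x, essential) {
  idx <- if (inherits(essential, "essential_terms")) essential$indices else essential
  if (length(idx) == 0L) {
    stop(paste("the essential term set is empty: nothing to project onto;",
               "lower the penalties or use the hierarchical (HIB) mapping"))
  }
  if (any(idx < 1L) || any(idx > ncol(x))) stop("essential index out of range")
  x[, idx, drop = FALSE]
}

#' Refit one-vs-rest classifiers on the essential features
#'
#' The classification-stage weights are obtained by solving the same
#' penalized problems as the selection stage, but over the S-dimensional
#' essential feature space only (the refit uses training data alone).
#'
#' @param xs N x S projected training matrix from [project_features()].
#' @param labels label sets or -1/+1 matrix.
#' @param lambda,gamma per-class penalties (recycled); defaults should be
#'   the selection-stage penalties.
#' @param mode `"mlasso"` or `"men"`.
#' @inheritParams fit_feature_selection
#' @return a `"selection_fits"` object over the S-dimensional space.
#' @export
refit_selected <- function(xs, labels, lambda, gamma = 0,
                           mode = c("mlasso", "men"),
                           standardize = TRUE, intercept = TRUE) {
  mode <- match.arg(mode)
  fit_feature_selection(xs, labels, mode = mode, lambda = lambda,
                        gamma = if (mode == "mlasso") 0 else gamma,
                        standardize = standardize, intercept = intercept)
}

# ---- the fitted-model object -----------------------------------------------

#' Fit a multi-label sparse localization model (mLASSO / mEN)
#'
#' The full training pipeline: transform the label sets to one-vs-rest
#' +/-1 labels, fit M penalized regressions on the GO term-frequency
#' matrix (LASSO for `mode = "mlasso"`, elastic net for `mode = "men"`),
#' take the union of the non-zero supports as the essential GO terms,
#' project the design onto them, and refit the M classifiers on the
#' reduced space. Scores of a query are affine functions
#' \eqn{s_m = \epsilon_{0,m} + \tilde\beta_m^\top x^s}; the predicted label
#' set contains every location with a positive score, falling back to the
#' argmax when all scores are negative (see [decide_labels()]).
#'
#' Penalties default to per-class 5-fold cross-validation on a 20-point
#' logarithmic lambda grid (gamma from \{0.01, 0.1, 1\} for mEN); the
#' refit reuses the selection-stage penalties unless `refit_lambda` /
#' `refit_gamma` are given.
#'
#' @param x N x T numeric matrix of GO term frequencies with column names,
#'   or a named list of GO multisets (a vocabulary is then built from
#'   them, or taken from `vocabulary`).
#' @param labels list of integer label sets (values in 1..M), or an
#'   N x M matrix of -1/+1 transformed labels.
#' @param mode `"mlasso"` or `"men"`.
#' @param M number of locations; inferred from `labels` when missing.
#' @param lambda,gamma penalties, see [fit_feature_selection()].
#' @param refit_lambda,refit_gamma penalties for the refit stage (default:
#'   the selection-stage values).
#' @param vocabulary optional `"go_vocabulary"` used when `x` is a list of
#'   multisets.
#' @param nfolds,nlambda,lambda_min_ratio CV controls.
#' @param standardize,intercept solver controls; with `intercept = FALSE`
#'   all model intercepts are zero.
#' @return an object of class `"sparseloc"`: the essential term set, the
#'   S x M refit weight matrix (original count scale), per-class
#'   intercepts, penalties for both stages, the selection-stage fits, and
#'   the vocabulary.
#' @seealso [predict.sparseloc()], [loocv()], [feature_breakdown()]
#' @examples
#' sim <- make_planted_dataset(n = 80, t = 30, m = 3, k = 4, seed = 1)
#' fit <- sparseloc(sim$x, sim$labels, mode = "mlasso", lambda = 40)
#' fit
#' predict(fit, sim$x[1:3, , drop = FALSE])
#' @export
sparseloc <- function(x, labels, mode = c("mlasso", "men"), M = NULL,
                      lambda = NULL, gamma = NULL,
                      refit_lambda = NULL, refit_gamma = NULL,
                      vocabulary = NULL, nfolds = 5L, nlambda = 20L,
                      lambda_min_ratio = 0.01, standardize = TRUE,
                      intercept = TRUE) {
  mode <- match.arg(mode)
  cl <- match.call()
  if (is.list(x) && !is.data.frame(x)) {
    if (is.null(vocabulary)) vocabulary <- build_vocabulary(x)
    x <- build_go_matrix(x, vocabulary)
  } else {
    x <- as.matrix(x)
    if (is.null(vocabulary) && !is.null(colnames(x))) {
      vocabulary <- structure(list(terms = colnames(x),
                                   index = stats::setNames(seq_len(ncol(x)),
                                                           colnames(x))),
                              class = "go_vocabulary")
    }
  }
  if (is.null(M)) {
    M <- if (is.matrix(labels)) ncol(labels) else max(unlist(labels))
  }
  y <- as_label_matrix(labels, M)
  selection <- fit_feature_selection(x, y, mode = mode, lambda = lambda,
                                     gamma = gamma, nfolds = nfolds,
                                     nlambda = nlambda,
                                     lambda_min_ratio = lambda_min_ratio,
                                     standardize = standardize,
                                     intercept = intercept)
  essential <- select_essential_terms(selection, vocabulary)
  xs <- project_features(x, essential)
  rl <- if (is.null(refit_lambda)) selection$lambda else rep_len(refit_lambda, M)
  rg <- if (is.null(refit_gamma)) selection$gamma else rep_len(refit_gamma, M)
  refit <- refit_selected(xs, y, lambda = rl, gamma = rg, mode = mode,
                          standardize = standardize, intercept = intercept)
  weights <- vapply(refit$fits, function(f) f$beta, numeric(essential$S))
  weights <- matrix(weights, nrow = essential$S, ncol = M,
                    dimnames = list(essential$terms, NULL))
  intercepts <- vapply(refit$fits, function(f) f$intercept, 0)
  structure(list(mode = mode, M = M, N = nrow(x), T = ncol(x),
                 vocabulary = vocabulary, essential = essential,
                 weights = weights, intercepts = intercepts,
                 selection = selection, refit = refit,
                 penalties = list(selection_lambda = selection$lambda,
                                  selection_gamma = selection$gamma,
                                  refit_lambda = rl, refit_gamma = rg),
                 standardize = standardize, intercept = intercept,
                 call = cl),
            class = "sparseloc")
}

#' @export
print.sparseloc <- function(x, ...) {
  cat(sprintf("%s localization model\n",
              if (x$mode == "mlasso") "Multi-label LASSO (mLASSO)"
              else "Multi-label elastic net (mEN)"))
  cat(sprintf("  %d proteins, %d locations, T = %d GO terms\n",
              x$N, x$M, x$T))
  cat(sprintf("  essential GO terms: S = %d (%.1f%% of vocabulary)\n",
              x$essential$S, 100 * x$essential$S / max(1, x$T)))
  cat(sprintf("  per-class lambda: %s\n",
              paste(signif(x$penalties$selection_lambda, 3), collapse = " ")))
  if (x$mode == "men") {
    cat(sprintf("  per-class gamma:  %s\n",
                paste(signif(x$penalties$selection_gamma, 3), collapse = " ")))
  }
  invisible(x)
}

#' @export
coef.sparseloc <- function(object, stage = c("refit", "selection"), ...) {
  stage <- match.arg(stage)
  if (stage == "refit") return(object$weights)
  b <- vapply(object$selection$fits, function(f) f$beta, numeric(object$T))
  matrix(b, nrow = object$T, ncol = object$M,
         dimnames = list(if (!is.null(object$vocabulary))
           object$vocabulary$terms else NULL, NULL))
}

#' @export
summary.sparseloc <- function(object, threshold = 0.1, ...) {
  structure(list(model = object,
                 weight_summary = weight_summary(object),
                 significance = classify_weights(object, threshold),
                 threshold = threshold),
            class = "summary.sparseloc")
}

#' @export
print.summary.sparseloc <- function(x, ...) {
  print(x$model)
  cat("\nPer-location weight summary:\n")
  print(x$weight_summary, row.names = FALSE)
  sig <- x$significance
  cat(sprintf("\nsignificantly essential (|weight| > %g): %d positive, %d negative\n",
              x$threshold, sum(sig$significant == "positive", na.rm = TRUE),
              sum(sig$significant == "negative", na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.sparseloc <- function(x, which = c("counts", "distribution"), ...) {
  which <- match.arg(which)
  ws <- weight_summary(x)
  if (which == "counts") {
    h <- t(as.matrix(ws[, c("positive", "negative")]))
    graphics::barplot(h, beside = TRUE, names.arg = ws$location,
                      legend.text = c("positive", "negative"),
                      xlab = "subcellular location",
                      ylab = "number of non-zero weights",
                      main = sprintf("%s: location-specific weights", x$mode),
                      ...)
  } else {
    w <- x$weights[x$weights != 0]
    graphics::hist(w, breaks = 30, xlab = "weight",
                   main = sprintf("%s: non-zero weight distribution", x$mode),
                   ...)
    graphics::abline(v = c(-0.1, 0, 0.1), lty = 3)
  }
  invisible(x)
}
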