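# Leave-one-out cross-validation harness.

#' Leave-one-out cross-validation of a localization model
#'
#' For each protein: train on the remaining N - 1 proteins, predict the
#' held-out one, and accumulate all multi-label metrics. By default
#' (`global_selection = FALSE`) the entire pipeline -- vocabulary
#' construction (when `x` is a list of GO multisets), penalty selection,
#' feature selection and refit -- is re-run inside every fold, so the
#' held-out protein never influences any training decision. With
#' `global_selection = TRUE` the essential terms (and penalties) are
#' chosen once on the full data set and only the per-class refits are
#' re-run per fold; this mirrors protocols that report cross-validated
#' accuracy after a single global feature selection, at the cost of a
#' selection bias.
#'
#' @param x N x T count matrix, or a named list of GO multisets.
#' @param labels list of label sets (values in 1..M).
#' @param M number of locations (inferred when missing).
#' @param mode,lambda,gamma,... passed to [sparseloc()].
#' @param global_selection see above.
#' @param dag,hib optional DAG and [hib_params()] enabling the HIB
#'   fallback for held-out proteins lacking essential terms.
#' @param fold_hook optional `function(i, train_idx)` called before each
#'   fold (instrumentation; e.g. leakage assertions in tests).
#' @param on_null what to do when a held-out protein carries none of the
#'   fold's essential terms and no DAG is available: `"error"` aborts with
#'   the fold index (the strict contract), `"intercept"` scores the zero
#'   feature vector, i.e. falls back to the intercept-only decision.
#' @param seed optional seed applied identically before every fold's
#'   penalty CV, making the run reproducible.
#' @return class `"sparseloc_eval"` (see [evaluate_predictions()]) with an
#'   added `predictions` element (the per-protein predicted sets) and
#'   `path` (plain/hib per protein).
#' @export
loocv <- function(x, labels, M = NULL, mode = c("mlasso", "men"),
                  lambda = NULL, gamma = NULL, global_selection = FALSE,
                  dag = NULL, hib = NULL, fold_hook = NULL,
                  on_null = c("error", "intercept"), seed = NULL, ...) {
  mode <- match.arg(mode)
  on_null <- match.arg(on_null)
  is_multisets <- is.list(x) && !is.data.frame(x)
  N <- if (is_multisets) length(x) else nrow(x)
  if (N < 2L) stop("LOOCV needs at least two proteins")
  if (length(labels) != N) stop("labels and data disagree on N")
  if (is.null(M)) M <- max(unlist(labels))

  global_model <- NULL
  if (global_selection) {
    if (!is.null(seed)) set.seed(seed)
    global_model <- sparseloc(x, labels, mode = mode, M = M,
                              lambda = lambda, gamma = gamma, ...)
  }

  predictions <- vector("list", N)
  paths <- character(N)
  for (i in seq_len(N)) {
    train_idx <- setdiff(seq_len(N), i)
    if (!is.null(fold_hook)) fold_hook(i, train_idx)
    if (!is.null(seed)) set.seed(seed + i)
    fit_i <- tryCatch({
      if (global_selection) {
        # keep the global essential set; refit the classifiers per fold
        xt <- if (is_multisets) {
          build_go_matrix(x[train_idx], global_model$vocabulary)
        } else x[train_idx, , drop = FALSE]
        refit_fold(global_model, xt, labels[train_idx])
      } else {
        sparseloc(if (is_multisets) x[train_idx] else
          x[train_idx, , drop = FALSE],
          labels[train_idx], mode = mode, M = M,
          lambda = lambda, gamma = gamma, ...)
      }
    }, error = function(e) {
      stop(sprintf("LOOCV fold %d: %s", i, conditionMessage(e)), call. = FALSE)
    })
    query <- if (is_multisets) x[i] else x[i, , drop = FALSE]
    pred <- tryCatch(
      predict(fit_i, query, dag = dag, hib = hib),
      sparseloc_null_feature_vector = function(e) {
        if (on_null == "error") {
          stop(sprintf("LOOCV fold %d: %s", i, conditionMessage(e)),
               call. = FALSE)
        }
        list(labels = list(decide_labels(fit_i$intercepts)), path = "null")
      },
      error = function(e) {
        stop(sprintf("LOOCV fold %d: %s", i, conditionMessage(e)), call. = FALSE)
      })
    predictions[[i]] <- pred$labels[[1L]]
    paths[i] <- pred$path[1L]
  }
  report <- evaluate_predictions(labels, predictions, M)
  report$predictions <- predictions
  report$path <- paths
  report
}

# re-run the refit stage of a fitted model on a training subset (the
# essential set and penalties stay fixed); used by global-selection LOOCV
refit_fold <- function(model, x_train, labels_train) {
  xs <- project_features(x_train, model$essential)
  refit <- refit_selected(xs, as_label_matrix(labels_train, model$M),
                          lambda = model$penalties$refit_lambda,
                          gamma = model$penalties$refit_gamma,
                          mode = model$mode,
                          standardize = model$standardize,
                          intercept = model$intercept)
  out <- model
  w <- vapply(refit$fits, function(f) f$beta, numeric(model$essential$S))
  out$weights <- matrix(w, nrow = model$essential$S, ncol = model$M,
                        dimnames = dimnames(model$weights))
  out$intercepts <- vapply(refit$fits, function(f) f$intercept, 0)
  out$refit <- refit
  out
}
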