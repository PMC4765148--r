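# Scoring and the multi-label decision scheme.

#' Location scores of query feature vectors
#'
#' The score of location m is \eqn{s_m = \epsilon_{0,m} +
#' \tilde\beta_m^\top x^s}, an affine function of the S-dimensional
#' essential feature vector. Per-term products (weight times term
#' frequency) are the feature scores reported by [feature_breakdown()].
#'
#' @param model a `"sparseloc"` fit.
#' @param xs numeric vector of length S, or an N x S matrix.
#' @return length-M score vector, or an N x M score matrix.
#' @export
localization_scores <- function(model, xs) {
  if (is.null(dim(xs))) xs <- matrix(xs, nrow = 1L)
  if (ncol(xs) != model$essential$S) {
    stop(sprintf("feature vector has %d entries, model expects S = %d",
                 ncol(xs), model$essential$S))
  }
  scores <- xs %*% model$weights
  sweep(scores, 2L, model$intercepts, "+")
}

#' Multi-label decision scheme
#'
#' Converts a score vector into a non-empty predicted label set: when any
#' score is positive, every location with a positive score is predicted
#' (multi-location prediction); when all scores are non-positive the
#' single location with the maximal score is predicted (ties broken
#' toward the lowest class index). The predicted set is therefore never
#' empty.
#'
#' @param scores length-M numeric vector, or an N x M matrix (one row per
#'   protein).
#' @return integer vector of predicted locations, or a list of such
#'   vectors for a matrix input.
#' @export
decide_labels <- function(scores) {
  if (is.matrix(scores)) {
    return(apply(scores, 1L, decide_labels, simplify = FALSE))
  }
  if (anyNA(scores) || any(is.nan(scores))) stop("NaN/NA score")
  pos <- which(scores > 0)
  if (length(pos)) pos else which.max(scores)
}

#' Predict subcellular locations for query proteins
#'
#' Builds the essential-space feature vector of each query (from a count
#' matrix in vocabulary space, or from GO multisets), scores all M
#' locations and applies the decision scheme. A query annotated with none
#' of the essential terms has an all-zero projected vector; when a GO DAG
#' is supplied the hierarchical (HIB) mapping converts its annotations to
#' effective essential-term counts instead, otherwise an error of class
#' `"sparseloc_null_feature_vector"` is raised. The `path` field records
#' which route each query took.
#'
#' @param object a `"sparseloc"` model.
#' @param newdata N x T count matrix in vocabulary space (or N x S in
#'   essential space), or a (list of) GO multiset(s).
#' @param dag optional `"go_dag"` enabling the HIB fallback.
#' @param hib [hib_params()] for the fallback (default parameters if a
#'   `dag` is given).
#' @param type `"response"` returns predictions with scores; `"scores"`
#'   the raw score matrix.
#' @param ... ignored.
#' @return class `"sparseloc_prediction"`: list with `scores` (N x M),
#'   `labels` (list of predicted sets) and `path` (`"plain"` or `"hib"`
#'   per query), or the score matrix for `type = "scores"`.
#' @export
predict.sparseloc <- function(object, newdata, dag = NULL, hib = NULL,
                              type = c("response", "scores"), ...) {
  type <- match.arg(type)
  S <- object$essential$S
  multisets <- NULL
  if (is.list(newdata) && !is.data.frame(newdata)) {
    multisets <- newdata
  } else if (!is.matrix(newdata) && !is.null(names(newdata))) {
    multisets <- list(newdata)   # a single GO multiset
  } else if (!is.matrix(newdata)) {
    newdata <- matrix(newdata, nrow = 1L)  # a single feature vector
  }
  if (!is.null(multisets)) {
    xs <- do.call(rbind, lapply(multisets, function(ms) {
      v <- numeric(S)
      names(v) <- object$essential$terms
      hit <- names(ms) %in% object$essential$terms
      v[names(ms)[hit]] <- ms[hit]
      v
    }))
    full <- multisets
  } else {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) == object$T && object$T != S) {
      xs <- project_features(newdata, object$essential)
      full <- apply(newdata, 1L, function(r) {
        r <- r[r > 0]
        stats::setNames(as.integer(r), names(r))
      }, simplify = FALSE)
    } else if (ncol(newdata) == S) {
      xs <- newdata
      full <- NULL
    } else {
      stop(sprintf("newdata has %d columns; expected T = %d or S = %d",
                   ncol(newdata), object$T, S))
    }
  }
  path <- rep("plain", nrow(xs))
  nullrows <- which(rowSums(abs(xs)) == 0)
  if (length(nullrows)) {
    if (is.null(dag)) {
      stop(structure(
        class = c("sparseloc_null_feature_vector", "error", "condition"),
        list(message = paste("query has no essential GO terms and no DAG",
                             "was supplied for hierarchical mapping"),
             call = NULL)))
    }
    if (is.null(hib)) hib <- hib_params()
    for (i in nullrows) {
      ms <- if (!is.null(full)) full[[i]] else NULL
      if (is.null(ms) || length(ms) == 0L) next
      xs[i, ] <- suppressWarnings(
        map_to_essential(ms, object$essential, dag, hib))
      path[i] <- "hib"
    }
    still <- which(rowSums(abs(xs)) == 0)
    if (length(still)) {
      stop(structure(
        class = c("sparseloc_null_feature_vector", "error", "condition"),
        list(message = sprintf(
          "query %d yields a null feature vector even after HIB mapping",
          still[1L]), call = NULL)))
    }
  }
  scores <- localization_scores(object, xs)
  if (type == "scores") return(scores)
  structure(list(scores = scores, labels = decide_labels(scores),
                 path = path, xs = xs),
            class = "sparseloc_prediction")
}

#' @export
print.sparseloc_prediction <- function(x, ...) {
  n <- nrow(x$scores)
  cat(sprintf("predictions for %d quer%s\n", n, if (n == 1L) "y" else "ies"))
  for (i in seq_len(min(n, 10L))) {
    cat(sprintf("  %s: {%s}  (max score %.3f, via %s)\n",
                if (!is.null(rownames(x$scores))) rownames(x$scores)[i] else i,
                paste(x$labels[[i]], collapse = ","),
                max(x$scores[i, ]), x$path[i]))
  }
  if (n > 10L) cat(sprintf("  ... %d more\n", n - 10L))
  invisible(x)
}
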