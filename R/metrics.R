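# Multi-label evaluation metrics. Truth and prediction are lists of
# non-empty integer label sets; every metric lies in [0, 1].

check_pairs <- function(truth, prediction) {
  if (length(truth) == 0L) stop("no label-set pairs to evaluate")
  if (length(truth) != length(prediction)) {
    stop("truth and prediction differ in length")
  }
  if (any(lengths(truth) == 0L) || any(lengths(prediction) == 0L)) {
    stop("label sets must be non-empty")
  }
  invisible(TRUE)
}

#' Overall actual accuracy (OAA)
#'
#' Fraction of proteins whose predicted label set equals the true label
#' set exactly; a partial match contributes nothing. The most stringent of
#' the multi-label metrics.
#'
#' @param truth,prediction lists of non-empty integer label sets.
#' @return scalar in \[0, 1\].
#' @export
overall_actual_accuracy <- function(truth, prediction) {
  check_pairs(truth, prediction)
  mean(mapply(function(a, b) setequal(a, b), truth, prediction))
}

#' Overall locative accuracy (OLA)
#'
#' Number of correctly predicted locative proteins over the total number
#' of locative proteins: \eqn{\sum_i |Y_i \cap Y^*_i| / \sum_i |Y_i|}. A
#' protein with k true locations counts as k locative proteins.
#'
#' @inheritParams overall_actual_accuracy
#' @return scalar in \[0, 1\].
#' @export
overall_locative_accuracy <- function(truth, prediction) {
  check_pairs(truth, prediction)
  hits <- mapply(function(a, b) length(intersect(a, b)), truth, prediction)
  sum(hits) / sum(lengths(truth))
}

#' Per-protein multi-label accuracy, precision, recall and F1
#'
#' Averages over proteins of the per-instance quantities
#' \eqn{|Y \cap Y^*| / |Y \cup Y^*|} (accuracy, the Jaccard index),
#' \eqn{|Y \cap Y^*| / |Y^*|} (precision), \eqn{|Y \cap Y^*| / |Y|}
#' (recall) and \eqn{2|Y \cap Y^*| / (|Y| + |Y^*|)} (F1, the per-instance
#' harmonic combination of precision and recall).
#'
#' @inheritParams overall_actual_accuracy
#' @return scalar in \[0, 1\].
#' @export
multilabel_accuracy <- function(truth, prediction) {
  check_pairs(truth, prediction)
  mean(mapply(function(a, b) {
    length(intersect(a, b)) / length(union(a, b))
  }, truth, prediction))
}

#' @rdname multilabel_accuracy
#' @export
multilabel_precision <- function(truth, prediction) {
  check_pairs(truth, prediction)
  mean(mapply(function(a, b) length(intersect(a, b)) / length(b),
              truth, prediction))
}

#' @rdname multilabel_accuracy
#' @export
multilabel_recall <- function(truth, prediction) {
  check_pairs(truth, prediction)
  mean(mapply(function(a, b) length(intersect(a, b)) / length(a),
              truth, prediction))
}

#' @rdname multilabel_accuracy
#' @export
multilabel_f1 <- function(truth, prediction) {
  check_pairs(truth, prediction)
  mean(mapply(function(a, b) {
    2 * length(intersect(a, b)) / (length(a) + length(b))
  }, truth, prediction))
}

#' Hamming loss
#'
#' Fraction of misclassified instance-label pairs:
#' \eqn{\frac{1}{NM}\sum_i |Y_i \,\Delta\, Y^*_i|} (symmetric
#' difference). Lower is better; 0 means perfect prediction.
#'
#' @inheritParams overall_actual_accuracy
#' @param M number of locations.
#' @return scalar in \[0, 1\].
#' @export
hamming_loss <- function(truth, prediction, M) {
  check_pairs(truth, prediction)
  if (any(unlist(c(truth, prediction)) > M)) stop("label exceeds M")
  sd_ <- mapply(function(a, b) length(setdiff(a, b)) + length(setdiff(b, a)),
                truth, prediction)
  sum(sd_) / (length(truth) * M)
}

per_class_confusion <- function(truth, prediction, M) {
  tp <- fp <- fn <- integer(M)
  for (i in seq_along(truth)) {
    a <- truth[[i]]; b <- prediction[[i]]
    hit <- intersect(a, b)
    tp[hit] <- tp[hit] + 1L
    fp[setdiff(b, a)] <- fp[setdiff(b, a)] + 1L
    fn[setdiff(a, b)] <- fn[setdiff(a, b)] + 1L
  }
  list(tp = tp, fp = fp, fn = fn)
}

#' Micro- and macro-averaged F1
#'
#' `micro_f1` pools true/false positives and false negatives across the M
#' binary one-vs-rest decisions before computing a single F1, so large
#' locations dominate. `macro_f1` computes a per-class F1 and averages the
#' M values with equal weight; by default a class that never occurs in
#' truth nor prediction contributes an F1 of 0 (a conservative choice;
#' set `include_empty_classes = FALSE` to drop such classes from the
#' average).
#'
#' @inheritParams hamming_loss
#' @param include_empty_classes see above (macro only).
#' @return scalar in \[0, 1\].
#' @export
micro_f1 <- function(truth, prediction, M) {
  check_pairs(truth, prediction)
  cf <- per_class_confusion(truth, prediction, M)
  tp <- sum(cf$tp); fp <- sum(cf$fp); fn <- sum(cf$fn)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' @rdname micro_f1
#' @export
macro_f1 <- function(truth, prediction, M, include_empty_classes = TRUE) {
  check_pairs(truth, prediction)
  cf <- per_class_confusion(truth, prediction, M)
  denom <- 2 * cf$tp + cf$fp + cf$fn
  f1 <- ifelse(denom == 0, 0, 2 * cf$tp / denom)
  if (!include_empty_classes) {
    keep <- denom > 0
    if (!any(keep)) return(0)
    f1 <- f1[keep]
  }
  mean(f1)
}

#' Locative protein count
#'
#' A protein residing in k subcellular locations counts as k locative
#' proteins. Given the co-location breakdown (number of proteins with 1,
#' 2, 3, ... locations) the locative total is \eqn{\sum_k k \, n_k}.
#'
#' @param breakdown integer vector; element k is the number of proteins
#'   with exactly k locations.
#' @return integer locative count.
#' @examples
#' locative_count(c(2580, 480, 43, 3))  # 3681
#' @export
locative_count <- function(breakdown) {
  if (any(breakdown < 0)) stop("negative count in breakdown")
  sum(seq_along(breakdown) * breakdown)
}

#' Per-location locative accuracies
#'
#' For each location m: the number of proteins truly in m that were
#' predicted in m, divided by the number of proteins truly in m.
#'
#' @inheritParams hamming_loss
#' @return data.frame with columns `location`, `correct`, `total`,
#'   `accuracy` (NA when a location never occurs in truth).
#' @export
per_location_accuracy <- function(truth, prediction, M) {
  check_pairs(truth, prediction)
  correct <- total <- integer(M)
  for (i in seq_along(truth)) {
    a <- truth[[i]]
    total[a] <- total[a] + 1L
    hit <- intersect(a, prediction[[i]])
    correct[hit] <- correct[hit] + 1L
  }
  data.frame(location = seq_len(M), correct = correct, total = total,
             accuracy = ifelse(total > 0, correct / total, NA_real_))
}

#' Full multi-label evaluation report
#'
#' Computes all nine metrics plus per-location locative accuracies and the
#' actual/locative protein counts.
#'
#' @inheritParams hamming_loss
#' @return class `"sparseloc_eval"`: a list of all metrics.
#' @export
evaluate_predictions <- function(truth, prediction, M) {
  check_pairs(truth, prediction)
  structure(list(
    oaa = overall_actual_accuracy(truth, prediction),
    ola = overall_locative_accuracy(truth, prediction),
    accuracy = multilabel_accuracy(truth, prediction),
    precision = multilabel_precision(truth, prediction),
    recall = multilabel_recall(truth, prediction),
    f1 = multilabel_f1(truth, prediction),
    micro_f1 = micro_f1(truth, prediction, M),
    macro_f1 = macro_f1(truth, prediction, M),
    hamming_loss = hamming_loss(truth, prediction, M),
    per_location = per_location_accuracy(truth, prediction, M),
    n_actual = length(truth),
    n_locative = sum(lengths(truth)),
    M = M), class = "sparseloc_eval")
}

#' @export
print.sparseloc_eval <- function(x, digits = 3, ...) {
  cat(sprintf("multi-label evaluation: %d actual / %d locative proteins, M = %d\n",
              x$n_actual, x$n_locative, x$M))
  metrics <- c(OAA = x$oaa, OLA = x$ola, Accuracy = x$accuracy,
               Precision = x$precision, Recall = x$recall, F1 = x$f1,
               `Micro F1` = x$micro_f1, `Macro F1` = x$macro_f1,
               HL = x$hamming_loss)
  for (nm in names(metrics)) {
    cat(sprintf("  %-9s %.*f\n", nm, digits, metrics[[nm]]))
  }
  invisible(x)
}
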