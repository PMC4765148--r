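# Interpretability reports: per-protein feature-score tables, weight
# catalogs with significance intervals, and term-location edge lists.

#' Per-protein feature-score breakdown for one location
#'
#' Lists, for a single query and location, every essential GO term with a
#' non-zero weight and a non-zero term frequency, together with its
#' feature score (weight times term frequency), sorted by feature score in
#' descending order (ties broken by vocabulary order). The feature scores
#' plus the location's intercept sum exactly to the location score, so the
#' table decomposes the prediction into per-term contributions.
#'
#' @param model a `"sparseloc"` fit.
#' @param xs query feature vector of length S (essential space), e.g. a
#'   row of `predict(...)$xs`.
#' @param location location index in 1..M.
#' @return data.frame with columns `term`, `location`, `weight`,
#'   `term_freq`, `feature_score`, plus attributes `intercept` and
#'   `score`.
#' @export
feature_breakdown <- function(model, xs, location) {
  if (length(location) != 1L || location < 1L || location > model$M) {
    stop("unknown location")
  }
  xs <- as.numeric(xs)
  if (length(xs) != model$essential$S) {
    stop(sprintf("query vector has %d entries, expected S = %d",
                 length(xs), model$essential$S))
  }
  w <- model$weights[, location]
  fs <- w * xs
  keep <- which(w != 0 & xs != 0)
  ord <- keep[order(-fs[keep], keep)]
  terms <- model$essential$terms
  out <- data.frame(
    term = if (is.null(terms)) as.character(ord) else terms[ord],
    location = rep(location, length(ord)),
    weight = unname(w[ord]),
    term_freq = xs[ord],
    feature_score = unname(fs[ord]))
  score <- model$intercepts[location] + sum(fs)
  attr(out, "intercept") <- unname(model$intercepts[location])
  attr(out, "score") <- unname(score)
  out
}

#' Significance catalog of model weights
#'
#' Assigns every non-zero (term, location) weight to one of the four
#' intervals \eqn{\beta \le -0.1}, \eqn{-0.1 < \beta < 0},
#' \eqn{0 < \beta \le 0.1}, \eqn{\beta > 0.1}, and flags the
#' *significantly essential* terms: positive-significant when
#' \eqn{\beta > } `threshold`, negative-significant when
#' \eqn{\beta < -}`threshold`. Positive significant weights indicate with
#' high confidence that a protein carrying the term resides in the
#' location; negative ones that it does not.
#'
#' @param model a `"sparseloc"` fit.
#' @param threshold positive significance threshold (default 0.1, the
#'   interval boundary).
#' @return data.frame with columns `term`, `location`, `weight`,
#'   `interval` (factor with the four interval labels) and `significant`
#'   (`"positive"`, `"negative"` or `NA`).
#' @export
classify_weights <- function(model, threshold = 0.1) {
  if (threshold <= 0) stop("threshold must be positive")
  w <- model$weights
  nz <- which(w != 0, arr.ind = TRUE)
  b <- w[nz]
  lev <- c("beta<=-0.1", "-0.1<beta<0", "0<beta<=0.1", "beta>0.1")
  interval <- factor(ifelse(b <= -0.1, lev[1L],
                     ifelse(b < 0, lev[2L],
                     ifelse(b <= 0.1, lev[3L], lev[4L]))), levels = lev)
  significant <- ifelse(b > threshold, "positive",
                 ifelse(b < -threshold, "negative", NA_character_))
  terms <- model$essential$terms
  out <- data.frame(
    term = if (is.null(terms)) as.character(nz[, 1L]) else terms[nz[, 1L]],
    location = unname(nz[, 2L]),
    weight = unname(b),
    interval = interval,
    significant = significant)
  out[order(out$location, match(out$term, terms)), , drop = FALSE]
}

#' Per-location weight summary
#'
#' Counts of non-zero, positive and negative refit weights per location,
#' plus the histogram over the four significance intervals -- the tabular
#' form of the location-specific weight analysis.
#'
#' @param model a `"sparseloc"` fit.
#' @return data.frame with one row per location.
#' @export
weight_summary <- function(model) {
  w <- model$weights
  interval_counts <- function(b) {
    b <- b[b != 0]
    c(n_le_m01 = sum(b <= -0.1),
      n_m01_0 = sum(b > -0.1 & b < 0),
      n_0_01 = sum(b > 0 & b <= 0.1),
      n_gt_01 = sum(b > 0.1))
  }
  out <- data.frame(
    location = seq_len(model$M),
    nonzero = apply(w, 2L, function(b) sum(b != 0)),
    positive = apply(w, 2L, function(b) sum(b > 0)),
    negative = apply(w, 2L, function(b) sum(b < 0)))
  cbind(out, t(apply(w, 2L, interval_counts)))
}

#' Term-location network edge list
#'
#' One edge per non-zero (term, location) weight: the structure behind
#' circular network displays linking essential GO terms to the locations
#' whose prediction they contribute to. Terms connected to every location
#' are broad indicators; terms with a single edge are location-specific.
#'
#' @param model a `"sparseloc"` fit.
#' @return data.frame with columns `term`, `location`, `sign`
#'   (`"+"`/`"-"`) and `weight`, ordered by term then location.
#' @export
network_edges <- function(model) {
  w <- model$weights
  nz <- which(w != 0, arr.ind = TRUE)
  terms <- model$essential$terms
  out <- data.frame(
    term = if (is.null(terms)) as.character(nz[, 1L]) else terms[nz[, 1L]],
    location = unname(nz[, 2L]),
    sign = ifelse(w[nz] > 0, "+", "-"),
    weight = unname(w[nz]))
  out[order(nz[, 1L], nz[, 2L]), , drop = FALSE]
}

#' Overlap of the essential term sets of two models
#'
#' Compares the essential GO terms selected by two models sharing a
#' vocabulary (typically an mLASSO and an mEN fit on the same data),
#' globally and per location: intersection, and the terms unique to each
#' side. A nested result (`only_a` empty) means model B's selection
#' contains model A's entirely.
#'
#' @param model_a,model_b `"sparseloc"` fits over the same vocabulary.
#' @return list with `global` and `per_location`, each holding `common`,
#'   `only_a`, `only_b` (character vectors of term ids or indices).
#' @export
overlap_report <- function(model_a, model_b) {
  ta <- model_a$vocabulary$terms
  tb <- model_b$vocabulary$terms
  if (!identical(ta, tb)) stop("models do not share a vocabulary")
  ga <- essential_ids(model_a)
  gb <- essential_ids(model_b)
  per_loc <- lapply(seq_len(min(model_a$M, model_b$M)), function(m) {
    a <- location_support(model_a, m)
    b <- location_support(model_b, m)
    list(common = intersect(a, b), only_a = setdiff(a, b),
         only_b = setdiff(b, a))
  })
  list(global = list(common = intersect(ga, gb), only_a = setdiff(ga, gb),
                     only_b = setdiff(gb, ga)),
       per_location = per_loc)
}

# terms carrying a non-zero refit weight in at least one location: the
# global set reported is consistent with the per-location supports
essential_ids <- function(model) {
  nz <- which(rowSums(model$weights != 0) > 0)
  if (is.null(model$essential$terms)) {
    as.character(model$essential$indices[nz])
  } else {
    model$essential$terms[nz]
  }
}

location_support <- function(model, m) {
  nz <- which(model$weights[, m] != 0)
  if (is.null(model$essential$terms)) {
    as.character(model$essential$indices[nz])
  } else {
    model$essential$terms[nz]
  }
}
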