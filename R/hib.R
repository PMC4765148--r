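# Hierarchical-information-based (HIB) mapping of non-essential GO terms
# onto essential GO terms through the GO DAG. A query protein annotated
# only with non-essential terms would otherwise project to an all-zero
# feature vector; HIB converts its term counts into "effective" counts of
# the essential terms, weighted by a decaying function of DAG distance.

#' Parameters of the hierarchical GO-DAG mapping
#'
#' The contribution of an annotated term G (count \eqn{f_G}) to the
#' effective count of an essential term E is \eqn{f_G \cdot w(d)}, where d
#' is the depth distance between G and E in the DAG and w a non-increasing
#' decay with \eqn{w(0) = 1}. Contributions beyond `max_distance` are zero.
#'
#' @param max_distance maximal DAG distance D considered (default 5).
#' @param decay decay family: `"power2"` is \eqn{w(d) = 2^{-d}} (default),
#'   `"inverse"` is \eqn{w(d) = 1/(1+d)}, or pass a function of d.
#' @param edge_types DAG edge types traversed.
#' @param nearest_only if `TRUE`, each annotated term contributes only to
#'   its nearest essential term(s) instead of all within reach.
#' @param strict error (instead of warn) on terms absent from the DAG.
#' @return class `"hib_params"`.
#' @export
hib_params <- function(max_distance = 5L, decay = c("power2", "inverse"),
                       edge_types = c("is_a", "part_of"),
                       nearest_only = FALSE, strict = FALSE) {
  if (max_distance < 0) stop("max_distance must be >= 0")
  wfun <- if (is.function(decay)) {
    decay
  } else {
    switch(match.arg(decay),
           power2 = function(d) 2^(-d),
           inverse = function(d) 1 / (1 + d))
  }
  if (abs(wfun(0) - 1) > 1e-12) stop("decay must satisfy w(0) = 1")
  if (wfun(1) > wfun(0) + 1e-12 || wfun(3) > wfun(1) + 1e-12) {
    stop("decay must be non-increasing in distance")
  }
  structure(list(max_distance = max_distance, decay = wfun,
                 edge_types = edge_types, nearest_only = nearest_only,
                 strict = strict),
            class = "hib_params")
}

#' Map a GO multiset onto essential terms through the DAG
#'
#' Computes, for every essential term E, the effective number of
#' occurrences \eqn{\sum_G f_G \, w(d(G, E))} over the annotated terms G
#' within `max_distance` of E (same taxonomy only). The resulting vector is
#' non-null as long as at least one annotated term is close enough to some
#' essential term; if none is, a zero vector is returned and a warning of
#' class `"sparseloc_null_feature_vector"` is signalled. With
#' `max_distance = 0` the mapping reduces to the plain projection of the
#' term-frequency vector onto the essential terms.
#'
#' @param multiset named integer vector of GO term counts for one protein.
#' @param essential character vector of essential GO term ids (or an
#'   `"essential_terms"` object).
#' @param dag a `"go_dag"`.
#' @param params a [hib_params()] object.
#' @return numeric vector of effective counts named by the essential terms.
#' @export
map_to_essential <- function(multiset, essential, dag,
                             params = hib_params()) {
  if (inherits(essential, "essential_terms")) essential <- essential$terms
  if (length(essential) == 0L) stop("essential term set is empty")
  out <- numeric(length(essential))
  names(out) <- essential
  ess_idx <- match(essential, dag$ids)
  missing_ess <- is.na(ess_idx)
  if (any(missing_ess)) {
    msg <- sprintf("%d essential term(s) absent from the DAG", sum(missing_ess))
    if (params$strict) stop(msg) else warning(msg)
  }
  for (g in names(multiset)) {
    gi <- dag$index[[g]]
    if (is.null(gi)) {
      msg <- sprintf("query term %s absent from the DAG, skipped", g)
      if (params$strict) stop(msg) else warning(msg)
      next
    }
    dist <- bfs_distances(dag, gi, max_distance = params$max_distance,
                          edge_types = params$edge_types)
    de <- dist[ess_idx]
    de[missing_ess] <- Inf
    reach <- which(is.finite(de) & de <= params$max_distance)
    if (length(reach) == 0L) next
    if (params$nearest_only) reach <- reach[de[reach] == min(de[reach])]
    out[reach] <- out[reach] + multiset[[g]] * params$decay(de[reach])
  }
  if (all(out == 0)) {
    warning(structure(
      class = c("sparseloc_null_feature_vector", "warning", "condition"),
      list(message = "no annotated GO term is within reach of any essential term",
           call = NULL)))
  }
  out
}
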