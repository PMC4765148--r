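# Replicated simulation studies on planted data.

#' Support-recovery study on planted synthetic data
#'
#' Repeatedly generates a planted multi-label dataset, runs the mLASSO
#' selection stage (per-class cross-validated lambda), and measures how
#' often each class's selected support contains the planted support.
#' Alongside, an mEN selection is run at the same per-class lambdas with a
#' small ridge penalty, and the study records how often the mEN essential
#' set contains the mLASSO essential set -- the nesting tendency expected
#' from the elastic net's grouping behavior.
#'
#' @param n_seeds number of replicates.
#' @param n,t,m,k,sigma planted-data settings, see
#'   [make_planted_dataset()].
#' @param en_gamma ridge penalty of the mEN run (default 0.01).
#' @param seed base seed; replicate r uses data seed `seed + r`.
#' @param nfolds,nlambda,lambda_min_ratio CV controls for the per-class
#'   penalty search.
#' @return list with `per_class_rate` (fraction of (replicate, class)
#'   pairs whose mLASSO support contains the planted support),
#'   `en_containment_rate` (fraction of replicates with mLASSO essential
#'   set nested in the mEN essential set), and a per-replicate `detail`
#'   data.frame.
#' @export
support_recovery_study <- function(n_seeds = 20L, n = 500L, t = 200L,
                                   m = 4L, k = 10L, sigma = 0.5,
                                   en_gamma = 0.01, seed = 1L,
                                   nfolds = 5L, nlambda = 20L,
                                   lambda_min_ratio = 0.01) {
  contained <- 0L
  total <- 0L
  nested <- 0L
  detail <- vector("list", n_seeds)
  for (r in seq_len(n_seeds)) {
    sim <- make_planted_dataset(n = n, t = t, m = m, k = k, sigma = sigma,
                                seed = seed + r)
    set.seed(seed * 1000L + r)   # fixes the CV folds for this replicate
    sel <- fit_feature_selection(sim$x, sim$labels, mode = "mlasso",
                                 nfolds = nfolds, nlambda = nlambda,
                                 lambda_min_ratio = lambda_min_ratio)
    ok <- logical(m)
    for (cl in seq_len(m)) {
      ok[cl] <- all(sim$truth$support[[cl]] %in% sel$fits[[cl]]$active)
    }
    contained <- contained + sum(ok)
    total <- total + m
    sel_en <- fit_feature_selection(sim$x, sim$labels, mode = "men",
                                    lambda = sel$lambda, gamma = en_gamma)
    ess_l <- select_essential_terms(sel)$indices
    ess_e <- select_essential_terms(sel_en)$indices
    is_nested <- all(ess_l %in% ess_e)
    nested <- nested + is_nested
    detail[[r]] <- data.frame(replicate = r, classes_contained = sum(ok),
                              S_lasso = length(ess_l),
                              S_en = length(ess_e), nested = is_nested)
  }
  list(per_class_rate = contained / total,
       en_containment_rate = nested / n_seeds,
       detail = do.call(rbind, detail))
}
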