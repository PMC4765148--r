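# One-vs-rest training, essential-term selection, scoring and decisions.

test_that("label transformation is the +/-1 one-vs-rest encoding", {
  expect_identical(transform_labels(list(1L), 3)[1, ], c(1, -1, -1))
  expect_identical(transform_labels(list(1:3), 3)[1, ], c(1, 1, 1))
  y <- transform_labels(list(c(1L, 3L), 2L), 3)
  expect_identical(dim(y), c(2L, 3L))
  expect_true(all(y %in% c(-1, 1)))
  expect_error(transform_labels(list(integer(0)), 3), "empty")
  expect_error(transform_labels(list(4L), 3), "outside")
  # column sums of (y+1)/2 are the per-location locative counts
  set.seed(41)
  comp <- make_benchmark_like_composition(scale = 0.02, seed = 41)
  y <- transform_labels(comp$labels, comp$M)
  counts <- colSums((y + 1) / 2)
  hand <- vapply(seq_len(comp$M), function(m) {
    sum(vapply(comp$labels, function(s) m %in% s, TRUE))
  }, 0)
  expect_identical(unname(counts), hand)
  expect_identical(sum(counts), as.numeric(comp$n_locative))
})

test_that("selection reduces to single fits and unions supports", {
  set.seed(42)
  x <- random_count_matrix(30, 12)
  labels <- random_label_sets(30, 1)
  # M = 1 is exactly one lasso call
  sel <- fit_feature_selection(x, labels, mode = "mlasso", lambda = 8)
  y <- transform_labels(labels, 1)
  single <- fit_lasso(x, y[, 1], 8)
  expect_identical(sel$fits[[1]]$beta, single$beta)
  # huge penalties empty every support
  labels3 <- random_label_sets(30, 3)
  sel0 <- fit_feature_selection(x, labels3, mode = "mlasso", lambda = 1e6)
  ess0 <- select_essential_terms(sel0)
  expect_identical(ess0$S, 0L)
  expect_identical(ess0$indices, integer(0))
  # union by hand
  fake <- list(list(active = 2L), list(active = c(2L, 5L)))
  ess <- select_essential_terms(fake, colnames(x))
  expect_identical(ess$indices, c(2L, 5L))
  expect_identical(ess$terms, colnames(x)[c(2, 5)])
})

test_that("projection gathers essential columns; empty set errors", {
  set.seed(43)
  x <- random_count_matrix(10, 8)
  ess <- structure(list(indices = c(2L, 7L), S = 2L),
                   class = "essential_terms")
  expect_identical(project_features(x, ess), x[, c(2, 7)])
  full <- structure(list(indices = 1:8, S = 8L), class = "essential_terms")
  expect_identical(project_features(x, full), x)
  idx <- sort(sample.int(8, 3))
  expect_identical(project_features(x, idx), x[, idx])
  empty <- structure(list(indices = integer(0), S = 0L),
                     class = "essential_terms")
  expect_error(project_features(x, empty), "HIB")
  expect_error(project_features(x, c(1L, 9L)), "out of range")
})

test_that("refit with no penalty and S < N recovers per-class OLS", {
  set.seed(44)
  x <- random_count_matrix(40, 5)
  labels <- random_label_sets(40, 2)
  y <- transform_labels(labels, 2)
  re <- refit_selected(x, y, lambda = 0, mode = "mlasso")
  for (m in 1:2) {
    ls <- stats::lm.fit(cbind(1, x), y[, m])$coefficients
    expect_equal(unname(re$fits[[m]]$beta), unname(ls[-1]),
                 tolerance = 1e-7)
    expect_equal(re$fits[[m]]$intercept, unname(ls[1]), tolerance = 1e-7)
  }
})

test_that("scores are affine in the features and decompose per term", {
  set.seed(45)
  sim <- make_planted_dataset(n = 60, t = 20, m = 3, k = 4, seed = 45)
  fit <- sparseloc(sim$x, sim$labels, mode = "mlasso", lambda = 30)
  S <- fit$essential$S
  expect_gt(S, 0)
  # zero vector scores to the intercepts
  expect_equal(drop(localization_scores(fit, numeric(S))),
               unname(fit$intercepts))
  # brute-force dot product on random vectors
  for (rep in 1:5) {
    v <- rpois(S, 2)
    sc <- drop(localization_scores(fit, v))
    brute <- vapply(1:3, function(m) {
      fit$intercepts[m] + sum(fit$weights[, m] * v)
    }, 0)
    expect_equal(sc, unname(brute), tolerance = 1e-12)
  }
  expect_error(localization_scores(fit, numeric(S + 1)), "expects S")
})

test_that("decision scheme: positive set, else lowest-index argmax", {
  expect_identical(decide_labels(c(-3, -1, -2)), 2L)
  expect_identical(decide_labels(c(0.5, -0.2, 0.1)), c(1L, 3L))
  expect_identical(decide_labels(c(-1, -1, -5)), 1L)  # tie -> lowest index
  expect_identical(decide_labels(c(0, 0, 0)), 1L)     # 0 is not positive
  expect_error(decide_labels(c(NaN, 1)), "NaN")
  # exhaustive sign patterns for M <= 5: never empty, singleton when all <= 0
  set.seed(46)
  for (M in 1:5) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), M)))
    for (r in seq_len(nrow(signs))) {
      sc <- signs[r, ] * runif(M, 0.1, 2)
      d <- decide_labels(sc)
      expect_gt(length(d), 0)
      if (all(sc <= 0)) {
        expect_length(d, 1L)
        expect_identical(d, which.max(sc))
      } else {
        expect_identical(sort(d), which(sc > 0))
      }
    }
  }
})

test_that("predict composes projection, scoring and decision", {
  sim <- make_planted_dataset(n = 60, t = 20, m = 3, k = 4, seed = 47)
  fit <- sparseloc(sim$x, sim$labels, mode = "mlasso", lambda = 30)
  idx <- which(rowSums(project_features(sim$x, fit$essential)) > 0)[1:5]
  pr <- predict(fit, sim$x[idx, , drop = FALSE])
  xs <- project_features(sim$x[idx, , drop = FALSE], fit$essential)
  manual_scores <- localization_scores(fit, xs)
  expect_equal(pr$scores, manual_scores)
  expect_identical(pr$labels, decide_labels(manual_scores))
  expect_true(all(pr$path == "plain"))
  expect_true(all(lengths(pr$labels) >= 1))
  # a multiset input routes through the same scores
  ms <- stats::setNames(as.integer(sim$x[idx[1], sim$x[idx[1], ] > 0]),
                        colnames(sim$x)[sim$x[idx[1], ] > 0])
  pr1 <- predict(fit, ms)
  expect_equal(drop(pr1$scores), drop(pr$scores[1, ]))
})

test_that("queries without essential terms fall back to HIB or error", {
  # essential terms chosen from a chain DAG; query annotated elsewhere
  chain <- c("[Term]", "id: GO:0000001", "namespace: cellular_component",
             "", "[Term]", "id: GO:0000002",
             "namespace: cellular_component", "is_a: GO:0000001",
             "", "[Term]", "id: GO:0000003",
             "namespace: cellular_component", "is_a: GO:0000002")
  dag <- read_obo(chain)
  set.seed(48)
  # build a small model whose essential set we control via the vocabulary
  x <- cbind(`GO:0000001` = rpois(30, 2) + 1L, `GO:0000002` = rpois(30, 1))
  labels <- lapply(seq_len(30), function(i) if (x[i, 1] > 2) 1L else 2L)
  fit <- sparseloc(x, labels, mode = "mlasso", lambda = 1)
  expect_true("GO:0000001" %in% fit$essential$terms)
  query <- c("GO:0000003" = 4L)  # no essential terms, 2 hops away
  expect_error(predict(fit, query), class = "sparseloc_null_feature_vector")
  pr <- predict(fit, query, dag = dag)
  expect_identical(pr$path, "hib")
  expect_true(all(abs(pr$xs) > 0))
})

test_that("class order permutation permutes components consistently", {
  sim <- make_planted_dataset(n = 50, t = 15, m = 3, k = 3, seed = 49)
  perm <- c(3L, 1L, 2L)
  labels_p <- lapply(sim$labels, function(s) sort(match(s, perm)))
  lam <- c(20, 30, 25)
  set.seed(7)
  fit <- sparseloc(sim$x, sim$labels, mode = "mlasso", M = 3, lambda = lam)
  set.seed(7)
  fit_p <- sparseloc(sim$x, labels_p, mode = "mlasso", M = 3,
                     lambda = lam[order(match(seq_len(3), perm))])
  # location m of the original equals location match(m, perm) of permuted
  for (m in 1:3) {
    expect_identical(fit$essential$per_class[[m]],
                     fit_p$essential$per_class[[match(m, perm)]])
  }
  expect_identical(fit$essential$indices, fit_p$essential$indices)
  pr <- predict(fit, sim$x[1:4, , drop = FALSE])
  pr_p <- predict(fit_p, sim$x[1:4, , drop = FALSE])
  expect_equal(pr$scores, pr_p$scores[, match(seq_len(3), perm)],
               ignore_attr = TRUE)
})

test_that("identical inputs and seeds give identical models end to end", {
  sim <- make_planted_dataset(n = 50, t = 20, m = 2, k = 3, seed = 50)
  set.seed(123)
  f1 <- sparseloc(sim$x, sim$labels, mode = "men", nlambda = 8,
                  lambda_min_ratio = 0.05, gamma = c(0.1, 1))
  set.seed(123)
  f2 <- sparseloc(sim$x, sim$labels, mode = "men", nlambda = 8,
                  lambda_min_ratio = 0.05, gamma = c(0.1, 1))
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$penalties, f2$penalties)
  ok <- which(rowSums(project_features(sim$x, f1$essential)) > 0)
  expect_identical(predict(f1, sim$x[ok, , drop = FALSE])$labels,
                   predict(f2, sim$x[ok, , drop = FALSE])$labels)
})

test_that("models serialize to JSON and predict identically after reload", {
  sim <- make_planted_dataset(n = 40, t = 12, m = 2, k = 3, seed = 51)
  fit <- sparseloc(sim$x, sim$labels, mode = "mlasso", lambda = 20)
  path <- tempfile(fileext = ".json")
  write_sparseloc(fit, path)
  back <- read_sparseloc(path)
  expect_identical(back$mode, fit$mode)
  expect_identical(back$essential$terms, fit$essential$terms)
  expect_equal(back$weights, fit$weights, ignore_attr = TRUE)
  expect_equal(back$intercepts, unname(fit$intercepts))
  ok <- which(rowSums(project_features(sim$x, fit$essential)) > 0)
  pr_a <- predict(fit, sim$x[ok, , drop = FALSE])
  pr_b <- predict(back, sim$x[ok, , drop = FALSE])
  expect_equal(pr_a$scores, pr_b$scores, ignore_attr = TRUE)
  expect_identical(pr_a$labels, pr_b$labels)
  other <- tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), other)
  expect_error(read_sparseloc(other), "not a sparseloc model")
})
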