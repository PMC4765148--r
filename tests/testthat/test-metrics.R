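# Multi-label metrics vs direct set arithmetic, plus the LOOCV harness.

test_that("worked single-pair examples match the definitions", {
  t1 <- list(c(1L, 2L)); p1 <- list(1L)
  expect_identical(overall_actual_accuracy(t1, p1), 0)
  expect_identical(overall_locative_accuracy(t1, p1), 0.5)
  expect_identical(multilabel_accuracy(t1, p1), 0.5)
  expect_identical(multilabel_precision(t1, p1), 1)
  expect_identical(multilabel_recall(t1, p1), 0.5)
  expect_equal(multilabel_f1(t1, p1), 2 / 3)
  expect_equal(hamming_loss(list(1L), list(2L), M = 3), 2 / 3)
  ident <- random_label_sets(5, 4)
  expect_identical(overall_actual_accuracy(ident, ident), 1)
  expect_identical(overall_locative_accuracy(ident, ident), 1)
  expect_identical(multilabel_f1(ident, ident), 1)
  expect_identical(hamming_loss(ident, ident, 4), 0)
  expect_identical(micro_f1(ident, ident, 4), 1)
  expect_error(overall_actual_accuracy(list(), list()), "no label-set")
  expect_error(hamming_loss(list(1L), list(5L), M = 3), "exceeds M")
})

test_that("all nine metrics match brute-force oracles on random pairs", {
  set.seed(21)
  M <- 6L
  for (rep in 1:5) {
    n <- 40L
    truth <- random_label_sets(n, M)
    pred <- random_label_sets(n, M)
    inter <- mapply(function(a, b) length(intersect(a, b)), truth, pred)
    uni <- mapply(function(a, b) length(union(a, b)), truth, pred)
    expect_equal(overall_actual_accuracy(truth, pred),
                 sum(mapply(function(a, b) identical(sort(a), sort(b)),
                            truth, pred)) / n)
    expect_equal(overall_locative_accuracy(truth, pred),
                 sum(inter) / sum(lengths(truth)))
    expect_equal(multilabel_accuracy(truth, pred), mean(inter / uni))
    expect_equal(multilabel_precision(truth, pred),
                 mean(inter / lengths(pred)))
    expect_equal(multilabel_recall(truth, pred),
                 mean(inter / lengths(truth)))
    expect_equal(multilabel_f1(truth, pred),
                 mean(2 * inter / (lengths(truth) + lengths(pred))))
    # dense 0/1 matrix mismatch rate for Hamming loss
    tm <- t(vapply(truth, function(s) as.integer(seq_len(M) %in% s),
                   integer(M)))
    pm <- t(vapply(pred, function(s) as.integer(seq_len(M) %in% s),
                   integer(M)))
    expect_equal(hamming_loss(truth, pred, M), mean(tm != pm))
    # per-class confusion tallies for micro/macro F1
    tp <- colSums(tm == 1 & pm == 1)
    fp <- colSums(tm == 0 & pm == 1)
    fn <- colSums(tm == 1 & pm == 0)
    expect_equal(micro_f1(truth, pred, M),
                 2 * sum(tp) / (2 * sum(tp) + sum(fp) + sum(fn)))
    f1c <- ifelse(2 * tp + fp + fn == 0, 0, 2 * tp / (2 * tp + fp + fn))
    expect_equal(macro_f1(truth, pred, M), mean(f1c))
  }
})

test_that("metric ordering chain holds on randomized pair sets", {
  set.seed(22)
  for (rep in 1:20) {
    M <- sample(3:8, 1)
    truth <- random_label_sets(15, M)
    pred <- random_label_sets(15, M)
    oaa <- overall_actual_accuracy(truth, pred)
    acc <- multilabel_accuracy(truth, pred)
    f1 <- multilabel_f1(truth, pred)
    ola <- overall_locative_accuracy(truth, pred)
    expect_lte(oaa, acc + 1e-12)
    expect_lte(acc, f1 + 1e-12)
    expect_lte(f1, 1)
    expect_lte(oaa, ola + 1e-12)
    # instance-wise: precision and recall dominate the Jaccard accuracy
    expect_lte(acc, multilabel_precision(truth, pred) + 1e-12)
    expect_lte(acc, multilabel_recall(truth, pred) + 1e-12)
  }
})

test_that("macro F1 dilutes absent classes while micro F1 ignores them", {
  truth <- list(1L, 1L, 1L)
  pred <- list(1L, 1L, 1L)
  expect_identical(micro_f1(truth, pred, M = 4), 1)
  expect_equal(macro_f1(truth, pred, M = 4), 0.25)
  expect_identical(macro_f1(truth, pred, M = 4,
                            include_empty_classes = FALSE), 1)
})

test_that("hamming loss of complement singleton predictions is 2/M", {
  M <- 5L
  truth <- list(1L, 2L, 3L)
  wrong <- list(2L, 3L, 4L)
  expect_equal(hamming_loss(truth, wrong, M), 2 / M)
})

test_that("locative counting follows the k-per-protein rule", {
  expect_identical(locative_count(c(2580, 480, 43, 3)), 3681)
  expect_identical(locative_count(c(0, 0, 43)), 129)
  expect_identical(locative_count(c(7)), 7)
  expect_error(locative_count(c(3, -1)), "negative")
})

test_that("per-location accuracies count locative hits per location", {
  truth <- list(c(1L, 2L), 2L, 3L)
  pred <- list(1L, 2L, 1L)
  pl <- per_location_accuracy(truth, pred, M = 3)
  expect_identical(pl$total, c(1L, 2L, 1L))
  expect_identical(pl$correct, c(1L, 1L, 0L))
  expect_equal(pl$accuracy, c(1, 0.5, 0))
})

test_that("evaluation report is internally consistent", {
  set.seed(23)
  truth <- random_label_sets(30, 5)
  pred <- random_label_sets(30, 5)
  ev <- evaluate_predictions(truth, pred, 5)
  expect_identical(ev$n_actual, 30L)
  expect_identical(ev$n_locative, sum(lengths(truth)))
  expect_identical(ev$oaa, overall_actual_accuracy(truth, pred))
  expect_identical(ev$hamming_loss, hamming_loss(truth, pred, 5))
  expect_output(print(ev), "OAA")
})

test_that("LOOCV equals a manual fold loop on a synthetic set", {
  sim <- make_planted_dataset(n = 40, t = 15, m = 3, k = 3, sigma = 0.3,
                              seed = 31)
  lam <- 25
  rep1 <- loocv(sim$x, sim$labels, M = 3, mode = "mlasso", lambda = lam,
                on_null = "intercept")
  manual <- vector("list", 40)
  for (i in 1:40) {
    fit_i <- sparseloc(sim$x[-i, , drop = FALSE], sim$labels[-i],
                       mode = "mlasso", M = 3, lambda = lam)
    manual[[i]] <- tryCatch(
      predict(fit_i, sim$x[i, , drop = FALSE])$labels[[1]],
      sparseloc_null_feature_vector = function(e) {
        decide_labels(fit_i$intercepts)
      })
  }
  expect_identical(rep1$predictions, manual)
  want <- evaluate_predictions(sim$labels, manual, 3)
  expect_identical(rep1$oaa, want$oaa)
  expect_identical(rep1$ola, want$ola)
  expect_identical(rep1$hamming_loss, want$hamming_loss)
})

test_that("LOOCV hooks prove the held-out protein never enters training", {
  sim <- make_planted_dataset(n = 12, t = 8, m = 2, k = 2, seed = 32)
  seen <- list()
  loocv(sim$x, sim$labels, M = 2, mode = "mlasso", lambda = 10,
        on_null = "intercept",
        fold_hook = function(i, train_idx) {
          seen[[length(seen) + 1L]] <<- list(i = i, train = train_idx)
        })
  expect_length(seen, 12L)
  for (s in seen) expect_false(s$i %in% s$train)
  expect_identical(vapply(seen, `[[`, 0L, "i"), 1:12)
})

test_that("degenerate trainers produce the expected extremes", {
  # the model sees perfectly separable labels driven by one high-signal
  # column per class -> LOOCV must recover them essentially exactly
  set.seed(33)
  n <- 30
  x <- cbind(matrix(rpois(n * 2, 3), n, 2), matrix(rpois(n * 4, 1), n, 4))
  colnames(x) <- sprintf("GO:%07d", 1:6)
  labels <- lapply(seq_len(n), function(i) {
    if (x[i, 1] >= x[i, 2]) 1L else 2L
  })
  # a trivial fixed-wrong-prediction run: OAA is 0 by construction
  truth <- random_label_sets(10, 4)
  fixed_wrong <- lapply(truth, function(s) setdiff(1:4, s)[1])
  expect_identical(overall_actual_accuracy(truth, fixed_wrong), 0)
  # perfect predictor: all metrics 1 / HL 0
  ev <- evaluate_predictions(truth, truth, 4)
  expect_identical(ev$oaa, 1)
  expect_identical(ev$f1, 1)
  expect_identical(ev$hamming_loss, 0)
})
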