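test_that("precision, recall and F1 follow the stated formulas", {
  # binary counts TP=3, FP=1, TN=4, FN=2
  truth <- c(rep("pos", 5), rep("neg", 5))
  pred <- c("pos", "pos", "pos", "neg", "neg",
            "pos", "neg", "neg", "neg", "neg")
  cc <- confusion_counts(truth, pred)
  pos_row <- dplyr::filter(cc$per_class, class == "pos")
  expect_equal(unlist(pos_row[, c("TP", "FP", "FN", "TN")]),
               c(TP = 3L, FP = 1L, FN = 2L, TN = 4L))
  m <- compute_metrics(cc)
  per <- attr(m, "per_class")
  pos <- dplyr::filter(per, class == "pos")
  expect_equal(pos$precision, 0.75)
  expect_equal(pos$recall, 0.6)
  expect_equal(pos$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6), tolerance = 1e-6)

  perfect <- compute_metrics(confusion_counts(truth, truth))
  expect_equal(unlist(perfect[, 1:4]), c(accuracy = 1, precision = 1,
                                         recall = 1, f1 = 1))
})

test_that("macro and weighted averaging coincide only on balanced classes", {
  truth <- rep(c("a", "b", "c"), each = 10)
  set.seed(3)
  pred <- sample(c("a", "b", "c"), 30, replace = TRUE)
  cc <- confusion_counts(truth, pred)
  expect_equal(compute_metrics(cc, "macro")[, 1:4],
               compute_metrics(cc, "weighted")[, 1:4])
  # a never-predicted class yields 0 precision with a warning, not NaN
  truth2 <- c("a", "a", "b")
  pred2 <- c("a", "a", "a")
  expect_warning(m2 <- compute_metrics(confusion_counts(truth2, pred2)),
                 "undefined")
  expect_false(any(is.nan(unlist(m2[, 1:4]))))
})

test_that("metrics agree with a per-instance loop oracle on random tables", {
  set.seed(11)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    n <- sample(10:40, 1)
    classes <- letters[1:k]
    truth <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    # ensure all classes appear in truth so no undefined recall warnings
    truth[seq_len(k)] <- classes
    got <- suppressWarnings(
      compute_metrics(confusion_counts(truth, pred, levels = classes)))
    want <- oracle_metrics(truth, pred)
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
    expect_equal(got$f1, want$f1)
  }
})

test_that("one-vs-rest AUROC uses midranks and is monotone-invariant", {
  # perfectly separated scores
  labels <- rep(c("x", "y"), each = 20)
  scores <- cbind(x = c(stats::runif(20, 0.6, 1), stats::runif(20, 0, 0.4)))
  scores <- cbind(scores, y = 1 - scores[, "x"])
  expect_equal(auroc_ovr(scores, labels)$macro, 1.0)
  expect_error(auroc_ovr(scores, rep("x", 40)), "two classes")

  # label-independent scores sit near 0.5 at n = 1000
  set.seed(19)
  n <- 1000
  lab <- sample(c("x", "y"), n, replace = TRUE)
  sc <- stats::runif(n)
  big <- auroc_ovr(cbind(x = sc, y = stats::runif(n)), lab)
  expect_equal(big$per_class[["x"]], 0.5, tolerance = 0.05)

  # midrank tie handling agrees with exhaustive pairwise comparison
  set.seed(23)
  for (i in 1:30) {
    m <- sample(10:50, 1)
    lab2 <- sample(c("x", "y"), m, replace = TRUE)
    lab2[1:2] <- c("x", "y")
    sc2 <- sample(seq(0, 1, 0.1), m, replace = TRUE)  # heavy ties
    got <- auroc_ovr(cbind(x = sc2, y = -sc2), lab2)$per_class[["x"]]
    expect_equal(got, oracle_auc(sc2, lab2 == "x"))
    # strictly monotone transform leaves the AUC unchanged
    expect_equal(auroc_ovr(cbind(x = exp(3 * sc2), y = -sc2),
                           lab2)$per_class[["x"]], got)
  }
})

test_that("stratified folds are balanced, disjoint, covering, seeded", {
  labels <- rep(c("neg", "eq", "pos"), times = c(81, 198, 264))  # n = 543
  folds <- crossval_splits(labels, k = 5, seed = 2)
  sizes <- lengths(folds)
  expect_true(all(abs(sizes - 543 / 5) <= 1))
  all_idx <- sort(unlist(folds))
  expect_identical(all_idx, seq_along(labels))  # disjoint cover
  # per-class stratification within one of each fold
  for (f in folds) {
    tab <- table(factor(labels[f], levels = c("neg", "eq", "pos")))
    expect_true(all(abs(tab - c(81, 198, 264) / 5) <= 1))
  }
  expect_identical(crossval_splits(labels, k = 5, seed = 2), folds)
  expect_false(identical(crossval_splits(labels, k = 5, seed = 3), folds))
  expect_error(crossval_splits(c("a", "a", "b"), k = 2), "at least k")
})

test_that("cross-validated training reports per-fold and mean metrics", {
  rois <- make_roi_set(c(NEGATIVE = 9, EQUIVOCAL = 9, POSITIVE = 9),
                       jitter_sd = 0, seed = 5)
  cv <- crossval_classifier(rois, k = 3, train_config(seed = 4, epochs = 10))
  expect_equal(nrow(cv$per_fold), 3)
  expect_equal(cv$mean$accuracy, mean(cv$per_fold$accuracy))
  expect_true(all(cv$per_fold$accuracy >= 0 & cv$per_fold$accuracy <= 1))
})
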