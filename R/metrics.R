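#' Confusion counts from labels
#'
#' Cross-tabulates true and predicted labels (rows = true, columns =
#' predicted) and derives per-class TP/FP/TN/FN in one-vs-rest form.
#'
#' @param truth,predicted vectors of class labels.
#' @param levels class levels; defaults to the union of observed labels.
#' @return a list of class `bus_confusion` with `table` (K x K matrix) and
#'   `per_class` (tibble of TP/FP/TN/FN).
#' @export
confusion_counts <- function(truth, predicted, levels = NULL) {
  levels <- levels %||% sort(unique(c(truth, predicted)))
  t_f <- factor(truth, levels = levels)
  p_f <- factor(predicted, levels = levels)
  tab <- table(true = t_f, predicted = p_f)
  n <- sum(tab)
  per <- purrr::map_dfr(levels, function(cl) {
    tp <- tab[cl, cl]
    fp <- sum(tab[, cl]) - tp
    fn <- sum(tab[cl, ]) - tp
    tibble::tibble(class = cl, TP = as.integer(tp), FP = as.integer(fp),
                   FN = as.integer(fn), TN = as.integer(n - tp - fp - fn))
  })
  structure(list(table = unclass(tab), per_class = per, n = n),
            class = "bus_confusion")
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' `F1 = 2 * precision * recall / (precision + recall)`, aggregated by
#' macro (unweighted mean over classes, the default) or support-weighted
#' averaging; accuracy is the overall fraction of correct predictions.
#' A class with an undefined ratio (zero denominator) contributes 0 with a
#' warning rather than NaN.
#'
#' @param counts a `bus_confusion` (or a K x K table, rows = true).
#' @param averaging `"macro"` or `"weighted"`.
#' @return a one-row tibble: `accuracy`, `precision`, `recall`, `f1`,
#'   `averaging`; the per-class table is attached as attribute
#'   `"per_class"`.
#' @export
compute_metrics <- function(counts, averaging = c("macro", "weighted")) {
  averaging <- match.arg(averaging)
  if (!inherits(counts, "bus_confusion")) {
    tab <- as.matrix(counts)
    levels <- rownames(tab) %||% as.character(seq_len(nrow(tab)))
    counts <- list(table = tab, n = sum(tab))
    counts$per_class <- purrr::map_dfr(seq_along(levels), function(i) {
      tp <- tab[i, i]
      tibble::tibble(class = levels[i], TP = tp, FP = sum(tab[, i]) - tp,
                     FN = sum(tab[i, ]) - tp,
                     TN = sum(tab) - sum(tab[, i]) - sum(tab[i, ]) + tp)
    })
  }
  stopifnot(counts$n >= 1)
  safe_ratio <- function(num, den, what, class) {
    ifelse(den == 0, {
      if (any(den == 0)) {
        warning("undefined ", what, " for class ",
                paste(class[den == 0], collapse = ", "),
                " (zero denominator); reporting 0", call. = FALSE)
      }
      0
    }, num / den)
  }
  per <- counts$per_class |>
    dplyr::mutate(
      support = .data$TP + .data$FN,
      precision = safe_ratio(.data$TP, .data$TP + .data$FP, "precision",
                             .data$class),
      recall = safe_ratio(.data$TP, .data$TP + .data$FN, "recall",
                          .data$class),
      f1 = ifelse(.data$precision + .data$recall == 0, 0,
                  2 * .data$precision * .data$recall /
                    (.data$precision + .data$recall))
    )
  w <- if (averaging == "macro") rep(1, nrow(per)) else per$support
  agg <- function(v) sum(v * w) / sum(w)
  out <- tibble::tibble(
    accuracy = sum(diag(as.matrix(counts$table))) / counts$n,
    precision = agg(per$precision),
    recall = agg(per$recall),
    f1 = agg(per$f1),
    averaging = averaging
  )
  attr(out, "per_class") <- per
  out
}

# midrank (Wilcoxon) AUC for one binary split
auc_binary <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  r <- rank(scores)  # midranks on ties
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest macro AUROC
#'
#' Per-class AUC by the midrank (Wilcoxon) statistic of that class's score
#' column against the rest, macro-averaged over the classes present in the
#' labels. Invariant under strictly monotone transformations of the
#' scores.
#'
#' @param scores numeric matrix, one column per class (named), one row per
#'   instance; or a data frame.
#' @param labels true class labels.
#' @return a list with `per_class` (named AUC vector) and `macro`.
#' @export
auroc_ovr <- function(scores, labels) {
  scores <- as.matrix(scores)
  present <- intersect(colnames(scores), unique(labels))
  if (length(unique(labels)) < 2) {
    stop("AUROC needs at least two classes in the labels", call. = FALSE)
  }
  per <- vapply(present, function(cl) {
    auc_binary(scores[, cl], labels == cl)
  }, numeric(1))
  list(per_class = per, macro = mean(per))
}

#' Stratified cross-validation folds
#'
#' Deals each class's shuffled indices round-robin into k folds with a
#' fold pointer persisting across classes, so folds are stratified *and*
#' globally balanced: per-class and total fold sizes each differ by at
#' most one.
#'
#' @param labels class label vector (folds stratify on it).
#' @param k number of folds (>= 2); every class must have at least k
#'   members.
#' @param seed integer seed; identical seeds give identical folds.
#' @return a list of k integer index vectors (disjoint, covering
#'   `seq_along(labels)`).
#' @export
crossval_splits <- function(labels, k = 5L, seed = 1L) {
  stopifnot(k >= 2)
  tab <- table(labels)
  if (any(tab < k)) {
    stop("every class needs at least k = ", k, " members; smallest has ",
         min(tab), call. = FALSE)
  }
  with_seed_(seed, {
    folds <- vector("list", k)
    ptr <- 0L
    for (cl in sample(names(tab))) {
      idx <- sample(which(labels == cl))
      for (i in idx) {
        folds[[ptr %% k + 1L]] <- c(folds[[ptr %% k + 1L]], i)
        ptr <- ptr + 1L
      }
    }
    folds
  })
}

#' Cross-validated evaluation of a stiffness classifier backend
#'
#' Trains on k-1 folds and evaluates on the held-out fold, k times;
#' reports per-fold metrics and their mean.
#'
#' @param dataset tibble with `roi` list-column and `class` column.
#' @param k folds.
#' @param cfg a [train_config()].
#' @param averaging passed to [compute_metrics()].
#' @return a list with `per_fold` (tibble) and `mean` (one-row tibble).
#' @export
crossval_classifier <- function(dataset, k = 5L, cfg = train_config(),
                                averaging = "macro") {
  folds <- crossval_splits(dataset$class, k = k, seed = cfg$seed)
  per <- purrr::imap_dfr(folds, function(test_idx, i) {
    model <- train_classifier(dataset[-test_idx, ], cfg)
    pred <- classify_stiffness_all(dataset$roi[test_idx], model)
    m <- compute_metrics(confusion_counts(dataset$class[test_idx],
                                          pred$class,
                                          levels = stiffness_classes()),
                         averaging = averaging)
    dplyr::mutate(m, fold = i, .before = 1)
  })
  list(per_fold = per,
       mean = dplyr::summarise(per, dplyr::across(
         c("accuracy", "precision", "recall", "f1"), mean)))
}

#' Write a confusion matrix as CSV (rows = true, columns = predicted)
#'
#' @param counts a `bus_confusion`.
#' @param path output CSV path.
#' @export
write_confusion_csv <- function(counts, path) {
  utils::write.csv(as.data.frame.matrix(counts$table), path)
  invisible(path)
}
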