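# Independent brute-force oracles, deliberately written without reusing any
# package internals.

# colored-pixel density of the region above the bottom-third band, by an
# explicit per-pixel loop
oracle_density <- function(px, tol = 2) {
  h <- dim(px)[1]
  region <- floor(2 * h / 3)
  hits <- 0L
  for (r in seq_len(region)) {
    for (cc in seq_len(dim(px)[2])) {
      v <- px[r, cc, ]
      if (max(abs(v[1] - v[2]), abs(v[2] - v[3]), abs(v[1] - v[3])) > tol) {
        hits <- hits + 1L
      }
    }
  }
  hits / (region * dim(px)[2])
}

# Levenshtein distance by dynamic programming
oracle_lev <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  d <- matrix(0L, na + 1, nb + 1)
  d[, 1] <- 0:na; d[1, ] <- 0:nb
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      cost <- if (ca[i] == cb[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + cost)
    }
  }
  d[na + 1, nb + 1]
}

# one-vs-rest AUC by exhaustive pairwise comparison (ties count 1/2)
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# accuracy / macro precision / recall / F1 by a per-instance loop
oracle_metrics <- function(truth, pred) {
  classes <- sort(unique(c(truth, pred)))
  prec <- rec <- f1 <- numeric(0)
  for (cl in classes) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    prec <- c(prec, p); rec <- c(rec, r)
    f1 <- c(f1, if (p + r == 0) 0 else 2 * p * r / (p + r))
  }
  list(accuracy = mean(truth == pred), precision = mean(prec),
       recall = mean(rec), f1 = mean(f1))
}

# small-frame spec used across tests (well above the 300 px contract floor,
# small enough to keep the suite fast)
small_spec <- function(seed = 1L, ...) {
  fixture_spec(image_size = c(360L, 480L), seed = seed, ...)
}

# a blank grayscale frame of the given size
flat_gray <- function(h, w, value = 100) {
  array(value, c(h, w, 3L))
}
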