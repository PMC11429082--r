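test_that("inverse-frequency class weights match the stated formula", {
  w <- class_weights(c(NEGATIVE = 48, EQUIVOCAL = 118, POSITIVE = 157))
  expect_equal(unname(w), c(2.243, 0.912, 0.686), tolerance = 1e-3)
  expect_equal(names(which.max(w)), "NEGATIVE")  # minority largest
  expect_equal(unname(class_weights(c(a = 10, b = 10, c = 10))), rep(1, 3))
  # scale-invariant and permutation-equivariant
  w2 <- class_weights(2 * c(NEGATIVE = 48, EQUIVOCAL = 118, POSITIVE = 157))
  expect_equal(w, w2)
  wp <- class_weights(c(POSITIVE = 157, NEGATIVE = 48, EQUIVOCAL = 118))
  expect_equal(wp[names(w)], w)
  expect_error(class_weights(c(a = 0, b = 5)), "> 0")
})

test_that("ROI extraction returns the generated rectangle, never the bar", {
  for (sd in 1:8) {
    s <- make_scan(small_spec(seed = sd), "SWE",
                   list(annotation_text = "", true_class = "POSITIVE"),
                   scan_seed = sd)
    roi <- extract_roi(s, "SWE")
    expect_equal(roi$origin_bbox, s$truth$roi_bbox)
    bb <- roi$origin_bbox
    expect_lt(bb[["height"]] / bb[["width"]], 5)  # aspect filter held
  }
  b <- make_scan(small_spec(seed = 3), "B_MODE",
                 list(annotation_text = ""))
  expect_error(extract_roi(b$pixels, "SWE"), "no ROI")
})

test_that("the color baseline thresholds the high-stiffness fraction", {
  mk <- function(frac) {
    px <- array(0, c(32, 32, 3))
    n_high <- round(frac * 32 * 32)
    highs <- seq_len(n_high)
    px[, , 1][highs] <- 240                      # red-dominant
    px[, , 3][setdiff(1:(32 * 32), highs)] <- 240  # blue-dominant
    px
  }
  expect_identical(color_baseline(mk(0)), "NEGATIVE")
  expect_identical(color_baseline(mk(1)), "POSITIVE")
  expect_identical(color_baseline(mk(0.5), thresholds = c(0.2, 0.8)),
                   "EQUIVOCAL")
  expect_error(color_baseline(flat_gray(32, 32)), "empty ROI")
  # noiseless fixture ROIs are classified perfectly
  rois <- make_roi_set(c(NEGATIVE = 50, EQUIVOCAL = 50, POSITIVE = 50),
                       jitter_sd = 0, seed = 6)
  pred <- vapply(rois$roi, color_baseline, character(1))
  expect_equal(mean(pred == rois$class), 1.0)
})

test_that("classification returns proper probabilities with severe-side ties", {
  model <- color_baseline_model()
  rois <- make_roi_set(c(NEGATIVE = 5, POSITIVE = 5), seed = 2)
  for (roi in rois$roi) {
    res <- classify_stiffness(roi, model)
    expect_equal(sum(res$probabilities), 1, tolerance = 1e-6)
  }
  # severity tie-break on an explicit tied vector via the nnet surface
  fake <- structure(list(backend = "color_baseline",
                         fit = list(thresholds = c(0.3, 0.7)),
                         class_order = stiffness_classes()),
                    class = "bus_classifier")
  expect_error(classify_stiffness(rois$roi[[1]], "not a model"),
               "not a fitted")
  probs <- c(NEGATIVE = 0.2, EQUIVOCAL = 0.4, POSITIVE = 0.4)
  ord <- stiffness_classes()
  best <- ord[max(which(probs[ord] >= max(probs) - 1e-12))]
  expect_identical(best, "POSITIVE")
})

test_that("training is seeded, class-weighted, and learns the encoding", {
  train <- make_roi_set(c(NEGATIVE = 40, EQUIVOCAL = 40, POSITIVE = 40),
                        jitter_sd = 0, seed = 3)
  test <- make_roi_set(c(NEGATIVE = 20, EQUIVOCAL = 20, POSITIVE = 20),
                       jitter_sd = 0, seed = 103)
  cfg <- train_config(seed = 7, epochs = 30)
  m1 <- train_classifier(train, cfg)
  p1 <- classify_stiffness_all(test, m1)
  expect_equal(mean(p1$class == test$class), 1.0)
  # determinism: same data and seed give identical predictions
  m2 <- train_classifier(train, cfg)
  p2 <- classify_stiffness_all(test, m2)
  expect_identical(p1, p2)
  # probability simplex
  expect_true(all(abs(rowSums(as.matrix(p1[, -1])) - 1) < 1e-6))
  # single-class data refuses to train
  single <- dplyr::filter(train, class == "POSITIVE")
  expect_error(train_classifier(single, cfg), "two classes")
})

test_that("models serialize with their metadata", {
  train <- make_roi_set(c(NEGATIVE = 15, POSITIVE = 15), seed = 4)
  m <- train_classifier(train, train_config(seed = 5, epochs = 10))
  path <- withr::local_tempfile(fileext = ".rds")
  write_classifier(m, path)
  back <- read_classifier(path)
  expect_identical(glance(back)$seed, 5L)
  expect_identical(glance(back)$backend, "nnet")
  expect_equal(nrow(tidy(back)), 2)
  rois <- make_roi_set(c(NEGATIVE = 3, POSITIVE = 3), seed = 9)
  expect_identical(classify_stiffness_all(rois, m),
                   classify_stiffness_all(rois, back))
})
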