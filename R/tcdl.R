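#' Elastography region-of-interest crops
#'
#' A `bus_roi` is a crop of the colored elastography overlay, together with
#' its bounding box in parent-image coordinates.
#'
#' @param pixels h x w x 3 array, h and w at least 16.
#' @param origin_bbox named vector `c(top, left, height, width)` (1-based,
#'   inclusive) locating the crop in its parent frame.
#' @return an object of class `bus_roi`.
#' @export
bus_roi <- function(pixels, origin_bbox) {
  stopifnot(dim(pixels)[1] >= 16, dim(pixels)[2] >= 16)
  structure(list(pixels = pixels, origin_bbox = origin_bbox),
            class = "bus_roi")
}

#' Extract the elastography ROI from a colored frame
#'
#' Crops the bounding box of the largest colored contour, excluding the
#' legend-bar component (thin, right-edge, aspect-filtered). Valid for
#' SWE, SE, and Doppler frames.
#'
#' @param image a `bus_scan` or pixel array.
#' @param mode the frame's mode (one of `SWE`, `SE`, `DOPPLER`).
#' @param cfg an [icvf_config()].
#' @return a `bus_roi`.
#' @export
extract_roi <- function(image, mode = "SWE", cfg = icvf_config()) {
  stopifnot(mode %in% c("SWE", "SE", "DOPPLER"))
  px <- as_pixels(image)
  contours <- detect_color_contours(px, cfg$min_contour_area_px,
                                    cfg$grayscale_tol, cfg)
  contours <- dplyr::filter(contours,
                            !(.data$aspect > cfg$legend_aspect &
                                .data$touches_right))
  if (nrow(contours) == 0) {
    stop("no ROI: no colored contour found in frame", call. = FALSE)
  }
  top <- dplyr::slice_max(contours, .data$area_px, n = 1, with_ties = FALSE)
  bus_roi(px[top$top:(top$top + top$height - 1L),
             top$left:(top$left + top$width - 1L), , drop = FALSE],
          origin_bbox = c(top = top$top, left = top$left,
                          height = top$height, width = top$width))
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (K * n_c)` for class counts `n_c` (K classes, N total), so the
#' minority class receives the largest weight and balanced counts give all
#' weights 1. Scale-invariant in the counts and permutation-equivariant in
#' the input map.
#'
#' @param counts named vector/list of per-class counts, all > 0.
#' @return named numeric vector of weights.
#' @export
class_weights <- function(counts) {
  counts <- unlist(counts)
  if (any(counts <= 0)) stop("all class counts must be > 0", call. = FALSE)
  n <- sum(counts)
  k <- length(counts)
  n / (k * counts)
}

#' Training configuration for the stiffness classifier
#'
#' @param epochs optimizer budget (the nnet backend runs `10 * epochs`
#'   BFGS iterations at most; early convergence stops sooner).
#' @param batch_size kept for config compatibility with minibatch backends;
#'   the nnet backend fits full-batch.
#' @param learning_rate kept for config compatibility; unused by BFGS.
#' @param class_weights optional named weights; `NULL` = inverse-frequency
#'   weights from the training counts, `"none"` = unweighted.
#' @param hidden hidden units of the nnet backend.
#' @param decay L2 weight decay of the nnet backend.
#' @param seed integer; training is reproducible under a fixed seed.
#' @return a list of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 8L, learning_rate = 1e-3,
                         class_weights = NULL, hidden = 8L, decay = 1e-3,
                         seed = 1L) {
  stopifnot(epochs >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs), batch_size = batch_size,
                 learning_rate = learning_rate, class_weights = class_weights,
                 hidden = hidden, decay = decay, seed = as.integer(seed)),
            class = "train_config")
}

# aspect-preserving resize: zero-pad to square, then bilinear resize
resize_roi <- function(px, size = 224L) {
  h <- dim(px)[1]; w <- dim(px)[2]
  s <- max(h, w)
  padded <- array(0, c(s, s, 3L))
  r0 <- floor((s - h) / 2); c0 <- floor((s - w) / 2)
  padded[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w), ] <- px
  img <- EBImage::Image(aperm(padded / 255, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(img, w = size, h = size)
  aperm(EBImage::imageData(out), c(2, 1, 3)) * 255
}

# fraction of colored pixels in the high-stiffness (red-dominant) band
high_stiffness_fraction <- function(px, tol = 2) {
  colored <- channel_diff(px) > tol
  if (!any(colored)) return(NA_real_)
  red <- px[, , 1] >= px[, , 3]
  sum(colored & red) / sum(colored)
}

# patch-grid color features of a 224x224 crop: per-cell mean RGB plus
# high-stiffness fraction (grid x grid x 4 features)
roi_features <- function(roi, grid = 4L) {
  px <- resize_roi(if (inherits(roi, "bus_roi")) roi$pixels else roi)
  size <- dim(px)[1]
  cuts <- round(seq(0, size, length.out = grid + 1L))
  feats <- numeric(0)
  for (i in seq_len(grid)) {
    for (j in seq_len(grid)) {
      cell <- px[(cuts[i] + 1):cuts[i + 1], (cuts[j] + 1):cuts[j + 1], ,
                 drop = FALSE]
      f <- high_stiffness_fraction(cell)
      feats <- c(feats, mean(cell[, , 1]) / 255, mean(cell[, , 2]) / 255,
                 mean(cell[, , 3]) / 255, if (is.na(f)) 0 else f)
    }
  }
  feats
}

#' Train the stiffness classifier
#'
#' Reference trainable backend: ROIs are padded to square and resized to
#' 224 x 224 preserving aspect ratio, summarised by a patch-grid of color
#' features, and classified by a single-hidden-layer softmax network
#' ([nnet::nnet]) whose loss is weighted by inverse-frequency class weights
#' (the minority class is penalized more heavily). Deterministic under the
#' config seed. Deep convolutional backends are a plug-in point: any object
#' with the same predict surface can replace the fitted model.
#'
#' @param dataset a tibble with list-column `roi` (`bus_roi` or pixel
#'   arrays) and column `class`, or a list of `(roi, class)` pairs. At
#'   least two classes must be present.
#' @param cfg a [train_config()].
#' @return a fitted `bus_classifier`.
#' @export
train_classifier <- function(dataset, cfg = train_config()) {
  if (!is.data.frame(dataset)) {
    dataset <- tibble::tibble(roi = purrr::map(dataset, 1),
                              class = purrr::map_chr(dataset, 2))
  }
  y <- factor(dataset$class, levels = stiffness_classes())
  y <- droplevels(y)
  if (nlevels(y) < 2) {
    stop("training set must contain at least two classes", call. = FALSE)
  }
  w_class <- if (identical(cfg$class_weights, "none")) {
    stats::setNames(rep(1, nlevels(y)), levels(y))
  } else if (is.null(cfg$class_weights)) {
    class_weights(table(y))
  } else unlist(cfg$class_weights)
  x <- t(vapply(dataset$roi, roi_features, numeric(4L * 16L)))
  targets <- nnet::class.ind(y)
  fit <- with_seed_(cfg$seed, {
    nnet::nnet(x, targets, size = cfg$hidden, softmax = TRUE,
               weights = unname(w_class[as.character(y)]),
               decay = cfg$decay, maxit = 10L * cfg$epochs,
               trace = FALSE, MaxNWts = 5000L)
  })
  structure(
    list(backend = "nnet", fit = fit, class_order = levels(y),
         input_size = 224L,
         metadata = list(seed = cfg$seed, epochs = cfg$epochs,
                         n_train = nrow(dataset),
                         class_weights = w_class)),
    class = "bus_classifier"
  )
}

#' Deterministic color-statistics classifier
#'
#' Reference non-trained backend and independent check for the trainable
#' one: computes the fraction `f` of colored ROI pixels in the
#' high-stiffness hue band and thresholds it — `f < low` is negative,
#' `f > high` positive, otherwise equivocal. The default thresholds are the
#' midpoints between the synthetic class encodings.
#'
#' @param roi a `bus_roi` or pixel array.
#' @param thresholds `c(low, high)` with `0 <= low < high <= 1`.
#' @return a stiffness class string.
#' @export
color_baseline <- function(roi, thresholds = c(0.3, 0.7)) {
  stopifnot(thresholds[1] >= 0, thresholds[1] < thresholds[2],
            thresholds[2] <= 1)
  px <- if (inherits(roi, "bus_roi")) roi$pixels else roi
  f <- high_stiffness_fraction(px)
  if (is.na(f)) stop("empty ROI: no colored pixels", call. = FALSE)
  if (f < thresholds[1]) "NEGATIVE"
  else if (f > thresholds[2]) "POSITIVE"
  else "EQUIVOCAL"
}

#' @rdname color_baseline
#' @return `color_baseline_model()` wraps the baseline as a
#'   `bus_classifier` usable wherever a fitted model is expected.
#' @export
color_baseline_model <- function(thresholds = c(0.3, 0.7)) {
  structure(
    list(backend = "color_baseline", fit = list(thresholds = thresholds),
         class_order = stiffness_classes(), input_size = 224L,
         metadata = list(seed = NA_integer_, epochs = 0L)),
    class = "bus_classifier"
  )
}

#' Classify the stiffness of an ROI
#'
#' Returns the argmax class of the model's probability vector; exact ties
#' are broken toward the more severe class (positive > equivocal >
#' negative), the clinically conservative choice.
#'
#' @param roi a `bus_roi` or pixel array.
#' @param model a fitted `bus_classifier`.
#' @return list with `class` and `probabilities` (named length-3 vector
#'   over `stiffness_classes()`, summing to 1).
#' @export
classify_stiffness <- function(roi, model) {
  if (!inherits(model, "bus_classifier")) {
    stop("model is not a fitted bus_classifier", call. = FALSE)
  }
  probs <- stats::setNames(rep(0, 3), stiffness_classes())
  if (model$backend == "color_baseline") {
    cls <- color_baseline(roi, model$fit$thresholds)
    probs[cls] <- 1
  } else {
    x <- matrix(roi_features(roi), nrow = 1)
    p <- stats::predict(model$fit, x)
    probs[model$class_order] <- as.numeric(p)
    probs <- probs / sum(probs)
  }
  ord <- stiffness_classes()  # severity-ascending
  best <- max(probs)
  cls <- ord[max(which(probs[ord] >= best - 1e-12))]
  list(class = cls, probabilities = probs)
}

#' Classify many ROIs
#'
#' @param rois list of ROIs or a tibble with a `roi` list-column.
#' @param model a fitted `bus_classifier`.
#' @return a tibble with `class` and one probability column per stiffness
#'   class.
#' @export
classify_stiffness_all <- function(rois, model) {
  if (is.data.frame(rois)) rois <- rois$roi
  res <- purrr::map(rois, classify_stiffness, model = model)
  tibble::tibble(
    class = purrr::map_chr(res, "class"),
    NEGATIVE = purrr::map_dbl(res, ~ .x$probabilities[["NEGATIVE"]]),
    EQUIVOCAL = purrr::map_dbl(res, ~ .x$probabilities[["EQUIVOCAL"]]),
    POSITIVE = purrr::map_dbl(res, ~ .x$probabilities[["POSITIVE"]])
  )
}

#' Save or load a fitted classifier
#'
#' Single-file serialization with embedded metadata (backend, class order,
#' training seed and epochs).
#'
#' @param model a `bus_classifier`.
#' @param path file path.
#' @return `write_classifier()` returns `path` invisibly;
#'   `read_classifier()` the model.
#' @export
write_classifier <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "bus_classifier")) {
    stop("file does not contain a bus_classifier", call. = FALSE)
  }
  model
}

#' @export
print.bus_classifier <- function(x, ...) {
  cat(sprintf("<bus_classifier backend=%s classes=%s trained on n=%s>\n",
              x$backend, paste(x$class_order, collapse = "/"),
              x$metadata$n_train %||% "-"))
  invisible(x)
}

#' Tidy a fitted stiffness classifier
#'
#' @param x a `bus_classifier`.
#' @param ... unused.
#' @return `tidy()`: one row per class with its training weight;
#'   `glance()`: one row of model-level metadata.
#' @method tidy bus_classifier
#' @export
tidy.bus_classifier <- function(x, ...) {
  w <- x$metadata$class_weights
  tibble::tibble(
    class = x$class_order,
    weight = if (is.null(w)) NA_real_ else unname(w[x$class_order])
  )
}

#' @rdname tidy.bus_classifier
#' @method glance bus_classifier
#' @export
glance.bus_classifier <- function(x, ...) {
  tibble::tibble(
    backend = x$backend,
    n_classes = length(x$class_order),
    n_train = x$metadata$n_train %||% NA_integer_,
    seed = x$metadata$seed,
    epochs = x$metadata$epochs
  )
}
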