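#' Scan-mode labels and stiffness classes
#'
#' `mode_labels()` returns the four ultrasound scan modes the rule-based
#' classifier distinguishes; `stiffness_classes()` the three elasticity
#' classes, ordered from least to most severe.
#'
#' @return a character vector of labels.
#' @export
mode_labels <- function() c("B_MODE", "DOPPLER", "SWE", "SE")

#' @rdname mode_labels
#' @export
stiffness_classes <- function() c("NEGATIVE", "EQUIVOCAL", "POSITIVE")

#' Configuration for visual-feature mode classification
#'
#' Tunable thresholds of the decision procedure. `grayscale_tol` absorbs
#' chroma round-off from lossy exports; `doppler_density_threshold` is the
#' colored-pixel fraction (of the scan region, excluding the annotation
#' band) below which a frame counts as "low density";
#' `rectangularity_threshold` is the contour area / bounding-box area ratio
#' below which the largest contour counts as "irregular". The defaults were
#' calibrated once on the synthetic fixtures.
#'
#' @param grayscale_tol integer >= 0, max allowed channel difference for a
#'   grayscale pixel.
#' @param doppler_density_threshold fraction in (0,1).
#' @param rectangularity_threshold fraction in (0,1].
#' @param min_contour_area_px smallest connected colored component kept.
#' @param legend_aspect minimum height/width ratio for a component to count
#'   as a legend bar.
#' @param legend_right_frac legend bars must touch the right `1 -
#'   legend_right_frac` strip of the frame.
#' @return a list of class `icvf_config`.
#' @export
icvf_config <- function(grayscale_tol = 2L,
                        doppler_density_threshold = 0.02,
                        rectangularity_threshold = 0.75,
                        min_contour_area_px = 25L,
                        legend_aspect = 5,
                        legend_right_frac = 0.85) {
  structure(
    list(grayscale_tol = grayscale_tol,
         doppler_density_threshold = doppler_density_threshold,
         rectangularity_threshold = rectangularity_threshold,
         min_contour_area_px = min_contour_area_px,
         legend_aspect = legend_aspect,
         legend_right_frac = legend_right_frac),
    class = "icvf_config"
  )
}

# per-pixel max channel difference, H x W matrix
channel_diff <- function(px) {
  pmax(abs(px[, , 1] - px[, , 2]),
       abs(px[, , 2] - px[, , 3]),
       abs(px[, , 1] - px[, , 3]))
}

#' Is a frame grayscale?
#'
#' TRUE iff every pixel has max channel difference at most `tol`.
#'
#' @param image a `bus_scan` or pixel array.
#' @param tol integer >= 0.
#' @return logical scalar.
#' @export
is_grayscale <- function(image, tol = 2L) {
  stopifnot(tol >= 0)
  px <- as_pixels(image)
  max(channel_diff(px)) <= tol
}

#' Colored-pixel density of the scan region
#'
#' Fraction of pixels whose max channel difference exceeds `tol`, restricted
#' to the image region above the annotation text band (the bottom third is
#' excluded so colored annotation glyphs can never pollute mode evidence).
#'
#' @inheritParams is_grayscale
#' @return fraction in \[0, 1\].
#' @export
color_pixel_density <- function(image, tol = 2L) {
  px <- as_pixels(image)
  rows <- scan_region_rows(dim(px)[1])
  d <- channel_diff(px[rows, , , drop = FALSE])
  mean(d > tol)
}

#' Connected colored contours of the scan region
#'
#' Labels connected components of the colored-pixel mask (scan region only)
#' and summarises each as a row of a tibble: pixel area, bounding box
#' (`top`, `left`, `height`, `width`, 1-based, inclusive), rectangularity
#' (area / bbox area), aspect ratio, and whether the component touches the
#' right-edge strip where vendor legend bars live. Sorted by area,
#' descending.
#'
#' @inheritParams is_grayscale
#' @param min_area_px smallest component kept (>= 1).
#' @param cfg an [icvf_config()].
#' @return a tibble with one row per contour.
#' @export
detect_color_contours <- function(image, min_area_px = 25L, tol = 2L,
                                  cfg = icvf_config()) {
  stopifnot(min_area_px >= 1)
  px <- as_pixels(image)
  h <- dim(px)[1]; w <- dim(px)[2]
  rows <- scan_region_rows(h)
  mask <- channel_diff(px[rows, , , drop = FALSE]) > tol
  empty <- tibble::tibble(
    label = integer(), area_px = integer(), top = integer(), left = integer(),
    height = integer(), width = integer(), rectangularity = double(),
    aspect = double(), touches_right = logical()
  )
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(mask)
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  out <- tibble::tibble(label = as.integer(labs),
                        row = idx[, 1], col = idx[, 2]) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      area_px = dplyr::n(),
      top = min(.data$row), left = min(.data$col),
      height = max(.data$row) - min(.data$row) + 1L,
      width = max(.data$col) - min(.data$col) + 1L,
      .groups = "drop"
    ) |>
    dplyr::filter(.data$area_px >= min_area_px) |>
    dplyr::mutate(
      rectangularity = .data$area_px / (.data$height * .data$width),
      aspect = .data$height / .data$width,
      touches_right = (.data$left + .data$width - 1L) >=
        ceiling(cfg$legend_right_frac * w)
    ) |>
    dplyr::arrange(dplyr::desc(.data$area_px))
  if (nrow(out) == 0) empty else out
}

#' Locate the vertical color legend bar
#'
#' The legend bar is taken to be the tallest thin colored component (aspect
#' ratio above `cfg$legend_aspect`) touching the right strip of the frame.
#'
#' @inheritParams detect_color_contours
#' @param contours optionally, precomputed [detect_color_contours()] output.
#' @return a one-row tibble (bounding box) or `NULL` when no bar is found.
#' @export
detect_legend_bar <- function(image, contours = NULL, cfg = icvf_config()) {
  if (is.null(contours)) {
    contours <- detect_color_contours(image, cfg$min_contour_area_px,
                                      cfg$grayscale_tol, cfg)
  }
  bars <- dplyr::filter(contours, .data$aspect > cfg$legend_aspect,
                        .data$touches_right)
  if (nrow(bars) == 0) return(NULL)
  dplyr::slice_max(bars, .data$height, n = 1, with_ties = FALSE)
}

#' Detect the "kPa" unit label next to the legend bar
#'
#' Shear-wave elastography frames carry a color legend bar annotated with
#' kilopascal units; strain elastography frames have the bar without the
#' unit text. Looks for the string "kPa" (case-insensitive) in a window
#' around the detected legend bar using the given text recognizer.
#'
#' @inheritParams detect_legend_bar
#' @param recognizer a text recognizer (see [recognizer_template()]).
#' @return logical scalar; FALSE when no legend bar is present.
#' @export
detect_kpa_text <- function(image, recognizer = recognizer_template(),
                            cfg = icvf_config()) {
  px <- as_pixels(image)
  bar <- detect_legend_bar(image, cfg = cfg)
  if (is.null(bar)) return(FALSE)
  h <- dim(px)[1]; w <- dim(px)[2]
  r0 <- max(1L, bar$top - 60L)
  r1 <- min(h, bar$top + bar$height - 1L)
  c0 <- max(1L, bar$left - 90L)
  c1 <- min(w, bar$left + bar$width + 40L)
  window <- px[r0:r1, c0:c1, , drop = FALSE]
  tokens <- recognize(window, recognizer)
  any(grepl("kpa", tokens$text, ignore.case = TRUE))
}

#' Classify the ultrasound mode of a frame from visual features
#'
#' The rule-based decision procedure, applied in fixed branch order:
#' a grayscale frame is B-mode; otherwise, if the colored-pixel density is
#' low and the largest color contours are irregular (non-rectangular), the
#' frame is Doppler; otherwise, if a "kPa" unit label is present near the
#' color legend bar, it is shear-wave elastography; otherwise strain
#' elastography. A colored frame that would satisfy the Doppler density
#' test but shows a rectangular contour falls through to the kPa check
#' (the conjunction is required). Note the branch order is literal: a
#' hypothetical Doppler frame that also displayed a kPa legend would still
#' be labeled Doppler.
#'
#' @inheritParams detect_kpa_text
#' @return one of `mode_labels()`.
#' @export
classify_mode <- function(image, cfg = icvf_config(),
                          recognizer = recognizer_template()) {
  px <- as_pixels(image)
  d <- dim(px)
  if (d[1] < 300 || d[2] < 300) {
    stop("frame too small to classify (need at least 300 x 300 px)",
         call. = FALSE)
  }
  if (any(is.na(px))) stop("unreadable image: NA pixels", call. = FALSE)
  if (is_grayscale(px, cfg$grayscale_tol)) return("B_MODE")
  density <- color_pixel_density(px, cfg$grayscale_tol)
  contours <- detect_color_contours(px, cfg$min_contour_area_px,
                                    cfg$grayscale_tol, cfg)
  max_rect <- if (nrow(contours) == 0) 0 else max(contours$rectangularity)
  if (density < cfg$doppler_density_threshold &&
      max_rect < cfg$rectangularity_threshold) {
    return("DOPPLER")
  }
  if (detect_kpa_text(px, recognizer, cfg)) "SWE" else "SE"
}

#' Classify the mode of many frames
#'
#' Tidy wrapper over [classify_mode()]: takes a data frame with a `path`
#' column (or a character vector of paths) and returns it with a `mode`
#' column appended.
#'
#' @param paths data frame with a `path` column, or character vector.
#' @inheritParams classify_mode
#' @return a tibble with columns `path` and `mode`.
#' @export
classify_modes <- function(paths, cfg = icvf_config(),
                           recognizer = recognizer_template()) {
  if (is.character(paths)) paths <- tibble::tibble(path = paths)
  paths |>
    tibble::as_tibble() |>
    dplyr::mutate(mode = purrr::map_chr(
      .data$path, ~ classify_mode(read_scan_png(.x), cfg, recognizer)
    ))
}
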