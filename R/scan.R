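#' Ultrasound scan frames
#'
#' A `bus_scan` wraps an H x W x 3 array of 8-bit RGB intensities together
#' with provenance (source path, patient id) and, for synthetic frames, the
#' embedded ground truth used by the test suite.
#'
#' @param pixels H x W x 3 numeric array with values in 0..255, H and W both
#'   at least 300 for real frames (smaller arrays are allowed for unit-level
#'   helpers but `classify_mode()` enforces the contract).
#' @param source_path origin of the frame on disk, if any.
#' @param patient_id patient identifier.
#' @param truth optional list of generator ground truth (see
#'   [make_scan()]).
#' @return an object of class `bus_scan`.
#' @export
bus_scan <- function(pixels, source_path = NA_character_,
                     patient_id = NA_character_, truth = NULL) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  structure(
    list(pixels = pixels, source_path = source_path,
         patient_id = patient_id, truth = truth),
    class = "bus_scan"
  )
}

#' @export
print.bus_scan <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<bus_scan %d x %d px, patient %s%s>\n", d[1], d[2],
              x$patient_id,
              if (!is.null(x$truth)) paste0(", truth mode ", x$truth$true_mode)
              else ""))
  invisible(x)
}

# Accept a bus_scan or a bare pixel array everywhere image math happens.
as_pixels <- function(image) {
  if (inherits(image, "bus_scan")) image$pixels
  else if (is.array(image) && length(dim(image)) == 3L) image
  else stop("expected a bus_scan or an H x W x 3 pixel array", call. = FALSE)
}

#' Read and write scan frames as PNG
#'
#' Frames travel as 8-bit RGB PNG files (grayscale PNGs are expanded to
#' three identical channels on read).
#'
#' @param path file path.
#' @param patient_id patient identifier attached to the returned scan.
#' @return `read_scan_png()` returns a `bus_scan`; `write_scan_png()` returns
#'   `path` invisibly.
#' @export
read_scan_png <- function(path, patient_id = NA_character_) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 2L) raw <- array(raw, c(dim(raw), 1L))
  if (dim(raw)[3] == 1L) raw <- raw[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(raw)[3] == 4L) raw <- raw[, , 1:3, drop = FALSE]
  bus_scan(round(raw * 255), source_path = path, patient_id = patient_id)
}

#' @rdname read_scan_png
#' @param scan a `bus_scan` or pixel array.
#' @export
write_scan_png <- function(scan, path) {
  px <- as_pixels(scan)
  png::writePNG(px / 255, path)
  invisible(path)
}

#' Display a scan frame
#'
#' @param object a `bus_scan`.
#' @param ... unused.
#' @return a ggplot raster of the frame, captioned with the embedded
#'   ground-truth mode when present.
#' @method autoplot bus_scan
#' @export
autoplot.bus_scan <- function(object, ...) {
  px <- object$pixels / 255
  h <- dim(px)[1]; w <- dim(px)[2]
  df <- expand.grid(row = seq_len(h), col = seq_len(w))
  df$fill <- grDevices::rgb(px[, , 1], px[, , 2], px[, , 3])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = if (!is.null(object$truth)) object$truth$true_mode else NULL,
      x = NULL, y = NULL
    ) +
    ggplot2::theme_void()
}

# Scan-region boundary: the annotation band is the bottom third of the frame
# (0-based rows floor(2H/3)..H-1); everything above it is scan content.
scan_region_rows <- function(h) {
  seq_len(floor(2 * h / 3))
}

# run an expression under a temporary RNG state
with_seed_ <- function(seed, code) {
  withr::with_seed(seed, code)
}
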