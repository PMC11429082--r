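#' Text recognizers
#'
#' Text recognition is a pluggable adapter behind a single generic surface:
#' [recognize()] takes an image region and a recognizer object and returns
#' a tibble of tokens. Two recognizers ship with the package:
#'
#' * `recognizer_template()` — a deterministic template matcher for the
#'   packaged bitmap font. It binarizes on the minimum channel (burned-in
#'   annotation text is pure white; colored overlay pixels and speckle have
#'   a low minimum channel), segments lines and glyph runs, and matches each
#'   glyph bitmap exactly. Confidence is always 1.
#' * `recognizer_mock()` — bypasses pixels entirely: it returns the ground
#'   truth string attached to a synthetic frame after corrupting it with
#'   [inject_confusions()]. This isolates the confusion-correction stage
#'   from rendering/recognition in tests.
#'
#' An adapter for an external OCR engine can be added by constructing a
#' `bus_recognizer` whose `fn(px)` returns the same token tibble.
#'
#' @param threshold binarization threshold on the minimum channel (0..255).
#' @param scale font unit size in pixels used at render time.
#' @return an object of class `bus_recognizer`.
#' @export
recognizer_template <- function(threshold = 200, scale = 2L) {
  structure(
    list(kind = "template",
         fn = function(px, ...) template_recognize(px, threshold, scale)),
    class = "bus_recognizer"
  )
}

#' @rdname recognizer_template
#' @param rate confusion injection rate in \[0, 1\].
#' @param seed integer seed for the injected corruption.
#' @export
recognizer_mock <- function(rate = 0, seed = 1L) {
  structure(
    list(kind = "mock",
         fn = function(px, truth_text = NULL, ...) {
           if (is.null(truth_text)) {
             stop("mock recognizer needs the frame's ground-truth text",
                  call. = FALSE)
           }
           corrupted <- inject_confusions(truth_text, rate, seed)
           toks <- strsplit(corrupted, " +")[[1]]
           toks <- toks[nzchar(toks)]
           tibble::tibble(
             text = toks,
             top = NA_integer_, left = seq_along(toks),
             height = NA_integer_, width = NA_integer_,
             confidence = 1
           )
         }),
    class = "bus_recognizer"
  )
}

#' Recognize text tokens in an image region
#'
#' @param band pixel array (or `bus_scan`) holding the region to read.
#' @param recognizer a `bus_recognizer`.
#' @param ... passed to the recognizer (the mock recognizer takes
#'   `truth_text`).
#' @return tibble with columns `text`, `top`, `left`, `height`, `width`
#'   (band coordinates, 1-based) and `confidence`, ordered top-to-bottom
#'   then left-to-right.
#' @export
recognize <- function(band, recognizer = recognizer_template(), ...) {
  if (!inherits(recognizer, "bus_recognizer")) {
    stop("recognizer unavailable: expected a bus_recognizer", call. = FALSE)
  }
  px <- as_pixels(band)
  recognizer$fn(px, ...)
}

# --- template matcher internals ----------------------------------------

empty_tokens <- function() {
  tibble::tibble(text = character(), top = integer(), left = integer(),
                 height = integer(), width = integer(), confidence = double())
}

# split a sorted integer vector into runs of consecutive values (allowing
# gaps below `gap`)
split_runs <- function(v, gap = 1L) {
  if (length(v) == 0) return(list())
  breaks <- which(diff(v) > gap)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(v))
  Map(function(s, e) v[s]:v[e], starts, ends)
}

template_recognize <- function(px, threshold = 200, scale = 2L) {
  mask <- pmin(px[, , 1], px[, , 2], px[, , 3]) >= threshold
  if (!any(mask)) return(empty_tokens())
  lookup <- glyph_lookup()
  units <- .busrep_font_units
  out <- list()
  line_rows <- split_runs(which(rowSums(mask) > 0), gap = 2L * scale)
  for (lr in line_rows) {
    line_top <- min(lr)
    rows <- line_top:(line_top + units$height * scale - 1L)
    rows <- rows[rows <= nrow(mask)]
    lm <- mask[rows, , drop = FALSE]
    on_cols <- which(colSums(lm) > 0)
    runs <- split_runs(on_cols)
    if (length(runs) == 0) next
    # group glyph runs into tokens: a space leaves a gap of >= 6 font units
    # between ink runs, intra-word gaps are at most 4 units
    gaps <- if (length(runs) > 1) {
      vapply(seq_len(length(runs) - 1L), function(i) {
        (min(runs[[i + 1L]]) - max(runs[[i]]) - 1L) / scale
      }, numeric(1))
    } else numeric(0)
    token_break <- c(FALSE, gaps >= 6)
    token_id <- cumsum(token_break)
    for (tid in unique(token_id)) {
      tok_runs <- runs[token_id == tid]
      chars <- vapply(tok_runs, function(cols) {
        cell <- lm[, cols, drop = FALSE]
        # exact downsample: rendering replicates each font unit scale x scale
        unit <- cell[seq(1L, nrow(cell), by = scale),
                     seq(1L, ncol(cell), by = scale), drop = FALSE]
        if (nrow(unit) < units$height) {
          unit <- rbind(unit, matrix(FALSE, units$height - nrow(unit),
                                     ncol(unit)))
        }
        key <- paste(as.integer(unit), collapse = "")
        ch <- get0(key, envir = lookup, ifnotfound = "?")
        ch
      }, character(1))
      left <- min(tok_runs[[1]])
      right <- max(tok_runs[[length(tok_runs)]])
      out[[length(out) + 1L]] <- tibble::tibble(
        text = paste(chars, collapse = ""),
        top = line_top, left = left,
        height = units$height * scale, width = right - left + 1L,
        confidence = 1
      )
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$top, .data$left)
}
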