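#' Crop the burned-in annotation band
#'
#' Operator annotations live in the bottom third of the exported frame:
#' for an H-row image the band is 0-based rows `floor(2H/3) .. H-1`
#' (1-based `floor(2H/3)+1 .. H`).
#'
#' @param image a `bus_scan` or pixel array with at least 3 rows.
#' @return the band as a pixel array (width unchanged).
#' @export
crop_text_band <- function(image) {
  px <- as_pixels(image)
  h <- dim(px)[1]
  stopifnot(h >= 3)
  px[(floor(2 * h / 3) + 1L):h, , , drop = FALSE]
}

#' The shipped character confusion matrix
#'
#' Context-weighted OCR confusion pairs: each row says that a recognized
#' `misread` character should be replaced by `intended` when the token-level
#' `context` predicate holds, with `weight` ranking pairs by observed
#' frequency (S->5 ranks highest; it is the most frequent confusion,
#' especially with "cm" adjacent). Corrections are directional
#' (misread -> intended only). The matrix is user-extensible: persist it
#' with [write_confusion_matrix()], edit, and reload with
#' [read_confusion_matrix()].
#'
#' Context predicates (documented in the methods vignette):
#' * `in_numeric_field` — the token contains a digit, a decimal point or a
#'   colon;
#' * `cm_adjacent` — a neighbouring token (±1) equals "cm"/"CM", or the
#'   token itself ends in "cm"/"CM";
#' * `in_clock_token` — a neighbouring token is an "h" clock marker.
#'
#' A candidate substitution is applied only if the fully corrected token
#' parses as a number, clock time, or size/depth expression, so alphabetic
#' words ("SIZE", "RIGHT") are never mangled.
#'
#' @return a tibble with columns `misread`, `intended`, `weight`, `context`.
#' @export
default_confusion_matrix <- function() {
  tibble::tibble(
    misread  = c("S", "S", "I", "Z", "b"),
    intended = c("5", "5", "1", "2", "6"),
    weight   = c(5, 4, 3, 2, 1),
    context  = c("cm_adjacent", "in_numeric_field", "in_numeric_field",
                 "in_numeric_field", "in_numeric_field")
  )
}

#' @rdname default_confusion_matrix
#' @param path CSV file with columns `misread,intended,weight,context`.
#' @export
read_confusion_matrix <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "character",
                                             "numeric", "character"))
  stopifnot(all(c("misread", "intended", "weight", "context") %in% names(df)))
  tibble::as_tibble(df)
}

#' @rdname default_confusion_matrix
#' @param matrix a confusion-matrix tibble.
#' @export
write_confusion_matrix <- function(matrix, path) {
  utils::write.csv(matrix, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# does a corrected token parse as a number / clock / size-depth expression?
numeric_shape <- function(tok) {
  grepl("^[0-9]+$", tok) ||                      # bare integer
    grepl("^[0-9]+\\.[0-9]+$", tok) ||           # decimal
    grepl("^[0-9]{1,2}:[0-9]{2}$", tok) ||       # clock
    grepl("^[0-9]+(\\.[0-9]+)?(cm|CM),?$", tok)  # attached unit
}

token_contexts <- function(tokens, i) {
  tok <- tokens[i]
  prev <- if (i > 1) tokens[i - 1] else ""
  nxt <- if (i < length(tokens)) tokens[i + 1] else ""
  is_cm <- function(x) grepl("^(cm|CM),?$", x)
  is_h <- function(x) grepl("^h,?$", x, ignore.case = TRUE)
  ctx <- character(0)
  if (grepl("[0-9.:]", tok)) ctx <- c(ctx, "in_numeric_field")
  if (is_cm(prev) || is_cm(nxt) || grepl("(cm|CM),?$", tok)) {
    ctx <- c(ctx, "cm_adjacent", "in_numeric_field")
  }
  if (is_h(prev) || is_h(nxt)) {
    ctx <- c(ctx, "in_clock_token", "in_numeric_field")
  }
  unique(ctx)
}

#' Correct recognition errors with the confusion matrix
#'
#' For each token in a context covered by the matrix, substitutes
#' misread characters by their intended partners (highest-weight applicable
#' pair per character) and keeps the corrected token only if it then parses
#' as a numeric/clock/size expression. Characters outside numeric, size, or
#' clock contexts are untouched. The operation is idempotent.
#'
#' @param tokens a token tibble from [recognize()] or a character vector.
#' @param matrix confusion pairs, see [default_confusion_matrix()].
#' @return the tokens with corrected `text` (same type as the input).
#' @export
apply_confusion_correction <- function(tokens,
                                       matrix = default_confusion_matrix()) {
  stopifnot(nrow(matrix) >= 1)
  texts <- if (is.character(tokens)) tokens else tokens$text
  matrix <- dplyr::arrange(matrix, dplyr::desc(.data$weight))
  out <- texts
  for (i in seq_along(texts)) {
    ctx <- token_contexts(texts, i)
    if (length(ctx) == 0) next
    # rows whose context predicate holds; sorted by weight, so match()
    # below picks the highest-weight pair per misread character
    applicable <- matrix[matrix$context %in% ctx, , drop = FALSE]
    if (nrow(applicable) == 0) next
    chars <- strsplit(texts[i], "")[[1]]
    hit <- FALSE
    for (j in seq_along(chars)) {
      k <- match(chars[j], applicable$misread)
      if (!is.na(k)) {
        chars[j] <- applicable$intended[k]
        hit <- TRUE
      }
    }
    if (!hit) next
    cand <- paste(chars, collapse = "")
    if (numeric_shape(cand)) out[i] <- cand
  }
  if (is.character(tokens)) out else dplyr::mutate(tokens, text = out)
}

# --- cleaning and parsing ----------------------------------------------

strip_punct <- function(x) gsub(",$", "", x)

#' Parse side, clock-face location, depth, and size from corrected tokens
#'
#' Understands both operator dialects: `LEFT 2:00 5CM [LO]` and
#' `RIGHT 9 h, 6 CM`. The location key is (side, clock hour, clock minute,
#' depth in cm from the nipple); qualifiers such as "LO" are retained but
#' excluded from the key. Per the cleaning rule, only decimal numbers
#' (optionally chained with "×") are retained as size dimensions; integer
#' distances with a cm unit are depths. Unparseable fields come back as
#' `NULL`, never a guess; the only error is two contradictory sides in one
#' annotation.
#'
#' @param tokens token tibble or character vector (already corrected).
#' @return list with elements `location` (list: `side`, `clock_hour`,
#'   `clock_minute`, `depth_cm`, `qualifiers`) or `NULL`, and `size` (list:
#'   `dims_cm`, `raw_text`) or `NULL`.
#' @export
clean_and_parse <- function(tokens) {
  toks <- if (is.character(tokens)) tokens else tokens$text
  toks <- toks[nzchar(toks)]
  n <- length(toks)
  up <- toupper(strip_punct(toks))
  used <- logical(n)

  sides <- unique(up[up %in% c("LEFT", "RIGHT")])
  if (length(sides) > 1) {
    stop("contradictory sides in one annotation: ",
         paste(sides, collapse = " vs "), call. = FALSE)
  }
  side <- if (length(sides) == 1) sides else NULL
  used[up %in% c("LEFT", "RIGHT")] <- TRUE

  clock_hour <- clock_minute <- NULL
  ci <- which(grepl("^[0-9]{1,2}:[0-9]{2}$", up) & !used)
  if (length(ci) >= 1) {
    parts <- strsplit(up[ci[1]], ":")[[1]]
    h <- as.integer(parts[1]); m <- as.integer(parts[2])
    if (h >= 1 && h <= 12 && m <= 59) {
      clock_hour <- h; clock_minute <- m
      used[ci[1]] <- TRUE
      # "11:30 h," dialect: absorb the marker
      if (ci[1] < n && grepl("^H$", up[ci[1] + 1])) used[ci[1] + 1] <- TRUE
    }
  }
  if (is.null(clock_hour)) {
    hi <- which(up == "H")
    if (length(hi) >= 1 && hi[1] > 1) {
      cand <- up[hi[1] - 1]
      if (grepl("^[0-9]{1,2}$", cand) &&
          as.integer(cand) >= 1 && as.integer(cand) <= 12) {
        clock_hour <- as.integer(cand); clock_minute <- 0L
        used[c(hi[1] - 1, hi[1])] <- TRUE
      }
    }
  }

  depth_cm <- NULL
  di <- which(grepl("^[0-9]+CM$", up) & !used)
  if (length(di) >= 1) {
    depth_cm <- as.numeric(sub("CM$", "", up[di[1]]))
    used[di[1]] <- TRUE
  } else {
    di <- which(up == "CM")
    for (k in di) {
      if (k > 1 && grepl("^[0-9]+$", up[k - 1]) && !used[k - 1]) {
        depth_cm <- as.numeric(up[k - 1])
        used[c(k - 1, k)] <- TRUE
        break
      }
    }
  }

  dims <- numeric(0); raw <- character(0)
  si <- which(grepl("^[0-9]+\\.[0-9]+(CM)?$", up))
  for (k in si) {
    if (used[k]) next
    dims <- c(dims, as.numeric(sub("CM$", "", up[k])))
    raw <- c(raw, toks[k])
    used[k] <- TRUE
    if (k < n && (up[k + 1] == "×" || up[k + 1] == "X")) used[k + 1] <- TRUE
    if (grepl("CM$", up[k])) next
    if (k < n && up[k + 1] == "CM") used[k + 1] <- TRUE
  }
  # trailing bare unit after a size chain
  used[up %in% c("CM", "×", "X")] <- TRUE

  qualifiers <- up[!used & grepl("^[A-Z]+$", up)]

  location <- if (!is.null(side) && !is.null(clock_hour) &&
                  !is.null(depth_cm)) {
    list(side = side, clock_hour = clock_hour, clock_minute = clock_minute,
         depth_cm = depth_cm, qualifiers = qualifiers)
  } else NULL
  size <- if (length(dims) > 0) {
    list(dims_cm = dims, raw_text = paste(raw, collapse = " × "))
  } else NULL
  list(location = location, size = size)
}

#' Character error rate
#'
#' Levenshtein edit distance between recognized and true strings,
#' normalized by the truth length, expressed as a percentage.
#'
#' @param predicted recognized string(s).
#' @param truth ground-truth string(s); must be non-empty.
#' @return CER in percent (vectorized over pairs).
#' @export
character_error_rate <- function(predicted, truth) {
  if (any(!nzchar(truth))) stop("truth must be non-empty", call. = FALSE)
  d <- mapply(function(p, t) utils::adist(p, t)[1, 1], predicted, truth)
  unname(as.numeric(d) / nchar(truth) * 100)
}

#' Pooled character error rate over a corpus
#'
#' Total edit distance over total truth length, in percent — the corpus
#' analogue of [character_error_rate()].
#'
#' @inheritParams character_error_rate
#' @return a single percentage.
#' @export
pooled_cer <- function(predicted, truth) {
  if (any(!nzchar(truth))) stop("truth must be non-empty", call. = FALSE)
  d <- mapply(function(p, t) utils::adist(p, t)[1, 1], predicted, truth)
  sum(d) / sum(nchar(truth)) * 100
}

#' Extract the annotation of one frame
#'
#' Convenience composition of the text-extraction stage: crop the band,
#' recognize, correct, parse.
#'
#' @param scan a `bus_scan`.
#' @param recognizer a `bus_recognizer`.
#' @param matrix confusion matrix.
#' @return as [clean_and_parse()], plus `text` (the corrected string).
#' @export
extract_annotation <- function(scan, recognizer = recognizer_template(),
                               matrix = default_confusion_matrix()) {
  band <- crop_text_band(scan)
  args <- list(band, recognizer)
  if (identical(recognizer$kind, "mock")) {
    args$truth_text <- scan$truth$annotation_text %||% ""
    if (!nzchar(args$truth_text)) {
      return(list(location = NULL, size = NULL, text = ""))
    }
  }
  tokens <- do.call(recognize, args)
  if (nrow(tokens) == 0) return(list(location = NULL, size = NULL, text = ""))
  tokens <- apply_confusion_correction(tokens, matrix)
  parsed <- clean_and_parse(tokens)
  parsed$text <- paste(tokens$text, collapse = " ")
  parsed
}
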