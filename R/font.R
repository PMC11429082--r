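# Packaged 5x7 monospaced bitmap font used for burned-in annotation text.
# Rendering is exact pixel replication (integer scale factor), so the
# template-matching recognizer can invert it deterministically.

.busrep_glyphs <- list(
  "A" = c(".###.", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
  "B" = c("####.", "#...#", "#...#", "####.", "#...#", "#...#", "####."),
  "C" = c(".###.", "#...#", "#....", "#....", "#....", "#...#", ".###."),
  "D" = c("####.", "#...#", "#...#", "#...#", "#...#", "#...#", "####."),
  "E" = c("#####", "#....", "#....", "####.", "#....", "#....", "#####"),
  "F" = c("#####", "#....", "#....", "####.", "#....", "#....", "#...."),
  "G" = c(".###.", "#...#", "#....", "#.###", "#...#", "#...#", ".###."),
  "H" = c("#...#", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
  "I" = c(".###.", "..#..", "..#..", "..#..", "..#..", "..#..", ".###."),
  "J" = c("..###", "...#.", "...#.", "...#.", "#..#.", "#..#.", ".##.."),
  "K" = c("#...#", "#..#.", "#.#..", "##...", "#.#..", "#..#.", "#...#"),
  "L" = c("#....", "#....", "#....", "#....", "#....", "#....", "#####"),
  "M" = c("#...#", "##.##", "#.#.#", "#.#.#", "#...#", "#...#", "#...#"),
  "N" = c("#...#", "##..#", "#.#.#", "#..##", "#...#", "#...#", "#...#"),
  "O" = c(".###.", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
  "P" = c("####.", "#...#", "#...#", "####.", "#....", "#....", "#...."),
  "Q" = c(".###.", "#...#", "#...#", "#...#", "#.#.#", "#..#.", ".##.#"),
  "R" = c("####.", "#...#", "#...#", "####.", "#.#..", "#..#.", "#...#"),
  "S" = c(".####", "#....", "#....", ".###.", "....#", "....#", "####."),
  "T" = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "..#.."),
  "U" = c("#...#", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
  "V" = c("#...#", "#...#", "#...#", "#...#", "#...#", ".#.#.", "..#.."),
  "W" = c("#...#", "#...#", "#...#", "#.#.#", "#.#.#", "##.##", "#...#"),
  "X" = c("#...#", "#...#", ".#.#.", "..#..", ".#.#.", "#...#", "#...#"),
  "Y" = c("#...#", "#...#", ".#.#.", "..#..", "..#..", "..#..", "..#.."),
  "Z" = c("#####", "....#", "...#.", "..#..", ".#...", "#....", "#####"),
  "0" = c(".###.", "#...#", "#..##", "#.#.#", "##..#", "#...#", ".###."),
  "1" = c("..#..", ".##..", "..#..", "..#..", "..#..", "..#..", ".###."),
  "2" = c(".###.", "#...#", "....#", "...#.", "..#..", ".#...", "#####"),
  "3" = c(".###.", "#...#", "....#", "..##.", "....#", "#...#", ".###."),
  "4" = c("...#.", "..##.", ".#.#.", "#..#.", "#####", "...#.", "...#."),
  "5" = c("#####", "#....", "####.", "....#", "....#", "#...#", ".###."),
  "6" = c("..##.", ".#...", "#....", "####.", "#...#", "#...#", ".###."),
  "7" = c("#####", "....#", "...#.", "..#..", ".#...", ".#...", ".#..."),
  "8" = c(".###.", "#...#", "#...#", ".###.", "#...#", "#...#", ".###."),
  "9" = c(".###.", "#...#", "#...#", ".####", "....#", "...#.", ".##.."),
  "." = c(".....", ".....", ".....", ".....", ".....", ".##..", ".##.."),
  ":" = c(".....", ".##..", ".##..", ".....", ".##..", ".##..", "....."),
  "," = c(".....", ".....", ".....", ".....", ".##..", "..#..", ".#..."),
  "×" = c(".....", "#...#", ".#.#.", "..#..", ".#.#.", "#...#", "....."),
  "a" = c(".....", ".....", ".###.", "....#", ".####", "#...#", ".####"),
  "b" = c("#....", "#....", "####.", "#...#", "#...#", "#...#", "####."),
  "h" = c("#....", "#....", "####.", "#...#", "#...#", "#...#", "#...#"),
  "k" = c("#....", "#....", "#..#.", "#.#..", "##...", "#.#..", "#..#.")
)

# glyph cell geometry, in font units
.busrep_font_units <- list(width = 5L, height = 7L, advance = 6L)

#' @keywords internal
glyph_matrix <- function(ch) {
  rows <- .busrep_glyphs[[ch]]
  if (is.null(rows)) {
    stop("no glyph for character ", sQuote(ch), call. = FALSE)
  }
  do.call(rbind, lapply(strsplit(rows, ""), function(r) r == "#"))
}

# pattern string -> character lookup, keyed on the 7-row, ink-cropped bitmap
.busrep_env <- new.env(parent = emptyenv())

glyph_lookup <- function() {
  if (is.null(.busrep_env$lookup)) {
    tbl <- new.env(parent = emptyenv())
    for (ch in names(.busrep_glyphs)) {
      g <- glyph_matrix(ch)
      cols <- which(colSums(g) > 0)
      key <- paste(as.integer(g[, min(cols):max(cols), drop = FALSE]),
                   collapse = "")
      assign(key, ch, envir = tbl)
    }
    .busrep_env$lookup <- tbl
  }
  .busrep_env$lookup
}

# ink column offset (in units) of a glyph's leftmost ink column
glyph_ink_offset <- function(ch) {
  g <- glyph_matrix(ch)
  min(which(colSums(g) > 0)) - 1L
}

#' Render text into a pixel array with the packaged bitmap font
#'
#' Stamps each glyph as `scale`-by-`scale` pixel blocks; characters advance by
#' 6 font units, a space by one full advance. Characters without a glyph
#' raise an error. Used by the fixture generator for burned-in annotations
#' and the "kPa" legend label.
#'
#' @param px H x W x 3 numeric array, intensities in 0..255.
#' @param text string to render (single line).
#' @param row,col 1-based pixel position of the text's top-left corner.
#' @param scale integer pixel size of one font unit.
#' @param value intensity written into all three channels (white text keeps
#'   grayscale frames grayscale).
#' @return the modified pixel array.
#' @keywords internal
render_text <- function(px, text, row, col, scale = 2L, value = 255) {
  chars <- strsplit(text, "")[[1]]
  adv <- .busrep_font_units$advance * scale
  x <- col
  for (ch in chars) {
    if (ch == " ") {
      x <- x + adv
      next
    }
    g <- glyph_matrix(ch)
    ink <- which(g, arr.ind = TRUE)
    for (i in seq_len(nrow(ink))) {
      r0 <- row + (ink[i, 1] - 1L) * scale
      c0 <- x + (ink[i, 2] - 1L) * scale
      px[r0:(r0 + scale - 1L), c0:(c0 + scale - 1L), ] <- value
    }
    x <- x + adv
  }
  px
}

# pixel width of a rendered string
text_pixel_width <- function(text, scale = 2L) {
  nchar(text) * .busrep_font_units$advance * scale
}
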