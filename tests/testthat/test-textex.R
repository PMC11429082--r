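test_that("band cropping takes exactly the bottom third", {
  px <- array(0, c(970, 40, 3))
  px[647:970, , 1] <- 7  # 1-based rows 647..970 = 0-based 646..969
  band <- crop_text_band(px)
  expect_equal(dim(band), c(324, 40, 3))
  expect_true(all(band[, , 1] == 7))
  expect_equal(dim(crop_text_band(array(0, c(3, 10, 3))))[1], 1)
})

test_that("the template recognizer reads rendered annotations exactly", {
  spec <- small_spec(seed = 21)
  s <- make_scan(spec, "B_MODE",
                 list(annotation_text = "LEFT 2:00 5CM"))
  toks <- recognize(crop_text_band(s))
  expect_identical(toks$text, c("LEFT", "2:00", "5CM"))
  expect_true(all(toks$confidence == 1))
  # tokens ordered left to right
  expect_true(all(diff(toks$left) > 0))
  # empty band
  expect_equal(nrow(recognize(flat_gray(60, 200))), 0)
})

test_that("recognition of corrupted renderings matches the injected string", {
  s <- make_scan(small_spec(seed = 8, confusion_injection_rate = 1),
                 "B_MODE", list(annotation_text = "LEFT 2:00 5CM"))
  expect_identical(s$truth$rendered_text, "LEFT Z:00 SCM")
  toks <- recognize(crop_text_band(s))
  expect_identical(toks$text, c("LEFT", "Z:00", "SCM"))
  mock <- recognizer_mock(rate = 1, seed = 8)
  mtoks <- recognize(flat_gray(10, 10), mock, truth_text = "LEFT 2:00 5CM")
  expect_identical(mtoks$text, c("LEFT", "Z:00", "SCM"))
})

test_that("confusion correction fixes numeric contexts and spares words", {
  fix <- function(x) apply_confusion_correction(x)
  expect_identical(fix(c("1.S", "cm")), c("1.5", "cm"))
  expect_identical(fix(c("SCM")), c("5CM"))
  expect_identical(fix(c("Z:00")), c("2:00"))
  expect_identical(fix(c("bCM")), c("6CM"))
  expect_identical(fix(c("SIZE")), c("SIZE"))
  expect_identical(fix(c("RIGHT", "Z", "h,", "b", "CM")),
                   c("RIGHT", "2", "h,", "6", "CM"))
  # correction is idempotent
  corpus <- list(c("LEFT", "Z:00", "SCM"), c("0.4I", "×", "I.Z", "CM"),
                 c("RIGHT", "IZ", "h,", "SCM", "LO"))
  for (toks in corpus) {
    once <- fix(toks)
    expect_identical(fix(once), once)
  }
})

test_that("corrupt -> recognize -> correct recovers every fixture string", {
  corpus <- make_annotation_strings(60, seed = 14)
  rates <- rep(c(0.25, 0.5, 0.75, 1), length.out = nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    truth <- corpus$text[i]
    mock <- recognizer_mock(rate = rates[i], seed = 900 + i)
    toks <- recognize(flat_gray(10, 10), mock, truth_text = truth)
    corrected <- apply_confusion_correction(toks)
    expect_equal(
      character_error_rate(paste(corrected$text, collapse = " "), truth), 0)
  }
})

test_that("parsing recovers location key, size, and qualifiers", {
  p <- clean_and_parse(c("RIGHT", "9", "h,", "6", "CM"))
  expect_identical(p$location$side, "RIGHT")
  expect_equal(p$location$clock_hour, 9)
  expect_equal(p$location$clock_minute, 0)
  expect_equal(p$location$depth_cm, 6)
  expect_null(p$size)

  p2 <- clean_and_parse(c("0.41", "×", "1.2", "cm"))
  expect_equal(p2$size$dims_cm, c(0.41, 1.2))
  expect_null(p2$location)

  p3 <- clean_and_parse(c("LEFT", "2:00", "5CM", "LO"))
  expect_identical(p3$location$side, "LEFT")
  expect_equal(p3$location$clock_hour, 2)
  expect_equal(p3$location$clock_minute, 0)
  expect_equal(p3$location$depth_cm, 5)
  expect_identical(p3$location$qualifiers, "LO")

  # half-hour clock dialect
  p4 <- clean_and_parse(c("LEFT", "11:30", "h,", "4", "CM"))
  expect_equal(p4$location$clock_hour, 11)
  expect_equal(p4$location$clock_minute, 30)

  expect_error(clean_and_parse(c("LEFT", "RIGHT", "5CM")), "contradictory")
  # unparseable fields are NULL, never a guess
  p5 <- clean_and_parse(c("LEFT", "5CM"))
  expect_null(p5$location)
  expect_null(p5$size)
})

test_that("parsing never errors on arbitrary token soup", {
  set.seed(77)
  alphabet <- c(LETTERS, 0:9, ".", ":", ",", "×", "CM", "h", "cm", "")
  for (i in 1:60) {
    toks <- sample(alphabet, sample(1:8, 1), replace = TRUE)
    if (sum(toupper(toks) %in% c("LEFT", "RIGHT")) > 1) next
    expect_no_error(clean_and_parse(toks))
  }
})

test_that("character error rate is normalized Levenshtein distance", {
  expect_equal(character_error_rate("LEFT 2:00 5CM", "LEFT 2:00 5CM"), 0)
  expect_equal(character_error_rate("LEFT Z:00 SCM", "LEFT 2:00 5CM"),
               2 / 13 * 100)
  expect_equal(character_error_rate("", "ABCD"), 100)
  expect_error(character_error_rate("x", ""), "non-empty")
  # agreement with an independent DP oracle on random string pairs
  set.seed(5)
  pool <- c(LETTERS[1:6], 0:3, " ", ".")
  for (i in 1:100) {
    a <- paste(sample(pool, sample(0:12, 1), TRUE), collapse = "")
    b <- paste(sample(pool, sample(1:12, 1), TRUE), collapse = "")
    expect_equal(character_error_rate(a, b),
                 oracle_lev(a, b) / nchar(b) * 100)
  }
})

test_that("the confusion matrix round-trips through its CSV format", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_confusion_matrix(default_confusion_matrix(), path)
  back <- read_confusion_matrix(path)
  expect_equal(back, default_confusion_matrix())
  shipped <- read_confusion_matrix(
    system.file("extdata", "confusion_matrix.csv", package = "busrep"))
  expect_equal(shipped, default_confusion_matrix())
})
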