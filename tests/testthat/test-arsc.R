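records_fixture <- function() {
  tibble::tibble(
    path = paste0("s", 1:6),
    mode = c("B_MODE", "SWE", "B_MODE", "SWE", "DOPPLER", "B_MODE"),
    stiffness = c(NA, "POSITIVE", NA, "NEGATIVE", NA, NA),
    side = c("LEFT", "LEFT", "RIGHT", "RIGHT", "RIGHT", NA),
    clock_hour = c(2L, 2L, 9L, 9L, 9L, NA),
    clock_minute = c(0L, 0L, 0L, 0L, 0L, NA),
    depth_cm = c(5, 5, 6, 6, 6, NA),
    qualifiers = list(character(), "LO", character(), character(),
                      character(), character()),
    size_dims = list(c(0.8), NULL, c(0.41, 1.2), NULL, NULL, NULL)
  )
}

test_that("grouping partitions location-bearing records by normalized key", {
  groups <- group_scans(records_fixture())
  expect_equal(nrow(groups), 2)  # qualifier twin joins its group
  expect_equal(groups$n_members, c(2L, 3L))
  # partition: every located record in exactly one group
  expect_equal(sum(groups$n_members), 5)
  expect_identical(groups$swe_class, c("POSITIVE", "NEGATIVE"))
  expect_equal(groups$size_dims[[2]], c(0.41, 1.2))
  expect_equal(nrow(group_scans(records_fixture()[0, ])), 0)
})

test_that("group ordering and depth tolerance behave as documented", {
  recs <- records_fixture()[c(3, 1), ]
  g <- group_scans(recs)
  expect_identical(g$side, c("LEFT", "RIGHT"))  # LEFT first
  # near-miss depths merge only under a tolerance
  recs2 <- records_fixture()
  recs2$depth_cm[4] <- 6.2
  expect_equal(nrow(group_scans(recs2)), 3)
  expect_equal(nrow(group_scans(recs2, depth_tol = 0.5)), 2)
})

test_that("the findings template renders the canonical worked example", {
  sentence <- formulate_sentence(list(
    side = "RIGHT", clock_hour = 9L, clock_minute = 0L, depth_cm = 6,
    size_dims = c(0.41, 1.2), doppler_class = NA_character_,
    swe_class = "positive", se_class = NA_character_
  ))
  expect_identical(
    sentence$rendered,
    paste0("0.41 × 1.2 cm mass in RIGHT 9 h, 6 CM from nipple Doppler (), ",
           "Shearwave Elastography (positive), Strain Elastography (), ",
           "Category ()")
  )
  # integer depth renders without a decimal point
  expect_match(sentence$rendered, " 6 CM ", fixed = TRUE)
  expect_true("category" %in% sentence$pending)
  expect_false("size" %in% sentence$pending)

  blank <- formulate_sentence(list(side = "LEFT", clock_hour = 3L,
                                   clock_minute = 0L, depth_cm = 4,
                                   size_dims = NULL,
                                   doppler_class = NA, swe_class = NA,
                                   se_class = NA))
  expect_match(blank$rendered, "^\\(\\) mass in LEFT 3 h, 4 CM")
  expect_setequal(blank$pending, c("size", "doppler", "swe", "se",
                                   "category"))
})

test_that("rendered sentences parse back to their structured slots", {
  groups <- group_scans(records_fixture())
  for (i in seq_len(nrow(groups))) {
    s <- formulate_sentence(groups[i, ])
    back <- parse_report_sentence(s$rendered)
    expect_identical(back$rendered, s$rendered)
    expect_identical(back$side, s$side)
    expect_equal(back$depth_cm, s$depth_cm)
  }
  expect_error(parse_report_sentence("not a sentence"), "not a findings")
})

test_that("report compilation writes deterministic text plus JSON sidecar", {
  groups <- group_scans(records_fixture())
  dir <- withr::local_tempdir()
  path <- file.path(dir, "report.txt")
  r1 <- compile_report("P9", groups, path = path)
  bytes1 <- readBin(path, "raw", file.size(path))
  r2 <- compile_report("P9", groups, path = path)
  bytes2 <- readBin(path, "raw", file.size(path))
  expect_identical(bytes1, bytes2)
  expect_length(r1$sentences, 2)
  expect_identical(tidy(r1)$rendered,
                   purrr::map_chr(r2$sentences, "rendered"))
  sidecar <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_length(sidecar$sentences, 2)
  # zero groups: header still written, findings empty
  r0 <- compile_report("P0", list(), path = file.path(dir, "empty.txt"))
  lines <- readLines(file.path(dir, "empty.txt"))
  expect_identical(lines, c("Patient: P0", "Findings:"))
})

test_that("report matching compares location key and elastography types", {
  gen <- formulate_sentence(list(side = "RIGHT", clock_hour = 9L,
                                 clock_minute = 0L, depth_cm = 6,
                                 size_dims = c(1.1),
                                 doppler_class = NA, swe_class = "positive",
                                 se_class = NA))
  truth <- formulate_sentence(list(side = "RIGHT", clock_hour = 9L,
                                   clock_minute = 0L, depth_cm = 6,
                                   size_dims = c(2.2),
                                   doppler_class = NA,
                                   swe_class = "negative", se_class = NA))
  expect_true(match_report(gen, gen))
  expect_true(match_report(gen, truth))  # class value not compared
  no_swe <- formulate_sentence(list(side = "RIGHT", clock_hour = 9L,
                                    clock_minute = 0L, depth_cm = 6,
                                    size_dims = NULL, doppler_class = NA,
                                    swe_class = NA, se_class = NA))
  expect_false(match_report(gen, no_swe))
  deeper <- formulate_sentence(list(side = "RIGHT", clock_hour = 9L,
                                    clock_minute = 0L, depth_cm = 5,
                                    size_dims = NULL, doppler_class = NA,
                                    swe_class = "positive", se_class = NA))
  expect_false(match_report(deeper, gen))
})

test_that("match ratio counts matched truth sentences, pooled and per patient", {
  mk_report <- function(id, hours, swe = TRUE) {
    groups <- purrr::map(hours, ~ list(
      side = "LEFT", clock_hour = .x, clock_minute = 0L, depth_cm = 3,
      size_dims = c(1.1), doppler_class = NA,
      swe_class = if (swe) "positive" else NA, se_class = NA))
    compile_report(id, groups)
  }
  truth <- mk_report("A", c(1, 2, 3, 4))
  gen <- mk_report("A", c(1, 2, 3, 8))  # 3 of 4 match
  res <- report_match_ratio(list(list(generated = gen, truth = truth)))
  expect_equal(res$pooled, 0.75)
  expect_equal(res$per_patient$n_matched, 3L)
  full <- report_match_ratio(list(list(generated = truth, truth = truth)))
  expect_equal(full$pooled, 1.0)
  none <- report_match_ratio(list(list(
    generated = mk_report("A", c(1, 2), swe = FALSE), truth = truth)))
  expect_equal(none$pooled, 0)
})
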