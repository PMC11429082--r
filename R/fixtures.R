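#' Specification of a synthetic patient study
#'
#' The fixture generator emulates the burned-in layout of a single-vendor
#' breast ultrasound export: grayscale B-mode speckle, Doppler frames with
#' small irregular colored flow blobs, shear-wave elastography (SWE) frames
#' with a vertical color legend bar labeled "kPa" and a large rectangular
#' colored stiffness ROI, strain elastography (SE) frames with the bar but
#' no unit label, and operator annotations ("LEFT 2:00 5CM") rendered in a
#' packaged bitmap font in the bottom third of the frame. Every generated
#' object carries its ground truth so downstream stages are testable
#' without clinical data.
#'
#' @param patient_id patient identifier.
#' @param n_lesions number of annotated lesions (>= 0); the study contains
#'   exactly this many distinct normalized (side, clock, depth) keys.
#' @param modes_per_lesion modes scanned for each lesion (subset of
#'   [mode_labels()]).
#' @param image_size `c(height, width)` in pixels; the default matches the
#'   roughly 1292 x 970 export resolution of the emulated scanner.
#' @param seed integer; identical specs (including seed) generate
#'   byte-identical images and strings.
#' @param confusion_injection_rate fraction in \[0,1\]: probability that each
#'   confusable character of the *rendered* annotation is replaced by its
#'   OCR confusion partner (5->S, 1->I, 2->Z, 6->b), emulating upstream
#'   recognition errors burned into the text the recognizer will read.
#' @param n_distractors number of extra frames without annotations
#'   (`NULL` = seeded choice of 0..4); grouping must ignore them.
#' @param roi_jitter_sd standard deviation of the per-ROI jitter on the
#'   high-stiffness color fraction (0 = noiseless class encoding).
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(patient_id = "P001",
                         n_lesions = 1L,
                         modes_per_lesion = c("B_MODE", "SWE"),
                         image_size = c(970L, 1292L),
                         seed = 1L,
                         confusion_injection_rate = 0,
                         n_distractors = NULL,
                         roi_jitter_sd = 0) {
  stopifnot(n_lesions >= 0, all(modes_per_lesion %in% mode_labels()),
            length(image_size) == 2L,
            confusion_injection_rate >= 0, confusion_injection_rate <= 1)
  structure(
    list(patient_id = patient_id, n_lesions = as.integer(n_lesions),
         modes_per_lesion = modes_per_lesion,
         image_size = as.integer(image_size), seed = as.integer(seed),
         confusion_injection_rate = confusion_injection_rate,
         n_distractors = n_distractors,
         roi_jitter_sd = roi_jitter_sd),
    class = "fixture_spec"
  )
}

# Stiffness color encoding of synthetic SWE ROIs: each ROI pixel is drawn
# from the high-stiffness (red) band with probability p and the
# low-stiffness (blue) band otherwise. The emulated scanner colormap is not
# a reproduction of any vendor's.
.busrep_stiffness_p <- c(NEGATIVE = 0.1, EQUIVOCAL = 0.5, POSITIVE = 0.9)

# sample nr x nc ROI pixels: red-family vs blue-family
roi_pixels <- function(nr, nc, p_high) {
  n <- nr * nc
  high <- stats::runif(n) < p_high
  r <- ifelse(high, stats::runif(n, 200, 255), stats::runif(n, 0, 60))
  g <- ifelse(high, stats::runif(n, 0, 80),  stats::runif(n, 40, 100))
  b <- ifelse(high, stats::runif(n, 0, 60),  stats::runif(n, 180, 255))
  array(c(r, g, b), c(nr, nc, 3L))
}

speckle_background <- function(h, w) {
  g <- matrix(stats::runif(h * w, 20, 160), h, w)
  array(rep(g, 3L), c(h, w, 3L))
}

# stamp a dark elliptical lesion into the grayscale background
add_lesion_ellipse <- function(px, rows) {
  h <- length(rows); w <- dim(px)[2]
  cy <- stats::runif(1, 0.3, 0.7) * h
  cx <- stats::runif(1, 0.2, 0.6) * w
  ry <- stats::runif(1, 0.05, 0.12) * h
  rx <- stats::runif(1, 0.05, 0.12) * w
  rr <- outer(seq_len(h) - cy, rep(1, w)) / ry
  cc <- outer(rep(1, h), seq_len(w) - cx) / rx
  inside <- rr^2 + cc^2 <= 1
  val <- stats::runif(1, 10, 60)
  for (ch in 1:3) {
    plane <- px[rows, , ch]
    plane[inside] <- val
    px[rows, , ch] <- plane
  }
  px
}

# thick diagonal stroke: deterministic irregular (non-rectangular) blob
add_doppler_blob <- function(px, region_h, w) {
  len <- max(30, round(0.14 * min(region_h, w)))
  thick <- max(5, round(len / 7))
  r0 <- round(stats::runif(1, 0.15, 0.6) * region_h)
  c0 <- round(stats::runif(1, 0.15, 0.6) * w)
  col <- if (stats::runif(1) < 0.5) c(230, 40, 40) else c(50, 60, 230)
  for (i in seq_len(len)) {
    rr <- r0 + i
    cc <- (c0 + i):(c0 + i + thick - 1L)
    cc <- cc[cc >= 1 & cc <= w]
    if (rr < 1 || rr > region_h || length(cc) == 0) next
    jit <- stats::runif(3, -20, 20)
    px[rr, cc, 1] <- pmin(255, pmax(0, col[1] + jit[1]))
    px[rr, cc, 2] <- pmin(255, pmax(0, col[2] + jit[2]))
    px[rr, cc, 3] <- pmin(255, pmax(0, col[3] + jit[3]))
  }
  px
}

# vertical rainbow legend bar touching the right strip; returns its bbox
add_legend_bar <- function(px, h, w) {
  bw <- max(6L, round(0.008 * w))
  bh <- round(0.35 * h)
  top <- round(0.12 * h)
  left <- round(0.93 * w)
  hue <- seq(0, 0.66, length.out = bh)  # red (stiff) down to blue (soft)
  rgb <- grDevices::hsv(hue, 1, 1)
  cols <- grDevices::col2rgb(rgb)
  for (i in seq_len(bh)) {
    px[top + i - 1L, left:(left + bw - 1L), 1] <- cols[1, i]
    px[top + i - 1L, left:(left + bw - 1L), 2] <- cols[2, i]
    px[top + i - 1L, left:(left + bw - 1L), 3] <- cols[3, i]
  }
  list(px = px, bbox = list(top = top, left = left, height = bh, width = bw))
}

#' Generate one synthetic scan frame
#'
#' Renders a frame realizing the visual attributes the mode classifier keys
#' on: B-mode frames are exactly grayscale; Doppler frames contain small
#' irregular colored blobs (colored fraction below the Doppler density
#' threshold); SWE frames contain a vertical color legend bar with an
#' adjacent "kPa" label and one large axis-aligned rectangular colored ROI
#' whose color mix encodes the stiffness class; SE frames are structurally
#' identical minus the "kPa" text. The annotation string (if any) is
#' rendered in the bottom third, after optional confusion injection at the
#' spec's rate.
#'
#' @param spec a [fixture_spec()].
#' @param mode one of [mode_labels()].
#' @param truth ground-truth list with elements `annotation_text` (string,
#'   may be empty), `true_class` (stiffness class or `NULL`), plus any
#'   parsed fields the caller wants to carry along.
#' @param scan_seed seed for this frame (defaults to `spec$seed`).
#' @return a `bus_scan` whose `truth` records `true_mode`, `true_class`,
#'   `annotation_text` (the clean string), `rendered_text` (after confusion
#'   injection) and, for SWE/SE/Doppler frames, the generated ROI bounding
#'   box `roi_bbox`.
#' @export
make_scan <- function(spec, mode, truth = list(annotation_text = ""),
                      scan_seed = spec$seed) {
  if (!mode %in% mode_labels()) {
    stop("unsupported mode: ", mode, call. = FALSE)
  }
  h <- spec$image_size[1]; w <- spec$image_size[2]
  stopifnot(h >= 300, w >= 300)
  with_seed_(scan_seed, {
    px <- speckle_background(h, w)
    region <- scan_region_rows(h)
    px <- add_lesion_ellipse(px, region)
    roi_bbox <- NULL
    if (mode == "DOPPLER") {
      px <- add_doppler_blob(px, length(region), w)
    } else if (mode %in% c("SWE", "SE")) {
      res <- add_legend_bar(px, h, w)
      px <- res$px
      bar <- res$bbox
      if (mode == "SWE") {
        kpa_row <- max(1L, bar$top - 30L)
        kpa_col <- max(1L, bar$left - 40L)
        px <- render_text(px, "kPa", kpa_row, kpa_col, scale = 2L)
      }
      # large rectangular stiffness ROI, clear of the bar and the text band
      rh <- round(stats::runif(1, 0.22, 0.34) * h)
      rw <- round(stats::runif(1, 0.22, 0.34) * w)
      top <- round(stats::runif(1, 0.08, 0.55) * h)
      top <- min(top, max(region) - rh)
      left <- round(stats::runif(1, 0.05, 0.5) * w)
      left <- min(left, round(0.88 * w) - rw)
      p_high <- if (mode == "SWE" && !is.null(truth$true_class)) {
        .busrep_stiffness_p[[truth$true_class]]
      } else 0.3
      p_high <- min(0.98, max(0.02,
        p_high + stats::rnorm(1, 0, spec$roi_jitter_sd)))
      px[top:(top + rh - 1L), left:(left + rw - 1L), ] <-
        roi_pixels(rh, rw, p_high)
      roi_bbox <- c(top = top, left = left, height = rh, width = rw)
    }
    ann <- truth$annotation_text %||% ""
    rendered <- ann
    if (nzchar(ann)) {
      rendered <- inject_confusions(ann, spec$confusion_injection_rate,
                                    scan_seed)
      px <- render_annotation(px, rendered, h, w)
    }
    tr <- truth
    tr$true_mode <- mode
    tr$annotation_text <- ann
    tr$rendered_text <- rendered
    tr$roi_bbox <- roi_bbox
    bus_scan(px, patient_id = spec$patient_id, truth = tr)
  })
}

# render (and wrap, if needed) the annotation into the bottom-third band
render_annotation <- function(px, text, h, w, scale = 2L) {
  band_top <- floor(2 * h / 3) + 1L
  margin <- 24L
  max_px <- w - 2L * margin
  words <- strsplit(text, " ")[[1]]
  lines <- character(0)
  cur <- ""
  for (wd in words) {
    cand <- if (nzchar(cur)) paste(cur, wd) else wd
    if (text_pixel_width(cand, scale) > max_px && nzchar(cur)) {
      lines <- c(lines, cur)
      cur <- wd
    } else cur <- cand
  }
  lines <- c(lines, cur)
  row <- band_top + 20L
  for (ln in lines) {
    px <- render_text(px, ln, row, margin, scale = scale)
    row <- row + (.busrep_font_units$height + 4L) * scale
  }
  px
}

#' Inject OCR-style character confusions into a string
#'
#' The inverse of the documented confusion pairs: each occurrence of the
#' digits 5, 1, 2, 6 is independently replaced by S, I, Z, b with
#' probability `rate`. Only characters present in the confusion table are
#' eligible; deterministic under a fixed seed.
#'
#' @param text input string.
#' @param rate fraction in \[0, 1\].
#' @param seed integer seed.
#' @return the corrupted string.
#' @export
inject_confusions <- function(text, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  pairs <- c("5" = "S", "1" = "I", "2" = "Z", "6" = "b")
  chars <- strsplit(text, "")[[1]]
  eligible <- chars %in% names(pairs)
  if (!any(eligible) || rate == 0) return(text)
  with_seed_(seed, {
    hit <- eligible & (stats::runif(length(chars)) < rate)
    chars[hit] <- pairs[chars[hit]]
  })
  paste(chars, collapse = "")
}

# --- study-level generation --------------------------------------------

clock_to_text <- function(hour, minute) {
  if (minute == 0) as.character(hour) else sprintf("%d:%02d", hour, minute)
}

# annotation string for a lesion, in one of the two emulated operator
# dialects; optionally with a qualifier and/or a size suffix
annotation_string <- function(loc, style, qualifier = NULL, size = NULL) {
  base <- if (style == "colon") {
    sprintf("%s %d:%02d %dCM", loc$side, loc$clock_hour, loc$clock_minute,
            loc$depth_cm)
  } else {
    sprintf("%s %s h, %d CM", loc$side, clock_to_text(loc$clock_hour,
            loc$clock_minute), loc$depth_cm)
  }
  if (!is.null(qualifier)) base <- paste(base, qualifier)
  if (!is.null(size)) {
    base <- paste(base, paste0(paste(
      vapply(size, function(d) format(d, trim = TRUE), character(1)),
      collapse = " × "), " CM"))
  }
  base
}

#' Generate a synthetic patient study with ground truth
#'
#' Produces one frame per (lesion, mode) pair plus unannotated distractor
#' frames, and the ground-truth findings report (one sentence per annotated
#' lesion). Lesions receive distinct normalized (side, clock, depth) keys;
#' annotation dialect ("2:00" vs "9 h"), qualifiers on repeat scans, sizes,
#' and stiffness classes are drawn under the spec's seed, so identical
#' specs yield byte-identical studies.
#'
#' @param spec a [fixture_spec()].
#' @return a list with elements `scans` (list of `bus_scan`), `truth_report`
#'   (a `bus_report`, see [compile_report()]) and `truth` (a tibble of
#'   per-lesion ground truth).
#' @export
make_patient_study <- function(spec) {
  n <- spec$n_lesions
  with_seed_(spec$seed, {
    # distinct location keys
    keys <- tibble::tibble(side = character(), clock_hour = integer(),
                           clock_minute = integer(), depth_cm = integer())
    while (nrow(keys) < n) {
      cand <- tibble::tibble(
        side = sample(c("LEFT", "RIGHT"), 1),
        clock_hour = sample(1:12, 1),
        clock_minute = sample(c(0L, 30L), 1, prob = c(0.8, 0.2)),
        depth_cm = sample(1:12, 1)
      )
      keys <- dplyr::distinct(dplyr::bind_rows(keys, cand))
    }
    lesions <- keys |>
      dplyr::mutate(
        style = sample(c("colon", "hour"), dplyr::n(), replace = TRUE),
        true_class = sample(stiffness_classes(), dplyr::n(), replace = TRUE),
        size = purrr::map(seq_len(dplyr::n()), function(i) {
          nd <- sample(1:2, 1)
          d <- round(stats::runif(nd, 0.2, 3.4), sample(1:2, 1))
          # sizes are annotated as decimals; depths as integers — keep the
          # grammar unambiguous
          d[d == round(d)] <- d[d == round(d)] + 0.1
          d
        })
      )
    n_extra <- spec$n_distractors %||% sample(0:4, 1)
    scan_plan <- list()
    for (i in seq_len(n)) {
      loc <- as.list(lesions[i, c("side", "clock_hour", "clock_minute",
                                  "depth_cm")])
      modes <- spec$modes_per_lesion
      for (j in seq_along(modes)) {
        qualifier <- if (j > 1 && stats::runif(1) < 0.5) {
          sample(c("LO", "UO", "MED", "LAT"), 1)
        } else NULL
        size <- if (j == 1) lesions$size[[i]] else NULL
        ann <- annotation_string(loc, lesions$style[i], qualifier, size)
        scan_plan[[length(scan_plan) + 1L]] <- list(
          mode = modes[j], lesion = i,
          truth = list(
            annotation_text = ann,
            true_class = if (modes[j] == "SWE") lesions$true_class[i]
                         else NULL,
            location = c(loc, list(qualifiers = qualifier %||% character())),
            size = size
          )
        )
      }
    }
    for (k in seq_len(n_extra)) {
      scan_plan[[length(scan_plan) + 1L]] <- list(
        mode = sample(c("B_MODE", "DOPPLER"), 1), lesion = NA_integer_,
        truth = list(annotation_text = "", true_class = NULL)
      )
    }
    seeds <- spec$seed + 1000L + seq_along(scan_plan)
    scans <- purrr::map2(scan_plan, seeds, function(pl, sd) {
      make_scan(spec, pl$mode, pl$truth, scan_seed = sd)
    })
    truth_groups <- purrr::map(seq_len(n), function(i) {
      list(side = lesions$side[i], clock_hour = lesions$clock_hour[i],
           clock_minute = lesions$clock_minute[i],
           depth_cm = as.numeric(lesions$depth_cm[i]),
           size_dims = lesions$size[[i]],
           doppler_class = NA_character_,
           swe_class = if ("SWE" %in% spec$modes_per_lesion) {
             tolower(lesions$true_class[i])
           } else NA_character_,
           se_class = NA_character_)
    })
    truth_report <- compile_report(spec$patient_id, truth_groups)
    list(scans = scans, truth_report = truth_report,
         truth = dplyr::mutate(lesions, lesion = dplyr::row_number()))
  })
}

#' Write a study to disk as PNG frames plus a ground-truth sidecar
#'
#' @param study output of [make_patient_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly. Frames are written as `scan_###.png`; ground
#'   truth (per-frame annotation strings, modes, classes, and the truth
#'   report text) as `truth.json`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(study$scans))
  for (i in seq_along(study$scans)) {
    paths[i] <- file.path(dir, sprintf("scan_%03d.png", i))
    write_scan_png(study$scans[[i]], paths[i])
  }
  truth <- list(
    patient_id = study$scans[[1]]$patient_id %||% NA_character_,
    frames = purrr::map2(paths, study$scans, function(p, s) {
      list(path = basename(p), true_mode = s$truth$true_mode,
           true_class = s$truth$true_class,
           annotation_text = s$truth$annotation_text,
           rendered_text = s$truth$rendered_text)
    }),
    truth_report = study$truth_report$text
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}

#' Generate a corpus of annotation strings with ground truth
#'
#' Samples operator annotation strings (both dialects, with qualifiers and
#' sizes at realistic rates) without rendering any pixels — the input for
#' recognition/correction experiments at corpus scale.
#'
#' @param n number of strings.
#' @param seed integer seed.
#' @return a tibble with columns `text` (the clean annotation), `side`,
#'   `clock_hour`, `clock_minute`, `depth_cm`.
#' @export
make_annotation_strings <- function(n, seed = 1L) {
  with_seed_(seed, {
    purrr::map_dfr(seq_len(n), function(i) {
      loc <- list(side = sample(c("LEFT", "RIGHT"), 1),
                  clock_hour = sample(1:12, 1),
                  clock_minute = sample(c(0L, 30L), 1, prob = c(0.8, 0.2)),
                  depth_cm = sample(1:12, 1))
      qualifier <- if (stats::runif(1) < 0.3) {
        sample(c("LO", "UO", "MED", "LAT"), 1)
      } else NULL
      size <- if (stats::runif(1) < 0.5) {
        nd <- sample(1:2, 1)
        d <- round(stats::runif(nd, 0.2, 3.4), sample(1:2, 1))
        d[d == round(d)] <- d[d == round(d)] + 0.1
        d
      } else NULL
      tibble::tibble(
        text = annotation_string(loc, sample(c("colon", "hour"), 1),
                                 qualifier, size),
        side = loc$side, clock_hour = loc$clock_hour,
        clock_minute = loc$clock_minute, depth_cm = loc$depth_cm
      )
    })
  })
}

#' Generate synthetic stiffness ROIs
#'
#' Stand-alone ROI sampler for classifier experiments: each ROI is a small
#' rectangle of stiffness-colormap pixels whose high-stiffness fraction
#' encodes the class (0.1 / 0.5 / 0.9 for negative / equivocal / positive)
#' plus optional per-ROI Gaussian jitter.
#'
#' @param counts named vector of ROIs per class (names from
#'   [stiffness_classes()]).
#' @param jitter_sd per-ROI jitter on the high-stiffness fraction.
#' @param seed integer seed.
#' @return a tibble with list-column `roi` (`bus_roi` objects) and column
#'   `class`, in shuffled order.
#' @export
make_roi_set <- function(counts = c(NEGATIVE = 100, EQUIVOCAL = 100,
                                    POSITIVE = 100),
                         jitter_sd = 0, seed = 1L) {
  stopifnot(all(names(counts) %in% stiffness_classes()))
  with_seed_(seed, {
    rows <- purrr::imap(counts, function(k, cls) {
      purrr::map(seq_len(k), function(i) {
        nr <- sample(60:140, 1); nc <- sample(60:140, 1)
        p <- min(0.98, max(0.02, .busrep_stiffness_p[[cls]] +
                             stats::rnorm(1, 0, jitter_sd)))
        list(roi = bus_roi(roi_pixels(nr, nc, p),
                           origin_bbox = c(top = 1L, left = 1L,
                                           height = nr, width = nc)),
             class = cls)
      })
    })
    flat <- purrr::flatten(rows)
    out <- tibble::tibble(
      roi = purrr::map(flat, "roi"),
      class = purrr::map_chr(flat, "class")
    )
    out[sample(nrow(out)), ]
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
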