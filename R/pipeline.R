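#' Pipeline configuration
#'
#' The effective configuration of a report-generation run: mode-classifier
#' thresholds, confusion matrix, recognizer backend, stiffness model, and
#' seed. [run_pipeline()] echoes the effective config into the output
#' directory as JSON so runs are reproducible.
#'
#' @param icvf an [icvf_config()].
#' @param confusion confusion-matrix tibble or path to its CSV.
#' @param recognizer `"template"` or a `bus_recognizer`.
#' @param model a `bus_classifier`, a path to a serialized one, or `NULL`
#'   for the deterministic color baseline.
#' @param depth_tol grouping depth tolerance in cm (default 0 = exact).
#' @param seed integer seed recorded with the run.
#' @param out_dir optional output directory for the report, stage CSVs and
#'   the echoed config.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(icvf = icvf_config(),
                            confusion = default_confusion_matrix(),
                            recognizer = "template",
                            model = NULL,
                            depth_tol = 0,
                            seed = 1L,
                            out_dir = NULL) {
  if (is.character(confusion)) confusion <- read_confusion_matrix(confusion)
  if (is.character(recognizer)) {
    recognizer <- switch(recognizer,
      template = recognizer_template(),
      stop("unknown recognizer backend: ", recognizer, call. = FALSE))
  }
  if (is.character(model)) model <- read_classifier(model)
  if (is.null(model)) model <- color_baseline_model()
  structure(
    list(icvf = icvf, confusion = confusion, recognizer = recognizer,
         model = model, depth_tol = depth_tol, seed = as.integer(seed),
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Build per-scan records from classified, annotated frames
#'
#' @param scans list of `bus_scan` objects.
#' @param cfg a [pipeline_config()].
#' @return a tibble with one row per scan: `path`, `mode`, `stiffness`,
#'   `side`, `clock_hour`, `clock_minute`, `depth_cm`, and list-columns
#'   `qualifiers` and `size_dims` — the input of [group_scans()].
#' @export
scan_records <- function(scans, cfg = pipeline_config()) {
  purrr::map_dfr(scans, function(scan) {
    mode <- classify_mode(scan, cfg$icvf, cfg$recognizer)
    stiffness <- NA_character_
    if (mode == "SWE") {
      roi <- tryCatch(extract_roi(scan, mode, cfg$icvf),
                      error = function(e) NULL)
      if (!is.null(roi)) {
        stiffness <- classify_stiffness(roi, cfg$model)$class
      }
    }
    ann <- extract_annotation(scan, cfg$recognizer, cfg$confusion)
    loc <- ann$location
    tibble::tibble(
      path = scan$source_path,
      mode = mode,
      stiffness = stiffness,
      side = loc$side %||% NA_character_,
      clock_hour = loc$clock_hour %||% NA_integer_,
      clock_minute = loc$clock_minute %||% NA_integer_,
      depth_cm = loc$depth_cm %||% NA_real_,
      qualifiers = list(loc$qualifiers %||% character()),
      size_dims = list(ann$size$dims_cm),
      text = ann$text
    )
  })
}

#' Run the full report-generation pipeline on a study directory
#'
#' End-to-end orchestration: every readable PNG frame is mode-classified
#' from visual features; shear-wave frames additionally get their
#' elastography ROI extracted and stiffness-classified; independently, the
#' annotation band of every frame is recognized, confusion-corrected and
#' parsed. The two streams merge at grouping time: records are grouped by
#' normalized location key and compiled into the findings report.
#' Unreadable files are skipped with a warning; a directory with no usable
#' image is an error.
#'
#' @param study_dir directory of PNG frames (or a list of `bus_scan`
#'   objects).
#' @param cfg a [pipeline_config()].
#' @param patient_id defaults to the directory basename.
#' @return a `bus_report`; stage tables are attached as attributes
#'   `"records"` and `"groups"`, and written as CSV when `cfg$out_dir`
#'   is set.
#' @export
run_pipeline <- function(study_dir, cfg = pipeline_config(),
                         patient_id = NULL) {
  if (is.character(study_dir)) {
    patient_id <- patient_id %||% basename(normalizePath(study_dir))
    paths <- sort(list.files(study_dir, pattern = "\\.png$",
                             full.names = TRUE, ignore.case = TRUE))
    scans <- purrr::compact(purrr::map(paths, function(p) {
      tryCatch(read_scan_png(p, patient_id), error = function(e) {
        warning("skipping unreadable file ", p, ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    }))
  } else {
    scans <- study_dir
    patient_id <- patient_id %||% scans[[1]]$patient_id %||% "unknown"
  }
  if (length(scans) == 0) {
    stop("no usable images in study", call. = FALSE)
  }
  records <- scan_records(scans, cfg)
  message(sprintf("[busrep] %d frames: %s", nrow(records),
                  paste(sprintf("%s=%d", names(table(records$mode)),
                                table(records$mode)), collapse = " ")))
  groups <- group_scans(records, depth_tol = cfg$depth_tol)
  annotated <- dplyr::filter(groups, .data$n_members > 0)
  message(sprintf("[busrep] %d location groups, %d with annotations",
                  nrow(groups), nrow(annotated)))
  out_path <- NULL
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(
      dplyr::select(records, !dplyr::where(is.list)),
      file.path(cfg$out_dir, "records.csv"), row.names = FALSE)
    echo <- cfg
    echo$model <- echo$model$backend
    echo$recognizer <- echo$recognizer$kind
    jsonlite::write_json(echo[c("depth_tol", "seed", "model", "recognizer")],
                         file.path(cfg$out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    out_path <- file.path(cfg$out_dir, "report.txt")
  }
  report <- compile_report(patient_id, annotated, path = out_path)
  attr(report, "records") <- records
  attr(report, "groups") <- groups
  report
}

#' Evaluate generated reports against ground truth
#'
#' Produces the per-patient correctness table of the report-generation
#' evaluation: scans processed, location groups found, suspicious
#' (annotation-bearing) groups, correctly generated sentences, and the
#' match ratio, with a pooled ratio over all patients.
#'
#' @param generated,truth lists of `bus_report` objects, same order.
#' @return a list with `per_patient` (tibble) and `pooled`.
#' @export
evaluate_reports <- function(generated, truth) {
  pairs <- purrr::map2(generated, truth,
                       ~ list(generated = .x, truth = .y))
  res <- report_match_ratio(pairs)
  res$per_patient <- res$per_patient |>
    dplyr::mutate(
      n_groups = purrr::map_int(generated, ~ length(.x$sentences)),
      .after = "patient_id"
    )
  res
}
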