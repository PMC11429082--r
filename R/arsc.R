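# report structuring: location-keyed grouping, findings template, matching

# severity-majority vote for per-type class consolidation within a group
consolidate_class <- function(classes) {
  classes <- toupper(classes[!is.na(classes)])
  if (length(classes) == 0) return(NA_character_)
  tab <- table(factor(classes, levels = stiffness_classes()))
  winners <- names(tab)[tab == max(tab) & tab > 0]
  winners[length(winners)]  # levels are severity-ascending: tie -> severe
}

format_dim <- function(x) format(x, trim = TRUE, scientific = FALSE)

#' Group annotated scans by normalized location key
#'
#' Partitions the location-bearing scan records by the normalized
#' (side, clock hour, clock minute, depth) key: records differing only in
#' qualifiers ("LEFT 2:00 5CM" vs "LEFT 2:00 5CM LO") share a group;
#' records without a parsed location (distractors) are excluded from all
#' groups. Within a group the per-elastography-type class is the majority
#' vote of its members' predictions (ties toward the severe class) and the
#' consolidated size is the maximal-dimension annotation (a warning is
#' logged when member sizes disagree).
#'
#' @param records a tibble with columns `mode`, `stiffness` (or NA),
#'   `side`, `clock_hour`, `clock_minute`, `depth_cm` (NA when no
#'   location), list-columns `size_dims` and `qualifiers`, and optionally
#'   `path`. See [scan_records()].
#' @param depth_tol numeric tolerance for depth equality (default 0 =
#'   exact match after parsing).
#' @return a tibble of groups ordered by (side, clock, depth) with columns
#'   `side`, `clock_hour`, `clock_minute`, `depth_cm`, `n_members`,
#'   `members` (nested tibble), `size_dims` (list), `doppler_class`,
#'   `swe_class`, `se_class`.
#' @export
group_scans <- function(records, depth_tol = 0) {
  records <- tibble::as_tibble(records)
  located <- dplyr::filter(records, !is.na(.data$side) &
                             !is.na(.data$clock_hour) &
                             !is.na(.data$depth_cm))
  if (nrow(located) == 0) {
    return(tibble::tibble(
      side = character(), clock_hour = integer(), clock_minute = integer(),
      depth_cm = double(), n_members = integer(), members = list(),
      size_dims = list(), doppler_class = character(),
      swe_class = character(), se_class = character()
    ))
  }
  if (depth_tol > 0) {
    # snap near-miss depths onto the smallest member of each cluster
    depths <- sort(unique(located$depth_cm))
    anchor <- depths[c(TRUE, diff(depths) > depth_tol)]
    located$depth_cm <- vapply(located$depth_cm, function(d) {
      anchor[max(which(anchor <= d + 1e-9))]
    }, numeric(1))
  }
  located |>
    dplyr::group_by(.data$side, .data$clock_hour, .data$clock_minute,
                    .data$depth_cm) |>
    tidyr::nest(members = !dplyr::group_cols()) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      n_members = purrr::map_int(.data$members, nrow),
      size_dims = purrr::map(.data$members, function(m) {
        sizes <- purrr::compact(m$size_dims)
        if (length(sizes) == 0) return(NULL)
        keys <- vapply(sizes, function(s) paste(format_dim(s),
                                                collapse = "x"),
                       character(1))
        if (length(unique(keys)) > 1) {
          warning("group members disagree on size; keeping the ",
                  "maximal-dimension annotation", call. = FALSE)
        }
        sizes[[which.max(vapply(sizes, max, numeric(1)))]]
      }),
      doppler_class = purrr::map_chr(.data$members, ~ consolidate_class(
        .x$stiffness[.x$mode == "DOPPLER"])),
      swe_class = purrr::map_chr(.data$members, ~ consolidate_class(
        .x$stiffness[.x$mode == "SWE"])),
      se_class = purrr::map_chr(.data$members, ~ consolidate_class(
        .x$stiffness[.x$mode == "SE"]))
    ) |>
    dplyr::arrange(.data$side, .data$clock_hour, .data$clock_minute,
                   .data$depth_cm)
}

slot_text <- function(class) {
  if (is.null(class) || length(class) == 0 || is.na(class)) "()"
  else paste0("(", tolower(class), ")")
}

#' Render the findings sentence for one scan group
#'
#' Instantiates the findings template in the reporting dialect of the
#' emulated workflow: sizes joined with " × " plus " cm"; the location as
#' "SIDE H h, D CM from nipple" (integer depths render without a decimal
#' point); one slot per elastography type filled with the predicted class
#' in parentheses, or "()" when absent; the BI-RADS category slot is always
#' "()" — it is radiologist-entered, never inferred. Slots that could not
#' be filled automatically are listed in `pending`.
#'
#' @param group a one-row tibble from [group_scans()] or a list with the
#'   same fields.
#' @return a list of class `bus_sentence` with the slot values, the
#'   `rendered` string, and `pending` (slot names awaiting radiologist
#'   input).
#' @export
formulate_sentence <- function(group) {
  g <- as.list(group)
  # one-row tibble columns may arrive as length-1 lists
  g <- purrr::map(g, function(v) if (is.list(v) && length(v) == 1 &&
                                     !is.data.frame(v[[1]])) v[[1]] else v)
  dims <- g$size_dims
  size_text <- if (is.null(dims) || length(dims) == 0 || all(is.na(dims))) {
    "()"
  } else {
    paste0(paste(vapply(dims, format_dim, character(1)), collapse = " × "),
           " cm")
  }
  clock <- clock_to_text(g$clock_hour, g$clock_minute)
  location_text <- sprintf("%s %s h, %s CM", g$side, clock,
                           format_dim(g$depth_cm))
  slots <- list(doppler = slot_text(g$doppler_class),
                swe = slot_text(g$swe_class),
                se = slot_text(g$se_class))
  rendered <- paste0(
    size_text, " mass in ", location_text, " from nipple Doppler ",
    slots$doppler, ", Shearwave Elastography ", slots$swe,
    ", Strain Elastography ", slots$se, ", Category ()"
  )
  pending <- c(
    if (identical(size_text, "()")) "size",
    names(slots)[vapply(slots, identical, logical(1), "()")],
    "category"
  )
  structure(
    list(size_text = size_text, location_text = location_text,
         side = g$side, clock_hour = g$clock_hour,
         clock_minute = g$clock_minute %||% 0L,
         depth_cm = as.numeric(g$depth_cm),
         doppler_slot = slots$doppler, swe_slot = slots$swe,
         se_slot = slots$se, category_slot = "()",
         rendered = rendered, pending = pending),
    class = "bus_sentence"
  )
}

#' @export
print.bus_sentence <- function(x, ...) {
  cat(x$rendered, "\n")
  invisible(x)
}

#' Parse a rendered findings sentence back into its slots
#'
#' Template inversion: recovers the structured slots from the rendered
#' sentence string, so reports round-trip losslessly.
#'
#' @param text a rendered findings sentence.
#' @return a `bus_sentence`.
#' @export
parse_report_sentence <- function(text) {
  m <- regmatches(text, regexec(
    paste0("^(.*) mass in (LEFT|RIGHT) ([0-9:]+) h, ([0-9.]+) CM from ",
           "nipple Doppler (\\([a-z]*\\)), Shearwave Elastography ",
           "(\\([a-z]*\\)), Strain Elastography (\\([a-z]*\\)), ",
           "Category \\(\\)$"),
    text))[[1]]
  if (length(m) == 0) stop("not a findings sentence: ", text, call. = FALSE)
  size_text <- m[2]
  dims <- if (identical(size_text, "()")) NULL else {
    as.numeric(strsplit(sub(" cm$", "", size_text), " × ")[[1]])
  }
  clock <- strsplit(m[4], ":")[[1]]
  unslot <- function(s) if (s == "()") NA_character_ else {
    toupper(sub("^\\((.*)\\)$", "\\1", s))
  }
  formulate_sentence(list(
    side = m[3], clock_hour = as.integer(clock[1]),
    clock_minute = if (length(clock) > 1) as.integer(clock[2]) else 0L,
    depth_cm = as.numeric(m[5]), size_dims = dims,
    doppler_class = unslot(m[6]), swe_class = unslot(m[7]),
    se_class = unslot(m[8])
  ))
}

#' Compile the patient findings report
#'
#' One findings sentence per annotation-bearing group, in group order. When
#' `path` is given, writes the UTF-8 text report plus a structured JSON
#' sidecar for downstream editing. Output is byte-identical across reruns
#' with fixed inputs: the generation timestamp is externalized to the
#' `timestamp` argument and not embedded in the findings text.
#'
#' @param patient_id patient identifier.
#' @param groups tibble from [group_scans()], or a list of group lists.
#' @param path optional output path for the text report (a `.json` sidecar
#'   is written next to it).
#' @param timestamp optional POSIXct recorded on the report object.
#' @return a list of class `bus_report` with `patient_id`, `sentences`
#'   (list of `bus_sentence`) and `text` (the full report text).
#' @export
compile_report <- function(patient_id, groups, path = NULL,
                           timestamp = NULL) {
  glist <- if (is.data.frame(groups)) {
    purrr::map(seq_len(nrow(groups)), ~ groups[.x, ])
  } else groups
  sentences <- purrr::map(glist, formulate_sentence)
  header <- c(paste0("Patient: ", patient_id), "Findings:")
  body <- purrr::map_chr(sentences, "rendered")
  text <- paste(c(header, body), collapse = "\n")
  report <- structure(
    list(patient_id = patient_id, sentences = sentences, text = text,
         generated = timestamp),
    class = "bus_report"
  )
  if (!is.null(path)) {
    ok <- tryCatch({
      writeLines(text, path, useBytes = FALSE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      stop("failed to write report to ", path, ": ",
           conditionMessage(ok), call. = FALSE)
    }
    jsonlite::write_json(
      list(patient_id = patient_id,
           sentences = purrr::map(sentences, function(s) {
             s[c("size_text", "side", "clock_hour", "clock_minute",
                 "depth_cm", "doppler_slot", "swe_slot", "se_slot",
                 "category_slot", "rendered", "pending")]
           })),
      sub("\\.[^.]*$", ".json", path), auto_unbox = TRUE, null = "null",
      digits = NA)
  }
  report
}

#' @export
print.bus_report <- function(x, ...) {
  cat(x$text, "\n", sep = "")
  invisible(x)
}

#' Tidy a compiled report
#'
#' @param x a `bus_report`.
#' @param ... unused.
#' @return one row per findings sentence with its structured slots.
#' @method tidy bus_report
#' @export
tidy.bus_report <- function(x, ...) {
  purrr::map_dfr(x$sentences, function(s) {
    tibble::tibble(
      side = s$side, clock_hour = s$clock_hour,
      clock_minute = s$clock_minute, depth_cm = s$depth_cm,
      size_text = s$size_text, doppler = s$doppler_slot,
      swe = s$swe_slot, se = s$se_slot, rendered = s$rendered
    )
  })
}

sentence_key <- function(s) {
  paste(s$side, s$clock_hour, s$clock_minute, format_dim(s$depth_cm),
        sep = "|")
}

sentence_types <- function(s) {
  types <- c("Doppler", "SWE", "SE")[c(s$doppler_slot, s$swe_slot,
                                       s$se_slot) != "()"]
  sort(types)
}

#' Does a generated sentence match its ground truth?
#'
#' The report-correctness criterion: a generated findings sentence matches
#' the ground truth iff the normalized location key (side, clock, depth)
#' is equal and the set of elastography types with a filled class slot is
#' equal. Class values themselves are not compared.
#'
#' @param generated,truth `bus_sentence` objects (or rendered strings,
#'   which are parsed first).
#' @return logical scalar.
#' @export
match_report <- function(generated, truth) {
  if (is.character(generated)) generated <- parse_report_sentence(generated)
  if (is.character(truth)) truth <- parse_report_sentence(truth)
  identical(sentence_key(generated), sentence_key(truth)) &&
    identical(sentence_types(generated), sentence_types(truth))
}

#' Report match ratio over patients
#'
#' The proportion of ground-truth findings sentences (one per suspicious
#' mass) for which the generated report contains a matching sentence,
#' per patient and pooled.
#'
#' @param pairs a list of `list(generated = , truth = )` pairs of
#'   `bus_report` objects.
#' @return a list with `per_patient` (tibble: `patient_id`, `n_truth`,
#'   `n_matched`, `ratio`) and `pooled` (single fraction).
#' @export
report_match_ratio <- function(pairs) {
  per <- purrr::map_dfr(pairs, function(p) {
    truth_sentences <- p$truth$sentences
    gen_sentences <- p$generated$sentences
    matched <- vapply(truth_sentences, function(ts) {
      any(vapply(gen_sentences, match_report, logical(1), truth = ts))
    }, logical(1))
    tibble::tibble(patient_id = p$truth$patient_id,
                   n_truth = length(truth_sentences),
                   n_matched = sum(matched))
  })
  if (sum(per$n_truth) == 0) {
    stop("no ground-truth sentences to score", call. = FALSE)
  }
  per$ratio <- ifelse(per$n_truth == 0, NA_real_,
                      per$n_matched / per$n_truth)
  list(per_patient = per, pooled = sum(per$n_matched) / sum(per$n_truth))
}
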