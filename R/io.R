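# Plain-text I/O: long-format trace CSV + JSON event/metadata sidecar for
# recordings, TSV for DEG tables and response tables, newline-delimited
# gene sets, JSON for test results. Writers and readers round-trip exactly.

#' Write / read an imaging recording
#'
#' A recording is stored as a long-format CSV of traces (`time_s`,
#' `roi_id`, `roi_type`, `value`) and a JSON sidecar holding the sampling
#' interval, the stimulus events and the subject/pair/role/treatment
#' metadata. `read_recording()` accepts any files with that layout, so real
#' exports with identical columns load the same way.
#'
#' @param recording A [ca_recording()].
#' @param csv_path Path of the trace CSV.
#' @param json_path Path of the JSON sidecar; defaults to the CSV path with
#'   a `.json` extension.
#' @return `write_recording()` returns the paths invisibly;
#'   `read_recording()` returns a [ca_recording()].
#' @export
write_recording <- function(recording, csv_path,
                            json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(recording, "ca_recording"))
  readr::write_csv(recording$traces, csv_path)
  sidecar <- list(
    sampling_interval = recording$sampling_interval,
    subject_id = recording$subject_id, pair_id = recording$pair_id,
    role = recording$role, treatment = recording$treatment,
    events = recording$events)
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv_path, json = json_path))
}

#' @rdname write_recording
#' @export
read_recording <- function(csv_path,
                           json_path = sub("\\.csv$", ".json", csv_path)) {
  if (!file.exists(csv_path) || !file.exists(json_path)) {
    stop_twindff(sprintf("recording files not found: %s / %s",
                         csv_path, json_path), "io")
  }
  hdr <- names(readr::read_csv(csv_path, n_max = 0, show_col_types = FALSE))
  missing_cols <- setdiff(c("time_s", "roi_id", "roi_type", "value"), hdr)
  if (length(missing_cols) > 0) {
    stop_twindff(paste0("trace CSV is missing column(s): ",
                        paste(missing_cols, collapse = ", ")), "io")
  }
  traces <- readr::read_csv(csv_path, show_col_types = FALSE,
                            col_types = readr::cols(
                              time_s = readr::col_double(),
                              roi_id = readr::col_character(),
                              roi_type = readr::col_character(),
                              value = readr::col_double()))
  side <- tryCatch(jsonlite::read_json(json_path, simplifyVector = TRUE),
                   error = function(e) {
                     stop_twindff(paste0("malformed event JSON: ",
                                         conditionMessage(e)), "io")
                   })
  for (field in c("sampling_interval", "events")) {
    if (is.null(side[[field]])) {
      stop_twindff(sprintf("JSON sidecar is missing field '%s'.", field),
                   "io")
    }
  }
  ca_recording(traces, tibble::as_tibble(side$events),
               side$sampling_interval,
               subject_id = side$subject_id %||% NA_character_,
               pair_id = side$pair_id %||% NA_character_,
               role = side$role %||% NA_character_,
               treatment = side$treatment %||% NA_character_)
}

#' Write / read a response table
#'
#' Tab-separated table of per-cell calibrated responses as produced by
#' [process_recording()].
#'
#' @param responses Response tibble.
#' @param path File path.
#' @return The path (writer, invisibly) or the tibble (reader).
#' @export
write_responses <- function(responses, path) {
  readr::write_tsv(responses, path)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) {
    stop_twindff(paste0("response table not found: ", path), "io")
  }
  out <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("pair_id", "role", "treatment", "agent")
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    stop_twindff(paste0("response table is missing column(s): ",
                        paste(missing, collapse = ", ")), "io")
  }
  out
}

#' Write / read a DEG table
#'
#' Tab-separated differential-expression table with header columns
#' `gene_id`, `log2fc`, `padj`.
#'
#' @param deg_table Tibble with the three required columns.
#' @param path File path.
#' @return The path (writer, invisibly) or a validated tibble (reader).
#' @export
write_deg_table <- function(deg_table, path) {
  readr::write_tsv(validate_deg_table(deg_table), path)
  invisible(path)
}

#' @rdname write_deg_table
#' @export
read_deg_table <- function(path) {
  if (!file.exists(path)) {
    stop_twindff(paste0("DEG table not found: ", path), "io")
  }
  out <- readr::read_tsv(path, show_col_types = FALSE)
  validate_deg_table(out)
}

#' Write / read a gene set
#'
#' One gene id per line, no header.
#'
#' @param genes Character vector.
#' @param path File path.
#' @return The path (writer, invisibly) or a character vector (reader).
#' @export
write_gene_set <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' @rdname write_gene_set
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) {
    stop_twindff(paste0("gene set not found: ", path), "io")
  }
  genes <- readLines(path)
  genes <- genes[nzchar(genes)]
  if (anyDuplicated(genes)) {
    stop_twindff("gene set contains duplicates.", "io")
  }
  genes
}

#' Write a twin-contrast result to JSON
#'
#' Serialises both levels of a [twin_contrast_test()] fit: the per-pair
#' differences and the pooled random-effects result.
#'
#' @param x A `twin_contrast` object.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_twin_contrast <- function(x, path) {
  stopifnot(inherits(x, "twin_contrast"))
  out <- list(agent = x$agent, treatment = x$treatment,
              n_outliers_removed = x$n_outliers_removed,
              pairs = x$pairs,
              pooled = list(estimate = x$pooled$pooled, se = x$pooled$se,
                            tau2 = x$pooled$tau2, Q = x$pooled$Q,
                            z = x$pooled$z, p = x$pooled$p, k = x$pooled$k))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
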