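#' Convert a flat file into a Webin checklist
#'
#' Runs the full per-record loop: the input format is detected from the
#' file extension, every record is parsed, audited (marker-abbreviation
#' coherence, then minimal feature prerequisites) and processed (mandatory
#' qualifiers first, then optional ones with INSDC spell-checking). A
#' record failing a prerequisite or a processing step is skipped with a
#' logged reason; a coherence failure aborts the whole run before any
#' output is finalized, because it indicates that the wrong checklist type
#' was selected for the file. Successfully processed rows are buffered and
#' written collectively after the loop, so an aborted run leaves no
#' (partial) output file behind.
#'
#' The four run parameters mirror the converter's command-line interface:
#' input file, output file, checklist type and the environmental-sample
#' flag, which applies uniformly to all records of the file.
#'
#' @param input Path to the `.embl` or `.gb` flat file.
#' @param output Path of the tab-delimited checklist to write.
#' @param checklist One of [checklist_types()].
#' @param env_sample `"yes"`/`"no"` (case-insensitive) or a logical: do the
#'   records stem from environmental samples?
#' @param force Overwrite an existing output file?
#' @param quiet Suppress per-record skip messages (they go to the message
#'   stream, keeping standard output clean for pipelines)?
#' @return A `conversion_summary`: counts of records parsed, written and
#'   skipped, per-record skip reasons, and the abort state.
#' @examples
#' \donttest{
#' f <- tempfile(fileext = ".embl")
#' out <- tempfile(fileext = ".tsv")
#' fixture_file(lapply(1:3, function(s) fixture_record("rRNA", seed = s)),
#'              format = "embl", path = f)
#' convert_flatfile(f, out, "rRNA", env_sample = "no")
#' }
#' @export
convert_flatfile <- function(input, output, checklist, env_sample,
                             force = FALSE, quiet = FALSE) {
  env <- interpret_env_flag(env_sample)
  schema <- get_schema(checklist)
  if (file.exists(output) && !isTRUE(force))
    stop_output(sprintf(
      "output file '%s' already exists; use force to overwrite it", output))
  fmt <- detect_flatfile_format(input)
  records <- read_flatfile(input, fmt)

  rows <- list()
  skips <- list()
  note <- function(msg) if (!quiet) message(msg)

  for (rec in records) {
    markers <- parse_marker_abbreviations(rec)
    coh <- check_checklist_coherence(markers, schema, rec$record_id)
    if (coh$status == "fatal") {
      note(sprintf("ABORT: %s", coh$reason))
      return(new_summary(schema$checklist, length(records), 0L, list(),
                         aborted = TRUE, abort_reason = coh$reason,
                         output = NA_character_))
    }
    pre <- check_feature_prerequisites(rec, schema)
    if (pre$status == "skip") {
      skips[[length(skips) + 1L]] <- list(record_id = rec$record_id,
                                          reason = pre$reason)
      note(sprintf("skipping %s: %s", rec$record_id, pre$reason))
      next
    }
    row <- tryCatch(extract_row(rec, schema, env),
                    fw_record_error = function(e) e)
    if (inherits(row, "error")) {
      skips[[length(skips) + 1L]] <- list(record_id = rec$record_id,
                                          reason = conditionMessage(row))
      note(sprintf("skipping %s: %s", rec$record_id, conditionMessage(row)))
      next
    }
    rows[[length(rows) + 1L]] <- row
  }

  doc <- checklist_document(schema, rows)
  # write to a temporary sibling, then move into place atomically
  tmp <- tempfile(pattern = ".flat2webin_", tmpdir = dirname(output),
                  fileext = ".tsv")
  withCallingHandlers(
    write_checklist(doc, tmp, force = TRUE),
    warning = function(w) {
      note(conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (file.exists(output)) file.remove(output)
  if (!file.rename(tmp, output)) {
    file.copy(tmp, output, overwrite = TRUE)
    file.remove(tmp)
  }

  new_summary(schema$checklist, length(records), length(rows), skips,
              aborted = FALSE, abort_reason = "", output = output)
}

interpret_env_flag <- function(env_sample) {
  if (is.logical(env_sample) && length(env_sample) == 1L && !is.na(env_sample))
    return(env_sample)
  if (is.character(env_sample) && length(env_sample) == 1L) {
    v <- tolower(trimws(env_sample))
    if (v == "yes") return(TRUE)
    if (v == "no") return(FALSE)
  }
  stop_usage("the environmental-sample flag must be either 'yes' or 'no'")
}

new_summary <- function(checklist, n_records, n_written, skips, aborted,
                        abort_reason, output) {
  skip_df <- if (length(skips)) {
    data.frame(record_id = vapply(skips, `[[`, character(1), "record_id"),
               reason = vapply(skips, `[[`, character(1), "reason"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(record_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  structure(
    list(checklist = checklist, n_records = n_records, n_written = n_written,
         n_skipped = nrow(skip_df), skip_reasons = skip_df, aborted = aborted,
         abort_reason = abort_reason, output = output),
    class = "conversion_summary")
}

#' @export
print.conversion_summary <- function(x, ...) {
  cat(sprintf("Checklist type:    %s\n", x$checklist))
  cat(sprintf("Records parsed:    %d\n", x$n_records))
  if (x$aborted) {
    cat("Run ABORTED; no output file was written.\n")
    cat(sprintf("Reason: %s\n", x$abort_reason))
  } else {
    cat(sprintf("Rows written:      %d\n", x$n_written))
    cat(sprintf("Records skipped:   %d\n", x$n_skipped))
    if (x$n_skipped)
      cat(paste0("  - ", x$skip_reasons$reason, collapse = "\n"), "\n", sep = "")
    cat(sprintf("Output checklist:  %s\n", x$output))
  }
  invisible(x)
}
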