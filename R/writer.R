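#' Bundle checklist rows with their schema
#'
#' @param schema A `checklist_schema`.
#' @param rows Data frame (possibly 0-row) whose column names equal the
#'   schema's column names, in schema order; or a list of named character
#'   vectors as returned by [extract_row()].
#' @return A `checklist_document`.
#' @export
checklist_document <- function(schema, rows) {
  stopifnot(inherits(schema, "checklist_schema"))
  cn <- schema$columns$name
  if (is.list(rows) && !is.data.frame(rows)) {
    rows <- if (length(rows)) {
      as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE,
                    check.names = FALSE)
    } else {
      stats::setNames(as.data.frame(rep(list(character()), length(cn)),
                                    check.names = FALSE), cn)
    }
  }
  if (!identical(names(rows), cn))
    stop_usage(sprintf(
      "row columns do not match the %s schema (expected: %s)",
      schema$checklist, paste(cn, collapse = ", ")))
  structure(list(schema = schema, rows = rows), class = "checklist_document")
}

#' Write a checklist document as a tab-delimited file
#'
#' The output is a plain UTF-8 text file with `\n` line terminators: one
#' header line with the tab-joined column names, then one line per row
#' with the tab-joined cell values in header order, `SEQUENCE` always
#' last. Cells were sanitized during extraction, so no quoting dialect is
#' needed; the file opens in any spreadsheet editor and can be augmented
#' (e.g. a LOCALITY column inserted before SEQUENCE) before upload.
#' An existing file is only overwritten when `force = TRUE`.
#'
#' @param doc A `checklist_document`.
#' @param path Output file path.
#' @param force Overwrite an existing file?
#' @return Invisibly, a list with `path` and `n_rows`.
#' @export
write_checklist <- function(doc, path, force = FALSE) {
  stopifnot(inherits(doc, "checklist_document"))
  if (file.exists(path) && !isTRUE(force))
    stop_output(sprintf(
      "output file '%s' already exists; use force to overwrite it", path))
  rows <- doc$rows
  lines <- paste(names(rows), collapse = "\t")
  if (nrow(rows))
    lines <- c(lines, do.call(paste, c(unname(as.list(rows)), sep = "\t")))
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  if (!nrow(rows))
    warning(sprintf("checklist '%s' written with a header row only (0 data rows)",
                    path), call. = FALSE)
  invisible(list(path = path, n_rows = nrow(rows)))
}

#' Read a checklist file back into a data frame
#'
#' Convenience reader for round trips and post-processing checks; all
#' cells are kept as character and column names are not mangled.
#'
#' @param path Path to a tab-delimited checklist.
#' @return Data frame of character columns.
#' @export
read_checklist <- function(path) {
  utils::read.delim(path, check.names = FALSE, colClasses = "character",
                    na.strings = NULL, quote = "", comment.char = "")
}
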