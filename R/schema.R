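#' The six supported checklist types
#'
#' @return Character vector of the checklist-type names accepted by the
#'   converter (case-sensitive).
#' @export
checklist_types <- function() {
  c("gene_intron", "IGS", "trnK_matK", "rRNA", "ITS", "ETS")
}

load_schema_file <- function() {
  if (is.null(.fw_cache$schemas)) {
    .fw_cache$schemas <- yaml::read_yaml(
      system.file("extdata", "checklist_schemas.yaml",
                  package = "flat2webin", mustWork = TRUE))
  }
  .fw_cache$schemas
}

columns_to_df <- function(groups) {
  cols <- do.call(c, groups)  # flatten the anchor groups
  df <- data.frame(
    name = vapply(cols, function(cl) cl$name, character(1)),
    kind = vapply(cols, function(cl) cl$kind, character(1)),
    requirement = vapply(cols, function(cl) cl$requirement, character(1)),
    feature = vapply(cols, function(cl) cl$feature %||% NA_character_, character(1)),
    qualifier = vapply(cols, function(cl) cl$qualifier %||% NA_character_, character(1)),
    rule = vapply(cols, function(cl) cl$rule %||% NA_character_, character(1)),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  df$permitted <- I(lapply(cols, function(cl) as.character(cl$permitted %||% character())))
  df
}

#' Retrieve the column schema of a checklist type
#'
#' Each schema lists the checklist's columns in output order (universal
#' columns first, marker-specific columns as in the Webin definition,
#' a documented subset of ENA's optional columns, and `SEQUENCE` last),
#' together with each column's value kind, requirement level, the flat-file
#' feature/qualifier it is read from, and any special parsing rule. The
#' schema also carries the marker-synonym set used by the input audit.
#' Definitions live in a bundled, human-editable YAML file
#' (`system.file("extdata", "checklist_schemas.yaml", package = "flat2webin")`).
#'
#' @param checklist One of [checklist_types()] (case-sensitive).
#' @return A `checklist_schema`: list with `checklist`, `description`,
#'   `columns` (data frame), `synonyms` and `synonym_patterns`.
#' @examples
#' sch <- get_schema("rRNA")
#' sch$columns$name
#' @export
get_schema <- function(checklist) {
  raw <- load_schema_file()
  if (!is.character(checklist) || length(checklist) != 1L ||
      !checklist %in% names(raw$checklists))
    stop_usage(sprintf(
      "unknown checklist type '%s'; valid types are: %s",
      paste(checklist, collapse = ","), paste(checklist_types(), collapse = ", ")))
  def <- raw$checklists[[checklist]]
  pats <- raw$synonym_patterns %||% list()
  structure(
    list(
      checklist = checklist,
      description = def$description %||% "",
      ena_accession = def$ena_accession %||% "",
      columns = columns_to_df(def$columns),
      synonyms = as.character(def$synonyms),
      synonym_patterns = pats
    ),
    class = "checklist_schema"
  )
}

#' @export
print.checklist_schema <- function(x, ...) {
  mand <- mandatory_columns(x)
  cat(sprintf("<checklist_schema> %s - %s\n", x$checklist, x$description))
  cat(sprintf("  %d columns (%d mandatory): %s\n", nrow(x$columns), nrow(mand),
              paste(x$columns$name, collapse = ", ")))
  invisible(x)
}

#' Mandatory columns of a schema, with conditional promotions
#'
#' Returns the columns that must be non-empty in every row: those marked
#' mandatory, plus conditional columns whose condition holds. For the ITS
#' checklist, `ISOLATION_SOURCE` is promoted when the records are
#' environmental samples. For the ETS checklist, exactly one of the two
#' flank columns is mandatory: the one matching the ETS type (a 5' ETS
#' borders the 18S gene, a 3' ETS the 28S gene); the other flank stays
#' optional.
#'
#' @param schema A `checklist_schema`.
#' @param env_sample Logical; are the records environmental samples?
#' @param ets_type `"5'"` or `"3'"`; which ETS flank is mandatory
#'   (ignored for other checklists).
#' @return The subset of `schema$columns` that is mandatory, in schema order.
#' @examples
#' nrow(mandatory_columns(get_schema("ITS")))                     # 7
#' nrow(mandatory_columns(get_schema("ITS"), env_sample = TRUE))  # 8
#' @export
mandatory_columns <- function(schema, env_sample = FALSE, ets_type = "5'") {
  stopifnot(inherits(schema, "checklist_schema"))
  ets_type <- match.arg(ets_type, c("5'", "3'"))
  cols <- schema$columns
  keep <- cols$requirement == "mandatory"
  cond <- cols$requirement == "conditional"
  rule <- ifelse(is.na(cols$rule), "", cols$rule)
  keep <- keep | (cond & rule == "env_mandatory" & isTRUE(env_sample))
  keep <- keep | (cond & rule == sprintf("flank_%s", ets_type))
  cols[keep, , drop = FALSE]
}

# permitted SEDIMENT tokens for the rRNA checklist
permitted_sediments <- function() {
  sch <- get_schema("rRNA")
  sch$columns$permitted[[which(sch$columns$name == "SEDIMENT")]]
}

# all synonym tokens across the six checklists, with their match patterns
all_marker_synonyms <- function() {
  raw <- load_schema_file()
  tokens <- unique(unlist(lapply(raw$checklists, function(cl) cl$synonyms)))
  pats <- raw$synonym_patterns %||% list()
  stats::setNames(
    lapply(tokens, function(tk) as.character(pats[[tk]] %||% tk)),
    tokens)
}
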