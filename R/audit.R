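# Input audit: the two per-record checks run before any data processing.
# Marker-abbreviation coherence failures are fatal (they indicate that the
# user selected the wrong checklist type for the whole file); missing
# feature prerequisites merely skip the record.

audit_outcome <- function(status, reason = "", record_id = "") {
  structure(list(status = status, reason = reason, record_id = record_id),
            class = "audit_outcome")
}

#' @export
print.audit_outcome <- function(x, ...) {
  cat(sprintf("<audit> %s%s%s\n", x$status,
              if (nzchar(x$record_id)) paste0(" [", x$record_id, "]") else "",
              if (nzchar(x$reason)) paste0(": ", x$reason) else ""))
  invisible(x)
}

# qualifier values scanned for marker abbreviations
.marker_qualifiers <- c("gene", "note", "product", "standard_name")

#' Recognize marker abbreviations in a record
#'
#' Scans the `gene`, `note`, `product` and `standard_name` qualifier values
#' of all non-source features for the marker-synonym tokens of the six
#' checklist schemas (case-insensitive substring matching; some tokens
#' match via alternative patterns, e.g. `rRNA` also matches
#' "ribosomal RNA"). The result feeds the coherence check against the
#' user-selected checklist type.
#'
#' @param record A `seq_record`.
#' @return Sorted character vector of recognized synonym tokens (possibly
#'   empty).
#' @export
parse_marker_abbreviations <- function(record) {
  vals <- unlist(lapply(record$features, function(f) {
    if (f$key == "source") return(character())
    unlist(lapply(.marker_qualifiers, function(q) qualifier_values(f, q)))
  }), use.names = FALSE)
  if (!length(vals)) return(character())
  syn <- all_marker_synonyms()
  found <- names(syn)[vapply(syn, function(p) contains_any(vals, p), logical(1))]
  sort(unique(found))
}

#' Check coherence between recognized markers and the selected checklist
#'
#' If the record carries recognizable marker abbreviations but none of them
#' belongs to the selected checklist's synonym set, the mismatch indicates
#' an incorrect checklist selection by the user and the whole run must be
#' aborted (`status = "fatal"`). A record without any recognizable marker
#' is passed on to prerequisite checking (`"ok"` here).
#'
#' @param markers Tokens from [parse_marker_abbreviations()].
#' @param checklist Checklist type name, or a `checklist_schema`.
#' @param record_id Identifier used in diagnostics.
#' @return An `audit_outcome` with status `"ok"` or `"fatal"`.
#' @export
check_checklist_coherence <- function(markers, checklist, record_id = "") {
  schema <- if (inherits(checklist, "checklist_schema")) checklist
            else get_schema(checklist)
  if (!length(markers))
    return(audit_outcome("ok", record_id = record_id))
  if (length(intersect(markers, schema$synonyms)))
    return(audit_outcome("ok", record_id = record_id))
  audit_outcome(
    "fatal",
    sprintf(paste0(
      "record %s carries marker abbreviations (%s) that do not match ",
      "checklist type '%s'; this indicates an incorrect checklist selection"),
      record_id, paste(markers, collapse = ", "), schema$checklist),
    record_id = record_id)
}

has_feature <- function(record, key, with_qualifier = NULL) {
  for (f in record$features) {
    if (f$key != key) next
    if (is.null(with_qualifier)) return(TRUE)
    if (length(qualifier_values(f, with_qualifier))) return(TRUE)
  }
  FALSE
}

features_of <- function(record, keys) {
  Filter(function(f) f$key %in% keys, record$features)
}

qualifier_pool <- function(record, keys, qualifier) {
  unlist(lapply(features_of(record, keys),
                function(f) qualifier_values(f, qualifier)),
         use.names = FALSE)
}

#' Check the minimal feature prerequisites of a record
#'
#' Verifies that the record carries the annotation features without which
#' the mandatory marker-specific columns of the selected checklist could
#' not be filled (for example, the rRNA checklist needs at least one `rRNA`
#' feature bearing a `product` qualifier, from which `SEDIMENT` is read).
#' A record failing this check is skipped; the run continues. A missing
#' `organism` qualifier on the source feature is also a prerequisite
#' failure, because `ORGANISM_NAME` is mandatory in every checklist, as is
#' a source feature that is not the first entry of the feature table.
#'
#' @param record A `seq_record`.
#' @param checklist Checklist type name, or a `checklist_schema`.
#' @return An `audit_outcome` with status `"ok"` or `"skip"`.
#' @export
check_feature_prerequisites <- function(record, checklist) {
  schema <- if (inherits(checklist, "checklist_schema")) checklist
            else get_schema(checklist)
  id <- record$record_id
  skip <- function(msg) audit_outcome("skip", sprintf("record %s: %s", id, msg), id)

  if (length(record$issues))
    return(skip(paste("unusable feature locations -",
                      paste(record$issues, collapse = "; "))))
  if (!length(record$features) || record$features[[1L]]$key != "source")
    return(skip("the source feature is missing or not at the top of the feature table"))
  if (is.na(record$organism) || !nzchar(record$organism))
    return(skip("the source feature lacks an /organism qualifier (ORGANISM_NAME is mandatory)"))

  ok <- audit_outcome("ok", record_id = id)
  switch(schema$checklist,
    gene_intron = {
      if (!has_feature(record, "intron"))
        return(skip("no intron feature (5'_INTRON/3'_INTRON cannot be derived)"))
      if (!has_feature(record, "gene", "note"))
        return(skip("no gene feature with a /note qualifier (GENE cannot be filled)"))
      ok
    },
    IGS = {
      if (!has_feature(record, "misc_feature", "product"))
        return(skip("no misc_feature with a /product qualifier (GENE1/GENE2 cannot be derived)"))
      ok
    },
    trnK_matK = {
      trna_genes <- qualifier_pool(record, "tRNA", "gene")
      if (!has_feature(record, "intron") && !name_matches(trna_genes, "trnK"))
        return(skip("neither an intron feature nor a tRNA feature for gene trnK-UUU is present"))
      cds_names <- c(qualifier_pool(record, c("gene", "CDS"), "note"),
                     qualifier_pool(record, c("gene", "CDS"), "gene"))
      if (!name_matches(cds_names, "matK") && !name_matches(cds_names, "trnK"))
        return(skip("no matK/trnK gene feature is present"))
      ok
    },
    rRNA = {
      if (!has_feature(record, "rRNA", "product"))
        return(skip("no rRNA feature with a /product qualifier (SEDIMENT cannot be parsed)"))
      ok
    },
    ITS = {
      if (!has_feature(record, "rRNA", "gene") &&
          !has_feature(record, "misc_RNA", "note"))
        return(skip("neither an rRNA feature with /gene nor a misc_RNA feature with /note is present"))
      ok
    },
    ETS = {
      rr <- qualifier_pool(record, "rRNA", "gene")
      notes <- qualifier_pool(record, "misc_RNA", "note")
      flanks <- name_matches(rr, "18S") || name_matches(rr, "28S")
      note_ok <- contains_any(notes, unlist(schema$synonym_patterns[c("5' ETS", "3' ETS")]))
      if (!flanks && !note_ok)
        return(skip(paste("neither an rRNA feature for the 18S/28S rDNA gene nor a",
                          "misc_RNA feature with a 5'/3' ETS note is present")))
      ok
    },
    stop_usage(sprintf("no prerequisite rules for checklist '%s'", schema$checklist))
  )
}
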