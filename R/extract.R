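# Data processing: fill a checklist row from an audited record, mandatory
# columns first, then optional ones, applying the special parsing rules of
# the selected checklist type. All extractors are pure functions of
# (record, env_sample, schema); any failure raises a per-record condition
# that the conversion loop turns into a skip.

# 5'-most feature of the given key(s), optionally required to carry a
# qualifier; NULL when none qualifies.
first_feature <- function(record, keys, with_qualifier = NULL) {
  cand <- features_of(record, keys)
  if (!is.null(with_qualifier))
    cand <- Filter(function(f) length(qualifier_values(f, with_qualifier)), cand)
  cand <- Filter(function(f) !is.null(f$location), cand)
  if (!length(cand)) return(NULL)
  starts <- vapply(cand, function(f) loc_start(f$location), numeric(1))
  cand[[which.min(starts)]]
}

its_note_patterns <- list(
  ITS1 = c("ITS1", "ITS 1", "internal transcribed spacer 1"),
  ITS2 = c("ITS2", "ITS 2", "internal transcribed spacer 2")
)
ets_note_patterns <- list(
  "5'" = c("5' ETS", "5′ ETS"),
  "3'" = c("3' ETS", "3′ ETS")
)

#' Extract the universal checklist columns
#'
#' `ORGANISM_NAME` is copied from the source feature's `organism`
#' qualifier, `ENV_SAMPLE` reflects the run-level environmental-sample
#' flag (it applies uniformly to every record of the file), and `SEQUENCE`
#' is the normalized, uppercase, single-line sequence.
#'
#' @param record A `seq_record`.
#' @param env_sample Logical environmental-sample flag.
#' @return Named character vector with the three universal columns.
#' @export
extract_common <- function(record, env_sample = FALSE) {
  if (is.na(record$organism) || !nzchar(record$organism))
    stop_record(sprintf(
      "record %s: the source feature lacks an /organism qualifier",
      record$record_id))
  c(ORGANISM_NAME = sanitize_cell(record$organism),
    ENV_SAMPLE = yn(isTRUE(env_sample)),
    SEQUENCE = record$sequence)
}

#' Extract the gene_intron marker columns
#'
#' The intron's start/end positions (`5'_INTRON`, `3'_INTRON`, 1-based
#' flat-file coordinates) and its completeness (`5'_PARTIAL`,
#' `3'_PARTIAL`) are determined by the intron feature's location, never by
#' qualifier text. `GENE` is the note of the 5'-most gene feature carrying
#' one; `NUMBER` is the intron's `number` qualifier, defaulting to `"1"`
#' for a single un-numbered intron (common barcoding introns such as trnL
#' or rps16 are first introns).
#'
#' @param record An audited `seq_record`.
#' @return List with `values` (named character) and `extras`.
#' @export
extract_gene_intron <- function(record) {
  id <- record$record_id
  introns <- Filter(function(f) !is.null(f$location), features_of(record, "intron"))
  if (!length(introns))
    stop_record(sprintf("record %s: no intron feature with a usable location", id))
  if (length(introns) > 1L) {
    nums <- unlist(lapply(introns, qualifier_values, name = "number"))
    if (length(nums) < length(introns) || anyDuplicated(nums))
      stop_record(sprintf(
        "record %s: %d intron features without distinguishing /number qualifiers",
        id, length(introns)))
  }
  starts <- vapply(introns, function(f) loc_start(f$location), numeric(1))
  intron <- introns[[which.min(starts)]]

  gene <- first_feature(record, "gene", "note")
  if (is.null(gene))
    stop_record(sprintf("record %s: no gene feature with a /note qualifier", id))

  num <- qualifier_values(intron, "number")
  num <- if (length(num) && nzchar(num[[1L]])) num[[1L]] else "1"

  loc <- intron$location
  list(values = c(
    GENE = sanitize_cell(qualifier_values(gene, "note")[[1L]]),
    "5'_PARTIAL" = yn(loc$partial5),
    "3'_PARTIAL" = yn(loc$partial3),
    "5'_INTRON" = as.character(loc_start(loc)),
    "3'_INTRON" = as.character(loc_end(loc)),
    NUMBER = sanitize_cell(num)
  ), extras = character())
}

#' Extract the IGS marker columns
#'
#' The two flanking gene names are parsed from the spacer `misc_feature`'s
#' `product` qualifier, expected in the form `"X-Y intergenic spacer"`.
#' `G1PRESENT`/`G2PRESENT` report whether a gene feature whose `note`
#' names the respective gene exists in the record (matching is
#' case-insensitive and tolerates anticodon suffixes: "trnH" matches
#' "trnH-GUG").
#'
#' @inheritParams extract_gene_intron
#' @export
extract_igs <- function(record) {
  id <- record$record_id
  mf <- first_feature(record, "misc_feature", "product")
  if (is.null(mf))
    stop_record(sprintf("record %s: no misc_feature with a /product qualifier", id))
  prod <- qualifier_values(mf, "product")[[1L]]
  base <- sub("\\s+intergenic\\s+spacer\\s*$", "", prod, ignore.case = TRUE)
  genes <- trimws(strsplit(base, "-", fixed = TRUE)[[1L]])
  genes <- genes[nzchar(genes)]
  if (identical(base, prod) || length(genes) != 2L)
    stop_record(sprintf(
      "record %s: misc_feature product '%s' is not of the form 'X-Y intergenic spacer'",
      id, prod))
  notes <- qualifier_pool(record, "gene", "note")
  list(values = c(
    GENE1 = sanitize_cell(genes[[1L]]),
    G1PRESENT = yn(name_matches(notes, genes[[1L]])),
    GENE2 = sanitize_cell(genes[[2L]]),
    G2PRESENT = yn(name_matches(notes, genes[[2L]]))
  ), extras = character())
}

#' Extract the trnK_matK marker columns
#'
#' `INTRON` is `"yes"` iff an intron feature or a tRNA feature for gene
#' trnK-UUU is present. The completeness of the matK coding region is read
#' from the matK feature's location: `5'_CDS`/`3'_CDS` are `"yes"` when
#' the respective end lies within the record (not marked partial), and
#' `5'_PARTIAL`/`3'_PARTIAL` are their complements.
#'
#' @inheritParams extract_gene_intron
#' @export
extract_trnK_matK <- function(record) {
  id <- record$record_id
  cand <- Filter(function(f) {
    vals <- c(qualifier_values(f, "note"), qualifier_values(f, "gene"))
    name_matches(vals, "matK")
  }, features_of(record, c("gene", "CDS")))
  cand <- Filter(function(f) !is.null(f$location), cand)
  if (!length(cand))
    stop_record(sprintf("record %s: no matK gene/CDS feature", id))
  starts <- vapply(cand, function(f) loc_start(f$location), numeric(1))
  matk <- cand[[which.min(starts)]]

  trna_genes <- c(qualifier_pool(record, "tRNA", "gene"),
                  qualifier_pool(record, "tRNA", "note"),
                  qualifier_pool(record, "tRNA", "product"))
  intron_present <- has_feature(record, "intron") ||
    name_matches(trna_genes, "trnK") || name_matches(trna_genes, "tRNA-Lys")

  loc <- matk$location
  list(values = c(
    "5'_CDS" = yn(!loc$partial5),
    "3'_CDS" = yn(!loc$partial3),
    "5'_PARTIAL" = yn(loc$partial5),
    "3'_PARTIAL" = yn(loc$partial3),
    INTRON = yn(intron_present)
  ), extras = character())
}

#' Extract the rRNA marker column
#'
#' `SEDIMENT` is the Svedberg token recognized case-insensitively inside
#' the rRNA feature's `product` value; it must be one of the nine
#' permitted sediments (5S, 5.8S, 12S, 16S, 18S, 23S, 25S, 26S, 28S).
#' A product naming no permitted sediment is a processing error.
#'
#' @inheritParams extract_gene_intron
#' @export
extract_rRNA <- function(record) {
  id <- record$record_id
  rr <- first_feature(record, "rRNA", "product")
  if (is.null(rr))
    stop_record(sprintf("record %s: no rRNA feature with a /product qualifier", id))
  prod <- qualifier_values(rr, "product")[[1L]]
  permitted <- permitted_sediments()
  # longest token first, so "5.8S" wins over any shorter overlap
  for (tok in permitted[order(-nchar(permitted))]) {
    if (name_matches(prod, tok))
      return(list(values = c(SEDIMENT = tok), extras = character()))
  }
  stop_record(sprintf(
    "record %s: rRNA product '%s' names none of the permitted sediments (%s)",
    id, prod, paste(permitted, collapse = ", ")))
}

#' Extract the ITS marker columns
#'
#' `18S`/`28S` report the presence of rRNA features whose `gene` qualifier
#' names the respective flank gene; `ITS1`/`ITS2` the presence of misc_RNA
#' features whose `note` names the spacer (both "ITS1" and "internal
#' transcribed spacer 1" spellings are recognized). The completeness of
#' the 5.8S rDNA gene is not read from any feature: it is inferred, as
#' `"yes"` exactly when both ITS1 and ITS2 are present, and emitted in the
#' optional `5.8S` column. When the records are environmental samples the
#' otherwise optional `ISOLATION_SOURCE` column becomes mandatory and is
#' copied from the source feature's `isolation_source` qualifier; its
#' absence is then a processing error.
#'
#' @inheritParams extract_common
#' @export
extract_ITS <- function(record, env_sample = FALSE) {
  id <- record$record_id
  rr_genes <- qualifier_pool(record, "rRNA", "gene")
  notes <- qualifier_pool(record, "misc_RNA", "note")
  its1 <- contains_any(notes, its_note_patterns$ITS1)
  its2 <- contains_any(notes, its_note_patterns$ITS2)

  vals <- c("18S" = yn(name_matches(rr_genes, "18S")),
            ITS1 = yn(its1),
            ITS2 = yn(its2),
            "28S" = yn(name_matches(rr_genes, "28S")))
  iso <- qualifier_pool(record, "source", "isolation_source")
  if (isTRUE(env_sample) && (!length(iso) || !nzchar(iso[[1L]])))
    stop_record(sprintf(
      "record %s: environmental sample without an /isolation_source qualifier (ISOLATION_SOURCE is mandatory)",
      id))
  if (length(iso) && nzchar(iso[[1L]]))
    vals <- c(vals, ISOLATION_SOURCE = sanitize_cell(iso[[1L]]))
  list(values = vals, extras = c("5.8S" = yn(its1 && its2)))
}

#' Extract the ETS marker columns
#'
#' `ETS_TYPE` is read from a misc_RNA feature whose note says "5' ETS" or
#' "3' ETS"; without such a note it is inferred from which flank rDNA gene
#' is annotated (18S implies a 5' ETS, 28S a 3' ETS). A note contradicting
#' the annotated flank (e.g. a 5' note with only the 28S flank present),
#' notes for both types, or flank-only inference with both or neither
#' flank annotated are processing errors. `18S`/`28S` report flank rRNA
#' presence.
#'
#' @inheritParams extract_gene_intron
#' @export
extract_ETS <- function(record) {
  id <- record$record_id
  rr_genes <- qualifier_pool(record, "rRNA", "gene")
  notes <- qualifier_pool(record, "misc_RNA", "note")
  has18 <- name_matches(rr_genes, "18S")
  has28 <- name_matches(rr_genes, "28S")
  note5 <- contains_any(notes, ets_note_patterns[["5'"]])
  note3 <- contains_any(notes, ets_note_patterns[["3'"]])

  type <- if (note5 && note3) {
    stop_record(sprintf("record %s: misc_RNA notes name both a 5' and a 3' ETS", id))
  } else if (note5) {
    if (!has18 && has28)
      stop_record(sprintf(
        "record %s: note says 5' ETS but only the 28S flank is annotated", id))
    "5'"
  } else if (note3) {
    if (!has28 && has18)
      stop_record(sprintf(
        "record %s: note says 3' ETS but only the 18S flank is annotated", id))
    "3'"
  } else if (has18 && !has28) {
    "5'"
  } else if (has28 && !has18) {
    "3'"
  } else {
    stop_record(sprintf(
      "record %s: ETS type cannot be inferred (no ETS note and no single flank rDNA annotation)",
      id))
  }
  list(values = c("18S" = yn(has18), ETS_TYPE = type, "28S" = yn(has28)),
       extras = character())
}

spell_check_record <- function(record) {
  id <- record$record_id
  for (f in record$features) {
    vk <- validate_feature_key(f$key)
    if (vk$status == "near_miss")
      stop_record(sprintf(
        "record %s: feature key '%s' is not INSDC-compliant; did you mean '%s'?",
        id, f$key, vk$suggestion))
    if (vk$status == "unknown")
      stop_record(sprintf(
        "record %s: unknown feature key '%s' (not in the INSDC dictionary)",
        id, f$key))
    for (qn in unique(names(f$qualifiers))) {
      vq <- validate_qualifier(f$key, qn)
      if (vq$status == "near_miss")
        stop_record(sprintf(
          "record %s: qualifier '/%s' is not permitted on feature '%s'; did you mean '/%s'?",
          id, qn, f$key, vq$suggestion))
      if (vq$status == "unknown")
        stop_record(sprintf(
          "record %s: qualifier '/%s' is not permitted on feature '%s'",
          id, qn, f$key))
    }
  }
  invisible(TRUE)
}

#' Fill the optional columns of a row
#'
#' Runs after mandatory extraction has succeeded. Every feature key and
#' qualifier name of the record is spell-checked against the INSDC
#' dictionary (a near miss aborts the record with the canonical spelling
#' suggested). Optional columns mapped to a source qualifier are copied
#' when present and left empty otherwise; rule-derived optional values
#' (such as the inferred 5.8S completeness of the ITS checklist) are
#' taken from `extras`.
#'
#' @param record A `seq_record`.
#' @param schema A `checklist_schema`.
#' @param values Named character vector of the row so far.
#' @param extras Named character vector of rule-derived optional values.
#' @return The completed named character vector.
#' @export
extract_optional <- function(record, schema, values, extras = character()) {
  spell_check_record(record)
  cols <- schema$columns
  opt <- which(cols$requirement %in% c("optional", "conditional"))
  for (i in opt) {
    nm <- cols$name[[i]]
    if (nzchar(values[[nm]])) next
    if (nm %in% names(extras)) {
      values[[nm]] <- extras[[nm]]
    } else if (!is.na(cols$feature[[i]]) && cols$feature[[i]] == "source" &&
               !is.na(cols$qualifier[[i]])) {
      v <- qualifier_pool(record, "source", cols$qualifier[[i]])
      if (length(v) && nzchar(v[[1L]])) values[[nm]] <- sanitize_cell(v[[1L]])
    }
  }
  values
}

validate_row <- function(schema, values, env_sample, record_id) {
  cols <- schema$columns
  ets_type <- if (schema$checklist == "ETS") values[["ETS_TYPE"]] else "5'"
  mand <- mandatory_columns(schema, env_sample = env_sample,
                            ets_type = if (ets_type %in% c("5'", "3'")) ets_type else "5'")
  for (nm in mand$name) {
    if (!nzchar(values[[nm]]))
      stop_record(sprintf("record %s: mandatory column %s is empty", record_id, nm))
  }
  for (i in seq_len(nrow(cols))) {
    v <- values[[cols$name[[i]]]]
    if (!nzchar(v)) next
    kind <- cols$kind[[i]]
    bad <- switch(kind,
      yes_no = !v %in% c("yes", "no"),
      integer = !grepl("^[0-9]+$", v),
      enum = !v %in% cols$permitted[[i]],
      FALSE)
    if (bad)
      stop_record(sprintf(
        "record %s: column %s holds '%s', which is not a valid %s value",
        record_id, cols$name[[i]], v, kind))
  }
  invisible(TRUE)
}

#' Build one complete checklist row from an audited record
#'
#' Applies the universal extraction, the marker-specific extractor of the
#' schema's checklist type (mandatory qualifiers first), and then the
#' optional extraction with INSDC spell-checking, finally validating that
#' every mandatory (and promoted conditional) column is non-empty and that
#' yes/no, integer and enumerated columns hold well-formed values.
#'
#' @param record A `seq_record` that passed the input audit.
#' @param schema A `checklist_schema`.
#' @param env_sample Logical environmental-sample flag.
#' @return Named character vector over the schema's columns, in order.
#' @export
extract_row <- function(record, schema, env_sample = FALSE) {
  stopifnot(inherits(schema, "checklist_schema"))
  values <- stats::setNames(rep("", nrow(schema$columns)), schema$columns$name)
  common <- extract_common(record, env_sample)
  res <- switch(schema$checklist,
    gene_intron = extract_gene_intron(record),
    IGS = extract_igs(record),
    trnK_matK = extract_trnK_matK(record),
    rRNA = extract_rRNA(record),
    ITS = extract_ITS(record, env_sample),
    ETS = extract_ETS(record))
  values[names(common)] <- common
  values[names(res$values)] <- res$values
  values <- extract_optional(record, schema, values, res$extras)
  validate_row(schema, values, env_sample, record$record_id)
  values
}
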