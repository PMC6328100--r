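# Seeded generator of dummy flat files for all six marker types. Every
# generated record carries its own ground-truth manifest, including the
# checklist row it should produce; the expected row is computed directly
# from the generation parameters, never by running the parser or the
# extractors, so it can serve as an independent oracle for the whole
# pipeline. The sequences are random; only the feature STRUCTURE of each
# marker is emulated (a gene spanning an intron, two genes flanking a
# spacer, the trnK intron enclosing matK, a single rDNA gene, the
# 18S-ITS1-5.8S-ITS2-28S ladder, an ETS next to its flank gene).

loc_text <- function(start, end, partial5 = FALSE, partial3 = FALSE) {
  paste0(if (partial5) "<" else "", start, "..", if (partial3) ">" else "", end)
}

fx_feature <- function(key, loc, ...) {
  quals <- c(...)
  list(key = key, loc = loc, quals = quals)
}

#' Generate one dummy sequence record with its ground truth
#'
#' Produces a synthetic annotated record whose feature layout matches the
#' structure of the requested marker, together with a manifest entry
#' holding the generation parameters and the checklist row the record is
#' expected to yield. Identical `(parameters, seed)` give byte-identical
#' records.
#'
#' @param marker One of [checklist_types()].
#' @param seed Integer seed driving the random sequence and layout.
#' @param record_id Record identifier; default derived from the seed.
#' @param organism Organism name written into the source feature.
#' @param seq_len Sequence length in bp (200-2000); default drawn from the
#'   seed.
#' @param partial5,partial3 Mark the marker's focal feature (the intron
#'   for gene_intron, the matK gene for trnK_matK, the rRNA gene for rRNA)
#'   as 5'/3'-partial in its location.
#' @param gene Gene name for gene_intron (default `"trnL"`).
#' @param intron_number Value of the intron's `number` qualifier.
#' @param include_number Write the `number` qualifier at all? (A single
#'   un-numbered intron defaults to NUMBER 1 in the checklist.)
#' @param igs_genes Two flanking gene names for IGS.
#' @param flanking_genes Annotate the two flanking gene features (IGS)?
#' @param include_intron Annotate the trnK intron feature (trnK_matK)?
#' @param include_trnK_trna Annotate a tRNA feature for trnK-UUU
#'   (trnK_matK)?
#' @param sediment Sediment token for the rRNA checklist's product.
#' @param its_parts Which parts of the rDNA cistron ladder to annotate
#'   (ITS), a subset of `c("18S","ITS1","5.8S","ITS2","28S")`.
#' @param isolation_source Optional `isolation_source` qualifier value for
#'   the source feature.
#' @param ets_type `"5'"` or `"3'"` (ETS).
#' @param include_ets_note Annotate the misc_RNA feature with the
#'   "5'/3' ETS" note (ETS)?
#' @param include_18s,include_28s Annotate the flank rDNA genes (ETS);
#'   defaults follow `ets_type`.
#' @param optional_qualifiers Named list of extra source qualifiers to
#'   write (and expect) verbatim, e.g. `list(country = "France")`.
#' @return A `fixture_record`: list with `record_id`, `marker`,
#'   `organism`, `seq_len`, `sequence`, `features` (key, location text,
#'   qualifiers) and `expected` (named character vector of the
#'   marker-specific and optional checklist cells).
#' @export
fixture_record <- function(marker, seed = 1L,
                           record_id = NULL,
                           organism = "Pulsatilla vulgaris",
                           seq_len = NULL,
                           partial5 = FALSE, partial3 = FALSE,
                           gene = "trnL",
                           intron_number = "1", include_number = TRUE,
                           igs_genes = c("trnH", "psbA"),
                           flanking_genes = TRUE,
                           include_intron = TRUE, include_trnK_trna = FALSE,
                           sediment = "18S",
                           its_parts = c("18S", "ITS1", "5.8S", "ITS2", "28S"),
                           isolation_source = NULL,
                           ets_type = "5'",
                           include_ets_note = TRUE,
                           include_18s = NULL, include_28s = NULL,
                           optional_qualifiers = list()) {
  marker <- match.arg(marker, checklist_types())
  with_seed(seed, {
    L <- seq_len %||% sample(600:1200, 1L)
    if (L < 200L || L > 2000L)
      stop_usage("fixture sequence length must lie in [200, 2000]")
    record_id <- record_id %||% sprintf("SYN%05d", seed %% 100000L)
    sequence <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                      collapse = "")

    src_quals <- c(organism = organism, mol_type = "genomic DNA")
    if (!is.null(isolation_source))
      src_quals <- c(src_quals, isolation_source = isolation_source)
    for (nm in names(optional_qualifiers))
      src_quals <- c(src_quals,
                     stats::setNames(as.character(optional_qualifiers[[nm]]), nm))
    feats <- list(fx_feature("source", loc_text(1L, L), src_quals))
    expected <- c(ORGANISM_NAME = organism, SEQUENCE = sequence)

    if (marker == "gene_intron") {
      i1 <- if (partial5) 1L else max(2L, round(L * 0.06))
      i2 <- if (partial3) L else round(L * 0.8)
      feats <- c(feats, list(
        fx_feature("gene", loc_text(1L, L), c(note = gene)),
        fx_feature("intron", loc_text(i1, i2, partial5, partial3),
                   c(c(gene = gene),
                     if (include_number) c(number = intron_number)))))
      expected <- c(expected,
        GENE = gene,
        "5'_PARTIAL" = yn(partial5), "3'_PARTIAL" = yn(partial3),
        "5'_INTRON" = as.character(i1), "3'_INTRON" = as.character(i2),
        NUMBER = if (include_number) intron_number else "1")

    } else if (marker == "IGS") {
      a <- round(L * 0.3); b <- round(L * 0.7)
      if (flanking_genes)
        feats <- c(feats, list(
          fx_feature("gene", loc_text(1L, a),
                     c(note = paste0(igs_genes[[1L]], "-GUG"))),
          fx_feature("gene", loc_text(b, L), c(note = igs_genes[[2L]]))))
      feats <- c(feats, list(
        fx_feature("misc_feature", loc_text(a + 1L, b - 1L),
                   c(product = paste0(igs_genes[[1L]], "-", igs_genes[[2L]],
                                      " intergenic spacer")))))
      expected <- c(expected,
        GENE1 = igs_genes[[1L]], G1PRESENT = yn(flanking_genes),
        GENE2 = igs_genes[[2L]], G2PRESENT = yn(flanking_genes))

    } else if (marker == "trnK_matK") {
      m1 <- if (partial5) 1L else round(L * 0.1)
      m2 <- if (partial3) L else round(L * 0.9)
      if (include_intron)
        feats <- c(feats, list(
          fx_feature("intron", loc_text(1L, L, TRUE, TRUE),
                     c(gene = "trnK", number = "1"))))
      if (include_trnK_trna)
        feats <- c(feats, list(
          fx_feature("tRNA", loc_text(1L, L, TRUE, TRUE),
                     c(gene = "trnK-UUU", product = "tRNA-Lys"))))
      feats <- c(feats, list(
        fx_feature("gene", loc_text(m1, m2, partial5, partial3),
                   c(note = "matK"))))
      expected <- c(expected,
        "5'_CDS" = yn(!partial5), "3'_CDS" = yn(!partial3),
        "5'_PARTIAL" = yn(partial5), "3'_PARTIAL" = yn(partial3),
        INTRON = yn(include_intron || include_trnK_trna))

    } else if (marker == "rRNA") {
      feats <- c(feats, list(
        fx_feature("rRNA", loc_text(1L, L, partial5, partial3),
                   c(gene = paste(sediment, "rRNA"),
                     product = paste(sediment, "ribosomal RNA")))))
      expected <- c(expected, SEDIMENT = sediment)

    } else if (marker == "ITS") {
      cuts <- round(L * c(0.2, 0.4, 0.55, 0.75))
      spans <- list("18S" = c(1L, cuts[1]),
                    ITS1 = c(cuts[1] + 1L, cuts[2]),
                    "5.8S" = c(cuts[2] + 1L, cuts[3]),
                    ITS2 = c(cuts[3] + 1L, cuts[4]),
                    "28S" = c(cuts[4] + 1L, L))
      for (part in names(spans)) {
        if (!part %in% its_parts) next
        sp <- spans[[part]]
        feats <- c(feats, switch(part,
          "18S" = list(fx_feature("rRNA", loc_text(sp[1], sp[2], TRUE, FALSE),
                                  c(gene = "18S rRNA"))),
          "28S" = list(fx_feature("rRNA", loc_text(sp[1], sp[2], FALSE, TRUE),
                                  c(gene = "28S rRNA"))),
          "5.8S" = list(fx_feature("rRNA", loc_text(sp[1], sp[2]),
                                   c(gene = "5.8S rRNA"))),
          ITS1 = list(fx_feature("misc_RNA", loc_text(sp[1], sp[2]),
                                 c(note = "ITS1 (internal transcribed spacer 1)"))),
          ITS2 = list(fx_feature("misc_RNA", loc_text(sp[1], sp[2]),
                                 c(note = "ITS2 (internal transcribed spacer 2)")))))
      }
      both <- all(c("ITS1", "ITS2") %in% its_parts)
      expected <- c(expected,
        "18S" = yn("18S" %in% its_parts),
        ITS1 = yn("ITS1" %in% its_parts),
        ITS2 = yn("ITS2" %in% its_parts),
        "28S" = yn("28S" %in% its_parts),
        "5.8S" = yn(both))
      if (!is.null(isolation_source))
        expected <- c(expected, ISOLATION_SOURCE = isolation_source)

    } else if (marker == "ETS") {
      ets_type <- match.arg(ets_type, c("5'", "3'"))
      include_18s <- include_18s %||% (ets_type == "5'")
      include_28s <- include_28s %||% (ets_type == "3'")
      d <- round(L * 0.6)
      if (include_ets_note)
        feats <- c(feats, list(
          fx_feature("misc_RNA",
                     if (ets_type == "5'") loc_text(1L, d, TRUE, FALSE)
                     else loc_text(L - d, L, FALSE, TRUE),
                     c(note = paste0(ets_type, " ETS")))))
      if (include_18s)
        feats <- c(feats, list(
          fx_feature("rRNA", loc_text(d + 1L, L, FALSE, TRUE),
                     c(gene = "18S rRNA"))))
      if (include_28s)
        feats <- c(feats, list(
          fx_feature("rRNA", loc_text(1L, L - d - 1L, TRUE, FALSE),
                     c(gene = "28S rRNA"))))
      expected <- c(expected,
        "18S" = yn(include_18s), ETS_TYPE = ets_type, "28S" = yn(include_28s))
    }

    for (nm in names(optional_qualifiers))
      expected[nm] <- as.character(optional_qualifiers[[nm]])

    structure(
      list(record_id = record_id, marker = marker, organism = organism,
           seq_len = L, sequence = sequence, features = feats,
           expected = expected),
      class = "fixture_record")
  })
}

wrap_sequence_embl <- function(sequence) {
  groups <- substring(tolower(sequence),
                      seq(1L, nchar(sequence), by = 10L),
                      pmin(seq(10L, nchar(sequence) + 9L, by = 10L),
                           nchar(sequence)))
  lines <- character()
  for (i in seq(1L, length(groups), by = 6L)) {
    chunk <- groups[seq(i, min(i + 5L, length(groups)))]
    upto <- min((i + 5L) * 10L, nchar(sequence))
    lines <- c(lines, sprintf("     %-66s%9d", paste(chunk, collapse = " "), upto))
  }
  lines
}

wrap_sequence_genbank <- function(sequence) {
  groups <- substring(tolower(sequence),
                      seq(1L, nchar(sequence), by = 10L),
                      pmin(seq(10L, nchar(sequence) + 9L, by = 10L),
                           nchar(sequence)))
  lines <- character()
  for (i in seq(1L, length(groups), by = 6L)) {
    chunk <- groups[seq(i, min(i + 5L, length(groups)))]
    lines <- c(lines, sprintf("%9d %s", (i - 1L) * 10L + 1L,
                              paste(chunk, collapse = " ")))
  }
  lines
}

render_qualifier <- function(name, value) {
  if (grepl("^[0-9]+$", value)) sprintf("/%s=%s", name, value)
  else if (!nzchar(value)) sprintf("/%s", name)
  else sprintf("/%s=\"%s\"", name, value)
}

render_entry_embl <- function(rec) {
  base <- nchar(gsub("[^ACGT]", "", rec$sequence))
  counts <- vapply(c("A", "C", "G", "T"), function(b)
    lengths(regmatches(rec$sequence, gregexpr(b, rec$sequence, fixed = TRUE))),
    integer(1))
  lines <- c(
    sprintf("ID   %s; SV 1; linear; genomic DNA; STD; PLN; %d BP.",
            rec$record_id, rec$seq_len),
    "XX",
    sprintf("DE   synthetic %s DNA barcoding record (dummy sequence).",
            rec$marker),
    "XX",
    "FH   Key             Location/Qualifiers",
    "FH")
  for (f in rec$features) {
    lines <- c(lines, sprintf("FT   %-16s%s", f$key, f$loc))
    for (i in seq_along(f$quals))
      lines <- c(lines, sprintf("FT   %-16s%s", "",
                                render_qualifier(names(f$quals)[[i]],
                                                 f$quals[[i]])))
  }
  lines <- c(lines, "XX",
             sprintf("SQ   Sequence %d BP; %d A; %d C; %d G; %d T; %d other;",
                     rec$seq_len, counts[["A"]], counts[["C"]], counts[["G"]],
                     counts[["T"]], rec$seq_len - base),
             wrap_sequence_embl(rec$sequence),
             "//")
  lines
}

render_entry_genbank <- function(rec) {
  lines <- c(
    # LOCUS columns: name starts at 13, length right-justified to column 40
    sprintf("LOCUS       %s%*d bp    DNA     linear   PLN 01-JAN-2019",
            rec$record_id, 28L - nchar(rec$record_id), rec$seq_len),
    sprintf("DEFINITION  synthetic %s DNA barcoding record (dummy sequence).",
            rec$marker),
    sprintf("ACCESSION   %s", rec$record_id),
    "FEATURES             Location/Qualifiers")
  for (f in rec$features) {
    lines <- c(lines, sprintf("     %-16s%s", f$key, f$loc))
    for (i in seq_along(f$quals))
      lines <- c(lines, sprintf("     %-16s%s", "",
                                render_qualifier(names(f$quals)[[i]],
                                                 f$quals[[i]])))
  }
  c(lines, "ORIGIN", wrap_sequence_genbank(rec$sequence), "//")
}

#' Write dummy records as a multi-record flat file
#'
#' Renders the given fixture records in the requested dialect (EMBL with
#' ID/FT/SQ line types and 60-residue sequence lines; GenBank with
#' LOCUS/FEATURES/ORIGIN and 10-column sequence blocks, both with `//`
#' entry terminators) and writes them to `path`. An empty record list
#' produces an empty file, useful for testing the parser's empty-input
#' error.
#'
#' @param records List of `fixture_record` objects (may be empty; markers
#'   may be mixed, e.g. to exercise coherence aborts).
#' @param format `"embl"` or `"genbank"`.
#' @param path Output file path; conventionally ending in `.embl`/`.gb`
#'   so that the converter's format detection applies.
#' @return Invisibly, a `fixture_manifest`: list with `path`, `format`
#'   and the `records` in file order.
#' @export
fixture_file <- function(records, format = c("embl", "genbank"), path) {
  format <- match.arg(format)
  stopifnot(all(vapply(records, inherits, logical(1), "fixture_record")))
  render <- switch(format, embl = render_entry_embl,
                   genbank = render_entry_genbank)
  lines <- unlist(lapply(records, render), use.names = FALSE) %||% character()
  con <- file(path, open = "wb", encoding = "UTF-8")
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  invisible(structure(list(path = path, format = format, records = records),
                      class = "fixture_manifest"))
}

#' Expected checklist rows of a set of fixture records
#'
#' Assembles, from the manifests alone (without parsing or extracting
#' anything), the checklist that a conversion of these records must
#' produce: one row per record over the schema's columns, mandatory cells
#' from each record's ground truth, optional cells from the echoed
#' optional qualifiers, everything else empty.
#'
#' @param x A `fixture_manifest` or a list of `fixture_record`s.
#' @param checklist Checklist type; defaults to the first record's marker.
#' @param env_sample Logical environmental-sample flag used for the
#'   `ENV_SAMPLE` cells.
#' @return Data frame of character columns in schema order.
#' @export
expected_checklist <- function(x, checklist = NULL, env_sample = FALSE) {
  records <- if (inherits(x, "fixture_manifest")) x$records else x
  stopifnot(length(records) > 0L)
  checklist <- checklist %||% records[[1L]]$marker
  schema <- get_schema(checklist)
  cn <- schema$columns$name
  rows <- lapply(records, function(rec) {
    vals <- stats::setNames(rep("", length(cn)), cn)
    vals["ENV_SAMPLE"] <- yn(isTRUE(env_sample))
    known <- intersect(names(rec$expected), cn)
    vals[known] <- rec$expected[known]
    vals
  })
  as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE,
                check.names = FALSE)
}
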