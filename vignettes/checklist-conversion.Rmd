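---
title: "From annotated flat files to ENA Webin checklists: method and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From annotated flat files to ENA Webin checklists: method and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flat2webin)
```

## The problem

The interactive Webin submission route of the European Nucleotide Archive
(ENA) accepts annotated DNA sequences as pre-tailored, tab-delimited
spreadsheets ("checklists"), one column set per marker type and one row per
sequence. Plant and fungal DNA-barcoding studies routinely produce dozens
to hundreds of sequences of a handful of standard markers, annotated in
EMBL- or GenBank-formatted flat files by assembly/annotation suites.
Transcribing feature tables into checklists by hand is tedious and
error-prone; `flat2webin` automates the conversion for the six checklist
types that cover the common plant and fungal barcoding markers:

| type          | marker                                               |
|---------------|------------------------------------------------------|
| `gene_intron` | any gene intron (e.g. the *trnL* intron)             |
| `IGS`         | any intergenic spacer (e.g. *trnH–psbA*)             |
| `trnK_matK`   | the plastid *trnK/matK* region (*matK* sits inside the group II intron of *trnK*-UUU) |
| `rRNA`        | a nuclear ribosomal rDNA gene (18S/28S/5.8S, ...)    |
| `ITS`         | the internal transcribed spacers of the rDNA cistron |
| `ETS`         | the external transcribed spacer                      |

Single-exon coding markers (*rbcL*-style) are deliberately not supported:
their checklists are trivial to fill in a spreadsheet editor and do not
warrant automation.

## The procedure

A run takes exactly four parameters: the input flat file (format detected
from the `.embl`/`.gb` ending), the output path, the checklist type, and a
yes/no flag stating whether all records of the file are environmental
samples. Each record of the file then passes through two stages.

**Input audit.** First, marker abbreviations are collected from the
`gene`, `note`, `product` and `standard_name` qualifiers of the record's
annotation features and compared with the selected checklist's synonym set.
Recognizable markers that are *all* foreign to the selected checklist mean
the user picked the wrong checklist for the file; this is not a per-record
problem, so the whole run aborts and no output file is left behind (rows
are buffered and only written after the loop completes). Second, the
record is checked for the minimal features without which the mandatory
columns could not be filled — e.g. the rRNA checklist needs an `rRNA`
feature carrying a `product` qualifier, from which `SEDIMENT` is parsed.
Records failing a prerequisite are skipped with a logged reason and the
conversion continues; a file with no `organism` qualifier on its source
feature fails here too, since `ORGANISM_NAME` is universally mandatory.

**Data processing.** Mandatory columns are extracted first; only if all of
them can be filled are the optional columns attempted. During processing,
feature keys and qualifier names are spell-checked against a bundled INSDC
vocabulary; a near miss ("countryy", "rrna") skips the record with the
canonical spelling suggested, which catches silent information loss before
submission. Any processing failure skips only the current record.

### Special parsing rules

* `gene_intron`: the intron's start/end (`5'_INTRON`, `3'_INTRON`,
  1-based flat-file coordinates) and completeness (`5'_PARTIAL`,
  `3'_PARTIAL`) are read from the intron feature's *location* —
  `<`/`>` markers included — never from qualifier text.
* `trnK_matK`: `INTRON` is `yes` exactly when an intron feature *or* a
  tRNA feature for *trnK*-UUU is present; `5'_CDS`/`3'_CDS` report whether
  the respective end of the *matK* gene lies within the record, and the
  `PARTIAL` columns are their complements.
* `ITS`: the completeness of the 5.8S rDNA gene is not read from any
  feature but *inferred* — `yes` exactly when both ITS1 and ITS2 are
  annotated. With the environmental-sample flag set, the otherwise
  optional `ISOLATION_SOURCE` column becomes mandatory and its absence is
  a processing error.
* `ETS`: `ETS_TYPE` comes from a misc_RNA note saying "5' ETS"/"3' ETS",
  or, without a note, is inferred from which flank rDNA gene is annotated
  (18S ⇒ 5', 28S ⇒ 3'). Contradictions (a 5' note with only the 28S flank
  annotated; no note and both or neither flank) are processing errors.
* `rRNA`: `SEDIMENT` must be one of the nine permitted Svedberg tokens
  (5S, 5.8S, 12S, 16S, 18S, 23S, 25S, 26S, 28S), matched
  case-insensitively at token boundaries inside the `product` value, the
  longest token first, so "5.8S ribosomal RNA" can never be mistaken for a
  shorter overlap.

## Design choices where the layout was open

**ETS mandatory count.** The published checklist definitions list three
marker-specific ETS columns (18S, ETS_TYPE, 28S) yet count five mandatory
columns in total (three universal + two). We resolve this by making
exactly one flank column mandatory — the one matching the ETS type (5'
ETS ⇒ 18S, 3' ETS ⇒ 28S) — and leaving the other optional. This is the
only reading consistent with both the count and the either/or feature
prerequisite; `mandatory_columns()` exposes the choice via its `ets_type`
argument.

**ETS feature prerequisite.** A single ETS sequence record borders one
flank of the rDNA cistron, not both, and the flank-inference rule above
needs exactly one annotated flank. The audit therefore requires *either*
an ETS note *or* at least one flank rDNA gene, not both flanks at once.

**Optional columns.** ENA's optional column inventories are large and
checklist-version-dependent; we implement a documented subset common to
the six types (`clone`, `collection_date`, `country`, `ecotype`,
`haplotype`, `isolate`, `lat_lon`, `PCR_primers`, `specimen_voucher`,
`strain`, each copied from the source qualifier of the same name, plus the
inferred `5.8S` column for ITS). The schema file
(`system.file("extdata", "checklist_schemas.yaml", package = "flat2webin")`)
is human-editable, so the full ENA sets can be added without code changes.

**Column order.** Universal columns first, marker-specific mandatory
columns in their published order, the optional subset alphabetically, and
`SEQUENCE` always last — so users can insert columns such as `LOCALITY`
before `SEQUENCE`, and checklists with identical schemas can be
concatenated (dropping the second header) before upload.

**NUMBER default.** A single intron without a `number` qualifier yields
`NUMBER = 1`: the common barcoding introns (*trnL*, *rps16*, *rpl16*) are
first introns. Records with several introns and no distinguishing
`number` qualifiers are skipped as ambiguous rather than guessed at.

**One row per record.** When several features could fill a single-feature
slot (e.g. two rRNA features with products), the 5'-most qualifying
feature is used; rows are never multiplied, so the output always has as
many data rows as records that passed audit and processing.

**Gene-name matching.** Presence tests (IGS flanks, ITS/ETS flank genes,
*trnK*-UUU) are case-insensitive and token-delimited, so "trnH" matches
"trnH-GUG" but not "atrnH". The ITS1/ITS2 note spellings accepted
("ITS1", "internal transcribed spacer 1", ...) are table-driven.

**Coordinates.** All coordinates stay 1-based inclusive exactly as
written in the flat file; there is no half-open conversion anywhere, so
checklist intron positions can be compared directly with the annotation.
Only the location constructs barcoding records need are accepted
(interval, single base, `complement`, `join`, partial markers);
`order(...)` and remote references make the *record* unusable (skip), not
the run. On the minus strand the `<`/`>` markers are mirrored, because
the written low coordinate is the biological 3' end.

**Error containment.** Parse-level defects of the file (bad delimiters,
length disagreements, feature table before the header) abort with exit
code 2; a coherence mismatch aborts with exit code 3 and discards
buffered output; every other problem is contained to its record. Existing
output files are never overwritten without `--force`, protecting manually
edited checklists.

## The fixture generator

Real barcoding submissions cannot be redistributed with a package, so
`fixture_record()`/`fixture_file()` generate dummy records for all six
markers with the characteristic feature structure of each (a gene spanning
an intron; two genes flanking a spacer `misc_feature`; the *trnK* intron
enclosing *matK*; a single rDNA gene; the 18S–ITS1–5.8S–ITS2–28S ladder;
an ETS beside its flank gene), rendered in both dialects with realistic
line wrapping. Sequences are seeded random strings of 200–2000 bp —
defaults draw 600–1200 bp, the typical length range of these markers —
and every generated record carries a manifest holding the checklist row it
must produce, computed from the generation parameters alone. The manifest
is therefore an oracle that is independent of the parser and extractors,
and the test suite checks the full pipeline against it across all markers,
both dialects and partial/complete variants (an external flat-file parser
is additionally used to cross-check record structure).

What the dummies do *not* emulate: realistic base composition or
evolutionary signal, annotation idiosyncrasies of specific suites beyond
wrapped qualifier values, multi-interval (`join`) gene models, and
taxonomic metadata beyond the organism name. Passing tests show that the
conversion logic is faithful to the documented rules, not that every
real-world annotation style is recognized; the synonym and note-spelling
tables are deliberately editable for that reason.

## Problem sizes and numerical notes

The test suite and the acceptance script run on generated files of 1–4
records of 250–600 bp (about a hundred randomized files for the
row-conservation property), which exercises every code path; conversion
cost is linear in records and the tool comfortably handles the
hundreds-of-sequences batches typical of barcoding studies. There are no
tolerances anywhere: every comparison in the pipeline is exact string or
integer equality, and conversion output is byte-deterministic for
identical inputs.

## Known limitations

* Protein records, CON/WGS entries and flat-file *writing* are out of
  scope, as are GUI operation and direct upload to ENA.
* Qualifier *values* are not validated (e.g. `lat_lon` grammar); ENA's
  own validator covers that after upload.
* The INSDC vocabulary and optional-column subset are curated snapshots;
  both ship as editable YAML with their source version recorded.
* Checklist-type names are matched case-sensitively (`ITS`, not `its`),
  keeping the interface bit-exact with the published names.
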