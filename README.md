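# flat2webin

Convert multi-record **EMBL** or **GenBank** flat files of common plant and
fungal DNA-barcoding markers into submission-ready, tab-delimited
**checklists** for the interactive Webin submission system of the European
Nucleotide Archive (ENA).

Barcoding studies produce batches of annotated sequences of a small set of
standard markers; ENA's interactive route accepts them as marker-specific
spreadsheets with idiosyncratic columns. `flat2webin` parses each record of
a flat file, audits it against the selected checklist type, and writes one
checklist row per record. Six checklist types are supported:

* `gene_intron` — any gene intron (e.g. the *trnL* intron)
* `IGS` — any intergenic spacer (e.g. *trnH–psbA*)
* `trnK_matK` — the plastid *trnK/matK* region
* `rRNA` — a nuclear ribosomal rDNA gene (18S/28S/5.8S, ...)
* `ITS` — the nuclear ribosomal internal transcribed spacer
* `ETS` — the nuclear ribosomal external transcribed spacer

The conversion applies the markers' special parsing rules: intron
coordinates and completeness are taken from feature *locations* (never from
qualifier text); `trnK_matK` requires an intron or a *trnK*-UUU tRNA
feature; ITS infers the completeness of the 5.8S gene from the joint
presence of ITS1 and ITS2, and promotes `ISOLATION_SOURCE` to mandatory
for environmental samples; the rRNA `SEDIMENT` must be one of the nine
permitted Svedberg tokens. Feature and qualifier spellings are checked
against a bundled INSDC vocabulary, with canonical suggestions for typos.
Records missing a feature prerequisite are skipped with a reason; a file
whose markers contradict the selected checklist type aborts the run whole,
leaving no partial output.

## Worked example

```r
library(flat2webin)

recs <- list(
  fixture_record("trnK_matK", seed = 1, organism = "Pulsatilla vulgaris"),
  fixture_record("trnK_matK", seed = 2, organism = "Pulsatilla alpina",
                 partial5 = TRUE),
  fixture_record("trnK_matK", seed = 3, organism = "Pulsatilla pratensis")
)
fixture_file(recs, "embl", "example_trnKmatK.embl")

convert_flatfile("example_trnKmatK.embl", "example_trnKmatK.tsv",
                 checklist = "trnK_matK", env_sample = "no")
#> Checklist type:    trnK_matK
#> Records parsed:    3
#> Rows written:      3
#> Records skipped:   0
#> Output checklist:  example_trnKmatK.tsv
```

The checklist holds one row per record (`SEQUENCE` shortened here):

```
         ORGANISM_NAME 5'_CDS 3'_CDS 5'_PARTIAL 3'_PARTIAL INTRON         SEQUENCE
1  Pulsatilla vulgaris    yes    yes         no         no    yes  CAGGCCGGAAAC...
2    Pulsatilla alpina     no    yes        yes         no    yes  TAAATAACGAGC...
3 Pulsatilla pratensis    yes    yes         no         no    yes  CTGGTTCGTTTT...
```

The second record's *matK* gene was annotated `<1..N` (5'-partial), so its
`5'_CDS` is `no` and `5'_PARTIAL` is `yes` — read from the location, as a
curator would. The file uploads directly via Webin's interactive route, or
can first be edited in any spreadsheet program (e.g. a `LOCALITY` column
inserted before `SEQUENCE`).

The same conversion from a shell:

```sh
flat2webin -i example_trnKmatK.embl -o example_trnKmatK.tsv -c trnK_matK -e no
```

Exit codes: 0 success, 1 usage/configuration error, 2 flat-file parse
failure, 3 marker/checklist coherence abort. The script is installed under
the package's `exec/` directory (`system.file("exec", "flat2webin",
package = "flat2webin")`).

## Documentation

The vignette (`vignettes/checklist-conversion.Rmd`) describes the
conversion procedure, the per-marker parsing rules, the schema layout
decisions, what the fixture generator does and does not emulate, and known
limitations. The checklist schemas and the INSDC vocabulary ship as
editable YAML under `inst/extdata/`.
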