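# Shared conveniences: write fixture records to a correctly named temp
# flat file, and parse a single rendered record.

tmp_flatfile <- function(records, format = "embl") {
  path <- tempfile(fileext = if (format == "embl") ".embl" else ".gb")
  fixture_file(records, format, path)
}

parse_fixture <- function(record, format = "embl") {
  man <- tmp_flatfile(list(record), format)
  on.exit(unlink(man$path))
  read_flatfile(man$path)[[1L]]
}

tmp_tsv <- function() tempfile(fileext = ".tsv")

# all six markers with a representative generated record each
one_of_each <- function(seed = 1L) {
  stats::setNames(
    lapply(checklist_types(), function(ct) fixture_record(ct, seed = seed)),
    checklist_types())
}
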