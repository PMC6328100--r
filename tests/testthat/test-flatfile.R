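test_that("format detection follows the file extension, case-insensitively", {
  expect_identical(detect_flatfile_format("ex/example_trnKmatK.embl"), "embl")
  expect_identical(detect_flatfile_format("records.gb"), "genbank")
  expect_identical(detect_flatfile_format("RECORDS.EMBL"), "embl")
  expect_identical(detect_flatfile_format("x.GB"), "genbank")
  err <- expect_error(detect_flatfile_format("records.fasta"),
                      class = "fw_usage_error")
  expect_match(conditionMessage(err), "\\.embl")
  expect_match(conditionMessage(err), "\\.gb")
  expect_error(detect_flatfile_format("records.gbk"), class = "fw_usage_error")
})

test_that("location strings parse into intervals, strand and partiality", {
  loc <- parse_location("38..620", 650)
  expect_equal(loc$intervals, data.frame(start = 38L, end = 620L))
  expect_identical(loc$strand, "+")
  expect_false(loc$partial5)
  expect_false(loc$partial3)

  expect_true(parse_location("<1..620", 650)$partial5)
  expect_false(parse_location("<1..620", 650)$partial3)
  expect_true(parse_location("38..>650", 650)$partial3)

  comp <- parse_location("complement(10..20)", 650)
  expect_identical(comp$strand, "-")
  expect_equal(comp$intervals, data.frame(start = 10L, end = 20L))

  # partial markers are mirrored on the minus strand: the written low
  # coordinate is the biological 3' end
  expect_true(parse_location("complement(<10..20)", 650)$partial3)
  expect_true(parse_location("complement(10..>20)", 650)$partial5)

  expect_equal(parse_location("5", 650)$intervals,
               data.frame(start = 5L, end = 5L))

  j <- parse_location("join(1..10,20..30)", 650)
  expect_equal(j$intervals, data.frame(start = c(1L, 20L), end = c(10L, 30L)))
})

test_that("unsupported or out-of-bounds locations are per-record errors", {
  expect_error(parse_location("order(1..10,20..30)", 650), class = "fw_record_error")
  expect_error(parse_location("J01749:1..100", 650), class = "fw_record_error")
  expect_error(parse_location("20..10", 650), class = "fw_record_error")
  expect_error(parse_location("1..700", 650), class = "fw_record_error")
  expect_error(parse_location("0..10", 650), class = "fw_record_error")
  expect_error(parse_location("join(20..30,1..10)", 650), class = "fw_record_error")
  expect_error(parse_location("banana", 650), class = "fw_record_error")
})

test_that("generated files round-trip: parsed structure equals the manifest", {
  for (fmt in c("embl", "genbank")) {
    recs <- lapply(1:3, function(s)
      fixture_record("gene_intron", seed = s, partial5 = s == 2))
    man <- tmp_flatfile(recs, fmt)
    parsed <- read_flatfile(man$path)
    expect_length(parsed, 3L)
    for (i in 1:3) {
      expect_identical(parsed[[i]]$record_id, recs[[i]]$record_id)
      expect_identical(parsed[[i]]$organism, recs[[i]]$organism)
      expect_identical(parsed[[i]]$sequence, recs[[i]]$sequence)
      expect_identical(
        vapply(parsed[[i]]$features, `[[`, character(1), "key"),
        vapply(recs[[i]]$features, `[[`, character(1), "key"))
      expect_identical(parsed[[i]]$features[[1L]]$key, "source")
      expect_identical(
        vapply(parsed[[i]]$features, `[[`, character(1), "location_text"),
        vapply(recs[[i]]$features, `[[`, character(1), "loc"))
    }
    # determinism: a second parse yields an identical structure
    expect_identical(read_flatfile(man$path), parsed)
    unlink(man$path)
  }
})

test_that("sequence case is normalized: lowercase and uppercase twins parse alike", {
  man <- tmp_flatfile(list(fixture_record("rRNA", seed = 11)), "embl")
  lines <- readLines(man$path)
  upper <- sub("\\.embl$", "_UP.embl", man$path)
  seq_zone <- seq(grep("^SQ", lines) + 1L, length(lines) - 1L)
  lines[seq_zone] <- toupper(lines[seq_zone])
  writeLines(lines, upper)
  expect_identical(read_flatfile(upper), read_flatfile(man$path))
})

test_that("structural defects abort parsing with an informative error", {
  empty <- tempfile(fileext = ".embl")
  file.create(empty)
  expect_error(read_flatfile(empty), class = "fw_parse_error")

  expect_error(read_flatfile(tempfile(fileext = ".embl")),
               class = "fw_parse_error")  # file does not exist

  # declared length disagreeing with the sequence block
  man <- tmp_flatfile(list(fixture_record("rRNA", seed = 3, seq_len = 600)), "genbank")
  lines <- readLines(man$path)
  lines[1] <- sub("600 bp", "601 bp", lines[1])
  writeLines(lines, man$path)
  err <- expect_error(read_flatfile(man$path), class = "fw_parse_error")
  expect_match(conditionMessage(err), "601")

  # content after the last record terminator
  man2 <- tmp_flatfile(list(fixture_record("rRNA", seed = 4)), "embl")
  cat("ID   TRAILING; SV 1; linear\n", file = man2$path, append = TRUE)
  expect_error(read_flatfile(man2$path), class = "fw_parse_error")

  # feature table before the header
  bad <- tempfile(fileext = ".embl")
  writeLines(c("FT   source          1..4",
               "ID   X; SV 1; linear; genomic DNA; STD; PLN; 4 BP.",
               "SQ   Sequence 4 BP;", "     acgt", "//"), bad)
  expect_error(read_flatfile(bad), class = "fw_parse_error")
})

test_that("a GenBank entry declaring 600 bp with 600 letters parses to length 600", {
  man <- tmp_flatfile(list(fixture_record("ITS", seed = 9, seq_len = 600)), "genbank")
  rec <- read_flatfile(man$path)[[1L]]
  expect_identical(nchar(rec$sequence), 600L)
  expect_match(rec$sequence, "^[ACGTN]+$")
})

test_that("an unparseable location is recorded as a record issue, not a parse abort", {
  fx <- fixture_record("gene_intron", seed = 5)
  fx$features[[3L]]$loc <- "order(1..10,20..30)"
  rec <- parse_fixture(fx)
  expect_gt(length(rec$issues), 0L)
  expect_length(read_flatfile(tmp_flatfile(list(fx))$path), 1L)
})

test_that("an independent parser agrees on identifiers, lengths and feature keys", {
  py <- Sys.which("python")
  expect_true(nzchar(py))
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "from Bio import SeqIO",
    "with open(sys.argv[1]) as fh:",
    "    recs = list(SeqIO.parse(fh, sys.argv[2]))",
    "print(json.dumps([{'id': r.name, 'n': len(r.seq),",
    "  'keys': [f.type for f in r.features],",
    "  'organism': r.features[0].qualifiers.get('organism', [''])[0]}",
    "  for r in recs]))"), script)
  for (fmt in c("embl", "genbank")) {
    recs <- lapply(1:2, function(s)
      fixture_record("trnK_matK", seed = s, partial5 = s == 2))
    man <- tmp_flatfile(recs, fmt)
    ours <- read_flatfile(man$path)
    ref <- jsonlite::fromJSON(
      system2(py, c(script, man$path, fmt), stdout = TRUE),
      simplifyVector = FALSE)
    expect_length(ours, length(ref))
    for (i in seq_along(ref)) {
      expect_identical(ours[[i]]$record_id, ref[[i]]$id)
      expect_identical(nchar(ours[[i]]$sequence), as.integer(ref[[i]]$n))
      expect_identical(vapply(ours[[i]]$features, `[[`, character(1), "key"),
                       vapply(ref[[i]]$keys, identity, character(1)))
      expect_identical(ours[[i]]$organism, ref[[i]]$organism)
    }
  }
})
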