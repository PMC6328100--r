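test_that("universal columns are copied from the source feature and run flag", {
  rec <- parse_fixture(fixture_record("rRNA", seed = 1,
                                      organism = "Arabidopsis thaliana"))
  cm <- extract_common(rec, env_sample = FALSE)
  expect_identical(cm[["ORGANISM_NAME"]], "Arabidopsis thaliana")
  expect_identical(cm[["ENV_SAMPLE"]], "no")
  expect_identical(cm[["SEQUENCE"]], rec$sequence)
  expect_match(cm[["SEQUENCE"]], "^[ACGTN]+$")
  expect_identical(extract_common(rec, TRUE)[["ENV_SAMPLE"]], "yes")
})

test_that("gene_intron coordinates and partiality come from the intron location", {
  fx <- fixture_record("gene_intron", seed = 2, seq_len = 650)
  rec <- parse_fixture(fx)
  v <- extract_gene_intron(rec)$values
  expect_identical(v[["GENE"]], "trnL")
  expect_identical(v[["5'_INTRON"]], fx$expected[["5'_INTRON"]])
  expect_identical(v[["3'_INTRON"]], fx$expected[["3'_INTRON"]])
  expect_identical(v[["NUMBER"]], "1")
  expect_identical(v[["5'_PARTIAL"]], "no")
  expect_identical(v[["3'_PARTIAL"]], "no")
  expect_lte(as.integer(v[["5'_INTRON"]]), as.integer(v[["3'_INTRON"]]))

  p5 <- extract_gene_intron(parse_fixture(
    fixture_record("gene_intron", seed = 3, partial5 = TRUE)))$values
  expect_identical(p5[["5'_PARTIAL"]], "yes")
  expect_identical(p5[["5'_INTRON"]], "1")
  p3 <- extract_gene_intron(parse_fixture(
    fixture_record("gene_intron", seed = 4, partial3 = TRUE)))$values
  expect_identical(p3[["3'_PARTIAL"]], "yes")

  # mutating qualifier text never changes the reported coordinates
  fx$features[[3L]]$quals[["note"]] <- "intron at 999..1000, partial"
  mutated <- extract_gene_intron(parse_fixture(fx))$values
  expect_identical(mutated[c("5'_INTRON", "3'_INTRON", "5'_PARTIAL", "3'_PARTIAL")],
                   v[c("5'_INTRON", "3'_INTRON", "5'_PARTIAL", "3'_PARTIAL")])
})

test_that("a single un-numbered intron defaults to NUMBER 1; ambiguous introns skip", {
  fx <- fixture_record("gene_intron", seed = 5, include_number = FALSE)
  expect_identical(extract_gene_intron(parse_fixture(fx))$values[["NUMBER"]], "1")

  # two introns, neither numbered: ambiguous
  fx2 <- fixture_record("gene_intron", seed = 6, seq_len = 900,
                        include_number = FALSE)
  fx2$features <- c(fx2$features,
                    list(list(key = "intron", loc = "850..880", quals = c())))
  expect_error(extract_gene_intron(parse_fixture(fx2)), class = "fw_record_error")
})

test_that("IGS gene names come from the spacer product; presence from gene notes", {
  rec <- parse_fixture(fixture_record("IGS", seed = 7))
  v <- extract_igs(rec)$values
  expect_identical(unname(v[c("GENE1", "GENE2")]), c("trnH", "psbA"))
  expect_identical(unname(v[c("G1PRESENT", "G2PRESENT")]), c("yes", "yes"))

  nog <- parse_fixture(fixture_record("IGS", seed = 8, flanking_genes = FALSE))
  v2 <- extract_igs(nog)$values
  expect_identical(unname(v2[c("G1PRESENT", "G2PRESENT")]), c("no", "no"))

  # a product that does not name two genes is a processing error
  bad <- fixture_record("IGS", seed = 9)
  bad$features[[4L]]$quals[["product"]] <- "spacer"
  expect_error(extract_igs(parse_fixture(bad)), class = "fw_record_error")
})

test_that("trnK_matK INTRON is yes iff an intron or trnK-UUU tRNA feature exists", {
  with_intron <- parse_fixture(fixture_record("trnK_matK", seed = 10))
  expect_identical(extract_trnK_matK(with_intron)$values[["INTRON"]], "yes")

  with_trna <- parse_fixture(fixture_record("trnK_matK", seed = 11,
                                            include_intron = FALSE,
                                            include_trnK_trna = TRUE))
  expect_identical(extract_trnK_matK(with_trna)$values[["INTRON"]], "yes")

  neither <- parse_fixture(fixture_record("trnK_matK", seed = 12,
                                          include_intron = FALSE,
                                          include_trnK_trna = FALSE))
  expect_identical(extract_trnK_matK(neither)$values[["INTRON"]], "no")
})

test_that("trnK_matK CDS completeness mirrors the matK location partiality", {
  full <- extract_trnK_matK(parse_fixture(
    fixture_record("trnK_matK", seed = 13)))$values
  expect_identical(unname(full[c("5'_CDS", "3'_CDS", "5'_PARTIAL", "3'_PARTIAL")]),
                   c("yes", "yes", "no", "no"))
  p5 <- extract_trnK_matK(parse_fixture(
    fixture_record("trnK_matK", seed = 14, partial5 = TRUE)))$values
  expect_identical(unname(p5[c("5'_CDS", "5'_PARTIAL")]), c("no", "yes"))
  expect_identical(unname(p5[c("3'_CDS", "3'_PARTIAL")]), c("yes", "no"))

  # no matK feature at all is a processing error
  bad <- fixture_record("trnK_matK", seed = 15)
  bad$features <- Filter(function(f) !identical(unname(f$quals["note"]), "matK"),
                         bad$features)
  expect_error(extract_trnK_matK(parse_fixture(bad)), class = "fw_record_error")
})

test_that("rRNA SEDIMENT accepts exactly the nine permitted tokens", {
  for (sed in c("5S", "5.8S", "12S", "16S", "18S", "23S", "25S", "26S", "28S")) {
    rec <- parse_fixture(fixture_record("rRNA", seed = 16, sediment = sed))
    expect_identical(extract_rRNA(rec)$values[["SEDIMENT"]], sed, label = sed)
  }
  bad <- fixture_record("rRNA", seed = 17)
  bad$features[[2L]]$quals[["product"]] <- "17S ribosomal RNA"
  err <- expect_error(extract_rRNA(parse_fixture(bad)), class = "fw_record_error")
  expect_match(conditionMessage(err), "17S")
})

test_that("ITS presence flags and the 5.8S completeness inference", {
  full <- extract_ITS(parse_fixture(fixture_record("ITS", seed = 18)))
  expect_identical(unname(full$values[c("18S", "ITS1", "ITS2", "28S")]),
                   rep("yes", 4L))
  expect_identical(full$extras[["5.8S"]], "yes")

  only2 <- extract_ITS(parse_fixture(
    fixture_record("ITS", seed = 19, its_parts = c("ITS2", "28S"))))
  expect_identical(only2$values[["ITS1"]], "no")
  expect_identical(only2$values[["ITS2"]], "yes")
  expect_identical(only2$extras[["5.8S"]], "no")
})

test_that("environmental ITS samples require an isolation_source", {
  with_iso <- parse_fixture(fixture_record("ITS", seed = 20,
                                           isolation_source = "soil"))
  v <- extract_ITS(with_iso, env_sample = TRUE)$values
  expect_identical(v[["ISOLATION_SOURCE"]], "soil")

  without <- parse_fixture(fixture_record("ITS", seed = 21))
  err <- expect_error(extract_ITS(without, env_sample = TRUE),
                      class = "fw_record_error")
  expect_match(err$message, "isolation_source")
  # without the env flag the same record processes fine
  expect_silent(extract_ITS(without, env_sample = FALSE))
})

test_that("ETS type comes from the note, or is inferred from the annotated flank", {
  noted <- extract_ETS(parse_fixture(fixture_record("ETS", seed = 22)))$values
  expect_identical(unname(noted[c("ETS_TYPE", "18S", "28S")]),
                   c("5'", "yes", "no"))

  flank3 <- extract_ETS(parse_fixture(
    fixture_record("ETS", seed = 23, ets_type = "3'",
                   include_ets_note = FALSE)))$values
  expect_identical(flank3[["ETS_TYPE"]], "3'")

  # contradictory: note says 5' but only the 28S flank is annotated
  bad <- fixture_record("ETS", seed = 24, ets_type = "5'",
                        include_18s = FALSE, include_28s = TRUE)
  expect_error(extract_ETS(parse_fixture(bad)), class = "fw_record_error")

  # no note and both flanks annotated: ambiguous
  amb <- fixture_record("ETS", seed = 25, include_ets_note = FALSE,
                        include_18s = TRUE, include_28s = TRUE)
  expect_error(extract_ETS(parse_fixture(amb)), class = "fw_record_error")
})

test_that("optional qualifiers are copied and spell-checked", {
  fx <- fixture_record("rRNA", seed = 26,
                       optional_qualifiers = list(specimen_voucher = "FR-2018-017",
                                                  country = "France"))
  schema <- get_schema("rRNA")
  row <- extract_row(parse_fixture(fx), schema)
  expect_identical(row[["specimen_voucher"]], "FR-2018-017")
  expect_identical(row[["country"]], "France")
  expect_identical(row[["clone"]], "")  # absent optionals stay empty

  # a near-miss qualifier name aborts the record with the canonical suggestion
  typo <- fixture_record("rRNA", seed = 27)
  typo$features[[1L]]$quals <- c(typo$features[[1L]]$quals,
                                 c(countryy = "France"))
  err <- expect_error(extract_row(parse_fixture(typo), schema),
                      class = "fw_record_error")
  expect_match(conditionMessage(err), "country")
})

test_that("cells are sanitized against TSV-breaking characters", {
  fx <- fixture_record("rRNA", seed = 28,
                       organism = "Genus\tspecies var. odd")
  row <- extract_row(parse_fixture(fx), get_schema("rRNA"))
  expect_false(grepl("[\t\r\n]", row[["ORGANISM_NAME"]]))
  expect_identical(row[["ORGANISM_NAME"]], "Genus species var. odd")
})

test_that("extraction is a pure function of record, schema and flag", {
  rec <- parse_fixture(fixture_record("ITS", seed = 29, isolation_source = "bark"))
  schema <- get_schema("ITS")
  expect_identical(extract_row(rec, schema, TRUE), extract_row(rec, schema, TRUE))
})

test_that("extracted rows equal the generator manifest field-for-field", {
  for (ct in checklist_types()) {
    fx <- fixture_record(ct, seed = 30)
    row <- extract_row(parse_fixture(fx), get_schema(ct))
    exp <- expected_checklist(list(fx), ct)
    expect_identical(as.list(row), as.list(exp[1, ]), label = ct)
  }
})
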