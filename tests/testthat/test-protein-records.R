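# UniProt feature-column parsing, record readers/writers, validation.

test_that("feature-column text parses into intervals with notes", {
  ft <- parseFeatureString(
    'TOPO_DOM 1..5; /note="Extracellular"; TOPO_DOM 27..80; /note="Cytoplasmic"',
    "TOPO_DOM")
  expect_equal(nrow(ft), 2L)
  expect_equal(ft$start, c(1L, 27L))
  expect_equal(ft$end, c(5L, 80L))
  expect_equal(ft$note, c("Extracellular", "Cytoplasmic"))

  tm <- parseFeatureString('TRANSMEM 6..26; /note="Helical"', "TRANSMEM")
  expect_equal(tm$start, 6L)
  expect_equal(tm$end, 26L)

  expect_equal(nrow(parseFeatureString("", "TOPO_DOM")), 0L)
  expect_equal(nrow(parseFeatureString(NA_character_, "TOPO_DOM")), 0L)
})

test_that("qualifiers other than /note are ignored, quoted ; survives", {
  ft <- parseFeatureString(
    'TOPO_DOM 1..10; /note="Cytoplasmic; in dimer"; /evidence="ECO:0000255"',
    "TOPO_DOM")
  expect_equal(ft$note, "Cytoplasmic; in dimer")
})

test_that("malformed feature tokens are loud", {
  expect_error(parseFeatureString("TOPO_DOM 9..3", "TOPO_DOM"),
               "inverted interval")
  expect_error(parseFeatureString("TOPO_DOM 5", "TOPO_DOM"),
               "malformed interval")
  expect_error(parseFeatureString("TOPO_DOM a..b", "TOPO_DOM"),
               "malformed interval")
})

writeRecordsFixture <- function(path) {
  writeLines(c(
    paste("Entry", "Entry Name", "Sequence", "Topological domain",
          "Transmembrane", sep = "\t"),
    paste("P00001", "REC1_HUMAN",
          paste0(strrep("G", 30), strrep("A", 21), strrep("G", 29)),
          'TOPO_DOM 1..30; /note="Extracellular"; TOPO_DOM 52..80; /note="Cytoplasmic"',
          'TRANSMEM 31..51; /note="Helical"', sep = "\t"),
    paste("P00002", "REC2_HUMAN", strrep("G", 40), "", "", sep = "\t")
  ), path)
}

test_that("records TSV reads into an annotated set", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeRecordsFixture(f)
  x <- readRecordsTSV(f)
  expect_s4_class(x, "TopoProteinSet")
  expect_equal(length(x), 2L)
  expect_equal(accessions(x), c("P00001", "P00002"))
  ft <- as.data.frame(features(x))
  expect_equal(nrow(ft), 3L)
  expect_equal(sum(ft$kind == "TRANSMEM"), 1L)
  expect_equal(as.character(classifyCterm(x)),
               c("CYTOPLASMIC", "UNANNOTATED"))
})

test_that("records TSV rejects structural problems", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Entry\tTopological domain", "P1\tx"), f)
  expect_error(readRecordsTSV(f), "required column 'Sequence'")

  writeLines(c("Entry\tSequence", "P1\tAAAA", "P1\tGGGG"), f)
  expect_error(readRecordsTSV(f), "duplicate accession")

  writeLines(c("Entry\tSequence", "P1\t"), f)
  expect_error(readRecordsTSV(f), "empty sequence")

  # empty file with a header is an empty set, not an error
  writeLines("Entry\tSequence", f)
  expect_equal(length(readRecordsTSV(f)), 0L)
})

test_that("FASTA plus sidecar features joins on accession", {
  fa <- withr::local_tempfile(fileext = ".fa")
  fe <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(">P1 some description", strrep("G", 50),
               ">P2", strrep("A", 40),
               ">P3", strrep("C", 30)), fa)
  writeLines(c("accession\tkind\tstart\tend\tnote",
               "P1\tTOPO_DOM\t1\t20\tExtracellular",
               "P1\tTRANSMEM\t21\t41\tHelical",
               "P1\tTOPO_DOM\t42\t50\tCytoplasmic",
               "P2\tTOPO_DOM\t1\t40\tCytoplasmic",
               "P2\tINTRAMEM\t10\t20\t"), fe)
  expect_warning(x <- readRecordsFASTA(fa, fe), "overlaps")
  expect_equal(length(x), 3L)
  ft <- as.data.frame(features(x))
  expect_equal(nrow(ft), 5L)
  expect_equal(nrow(ft[ft$accession == "P3", ]), 0L)

  # orphan feature rows are an error listing the orphan
  writeLines(c("accession\tkind\tstart\tend\tnote",
               "P9\tTOPO_DOM\t1\t10\tCytoplasmic"), fe)
  expect_error(readRecordsFASTA(fa, fe), "P9")

  # no feature file: all records unannotated
  y <- readRecordsFASTA(fa)
  expect_equal(nrow(as.data.frame(features(y))), 0L)
  expect_true(all(classifyCterm(y) == "UNANNOTATED"))
})

test_that("JSON round trip is lossless", {
  lib <- generateLibrary(seed = 11, n = 12)
  f <- withr::local_tempfile(fileext = ".json")
  writeRecordsJSON(lib$records, f)
  back <- readRecordsJSON(f)
  expect_equal(accessions(back), accessions(lib$records))
  expect_equal(as.character(sequences(back)),
               as.character(sequences(lib$records)))
  expect_equal(unname(entryNames(back)), unname(entryNames(lib$records)))
  expect_equal(as.data.frame(features(back)),
               as.data.frame(features(lib$records)))

  # empty set round trip
  e <- TopoProteinSet(stats::setNames(character(0), character(0)))
  writeRecordsJSON(e, f)
  expect_equal(length(readRecordsJSON(f)), 0L)
})

test_that("unknown JSON schema or version is rejected", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(schema = "something-else", version = 1,
                            records = list()), f, auto_unbox = TRUE)
  expect_error(readRecordsJSON(f), "schema")
  jsonlite::write_json(list(schema = "topomotif-records", version = 99,
                            records = list()), f, auto_unbox = TRUE)
  expect_error(readRecordsJSON(f), "version")
})

test_that("TSV write/read round trips, including through the JSON model", {
  lib <- generateLibrary(seed = 13, n = 8)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeRecordsTSV(lib$records, f)
  back <- readRecordsTSV(f)
  expect_equal(as.character(sequences(back)),
               as.character(sequences(lib$records)))
  expect_equal(as.data.frame(features(back)),
               as.data.frame(features(lib$records)))
  # TSV -> model -> JSON -> model identity
  j <- withr::local_tempfile(fileext = ".json")
  writeRecordsJSON(back, j)
  again <- readRecordsJSON(j)
  expect_equal(as.character(sequences(again)),
               as.character(sequences(lib$records)))
  expect_equal(as.data.frame(features(again)),
               as.data.frame(features(lib$records)))
})

test_that("ingest validation rejects corrupted annotations", {
  # feature extending past the sequence end
  expect_error(
    mkSet(filler(50), feat("P1", "TOPO_DOM", 40, 60, "Cytoplasmic")),
    "extends past sequence length")
  # overlapping same-kind features
  expect_error(
    mkSet(filler(80), rbind(feat("P1", "TRANSMEM", 10, 30, ""),
                            feat("P1", "TRANSMEM", 25, 45, ""))),
    "overlapping TRANSMEM")
  # inverted interval
  expect_error(
    mkSet(filler(80), feat("P1", "TOPO_DOM", 20, 10, "Cytoplasmic")),
    "invalid feature interval")
  # feature for an absent accession
  expect_error(
    mkSet(filler(80), feat("P2", "TOPO_DOM", 1, 10, "Cytoplasmic")),
    "unknown accession")
  # cross-kind overlap is a warning, not an error
  expect_warning(
    mkSet(filler(80), rbind(feat("P1", "TOPO_DOM", 1, 40, "Cytoplasmic"),
                            feat("P1", "TRANSMEM", 35, 55, ""))),
    "overlaps a membrane segment")
  # property: corrupting any generated record's feature end past the
  # sequence length is always rejected
  lib <- generateLibrary(seed = 17, n = 6)
  ft <- as.data.frame(features(lib$records))
  seqs <- as.character(sequences(lib$records))
  for (acc in accessions(lib$records)[1:3]) {
    bad <- ft
    i <- which(bad$accession == acc)[1]
    bad$end[i] <- nchar(seqs[[acc]]) + 5L
    expect_error(
      suppressWarnings(TopoProteinSet(seqs, features = bad)),
      "extends past|overlapping")
  }
})

test_that("subsetting carries features and show() summarizes", {
  lib <- generateLibrary(seed = 19, n = 5)
  sub <- lib$records[c(2, 4)]
  expect_equal(length(sub), 2L)
  expect_setequal(unique(as.data.frame(features(sub))$accession),
                  accessions(sub))
  byName <- lib$records[accessions(lib$records)[2]]
  expect_equal(accessions(byName), accessions(lib$records)[2])
  expect_error(lib$records["NOPE"], "unknown accession")
  expect_output(show(lib$records), "TopoProteinSet with 5 protein")
})
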