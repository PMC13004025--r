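# End-to-end census: tail filter, windowed scan, filters, summaries.

test_that("the cytoplasmic-tail filter keeps exactly cytoplasmic C termini", {
  mk <- function(acc, note) {
    list(seq = filler(80),
         ft = feat(acc, "TOPO_DOM", 27, 80, note))
  }
  notes <- c(rep("Cytoplasmic", 6), rep("Extracellular", 3))
  accs <- sprintf("P%02d", 1:10)
  seqs <- stats::setNames(rep(filler(80), 10), accs)
  ft <- do.call(rbind, lapply(1:9, function(i)
    feat(accs[i], "TOPO_DOM", 27, 80, notes[i])))
  # the tenth protein has no covering domain at all
  x <- TopoProteinSet(seqs, features = ft)
  kept <- filterCytoplasmicTails(x)
  expect_equal(length(kept), 6L)
  expect_equal(accessions(kept), accs[1:6])
  expect_match(provenance(kept)[length(provenance(kept))],
               "kept 6 of 10")
  # empty set and all-cytoplasmic identity
  expect_equal(length(filterCytoplasmicTails(
    TopoProteinSet(stats::setNames(character(0), character(0))))), 0L)
  allc <- x[1:6]
  expect_equal(accessions(filterCytoplasmicTails(allc)), accessions(allc))
})

test_that("a planted tail motif at distance 30 yields one passing match", {
  # GLUT4-like: cytoplasmic tail carrying LEYL 30 residues past the TM
  x <- singlePassWithMotif("LEYL", 30, tailLen = 80)
  m <- scanProteome(x, recyclingPatterns()["LxxL"])
  expect_equal(nrow(m), 1L)
  expect_true(m$passes)
  expect_equal(m$membraneDistance, 30L)
  expect_equal(m$matched, "LEYL")
})

test_that("matches outside the last-window residues are not emitted", {
  # motif sits 120 residues from the C terminus of a 172-residue protein
  x <- singlePassWithMotif("LENL", 0, tailLen = 121)
  stopifnot(nchar(as.character(sequences(x)[[1]])) - 52 >= 100)
  m <- scanProteome(x, recyclingPatterns()["LxxL"],
                    searchConfig(windowLen = 100))
  expect_equal(nrow(m), 0L)
  # with a window covering the whole protein the match appears
  m2 <- scanProteome(x, recyclingPatterns()["LxxL"],
                     searchConfig(windowLen = 1000))
  expect_equal(nrow(m2), 1L)
  # boundary: the entire match must lie inside the window
  L <- nchar(as.character(sequences(x)[[1]]))
  wExact <- L - 52 + 1  # window that starts exactly at the motif start
  expect_equal(nrow(scanProteome(x, recyclingPatterns()["LxxL"],
                                 searchConfig(windowLen = wExact))), 1L)
  expect_equal(nrow(scanProteome(x, recyclingPatterns()["LxxL"],
                                 searchConfig(windowLen = wExact - 1))), 0L)
})

test_that("an extracellular-loop match is emitted but fails the filter", {
  # 2-pass protein, cytoplasmic C terminus: loop between the TMs faces
  # the extracellular side and carries the only LxxL
  chars <- strsplit(filler(150, "G"), "")[[1]]
  chars[78:81] <- strsplit("LENL", "")[[1]]
  ft <- rbind(feat("P1", "TOPO_DOM", 1, 30, "Cytoplasmic"),
              feat("P1", "TRANSMEM", 31, 51, "Helical"),
              feat("P1", "TOPO_DOM", 52, 100, "Extracellular"),
              feat("P1", "TRANSMEM", 101, 121, "Helical"),
              feat("P1", "TOPO_DOM", 122, 150, "Cytoplasmic"))
  x <- mkSet(paste(chars, collapse = ""), ft)
  m <- scanProteome(x, recyclingPatterns()["LxxL"])
  expect_equal(nrow(m), 1L)
  expect_false(m$passes)
  expect_match(m$reasons, "not cytoplasmic")
  # and it never reaches the summary counts
  s <- summarizeCensus(m, recyclingPatterns()["LxxL"])
  expect_equal(s$summary$nUniqueProteins, 0L)
})

test_that("membrane filter keeps >= threshold and flagged undefined", {
  m <- data.frame(accession = sprintf("P%d", 1:4), pattern = "LxxL",
                  membraneDistance = c(14L, 15L, 16L, NA),
                  stringsAsFactors = FALSE)
  kept <- applyMembraneFilter(m, 15)
  expect_equal(kept$accession, c("P2", "P3", "P4"))
  expect_true(is.na(kept$membraneDistance[3]))
  expect_equal(nrow(applyMembraneFilter(m, 0)), 4L)
  expect_equal(nrow(applyMembraneFilter(m[1:3, ], 100)), 0L)
})

test_that("summary counts matches and unique proteins per pattern", {
  # 5 passing matches over 3 proteins for one pattern
  m <- data.frame(
    accession = c("A", "A", "B", "B", "C"), pattern = "LxxL",
    start = c(10L, 20L, 5L, 9L, 7L), end = c(13L, 23L, 8L, 12L, 10L),
    matched = "LENL", membraneDistance = c(20L, 30L, 10L, 14L, NA),
    distanceUndefined = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    cytoplasmicOK = TRUE, distanceOK = TRUE, passes = TRUE, reasons = "",
    stringsAsFactors = FALSE)
  s <- summarizeCensus(m, recyclingPatterns()["LxxL"])
  expect_equal(s$summary$nMatches, 5L)
  expect_equal(s$summary$nUniqueProteins, 3L)
  # distance-filtered: A (both >= 15), C (undefined, flagged); B fails
  expect_equal(s$summary$nUniqueProteinsDistanceFiltered, 2L)
  # per-protein best match is the most C-terminal one
  expect_equal(s$proteins$start[s$proteins$accession == "A"], 20L)
  expect_equal(s$proteins$proteinClass, rep("", 3))
  # zero matches give zeros and empty protein lists
  z <- summarizeCensus(emptyish <- m[0, ], recyclingPatterns())
  expect_equal(z$summary$nMatches, rep(0L, 5))
  expect_equal(nrow(z$proteins), 0L)
})

test_that("dedup count equals the number of distinct passing accessions", {
  lib <- generateLibrary(seed = 29, n = 60)
  m <- scanProteome(lib$records, recyclingPatterns())
  s <- summarizeCensus(m, recyclingPatterns())
  for (nm in names(recyclingPatterns())) {
    sub <- m[m$pattern == nm & m$cytoplasmicOK, ]
    expect_equal(s$summary$nUniqueProteins[s$summary$pattern == nm],
                 length(unique(sub$accession)))
  }
})

test_that("anchored patterns are evaluated at the C terminus regardless of window", {
  x <- singlePassWithMotif("DSAL", 0, tailLen = 60)
  # put the PDZ motif flush at the C terminus
  seqchars <- strsplit(as.character(sequences(x)[[1]]), "")[[1]]
  L <- length(seqchars)
  seqchars[(L - 3):L] <- strsplit("ETAL", "")[[1]]
  ft <- as.data.frame(features(x))
  x2 <- mkSet(paste(seqchars, collapse = ""), ft)
  pdz <- recyclingPatterns()["PDZ"]
  m4 <- scanProteome(x2, pdz, searchConfig(windowLen = 4))
  mBig <- scanProteome(x2, pdz, searchConfig(windowLen = 500))
  expect_equal(m4[, c("start", "end", "matched")],
               mBig[, c("start", "end", "matched")])
  expect_equal(m4$end, L)
})

test_that("a window shorter than a non-anchored pattern is rejected", {
  x <- singlePassWithMotif("LENL", 5)
  expect_error(scanProteome(x, recyclingPatterns()["LxxL"],
                            searchConfig(windowLen = 3)),
               "shorter than the longest non-anchored pattern")
})

test_that("tightening any filter never adds a passing match", {
  lib <- generateLibrary(seed = 31, n = 50)
  pats <- recyclingPatterns()
  key <- function(m) paste(m$accession, m$pattern, m$start)[m$passes]
  base <- scanProteome(lib$records, pats, searchConfig(windowLen = 100))
  # shrinking the window
  for (w in c(60, 30, 20)) {
    smaller <- scanProteome(lib$records, pats, searchConfig(windowLen = w))
    expect_true(all(key(smaller) %in% key(base)))
    base2 <- smaller
  }
  # requiring cytoplasmic context
  loose <- scanProteome(lib$records, pats,
                        searchConfig(requireCytoplasmic = FALSE))
  strict <- scanProteome(lib$records, pats,
                         searchConfig(requireCytoplasmic = TRUE))
  expect_true(all(key(strict) %in% key(loose)))
  # raising the distance threshold
  d15 <- scanProteome(lib$records, pats,
                      searchConfig(minMembraneDistance = 15))
  d30 <- scanProteome(lib$records, pats,
                      searchConfig(minMembraneDistance = 30))
  expect_true(all(key(d30) %in% key(d15)))
})

test_that("a window at least the longest sequence imposes no constraint", {
  lib <- generateLibrary(seed = 37, n = 30)
  maxLen <- max(Biostrings::width(sequences(lib$records)))
  a <- scanProteome(lib$records, recyclingPatterns(),
                    searchConfig(windowLen = maxLen))
  b <- scanProteome(lib$records, recyclingPatterns(),
                    searchConfig(windowLen = maxLen + 500))
  expect_equal(a, b)
})

test_that("runCensus writes deterministic outputs and stage provenance", {
  lib <- generateLibrary(seed = 41, n = 50)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  runCensus(lib$records, outDir = d1)
  runCensus(lib$records, outDir = d2)
  for (f in c("matches.tsv", "summary.tsv", "proteins.tsv",
              "provenance.json")) {
    expect_identical(readBin(file.path(d1, f), "raw",
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             file.size(file.path(d2, f))),
                     info = f)
  }
  prov <- jsonlite::read_json(file.path(d1, "provenance.json"))
  expect_equal(prov$n_input, 50L)
  expect_true(prov$n_cytoplasmic_tails <= prov$n_input)
  expect_equal(length(prov$patterns), 5L)

  # the same census run from the TSV serialization gives the same summary
  f <- withr::local_tempfile(fileext = ".tsv")
  writeRecordsTSV(lib$records, f)
  fromFile <- runCensus(f)
  fromMem <- runCensus(lib$records)
  expect_equal(fromFile$summary$summary, fromMem$summary$summary)
})

test_that("census equals the independent oracle on synthetic libraries", {
  for (seed in c(43, 47, 53)) {
    lib <- generateLibrary(seed = seed, n = 80)
    m <- scanProteome(filterCytoplasmicTails(lib$records),
                      recyclingPatterns())
    got <- m[m$cytoplasmicOK, c("accession", "pattern", "start", "end")]
    rownames(got) <- NULL
    want <- oracleCensus(lib$records, oraclePatternTable())
    expect_equal(got, want$matches[, c("accession", "pattern", "start",
                                       "end")])
    s <- summarizeCensus(m, recyclingPatterns())
    expect_equal(s$summary, want$summary)
  }
})
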