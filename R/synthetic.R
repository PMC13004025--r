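# Synthetic membrane-protein generator: records with known topology and
# planted motifs, so every pipeline stage can be exercised with exact,
# oracle-recomputed ground truth and no external download.

#' Describe a synthetic membrane topology
#'
#' A `TopologySpec` lays out a protein as
#' `[N-terminal domain][TM1][loop1]...[TMn][C-terminal tail]`, with
#' `TRANSMEM` segments and alternating Cytoplasmic/Extracellular
#' `TOPO_DOM`s tiling the sequence without gaps or overlaps. The side of
#' every domain is implied by `ctermSide` and the number of membrane
#' passes. `nTm = 0` describes a peripheral protein: a single topological
#' domain and no membrane segment (its motifs have undefined membrane
#' distance).
#'
#' @param nTm number of transmembrane segments (0 for peripheral).
#' @param tmLen residues per transmembrane segment (default 21, a typical
#'   helix span).
#' @param ntermLen length of the N-terminal domain (ignored for `nTm = 0`).
#' @param loopLens integer vector of the `nTm - 1` inter-segment loop
#'   lengths (default 15 residues each).
#' @param tailLen length of the C-terminal tail (for `nTm = 0`, the whole
#'   protein length).
#' @param ctermSide which side the C terminus faces.
#' @return object of class `TopologySpec`.
#' @export
topologySpec <- function(nTm, tmLen = 21L, ntermLen = 30L, loopLens = NULL,
                         tailLen = 60L,
                         ctermSide = c("cytoplasmic", "extracellular")) {
  ctermSide <- match.arg(ctermSide)
  if (!isCount(nTm, allowZero = TRUE)) stop("nTm must be >= 0")
  nTm <- as.integer(nTm)
  if (nTm >= 1L) {
    if (is.null(loopLens)) loopLens <- rep(15L, max(0L, nTm - 1L))
    if (length(loopLens) != nTm - 1L)
      stop("loopLens must have nTm - 1 entries")
    if (nTm > 1L && any(loopLens < 1L)) stop("loop lengths must be >= 1")
    if (!isCount(tmLen) || !isCount(ntermLen) || !isCount(tailLen))
      stop("tmLen, ntermLen and tailLen must be positive integers")
  } else {
    loopLens <- integer(0)
    if (!isCount(tailLen)) stop("tailLen must be a positive integer")
  }
  structure(list(nTm = nTm, tmLen = as.integer(tmLen),
                 ntermLen = as.integer(ntermLen),
                 loopLens = as.integer(loopLens),
                 tailLen = as.integer(tailLen), ctermSide = ctermSide),
            class = "TopologySpec")
}

# Side of the domain k transmembrane segments away from the C terminus.
#' @noRd
flipSide <- function(side, times) {
  if (times %% 2L == 0L) side
  else if (side == "cytoplasmic") "extracellular" else "cytoplasmic"
}

#' @noRd
sideNote <- function(side) {
  if (side == "cytoplasmic") "Cytoplasmic" else "Extracellular"
}

# Lay a TopologySpec out as absolute coordinates.
# Returns list(length, features, tailStart, lastTmEnd, loops) where loops is
# a data.frame (index, start, end, side, upstreamTmEnd).
#' @noRd
renderTopology <- function(topo) {
  stopifnot(inherits(topo, "TopologySpec"))
  if (topo$nTm == 0L) {
    L <- topo$tailLen
    feats <- data.frame(kind = "TOPO_DOM", start = 1L, end = L,
                        note = sideNote(topo$ctermSide),
                        stringsAsFactors = FALSE)
    return(list(length = L, features = feats, tailStart = 1L,
                lastTmEnd = NA_integer_,
                loops = data.frame(index = integer(0), start = integer(0),
                                   end = integer(0), side = character(0),
                                   upstreamTmEnd = integer(0))))
  }
  feats <- list()
  loops <- list()
  pos <- 1L
  ntermSide <- flipSide(topo$ctermSide, topo$nTm)
  feats[[1]] <- data.frame(kind = "TOPO_DOM", start = pos,
                           end = pos + topo$ntermLen - 1L,
                           note = sideNote(ntermSide),
                           stringsAsFactors = FALSE)
  pos <- pos + topo$ntermLen
  for (k in seq_len(topo$nTm)) {
    tmStart <- pos
    feats[[length(feats) + 1L]] <- data.frame(
      kind = "TRANSMEM", start = tmStart, end = tmStart + topo$tmLen - 1L,
      note = "Helical", stringsAsFactors = FALSE)
    pos <- tmStart + topo$tmLen
    if (k < topo$nTm) {
      side <- flipSide(topo$ctermSide, topo$nTm - k)
      loopEnd <- pos + topo$loopLens[k] - 1L
      feats[[length(feats) + 1L]] <- data.frame(
        kind = "TOPO_DOM", start = pos, end = loopEnd,
        note = sideNote(side), stringsAsFactors = FALSE)
      loops[[length(loops) + 1L]] <- data.frame(
        index = k, start = pos, end = loopEnd, side = side,
        upstreamTmEnd = pos - 1L, stringsAsFactors = FALSE)
      pos <- loopEnd + 1L
    }
  }
  tailStart <- pos
  L <- pos + topo$tailLen - 1L
  feats[[length(feats) + 1L]] <- data.frame(
    kind = "TOPO_DOM", start = tailStart, end = L,
    note = sideNote(topo$ctermSide), stringsAsFactors = FALSE)
  list(length = L, features = do.call(rbind, feats), tailStart = tailStart,
       lastTmEnd = tailStart - 1L,
       loops = if (length(loops)) do.call(rbind, loops) else
         data.frame(index = integer(0), start = integer(0),
                    end = integer(0), side = character(0),
                    upstreamTmEnd = integer(0)))
}

#' Describe a motif to plant in a synthetic protein
#'
#' @param motif literal residues to plant, e.g. `"LENL"`.
#' @param location `"tail"` for the C-terminal tail, or an integer `k` for
#'   the k-th inter-segment loop. The target region must face the
#'   cytoplasm; requesting a plant in an extracellular region is an error
#'   at generation time.
#' @param distanceFromTm residues between the end of the nearest upstream
#'   membrane segment and the first motif residue (the motif's membrane
#'   distance, exactly, provided the downstream flank is at least as far).
#' @param atCterm if `TRUE`, place the motif flush with the region's last
#'   residue (for C-terminally anchored motifs); `distanceFromTm` is then
#'   ignored.
#' @return object of class `PlantSpec`.
#' @export
plantSpec <- function(motif, location = "tail", distanceFromTm = 20L,
                      atCterm = FALSE) {
  motif <- toupper(motif)
  if (!grepl("^[A-Z]+$", motif)) stop("motif must be residue letters")
  if (!identical(location, "tail")) {
    if (!isCount(location)) stop("location must be 'tail' or a loop index")
    location <- as.integer(location)
  }
  if (!isCount(distanceFromTm, allowZero = TRUE))
    stop("distanceFromTm must be a non-negative integer")
  structure(list(motif = motif, location = location,
                 distanceFromTm = as.integer(distanceFromTm),
                 atCterm = isTRUE(atCterm)),
            class = "PlantSpec")
}

#' Background residue composition for synthetic sequences
#'
#' Sampling weights over the 20 standard residues used to draw background
#' sequence. Residues that are critical for the built-in motif classes
#' (L; the aromatic/hydrophobic consensus residues F, Y, W, V, M; N; and
#' the PDZ residues D, E, S, T) are down-weighted to `rareWeight` so that
#' accidental motif occurrences stay rare but non-zero — ground truth is
#' recomputed from the emitted sequences rather than assumed accident-free.
#'
#' @param rareWeight relative weight of the down-weighted residues (others
#'   have weight 1).
#' @return named numeric vector of sampling probabilities summing to 1.
#' @export
backgroundComposition <- function(rareWeight = 0.35) {
  w <- stats::setNames(rep(1, length(AA20)), AA20)
  w[c("L", "F", "Y", "W", "V", "M", "N", "D", "E", "S", "T")] <- rareWeight
  w / sum(w)
}

#' Generate one synthetic membrane protein
#'
#' Draws a background sequence from `composition`, overwrites the planted
#' motifs at their exact requested positions, and renders the topology as
#' `TOPO_DOM`/`TRANSMEM` features. Deterministic for a fixed seed.
#'
#' Errors: planting into a region that does not face the cytoplasm;
#' a tail or loop too short to hold the motif at the requested membrane
#' distance (for loops, the downstream flank must be at least the requested
#' distance so that the two-sided membrane distance equals it exactly).
#'
#' @param topo a [topologySpec()].
#' @param plants list of [plantSpec()]s.
#' @param accession,entryName identifiers for the record.
#' @param composition named sampling weights over residues (see
#'   [backgroundComposition()]).
#' @param seed optional integer; when given, generation runs under this
#'   seed and the caller's RNG state is untouched.
#' @return list with `record` (a one-protein [TopoProteinSet-class]) and
#'   `plants` (data.frame `accession`, `motif`, `start`, `end`).
#' @export
generateProtein <- function(topo, plants = list(), accession = "SYN0001",
                            entryName = accession,
                            composition = backgroundComposition(),
                            seed = NULL) {
  if (inherits(plants, "PlantSpec")) plants <- list(plants)
  build <- function() {
    layout <- renderTopology(topo)
    chars <- sample(names(composition), layout$length, replace = TRUE,
                    prob = composition)
    planted <- list()
    for (pl in plants) {
      stopifnot(inherits(pl, "PlantSpec"))
      mlen <- nchar(pl$motif)
      if (identical(pl$location, "tail")) {
        regionStart <- layout$tailStart
        regionEnd <- layout$length
        regionSide <- topo$ctermSide
        upstreamTmEnd <- layout$lastTmEnd
      } else {
        li <- layout$loops[layout$loops$index == pl$location, , drop = FALSE]
        if (nrow(li) == 0L)
          stop(sprintf("no loop %d in this topology", pl$location))
        regionStart <- li$start; regionEnd <- li$end
        regionSide <- li$side
        upstreamTmEnd <- li$upstreamTmEnd
      }
      if (regionSide != "cytoplasmic")
        stop(sprintf("plant region (%s) is not cytoplasmic",
                     if (identical(pl$location, "tail")) "tail"
                     else paste0("loop ", pl$location)))
      if (pl$atCterm) {
        s <- regionEnd - mlen + 1L
        if (s < regionStart) stop("region too short for C-terminal plant")
      } else if (is.na(upstreamTmEnd)) {
        # peripheral protein: no membrane reference, place near the C terminus
        s <- max(regionStart, layout$length - mlen - 10L)
      } else {
        s <- upstreamTmEnd + pl$distanceFromTm + 1L
        e <- s + mlen - 1L
        if (e > regionEnd)
          stop(sprintf(
            "%s too short for motif at membrane distance %d",
            if (identical(pl$location, "tail")) "tail" else "loop",
            pl$distanceFromTm))
        if (!identical(pl$location, "tail")) {
          downstreamGap <- regionEnd - e
          if (downstreamGap < pl$distanceFromTm)
            stop(sprintf(
              "loop too short for motif at membrane distance %d",
              pl$distanceFromTm))
        }
      }
      e <- s + mlen - 1L
      chars[s:e] <- strsplit(pl$motif, "", fixed = TRUE)[[1]]
      planted[[length(planted) + 1L]] <- data.frame(
        accession = accession, motif = pl$motif, start = s, end = e,
        stringsAsFactors = FALSE)
    }
    seqs <- stats::setNames(paste(chars, collapse = ""), accession)
    ft <- cbind(accession = accession, layout$features,
                stringsAsFactors = FALSE)
    record <- TopoProteinSet(seqs, entryNames = entryName, features = ft,
                             provenance = "synthetic: generateProtein")
    plantsDf <- if (length(planted)) do.call(rbind, planted) else
      data.frame(accession = character(0), motif = character(0),
                 start = integer(0), end = integer(0),
                 stringsAsFactors = FALSE)
    list(record = record, plants = plantsDf)
  }
  if (is.null(seed)) build() else withSeed(seed, build())
}

#' Default archetype mix for synthetic libraries
#'
#' Proportions of protein archetypes emitted by [generateLibrary()]:
#' single-pass proteins with a cytoplasmic tail carrying a planted
#' bileucine motif (0.30), plain single-pass cytoplasmic-tail proteins
#' (0.20), multi-pass proteins with a bileucine plant in the tail (0.15)
#' or in a cytoplasmic loop (0.10), single-pass proteins with an
#' extracellular C terminus (0.15), peripheral proteins without membrane
#' segments (0.05), and single-pass proteins with a C-terminally anchored
#' PDZ-type plant (0.05).
#'
#' @return data.frame with columns `archetype`, `prob` (summing to 1).
#' @export
defaultArchetypeMix <- function() {
  data.frame(
    archetype = c("single_cyto_lxxl", "single_cyto", "multi_tail_lxxl",
                  "multi_loop_lxxl", "single_extracellular", "peripheral",
                  "single_pdz"),
    prob = c(0.30, 0.20, 0.15, 0.10, 0.15, 0.05, 0.05),
    stringsAsFactors = FALSE)
}

LXXL_PLANTS <- c("LENL", "LEYL", "LTKL", "LEVL", "LAAL", "LSRL")
PDZ_PLANTS <- c("ETAL", "DSAV", "ESGL")

#' @noRd
drawArchetype <- function(name) {
  # uniform integer draw safe against R's scalar sample() expansion
  rint <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L
  switch(name,
    single_cyto_lxxl = {
      tailLen <- rint(40L, 120L)
      dist <- rint(5L, min(40L, tailLen - 6L))
      list(topo = topologySpec(1L, ntermLen = rint(20L, 60L),
                               tailLen = tailLen),
           plants = list(plantSpec(sample(LXXL_PLANTS, 1L),
                                   distanceFromTm = dist)))
    },
    single_cyto = list(
      topo = topologySpec(1L, ntermLen = rint(20L, 60L),
                          tailLen = rint(20L, 120L)),
      plants = list()),
    multi_tail_lxxl = {
      nTm <- sample(c(2L, 3L, 4L, 7L), 1L)
      tailLen <- rint(40L, 100L)
      dist <- rint(5L, min(40L, tailLen - 6L))
      list(topo = topologySpec(nTm, ntermLen = rint(15L, 40L),
                               loopLens = sample(8:40, nTm - 1L,
                                                 replace = TRUE),
                               tailLen = tailLen),
           plants = list(plantSpec(sample(LXXL_PLANTS, 1L),
                                   distanceFromTm = dist)))
    },
    multi_loop_lxxl = {
      # loop 1 of a 3-pass protein faces the cytoplasm when the tail does
      dist <- rint(3L, 20L)
      loop1 <- 2L * dist + 4L + rint(0L, 10L)
      list(topo = topologySpec(3L, ntermLen = rint(15L, 40L),
                               loopLens = c(loop1, rint(8L, 25L)),
                               tailLen = rint(20L, 80L)),
           plants = list(plantSpec(sample(LXXL_PLANTS, 1L), location = 1L,
                                   distanceFromTm = dist)))
    },
    single_extracellular = list(
      topo = topologySpec(1L, ntermLen = rint(20L, 60L),
                          tailLen = rint(20L, 120L),
                          ctermSide = "extracellular"),
      plants = list()),
    peripheral = list(
      topo = topologySpec(0L, tailLen = rint(80L, 200L)),
      plants = list(plantSpec(sample(LXXL_PLANTS, 1L)))),
    single_pdz = list(
      topo = topologySpec(1L, ntermLen = rint(20L, 60L),
                          tailLen = rint(20L, 100L)),
      plants = list(plantSpec(sample(PDZ_PLANTS, 1L), atCterm = TRUE))),
    stop("unknown archetype: ", name))
}

#' Generate a synthetic membrane proteome with exact ground truth
#'
#' Draws `n` proteins from the archetype mix, plants motifs as specified,
#' and recomputes the per-pattern ground truth from the emitted sequences
#' with an independent route (regular-expression scan plus the interval
#' predicates), so accidental background matches are part of the truth by
#' construction. Identical seeds produce byte-identical libraries.
#'
#' @param seed integer RNG seed.
#' @param n number of proteins (positive).
#' @param mix data.frame with columns `archetype`, `prob` (see
#'   [defaultArchetypeMix()]); probabilities must sum to 1.
#' @param patterns pattern list for the ground-truth recount (default
#'   [recyclingPatterns()]).
#' @param config the [searchConfig()] the truth is computed under.
#' @param composition background residue weights.
#' @return list with `records` (a [TopoProteinSet-class]), `truth` (per
#'   pattern: sorted accession sets `accessions` and, when the pattern has
#'   a distance threshold, `accessionsDistanceFiltered`), `plants`
#'   (data.frame of planted intervals) and `seed`.
#' @export
generateLibrary <- function(seed, n, mix = defaultArchetypeMix(),
                            patterns = recyclingPatterns(),
                            config = searchConfig(),
                            composition = backgroundComposition()) {
  if (!isCount(n)) stop("n must be a positive integer")
  stopifnot(is.data.frame(mix),
            all(c("archetype", "prob") %in% names(mix)))
  if (abs(sum(mix$prob) - 1) > 1e-8)
    stop("archetype proportions must sum to 1")
  out <- withSeed(seed, {
    seqsList <- character(n)
    accs <- sprintf("SYN%04d", seq_len(n))
    ftList <- vector("list", n)
    plantList <- vector("list", n)
    kinds <- sample(mix$archetype, n, replace = TRUE, prob = mix$prob)
    for (i in seq_len(n)) {
      spec <- drawArchetype(kinds[i])
      gp <- generateProtein(spec$topo, spec$plants, accession = accs[i],
                            entryName = paste0(kinds[i], "_", accs[i]),
                            composition = composition)
      seqsList[i] <- as.character(sequences(gp$record)[[1]])
      ft <- as.data.frame(features(gp$record))
      ftList[[i]] <- ft
      plantList[[i]] <- gp$plants
    }
    records <- TopoProteinSet(
      stats::setNames(seqsList, accs),
      entryNames = paste0(kinds, "_", accs),
      features = do.call(rbind, ftList),
      provenance = sprintf("synthetic library: seed %d, n %d", seed, n))
    list(records = records, plants = do.call(rbind, plantList))
  })
  truth <- regexRecount(out$records, patterns, config)
  list(records = out$records, truth = truth, plants = out$plants,
       seed = as.integer(seed))
}

# Independent recount used for ground truth: regex matching (via
# patternToRegex and zero-width lookahead) instead of the element scanner,
# plus the interval predicates. Returns per-pattern passing accession sets.
#' @noRd
regexRecount <- function(x, patterns, config = searchConfig()) {
  ftByAcc <- splitFeatures(x)
  accs <- accessions(x)
  seqs <- as.character(sequences(x))
  widths <- Biostrings::width(sequences(x))
  truth <- list()
  for (p in patterns) {
    thr <- if (!is.na(p@minMembraneDistance)) p@minMembraneDistance
           else config$minMembraneDistance
    passAcc <- character(0)
    passAccDist <- character(0)
    for (i in seq_along(accs)) {
      L <- widths[i]
      ft <- ftByAcc[[accs[i]]]
      if (ctermClassOne(ft, L) != "CYTOPLASMIC") next
      if (p@anchorCterm) {
        hit <- regexpr(paste0("(?=", patternToRegex(p, anchored = FALSE),
                              "$)"), seqs[i], perl = TRUE)
        starts <- if (hit[1] == -1L) integer(0) else as.integer(hit[1])
      } else {
        wstart <- max(1L, L - config$windowLen + 1L)
        win <- substring(seqs[i], wstart, L)
        hit <- gregexpr(paste0("(?=", patternToRegex(p, anchored = FALSE),
                               ")"), win, perl = TRUE)[[1]]
        starts <- if (hit[1] == -1L) integer(0) else
          as.integer(hit) + wstart - 1L
      }
      for (s in starts) {
        e <- s + patternLength(p) - 1L
        if (config$requireCytoplasmic &&
            is.null(enclosingCytoOne(ft, s, e))) next
        passAcc <- union(passAcc, accs[i])
        if (!is.na(thr)) {
          d <- membraneDistanceOne(ft, s, e)
          if (is.na(d) || d >= thr)
            passAccDist <- union(passAccDist, accs[i])
        }
      }
    }
    truth[[p@name]] <- list(
      accessions = sort(passAcc, method = "radix"),
      accessionsDistanceFiltered =
        if (is.na(thr)) NULL else sort(passAccDist, method = "radix"))
  }
  truth
}

#' Write a synthetic library to disk
#'
#' Writes `records.tsv` (UniProt-style dialect, [writeRecordsTSV()]),
#' `records.json` ([writeRecordsJSON()]) and `truth.json` (planted
#' intervals and per-pattern ground-truth accession sets) into `outDir`.
#' Deterministic: the same library always produces byte-identical files.
#'
#' @param lib result of [generateLibrary()].
#' @param outDir output directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
writeLibrary <- function(lib, outDir) {
  stopifnot(is.list(lib), methods::is(lib$records, "TopoProteinSet"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeRecordsTSV(lib$records, file.path(outDir, "records.tsv"))
  writeRecordsJSON(lib$records, file.path(outDir, "records.json"))
  jsonlite::write_json(
    list(seed = lib$seed, plants = lib$plants, truth = lib$truth),
    file.path(outDir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(outDir)
}

# Printed worked-example peptides embedded in synthetic scaffolds.
# Each fixture is a synthetic single-pass protein: deterministic
# glycine/serine filler (which matches none of the built-in motif
# classes), one transmembrane segment, an extracellular N-terminal domain
# and a cytoplasmic tail that carries the peptide at its published
# coordinates. The fixtures certify coordinates and topology handling,
# not native sequence context.
PEPTIDE_FIXTURES <- list(
  list(accession = "SYN-GLUT4", entry = "GLUT4_SYNTHETIC",
       peptide = "TELEYLGP", pepStart = 498L, length = 505L,
       tm = c(449L, 469L)),
  list(accession = "SYN-MOR", entry = "MOR_SYNTHETIC",
       peptide = "QLENLE", pepStart = 406L, length = 411L,
       tm = c(350L, 370L)),
  list(accession = "SYN-DMT1", entry = "DMT1II_SYNTHETIC",
       peptide = "QPELYLL", pepStart = 551L, length = 557L,
       tm = c(500L, 520L)),
  list(accession = "SYN-ADCY9", entry = "ADCY9_SYNTHETIC",
       peptide = "LTKL", pepStart = 1344L, length = 1353L,
       tm = c(1280L, 1300L)),
  list(accession = "SYN-SLC12A7", entry = "S12A7_SYNTHETIC",
       peptide = "LEVL", pepStart = 1058L, length = 1083L,
       tm = c(1000L, 1020L)),
  list(accession = "SYN-PLXNA1", entry = "PLXNA1_SYNTHETIC",
       peptide = "LAAL", pepStart = 1867L, length = 1896L,
       tm = c(1800L, 1820L))
)

#' Synthetic scaffolds carrying published worked-example peptides
#'
#' Returns six synthetic full-length records, each embedding a published
#' C-terminal recycling-motif peptide at its published coordinates: the
#' GLUT4 tail peptide TELEYLGP (residues 498-505, bileucine LEYL at 500),
#' the MOR recycling sequence core QLENLE (Q406, leucines 407 and 410),
#' the DMT1-II tail QPELYLL (551-557, leucines 554 and 557), and the
#' bileucine contexts of adenylyl cyclase 9 (1344-LTKL), SLC12A7
#' (1058-LEVL) and plexin A1 (1867-LAAL). The scaffolds are deterministic
#' glycine/serine filler with a single transmembrane segment and a
#' cytoplasmic C-terminal tail, so the only motif matches are the
#' embedded peptides; they are synthetic stand-ins that certify
#' coordinates, not native sequences.
#'
#' @return a [TopoProteinSet-class] of six records.
#' @examples
#' fx <- syntheticPeptideFixtures()
#' scanProteome(fx["SYN-GLUT4"], recyclingPatterns()["LxxL"])
#' @export
syntheticPeptideFixtures <- function() {
  gsFill <- function(L) paste(rep_len(c("G", "S"), L), collapse = "")
  seqs <- character(0)
  ftList <- list()
  for (fx in PEPTIDE_FIXTURES) {
    chars <- strsplit(gsFill(fx$length), "", fixed = TRUE)[[1]]
    s <- fx$pepStart
    e <- s + nchar(fx$peptide) - 1L
    stopifnot(e <= fx$length, s > fx$tm[2])
    chars[s:e] <- strsplit(fx$peptide, "", fixed = TRUE)[[1]]
    seqs[fx$accession] <- paste(chars, collapse = "")
    ftList[[length(ftList) + 1L]] <- data.frame(
      accession = fx$accession,
      kind = c("TOPO_DOM", "TRANSMEM", "TOPO_DOM"),
      start = c(1L, fx$tm[1], fx$tm[2] + 1L),
      end = c(fx$tm[1] - 1L, fx$tm[2], fx$length),
      note = c("Extracellular", "Helical", "Cytoplasmic"),
      stringsAsFactors = FALSE)
  }
  TopoProteinSet(seqs,
                 entryNames = vapply(PEPTIDE_FIXTURES, `[[`, character(1),
                                     "entry"),
                 features = do.call(rbind, ftList),
                 provenance = "synthetic peptide fixtures")
}
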