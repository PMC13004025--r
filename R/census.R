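#' Census search configuration
#'
#' Bundles the positional constraints applied during a proteome motif
#' census: the C-terminal search window, whether a match must lie inside a
#' cytoplasmic topological domain, an optional global minimum membrane
#' distance, and whether the per-pattern protein lists are deduplicated.
#'
#' The window restricts non-anchored patterns to the last `windowLen`
#' residues of each protein (the whole sequence when shorter), with the
#' entire match required inside the window. C-terminally anchored patterns
#' are evaluated at the C terminus only, independent of the window, so a
#' PDZ-type motif is always tested against the final residues of the
#' protein.
#'
#' @param windowLen positive integer; C-terminal window length (default 100).
#' @param requireCytoplasmic logical; require each match to lie fully inside
#'   a cytoplasmic topological domain (default `TRUE`).
#' @param minMembraneDistance optional integer applied to every pattern that
#'   does not carry its own threshold; `NA` (default) disables it.
#' @param dedupe logical; collapse per-pattern protein lists to unique
#'   proteins (default `TRUE`).
#' @return an object of class `SearchConfig` (a validated list).
#' @export
searchConfig <- function(windowLen = 100L, requireCytoplasmic = TRUE,
                         minMembraneDistance = NA_integer_, dedupe = TRUE) {
  if (!isCount(windowLen)) stop("windowLen must be a positive integer")
  if (!is.na(minMembraneDistance) &&
      !isCount(minMembraneDistance, allowZero = TRUE))
    stop("minMembraneDistance must be a non-negative integer or NA")
  structure(list(
    windowLen = as.integer(windowLen),
    requireCytoplasmic = isTRUE(requireCytoplasmic),
    minMembraneDistance = if (is.na(minMembraneDistance)) NA_integer_
                          else as.integer(minMembraneDistance),
    dedupe = isTRUE(dedupe)
  ), class = "SearchConfig")
}

#' @export
print.SearchConfig <- function(x, ...) {
  cat(sprintf(
    "SearchConfig: window %d aa, cytoplasmic %s, min membrane distance %s, dedupe %s\n",
    x$windowLen, if (x$requireCytoplasmic) "required" else "not required",
    if (is.na(x$minMembraneDistance)) "none" else x$minMembraneDistance,
    if (x$dedupe) "on" else "off"))
  invisible(x)
}

#' Keep only proteins with cytoplasmic C termini
#'
#' Retains exactly the proteins whose C terminus classifies as
#' `CYTOPLASMIC` (see [classifyCterm()]); proteins with extracellular,
#' otherwise-annotated or unannotated C termini are dropped. The counts
#' before and after, with the class breakdown, are appended to the set's
#' provenance.
#'
#' @param x a [TopoProteinSet-class].
#' @return the filtered [TopoProteinSet-class].
#' @export
filterCytoplasmicTails <- function(x) {
  stopifnot(methods::is(x, "TopoProteinSet"))
  if (length(x) == 0L) return(x)
  cls <- classifyCterm(x)
  keep <- which(cls == "CYTOPLASMIC")
  breakdown <- table(cls)
  out <- x[keep]
  provenance(out) <- c(provenance(x), sprintf(
    "cytoplasmic-tail filter: kept %d of %d (%s)",
    length(keep), length(x),
    paste(sprintf("%s=%d", names(breakdown), as.integer(breakdown)),
          collapse = ", ")))
  out
}

#' Scan a proteome for motif matches with topology annotation
#'
#' Runs every pattern against the C-terminal search window of every protein
#' and annotates each raw occurrence with its topological context and
#' filter verdicts. All overlapping occurrences are reported. For each
#' match the output records the protein's C-terminus class, the note of the
#' cytoplasmic domain fully containing the match (if any), the membrane
#' distance (see [membraneDistance()]; `NA` when the protein has no
#' flanking membrane segment), and the per-filter verdicts:
#'
#' * `cytoplasmicOK` — match lies fully inside a cytoplasmic topological
#'   domain, or the cytoplasmic requirement is disabled;
#' * `distanceOK` — membrane distance meets the pattern's threshold (or the
#'   config-wide threshold); `NA` when no threshold applies. An undefined
#'   membrane distance passes the threshold but is flagged in
#'   `distanceUndefined`;
#' * `passes` — all applicable filters hold.
#'
#' Output rows are sorted by accession, pattern name, start; the pipeline
#' is fully deterministic.
#'
#' @param x a [TopoProteinSet-class].
#' @param patterns list of [MotifPattern-class] (e.g.
#'   [recyclingPatterns()]).
#' @param config a [searchConfig()].
#' @return data.frame of annotated matches (possibly zero rows) with
#'   columns `accession`, `pattern`, `start`, `end`, `matched`,
#'   `ctermClass`, `domainNote`, `membraneDistance`, `distanceUndefined`,
#'   `cytoplasmicOK`, `distanceOK`, `passes`, `reasons`.
#' @export
scanProteome <- function(x, patterns, config = searchConfig()) {
  stopifnot(methods::is(x, "TopoProteinSet"),
            inherits(config, "SearchConfig"))
  if (methods::is(patterns, "MotifPattern")) patterns <- list(patterns)
  stopifnot(all(vapply(patterns, methods::is, logical(1), "MotifPattern")))
  lens <- vapply(patterns, patternLength, integer(1))
  anchored <- vapply(patterns, function(p) p@anchorCterm, logical(1))
  if (any(!anchored) && config$windowLen < max(lens[!anchored]))
    stop("windowLen is shorter than the longest non-anchored pattern")
  ftByAcc <- splitFeatures(x)
  widths <- Biostrings::width(sequences(x))
  accs <- accessions(x)
  seqs <- as.character(sequences(x))
  cterm <- as.character(classifyCterm(x))
  rows <- list()
  for (i in seq_along(accs)) {
    L <- widths[i]
    ft <- ftByAcc[[accs[i]]]
    for (p in patterns) {
      if (p@anchorCterm) {
        raw <- scanSequence(p, seqs[i], offset = 1L)
      } else {
        wstart <- max(1L, L - config$windowLen + 1L)
        raw <- scanSequence(p, substring(seqs[i], wstart, L),
                            offset = wstart)
      }
      if (nrow(raw) == 0L) next
      thr <- if (!is.na(p@minMembraneDistance)) p@minMembraneDistance
             else config$minMembraneDistance
      for (k in seq_len(nrow(raw))) {
        s <- raw$start[k]; e <- raw$end[k]
        encl <- enclosingCytoOne(ft, s, e)
        dist <- membraneDistanceOne(ft, s, e)
        cytoOK <- !config$requireCytoplasmic || !is.null(encl)
        distOK <- if (is.na(thr)) NA
                  else is.na(dist) || dist >= thr
        passes <- cytoOK && (is.na(distOK) || distOK)
        reasons <- character(0)
        if (!cytoOK) reasons <- c(reasons, "not cytoplasmic")
        if (isFALSE(distOK)) reasons <- c(reasons, "too close to membrane")
        rows[[length(rows) + 1L]] <- data.frame(
          accession = accs[i],
          pattern = p@name,
          start = s, end = e, matched = raw$matched[k],
          ctermClass = cterm[i],
          domainNote = if (is.null(encl)) NA_character_ else encl$note,
          membraneDistance = dist,
          distanceUndefined = is.na(dist),
          cytoplasmicOK = cytoOK,
          distanceOK = distOK,
          passes = passes,
          reasons = paste(reasons, collapse = "; "),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else emptyMatchFrame()
  out <- out[order(out$accession, out$pattern, out$start,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @noRd
emptyMatchFrame <- function() {
  data.frame(accession = character(0), pattern = character(0),
             start = integer(0), end = integer(0), matched = character(0),
             ctermClass = character(0), domainNote = character(0),
             membraneDistance = integer(0), distanceUndefined = logical(0),
             cytoplasmicOK = logical(0), distanceOK = logical(0),
             passes = logical(0), reasons = character(0),
             stringsAsFactors = FALSE)
}

#' Filter matches by membrane distance
#'
#' Keeps the matches whose membrane distance is at least `minDistance`.
#' Matches with an undefined distance (protein without a flanking membrane
#' segment) are kept — the filter targets membrane-anchored cargo and
#' silently dropping unannotated proteins would hide data — but remain
#' flagged via their `distanceUndefined` column.
#'
#' @param matches match data.frame from [scanProteome()].
#' @param minDistance non-negative integer threshold (e.g. 15 for the
#'   bileucine/Retromer criterion).
#' @return subset of `matches`.
#' @export
applyMembraneFilter <- function(matches, minDistance) {
  stopifnot(is.data.frame(matches),
            isCount(minDistance, allowZero = TRUE))
  keep <- is.na(matches$membraneDistance) |
    matches$membraneDistance >= minDistance
  out <- matches[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a motif census
#'
#' Tallies the scan results per pattern on matches that pass the window and
#' cytoplasmic filters: the number of matches, the number of unique
#' proteins, and — for patterns carrying a membrane-distance threshold (or
#' under a config-wide threshold) — the number of unique proteins whose
#' match also satisfies that distance, mirroring the two-stage parse in
#' which a motif list is first deduplicated and then distance-filtered.
#'
#' @param matches match data.frame from [scanProteome()].
#' @param patterns the pattern list used for the scan (so patterns with zero
#'   matches still appear).
#' @param config the [searchConfig()] used for the scan.
#' @return list of class `CensusSummary` with elements
#'   `summary` (per-pattern data.frame: `pattern`, `nMatches`,
#'   `nUniqueProteins`, `nUniqueProteinsDistanceFiltered`) and `proteins`
#'   (per pattern x protein: the most C-terminal passing match, with an
#'   empty `proteinClass` column reserved for external annotation).
#' @export
summarizeCensus <- function(matches, patterns, config = searchConfig()) {
  stopifnot(is.data.frame(matches))
  if (methods::is(patterns, "MotifPattern")) patterns <- list(patterns)
  summaryRows <- list()
  proteinRows <- list()
  for (p in patterns) {
    thr <- if (!is.na(p@minMembraneDistance)) p@minMembraneDistance
           else config$minMembraneDistance
    sub <- matches[matches$pattern == p@name & matches$cytoplasmicOK, ,
                   drop = FALSE]
    nMatches <- nrow(sub)
    uniq <- unique(sub$accession)
    nUniqueDist <- if (is.na(thr)) NA_integer_ else {
      ok <- is.na(sub$membraneDistance) | sub$membraneDistance >= thr
      length(unique(sub$accession[ok]))
    }
    summaryRows[[length(summaryRows) + 1L]] <- data.frame(
      pattern = p@name,
      nMatches = nMatches,
      nUniqueProteins = length(uniq),
      nUniqueProteinsDistanceFiltered = nUniqueDist,
      stringsAsFactors = FALSE)
    if (nMatches) {
      accGroups <- if (isTRUE(config$dedupe)) split(sub, sub$accession)
                   else split(sub, seq_len(nrow(sub)))
      for (grp in accGroups) {
        best <- grp[which.max(grp$start), , drop = FALSE]
        best$proteinClass <- ""
        proteinRows[[length(proteinRows) + 1L]] <-
          best[, c("pattern", "accession", "start", "end", "matched",
                   "membraneDistance", "distanceUndefined", "proteinClass"),
               drop = FALSE]
      }
    }
  }
  proteins <- if (length(proteinRows)) do.call(rbind, proteinRows) else
    data.frame(pattern = character(0), accession = character(0),
               start = integer(0), end = integer(0), matched = character(0),
               membraneDistance = integer(0), distanceUndefined = logical(0),
               proteinClass = character(0), stringsAsFactors = FALSE)
  proteins <- proteins[order(proteins$pattern, proteins$accession,
                             method = "radix"), , drop = FALSE]
  rownames(proteins) <- NULL
  structure(list(summary = do.call(rbind, summaryRows), proteins = proteins),
            class = "CensusSummary")
}

#' @export
print.CensusSummary <- function(x, ...) {
  cat("Motif census summary\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("%d protein entries listed\n", nrow(x$proteins)))
  invisible(x)
}

#' Run the end-to-end motif census
#'
#' Orchestrates the full workflow: read the proteome (TSV export, JSON
#' fixture, or an in-memory [TopoProteinSet-class]), keep proteins with
#' cytoplasmic C termini, scan the configured patterns in the C-terminal
#' window, annotate topology and membrane distance, and summarize per
#' pattern. Fully deterministic: the same inputs always produce
#' byte-identical outputs.
#'
#' @param records a [TopoProteinSet-class], or a path to a records TSV
#'   (read with [readRecordsTSV()]) or `.json` fixture (read with
#'   [readRecordsJSON()]).
#' @param patterns list of [MotifPattern-class], or a path to a pattern TSV
#'   (read with [readPatternTable()]); defaults to [recyclingPatterns()].
#' @param config a [searchConfig()].
#' @param outDir optional output directory; when given, writes
#'   `matches.tsv` (all matches with filter verdicts, for audit),
#'   `summary.tsv`, `proteins.tsv` (deduplicated per-pattern protein lists
#'   with the reserved `proteinClass` column) and `provenance.json`
#'   (per-stage counts and configuration).
#' @return invisibly, a list with `records` (filtered set), `matches`,
#'   `summary` (a `CensusSummary`) and `provenance`.
#' @export
runCensus <- function(records, patterns = recyclingPatterns(),
                      config = searchConfig(), outDir = NULL) {
  if (is.character(records)) {
    records <- if (grepl("\\.json$", records, ignore.case = TRUE))
      readRecordsJSON(records) else readRecordsTSV(records)
  }
  stopifnot(methods::is(records, "TopoProteinSet"))
  if (is.character(patterns)) patterns <- readPatternTable(patterns)
  nInput <- length(records)
  cls <- if (nInput) classifyCterm(records) else factor(character(0))
  filtered <- withCallingHandlers(
    filterCytoplasmicTails(records),
    error = function(e) stop("cytoplasmic-tail filter: ",
                             conditionMessage(e)))
  matches <- withCallingHandlers(
    scanProteome(filtered, patterns, config),
    error = function(e) stop("proteome scan: ", conditionMessage(e)))
  summary <- withCallingHandlers(
    summarizeCensus(matches, patterns, config),
    error = function(e) stop("census summary: ", conditionMessage(e)))
  prov <- list(
    tool = "topomotif runCensus",
    package_version = as.character(utils::packageVersion("topomotif")),
    input_provenance = provenance(records),
    n_input = nInput,
    cterm_breakdown = as.list(table(cls)),
    n_cytoplasmic_tails = length(filtered),
    patterns = lapply(patterns, function(p) list(
      name = p@name, pattern = p@sourceText,
      anchor_cterm = p@anchorCterm,
      min_membrane_distance = p@minMembraneDistance)),
    config = unclass(config),
    n_matches = nrow(matches),
    n_passing_matches = sum(matches$passes)
  )
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTsv(matches, file.path(outDir, "matches.tsv"))
    writeTsv(summary$summary, file.path(outDir, "summary.tsv"))
    writeTsv(summary$proteins, file.path(outDir, "proteins.tsv"))
    jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(records = filtered, matches = matches, summary = summary,
                 provenance = prov))
}
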