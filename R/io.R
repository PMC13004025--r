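#' Parse a UniProt tabular feature column
#'
#' UniProt TSV exports encode features of one kind as semicolon-separated
#' tokens, e.g. `TOPO_DOM 1..5; /note="Extracellular"; TOPO_DOM 27..80;
#' /note="Cytoplasmic"`. Each `KIND a..b` token opens a feature; a following
#' `/note="..."` qualifier is captured as its note; all other qualifiers
#' (`/evidence=...` etc.) are ignored.
#'
#' @param text feature column text for one protein (may be empty or `NA`).
#' @param kind feature kind expected in this column: `"TOPO_DOM"`,
#'   `"TRANSMEM"` or `"INTRAMEM"`.
#' @return data.frame with columns `kind`, `start`, `end`, `note` (1-based
#'   inclusive coordinates); zero rows for empty input.
#' @examples
#' parseFeatureString(
#'   'TOPO_DOM 1..5; /note="Extracellular"; TOPO_DOM 27..80; /note="Cytoplasmic"',
#'   "TOPO_DOM")
#' @export
parseFeatureString <- function(text, kind = c("TOPO_DOM", "TRANSMEM",
                                              "INTRAMEM")) {
  kind <- match.arg(kind)
  empty <- data.frame(kind = character(0), start = integer(0),
                      end = integer(0), note = character(0),
                      stringsAsFactors = FALSE)
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    return(empty)
  tokens <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  # re-join tokens split inside a quoted qualifier value
  # (e.g. /note="Cytoplasmic; in dimer")
  merged <- character(0)
  for (tok in tokens) {
    open <- length(merged) &&
      nchar(gsub('[^"]', "", merged[length(merged)])) %% 2L == 1L
    if (open) merged[length(merged)] <-
        paste0(merged[length(merged)], "; ", tok)
    else merged <- c(merged, tok)
  }
  tokens <- merged
  feats <- list()
  for (tok in tokens) {
    if (startsWith(tok, paste0(kind, " ")) || tok == kind) {
      body <- trimws(sub(paste0("^", kind), "", tok))
      m <- regmatches(body, regexec("^([0-9]+)\\.\\.([0-9]+)$", body))[[1]]
      if (length(m) != 3L)
        stop(sprintf("malformed interval in %s token '%s'", kind, tok))
      s <- as.integer(m[2]); e <- as.integer(m[3])
      if (s > e)
        stop(sprintf("inverted interval in %s token '%s'", kind, tok))
      feats[[length(feats) + 1L]] <- list(start = s, end = e, note = "")
    } else if (startsWith(tok, "/note=")) {
      if (length(feats)) {
        note <- sub("^/note=", "", tok)
        note <- gsub('^"|"$', "", note)
        feats[[length(feats)]]$note <- note
      }
    } else if (startsWith(tok, "/")) {
      next  # other qualifiers (/evidence=...) are ignored
    } else {
      stop(sprintf("unrecognized token '%s' in %s feature text", tok, kind))
    }
  }
  if (!length(feats)) return(empty)
  data.frame(
    kind = kind,
    start = vapply(feats, `[[`, integer(1), "start"),
    end = vapply(feats, `[[`, integer(1), "end"),
    note = vapply(feats, `[[`, character(1), "note"),
    stringsAsFactors = FALSE
  )
}

#' Read protein records from a UniProt-style TSV export
#'
#' Expects a tab-separated file with one protein per row. Default column
#' names match a UniProt export (`Entry`, `Entry Name`, `Sequence`,
#' `Topological domain`, `Transmembrane`, `Intramembrane`); the mapping is
#' configurable via `columns`. Feature columns are parsed with
#' [parseFeatureString()]. Rows with an empty sequence are rejected.
#'
#' @param file path to the TSV.
#' @param columns named list overriding the default column mapping; names
#'   among `accession`, `entryName`, `sequence`, `topoDom`, `transmem`,
#'   `intramem`. `entryName`, `topoDom`, `transmem` and `intramem` columns
#'   are optional in the file.
#' @return a [TopoProteinSet-class].
#' @export
readRecordsTSV <- function(file, columns = list()) {
  defaults <- list(accession = "Entry", entryName = "Entry Name",
                   sequence = "Sequence", topoDom = "Topological domain",
                   transmem = "Transmembrane", intramem = "Intramembrane")
  cols <- utils::modifyList(defaults, columns)
  df <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", colClasses = "character",
                          na.strings = NULL)
  for (need in c("accession", "sequence")) {
    if (!(cols[[need]] %in% names(df)))
      stop(sprintf("required column '%s' not found in %s", cols[[need]], file))
  }
  if (nrow(df) == 0L)
    return(TopoProteinSet(stats::setNames(character(0), character(0)),
                          provenance = paste0("records TSV: ", file)))
  acc <- trimws(df[[cols$accession]])
  seqs <- toupper(gsub("[[:space:]]", "", df[[cols$sequence]]))
  if (any(!nzchar(seqs)))
    stop("row(s) with empty sequence: ",
         paste(acc[!nzchar(seqs)], collapse = ", "))
  if (anyDuplicated(acc))
    stop("duplicate accession(s): ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  entryName <- if (cols$entryName %in% names(df)) df[[cols$entryName]] else acc
  featList <- lapply(seq_along(acc), function(i) {
    parts <- list()
    if (cols$topoDom %in% names(df))
      parts <- c(parts, list(parseFeatureString(df[[cols$topoDom]][i],
                                                "TOPO_DOM")))
    if (cols$transmem %in% names(df))
      parts <- c(parts, list(parseFeatureString(df[[cols$transmem]][i],
                                                "TRANSMEM")))
    if (cols$intramem %in% names(df))
      parts <- c(parts, list(parseFeatureString(df[[cols$intramem]][i],
                                                "INTRAMEM")))
    ft <- do.call(rbind, parts)
    if (is.null(ft) || nrow(ft) == 0L) return(NULL)
    cbind(accession = acc[i], ft, stringsAsFactors = FALSE)
  })
  ft <- do.call(rbind, featList)
  if (is.null(ft)) ft <- emptyFeatureFrame()
  TopoProteinSet(stats::setNames(seqs, acc), entryNames = entryName,
                 features = ft, provenance = paste0("records TSV: ", file))
}

#' Read protein records from FASTA plus a sidecar feature TSV
#'
#' Sequences come from a FASTA file (identifier = first word of the header);
#' topology features from a TSV with columns `accession`, `kind`, `start`,
#' `end`, `note`. FASTA entries without feature rows are kept unannotated;
#' a feature row whose accession is absent from the FASTA is an error.
#'
#' @param fastaFile path to the FASTA file.
#' @param featuresFile path to the feature TSV, or `NULL` for no annotation.
#' @return a [TopoProteinSet-class].
#' @export
readRecordsFASTA <- function(fastaFile, featuresFile = NULL) {
  seqs <- Biostrings::readAAStringSet(fastaFile)
  names(seqs) <- vapply(strsplit(names(seqs), "[[:space:]]+"), `[[`,
                        character(1), 1L)
  ft <- emptyFeatureFrame()
  prov <- paste0("records FASTA: ", fastaFile)
  if (!is.null(featuresFile)) {
    ft <- utils::read.delim(featuresFile, stringsAsFactors = FALSE,
                            quote = "", check.names = FALSE)
    needed <- c("accession", "kind", "start", "end")
    missing <- setdiff(needed, names(ft))
    if (length(missing))
      stop("feature file is missing column(s): ",
           paste(missing, collapse = ", "))
    if (!("note" %in% names(ft))) ft$note <- ""
    orphans <- setdiff(unique(ft$accession), names(seqs))
    if (length(orphans))
      stop("feature rows reference accession(s) absent from the FASTA: ",
           paste(orphans, collapse = ", "))
    prov <- c(prov, paste0("features TSV: ", featuresFile))
  }
  TopoProteinSet(seqs, features = ft, provenance = prov)
}

#' Write protein records as a UniProt-style TSV
#'
#' Inverse of [readRecordsTSV()]: writes one row per protein with columns
#' `Entry`, `Entry Name`, `Sequence`, `Topological domain`, `Transmembrane`,
#' `Intramembrane`, rendering features back into the UniProt tabular
#' dialect (`KIND a..b; /note="..."`). Reading the file back reproduces the
#' set.
#'
#' @param x a [TopoProteinSet-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeRecordsTSV <- function(x, file) {
  stopifnot(methods::is(x, "TopoProteinSet"))
  ft <- as.data.frame(features(x))
  renderKind <- function(acc, kind) {
    sub <- ft[ft$accession == acc & ft$kind == kind, , drop = FALSE]
    if (nrow(sub) == 0L) return("")
    sub <- sub[order(sub$start), , drop = FALSE]
    paste(sprintf('%s %d..%d; /note="%s"', kind, sub$start, sub$end,
                  sub$note), collapse = "; ")
  }
  acc <- accessions(x)
  df <- data.frame(
    Entry = acc,
    `Entry Name` = unname(entryNames(x)),
    Sequence = as.character(sequences(x)),
    `Topological domain` = vapply(acc, renderKind, character(1), "TOPO_DOM"),
    Transmembrane = vapply(acc, renderKind, character(1), "TRANSMEM"),
    Intramembrane = vapply(acc, renderKind, character(1), "INTRAMEM"),
    stringsAsFactors = FALSE, check.names = FALSE)
  writeTsv(df, file)
  invisible(file)
}

RECORDS_SCHEMA <- "topomotif-records"
RECORDS_SCHEMA_VERSION <- 1L

#' Write / read protein records as versioned JSON
#'
#' Lossless round trip of a [TopoProteinSet-class] through a small versioned
#' JSON schema (`topomotif-records`, version 1): top-level `schema`,
#' `version`, `provenance`, and a `records` array of
#' `{accession, entry_name, sequence, features:[{kind,start,end,note}]}`.
#'
#' @param x a [TopoProteinSet-class].
#' @param file path to write to / read from.
#' @return `writeRecordsJSON` returns `file` invisibly; `readRecordsJSON`
#'   returns a [TopoProteinSet-class]. An unknown schema or version is an
#'   error.
#' @export
writeRecordsJSON <- function(x, file) {
  stopifnot(methods::is(x, "TopoProteinSet"))
  ft <- as.data.frame(features(x))
  recs <- lapply(seq_len(length(x)), function(i) {
    acc <- accessions(x)[i]
    sub <- ft[ft$accession == acc, c("kind", "start", "end", "note"),
              drop = FALSE]
    rownames(sub) <- NULL
    list(accession = acc,
         entry_name = unname(entryNames(x)[i]),
         sequence = as.character(sequences(x)[[i]]),
         features = sub)
  })
  payload <- list(schema = RECORDS_SCHEMA, version = RECORDS_SCHEMA_VERSION,
                  provenance = provenance(x), records = recs)
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname writeRecordsJSON
#' @export
readRecordsJSON <- function(file) {
  payload <- jsonlite::read_json(file, simplifyVector = FALSE)
  if (!identical(payload$schema, RECORDS_SCHEMA))
    stop("not a ", RECORDS_SCHEMA, " file: schema is ",
         deparse(payload$schema))
  if (!identical(as.integer(payload$version), RECORDS_SCHEMA_VERSION))
    stop("unsupported ", RECORDS_SCHEMA, " schema version: ",
         payload$version)
  recs <- payload$records
  acc <- vapply(recs, `[[`, character(1), "accession")
  seqs <- vapply(recs, `[[`, character(1), "sequence")
  entry <- vapply(recs, `[[`, character(1), "entry_name")
  ftRows <- lapply(recs, function(r) {
    if (!length(r$features)) return(NULL)
    data.frame(
      accession = r$accession,
      kind = vapply(r$features, `[[`, character(1), "kind"),
      start = vapply(r$features, function(f) as.integer(f$start), integer(1)),
      end = vapply(r$features, function(f) as.integer(f$end), integer(1)),
      note = vapply(r$features, function(f)
        if (is.null(f$note)) "" else as.character(f$note), character(1)),
      stringsAsFactors = FALSE)
  })
  ft <- do.call(rbind, ftRows)
  if (is.null(ft)) ft <- emptyFeatureFrame()
  TopoProteinSet(stats::setNames(seqs, acc), entryNames = entry,
                 features = ft,
                 provenance = unlist(payload$provenance) %||% character())
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
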