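#' MotifPattern: a compiled short-linear-motif pattern
#'
#' A `MotifPattern` holds one pattern written in the compact motif grammar
#' used for recycling-motif searches: a literal residue matches itself,
#' `@` matches any residue, and a bracketed group such as `[FYW]` matches any
#' of the listed residues. A pattern may additionally be anchored at the
#' C terminus, in which case only an occurrence ending at the final residue
#' of a protein counts (the convention used for class I PDZ-binding motifs,
#' which must terminate the protein).
#'
#' @slot sourceText the pattern as written, e.g. `"L@@L"`.
#' @slot elements list with one character vector of allowed residues per
#'   position; positions flagged in `isAny` ignore this and accept any letter.
#' @slot isAny logical vector marking `@` positions.
#' @slot anchorCterm must the match end at the final residue of the protein?
#' @slot name short label used in census output (defaults to `sourceText`).
#' @slot minMembraneDistance minimum number of residues between the motif and
#'   the nearest membrane segment for the distance-filtered census count, or
#'   `NA` when no distance criterion applies to this motif.
#'
#' @seealso [parsePattern()], [scanSequence()], [recyclingPatterns()]
#' @exportClass MotifPattern
setClass("MotifPattern",
  representation(
    sourceText = "character",
    elements = "list",
    isAny = "logical",
    anchorCterm = "logical",
    name = "character",
    minMembraneDistance = "integer"
  )
)

setValidity("MotifPattern", function(object) {
  msgs <- character()
  n <- length(object@elements)
  if (n < 1L) msgs <- c(msgs, "pattern must have at least one element")
  if (length(object@isAny) != n)
    msgs <- c(msgs, "isAny must have one entry per element")
  for (i in seq_len(n)) {
    if (isTRUE(object@isAny[i])) next
    el <- object@elements[[i]]
    if (length(el) == 0L)
      msgs <- c(msgs, sprintf("element %d is empty", i))
    if (!all(el %in% AA20))
      msgs <- c(msgs, sprintf("element %d contains non-standard residues", i))
  }
  if (length(object@anchorCterm) != 1L || is.na(object@anchorCterm))
    msgs <- c(msgs, "anchorCterm must be TRUE or FALSE")
  if (length(msgs)) msgs else TRUE
})

#' Parse a motif pattern string
#'
#' Compiles a pattern written in the motif grammar (`"L@@L"`,
#' `"[FYW]@[LMV]"`, ...) into a [MotifPattern-class] object. The grammar has
#' exactly three token types: a single residue letter, `@` for any residue,
#' and a bracketed residue class. There is no repetition, alternation or
#' negation. Input is uppercased before parsing.
#'
#' @param text pattern string, non-empty.
#' @param anchorCterm logical; if `TRUE` the pattern only matches at the very
#'   C terminus of a protein (used for PDZ-binding motifs).
#' @param name optional short label for census output; defaults to `text`.
#' @param minMembraneDistance optional integer: minimum residues between a
#'   match and the nearest membrane segment for the distance-filtered census
#'   tally (`NA`, the default, disables the criterion for this motif).
#' @return a [MotifPattern-class] object.
#' @examples
#' parsePattern("L@@L")
#' parsePattern("[DE][ST]@[GAVCPLIMWF]", anchorCterm = TRUE)
#' @export
parsePattern <- function(text, anchorCterm = FALSE, name = text,
                         minMembraneDistance = NA_integer_) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      nchar(text) == 0L)
    stop("pattern text must be a single non-empty string")
  chars <- strsplit(toupper(text), "", fixed = TRUE)[[1]]
  elements <- list()
  isAny <- logical()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "@") {
      elements <- c(elements, list(character(0)))
      isAny <- c(isAny, TRUE)
      i <- i + 1L
    } else if (ch == "[") {
      close <- NA_integer_
      j <- i + 1L
      while (j <= n) {
        if (chars[j] == "[")
          stop(sprintf("nested bracket at position %d in pattern '%s'",
                       j, text))
        if (chars[j] == "]") { close <- j; break }
        j <- j + 1L
      }
      if (is.na(close))
        stop(sprintf("unbalanced bracket at position %d in pattern '%s'",
                     i, text))
      inner <- chars[seq.int(i + 1L, length.out = close - i - 1L)]
      if (length(inner) == 0L)
        stop(sprintf("empty bracket group at position %d in pattern '%s'",
                     i, text))
      bad <- which(!(inner %in% AA20))
      if (length(bad))
        stop(sprintf(
          "invalid residue '%s' at position %d in pattern '%s'",
          inner[bad[1]], i + bad[1], text))
      elements <- c(elements, list(unique(inner)))
      isAny <- c(isAny, FALSE)
      i <- close + 1L
    } else if (ch == "]") {
      stop(sprintf("unbalanced bracket at position %d in pattern '%s'",
                   i, text))
    } else if (ch %in% AA20) {
      elements <- c(elements, list(ch))
      isAny <- c(isAny, FALSE)
      i <- i + 1L
    } else {
      stop(sprintf("invalid character '%s' at position %d in pattern '%s'",
                   ch, i, text))
    }
  }
  methods::new("MotifPattern",
    sourceText = toupper(text),
    elements = elements,
    isAny = isAny,
    anchorCterm = isTRUE(anchorCterm),
    name = as.character(name),
    minMembraneDistance =
      if (is.na(minMembraneDistance)) NA_integer_
      else as.integer(minMembraneDistance)
  )
}

#' Length of a motif pattern
#'
#' @param x a [MotifPattern-class].
#' @return integer number of residue positions the pattern spans.
#' @export
setGeneric("patternLength", function(x) standardGeneric("patternLength"))

#' @rdname patternLength
#' @export
setMethod("patternLength", "MotifPattern", function(x) length(x@elements))

#' Render a compiled pattern back to grammar text
#'
#' Inverse of [parsePattern()]: single-residue elements render as the
#' residue, any-elements as `@`, multi-residue classes as a bracket group in
#' the residue order seen at parse time (so a parse/render round trip
#' reproduces the source text).
#'
#' @param pattern a [MotifPattern-class].
#' @return character pattern string.
#' @export
renderPattern <- function(pattern) {
  stopifnot(methods::is(pattern, "MotifPattern"))
  paste(vapply(seq_along(pattern@elements), function(i) {
    if (pattern@isAny[i]) return("@")
    el <- pattern@elements[[i]]
    if (length(el) == 1L) el else paste0("[", paste(el, collapse = ""), "]")
  }, character(1)), collapse = "")
}

setMethod("show", "MotifPattern", function(object) {
  cat(sprintf("MotifPattern '%s' (%s): %d positions%s%s\n",
              object@name, object@sourceText, patternLength(object),
              if (object@anchorCterm) ", C-terminally anchored" else "",
              if (!is.na(object@minMembraneDistance))
                sprintf(", membrane distance >= %d",
                        object@minMembraneDistance) else ""))
})

#' Enumerate all matches of a pattern in a sequence
#'
#' Scans an amino-acid sequence for every (possibly overlapping) occurrence
#' of a motif pattern. Coordinates are reported 1-based inclusive in the
#' numbering defined by `offset` (the residue number of the first character
#' of `sequence`), so a C-terminal peptide can be scanned in the numbering of
#' its full-length parent protein. Sequences are uppercased on ingest.
#' `@` accepts any letter, including ambiguity codes such as X or U; explicit
#' residue classes accept only their listed residues, so ambiguous residues
#' never satisfy a specific class.
#'
#' @param pattern a [MotifPattern-class].
#' @param sequence amino-acid string (single character value).
#' @param offset 1-based residue number of the first residue of `sequence`.
#' @return data.frame with columns `start`, `end` (inclusive, in `offset`
#'   numbering) and `matched` (the matching substring), sorted by `start`.
#'   A sequence shorter than the pattern yields zero rows. If the pattern is
#'   C-terminally anchored, only a match ending at the final residue is
#'   reported.
#' @examples
#' scanSequence(parsePattern("L@@L"), "TELEYLGP", offset = 498)
#' @export
scanSequence <- function(pattern, sequence, offset = 1L) {
  stopifnot(methods::is(pattern, "MotifPattern"))
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a single string")
  if (!isCount(offset)) stop("offset must be a positive integer")
  offset <- as.integer(offset)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  m <- patternLength(pattern)
  empty <- data.frame(start = integer(0), end = integer(0),
                      matched = character(0), stringsAsFactors = FALSE)
  if (n < m || n == 0L) return(empty)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  nStarts <- n - m + 1L
  hit <- rep(TRUE, nStarts)
  for (j in seq_len(m)) {
    ok <- if (pattern@isAny[j]) chars %in% LETTERS
          else chars %in% pattern@elements[[j]]
    hit <- hit & ok[j:(j + nStarts - 1L)]
  }
  starts <- which(hit)
  if (pattern@anchorCterm) starts <- starts[starts == nStarts]
  if (length(starts) == 0L) return(empty)
  data.frame(
    start = starts + offset - 1L,
    end = starts + m - 1L + offset - 1L,
    matched = substring(sequence, starts, starts + m - 1L),
    stringsAsFactors = FALSE
  )
}

#' Translate a motif pattern to an equivalent regular expression
#'
#' Produces a character-class regular expression with the same per-position
#' semantics as the motif grammar (`@` becomes `[A-Z]`, a residue class
#' becomes a regex class). Scanning with this regex under overlap
#' enumeration (e.g. a zero-width lookahead) yields the same match set as
#' [scanSequence()]; it is used by the independent cross-check route, not by
#' the main scanner.
#'
#' @param pattern a [MotifPattern-class].
#' @param anchored if `TRUE` and the pattern is C-terminally anchored, a
#'   `$` anchor is appended.
#' @return regular-expression string.
#' @export
patternToRegex <- function(pattern, anchored = TRUE) {
  stopifnot(methods::is(pattern, "MotifPattern"))
  body <- paste(vapply(seq_along(pattern@elements), function(i) {
    if (pattern@isAny[i]) return("[A-Z]")
    el <- pattern@elements[[i]]
    if (length(el) == 1L) el else paste0("[", paste(el, collapse = ""), "]")
  }, character(1)), collapse = "")
  if (anchored && pattern@anchorCterm) paste0(body, "$") else body
}

#' The five built-in recycling-motif patterns
#'
#' Returns the compiled pattern set used for the recycling-motif census:
#' the bileucine core `L@@L` (LxxL), `N@@Y` (N\[P/x\]xY, Retriever),
#' `[FYW]@[LMV]` (canonical Retromer consensus),
#' `[GAVCPLIMWF]@[FYV]@[FY]` (ESCPE-1 consensus), and the C-terminally
#' anchored class I PDZ-binding motif `[DE][ST]@[GAVCPLIMWF]`. The LxxL
#' pattern carries a 15-residue minimum membrane distance for its
#' distance-filtered tally, reflecting the requirement that Retromer cargo
#' motifs sit at least 15 residues from the membrane.
#'
#' The same table ships as `system.file("extdata", "recycling_motifs.tsv",
#' package = "topomotif")` for use with [readPatternTable()] and the CLI.
#'
#' @return list of [MotifPattern-class] objects, named by motif label.
#' @export
recyclingPatterns <- function() {
  pats <- list(
    parsePattern("L@@L", name = "LxxL", minMembraneDistance = 15L),
    parsePattern("N@@Y", name = "NxxY"),
    parsePattern("[FYW]@[LMV]", name = "Retromer_FxL"),
    parsePattern("[GAVCPLIMWF]@[FYV]@[FY]", name = "ESCPE1"),
    parsePattern("[DE][ST]@[GAVCPLIMWF]", anchorCterm = TRUE, name = "PDZ")
  )
  names(pats) <- vapply(pats, function(p) p@name, character(1))
  pats
}

#' Read a motif pattern table
#'
#' Reads a TSV with columns `pattern`, `name`, `anchor_cterm` (true/false)
#' and `min_membrane_distance` (integer or empty) and compiles one
#' [MotifPattern-class] per row.
#'
#' @param file path to the pattern TSV.
#' @return named list of [MotifPattern-class] objects.
#' @export
readPatternTable <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE, quote = "",
                          check.names = FALSE, colClasses = "character")
  required <- c("pattern", "name", "anchor_cterm", "min_membrane_distance")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("pattern file is missing column(s): ", paste(missing, collapse = ", "))
  pats <- lapply(seq_len(nrow(df)), function(i) {
    dist <- df$min_membrane_distance[i]
    dist <- if (is.na(dist) || !nzchar(trimws(dist))) NA_integer_
            else as.integer(dist)
    parsePattern(df$pattern[i],
                 anchorCterm = tolower(trimws(df$anchor_cterm[i])) %in%
                   c("true", "t", "1", "yes"),
                 name = df$name[i],
                 minMembraneDistance = dist)
  })
  names(pats) <- df$name
  pats
}
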