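#' TopoProteinSet: protein sequences with membrane-topology annotations
#'
#' Container for a set of proteins, each with an amino-acid sequence and
#' UniProt-style topology features (`TOPO_DOM`, `TRANSMEM`, `INTRAMEM`) with
#' 1-based inclusive coordinates. Sequences are held as a
#' [Biostrings::AAStringSet] named by accession; features are a
#' [S4Vectors::DataFrame] with columns `accession`, `kind`, `start`, `end`,
#' `note`.
#'
#' Validity requires: unique accessions; non-empty alphabetic sequences;
#' every feature interval within its sequence; and same-kind features of one
#' protein pairwise disjoint (overlapping same-kind features indicate a
#' corrupted annotation and are rejected on ingest). Overlap between a
#' `TOPO_DOM` and a membrane segment of the same protein is tolerated with a
#' warning at construction, as a real annotation keeps these disjoint.
#'
#' @slot sequences [Biostrings::AAStringSet], names are accessions.
#' @slot entryNames character entry names, parallel to `sequences`.
#' @slot features [S4Vectors::DataFrame] of topology features.
#' @slot provenance character vector; free-text history (source file,
#'   filters applied).
#'
#' @seealso [TopoProteinSet()], [readRecordsTSV()], [readRecordsFASTA()]
#' @exportClass TopoProteinSet
setClass("TopoProteinSet",
  representation(
    sequences = "AAStringSet",
    entryNames = "character",
    features = "DataFrame",
    provenance = "character"
  )
)

FEATURE_KINDS <- c("TOPO_DOM", "TRANSMEM", "INTRAMEM")
MEMBRANE_KINDS <- c("TRANSMEM", "INTRAMEM")

#' @noRd
emptyFeatureFrame <- function() {
  data.frame(accession = character(0), kind = character(0),
             start = integer(0), end = integer(0), note = character(0),
             stringsAsFactors = FALSE)
}

setValidity("TopoProteinSet", function(object) {
  msgs <- character()
  acc <- names(object@sequences)
  if (is.null(acc) || anyNA(acc) || any(!nzchar(acc)))
    return("sequences must be named by accession")
  if (anyDuplicated(acc))
    msgs <- c(msgs, sprintf("duplicate accession(s): %s",
                            paste(unique(acc[duplicated(acc)]),
                                  collapse = ", ")))
  if (length(object@entryNames) != length(object@sequences))
    msgs <- c(msgs, "entryNames must be parallel to sequences")
  w <- Biostrings::width(object@sequences)
  if (any(w == 0L))
    msgs <- c(msgs, "sequences must be non-empty")
  seqs <- as.character(object@sequences)
  if (any(grepl("[^A-Za-z]", seqs)))
    msgs <- c(msgs, "sequences must be alphabetic")
  ft <- as.data.frame(object@features)
  if (nrow(ft)) {
    needed <- c("accession", "kind", "start", "end", "note")
    if (!all(needed %in% names(ft)))
      return("features must have columns accession, kind, start, end, note")
    orphan <- setdiff(unique(ft$accession), acc)
    if (length(orphan))
      msgs <- c(msgs, sprintf("features reference unknown accession(s): %s",
                              paste(orphan, collapse = ", ")))
    if (!all(ft$kind %in% FEATURE_KINDS))
      msgs <- c(msgs, sprintf("unknown feature kind(s): %s",
                              paste(setdiff(unique(ft$kind), FEATURE_KINDS),
                                    collapse = ", ")))
    bad <- ft$start < 1L | ft$end < ft$start
    if (any(bad))
      msgs <- c(msgs, sprintf(
        "invalid feature interval for %s (%s %d..%d)",
        ft$accession[bad][1], ft$kind[bad][1],
        ft$start[bad][1], ft$end[bad][1]))
    lens <- stats::setNames(w, acc)
    over <- ft$end > lens[ft$accession]
    if (any(over, na.rm = TRUE)) {
      i <- which(over)[1]
      msgs <- c(msgs, sprintf(
        "feature %s %d..%d of %s extends past sequence length %d",
        ft$kind[i], ft$start[i], ft$end[i], ft$accession[i],
        lens[ft$accession[i]]))
    }
    # same-kind features of one protein must be pairwise disjoint
    byKey <- split(ft, paste(ft$accession, ft$kind, sep = "\r"))
    for (grp in byKey) {
      if (nrow(grp) < 2L) next
      grp <- grp[order(grp$start), ]
      if (any(grp$start[-1L] <= grp$end[-nrow(grp)]))
        msgs <- c(msgs, sprintf(
          "overlapping %s features in %s", grp$kind[1], grp$accession[1]))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a TopoProteinSet
#'
#' @param sequences named character vector or [Biostrings::AAStringSet] of
#'   amino-acid sequences; names are accessions.
#' @param entryNames optional character entry names (defaults to accessions).
#' @param features data.frame (or DataFrame) with columns `accession`,
#'   `kind` (`TOPO_DOM`/`TRANSMEM`/`INTRAMEM`), `start`, `end` (1-based
#'   inclusive) and `note`.
#' @param provenance character vector recording where the set came from.
#' @return a validated [TopoProteinSet-class].
#' @examples
#' x <- TopoProteinSet(
#'   c(P1 = "MALWTRLRPLLALLALWPPPPA"),
#'   features = data.frame(accession = "P1", kind = "TOPO_DOM",
#'                         start = 10, end = 22, note = "Cytoplasmic"))
#' x
#' @export
TopoProteinSet <- function(sequences, entryNames = NULL,
                           features = emptyFeatureFrame(),
                           provenance = character()) {
  if (!methods::is(sequences, "AAStringSet")) {
    nms <- names(sequences)
    sequences <- Biostrings::AAStringSet(toupper(as.character(sequences)))
    names(sequences) <- nms
  }
  if (is.null(entryNames)) entryNames <- names(sequences)
  ft <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(ft)) {
    ft$accession <- as.character(ft$accession)
    ft$kind <- as.character(ft$kind)
    ft$start <- as.integer(ft$start)
    ft$end <- as.integer(ft$end)
    ft$note <- if ("note" %in% names(ft)) {
      ifelse(is.na(ft$note), "", as.character(ft$note))
    } else ""
  } else {
    ft <- emptyFeatureFrame()
  }
  # canonical feature order, so serialization round trips are identities
  ft <- ft[order(ft$accession, ft$start, ft$kind, method = "radix"), ,
           drop = FALSE]
  rownames(ft) <- NULL
  obj <- methods::new("TopoProteinSet",
    sequences = sequences,
    entryNames = as.character(entryNames),
    features = S4Vectors::DataFrame(ft),
    provenance = as.character(provenance)
  )
  warnCrossKindOverlap(obj)
  obj
}

# Different-kind overlap (TOPO_DOM vs membrane segment) is tolerated but loud.
#' @noRd
warnCrossKindOverlap <- function(object) {
  ft <- as.data.frame(object@features)
  if (!nrow(ft)) return(invisible(NULL))
  for (acc in unique(ft$accession)) {
    sub <- ft[ft$accession == acc, ]
    topo <- sub[sub$kind == "TOPO_DOM", ]
    mem <- sub[sub$kind %in% MEMBRANE_KINDS, ]
    if (!nrow(topo) || !nrow(mem)) next
    for (i in seq_len(nrow(topo))) {
      clash <- mem$start <= topo$end[i] & mem$end >= topo$start[i]
      if (any(clash)) {
        warning(sprintf(
          "%s: TOPO_DOM %d..%d overlaps a membrane segment; keeping both",
          acc, topo$start[i], topo$end[i]), call. = FALSE)
      }
    }
  }
  invisible(NULL)
}

#' @rdname TopoProteinSet-accessors
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))

#' Accessors for TopoProteinSet
#'
#' `accessions()` returns the accession of each protein, `entryNames()` the
#' entry names, `sequences()` the [Biostrings::AAStringSet], `features()`
#' the topology feature table, and `provenance()` the recorded history.
#'
#' @param x a [TopoProteinSet-class].
#' @name TopoProteinSet-accessors
#' @export
setMethod("accessions", "TopoProteinSet", function(x) names(x@sequences))

#' @rdname TopoProteinSet-accessors
#' @export
setGeneric("entryNames", function(x) standardGeneric("entryNames"))

#' @rdname TopoProteinSet-accessors
#' @export
setMethod("entryNames", "TopoProteinSet", function(x)
  stats::setNames(x@entryNames, names(x@sequences)))

#' @rdname TopoProteinSet-accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname TopoProteinSet-accessors
#' @export
setMethod("sequences", "TopoProteinSet", function(x) x@sequences)

#' @rdname TopoProteinSet-accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname TopoProteinSet-accessors
#' @export
setMethod("features", "TopoProteinSet", function(x) x@features)

#' @rdname TopoProteinSet-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname TopoProteinSet-accessors
#' @export
setMethod("provenance", "TopoProteinSet", function(x) x@provenance)

#' @rdname TopoProteinSet-accessors
#' @param value replacement provenance character vector.
#' @export
setGeneric("provenance<-", function(x, value) standardGeneric("provenance<-"))

#' @rdname TopoProteinSet-accessors
#' @export
setMethod("provenance<-", "TopoProteinSet", function(x, value) {
  x@provenance <- as.character(value)
  x
})

#' @describeIn TopoProteinSet number of proteins in the set
#' @param x a [TopoProteinSet-class].
#' @export
setMethod("length", "TopoProteinSet", function(x) length(x@sequences))

#' Subset a TopoProteinSet
#'
#' Subsets by integer/logical index or accession, carrying the matching
#' features along.
#'
#' @param x a [TopoProteinSet-class].
#' @param i integer, logical or character (accession) index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "TopoProteinSet", function(x, i, j, ..., drop = FALSE) {
  acc <- names(x@sequences)
  idx <- if (is.character(i)) {
    pos <- match(i, acc)
    if (anyNA(pos))
      stop("unknown accession(s): ", paste(i[is.na(pos)], collapse = ", "))
    pos
  } else if (is.logical(i)) which(rep_len(i, length(acc))) else as.integer(i)
  keep <- acc[idx]
  ft <- as.data.frame(x@features)
  ft <- ft[ft$accession %in% keep, , drop = FALSE]
  rownames(ft) <- NULL
  methods::new("TopoProteinSet",
    sequences = x@sequences[idx],
    entryNames = x@entryNames[idx],
    features = S4Vectors::DataFrame(ft),
    provenance = x@provenance)
})

setMethod("show", "TopoProteinSet", function(object) {
  ft <- as.data.frame(object@features)
  cat(sprintf("TopoProteinSet with %d protein(s), %d topology feature(s)\n",
              length(object), nrow(ft)))
  if (length(object)) {
    n <- min(length(object), 5L)
    w <- Biostrings::width(object@sequences)
    for (i in seq_len(n)) {
      cat(sprintf("  %s (%s): %d aa, %d feature(s)\n",
                  names(object@sequences)[i], object@entryNames[i], w[i],
                  sum(ft$accession == names(object@sequences)[i])))
    }
    if (length(object) > n) cat(sprintf("  ... and %d more\n",
                                        length(object) - n))
  }
  if (length(object@provenance))
    cat("provenance:", paste(object@provenance, collapse = " | "), "\n")
})
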