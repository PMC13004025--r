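#' Classify the C terminus of each protein
#'
#' A protein's C terminus is classified by the `TOPO_DOM` feature covering
#' its final residue: `CYTOPLASMIC` if the note begins (case-insensitively)
#' with "Cytoplasmic", `EXTRACELLULAR` if it begins with "Extracellular",
#' `OTHER_ANNOTATED` for any other covering topological domain (e.g.
#' "Lumenal"), and `UNANNOTATED` when no topological domain covers the final
#' residue. Prefix matching tolerates qualified notes such as
#' "Cytoplasmic; in dimer". The result is independent of feature order.
#'
#' @param x a [TopoProteinSet-class].
#' @return factor named by accession with levels `CYTOPLASMIC`,
#'   `EXTRACELLULAR`, `OTHER_ANNOTATED`, `UNANNOTATED`.
#' @export
classifyCterm <- function(x) {
  stopifnot(methods::is(x, "TopoProteinSet"))
  ftByAcc <- splitFeatures(x)
  lens <- Biostrings::width(sequences(x))
  acc <- accessions(x)
  out <- vapply(seq_along(acc), function(i) {
    ctermClassOne(ftByAcc[[acc[i]]], lens[i])
  }, character(1))
  factor(stats::setNames(out, acc),
         levels = c("CYTOPLASMIC", "EXTRACELLULAR", "OTHER_ANNOTATED",
                    "UNANNOTATED"))
}

# Per-accession feature frames (NULL-safe lookup via [[ on a plain list).
#' @noRd
splitFeatures <- function(x) {
  ft <- as.data.frame(features(x))
  if (!nrow(ft)) return(stats::setNames(list(), character(0)))
  split(ft, ft$accession)
}

#' @noRd
ctermClassOne <- function(ft, len) {
  if (is.null(ft) || nrow(ft) == 0L) return("UNANNOTATED")
  sub <- ft[ft$kind == "TOPO_DOM" & ft$start <= len & ft$end >= len, ,
            drop = FALSE]
  if (nrow(sub) == 0L) return("UNANNOTATED")
  note <- tolower(sub$note[1])
  if (startsWith(note, "cytoplasmic")) "CYTOPLASMIC"
  else if (startsWith(note, "extracellular")) "EXTRACELLULAR"
  else "OTHER_ANNOTATED"
}

#' @noRd
enclosingCytoOne <- function(ft, start, end) {
  if (is.null(ft) || nrow(ft) == 0L) return(NULL)
  sub <- ft[ft$kind == "TOPO_DOM" &
              startsWith(tolower(ft$note), "cytoplasmic") &
              ft$start <= start & ft$end >= end, , drop = FALSE]
  if (nrow(sub) == 0L) return(NULL)
  rownames(sub) <- NULL
  sub[1L, c("kind", "start", "end", "note"), drop = FALSE]
}

#' @noRd
membraneDistanceOne <- function(ft, start, end) {
  if (is.null(ft) || nrow(ft) == 0L) return(NA_integer_)
  mem <- ft[ft$kind %in% MEMBRANE_KINDS, , drop = FALSE]
  if (nrow(mem) == 0L) return(NA_integer_)
  if (any(mem$start <= end & mem$end >= start)) return(0L)
  upstream <- mem$end[mem$end < start]
  downstream <- mem$start[mem$start > end]
  gaps <- integer(0)
  if (length(upstream)) gaps <- c(gaps, start - max(upstream) - 1L)
  if (length(downstream)) gaps <- c(gaps, min(downstream) - end - 1L)
  if (!length(gaps)) return(NA_integer_)
  as.integer(min(gaps))
}

#' Cytoplasmic domain fully containing an interval
#'
#' Returns the `TOPO_DOM` feature whose note begins (case-insensitively)
#' with "Cytoplasmic" and which fully contains the interval
#' `[start, end]`, or `NULL` when no such domain contains it — including a
#' match straddling a transmembrane boundary or one lying in an
#' extracellular region.
#'
#' @param x a [TopoProteinSet-class].
#' @param accession protein accession.
#' @param start,end 1-based inclusive interval within the sequence.
#' @return one-row data.frame (`kind`, `start`, `end`, `note`) or `NULL`.
#' @export
enclosingCytoplasmicDomain <- function(x, accession, start, end) {
  stopifnot(methods::is(x, "TopoProteinSet"), start >= 1L, end >= start)
  enclosingCytoOne(featuresFor(x, accession), start, end)
}

#' @noRd
featuresFor <- function(x, accession) {
  ft <- as.data.frame(features(x))
  ft[ft$accession == accession, , drop = FALSE]
}

#' Sequence distance from an interval to the nearest membrane segment
#'
#' Counts the residues strictly between a motif interval and the nearest
#' flanking membrane segment (`TRANSMEM` or `INTRAMEM`), minimized over both
#' flanks. With an upstream segment ending at `U` and a downstream segment
#' starting at `D`, the gaps are `start - U - 1` and `D - end - 1`; the
#' distance is the smaller of the defined gaps. A motif starting immediately
#' after a membrane segment therefore has distance 0, and an interval
#' overlapping a membrane segment has distance 0. When the protein has no
#' membrane segment on either side of the interval the distance is
#' undefined and `NA` is returned (peripheral or lipid-anchored proteins).
#'
#' @param x a [TopoProteinSet-class].
#' @param accession protein accession.
#' @param start,end 1-based inclusive interval within the sequence.
#' @return non-negative integer, or `NA` when undefined.
#' @examples
#' x <- TopoProteinSet(
#'   c(P1 = paste(rep("A", 60), collapse = "")),
#'   features = data.frame(accession = "P1", kind = "TRANSMEM",
#'                         start = 6, end = 26, note = "Helical"))
#' membraneDistance(x, "P1", 42, 45)  # 42 - 26 - 1 = 15
#' @export
membraneDistance <- function(x, accession, start, end) {
  stopifnot(methods::is(x, "TopoProteinSet"), start >= 1L, end >= start)
  membraneDistanceOne(featuresFor(x, accession), start, end)
}
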