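# Small builders for hand-crafted protein records used across test files.

filler <- function(L, ch = "A") paste(rep(ch, L), collapse = "")

# single protein set from a sequence and a feature table
mkSet <- function(seq, features, accession = "P1") {
  TopoProteinSet(stats::setNames(seq, accession), features = features)
}

feat <- function(accession, kind, start, end, note = "") {
  data.frame(accession = accession, kind = kind, start = start, end = end,
             note = note, stringsAsFactors = FALSE)
}

# single-pass protein: extracellular N-term, one TM, cytoplasmic tail,
# with a motif planted at a given distance after the TM end
singlePassWithMotif <- function(motif, distance, tailLen = 60,
                                ntermLen = 30, tmLen = 21,
                                accession = "P1", tailNote = "Cytoplasmic") {
  tmStart <- ntermLen + 1
  tmEnd <- ntermLen + tmLen
  L <- tmEnd + tailLen
  chars <- strsplit(filler(L, "G"), "")[[1]]
  s <- tmEnd + distance + 1
  e <- s + nchar(motif) - 1
  stopifnot(e <= L)
  chars[s:e] <- strsplit(motif, "")[[1]]
  ft <- rbind(
    feat(accession, "TOPO_DOM", 1, ntermLen, "Extracellular"),
    feat(accession, "TRANSMEM", tmStart, tmEnd, "Helical"),
    feat(accession, "TOPO_DOM", tmEnd + 1, L, tailNote))
  mkSet(paste(chars, collapse = ""), ft, accession)
}
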