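# Independent oracle implementations used to cross-check the package.
# Everything here re-derives the semantics from scratch: its own pattern
# tokenizer, a naive all-start-positions scanner, a regex-based census with
# its own interval arithmetic. It never calls the package scanner or the
# package topology predicates.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# tokenize a grammar-valid pattern into a list of allowed-residue vectors
# (NULL = any residue)
oracleElements <- function(text) {
  toks <- regmatches(text, gregexpr("\\[[A-Z]+\\]|@|[A-Z]",
                                    toupper(text)))[[1]]
  lapply(toks, function(t) {
    if (t == "@") NULL
    else if (startsWith(t, "[")) strsplit(gsub("\\[|\\]", "", t), "")[[1]]
    else t
  })
}

# brute-force scan over every start position
oracleScan <- function(text, sequence, offset = 1, anchored = FALSE) {
  elems <- oracleElements(text)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  m <- length(elems)
  hits <- integer(0)
  if (n >= m) {
    for (s in 1:(n - m + 1)) {
      ok <- TRUE
      for (j in seq_len(m)) {
        ch <- substr(sequence, s + j - 1, s + j - 1)
        el <- elems[[j]]
        if (is.null(el)) {
          if (!(ch %in% LETTERS)) { ok <- FALSE; break }
        } else if (!(ch %in% el)) { ok <- FALSE; break }
      }
      if (ok && (!anchored || s + m - 1 == n)) hits <- c(hits, s)
    }
  }
  data.frame(start = hits + offset - 1,
             end = hits + m - 1 + offset - 1)
}

# random grammar-valid pattern text
randomPatternText <- function(maxLen = 6) {
  len <- sample(2:maxLen, 1)
  paste(vapply(seq_len(len), function(i) {
    kind <- sample(c("letter", "any", "class"), 1,
                   prob = c(0.4, 0.3, 0.3))
    switch(kind,
      letter = sample(AA, 1),
      any = "@",
      class = paste0("[", paste(sample(AA, sample(2:8, 1)),
                                collapse = ""), "]"))
  }, character(1)), collapse = "")
}

randomSequence <- function(len, alphabet = AA) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# --- independent census ----------------------------------------------------

# regex translation done from the token list, not via the package
oracleRegex <- function(text) {
  paste(vapply(oracleElements(text), function(el) {
    if (is.null(el)) "[A-Z]"
    else if (length(el) == 1) el
    else paste0("[", paste(el, collapse = ""), "]")
  }, character(1)), collapse = "")
}

oracleCtermCytoplasmic <- function(ft, len) {
  sub <- ft[ft$kind == "TOPO_DOM" & ft$start <= len & ft$end >= len, ,
            drop = FALSE]
  nrow(sub) > 0 && grepl("^cytoplasmic", tolower(sub$note[1]))
}

oracleInCyto <- function(ft, s, e) {
  any(ft$kind == "TOPO_DOM" & grepl("^cytoplasmic", tolower(ft$note)) &
        ft$start <= s & ft$end >= e)
}

oracleMemDist <- function(ft, s, e) {
  mem <- ft[ft$kind %in% c("TRANSMEM", "INTRAMEM"), , drop = FALSE]
  if (nrow(mem) == 0) return(NA_integer_)
  if (any(mem$start <= e & mem$end >= s)) return(0L)
  gaps <- c()
  up <- mem$end[mem$end < s]
  dn <- mem$start[mem$start > e]
  if (length(up)) gaps <- c(gaps, s - max(up) - 1)
  if (length(dn)) gaps <- c(gaps, min(dn) - e - 1)
  if (!length(gaps)) NA_integer_ else as.integer(min(gaps))
}

# full census re-derivation. patterns: data.frame(text, name, anchored,
# minDist). Returns list(matches = passing (window+cytoplasmic) matches,
# summary = per-pattern counts).
oracleCensus <- function(x, patterns, windowLen = 100,
                         requireCyto = TRUE, configMinDist = NA) {
  ftAll <- as.data.frame(features(x))
  accs <- accessions(x)
  seqs <- as.character(sequences(x))
  lens <- nchar(seqs)
  rows <- list()
  for (i in seq_along(accs)) {
    ft <- ftAll[ftAll$accession == accs[i], , drop = FALSE]
    if (!oracleCtermCytoplasmic(ft, lens[i])) next
    for (k in seq_len(nrow(patterns))) {
      m <- nchar(gsub("\\[[A-Z]+\\]", "x", patterns$text[k]))
      rx <- oracleRegex(patterns$text[k])
      if (patterns$anchored[k]) {
        hit <- regexpr(paste0("(?=", rx, "$)"), seqs[i], perl = TRUE)
        starts <- if (hit[1] == -1) integer(0) else as.integer(hit[1])
      } else {
        ws <- max(1, lens[i] - windowLen + 1)
        g <- gregexpr(paste0("(?=", rx, ")"),
                      substr(seqs[i], ws, lens[i]), perl = TRUE)[[1]]
        starts <- if (g[1] == -1) integer(0) else as.integer(g) + ws - 1
      }
      for (s in starts) {
        e <- s + m - 1
        if (requireCyto && !oracleInCyto(ft, s, e)) next
        rows[[length(rows) + 1]] <- data.frame(
          accession = accs[i], pattern = patterns$name[k],
          start = s, end = e,
          dist = oracleMemDist(ft, s, e),
          stringsAsFactors = FALSE)
      }
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(0), pattern = character(0),
               start = integer(0), end = integer(0), dist = integer(0))
  matches <- matches[order(matches$accession, matches$pattern,
                           matches$start, method = "radix"), , drop = FALSE]
  rownames(matches) <- NULL
  summary <- do.call(rbind, lapply(seq_len(nrow(patterns)), function(k) {
    sub <- matches[matches$pattern == patterns$name[k], , drop = FALSE]
    thr <- if (!is.na(patterns$minDist[k])) patterns$minDist[k]
           else configMinDist
    data.frame(
      pattern = patterns$name[k],
      nMatches = nrow(sub),
      nUniqueProteins = length(unique(sub$accession)),
      nUniqueProteinsDistanceFiltered = if (is.na(thr)) NA_integer_ else
        length(unique(sub$accession[is.na(sub$dist) | sub$dist >= thr])),
      stringsAsFactors = FALSE)
  }))
  list(matches = matches, summary = summary)
}

# the built-in pattern set in the oracle's own table form
oraclePatternTable <- function() {
  data.frame(
    text = c("L@@L", "N@@Y", "[FYW]@[LMV]", "[GAVCPLIMWF]@[FYV]@[FY]",
             "[DE][ST]@[GAVCPLIMWF]"),
    name = c("LxxL", "NxxY", "Retromer_FxL", "ESCPE1", "PDZ"),
    anchored = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    minDist = c(15L, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}
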