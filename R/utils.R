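# Internal helpers shared across modules.

# The 20 standard amino acids, alphabetical one-letter codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' @noRd
isCount <- function(x, allowZero = FALSE) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x) &&
    (x > 0 || (allowZero && x == 0))
}

# write.table wrapper with a fixed, reproducible dialect
#' @noRd
writeTsv <- function(df, file) {
  utils::write.table(df, file = file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "", eol = "\n")
}
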