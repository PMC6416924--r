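# Internal helpers: classed error conditions, reverse complement, IUPAC classes.

# let data.table's [ semantics apply inside this namespace
.datatable.aware <- TRUE

gbStop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "gb_error")))
}

# Reverse complement of plain character vectors (ACGTN). Vectorized through
# Biostrings so large batches of 23/30-mers stay fast.
revComp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  if (any(ok)) {
    out[ok] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[ok]))
    )
  }
  out
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Regex character class matching one degenerate base. N deliberately expands
# to [ACGT]: windows containing literal N are never reported as sites.
iupacClass <- function(base) {
  set <- IUPAC_SETS[[base]]
  if (is.null(set)) gbStop("gb_bad_pam", "invalid PAM character '%s'", base)
  paste0("[", paste(set, collapse = ""), "]")
}

complementBase <- function(base) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  out <- comp[base]
  if (anyNA(out)) gbStop("gb_bad_pam", "invalid PAM character")
  unname(out)
}
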