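# Shared low-level helpers. DNA alphabet internally; RNA labels only at the
# reporting layer (stop codons printed as UAA/UAG/UGA).

# stop codons of genetic code 11 (same set as the standard code), DNA alphabet
STOP_DNA <- c("TAA", "TAG", "TGA")
STOP_RNA <- c("UAA", "UAG", "UGA")

#' Convert DNA codon labels to RNA and back
#'
#' Label-level transliteration (`T` \eqn{\leftrightarrow} `U`) used at the
#' reporting boundary: all sequences are handled internally as DNA, all
#' user-facing codon labels are RNA.
#'
#' @param x character vector of codons or sequences.
#' @return character vector of the same length.
#' @examples
#' toRNA("TAA")  # "UAA"
#' toDNA("UGA")  # "TGA"
#' @export
toRNA <- function(x) chartr("Tt", "Uu", x)

#' @rdname toRNA
#' @export
toDNA <- function(x) chartr("Uu", "Tt", x)

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.5 -> 1), as used when reproducing
#' printed percentages; base R `round()` rounds half to even.
#'
#' @param x numeric vector (non-negative in all reporting uses).
#' @param digits integer number of decimal places.
#' @return numeric vector.
#' @examples
#' roundHalfUp(0.5)        # 1
#' roundHalfUp(7.45, 1)    # 7.5
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# reverse complement on plain character vectors (vectorized via Biostrings)
revComp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substring with circular wrap-around; start/end are 1-based and end may
# exceed the contig length (or start drop below 1) when circular
wrapSubstr <- function(seq, start, end, circular = FALSE) {
  L <- nchar(seq)
  if (start >= 1L && end <= L) return(substr(seq, start, end))
  if (!circular) {
    s <- max(1L, start); e <- min(L, end)
    if (s > e) return("")
    return(substr(seq, s, e))
  }
  idx <- ((seq.int(start, end) - 1L) %% L) + 1L
  paste(strsplit(seq, "", fixed = TRUE)[[1]][idx], collapse = "")
}

# split a sequence into in-frame triplets (drops a trailing partial codon)
splitCodons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# stop codons for a genetic code id ("11" default); always DNA alphabet
stopCodonsFor <- function(geneticCodeId = 11L) {
  gc <- Biostrings::getGeneticCode(as.character(geneticCodeId))
  names(gc)[gc == "*"]
}

# all 64 DNA codons in lexicographic (Biostrings column) order
allCodons <- function() {
  b <- c("A", "C", "G", "T")
  paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L), rep(b, 16L))
}
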