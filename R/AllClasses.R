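#' GenomeDataset: contigs, gene records and genetic code for one genome
#'
#' Central container for one genome: its contigs (a
#' [Biostrings::DNAStringSet] whose `mcols()$circular` flags circular
#' replicons), and one gene record per annotated single-segment CDS, held as
#' a [GenomicRanges::GRanges] with metadata columns
#' `gene_id`, `cds` (sense-strand sequence), `stop_codon` (DNA triplet or
#' `NA` when absent), `downstream` (sense-strand 3' context, the first base
#' being position +4), `context_len_obtained`, `is_heg`, `valid`, `reason`
#' and `overlap_flag` (downstream window overlaps another annotated CDS).
#'
#' Coordinates are GFF3-style 1-based inclusive throughout.
#'
#' @slot genomeId single genome identifier.
#' @slot contigs `DNAStringSet` of contig sequences over `{A,C,G,T,N}`.
#' @slot genes `GRanges` of gene records (metadata columns above).
#' @slot geneticCodeId NCBI translation table id; 11 (bacterial/archaeal/
#'   plant plastid) by default. Its stop set defines which terminal triplets
#'   count as stop codons.
#'
#' @aliases GenomeDataset-class
#' @export
setClass("GenomeDataset",
  slots = c(
    genomeId = "character",
    contigs = "DNAStringSet",
    genes = "GRanges",
    geneticCodeId = "integer"
  )
)

setValidity("GenomeDataset", function(object) {
  msg <- character(0)
  if (length(object@genomeId) != 1L) {
    msg <- c(msg, "genomeId must be a single string")
  }
  cn <- names(object@contigs)
  if (is.null(cn) || anyDuplicated(cn)) {
    msg <- c(msg, "contigs must have unique names")
  }
  if (length(object@genes) > 0L) {
    bad <- setdiff(as.character(GenomicRanges::seqnames(object@genes)), cn)
    if (length(bad)) {
      msg <- c(msg, paste0("gene records reference unknown contigs: ",
                           paste(unique(bad), collapse = ", ")))
    }
    gid <- S4Vectors::mcols(object@genes)$gene_id
    if (is.null(gid) || anyDuplicated(gid)) {
      msg <- c(msg, "gene_id must be present and unique within a genome")
    }
  }
  if (length(msg)) msg else TRUE
})

#' StopUsageTable: stop-codon counts and frequencies for one gene class
#'
#' Counts and relative frequencies of the three termination codons in a gene
#' class of one genome. Codon labels are RNA (`UAA`, `UAG`, `UGA`) at this
#' reporting layer. `freqs` are `NA` when the class is empty.
#'
#' @slot genomeId genome identifier.
#' @slot geneClass one of `"ALL"`, `"HEG"` (highly expressed genes) or
#'   `"LEG"` (the complement of the HEG set among valid genes).
#' @slot counts named integer vector `c(UAA=, UAG=, UGA=)`.
#' @slot total sum of `counts`.
#' @slot freqs named numeric vector, `counts / total`.
#'
#' @aliases StopUsageTable-class
#' @export
setClass("StopUsageTable",
  slots = c(
    genomeId = "character",
    geneClass = "character",
    counts = "integer",
    total = "integer",
    freqs = "numeric"
  )
)

setValidity("StopUsageTable", function(object) {
  msg <- character(0)
  if (!identical(names(object@counts), STOP_RNA)) {
    msg <- c(msg, "counts must be named UAA, UAG, UGA (in that order)")
  }
  if (any(object@counts < 0L)) msg <- c(msg, "counts must be non-negative")
  if (sum(object@counts) != object@total) {
    msg <- c(msg, "total must equal sum(counts)")
  }
  if (object@total > 0L && abs(sum(object@freqs) - 1) > 1e-12) {
    msg <- c(msg, "freqs must sum to 1 when total > 0")
  }
  if (length(msg)) msg else TRUE
})
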