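# Shared fixtures: small on-the-fly FASTA/GFF writers, an independent
# reverse-complement oracle, and gene-table builders for context tests.

writeTempFasta <- function(records, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(records), function(h) {
    c(paste0(">", h), records[[h]])
  })), path)
  path
}

writeTempGff <- function(rows, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", rows), path)
  path
}

gffRow <- function(contig, start, end, strand, attrs, type = "CDS",
                   phase = "0") {
  paste(contig, "test", type, start, end, ".", strand, phase, attrs,
        sep = "\t")
}

# independently constructed 64-codon catalogue
allCodonsForTest <- function() {
  b <- c("A", "C", "G", "T")
  apply(expand.grid(b3 = b, b2 = b, b1 = b)[, 3:1], 1, paste0,
        collapse = "")
}

# independent reverse-complement oracle (no Biostrings)
oracleRevComp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# minimal gene table for context statistics built directly from vectors
makeGeneTable <- function(stop_codon, downstream,
                          is_heg = rep(TRUE, length(stop_codon))) {
  data.frame(gene_id = sprintf("g%05d", seq_along(stop_codon)),
             cds = paste0("ATGGCA", stop_codon),
             stop_codon = stop_codon, downstream = downstream,
             is_heg = is_heg, stringsAsFactors = FALSE)
}

# strand-symmetry transformation: reverse-complement every contig and remap
# each gene (start, end, strand) -> (L-end+1, L-start+1, opposite strand);
# returns the dataset rebuilt through the ordinary extraction path
flipDataset <- function(ds) {
  ctg <- contigs(ds)
  flipped <- Biostrings::reverseComplement(ctg)
  names(flipped) <- names(ctg)
  S4Vectors::mcols(flipped)$circular <- S4Vectors::mcols(ctg)$circular
  df <- geneTable(ds)
  L <- stats::setNames(Biostrings::width(ctg), names(ctg))[df$contig_id]
  tab <- data.frame(gene_id = df$gene_id, contig_id = df$contig_id,
                    start = L - df$end + 1L, end = L - df$start + 1L,
                    strand = ifelse(df$strand == "+", "-", "+"),
                    stringsAsFactors = FALSE)
  buildGenomeDataset(genomeId(ds), flipped, tab,
                     contextLen = max(df$context_len_obtained, 30L),
                     geneticCodeId = geneticCodeId(ds),
                     hegIds = df$gene_id[df$is_heg])
}
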