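# HEG labelling: external gene-id lists (the primary route, mirroring
# database-predicted highly expressed genes), plus an optional codon
# adaptation index (CAI) classifier so the full pipeline can run on data
# with no external list.

#' Flag highly expressed genes from an id list
#'
#' Reads a plain-text list (one gene id per line; blank lines and `#`
#' comments ignored) and sets `is_heg` on the matching gene records. File
#' labels always override any CAI-based classification.
#'
#' @param path list file.
#' @param dataset a [GenomeDataset-class].
#' @return the dataset with `is_heg` set. Ids in the list that match no
#'   gene are reported in a warning; an empty or fully unmatched list is an
#'   error (it usually means an id-scheme mismatch).
#' @export
loadHegList <- function(path, dataset) {
  ln <- readLines(path)
  ln <- trimws(sub("#.*$", "", ln))
  ids <- ln[nzchar(ln)]
  if (length(ids) == 0L) stop("HEG list ", path, " contains no gene ids")
  gid <- S4Vectors::mcols(dataset@genes)$gene_id
  hit <- ids %in% gid
  if (!any(hit)) {
    stop("no HEG list id matches a gene id (id-scheme mismatch?): ",
         path)
  }
  if (any(!hit)) {
    warning("HEG list ids not found in dataset: ",
            paste(ids[!hit], collapse = ", "))
  }
  S4Vectors::mcols(dataset@genes)$is_heg <- gid %in% ids
  methods::validObject(dataset)
  dataset
}

# synonymous families (codon -> amino acid) for a genetic code, stop codons
# excluded
senseFamilies <- function(geneticCodeId = 11L) {
  gc <- Biostrings::getGeneticCode(as.character(geneticCodeId))
  gc[gc != "*"]
}

#' Relative-adaptiveness weights for the codon adaptation index
#'
#' Counts in-frame codons of the reference gene set (terminal stop codons
#' excluded) and normalizes within each synonymous family to the most
#' frequent member: `w(c) = count(c) / max count in family(c)`. Codons never
#' observed in the reference receive a pseudo-count of 0.5 so that no weight
#' is zero.
#'
#' @param referenceGenes character vector of reference CDS (classically the
#'   ribosomal-protein genes), or a [GenomeDataset-class] whose HEG class is
#'   used.
#' @param geneticCodeId NCBI translation table id (default 11; defines the
#'   synonymous families).
#' @return list with `w` (named weights over the 61 sense codons, in (0,1],
#'   family maxima at 1) and `referenceSize` (number of reference genes).
#' @export
caiWeights <- function(referenceGenes, geneticCodeId = 11L) {
  if (methods::is(referenceGenes, "GenomeDataset")) {
    referenceGenes <- classGenes(referenceGenes, "HEG")$cds
  }
  stopifnot(length(referenceGenes) >= 1L)
  fam <- senseFamilies(geneticCodeId)
  stops <- stopCodonsFor(geneticCodeId)
  codons <- unlist(lapply(referenceGenes, splitCodons), use.names = FALSE)
  # drop terminal stops (and any stray stop triplet) plus ambiguous codons
  codons <- codons[!(codons %in% stops) & !grepl("N", codons, fixed = TRUE)]
  cnt <- table(factor(codons, levels = names(fam)))
  cnt <- ifelse(cnt == 0L, 0.5, as.numeric(cnt))
  names(cnt) <- names(fam)
  w <- cnt
  for (aa in unique(fam)) {
    members <- names(fam)[fam == aa]
    w[members] <- cnt[members] / max(cnt[members])
  }
  list(w = w, referenceSize = length(referenceGenes))
}

#' Codon adaptation index of a gene
#'
#' Geometric mean of the relative-adaptiveness weights over the gene's sense
#' codons, computed in log space. The terminal stop codon and the
#' single-codon families (ATG, TGG under code 11) are excluded, per the
#' standard convention; codons containing `N` are skipped.
#'
#' @param gene a CDS (character scalar) or character vector of CDS.
#' @param weights output of [caiWeights()].
#' @param geneticCodeId NCBI translation table id (default 11).
#' @return numeric vector of CAI values in (0, 1].
#' @export
caiScore <- function(gene, weights, geneticCodeId = 11L) {
  fam <- senseFamilies(geneticCodeId)
  famSize <- table(fam)
  scorable <- names(fam)[famSize[fam] > 1L]
  stops <- stopCodonsFor(geneticCodeId)
  vapply(gene, function(g) {
    cod <- splitCodons(g)
    if (length(cod) && cod[length(cod)] %in% stops) {
      cod <- cod[-length(cod)]
    }
    cod <- cod[cod %in% scorable]
    if (length(cod) == 0L) {
      stop("gene has no scorable codons (nothing outside single-codon ",
           "families)")
    }
    exp(mean(log(weights$w[cod])))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Classify highly expressed genes by CAI quantile
#'
#' Scores every valid gene with [caiScore()] and flags the top
#' `(1 - quantile)` share as HEG, ties broken deterministically by gene id.
#' This is pipeline plumbing for datasets without an external HEG list; it
#' is not a reimplementation of any database's HEG prediction.
#'
#' @param dataset a [GenomeDataset-class].
#' @param quantile score quantile above which genes are flagged (default
#'   0.95, i.e. the top 5%); 0 flags every valid gene.
#' @param referenceGenes reference CDS for [caiWeights()]; defaults to all
#'   valid CDS of the dataset (genome-average weights).
#' @return list with `dataset` (flags replaced) and `scores` (data.frame
#'   `gene_id`, `cai`, `is_heg`).
#' @export
classifyHegByCai <- function(dataset, quantile = 0.95,
                             referenceGenes = NULL) {
  df <- geneTable(dataset, validOnly = TRUE)
  stopifnot(nrow(df) > 0L)
  if (is.null(referenceGenes)) referenceGenes <- df$cds
  w <- caiWeights(referenceGenes, dataset@geneticCodeId)
  cai <- caiScore(df$cds, w, dataset@geneticCodeId)
  n <- nrow(df)
  k <- floor((1 - quantile) * n + 1e-9)
  ord <- order(-cai, df$gene_id)
  flagged <- df$gene_id[ord[seq_len(k)]]
  gid <- S4Vectors::mcols(dataset@genes)$gene_id
  S4Vectors::mcols(dataset@genes)$is_heg <- gid %in% flagged
  scores <- data.frame(gene_id = df$gene_id, cai = cai,
                       is_heg = df$gene_id %in% flagged,
                       stringsAsFactors = FALSE)
  list(dataset = dataset, scores = scores)
}
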