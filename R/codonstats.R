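# Stop-codon usage tables, genome GC content and whole-codon usage.

#' Genome GC content
#'
#' Fraction (G+C)/(A+C+G+T) over all contigs; `N` is excluded from both
#' numerator and denominator. By construction the value is invariant under
#' reverse complement of any contig.
#'
#' @param x a [GenomeDataset-class], `DNAStringSet`, or character vector of
#'   sequences.
#' @return fraction in `[0,1]`.
#' @export
genomeGC <- function(x) {
  if (methods::is(x, "GenomeDataset")) x <- contigs(x)
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  lf <- colSums(Biostrings::letterFrequency(x, c("A", "C", "G", "T")))
  tot <- sum(lf)
  if (tot == 0) stop("undefined GC: no unambiguous bases in input")
  unname((lf[["C"]] + lf[["G"]]) / tot)
}

#' GC content of the coding sequences of a gene class
#'
#' Companion to [genomeGC()] for sensitivity checks: GC computed over the
#' valid CDS of one gene class rather than the whole genome.
#'
#' @param x a [GenomeDataset-class].
#' @param geneClass `"ALL"`, `"HEG"` or `"LEG"`.
#' @export
cdsGC <- function(x, geneClass = "ALL") {
  df <- classGenes(x, geneClass)
  if (nrow(df) == 0L) stop("no valid genes in class ", geneClass)
  genomeGC(df$cds)
}

# valid genes of one class as a data.frame; accepts a GenomeDataset or a
# gene table (data.frame with at least stop_codon; is_heg needed for
# HEG/LEG)
classGenes <- function(x, geneClass = c("ALL", "HEG", "LEG")) {
  geneClass <- match.arg(geneClass)
  df <- if (methods::is(x, "GenomeDataset")) geneTable(x, validOnly = TRUE)
        else x
  if (!is.null(df$valid)) df <- df[df$valid, , drop = FALSE]
  if (geneClass != "ALL") {
    if (is.null(df$is_heg)) stop("gene table lacks an is_heg column")
    df <- df[if (geneClass == "HEG") df$is_heg else !df$is_heg, ,
             drop = FALSE]
  }
  df
}

#' Count stop codons in a gene class
#'
#' Tallies the termination codon of every valid gene in a class. `LEG`
#' (low-expressed genes) is the complement of the HEG set among valid genes,
#' so per codon `ALL = HEG + LEG`.
#'
#' @param x a [GenomeDataset-class] or a gene table data.frame with columns
#'   `stop_codon` (DNA triplets) and, for class filtering, `is_heg`.
#' @param geneClass `"ALL"`, `"HEG"` or `"LEG"`.
#' @param genomeId genome label for the table (taken from the dataset when
#'   `x` is one).
#' @return a [StopUsageTable-class]. An empty class yields a warning and
#'   `NA` frequencies (missing, not zero).
#' @export
countStopCodons <- function(x, geneClass = "ALL", genomeId = NA_character_) {
  if (methods::is(x, "GenomeDataset")) genomeId <- x@genomeId
  df <- classGenes(x, geneClass)
  sc <- df$stop_codon[!is.na(df$stop_codon)]
  counts <- stats::setNames(
    as.integer(table(factor(sc, levels = STOP_DNA))), STOP_RNA)
  total <- sum(counts)
  if (total == 0L) {
    warning("empty gene class ", geneClass,
            ": stop frequencies are undefined")
    freqs <- stats::setNames(rep(NA_real_, 3L), STOP_RNA)
  } else {
    freqs <- counts / total
  }
  methods::new("StopUsageTable", genomeId = as.character(genomeId),
               geneClass = geneClass, counts = counts,
               total = as.integer(total), freqs = freqs)
}

#' Build a StopUsageTable from raw counts
#'
#' For published count tables (no sequences involved), e.g. codon-usage
#' database tallies.
#'
#' @param counts named vector with elements `UAA`, `UAG`, `UGA` (RNA labels).
#' @param geneClass,genomeId table labels.
#' @export
stopUsageTable <- function(counts, geneClass = "ALL",
                           genomeId = NA_character_) {
  stopifnot(all(STOP_RNA %in% names(counts)))
  counts <- stats::setNames(as.integer(counts[STOP_RNA]), STOP_RNA)
  total <- sum(counts)
  freqs <- if (total > 0L) counts / total else
    stats::setNames(rep(NA_real_, 3L), STOP_RNA)
  methods::new("StopUsageTable", genomeId = as.character(genomeId),
               geneClass = geneClass, counts = counts,
               total = as.integer(total), freqs = freqs)
}

#' @rdname StopUsageTable-accessors
#' @param x a [StopUsageTable-class].
#' @export
setMethod("stopCounts", "StopUsageTable", function(x) x@counts)

#' @rdname StopUsageTable-accessors
#' @export
setMethod("stopFreqs", "StopUsageTable", function(x) x@freqs)

setMethod("show", "StopUsageTable", function(object) {
  cat("StopUsageTable:", object@genomeId, "/", object@geneClass,
      "(n =", paste0(object@total, ")"), "\n")
  print(rbind(count = object@counts,
              freq = round(object@freqs, 4)))
})

#' Stop-codon percentages at reporting precision
#'
#' `100 * freq`, rounded half-up to `decimals` places. Rounding happens only
#' here, at the reporting layer; internal frequencies keep full precision.
#'
#' @param x a [StopUsageTable-class] (`total > 0`).
#' @param decimals decimal places (0 reproduces whole-percent prints such as
#'   64/29; 1 gives e.g. 7.4).
#' @return named numeric vector `c(UAA=, UAG=, UGA=)` of percentages.
#' @export
setMethod("stopPercentages", "StopUsageTable", function(x, decimals = 1) {
  if (x@total == 0L) stop("percentages undefined for an empty class")
  roundHalfUp(100 * x@freqs, decimals)
})

#' Whole-codon usage of a gene set
#'
#' In-frame triplet counts over all codon positions of the valid CDS,
#' including the terminal stop codon. Codons containing `N` are ignored.
#' Usage is additive over gene sets: `codonUsage(c(g1, g2))` equals the
#' elementwise sum of the separate tables.
#'
#' @param x a [GenomeDataset-class], gene table data.frame, or character
#'   vector of CDS.
#' @return data.frame of 64 rows: `codon` (DNA), `codon_rna`, `count`,
#'   `freq`.
#' @export
codonUsage <- function(x) {
  cds <- if (is.character(x)) x else classGenes(x, "ALL")$cds
  codons <- allCodons()
  if (length(cds) == 0L) {
    counts <- stats::setNames(integer(64L), codons)
  } else {
    m <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(cds), width = 3L, step = 3L)
    counts <- colSums(m)[codons]
  }
  tot <- sum(counts)
  data.frame(codon = codons, codon_rna = toRNA(codons),
             count = as.integer(counts),
             freq = if (tot > 0) as.numeric(counts / tot) else NA_real_,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Ratio of two codons in a usage table
#'
#' @param usage data.frame from [codonUsage()].
#' @param a,b codons (DNA or RNA labels).
#' @return `count(a) / count(b)`.
#' @export
codonRatio <- function(usage, a, b) {
  cnt <- stats::setNames(usage$count, usage$codon)
  a <- toDNA(a); b <- toDNA(b)
  stopifnot(a %in% names(cnt), b %in% names(cnt))
  unname(cnt[a] / cnt[b])
}

#' One-row per-genome summary
#'
#' Genome GC content, gene counts, and the stop-codon counts/frequencies of
#' the ALL, HEG and LEG classes, flattened to one data.frame row. Column
#' `uag_fraction_heg` duplicates `heg_uag_freq` for the UAG screen.
#'
#' @param x a [GenomeDataset-class].
#' @return one-row data.frame; rows for several genomes can be `rbind`-ed
#'   into the cohort summary consumed by [gcStopCorrelation()] and
#'   [uagHegScreen()].
#' @export
genomeSummary <- function(x) {
  stopifnot(methods::is(x, "GenomeDataset"))
  df <- geneTable(x, validOnly = TRUE)
  out <- data.frame(genome_id = x@genomeId, gc = genomeGC(x),
                    n_genes_all = nrow(df), n_genes_heg = sum(df$is_heg),
                    stringsAsFactors = FALSE)
  for (cls in c("ALL", "HEG", "LEG")) {
    tab <- suppressWarnings(countStopCodons(x, cls))
    pre <- tolower(cls)
    cnt <- stopCounts(tab); frq <- stopFreqs(tab)
    for (cod in STOP_RNA) {
      out[[paste0(pre, "_", tolower(cod), "_count")]] <- cnt[[cod]]
      out[[paste0(pre, "_", tolower(cod), "_freq")]] <- frq[[cod]]
    }
    out[[paste0(pre, "_total")]] <- tab@total
  }
  out$uag_fraction_heg <- out$heg_uag_freq
  out
}
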