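# 3' context of stop codons: +4 nucleotide profiles, downstream-codon
# frequencies vs the 1/64 chance expectation, tandem stops, and the extended
# downstream preference scan.
#
# Position convention (the main off-by-three hazard): the stop codon
# occupies +1..+3, the first downstream base is +4, and "+456" is the first
# full downstream codon. downstream[1] is therefore position +4.

#' Chance expectation for a downstream codon
#'
#' The uniform expectation 1/64 for any given triplet, drawn as the
#' reference line of downstream-codon frequency reports (1.5625%, commonly
#' printed rounded as 2%).
#'
#' @return 1/64.
#' @export
chanceExpectation <- function() 1 / 64

#' Bin a genome GC content into LOW / MID / HIGH
#'
#' `LOW` below 40% GC, `MID` in `[40%, 60%]`, `HIGH` above 60%. The closed
#' MID interval makes the bins a partition; boundary genomes fall in MID.
#'
#' @param gc numeric vector of GC fractions in `[0,1]`.
#' @param low,high bin edges (fractions; defaults 0.40 and 0.60).
#' @return factor with levels `LOW`, `MID`, `HIGH`.
#' @examples
#' gcBin(c(0.3354, 0.5193, 0.6714))  # LOW MID HIGH
#' @export
gcBin <- function(gc, low = 0.40, high = 0.60) {
  stopifnot(all(gc >= 0 & gc <= 1, na.rm = TRUE), low < high)
  factor(ifelse(gc < low, "LOW", ifelse(gc <= high, "MID", "HIGH")),
         levels = c("LOW", "MID", "HIGH"))
}

# per-row +4.. base matrix helpers ------------------------------------------

# base frequencies of a character vector restricted to A/C/G/T, reported in
# RNA labels; returns c(A=,C=,G=,U=) and attr n
baseFreqs <- function(b) {
  b <- b[b %in% c("A", "C", "G", "T")]
  n <- length(b)
  f <- table(factor(b, levels = c("A", "C", "G", "T"))) / max(n, 1L)
  out <- stats::setNames(as.numeric(f), c("A", "C", "G", "U"))
  attr(out, "n") <- n
  out
}

#' Nucleotide profile at position +4
#'
#' Frequency of A/C/G/U at the first base 3' of the stop codon, per stop
#' codon identity (and optionally pooled). Genes need at least one
#' downstream base; an ambiguous (`N`) +4 base is dropped. Strata with no
#' contributing genes are omitted with a warning.
#'
#' @param x a [GenomeDataset-class] or gene table data.frame (columns
#'   `stop_codon`, `downstream`; `is_heg` when filtering by class).
#' @param geneClass `"ALL"`, `"HEG"` or `"LEG"`.
#' @param by `"stop_codon"` for one row per stop codon (default), or `NULL`
#'   to pool all stops.
#' @return data.frame with columns `stop_codon` (RNA; `"all"` when pooled),
#'   `A`, `C`, `G`, `U` (frequencies summing to 1) and `n`.
#' @export
plus4Profile <- function(x, geneClass = "ALL", by = "stop_codon") {
  df <- classGenes(x, geneClass)
  df <- df[!is.na(df$stop_codon) & nchar(df$downstream) >= 1L, , drop = FALSE]
  plus4 <- substr(df$downstream, 1L, 1L)
  strata <- if (is.null(by)) rep("all", nrow(df)) else df$stop_codon
  levs <- if (is.null(by)) "all" else STOP_DNA
  rows <- lapply(levs, function(s) {
    f <- baseFreqs(plus4[strata == s])
    n <- attr(f, "n")
    if (n == 0L) return(NULL)
    cbind(data.frame(stop_codon = if (s == "all") "all" else toRNA(s),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(f)), n = n)
  })
  empty <- levs[vapply(rows, is.null, logical(1))]
  if (length(empty)) {
    warning("stratum with no +4 observations omitted: ",
            paste(toRNA(empty), collapse = ", "))
  }
  do.call(rbind, rows)
}

# +4..+6 triplets of the genes of a class: >=3 downstream bases, no N
downstreamTriplets <- function(x, geneClass = "ALL") {
  df <- classGenes(x, geneClass)
  df <- df[!is.na(df$stop_codon) & nchar(df$downstream) >= 3L, , drop = FALSE]
  tri <- substr(df$downstream, 1L, 3L)
  keep <- !grepl("N", tri, fixed = TRUE)
  list(triplet = tri[keep], primary = df$stop_codon[keep])
}

#' Downstream-codon (+4..+6) frequency table
#'
#' Counts of the first full codon 3' of the stop, over genes with at least
#' three downstream bases (triplets containing `N` are excluded). The report
#' includes the codons at or above the 1/64 chance expectation and the UNN
#' aggregate (triplets starting with U).
#'
#' @inheritParams plus4Profile
#' @return list with `table` (64-row data.frame `codon`, `codon_rna`,
#'   `count`, `freq`), `n`, `chance` (= 1/64), `above_chance` (RNA codons
#'   with `freq >= 1/64`, by descending frequency) and `unn_fraction`.
#' @export
downstreamCodonFreq <- function(x, geneClass = "ALL") {
  dt <- downstreamTriplets(x, geneClass)
  codons <- allCodons()
  counts <- as.integer(table(factor(dt$triplet, levels = codons)))
  n <- sum(counts)
  freq <- if (n > 0L) counts / n else rep(NA_real_, 64L)
  tab <- data.frame(codon = codons, codon_rna = toRNA(codons),
                    count = counts, freq = freq, stringsAsFactors = FALSE)
  above <- tab[!is.na(tab$freq) & tab$freq >= chanceExpectation(), ]
  above <- above[order(-above$freq, above$codon), ]
  list(table = tab, n = n, chance = chanceExpectation(),
       above_chance = above$codon_rna,
       unn_fraction = if (n > 0L)
         sum(tab$freq[substr(tab$codon, 1L, 1L) == "T"]) else NA_real_)
}

#' Tandem stop-codon fraction
#'
#' Fraction of genes whose +4..+6 triplet is itself a stop codon (a "tandem
#' stop"), with a breakdown by primary stop identity and the full
#' primary-by-tandem pair counts — the pattern of a UAG termination codon
#' immediately followed by UAA or UAG is read off the pair table.
#'
#' Computed on the same gene subset as [downstreamCodonFreq()], so the
#' overall fraction equals the sum of that table's frequencies over
#' UAA/UAG/UGA.
#'
#' @inheritParams plus4Profile
#' @return list with `fraction`, `n`, `by_stop` (data.frame `stop_codon`,
#'   `n`, `tandem_fraction`) and `pairs` (data.frame `primary`, `tandem`,
#'   `count`; RNA labels).
#' @export
tandemStopFraction <- function(x, geneClass = "ALL") {
  dt <- downstreamTriplets(x, geneClass)
  n <- length(dt$triplet)
  is_tandem <- dt$triplet %in% STOP_DNA
  by_stop <- do.call(rbind, lapply(STOP_DNA, function(s) {
    sel <- dt$primary == s
    data.frame(stop_codon = toRNA(s), n = sum(sel),
               tandem_fraction = if (any(sel)) mean(is_tandem[sel])
                                 else NA_real_,
               stringsAsFactors = FALSE)
  }))
  pairs <- expand.grid(primary = STOP_DNA, tandem = STOP_DNA,
                       stringsAsFactors = FALSE)
  pairs$count <- mapply(function(p, t) sum(dt$primary == p & dt$triplet == t),
                        pairs$primary, pairs$tandem)
  pairs$primary <- toRNA(pairs$primary)
  pairs$tandem <- toRNA(pairs$tandem)
  list(fraction = if (n > 0L) mean(is_tandem) else NA_real_, n = n,
       by_stop = by_stop, pairs = pairs)
}

#' Extended downstream preference scan
#'
#' Per-position nucleotide frequencies over the first `nCodons` downstream
#' codon slots (positions +4 onwards), with a preference statistic per
#' position: the frequency of the most frequent base minus the uniform
#' expectation 0.25. A position is flagged `preferred` when the statistic
#' exceeds `threshold`. Genes with truncated context contribute to the
#' positions they cover.
#'
#' The statistic is this package's operationalization of downstream
#' "preference"; the threshold default 0.15 is configurable.
#'
#' @inheritParams plus4Profile
#' @param nCodons downstream codon slots to scan (default 10).
#' @param threshold preference call threshold (default 0.15).
#' @return data.frame with one row per scanned position: `slot` (1-based
#'   codon slot; slot 1 is +4..+6), `position` (genomic offset, +4 ...),
#'   `A`, `C`, `G`, `U`, `n`, `max_base` (RNA), `preference`, `preferred`.
#' @export
extendedPreferenceScan <- function(x, geneClass = "ALL", nCodons = 10L,
                                   threshold = 0.15) {
  df <- classGenes(x, geneClass)
  df <- df[!is.na(df$stop_codon), , drop = FALSE]
  npos <- 3L * nCodons
  rows <- lapply(seq_len(npos), function(p) {
    b <- substr(df$downstream[nchar(df$downstream) >= p], p, p)
    f <- baseFreqs(b)
    n <- attr(f, "n")
    if (n == 0L) return(NULL)
    imax <- which.max(f)
    cbind(data.frame(slot = (p - 1L) %/% 3L + 1L, position = p + 3L),
          as.data.frame(as.list(f)),
          data.frame(n = n, max_base = names(f)[imax],
                     preference = unname(f[imax]) - 0.25,
                     preferred = unname(f[imax]) - 0.25 > threshold,
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' Screen genomes for UAG-rich highly expressed genes
#'
#' Returns the genomes whose HEG UAG stop fraction strictly exceeds
#' `threshold` (default 15%), sorted by descending fraction.
#'
#' @param summaries cohort summary data.frame (rbind of [genomeSummary()]
#'   rows; needs `genome_id` and `uag_fraction_heg`).
#' @param threshold fraction cutoff (default 0.15).
#' @return data.frame `genome_id`, `uag_fraction_heg`.
#' @export
uagHegScreen <- function(summaries, threshold = 0.15) {
  stopifnot(all(c("genome_id", "uag_fraction_heg") %in% names(summaries)))
  hit <- summaries[!is.na(summaries$uag_fraction_heg) &
                     summaries$uag_fraction_heg > threshold,
                   c("genome_id", "uag_fraction_heg")]
  hit <- hit[order(-hit$uag_fraction_heg, hit$genome_id), ]
  rownames(hit) <- NULL
  hit
}
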