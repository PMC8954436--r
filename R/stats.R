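# Statistical layer: Pearson correlation of stop frequencies with GC across
# genomes, and Student's t-test grouping of +4 nucleotide frequencies.

#' Pearson correlation with two-sided p-value
#'
#' Standard product-moment correlation; the p-value comes from the t
#' transform with n-2 degrees of freedom (via [stats::cor.test()]).
#' Symmetric in its arguments and invariant under positive affine maps of
#' either one.
#'
#' @param x,y numeric vectors of equal length `>= 3`, each with nonzero
#'   variance (zero variance raises an undefined-correlation error).
#' @return list with `r`, `p` (two-sided) and `n`.
#' @export
pearsonCorr <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations for a correlation")
  if (anyNA(x) || anyNA(y)) stop("missing values in correlation input")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined correlation: zero variance in input")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlation of stop-codon frequencies with genome GC across a cohort
#'
#' For each termination codon, the Pearson correlation between its
#' class-level frequency and genome GC content over the genomes of a cohort
#' summary. Genomes with an empty class (NA frequencies) are dropped.
#'
#' @param summaries cohort summary data.frame (rbind of [genomeSummary()]
#'   rows).
#' @param geneClass `"HEG"` (default, matching stop-usage-vs-GC figures of
#'   cohorts under translational selection), `"ALL"` or `"LEG"`.
#' @param strict with the default `TRUE`, degenerate input (zero variance,
#'   fewer than 3 genomes) raises the [pearsonCorr()] error; `strict =
#'   FALSE` downgrades it to a warning and an `NA` row, which keeps cohort
#'   reports running when e.g. a rare stop codon never varies.
#' @return data.frame with one row per stop codon: `stop_codon` (RNA),
#'   `gene_class`, `n`, `r`, `p`.
#' @export
gcStopCorrelation <- function(summaries, geneClass = "HEG",
                              strict = TRUE) {
  pre <- tolower(geneClass)
  do.call(rbind, lapply(STOP_RNA, function(cod) {
    ycol <- paste0(pre, "_", tolower(cod), "_freq")
    stopifnot(ycol %in% names(summaries))
    keep <- !is.na(summaries[[ycol]])
    res <- tryCatch(
      pearsonCorr(summaries$gc[keep], summaries[[ycol]][keep]),
      error = function(e) {
        if (strict) stop(e)
        warning(geneClass, "/", cod, ": ", conditionMessage(e))
        list(r = NA_real_, p = NA_real_, n = sum(keep))
      })
    data.frame(stop_codon = cod, gene_class = geneClass, n = res$n,
               r = res$r, p = res$p, stringsAsFactors = FALSE)
  }))
}

#' Two-sample Student's t-test
#'
#' Pooled-variance two-sided Student's t by default (`welch = TRUE` switches
#' to the Welch form). Degenerate inputs follow explicit conventions rather
#' than erroring: when the pooled variance is zero, equal means give
#' `t = 0, p = 1` and unequal means give `t = +/-Inf, p = 0`.
#'
#' @param a,b numeric samples, each of length `>= 2`.
#' @param welch use Welch's unequal-variance form.
#' @return list with `t`, `p` (two-sided) and `df`.
#' @export
studentT <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    df <- length(a) + length(b) - 2L
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = df))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0, df = df))
  }
  tt <- stats::t.test(a, b, var.equal = !welch, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

# maximal cliques of a small symmetric adjacency matrix (k <= ~12),
# by exhaustive subset enumeration; returns a list of integer member sets
maximalCliques <- function(adj) {
  k <- nrow(adj)
  cliques <- list()
  for (m in seq_len(2^k - 1L)) {
    members <- which(bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    if (length(members) > 1L) {
      pr <- utils::combn(members, 2L)
      if (!all(adj[cbind(pr[1L, ], pr[2L, ])])) next
    }
    cliques[[length(cliques) + 1L]] <- members
  }
  is_max <- vapply(cliques, function(ci) {
    !any(vapply(cliques, function(cj) {
      length(cj) > length(ci) && all(ci %in% cj)
    }, logical(1)))
  }, logical(1))
  cliques[is_max]
}

#' Group +4 nucleotides by pairwise Student's t-tests
#'
#' Runs all six pairwise [studentT()] tests on per-genome frequency
#' observations of the four nucleotides within one stratum and assembles a
#' compact letter display at significance level `alpha` (default 0.01, no
#' multiple-testing correction; `holm = TRUE` applies a Holm correction to
#' the six p-values).
#'
#' Letters are the maximal cliques of the non-significance graph, ordered by
#' the highest member mean: two nucleotides share a letter if and only if
#' their difference is non-significant together with every other member of
#' that letter. This satisfies both grouping invariants (sharing a letter
#' implies pairwise non-significance; sharing none implies significance)
#' even when pairwise non-significance is non-transitive, in which case a
#' nucleotide can carry several letters. The result depends only on the
#' data, not on input order (ties in means break alphabetically).
#'
#' @param freqs observations per nucleotide: a named list of numeric vectors
#'   or a matrix/data.frame with columns named among `A`, `C`, `G`, `U` (or
#'   `T`), one row/element entry per genome.
#' @param alpha pairwise significance level (default 0.01).
#' @param welch,holm test variant flags (defaults: pooled-variance Student,
#'   uncorrected).
#' @return list with `groups` (data.frame `nucleotide`, `mean`, `letters`,
#'   sorted by descending mean) and `p` (4x4 symmetric p-value matrix).
#'   With fewer than 2 genomes per nucleotide: a warning and `NULL` groups.
#' @export
groupNucleotides <- function(freqs, alpha = 0.01, welch = FALSE,
                             holm = FALSE) {
  if (is.matrix(freqs) || is.data.frame(freqs)) {
    freqs <- as.list(as.data.frame(freqs))
  }
  names(freqs) <- toRNA(names(freqs))
  nts <- intersect(c("A", "C", "G", "U"), names(freqs))
  stopifnot(length(nts) >= 2L)
  freqs <- freqs[nts]
  if (any(lengths(freqs) < 2L)) {
    warning("fewer than 2 genomes in stratum: no grouping performed")
    return(list(groups = NULL, p = NULL))
  }
  k <- length(nts)
  p <- matrix(NA_real_, k, k, dimnames = list(nts, nts))
  pr <- utils::combn(k, 2L)
  pvals <- apply(pr, 2L, function(ij) {
    studentT(freqs[[ij[1L]]], freqs[[ij[2L]]], welch = welch)$p
  })
  if (holm) pvals <- stats::p.adjust(pvals, method = "holm")
  for (j in seq_len(ncol(pr))) {
    p[pr[1L, j], pr[2L, j]] <- p[pr[2L, j], pr[1L, j]] <- pvals[j]
  }
  means <- vapply(freqs, mean, numeric(1))
  # order by descending mean, ties alphabetical, before assigning letters
  ord <- order(-means, nts)
  nonsig <- p >= alpha
  diag(nonsig) <- TRUE
  cliques <- maximalCliques(nonsig[ord, ord, drop = FALSE])
  best <- vapply(cliques, function(m) min(m), numeric(1))  # ord is by mean
  cliques <- cliques[order(best)]
  letters_per <- stats::setNames(vector("list", k), nts[ord])
  for (i in seq_along(cliques)) {
    for (m in cliques[[i]]) {
      letters_per[[m]] <- c(letters_per[[m]], letters[i])
    }
  }
  groups <- data.frame(
    nucleotide = nts[ord],
    mean = unname(means[ord]),
    letters = vapply(letters_per, function(l) paste(sort(l), collapse = ""),
                     character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(groups = groups, p = p)
}

#' Per-genome +4 frequency observations for a stratum
#'
#' Builds the observation matrix consumed by [groupNucleotides()]: one row
#' per genome, columns `A`, `C`, `G`, `U`, holding each genome's +4
#' nucleotide frequencies for one (gene class, stop codon) stratum. Genomes
#' with no contributing genes are dropped.
#'
#' @param datasets list of [GenomeDataset-class] objects.
#' @param stopCodon stop codon (RNA or DNA label), or `"all"` to pool stops.
#' @param geneClass `"ALL"`, `"HEG"` or `"LEG"`.
#' @return numeric matrix (genomes x 4), rownames the genome ids.
#' @export
plus4ByGenome <- function(datasets, stopCodon = "all", geneClass = "ALL") {
  rows <- lapply(datasets, function(d) {
    prof <- suppressWarnings(
      plus4Profile(d, geneClass,
                   by = if (identical(stopCodon, "all")) NULL
                        else "stop_codon"))
    if (is.null(prof)) return(NULL)
    sel <- prof$stop_codon == if (identical(stopCodon, "all")) "all"
                              else toRNA(stopCodon)
    if (!any(sel)) return(NULL)
    stats::setNames(as.numeric(prof[sel, c("A", "C", "G", "U")]),
                    c("A", "C", "G", "U"))
  })
  names(rows) <- vapply(datasets, genomeId, character(1))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  do.call(rbind, rows)
}
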