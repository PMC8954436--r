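# Genome / annotation input and strand-aware CDS + downstream-context
# extraction. Coordinates are GFF3 1-based inclusive everywhere; no half-open
# conversion is exposed.

#' Read contigs from a FASTA file
#'
#' Reads genome contigs, uppercases the sequence, and folds every IUPAC
#' letter outside `{A,C,G,T}` to `N` (counting analyses never impute
#' ambiguous bases). The contig id is the header token before the first
#' whitespace. A `circular=true` token anywhere in the header description
#' marks the contig circular (the convention used by [writeSimulatedGenome()]);
#' otherwise the `circular` argument applies.
#'
#' @param path FASTA file.
#' @param circular default circularity for contigs whose header carries no
#'   `circular=` token; scalar or one value per contig.
#' @return A [Biostrings::DNAStringSet] with unique names and a logical
#'   `mcols()$circular` column.
#' @export
readContigs <- function(path, circular = FALSE) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("FASTA format error: no records in ", path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("FASTA format error: duplicate contig id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  circ <- rep_len(circular, length(x))
  tok <- regmatches(headers, regexpr("circular=(true|false)", headers,
                                     ignore.case = TRUE))
  has_tok <- grepl("circular=(true|false)", headers, ignore.case = TRUE)
  circ[has_tok] <- grepl("true", tok, ignore.case = TRUE)
  seqs <- toupper(as.character(x))
  seqs <- gsub("[^ACGT]", "N", seqs)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$circular <- circ
  out
}

#' Read single-segment CDS features from a GFF3 file
#'
#' Consumes rows with feature type `CDS` only. The gene id is taken from the
#' `ID=` attribute, falling back to `locus_tag=`. Multi-segment CDS (the same
#' id on several rows) are rejected with reason `"multi-segment"` — the scope
#' is prokaryotic, unspliced CDS. A non-zero phase is reported (message) and
#' otherwise ignored: CDS are assumed phase 0.
#'
#' @param path GFF3 file.
#' @param contigs optional `DNAStringSet` (or character vector of contig
#'   ids); when given, CDS referencing unknown contigs raise an error that
#'   lists the offending gene ids.
#' @return A list with `cds`, a data.frame of columns
#'   `gene_id, contig_id, start, end, strand`, and `rejected`, a data.frame
#'   of `gene_id, reason`.
#' @export
readGffCds <- function(path, contigs = NULL) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) {
                   stop("GFF3 format error in ", path, ": ",
                        conditionMessage(e))
                 })
  gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  m <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(m)) as.character(m$ID) else rep(NA_character_, length(gr))
  if ("locus_tag" %in% names(m)) {
    lt <- as.character(m$locus_tag)
    id[is.na(id) | id == ""] <- lt[is.na(id) | id == ""]
  }
  if (anyNA(id) || any(id == "")) {
    stop("GFF3 format error: CDS row(s) without ID or locus_tag attribute")
  }
  if ("phase" %in% names(m)) {
    ph <- suppressWarnings(as.integer(as.character(m$phase)))
    nz <- !is.na(ph) & ph != 0L
    if (any(nz)) {
      message("ignoring non-zero phase on ", sum(nz),
              " CDS row(s); CDS are treated as phase 0")
    }
  }
  multi <- unique(id[duplicated(id)])
  keep <- !(id %in% multi)
  rejected <- data.frame(gene_id = multi,
                         reason = rep("multi-segment", length(multi)),
                         stringsAsFactors = FALSE)
  cds <- data.frame(
    gene_id = id[keep],
    contig_id = as.character(GenomicRanges::seqnames(gr))[keep],
    start = BiocGenerics::start(gr)[keep],
    end = BiocGenerics::end(gr)[keep],
    strand = as.character(BiocGenerics::strand(gr))[keep],
    stringsAsFactors = FALSE
  )
  if (any(!cds$strand %in% c("+", "-"))) {
    stop("GFF3 format error: CDS with missing strand")
  }
  if (!is.null(contigs)) {
    ids <- if (is.character(contigs)) contigs else names(contigs)
    bad <- !(cds$contig_id %in% ids)
    if (any(bad)) {
      stop("CDS reference unknown contig(s); offending gene ids: ",
           paste(cds$gene_id[bad], collapse = ", "))
    }
  }
  list(cds = cds, rejected = rejected)
}

#' Extract a CDS and its 3' downstream context from a contig
#'
#' Returns the coding sequence in gene-sense orientation and up to
#' `contextLen` bases of genomic context 3' of the stop codon, also in
#' gene-sense orientation (its first base is position +4, the stop codon
#' occupying +1..+3). On the minus strand both are reverse complements of
#' the corresponding genomic windows. On circular contigs the context window
#' wraps around the origin; on linear contigs it truncates at the edge, so
#' the returned context may be shorter than `contextLen`.
#'
#' @param contig a `DNAString`, single-element `DNAStringSet`, or character
#'   sequence.
#' @param start,end 1-based inclusive CDS coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param contextLen bases of downstream context requested (default 30, i.e.
#'   10 codons, enough for the extended downstream preference scan).
#' @param circular is the contig circular?
#' @return list with character `cds` and `downstream`.
#' @export
extractCdsContext <- function(contig, start, end, strand,
                              contextLen = 30L, circular = FALSE) {
  seq <- if (is.character(contig)) contig else as.character(contig)[1]
  L <- nchar(seq)
  if (start < 1L || end > L || start > end) {
    stop("coordinates out of range: [", start, ",", end, "] on a contig of ",
         "length ", L)
  }
  region <- substr(seq, start, end)
  if (strand == "+") {
    ds <- if (contextLen > 0L) {
      wrapSubstr(seq, end + 1L, end + contextLen, circular)
    } else ""
    list(cds = region, downstream = ds)
  } else if (strand == "-") {
    up <- if (contextLen > 0L) {
      wrapSubstr(seq, start - contextLen, start - 1L, circular)
    } else ""
    list(cds = revComp(region), downstream = revComp(up))
  } else {
    stop("strand must be '+' or '-'")
  }
}

#' Validate coding sequences under a genetic code
#'
#' A CDS is valid when it is at least 6 nt, a whole number of codons, free of
#' in-frame internal stop codons, and ends in a stop codon of the given
#' genetic code. Validation is total: every input yields exactly one
#' `(valid, reason)` outcome, never an exception. Reasons, checked in order:
#' `"length"`, `"ambiguous"` (terminal triplet contains `N` — the stop is not
#' guessed), `"no_stop"`, `"internal_stop"`, else `"ok"`.
#'
#' @param cds character vector of DNA coding sequences.
#' @param geneticCodeId NCBI translation table id (default 11).
#' @return data.frame with columns `valid` (logical), `reason`, and
#'   `stop_codon` (DNA triplet, `NA` when no valid stop).
#' @export
validateCds <- function(cds, geneticCodeId = 11L) {
  stops <- stopCodonsFor(geneticCodeId)
  n <- length(cds)
  valid <- logical(n)
  reason <- character(n)
  stop_codon <- rep(NA_character_, n)
  len <- nchar(cds)
  term <- ifelse(len >= 3L, substr(cds, len - 2L, len), "")
  for (i in seq_len(n)) {
    if (len[i] < 6L || len[i] %% 3L != 0L) {
      reason[i] <- "length"
    } else if (grepl("N", term[i], fixed = TRUE)) {
      reason[i] <- "ambiguous"
    } else if (!(term[i] %in% stops)) {
      reason[i] <- "no_stop"
    } else {
      internal <- splitCodons(substr(cds[i], 1L, len[i] - 3L))
      if (any(internal %in% stops)) {
        reason[i] <- "internal_stop"
        stop_codon[i] <- term[i]
      } else {
        reason[i] <- "ok"
        valid[i] <- TRUE
        stop_codon[i] <- term[i]
      }
    }
  }
  data.frame(valid = valid, reason = reason, stop_codon = stop_codon,
             stringsAsFactors = FALSE)
}

#' Assemble a GenomeDataset from contigs and CDS coordinates
#'
#' Extracts every CDS and its downstream context ([extractCdsContext()]),
#' validates the coding sequences ([validateCds()]), and flags genes whose
#' downstream window overlaps another annotated CDS (such genes still
#' contribute to context statistics; the flag supports optional filtering).
#'
#' @param genomeId genome identifier.
#' @param contigs `DNAStringSet` from [readContigs()] (needs a
#'   `mcols()$circular` column; absent means linear).
#' @param cdsTable data.frame `gene_id, contig_id, start, end, strand`, as
#'   produced by [readGffCds()].
#' @param contextLen downstream context length to extract (default 30 nt).
#' @param geneticCodeId NCBI translation table id (default 11).
#' @param hegIds optional character vector of highly-expressed gene ids.
#' @return a [GenomeDataset-class] object.
#' @export
buildGenomeDataset <- function(genomeId, contigs, cdsTable,
                               contextLen = 30L, geneticCodeId = 11L,
                               hegIds = character(0)) {
  stopifnot(is.data.frame(cdsTable))
  circ <- S4Vectors::mcols(contigs)$circular
  if (is.null(circ)) circ <- rep(FALSE, length(contigs))
  circ <- stats::setNames(circ, names(contigs))
  seqs <- stats::setNames(as.character(contigs), names(contigs))
  n <- nrow(cdsTable)
  # batched extraction (vectorized substr; circular edge cases individually)
  seqv <- seqs[cdsTable$contig_id]
  Lv <- nchar(seqv)
  if (n > 0L && any(cdsTable$start < 1L | cdsTable$end > Lv |
                    cdsTable$start > cdsTable$end)) {
    stop("coordinates out of range in CDS table")
  }
  plus <- cdsTable$strand == "+"
  region <- substr(seqv, cdsTable$start, cdsTable$end)
  ds_s <- ifelse(plus, cdsTable$end + 1L, cdsTable$start - contextLen)
  ds_e <- ifelse(plus, cdsTable$end + contextLen, cdsTable$start - 1L)
  dsRaw <- substr(seqv, pmax(1L, ds_s), pmin(Lv, ds_e))
  wrap <- which(as.logical(circ[cdsTable$contig_id]) &
                  (ds_s < 1L | ds_e > Lv))
  for (i in wrap) {
    dsRaw[i] <- wrapSubstr(seqv[i], ds_s[i], ds_e[i], circular = TRUE)
  }
  cds <- character(n); downstream <- character(n)
  cds[plus] <- region[plus]
  cds[!plus] <- revComp(region[!plus])
  downstream[plus] <- dsRaw[plus]
  downstream[!plus] <- revComp(dsRaw[!plus])
  val <- validateCds(cds, geneticCodeId)

  # genomic footprint of each downstream window, for the overlap flag
  contigLen <- stats::setNames(nchar(seqs), names(seqs))
  obtained <- nchar(downstream)
  ds_start <- ifelse(cdsTable$strand == "+", cdsTable$end + 1L,
                     cdsTable$start - obtained)
  ds_end <- ifelse(cdsTable$strand == "+", cdsTable$end + obtained,
                   cdsTable$start - 1L)
  overlap <- rep(FALSE, n)
  if (n > 1L) {
    ok <- obtained > 0L
    dsr <- GenomicRanges::GRanges(
      cdsTable$contig_id[ok],
      IRanges::IRanges(pmax(1L, ds_start[ok]),
                       pmin(contigLen[cdsTable$contig_id[ok]], ds_end[ok])))
    cdsr <- GenomicRanges::GRanges(
      cdsTable$contig_id, IRanges::IRanges(cdsTable$start, cdsTable$end))
    hits <- GenomicRanges::findOverlaps(dsr, cdsr)
    self <- which(ok)[S4Vectors::queryHits(hits)] == S4Vectors::subjectHits(hits)
    overlap[which(ok)[unique(S4Vectors::queryHits(hits)[!self])]] <- TRUE
  }

  gr <- GenomicRanges::GRanges(
    seqnames = cdsTable$contig_id,
    ranges = IRanges::IRanges(cdsTable$start, cdsTable$end),
    strand = cdsTable$strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = cdsTable$gene_id,
    cds = cds,
    stop_codon = val$stop_codon,
    downstream = downstream,
    context_len_obtained = obtained,
    is_heg = cdsTable$gene_id %in% hegIds,
    valid = val$valid,
    reason = val$reason,
    overlap_flag = overlap
  )
  methods::new("GenomeDataset", genomeId = as.character(genomeId),
               contigs = contigs, genes = gr,
               geneticCodeId = as.integer(geneticCodeId))
}

#' Accessors for GenomeDataset
#'
#' @param x a [GenomeDataset-class].
#' @param ... for `geneTable`, `validOnly = TRUE` keeps genes with a valid
#'   CDS only.
#' @name GenomeDataset-accessors
#' @aliases genomeId contigs geneRecords geneticCodeId geneTable qcTable
NULL

#' @rdname GenomeDataset-accessors
#' @export
setMethod("genomeId", "GenomeDataset", function(x) x@genomeId)

#' @rdname GenomeDataset-accessors
#' @export
setMethod("contigs", "GenomeDataset", function(x) x@contigs)

#' @rdname GenomeDataset-accessors
#' @export
setMethod("geneRecords", "GenomeDataset", function(x) x@genes)

#' @rdname GenomeDataset-accessors
#' @export
setMethod("geneticCodeId", "GenomeDataset", function(x) x@geneticCodeId)

#' @rdname GenomeDataset-accessors
#' @export
setMethod("geneTable", "GenomeDataset", function(x, validOnly = FALSE) {
  gr <- x@genes
  df <- data.frame(
    gene_id = S4Vectors::mcols(gr)$gene_id,
    genome_id = x@genomeId,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    stringsAsFactors = FALSE
  )
  keep <- c("cds", "stop_codon", "downstream", "context_len_obtained",
            "is_heg", "valid", "reason", "overlap_flag")
  df <- cbind(df, as.data.frame(S4Vectors::mcols(gr)[, keep]))
  if (validOnly) df <- df[df$valid, , drop = FALSE]
  rownames(df) <- NULL
  df
})

#' @rdname GenomeDataset-accessors
#' @export
setMethod("qcTable", "GenomeDataset", function(x) {
  df <- geneTable(x)
  data.frame(
    gene_id = df$gene_id,
    valid = df$valid,
    reason = df$reason,
    stop_codon = toRNA(df$stop_codon),
    context_len_obtained = df$context_len_obtained,
    overlap_flag = df$overlap_flag,
    stringsAsFactors = FALSE
  )
})

setMethod("show", "GenomeDataset", function(object) {
  df <- S4Vectors::mcols(object@genes)
  cat("GenomeDataset:", object@genomeId, "\n")
  cat("  ", length(object@contigs), "contig(s),",
      sum(as.numeric(Biostrings::width(object@contigs))), "bp\n")
  cat("  ", length(object@genes), "gene record(s);",
      if (length(object@genes)) sum(df$valid) else 0L, "valid CDS;",
      if (length(object@genes)) sum(df$is_heg) else 0L, "HEG\n")
  cat("   genetic code:", object@geneticCodeId, "\n")
})
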