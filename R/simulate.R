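# Synthetic genome generator. Emits genomes whose stop-codon usage, GC
# content, +4 nucleotide distribution, downstream composition and
# tandem-stop rate are known exactly (the truth record), so that every
# downstream statistic has a parameter-recovery test. One contig per genome;
# genes are placed without overlap, with intergenic spacers at least as long
# as the downstream context window.

#' Configuration for the synthetic-genome generator
#'
#' Builds (and validates) the parameter set of [simulateGenome()] /
#' [simulateGcGradientCohort()]. Defaults describe a bacterium-like genome
#' under translational selection: stop usage near the E. coli values (HEG
#' strongly UAA-dominated with UAG rare), a U-dominant +4 base, downstream
#' composition matching the genome base composition, no forced tandem
#' stops, circular replicons, and genes on both strands.
#'
#' @param seed root seed; each genome derives its own stream from it by a
#'   fixed counter scheme, so cohorts are reproducible independent of
#'   generation order.
#' @param nGenomes,genesPerGenome cohort and genome size.
#' @param hegFraction fraction of genes flagged HEG.
#' @param gcTargets genome GC: a scalar, one value per genome, or a
#'   length-2 range spanned evenly by the cohort.
#' @param stopProbs per-class stop-codon model, a list with elements `HEG`
#'   and `LEG`; each is either a probability triple `c(UAA=,UAG=,UGA=)` or a
#'   list `list(intercept=c(...), slope=c(...))` evaluated linearly in GC
#'   (clamped at 0 and renormalized), which generates GC-linked stop-usage
#'   gradients.
#' @param plus4Dist distribution of the +4 base: a named vector over
#'   `A,C,G,U` (RNA or DNA labels) applied after every stop, a list keyed by
#'   stop codon, or `NULL` to leave the +4 base to `downstreamModel`.
#' @param downstreamModel downstream-context model:
#'   `list(type="iid", probs=...)` with `probs` a base distribution (`NULL`
#'   means the genome base composition), or `list(type="codon", probs=...)`
#'   with `probs` a distribution over codons (e.g. the 61 sense codons
#'   only, which makes tandem stops impossible).
#' @param tandemRate fraction of genes whose +4..+6 triplet is overridden
#'   by a uniformly chosen stop codon.
#' @param contextLen downstream context emitted per gene (default 30 nt).
#' @param geneLengthCodons internal codons per gene between the ATG start
#'   and the stop.
#' @param circularFraction probability that a genome's contig is circular.
#' @param reverseStrandFraction probability that a gene lies on the minus
#'   strand.
#' @return validated config (class `simulationConfig`).
#' @export
simulationConfig <- function(seed = 1L,
                             nGenomes = 1L,
                             genesPerGenome = 500L,
                             hegFraction = 0.1,
                             gcTargets = 0.50,
                             stopProbs = list(
                               HEG = c(UAA = 0.87, UAG = 0.01, UGA = 0.12),
                               LEG = c(UAA = 0.60, UAG = 0.10, UGA = 0.30)),
                             plus4Dist = c(U = 0.45, A = 0.25,
                                           C = 0.15, G = 0.15),
                             downstreamModel = list(type = "iid",
                                                    probs = NULL),
                             tandemRate = 0,
                             contextLen = 30L,
                             geneLengthCodons = 60L,
                             circularFraction = 1,
                             reverseStrandFraction = 0.5) {
  cfg <- list(seed = as.integer(seed), nGenomes = as.integer(nGenomes),
              genesPerGenome = as.integer(genesPerGenome),
              hegFraction = hegFraction, gcTargets = gcTargets,
              stopProbs = stopProbs, plus4Dist = plus4Dist,
              downstreamModel = downstreamModel, tandemRate = tandemRate,
              contextLen = as.integer(contextLen),
              geneLengthCodons = as.integer(geneLengthCodons),
              circularFraction = circularFraction,
              reverseStrandFraction = reverseStrandFraction)
  stopifnot(cfg$nGenomes >= 1L, cfg$genesPerGenome >= 1L,
            cfg$hegFraction >= 0, cfg$hegFraction <= 1,
            cfg$tandemRate >= 0, cfg$tandemRate <= 1,
            cfg$contextLen >= 0L, cfg$geneLengthCodons >= 2L,
            cfg$circularFraction >= 0, cfg$circularFraction <= 1,
            cfg$reverseStrandFraction >= 0,
            cfg$reverseStrandFraction <= 1,
            all(cfg$gcTargets > 0 & cfg$gcTargets < 1))
  for (cls in c("HEG", "LEG")) {
    sp <- cfg$stopProbs[[cls]]
    if (is.null(sp)) stop("stopProbs must contain HEG and LEG entries")
    if (is.numeric(sp)) checkProbs(sp, STOP_RNA)
  }
  if (!is.null(cfg$plus4Dist) && is.numeric(cfg$plus4Dist)) {
    checkProbs(cfg$plus4Dist)
  }
  if (identical(cfg$downstreamModel$type, "iid") &&
      !is.null(cfg$downstreamModel$probs)) {
    checkProbs(cfg$downstreamModel$probs)
  }
  if (identical(cfg$downstreamModel$type, "codon")) {
    checkProbs(cfg$downstreamModel$probs)
  }
  structure(cfg, class = "simulationConfig")
}

checkProbs <- function(p, expectNames = NULL) {
  if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
    stop("probability vector must be non-negative and sum to 1")
  }
  if (!is.null(expectNames) && !all(expectNames %in% toRNA(names(p)))) {
    stop("probability vector must be named ",
         paste(expectNames, collapse = ", "))
  }
  invisible(p)
}

# per-genome seed stream: fixed affine counter on the root seed, kept
# inside the 32-bit integer range
derivedSeed <- function(seed, genomeIndex) {
  as.integer((as.numeric(seed) + 1000003 * genomeIndex) %% 2147483629)
}

# iid base probabilities c(A=,C=,G=,T=) at a given GC fraction
baseProbsAt <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

# GC of an iid codon conditioned on not being a stop codon, as a function
# of the raw base GC theta
condBodyGC <- function(theta) {
  a <- (1 - theta) / 2; g <- theta / 2
  pTAA <- a^3; pTAG <- a * a * g; pTGA <- a * g * a
  pStop <- pTAA + pTAG + pTGA
  (3 * theta - (pTAG + pTGA)) / (3 * (1 - pStop))
}

# solve the raw base GC so that stop-free body codons hit the target GC
solveBodyTheta <- function(target) {
  stats::uniroot(function(th) condBodyGC(th) - target,
                 interval = c(1e-3, 1 - 1e-3), tol = 1e-9)$root
}

# draw m stop-free codons as a character vector, iid bases at theta
drawBodyCodons <- function(m, theta) {
  p <- baseProbsAt(theta)
  draw <- function(k) {
    b <- matrix(sample(names(p), 3L * k, replace = TRUE, prob = p),
                nrow = 3L)
    paste0(b[1L, ], b[2L, ], b[3L, ])
  }
  out <- draw(m)
  bad <- which(out %in% STOP_DNA)
  while (length(bad)) {
    out[bad] <- draw(length(bad))
    bad <- bad[out[bad] %in% STOP_DNA]
  }
  out
}

# evaluate a per-class stop model at a GC value -> c(TAA=,TAG=,TGA=) DNA keys
evalStopProbs <- function(sp, gc) {
  if (is.numeric(sp)) {
    names(sp) <- toRNA(names(sp))
    p <- sp[STOP_RNA]
  } else {
    int <- sp$intercept; names(int) <- toRNA(names(int))
    slo <- sp$slope; names(slo) <- toRNA(names(slo))
    p <- int[STOP_RNA] + slo[STOP_RNA] * gc
    p <- pmax(p, 0)
  }
  p <- p / sum(p)
  stats::setNames(as.numeric(p), STOP_DNA)
}

# draw the downstream matrix (contextLen x n) under the configured model
drawDownstream <- function(cfg, n, gcTarget, stops) {
  ctx <- cfg$contextLen
  if (ctx == 0L) return(matrix(character(0), nrow = 0L, ncol = n))
  dm <- cfg$downstreamModel
  if (identical(dm$type, "codon")) {
    probs <- dm$probs
    names(probs) <- toDNA(names(probs))
    nslots <- ceiling(ctx / 3L)
    cod <- sample(names(probs), nslots * n, replace = TRUE, prob = probs)
    bases <- matrix(unlist(strsplit(cod, ""), use.names = FALSE),
                    nrow = 3L * nslots)
    m <- bases[seq_len(ctx), , drop = FALSE]
  } else {
    probs <- dm$probs
    if (is.null(probs)) probs <- baseProbsAt(gcTarget)
    names(probs) <- toDNA(names(probs))
    m <- matrix(sample(names(probs), ctx * n, replace = TRUE, prob = probs),
                nrow = ctx)
  }
  # +4 base from the per-stop distribution, when one is configured
  if (!is.null(cfg$plus4Dist)) {
    p4 <- cfg$plus4Dist
    for (s in STOP_DNA) {
      d <- if (is.list(p4)) p4[[toRNA(s)]] %||% p4[[s]] else p4
      if (is.null(d)) next
      names(d) <- toDNA(names(d))
      sel <- which(stops == s)
      if (length(sel)) {
        m[1L, sel] <- sample(names(d), length(sel), replace = TRUE,
                             prob = d)
      }
    }
  }
  # forced tandem stops at +4..+6
  if (cfg$tandemRate > 0 && ctx >= 3L) {
    forced <- which(stats::runif(n) < cfg$tandemRate)
    if (length(forced)) {
      tand <- sample(STOP_DNA, length(forced), replace = TRUE)
      m[1:3, forced] <- matrix(unlist(strsplit(tand, ""),
                                      use.names = FALSE), nrow = 3L)
    }
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# resolve the per-genome GC targets of a cohort
resolveGcTargets <- function(cfg) {
  g <- cfg$gcTargets
  if (length(g) == cfg$nGenomes) return(g)
  if (length(g) == 1L) return(rep(g, cfg$nGenomes))
  if (length(g) == 2L) {
    return(seq(g[1L], g[2L], length.out = cfg$nGenomes))
  }
  stop("gcTargets must be a scalar, a range, or one value per genome")
}

#' Simulate one genome with a known truth record
#'
#' Generates a single-contig genome: gene bodies drawn codon-wise from a
#' GC-matched sense-codon distribution (internal stops excluded by
#' rejection), per-class stop codons from `stopProbs`, downstream context
#' from `plus4Dist`/`downstreamModel` with `tandemRate` genes overridden at
#' +4..+6, genes on both strands, intergenic spacers of at least
#' `contextLen`, and (on circular contigs) the last gene's context wrapping
#' the origin. Spacer composition is solved so that realized genome GC
#' matches the target. Fully deterministic given `(seed, genomeIndex)`.
#'
#' @param config a [simulationConfig()].
#' @param genomeIndex 1-based genome counter within the cohort.
#' @return list with `dataset` (a [GenomeDataset-class] rebuilt through the
#'   ordinary extraction path, HEG flags set) and `truth` (planted
#'   parameters: per-gene stop codon, +4 base, downstream string, strand,
#'   coordinates and HEG flag; realized GC; per-class planted stop counts;
#'   config echo).
#' @export
simulateGenome <- function(config, genomeIndex = 1L) {
  stopifnot(inherits(config, "simulationConfig"))
  cfg <- config
  set.seed(derivedSeed(cfg$seed, genomeIndex))
  gid <- sprintf("sim%03d", genomeIndex)
  contig_id <- paste0(gid, "_c1")
  n <- cfg$genesPerGenome
  ctx <- cfg$contextLen
  gcT <- resolveGcTargets(cfg)
  gcTarget <- if (genomeIndex <= length(gcT)) {
    gcT[genomeIndex]
  } else if (length(unique(gcT)) == 1L) {
    gcT[1L]   # replicate genomes beyond the cohort share the scalar target
  } else {
    stop("genomeIndex ", genomeIndex, " outside the configured cohort")
  }

  circular <- stats::runif(1) < cfg$circularFraction
  is_heg <- rep(FALSE, n)
  nHeg <- round(cfg$hegFraction * n)
  if (nHeg > 0L) is_heg[sample.int(n, nHeg)] <- TRUE
  strand <- ifelse(stats::runif(n) < cfg$reverseStrandFraction, "-", "+")
  if (circular) strand[n] <- "+"   # the origin-wrapping gene

  # planted stop codons per class
  stops <- character(n)
  for (cls in c("HEG", "LEG")) {
    sel <- if (cls == "HEG") is_heg else !is_heg
    if (any(sel)) {
      p <- evalStopProbs(cfg$stopProbs[[cls]], gcTarget)
      stops[sel] <- sample(STOP_DNA, sum(sel), replace = TRUE, prob = p)
    }
  }

  # gene bodies: ATG + stop-free codons + planted stop
  theta <- solveBodyTheta(gcTarget)
  body <- matrix(drawBodyCodons(n * cfg$geneLengthCodons, theta), ncol = n)
  cds <- paste0("ATG", apply(body, 2L, paste, collapse = ""), stops)

  # downstream context (sense orientation)
  dsm <- drawDownstream(cfg, n, gcTarget, stops)
  downstream <- if (ctx > 0L) apply(dsm, 2L, paste, collapse = "")
                else rep("", n)

  # genomic renderings
  genomic_cds <- ifelse(strand == "+", cds, revComp(cds))
  genomic_ds <- ifelse(strand == "+", downstream, revComp(downstream))

  prePadLen <- 5L + sample.int(16L, n, replace = TRUE) - 1L
  tailPadLen <- if (circular) 0L else 5L + sample.int(16L, 1L) - 1L
  wrapK <- if (circular && ctx > 0L) max(1L, ctx %/% 2L) else 0L

  # assemble piece lengths to locate CDS coordinates, pads drawn last with
  # a composition solved so the whole contig hits the GC target
  pieces <- character(0)
  kind <- character(0)       # "pad" pieces get their content later
  gene_of <- integer(0)
  addPiece <- function(seqs, kinds, genes) {
    pieces <<- c(pieces, seqs); kind <<- c(kind, kinds)
    gene_of <<- c(gene_of, genes)
  }
  if (circular && ctx > 0L) {
    addPiece(substring(downstream[n], wrapK + 1L, ctx), "wrap", n)
  }
  for (i in seq_len(n)) {
    addPiece(strrep("?", prePadLen[i]), "pad", NA_integer_)
    if (strand[i] == "-" && ctx > 0L) addPiece(genomic_ds[i], "ds", i)
    addPiece(genomic_cds[i], "cds", i)
    if (strand[i] == "+" && ctx > 0L) {
      if (circular && i == n) {
        addPiece(substring(downstream[n], 1L, wrapK), "ds", i)
      } else {
        addPiece(genomic_ds[i], "ds", i)
      }
    }
  }
  if (!circular) addPiece(strrep("?", tailPadLen), "pad", NA_integer_)

  lens <- nchar(pieces)
  total <- sum(lens)
  nonpad <- pieces[kind != "pad"]
  gcNonPad <- sum(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(nonpad), c("C", "G")))
  padLen <- sum(lens[kind == "pad"])
  padGC <- (gcTarget * total - gcNonPad) / padLen
  if (padGC < 0 || padGC > 1) {
    stop("unreachable GC target ", gcTarget,
         " given gene content; adjust the configuration")
  }
  padBases <- sample(c("A", "C", "G", "T"), padLen, replace = TRUE,
                     prob = baseProbsAt(padGC))
  off <- 0L
  for (j in which(kind == "pad")) {
    pieces[j] <- paste(padBases[off + seq_len(lens[j])], collapse = "")
    off <- off + lens[j]
  }

  starts <- cumsum(c(1L, lens[-length(lens)]))
  cds_idx <- which(kind == "cds")
  gstart <- starts[cds_idx][order(gene_of[cds_idx])]
  gend <- gstart + nchar(cds) - 1L
  contig <- paste(pieces, collapse = "")

  contigs <- Biostrings::DNAStringSet(stats::setNames(contig, contig_id))
  S4Vectors::mcols(contigs)$circular <- circular
  gene_ids <- sprintf("%s_g%04d", gid, seq_len(n))
  cdsTable <- data.frame(gene_id = gene_ids, contig_id = contig_id,
                         start = gstart, end = gend, strand = strand,
                         stringsAsFactors = FALSE)
  dataset <- buildGenomeDataset(gid, contigs, cdsTable,
                                contextLen = ctx,
                                hegIds = gene_ids[is_heg])

  genesTruth <- data.frame(
    gene_id = gene_ids, start = gstart, end = gend, strand = strand,
    stop_codon = stops,
    plus4 = if (ctx > 0L) substr(downstream, 1L, 1L) else NA_character_,
    downstream = downstream, is_heg = is_heg, cds = cds,
    stringsAsFactors = FALSE)
  plantedCounts <- lapply(c(ALL = "ALL", HEG = "HEG", LEG = "LEG"),
    function(cls) {
      sel <- switch(cls, ALL = rep(TRUE, n), HEG = is_heg, LEG = !is_heg)
      stats::setNames(as.integer(table(factor(stops[sel],
                                              levels = STOP_DNA))),
                      STOP_RNA)
    })
  truth <- list(genome_id = gid, gc_target = gcTarget,
                gc_realized = genomeGC(contigs), circular = circular,
                stop_counts = plantedCounts, genes = genesTruth,
                config = unclass(cfg))
  list(dataset = dataset, truth = truth)
}

#' Simulate a GC-gradient cohort
#'
#' Genome `i` of `nGenomes` receives a GC target evenly spaced across the
#' `gcTargets` range; the stop-codon model is evaluated at each genome's
#' GC, so intercept/slope configurations plant GC-linked stop-usage
#' gradients (rising UGA and falling UAA with GC, while UAG stays low and
#' flat, in the default gradient below).
#'
#' @param config a [simulationConfig()]; `gcTargets` should be a range,
#'   e.g. `c(0.30, 0.70)`.
#' @return list of [simulateGenome()] results, one per genome.
#' @export
simulateGcGradientCohort <- function(config) {
  stopifnot(inherits(config, "simulationConfig"))
  lapply(seq_len(config$nGenomes),
         function(i) simulateGenome(config, i))
}

#' Default GC-linked stop-codon model
#'
#' The gradient used by cohort simulations: `p(UGA) = 0.1 + 0.6 gc`,
#' `p(UAA) = 0.8 - 0.6 gc`, `p(UAG) = 0.1` (GC-independent), renormalized.
#'
#' @return a `stopProbs` list accepted by [simulationConfig()] (same model
#'   for HEG and LEG).
#' @export
gcGradientStopProbs <- function() {
  m <- list(intercept = c(UAA = 0.8, UAG = 0.1, UGA = 0.1),
            slope = c(UAA = -0.6, UAG = 0, UGA = 0.6))
  list(HEG = m, LEG = m)
}

#' Write a simulated genome to disk
#'
#' Emits the files a real-genome run would consume: `genome.fasta` (header
#' carries a `circular=true|false` token), `genes.gff3` (CDS features with
#' `ID=` attributes), `heg.txt` (one HEG id per line) and `truth.json`.
#'
#' @param sim result of [simulateGenome()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeSimulatedGenome <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ds <- sim$dataset
  ctg <- contigs(ds)
  circ <- S4Vectors::mcols(ctg)$circular
  out <- ctg
  names(out) <- paste0(names(ctg), " circular=",
                       ifelse(circ, "true", "false"))
  Biostrings::writeXStringSet(out, file.path(dir, "genome.fasta"),
                              width = 80L)
  gr <- geneRecords(ds)
  gff <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::IRanges(BiocGenerics::start(gr),
                              BiocGenerics::end(gr)),
    strand = BiocGenerics::strand(gr))
  S4Vectors::mcols(gff)$source <- "stopContext"
  S4Vectors::mcols(gff)$type <- "CDS"
  S4Vectors::mcols(gff)$phase <- 0L
  S4Vectors::mcols(gff)$ID <- S4Vectors::mcols(gr)$gene_id
  rtracklayer::export(gff, file.path(dir, "genes.gff3"), format = "gff3")
  heg <- S4Vectors::mcols(gr)$gene_id[S4Vectors::mcols(gr)$is_heg]
  writeLines(c("# predicted highly expressed genes", heg),
             file.path(dir, "heg.txt"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a (simulated or real) genome directory into a GenomeDataset
#'
#' Expects `genome.fasta`, `genes.gff3` and optionally `heg.txt` in `dir`,
#' the layout written by [writeSimulatedGenome()].
#'
#' @param dir directory path.
#' @param genomeId genome label; default the directory name.
#' @param contextLen downstream context length to extract.
#' @return a [GenomeDataset-class].
#' @export
readGenomeDir <- function(dir, genomeId = basename(dir), contextLen = 30L) {
  ctg <- readContigs(file.path(dir, "genome.fasta"))
  ann <- readGffCds(file.path(dir, "genes.gff3"), ctg)
  ds <- buildGenomeDataset(genomeId, ctg, ann$cds, contextLen = contextLen)
  hegPath <- file.path(dir, "heg.txt")
  if (file.exists(hegPath)) ds <- loadHegList(hegPath, ds)
  ds
}
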