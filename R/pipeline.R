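# Pipeline stages tying the modules together and writing TSV/JSON reports.
# All analysis stages are deterministic: identical inputs + config give
# byte-identical output tables. The thin command-line front-end in
# inst/scripts/stopcontext.R dispatches to these functions.

#' Pipeline run configuration
#'
#' Collects and validates the knobs of the pipeline stages; the validated
#' config is echoed verbatim (JSON) into the output directory by every
#' stage.
#'
#' @param genomeDirs character vector of genome directories (layout of
#'   [readGenomeDir()]).
#' @param outDir output directory for tables and logs.
#' @param contextLen downstream context length (nt) to extract.
#' @param gcBins the LOW/MID and MID/HIGH GC bin edges, as fractions.
#' @param alpha significance level of the pairwise +4 grouping tests.
#' @param decimals reporting decimals for percentages.
#' @param welch,holm,perGene statistical variants: Welch instead of pooled
#'   Student, Holm correction of the six pairwise p-values, and per-gene
#'   (instead of per-genome) t-test observations.
#' @param caiMode classify HEG by CAI quantile instead of requiring
#'   `heg.txt` files.
#' @param caiQuantile CAI quantile for `caiMode`.
#' @param uagThreshold HEG UAG fraction above which a genome is reported by
#'   the screen.
#' @param preferenceThreshold call threshold of the extended downstream
#'   preference scan.
#' @param seed seed for stages that simulate.
#' @param simulation a [simulationConfig()] used by [runSimulate()].
#' @return validated config list (class `runConfig`).
#' @export
runConfig <- function(genomeDirs = character(0), outDir = "stopcontext-out",
                      contextLen = 30L, gcBins = c(0.40, 0.60),
                      alpha = 0.01, decimals = 1, welch = FALSE,
                      holm = FALSE, perGene = FALSE, caiMode = FALSE,
                      caiQuantile = 0.95, uagThreshold = 0.15,
                      preferenceThreshold = 0.15, seed = 1L,
                      simulation = NULL) {
  stopifnot(length(gcBins) == 2L, gcBins[1] < gcBins[2],
            gcBins[1] > 0, gcBins[2] < 1,
            alpha > 0, alpha < 1, contextLen >= 0L,
            uagThreshold >= 0, uagThreshold <= 1)
  if (is.null(simulation)) simulation <- simulationConfig(seed = seed)
  structure(list(genomeDirs = genomeDirs, outDir = outDir,
                 contextLen = as.integer(contextLen), gcBins = gcBins,
                 alpha = alpha, decimals = decimals, welch = welch,
                 holm = holm, perGene = perGene, caiMode = caiMode,
                 caiQuantile = caiQuantile, uagThreshold = uagThreshold,
                 preferenceThreshold = preferenceThreshold,
                 seed = as.integer(seed), simulation = simulation),
            class = "runConfig")
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

echoConfig <- function(config) {
  if (!dir.exists(config$outDir)) dir.create(config$outDir, recursive = TRUE)
  jsonlite::write_json(unclass(config),
                       file.path(config$outDir, "run-config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

loadDatasets <- function(config) {
  ds <- lapply(config$genomeDirs, readGenomeDir,
               contextLen = config$contextLen)
  if (config$caiMode) {
    ds <- lapply(ds, function(d) {
      classifyHegByCai(d, quantile = config$caiQuantile)$dataset
    })
  }
  ds
}

#' Simulate a cohort into the output directory
#'
#' Runs the synthetic generator for every genome of
#' `config$simulation` and writes each genome (FASTA, GFF3, HEG list,
#' truth JSON) under `outDir/genomes/`.
#'
#' @param config a [runConfig()].
#' @return character vector of genome directories (also stored in the
#'   returned config echo on disk), invisibly.
#' @export
runSimulate <- function(config) {
  echoConfig(config)
  scfg <- config$simulation
  dirs <- vapply(seq_len(scfg$nGenomes), function(i) {
    sim <- simulateGenome(scfg, i)
    writeSimulatedGenome(sim,
                         file.path(config$outDir, "genomes",
                                   sim$truth$genome_id))
  }, character(1))
  invisible(dirs)
}

#' Stop-usage and genome-summary tables
#'
#' Writes `stop_usage.tsv` (one row per genome x gene class, with
#' UAA/UAG/UGA counts, frequencies, percentages at the configured reporting
#' precision, and genome GC), `genome_summary.tsv` (the
#' [genomeSummary()] cohort table plus the GC bin) and `qc.tsv`
#' (per-gene validation outcomes).
#'
#' @param config a [runConfig()].
#' @param datasets optional pre-loaded list of [GenomeDataset-class]
#'   objects (loaded from `config$genomeDirs` when omitted).
#' @return the cohort summary data.frame, invisibly.
#' @export
runAnalyze <- function(config, datasets = NULL) {
  echoConfig(config)
  if (is.null(datasets)) datasets <- loadDatasets(config)
  rows <- list(); qc <- list(); summ <- list()
  for (d in datasets) {
    gc <- genomeGC(d)
    for (cls in c("ALL", "HEG", "LEG")) {
      tab <- suppressWarnings(countStopCodons(d, cls))
      if (tab@total == 0L && cls == "HEG") {
        warning("genome ", genomeId(d),
                ": empty HEG class, HEG frequencies reported as missing")
      }
      pct <- if (tab@total > 0L)
        stopPercentages(tab, config$decimals)
      else stats::setNames(rep(NA_real_, 3L), STOP_RNA)
      cnt <- stopCounts(tab); frq <- stopFreqs(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = genomeId(d), gene_class = cls,
        UAA_count = cnt[["UAA"]], UAG_count = cnt[["UAG"]],
        UGA_count = cnt[["UGA"]], total = tab@total,
        UAA_freq = frq[["UAA"]], UAG_freq = frq[["UAG"]],
        UGA_freq = frq[["UGA"]],
        UAA_pct = pct[["UAA"]], UAG_pct = pct[["UAG"]],
        UGA_pct = pct[["UGA"]], gc = gc, stringsAsFactors = FALSE)
    }
    qc[[length(qc) + 1L]] <- cbind(genome_id = genomeId(d), qcTable(d))
    s <- genomeSummary(d)
    s$gc_bin <- as.character(gcBin(s$gc, config$gcBins[1], config$gcBins[2]))
    summ[[length(summ) + 1L]] <- s
  }
  usage <- do.call(rbind, rows)
  summary <- do.call(rbind, summ)
  writeTsv(usage, file.path(config$outDir, "stop_usage.tsv"))
  writeTsv(summary, file.path(config$outDir, "genome_summary.tsv"))
  writeTsv(do.call(rbind, qc), file.path(config$outDir, "qc.tsv"))
  invisible(summary)
}

#' Downstream-context tables
#'
#' Per (GC bin, gene class) stratum over the cohort, writes
#' `plus4_profile.tsv` (per-genome +4 nucleotide frequencies by stop
#' codon), `plus4_groups.tsv` (compact-letter grouping of the +4
#' frequencies across the genomes of each stratum), `downstream_codons.tsv`
#' (pooled +4..+6 codon table with the 1/64 chance expectation),
#' `tandem.tsv` (tandem-stop fractions), `extended_scan.tsv` (downstream
#' preference scan) and `uag_screen.tsv` (genomes whose HEG UAG fraction
#' exceeds the configured threshold).
#'
#' @inheritParams runAnalyze
#' @return invisibly, the list of written file paths.
#' @export
runContext <- function(config, datasets = NULL) {
  echoConfig(config)
  if (is.null(datasets)) datasets <- loadDatasets(config)
  gcs <- vapply(datasets, genomeGC, numeric(1))
  bins <- gcBin(gcs, config$gcBins[1], config$gcBins[2])
  prof <- list(); grp <- list(); codons <- list(); tandem <- list()
  scan <- list(); summ <- list()
  for (bin in levels(bins)) {
    sel <- which(bins == bin)
    if (!length(sel)) next
    for (cls in c("ALL", "HEG", "LEG")) {
      genes <- do.call(rbind, lapply(datasets[sel], function(d) {
        classGenes(d, cls)
      }))
      if (is.null(genes) || nrow(genes) == 0L) next
      # per-genome +4 rows
      for (i in sel) {
        p <- suppressWarnings(plus4Profile(datasets[[i]], cls))
        if (!is.null(p)) {
          prof[[length(prof) + 1L]] <-
            cbind(genome_id = genomeId(datasets[[i]]), gene_class = cls,
                  gc_bin = bin, position = 4L, p)
        }
      }
      # grouping across the genomes of the stratum, per stop codon
      if (length(sel) >= 2L) {
        for (cod in STOP_RNA) {
          obs <- plus4ByGenome(datasets[sel], cod, cls)
          if (is.null(obs) || nrow(obs) < 2L) next
          g <- suppressWarnings(groupNucleotides(
            obs, alpha = config$alpha, welch = config$welch,
            holm = config$holm))
          if (is.null(g$groups)) next
          grp[[length(grp) + 1L]] <-
            cbind(gc_bin = bin, gene_class = cls, stop_codon = cod,
                  g$groups)
        }
      }
      dc <- downstreamCodonFreq(genes)
      codons[[length(codons) + 1L]] <-
        cbind(gc_bin = bin, gene_class = cls, dc$table,
              n = dc$n, chance = dc$chance,
              unn_fraction = dc$unn_fraction)
      ts <- tandemStopFraction(genes)
      tandem[[length(tandem) + 1L]] <-
        cbind(gc_bin = bin, gene_class = cls,
              data.frame(fraction = ts$fraction, n = ts$n), ts$by_stop)
      es <- extendedPreferenceScan(genes,
                                   threshold = config$preferenceThreshold)
      if (!is.null(es)) {
        scan[[length(scan) + 1L]] <- cbind(gc_bin = bin, gene_class = cls,
                                           es)
      }
    }
  }
  summaries <- do.call(rbind, lapply(datasets, genomeSummary))
  screen <- uagHegScreen(summaries, config$uagThreshold)
  paths <- c(
    writeTsv(do.call(rbind, prof),
             file.path(config$outDir, "plus4_profile.tsv")),
    writeTsv(do.call(rbind, grp),
             file.path(config$outDir, "plus4_groups.tsv")),
    writeTsv(do.call(rbind, codons),
             file.path(config$outDir, "downstream_codons.tsv")),
    writeTsv(do.call(rbind, tandem), file.path(config$outDir, "tandem.tsv")),
    writeTsv(do.call(rbind, scan),
             file.path(config$outDir, "extended_scan.tsv")),
    writeTsv(screen, file.path(config$outDir, "uag_screen.tsv")))
  invisible(paths)
}

#' Stop-frequency vs GC correlation table
#'
#' Writes `correlation.tsv`: Pearson r and two-sided p of each stop codon's
#' class-level frequency against genome GC, for the HEG and ALL classes.
#'
#' @inheritParams runAnalyze
#' @return the correlation data.frame, invisibly.
#' @export
runCorrelate <- function(config, datasets = NULL) {
  echoConfig(config)
  if (is.null(datasets)) datasets <- loadDatasets(config)
  summaries <- do.call(rbind, lapply(datasets, genomeSummary))
  res <- rbind(gcStopCorrelation(summaries, "HEG", strict = FALSE),
               gcStopCorrelation(summaries, "ALL", strict = FALSE))
  writeTsv(res, file.path(config$outDir, "correlation.tsv"))
  invisible(res)
}

#' Run the full analysis report
#'
#' [runAnalyze()], [runContext()] and [runCorrelate()] over the configured
#' genomes, sharing one load of the data.
#'
#' @inheritParams runAnalyze
#' @return invisibly, the cohort summary data.frame.
#' @export
runReport <- function(config, datasets = NULL) {
  if (is.null(datasets)) datasets <- loadDatasets(config)
  s <- runAnalyze(config, datasets)
  runContext(config, datasets)
  runCorrelate(config, datasets)
  invisible(s)
}
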