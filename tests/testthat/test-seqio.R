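test_that("FASTA contigs are read with id tokenization, case folding and N folding", {
  p <- writeTempFasta(list("c1" = "ACGT"))
  x <- readContigs(p)
  expect_equal(as.character(x), c(c1 = "ACGT"))

  p <- writeTempFasta(list("c1" = c("acg", "t")))
  expect_equal(unname(as.character(readContigs(p))), "ACGT")

  p <- writeTempFasta(list("c1 desc words" = "AC"))
  expect_equal(names(readContigs(p)), "c1")

  # IUPAC codes outside A/C/G/T fold to N
  p <- writeTempFasta(list("c1" = "ACGRYSWN"))
  expect_equal(unname(as.character(readContigs(p))), "ACGNNNNN")

  # circular token in the description
  p <- writeTempFasta(list("c1 circular=true" = "ACGT",
                           "c2 circular=false" = "ACGT",
                           "c3" = "ACGT"))
  x <- readContigs(p)
  expect_equal(S4Vectors::mcols(x)$circular, c(TRUE, FALSE, FALSE))
})

test_that("FASTA format errors are raised", {
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(readContigs(empty), "no records")
  dup <- writeTempFasta(list("c1" = "ACGT", "c1 other" = "GGCC"))
  expect_error(readContigs(dup), "duplicate")
})

test_that("GFF3 CDS rows are parsed with ID/locus_tag precedence and multi-segment rejection", {
  p <- writeTempGff(c(
    gffRow("c1", 4, 12, "+", "ID=g1"),
    gffRow("c1", 2, 4, "+", "ID=x1", type = "gene"),
    gffRow("c1", 20, 28, "-", "ID=g2"),
    gffRow("c1", 40, 45, "+", "ID=g2"),
    gffRow("c1", 50, 58, "+", "locus_tag=lt0042")
  ))
  res <- readGffCds(p)
  expect_equal(res$rejected,
               data.frame(gene_id = "g2", reason = "multi-segment",
                          stringsAsFactors = FALSE))
  expect_equal(res$cds$gene_id, c("g1", "lt0042"))
  expect_equal(res$cds[res$cds$gene_id == "g1", ],
               data.frame(gene_id = "g1", contig_id = "c1", start = 4L,
                          end = 12L, strand = "+",
                          stringsAsFactors = FALSE),
               ignore_attr = TRUE)
})

test_that("GFF3 errors: unknown contig and invalid coordinates", {
  p <- writeTempGff(gffRow("cX", 4, 12, "+", "ID=g1"))
  ctg <- readContigs(writeTempFasta(list("c1" = "ACGTACGTACGTACGT")))
  expect_error(readGffCds(p, ctg), "g1")
  bad <- writeTempGff(gffRow("c1", 12, 4, "+", "ID=g1"))
  expect_error(readGffCds(bad, ctg), "format error")
})

test_that("CDS and downstream context extraction is strand-aware", {
  contig <- "AAATGACCCTAAGTTT"
  ex <- extractCdsContext(contig, 3, 12, "+", contextLen = 4)
  expect_equal(ex$cds, "ATGACCCTAA")
  expect_equal(ex$downstream, "GTTT")

  # minus strand checked against an independent reverse-complement oracle
  ex <- extractCdsContext(contig, 3, 12, "-", contextLen = 4)
  expect_equal(ex$cds, oracleRevComp(substr(contig, 3, 12)))
  expect_equal(ex$downstream, oracleRevComp(substr(contig, 1, 2)))

  # circular wrap: stop TAA ends at position 3 of "TAAAC"
  ex <- extractCdsContext("TAAAC", 1, 3, "+", contextLen = 4,
                          circular = TRUE)
  expect_equal(ex$downstream, "ACTA")
  # linear contig truncates instead
  ex <- extractCdsContext("TAAAC", 1, 3, "+", contextLen = 4)
  expect_equal(ex$downstream, "AC")

  expect_error(extractCdsContext("ACGT", 2, 9, "+"), "out of range")
})

test_that("circular extraction matches a brute-force index oracle", {
  set.seed(11)
  for (i in 1:50) {
    L <- sample(30:60, 1)
    contig <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    start <- sample(seq_len(L - 10L), 1)
    end <- start + 8L
    ctx <- sample(1:15, 1)
    chars <- strsplit(contig, "")[[1]]
    wrapIdx <- function(i) ((i - 1) %% L) + 1
    expPlus <- paste(chars[wrapIdx((end + 1):(end + ctx))], collapse = "")
    expMinus <- oracleRevComp(
      paste(chars[wrapIdx((start - ctx):(start - 1))], collapse = ""))
    expect_equal(extractCdsContext(contig, start, end, "+", ctx,
                                   circular = TRUE)$downstream, expPlus)
    expect_equal(extractCdsContext(contig, start, end, "-", ctx,
                                   circular = TRUE)$downstream, expMinus)
  }
})

test_that("CDS validation is total and reports the stated reasons", {
  expect_equal(validateCds("ATGTAA"),
               data.frame(valid = TRUE, reason = "ok", stop_codon = "TAA",
                          stringsAsFactors = FALSE))
  expect_equal(validateCds("ATGTGAAAATAA")$reason, "internal_stop")
  v <- validateCds("ATGAAA")
  expect_false(v$valid)
  expect_equal(v$reason, "no_stop")
  expect_true(is.na(v$stop_codon))
  expect_equal(validateCds("ATGTA")$reason, "length")
  expect_equal(validateCds("ATGAAATANA")$reason, "length")
  expect_equal(validateCds("ATGAAATNA")$reason, "ambiguous")

  # totality: every input yields exactly one reason; reason counts sum to n
  set.seed(5)
  cds <- vapply(1:200, function(i) {
    paste(sample(c("A", "C", "G", "T", "N"), sample(3:30, 1), TRUE,
                 prob = c(rep(0.24, 4), 0.04)), collapse = "")
  }, character(1))
  v <- validateCds(cds)
  expect_equal(nrow(v), 200L)
  expect_equal(sum(table(v$reason)), 200L)
  expect_true(all(v$reason %in%
                    c("ok", "length", "internal_stop", "no_stop",
                      "ambiguous")))
  expect_equal(v$valid, v$reason == "ok")
})

test_that("generator placements round-trip through extraction on both strands, linear and circular", {
  for (seed in 1:2) {
    cfg <- simulationConfig(seed = seed, genesPerGenome = 250,
                            hegFraction = 0.2, circularFraction = 0.5,
                            reverseStrandFraction = 0.5,
                            geneLengthCodons = 20)
    sim <- simulateGenome(cfg, seed)
    df <- geneTable(sim$dataset)
    expect_equal(df$cds, sim$truth$genes$cds)
    expect_equal(df$downstream, sim$truth$genes$downstream)
    expect_true(any(df$strand == "-") && any(df$strand == "+"))
  }
})

test_that("gene records are invariant under the strand-symmetry transformation", {
  cfg <- simulationConfig(seed = 3, genesPerGenome = 120,
                          hegFraction = 0.3, circularFraction = 0.5,
                          reverseStrandFraction = 0.5,
                          geneLengthCodons = 15)
  ds <- simulateGenome(cfg, 1)$dataset
  flipped <- flipDataset(ds)
  a <- geneTable(ds)
  b <- geneTable(flipped)[match(geneTable(ds)$gene_id,
                                geneTable(flipped)$gene_id), ]
  expect_equal(a$cds, b$cds)
  expect_equal(a$downstream, b$downstream)
  expect_equal(a$stop_codon, b$stop_codon)
})

test_that("overlap of the downstream window with another CDS is flagged", {
  contig <- Biostrings::DNAStringSet(c(c1 = paste(
    rep("ACGT", 30), collapse = "")))
  S4Vectors::mcols(contig)$circular <- FALSE
  tab <- data.frame(gene_id = c("g1", "g2"), contig_id = "c1",
                    start = c(1L, 15L), end = c(12L, 26L),
                    strand = "+", stringsAsFactors = FALSE)
  ds <- buildGenomeDataset("t", contig, tab, contextLen = 10L)
  qc <- qcTable(ds)
  expect_true(qc$overlap_flag[qc$gene_id == "g1"])   # window hits g2
  expect_false(qc$overlap_flag[qc$gene_id == "g2"])
})
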