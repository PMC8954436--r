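test_that("GC bins partition at 40% and 60% with boundaries in MID", {
  expect_equal(as.character(gcBin(c(0.3354, 0.5193, 0.6714))),
               c("LOW", "MID", "HIGH"))
  expect_equal(as.character(gcBin(c(0.40, 0.60))), c("MID", "MID"))
  expect_equal(as.character(gcBin(c(0.399999, 0.600001))),
               c("LOW", "HIGH"))
})

test_that("the downstream chance expectation is 1/64, printed as 2%", {
  expect_equal(chanceExpectation(), 1 / 64)
  expect_equal(roundHalfUp(100 * chanceExpectation(), 0), 2)
})

test_that("+4 profiles report per-stop base frequencies in RNA labels", {
  g <- makeGeneTable(c("TAA", "TAA"), c("TGGG", "AGGG"))
  p <- suppressWarnings(plus4Profile(g))  # UAG/UGA strata empty here
  expect_equal(p$stop_codon, "UAA")
  expect_equal(p[, c("A", "C", "G", "U")],
               data.frame(A = 0.5, C = 0, G = 0, U = 0.5),
               ignore_attr = TRUE)
  expect_equal(p$n, 2L)

  # degenerate n = 1: unit mass on the observed base
  p1 <- suppressWarnings(plus4Profile(makeGeneTable("TGA", "C")))
  expect_equal(p1$C, 1)
  expect_equal(rowSums(p1[, c("A", "C", "G", "U")]), 1)

  # empty stratum omitted with warning
  expect_warning(plus4Profile(makeGeneTable("TAA", "T")), "UAG")
})

test_that("a planted +4 distribution is recovered within 3 binomial SE", {
  p4 <- c(U = 0.7, A = 0.1, C = 0.1, G = 0.1)
  n <- 2000L
  cfg <- simulationConfig(seed = 14, genesPerGenome = n, hegFraction = 1,
                          plus4Dist = p4, geneLengthCodons = 8)
  ds <- simulateGenome(cfg, 1)$dataset
  prof <- plus4Profile(geneTable(ds, validOnly = TRUE), by = NULL)
  for (b in names(p4)) {
    se <- sqrt(p4[[b]] * (1 - p4[[b]]) / n)
    expect_lt(abs(prof[[b]] - p4[[b]]), 3 * se)
  }
})

test_that("downstream codon table counts the +4..+6 triplet against 1/64", {
  g <- makeGeneTable(rep("TAA", 4), rep("TTTG", 4))
  dc <- downstreamCodonFreq(g)
  tab <- stats::setNames(dc$table$freq, dc$table$codon)
  expect_equal(unname(tab["TTT"]), 1)
  expect_equal(dc$unn_fraction, 1)
  expect_equal(dc$above_chance, "UUU")
  expect_equal(dc$chance, 1 / 64)

  # uniform iid downstream: every codon within 5 SE of 1/64 and the UNN
  # aggregate within 3 SE of 16/64
  n <- 3000L
  cfg <- simulationConfig(
    seed = 15, genesPerGenome = n, hegFraction = 1, plus4Dist = NULL,
    downstreamModel = list(type = "iid",
                           probs = c(A = 0.25, C = 0.25, G = 0.25,
                                     T = 0.25)),
    geneLengthCodons = 8)
  ds <- simulateGenome(cfg, 1)$dataset
  dc <- downstreamCodonFreq(geneTable(ds, validOnly = TRUE))
  expect_equal(dc$n, n)
  se <- sqrt((1 / 64) * (63 / 64) / n)
  expect_true(all(abs(dc$table$freq - 1 / 64) < 5 * se))
  seU <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(dc$unn_fraction - 0.25), 3 * seU)
})

test_that("tandem stop fraction matches construction and planted rates", {
  expect_equal(tandemStopFraction(
    makeGeneTable(rep("TGA", 3), rep("TAAC", 3)))$fraction, 1)

  # sense-codon-only downstream model: tandem stops impossible
  sense <- setdiff(allCodonsForTest(), c("TAA", "TAG", "TGA"))
  cfg <- simulationConfig(
    seed = 16, genesPerGenome = 500, hegFraction = 1, plus4Dist = NULL,
    downstreamModel = list(
      type = "codon",
      probs = stats::setNames(rep(1 / 61, 61), sense)),
    tandemRate = 0, geneLengthCodons = 8)
  ds <- simulateGenome(cfg, 1)$dataset
  expect_equal(tandemStopFraction(geneTable(ds, validOnly = TRUE))$fraction,
               0)

  # planted tandem rate recovered within 3 binomial SE; non-tandem
  # background contributes nothing because the model is sense-only
  rate <- 0.10; n <- 3000L
  cfg <- simulationConfig(
    seed = 17, genesPerGenome = n, hegFraction = 1, plus4Dist = NULL,
    downstreamModel = list(
      type = "codon",
      probs = stats::setNames(rep(1 / 61, 61), sense)),
    tandemRate = rate, geneLengthCodons = 8)
  ds <- simulateGenome(cfg, 1)$dataset
  ts <- tandemStopFraction(geneTable(ds, validOnly = TRUE))
  expect_lt(abs(ts$fraction - rate), 3 * sqrt(rate * (1 - rate) / n))
  # the pair table carries the primary-by-tandem breakdown
  expect_equal(sum(ts$pairs$count), sum(round(ts$by_stop$tandem_fraction *
                                                ts$by_stop$n)))
})

test_that("+4 profile is the first-base marginal of the downstream codon table", {
  cfg <- simulationConfig(seed = 18, genesPerGenome = 400, hegFraction = 1,
                          geneLengthCodons = 8)
  df <- geneTable(simulateGenome(cfg, 1)$dataset, validOnly = TRUE)
  tri <- substr(df$downstream, 1, 3)
  df <- df[nchar(df$downstream) >= 3 & !grepl("N", tri, fixed = TRUE), ]
  dc <- downstreamCodonFreq(df)
  marg <- vapply(c(A = "A", C = "C", G = "G", U = "T"), function(b) {
    sum(dc$table$freq[substr(dc$table$codon, 1, 1) == b])
  }, numeric(1))
  prof <- plus4Profile(df, by = NULL)
  expect_equal(as.numeric(prof[, c("A", "C", "G", "U")]), unname(marg),
               tolerance = 1e-12)
  # and the tandem fraction is the stop-codon mass of the same table
  expect_equal(tandemStopFraction(df)$fraction,
               sum(dc$table$freq[dc$table$codon %in%
                                   c("TAA", "TAG", "TGA")]),
               tolerance = 1e-12)
})

test_that("extended preference scan flags planted motifs and stays quiet on uniform input", {
  # uniform downstream: small statistics, no position called preferred
  cfg <- simulationConfig(
    seed = 19, genesPerGenome = 2000, hegFraction = 1, plus4Dist = NULL,
    downstreamModel = list(type = "iid",
                           probs = c(A = 0.25, C = 0.25, G = 0.25,
                                     T = 0.25)),
    geneLengthCodons = 8)
  df <- geneTable(simulateGenome(cfg, 1)$dataset, validOnly = TRUE)
  es <- extendedPreferenceScan(df)
  expect_equal(nrow(es), 30L)
  expect_true(all(es$preference < 0.05))
  expect_false(any(es$preferred))
  expect_true(all(abs(rowSums(es[, c("A", "C", "G", "U")]) - 1) < 1e-12))

  # planted TTT at slot 1 with probability 1
  g <- makeGeneTable(rep("TAA", 50),
                     paste0("TTT", strrep("A", 27)))
  es <- extendedPreferenceScan(g)
  s1 <- es[es$slot == 1, ]
  expect_equal(s1$preference, rep(0.75, 3))
  expect_equal(s1$max_base, rep("U", 3))
  expect_true(all(s1$preferred))
  expect_equal(s1$position, 4:6)

  # nCodons = 1 reduces to the per-position +4..+6 profile
  es1 <- extendedPreferenceScan(g, nCodons = 1)
  expect_equal(es1, es[es$slot == 1, ], ignore_attr = TRUE)

  # truncated context contributes to leading positions only
  g2 <- makeGeneTable(rep("TAA", 10), strrep("G", 6))
  es2 <- extendedPreferenceScan(g2)
  expect_equal(nrow(es2), 6L)
  expect_equal(unique(es2$n), 10L)
})

test_that("the UAG screen returns genomes strictly above threshold, sorted", {
  summaries <- data.frame(
    genome_id = c("gA", "gB", "gC"),
    uag_fraction_heg = c(4 / 25, 2 / 255, 0.30),
    stringsAsFactors = FALSE)
  hit <- uagHegScreen(summaries, 0.15)
  expect_equal(hit$genome_id, c("gC", "gA"))

  # E. coli-like HEG counts are excluded (0.8% UAG)
  ec <- stopUsageTable(c(UAA = 223, UAG = 2, UGA = 30))
  expect_lt(stopFreqs(ec)[["UAG"]], 0.15)

  # planted cohort: exactly the 7 UAG-rich genomes come back
  pHigh <- c(UAA = 0.5, UAG = 0.4, UGA = 0.1)
  pLow <- c(UAA = 0.68, UAG = 0.02, UGA = 0.30)
  rows <- lapply(1:50, function(i) {
    p <- if (i <= 7) pHigh else pLow
    cfg <- simulationConfig(seed = 1000 + i, genesPerGenome = 60,
                            hegFraction = 1,
                            stopProbs = list(HEG = p, LEG = p),
                            geneLengthCodons = 6)
    genomeSummary(simulateGenome(cfg, i)$dataset)
  })
  summaries <- do.call(rbind, rows)
  hit <- uagHegScreen(summaries, 0.15)
  expect_setequal(hit$genome_id, summaries$genome_id[1:7])
})
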