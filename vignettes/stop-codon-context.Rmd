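---
title: "Stop codon usage and 3' termination context: models and methods"
author: "stopContext"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stop codon usage and 3' termination context: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopContext)
```

## The scientific question

Translation in bacteria terminates at one of three codons — UAA (ochre),
UAG (amber), UGA (opal) — and the three are far from interchangeable. In
genomes under strong translational selection the termination codon of
highly expressed genes (HEG: ribosomal proteins and similar
prediction-based sets) is overwhelmingly UAA, UAG is rare, and the balance
between UAA and UGA tracks genome GC content. Termination efficiency also
depends on the sequence 3′ of the stop — most strongly the first
downstream base (the *+4 nucleotide*; the stop itself occupies positions
+1..+3) and, more weakly, the next several codons.

`stopContext` provides the full measurement pipeline for these questions:
strand-aware CDS + downstream-context extraction from FASTA/GFF3,
stop-usage tables per gene class (ALL / HEG / LEG), GC stratification,
+4 and downstream-codon profiling against the 1/64 chance expectation,
tandem-stop detection, Pearson correlation of stop frequencies with GC
across a genome cohort, a Student's-t compact-letter grouping of +4
frequencies, an optional CAI-based HEG classifier, and a synthetic-genome
generator with an exact truth record.

## Coordinate and alphabet conventions

* **Positions**: the stop codon occupies +1..+3; the first downstream base
  is +4; "+456" denotes the first full downstream codon. The main
  implementation hazard in this domain is an off-by-three in this
  convention, so it is fixed package-wide: `downstream[1]` *is* the +4
  base.
* **Coordinates**: GFF3 1-based inclusive everywhere; no half-open
  conversion is exposed. CDS are single-segment (prokaryotic scope);
  multi-segment CDS are rejected with a logged reason, and a non-zero
  phase column is reported and ignored.
* **Alphabet**: DNA internally; RNA labels (UAA/UAG/UGA, and U in base
  frequency tables) at every reporting boundary. IUPAC letters outside
  A/C/G/T fold to `N` at read time, and an `N` inside a terminal triplet
  makes the gene `ambiguous` rather than guessing a stop — counting
  analyses never impute.
* **Circularity**: FASTA has no standard slot for it, so the generator
  writes a `circular=true|false` token into the header description and
  `readContigs()` parses it back. On circular contigs the downstream
  window wraps the origin; on linear contigs it truncates, and truncated
  genes contribute to whatever positions they cover (no imputation, no
  wholesale exclusion).

## Gene validation

A CDS is *valid* when it is ≥ 6 nt, a whole number of codons, free of
in-frame internal stops, and ends in a stop codon of the configured
genetic code (NCBI table 11 by default — the bacterial/archaeal/plastid
code, whose stop set matches the standard code). Validation is total:
every gene gets exactly one `(valid, reason)` outcome with
`reason ∈ {ok, length, ambiguous, no_stop, internal_stop}`, reported in a
QC table. Genes without a valid stop are excluded from all stop and
context statistics but remain visible in QC. Genes whose downstream
window overlaps another annotated CDS are profiled (real bacterial
genomes are gene-dense and the published analyses do not filter them) but
carry an `overlap_flag` for optional filtering.

## Stop-usage statistics

`countStopCodons()` tallies terminal codons per gene class. LEG is
defined as the complement of the HEG set among valid genes — the source
analyses contrast HEG with "low expressed genes" without defining the
membership, and the complement is the choice that makes
`ALL = HEG + LEG` an exact per-codon identity (enforced by test).
Frequencies keep full precision internally; `stopPercentages()` rounds
half-up only at the reporting layer, which is what reproduces printed
values such as 7.4% / 64% / 29% from the E. coli counts 321 / 2765 /
1249. A cautionary detail from the E. coli HEG table: the widely quoted
class size of 253 genes is inconsistent with its own per-codon counts
(223 + 2 + 30 = 255); the percentages (87 / 12 / 0.8) follow the count
sum, which is the denominator this package always uses.

Genome GC is whole-genome (all contigs, `N` excluded from numerator and
denominator), matching how organism-level GC values are quoted; a
CDS-only GC per class (`cdsGC()`) is available for sensitivity checks.
GC bins are `LOW < 40%`, `MID = [40%, 60%]`, `HIGH > 60%` — the closed
MID interval makes the bins a partition, with boundary genomes in MID.

## Downstream context statistics

* `plus4Profile()`: frequency of A/C/G/U at +4, stratified by stop codon.
  An `N` at +4 drops that gene from the profile; genes with an `N`
  elsewhere in the +4..+6 triplet still contribute their +4 base.
* `downstreamCodonFreq()`: the +4..+6 triplet against the chance
  expectation `1/64` (1.5625%, conventionally printed as 2%), with the
  at-or-above-chance codon list and the UNN aggregate. Only genes with
  ≥ 3 unambiguous downstream bases contribute; on that subset the +4
  profile is exactly the first-base marginal of this table (tested).
* `tandemStopFraction()`: the fraction of genes whose +4..+6 triplet is
  itself a stop, with per-primary-stop breakdown and the full
  primary×tandem pair table (which is where a UAG immediately followed by
  UAA or UAG — the pattern of the two known UAG-terminated E. coli HEG —
  shows up).
* `extendedPreferenceScan()`: per-position base frequencies over the
  first 10 downstream codon slots. "Preference" has no established
  definition, so the package states one: frequency of the most frequent
  base minus the uniform 0.25, with a position flagged *preferred* above
  a configurable threshold (default 0.15). Under uniform downstream
  composition the statistic has positive bias ≈ `1.03·SE(f)` (expected
  maximum of four near-normal deviates), far below the threshold at any
  realistic *n*.
* `uagHegScreen()`: genomes whose HEG UAG fraction strictly exceeds 15%
  (configurable), sorted descending.

## Statistical layer

`pearsonCorr()` is the standard product-moment correlation with the
two-sided p from the t transform on n−2 df; zero variance raises an
undefined-correlation error. `gcStopCorrelation()` applies it per stop
codon across a cohort, defaulting to HEG frequencies (the class the
figure-level analyses use); `strict = FALSE` converts degenerate strata
into `NA` rows with a warning so a cohort report survives a stop codon
that never varies.

`studentT()` is the pooled-variance two-sample Student's t (Welch behind
a flag), with explicit degenerate conventions: both samples constant and
equal → `p = 1`; zero pooled variance with unequal means → `p = 0`.

`groupNucleotides()` runs all six pairwise tests on per-genome +4
frequencies within one stratum at `alpha = 0.01` (bare threshold, as the
source analysis states; Holm correction behind a flag) and assembles a
compact letter display. The observation unit is the genome, not the gene:
figure-level groupings aggregate genomes within GC bins, and per-genome
frequencies are the replicate unit (a per-gene mode is available via the
gene table). Letters are the **maximal cliques of the non-significance
graph** (exhaustive enumeration over the four nucleotides), ordered by
the highest member mean, ties alphabetical. A greedy
join-the-first-compatible-letter rule was considered and rejected: with
non-transitive pairwise outcomes it can leave two non-significant
nucleotides sharing no letter, violating the display's defining
invariants. The clique construction provably satisfies both ("share a
letter ⇒ pairwise non-significant" and "share none ⇒ pairwise
significant") and coincides with the greedy result whenever
non-significance is transitive; in non-transitive cases a nucleotide
simply carries several letters, as in standard compact-letter-display
practice.

**A calibration caveat worth knowing about**: the four +4 frequencies of
one genome sum to 1, so across genomes the per-nucleotide samples are
negatively correlated (for a multinomial, `cor = −1/3` at p = 0.25). The
two-sample t assumes independent samples, and on compositional null data
the bare pairwise rule is therefore anti-conservative (empirically ~11%
of null strata acquire more than one letter at alpha = 0.01, versus the
6·alpha = 6% Bonferroni envelope that holds when each nucleotide's
frequencies are drawn independently). The package's calibration test
draws the null accordingly (independent Binomial(200, 0.25)/200
frequencies per nucleotide, 2000 strata, 30 genomes each); users applying
the grouping to real compositional data should treat borderline pairwise
p-values near alpha with caution or enable the Holm flag.

## CAI plumbing

HEG labels normally come from an external id list and always override
everything else — the source analyses consumed database predictions, they
did not recompute them, and neither does this package. For data with no
list, `classifyHegByCai()` scores genes with a standard codon adaptation
index: relative-adaptiveness weights `w(c) = count(c)/max count in
family(c)` from a reference set (pseudo-count 0.5 for unobserved codons,
so no weight is zero), gene score the geometric mean of `w` over sense
codons, computed in log space, with the terminal stop and the
single-codon families (ATG, TGG) excluded. The classification quantile
(default 0.95) is deliberately configurable: database HEG thresholds are
not published per genome, so any default is a stand-in.

## The synthetic-genome generator

The generator exists so that every downstream statistic has a
parameter-recovery test against an exact truth record, and its defaults
describe the study conditions the analyses address: a bacterium-like
genome under translational selection.

* **Stop usage**: HEG `(UAA, UAG, UGA) = (0.87, 0.01, 0.12)` and LEG
  `(0.60, 0.10, 0.30)` — the E. coli class tables to two decimals.
  Cohort simulations use the GC-linked model
  `p(UGA) = 0.1 + 0.6·gc`, `p(UAA) = 0.8 − 0.6·gc`, `p(UAG) = 0.1`
  (renormalized), i.e. rising UGA, falling UAA and low flat UAG across
  the 30–70% GC span that brackets real bacterial genomes.
* **+4 base**: U-dominant, `(U, A, C, G) = (0.45, 0.25, 0.15, 0.15)`,
  reflecting the near-universal U preference after stops in HEG;
  remaining downstream bases are i.i.d. at the genome base composition.
* **Tandem stops**: `tandemRate = 0` by default — no forcing, because the
  empirical finding is *no* enrichment of second stops; background tandem
  triplets still arise from the downstream model at roughly the 3/64
  chance level. A non-zero rate overrides +4..+6 with a uniformly chosen
  stop for that share of genes.
* **Architecture**: one contig per genome, circular by default (bacterial
  chromosomes are), genes on both strands (50% minus), non-overlapping,
  with intergenic spacers of at least the context length; on circular
  contigs the last gene's context wraps the origin so wrap-around
  extraction is exercised by construction. Gene bodies are 60 internal
  codons by default — compact relative to the ~300-codon bacterial
  average, a pure fixture-size choice that no statistic here depends on,
  since every statistic conditions on the stop and its context. Cohort
  tests use 300 genes per genome × 60 genomes and the recovery tests use
  1,000–5,000 genes; these sizes put Monte-Carlo noise well inside the
  asserted bounds while keeping a full test run in minutes.
* **GC matching**: body codons are drawn i.i.d. per base at a rate θ
  solved (1-d root find) so that the *stop-free* codon distribution hits
  the target GC; spacer composition is then solved in closed form so the
  whole contig matches the target. Realized genome GC lands within 0.02
  of target (typically within 0.005); targets outside the reachable range
  raise an explicit error.
* **Reproducibility**: one root seed; genome *i* uses the derived stream
  `(seed + 1000003·i) mod 2147483629`, so cohorts are reproducible
  independent of generation order, and the same `(seed, index)` is
  byte-identical on disk. The truth JSON records every planted per-gene
  quantity plus a config echo, and re-ingesting the emitted FASTA+GFF3
  through the ordinary extraction path reproduces it exactly — not
  statistically — including minus-strand and origin-wrapping genes.

## What the synthetic data does and does not show

The generator emulates the *distributional* structure the statistics
measure: multinomial stop choice per class, GC-linked stop gradients,
position-specific downstream composition, controllable tandem rate,
strand and circularity effects. It deliberately omits operons,
overlapping genes, realistic length distributions, amino-acid-level
codon correlations and mRNA secondary structure. Passing recovery tests
therefore demonstrates that the *measurement machinery* is correct and
unbiased under known truth — not that real genomes satisfy the generative
assumptions. Conclusions about real cohorts still rest on the real
FASTA/GFF3 inputs the pipeline consumes.

## Numerical choices

* Rounding of reported percentages is half-up (`roundHalfUp()`), applied
  only at the reporting layer.
* Frequency tables renormalize exactly; tests assert `|Σf − 1| < 1e−12`.
* CAI is computed in log space to avoid underflow on long genes.
* Degenerate inputs have defined outcomes rather than incidental ones:
  empty gene classes report missing (not zero) frequencies with a
  warning; single-observation profiles are unit masses; the t-test
  conventions above; quantile ties in the CAI classifier break by gene
  id.

## Known limitations

* Prokaryotic single-segment CDS only; no spliced genes, no GenBank
  flat files, no ORF calling.
* The pairwise grouping test is anti-conservative on compositional data
  (see above).
* The extended-preference statistic is this package's operationalization;
  alternative definitions (e.g. information content) would need their own
  calibration.
* LEG-as-complement means LEG inherits every mis-annotation that is not
  in the HEG list.
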