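---
title: "Mining microsatellite loci and estimating marker-development success rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining microsatellite loci and estimating marker-development success rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmine)
```

## The model

Microsatellite marker development from an enriched, barcoded
sequencing run is a funnel. Each stage discards reads, and the quantity
of practical interest is how many *usable polymorphic markers* a run of
`N` reads can be expected to deliver. `palmine` models the funnel as a
deterministic filter cascade followed by a simple proportional
extrapolation:

1. reads are assigned to species by their MID barcode (exact prefix
   match) and the barcode is trimmed;
2. reads carrying a perfect tetra-nucleotide tandem repeat of at least
   10 complete units are retained;
3. reads whose repeat has at least 25 bp of flank on *each* side, no
   flank homopolymer longer than 5 bases, and mean base quality of at
   least 20 become *candidates*;
4. of the candidates actually taken to the lab (`NTPP` tested primer
   pairs), some number `SIPL` prove polymorphic; the ratio `SIPL/NTPP`
   is assumed to apply uniformly to all candidates, giving the
   *potentially amplifiable loci*:

   `PAL = round_half_down(SIPL/NTPP x candidates)`

   and the *success rate* `PAL / N`.

The extrapolation's key assumption is that the tested primer pairs are
a representative sample of all candidates — there is no confidence
interval attached, and none is published for this design; the package
reproduces the arithmetic, not an uncertainty model. One conceptual
wrinkle is inherited deliberately: the extrapolated PAL count may
exceed the number of loci that were polymorphic among those actually
tested, because it scales a rate, and we do not reinterpret it.

## Interpretation choices where the procedure is under-specified

Several steps of the published procedure leave room for
interpretation. The package fixes each one explicitly:

* **"Tetra-nucleotide" means minimal period exactly 4.** A run of
  `AAAA` or `ACAC` written as tetramers is a homopolymer or
  dinucleotide repeat in disguise; all 13 enrichment probes have
  minimal period 4, so period-1 and period-2 tetramers are excluded
  from mining.
* **Whole units only.** "At least ten repeat motifs" counts complete
  units; trailing bases that continue the period extend the repeat
  region (and therefore shorten the flank) but do not increase the
  unit count. Fractional-unit counting, as some repeat finders do,
  is explicitly not emulated.
* **Uninterrupted means strictly perfect.** Two 9-unit runs split by a
  single base are two sub-threshold runs, never merged.
* **One hit per physical run.** A run read in a different phase
  (`AGATAGAT...` vs `GATAGATA...`) is the same locus; the leftmost
  phase is reported, and motif classes are canonicalized under
  rotation and reverse complement so tallies group correctly.
* **Read quality is summarized as the mean base score.** The published
  rule ("score values below 20 of a maximum of 40") does not name the
  statistic. Mean per-base Phred-like quality over the MID-trimmed
  read is the default; a stricter minimum-over-flanks mode is
  available (`cascade_config(quality_stat = "min")`). The boundary is
  inclusive: a mean of exactly 20 is kept.
* **Flank homopolymers, not repeat homopolymers.** The "more than five
  repetitive nucleotides" screen targets primer regions; a perfect
  minimal-period-4 repeat cannot contain a run longer than 5 anyway.
* **MID matching is exact-prefix with zero mismatches**, and the tag is
  trimmed before any flank accounting, so barcode bases can never pad a
  flank. A mismatch allowance (`max_mismatch`) exists for robustness
  experiments; `N` never matches a tag base. Whether the original run
  tolerated barcode mismatches is unknowable from the publication;
  exactness is the conservative default.
* **PAL rounding is half-down.** Three published values pin the rule:
  28.71 rounds to 29, 154.15 to 154, and 217.5 — an exact tie — to
  217. Only round-half-down is consistent with all three. The
  implementation guards the tie numerically (`ceiling(x - 0.5 - 1e-9)`)
  because quantities such as 15/22 x 319 are exact halves in rational
  arithmetic but not representable in binary doubles.
* **Percentages print half-up** at two decimals by default (three
  where a finer published figure requires it).

## The primer screen

The published pipeline designed primers with Primer3 at default
settings. `palmine`'s screen is deliberately a *documented simplified
stand-in*, not a Primer3 clone: it scans each flank for windows of
18-27 bases whose duplex melting temperature is closest to 60 °C,
subject to a Tm window of 57-63 °C, GC fraction 0.20-0.80, no
single-base run over 4 inside a primer, an optional 3' G/C clamp (off
by default), and at most 3 consecutive complementary bases between the
two 3' ends. Ties on temperature go to the shorter amplicon, then the
leftmost forward primer.

Melting temperatures use SantaLucia (1998) unified nearest-neighbour
thermodynamics with terminal initiation penalties, an entropy salt
correction of `0.368 (N-1) ln[Na+]` at 50 mM monovalent cations, and an
excess-primer concentration term at 50 nM. These constants are pinned
in `primer_config()` because a reproducible screen requires a pinned Tm
model; secondary-structure free energies and mispriming libraries are
out of scope. Consequently the `primer_designed` stage is reported but
is *not* part of the candidate count used for PAL extrapolation, which
follows the flank/homopolymer/quality stages as published.

## The synthetic data generator

No raw reads from the original run are deposited anywhere, so the
package ships a generator that emulates the run's shape: 200-600 bp
reads, MID prefixes, Phred-like qualities capped at 40, and planted
perfect repeats drawn from the 13 enrichment-probe motifs. Defaults
are chosen once to mirror the study conditions: three species of 1,000
reads each, 3% of reads carrying a qualifying repeat (the observed
repeat-bearing rates were 2.1-4.8%), planted unit counts of 5-30, and
1% of reads in each of five decoy classes.

Decoys are *margin-separated* so that each read's expected fate is a
theorem, not a likelihood: failing flanks are 24 bp vs passing flanks
of at least 26; failing homopolymers are runs of exactly 6 vs clean
flanks capped at 5; failing quality means are truncated below 18 vs
passing means above 22. Background sequence is i.i.d. uniform ACGT
rejection-sampled to contain no qualifying repeat and no flank run
over 5, and the flank base adjacent to a planted repeat is resampled
so it cannot continue the repeat's period — otherwise a lucky flank
base would silently extend the planted repeat and falsify the
manifest's coordinates. The interrupting base of an interrupted-repeat
decoy is likewise excluded from the two bases that would let either
half extend across it.

What the generator does *not* emulate: 454 homopolymer miscalls,
flowgram noise, chimeras, read-length and quality profiles of real
instruments, or any correlation between repeat content and quality. A
green end-to-end suite therefore demonstrates that the cascade
implements its stated rules exactly on data whose truth is known — not
that those rules are optimal for real 454 error profiles.

## Population-genetic summaries

Marker characterization uses direct-count observed heterozygosity and
Nei's unbiased expected heterozygosity `2n/(2n-1) (1 - sum p_i^2)`.
Hardy-Weinberg testing is the conditional exact test on genotype
counts given allele counts (Levene's distribution): full enumeration
of genotype tables for loci with up to 3 alleles, and seeded
Monte-Carlo shuffling of gene copies above that, with the
`(1 + hits)/(B + 1)` estimator. The p-value aggregates tables no more
probable than the one observed, with a `1e-10` log-probability
tolerance against floating-point ties. Null-allele frequency
estimation and linkage-disequilibrium testing are out of scope; a
Bonferroni-adjusted alpha utility covers the multiple-testing note in
the report layer. Polymorphism is defined as at least 2 observed
alleles, everywhere and without exception — published marker tables
occasionally flag such loci inconsistently, and this package does not
attempt to mirror that.

## Numerical and degenerate-input behaviour

* Empty FASTA/FASTQ files yield empty read tables; empty read tables
  yield zero-count tallies and empty reports rather than errors.
* A QUAL file must match its FASTA record-for-record (IDs and
  lengths); FASTQ qualities above 40 are clipped to 40 with a warning,
  matching the 454 ceiling.
* Reads without quality values pass the quality filter with a warning
  rather than silently failing the whole run.
* `NTPP = 0` or zero reads make the ratio/success-rate undefined and
  raise errors naming the offending field; tally tables are validated
  against the chain `0 <= SIPL <= NTPP <= candidates <= repeat reads
  <= reads` before any arithmetic.
* All repeat coordinates are 0-based half-open, stated in every export
  header, so `left_flank = start` and `right_flank = length - end`
  hold by construction.

## Problem sizes used in validation

The test suite checks the miner against a brute-force
periodic-extension oracle exhaustively on all two-letter strings up to
length 12 (8,176 strings, at a lowered unit threshold of 2 so hits
exist at such lengths — with the production threshold of 10 no string
under 40 bp can contain a hit) and on 1,000 random 300-bp strings, a
third of them with planted repeats, at unit thresholds 10 and 3.
End-to-end validation runs three simulator configurations by five
seeds at ~3,000 reads each and requires every cascade stage count to
equal the manifest prediction exactly. Heterozygosity formulas are
checked against an independent counting oracle at `1e-12`;
enumeration-based HWE p-values against the closed-form two-allele
conditional distribution at `1e-10`.

## Known limitations

* The repeat miner handles perfect repeats only; compound and
  interrupted repeat models (as in alignment-scored repeat finders)
  are out of scope, and unit lengths other than 4 are supported but
  only smoke-tested.
* The primer screen's Tm model is one defensible parameterization;
  absolute temperatures differ between conventions by 1-2 °C, so
  screens with other tools will not agree read-for-read.
* The PAL extrapolation inherits the design's assumptions: no
  uncertainty quantification, and a tested-pairs sample treated as
  representative.
* SFF flowgram input, paired-end logic, and adapter trimming beyond
  the MID prefix are not implemented.
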