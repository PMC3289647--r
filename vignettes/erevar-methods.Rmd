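---
title: "Methods: estrogen response element variant discovery and stratified association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estrogen response element variant discovery and stratified association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erevar)
```

## The scientific problem

Nuclear estrogen receptors (ERα, ERβ) are transcription factors: as homo-
or heterodimers they bind estrogen response elements (EREs), 13-bp
palindromic inverted repeats with minimal consensus 5'-GGTCAnnnTGACC-3'
(n = any base). Many functional EREs diverge from the consensus, and a
single-nucleotide change can abolish receptor binding. A SNP inside an ER
binding site can therefore change the transcription of nearby
estrogen-responsive genes, a plausible mechanism for sex-biased disorders
such as major depression and bipolar disorder. `erevar` implements the
hypothesis-driven association design built on that idea: restrict the
genome-wide SNP panel to variants with evidence of sitting in ER binding
sites, then test those few hundred SNPs for case-control association
separately by disease and sex, with a correspondingly mild multiple-testing
burden.

## Candidate discovery

Candidates come from two complementary sources.

**ChIP consensus regions.** Three published genome-wide ER binding-region
sets (two ERα, one ERβ, from different ChIP technologies) are intersected
positionally: a base belongs to the consensus when at least one region
from *every* set covers it, after per-set merging of overlapping and
book-ended intervals. Every known SNP falling in the consensus is a
candidate regardless of local sequence, on the grounds that three
independent functional experiments agreeing on a region outweighs motif
prediction. "Agreement" could alternatively be read as whole-region
reciprocal overlap; positional intersection was chosen because it is
strand- and length-agnostic and needs no arbitrary overlap fraction. All
interval algebra is half-open and 0-based at the file boundary (BED
convention) and is delegated to `GenomicRanges` behind the package's
interval functions.

**Disrupting ERE half-sites.** The genome is scanned in its SNP-masked
form — known SNP positions replaced by IUPAC ambiguity codes encoding
their alleles (e.g. `Y` for C/T) — for the two half-site cores GGTCA and
TGACC. Scanning both cores on the forward strand covers both orientations
without double counting, since TGACC is the reverse complement of GGTCA.
A window *matches* when at every pattern position the residue's allele
set contains the consensus base: the binding site exists under at least
one allele. A matched site is *disrupting* when some masked position
carries an allele different from the consensus base there, i.e. the other
allele breaks the site. For 5-bp half-sites every masked position in a
hit is automatically disrupting (each ambiguity code spans at least two
bases), but the distinction matters in the optional 13-bp full-site mode:
a SNP in an `nnn` spacer column matches under every allele and is *not*
counted as disrupting, which is the conservative reading of "binding-site
disrupting". `N` residues are treated as assembly gaps, not variants, and
are excluded from masked-position bookkeeping (configurable).

Disrupting half-site SNPs are kept only when they fall inside the *union*
of the three ChIP sets — in-silico prediction validated by at least one
functional experiment. When a SNP qualifies both ways, the consensus
provenance is recorded as primary.

## LD proxies

Candidates that were not genotyped on the study arrays are replaced by a
genotyped proxy in high linkage disequilibrium. The threshold is
r² ≥ 0.89, inclusive, reconciling the two forms in which the design is
usually quoted (strictly above 0.89 and equal to 0.89). One proxy per
candidate is substituted — the genotyped partner with maximal r², ties
broken by smallest base-pair distance and then lexicographic rsid, with
both orderings of each LD record searched. Candidates with no qualifying
partner are dropped and logged. A proxy may stand in for more than one
source SNP; nothing in the design forbids it and the panel is
deduplicated downstream.

## Genotype quality control

QC is applied independently within each disease × sex analysis stratum,
in the conventional GWAS order:

1. individuals with missing-call fraction > 0.1 are removed;
2. recomputed on the survivors, SNPs are removed for missingness > 0.05;
3. then for minor allele frequency < 0.01 over cases and controls
   together;
4. then for a Hardy–Weinberg exact p-value < 0.001 computed in controls
   only.

The thresholds are the study's; the order is not stated there and follows
toolchain convention. Per-stratum QC is what makes the four final panels
differ in size even though they start from the same candidates. Person
missingness is computed on the candidate panel (not the full array),
since the panel is the analysis universe here.

The Hardy–Weinberg test is the conditional exact test: given the allele
totals, every attainable heterozygote count is enumerated, and the
two-sided p is the sum of probabilities no larger than the observed
configuration's (no mid-p), matching the era's default behaviour. The
enumeration is implemented in log-space and is exact for any sample size
used here.

## Association model

The test is allelic: each SNP contributes a 2 × 2 table of minor/major
allele counts (two alleles per called individual) in cases versus
controls. The minor allele is designated by pooled case + control
frequency within the stratum, ties broken toward the lexicographically
smaller allele. The choice of an allelic rather than genotypic test is
forced by the reported results themselves: the published per-stratum
minor-allele frequencies, odds ratios and confidence bounds are mutually
consistent only under the allelic 2 × 2 reconstruction.

* **p-value** — two-tailed Fisher's exact test under the probability-mass
  convention: conditioning on the margins, sum the hypergeometric
  probabilities of every table no more probable than the observed one.
  Implemented directly on `stats::dhyper` with a 1 + 1e-7 relative guard
  on the probability comparison (the standard protection against
  floating-point ties).
* **Effect size** — minor-allele odds ratio (ad)/(bc) with the Woolf
  (log-normal) 95% interval, `exp(log OR ± 1.959964 · √(1/a+1/b+1/c+1/d))`.
  Zero cells are an error unless the optional Haldane–Anscombe +0.5
  correction is enabled (off by default; the exact p needs no
  correction).
* **Multiplicity** — Bonferroni across the whole study: p × (diseases ×
  sexes × panel size). With unequal post-QC panels the single factor uses
  the largest panel (2 × 2 × 225 = 900 at the original study's scale);
  corrected values above 1 display as ">1" while the numeric value is
  retained.
* **Display** — odds ratios, bounds and corrected p-values are rounded
  half-up to 3 decimals only at display time; full precision is kept
  internally.

## The synthetic-data generator

Real inputs for this design are access-controlled (dbGaP genotypes) or
external downloads (ChIP region sets, HapMap LD), so the generator emits
every input with known ground truth. Its defaults are the study
conditions: cohort sizes 487/490 female and 477/508 male cases/controls
for bipolar disorder, 1200/1076 and 527/682 for major depression; a
planted causal SNP at allelic odds ratio 0.681 in female bipolar cases;
QC thresholds as above. The genome is scaled to 2 chromosomes × 100 kb
with ~60 planted half-sites, ~300 masked SNPs and 40 regions per ChIP
source — large enough for every pipeline stage to have non-trivial input,
small enough to run in seconds.

Design choices worth knowing:

* **Motif-exact genomes.** Chance half-site occurrences in the random
  background are scrubbed (one base mutated, protected positions
  untouched), so the planted coordinates are exactly the scannable truth
  and recovery can be asserted as equality rather than enrichment.
* **Non-disrupting planted sites are unmasked copies.** For a 5-bp
  half-site any masked position necessarily carries a site-breaking
  allele, so the "matched but not disrupting" class is realised by exact
  motif copies with no SNP inside.
* **Three-way overlap by construction.** At each consensus locus one
  rotating source gets exactly the core interval and the other two extend
  it, so the positional intersection equals the recorded core; two-way
  and single-source loci are placed on disjoint slots and cannot create
  spurious triple overlaps.
* **Effect model.** The causal SNP shifts the case allele frequency to
  `p1 = OR·p0 / (1 − p0 + OR·p0)`; genotypes are two independent allele
  draws (Hardy–Weinberg), making the planted OR the estimand of the
  allelic test. Violator SNPs get 90% forced heterozygosity in controls —
  the stratum the QC filter examines. Missingness is applied per person
  and per SNP with planted high-missingness victims for the QC tests.
* **Determinism.** Every generator seeds its own stream from the master
  seed; identical configurations give byte-identical files.

What the generator does *not* emulate: realistic LD structure (r² values
are asserted, not computed from haplotypes), population stratification,
genotyping-batch artefacts, and the X-chromosome dosage question. Passing
tests on synthetic data therefore demonstrate correctness of the
pipeline's logic and calibration of its statistics under the stated
model, not robustness to those real-data complications.

## Verification conditions

The test suite checks each exact computation against an independent
oracle: Fisher p against direct hypergeometric enumeration (exhaustive
for all margins up to 12, sampled up to 60), the Hardy–Weinberg test
against full enumeration (exhaustive to 50 alleles, sampled to 200),
interval operations against per-base boolean vectors on 10-kb toy
chromosomes, and the motif scanner against brute-force enumeration of
every ambiguity resolution on sequences up to 200 bp. Calibration runs
use 500 null SNPs at the female-bipolar stratum size for the type-I error
(expected within 0.05 ± 0.02 at α = 0.05; the exact test's discreteness
makes it mildly conservative, so uniformity of null p-values is tested
one-sidedly against anti-conservative departure) and 200 replicates for
planted-OR recovery (median within ±0.05 of truth). These sizes keep the
whole suite in minutes on one core while leaving the statistical checks
well-powered.

## Known limitations

* The published genome-scale counts (343 consensus regions, 351 and 95
  candidate SNPs, final panels of 225/224/218/217) depend on the external
  ChIP, HapMap and dbGaP data and are deliberately not asserted; the
  properties those numbers obey are tested on generated data instead.
* Position-weight-matrix scoring, tethered (AP-1/SP-1) binding, covariate
  adjustment, genomic control and permutation-based multiplicity are out
  of scope.
* The scanner is written for clarity at the package's working scale
  (megabases), not for whole-genome hg18 throughput.
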