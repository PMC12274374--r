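---
title: "Methods: amplicon-seq resistance genotyping and bioassay modelling in kdrseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplicon-seq resistance genotyping and bioassay modelling in kdrseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdrseq)
```

## The problem

Insecticide resistance in *Aedes aegypti* is monitored two ways: phenotypically,
with CDC bottle bioassays that expose field-caught adults to diagnostic doses of
deltamethrin or malathion and score knockdown at the diagnostic time; and
molecularly, by genotyping canonical resistance loci — the voltage-gated sodium
channel (*vgsc*, "kdr" mutations such as V410L, V1016I/G, F1534C), the
acetylcholinesterase *ace-1*, the GABA-receptor subunit *rdl* (A296S) and the
glutathione-S-transferase *GSTe2* — by pooled, dual-indexed amplicon
sequencing. `kdrseq` implements both arms as a desk-scale, fully testable
pipeline: a synthetic-data generator stands in for wet-lab sequencing so every
downstream stage can be validated against a recorded truth table, and the
statistical layer (genotype/allele-frequency tables, linkage disequilibrium,
offset Poisson mortality regression) runs equally on synthetic or bundled
published-style tables.

## The amplicon panel

The default panel has ten amplicons (mean 453 bp, range 321–709 bp): nine
resistance amplicons across four genes and one mitochondrial COI amplicon for
species confirmation. Amplicons are anchored at the real genomic coordinates of
the fourteen target SNPs, and each coding amplicon carries a transcript model
(CDS segments with strand and frame) chosen so that the codon numbering of the
mapped consequences reproduces the numbering used in surveillance reports
(F1534C at codon 1534, the two codon-1016 alleles at 1016, V410L at 410, and so
on). *vgsc* and *ace-1* are minus-strand transcripts in this frame; *rdl* and
*GSTe2* are plus-strand. Background sequence is random (seed-deterministic) with
the three bases of every target codon forced to the stated reference codon, so
translation of reference and alternative codons yields the documented amino-acid
changes, including the Q1805 stop-gain and the intron/splice classes.

The codon-1016 amplicon carries an intron whose field haplotype is strongly
diverged from the nominal reference; the panel therefore defines an *alternate
reference* for this amplicon (the intron resampled at random), and the read
simulator draws reads from the divergent haplotype. This reproduces, at desk
scale, the practical need to remap that amplicon against an alternate sequence:
with the alternate reference disabled, reads covering the intron fall below the
0.8 identity floor and are dropped, taking the codon-1016 genotypes with them.

### The two codon-1016 alleles

The reference codon is GTA (valine) read on the minus strand, with codon
positions 1/2/3 at descending genomic coordinates. The glycine allele (V1016G)
is an A→C change at the codon-2 genomic position; the isoleucine allele
(V1016I) is a C→T change at the codon-1 position. Since both positions sit in
one codon, a diploid carrying one mutation on each chromosome is a *compound
heterozygote* (V1016G/V1016I), distinguishable from a cis double mutant only by
read-backed phasing — amplicon reads span the whole codon, so each read votes
for a codon haplotype.

## Synthetic data generator

The generator defines the study conditions; its defaults are the conditions the
analysis is validated under, not tuning knobs.

* **Populations.** One `population_spec` per collection site (Bayamon 51,
  Dorado 42, Guánica 7, Ponce 33, San Juan 45 individuals by default) with the
  bundled per-site allele frequencies for the six detected resistance
  mutations and count-table-derived frequencies for the eight minor panel
  mutations. Unlinked loci are drawn per chromosome under Hardy–Weinberg.
* **Linkage.** The four kdr loci are drawn from a haplotype table constructed
  by a single latent-uniform (comonotone) coupling: one uniform per
  chromosome, each locus mutant when the uniform falls below its frequency,
  V1016G occupying the interval directly above V1016I. This reproduces the
  marginals exactly, makes the two 1016 alleles mutually exclusive per
  chromosome, and concentrates the rare wild-type alleles on shared
  haplotypes — which is what gives the strong pairwise r² seen among kdr loci
  even at near-fixation frequencies. Any explicit haplotype table can be
  supplied instead; it is validated against the per-locus marginals (1e-9).
* **Reads.** Coverage is Poisson per sample × amplicon around a per-amplicon
  lognormal multiplier (sdlog `coverage_dispersion`, default 0.6, mean-1
  parameterisation), emulating the wide per-amplicon coverage variation of
  multiplex PCR around the ~190-fold study mean. Each read pair is a
  primer-to-primer fragment: R1 is the first 250 bases, R2 the
  reverse-complement end, with the 8-bp forward/reverse sample tags prepended
  and constant Phred quality (default Q37). Substitution errors hit insert
  bases uniformly (default 0.1%); indels, PCR chimeras and realistic
  instrument error profiles are out of scope. With probability `mistag_rate`
  one of the two tags is swapped for another sample's tag (index hopping). If
  the expected pool yield falls below `min_pool_reads` (default 50,000),
  coverage is scaled up to the floor. A truth table records each pair's
  sample, amplicon and source haplotype.
* **Read geometry caveat.** Real 250-bp paired reads tile 321–709 bp amplicons
  with varying insert sizes; the generator's two-ends-of-the-fragment model is
  a stand-in. Consequences: the interior of the 709-bp COI amplicon is
  uncovered, and positions covered by both mates count twice in the pileup.
  Neither affects the target SNPs, which all sit within a mate length of an
  amplicon end.
* **Bioassays.** Deaths per bottle are Binomial(n, p) with 18–25 mosquitoes
  per bottle, aggregated per site × insecticide × dose cell.

Passing tests on these simulations demonstrate internal consistency of the
pipeline under the stated error model; they do not certify performance on real
instrument data, which adds adapter read-through, quality decay, indels and
chimeric reads.

## Demultiplexing and trimming

A pair is assigned when each of its two 8-bp tags matches exactly one known tag
within `max_mismatch` substitutions and the two resolved tags identify a single
sample. Tag pairs resolving to different samples are removed as mis-tags
(index hops); unmatched or ambiguous tags are removed as unknown. The design
generates barcodes at pairwise Hamming distance ≥ 3, so the default
`max_mismatch = 1` is unambiguous; distance ties are treated as unknown rather
than guessed. Conservation (assigned + mis-tag + unknown = input) is asserted
in the tests.

Trimming applies, in order: removal of leading and trailing bases below Q3, a
5'→3' sliding window (4 bases, mean Q20) that truncates the read before the
first failing window and clips back to the last base at or above the window
threshold, and a 36-base minimum length applied to both mates of a pair.
Records whose sequence and quality lengths disagree are rejected with a log
entry. These are the canonical leading/trailing/sliding-window semantics; the
window rule is validated against a literal step-by-step re-simulation in the
tests.

## Alignment and pileups

Reads are assigned by k-mer-seeded (k = 15) ungapped extension against every
reference and alternate reference in both orientations; the best-scoring
diagonal wins and the read fails below 0.8 identity. Ungapped alignment is a
deliberate choice: the panel targets SNPs, so indel-bearing reads are dropped
(with a reason) rather than modelled, keeping the aligner exact and testable —
its mismatch counts are compared against a brute-force all-offsets oracle in
the tests. Pileups accumulate each aligned base once, indexed by 1-based
genomic coordinates. An amplicon counts as covered at median depth ≥ 5 (the
published QC names no depth threshold; 5 is a conservative floor for a panel
averaging far deeper), and a sample passes QC with ≥ 6 of 10 amplicons
covered. The COI majority consensus is compared to the reference COI sequence;
identity ≥ 0.95 confirms the species (no published cutoff; 0.95 comfortably
separates congeners at COI while tolerating residual consensus error).

## Genotype calling and phasing

Two independent callers run per target SNP per sample, using the ref/alt base
counts at the site (depth = ref + alt, minimum 10):

1. **Binomial likelihood**: alt count k at depth d under Binomial(d, p) with
   p = e, 0.5, 1−e for hom-ref / het / hom-alt (e = 1% by default), flat
   prior, maximum posterior; no-call when the posterior odds of best over
   second-best fall below 10.
2. **Allele-fraction thresholds**: < 0.1 hom-ref, [0.2, 0.8] het, > 0.9
   hom-alt, with explicit no-call gap zones in between.

The consensus is the strict intersection — any disagreement or no-call
propagates — mirroring dual-caller filtering used to maximise confidence in
called SNPs; the deliberate gap zones of caller 2 create a testable
discordance surface at extreme allele-fraction noise. Consequences are
annotated in the transcript frame (reverse-complemented codons for
minus-strand genes), and a nomenclature table maps the panel frame to
field-standard legacy names (e.g. codon 910 in this frame → L944I). Multi-SNP
codons are resolved by read-backed phasing: spanning reads vote for codon
haplotypes, and the best-supported pair consistent with the diploid calls is
translated; a multi-variant codon with no spanning reads is reported
unresolved with its unphased amino acids. Calls are exported as a minimal VCF
(GT:DP:AF), with resolved codon-1016 compound heterozygotes written phased
with a PS tag.

## Population genetics

Allele frequencies are (n_het + 2·n_hom-alt) / (2n) over QC-passed consensus
calls, no-calls excluded per locus, rounded half-up (2 dp in the detailed
table, 1 dp in the per-site table, matching the printed precisions; half-up
because that is how surveillance tables are printed, and `round()`'s
banker's rounding would disagree on exact .005 boundaries). Cross-site
differences use Pearson's chi-squared on the site × allele chromosome-count
table (df = sites − 1), with a small-sample warning when any expected cell
falls below 1. Mortality–frequency association uses midrank Spearman
correlation with an exact permutation p-value below 10 sites (Monte Carlo
above 8 where enumeration is infeasible).

Pairwise LD r² comes from haplotype frequencies: counted directly when phase
is known, otherwise estimated by EM over the nine unphased two-locus genotype
classes, splitting double heterozygotes between cis and trans by their current
expected proportions. EM initialises at linkage equilibrium, iterates to a
1e-8 change tolerance with a 1,000-iteration cap, and is flagged undefined at
monomorphic loci. The screen computes all same-chromosome pairs within a
configurable distance window (default 20 bp – 10 kbp). The published analysis
states that window yet reports r² between kdr loci 44–97 kbp apart; the window
is therefore an argument, and the pipeline emits both the windowed screen and
an explicitly wide-window kdr-block screen. Within the block, the
V1016G–V1016I pair (1 bp apart) falls under the minimum distance and is
excluded — appropriately, since the two alleles are mutually exclusive by
construction and their pairwise "LD" is an artefact of allelic identity.

## Bioassay statistics

Mortality classification follows WHO/CDC criteria: ≥ 98% susceptible, 90–97%
possible resistance, < 90% resistant, applied to the diagnostic-time
percentage. Printed table cells are inverted to integer deaths by nearest-
integer rounding of pct·n/100; a cell with no integer within 0.05 points is
flagged inconsistent rather than silently accepted (the bundled table contains
exactly one such cell, a starred control-colony entry). Pooled mortality is
100·Σdeaths/Σn rounded half-up to 1 dp.

The mortality model is Poisson log-linear with offset:
log E(deaths) = log n + β₀ + site + insecticide + γ·concentration, reference
levels Bayamon and deltamethrin, fitted by Fisher scoring to a score-norm of
1e-8 (equivalent to IRLS for the canonical log link). Standard errors come
from the inverse Fisher information; nested models are compared by likelihood
ratio against chi-squared. Concentration coding is configurable — numeric dose
multiplier (default) or log µg/bottle — because the published analysis does
not state its coding; coefficient magnitudes are therefore validated only
directionally (malathion > 0 vs deltamethrin, Ponce > 0 vs Bayamon), and the
tests assert direction and significance, not the printed point estimates.
Control and reference-colony rows are excluded from the regression; no
control-mortality (Abbott) correction is applied because none is described for
the source data.

## Numerical and design choices

* Rounding half-up everywhere a printed table is reproduced.
* Likelihood-caller no-call odds 10; calling depth floor 10; identity floor
  0.8; species identity 0.95; covered-amplicon depth 5; QC 6 of 10 amplicons.
* EM: equilibrium start, |Δp| < 1e-8, ≤ 1000 iterations. IRLS: β = 0 start,
  score norm < 1e-8, ≤ 100 iterations, singular-design error on separation.
* Demultiplexer ties → unknown; the mis-tag rule is strict dual-tag
  consistency (the published pipeline's exact heuristic is unspecified).
* The pipeline demo and the test suite run deliberately small problem sizes —
  cohorts of 8–20 samples at 25–60-fold coverage, 1,000-replicate null
  simulations — chosen so the full validation remains quick on a laptop while
  keeping every binomial acceptance band (3 SE) meaningful at those sizes.

## Known limitations

* No indel, CNV or structural-variant support; ungapped alignment drops
  indel-bearing reads.
* The read simulator's fragment geometry and constant base quality are
  idealisations; trimming is exercised mainly by constructed reads.
* Species confirmation is a COI identity check, not a phylogenetic placement.
* Near-fixation loci make r² estimates unstable in small cohorts; monomorphic
  loci are flagged rather than estimated.
* The bundled published-style tables carry their source's internal
  inconsistencies (one bioassay cell that does not round-trip, one genotype
  row whose printed frequency disagrees with its own counts); the package
  always recomputes from counts and flags, rather than repairs, such cells.
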