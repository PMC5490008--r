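---
title: "Simulating viral microdiversity and measuring its footprint on metagenomic analysis"
author: "virodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating viral microdiversity and measuring its footprint on metagenomic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question this package addresses

Marine viral populations are rarely clonal. A single "species" —
reads recruiting to one reference genome at or above 95% nucleotide
identity — typically contains a cloud of co-occurring variants:
SNP-level differences, members diverging down to ~75% average
nucleotide identity (ANI), and localized hypervariable islands where
divergence is far above the genome-wide rate. `virodiv` simulates such
populations under controlled, replayable conditions and quantifies
what that structure does to the standard metagenomic toolchain:
fragment-recruitment abundance estimates, SNP calling, and — most
consequentially — de novo genome assembly, where co-assembled variants
collapse into consensus contigs that mix alleles from distinct parent
genomes (chimeras) or fail to assemble at all.

## Population model

A focal genome is drawn i.i.d. at a chosen GC content (default length
15 kb, GC 0.45 — the scale of a small dsDNA phage genome). Variants
are derived from it by substitution only: no indels, no recombination,
no transition bias (each substituted base is replaced uniformly by one
of the other three). Every variant carries its full mutation record,
so any child can be replayed from its parent byte-for-byte; that
record is also what makes assembly evaluation provenance-aware.

Three scenario presets mirror increasing microdiversity:

* **A** — two genomes differing by exactly 20 SNPs at uniformly drawn
  positions: population structure below the species threshold, the
  minimal microdiversity that already defeats consensus assembly.
* **B** — five genomes, each calibrated to an ANI of at least 95%
  against the focal genome, with no elevated island divergence.
* **C** — ten genomes spread across 75–95% ANI against the focal
  genome, each additionally carrying a hypervariable island (default
  divergence 0.10) at positions 9,000–9,700, scaled proportionally
  into shorter genomes.

Calibration targets sit one tolerance unit inside the stated ranges
(B: 96–99%; C: nine targets evenly spaced over 76–94%): a generator
calibrated to ±1 percentage point can only honor a *hard* range bound
by aiming inside it. The ANI reading is variant-vs-focal; all-pairs
ANI is not constrained (the alternative reading would require solving
a coupled design problem the data do not demand).

`evolveToANI()` doses substitutions, measures the child against the
parent with `fragmentANI()`, and re-doses proportionally on the
divergence scale until the measured ANI is within `tolPct` (default 1)
of the target, normally in two to four iterations. Because the
measuring stick is the same statistic used everywhere else in the
package, calibrated populations are self-consistent under later
re-measurement.

## Alignment engine and fragment ANI

All searching goes through one seed-and-extend local aligner: exact
k-mer seeds (default k = 11) against the reference set, banded affine
Smith–Waterman extension (band half-width 16) around clustered seed
diagonals, BLASTN-like scores (+1/−2, gap of length L costs
5 + 2(L−1)). Alignments are filtered by raw score (≥ 20) and length
(≥ 30 columns) rather than an e-value: deterministic, and independent
of database size at desk scale. `N` never counts as a match. Small
problems (≤ 4 Mcell) are solved by exhaustive dynamic programming; the
test suite checks both paths against `Biostrings::pairwiseAlignment`
as an independent DP oracle.

Fragment ANI tiles one genome into 100-bp fragments every 50 bp, takes
each fragment's best local hit, accepts it when it covers at least 70%
of the fragment, and averages. One numerical choice matters here: the
identity a fragment contributes is computed **over the whole fragment
span**, counting unaligned fragment ends as non-identity columns. A
raw local alignment trims diverged ends, which inflates per-fragment
identity at high divergence; with trimming, the ANI statistic
saturates near 78–80% no matter how diverged the genomes are, and no
substitution dose can realize a 75% target. Whole-span identity
reduces to the usual pident at full coverage and tracks
1 − substitution rate closely across the 75–100% range. Fragments with
no accepted hit are excluded from the mean but reported via the
aligned fraction, keeping ANI and coverage separable. Symmetric mode
(the default) averages both directions.

## Read simulation

Paired-end reads (default 150 bp, insert 300 ± 30 bp clamped to
[read length, genome length]) are drawn genome-by-genome with
probability proportional to abundance × genome length, fragment starts
uniform. The error model is substitution-only and uniform along the
read (default rate 0.001, an Illumina-like post-QC rate), with
constant Q40 quality strings; the SNP caller therefore takes its error
rate as a parameter instead of reading qualities. Background
communities are i.i.d. random genomes — unrelated to the focal
population by construction (aligned fraction < 0.05), standing in for
the natural virome a focal population is spiked into; a configurable
fraction of read pairs (default 0.5) comes from the background. What
this emulates: abundance-weighted sampling, sequencing error, spike-in
designs. What it does not: platform error profiles, indel errors,
GC-coverage bias, amplification chimeras. Tests passing on these reads
show the *analysis machinery* is correct, not that real viromes are
this tame.

## Recruitment statistics

Recruitment filters follow the virome-analysis convention: identity
floor 50%, hits below 80% query coverage removed, species cutoff 95%,
genus cutoff 70%. Best-hit assignment keeps each read's single
top-scoring hit, ties broken deterministically (score, then genome id,
then subject start). The abundance statistic is KPKG — kb of reads
recruited per kb of genome per Gb of metagenome:

    KPKG = (aligned query bases / 1000) / (genome kb) / (metagenome Gb)

The aligned query span is the recruited quantity; that matches the
read-counting intuition behind the statistic's name. Relative
recruitment divides per-set mean KPKG by the sum over sets. Diversity
curves bin retained-hit identities (1-point bins over 70–100 by
default, last bin closed); a broad sub-95% shoulder against a single
reference is the recruitment signature of a microdiverse population.

## SNP calling

Pileups accumulate allele counts from alignments at ≥ 95% identity and
≥ 70% read coverage; gap columns contribute nothing. At each site the
most frequent non-reference allele is tested against
Binomial(depth, error rate) — the exact upper tail at the observed
count, no continuity correction; a site is a SNP when depth ≥ 5 and
p < 10⁻⁶. Only the top alternative allele is tested (bi-allelic
model): the minimal faithful reading of a binomial variant test. The
summary statistic is SNPs per kb of *effective* genome (positions at
calling depth) per Mb of mapped read bases, which makes counts
comparable across references with different coverage. Calls export as
VCF v4.2 (QUAL = −10·log₁₀ p, INFO DP and AD).

## Assembly and chimera detection

The assembler is a deliberately small de Bruijn implementation:
k-mers (odd k, default 31, limited to ≤ 31 by 2-bit packing into
64-bit words) counted from reads and their reverse complements, an
abundance floor (default 2) that removes almost all error k-mers,
unitig compaction, and simple-bubble popping. A bubble — two unitig
paths diverging and reconverging — is the graph footprint of an
isolated SNP between co-assembled haplotypes; popping keeps the
higher-coverage branch, with coverage ties broken toward the branch
whose canonical (strand-independent) sequence sorts first, so both
strand twins of a bubble resolve consistently. This per-bubble
winner-take-all is exactly the consensus behavior that manufactures
chimeras: with two equally abundant haplotypes each bubble is a coin
flip, and the emitted contig interleaves parental alleles.

The evaluator aligns contigs to every truth genome and reports
per-genome recovery (fraction covered by alignments at ≥ 99%
identity — high enough that a consensus collapsing ≤ 95%-ANI variants
cannot count as recovering the focal genome) and a per-contig allele
table at the population's discriminating sites. A contig is chimeric
when it carries alleles from at least two parents and no single parent
explains all informative sites. Contigs aligning nowhere are reported
unassigned, never an error; external assembler output enters through a
plain FASTA path and gets the identical report.

## Peptide recruitment and sorter arithmetic

ORFs (ATG/GTG starts, stop-bounded, both strands, ≥ 60 aa) are
digested with trypsin rules — cleave after K or R except before P, up
to 4 missed cleavages, minimum length 6 — and peptides are matched
against proteomes at 100% identity and full coverage (exact
substring); per-genome counts are normalized by genome kb. Peptide
masses and the carboxymethyl modification are recorded parameters but
deliberately unused: the comparison is sequence-level, not
spectrum-level.

Droplet arithmetic for single-virus sorting is closed-form: with
38,700 drops/s and a net particle rate of 30/s (50 events/s minus
20/s electronic noise — the midpoint convention applied to the
instrument's stated 40–50 and 20–30 ranges, fixed at net 30 to match
the worked configuration), one particle rides every 1,290 drops
(≈ 1/1,300), and the Poisson doublet probability
P(N ≥ 2 | N ≥ 1) ≈ λ/2 ≈ 3.9 × 10⁻⁴.

## Problem sizes, determinism, degenerate inputs

The package's own test and acceptance runs use 15-kb genomes,
20–50× coverage, 5–10 seeded replicates — sizes chosen so a full
scenario contrast (five seeds of scenario C plus clonal controls) is a
minutes-scale desk computation while leaving binomial intervals tight
enough to assert against. Every stochastic function takes an explicit
seed; the pipeline expands one global seed into per-stage seeds by a
fixed integer derivation recorded in the run manifest, and identical
configurations produce byte-identical artifacts. Degenerate inputs
fail loudly and early: empty sequences, non-nucleotide symbols (named
in the error), genomes shorter than a fragment, unalignable pairs in
`genomeDiff()`, all-zero means in relative recruitment, empty
effective genomes in the SNP frequency.

## Known limitations

Substitution-only evolution and reads; no recombination or selection;
the assembler resolves neither repeats nor paired-end ambiguity and is
not a production assembler (external contigs can be evaluated
instead); the aligner has no e-value statistics and is not tuned for
databases beyond desk scale; peptide matching ignores masses. The
k-mer range stops at 31. Fragment-ANI values at deep divergence
(< ~80%) depend visibly on the whole-span identity convention
described above; comparisons across tools should compare conventions
first.
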