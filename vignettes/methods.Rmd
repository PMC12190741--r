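---
title: "Methods: simulating and benchmarking sex-chromosome variant calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and benchmarking sex-chromosome variant calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexchrombench)
```

`sexchrombench` is a closed-loop simulation: it generates a genome whose
regional structure mimics the human X/Y pair, simulates individuals and
their sequencing reads, runs an explicit alignment/calling/filtering
pipeline against differently masked references, and scores every call
against the generator's own truth. Because every component is synthetic and
seeded, every contrast the package reports is mechanistically attributable
and exactly reproducible. This vignette records the models, the defaults and
why they were chosen, and what the results do and do not say about real
data.

## The genome model

A `genome_architecture()` tiles each sex chromosome with five region
classes in the order `PAR1 | XTR | AMP | NONPAR | PAR2`; homologous classes
have equal lengths on X and Y, PARs sit at the chromosome tips, and an
optional autosome `A` provides a diploid baseline. Coordinates are 0-based
half-open internally (BED convention); VCF output is 1-based.

Sequence similarity between the X and Y copies is controlled per class:

* **PARs**: identical by default (`s_par = 1`), reflecting ongoing
  recombination. This identity — and the fact that the default reference
  carries *both* copies — is the entire mechanism behind the PAR mapping
  collapse.
* **XTR**: the Y copy is the X copy with exactly
  `floor((1 − s_xtr) · L)` uniformly placed single-base substitutions,
  `s_xtr = 0.9878` by default (the reported X–Y identity of the human XTR).
  Divergence is exact, not expected: a 30-kb XTR diverges at exactly 366
  positions.
* **AMP** and **NONPAR**: drawn independently on X and Y (unrelated
  sequence). Ampliconic regions carry no internal repeat structure here;
  the class exists so region-stratified reports have the human-style rows.

Default sizes (X = Y = 200 kb with PAR1 10 kb, XTR 30 kb, AMP 10 kb, PAR2
5 kb; autosome 100 kb) are a deliberate ~1000-fold reduction of the human
chromosomes that keeps every mapping/calling mechanism intact while the
full factorial runs in minutes on one CPU. Tests use a 60-kb version of the
same layout; the acceptance script uses the 200-kb default.

## Individuals and truth sets

`simulate_cohort()` draws, per sample and per haplotype copy, SNP positions
as a Bernoulli process at density `theta = 0.001` per bp per haplotype —
the human heterozygosity scale — with the alternate allele uniform over the
three non-reference bases. Karyotype determines which haplotypes exist: XX
samples carry two full X copies; XY samples carry one X copy plus a
"Y-complement" consisting of the X-anchored PARs and the non-PAR Y. PAR
variants are therefore always recorded in X coordinates (the convention
under which PARs are called diploid on X for everyone), XX samples can
never carry Y-linked variants, and the golden VCF of an XY sample carries
haploid genotypes (`1`) on non-PAR X/Y and diploid genotypes elsewhere. If
both haplotypes hit the same position the second draw adopts the first
allele, keeping sites biallelic (with independent draws this is rare;
real shared variation is far more concordant than i.i.d. draws, see
*Limitations*).

## Reads, qualities, errors, trimming

`simulate_reads()` draws fragments independently within each (haplotype
copy × region segment): region classes are simulated as separate templates,
which matches how per-region ploidy/coverage settings are applied in
practice, and means no fragment straddles a region boundary. Depth is
expressed per haplotype copy (`coverage_policy(depth_per_copy = 10)`):
diploid regions get 20x, each haploid chromosome 10x, the conventional
half-coverage expectation for haploid chromosomes. Fragment lengths are
normal (mean 350, sd 50); reads are 150 bp; the reverse mate is
reverse-complemented; the true origin of every read is kept as hidden
metadata so depth and mapping oracles never depend on the mapper.

Base qualities follow a two-state model: Q25 baseline with a Q12 run at the
3' end of half the reads (expected 10% of bases demoted), so the quality
trimmer has realistic work to do. Sequencing errors flip a base to a
uniformly chosen different base with probability `10^(-Q/10)` derived from
its own quality (constant-rate and error-free overrides exist for tests).
`trim_reads()` implements end-trimming of sub-Q20 runs on both sides,
discards reads shorter than 75 bp after trimming, and removes reads whose
arithmetic mean quality is below 20. Two choices the underlying tools leave
ambiguous are fixed here and tested: *mean quality* is the arithmetic mean
of Phred scores, and mates are dropped jointly if either fails.

## The mapper

`map_reads()` is a deliberately transparent stand-in for a production
aligner: ungapped (the simulation is SNP-only), scoring each candidate
placement by Hamming distance over the full read on both strands, with
candidates proposed by a k-mer positional index (k = 21, seed stride 7).
Reference `N` mismatches everything, which is exactly how hard masking
repels reads. Reads with more than `max_mm = 25` mismatches at their best
placement are unaligned.

MAPQ is a declared surrogate: 0 when two or more placements are co-optimal
(the multi-mapper convention), otherwise `min(60, 6·(second_best − best) +
20)`. Only the two ends of this scale matter downstream: MAPQ 0 reads are
always excluded from calling, and the MQ < 40 hard filter consumes the
rest. Ties are broken uniformly by a per-read counter-based hash of the
seed, so each read's placement is independent of every other read and of
reference masking elsewhere — this is why contrasts on untouched regions
(e.g. the non-PAR Y under default vs SCC alignment) are *exactly* zero
rather than Monte-Carlo zero. On genomes of tens of kb the seeded index is
verified in the test suite to agree with an exhaustive-scan oracle on
placement set, mismatch count, tie count, and MAPQ for every read.

One knock-on effect deserves note: with ~1.2% X–Y divergence a 150-bp XTR
read typically has only 1–2 discriminating positions, so its surrogate MAPQ
lands at 26–32 and XTR sites largely fail the MQ < 40 filter under
references where both XTR copies are present. The XTR false-negative
proportion is therefore much higher here than a BWA-based pipeline would
show; the package makes no claim to reproduce BWA's MAPQ distribution, and
all reported contrasts (XX XTR gain under SCC, XY XTR neutrality, the
Y-XTR-masking blow-up) are directions this surrogate preserves.

## Calling

Calling is pileup-based (no local reassembly; the simulation has no
indels). Reads below MAPQ 20 — and multi-mappers at MAPQ 0 always — are
excluded. Candidate sites need at least 2 pooled non-reference bases across
the cohort. Per site, the alternate allele is the most frequent non-reference
base cohort-wide (ties alphabetical); lower-count alternates are dropped,
keeping sites biallelic.

Genotype likelihoods use the standard biallelic substitution model with the
per-base error probability `e` floored at `1e-4` (guarding against zero
likelihoods): `P(b|a) = 1 − e` if `b = a`, else `e/3`; haploid likelihoods
multiply over reads, diploid genotypes average the two allele terms per
read. The per-sample genotype is the MAP under a prior of `1e-3` per
variant genotype (the conventional heterozygosity prior, configurable).
Ploidy per (karyotype, chromosome, position) follows the region-ploidy map;
`force_diploid` mode maps every non-zero ploidy to 2, i.e. "process the sex
chromosomes like autosomes". Mixed ploidy across samples at one site is
supported, so X can be joint-called across XX and XY samples.

Site QUAL is the phred-scaled posterior that *all* samples are homozygous
or hemizygous reference (independence across samples); sites with at least
one alternate allele among the MAP genotypes are emitted. Annotations
follow the conventional definitions: DP (depth over genotyped samples), AN
(ploidy-weighted count of genotyped allele copies), QD (QUAL over the
summed depth of variant-carrying samples), MQ (RMS read MAPQ), FS
(phred-scaled two-sided Fisher exact p of the ref/alt × strand table), SOR
(symmetric strand odds ratio with +1 pseudocounts), and MQRankSum /
ReadPosRankSum (alt-vs-ref Wilcoxon rank-sum z with tie correction,
normal approximation; distance from the closer read end for the latter).

## Filtering

`apply_hard_filters()` applies the conventional SNP hard-filter set exactly
as written — `QD < 2.0`, `QUAL < 30.0`, `SOR > 3.0`, `FS > 60.0`,
`MQ < 40.0`, `MQRankSum < −12.5`, `ReadPosRankSum < −8.0` — with strict
comparisons (a site at MQ = 40.0 passes) and the GATK convention that a
missing annotation never fails its filter. Labels are conjunctive, so
composition is order-independent.

Two threshold families are ploidy-sensitive and exposed for sweeps:

* `dp_band_filter()` retains sites whose DP lies within 50–150% of a mean
  depth, *inclusive* at both ends (a stated choice). The mean may be
  derived from autosomal sites ("diploid-based") or from X/Y non-PAR sites
  of XY samples ("haploid-based") via `mean_site_dp()`; a haploid site at
  DP 8 survives the haploid band [5, 15] but not the diploid band [10, 30],
  which is the mechanism behind diploid-band true-positive loss.
* `an_filter()` retains sites with `AN ≥ k` (direction: AN counts
  successfully genotyped allele copies, so high AN is good support). With
  `n` haploid-called XY samples AN cannot exceed `n` on X/Y non-PARs, so
  any `k > n` — e.g. the diploid-based 20 with ten samples — removes every
  site there. This is an analytic consequence, asserted as a test.

`threshold_sweep()` scores retained TP/FP per region class against the
golden truth over a vector of QD, AN, or DP-band thresholds.

## Benchmarking

`classify_calls()` implements site/allele-level scoring: TP = called and
simulated with matching ref and alt; FP = called, not simulated; FN =
simulated, not called. Genotype concordance is deliberately not scored (the
definitions are site-level). A position called with the wrong alternate
allele contributes one FP *and* one FN, flagged `alt_mismatch` so the
convention is auditable. Joint VCFs are exploded to per-sample call sets (a
sample has a site iff it carries ≥ 1 alternate allele) before
classification, and TP + FN = simulated-site count per sample and region by
construction — asserted on every run. `stratify_by_region()` reports per
class (PARs pooled, XTR, AMP, non-PAR-minus-XTR) with proportions over
simulated totals; `window_counts()` tallies fixed windows anchored at 0
(default 50 kb, last window truncated).

`run_experiment()` wires the factorial together — cohorts are simulated
once, reads reused across reference kinds, calls made per (reference kind ×
ploidy mode), hard filters applied, every cell benchmarked raw and
filtered — and returns a deterministic report bundle.

## Design choices on points the underlying tools leave open

* **Ploidy-mode contrasts are reported on raw joint calls.** The
  haploid-vs-diploid comparison is about the genotype model; at depth-2
  sites the QUAL of the two models straddles the QUAL < 30 cutoff (29.5 vs
  30.5 under Q25 bases and the 1e-3 prior), so comparing after filtering
  would measure a knife-edge filter artifact rather than calling behaviour.
  On raw calls the diploid override inflates false positives (heterozygous
  calls at sites with a couple of coincident errors) while false negatives
  match the haploid run — the directions the benchmark is after.
* **XY PARs are simulated as diploid on X** for both karyotypes (truth,
  reads, and calls all X-anchored); how a read simulator should place the
  "second" PAR haplotype of an XY individual is ambiguous, and X-anchoring
  matches how PAR variants are conventionally recorded.
* **Mates aligned independently**; pairing constraints are not used for
  rescue. This keeps the mapper analyzable and is conservative for the
  multi-mapping phenomena studied here (pair rescue could only reduce PAR
  ambiguity by using information the default pipeline also would not have —
  both mates come from the same duplicated region).
* **Site-wise filtering** on the joint call set (INFO-level), not
  per-genotype.

## Numerical notes

Likelihood sums are accumulated in log10 space; posteriors are normalised
after subtracting the maximum; `post_ref` is floored at 1e-300 before the
QUAL transform; GQ is capped at 99. Fisher p-values are floored at 1e-320
before the FS transform. Rank-sum z-scores return NA when either allele
class is empty, and NA annotations pass filters. Determinism: all R-level
randomness flows through `set.seed()` on user-supplied seeds; the only
randomness in compiled code is the tie-break hash, which is a pure function
of (seed, read index).

## Problem sizes used by the shipped checks

The test suite exercises 40–60-kb genomes with 2–10 samples per cohort and
20 seeded replicates for the ploidy-contrast properties; the acceptance
script runs the 200-kb default architecture with ten samples per cohort.
These sizes were chosen so the full factorial stays in the minutes range on
a single CPU while each region class still carries tens to hundreds of
simulated variants.

## Limitations

* SNPs only — no indels or structural variants; ungapped mapping and
  pileup calling are adequate only because of this.
* Variants are i.i.d. across samples, so cohort-level site sharing is far
  lower than in real populations; cross-sample statistics (distinct-site
  unions, AN/AC spectra) scale differently than with real variants, and
  occasional discordant-allele collisions at one position are an artifact
  of independence.
* The MAPQ surrogate reproduces the multi-mapper (0) and unique (≥ 40)
  regimes, not a production aligner's full MAPQ distribution; XTR
  false-negative levels are correspondingly pessimistic here.
* The error model is quality-derived and position-independent apart from
  the demoted 3' runs; no GC bias, no adapter read-through, no duplicates.
* Ampliconic regions have no internal repeat structure, so the benchmark
  cannot reproduce intra-chromosomal multi-mapping on Y amplicons — only
  X–Y homology effects.

Passing tests therefore demonstrate that the pipeline mechanics and the
strategy contrasts are implemented and behave as the underlying theory
predicts at toy scale; they do not certify performance numbers on real
genomes.
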