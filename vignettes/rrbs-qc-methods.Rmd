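---
title: "Methods: simulation, alignment and QC for directional RRBS"
author: "rrbsqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, alignment and QC for directional RRBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrbsqc)
```

## The molecular model

Reduced-representation bisulfite sequencing restricts a methylation
experiment to the ~2–3% of the genome flanked by MspI sites. MspI
recognizes `CCGG` and cuts between the two Cs, leaving 5'-CG overhangs;
end repair fills these in, so every internal fragment carries a CpG at
both ends and its repaired top strand begins `CGG` and ends `CCG`. After
bisulfite conversion every unmethylated cytosine reads as T, while
5-methylcytosine (and, indistinguishably, 5-hydroxymethylcytosine) is
protected. In a *directional* library only the original top (OT) and
original bottom (OB) strands are sequenced, each from its fragment's MspI
end, so every read starts `CGG` (site CpG methylated) or `TGG`
(converted). These structural facts drive almost every QC metric in this
package: the GG check at read positions 2–3, the low-diversity problem at
the first three cycles that spike-in DNA addresses, the head/tail C
ratio, and the read "stacks" that make RRBS duplicates ambiguous.

Coordinates are 0-based half-open internally; SAM output is 1-based.
`N` bases never form MspI or CpG sites, and cytosine contexts touching an
`N` are excluded from every tally rather than guessed.

## The simulator

`simulate_reads()` is the package's fixture generator and is first-class,
tested code. Per fragment, a Poisson(`depth`) number of molecules is
drawn; each molecule picks OT with probability `ot_fraction` (0.5), then
each CpG cytosine on that strand is methylated as an independent
Bernoulli draw of the site's methylome level. Unmethylated and non-CpG
cytosines convert to T, each escaping conversion independently with
probability `conversion_failure` (default 0.01, matching the 97–99%
conversion rates typical of single-round bisulfite kits). Sequencing
errors substitute a uniformly chosen different base per position
(default 0.001, consistent with constant phred-37 qualities, the default
quality model). PCR duplication then emits `Geometric(dup_geometric_p)`
byte-identical extra copies per molecule (default p = 0.5, mean
multiplicity 2); the per-copy probability can be tilted by
`exp(-a*(len-150)/250 - b*retainedC)` to emulate preferential
amplification of short and cytosine-poor fragments. Both biases default
to 0 so that the duplicate pool is representative by construction. All
randomness flows from a single seed: identical configurations give
byte-identical FASTQ output.

The synthetic methylome is a four-component mixture calibrated to adult
human brain: 60% of CpGs uniform below 5%, 27.5% uniform above 95%, 2%
in the 45–50% band (the reproducible "imprinted-like" bump, 2–3x its
neighboring bins), and the remainder uniform in between. Mode
*placement* and weights are observed quantities; the uniform shape
*within* each mode is a modeling choice — only ranges, not
distributions, are empirically constrained.

What the generator deliberately does not emulate: CpG-island clustering
(the reference is i.i.d. random by default, with a `gc` knob), indels,
adapter read-through (a fixed adaptor suffix can be spliced in by tests),
paired ends, non-directional protocols, hydroxymethylation (invisible to
bisulfite chemistry anyway) and flow-cell physics. Passing tests
therefore validate the pipeline's arithmetic and its statistical
behavior under the stated molecular model, not performance on real
libraries.

### A consequence worth knowing about: the C ratio on random references

The head/tail C ratio (positions 1–10 vs 41–50) is meant to sit near 1
in a well-converted library. On an i.i.d. random reference this does
*not* happen, and the package makes no attempt to force it: read
position 1 is an obligate MspI-site CpG, methylated with probability
~0.35 under the brain methylome, while positions 2–3 are obligate Gs.
In real RRBS data the CpG-island enrichment of MspI fragments raises the
background C density roughly threefold, which cancels the position-1
spike almost exactly; on a uniform random genome the background is ~2%
C per position and the simulated ratio lands near 2. The metric is
implemented faithfully with configurable windows (the traditional
"bases 1–10 and 40–50" phrasing spans unequal widths, so the default
uses the equal-width 1–10 vs 41–50 and both are arguments).

## Alignment

`align_reads()` is a minimal directional three-letter aligner. Both the
forward strand and the reverse complement of each contig are C-to-T
reduced and seed-hashed; a read is C-to-T reduced and looked up by its
first 16 reduced bases in both spaces. Mismatches are counted in reduced
space, so a read T over a genomic C (a conversion event) is free while
disagreements involving A/G remain real. Within the minimal-mismatch
stratum a read is unique only if exactly one placement exists with at
most 2 mismatches (the classic `--best --n 2 --directional` policy);
ties — including equal-score hits on opposite strands — are discarded
rather than broken arbitrarily, and no indels are attempted (RRBS
50-mers anchored at MspI ends essentially never need them, so CIGAR is
always `<len>M`). MAPQ is fixed at 255 ("unavailable") since no mapping
quality model is defined. The seed-only lookup can miss a read whose
entire first 16 bases are corrupted; at the default error rate that is
~1.6% of reads, and the test suite bounds the behavior against a
brute-force all-offsets scorer, which the aligner must match exactly on
error-free reads.

Methylation calls cover every genomic cytosine on the read's strand of
origin: read C = methylated, read T = converted, anything else
(sequencing error) yields no call. Reverse-strand CpG calls are
re-attributed to the forward C of the CpG so both strands share one site
key; CHG/CHH calls keep the covered base's own position. SAM export
writes `XM` (Bismark-style per-base call string) and `XG`
(strand-of-origin) tags.

## Post-alignment QC

**Conversion rate.** Genome-wide, the estimator uses CHH+CHG calls only
(mammalian methylation is almost exclusively CpG, so non-CpG cytosines
should convert completely). On the mitochondrial contig a second,
deliberately different estimator uses *all* contexts, because mammalian
MT genomes are unmethylated — an internal negative control that also
flags residual CpG-context methylation above 2%.

**Duplicates.** The dedup key is (contig, start, strand, sequence), not
coordinates alone: same-stack reads with different methylation patterns
are genuine biological observations in RRBS, where fragments share
MspI-defined ends. Coverage is reported both ways; unique-only mean
coverage of ~2–4x against ~10x-larger with-duplicates coverage is the
expected desk-scale picture.

**Duplicate representativeness.** At loci with >10 deduplicated reads
and ≥4 CpGs at intermediate (strictly 0–1) unique-pool frequency, the
per-CpG frequency vectors of the unique pool and the all-read pool are
compared by Pearson correlation, with a two-sided p from
`t = r*sqrt(n-2)/sqrt(1-r^2)` on n−2 df (no permutation option in this
version; the t transform reproduces the canonical 4-site worked example,
r² = 0.95, p = 0.03). The selection thresholds default to ≥11 reads and
≥4 differential sites — the protocol's own worked example has exactly 4
CpGs, so "more than four" is read inclusively — and both are arguments.
"Differentially methylated" is operationalized as a unique-pool
frequency strictly inside (0,1); no numeric band is imposed. One
property of this statistic found during development and reflected in the
test suite: a *coherent* amplification bias (cytosine-content bias
dragging every site the same way) barely moves a per-locus Pearson,
while heavy-tailed per-molecule amplification (small geometric p,
random jackpots) visibly degrades it.

**Region controls.** Region methylation is coverage-weighted
(Σmethylated/Σtotal); the unweighted mean of per-CpG frequencies is
available behind a flag since reference protocols rarely state which
they used. The bundled hg19 table carries imprinted CpG islands
(expected mid-level methylation with narrow between-subject SDs) and two
housekeeping promoters (expected ~1%); checks pass within
`k_sd` (default 3) reference SDs with a 1-point SD floor, and
low-methylation regions additionally enforce a 5% ceiling. Imprinting is
tissue-specific: the bundled expectations are brain values, the sperm
column is annotation only, and users supply their own BED plus
expectations for other tissues.

## Numerical and testing choices

* Problem sizes: unit tests use 4–60 kb references; the heavier checks
  use a 100 kb reference with 10^5 reads for read-level metrics and
  twenty 20 kb references x 1000 error-free reads for the
  aligner-vs-brute-force equivalence. These sizes give every statistic
  at least ~10^5 observations where a tolerance of ±0.2 percentage
  points is asserted.
* Binomial discreteness: at depth ~20, sites with levels near 0 or 1
  step outside a ±3·SE band with probability up to ~2%, and levels near
  a 5%-bin edge legitimately fall into the neighboring histogram bin.
  Recovery tests therefore assert ≥95% of sites in-band and a centered
  signed error, not a uniform bound.
* Degenerate inputs: zero-variance frequency vectors, empty regions,
  contigs without calls, and tail windows without cytosines all return
  flagged/NA results with warnings rather than errors, so batch QC runs
  do not die on a degenerate locus; genuinely invalid arguments
  (negative sizes, non-cytosine positions) are errors.
* Histogram edges: methylation bins are half-open `[l, u)` with a closed
  last bin `[95, 100]`, so a frequency of exactly 1 is counted once.
* The gel window for size selection is applied to insert + adaptor
  overhead (default 65 bp, the two-step adaptor dimer length) with a
  default window of 150–400 bp; whether a published gel window includes
  adaptors is protocol-dependent, so both numbers are arguments rather
  than constants.

## Known limitations

The aligner is a desk-scale reference implementation, not a
production mapper: hash-based seeding in plain R is adequate for
megabase references and 10^5-read simulations but not for a real flow
cell. The simulator's i.i.d. reference understates CpG density inside
MspI fragments (see the C-ratio note above). Differential-methylation
testing between samples, smoothing and DMR segmentation are downstream
of this package's scope, as are BAM/CRAM encoding (SAM text only) and
restriction enzymes other than MspI.
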