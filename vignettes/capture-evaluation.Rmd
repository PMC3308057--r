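---
title: "Evaluating exome capture experiments with capeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating exome capture experiments with capeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capeval)
```

# The problem

Hybridization-based exome capture enriches a sequencing library for a set
of probe-defined *capture target regions* (CTRs).  Judging how well a kit
performs — and how trustworthy the genotypes called from its reads are —
requires a fixed battery of analyses: how many reads land on target, how
evenly the targets are covered, which annotated transcripts are fully
covered, how GC content depresses capture, whether heterozygous sites show
an excess of reference-allele reads, and how well sequencing-derived
genotypes agree with an orthogonal SNP array.  `capeval` implements that
battery, together with the variant-processing front end it presumes: read
cleanup, duplicate marking, pileup construction, allele-quality-ratio
genotype re-calling, and read-end-anomaly detection.

Because the original analyses ran on proprietary probe designs and real
human capture libraries, the package ships a seeded synthetic-data
generator that reproduces the *statistical structure* of such experiments
at desk scale, so every analysis is exercised end to end against known
truth.

# The quality-ratio genotype model

At a candidate variant position the pileup provides call bases with
per-base allele qualities.  Writing $A$ and $B$ for two allele-quality
sums, the quality ratio is

$$ r = \frac{A}{A + B} $$

with the rules, applied in order:

1. calls spanning more than two distinct alleles: $r = -1$ and the site
   is filtered (multiallelic);
2. reference and one variant allele present: $A$ is the reference
   quality sum, $B$ the variant quality sum;
3. two variant alleles and no reference call: $A$ is the larger of the
   two sums (ties broken lexicographically; $r = 0.5$ either way);
4. all calls one variant allele: $r = 0$.

Genotype classes follow fixed bands: $r > 0.8$ is considered a reference
call and filtered; $0.2 \le r \le 0.8$ heterozygous; $r < 0.2$ homozygous
variant.  Reading "between 0.2 and 0.8" as the closed interval is the only
choice under which the three published phrasings compose a total function
on $[0,1] \cup \{-1\}$; the edges are configurable in
`classifyGenotype()`.

A column becomes a candidate when at least one variant call reaches the
variant allele quality threshold (default Phred 20; indels require 50 and
tolerate no third allele).  "Variant allele quality" is not defined beyond
the tooling it came from, so the default is the maximum single-call
quality of a variant allele with an allele-quality-sum mode behind a flag
(`callSnvs(qualityMode = )`).

## Exact heterozygote-call accuracy

With a constant base quality $q$ every call contributes the same weight,
so at a true heterozygous site of depth $d$ the ratio reduces to $X/d$
where $X \sim \mathrm{Binomial}(d, \beta)$ counts reference-carrying reads
and $\beta$ is the reference sampling probability (0.5 when unbiased).
`hetCallAccuracyCurve()` evaluates
$P(0.2 \le X/d \le 0.8)$ exactly; at depth 11 this is
$1914/2048 \approx 0.9346$.  One property of the fixed closed band is
worth knowing: the curve is *not* monotone in depth.  Whenever $d$ is
divisible by 5 the values $0.2d$ and $0.8d$ are attainable counts that
fall exactly on the closed band edges, so those depths get a small bonus
and the next depth dips (e.g. 0.9785 at depth 10 versus 0.9346 at 11).
Between band-edge depths the curve is non-decreasing, and from depth 17
onwards it stays above 0.99.

## Allele balance

For heterozygous sites the same $A/(A+B)$ with $A$ the
reference-supporting evidence is reported as the *allele balance*: 0.5 is
ideal, values above 0.5 indicate that capture probes — designed from the
reference sequence — favour reference-allele fragments.  The default
evidence is the allele-quality sum, consistent with the ratio machinery; a
read-count mode exists because "more reference bases" can equally be read
as counts (with constant qualities the two coincide).

# Pipeline conventions

**Read cleanup order is fixed**: optional fixed-length trimming first
(e.g. 100 bp reads cut to 82 bp before anything else), then trimming of
the trailing run of Q2 base qualities (the Illumina 1.5-era "B block",
`'B'` at offset 64, `'#'` at offset 33 — exactly Q2, not "any low
quality"), then removal of any pair with a mate shorter than 36 bp (36
itself is kept).  Quality strings are converted between Phred+64 and
Phred+33 by pure offset arithmetic; the package works on the Sanger scale
internally.

**Duplicates** are fragments with identical chromosome, fragment outer
start, outer end and orientation; each group keeps its highest
summed-base-quality pair (ties broken by read name for determinism).
Keying on both fragment ends is stricter than leftmost-coordinate-only
and avoids over-collapsing deep synthetic data; a `leftmost` mode is
provided.  Unpaired survivors of filtering are dropped by default — the
pipeline is pair-oriented.

**Pileup semantics**: depth counts aligned (M/=/X) bases of non-duplicate
reads only — no soft clips, no spanned deletions.  Soft-clipped bases
contribute no call but their sequence is attached to the boundary column,
and zero-depth columns inside targets are represented explicitly so the
0x coverage class is countable.  The allele quality of a call is its base
quality; base- and mapping-quality floors default to 0 because no floor
is part of the method.

**Read-end anomalies (REAs)**: a position where at least 5 non-duplicate
reads share an identical aligned start (or, separately, end), making up
at least 30% of the aligned-base coverage there.  The boundary is the
first/last *aligned* base — soft clips do not shift it — and reads
starting at the position are included in its coverage (they do cover the
base; the alternative reading would only make the fraction larger).
Start- and end-side calls at one position are reported separately, and
clip sequences of supporting reads ride along as breakpoint evidence.
Shared boundaries caused by B-block trimming rather than clipping are
reported identically, with an empty clip list.

**Interval algebra** is 1-based closed inside R (the `GRanges`
convention), converted at the boundaries: BED and bedGraph input/output
are 0-based half-open, pileups and variants 1-based.  Abutting intervals
merge into one region — half-open adjacency means contiguous bases — and
all set operations ignore strand.  Design comparison uses the
one-base-pair-or-more overlap rule; the combined query is built by
pooling annotation and design intervals first and merging once (the
alternative — merging the annotation before pooling — changes region
counts slightly and is not what "combined into a single query" says).
GC content is the unweighted mean of per-target fractions over
unambiguous bases, emulating per-sequence GC of target FASTA records,
with a base-pair-weighted mode behind a flag.  Coverage classes for the
GC stratification (0x, <10x, >=10x, >=20x) are overlapping selections,
not a partition.  Per-exon coverage is $\sum \mathrm{depth} /
\mathrm{length}$ — implemented as printed in its source, an arithmetic
mean despite its historical "median coverage" label — and a transcript is
complete when every exon's mean reaches the threshold.

**SNP-chip comparison**: chip SNPs below a 95% genotyping success rate or
without a unique genomic placement are dropped; genotypes whose flanking
sequence maps to the minus strand are reverse-complemented.  The
sequenced genotype at a chip position is the re-called variant genotype
if one exists, else homozygous reference when pileup depth reaches a
configurable minimum (default 1 — the method states no floor).
Correlation is concordant/(concordant+discordant), tabulated per depth
bin (1–5, 6–10, ... by default) and per chip genotype class, with an
accumulative-minimum-coverage mode for threshold curves.  Chip SNPs with
no coverage are uncallable: excluded from every bin, counted separately.

# The synthetic experiment

`simConfig()` fixes every generator parameter; all generators are
deterministic given the seed (each derives a fixed offset stream, so the
functions can be called in any order).  The generator emulates:

* **targeted capture with off-target spillover** — fragments are
  on-target with probability $1 - \mathrm{offTargetRate}$ (default 0.40,
  the order of what real capture kits show), placed so that both mates
  overlap the chosen target; off-target fragments are placed uniformly in
  the inter-target space and never touch a target, which keeps the
  configured rate exactly recoverable from read overlap counts;
* **GC-dependent coverage depression** — a target's sampling weight falls
  linearly with $|GC - 0.5|$ (`gcBiasStrength`), strong enough to drive
  GC-extreme targets toward the 0x class;
* **reference-biased allele sampling** — at heterozygous truth sites a
  fragment carries the reference allele with probability `referenceBias`
  (default 0.5; 0.52 mimics the observed in-target excess). Draws are per
  fragment and site; PCR duplicate copies inherit their template's
  alleles, as real duplicates would;
* **PCR duplicates** — a `duplicateRate` fraction of final fragments are
  re-emissions of uniformly chosen templates;
* **B tails** — a fraction of reads get trailing Q2 qualities; the FASTQ
  export carries them intact while the truth alignments appear
  post-trimming, as they would after the cleanup stage;
* **read-end anomalies** — configured plants emit the requested number of
  boundary-sharing reads; supporters vary in aligned length so only the
  planted boundary is shared, and with `withSoftclip` they attach one
  common clip sequence (a shared breakpoint);
* **a SNP chip** — drawn from in-target truth plus invariant sites, with
  configured fractions of minus-strand (pre-flipped), deliberately
  discordant (hidden truth column), low-call-rate and multi-mapping SNPs.

Reads are emitted pre-aligned with ground-truth coordinates rather than
routed through an aligner: alignment is outside the package's scope and
truth coordinates make every oracle exact.  A FASTQ export exists for
users who want to run a real aligner.  Base qualities default to a
constant Q30 so the binomial closed form applies.  Fragment sizes are
normal (250 +/- 30 by default), truncated to
$[\mathrm{readLength}, 2 \cdot \mathrm{readLength} + 300]$, loosely
emulating 200–300 bp size selection; reads default to 82 bp.  Defaults
compress variant density (0.01/bp) and genome size relative to a human
exome so that a full run takes seconds, not hours.

What the generator does **not** emulate: sequencing errors and quality
decay along the read, indel truth (beyond REA boundary plants),
structural variants, alignment artefacts, multi-mapping reads, and probe-
level coverage texture within a target.  Passing tests therefore show
that the algorithms implement their contracts exactly and recover planted
parameters — not that they are robust to every artefact of real data.

## Problem sizes used by the test-suite experiments

The package's own checks run two mid-size experiments (300 kb genome, 150
targets of 300–500 bp, mean on-target depth 40–50, about 55 000 read
pairs, roughly 1 000 heterozygous in-target truth sites, a 2 000-SNP
chip), chosen so that binomial sampling noise sits several standard
errors inside every asserted tolerance: at depth ~40 the per-site balance
standard deviation is about 0.08, so ~1 000 sites pin the mean within
+/-0.008; a 2 000-SNP panel at 1% planted discordance determines the
expected correlation to within less than 0.1 percentage points.
Exhaustive oracles (all 55 986 pileup columns with depth <= 6 over three
alleles and two quality levels; per-base boolean vectors on <= 10 kb toy
chromosomes) cover the discrete logic completely.

# Numerical and degenerate-input choices

* Ratio band edges are closed at both 0.2 and 0.8 (see above); rule-(iii)
  ties are broken lexicographically and always give 0.5.
* `N` calls are excluded from allele accounting but count toward depth.
* A reference-only column is an error for `qualityRatio()` (not a
  variant), and an all-B read trims to length 0 and is left to the pair
  filter.
* Mapability lookups on uncovered bases error by default
  (`uncovered = "zero"` opts into treating them as 0).
* Empty region sets, empty bins and zero-site strata are represented
  (size 0, `NA` summaries) rather than dropped.
* All randomness flows through explicit seeds; downsampling and the
  generators are reproducible run to run.

# Limitations

* SAM round-trips go through coordinate sorting, so read order is not
  preserved (pairing via read names is).
* The variant caller approximates the historical pileup/VarFilter stage
  with configurable depth and quality bounds; it is documented as an
  approximation, not a reimplementation, and genotype-likelihood models
  are out of scope.
* hg18/hg19-style liftover is out of scope: all inputs must share one
  coordinate system, checked only through chromosome-name consistency.
* Transcript input is the exon-table form; BED12 is not parsed.
* The CLI (`inst/scripts/capeval`) wraps the exported functions for the
  most common steps; programmatic use remains the primary interface.
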