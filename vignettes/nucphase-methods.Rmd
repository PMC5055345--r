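---
title: "Methods: rotational positioning signals and TSS selection"
author: "nucphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rotational positioning signals and TSS selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucphase)
```

# The model

Nucleosomal DNA shows a ~10-bp periodic preference for flexible
dinucleotides: WW (W = A/T) steps where the minor groove faces the histone
octamer, SS (S = C/G) in counter-phase, and an analogous YY/RR alternation.
A promoter whose +1 nucleosome region carries this signal positions that
nucleosome *rotationally*: the histone octamer can slide by whole helical
turns but keeps the same face of the DNA against the core. The package
quantifies this signal, relates it to observed nucleosome maps (MNase) and
to Pol-II initiation patterns (CAGE), and measures how sequence variants
that strengthen or weaken the signal shift initiation dispersion.

The working hypotheses the pipeline encodes:

1. the +1 signal is measurable as spectral power of a binary dinucleotide
   track at the helical frequency;
2. rotational tolerance predicts secondary initiation sites at ~10-bp
   spacing around the dominant TSS in promoters lacking core promoter
   elements (CPEs);
3. initiation dispersion (the DI, a population variance in bp²) is
   anti-correlated with the +1 signal in CPE-less promoters;
4. variants that reduce +1 periodicity increase the DI of that promoter
   (negative ΔDI-on-Δpower slope).

# Coordinate frame

All TSS-relative coordinates place the dominant TSS base at offset 0,
increase in the direction of transcription, and are half-open
`[start, end)`; minus-strand promoters are mirrored so "downstream" always
means 3' of the TSS on the annotated strand. Annotation-style closed
windows that count the TSS as position 0 translate as `-a..+b` →
`[-a, b+1)`. The standard scan window `-1074..+1075` is therefore the
2,150-bp window `[-1074, 1076)`, whose 2,149-long dinucleotide track yields
exactly 200 sliding windows of 150 bp at shift 10; the CAGE profile window
`-103..+104` spans 208 bp. This convention matters: a ±1-bp shift of the
anchor visibly moves every 10-bp phase plot, so it is fixed package-wide in
one place (`extractWindow`, `relativeToGenomic`).

# The periodicity score

For a window $x_0,\dots,x_{L-1}$ of a binary dinucleotide track the score
at frequency $f$ is

$$P(f) = \frac{1}{L}\left|\sum_{n=0}^{L-1}(x_n-\bar x)\,
e^{-2\pi i f n}\right|^2 .$$

Numerical choices, each pinned by an oracle test against an explicit
double-loop evaluation:

* **Direct evaluation at f = 0.097** (period 10.3 bp). The target frequency
  is not a Fourier bin of a 150-bp window (bins are k/150), so the sum is
  evaluated directly rather than interpolated from a padded FFT; absolute
  power is then padding-independent.
* **Mean removal**: a window that is merely AT-rich but aperiodic scores 0;
  the statistic measures rotational signal, not composition.
* **N handling**: any dinucleotide touching an N scores 0, and windows in
  which more than 10% of dinucleotides touch an N are reported `NA` with a
  warning rather than biasing the spectrum.
* Window/shift defaults are 150/10 bp; window centers are reported at
  `start + 75` on the relative axis.

A promoter is called **concordant** when the mean window power over the +1
region strictly exceeds that over the nucleosome-free region (NFR). The
defaults — NFR `[-150, 0)`, N+1 `[+50, +200)` — follow the +1 scoring
region used for consensus motifs and the typical NFR span immediately
upstream of the TSS; both are arguments, since reasonable alternatives
(e.g. a narrower NFR) exist.

# Consensus motifs

The 240 motifs are all arrangements of the token multiset
{WW, SS, YY, RR, N, N} that do not start with N (6!/2! = 360 minus 120).
Each motif's four dinucleotide tokens have a well-defined cyclic order;
rotated to start at SS it either matches one of the two nucleosome
consensus orders (SS-RR-WW-YY, SS-YY-WW-RR — 40 motifs each) or is
"other". Matching allows ≤3 mismatches out of 10; pattern N matches
anything, a sequence N mismatches every non-N symbol. The match coordinate
is the **window start** — start versus center shifts every profile by a
constant 5 bp, so cross-motif comparisons (the only use made of the
scores) are unaffected. Matching is on the promoter-oriented forward
strand only; reverse-complement matching would double-count the
palindromic-by-class patterns without changing rankings. The motif score is
the periodicity score of the *mean* occurrence profile over +50..+200
(promoter context) or the whole ±75 dyad window (genomic context); scoring
the mean profile rather than per-sequence scores mirrors the aggregate
nature of the consensus.

In the "twice as strong" promoter split the dominance boundary is
inclusive (`score_A ≥ 2·score_B`), and promoters with both scores 0 stay
unassigned (no 0/0 call).

# Nucleosome maps

Only fragments of exactly 147 bp (the core particle) are used; duplicates
at identical coordinates count once. For single-end data, a plus-strand 5'
end at p pairs with a minus-strand 5' end "147 bp downstream" read as an
*inclusive span*: the partner sits at p+146 and the fragment is
`[p, p+147)`, making single- and paired-end fragments identical in length.
(The alternative gap-of-147 reading would shift every dyad by 0.5 bp; the
choice is isolated in one constant.) The dyad of a 147-bp fragment is its
exact central base, `start + 73`.

Aggregate profiles shift each tag 70 bp 3'-ward (half the ~140-bp
estimated fragment size), cap per-anchor per-position counts at 1
(duplicate removal), pool in strand-mirrored relative coordinates and
smooth with a centered 10-bp moving average. The unsmoothed profile
conserves mass (sum = retained events / anchors), which the tests assert.

# Initiation statistics

**Micro-peaks** binarise initiation: any 5-bp window (step 1 bp, the
natural reading of a local maximum *within* a 5-bp window) holding ≥100
tags contributes one mark at its highest-count position — leftmost on ties
— and overlapping windows that elect the same position contribute a single
mark. The threshold is an argument; synthetic tests scale it with the
simulated depth.

**Phasing** ranks promoters by the covariance between the binary micro-peak
array and a period-10 cosine whose maximum is anchored at the dominant TSS
(the phase the rotational model predicts; the anchor is an argument).
Promoters with an empty array score exactly 0 and form the weak class.

**Dispersion Index**: `DI = Σ(xᵢ − x̄)²/N` over tag 5' positions in the
100-bp window `[-50, +50)`; the divisor is N (population variance, no
Bessel correction) exactly as the statistic is defined, and the DI exists
only when more than 5 tags map in the window. Sample-specific DIs are
averaged per promoter.

# Promoter classes and the DI regression

PWMs are inputs (text matrices, one row per position, A C G T columns, a
`cutoff=` header); count matrices are converted to log2-odds against a
user-supplied background. A promoter is TATA+ when the best above-cutoff
hit *starts* at offsets −32..−26 (−29±3), Inr+ when a hit starts exactly at
offset 0 (the matrix start anchors at the TSS base — an alternative
internal anchor would be configured through the same `anchor` argument),
and CGI+ when an island starts before and ends after the TSS base (strict
containment; an island ending exactly at the TSS does not count).

For the DI-periodicity relation, promoters with a defined DI are ordered by
increasing DI and cut into equal bins (default 2,000 promoters per bin at
genome scale; tests use 10-20); CPE-positive promoters form their own bins
outside the ordering. A linear model of bin mean power on bin mean DI
provides slope, R², p and a 99% confidence band. Binning before regression
suppresses the large per-promoter DI sampling noise.

# Variants and the ML genome

The most-likely (ML) reference carries the population-major allele at
every variant site (ties go to the reference allele); a sample's
homozygous variant list is then restricted to sites where the sample
allele differs from the ML allele. Patching applies non-overlapping
SNPs/indels with reference-allele verification and returns a monotone
original→patched coordinate map.

ΔDI is sample minus reference. For the per-window regression, Δpower is
computed on the 150-bp sequence window centered at the window midpoint,
extracted from the patched genome through the coordinate map — so indels
perturb both content and phase, deliberately — versus the fixed reference
window. Windows report a slope only with ≥3 contributing promoters and a
non-degenerate regressor. A promoter with variants in several windows
contributes to each (sliding-window pooling).

# The synthetic cohort generator

The generator emulates exactly the structure the analysis assumes, one
chromosome per promoter (default 200 promoters, 10-kb chromosomes, TSS
centered, about half the promoters on the minus strand):

* **Sequence**: i.i.d. background (default uniform); inside the +1 window
  `[+50, +200)` slots at `round(k · 10.3)` bp carry the planted
  dinucleotide with probability `amplitude` (default 0.8). The planted
  period is 10.3 bp — the helical repeat the score targets — not 10.0; a
  10.0-bp plant measurably decoheres over a 150-bp window at f = 0.097.
* **Fragments**: exactly 147 bp; centers scatter around the planted dyad
  (+120) with Normal(0, 10) displacements *quantised to whole 10-bp
  periods* (rotational tolerance) plus a 1-bp residual cut-site wobble.
  Without quantisation the dyad-centered aggregate would lose the phase
  coherence that rotational positioning preserves in real chromatin.
* **CAGE**: in periodic mode, a dominant site (weight 0.5) plus secondary
  sites at ±10, ±20, ±30 bp with geometrically decaying weights
  (decay 0.6) — the phased-initiation pattern; in dispersed mode (broad,
  CPE-less-like promoters without a dominant site) positions are uniform
  with SD σ, so the measured DI tracks σ². Totals are Poisson (default
  1,000 tags/promoter), site counts multinomial.
* **Variants**: at most one SNP and one indel per promoter inside the +1
  window, homozygous, always the population-minor allele (so every planted
  variant survives the ML filter). After patching, the generator couples
  the sample condition's spread to its own measured power change:
  σ²_sample = σ²_ref − k·Δpower + noise (default k = 30 bp² per power
  unit, noise SD 1 bp²), i.e. planted ΔDI = −k·Δpower.
* **Determinism**: one global seed fans out through a fixed integer hash
  to per-(promoter, purpose) streams, so any subset of promoters is
  bit-reproducible irrespective of cohort size.

What the generator does **not** emulate: MNase sequence bias, realistic
linker-length distributions, diploid genomes, CAGE library artefacts,
expression-level variation, or correlated periodicity across the four
dinucleotide codes beyond what WW planting induces. Passing recovery tests
therefore demonstrate that the pipeline's inference is correct under the
stated generative model, not that real data meet that model.

# Test and verification scales

The oracle tests pin `powerAtFrequency` to an explicit double-loop DFT
(1,000 random windows, 1e-9), mismatch counting to a naive per-symbol scan
(10,000 pairs, exact) and the DI to a two-pass variance (1,000 tag sets,
1e-9). Parameter-recovery runs use 200-promoter cohorts (40-promoter,
2-kb-chromosome cohorts for the 100-replicate variant-coupling study, and
4-kb chromosomes where only ±500 bp matter), sizes at which every recovery
quantity is stable while the full suite runs in a few minutes. The
acceptance script recomputes all headline quantities from scratch at these
scales under a caller-supplied seed.

# Known limitations

* Absolute power values depend on the no-padding convention; rankings and
  all comparative results do not.
* The concordance call compares means over windows *centered* in the two
  regions; 150-bp windows centered near region edges mix in flanking
  sequence, slightly diluting sensitivity at sharp signal boundaries.
* `occurrenceProfile` holds one mismatch-indicator layer per IUPAC symbol
  in memory (5 × regions × length integers); genome-scale motif scans
  should be chunked by region set.
* Heterozygous variants are rejected rather than phased; allele-specific
  initiation is out of scope.
* CpG islands are consumed as intervals, never called from sequence.
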