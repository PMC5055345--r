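# nucphase

Rotational nucleosome positioning signals encoded in promoter DNA, and how
they shape transcription start site (TSS) selection by RNA polymerase II.

## The problem

Nucleosomal DNA favours a ~10-bp periodic placement of flexible
dinucleotides (WW = A/T pairs, in counter-phase with SS = C/G; likewise
YY/RR), the helical repeat that lets DNA bend around the histone octamer.
When such a signal sits in the **+1 nucleosome** (the first nucleosome
downstream of the TSS), it constrains the nucleosome rotationally: the
nucleosome may slide by whole helical turns (multiples of ~10 bp) but keeps
its phase. At promoters lacking core promoter elements (CPEs: TATA-box,
Initiator, DPE), this DNA-encoded +1 signal correlates with — and variants
suggest it drives — how focused Pol-II initiation is.

`nucphase` implements the complete analysis chain for this question, for
epigenomics researchers working with promoter annotations, CAGE 5'-tag
data, MNase-seq fragments and variant calls:

* **Periodicity scoring** — dinucleotide indicator tracks (WW/SS/YY/RR) and
  sliding-window (150 bp, shift 10) spectral power at a target frequency.
  The score of a window `x` of length `L` is the direct Fourier sum at
  exactly `f = 0.097` cycles/bp (period 10.3 bp):

  `P(f) = | Σₙ (xₙ − x̄) e^(−2πifn) |² / L`

  Mean removal makes the score measure periodicity, not composition, and
  the direct sum avoids FFT-grid interpolation (0.097 is not a bin of a
  150-bp window).
* **Consensus motifs** — the 240 degenerate 10-bp motifs obtained by
  permuting {WW, SS, YY, RR, N, N} (N-initial arrangements excluded),
  cyclic-order classification into the SS-RR-WW-YY / SS-YY-WW-RR nucleosome
  consensus classes, mismatch mapping (≤3 of 10), and periodic-enrichment
  scores of occurrence profiles in +1-nucleosome DNA (+50..+200 from the
  TSS) and in genomic-nucleosome DNA (±75 around MNase dyads).
* **Nucleosome maps** — 147-bp MNase fragment selection (paired or single
  end), dyad (midpoint) inference, and aggregate occupancy profiles around
  promoter sets (70-bp tag centering, per-position count cut-off 1, 10-bp
  smoothing).
* **Initiation statistics** — CAGE micro-peaks (binarised local maxima of
  5-bp windows holding ≥100 tags), 10-bp phasing of secondary initiation by
  cosine covariance, and the **Dispersion Index**
  `DI = Σᵢ (xᵢ − x̄)² / N` — the population variance of the N tag 5'-end
  positions in a 100-bp window around the dominant TSS (defined for N > 5).
* **Promoter classes** — PWM hits at constrained offsets (TATA at −29±3,
  Inr at the TSS), CpG-island overlap (island strictly containing the TSS),
  and DI-ordered binning with a periodicity-on-DI regression.
* **Variant effects** — a most-likely (ML) reference carrying the
  population-major allele at every site, genome patching with homozygous
  SNPs/indels plus a coordinate map, per-window ΔDI scans, and the
  per-window regression of ΔDI on Δperiodicity (negative slope: variants
  that weaken the +1 signal broaden initiation).
* **Synthetic cohorts** — a fully seeded generator producing genomes,
  promoters, fragments, CAGE tags and variants with the statistical
  structure above, so the whole pipeline is testable offline.

## Worked example

```r
library(nucphase)

cfg    <- simConfig(seed = 7, nPromoters = 50)   # planted WW signal in the N+1
cohort <- simulateCohort(cfg)
seqs   <- extractWindow(cohort$genome, cohort$promoters, c(-1074L, 1076L))

prof <- periodicityProfile(dinucleotideTrack(seqs[[1]], "WW"), code = "WW")
prof
#> PeriodicityProfile (WW): 200 windows of 150 bp (shift 10) at f=0.097
#>   power range [0.0003174, 1.357], peak at center +121 bp
concordanceCall(prof)
#> [1] TRUE
```

The first promoter's strongest 10.3-bp WW signal sits at +121 bp — inside
the +1 nucleosome — and the concordance call confirms the downstream signal
exceeds the nucleosome-free region upstream. Across the cohort, 45 of the
50 promoters are called concordant. Initiation dispersion per promoter:

```r
tags <- simulateCage(cfg, cohort, sigma = seq(2, 10, length.out = 50))
head(promoterDispersion(tags), 3)
#>   id       di nTags defined
#> 1 p1 3.864943   953    TRUE
#> 2 p2 4.715357  1048    TRUE
#> 3 p3 5.431658   966    TRUE
```

DI rises with the planted spread (p1 was planted at sigma = 2, so its
variance is ~4 bp²). Motif scoring over the +1 region recovers the
nucleosome consensus class even though only WW was planted — the A/T-rich
slots deplete SS in counter-phase:

```r
sc <- motifScores(extractWindow(cohort$genome, cohort$promoters,
                                c(-99L, 301L)), consensusMotifs())
head(sc[order(-sc$power), ], 5)
#>     pattern       class    power
#>  WWNRRSSYYN SS-YY-WW-RR 1.136695
#>  WWNRRSSNYY SS-YY-WW-RR 1.115567
#>  SSYYNWWRRN SS-YY-WW-RR 1.113940
#>  WWRRNSSNYY SS-YY-WW-RR 1.102989
#>  RRSSNYYWWN SS-YY-WW-RR 1.090194
```

End-to-end analyses (`runConcordanceAnalysis`, `runDispersionAnalysis`,
`runVariantAnalysis`) orchestrate these stages over a cohort and write TSV
outputs plus a reproducibility manifest.

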