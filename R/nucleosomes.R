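## MNase fragment handling: nucleosome-sized (147 bp) fragment selection,
## dyad (midpoint) inference, and aggregate occupancy profiles around
## anchor sets.

NUCLEOSOME_BP <- 147L
## Single-end pairing: a plus read at p pairs with a minus-strand 5' end
## "147 bp downstream", read as an inclusive span of 147 bp, i.e. the minus
## 5' end sits at p + 146 and the fragment is [p, p + 147).
.SINGLE_END_PARTNER_OFFSET <- NUCLEOSOME_BP - 1L

#' Select nucleosome-sized fragments from read pairs
#'
#' Keeps only fragments of exactly 147 bp (the nucleosome core particle)
#' and collapses duplicates mapping to the same location to a single record.
#'
#' @param fragments A \code{GRanges} (or data.frame with columns
#'   \code{chrom,start,end}, 0-based half-open) of read-pair fragments.
#' @return A \code{GRanges} of unique 147-bp fragments.
#' @export
fragmentsFromPairs <- function(fragments) {
  gr <- .asFragmentGRanges(fragments)
  gr <- gr[width(gr) == NUCLEOSOME_BP]
  unique(gr)
}

#' Infer nucleosome fragments from single-end reads
#'
#' A plus-strand read whose 5' end sits at p is paired with any minus-strand
#' 5' end at p + 146 (an inclusive 147-bp span), emitting the fragment
#' \code{[p, p+147)}; unmatched reads emit nothing.  Duplicates are
#' collapsed.
#'
#' @param chrom,pos,strand Parallel vectors of read 5'-end positions
#'   (0-based) and strands.
#' @return A \code{GRanges} of unique 147-bp fragments.
#' @export
fragmentsFromSingle <- function(chrom, pos, strand) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(strand))
  plus <- strand == "+"
  pk <- paste(chrom[!plus], pos[!plus])         # minus 5' ends, keyed
  hit <- paste(chrom[plus], pos[plus] + .SINGLE_END_PARTNER_OFFSET) %in% pk
  p <- pos[plus][hit]
  ch <- chrom[plus][hit]
  if (!length(p)) return(GRanges())
  unique(GRanges(ch, IRanges(start = p + 1L, width = NUCLEOSOME_BP)))
}

#' Nucleosome dyads from 147-bp fragments
#'
#' The inferred nucleosome position is the fragment midpoint: for a 147-bp
#' fragment \code{[start, start+147)} the dyad is the exact central (74th)
#' base, \code{start + 73} (0-based).  Duplicate dyads are collapsed.
#'
#' @param fragments A \code{GRanges} of 147-bp fragments.
#' @return A data.frame with columns \code{chrom}, \code{pos} (0-based dyad
#'   coordinates), sorted and unique per chromosome.
#' @export
dyadPositions <- function(fragments) {
  gr <- .asFragmentGRanges(fragments)
  if (any(width(gr) != NUCLEOSOME_BP))
    stop("all fragments must be exactly ", NUCLEOSOME_BP,
         " bp; filter with fragmentsFromPairs() first")
  df <- unique(data.frame(chrom = as.character(seqnames(gr)),
                          pos = start(gr) - 1L + (NUCLEOSOME_BP - 1L) %/% 2L))
  df[order(df$chrom, df$pos), , drop = FALSE]
}

.asFragmentGRanges <- function(fragments) {
  if (is(fragments, "GRanges")) {
    gr <- fragments
  } else {
    stopifnot(all(c("chrom", "start", "end") %in% names(fragments)))
    gr <- GRanges(fragments$chrom,
                  IRanges(start = fragments$start + 1L, end = fragments$end))
  }
  if (any(width(gr) <= 0L)) stop("fragments must have positive width")
  gr
}

#' Aggregate tag profile around an anchor set
#'
#' Builds the mean per-promoter coverage of (shifted) sequencing tags on a
#' TSS-relative axis, the standard aggregation for nucleosome maps around
#' promoters: each tag is shifted 3'-ward on its own strand by
#' \code{centering} bp (70 bp for ~140-bp MNase fragments, so that read
#' starts pile up at the dyad), per-(anchor, position) counts are capped at
#' \code{countCutoff} (1 removes PCR/mapping duplicates), counts are summed
#' over anchors in strand-mirrored relative coordinates, and the summed
#' profile is smoothed with a centered moving window.
#'
#' @param tags data.frame with columns \code{chrom,pos,strand} (tag 5' ends,
#'   0-based) and optional \code{count}.
#' @param promoters A [PromoterSet-class] of anchors.
#' @param span Half-open TSS-relative window, default \code{c(-1000, 1001)}.
#' @param centering 3'-ward shift applied to each tag (bp, default 70).
#' @param bin Width of the centered moving-average smoothing window
#'   (bp, default 10; 1 = no smoothing).
#' @param countCutoff Per-anchor per-position count cap (default 1).
#' @return A data.frame with columns \code{offset}, \code{raw} (mean capped
#'   count per anchor, unsmoothed) and \code{smoothed}.
#' @export
aggregateProfile <- function(tags, promoters, span = c(-1000L, 1001L),
                             centering = 70L, bin = 10L, countCutoff = 1L) {
  if (length(promoters) == 0L) stop("anchor set is empty")
  stopifnot(all(c("chrom", "pos", "strand") %in% names(tags)))
  cnt <- if (is.null(tags$count)) rep(1L, nrow(tags)) else tags$count
  shifted <- tags$pos + ifelse(tags$strand == "+", centering, -centering)
  n <- span[2L] - span[1L]
  total <- numeric(n)
  chrom <- promoterChrom(promoters)
  strnd <- promoterStrand(promoters)
  tss <- tssPosition(promoters)
  for (i in seq_len(length(promoters))) {
    onChrom <- tags$chrom == chrom[i]
    rel <- if (strnd[i] == "+") shifted[onChrom] - tss[i]
           else tss[i] - shifted[onChrom]
    keep <- rel >= span[1L] & rel < span[2L]
    if (!any(keep)) next
    idx <- rel[keep] - span[1L] + 1L
    percnt <- tapply(cnt[onChrom][keep], idx, sum)
    percnt <- pmin(percnt, countCutoff)
    at <- as.integer(names(percnt))
    total[at] <- total[at] + percnt
  }
  raw <- total / length(promoters)
  smoothed <- if (bin > 1L) {
    k <- rep(1 / bin, bin)
    as.numeric(stats::filter(raw, k, sides = 2L))
  } else raw
  data.frame(offset = span[1L]:(span[2L] - 1L), raw = raw,
             smoothed = smoothed)
}
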