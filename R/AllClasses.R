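#' @import methods
#' @importFrom GenomicRanges GRanges strand strand<- start end width seqnames
#'   mcols mcols<- findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits Rle runValue
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement subseq
#'   readDNAStringSet writeXStringSet replaceAt
#' @importFrom GenomeInfoDb seqlevels
NULL

#' PromoterSet: a set of anchored promoters
#'
#' Container for a promoter collection anchored at the dominant transcription
#' start site (TSS).  Each promoter is a width-1 [GenomicRanges::GRanges]
#' anchor on the annotated strand, carrying a unique identifier and an
#' optional set of class labels (e.g. \code{TATA+}, \code{Inr+}, \code{CGI+}).
#'
#' All promoter-relative coordinates used throughout the package place the
#' dominant TSS base at offset 0, increase in the direction of transcription,
#' and are half-open \code{[start, end)} intervals.
#'
#' @slot anchors A width-1 \code{GRanges}; \code{names()} are promoter ids,
#'   metadata column \code{labels} (CharacterList-like list of tags) optional.
#' @export
setClass("PromoterSet", representation(anchors = "GRanges"))

setValidity("PromoterSet", function(object) {
  a <- object@anchors
  msg <- character()
  if (length(a)) {
    if (is.null(names(a)) || anyNA(names(a)) || any(names(a) == ""))
      msg <- c(msg, "every promoter must have an id")
    if (anyDuplicated(names(a)))
      msg <- c(msg, sprintf("duplicate promoter id(s): %s",
                            paste(unique(names(a)[duplicated(names(a))]),
                                  collapse = ", ")))
    if (!all(as.character(strand(a)) %in% c("+", "-")))
      msg <- c(msg, "promoter strand must be '+' or '-'")
    if (!all(width(a) == 1L))
      msg <- c(msg, "anchors must be width-1 TSS positions")
    if (any(start(a) < 1L))
      msg <- c(msg, "TSS coordinates must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' TagStore: random-access per-base stranded tag counts
#'
#' Sparse store of 5'-end tag counts (CAGE or MNase read starts), queryable
#' for any (chrom, strand, window).  Positions absent from the input read
#' as zero.
#'
#' @slot tags A \code{GRanges} with a numeric \code{score} column holding
#'   per-base counts (multi-base input records are expanded on query).
#' @slot strandSpecific Logical; if \code{FALSE} queries ignore strand.
#' @export
setClass("TagStore",
         representation(tags = "GRanges", strandSpecific = "logical"))

setValidity("TagStore", function(object) {
  sc <- mcols(object@tags)$score
  if (is.null(sc)) return("tags must carry a 'score' count column")
  if (any(sc < 0)) return("tag counts must be non-negative")
  TRUE
})

#' PeriodicityProfile: sliding-window spectral power along one track
#'
#' Result of scanning a dinucleotide indicator track with a sliding window
#' and evaluating spectral power at a fixed target frequency in every window.
#'
#' @slot powers Non-negative numeric, one value per window position.
#' @slot centers TSS-relative window centers (bp).
#' @slot windowSize,shift Integer scan geometry (bp).
#' @slot frequency Target frequency (cycles/bp).
#' @slot code Dinucleotide code the track was built from ("" if unknown).
#' @export
setClass("PeriodicityProfile",
         representation(powers = "numeric", centers = "numeric",
                        windowSize = "integer", shift = "integer",
                        frequency = "numeric", code = "character"))

setValidity("PeriodicityProfile", function(object) {
  msg <- character()
  if (length(object@powers) != length(object@centers))
    msg <- c(msg, "powers and centers must have equal length")
  if (isTRUE(any(object@powers < -1e-12, na.rm = TRUE)))
    msg <- c(msg, "spectral powers must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "PromoterSet", function(object) {
  cat(sprintf("PromoterSet with %d promoters on %d sequence(s)\n",
              length(object@anchors),
              length(unique(as.character(seqnames(object@anchors))))))
  labs <- promoterLabels(object)
  tags <- sort(table(unlist(labs)), decreasing = TRUE)
  if (length(tags))
    cat("  labels:", paste(sprintf("%s(%d)", names(tags), tags),
                           collapse = " "), "\n")
  invisible(NULL)
})

#' @export
setMethod("show", "TagStore", function(object) {
  cat(sprintf("TagStore: %d records, %s tags, strand-%s\n",
              length(object@tags), format(sum(mcols(object@tags)$score)),
              if (object@strandSpecific) "specific" else "agnostic"))
  invisible(NULL)
})

#' @export
setMethod("show", "PeriodicityProfile", function(object) {
  cat(sprintf(
    "PeriodicityProfile (%s): %d windows of %d bp (shift %d) at f=%.3f\n",
    if (nzchar(object@code)) object@code else "?",
    length(object@powers), object@windowSize, object@shift,
    object@frequency))
  if (length(object@powers))
    cat(sprintf("  power range [%.4g, %.4g], peak at center %+d bp\n",
                min(object@powers), max(object@powers),
                as.integer(object@centers[which.max(object@powers)])))
  invisible(NULL)
})

#' Construct a PromoterSet
#'
#' @param chrom Character vector of sequence names.
#' @param tss 0-based genomic coordinates of the dominant TSS.
#' @param strand "+" or "-" per promoter.
#' @param id Unique promoter identifiers.
#' @param labels Optional list of character vectors of class labels.
#' @return A [PromoterSet-class].
#' @examples
#' PromoterSet(chrom = "chr1", tss = 999, strand = "+", id = "p1")
#' @export
PromoterSet <- function(chrom, tss, strand, id, labels = NULL) {
  gr <- GRanges(chrom, IRanges(start = as.integer(tss) + 1L, width = 1L),
                strand = strand)
  names(gr) <- as.character(id)
  if (is.null(labels)) labels <- rep(list(character()), length(gr))
  mcols(gr)$labels <- labels
  new("PromoterSet", anchors = gr)
}

#' Accessors for PromoterSet
#'
#' \code{tssPosition} returns 0-based genomic TSS coordinates;
#' \code{promoterStrand}, \code{promoterIds}, \code{promoterChrom} and
#' \code{promoterLabels} return the corresponding per-promoter vectors;
#' \code{anchors} returns the underlying width-1 \code{GRanges}.
#'
#' @param x A [PromoterSet-class].
#' @return Vectors parallel to the promoters (or a \code{GRanges}).
#' @name promoter-accessors
NULL

#' @rdname promoter-accessors
#' @export
tssPosition <- function(x) start(x@anchors) - 1L

#' @rdname promoter-accessors
#' @export
promoterStrand <- function(x) as.character(strand(x@anchors))

#' @rdname promoter-accessors
#' @export
promoterIds <- function(x) names(x@anchors)

#' @rdname promoter-accessors
#' @export
promoterChrom <- function(x) as.character(seqnames(x@anchors))

#' @rdname promoter-accessors
#' @export
promoterLabels <- function(x) {
  labs <- mcols(x@anchors)$labels
  if (is.null(labs)) labs <- rep(list(character()), length(x@anchors))
  names(labs) <- names(x@anchors)
  labs
}

#' @rdname promoter-accessors
#' @export
anchors <- function(x) x@anchors

#' Number of promoters in a PromoterSet
#' @param x A [PromoterSet-class].
#' @export
setMethod("length", "PromoterSet", function(x) length(x@anchors))

#' Subset a PromoterSet
#' @param x A [PromoterSet-class].
#' @param i Index vector (integer, logical or promoter ids).
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "PromoterSet", function(x, i, j, ..., drop = FALSE) {
  new("PromoterSet", anchors = x@anchors[i])
})
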