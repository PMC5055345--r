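## Degenerate 10-bp nucleosome consensus motifs: enumeration of the 240
## arrangements of the four dinucleotide tokens (WW, SS, YY, RR) plus two
## single Ns, cyclic-order classification, mismatch mapping, and periodic
## enrichment scoring of occurrence profiles at the target frequency.

.IUPAC_MATCH <- list(
  W = c("A", "T"), S = c("C", "G"), Y = c("C", "T"), R = c("A", "G"),
  N = c("A", "C", "G", "T", "N"))

#' Enumerate the degenerate nucleosome consensus motifs
#'
#' All distinct arrangements of the token multiset
#' \{WW, SS, YY, RR, N, N\} (each dinucleotide token contributes two
#' letters, each N one, so every pattern is 10 characters), discarding
#' arrangements that begin with an N: 6!/2! = 360 arrangements minus 120
#' N-initial ones leaves 240 motifs.
#'
#' @return A data.frame with columns \code{pattern} (10-char IUPAC string),
#'   \code{class} (cyclic-order class, see [classifyMotif()]), and
#'   \code{tokenOrder} (the dinucleotide tokens in order, "-"-separated).
#' @examples
#' m <- consensusMotifs()
#' nrow(m)                        # 240
#' "SSRRNWWNYY" %in% m$pattern    # TRUE
#' @export
consensusMotifs <- function() {
  dinucs <- c("WW", "SS", "YY", "RR")
  perms4 <- .permutations(4L)
  patterns <- character(0)
  slotsets <- utils::combn(6L, 2L, simplify = FALSE)  # N slot placements
  for (ns in slotsets) {
    if (1L %in% ns) next                # pattern must not start with N
    for (p in seq_len(nrow(perms4))) {
      tok <- character(6L)
      tok[ns] <- "N"
      tok[-ns] <- dinucs[perms4[p, ]]
      patterns <- c(patterns, paste(tok, collapse = ""))
    }
  }
  ## N-leading arrangements where the N is in slot 1 only are excluded above;
  ## arrangements with an N in slot 1 and the other N elsewhere never enter.
  patterns <- unique(patterns)
  data.frame(pattern = patterns,
             class = vapply(patterns, classifyMotif, character(1)),
             tokenOrder = vapply(patterns, function(x)
               paste(.motifTokens(x), collapse = "-"), character(1)),
             row.names = NULL)
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

.motifTokens <- function(pattern) {
  ch <- strsplit(pattern, "")[[1L]]
  ch <- ch[ch != "N"]
  stopifnot(length(ch) == 8L)
  paste0(ch[c(1, 3, 5, 7)], ch[c(2, 4, 6, 8)])
}

#' Cyclic-order class of a consensus motif
#'
#' The rotational-positioning consensus of nucleosomal DNA comes in two
#' cyclic dinucleotide orders, SS-RR-WW-YY and SS-YY-WW-RR (which differ
#' only in the relative placement of YY and RR around the SS/WW axis).  The
#' motif's four dinucleotide tokens (Ns ignored) are rotated to start at SS
#' and compared with the two reference orders; any other cyclic order is
#' \code{"other"}.
#'
#' @param pattern A 10-character motif from [consensusMotifs()].
#' @return \code{"SS-RR-WW-YY"}, \code{"SS-YY-WW-RR"} or \code{"other"}.
#' @examples
#' classifyMotif("YYWWNNRRSS")  # "SS-YY-WW-RR"
#' classifyMotif("RRWWNNYYSS")  # "SS-RR-WW-YY"
#' @export
classifyMotif <- function(pattern) {
  tok <- .motifTokens(pattern)
  rot <- which(tok == "SS")
  tok <- tok[((seq_len(4L) + rot - 2L) %% 4L) + 1L]
  if (identical(tok, c("SS", "RR", "WW", "YY"))) "SS-RR-WW-YY"
  else if (identical(tok, c("SS", "YY", "WW", "RR"))) "SS-YY-WW-RR"
  else "other"
}

#' Mismatch count between an IUPAC pattern and a sequence window
#'
#' A position mismatches when the sequence base falls outside the pattern
#' symbol's IUPAC class.  Pattern N matches any base (including a literal
#' N); a literal N in the sequence mismatches every non-N pattern symbol.
#'
#' @param pattern IUPAC string over \{W,S,Y,R,N\}.
#' @param window Sequence of the same length over \{A,C,G,T,N\}.
#' @return Integer mismatch count.
#' @export
motifMismatches <- function(pattern, window) {
  p <- strsplit(toupper(pattern), "")[[1L]]
  w <- strsplit(toupper(as.character(window)), "")[[1L]]
  if (length(p) != length(w))
    stop("pattern (", length(p), ") and window (", length(w),
         ") lengths differ")
  bad <- !p %in% names(.IUPAC_MATCH)
  if (any(bad)) stop("unsupported pattern symbol: ", p[bad][1L])
  sum(!mapply(function(ps, ws) ws %in% .IUPAC_MATCH[[ps]], p, w))
}

## Per-symbol mismatch indicator matrices for a region set: for each IUPAC
## class, a regions x positions 0/1 matrix marking bases outside the class.
.mismatchLayers <- function(regions) {
  regions <- toupper(as.character(regions))
  L <- unique(nchar(regions))
  if (length(L) != 1L) stop("all regions must have equal length")
  M <- matrix(unlist(strsplit(regions, ""), use.names = FALSE),
              nrow = length(regions), byrow = TRUE)
  layers <- lapply(.IUPAC_MATCH, function(cls)
    matrix(as.integer(!M %in% cls), nrow = nrow(M)))
  layers
}

#' Per-position motif occurrence profiles over aligned regions
#'
#' For every motif and every window start offset, the fraction of regions in
#' which the 10-bp window starting there matches the motif with at most
#' \code{maxMismatch} mismatches.  The match coordinate is the window start.
#'
#' @param regions Equal-length aligned sequences (\code{DNAStringSet} or
#'   character vector).
#' @param motifs Character vector of patterns (default: all 240 from
#'   [consensusMotifs()]).
#' @param maxMismatch Maximum allowed mismatches (default 3).
#' @return Numeric matrix, motifs x offsets (match frequencies in [0,1]);
#'   rownames are patterns.
#' @export
occurrenceProfile <- function(regions, motifs = consensusMotifs()$pattern,
                              maxMismatch = 3L) {
  regions <- as.character(regions)
  L <- unique(nchar(regions))
  if (length(L) != 1L) stop("all regions must have equal length")
  k <- nchar(motifs[1L])
  if (L < k) stop("regions (", L, " bp) shorter than the motif (", k, " bp)")
  layers <- .mismatchLayers(regions)
  noff <- L - k + 1L
  out <- matrix(NA_real_, nrow = length(motifs), ncol = noff,
                dimnames = list(motifs, NULL))
  for (m in seq_along(motifs)) {
    p <- strsplit(toupper(motifs[m]), "")[[1L]]
    mm <- matrix(0L, nrow = length(regions), ncol = noff)
    for (j in seq_len(k))
      mm <- mm + layers[[p[j]]][, j:(j + noff - 1L), drop = FALSE]
    out[m, ] <- colMeans(mm <= maxMismatch)
  }
  out
}

#' Periodic-enrichment score of consensus motifs
#'
#' The motif score is the spectral power at the target frequency (see
#' [powerAtFrequency()]) of the mean occurrence-frequency series, restricted
#' to a scoring sub-window of match-start offsets.  Two standard contexts:
#' promoter +1 nucleosome DNA (regions spanning TSS-relative
#' \code{[-99, 301)}, scored over starts +50..+200) and genomic nucleosome
#' DNA (dyad-centered \code{[-75, 76)} regions, scored over all starts).
#'
#' @inheritParams occurrenceProfile
#' @param regionStart TSS/dyad-relative offset of the first region base.
#' @param scoreFrom,scoreTo Inclusive relative offsets of the first and last
#'   scored match start; \code{NULL} scores every offset.
#' @param frequency Target frequency (default 0.097).
#' @return A data.frame with columns \code{pattern}, \code{class},
#'   \code{power}.
#' @export
motifScores <- function(regions, motifs = consensusMotifs(),
                        maxMismatch = 3L, regionStart = -99L,
                        scoreFrom = 50L, scoreTo = 200L,
                        frequency = 0.097) {
  if (length(as.character(regions)) < 10L)
    stop("need at least 10 regions for a stable average occurrence profile")
  prof <- occurrenceProfile(regions, motifs$pattern, maxMismatch)
  cols <- .scoreColumns(ncol(prof), regionStart, scoreFrom, scoreTo)
  data.frame(pattern = motifs$pattern, class = motifs$class,
             power = apply(prof[, cols, drop = FALSE], 1L, powerAtFrequency,
                           f = frequency),
             row.names = NULL)
}

.scoreColumns <- function(noff, regionStart, scoreFrom, scoreTo) {
  if (is.null(scoreFrom)) return(seq_len(noff))
  cols <- (scoreFrom - regionStart + 1L):(scoreTo - regionStart + 1L)
  if (cols[1L] < 1L || cols[length(cols)] > noff)
    stop("scoring window exceeds the region")
  cols
}

#' Per-promoter motif signal
#'
#' The single-promoter analogue of [motifScores()]: the spectral power of
#' that promoter's binary motif occurrence track over the scoring window.
#'
#' @inheritParams motifScores
#' @param region One aligned sequence per promoter.
#' @param pattern A single motif pattern.
#' @return Numeric vector of powers, one per region.
#' @export
promoterMotifSignal <- function(region, pattern, maxMismatch = 3L,
                                regionStart = -99L, scoreFrom = 50L,
                                scoreTo = 200L, frequency = 0.097) {
  regions <- as.character(region)
  cols <- .scoreColumns(nchar(regions[1L]) - nchar(pattern) + 1L,
                        regionStart, scoreFrom, scoreTo)
  vapply(regions, function(r) {
    powerAtFrequency(occurrenceProfile(r, pattern, maxMismatch)[1L, cols],
                     f = frequency)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Split promoters by relative class signal
#'
#' Assigns each promoter to the group of the motif class whose signal is at
#' least \code{ratio} times the rival class's signal (inclusive boundary);
#' promoters where neither dominates, or with no signal at all, stay
#' unassigned.
#'
#' @param scoreA,scoreB Per-promoter signals for the two class
#'   representatives.
#' @param ratio Dominance ratio (default 2).
#' @return Factor with levels \code{"A"}, \code{"B"}, \code{"unassigned"}.
#' @export
splitByClassSignal <- function(scoreA, scoreB, ratio = 2) {
  stopifnot(length(scoreA) == length(scoreB))
  out <- rep("unassigned", length(scoreA))
  out[scoreA >= ratio * scoreB & scoreA > 0] <- "A"
  out[scoreB >= ratio * scoreA & scoreB > 0] <- "B"
  factor(out, levels = c("A", "B", "unassigned"))
}
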