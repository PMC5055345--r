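## Promoter stratification: PWM hits for core promoter elements (CPEs) at
## constrained TSS-relative offsets, CpG-island overlap, and binning of
## promoters by Dispersion Index for the DI-vs-periodicity regression.

#' Best PWM hit in a TSS-relative search window
#'
#' Scores every allowed hit-start offset with the (log-odds) score matrix
#' and returns the highest-scoring offset whose score reaches the cutoff;
#' ties go to the smallest offset.
#'
#' @param seq One promoter-oriented sequence (character or
#'   \code{DNAString}).
#' @param scores Positions x 4 score matrix, columns A,C,G,T (see
#'   [pwmLogOdds()]).
#' @param cutoff Minimal accepted score.
#' @param searchOffsets Inclusive range \code{c(lo, hi)} of allowed hit
#'   START offsets on the TSS-relative axis.
#' @param seqStart TSS-relative offset of the first base of \code{seq}.
#' @return \code{list(offset=, score=)} or \code{NULL} when no offset
#'   reaches the cutoff.
#' @export
pwmBestHit <- function(seq, scores, cutoff, searchOffsets, seqStart) {
  s <- toupper(as.character(seq))
  L <- nchar(s)
  w <- nrow(scores)
  stopifnot(searchOffsets[2L] >= searchOffsets[1L])
  offs <- searchOffsets[1L]:searchOffsets[2L]
  first <- offs - seqStart + 1L                 # 1-based start in seq
  if (any(first < 1L) || any(first + w - 1L > L))
    stop("search window (plus PWM width ", w, ") exceeds the sequence")
  ch <- strsplit(s, "")[[1L]]
  base2col <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  sc <- vapply(first, function(f) {
    cols <- base2col[ch[f:(f + w - 1L)]]
    if (anyNA(cols)) return(-Inf)               # N or other ambiguity
    sum(scores[cbind(seq_len(w), cols)])
  }, numeric(1))
  ok <- which(sc >= cutoff)
  if (!length(ok)) return(NULL)
  best <- ok[which.max(sc[ok])]                 # which.max: leftmost tie
  list(offset = offs[best], score = sc[best])
}

#' Classify promoters by core promoter elements and CpG islands
#'
#' Applies each configured PWM within its allowed TSS-relative hit window
#' (TATA: hit start at -29+/-3, i.e. offsets -32..-26; Inr: exactly at the
#' TSS, offset 0) and intersects TSSs with CpG-island intervals (CGI+ only
#' when the island starts before and ends after the TSS, i.e. strictly
#' contains it).
#'
#' @param promoters A [PromoterSet-class].
#' @param genome A named \code{DNAStringSet}.
#' @param pwms Named list of configs; each element is a list with
#'   \code{scores} (positions x 4 matrix), \code{cutoff}, and \code{anchor}
#'   (inclusive \code{c(lo, hi)} range of allowed hit-start offsets).  The
#'   element name, suffixed "+", becomes the label (e.g. \code{TATA+}).
#' @param cgi Optional \code{GRanges} of CpG islands.
#' @return The \code{PromoterSet} with labels filled in; retrieve with
#'   [promoterLabels()].
#' @export
classifyPromoters <- function(promoters, genome, pwms = list(), cgi = NULL) {
  n <- length(promoters)
  labels <- rep(list(character()), n)
  for (nm in names(pwms)) {
    cfg <- pwms[[nm]]
    if (is.null(cfg$scores) || is.null(cfg$cutoff) || is.null(cfg$anchor))
      stop("PWM config '", nm, "' must supply scores, cutoff and anchor")
    w <- nrow(cfg$scores)
    win <- c(cfg$anchor[1L], cfg$anchor[2L] + w)   # half-open seq window
    seqs <- extractWindow(genome, promoters, win)
    for (i in seq_len(n)) {
      hit <- pwmBestHit(seqs[[i]], cfg$scores, cfg$cutoff,
                        searchOffsets = cfg$anchor, seqStart = win[1L])
      if (!is.null(hit)) labels[[i]] <- c(labels[[i]], paste0(nm, "+"))
    }
  }
  if (!is.null(cgi)) {
    tss <- tssPosition(promoters)
    tssGr <- GRanges(promoterChrom(promoters),
                     IRanges(start = tss + 1L, width = 1L))
    hits <- findOverlaps(tssGr, cgi, ignore.strand = TRUE)
    ## strict containment: island starts before and ends after the TSS base
    qi <- queryHits(hits); si <- subjectHits(hits)
    strict <- start(cgi)[si] < tss[qi] + 1L & end(cgi)[si] > tss[qi] + 1L
    for (i in unique(qi[strict]))
      labels[[i]] <- c(labels[[i]], "CGI+")
  }
  a <- promoters@anchors
  mcols(a)$labels <- labels
  new("PromoterSet", anchors = a)
}

#' Test promoters for a label
#'
#' @param promoters A [PromoterSet-class].
#' @param label Label string, e.g. \code{"TATA+"}.
#' @return Logical vector, one per promoter.
#' @export
hasLabel <- function(promoters, label) {
  vapply(promoterLabels(promoters), function(l) label %in% l, logical(1))
}

#' Bin promoters by Dispersion Index and regress periodicity on DI
#'
#' Orders (ungrouped) promoters by increasing DI, splits them into
#' consecutive bins of \code{binSize} (the last may be smaller), and
#' reports each bin's mean DI and mean N+1 periodicity power.  Promoters
#' carrying a group tag (e.g. \code{TATA+}) form their own bins regardless
#' of DI.  A linear model of bin mean power on bin mean DI is fitted across
#' the DI-ordered bins only, with slope, R-squared, p-value and a 99%
#' confidence band.
#'
#' @param di Per-promoter DI values (must be defined/non-NA for included
#'   promoters).
#' @param power Per-promoter N+1 periodicity power (e.g. the mean of the
#'   four dinucleotide powers over the +1 nucleosome region).
#' @param binSize Promoters per bin (default 2000).
#' @param group Optional character vector; non-NA/non-"" entries pull the
#'   promoter into a per-level group bin instead of the DI ordering.
#' @return A list with \code{bins} (data.frame: bin, type, n, meanDI,
#'   meanPower) and \code{fit} (list: slope, intercept, r2, p, band
#'   data.frame with 99% CI) or \code{NULL} when fewer than 2 DI bins
#'   exist (with a warning).
#' @export
binByDispersion <- function(di, power, binSize = 2000L, group = NULL) {
  stopifnot(length(di) == length(power))
  if (anyNA(di)) stop("DI must be defined for all included promoters")
  grouped <- if (is.null(group)) rep(FALSE, length(di))
             else !is.na(group) & group != ""
  o <- order(di[!grouped])
  dio <- di[!grouped][o]; po <- power[!grouped][o]
  nb <- ceiling(length(dio) / binSize)
  binId <- if (length(dio)) rep(seq_len(nb), each = binSize)[seq_along(dio)]
           else integer()
  bins <- data.frame(
    bin = paste0("DI_", seq_len(nb)),
    type = "DI",
    n = as.integer(tabulate(binId, nb)),
    meanDI = as.numeric(tapply(dio, binId, mean)),
    meanPower = as.numeric(tapply(po, binId, mean)))
  if (any(grouped)) {
    for (g in unique(group[grouped])) {
      sel <- grouped & group == g
      bins <- rbind(bins, data.frame(
        bin = g, type = "group", n = sum(sel),
        meanDI = mean(di[sel]), meanPower = mean(power[sel])))
    }
  }
  diBins <- bins[bins$type == "DI", , drop = FALSE]
  fit <- NULL
  if (nrow(diBins) < 2L) {
    warning("fewer than 2 DI bins; regression skipped")
  } else {
    m <- stats::lm(meanPower ~ meanDI, data = diBins)
    sm <- suppressWarnings(summary(m))
    band <- if (nrow(diBins) > 2L) {
      cbind(meanDI = diBins$meanDI,
            as.data.frame(suppressWarnings(
              stats::predict(m, interval = "confidence", level = 0.99))))
    } else NULL   # two bins: the fit is exact, no meaningful band
    fit <- list(slope = unname(stats::coef(m)[2L]),
                intercept = unname(stats::coef(m)[1L]),
                r2 = sm$r.squared,
                p = if (nrow(diBins) > 2L)
                      unname(sm$coefficients[2L, 4L]) else NA_real_,
                band = band)
  }
  list(bins = bins, fit = fit)
}
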