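## CAGE initiation-pattern statistics: micro-peak extraction (binarised
## local maxima of 5'-tag coverage), 10-bp phasing of secondary initiation
## sites via cosine covariance, and the Dispersion Index (DI) of tag
## positions around the dominant TSS.

#' Micro-peaks of a per-base tag profile
#'
#' Slides a window (default 5 bp, step 1) over the profile; wherever the
#' window's tag sum reaches \code{minTags}, the position with the highest
#' count inside the window (leftmost on ties) is marked.  Marks are
#' deduplicated and each contributes exactly 1, so the result is a binary
#' array that emphasises reproducible initiation sites while flattening
#' their magnitudes.
#'
#' @param counts Non-negative per-base tag counts.
#' @param window Window width in bp (default 5).
#' @param minTags Minimal window tag sum to qualify (default 100).
#' @return Integer 0/1 vector, same length as \code{counts}.
#' @examples
#' microPeaks(c(0, 0, 30, 50, 40, 0, 0), minTags = 100)  # mark at index 4
#' @export
microPeaks <- function(counts, window = 5L, minTags = 100) {
  n <- length(counts)
  if (n < window) stop("profile shorter than the micro-peak window")
  if (any(counts < 0)) stop("tag counts must be non-negative")
  marks <- integer(n)
  sums <- as.numeric(stats::filter(counts, rep(1, window), sides = 1L))
  ## sums[i] covers counts[(i-window+1):i]
  for (i in window:n) {
    if (is.na(sums[i]) || sums[i] < minTags) next
    w <- (i - window + 1L):i
    marks[w[which.max(counts[w])]] <- 1L
  }
  marks
}

#' Cumulative micro-peak frequency across promoters
#'
#' Converts each promoter's (strand-mirrored, TSS-relative) tag profile to a
#' micro-peak array and averages the arrays, giving the per-base frequency
#' of secondary initiation sites across the set.
#'
#' @param profiles Promoters x positions count matrix (e.g. from
#'   [tagProfiles()]); column names are TSS-relative offsets.
#' @inheritParams microPeaks
#' @return Numeric vector of per-base frequencies (named by offset).
#' @export
microPeakFrequency <- function(profiles, window = 5L, minTags = 100) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1L)
  if (nrow(profiles) == 0L) stop("empty promoter set")
  marks <- t(apply(profiles, 1L, microPeaks, window = window,
                   minTags = minTags))
  out <- colMeans(marks)
  names(out) <- colnames(profiles)
  out
}

#' Cosine covariance of a micro-peak array with a 10-bp phase
#'
#' Measures how strongly the binary micro-peak distribution is phased at the
#' helical period: the covariance between the array and
#' \code{cos(2*pi*(x - x0)/period)}, with the cosine maximum anchored at the
#' dominant TSS (offset \code{x0 = 0}).  In-phase marks (at multiples of the
#' period from the TSS) score positive, anti-phase marks negative, and an
#' empty array scores exactly 0.
#'
#' @param marks Binary micro-peak array.
#' @param offsets TSS-relative offsets of the array positions (defaults to
#'   names of \code{marks}, else an axis centered on 0).
#' @param period Phase period in bp (default 10).
#' @param x0 Phase anchor offset (default 0, the dominant TSS).
#' @return Covariance score (numeric scalar).
#' @export
cosineCovariance <- function(marks, offsets = NULL, period = 10, x0 = 0) {
  if (is.null(offsets)) {
    offsets <- if (!is.null(names(marks))) as.numeric(names(marks))
               else seq_along(marks) - 1L - (length(marks) - 1L) %/% 2L
  }
  stopifnot(length(offsets) == length(marks))
  stats::cov(marks, cos(2 * pi * (offsets - x0) / period))
}

#' Rank promoters by 10-bp phasing of their initiation pattern
#'
#' @param markMatrix Promoters x positions binary matrix of micro-peaks
#'   (rownames are promoter ids, colnames TSS-relative offsets).
#' @inheritParams cosineCovariance
#' @return A data.frame sorted by decreasing covariance score, with columns
#'   \code{id}, \code{score} and \code{weak} (\code{TRUE} when the score is
#'   exactly 0, the weak-signal class).
#' @export
rankByCosineCovariance <- function(markMatrix, period = 10, x0 = 0) {
  offsets <- as.numeric(colnames(markMatrix))
  score <- apply(markMatrix, 1L, cosineCovariance, offsets = offsets,
                 period = period, x0 = x0)
  out <- data.frame(id = rownames(markMatrix), score = score,
                    weak = score == 0, row.names = NULL)
  out[order(-out$score), , drop = FALSE]
}

#' Dispersion Index of transcription initiation
#'
#' The spread of CAGE tag 5'-end positions in a 100-bp window around the
#' dominant TSS, summarised as the population variance
#' \code{DI = sum((x_i - mean(x))^2) / N} over the N tag positions in the
#' window (no Bessel correction).  The DI is defined only when more than
#' \code{minTags} tags map in the window.
#'
#' @param offsets TSS-relative tag 5'-end positions.
#' @param counts Tag count at each position (default 1).
#' @param window Half-open relative window, default \code{c(-50, 50)}.
#' @param minTags Minimum tag count for a defined DI (default 5: the DI
#'   requires more than 5 tags).
#' @return A list with \code{di} (bp^2, \code{NA} when undefined),
#'   \code{nTags} and \code{defined}.
#' @export
dispersionIndex <- function(offsets, counts = NULL,
                            window = c(-50L, 50L), minTags = 5L) {
  if (is.null(counts)) counts <- rep(1L, length(offsets))
  stopifnot(length(counts) == length(offsets))
  keep <- offsets >= window[1L] & offsets < window[2L] & counts > 0
  x <- offsets[keep]; w <- counts[keep]
  n <- sum(w)
  if (n <= minTags)
    return(list(di = NA_real_, nTags = n, defined = FALSE))
  m <- sum(w * x) / n
  list(di = sum(w * (x - m)^2) / n, nTags = n, defined = TRUE)
}

#' Per-promoter Dispersion Index table from tag profiles
#'
#' @param profiles Promoters x positions count matrix with TSS-relative
#'   offsets as column names (e.g. from [tagProfiles()]).
#' @inheritParams dispersionIndex
#' @return A data.frame with columns \code{id}, \code{di}, \code{nTags},
#'   \code{defined}.
#' @export
promoterDispersion <- function(profiles, window = c(-50L, 50L),
                               minTags = 5L) {
  offsets <- as.numeric(colnames(profiles))
  rows <- lapply(seq_len(nrow(profiles)), function(i)
    dispersionIndex(offsets, profiles[i, ], window = window,
                    minTags = minTags))
  data.frame(id = rownames(profiles),
             di = vapply(rows, `[[`, numeric(1), "di"),
             nTags = vapply(rows, `[[`, numeric(1), "nTags"),
             defined = vapply(rows, `[[`, logical(1), "defined"),
             row.names = NULL)
}

#' Average per-promoter DI across samples
#'
#' Sample-specific DIs are averaged (over samples where the DI is defined)
#' into one robust DI per promoter.
#'
#' @param diTables List of data.frames from [promoterDispersion()], one per
#'   sample, all covering the same promoters in the same order.
#' @return A data.frame with columns \code{id}, \code{di} (mean of defined
#'   sample DIs, \code{NA} if none), \code{nSamples}.
#' @export
averageDispersion <- function(diTables) {
  stopifnot(length(diTables) >= 1L)
  ids <- diTables[[1L]]$id
  dis <- vapply(diTables, function(d) {
    stopifnot(identical(d$id, ids))
    ifelse(d$defined, d$di, NA_real_)
  }, numeric(length(ids)))
  dis <- matrix(dis, nrow = length(ids))
  nS <- rowSums(!is.na(dis))
  data.frame(id = ids,
             di = ifelse(nS > 0, rowMeans(dis, na.rm = TRUE), NA_real_),
             nSamples = nS, row.names = NULL)
}
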