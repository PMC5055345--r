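## Dinucleotide indicator tracks and sliding-window spectral scoring.
##
## The rotational-positioning score of a window is the squared modulus of
## the direct discrete Fourier sum of the mean-removed binary track,
## evaluated at exactly the target frequency (default 0.097 cycles/bp,
## period 10.3 bp) and normalised by window length:
##
##   P(f) = | sum_n (x_n - mean(x)) * exp(-2*pi*i*f*n) |^2 / L
##
## f = 0.097 is not a Fourier bin of a 150-bp window (bins are k/150), so
## the sum is evaluated directly rather than read off an FFT grid; mean
## removal makes composition-only (constant) windows score exactly 0, so
## the score measures periodicity, not dinucleotide abundance.

.DINUC_CLASS <- list(
  WW = c("A", "T"), SS = c("C", "G"),
  YY = c("C", "T"), RR = c("A", "G"))

#' Dinucleotide indicator track
#'
#' Converts a DNA sequence of length L into a binary series of length L-1
#' where position i is 1 iff bases i and i+1 both belong to the IUPAC
#' dinucleotide class: WW (W = A/T), SS (S = C/G), YY (Y = C/T) or
#' RR (R = A/G).  Any dinucleotide containing a literal N scores 0.
#'
#' @param seq A \code{DNAString}, \code{character(1)} sequence, or a
#'   \code{DNAStringSet}/character vector (a list of tracks is returned).
#' @param code One of \code{"WW"}, \code{"SS"}, \code{"YY"}, \code{"RR"}.
#' @return Integer 0/1 vector of length \code{nchar(seq) - 1}, with a
#'   logical attribute \code{"hasN"} flagging dinucleotides touching an N
#'   (used for window-level N filtering); or a list of such vectors.
#' @examples
#' dinucleotideTrack("AATT", "WW")  # 1 1 1
#' dinucleotideTrack("ACGT", "SS")  # 0 1 0
#' @export
dinucleotideTrack <- function(seq, code = c("WW", "SS", "YY", "RR")) {
  code <- match.arg(code)
  if (is(seq, "DNAStringSet") || (is.character(seq) && length(seq) > 1L))
    return(lapply(as.character(seq), dinucleotideTrack, code = code))
  s <- toupper(as.character(seq))
  L <- nchar(s)
  if (L < 2L) stop("sequence must have length >= 2")
  ch <- strsplit(s, "")[[1L]]
  bad <- !ch %in% c("A", "C", "G", "T", "N")
  if (any(bad))
    stop("sequence alphabet must be {A,C,G,T,N}; saw: ",
         paste(unique(ch[bad]), collapse = ","))
  inClass <- ch %in% .DINUC_CLASS[[code]]
  track <- as.integer(inClass[-L] & inClass[-1L])
  isN <- ch == "N"
  attr(track, "hasN") <- isN[-L] | isN[-1L]
  track
}

#' Spectral power at a single frequency
#'
#' Evaluates the discrete Fourier sum of the mean-removed series directly at
#' frequency \code{f} (no FFT grid, no padding):
#' \code{|sum((x - mean(x)) * exp(-2i*pi*f*(0:(L-1))))|^2 / L}.
#'
#' @param x Numeric series (typically a binary dinucleotide track window).
#' @param f Target frequency in cycles/bp, \code{0 < f < 0.5}.
#' @return Non-negative scalar; 0 for a constant series.
#' @export
powerAtFrequency <- function(x, f = 0.097) {
  L <- length(x)
  if (L < 2L) stop("series must have length >= 2")
  stopifnot(f > 0, f < 0.5)
  xc <- x - mean(x)
  ph <- 2 * pi * f * (seq_len(L) - 1L)
  (sum(xc * cos(ph))^2 + sum(xc * sin(ph))^2) / L
}

## All sliding-window powers of one track at one frequency, vectorised:
## rows of W are mean-removed windows, powers come from two matrix products.
.slidingPowers <- function(track, window, shift, f) {
  L <- length(track)
  nw <- (L - window) %/% shift + 1L
  starts <- (seq_len(nw) - 1L) * shift
  idx <- outer(starts, seq_len(window), "+")      # nw x window indices
  W <- matrix(track[idx], nrow = nw)
  W <- W - rowMeans(W)
  ph <- 2 * pi * f * (seq_len(window) - 1L)
  ((W %*% cos(ph))^2 + (W %*% sin(ph))^2)[, 1L] / window
}

#' Sliding-window periodicity profile
#'
#' Scans a dinucleotide track with a sliding window and reports the spectral
#' power at the target frequency in every window.
#'
#' @param track Binary track from [dinucleotideTrack()] (its \code{"hasN"}
#'   attribute, when present, drives N filtering).
#' @param window Window size in bp (default 150).
#' @param shift Window shift in bp (default 10).
#' @param frequency Target frequency in cycles/bp (default 0.097, i.e. a
#'   10.3-bp period).
#' @param trackStart TSS-relative offset of the first track position
#'   (default -1074, matching a scan of the \code{[-1074, 1076)} promoter
#'   window); window centers are reported at \code{start + window/2}.
#' @param maxNFraction Windows in which more than this fraction of
#'   dinucleotides touch an N are reported as \code{NA} with a warning.
#' @param code Dinucleotide code label stored in the result.
#' @return A [PeriodicityProfile-class] with
#'   \code{floor((length(track) - window)/shift) + 1} windows.
#' @export
periodicityProfile <- function(track, window = 150L, shift = 10L,
                               frequency = 0.097, trackStart = -1074L,
                               maxNFraction = 0.1, code = "") {
  L <- length(track)
  if (L < window)
    stop("track (", L, ") is shorter than the scan window (", window, ")")
  powers <- .slidingPowers(as.numeric(track), window, shift, frequency)
  nw <- length(powers)
  centers <- trackStart + (seq_len(nw) - 1L) * shift + window %/% 2L
  hasN <- attr(track, "hasN")
  if (!is.null(hasN) && any(hasN)) {
    starts <- (seq_len(nw) - 1L) * shift
    nfrac <- vapply(starts, function(s)
      mean(hasN[(s + 1L):(s + window)]), numeric(1))
    if (any(nfrac > maxNFraction)) {
      warning(sum(nfrac > maxNFraction),
              " window(s) skipped: >", maxNFraction * 100, "% ambiguous bases")
      powers[nfrac > maxNFraction] <- NA_real_
    }
  }
  new("PeriodicityProfile", powers = powers, centers = as.numeric(centers),
      windowSize = as.integer(window), shift = as.integer(shift),
      frequency = frequency, code = code)
}

#' Accessors for PeriodicityProfile
#' @param x A [PeriodicityProfile-class].
#' @return Numeric vectors.
#' @name profile-accessors
NULL

#' @rdname profile-accessors
#' @export
profilePowers <- function(x) x@powers

#' @rdname profile-accessors
#' @export
profileCenters <- function(x) x@centers

#' Periodogram scan over a range of periods
#'
#' Evaluates the sliding-window power at \code{f = 1/p} for each requested
#' period p, yielding a period x window matrix (the per-promoter analogue of
#' a spectrogram on the TSS-relative axis).
#'
#' @inheritParams periodicityProfile
#' @param periods Numeric vector of periods in bp (default \code{2:20}).
#' @return Numeric matrix (periods x windows); rownames are periods,
#'   colnames window centers.
#' @export
periodogramScan <- function(track, window = 150L, shift = 10L,
                            periods = 2:20, trackStart = -1074L) {
  out <- t(vapply(periods, function(p)
    profilePowers(periodicityProfile(track, window = window, shift = shift,
                                     frequency = 1 / p,
                                     trackStart = trackStart)),
    numeric((length(track) - window) %/% shift + 1L)))
  nw <- ncol(out)
  dimnames(out) <- list(periods,
                        trackStart + (seq_len(nw) - 1L) * shift + window %/% 2L)
  out
}

#' Per-promoter periodicity matrix
#'
#' Convenience wrapper: builds the dinucleotide track of each sequence and
#' stacks the sliding-window power profiles into a promoters x windows
#' matrix.
#'
#' @param seqs A \code{DNAStringSet} (or character vector) of TSS-aligned
#'   sequences, all the same length.
#' @inheritParams periodicityProfile
#' @param code Dinucleotide code.
#' @return Numeric matrix with one row per sequence; colnames are window
#'   centers on the TSS-relative axis.
#' @export
periodicityMatrix <- function(seqs, code = "WW", window = 150L, shift = 10L,
                              frequency = 0.097, trackStart = -1074L) {
  seqs <- as.character(seqs)
  stopifnot(length(unique(nchar(seqs))) == 1L)
  nw <- (nchar(seqs[1L]) - 1L - window) %/% shift + 1L
  out <- t(vapply(seqs, function(s)
    profilePowers(periodicityProfile(dinucleotideTrack(s, code),
                                     window = window, shift = shift,
                                     frequency = frequency,
                                     trackStart = trackStart)),
    numeric(nw)))
  colnames(out) <- trackStart + (seq_len(nw) - 1L) * shift + window %/% 2L
  out
}

#' Concordant-signal call
#'
#' A promoter shows a "concordant" rotational signal when its periodicity is
#' stronger over the +1 nucleosome region than over the nucleosome-free
#' region upstream of the TSS: the call is \code{TRUE} iff the mean power of
#' windows centered in \code{n1} strictly exceeds the mean power of windows
#' centered in \code{nfr}.
#'
#' @param profile A [PeriodicityProfile-class].
#' @param nfr Half-open TSS-relative window of the nucleosome-free region
#'   (default \code{c(-150, 0)}).
#' @param n1 Half-open TSS-relative window of the +1 nucleosome region
#'   (default \code{c(50, 200)}, the consensus-motif scoring region).
#' @return Logical scalar.
#' @export
concordanceCall <- function(profile, nfr = c(-150, 0), n1 = c(50, 200)) {
  centers <- profileCenters(profile)
  powers <- profilePowers(profile)
  inNfr <- centers >= nfr[1L] & centers < nfr[2L]
  inN1 <- centers >= n1[1L] & centers < n1[2L]
  if (!any(inNfr))
    stop("no window centers fall in the NFR region [",
         nfr[1L], ",", nfr[2L], ")")
  if (!any(inN1))
    stop("no window centers fall in the N+1 region [",
         n1[1L], ",", n1[2L], ")")
  mean(powers[inN1], na.rm = TRUE) > mean(powers[inNfr], na.rm = TRUE)
}
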