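## Seeded synthetic-data generator.  Emulates the statistical structure the
## analysis assumes: promoter sequences with a 10-bp periodic dinucleotide
## signal planted in the +1 nucleosome region, 147-bp MNase fragments
## jittered around a planted dyad, CAGE tag piles with a dominant TSS and
## 10-bp-phased (or dispersed) secondary starts, and homozygous SNP/indel
## edits whose effect on initiation dispersion is coupled to the change in
## rotational-positioning power they cause.
##
## One global seed fans out to independent per-promoter streams (a fixed
## hash of seed, promoter index and purpose), so any subset of promoters is
## reproducible irrespective of cohort size.

#' Synthetic-cohort configuration
#'
#' @param seed Global integer seed.
#' @param nPromoters Number of promoters (each on its own chromosome).
#' @param chromLength Chromosome length in bp (default 10000, TSS centered).
#' @param background Base composition of the background sequence (A,C,G,T).
#' @param amplitude Planting mixing weight a in [0,1]: the probability that
#'   each periodic slot in the +1 region carries the planted dinucleotide.
#' @param code Planted dinucleotide code ("WW", "SS", "YY" or "RR").
#' @param dnaPeriod Period (bp) of the planted dinucleotide signal; default
#'   10.3, the helical repeat of nucleosomal DNA (slots are placed at
#'   \code{round(phase + k * dnaPeriod)}).
#' @param period Spacing (bp) of secondary initiation sites (default 10).
#' @param phase Phase offset of the planted slots inside the window.
#' @param plantWindow Half-open TSS-relative window carrying the periodic
#'   signal (default \code{c(50, 200)}, the +1 nucleosome).
#' @param minusFraction Fraction of promoters annotated on the minus strand.
#' @param dyadOffset Planted +1 dyad position (TSS-relative, default +120).
#' @param fragmentJitter SD (bp) of rotational fragment-center displacement
#'   around the dyad (quantised to whole periods).
#' @param residualJitter SD (bp) of the base-level residual imprecision of
#'   fragment centers (MNase cut-site wobble; default 1).
#' @param fragmentDepth Expected fragments per promoter (Poisson).
#' @param tagDepth Expected CAGE tags per promoter (Poisson).
#' @param sigma Initiation spread (bp): SD of tag positions in dispersed
#'   mode; population DI tracks sigma^2.
#' @param periodicInitiation If \code{TRUE}, secondary starts sit at exact
#'   multiples of \code{period} from the TSS with geometrically decaying
#'   weights; otherwise tags scatter uniformly with SD \code{sigma}.
#' @param dominantWeight Weight of the dominant TSS in periodic mode.
#' @param secondaryDecay Geometric decay of secondary-site weights.
#' @param secondaryMax Number of secondary sites on each side.
#' @param cageWindow Half-open relative window of the emitted tag profiles.
#' @param variantWindow Window in which variants are planted.
#' @param pSNP,pIndel Per-promoter probabilities of one planted SNP/indel.
#' @param coupling k in the planted relation
#'   \code{deltaDI = -k * deltaPower + noise} (bp^2 per power unit).
#' @param couplingNoise SD of the noise term (bp^2).
#' @return A list of class \code{"simConfig"}.
#' @export
simConfig <- function(seed = 1L, nPromoters = 200L, chromLength = 10000L,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                      amplitude = 0.8, code = "WW", dnaPeriod = 10.3,
                      period = 10L, phase = 0L,
                      plantWindow = c(50L, 200L),
                      minusFraction = 0.5, dyadOffset = 120L,
                      fragmentJitter = 10, residualJitter = 1,
                      fragmentDepth = 50,
                      tagDepth = 1000, sigma = 5,
                      periodicInitiation = FALSE, dominantWeight = 0.5,
                      secondaryDecay = 0.6, secondaryMax = 3L,
                      cageWindow = c(-103L, 105L),
                      variantWindow = c(50L, 200L), pSNP = 0.5,
                      pIndel = 0.25, coupling = 30, couplingNoise = 1) {
  stopifnot(amplitude >= 0, amplitude <= 1, sigma >= 0, fragmentJitter >= 0,
            tagDepth >= 0, fragmentDepth >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "simConfig"
  cfg
}

## deterministic per-(promoter, purpose) stream seed below 2^31
.streamSeed <- function(seed, i, what) {
  salt <- c(seq = 11L, frag = 23L, cage = 37L, cageAlt = 41L, var = 53L)
  as.integer((as.numeric(seed) * 48271 + i * 7919 + salt[[what]] * 104729) %%
               2147483647)
}

#' Simulate a promoter cohort
#'
#' Generates one chromosome per promoter (TSS at the center, strand
#' alternating per \code{minusFraction}) with i.i.d. background bases and,
#' inside the planted window, the periodic dinucleotide planted with
#' probability \code{amplitude} at every \code{period}-spaced slot.
#'
#' @param cfg A [simConfig()].
#' @param amplitude Optional per-promoter amplitude vector overriding
#'   \code{cfg$amplitude} (recycled).
#' @return A list with \code{genome} (named \code{DNAStringSet}),
#'   \code{promoters} ([PromoterSet-class]) and \code{truth} (data.frame:
#'   id, chrom, tss, strand, amplitude, phase, windowStart, windowEnd).
#' @export
simulateCohort <- function(cfg, amplitude = NULL) {
  n <- cfg$nPromoters
  a <- rep(if (is.null(amplitude)) cfg$amplitude else amplitude,
           length.out = n)
  tss <- cfg$chromLength %/% 2L
  ## low-discrepancy per-index rule: strand of promoter i never depends on n
  strands <- ifelse((seq_len(n) * 0.6180339887498949) %% 1 <
                      cfg$minusFraction, "-", "+")
  seqs <- character(n)
  for (i in seq_len(n))
    seqs[i] <- .simulateSequence(cfg, i, a[i], tss, strands[i])
  genome <- DNAStringSet(seqs)
  names(genome) <- sprintf("chr%d", seq_len(n))
  promoters <- PromoterSet(chrom = names(genome), tss = rep(tss, n),
                           strand = strands, id = sprintf("p%d", seq_len(n)))
  truth <- data.frame(id = promoterIds(promoters), chrom = names(genome),
                      tss = tss, strand = strands, amplitude = a,
                      phase = cfg$phase, windowStart = cfg$plantWindow[1L],
                      windowEnd = cfg$plantWindow[2L])
  list(genome = genome, promoters = promoters, truth = truth)
}

.simulateSequence <- function(cfg, i, a, tss, strand) {
  set.seed(.streamSeed(cfg$seed, i, "seq"))
  L <- cfg$chromLength
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                  prob = cfg$background)
  if (a > 0) {
    letters2 <- .DINUC_CLASS[[cfg$code]]
    k <- 0:floor((cfg$plantWindow[2L] - 2L - cfg$plantWindow[1L] -
                    cfg$phase) / cfg$dnaPeriod)
    slots <- round(cfg$plantWindow[1L] + cfg$phase + k * cfg$dnaPeriod)
    plant <- stats::runif(length(slots)) < a
    for (s in slots[plant]) {
      g <- if (strand == "+") tss + s else tss - s - 1L
      pair <- sample(letters2, 2L, replace = TRUE)
      if (strand == "-") pair <- rev(chartr("ACGT", "TGCA", pair))
      bases[g + 1L] <- pair[1L]
      bases[g + 2L] <- pair[2L]
    }
  }
  paste(bases, collapse = "")
}

#' Simulate MNase fragments around the planted dyad
#'
#' Fragment centers scatter around the planted dyad with Normal(0, jitter)
#' displacements quantised to multiples of the initiation period (rotational
#' positioning: the nucleosome tolerates shifts by whole helical turns, so
#' the aggregate keeps its 10-bp phase), plus a 1-2 bp residual cut-site
#' wobble.  Every fragment is exactly 147 bp; the per-promoter count is
#' Poisson(fragmentDepth).
#'
#' @param cfg A [simConfig()].
#' @param cohort Output of [simulateCohort()].
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open).
#' @export
simulateFragments <- function(cfg, cohort) {
  tr <- cohort$truth
  out <- vector("list", nrow(tr))
  for (i in seq_len(nrow(tr))) {
    set.seed(.streamSeed(cfg$seed, i, "frag"))
    k <- stats::rpois(1L, cfg$fragmentDepth)
    if (k == 0L) { out[[i]] <- NULL; next }
    dyadG <- if (tr$strand[i] == "+") tr$tss[i] + cfg$dyadOffset
             else tr$tss[i] - cfg$dyadOffset
    ## rotational positioning: nucleosomes tolerate shifts by multiples of
    ## the helical period, so dyad jitter is quantised to period steps
    centers <- dyadG + round(stats::rnorm(k, 0, cfg$fragmentJitter) /
                               cfg$period) * cfg$period +
               round(stats::rnorm(k, 0, cfg$residualJitter))
    out[[i]] <- data.frame(chrom = tr$chrom[i],
                           start = centers - (NUCLEOSOME_BP - 1L) %/% 2L,
                           end = centers - (NUCLEOSOME_BP - 1L) %/% 2L +
                                 NUCLEOSOME_BP)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), start = integer(),
                      end = integer())
  res
}

#' Simulate CAGE tag profiles
#'
#' In periodic mode the dominant TSS carries \code{dominantWeight} of the
#' tags and secondary sites at +/- period, 2*period, ... carry geometrically
#' decaying weights, emulating 10-bp-phased secondary initiation.  In
#' dispersed mode (broad promoters, no dominant site) tag positions are
#' uniformly jittered with spread matched to \code{sigma}, so the population
#' DI of a promoter tracks sigma^2 with no 10-bp phase.  Per-promoter totals
#' are Poisson(tagDepth); per-site counts multinomial.
#'
#' @param cfg A [simConfig()].
#' @param cohort Output of [simulateCohort()].
#' @param sigma Optional per-promoter spread overriding \code{cfg$sigma}.
#' @param stream Internal: which tag stream to draw ("cage" or "cageAlt"
#'   for an independent second condition).
#' @return Promoters x positions count matrix over \code{cfg$cageWindow}
#'   (colnames are TSS-relative offsets, rownames promoter ids).
#' @export
simulateCage <- function(cfg, cohort, sigma = NULL, stream = "cage") {
  n <- length(cohort$promoters)
  sg <- rep(if (is.null(sigma)) cfg$sigma else sigma, length.out = n)
  win <- cfg$cageWindow
  npos <- win[2L] - win[1L]
  out <- matrix(0L, nrow = n, ncol = npos,
                dimnames = list(promoterIds(cohort$promoters),
                                win[1L]:(win[2L] - 1L)))
  for (i in seq_len(n)) {
    set.seed(.streamSeed(cfg$seed, i, stream))
    total <- stats::rpois(1L, cfg$tagDepth)
    if (total == 0L) next
    if (cfg$periodicInitiation) {
      k <- c(0L, rep(seq_len(cfg$secondaryMax), each = 2L) *
                 c(1L, -1L))
      sites <- k * cfg$period
      wts <- c(cfg$dominantWeight,
               rep(cfg$secondaryDecay^(rep(seq_len(cfg$secondaryMax),
                                           each = 2L) - 1L), 1L) *
                 (1 - cfg$dominantWeight) / 2)
      wts <- wts / sum(wts)
      cnt <- stats::rmultinom(1L, total, wts)[, 1L]
      pos <- sites
    } else {
      h <- sg[i] * sqrt(3)       # U(-h, h) has variance sigma^2
      draws <- round(stats::runif(total, -h, h))
      tab <- table(draws)
      pos <- as.integer(names(tab)); cnt <- as.integer(tab)
    }
    keep <- pos >= win[1L] & pos < win[2L]
    idx <- pos[keep] - win[1L] + 1L
    out[i, idx] <- out[i, idx] + cnt[keep]
  }
  out
}

#' Simulate homozygous variants with a coupled dispersion effect
#'
#' Plants at most one SNP and one indel per promoter inside
#' \code{variantWindow} (non-overlapping by construction), always homozygous
#' for a minor allele (population frequency of the sample allele < 0.5, so
#' every planted variant differs from the most-likely genome).  After
#' patching, the change in planted-window periodicity power determines the
#' promoter's sample-condition spread through the planted coupling
#' \code{deltaDI_target = -coupling * deltaPower + noise}.
#'
#' @param cfg A [simConfig()].
#' @param cohort Output of [simulateCohort()].
#' @return A list with \code{variants} (variant table with af/zygosity),
#'   \code{patchedGenomes} (named list of \code{patchedSequence} per chrom),
#'   \code{sigmaRef} and \code{sigmaSample} (per-promoter spreads), and
#'   \code{deltaPowerTrue} (the generator's own planted-window power change).
#' @export
simulateVariants <- function(cfg, cohort) {
  tr <- cohort$truth
  n <- nrow(tr)
  half <- 75L
  centerRel <- (cfg$plantWindow[1L] + cfg$plantWindow[2L]) %/% 2L
  sigmaRef <- rep(cfg$sigma, n)
  sigmaSample <- sigmaRef
  deltaPowerTrue <- numeric(n)
  variants <- vector("list", n)
  patched <- vector("list", n)
  names(patched) <- tr$chrom
  for (i in seq_len(n)) {
    set.seed(.streamSeed(cfg$seed, i, "var"))
    s <- as.character(cohort$genome[[tr$chrom[i]]])
    v <- .plantVariants(cfg, tr[i, ], s)
    variants[[i]] <- v
    pobj <- applyVariants(s, v)
    patched[[i]] <- pobj
    if (nrow(v)) {
      gLo <- if (tr$strand[i] == "+") tr$tss[i] + centerRel - half
             else tr$tss[i] - centerRel - half
      refWin <- substring(s, gLo + 1L, gLo + 2L * half)
      pLo <- mapToPatched(pobj, gLo + half) - half
      patWin <- substring(pobj$seq, pLo + 1L, pLo + 2L * half)
      if (tr$strand[i] == "-") {
        refWin <- as.character(reverseComplement(DNAString(refWin)))
        patWin <- as.character(reverseComplement(DNAString(patWin)))
      }
      dp <- powerAtFrequency(dinucleotideTrack(patWin, cfg$code)) -
            powerAtFrequency(dinucleotideTrack(refWin, cfg$code))
      deltaPowerTrue[i] <- dp
      dDI <- -cfg$coupling * dp + stats::rnorm(1L, 0, cfg$couplingNoise)
      sigmaSample[i] <- sqrt(max(sigmaRef[i]^2 + dDI, 0.25))
    }
  }
  list(variants = do.call(rbind, variants), patchedGenomes = patched,
       sigmaRef = sigmaRef, sigmaSample = sigmaSample,
       deltaPowerTrue = deltaPowerTrue)
}

.plantVariants <- function(cfg, trow, s) {
  rel2g <- function(r) if (trow$strand == "+") trow$tss + r
                       else trow$tss - r
  rows <- list()
  win <- cfg$variantWindow
  if (stats::runif(1L) < cfg$pSNP) {
    r <- sample(win[1L]:(win[2L] - 1L), 1L)
    g <- rel2g(r)
    ref <- substring(s, g + 1L, g + 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    rows <- c(rows, list(data.frame(chrom = trow$chrom, pos = g, ref = ref,
                                    alt = alt, kind = "SNP")))
  }
  if (stats::runif(1L) < cfg$pIndel) {
    for (try in 1:20) {       # rejection sampling: no overlap with the SNP
      r <- sample(win[1L]:(win[2L] - 5L), 1L)
      g <- rel2g(r)
      gLo <- min(g, rel2g(r + 3L)); gHi <- max(g, rel2g(r + 3L))
      clash <- length(rows) &&
        any(vapply(rows, function(v)
          v$pos + nchar(v$ref) > gLo - 1L & v$pos <= gHi + 1L, logical(1)))
      if (clash) next
      if (stats::runif(1L) < 0.5) {     # deletion of 1-3 bases
        len <- sample(1:3, 1L)
        ref <- substring(s, gLo + 1L, gLo + 1L + len)
        alt <- substring(ref, 1L, 1L)
      } else {                          # insertion of 1-3 bases
        ref <- substring(s, gLo + 1L, gLo + 1L)
        alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"),
                                        sample(1:3, 1L), replace = TRUE),
                                 collapse = ""))
      }
      rows <- c(rows, list(data.frame(chrom = trow$chrom, pos = gLo,
                                      ref = ref, alt = alt,
                                      kind = "indel")))
      break
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      kind = character(), af = numeric(),
                      zygosity = character()))
  out <- do.call(rbind, rows)
  out$af <- stats::runif(nrow(out), 0.05, 0.45)  # sample allele is minor
  out$zygosity <- "hom"
  out
}
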