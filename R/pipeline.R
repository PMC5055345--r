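## End-to-end analyses over a cohort: rotational-signal vs nucleosome-map
## concordance (heatmap ordering, concordant-signal strata), DI binning and
## regression with micro-peak aggregates, and the variant delta-DI /
## delta-power scan.  Each run can write its TSV outputs plus a manifest
## (config + seed + versions) sufficient to reproduce them byte-identically.

.writeTSV <- function(df, outDir, name) {
  if (is.null(outDir)) return(invisible(NULL))
  utils::write.table(df, file.path(outDir, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

.writeManifest <- function(outDir, cfg, extra = list()) {
  if (is.null(outDir)) return(invisible(NULL))
  m <- c(list(package = "nucphase",
              version = as.character(utils::packageVersion("nucphase")),
              rversion = paste(R.version$major, R.version$minor, sep = "."),
              config = unclass(cfg)),
         extra)
  jsonlite::write_json(m, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Fragment 5'-end tags from a fragment table
#'
#' MNase read 5' ends: the plus-strand tag at the fragment start and the
#' minus-strand tag at its last base.
#'
#' @param fragments data.frame with \code{chrom,start,end} (0-based
#'   half-open).
#' @return data.frame with \code{chrom,pos,strand}.
#' @export
fragmentTags <- function(fragments) {
  data.frame(chrom = rep(fragments$chrom, 2L),
             pos = c(fragments$start, fragments$end - 1L),
             strand = rep(c("+", "-"), each = nrow(fragments)))
}

#' Rotational-signal / nucleosome-map concordance analysis
#'
#' For every promoter: the sliding-window periodicity profile of the
#' ordering dinucleotide over \code{[-1074, 1076)}, the smoothed per-promoter
#' nucleosome profile from MNase tags, the Pearson correlation between the
#' two over +/-1 kb, and the number of dinucleotide codes (0-4) whose
#' periodicity calls the promoter "concordant" (stronger over the +1
#' nucleosome than over the NFR).  Promoters are ordered by decreasing
#' correlation and the periodicity heatmap is averaged in blocks of
#' \code{blockSize} rows; aggregate nucleosome profiles are reported per
#' concordance stratum.
#'
#' @param cohort List with \code{genome} and \code{promoters} (e.g. from
#'   [simulateCohort()]).
#' @param fragments 147-bp fragment table (e.g. from [simulateFragments()]).
#' @param codes Dinucleotide codes for the concordance count.
#' @param orderCode Code used for the heatmap and ordering (default WW).
#' @param scanWindow Relative sequence window scanned (default
#'   \code{c(-1074, 1076)}: 2150 bp, giving 200 windows of 150 bp at shift
#'   10).
#' @param nfr,n1 Concordance regions (see [concordanceCall()]).
#' @param blockSize Rows averaged per heatmap block (default 10).
#' @param centering,bin Aggregation parameters (see [aggregateProfile()]).
#' @param outDir Optional output directory for TSVs + manifest.
#' @param cfg Optional [simConfig()] recorded in the manifest.
#' @return A list: \code{order} (data.frame id, correlation, concordant
#'   count, rank), \code{heatmap} (block x window matrix), \code{strata}
#'   (data.frame offset x stratum mean occupancy), \code{profiles}
#'   (promoters x windows periodicity matrix).
#' @export
runConcordanceAnalysis <- function(cohort, fragments,
                                   codes = c("WW", "SS", "YY", "RR"),
                                   orderCode = "WW",
                                   scanWindow = c(-1074L, 1076L),
                                   nfr = c(-150, 0), n1 = c(50, 200),
                                   blockSize = 10L, centering = 70L,
                                   bin = 10L, outDir = NULL, cfg = NULL) {
  promoters <- cohort$promoters
  seqs <- extractWindow(cohort$genome, promoters, scanWindow,
                        drop.out.of.bounds = TRUE)
  if (length(seqs) < length(promoters)) {
    message(length(promoters) - length(seqs),
            " promoter(s) excluded: scan window out of bounds")
    promoters <- promoters[match(names(seqs), promoterIds(promoters))]
  }
  pmats <- lapply(codes, function(cd)
    periodicityMatrix(seqs, code = cd, trackStart = scanWindow[1L]))
  names(pmats) <- codes
  ordMat <- pmats[[orderCode]]
  centers <- as.numeric(colnames(ordMat))
  tags <- fragmentTags(fragments)
  span <- c(-1000L, 1001L)
  n <- length(promoters)
  nucProfiles <- matrix(NA_real_, n, span[2L] - span[1L])
  for (i in seq_len(n))
    nucProfiles[i, ] <- aggregateProfile(tags, promoters[i], span = span,
                                         centering = centering,
                                         bin = bin)$smoothed
  colIdx <- centers - span[1L] + 1L
  ok <- colIdx >= 1L & colIdx <= ncol(nucProfiles)
  correlation <- vapply(seq_len(n), function(i)
    suppressWarnings(stats::cor(ordMat[i, ok], nucProfiles[i, colIdx[ok]],
                                use = "complete.obs")),
    numeric(1))
  concordant <- rowSums(vapply(codes, function(cd)
    vapply(seq_len(n), function(i)
      concordanceCall(new("PeriodicityProfile",
                          powers = pmats[[cd]][i, ], centers = centers,
                          windowSize = 150L, shift = 10L,
                          frequency = 0.097, code = cd),
                      nfr = nfr, n1 = n1), logical(1)),
    logical(n)))
  o <- order(-correlation)
  ord <- data.frame(id = promoterIds(promoters)[o],
                    correlation = correlation[o],
                    concordant = concordant[o],
                    rank = seq_len(n))
  ## heatmap: correlation-ordered periodicity rows averaged in blocks
  blk <- rep(seq_len(ceiling(n / blockSize)), each = blockSize)[seq_len(n)]
  heatmap <- rowsum(ordMat[o, , drop = FALSE], blk) /
             as.vector(table(blk))
  rownames(heatmap) <- paste0("block", seq_len(nrow(heatmap)))
  ## aggregate nucleosome occupancy per concordance stratum
  offs <- span[1L]:(span[2L] - 1L)
  strata <- data.frame(offset = offs)
  for (s in sort(unique(concordant))) {
    sel <- concordant == s
    strata[[paste0("stratum", s)]] <- colMeans(nucProfiles[sel, ,
                                                           drop = FALSE])
  }
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    .writeTSV(ord, outDir, "concordance_order.tsv")
    .writeTSV(data.frame(block = rownames(heatmap),
                         round(heatmap, 10)), outDir,
              "periodicity_heatmap.tsv")
    .writeTSV(strata, outDir, "nucleosome_strata.tsv")
    .writeManifest(outDir, cfg, list(analysis = "concordance"))
  }
  list(order = ord, heatmap = heatmap, strata = strata, profiles = ordMat)
}

#' DI binning, periodicity regression and micro-peak aggregates
#'
#' Computes per-promoter DI from tag profiles, the mean N+1 periodicity
#' power across the four dinucleotides, DI-ordered bins with the power-on-DI
#' regression (CPE-labelled promoters in their own bins), micro-peak
#' cumulative frequencies, and the cosine-covariance ranking of phased
#' initiation.
#'
#' @param cohort List with \code{genome} and \code{promoters}.
#' @param profiles Promoters x positions CAGE count matrix (colnames are
#'   TSS-relative offsets), e.g. from [simulateCage()] or [tagProfiles()].
#' @param binSize Promoters per DI bin.
#' @param group Optional per-promoter CPE label (own bins; see
#'   [binByDispersion()]).
#' @param n1 Relative window of the +1 nucleosome (power averaging).
#' @param codes Dinucleotide codes averaged for the N+1 power.
#' @param minTags Micro-peak qualification threshold (tags per 5-bp window).
#' @param diWindow DI window (default \code{c(-50, 50)}).
#' @param scanWindow Sequence window for periodicity (default
#'   \code{c(-1074, 1076)}).
#' @param outDir,cfg See [runConcordanceAnalysis()].
#' @return A list: \code{di} (per-promoter DI table), \code{n1power},
#'   \code{bins}, \code{fit}, \code{micropeaks} (per-base frequency),
#'   \code{phasing} (cosine-covariance ranking).
#' @export
runDispersionAnalysis <- function(cohort, profiles, binSize = 20L,
                                  group = NULL, n1 = c(50, 200),
                                  codes = c("WW", "SS", "YY", "RR"),
                                  minTags = 100, diWindow = c(-50L, 50L),
                                  scanWindow = c(-1074L, 1076L),
                                  outDir = NULL, cfg = NULL) {
  promoters <- cohort$promoters
  di <- promoterDispersion(profiles, window = diWindow)
  seqs <- extractWindow(cohort$genome, promoters, scanWindow,
                        drop.out.of.bounds = TRUE)
  pmats <- lapply(codes, function(cd)
    periodicityMatrix(seqs, code = cd, trackStart = scanWindow[1L]))
  centers <- as.numeric(colnames(pmats[[1L]]))
  inN1 <- centers >= n1[1L] & centers < n1[2L]
  n1power <- Reduce(`+`, lapply(pmats, function(m)
    rowMeans(m[, inN1, drop = FALSE]))) / length(codes)
  ok <- di$defined
  bd <- binByDispersion(di$di[ok], n1power[ok], binSize = binSize,
                        group = if (is.null(group)) NULL else group[ok])
  marks <- t(apply(profiles, 1L, microPeaks, minTags = minTags))
  colnames(marks) <- colnames(profiles)
  mpFreq <- colMeans(marks)
  phasing <- rankByCosineCovariance(marks)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    .writeTSV(cbind(di, n1power = n1power), outDir, "dispersion_index.tsv")
    .writeTSV(bd$bins, outDir, "di_bins.tsv")
    if (!is.null(bd$fit))
      .writeTSV(data.frame(slope = bd$fit$slope,
                           intercept = bd$fit$intercept, r2 = bd$fit$r2,
                           p = bd$fit$p), outDir, "di_regression.tsv")
    .writeTSV(data.frame(offset = as.numeric(names(mpFreq)),
                         frequency = mpFreq), outDir,
              "micropeak_frequency.tsv")
    .writeTSV(phasing, outDir, "phasing_rank.tsv")
    .writeManifest(outDir, cfg, list(analysis = "dispersion"))
  }
  list(di = di, n1power = n1power, bins = bd$bins, fit = bd$fit,
       micropeaks = mpFreq, phasing = phasing)
}

#' Variant effect analysis on initiation dispersion
#'
#' Given reference- and sample-condition tag profiles and the sample's
#' variants, computes per-promoter delta-DI (sample minus reference), the
#' mean delta-DI per sliding variant-position window (SNPs and indels
#' separately), and the per-window regression of delta-DI on the variant's
#' delta-periodicity.
#'
#' @param cohort List with \code{genome} and \code{promoters}.
#' @param profilesRef,profilesSample CAGE count matrices for the two
#'   conditions.
#' @param variants Variant table (chrom, pos, ref, alt, kind).
#' @param patchedGenomes Named list of \code{patchedSequence} per chrom.
#' @param span Relative scan region (default \code{c(-1000, 1001)}).
#' @param windowSize,shift Scan geometry (150/10).
#' @param code,frequency Periodicity settings for delta-power.
#' @param diWindow DI window.
#' @param outDir,cfg See [runConcordanceAnalysis()].
#' @return A list: \code{deltaDI} (named vector), \code{byWindowSNP},
#'   \code{byWindowIndel} (delta-DI scans), \code{regression} (delta-power
#'   vs delta-DI window regressions).
#' @export
runVariantAnalysis <- function(cohort, profilesRef, profilesSample,
                               variants, patchedGenomes,
                               span = c(-1000L, 1001L), windowSize = 150L,
                               shift = 10L, code = "WW", frequency = 0.097,
                               diWindow = c(-50L, 50L), outDir = NULL,
                               cfg = NULL) {
  promoters <- cohort$promoters
  diRef <- promoterDispersion(profilesRef, window = diWindow)
  diSam <- promoterDispersion(profilesSample, window = diWindow)
  deltaDI <- ifelse(diRef$defined & diSam$defined,
                    diSam$di - diRef$di, NA_real_)
  names(deltaDI) <- diRef$id
  varPos <- variantRelativePositions(promoters, variants, span = span)
  bySNP <- deltaDIByWindow(deltaDI, varPos, kind = "SNP",
                           windowSize = windowSize, shift = shift,
                           span = span)
  byIndel <- deltaDIByWindow(deltaDI, varPos, kind = "indel",
                             windowSize = windowSize, shift = shift,
                             span = span)
  regr <- deltaPowerDeltaDI(promoters, cohort$genome, patchedGenomes,
                            deltaDI, varPos, kind = "any",
                            windowSize = windowSize, shift = shift,
                            span = span, code = code, frequency = frequency)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    .writeTSV(data.frame(id = names(deltaDI), deltaDI = deltaDI),
              outDir, "delta_di.tsv")
    .writeTSV(bySNP, outDir, "delta_di_by_window_snp.tsv")
    .writeTSV(byIndel, outDir, "delta_di_by_window_indel.tsv")
    .writeTSV(regr, outDir, "delta_power_regression.tsv")
    .writeManifest(outDir, cfg, list(analysis = "variants"))
  }
  list(deltaDI = deltaDI, byWindowSNP = bySNP, byWindowIndel = byIndel,
       regression = regr)
}
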