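## Variant effects on initiation dispersion: most-likely (ML) reference
## construction from population allele frequencies, genome patching with
## homozygous variants plus an original->patched coordinate map, and
## sliding-window quantification of delta-DI and of the delta-periodicity
## vs delta-DI relationship around the TSS.

#' Read homozygous-variant records from a VCF
#'
#' Parses a VCF v4.x file into the variant table used by the patching and
#' delta-DI machinery.  Only biallelic records are kept (others are skipped
#' with a warning); the population allele frequency is taken from the
#' \code{AF} INFO field and the zygosity from the first sample's genotype.
#'
#' @param path Path to a VCF file.
#' @param sample Sample column to read the genotype from (index or name).
#' @return A data.frame with columns \code{chrom}, \code{pos} (0-based),
#'   \code{ref}, \code{alt}, \code{kind} ("SNP"/"indel"), \code{zygosity}
#'   ("hom"/"het"), \code{af} (alternate-allele frequency, \code{NA} when
#'   absent).
#' @export
readVariants <- function(path, sample = 1L) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  multi <- lengths(alt) != 1L
  if (any(multi)) {
    warning(sum(multi), " non-biallelic record(s) skipped")
    vcf <- vcf[!multi]; rr <- rr[!multi]; alt <- alt[!multi]
  }
  af <- VariantAnnotation::info(vcf)$AF
  af <- if (is.null(af)) rep(NA_real_, length(vcf))
        else vapply(af, function(x)
          if (length(x)) as.numeric(x[1L]) else NA_real_, numeric(1))
  gt <- VariantAnnotation::geno(vcf)$GT
  gt <- if (is.null(gt)) rep(NA_character_, length(vcf)) else gt[, sample]
  zyg <- ifelse(gt %in% c("1/1", "1|1", "0/0", "0|0"), "hom", "het")
  ref <- as.character(VariantAnnotation::ref(vcf))
  altc <- as.character(unlist(alt))
  data.frame(chrom = as.character(seqnames(rr)), pos = start(rr) - 1L,
             ref = ref, alt = altc,
             kind = ifelse(nchar(ref) == 1L & nchar(altc) == 1L,
                           "SNP", "indel"),
             zygosity = zyg, af = af, row.names = NULL)
}

#' Most-likely allele per variant site
#'
#' The ML (most likely) reference carries, at every variant site, the allele
#' with the highest population frequency; ties go to the reference allele.
#' Variants without a frequency annotation are skipped with a warning.
#'
#' @param variants Variant table (see [readVariants()]) with an \code{af}
#'   column giving the alternate-allele frequency.
#' @return The table with an added \code{ml} column (the ML allele string).
#' @export
mostLikelyAlleles <- function(variants) {
  if (anyNA(variants$af)) {
    warning(sum(is.na(variants$af)),
            " variant(s) without allele frequency skipped")
    variants <- variants[!is.na(variants$af), , drop = FALSE]
  }
  variants$ml <- ifelse(variants$af > 0.5, variants$alt, variants$ref)
  variants
}

#' Sample variants that differ from the ML genome
#'
#' Restricts a sample's homozygous variant list to sites where the sample
#' allele differs from the ML allele — the only variants that distinguish
#' the sample genome from the ML reference.
#'
#' @param variants Output of [mostLikelyAlleles()]; homozygous records only
#'   are considered (heterozygous ones are dropped).
#' @return The filtered table with a \code{sampleAllele} column.
#' @export
differingVariants <- function(variants) {
  v <- variants[variants$zygosity == "hom", , drop = FALSE]
  v$sampleAllele <- v$alt        # hom records carry the non-reference allele
  v[v$sampleAllele != v$ml, , drop = FALSE]
}

#' Patch a sequence with (homozygous) variants
#'
#' Applies SNPs and indels to a reference sequence, producing the patched
#' sequence plus a monotone coordinate map from original to patched
#' coordinates.  Variants must be non-overlapping and their \code{ref}
#' alleles must match the sequence; heterozygous records are rejected.
#'
#' @param seq Reference sequence (character or \code{DNAString}).
#' @param variants Variant table with \code{pos} (0-based), \code{ref},
#'   \code{alt} (and optionally \code{zygosity}).
#' @return A list of class \code{"patchedSequence"} with elements
#'   \code{seq} (patched character string), \code{breaks} and \code{shifts}
#'   (the step map used by [mapToPatched()]), and \code{variants}.
#' @export
applyVariants <- function(seq, variants) {
  s <- as.character(seq)
  if (!is.null(variants$zygosity) && any(variants$zygosity != "hom"))
    stop("heterozygous variants cannot be applied to a haploid sequence")
  if (nrow(variants) == 0L)
    return(structure(list(seq = s, breaks = integer(), shifts = integer(),
                          variants = variants),
                     class = "patchedSequence"))
  v <- variants[order(variants$pos), , drop = FALSE]
  if (any(v$pos[-1L] < (v$pos + nchar(v$ref))[-nrow(v)]))
    stop("overlapping variants")
  if (v$pos[nrow(v)] + nchar(v$ref[nrow(v)]) > nchar(s))
    stop("variant extends beyond the sequence")
  obs <- substring(s, v$pos + 1L, v$pos + nchar(v$ref))
  if (any(obs != v$ref))
    stop("reference allele mismatch at position ",
         v$pos[which(obs != v$ref)[1L]], ": expected '",
         v$ref[which(obs != v$ref)[1L]], "', sequence has '",
         obs[which(obs != v$ref)[1L]], "'")
  pieces <- character(2L * nrow(v) + 1L)
  prev <- 0L
  for (i in seq_len(nrow(v))) {
    pieces[2L * i - 1L] <- substring(s, prev + 1L, v$pos[i])
    pieces[2L * i] <- v$alt[i]
    prev <- v$pos[i] + nchar(v$ref[i])
  }
  pieces[2L * nrow(v) + 1L] <- substring(s, prev + 1L, nchar(s))
  ## map: positions at/after the end of variant i gain its length change
  breaks <- v$pos + nchar(v$ref)
  shifts <- cumsum(nchar(v$alt) - nchar(v$ref))
  structure(list(seq = paste(pieces, collapse = ""),
                 breaks = as.integer(breaks), shifts = as.integer(shifts),
                 variants = v),
            class = "patchedSequence")
}

#' Map an original coordinate onto the patched axis
#'
#' @param patched A \code{patchedSequence} from [applyVariants()].
#' @param pos 0-based position(s) on the original sequence.
#' @return 0-based position(s) on the patched sequence.  Positions inside a
#'   replaced reference allele are clamped into the replacement.
#' @export
mapToPatched <- function(patched, pos) {
  if (!length(patched$breaks)) return(pos)
  idx <- findInterval(pos, patched$breaks)       # variants fully upstream
  shift <- c(0L, patched$shifts)[idx + 1L]
  v <- patched$variants
  out <- pos + shift
  ## clamp positions falling inside a replaced allele
  inside <- findInterval(pos, v$pos) # candidate variant at/ before pos
  hit <- inside > 0L & pos < (v$pos + nchar(v$ref))[pmax(inside, 1L)]
  if (any(hit)) {
    i <- inside[hit]
    rel <- pmin(pos[hit] - v$pos[i], nchar(v$alt[i]) - 1L)
    priorShift <- c(0L, patched$shifts)[i]
    out[hit] <- v$pos[i] + priorShift + rel
  }
  out
}

#' Invert a variant set onto the patched axis
#'
#' Produces the variant table that, applied to the patched sequence,
#' restores the original: ref and alt are swapped and positions are moved to
#' the patched axis.
#'
#' @param patched A \code{patchedSequence} from [applyVariants()].
#' @return A variant table usable with [applyVariants()].
#' @export
invertVariants <- function(patched) {
  v <- patched$variants
  if (is.null(v) || nrow(v) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character()))
  priorShift <- c(0L, patched$shifts)[seq_len(nrow(v))]
  data.frame(chrom = if (is.null(v$chrom)) NA_character_ else v$chrom,
             pos = v$pos + priorShift, ref = v$alt, alt = v$ref,
             zygosity = "hom", row.names = NULL)
}

#' TSS-relative variant positions per promoter
#'
#' @param promoters A [PromoterSet-class].
#' @param variants Variant table with \code{chrom}, \code{pos}, \code{kind}.
#' @param span Half-open relative window of interest (default
#'   \code{c(-1000, 1001)}).
#' @return Named list (by promoter id) of data.frames with columns
#'   \code{relPos}, \code{kind}.
#' @export
variantRelativePositions <- function(promoters, variants,
                                     span = c(-1000L, 1001L)) {
  out <- vector("list", length(promoters))
  names(out) <- promoterIds(promoters)
  chrom <- promoterChrom(promoters)
  strnd <- promoterStrand(promoters)
  tss <- tssPosition(promoters)
  for (i in seq_len(length(promoters))) {
    v <- variants[variants$chrom == chrom[i], , drop = FALSE]
    rel <- if (strnd[i] == "+") v$pos - tss[i] else tss[i] - v$pos
    keep <- rel >= span[1L] & rel < span[2L]
    out[[i]] <- data.frame(relPos = rel[keep], kind = v$kind[keep])
  }
  out
}

#' Mean delta-DI by variant position window
#'
#' For each sliding window on the TSS-relative axis, the mean DI difference
#' (sample minus reference) across promoters carrying at least one variant
#' of the requested kind inside the window.  Windows with no qualifying
#' promoter are reported as missing (dropped), not as zero.
#'
#' @param deltaDI Named per-promoter DI difference (sample - reference);
#'   promoters with undefined DI in either condition must be absent or NA.
#' @param varPos Output of [variantRelativePositions()].
#' @param kind \code{"SNP"}, \code{"indel"} or \code{"any"}.
#' @param windowSize,shift Window geometry in bp (defaults 150/10).
#' @param span Half-open relative scan region (default \code{c(-1000, 1001)}).
#' @return data.frame with columns \code{center}, \code{meanDeltaDI},
#'   \code{n}.
#' @export
deltaDIByWindow <- function(deltaDI, varPos, kind = "any",
                            windowSize = 150L, shift = 10L,
                            span = c(-1000L, 1001L)) {
  starts <- seq(span[1L], span[2L] - windowSize, by = shift)
  ids <- intersect(names(varPos), names(deltaDI)[!is.na(deltaDI)])
  rows <- lapply(starts, function(s) {
    inWin <- vapply(varPos[ids], function(v) {
      k <- if (kind == "any") rep(TRUE, nrow(v)) else v$kind == kind
      any(k & v$relPos >= s & v$relPos < s + windowSize)
    }, logical(1))
    if (!any(inWin)) return(NULL)
    data.frame(center = s + windowSize %/% 2L,
               meanDeltaDI = mean(deltaDI[ids][inWin]),
               n = sum(inWin))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(center = numeric(), meanDeltaDI = numeric(),
                      n = integer())
  out
}

#' Per-window regression of delta-DI on delta-periodicity
#'
#' For each sliding window, each promoter with a variant in the window
#' contributes a point: x = the change in dinucleotide periodicity power of
#' the 150-bp sequence window (patched minus reference, aligned through the
#' coordinate map so indels shift the patched window), y = the promoter's
#' delta-DI.  An ordinary least-squares slope, Pearson r and p-value are
#' reported per window; windows with fewer than \code{minPromoters} points
#' or a degenerate (zero-variance) regressor are omitted.  A negative slope
#' means variants that lower the rotational-positioning signal raise
#' initiation dispersion.
#'
#' @param promoters A [PromoterSet-class].
#' @param genome Named reference \code{DNAStringSet}.
#' @param patchedGenomes Named list (by chrom) of \code{patchedSequence}
#'   objects from [applyVariants()].
#' @inheritParams deltaDIByWindow
#' @param code Dinucleotide code for the periodicity (default \code{"WW"}).
#' @param frequency Target frequency (default 0.097).
#' @param minPromoters Minimum points per window (default 3).
#' @return data.frame with columns \code{center}, \code{slope}, \code{r},
#'   \code{p}, \code{n}.
#' @export
deltaPowerDeltaDI <- function(promoters, genome, patchedGenomes, deltaDI,
                              varPos, kind = "any", windowSize = 150L,
                              shift = 10L, span = c(-1000L, 1001L),
                              code = "WW", frequency = 0.097,
                              minPromoters = 3L) {
  starts <- seq(span[1L], span[2L] - windowSize, by = shift)
  ids <- intersect(names(varPos), names(deltaDI)[!is.na(deltaDI)])
  prom <- promoters[match(ids, promoterIds(promoters))]
  chrom <- promoterChrom(prom); strnd <- promoterStrand(prom)
  tss <- tssPosition(prom)
  refCache <- new.env(parent = emptyenv())
  half <- windowSize %/% 2L
  winPower <- function(s, i, patched) {
    centerRel <- s + half
    g <- if (strnd[i] == "+") tss[i] + centerRel else tss[i] - centerRel
    if (patched) {
      pobj <- patchedGenomes[[chrom[i]]]
      g <- mapToPatched(pobj, g)
      src <- pobj$seq
    } else {
      key <- paste0(i, ":", s)
      if (!is.null(refCache[[key]])) return(refCache[[key]])
      src <- as.character(genome[[chrom[i]]])
    }
    lo <- g - half; hi <- lo + windowSize          # 0-based half-open
    if (lo < 0L || hi > nchar(src)) return(NA_real_)
    w <- substring(src, lo + 1L, hi)
    if (strnd[i] == "-")
      w <- as.character(reverseComplement(DNAString(w)))
    p <- powerAtFrequency(dinucleotideTrack(w, code), f = frequency)
    if (!patched) refCache[[paste0(i, ":", s)]] <- p
    p
  }
  rows <- lapply(starts, function(s) {
    inWin <- vapply(varPos[ids], function(v) {
      k <- if (kind == "any") rep(TRUE, nrow(v)) else v$kind == kind
      any(k & v$relPos >= s & v$relPos < s + windowSize)
    }, logical(1))
    sel <- which(inWin)
    if (length(sel) < minPromoters) return(NULL)
    dp <- vapply(sel, function(i)
      winPower(s, i, TRUE) - winPower(s, i, FALSE), numeric(1))
    dd <- deltaDI[ids][sel]
    ok <- !is.na(dp) & !is.na(dd)
    if (sum(ok) < minPromoters || stats::sd(dp[ok]) == 0) return(NULL)
    m <- stats::lm(dd[ok] ~ dp[ok])
    data.frame(center = s + half,
               slope = unname(stats::coef(m)[2L]),
               r = stats::cor(dp[ok], dd[ok]),
               p = stats::cor.test(dp[ok], dd[ok])$p.value,
               n = sum(ok))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(center = numeric(), slope = numeric(), r = numeric(),
                      p = numeric(), n = integer())
  out
}
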