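## Promoter-relative coordinate frame
##
## All TSS-relative coordinates in this package place the dominant TSS base
## at offset 0 and increase in the direction of transcription; windows are
## half-open [start, end).  A closed annotation window "-a to +b" (with the
## TSS counted as position 0) therefore becomes the internal window
## [-a, b + 1).  On minus-strand promoters the frame is mirrored so that
## positive offsets are always downstream on the annotated strand.

#' Convert TSS-relative offsets to genomic coordinates
#'
#' @param promoters A [PromoterSet-class].
#' @param offset TSS-relative offset(s), recycled against promoters.
#' @return 0-based genomic coordinate(s): \code{tss + offset} on plus-strand
#'   promoters, \code{tss - offset} on minus-strand ones.
#' @export
relativeToGenomic <- function(promoters, offset) {
  sgn <- ifelse(promoterStrand(promoters) == "+", 1L, -1L)
  tssPosition(promoters) + sgn * as.integer(offset)
}

#' Convert genomic coordinates to TSS-relative offsets
#'
#' Inverse of [relativeToGenomic()].
#' @param promoters A [PromoterSet-class].
#' @param pos 0-based genomic coordinate(s).
#' @return TSS-relative offset(s).
#' @export
genomicToRelative <- function(promoters, pos) {
  sgn <- ifelse(promoterStrand(promoters) == "+", 1L, -1L)
  sgn * (as.integer(pos) - tssPosition(promoters))
}

#' Read a promoter table (BED6)
#'
#' Reads a BED6 file in which each record is the 1-bp dominant TSS of a
#' promoter: the TSS is \code{chromStart} on plus-strand records and
#' \code{chromEnd - 1} on minus-strand records (0-based).  The name column
#' holds the promoter id, which must be unique; the strand column is
#' mandatory.
#'
#' @param path Path to a BED6 file.
#' @return A [PromoterSet-class].
#' @export
readPromoters <- function(path) {
  if (!file.exists(path)) stop("promoter file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (!length(lines))
    return(PromoterSet(character(), integer(), character(), character()))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop(sprintf("malformed BED6 promoter record at line %d: %d field(s), 6 required (strand column is mandatory)",
                 which(nf < 6L)[1L], nf[which(nf < 6L)[1L]]))
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  starts <- suppressWarnings(as.integer(m[, 2L]))
  ends   <- suppressWarnings(as.integer(m[, 3L]))
  bad <- which(is.na(starts) | is.na(ends) | starts < 0L | ends <= starts)
  if (length(bad))
    stop(sprintf("malformed BED6 promoter record at line %d: bad coordinates '%s %s'",
                 bad[1L], m[bad[1L], 2L], m[bad[1L], 3L]))
  strands <- m[, 6L]
  if (!all(strands %in% c("+", "-")))
    stop(sprintf("missing or invalid strand at line %d ('%s')",
                 which(!strands %in% c("+", "-"))[1L],
                 strands[which(!strands %in% c("+", "-"))[1L]]))
  ids <- m[, 4L]
  if (anyDuplicated(ids))
    stop("duplicate promoter id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tss <- ifelse(strands == "+", starts, ends - 1L)
  PromoterSet(chrom = m[, 1L], tss = tss, strand = strands, id = ids)
}

#' Write a PromoterSet as BED6
#'
#' @param promoters A [PromoterSet-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writePromoters <- function(promoters, path) {
  tss <- tssPosition(promoters)
  df <- data.frame(chrom = promoterChrom(promoters), start = tss,
                   end = tss + 1L, name = promoterIds(promoters),
                   score = 0L, strand = promoterStrand(promoters))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract a TSS-relative sequence window
#'
#' Returns the genomic sequence spanning a TSS-relative window in transcript
#' orientation: index 1 of the result is the most upstream base, the base at
#' relative offset 0 is the dominant TSS base, and minus-strand promoters are
#' reverse-complemented.
#'
#' @param genome A named [Biostrings::DNAStringSet] (or single
#'   \code{DNAString} when all promoters share one sequence).
#' @param promoters A [PromoterSet-class].
#' @param window Integer \code{c(start, end)}: half-open TSS-relative window.
#' @param drop.out.of.bounds If \code{TRUE}, promoters whose window overruns
#'   the sequence are dropped with a warning and the result is named by the
#'   surviving ids; if \code{FALSE} (default) such a promoter is an error.
#' @return A \code{DNAStringSet}, one sequence of width
#'   \code{window[2] - window[1]} per (retained) promoter.
#' @export
extractWindow <- function(genome, promoters, window,
                          drop.out.of.bounds = FALSE) {
  stopifnot(length(window) == 2L, window[1L] < window[2L])
  if (is(genome, "DNAString"))
    genome <- DNAStringSet(list(genome))
  chrom <- promoterChrom(promoters)
  if (is.null(names(genome)) && length(genome) == 1L)
    names(genome) <- unique(chrom)
  missing <- setdiff(chrom, names(genome))
  if (length(missing))
    stop("sequence(s) absent from genome: ", paste(missing, collapse = ", "))
  tss <- tssPosition(promoters)
  plus <- promoterStrand(promoters) == "+"
  ## 0-based half-open genomic span of the window on each strand
  gstart <- ifelse(plus, tss + window[1L], tss - window[2L] + 1L)
  gend   <- gstart + (window[2L] - window[1L])
  slen <- width(genome)[match(chrom, names(genome))]
  ok <- gstart >= 0L & gend <= slen
  if (!all(ok)) {
    if (!drop.out.of.bounds)
      stop("window [", window[1L], ",", window[2L], ") exceeds sequence ",
           "bounds for promoter(s): ",
           paste(promoterIds(promoters)[!ok], collapse = ", "))
    warning(sum(!ok), " promoter(s) dropped: window exceeds sequence bounds")
    promoters <- promoters[ok]
    chrom <- chrom[ok]; gstart <- gstart[ok]; gend <- gend[ok]; plus <- plus[ok]
  }
  if (!length(gstart)) return(DNAStringSet())
  seqs <- DNAStringSet(lapply(seq_along(gstart), function(i)
    subseq(genome[[chrom[i]]], start = gstart[i] + 1L, end = gend[i])))
  if (any(!plus))
    seqs[!plus] <- reverseComplement(seqs[!plus])
  names(seqs) <- promoterIds(promoters)
  seqs
}

#' Read stranded per-base 5'-end tag counts
#'
#' Accepts either a BED6 file whose score column carries the per-base tag
#' count (strand taken from the strand column), or a bedGraph (no strand
#' column; supply \code{strand}).  Multi-base records distribute their count
#' to every covered base.
#'
#' @param path Path to a BED6 or bedGraph file.
#' @param format \code{"bed"} or \code{"bedGraph"} (default guessed from the
#'   file extension; \code{.bg}/\code{.bedgraph} read as bedGraph).
#' @param strand Strand to assign to bedGraph records ("+" or "-").
#' @param strandSpecific If \code{FALSE}, strand is ignored on query.
#' @return A [TagStore-class].
#' @export
readTagCounts <- function(path, format = NULL, strand = "+",
                          strandSpecific = TRUE) {
  if (is.null(format)) {
    format <- if (grepl("\\.(bg|bedgraph)$", tolower(path))) "bedGraph"
              else "bed"
  }
  gr <- rtracklayer::import(path, format = format)
  if (format == "bedGraph")
    strand(gr) <- strand
  if (is.null(mcols(gr)$score))
    stop("tag file carries no count (score) column: ", path)
  if (any(mcols(gr)$score < 0))
    stop("negative tag count in ", path)
  new("TagStore", tags = gr, strandSpecific = strandSpecific)
}

#' Build a TagStore from in-memory positions
#'
#' @param chrom,pos,strand,count Parallel vectors; \code{pos} is the 0-based
#'   base coordinate of each tag 5' end, \code{count} the tag count there.
#' @param strandSpecific Passed to the store.
#' @return A [TagStore-class].
#' @export
tagStore <- function(chrom, pos, strand, count = 1,
                     strandSpecific = TRUE) {
  gr <- GRanges(chrom, IRanges(start = as.integer(pos) + 1L, width = 1L),
                strand = strand)
  mcols(gr)$score <- count
  new("TagStore", tags = gr, strandSpecific = strandSpecific)
}

#' Query per-base tag counts over a genomic window
#'
#' @param store A [TagStore-class].
#' @param chrom Sequence name.
#' @param strand "+" or "-"; ignored when the store is not strand-specific.
#' @param start,end 0-based half-open genomic window.
#' @return Numeric vector of length \code{end - start}; positions without a
#'   record are 0.
#' @export
tagCounts <- function(store, chrom, strand, start, end) {
  stopifnot(end > start)
  n <- end - start
  out <- numeric(n)
  q <- GRanges(chrom, IRanges(start = start + 1L, end = end))
  t <- store@tags
  hits <- suppressWarnings(findOverlaps(q, t, ignore.strand = TRUE))
  idx <- subjectHits(hits)
  if (store@strandSpecific && length(idx))
    idx <- idx[as.character(GenomicRanges::strand(t)[idx]) == strand]
  for (i in idx) {
    lo <- max(start(t)[i], start + 1L) - (start + 1L) + 1L
    hi <- min(end(t)[i], end) - (start + 1L) + 1L
    out[lo:hi] <- out[lo:hi] + mcols(t)$score[i]
  }
  out
}

#' Per-promoter TSS-relative tag profiles
#'
#' Extracts, for each promoter, the per-base tag counts over a TSS-relative
#' window on the promoter's annotated strand, mirrored into transcript
#' orientation (element 1 = most upstream offset).
#'
#' @param store A [TagStore-class].
#' @param promoters A [PromoterSet-class].
#' @param window Half-open TSS-relative window \code{c(start, end)}.
#' @return Numeric matrix, promoters x positions; column names are relative
#'   offsets.
#' @export
tagProfiles <- function(store, promoters, window) {
  n <- window[2L] - window[1L]
  ids <- promoterIds(promoters)
  out <- matrix(0, nrow = length(ids), ncol = n,
                dimnames = list(ids, window[1L]:(window[2L] - 1L)))
  chrom <- promoterChrom(promoters)
  strnd <- promoterStrand(promoters)
  tss <- tssPosition(promoters)
  for (i in seq_along(ids)) {
    if (strnd[i] == "+") {
      v <- tagCounts(store, chrom[i], "+", tss[i] + window[1L],
                     tss[i] + window[2L])
    } else {
      v <- rev(tagCounts(store, chrom[i], "-", tss[i] - window[2L] + 1L,
                         tss[i] - window[1L] + 1L))
    }
    out[i, ] <- v
  }
  out
}

#' Read CpG-island (or any annotation) intervals from BED
#'
#' @param path Path to a BED file.
#' @return A \code{GRanges} of intervals.
#' @export
readIntervals <- function(path) rtracklayer::import(path, format = "bed")

#' Read a plain-text position weight matrix
#'
#' Format: an optional header line \code{># <name> cutoff=<value>} followed
#' by one row per matrix position with 4 whitespace-separated values in
#' A, C, G, T order.  Values may be counts (convert with
#' [pwmLogOdds()]) or ready-made scores.
#'
#' @param path Path to the matrix file.
#' @return A list with elements \code{matrix} (positions x 4, columns
#'   A,C,G,T), \code{cutoff} (numeric or \code{NA}) and \code{name}.
#' @export
readPWM <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  cutoff <- NA_real_; name <- ""
  if (grepl("^[>#]", lines[1L])) {
    hdr <- sub("^[>#]+\\s*", "", lines[1L])
    m <- regmatches(hdr, regexec("cutoff\\s*=\\s*(-?[0-9.eE+-]+)", hdr))[[1L]]
    if (length(m) == 2L) cutoff <- as.numeric(m[2L])
    name <- trimws(sub("cutoff\\s*=.*$", "", hdr))
    lines <- lines[-1L]
  }
  rows <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  if (any(lengths(rows) != 4L) || anyNA(unlist(rows)))
    stop("PWM rows must each contain 4 numeric values (A C G T): ", path)
  mat <- do.call(rbind, rows)
  colnames(mat) <- c("A", "C", "G", "T")
  list(matrix = mat, cutoff = cutoff, name = name)
}

#' Convert a count PWM to log-odds scores
#'
#' @param counts Positions x 4 count matrix (columns A,C,G,T).
#' @param background Background base frequencies (A,C,G,T), default uniform.
#' @param pseudocount Added to every cell before normalisation.
#' @return Positions x 4 log2-odds score matrix.
#' @export
pwmLogOdds <- function(counts, background = rep(0.25, 4), pseudocount = 0.5) {
  stopifnot(ncol(counts) == 4L, length(background) == 4L)
  p <- (counts + pseudocount) / rowSums(counts + pseudocount)
  log2(sweep(p, 2L, background, "/"))
}
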