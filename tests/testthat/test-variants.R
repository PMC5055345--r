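test_that("VCF records parse into the variant table", {
  f <- writeTempVcf(c(
    vcfRecord("chr1", 5, "A", "G", af = 0.7, gt = "1/1"),
    vcfRecord("chr1", 9, "C", "CTT", af = 0.4, gt = "0/1"),
    vcfRecord("chr1", 20, "TAA", "T", af = 0.2, gt = "1|1")))
  v <- readVariants(f)
  expect_equal(nrow(v), 3L)
  expect_equal(v$pos, c(4L, 8L, 19L))      # 0-based
  expect_equal(v$kind, c("SNP", "indel", "indel"))
  expect_equal(v$zygosity, c("hom", "het", "hom"))
  expect_equal(v$af, c(0.7, 0.4, 0.2))
})

test_that("the most-likely allele is the most frequent, ties to reference", {
  v <- data.frame(chrom = "c", pos = c(0, 1, 2), ref = c("A", "C", "G"),
                  alt = c("G", "T", "A"), kind = "SNP", zygosity = "hom",
                  af = c(0.7, 0.5, 0.2))
  ml <- mostLikelyAlleles(v)
  expect_equal(ml$ml, c("G", "C", "G"))
  # hom-alt equal to the ML allele drops out of the difference list
  d <- differingVariants(ml)
  expect_equal(d$pos, c(1, 2))
  # missing frequency is skipped with a warning
  v$af[1] <- NA
  expect_warning(ml2 <- mostLikelyAlleles(v), "without allele frequency")
  expect_equal(nrow(ml2), 2L)
})

test_that("patching applies SNPs and indels with a monotone coordinate map", {
  p <- applyVariants("ACGT", data.frame(chrom = "c", pos = 2L, ref = "G",
                                        alt = "T"))
  expect_equal(p$seq, "ACTT")
  expect_equal(mapToPatched(p, 0:3), 0:3)
  ins <- applyVariants("ACGT", data.frame(chrom = "c", pos = 1L, ref = "C",
                                          alt = "CAA"))
  expect_equal(ins$seq, "ACAAGT")
  expect_equal(mapToPatched(ins, 3L), 5L)
  del <- applyVariants("ACGTACGT", data.frame(chrom = "c", pos = 2L,
                                              ref = "GTA", alt = "G"))
  expect_equal(del$seq, "ACGCGT")
  expect_equal(mapToPatched(del, c(1L, 5L)), c(1L, 3L))
  idp <- applyVariants("ACGT", data.frame(chrom = character(),
                                          pos = integer(),
                                          ref = character(),
                                          alt = character()))
  expect_equal(idp$seq, "ACGT")
  expect_equal(mapToPatched(idp, 0:3), 0:3)
})

test_that("patching rejects invalid variant sets", {
  expect_error(applyVariants("ACGT", data.frame(
    chrom = "c", pos = c(0L, 1L), ref = c("AC", "CG"), alt = c("A", "C"))),
    "overlapping")
  expect_error(applyVariants("ACGT", data.frame(
    chrom = "c", pos = 1L, ref = "G", alt = "T")),
    "mismatch at position 1")
  expect_error(applyVariants("ACGT", data.frame(
    chrom = "c", pos = 1L, ref = "C", alt = "T", zygosity = "het")),
    "heterozygous")
})

test_that("patch followed by its inverse restores sequence and map", {
  set.seed(73)
  for (r in 1:20) {
    s <- randomSeq(200)
    pos <- sort(sample(seq(5, 180, by = 12), 5))
    vars <- do.call(rbind, lapply(pos, function(p0) {
      type <- sample(c("snp", "ins", "del"), 1)
      ref1 <- substr(s, p0 + 1, p0 + 1)
      if (type == "snp") {
        data.frame(chrom = "c", pos = p0, ref = ref1,
                   alt = sample(setdiff(c("A", "C", "G", "T"), ref1), 1))
      } else if (type == "ins") {
        data.frame(chrom = "c", pos = p0, ref = ref1,
                   alt = paste0(ref1, randomSeq(sample(1:3, 1))))
      } else {
        data.frame(chrom = "c", pos = p0,
                   ref = substr(s, p0 + 1, p0 + 1 + sample(1:3, 1)),
                   alt = ref1)
      }
    }))
    patched <- applyVariants(s, vars)
    restored <- applyVariants(patched$seq, invertVariants(patched))
    expect_equal(restored$seq, s)
  }
})

test_that("delta-DI windows pool promoters with variants in the window", {
  deltaDI <- c(p1 = 4)
  varPos <- list(p1 = data.frame(relPos = 120L, kind = "SNP"))
  out <- deltaDIByWindow(deltaDI, varPos, kind = "SNP")
  expect_true(all(out$meanDeltaDI == 4))
  expect_true(all(out$center >= 120 - 75 & out$center <= 120 + 75))
  # windows of 150 covering +120 start at -20..120, centers 55..195
  expect_equal(range(out$center), c(55, 195))
  none <- deltaDIByWindow(deltaDI,
                          list(p1 = data.frame(relPos = integer(),
                                               kind = character())))
  expect_equal(nrow(none), 0L)
  # indel-kind scan ignores the SNP
  expect_equal(nrow(deltaDIByWindow(deltaDI, varPos, kind = "indel")), 0L)
})

test_that("position-independent variant effects give a flat delta-DI scan", {
  set.seed(79)
  n <- 150
  deltaDI <- rnorm(n, 2, 1)
  names(deltaDI) <- paste0("p", 1:n)
  varPos <- lapply(1:n, function(i)
    data.frame(relPos = sample(-900:900, 2), kind = "SNP"))
  names(varPos) <- names(deltaDI)
  out <- deltaDIByWindow(deltaDI, varPos, kind = "SNP")
  se <- sapply(seq_len(nrow(out)), function(i) 1 / sqrt(out$n[i]))
  expect_true(all(abs(out$meanDeltaDI - mean(deltaDI)) < 4 * se + 1e-12))
})

test_that("the planted delta-power coupling is recovered by the regression", {
  cfg <- simConfig(seed = 83, nPromoters = 100, chromLength = 2000,
                   pSNP = 1, pIndel = 0.3, coupling = 2,
                   couplingNoise = 0.02, tagDepth = 2000)
  coh <- simulateCohort(cfg)
  vs <- simulateVariants(cfg, coh)
  # regress the generator-planted deltaDI target on the pipeline's own
  # delta-power at the +1 nucleosome window
  deltaDI <- vs$sigmaSample^2 - vs$sigmaRef^2
  names(deltaDI) <- promoterIds(coh$promoters)
  varPos <- variantRelativePositions(coh$promoters, vs$variants,
                                     span = c(-900L, 901L))
  out <- deltaPowerDeltaDI(coh$promoters, coh$genome, vs$patchedGenomes,
                           deltaDI, varPos, span = c(50L, 200L),
                           windowSize = 150L)
  expect_equal(nrow(out), 1L)
  expect_equal(out$center, 125)
  expect_gt(out$slope, -2.4)
  expect_lt(out$slope, -1.6)
  expect_lt(out$p, 0.01)
})

test_that("a periodicity-destroying SNP lowers power while raising DI", {
  # build a promoter whose N+1 is a perfect WW lattice, then break one slot
  cfg <- simConfig(seed = 89, nPromoters = 1, chromLength = 2000,
                   amplitude = 1, coupling = 30, couplingNoise = 0)
  coh <- simulateCohort(cfg)
  tr <- coh$truth
  slot <- round(50 + 7 * 10.3)        # a planted slot inside the N+1
  g <- if (tr$strand == "+") tr$tss + slot else tr$tss - slot
  s <- as.character(coh$genome[[tr$chrom]])
  ref <- substr(s, g + 1, g + 1)
  v <- data.frame(chrom = tr$chrom, pos = g, ref = ref,
                  alt = if (ref %in% c("A", "T")) "G" else "A",
                  kind = "SNP")
  patched <- applyVariants(s, v)
  win <- if (tr$strand == "+") c(tr$tss + 50, tr$tss + 200)
         else c(tr$tss - 199, tr$tss + 1 - 50)
  refWin <- substr(s, win[1] + 1, win[1] + 150)
  patWin <- substr(patched$seq, win[1] + 1, win[1] + 150)
  dPow <- powerAtFrequency(dinucleotideTrack(patWin, "WW")) -
          powerAtFrequency(dinucleotideTrack(refWin, "WW"))
  expect_lt(dPow, 0)
  # the generator couples this power loss to a DI increase
  dDI <- -cfg$coupling * dPow
  expect_gt(dDI, 0)
})
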