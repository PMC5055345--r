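test_that("motif enumeration yields the 240 valid arrangements", {
  m <- consensusMotifs()
  expect_equal(nrow(m), 240L)
  expect_equal(anyDuplicated(m$pattern), 0L)
  expect_false(any(startsWith(m$pattern, "N")))
  expect_true("SSRRNWWNYY" %in% m$pattern)
  expect_true("SSYYNWWNRR" %in% m$pattern)
  # token multiset invariant: each of WW,SS,YY,RR once, two Ns, length 10
  expect_true(all(nchar(m$pattern) == 10L))
  for (p in m$pattern) {
    ch <- strsplit(p, "")[[1]]
    expect_equal(sum(ch == "N"), 2L)
    expect_equal(sort(table(ch[ch != "N"]))[c("W", "S", "Y", "R")],
                 table(c("W", "W", "S", "S", "Y", "Y", "R", "R"))[
                   c("W", "S", "Y", "R")])
  }
})

test_that("cyclic-order classification matches the two consensus classes", {
  expect_equal(classifyMotif("YYWWNNRRSS"), "SS-YY-WW-RR")
  expect_equal(classifyMotif("RRWWNNYYSS"), "SS-RR-WW-YY")
  expect_equal(classifyMotif("SSRRNWWNYY"), "SS-RR-WW-YY")
  expect_equal(classifyMotif("SSYYNWWNRR"), "SS-YY-WW-RR")
  expect_equal(classifyMotif("SSWWNYYNRR"), "other")
  cls <- table(consensusMotifs()$class)
  # each named class collects the 4 rotations x 10 N placements
  expect_equal(unname(cls["SS-RR-WW-YY"]), 40L)
  expect_equal(unname(cls["SS-YY-WW-RR"]), 40L)
})

test_that("mismatch counting follows IUPAC classes with N rules", {
  expect_equal(motifMismatches("SSYYNWWNRR", "GGCCAAATAG"), 0L)
  expect_equal(motifMismatches("SSYYNWWNRR", "GGCCAAATAC"), 1L)
  expect_equal(motifMismatches("NNNNNNNNNN", "ACGTNNACGT"), 0L)
  expect_equal(motifMismatches("WWWWWWWWWW", "NNNNNNNNNN"), 10L)
  expect_error(motifMismatches("WW", "ACG"), "length")
  set.seed(13)
  for (r in 1:500) {
    pat <- paste(sample(c("W", "S", "Y", "R", "N"), 10, replace = TRUE),
                 collapse = "")
    win <- randomSeq(10, alphabet = c("A", "C", "G", "T", "N"))
    expect_identical(motifMismatches(pat, win), oracleMismatches(pat, win))
  }
})

test_that("occurrence profiles match a brute-force scanner", {
  set.seed(17)
  regions <- vapply(1:30, function(i) randomSeq(60), character(1))
  motifs <- sample(consensusMotifs()$pattern, 8)
  prof <- occurrenceProfile(regions, motifs, maxMismatch = 3L)
  for (m in motifs) {
    for (j in seq_len(60 - 10 + 1)) {
      brute <- mean(vapply(regions, function(r)
        oracleMismatches(m, substr(r, j, j + 9)) <= 3, logical(1)))
      expect_equal(unname(prof[m, j]), brute)
    }
  }
})

test_that("occurrence profile edge behaviours", {
  expect_equal(unname(occurrenceProfile("GGCCAAATAG", "SSYYNWWNRR",
                                        maxMismatch = 0L)[1, 1]), 1)
  allhit <- occurrenceProfile(c("ACGTACGTACGTACGT", "TTTTTTTTTTTTTTTT"),
                              "SSYYNWWNRR", maxMismatch = 10L)
  expect_true(all(allhit == 1))
  expect_error(occurrenceProfile("ACGTACG", "SSYYNWWNRR"), "shorter")
})

test_that("motif scores separate the planted class on a perfect lattice", {
  # perfect SS-YY-WW-RR lattice every 10 bp
  regions <- rep(paste(rep("GGCCAAATAG", 40), collapse = ""), 12)
  sc <- motifScores(regions, motifs = data.frame(
    pattern = c("SSYYNWWNRR", "SSRRNWWNYY"),
    class = c("SS-YY-WW-RR", "SS-RR-WW-YY")),
    regionStart = -99L, scoreFrom = 50L, scoreTo = 200L)
  expect_gt(sc$power[sc$pattern == "SSYYNWWNRR"],
            sc$power[sc$pattern == "SSRRNWWNYY"])
  # constant occurrence profile scores 0 under the mean-removed transform
  sc0 <- motifScores(regions[1:10], motifs = data.frame(
    pattern = "NNNNNNNNNN", class = "other"), maxMismatch = 10L,
    regionStart = -99L, scoreFrom = 50L, scoreTo = 200L)
  expect_equal(sc0$power, 0)
  expect_error(motifScores(regions[1:5], regionStart = -99L), "at least 10")
})

test_that("motif scores are invariant under region order permutation", {
  set.seed(23)
  regions <- vapply(1:20, function(i) randomSeq(400), character(1))
  motifs <- consensusMotifs()[1:5, ]
  a <- motifScores(regions, motifs)
  b <- motifScores(sample(regions), motifs)
  expect_equal(a$power, b$power)
})

test_that("N+1 and genomic-nucleosome scores correlate on planted data", {
  cfg <- simConfig(seed = 31, nPromoters = 60, fragmentDepth = 10)
  coh <- simulateCohort(cfg)
  n1regions <- extractWindow(coh$genome, coh$promoters, c(-99L, 301L))
  fr <- fragmentsFromPairs(simulateFragments(cfg, coh))
  dy <- dyadPositions(fr)
  # orient dyad windows by the promoter strand of their chromosome
  st <- promoterStrand(coh$promoters)[match(dy$chrom,
                                            promoterChrom(coh$promoters))]
  dyProm <- PromoterSet(dy$chrom2 <- dy$chrom, tss = dy$pos, strand = st,
                        id = sprintf("d%d", seq_len(nrow(dy))))
  gregions <- extractWindow(coh$genome, dyProm, c(-75L, 76L))
  motifs <- consensusMotifs()
  scN1 <- motifScores(n1regions, motifs, regionStart = -99L,
                      scoreFrom = 50L, scoreTo = 200L)
  scG <- motifScores(gregions, motifs, regionStart = -75L,
                     scoreFrom = NULL)
  expect_gt(cor(scN1$power, scG$power, method = "spearman"), 0.5)
})

test_that("class-signal split honours the inclusive dominance ratio", {
  sp <- splitByClassSignal(c(2.0, 1.9, 0, 1.0), c(1.0, 1.0, 0, 2.5),
                           ratio = 2)
  expect_equal(as.character(sp), c("A", "unassigned", "unassigned", "B"))
})

test_that("per-promoter motif signal is positive on a lattice promoter", {
  lattice <- paste(rep("GGCCAAATAG", 40), collapse = "")
  sig <- promoterMotifSignal(c(lattice, randomSeq(400)), "SSYYNWWNRR",
                             regionStart = -99L)
  expect_gt(sig[1], 0)
  expect_gt(sig[1], sig[2])
})
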