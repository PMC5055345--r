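test_that("micro-peak extraction marks window maxima above the tag cutoff", {
  expect_equal(which(microPeaks(c(0, 0, 30, 50, 40, 0, 0),
                                minTags = 100) == 1L), 4L)
  expect_equal(sum(microPeaks(rep(0, 20), minTags = 100)), 0L)
  # tie inside a qualifying window resolves to the leftmost maximum
  expect_equal(which(microPeaks(c(60, 60, 0, 0, 0), minTags = 100) == 1L),
               1L)
  # overlapping qualifying windows selecting one position yield one mark
  expect_equal(sum(microPeaks(c(0, 0, 200, 0, 0, 0, 0), minTags = 100)), 1L)
  expect_error(microPeaks(c(1, 2), window = 5L), "shorter")
  expect_error(microPeaks(c(-1, 0, 0, 0, 0)), "non-negative")
})

test_that("no mark sits at a position all of whose windows are sub-threshold", {
  set.seed(19)
  for (r in 1:50) {
    counts <- rpois(80, 10) * rbinom(80, 1, 0.3)
    marks <- microPeaks(counts, minTags = 60)
    for (i in which(marks == 1L)) {
      sums <- vapply(max(1, i - 4):min(i, 80 - 4), function(s)
        sum(counts[s:(s + 4)]), numeric(1))
      expect_gte(max(sums), 60)
    }
  }
})

test_that("micro-peak frequency averages binary arrays across promoters", {
  m <- rbind(p1 = c(0, 0, 0, 0, 0, 0, 0), p2 = c(0, 0, 0, 0, 0, 0, 0))
  m["p1", 6] <- 150; m["p2", 2] <- 150
  colnames(m) <- -3:3
  fr <- microPeakFrequency(m, minTags = 100)
  expect_equal(unname(fr[c("-2", "2")]), c(0.5, 0.5))
  expect_equal(sum(fr), 1)
  expect_error(microPeakFrequency(m[0, , drop = FALSE]), "empty")
})

test_that("planted 10-bp secondary starts give phased micro-peak aggregates", {
  cfg <- simConfig(seed = 41, nPromoters = 50, periodicInitiation = TRUE,
                   tagDepth = 1000)
  coh <- simulateCohort(cfg)
  prof <- simulateCage(cfg, coh)
  fr <- microPeakFrequency(prof, minTags = 100)
  offs <- as.numeric(names(fr))
  within30 <- fr[abs(offs) <= 30]
  ofs30 <- offs[abs(offs) <= 30]
  peaks <- ofs30[within30 > 0.5]
  expect_true(length(peaks) >= 3)
  expect_true(all(peaks %% 10 == 0))
})

test_that("cosine covariance separates in-phase from anti-phase marks", {
  offs <- -50:50
  inphase <- as.integer(offs %in% c(-20, -10, 0, 10, 20))
  names(inphase) <- offs
  expect_gt(cosineCovariance(inphase), 0)
  anti <- as.integer(offs %in% c(-15, -5, 5, 15))
  names(anti) <- offs
  expect_lt(cosineCovariance(anti), 0)
  empty <- integer(101); names(empty) <- offs
  expect_equal(cosineCovariance(empty), 0)
  mm <- rbind(a = inphase, b = anti, c = empty)
  colnames(mm) <- offs
  rk <- rankByCosineCovariance(mm)
  expect_equal(rk$id, c("a", "c", "b"))
  expect_equal(rk$weak, c(FALSE, TRUE, FALSE))
})

test_that("the dispersion index is the population variance of tag positions", {
  expect_equal(dispersionIndex(rep(3, 10))$di, 0)
  r <- dispersionIndex(c(rep(-1, 5), rep(1, 5)))
  expect_equal(r$di, 1.0)
  expect_true(r$defined)
  r5 <- dispersionIndex(rep(0, 5))
  expect_false(r5$defined)
  expect_true(is.na(r5$di))
  # counts weight positions
  expect_equal(dispersionIndex(c(-1, 1), counts = c(5, 5))$di, 1.0)
  # tags outside the 100-bp window are ignored
  expect_equal(dispersionIndex(c(rep(0, 10), 500, -500))$di, 0)
})

test_that("DI matches the two-pass variance oracle and its symmetries", {
  set.seed(29)
  for (r in 1:200) {
    pos <- sample(-49:49, sample(6:40, 1), replace = TRUE)
    di <- dispersionIndex(pos)$di
    expect_lt(abs(di - oracleVariance(pos)), 1e-9)
    # translation invariance
    expect_equal(dispersionIndex(pos - 10, window = c(-60, 40))$di, di,
                 tolerance = 1e-12)
  }
  # quadratic scaling
  pos <- c(-4, -2, 0, 2, 4, 6)
  expect_equal(dispersionIndex(pos * 3, window = c(-50, 50))$di,
               9 * dispersionIndex(pos)$di)
})

test_that("DI recovers the planted spread on dispersed synthetic tags", {
  cfg <- simConfig(seed = 47, nPromoters = 60, tagDepth = 300, sigma = 5)
  coh <- simulateCohort(cfg)
  prof <- simulateCage(cfg, coh)
  di <- promoterDispersion(prof)
  expect_true(all(di$defined))
  expect_lt(abs(mean(di$di) / 25 - 1), 0.1)
})

test_that("periodic initiation mode yields positive phasing for most promoters", {
  cfg <- simConfig(seed = 53, nPromoters = 60, periodicInitiation = TRUE,
                   tagDepth = 1000)
  coh <- simulateCohort(cfg)
  prof <- simulateCage(cfg, coh)
  marks <- t(apply(prof, 1, microPeaks, minTags = 100))
  colnames(marks) <- colnames(prof)
  rk <- rankByCosineCovariance(marks)
  expect_gte(mean(rk$score > 0), 0.95)
})

test_that("dispersed initiation mode has near-zero median phasing", {
  cfg <- simConfig(seed = 59, nPromoters = 60, periodicInitiation = FALSE,
                   tagDepth = 10000, sigma = 20)
  coh <- simulateCohort(cfg)
  prof <- simulateCage(cfg, coh)
  marks <- t(apply(prof, 1, microPeaks, minTags = 100))
  colnames(marks) <- colnames(prof)
  rk <- rankByCosineCovariance(marks)
  expect_lt(abs(median(rk$score)), 0.01)
})

test_that("sample-specific DIs average into one value per promoter", {
  d1 <- data.frame(id = c("a", "b"), di = c(2, 4),
                   nTags = c(10, 10), defined = c(TRUE, TRUE))
  d2 <- data.frame(id = c("a", "b"), di = c(4, NA),
                   nTags = c(10, 2), defined = c(TRUE, FALSE))
  avg <- averageDispersion(list(d1, d2))
  expect_equal(avg$di, c(3, 4))
  expect_equal(avg$nSamples, c(2L, 1L))
})
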