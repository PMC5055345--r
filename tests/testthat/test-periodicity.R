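test_that("dinucleotide tracks follow the IUPAC classes and kill Ns", {
  expect_equal(as.integer(dinucleotideTrack("AATT", "WW")), c(1L, 1L, 1L))
  expect_equal(as.integer(dinucleotideTrack("ACGT", "SS")), c(0L, 1L, 0L))
  expect_equal(as.integer(dinucleotideTrack("ANAT", "WW")), c(0L, 0L, 1L))
  expect_equal(as.integer(dinucleotideTrack("AGCT", "RR")), c(1L, 0L, 0L))
  expect_equal(as.integer(dinucleotideTrack("CTCT", "YY")), c(1L, 1L, 1L))
  expect_error(dinucleotideTrack("A", "WW"), "length")
  expect_error(dinucleotideTrack("AXGT", "WW"), "alphabet")
})

test_that("WW and SS tracks are pointwise disjoint on random sequences", {
  set.seed(42)
  for (r in 1:20) {
    s <- randomSeq(100, alphabet = c("A", "C", "G", "T", "N"))
    ww <- dinucleotideTrack(s, "WW")
    ss <- dinucleotideTrack(s, "SS")
    expect_true(all(ww + ss <= 1L))
  }
})

test_that("single-frequency power matches the brute-force DFT oracle", {
  x <- as.integer((0:149) %% 10 == 0)
  expect_lt(abs(powerAtFrequency(x, 0.1) - oraclePower(x, 0.1)), 1e-10)
  # thresholded cosine at the target period scores higher at 0.097 than 0.2
  y <- as.integer(0.5 * (1 + cos(2 * pi * 0.097 * (0:149))) >= 0.5)
  expect_gt(powerAtFrequency(y, 0.097), powerAtFrequency(y, 0.2))
  expect_equal(powerAtFrequency(rep(0, 50), 0.097), 0)
  expect_equal(powerAtFrequency(rep(1, 50), 0.123), 0)
  set.seed(7)
  for (r in 1:200) {
    w <- sample(0:1, sample(20:200, 1), replace = TRUE)
    f <- runif(1, 0.01, 0.49)
    expect_lt(abs(powerAtFrequency(w, f) - oraclePower(w, f)), 1e-9)
  }
})

test_that("power is invariant under cyclic shift of a perfectly periodic window", {
  x <- as.integer((0:149) %% 10 == 0)      # period 10, length 150 = 15 periods
  p0 <- powerAtFrequency(x, 0.1)
  for (k in c(1, 3, 7)) {
    xs <- c(x[(k + 1):150], x[1:k])
    expect_equal(powerAtFrequency(xs, 0.1), p0, tolerance = 1e-9)
  }
})

test_that("sliding-window profiles have the expected geometry", {
  track <- rep(0L, 30)
  prof <- periodicityProfile(track, window = 10L, shift = 5L,
                             trackStart = 0L)
  expect_equal(length(profilePowers(prof)), 5L)        # floor((30-10)/5)+1
  expect_equal(profileCenters(prof), 0 + (0:4) * 5 + 5)
  expect_error(periodicityProfile(rep(0L, 5), window = 10L), "shorter")
  # the scan of a 2150-bp promoter window yields 200 windows of 150/10
  prof2 <- periodicityProfile(rep(0L, 2149), window = 150L, shift = 10L)
  expect_equal(length(profilePowers(prof2)), 200L)
})

test_that("a planted periodic segment dominates the profile where planted", {
  set.seed(3)
  track <- as.integer(runif(500) < 0.05)
  plant <- 200:320                          # windows starting 110..200ish
  track[plant[plant %% 10 == 0]] <- 1L
  prof <- periodicityProfile(track, window = 100L, shift = 10L,
                             trackStart = 0L, frequency = 0.1)
  peak <- profileCenters(prof)[which.max(profilePowers(prof))]
  expect_gte(peak, 200); expect_lte(peak, 330)
})

test_that("random homogeneous tracks match the oracle window by window", {
  set.seed(101)
  track <- as.integer(runif(500) < 0.25)
  prof <- periodicityProfile(track, trackStart = 0L)
  pw <- profilePowers(prof)
  starts <- (seq_along(pw) - 1L) * 10L
  oracle <- vapply(starts, function(s)
    oraclePower(track[(s + 1):(s + 150)], 0.097), numeric(1))
  expect_equal(pw, oracle, tolerance = 1e-10)
  # smoke bound on a homogeneous track: no wild outlier windows
  expect_lt(max(pw), 5 * median(pw))
})

test_that("periodogram scan is consistent with the single-frequency profile", {
  set.seed(5)
  track <- as.integer(runif(400) < 0.1)
  # planted square wave of period 10 (5 on / 5 off) across 100..300
  track[100:300] <- as.integer(((100:300) %% 10) < 5)
  m <- periodogramScan(track, window = 100L, shift = 10L,
                       periods = c(5, 10, 10.3, 20), trackStart = 0L)
  planted <- colnames(m)[as.numeric(colnames(m)) >= 150 &
                         as.numeric(colnames(m)) <= 250]
  expect_true(all(m["10", planted] > m["5", planted]))
  expect_true(all(m["10", planted] > m["20", planted]))
  expect_equal(unname(m["10.3", ]),
               profilePowers(periodicityProfile(track, window = 100L,
                                                shift = 10L, trackStart = 0L,
                                                frequency = 1 / 10.3)))
  z <- periodogramScan(rep(0L, 300), window = 100L, shift = 10L,
                       periods = c(5, 10), trackStart = 0L)
  expect_true(all(z == 0))
})

test_that("concordance compares N+1 against NFR mean power strictly", {
  mk <- function(powers, centers)
    new("PeriodicityProfile", powers = powers, centers = centers,
        windowSize = 150L, shift = 10L, frequency = 0.097, code = "WW")
  centers <- seq(-999, 991, by = 10)
  pw <- rep(0, length(centers))
  pw[centers >= 50 & centers < 200] <- 1
  expect_true(concordanceCall(mk(pw, centers)))
  expect_false(concordanceCall(mk(rep(0.5, length(centers)), centers)))
  expect_error(concordanceCall(mk(1, 0), nfr = c(-150, 0), n1 = c(50, 200)),
               "no window centers")
})

test_that("windows with many ambiguous bases are skipped with a warning", {
  s <- paste0(paste(rep("N", 60), collapse = ""), randomSeq(200))
  tr <- dinucleotideTrack(s, "WW")
  expect_warning(prof <- periodicityProfile(tr, window = 50L, shift = 10L,
                                            trackStart = 0L),
                 "ambiguous")
  expect_true(any(is.na(profilePowers(prof))))
  expect_false(all(is.na(profilePowers(prof))))
})

test_that("mean N+1 power is non-decreasing in planted amplitude", {
  amps <- c(0, 0.25, 0.5, 0.75, 1.0)
  meanPower <- vapply(seq_along(amps), function(ai) {
    cfg <- simConfig(seed = 202, nPromoters = 40, chromLength = 1000,
                     amplitude = amps[ai])
    coh <- simulateCohort(cfg)
    seqs <- extractWindow(coh$genome, coh$promoters, c(45L, 215L))
    mean(vapply(as.character(seqs), function(s)
      powerAtFrequency(dinucleotideTrack(s, "WW")[6:155]), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanPower) > -1e-9))
})
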