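# Independent brute-force oracles used to pin the numerical definitions.

# Direct double-loop evaluation of |sum((x - mean) e^{-2 pi i f n})|^2 / L,
# written scalar-by-scalar so it shares no code path with the package.
oraclePower <- function(x, f) {
  L <- length(x)
  xbar <- sum(x) / L
  re <- 0; im <- 0
  for (n in 0:(L - 1)) {
    re <- re + (x[n + 1] - xbar) * cos(2 * pi * f * n)
    im <- im - (x[n + 1] - xbar) * sin(2 * pi * f * n)
  }
  (re * re + im * im) / L
}

# Naive symbol-by-symbol IUPAC mismatch count.
oracleMismatches <- function(pattern, window) {
  p <- strsplit(pattern, "")[[1]]
  w <- strsplit(window, "")[[1]]
  n <- 0L
  for (i in seq_along(p)) {
    ok <- switch(p[i],
      W = w[i] == "A" || w[i] == "T",
      S = w[i] == "C" || w[i] == "G",
      Y = w[i] == "C" || w[i] == "T",
      R = w[i] == "A" || w[i] == "G",
      N = TRUE,
      stop("bad symbol"))
    if (!ok) n <- n + 1L
  }
  n
}

# Two-pass population variance of weighted positions.
oracleVariance <- function(pos, counts = rep(1, length(pos))) {
  n <- sum(counts)
  m <- sum(pos * counts) / n
  s <- 0
  for (i in seq_along(pos)) s <- s + counts[i] * (pos[i] - m)^2
  s / n
}

randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Tiny on-disk fixtures built in code.
writeTempBed <- function(lines) {
  f <- tempfile(fileext = ".bed")
  writeLines(lines, f)
  f
}

writeTempVcf <- function(records,
                         header = c("##fileformat=VCFv4.2",
                           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"AF\">",
                           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
                           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                                 "FILTER", "INFO", "FORMAT", "S1",
                                 sep = "\t"))) {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(header, records), f)
  f
}

vcfRecord <- function(chrom, pos1, ref, alt, af = 0.1, gt = "1/1") {
  paste(chrom, pos1, ".", ref, alt, ".", "PASS",
        sprintf("AF=%s", af), "GT", gt, sep = "\t")
}
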