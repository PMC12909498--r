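test_that("time-domain features match closed forms and a summation oracle", {
  cst <- eegTimeFeatures(rep(3, 10))
  expect_equal(cst, c(MEA = 3, ENE = 90, VAR = 0, RMS = 3))

  alt <- eegTimeFeatures(c(1, -1, 1, -1))
  expect_equal(alt, c(MEA = 0, ENE = 4, VAR = 1, RMS = 1))

  set.seed(1)
  for (i in 1:5) {
    x <- rnorm(250)
    got <- eegTimeFeatures(x)
    # brute-force elementwise summation oracle
    n <- length(x); s1 <- 0; s2 <- 0
    for (v in x) { s1 <- s1 + v; s2 <- s2 + v * v }
    oracle <- c(MEA = s1 / n, ENE = s2, VAR = s2 / n - (s1 / n)^2,
                RMS = sqrt(s2 / n))
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  expect_error(eegTimeFeatures(numeric(0)), ">= 2 samples")
})

test_that("spectral features localize tones and match a bin-sum oracle", {
  rate <- 500; t <- seq_len(1000) / rate
  tone <- sin(2 * pi * 6 * t)
  f6 <- eegFreqFeatures(tone, rate, c(4, 8))
  binW <- rate / 1000
  expect_equal(f6[["CF"]], 6, tolerance = binW)
  expect_lt(f6[["FV"]], 0.01)
  expect_equal(f6[["MSF"]], 36, tolerance = 2 * 6 * binW)

  two <- sin(2 * pi * 5 * t) + sin(2 * pi * 7 * t)
  f57 <- eegFreqFeatures(two, rate, c(4, 8))
  expect_equal(f57[["CF"]], 6, tolerance = binW)
  expect_equal(f57[["FV"]], 1, tolerance = 0.05)

  set.seed(2)
  for (i in 1:5) {
    x <- rnorm(1000)
    got <- eegFreqFeatures(x, rate, c(8, 13))
    # direct weighted-sum-over-bins oracle
    X <- fft(x); P <- (Mod(X)^2 / 1000)[1:501]
    f <- (0:500) * rate / 1000
    sel <- f >= 8 & f < 13
    cf <- sum(f[sel] * P[sel]) / sum(P[sel])
    msf <- sum(f[sel]^2 * P[sel]) / sum(P[sel])
    expect_equal(got[["PSD"]], mean(P[sel]), tolerance = 1e-9)
    expect_equal(got[["CF"]], cf, tolerance = 1e-9)
    expect_equal(got[["MSF"]], msf, tolerance = 1e-9)
    expect_equal(got[["FV"]], msf - cf^2, tolerance = 1e-9)
    expect_true(got[["CF"]] >= 8 && got[["CF"]] < 13)
  }

  expect_warning(z <- eegFreqFeatures(rep(0, 1000), rate, c(8, 13)),
                 "zero in-band power")
  expect_equal(unname(z), c(0, 0, 0, 0))
})

test_that("ECG moments match conventions and a moment oracle", {
  sym <- ecgFeatures(c(-2, -1, 0, 1, 2))
  expect_equal(sym[["MEAN"]], 0)
  expect_equal(sym[["SKEW"]], 0)
  expect_equal(sym[["MAX"]], 2)
  expect_equal(sym[["MIN"]], -2)

  set.seed(3)
  big <- rnorm(200000)
  g <- ecgFeatures(big)
  expect_equal(g[["SKEW"]], 0, tolerance = 0.03)   # Gaussian g1
  expect_equal(g[["KURT"]], 0, tolerance = 0.06)   # excess convention

  for (i in 1:5) {
    x <- rexp(300) - rnorm(300)^2
    got <- ecgFeatures(x)
    n <- length(x); m <- sum(x) / n
    mk <- function(k) sum((x - m)^k) / n
    oracle <- c(MEAN = m, SD = sqrt(mk(2)), VAR = mk(2), MAX = max(x),
                MIN = min(x), SKEW = mk(3) / mk(2)^1.5,
                KURT = mk(4) / mk(2)^2 - 3)
    expect_equal(got, oracle, tolerance = 1e-10)
    expect_equal(got[["SD"]]^2, got[["VAR"]], tolerance = 1e-12)
  }

  expect_warning(k <- ecgFeatures(rep(5, 10)), "degenerate")
  expect_equal(unname(k[c("SKEW", "KURT")]), c(0, 0))
  expect_error(ecgFeatures(1:3), ">= 4 samples")
})

test_that("the feature matrix has the documented shape, order and cells", {
  spec <- cohortSpec(nSubjects = 1, durationS = 20, seed = 13)
  es <- preprocessPair(synthesizeEEG(spec, 1, "alert"),
                       synthesizeECG(spec, 1, "alert"), keepS = 20)
  fm <- buildFeatureMatrix(es)
  expect_s4_class(fm, "FeatureSet")
  expect_equal(nrow(fm), 16 * 4 * 8 + 7)
  expect_equal(ncol(fm), nEpochs(es))
  expect_false(isNormalized(fm))

  # deterministic channel-major, band-minor, feature-last order
  fm2 <- buildFeatureMatrix(es)
  expect_identical(rownames(fm), rownames(fm2))
  expect_identical(rownames(fm)[1:9],
                   c(paste("FP1.delta", eegFeatureTypes(), sep = "."),
                     "FP1.theta.MEA"))
  expect_identical(tail(rownames(fm), 7),
                   paste("ECG", ecgFeatureTypes(), sep = "."))

  # spot-check: matrix cells equal the single-segment ops applied directly
  x <- SummarizedExperiment::assay(fm, "features")
  ep <- getEpoch(es, 5)
  direct <- eegTimeFeatures(ep$eeg$theta["C3", ])
  expect_equal(x["C3.theta.MEA", 5], direct[["MEA"]], tolerance = 1e-12)
  expect_equal(x["C3.theta.ENE", 5], direct[["ENE"]], tolerance = 1e-12)
  raw <- Reduce(`+`, ep$eeg)
  spect <- eegFreqFeatures(raw["O2", ], 500, c(8, 13))
  expect_equal(x["O2.alpha.CF", 5], spect[["CF"]], tolerance = 1e-12)
  moments <- ecgFeatures(ep$ecg[1, ])
  expect_equal(x["ECG.SKEW", 5], moments[["SKEW"]], tolerance = 1e-12)
})

test_that("feature identities hold over generated epochs", {
  # identities must be checked on raw features; build a tiny raw set
  spec <- cohortSpec(nSubjects = 1, durationS = 30, seed = 14)
  raw <- cohortFeatures(spec, normalize = FALSE)
  x <- SummarizedExperiment::assay(raw, "features")
  for (ch in c("FP1", "O2")) for (b in c("delta", "beta")) {
    pre <- paste(ch, b, sep = ".")
    expect_equal(x[paste0(pre, ".RMS"), ]^2,
                 x[paste0(pre, ".VAR"), ] + x[paste0(pre, ".MEA"), ]^2,
                 tolerance = 1e-10)
    expect_equal(x[paste0(pre, ".ENE"), ], 1000 * x[paste0(pre, ".RMS"), ]^2,
                 tolerance = 1e-10)
    expect_true(all(x[paste0(pre, ".FV"), ] >= 0))
  }
})

test_that("per-subject z-scoring is exact, idempotent and baseline-invariant", {
  # hand oracle: population SD of (1,2,3) is sqrt(2/3)
  z <- (c(1, 2, 3) - 2) / sqrt(2 / 3)
  expect_equal(z, c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  spec <- cohortSpec(nSubjects = 2, durationS = 20, seed = 15)
  raw <- cohortFeatures(spec, normalize = FALSE)
  fm <- zscoreBySubject(raw)
  expect_true(isNormalized(fm))
  x <- SummarizedExperiment::assay(fm, "features")
  cd <- SummarizedExperiment::colData(fm)
  for (s in unique(cd$subject_id)) {
    sub <- x[, cd$subject_id == s]
    expect_equal(max(abs(rowMeans(sub))), 0, tolerance = 1e-10)
    expect_equal(range(sqrt(rowMeans(sub^2))), c(1, 1), tolerance = 1e-10)
  }
  # idempotence
  again <- zscoreBySubject(fm)
  expect_equal(SummarizedExperiment::assay(again, "features"), x,
               tolerance = 1e-12)
  # per-subject constant offsets vanish
  shifted <- raw
  xs <- SummarizedExperiment::assay(shifted, "features")
  cdr <- SummarizedExperiment::colData(shifted)
  xs[, cdr$subject_id == "S01"] <- xs[, cdr$subject_id == "S01"] + 100
  SummarizedExperiment::assay(shifted, "features") <- xs
  expect_equal(SummarizedExperiment::assay(zscoreBySubject(shifted), "features"),
               x, tolerance = 1e-8)
})

test_that("feature TSV round-trips with a stable header", {
  spec <- cohortSpec(nSubjects = 1, durationS = 10, seed = 16)
  fm <- cohortFeatures(spec)
  p1 <- file.path(tempdir(), "f1.tsv"); p2 <- file.path(tempdir(), "f2.tsv")
  writeFeatureTSV(fm, p1); writeFeatureTSV(fm, p2)
  expect_identical(readLines(p1)[1], readLines(p2)[1])
  back <- readFeatureTSV(p1)
  expect_equal(SummarizedExperiment::assay(back, "features"),
               SummarizedExperiment::assay(fm, "features"),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(isNormalized(back))
})
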