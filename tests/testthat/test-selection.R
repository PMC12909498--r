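test_that("two-group ANOVA matches a sums-of-squares oracle and equals t^2", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  # direct sums-of-squares oracle: F = (SSB/dfB) / (SSW/dfW), p from F(1,4)
  g <- mean(c(a, b))
  ssb <- 3 * (mean(a) - g)^2 + 3 * (mean(b) - g)^2
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  Fstat <- ssb / (ssw / 4)
  expect_equal(anovaPValue(a, b), pf(Fstat, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_warning(p1 <- anovaPValue(c(1, 1, 1), c(1, 1, 1)), "degenerate")
  expect_equal(p1, 1)

  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(sample(5:30, 1), mean = runif(1))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(anovaPValue(x, y), tt$p.value, tolerance = 1e-10)
    # F = t^2 equivalence through the shared p-value and statistic
    Fst <- oneway.test(c(x, y) ~ rep(1:2, c(length(x), length(y))),
                       var.equal = TRUE)$statistic
    expect_equal(unname(Fst), unname(tt$statistic)^2, tolerance = 1e-10)
  }
  expect_error(anovaPValue(1, c(1, 2)), ">= 2 values")
})

test_that("rank-sum AUC equals the pairwise oracle, handles ties, needs both classes", {
  expect_equal(aucRank(c(5, 4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE, FALSE)), 1)
  expect_equal(aucRank(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(aucRank(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  pairwiseAUC <- function(s, l) {
    pos <- s[l]; neg <- s[!l]
    wins <- 0
    for (p in pos) for (n in neg)
      wins <- wins + (p > n) + 0.5 * (p == n)
    wins / (length(pos) * length(neg))
  }
  set.seed(5)
  for (i in 1:200) {
    n <- sample(4:20, 1)
    s <- sample(seq(0, 2, by = 0.25), n, replace = TRUE)  # force ties
    l <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    expect_equal(aucRank(s, l), pairwiseAUC(s, l), tolerance = 1e-12)
  }
  # independent library cross-check
  set.seed(6)
  s <- rnorm(60); l <- rep(c("alert", "fatigue"), 30)
  expect_equal(aucRank(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, levels = c("alert", "fatigue"),
                                              direction = "<", quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("ANOVA screening retains effect-bearing types and honours thresholds", {
  fm <- smallCohortFeatures()
  rep <- anovaScreen(fm)
  # amplitude effects drive the amplitude-sensitive features in every band
  expect_true(all(c("ENE", "VAR", "RMS", "PSD") %in% rep@retainedEEG))
  expect_false("MEA" %in% rep@retainedEEG)   # mean of a zero-mean oscillation
  expect_true(all(rep@pValues$p >= 0 & rep@pValues$p <= 1))
  expect_equal(dim(rep@eegCounts), c(8L, 4L))

  # degenerate bound: every type with >= 1 significant pair anywhere survives
  rep0 <- anovaScreen(fm, minChannels = 0)
  expect_equal(sort(rep0@retainedEEG), sort(eegFeatureTypes()))

  single <- new("FeatureSet", fm[, SummarizedExperiment::colData(fm)$state == "alert"])
  expect_error(anovaScreen(single), "both states")
})

test_that("screening a null cohort rejects at roughly the nominal rate", {
  fm <- nullCohortFeatures()
  rep <- anovaScreen(fm)
  rate <- mean(rep@pValues$p < 0.01)
  expect_lt(rate, 0.03)
  expect_length(rep@retainedEEG, 0)
})

test_that("channel ranking recovers the injected occipital channels", {
  fm <- smallCohortFeatures()
  rep <- anovaScreen(fm)
  rk <- rankChannels(fm, rep, cfg = svmConfig(seed = 7), mode = "fused")
  expect_true(all(rk@aucFused >= 0 & rk@aucFused <= 1))
  expect_setequal(rk@ranking, eegMontage())
  expect_setequal(head(rk@ranking, 2), c("O1", "O2"))
  # deterministic given the seed
  rk2 <- rankChannels(fm, rep, cfg = svmConfig(seed = 7), mode = "fused")
  expect_identical(rk@aucFused, rk2@aucFused)
})

test_that("permuted labels give chance-level channel AUC", {
  fm <- smallCohortFeatures()
  rep <- anovaScreen(fm, minChannels = 0)  # keep types regardless of effect
  cd <- SummarizedExperiment::colData(fm)
  set.seed(8)
  perm <- fm
  SummarizedExperiment::colData(perm)$state <- sample(cd$state)
  rk <- rankChannels(new("FeatureSet", perm), rep,
                     cfg = svmConfig(seed = 8, folds = 5), mode = "fused")
  expect_true(all(abs(rk@aucFused - 0.5) < 0.06))
})

test_that("channel selection rules cut the ranking as documented", {
  auc <- setNames(c(rep(0.62, 8), rep(0.5, 8)), eegMontage())
  rk <- new("ChannelRanking",
            aucPerBand = matrix(NA_real_, 16, 4,
                                dimnames = list(eegMontage(),
                                                names(defaultBandEdges()))),
            aucFused = auc, mode = "fused",
            ranking = eegMontage()[order(-auc, seq_along(auc))],
            selected = character(0), rule = list())
  expect_setequal(selectedChannels(chooseChannels(rk, list(top_k = 16))),
                  eegMontage())
  sel <- chooseChannels(rk, list(min_auc = 0.55))
  expect_setequal(selectedChannels(sel), eegMontage()[1:8])
  expect_warning(fb <- chooseChannels(rk, list(min_auc = 1.1)), "falling back")
  expect_length(selectedChannels(fb), 1)
  expect_equal(selectedChannels(chooseChannels(rk, list(top_k = 3))),
               rk@ranking[1:3])
})

test_that("fusion widths follow the selection arithmetic", {
  fm <- smallCohortFeatures()
  mkReport <- function(eeg, ecg)
    new("AnovaReport", pValues = data.frame(), eegCounts = matrix(0, 8, 4),
        retainedEEG = eeg, retainedECG = ecg, alpha = 0.01, minChannels = 10)

  # reference selection outcome: 6 types x 4 bands x 8 channels + 4 ECG = 196
  rep6 <- mkReport(c("ENE", "VAR", "RMS", "PSD", "CF", "MSF"),
                   c("SD", "VAR", "MAX", "SKEW"))
  fused <- fuseFeatures(fm, rep6, eegMontage()[c(1, 2, 7, 8, 9, 10, 15, 16)])
  expect_equal(nrow(fused), 196)

  # no-selection identity: 8 types x 4 bands x 16 channels + 7 ECG = 519
  repAll <- mkReport(eegFeatureTypes(), ecgFeatureTypes())
  expect_equal(nrow(fuseFeatures(fm, repAll, eegMontage())), 519)

  # minimal: 1 type x 4 bands x 1 channel + 0 ECG = 4
  rep1 <- mkReport("PSD", character(0))
  expect_equal(nrow(fuseFeatures(fm, rep1, "O1")), 4)

  expect_error(fuseFeatures(fm, rep1, character(0)), "empty channel set")
})

test_that("selection artifacts serialize to JSON", {
  fm <- smallCohortFeatures()
  rep <- anovaScreen(fm)
  p <- file.path(tempdir(), "anova.json")
  writeAnovaReport(rep, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$alpha, 0.01)
  expect_setequal(back$retained_eeg, rep@retainedEEG)
  tab <- significanceTable(rep)
  expect_equal(nrow(tab), 8 * 4)
})
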