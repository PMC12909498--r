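rms <- function(x) sqrt(mean(x^2))

test_that("band-pass attenuates stop-band tones, passes in-band tones, kills DC", {
  stop50 <- toneRecording(50)
  expect_lt(rms(bandpassFilter(stop50)@samples) / rms(stop50@samples), 0.05)

  pass10 <- toneRecording(10)
  expect_equal(rms(bandpassFilter(pass10)@samples) / rms(pass10@samples), 1,
               tolerance = 0.05)

  dc <- Recording("S01", "alert", "ECG", 500, rep(3, 5000))
  expect_lt(max(abs(bandpassFilter(dc)@samples)), 1e-6)
})

test_that("band-pass is zero-phase and approximately idempotent in band", {
  pass10 <- toneRecording(10)
  once <- bandpassFilter(pass10)
  # zero phase: the filtered tone stays aligned with the input
  expect_gt(cor(as.numeric(once@samples), as.numeric(pass10@samples)), 0.999)
  twice <- bandpassFilter(once)
  expect_lt(abs(rms(twice@samples) / rms(once@samples) - 1), 0.01)
})

test_that("band edges at or above Nyquist are rejected naming the rate", {
  rec <- toneRecording(10, rate = 50)
  expect_error(bandpassFilter(rec, 0.5, 30), "rate 50")
  expect_error(bandpassFilter(rec, 5, 2), "lo < hi")
})

test_that("a 6 Hz tone lands in the theta band with >= 99% of its energy", {
  rec <- toneRecording(6)
  bd <- decomposeBands(bandpassFilter(rec))
  energies <- vapply(bd@bandSignals, function(m) sum(m^2), numeric(1))
  expect_gt(energies[["theta"]] / sum(energies), 0.99)
})

test_that("band signals sum back to the brick-wall-filtered input", {
  set.seed(8)
  rec <- Recording("S01", "alert", "EEG", 500,
                   matrix(rnorm(16 * 5000), 16, 5000))
  filt <- bandpassFilter(rec)
  bd <- decomposeBands(filt)
  recon <- Reduce(`+`, bd@bandSignals)
  # oracle: single brick-wall mask over the union of the band supports
  n <- ncol(filt@samples); f <- pmin(0:(n - 1), n:1) * 500 / n
  keep <- f >= 0.5 & f <= 30
  direct <- t(apply(filt@samples, 1, function(x) {
    z <- fft(x); z[!keep] <- 0; Re(fft(z, inverse = TRUE)) / n
  }))
  expect_lt(max(abs(recon - direct)) / max(abs(direct)), 1e-8)
})

test_that("white-noise band energies are proportional to band widths", {
  set.seed(9)
  rec <- Recording("S01", "alert", "ECG", 500, rnorm(250000))
  bd <- decomposeBands(rec)  # no pre-filter: flat spectrum across bands
  energies <- vapply(bd@bandSignals, function(m) sum(m^2), numeric(1))
  widths <- vapply(bd@bandEdges, diff, numeric(1))
  ratio <- (energies / sum(energies)) / (widths / sum(widths))
  expect_equal(unname(ratio), rep(1, 4), tolerance = 0.05)
})

test_that("overlapping band edges are rejected", {
  rec <- toneRecording(6)
  expect_error(decomposeBands(rec, list(a = c(1, 8), b = c(6, 12))), "overlap")
})

test_that("alignment trims both modalities to the later start", {
  spec <- cohortSpec(nSubjects = 1, durationS = 12, seed = 2)
  eeg <- synthesizeEEG(spec, 1, "alert")
  ecg <- synthesizeECG(spec, 1, "alert")
  al <- alignAndTrim(eeg, ecg, keepS = 10)
  expect_equal(ncol(al$eeg@samples), 10 * 500)
  expect_equal(ncol(al$ecg@samples), 10 * 250)
  expect_equal(al$eeg@startTime, al$ecg@startTime)

  # EEG starting 3 s later forces both to the EEG start
  eeg2 <- eeg; eeg2@startTime <- 3
  al2 <- alignAndTrim(eeg2, ecg, keepS = 5)
  expect_equal(al2$eeg@startTime, 3)
  expect_equal(al2$ecg@startTime, 3)
  expect_identical(al2$ecg@samples[1, 1:100],
                   ecg@samples[1, 3 * 250 + 1:100])

  expect_error(alignAndTrim(eeg, ecg, keepS = 600), "overlap is 12")
})

test_that("epoch counts follow floor((duration - window)/step) + 1", {
  mkEpochs <- function(durationS) {
    spec <- cohortSpec(nSubjects = 1, durationS = durationS, seed = 4)
    preprocessPair(synthesizeEEG(spec, 1, "alert"),
                   synthesizeECG(spec, 1, "alert"), keepS = durationS)
  }
  expect_equal(nEpochs(mkEpochs(2)), 1)
  expect_equal(nEpochs(mkEpochs(10)), 9)

  # count formula as a property over window/step combinations
  es <- mkEpochs(13)
  bd <- new("BandDecomposition", subjectId = "S01", state = "alert",
            rate = 500, channelLabels = eegMontage(), startTime = 0,
            bandEdges = defaultBandEdges(), bandSignals = es@eegBands)
  ecg <- Recording("S01", "alert", "ECG", 250, es@ecg)
  for (w in c(2, 3, 5)) for (s in c(1, 2, w)) {
    if (s > w) next
    es2 <- segmentEpochs(bd, ecg, windowS = w, stepS = s)
    expect_equal(nEpochs(es2), floor((13 - w) / s) + 1,
                 info = sprintf("w=%g s=%g", w, s))
  }
})

test_that("consecutive overlapping epochs share their overlap samples exactly", {
  spec <- cohortSpec(nSubjects = 1, durationS = 8, seed = 6)
  es <- preprocessPair(synthesizeEEG(spec, 1, "alert"),
                       synthesizeECG(spec, 1, "alert"), keepS = 8)
  e1 <- getEpoch(es, 1); e2 <- getEpoch(es, 2)
  # window 2 s, step 1 s: the last 1 s of epoch 1 is the first 1 s of epoch 2
  expect_identical(e1$eeg$alpha[, 501:1000], e2$eeg$alpha[, 1:500])
  expect_identical(e1$ecg[, 251:500, drop = FALSE],
                   e2$ecg[, 1:250, drop = FALSE])
})

test_that("sub-window recordings give an empty epoch set with a warning", {
  spec <- cohortSpec(nSubjects = 1, durationS = 1.5, seed = 6)
  eeg <- synthesizeEEG(spec, 1, "alert")
  ecg <- synthesizeECG(spec, 1, "alert")
  bd <- decomposeBands(bandpassFilter(eeg))
  expect_warning(es <- segmentEpochs(bd, bandpassFilter(ecg)),
                 "shorter than one window")
  expect_equal(nEpochs(es), 0)
})
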