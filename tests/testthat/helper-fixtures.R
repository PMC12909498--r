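# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Small default-effect cohort: 6 subjects x 60 s per state.
smallCohortFeatures <- function() {
  fixture("small_fm", function()
    cohortFeatures(cohortSpec(nSubjects = 6, durationS = 60, seed = 42)))
}

# Matching null cohort (no injected effects anywhere).
nullSpec <- function(nSubjects = 6, durationS = 60, seed = 99) {
  m <- defaultBandEffects(); m[, ] <- 1
  cohortSpec(nSubjects = nSubjects, durationS = durationS, bandEffects = m,
             ecgEffects = c(rrStdMult = 1, skewShift = 0), seed = seed)
}

# Null features are built from non-overlapping epochs (step = window):
# overlapping epochs are autocorrelated, which inflates the F-test's level
# above its nominal alpha even with no effect present.
nullCohortFeatures <- function() {
  fixture("null_fm", function() cohortFeatures(nullSpec(), stepS = 2))
}

# Sine-wave test recording helper.
toneRecording <- function(freqs, amps = rep(1, length(freqs)), rate = 500,
                          durationS = 10, modality = "ECG") {
  t <- seq_len(rate * durationS) / rate
  x <- rowSums(vapply(seq_along(freqs),
                      function(i) amps[i] * sin(2 * pi * freqs[i] * t),
                      numeric(length(t))))
  Recording("S01", "alert", modality, rate, x)
}

# Direct periodogram band-power oracle: mean of |X_k|^2 / N over band bins.
bandPowerOracle <- function(x, rate, lo, hi) {
  n <- length(x)
  P <- Mod(fft(x))^2 / n
  f <- (0:(n - 1)) * rate / n
  half <- f <= rate / 2
  sum(P[half & f >= lo & f < hi]) / n * 2
}
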