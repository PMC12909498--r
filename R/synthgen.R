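## Synthetic fatigue-modulated cohort generator.
##
## Each EEG channel is a sum of four band-limited Gaussian oscillations
## (white noise brick-wall filtered to each clinical band, scaled so the
## expected RMS equals the subject's baseline amplitude times the state
## multiplier) plus broadband Gaussian noise. The ECG is a train of
## Gaussian-bump PQRST-like beats with Gaussian RR jitter; fatigue scales
## the RR standard deviation and asymmetrizes the T bump.

.MOD31 <- 2147483647

## Seed ladder: master -> per-subject -> per-state -> per-modality
## substreams, so adding subjects or states never perturbs earlier draws.
## A short LCG walk keeps everything below 2^31 (and in exact double range).
.deriveSeed <- function(master, ...) {
  s <- (abs(as.numeric(master)) %% .MOD31)
  for (k in c(...)) s <- (s * 16807 + as.numeric(k) + 1) %% .MOD31
  as.integer(s)
}

.stateIndex <- function(state) {
  i <- match(state, .STATES)
  if (is.na(i)) stop(sprintf(
    "unknown state '%s'; expected one of: %s", state,
    paste(.STATES, collapse = ", ")), call. = FALSE)
  i
}

#' Default fatigue band-power effect multipliers
#'
#' Amplitude multipliers applied to each (band, channel) oscillation in the
#' fatigue state, encoding the expected spectral signature of mental
#' fatigue: a global slow-wave (delta and theta) rise, stronger theta
#' elevation over frontal and parietal sites, alpha elevation over
#' frontal/parietal sites that is strongest occipitally (diminished visual
#' vigilance), and a mild global beta suppression.
#'
#' @param channels channel labels (default the 16-electrode montage).
#' @return 4 x 16 numeric matrix, rows = bands, columns = channels.
#' @export
#' @examples
#' defaultBandEffects()["alpha", c("O1", "FP1")]
defaultBandEffects <- function(channels = eegMontage()) {
  m <- matrix(1, nrow = 4, ncol = length(channels),
              dimnames = list(names(defaultBandEdges()), channels))
  frontal  <- grep("^F", channels, value = TRUE)      # FP1 FP2 F3 F4 F7 F8
  parietal <- grep("^P", channels, value = TRUE)
  occip    <- grep("^O", channels, value = TRUE)
  m["delta", ] <- 1.12
  m["theta", ] <- 1.07
  m["theta", c(frontal, parietal)] <- 1.12
  m["alpha", c(frontal, parietal)] <- 1.07
  m["alpha", occip] <- 1.26
  m["beta", ] <- 0.92
  m
}

#' Specification of a synthetic alert/fatigue cohort
#'
#' Defines the study conditions for the generator: cohort size, recording
#' durations and rates matching the acquisition protocol (10-min EEG at
#' 500 Hz on the 16-electrode montage; single-channel ECG at 250 Hz), the
#' injected fatigue effects, between-subject baseline variability, and the
#' master seed.
#'
#' @param nSubjects number of subjects (>= 1).
#' @param durationS recording duration per state in seconds (default 600).
#' @param eegRate EEG sampling rate in Hz (default 500).
#' @param ecgRate ECG sampling rate in Hz (default 250).
#' @param channelLabels EEG montage labels (must match [eegMontage()]).
#' @param bandEffects band x channel matrix of fatigue amplitude
#'   multipliers (default [defaultBandEffects()]); all entries > 0.
#' @param ecgEffects named numeric with `rrStdMult` (fatigue multiplier on
#'   the RR-interval standard deviation) and `skewShift` (asymmetry added
#'   to the T-analogue bump under fatigue).
#' @param subjectVariability log-scale SD of per-subject baseline band
#'   amplitudes (log-normal draws; default 0.3).
#' @param noiseLevel relative broadband noise amplitude (default 1).
#' @param spatialCorrelation fraction of each band oscillation's variance
#'   shared across all channels (volume-conduction analogue; default 0.6).
#'   Inter-channel correlation keeps the joint information of the montage
#'   far below the sum of its per-channel effects, as on real scalp data.
#' @param seed master integer seed.
#' @return A `CohortSpec` S4 object.
#' @export
#' @examples
#' spec <- cohortSpec(nSubjects = 2, durationS = 20, seed = 7)
#' spec
cohortSpec <- function(nSubjects, durationS = 600, eegRate = 500,
                       ecgRate = 250, channelLabels = eegMontage(),
                       bandEffects = defaultBandEffects(channelLabels),
                       ecgEffects = c(rrStdMult = 1.3, skewShift = 0.25),
                       subjectVariability = 0.3, noiseLevel = 1,
                       spatialCorrelation = 0.6, seed = 1) {
  new("CohortSpec", nSubjects = nSubjects, durationS = durationS,
      eegRate = eegRate, ecgRate = ecgRate, channelLabels = channelLabels,
      bandEffects = bandEffects, ecgEffects = ecgEffects,
      subjectVariability = subjectVariability, noiseLevel = noiseLevel,
      spatialCorrelation = spatialCorrelation, seed = seed)
}

#' @rdname cohortSpec
#' @export
setClass("CohortSpec",
  representation(nSubjects = "numeric", durationS = "numeric",
                 eegRate = "numeric", ecgRate = "numeric",
                 channelLabels = "character", bandEffects = "matrix",
                 ecgEffects = "numeric", subjectVariability = "numeric",
                 noiseLevel = "numeric", spatialCorrelation = "numeric",
                 seed = "numeric"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nSubjects < 1) msg <- c(msg, "nSubjects must be >= 1")
  if (object@durationS <= 0) msg <- c(msg, "durationS must be > 0")
  if (!identical(object@channelLabels, eegMontage()))
    msg <- c(msg, "channelLabels must match the standard 16-electrode montage")
  if (any(object@bandEffects <= 0)) msg <- c(msg, "all multipliers must be > 0")
  if (!identical(rownames(object@bandEffects), names(defaultBandEdges())))
    msg <- c(msg, "bandEffects rows must be delta, theta, alpha, beta")
  if (!all(c("rrStdMult", "skewShift") %in% names(object@ecgEffects)))
    msg <- c(msg, "ecgEffects must name rrStdMult and skewShift")
  if (object@ecgEffects[["rrStdMult"]] <= 0)
    msg <- c(msg, "rrStdMult must be > 0")
  if (object@spatialCorrelation < 0 || object@spatialCorrelation >= 1)
    msg <- c(msg, "spatialCorrelation must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d subject(s), %g s/state, EEG %g Hz x 16 ch, ECG %g Hz\n",
    object@nSubjects, object@durationS, object@eegRate, object@ecgRate))
  cat(sprintf("  alpha multiplier on O1/O2: %g; rrStdMult %g; seed %g\n",
              object@bandEffects["alpha", "O1"],
              object@ecgEffects[["rrStdMult"]], object@seed))
})

## Baseline EEG band amplitudes (uV RMS) before subject variability; the
## roughly 1/f ordering with an alpha bump mimics resting scalp spectra.
.BASE_AMP <- c(delta = 8, theta = 5, alpha = 6, beta = 3)
.NOISE_AMP <- 3  # uV RMS of broadband noise at noiseLevel = 1

## Per-subject baseline band amplitudes, drawn from the subject's own
## substream (state-independent, so alert and fatigue share baselines).
.subjectBaselines <- function(spec, subjectIndex) {
  set.seed(.deriveSeed(spec@seed, subjectIndex, 0, 1))
  nb <- length(.BASE_AMP); nc <- length(spec@channelLabels)
  amp <- .BASE_AMP * matrix(exp(rnorm(nb * nc, 0, spec@subjectVariability)),
                            nrow = nb, dimnames = dimnames(spec@bandEffects))
  amp
}

## Per-subject ECG baselines: mean RR around 0.85 s, RR jitter SD 40 ms.
.subjectEcgBaseline <- function(spec, subjectIndex) {
  set.seed(.deriveSeed(spec@seed, subjectIndex, 0, 2))
  list(meanRR = 0.85 * exp(rnorm(1, 0, spec@subjectVariability / 3)),
       rrSd = 0.04 * exp(rnorm(1, 0, spec@subjectVariability / 3)))
}

## Frequency mask helpers: |f| in [lo, hi) (closed at the top for the band
## that ends the global pass band), over the two-sided FFT bin grid.
.fftFreqs <- function(n, rate) {
  k <- 0:(n - 1)
  pmin(k, n - k) * rate / n
}

.bandMask <- function(f, lo, hi, closeHi = FALSE) {
  if (closeHi) f >= lo & f <= hi else f >= lo & f < hi
}

#' Synthesize one subject's EEG recording
#'
#' Generates a 16-channel EEG recording for one subject in one state. Each
#' channel is the sum of four band-limited Gaussian oscillations whose RMS
#' amplitudes are the subject's log-normal baselines times the state
#' multipliers (1 in the alert state), plus independent broadband Gaussian
#' noise. Band power therefore scales as multiplier squared. Deterministic
#' given `(seed, subjectIndex, state)`.
#'
#' @param spec a [cohortSpec()].
#' @param subjectIndex subject number in `1:nSubjects`.
#' @param state `"alert"` or `"fatigue"`.
#' @return A [Recording-class] with 16 x `durationS * eegRate` samples.
#' @export
#' @examples
#' spec <- cohortSpec(nSubjects = 1, durationS = 4, seed = 3)
#' rec <- synthesizeEEG(spec, 1, "alert")
#' dim(rec@samples)
synthesizeEEG <- function(spec, subjectIndex, state) {
  si <- .stateIndex(state)
  stopifnot(subjectIndex >= 1, subjectIndex <= spec@nSubjects)
  n <- round(spec@durationS * spec@eegRate)
  amp <- .subjectBaselines(spec, subjectIndex)
  if (state == "fatigue") amp <- amp * spec@bandEffects
  edges <- defaultBandEdges()
  f <- .fftFreqs(n, spec@eegRate)
  topHi <- max(vapply(edges, `[`, numeric(1), 2L))
  masks <- lapply(names(edges), function(b) {
    e <- edges[[b]]
    .bandMask(f, e[1L], e[2L], closeHi = e[2L] == topHi)
  })
  names(masks) <- names(edges)
  ## gain per bin: amplitude / sqrt(band bin fraction) gives expected unit
  ## RMS per band before scaling (white noise spreads variance evenly).
  set.seed(.deriveSeed(spec@seed, subjectIndex, si, 10))
  rho <- spec@spatialCorrelation
  W0 <- fft(rnorm(n))  # band oscillation component shared by all channels
  out <- matrix(0, nrow = length(spec@channelLabels), ncol = n)
  for (c in seq_along(spec@channelLabels)) {
    gain <- numeric(n)
    for (b in names(edges))
      gain[masks[[b]]] <- amp[b, c] / sqrt(sum(masks[[b]]) / n)
    w <- sqrt(rho) * W0 + sqrt(1 - rho) * fft(rnorm(n))
    osc <- Re(fft(gain * w, inverse = TRUE)) / n
    out[c, ] <- osc + spec@noiseLevel * .NOISE_AMP * rnorm(n)
  }
  Recording(sprintf("S%02d", subjectIndex), state, "EEG", spec@eegRate, out,
            channelLabels = spec@channelLabels, startTime = 0)
}

## Gaussian-bump PQRST-like beat template evaluated at offsets t (seconds)
## from the R peak. The T-analogue bump is asymmetrized by `skew`: its
## right-hand width is inflated by (1 + skew), shifting the waveform's
## third moment.
.ecgTemplate <- function(t, skew = 0) {
  g <- function(t0, sigma, a) a * exp(-((t - t0)^2) / (2 * sigma^2))
  tSigma <- ifelse(t >= 0.30, 0.07 * (1 + skew), 0.07)
  p <- g(-0.20, 0.045, 0.15)
  q <- g(-0.040, 0.012, -0.15)
  r <- g(0, 0.020, 1.0)
  s <- g(0.040, 0.015, -0.25)
  tw <- 0.35 * exp(-((t - 0.30)^2) / (2 * tSigma^2))
  p + q + r + s + tw
}

#' Synthesize one subject's ECG recording
#'
#' Generates a single-channel ECG as a periodic train of Gaussian-bump
#' PQRST-like beats. RR intervals are Gaussian around the subject's
#' baseline mean RR; the fatigue state multiplies the RR standard
#' deviation by `ecgEffects["rrStdMult"]` and skews the T-analogue bump by
#' `ecgEffects["skewShift"]`. Deterministic given the seed context.
#'
#' @inheritParams synthesizeEEG
#' @return A [Recording-class] with 1 x `durationS * ecgRate` samples. The
#'   simulated RR intervals are attached as attribute `"rr"` of the
#'   samples matrix for recovery testing.
#' @export
synthesizeECG <- function(spec, subjectIndex, state) {
  si <- .stateIndex(state)
  stopifnot(subjectIndex >= 1, subjectIndex <= spec@nSubjects)
  base <- .subjectEcgBaseline(spec, subjectIndex)
  rrSd <- base$rrSd
  skew <- 0
  if (state == "fatigue") {
    rrSd <- rrSd * spec@ecgEffects[["rrStdMult"]]
    skew <- spec@ecgEffects[["skewShift"]]
  }
  if (spec@durationS < base$meanRR)
    stop(sprintf("duration %g s is shorter than one beat (mean RR %.2f s)",
                 spec@durationS, base$meanRR), call. = FALSE)
  n <- round(spec@durationS * spec@ecgRate)
  set.seed(.deriveSeed(spec@seed, subjectIndex, si, 20))
  nBeats <- ceiling(spec@durationS / (base$meanRR * 0.5)) + 2L
  rr <- pmax(0.3, rnorm(nBeats, base$meanRR, rrSd))
  beats <- cumsum(c(0.2, rr))
  beats <- beats[beats < spec@durationS + 0.5]
  x <- numeric(n)
  tGrid <- (seq_len(n) - 1) / spec@ecgRate
  halfW <- 0.55  # beat template support (s) either side of the R peak
  for (bt in beats) {
    i0 <- max(1L, floor((bt - halfW) * spec@ecgRate) + 1L)
    i1 <- min(n, ceiling((bt + halfW) * spec@ecgRate) + 1L)
    if (i0 > i1) next
    idx <- i0:i1
    x[idx] <- x[idx] + .ecgTemplate(tGrid[idx] - bt, skew = skew)
  }
  x <- x + spec@noiseLevel * 0.02 * rnorm(n)
  rec <- Recording(sprintf("S%02d", subjectIndex), state, "ECG",
                   spec@ecgRate, x, channelLabels = "ECG", startTime = 0)
  attr(rec@samples, "rr") <- rr[seq_len(min(length(rr), length(beats)))]
  rec
}

#' Ground truth of a synthetic cohort
#'
#' @slot bandMultipliers band x channel fatigue amplitude multipliers.
#' @slot ecgEffects the RR-SD multiplier and skew shift applied.
#' @slot seed master seed used.
#' @export
setClass("GroundTruth",
  representation(bandMultipliers = "matrix", ecgEffects = "numeric",
                 seed = "numeric"))

#' Generate a full synthetic cohort
#'
#' Synthesizes paired alert/fatigue EEG + ECG recordings for every subject
#' (all starting at a common timestamp per subject/state) together with a
#' [GroundTruth-class] manifest of the injected effects. For large cohorts
#' prefer [cohortFeatures()], which streams per subject and never holds
#' all recordings in memory.
#'
#' @param spec a [cohortSpec()].
#' @return List with `recordings` (per subject, per state: `eeg` and `ecg`
#'   [Recording-class] objects) and `groundTruth`.
#' @export
#' @examples
#' coh <- generateCohort(cohortSpec(nSubjects = 1, durationS = 6, seed = 1))
#' names(coh$recordings[["S01"]][["alert"]])
generateCohort <- function(spec) {
  recs <- lapply(seq_len(spec@nSubjects), function(s) {
    perState <- lapply(.STATES, function(st)
      list(eeg = synthesizeEEG(spec, s, st), ecg = synthesizeECG(spec, s, st)))
    names(perState) <- .STATES
    perState
  })
  names(recs) <- sprintf("S%02d", seq_len(spec@nSubjects))
  gt <- new("GroundTruth", bandMultipliers = spec@bandEffects,
            ecgEffects = spec@ecgEffects, seed = spec@seed)
  list(recordings = recs, groundTruth = gt)
}

#' Stream a cohort straight to features
#'
#' Synthesizes each subject/state pair, runs the preprocessing chain
#' (band-pass, band decomposition, alignment, segmentation) and feature
#' extraction, and discards the raw signals, returning one pooled
#' [FeatureSet-class]. This keeps memory flat in cohort size.
#'
#' @param spec a [cohortSpec()].
#' @param windowS,stepS epoch window and step in seconds (defaults 2 and 1).
#' @param normalize z-score per subject afterwards (default TRUE).
#' @param verbose print progress.
#' @return A [FeatureSet-class] covering all subjects and both states.
#' @export
cohortFeatures <- function(spec, windowS = 2, stepS = 1, normalize = TRUE,
                           verbose = FALSE) {
  blocks <- vector("list", spec@nSubjects * 2L)
  k <- 0L
  for (s in seq_len(spec@nSubjects)) {
    for (st in .STATES) {
      eeg <- synthesizeEEG(spec, s, st)
      ecg <- synthesizeECG(spec, s, st)
      es <- preprocessPair(eeg, ecg, keepS = spec@durationS,
                           windowS = windowS, stepS = stepS)
      k <- k + 1L
      blocks[[k]] <- buildFeatureMatrix(es)
      if (verbose) message(sprintf("  subject %d/%d %s: %d epochs",
                                   s, spec@nSubjects, st, nEpochs(es)))
    }
  }
  fm <- do.call(combineFeatureSets, blocks)
  if (normalize) fm <- zscoreBySubject(fm) else fm
}
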