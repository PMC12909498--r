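## Preprocessing: zero-phase band-pass filtering, brick-wall FFT band
## decomposition, timestamp alignment/trimming, and sliding-window
## segmentation into 2-s multimodal epochs.

## Squared-magnitude Butterworth response |H(f)|^2 on the two-sided FFT
## frequency grid of length n. Applying this gain in the frequency domain
## is the circular equivalent of forward-backward (zero-phase) filtering.
.butterGain2 <- function(n, rate, lo, hi, order = 4) {
  bf <- signal::butter(order, c(lo, hi) / (rate / 2), type = "pass")
  f <- .fftFreqs(n, rate)
  z <- exp(-2i * pi * f / rate)
  horner <- function(coef) {
    acc <- complex(length.out = n)
    for (c in coef) acc <- acc * z + c
    acc
  }
  Mod(horner(bf$b) / horner(bf$a))^2
}

#' Zero-phase band-pass filter a recording
#'
#' Applies a 4th-order Butterworth band-pass with zero phase (no group
#' delay) to every channel: the filter's squared-magnitude response --
#' exactly the response of a forward-backward pass -- is applied on the
#' FFT grid. The default 0.5-30 Hz band removes slow drifts (below
#' 0.5 Hz, including DC) and muscular high-frequency content.
#'
#' @param rec a [Recording-class].
#' @param lo,hi band edges in Hz; `0 < lo < hi < rate/2` required.
#' @param order Butterworth order (default 4).
#' @return A filtered [Recording-class] of identical shape.
#' @export
#' @examples
#' t <- seq(0, 2, by = 1 / 500)[-1]
#' rec <- Recording("S01", "alert", "ECG", 500, sin(2 * pi * 10 * t))
#' filt <- bandpassFilter(rec)
bandpassFilter <- function(rec, lo = 0.5, hi = 30, order = 4) {
  nyq <- rec@rate / 2
  if (!(lo > 0 && lo < hi))
    stop("band edges must satisfy 0 < lo < hi", call. = FALSE)
  if (hi >= nyq)
    stop(sprintf("upper edge %g Hz is at or above Nyquist (%g Hz for rate %g Hz)",
                 hi, nyq, rec@rate), call. = FALSE)
  n <- ncol(rec@samples)
  g <- .butterGain2(n, rec@rate, lo, hi, order)
  out <- rec
  for (c in seq_len(nrow(rec@samples)))
    out@samples[c, ] <- Re(fft(g * fft(rec@samples[c, ]), inverse = TRUE)) / n
  out
}

#' Brick-wall FFT band decomposition
#'
#' Splits an (already band-passed) recording into frequency-band components
#' by zeroing all FFT bins outside each band and inverse transforming.
#' Bands are half-open `[lo, hi)` except the band closing the global pass
#' band, which includes its upper edge. By linearity, the band signals sum
#' to the input restricted to the union of the band supports.
#'
#' @param rec a band-passed [Recording-class].
#' @param edges named list of `c(lo, hi)` pairs (default
#'   [defaultBandEdges()]); bands must not overlap and must lie within
#'   `(0, rate/2)`.
#' @param pregain optional length-`ncol(samples)` spectral gain applied
#'   before masking (used internally to fuse the zero-phase band-pass
#'   with the decomposition in one FFT pass).
#' @return A [BandDecomposition-class].
#' @export
decomposeBands <- function(rec, edges = defaultBandEdges(), pregain = NULL) {
  nyq <- rec@rate / 2
  em <- do.call(rbind, edges)
  if (any(em[, 1L] >= em[, 2L]) || any(em[, 1L] < 0) || any(em[, 2L] > nyq))
    stop("band edges must be increasing and within (0, rate/2)", call. = FALSE)
  o <- order(em[, 1L])
  if (any(em[o[-1L], 1L] < em[o[-length(o)], 2L]))
    stop("band edges overlap", call. = FALSE)
  n <- ncol(rec@samples)
  f <- .fftFreqs(n, rec@rate)
  topHi <- max(em[, 2L])
  masks <- lapply(edges, function(e)
    which(.bandMask(f, e[1L], e[2L], closeHi = e[2L] == topHi)))
  sig <- lapply(edges, function(e)
    matrix(0, nrow = nrow(rec@samples), ncol = n,
           dimnames = list(rec@channelLabels, NULL)))
  for (c in seq_len(nrow(rec@samples))) {
    z <- fft(rec@samples[c, ])
    if (!is.null(pregain)) z <- z * pregain
    for (b in names(edges)) {
      zb <- complex(length.out = n)
      zb[masks[[b]]] <- z[masks[[b]]]
      sig[[b]][c, ] <- Re(fft(zb, inverse = TRUE)) / n
    }
  }
  new("BandDecomposition", subjectId = rec@subjectId, state = rec@state,
      rate = rec@rate, channelLabels = rec@channelLabels,
      startTime = rec@startTime, bandEdges = edges, bandSignals = sig)
}

#' Align two recordings on the wall clock and trim to a common window
#'
#' Both recordings are trimmed to the same wall-clock window of length
#' `keepS` starting at the later of the two start times (the protocol
#' retains only the initial minutes of each synchronized session).
#'
#' @param eeg,ecg two [Recording-class] objects for the same subject and
#'   state with overlapping time ranges.
#' @param keepS seconds to keep (default 600).
#' @return List with trimmed `eeg` and `ecg`, both starting at the common
#'   start time, with `keepS * rate` samples each.
#' @export
alignAndTrim <- function(eeg, ecg, keepS = 600) {
  if (eeg@subjectId != ecg@subjectId || eeg@state != ecg@state)
    stop("recordings must come from the same subject and state", call. = FALSE)
  start <- max(eeg@startTime, ecg@startTime)
  end <- min(eeg@startTime + durationS(eeg), ecg@startTime + durationS(ecg))
  overlap <- end - start
  if (overlap < keepS)
    stop(sprintf("overlap is %.3f s but %.3f s requested", overlap, keepS),
         call. = FALSE)
  trim <- function(rec) {
    i0 <- round((start - rec@startTime) * rec@rate)
    out <- rec
    out@samples <- rec@samples[, i0 + seq_len(round(keepS * rec@rate)),
                               drop = FALSE]
    out@startTime <- start
    out
  }
  list(eeg = trim(eeg), ecg = trim(ecg))
}

#' Segment aligned recordings into overlapping multimodal epochs
#'
#' Cuts the band-decomposed EEG and the filtered ECG into sliding-window
#' epochs of `windowS` seconds advanced by `stepS` seconds (default 2 s
#' with 50\% overlap). Epoch count per recording is
#' `floor((duration - window) / step) + 1`; any trailing partial window is
#' discarded. EEG and ECG segments of one epoch cover the identical
#' wall-clock interval.
#'
#' @param eegBands a [BandDecomposition-class].
#' @param ecg the aligned, filtered ECG [Recording-class].
#' @param windowS,stepS window and step in seconds (`stepS <= windowS`).
#' @return An [EpochSet-class]; empty (with a warning) if the recording is
#'   shorter than one window.
#' @export
segmentEpochs <- function(eegBands, ecg, windowS = 2, stepS = 1) {
  stopifnot(stepS > 0, windowS > 0, stepS <= windowS)
  durE <- ncol(eegBands@bandSignals[[1L]]) / eegBands@rate
  durC <- ncol(ecg@samples) / ecg@rate
  if (abs(durE - durC) > 1 / min(eegBands@rate, ecg@rate))
    stop("EEG and ECG must be aligned and trimmed to equal duration",
         call. = FALSE)
  if (durE < windowS) {
    warning(sprintf("duration %.3f s is shorter than one window (%g s); empty epoch set",
                    durE, windowS))
    starts <- numeric(0)
  } else {
    nEp <- floor((durE - windowS) / stepS) + 1
    starts <- (seq_len(nEp) - 1) * stepS
  }
  new("EpochSet", subjectId = eegBands@subjectId, state = eegBands@state,
      windowS = windowS, stepS = stepS, eegRate = eegBands@rate,
      ecgRate = ecg@rate, channelLabels = eegBands@channelLabels,
      eegBands = eegBands@bandSignals, ecg = ecg@samples, starts = starts)
}

#' Full preprocessing chain for one recording pair
#'
#' Band-pass filters both modalities (0.5-30 Hz), aligns and trims them to
#' `keepS` seconds, brick-wall decomposes the EEG into the four bands and
#' segments both signals into overlapping epochs.
#'
#' @param eeg,ecg raw [Recording-class] objects (same subject and state).
#' @param keepS seconds to retain after alignment (default 600).
#' @param windowS,stepS epoching parameters (defaults 2 and 1 s).
#' @param lo,hi band-pass edges (defaults 0.5 and 30 Hz).
#' @param edges band partition for the EEG decomposition.
#' @return An [EpochSet-class].
#' @export
preprocessPair <- function(eeg, ecg, keepS = 600, windowS = 2, stepS = 1,
                           lo = 0.5, hi = 30, edges = defaultBandEdges()) {
  al <- alignAndTrim(eeg, ecg, keepS = keepS)
  ## the zero-phase band-pass and the brick-wall masks are both diagonal
  ## on the FFT grid, so they fuse into one pass over the EEG
  g <- .butterGain2(ncol(al$eeg@samples), al$eeg@rate, lo, hi)
  bd <- decomposeBands(al$eeg, edges, pregain = g)
  ecgF <- bandpassFilter(al$ecg, lo = lo, hi = hi)
  segmentEpochs(bd, ecgF, windowS = windowS, stepS = stepS)
}
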