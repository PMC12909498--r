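## Feature extraction: 8 features per (EEG channel, band) and 7 statistical
## moments per ECG epoch, then per-subject z-scoring.
##
## All moments use population conventions (divide by N), so the identities
## RMS^2 = VAR + MEA^2 and ENE = N * RMS^2 hold exactly. Skewness is the
## Fisher-Pearson g1 and kurtosis the excess g2 (0 for a Gaussian).

#' Time-domain features of one band-limited segment
#'
#' Computes the mean (MEA), energy (ENE = sum of squares), population
#' variance (VAR) and root mean square (RMS) of a single-channel segment,
#' quantifying amplitude and fluctuation intensity.
#'
#' @param segment numeric vector (length >= 2).
#' @return Named numeric vector `MEA`, `ENE`, `VAR`, `RMS`.
#' @export
#' @examples
#' eegTimeFeatures(c(1, -1, 1, -1))
eegTimeFeatures <- function(segment) {
  segment <- as.numeric(segment)
  if (length(segment) < 2L) stop("segment must have >= 2 samples", call. = FALSE)
  n <- length(segment)
  mea <- mean(segment)
  ene <- sum(segment^2)
  c(MEA = mea, ENE = ene, VAR = ene / n - mea^2, RMS = sqrt(ene / n))
}

## One-sided unnormalized periodogram of epoch columns: P[k+1, ] = |X_k|^2/N
## at frequencies k * rate / N, k = 0..N/2.
.periodogram <- function(X, rate) {
  n <- nrow(X)
  Z <- stats::mvfft(X)[seq_len(n %/% 2 + 1L), , drop = FALSE]
  list(P = (Re(Z)^2 + Im(Z)^2) / n, f = (0:(n %/% 2)) * rate / n)
}

## Spectral moments over band bins; zero-power columns give 0 with warning.
.specBandFeatures <- function(P, f, lo, hi, includeUpper = FALSE) {
  bins <- .bandMask(f, lo, hi, closeHi = includeUpper)
  if (!any(bins)) stop("band contains no frequency bins", call. = FALSE)
  Pb <- P[bins, , drop = FALSE]
  fb <- f[bins]
  s0 <- colSums(Pb)
  psd <- colMeans(Pb)
  bad <- s0 <= 0
  s0[bad] <- 1  # avoid 0/0; overwritten below
  cf <- colSums(fb * Pb) / s0
  msf <- colSums(fb^2 * Pb) / s0
  fv <- pmax(msf - cf^2, 0)
  if (any(bad)) {
    warning("zero in-band power: CF/FV/MSF undefined, emitted as 0")
    cf[bad] <- 0; msf[bad] <- 0; fv[bad] <- 0
  }
  list(PSD = psd, CF = cf, FV = fv, MSF = msf)
}

#' Frequency-domain features of one segment
#'
#' From the periodogram `P(f)` of the segment restricted to `[lo, hi)`:
#' the band power spectral density PSD (mean in-band periodogram power),
#' centroid frequency CF = sum(f P)/sum(P), mean square frequency
#' MSF = sum(f^2 P)/sum(P), and frequency variance FV = MSF - CF^2 (the
#' spectral spread; non-negative by construction).
#'
#' @param segment numeric vector (length >= 2).
#' @param rate sampling rate in Hz.
#' @param band `c(lo, hi)` in Hz within `(0, rate/2)`.
#' @param includeUpper include the bin at `hi` (used for the band closing
#'   the global pass band).
#' @return Named numeric vector `PSD`, `CF`, `FV`, `MSF`.
#' @export
#' @examples
#' t <- seq(0, 2, by = 1 / 500)[-1]
#' eegFreqFeatures(sin(2 * pi * 6 * t), 500, c(4, 8))
eegFreqFeatures <- function(segment, rate, band, includeUpper = FALSE) {
  segment <- as.numeric(segment)
  if (length(segment) < 2L) stop("segment must have >= 2 samples", call. = FALSE)
  if (!(band[1L] > 0 && band[2L] > band[1L] && band[2L] <= rate / 2))
    stop("band must lie within (0, rate/2)", call. = FALSE)
  pg <- .periodogram(matrix(segment, ncol = 1L), rate)
  out <- .specBandFeatures(pg$P, pg$f, band[1L], band[2L], includeUpper)
  vapply(out, `[`, numeric(1), 1L)
}

#' Statistical-moment features of one ECG segment
#'
#' The seven raw-waveform statistics used in place of short-window HRV:
#' mean, standard deviation, variance, maximum, minimum, skewness
#' (Fisher-Pearson g1) and excess kurtosis (g2). Population conventions
#' throughout; a constant segment yields SKEW = KURT = 0 with a warning.
#'
#' @param segment numeric vector (length >= 4).
#' @return Named numeric vector `MEAN`, `SD`, `VAR`, `MAX`, `MIN`, `SKEW`,
#'   `KURT`.
#' @export
#' @examples
#' ecgFeatures(c(-2, -1, 0, 1, 2))
ecgFeatures <- function(segment) {
  segment <- as.numeric(segment)
  if (length(segment) < 4L)
    stop("segment must have >= 4 samples (kurtosis defined)", call. = FALSE)
  m <- mean(segment)
  d <- segment - m
  m2 <- mean(d^2)
  if (m2 <= 0) {
    warning("degenerate (constant) segment: SKEW/KURT undefined, emitted as 0")
    sk <- 0; ku <- 0
  } else {
    sk <- mean(d^3) / m2^1.5
    ku <- mean(d^4) / m2^2 - 3
  }
  c(MEAN = m, SD = sqrt(m2), VAR = m2, MAX = max(segment),
    MIN = min(segment), SKEW = sk, KURT = ku)
}

## Vectorized ECG moments over epoch columns.
.ecgMoments <- function(X) {
  m1 <- colMeans(X)
  d <- X - rep(m1, each = nrow(X))
  m2 <- colMeans(d^2)
  zero <- m2 <= 0
  if (any(zero))
    warning("degenerate (constant) ECG epoch(s): SKEW/KURT emitted as 0")
  m2s <- ifelse(zero, 1, m2)
  sk <- ifelse(zero, 0, colMeans(d^3) / m2s^1.5)
  ku <- ifelse(zero, 0, colMeans(d^4) / m2s^2 - 3)
  rbind(MEAN = m1, SD = sqrt(m2), VAR = m2,
        MAX = apply(X, 2L, max), MIN = apply(X, 2L, min),
        SKEW = sk, KURT = ku)
}

## Feature block (519 x E) for one EpochSet.
.featureBlock <- function(es) {
  E <- nEpochs(es)
  if (E == 0L) stop("empty EpochSet", call. = FALSE)
  winE <- round(es@windowS * es@eegRate)
  winC <- round(es@windowS * es@ecgRate)
  idxE <- outer(seq_len(winE), as.integer(round(es@starts * es@eegRate)), `+`)
  idxC <- outer(seq_len(winC), as.integer(round(es@starts * es@ecgRate)), `+`)
  bands <- names(es@eegBands)
  edges <- defaultBandEdges()[bands]
  topHi <- max(vapply(edges, `[`, numeric(1), 2L))
  raw <- Reduce(`+`, es@eegBands)  # brick-wall 0.5-30 Hz composite
  nCh <- length(es@channelLabels)
  eFeats <- eegFeatureTypes()
  out <- matrix(NA_real_, nrow = nCh * length(bands) * 8L + 7L, ncol = E)
  rn <- character(nrow(out))
  r <- 0L
  for (c in seq_len(nCh)) {
    Xraw <- matrix(raw[c, ][idxE], nrow = winE)
    pg <- .periodogram(Xraw, es@eegRate)
    for (b in bands) {
      Xb <- matrix(es@eegBands[[b]][c, ][idxE], nrow = winE)
      mea <- colMeans(Xb)
      ene <- colSums(Xb^2)
      rms2 <- ene / winE
      e <- edges[[b]]
      sp <- .specBandFeatures(pg$P, pg$f, e[1L], e[2L],
                              includeUpper = e[2L] == topHi)
      vals <- rbind(mea, ene, rms2 - mea^2, sqrt(rms2),
                    sp$PSD, sp$CF, sp$FV, sp$MSF)
      out[r + 1:8, ] <- vals
      rn[r + 1:8] <- paste(es@channelLabels[c], b, eFeats, sep = ".")
      r <- r + 8L
    }
  }
  Xc <- matrix(es@ecg[1L, ][idxC], nrow = winC)
  out[r + 1:7, ] <- .ecgMoments(Xc)
  rn[r + 1:7] <- paste("ECG", ecgFeatureTypes(), sep = ".")
  rownames(out) <- rn
  colnames(out) <- sprintf("%s_%s_%04d", es@subjectId, es@state, seq_len(E))
  out
}

.featureRowData <- function(channelLabels, bands) {
  eeg <- expand.grid(feature = eegFeatureTypes(), band = bands,
                     channel = channelLabels, stringsAsFactors = FALSE)
  eeg <- eeg[, c("channel", "band", "feature")]
  S4Vectors::DataFrame(
    modality = c(rep("EEG", nrow(eeg)), rep("ECG", 7L)),
    channel = c(eeg$channel, rep("ECG", 7L)),
    band = c(eeg$band, rep(NA_character_, 7L)),
    feature = c(eeg$feature, ecgFeatureTypes()))
}

#' Build the epoch-by-feature matrix
#'
#' Computes, for every epoch, the 8 features per (channel, band) from the
#' EEG (time-domain features on the band component, frequency-domain
#' features from the raw epoch periodogram restricted to the band) plus
#' the 7 ECG moments, yielding 16 x 4 x 8 = 512 EEG rows and 7 ECG rows.
#' Rows are ordered channel-major, band-minor, feature-last, with the ECG
#' block appended; names follow `CH.BAND.FEAT` / `ECG.FEAT`.
#'
#' @param epochs an [EpochSet-class] or a list of them (pooled into one
#'   matrix).
#' @return An unnormalized [FeatureSet-class].
#' @export
buildFeatureMatrix <- function(epochs) {
  if (is(epochs, "EpochSet")) epochs <- list(epochs)
  blocks <- lapply(epochs, function(es) {
    list(assay = .featureBlock(es),
         cd = S4Vectors::DataFrame(subject_id = es@subjectId,
                                   state = es@state,
                                   epoch_index = seq_len(nEpochs(es))),
         channels = es@channelLabels, bands = names(es@eegBands))
  })
  rn <- rownames(blocks[[1L]]$assay)
  for (b in blocks[-1L])
    if (!identical(rownames(b$assay), rn))
      stop("epoch sets have mismatched feature layouts", call. = FALSE)
  assay <- do.call(cbind, lapply(blocks, `[[`, "assay"))
  cd <- do.call(rbind, lapply(blocks, `[[`, "cd"))
  rownames(cd) <- colnames(assay)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = assay),
    rowData = .featureRowData(blocks[[1L]]$channels, blocks[[1L]]$bands),
    colData = cd)
  S4Vectors::metadata(se)$normalized <- FALSE
  new("FeatureSet", se)
}

#' Combine feature sets column-wise
#'
#' @param ... [FeatureSet-class] objects with identical feature layouts.
#' @return A pooled [FeatureSet-class].
#' @export
combineFeatureSets <- function(...) {
  sets <- list(...)
  out <- do.call(SummarizedExperiment::cbind, sets)
  new("FeatureSet", out)
}

#' Z-score features within each subject
#'
#' Standardizes every feature to mean 0 and population SD 1 within each
#' subject, pooling that subject's epochs from both states, so that
#' classification rests on relative fatigue-induced shifts rather than
#' between-subject baselines. A feature with zero variance within a
#' subject is set to 0 for that subject (with a warning).
#'
#' @param fm an unnormalized [FeatureSet-class]; each subject needs >= 2
#'   epochs.
#' @return The normalized [FeatureSet-class] (idempotent on repeated use).
#' @export
zscoreBySubject <- function(fm) {
  x <- SummarizedExperiment::assay(fm, "features")
  cd <- SummarizedExperiment::colData(fm)
  warned <- FALSE
  for (s in unique(cd$subject_id)) {
    j <- which(cd$subject_id == s)
    if (length(j) < 2L)
      stop(sprintf("subject %s has fewer than 2 epochs", s), call. = FALSE)
    sub <- x[, j, drop = FALSE]
    mu <- rowMeans(sub)
    sdp <- sqrt(rowMeans((sub - mu)^2))
    zero <- sdp <= 0
    if (any(zero) && !warned) {
      warning(sprintf("zero-variance feature(s) within subject %s set to 0", s))
      warned <- TRUE
    }
    sdp[zero] <- 1
    z <- (sub - mu) / sdp
    z[zero, ] <- 0
    x[, j] <- z
  }
  out <- fm
  SummarizedExperiment::assay(out, "features") <- x
  S4Vectors::metadata(out)$normalized <- TRUE
  out
}

#' Write / read a FeatureSet as TSV
#'
#' Serializes the epoch-by-feature table with the stable header grammar
#' `CH.BAND.FEAT` / `ECG.FEAT` plus metadata columns `subject_id`,
#' `state`, `epoch_index`.
#'
#' @param fm a [FeatureSet-class].
#' @param path output TSV path.
#' @return `writeFeatureTSV` returns `path` invisibly; `readFeatureTSV`
#'   returns a [FeatureSet-class].
#' @export
writeFeatureTSV <- function(fm, path) {
  tab <- featureTable(fm)
  tab$normalized <- isNormalized(fm)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTSV
#' @export
readFeatureTSV <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  meta <- c("subject_id", "state", "epoch_index", "normalized")
  featCols <- setdiff(colnames(tab), meta)
  assay <- t(as.matrix(tab[, featCols]))
  colnames(assay) <- sprintf("%s_%s_%04d", tab$subject_id, tab$state,
                             tab$epoch_index)
  parts <- strsplit(featCols, ".", fixed = TRUE)
  rd <- S4Vectors::DataFrame(
    modality = ifelse(vapply(parts, `[`, "", 1L) == "ECG", "ECG", "EEG"),
    channel = vapply(parts, `[`, "", 1L),
    band = vapply(parts, function(p) if (length(p) == 3L) p[2L] else NA_character_, ""),
    feature = vapply(parts, function(p) p[length(p)], ""))
  cd <- S4Vectors::DataFrame(subject_id = as.character(tab$subject_id),
                             state = tab$state, epoch_index = tab$epoch_index,
                             row.names = colnames(assay))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = assay), rowData = rd, colData = cd)
  S4Vectors::metadata(se)$normalized <- isTRUE(all(tab$normalized))
  new("FeatureSet", se)
}
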