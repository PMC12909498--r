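#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay colData rowData assayNames
#' @importFrom S4Vectors metadata
#' @importFrom stats rnorm var sd fft mvfft oneway.test p.adjust predict rank setNames
#' @importFrom utils head tail write.table read.table modifyList
NULL

## Canonical constants -------------------------------------------------------

#' Standard 16-electrode montage
#'
#' Channel labels of the 16-electrode scalp montage (10-20 system subset)
#' expected by the pipeline: frontopolar (FP), frontal (F), central (C),
#' temporal (T), parietal (P) and occipital (O) sites; odd = left, even =
#' right hemisphere.
#'
#' @return Character vector of 16 channel labels in montage order.
#' @export
#' @examples
#' eegMontage()
eegMontage <- function() {
  c("FP1", "FP2", "F3", "F4", "F7", "F8", "C3", "C4",
    "T3", "T4", "T5", "T6", "P3", "P4", "O1", "O2")
}

#' Default EEG frequency band edges
#'
#' The conventional clinical partition of the 0.5-30 Hz pass band:
#' delta \[0.5, 4), theta \[4, 8), alpha \[8, 13), beta \[13, 30\] Hz.
#' Bands are half-open on the right except beta, which closes the pass band.
#'
#' @return Named list of `c(lo, hi)` pairs in Hz.
#' @export
#' @examples
#' defaultBandEdges()
defaultBandEdges <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

#' Feature-type name sets
#'
#' `eegFeatureTypes()` returns the 8 per-channel-band EEG feature names
#' (4 time-domain: MEA, ENE, VAR, RMS; 4 frequency-domain: PSD, CF, FV, MSF).
#' `ecgFeatureTypes()` returns the 7 ECG statistical-moment feature names.
#'
#' @return Character vector of feature-type names.
#' @export
eegFeatureTypes <- function() c("MEA", "ENE", "VAR", "RMS", "PSD", "CF", "FV", "MSF")

#' @rdname eegFeatureTypes
#' @export
ecgFeatureTypes <- function() c("MEAN", "SD", "VAR", "MAX", "MIN", "SKEW", "KURT")

.STATES <- c("alert", "fatigue")
.MODALITIES <- c("EEG", "ECG")

## Recording -----------------------------------------------------------------

#' Recording: one modality's continuous signal block
#'
#' A continuous multichannel signal for one subject in one state. EEG
#' recordings carry 16 rows (one per montage channel); ECG recordings one.
#' Sample values are in microvolt-scale arbitrary units.
#'
#' @slot subjectId character scalar.
#' @slot state `"alert"` or `"fatigue"`.
#' @slot modality `"EEG"` or `"ECG"`.
#' @slot rate sampling rate in Hz.
#' @slot channelLabels one label per row of `samples`.
#' @slot samples channels x time numeric matrix.
#' @slot startTime recording start in seconds on a common clock.
#' @export
setClass("Recording",
  representation(subjectId = "character", state = "character",
                 modality = "character", rate = "numeric",
                 channelLabels = "character", samples = "matrix",
                 startTime = "numeric"))

setValidity("Recording", function(object) {
  msg <- character()
  if (length(object@rate) != 1L || object@rate <= 0)
    msg <- c(msg, "rate must be a positive scalar")
  if (!object@state %in% .STATES)
    msg <- c(msg, sprintf("state must be one of %s", paste(.STATES, collapse = ", ")))
  if (!object@modality %in% .MODALITIES)
    msg <- c(msg, "modality must be 'EEG' or 'ECG'")
  if (nrow(object@samples) != length(object@channelLabels))
    msg <- c(msg, "samples row count must equal channel label count")
  if (object@modality == "EEG" && nrow(object@samples) != 16L)
    msg <- c(msg, "EEG recordings must have 16 channels")
  if (object@modality == "ECG" && nrow(object@samples) != 1L)
    msg <- c(msg, "ECG recordings must have exactly 1 channel")
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param subjectId subject identifier.
#' @param state `"alert"` or `"fatigue"`.
#' @param modality `"EEG"` or `"ECG"`.
#' @param rate sampling rate (Hz).
#' @param samples channels x time matrix (a vector is treated as one channel).
#' @param channelLabels channel names; defaults to the montage for 16-row
#'   input and `"ECG"` for single-row input.
#' @param startTime start time in seconds (common clock across modalities).
#' @return A [Recording-class] object.
#' @export
Recording <- function(subjectId, state, modality, rate, samples,
                      channelLabels = NULL, startTime = 0) {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1L)
  if (is.null(channelLabels)) {
    channelLabels <- if (nrow(samples) == 16L) eegMontage() else
      sprintf("%s%d", modality, seq_len(nrow(samples)))
    if (nrow(samples) == 1L) channelLabels <- modality
  }
  rownames(samples) <- channelLabels
  new("Recording", subjectId = as.character(subjectId), state = state,
      modality = modality, rate = rate, channelLabels = channelLabels,
      samples = samples, startTime = as.numeric(startTime))
}

#' @describeIn Recording duration of a recording in seconds.
#' @param x a `Recording`.
#' @export
durationS <- function(x) ncol(x@samples) / x@rate

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %s / %s / %s\n", object@subjectId, object@state,
              object@modality))
  cat(sprintf("  %d channel(s) x %d samples @ %g Hz (%.1f s, start %.2f s)\n",
              nrow(object@samples), ncol(object@samples), object@rate,
              durationS(object), object@startTime))
})

## BandDecomposition ---------------------------------------------------------

#' Band decomposition of an EEG recording
#'
#' Brick-wall FFT decomposition of a band-passed recording into the four
#' clinical bands. Each band signal has the same channels x time shape as the
#' source; summing the four reconstructs the source restricted to the union
#' of the band supports.
#'
#' @slot subjectId,state,rate,channelLabels,startTime provenance copied from
#'   the source recording.
#' @slot bandEdges named list of `c(lo, hi)` pairs.
#' @slot bandSignals named list of channels x time matrices, one per band.
#' @export
setClass("BandDecomposition",
  representation(subjectId = "character", state = "character",
                 rate = "numeric", channelLabels = "character",
                 startTime = "numeric", bandEdges = "list",
                 bandSignals = "list"))

setValidity("BandDecomposition", function(object) {
  msg <- character()
  if (!identical(names(object@bandEdges), names(object@bandSignals)))
    msg <- c(msg, "bandEdges and bandSignals must share names")
  dims <- lapply(object@bandSignals, dim)
  if (length(unique(dims)) > 1L)
    msg <- c(msg, "all band signals must share one shape")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BandDecomposition", function(object) {
  d <- dim(object@bandSignals[[1L]])
  cat(sprintf("BandDecomposition: %s / %s, bands [%s], %d x %d @ %g Hz\n",
              object@subjectId, object@state,
              paste(names(object@bandEdges), collapse = ", "),
              d[1L], d[2L], object@rate))
})

## EpochSet ------------------------------------------------------------------

#' Time-aligned multimodal epochs for one subject/state
#'
#' Stores the band-decomposed EEG and the filtered ECG of one recording pair
#' together with the sliding-window layout (window and step in seconds).
#' Epochs are materialized on demand via [getEpoch()]; consecutive epochs at
#' 50\% overlap share half their samples.
#'
#' @slot subjectId,state provenance.
#' @slot windowS,stepS window length and step in seconds.
#' @slot eegRate,ecgRate sampling rates in Hz.
#' @slot channelLabels EEG channel labels.
#' @slot eegBands named list of 16 x T band signal matrices.
#' @slot ecg 1 x T' filtered ECG matrix.
#' @slot starts epoch start times in seconds from the common origin.
#' @export
setClass("EpochSet",
  representation(subjectId = "character", state = "character",
                 windowS = "numeric", stepS = "numeric",
                 eegRate = "numeric", ecgRate = "numeric",
                 channelLabels = "character", eegBands = "list",
                 ecg = "matrix", starts = "numeric"))

#' @describeIn EpochSet number of epochs.
#' @param x an `EpochSet`.
#' @export
nEpochs <- function(x) length(x@starts)

#' Extract one epoch as a plain list
#'
#' @param x an [EpochSet-class].
#' @param i epoch index (1-based).
#' @return List with `subject_id`, `state`, `epoch_index`, `eeg` (named list
#'   of band -> 16 x window*eegRate matrices) and `ecg` (1 x window*ecgRate).
#' @export
getEpoch <- function(x, i) {
  stopifnot(i >= 1L, i <= nEpochs(x))
  s <- x@starts[i]
  ei <- round(s * x@eegRate) + seq_len(round(x@windowS * x@eegRate))
  ci <- round(s * x@ecgRate) + seq_len(round(x@windowS * x@ecgRate))
  list(subject_id = x@subjectId, state = x@state, epoch_index = i,
       eeg = lapply(x@eegBands, function(m) m[, ei, drop = FALSE]),
       ecg = x@ecg[, ci, drop = FALSE])
}

setMethod("show", "EpochSet", function(object) {
  cat(sprintf(
    "EpochSet: %s / %s, %d epochs (window %g s, step %g s), bands [%s]\n",
    object@subjectId, object@state, nEpochs(object), object@windowS,
    object@stepS, paste(names(object@eegBands), collapse = ", ")))
})

## FeatureSet ----------------------------------------------------------------

#' Epoch-by-feature matrix as a SummarizedExperiment
#'
#' Features are rows (with `rowData` columns `modality`, `channel`, `band`,
#' `feature`), epochs are columns (with `colData` columns `subject_id`,
#' `state`, `epoch_index`). The single assay `"features"` holds the values.
#' The full pre-selection block has 16 channels x 4 bands x 8 feature types
#' = 512 EEG rows plus 7 ECG rows. Row names follow the grammar
#' `CH.BAND.FEAT` / `ECG.FEAT`.
#'
#' @export
setClass("FeatureSet", contains = "SummarizedExperiment")

setValidity("FeatureSet", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  rd <- SummarizedExperiment::rowData(object)
  need.cd <- c("subject_id", "state", "epoch_index")
  need.rd <- c("modality", "channel", "band", "feature")
  if (!all(need.cd %in% colnames(cd)))
    msg <- c(msg, sprintf("colData must contain %s", paste(need.cd, collapse = ", ")))
  if (!all(need.rd %in% colnames(rd)))
    msg <- c(msg, sprintf("rowData must contain %s", paste(need.rd, collapse = ", ")))
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  if (any(!is.finite(SummarizedExperiment::assay(object, "features"))))
    msg <- c(msg, "feature values must be finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn FeatureSet whether per-subject z-scoring has been applied.
#' @param x a `FeatureSet`.
#' @export
isNormalized <- function(x) isTRUE(S4Vectors::metadata(x)$normalized)

#' @describeIn FeatureSet feature values as an epochs x features data.frame
#'   with `subject_id`, `state`, `epoch_index` metadata columns prepended.
#' @export
featureTable <- function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  cbind(cd, as.data.frame(t(SummarizedExperiment::assay(x, "features"))))
}

setMethod("show", "FeatureSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("FeatureSet: %d features x %d epochs (%d subjects; %s)\n",
              nrow(object), ncol(object),
              length(unique(cd$subject_id)),
              if (isNormalized(object)) "z-scored per subject" else "raw"))
})

## Selection-stage containers ------------------------------------------------

#' ANOVA screening report
#'
#' Per-feature alert-vs-fatigue one-way ANOVA p-values, the per
#' (feature-type, band) significant-channel counts, and the retained
#' feature-type sets for each modality. An EEG feature type is retained iff
#' its significant-channel count reaches `minChannels` in every band; an ECG
#' feature is retained iff `p < alpha`.
#'
#' @slot pValues data.frame with columns `name`, `modality`, `channel`,
#'   `band`, `feature`, `p`.
#' @slot eegCounts feature-type x band matrix of significant-channel counts.
#' @slot retainedEEG,retainedECG retained feature-type names.
#' @slot alpha significance level (default 0.01).
#' @slot minChannels retention threshold (default 10 channels per band).
#' @export
setClass("AnovaReport",
  representation(pValues = "data.frame", eegCounts = "matrix",
                 retainedEEG = "character", retainedECG = "character",
                 alpha = "numeric", minChannels = "numeric"))

setValidity("AnovaReport", function(object) {
  p <- object@pValues$p
  if (any(p < 0 | p > 1, na.rm = TRUE)) "p-values must lie in [0, 1]" else TRUE
})

setMethod("show", "AnovaReport", function(object) {
  cat(sprintf("AnovaReport: alpha = %g, minChannels = %d\n",
              object@alpha, object@minChannels))
  cat("  retained EEG feature types:",
      paste(object@retainedEEG, collapse = ", "), "\n")
  cat("  retained ECG features:    ",
      paste(object@retainedECG, collapse = ", "), "\n")
})

#' Linear SVM configuration for channel ranking
#'
#' @slot kernel only `"linear"` is supported (soft-margin formulation).
#' @slot cost slack/margin trade-off weight (the soft-margin C).
#' @slot folds number of stratified CV folds (default 10).
#' @slot seed fold-assignment seed.
#' @export
setClass("SvmConfig",
  representation(kernel = "character", cost = "numeric", folds = "numeric",
                 seed = "numeric"))

setValidity("SvmConfig", function(object) {
  msg <- character()
  if (object@kernel != "linear") msg <- c(msg, "only the linear kernel is supported")
  if (object@cost <= 0) msg <- c(msg, "C must be > 0")
  if (object@folds < 2) msg <- c(msg, "folds must be >= 2")
  if (length(msg)) msg else TRUE
})

#' @rdname SvmConfig-class
#' @param C regularization weight (default 1).
#' @param folds CV folds (default 10).
#' @param seed integer seed for fold assignment.
#' @export
svmConfig <- function(C = 1, folds = 10, seed = 1) {
  new("SvmConfig", kernel = "linear", cost = C, folds = folds, seed = seed)
}

#' Per-channel SVM-AUC ranking
#'
#' @slot aucPerBand channel x band matrix of mean out-of-fold AUCs (NA if
#'   not computed).
#' @slot aucFused named per-channel mean AUC using all four bands fused.
#' @slot mode `"per_band"` or `"fused"`.
#' @slot ranking channel labels in descending order of the ranking AUC
#'   (fused AUC in fused mode, per-band mean otherwise); ties broken by
#'   montage order.
#' @slot selected selected channel subset.
#' @slot rule list recording the selection rule used.
#' @export
setClass("ChannelRanking",
  representation(aucPerBand = "matrix", aucFused = "numeric",
                 mode = "character", ranking = "character",
                 selected = "character", rule = "list"))

setValidity("ChannelRanking", function(object) {
  msg <- character()
  auc <- c(object@aucPerBand, object@aucFused)
  if (any(auc < 0 | auc > 1, na.rm = TRUE)) msg <- c(msg, "AUC must lie in [0, 1]")
  if (!all(object@selected %in% object@ranking))
    msg <- c(msg, "selected channels must be a subset of the ranking")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ChannelRanking", function(object) {
  cat(sprintf("ChannelRanking (%s mode)\n", object@mode))
  cat("  ranking:", paste(object@ranking, collapse = " > "), "\n")
  if (length(object@selected))
    cat("  selected:", paste(object@selected, collapse = ", "), "\n")
})

#' @describeIn ChannelRanking the selected channel labels.
#' @param x a `ChannelRanking`.
#' @export
selectedChannels <- function(x) x@selected

## Model/evaluation containers -----------------------------------------------

#' Gradient-boosting hyperparameters
#'
#' Mirrors the regularized boosted-tree objective: `nTrees` additive trees,
#' depth-limited, with shrinkage `learningRate`, a per-leaf complexity
#' penalty `leafPenalty` (gamma) and L2 leaf-weight penalty `l2Weight`
#' (lambda).
#'
#' @slot nTrees number of boosting rounds (default 100).
#' @slot maxDepth maximum tree depth (default 6).
#' @slot learningRate shrinkage in (0, 1] (default 0.1).
#' @slot leafPenalty gamma >= 0.
#' @slot l2Weight lambda >= 0.
#' @slot seed RNG seed for tree construction.
#' @export
setClass("GbmHyperparams",
  representation(nTrees = "numeric", maxDepth = "numeric",
                 learningRate = "numeric", leafPenalty = "numeric",
                 l2Weight = "numeric", seed = "numeric"))

setValidity("GbmHyperparams", function(object) {
  msg <- character()
  if (object@nTrees < 1) msg <- c(msg, "nTrees must be >= 1")
  if (object@learningRate <= 0 || object@learningRate > 1)
    msg <- c(msg, "learningRate must lie in (0, 1]")
  if (object@leafPenalty < 0 || object@l2Weight < 0)
    msg <- c(msg, "penalties must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname GbmHyperparams-class
#' @param nTrees,maxDepth,learningRate,leafPenalty,l2Weight,seed see slots.
#' @export
gbmHyperparams <- function(nTrees = 100, maxDepth = 6, learningRate = 0.1,
                           leafPenalty = 0, l2Weight = 1, seed = 1) {
  new("GbmHyperparams", nTrees = nTrees, maxDepth = maxDepth,
      learningRate = learningRate, leafPenalty = leafPenalty,
      l2Weight = l2Weight, seed = seed)
}

#' Trained gradient-boosted fatigue classifier
#'
#' @slot booster the fitted xgboost booster.
#' @slot hp the [GbmHyperparams-class] used.
#' @slot featureNames training feature names, in order.
#' @slot positiveClass the state scored as positive (`"fatigue"`).
#' @export
setClass("FatigueModel",
  representation(booster = "ANY", hp = "GbmHyperparams",
                 featureNames = "character", positiveClass = "character"))

setMethod("show", "FatigueModel", function(object) {
  cat(sprintf(
    "FatigueModel: %d trees, depth %d, eta %g; %d features; positive = %s\n",
    object@hp@nTrees, object@hp@maxDepth, object@hp@learningRate,
    length(object@featureNames), object@positiveClass))
})

#' Cross-validation result
#'
#' @slot scheme `"cross_clip"` (epoch-shuffled stratified folds) or
#'   `"cross_subject"` (subject-disjoint folds).
#' @slot folds,repeats partition shape.
#' @slot perFold one row per (repeat, fold) with accuracy, precision,
#'   recall, F1 and the confusion counts.
#' @slot summary mean and SD per metric over all rows of `perFold`.
#' @export
setClass("CVResult",
  representation(scheme = "character", folds = "numeric", repeats = "numeric",
                 perFold = "data.frame", summary = "data.frame"))

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %s, %d-fold x %d repeat(s)\n", object@scheme,
              object@folds, object@repeats))
  print(object@summary, row.names = FALSE)
})

#' @describeIn CVResult the mean/SD metric summary table.
#' @param x a `CVResult`.
#' @export
cvSummary <- function(x) x@summary
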