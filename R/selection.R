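## Two-stage dimensionality reduction: one-way ANOVA screening per modality
## followed by per-channel linear-SVM AUC ranking and a channel cut.

#' Two-group one-way ANOVA p-value
#'
#' Fixed-effects one-way ANOVA of two groups (equivalent to the squared
#' pooled-variance t test). Degenerate pooled variance yields p = 1 with a
#' warning.
#'
#' @param groupA,groupB numeric vectors with >= 2 values each.
#' @return p-value in \[0, 1\].
#' @export
#' @examples
#' anovaPValue(c(1, 2, 3), c(4, 5, 6))
anovaPValue <- function(groupA, groupB) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs >= 2 values", call. = FALSE)
  if (var(groupA) + var(groupB) <= 0) {
    warning("degenerate (zero pooled variance) groups: p = 1")
    return(1)
  }
  x <- c(groupA, groupB)
  g <- factor(rep(c("A", "B"), c(length(groupA), length(groupB))))
  oneway.test(x ~ g, var.equal = TRUE)$p.value
}

#' ANOVA screening of the feature matrix
#'
#' Tests every feature for an alert-vs-fatigue mean difference with a
#' one-way ANOVA. EEG feature types are retained iff the number of
#' channels significant at `alpha` reaches `minChannels` in every
#' frequency band; each ECG feature is retained iff its own p-value is
#' below `alpha`. No multiple-testing correction is applied by default
#' (`adjust = "BH"` enables Benjamini-Hochberg before thresholding).
#'
#' @param fm a normalized [FeatureSet-class] containing both states.
#' @param alpha significance level (default 0.01).
#' @param minChannels per-band significant-channel threshold for EEG
#'   feature-type retention (default 10).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return An [AnovaReport-class].
#' @export
anovaScreen <- function(fm, alpha = 0.01, minChannels = 10,
                        adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  cd <- SummarizedExperiment::colData(fm)
  if (length(unique(cd$state)) < 2L)
    stop("both states must be present", call. = FALSE)
  x <- SummarizedExperiment::assay(fm, "features")
  rd <- as.data.frame(SummarizedExperiment::rowData(fm))
  a <- cd$state == "alert"
  p <- vapply(seq_len(nrow(x)), function(i) {
    withCallingHandlers(
      anovaPValue(x[i, a], x[i, !a]),
      warning = function(w) invokeRestart("muffleWarning"))
  }, numeric(1))
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  pv <- data.frame(name = rownames(x), modality = rd$modality,
                   channel = rd$channel, band = rd$band,
                   feature = rd$feature, p = p)
  eeg <- pv[pv$modality == "EEG", ]
  bands <- names(defaultBandEdges())
  counts <- matrix(0L, nrow = length(eegFeatureTypes()), ncol = length(bands),
                   dimnames = list(eegFeatureTypes(), bands))
  for (ft in eegFeatureTypes())
    for (b in bands)
      counts[ft, b] <- sum(eeg$p[eeg$feature == ft & eeg$band == b] < alpha)
  retainedEEG <- eegFeatureTypes()[apply(counts >= minChannels, 1L, all)]
  ecg <- pv[pv$modality == "ECG", ]
  retainedECG <- ecg$feature[ecg$p < alpha]
  new("AnovaReport", pValues = pv, eegCounts = counts,
      retainedEEG = retainedEEG, retainedECG = retainedECG,
      alpha = alpha, minChannels = minChannels)
}

#' Rank-sum AUC with midranks
#'
#' The area under the ROC curve computed from rank sums:
#' `AUC = (sum of positive ranks - T(T+1)/2) / (T * F)` with midranks for
#' ties, where `T` and `F` are the positive and negative counts. Equals
#' the probability that a random positive sample outranks a random
#' negative one (ties counted half).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical (TRUE = positive) or character/factor; in the
#'   latter case `positive` names the positive class.
#' @param positive positive class label (default `"fatigue"`).
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' aucRank(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE))
aucRank <- function(scores, labels, positive = "fatigue") {
  if (!is.logical(labels)) labels <- as.character(labels) == positive
  T <- sum(labels); F <- sum(!labels)
  if (T == 0L || F == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)  # midranks for ties
  (sum(r[labels]) - T * (T + 1) / 2) / (T * F)
}

## Stratified fold ids: shuffles within each class and deals round-robin,
## so every fold carries both classes whenever class counts allow.
.stratifiedFolds <- function(labels, k, seed) {
  if (min(table(labels)) < k)
    stop(sprintf("cannot build %d stratified folds: smallest class has %d samples",
                 k, min(table(labels))), call. = FALSE)
  fold <- integer(length(labels))
  set.seed(seed)
  for (cl in unique(labels)) {
    i <- which(labels == cl)
    fold[i] <- rep_len(seq_len(k), length(i))[sample.int(length(i))]
  }
  fold
}

## Mean out-of-fold AUC of a linear soft-margin SVM on feature matrix x.
## Decision scores (signed margins, oriented so higher = fatigue) are used
## as ROC inputs.
.svmCvAuc <- function(x, labels, cfg, fold) {
  k <- max(fold)
  aucs <- numeric(k)
  y <- factor(labels, levels = .STATES)
  for (f in seq_len(k)) {
    tr <- fold != f
    sc <- apply(x[tr, , drop = FALSE], 2L, sd) > 0
    m <- suppressWarnings(e1071::svm(
      x[tr, , drop = FALSE], y[tr], kernel = "linear", cost = cfg@cost,
      scale = sc))
    pr <- predict(m, x[!tr, , drop = FALSE], decision.values = TRUE)
    dv <- attr(pr, "decision.values")[, 1L]
    ## e1071 signs decision values toward the class named first in the
    ## "A/B" column label; flip so that higher score = fatigue.
    first <- strsplit(colnames(attr(pr, "decision.values"))[1L], "/")[[1L]][1L]
    if (first != "fatigue") dv <- -dv
    aucs[f] <- aucRank(dv, labels[!tr], positive = "fatigue")
  }
  mean(aucs)
}

.rankingFeatureRows <- function(fm, channel, bands, featureTypes) {
  rd <- SummarizedExperiment::rowData(fm)
  which(rd$modality == "EEG" & rd$channel == channel &
          rd$band %in% bands & rd$feature %in% featureTypes)
}

#' Rank EEG channels by single-channel SVM AUC
#'
#' Trains one linear soft-margin SVM per channel on that channel's
#' ANOVA-retained features (one band at a time in `per_band` mode; all
#' four bands concatenated in `fused` mode) and records the mean
#' out-of-fold AUC under stratified cross-validation. Channels are ranked
#' by descending AUC (fused AUC in fused mode, per-band mean otherwise)
#' with ties broken by montage order.
#'
#' @param fm a normalized [FeatureSet-class].
#' @param report an [AnovaReport-class] with >= 1 retained EEG feature
#'   type.
#' @param cfg an [svmConfig()].
#' @param mode `"fused"` (default) or `"per_band"`.
#' @param channels channels to rank (default the full montage).
#' @return A [ChannelRanking-class] (selection not yet applied).
#' @export
rankChannels <- function(fm, report, cfg = svmConfig(),
                         mode = c("fused", "per_band"),
                         channels = eegMontage()) {
  mode <- match.arg(mode)
  if (length(report@retainedEEG) == 0L)
    stop("no retained EEG feature types", call. = FALSE)
  cd <- SummarizedExperiment::colData(fm)
  labels <- cd$state
  fold <- .stratifiedFolds(labels, cfg@folds, cfg@seed)
  x <- SummarizedExperiment::assay(fm, "features")
  bands <- names(defaultBandEdges())
  perBand <- matrix(NA_real_, nrow = length(channels), ncol = length(bands),
                    dimnames = list(channels, bands))
  fused <- setNames(rep(NA_real_, length(channels)), channels)
  for (ch in channels) {
    if (mode == "per_band") {
      for (b in bands) {
        rows <- .rankingFeatureRows(fm, ch, b, report@retainedEEG)
        perBand[ch, b] <- .svmCvAuc(t(x[rows, , drop = FALSE]), labels, cfg, fold)
      }
    } else {
      rows <- .rankingFeatureRows(fm, ch, bands, report@retainedEEG)
      fused[ch] <- .svmCvAuc(t(x[rows, , drop = FALSE]), labels, cfg, fold)
    }
  }
  metric <- if (mode == "fused") fused else rowMeans(perBand)
  ord <- channels[order(-metric, match(channels, eegMontage()))]
  new("ChannelRanking", aucPerBand = perBand, aucFused = fused, mode = mode,
      ranking = ord, selected = character(0), rule = list())
}

#' Cut the channel ranking to a selected subset
#'
#' `top_k` keeps the k best-ranked channels (default 8); `min_auc` keeps
#' channels whose mean AUC exceeds the threshold, falling back to the
#' single best channel (with a warning) if none qualifies.
#'
#' @param ranking a [ChannelRanking-class].
#' @param rule a one-element named list: `list(top_k = k)` or
#'   `list(min_auc = thr)`.
#' @return The [ChannelRanking-class] with `selected` and `rule` filled.
#' @export
chooseChannels <- function(ranking, rule = list(top_k = 8)) {
  stopifnot(length(rule) == 1L, names(rule) %in% c("top_k", "min_auc"))
  metric <- if (ranking@mode == "fused") ranking@aucFused else
    rowMeans(ranking@aucPerBand)
  sel <- if (names(rule) == "top_k") {
    head(ranking@ranking, rule$top_k)
  } else {
    keep <- names(metric)[!is.na(metric) & metric > rule$min_auc]
    if (length(keep) == 0L) {
      warning("no channel exceeds min_auc; falling back to top_k = 1")
      head(ranking@ranking, 1L)
    } else {
      ranking@ranking[ranking@ranking %in% keep]
    }
  }
  ranking@selected <- sel
  ranking@rule <- rule
  ranking
}

#' Fuse selected EEG features with retained ECG features
#'
#' Restricts the feature matrix to the ANOVA-retained EEG feature types on
#' the selected channels (across all four bands) plus the retained ECG
#' features. With 6 retained EEG feature types, 8 channels and 4 retained
#' ECG features the fused width is 4 x 6 x 8 + 4 = 196 columns.
#'
#' @param fm a [FeatureSet-class].
#' @param report an [AnovaReport-class].
#' @param channels selected channel labels (non-empty).
#' @return The fused [FeatureSet-class].
#' @export
fuseFeatures <- function(fm, report, channels) {
  if (length(channels) == 0L) stop("empty channel set", call. = FALSE)
  rd <- SummarizedExperiment::rowData(fm)
  keep <- (rd$modality == "EEG" & rd$channel %in% channels &
             rd$feature %in% report@retainedEEG) |
    (rd$modality == "ECG" & rd$feature %in% report@retainedECG)
  new("FeatureSet", fm[keep, ])
}

#' Serialize selection artifacts
#'
#' `writeAnovaReport` and `writeChannelRanking` write JSON; the
#' significance table (significant-channel counts per feature type and
#' band) can be exported as TSV for heat-map rendering.
#'
#' @param report an [AnovaReport-class].
#' @param ranking a [ChannelRanking-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnovaReport <- function(report, path) {
  jsonlite::write_json(list(
    alpha = report@alpha, min_channels = report@minChannels,
    retained_eeg = report@retainedEEG, retained_ecg = report@retainedECG,
    significant_channel_counts = as.data.frame.table(
      report@eegCounts, responseName = "count", stringsAsFactors = FALSE),
    p_values = report@pValues), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeAnovaReport
#' @export
writeChannelRanking <- function(ranking, path) {
  jsonlite::write_json(list(
    mode = ranking@mode, ranking = ranking@ranking,
    selected = ranking@selected, rule = ranking@rule,
    auc_fused = as.list(ranking@aucFused),
    auc_per_band = as.data.frame.table(
      ranking@aucPerBand, responseName = "auc", stringsAsFactors = FALSE)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeAnovaReport
#' @export
significanceTable <- function(report) {
  as.data.frame.table(report@eegCounts, responseName = "significant_channels",
                      stringsAsFactors = FALSE) |>
    setNames(c("feature", "band", "significant_channels"))
}
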