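## Gradient-boosted classification of fused features and the two
## cross-validation schemes (epoch-shuffled cross-clip and subject-disjoint
## cross-subject). Positive class = fatigue, by convention.

.asXY <- function(fm, labels = NULL) {
  if (is(fm, "FeatureSet")) {
    x <- t(SummarizedExperiment::assay(fm, "features"))
    labels <- SummarizedExperiment::colData(fm)$state
  } else {
    x <- as.matrix(fm)
    if (is.null(labels)) stop("labels required for matrix input", call. = FALSE)
  }
  list(x = x, labels = as.character(labels))
}

#' Train the gradient-boosted fatigue classifier
#'
#' Fits an additive ensemble of depth-limited regression trees to the
#' logistic loss with per-leaf (`gamma`) and L2 leaf-weight (`lambda`)
#' regularization, via xgboost, configured exactly by `hp`. Deterministic
#' given the seed (single-threaded).
#'
#' @param fm a [FeatureSet-class] (labels taken from `colData(fm)$state`)
#'   or an epochs x features matrix.
#' @param labels state labels when `fm` is a matrix.
#' @param hp a [gbmHyperparams()].
#' @return A [FatigueModel-class].
#' @export
trainFatigueModel <- function(fm, labels = NULL, hp = gbmHyperparams()) {
  d <- .asXY(fm, labels)
  if (length(unique(d$labels)) < 2L)
    stop("labels must contain both classes", call. = FALSE)
  y <- as.integer(d$labels == "fatigue")
  set.seed(hp@seed)
  dtrain <- xgboost::xgb.DMatrix(d$x, label = y, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = hp@maxDepth,
                  eta = hp@learningRate, gamma = hp@leafPenalty,
                  lambda = hp@l2Weight, nthread = 1, seed = hp@seed),
    data = dtrain, nrounds = hp@nTrees, verbose = 0)
  new("FatigueModel", booster = booster, hp = hp,
      featureNames = colnames(d$x), positiveClass = "fatigue")
}

#' Predict fatigue probabilities
#'
#' @param object a [FatigueModel-class].
#' @param newdata a [FeatureSet-class] or epochs x features matrix with the
#'   training feature columns.
#' @param ... ignored.
#' @return Numeric vector of fatigue probabilities.
#' @export
setMethod("predict", "FatigueModel", function(object, newdata, ...) {
  x <- if (is(newdata, "FeatureSet"))
    t(SummarizedExperiment::assay(newdata, "features")) else as.matrix(newdata)
  if (!identical(colnames(x), object@featureNames))
    x <- x[, object@featureNames, drop = FALSE]
  predict(object@booster, xgboost::xgb.DMatrix(x, nthread = 1))
})

#' Confusion counts of a binary prediction
#'
#' @param predicted,truth label vectors (`"alert"` / `"fatigue"`).
#' @param positive positive class (default `"fatigue"`).
#' @return Named numeric `TP`, `TN`, `FP`, `FN`.
#' @export
confusionCounts <- function(predicted, truth, positive = "fatigue") {
  p <- predicted == positive
  t <- truth == positive
  c(TP = sum(p & t), TN = sum(!p & !t), FP = sum(p & !t), FN = sum(!p & t))
}

#' Classification metrics from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+FP+FN+TN); Precision = TP/(TP+FP);
#' Recall = TP/(TP+FN); F1 = 2 Precision Recall / (Precision + Recall).
#' Precision/recall with an empty denominator are reported as `NA`
#' (explicitly undefined) rather than 0.
#'
#' @param counts named numeric with `TP`, `TN`, `FP`, `FN` (sum > 0).
#' @return Named numeric `accuracy`, `precision`, `recall`, `F1`.
#' @export
#' @examples
#' computeMetrics(c(TP = 40, TN = 30, FP = 20, FN = 10))
computeMetrics <- function(counts) {
  stopifnot(all(c("TP", "TN", "FP", "FN") %in% names(counts)))
  if (sum(counts) <= 0) stop("all-zero confusion counts", call. = FALSE)
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  c(accuracy = (tp + tn) / sum(counts), precision = prec, recall = rec,
    F1 = f1)
}

## Fold-internal selection: re-runs the two-stage selection on the training
## rows and applies the resulting row subset to train and test. `selection`
## is a list(alpha, minChannels, svm = svmConfig, rule, mode). Falls back
## to the unselected matrix (with a warning) when nothing is retained.
.applySelection <- function(fm, trainIdx, selection) {
  sub <- new("FeatureSet", fm[, trainIdx])
  rep <- anovaScreen(sub, alpha = selection$alpha,
                     minChannels = selection$minChannels)
  if (length(rep@retainedEEG) == 0L && length(rep@retainedECG) == 0L) {
    warning("fold-internal selection retained nothing; using all features")
    return(seq_len(nrow(fm)))
  }
  channels <- character(0)
  if (length(rep@retainedEEG) > 0L) {
    rk <- rankChannels(sub, rep, cfg = selection$svm, mode = selection$mode)
    channels <- selectedChannels(chooseChannels(rk, rule = selection$rule))
  }
  rd <- SummarizedExperiment::rowData(fm)
  which((rd$modality == "EEG" & rd$channel %in% channels &
           rd$feature %in% rep@retainedEEG) |
          (rd$modality == "ECG" & rd$feature %in% rep@retainedECG))
}

.evalFold <- function(fm, trainIdx, testIdx, hp, selection) {
  rows <- if (is.null(selection)) seq_len(nrow(fm)) else
    .applySelection(fm, trainIdx, selection)
  x <- t(SummarizedExperiment::assay(fm, "features")[rows, , drop = FALSE])
  labels <- SummarizedExperiment::colData(fm)$state
  t0 <- proc.time()[["elapsed"]]
  model <- trainFatigueModel(x[trainIdx, , drop = FALSE], labels[trainIdx], hp)
  trainTime <- proc.time()[["elapsed"]] - t0
  prob <- predict(model, x[testIdx, , drop = FALSE])
  pred <- ifelse(prob > 0.5, "fatigue", "alert")
  m <- computeMetrics(confusionCounts(pred, labels[testIdx]))
  c(m, n_test = length(testIdx), train_time_s = trainTime)
}

.cvResult <- function(scheme, folds, repeats, rows) {
  perFold <- as.data.frame(do.call(rbind, rows))
  metrics <- c("accuracy", "precision", "recall", "F1")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(perFold[[m]], na.rm = TRUE), 0),
    sd = vapply(metrics, function(m) sd(perFold[[m]], na.rm = TRUE), 0))
  new("CVResult", scheme = scheme, folds = folds, repeats = repeats,
      perFold = perFold, summary = summary)
}

#' Cross-clip (epoch-shuffled) cross-validation
#'
#' Stratified shuffled k-fold over epochs: subjects are mixed across
#' folds, so overlapping and within-subject correlated epochs appear on
#' both sides of each split. This estimates an optimistic upper bound of
#' performance. When `selection` is supplied the two-stage selection is
#' re-run inside each training fold (leakage-free); `selection = NULL`
#' evaluates the matrix as given (use with globally selected features to
#' reproduce whole-dataset selection).
#'
#' @param fm a [FeatureSet-class].
#' @param hp a [gbmHyperparams()].
#' @param folds number of folds (default 4).
#' @param seed fold-assignment seed.
#' @param selection `NULL` or `list(alpha, minChannels, svm, rule, mode)`.
#' @return A [CVResult-class].
#' @export
crossClipCV <- function(fm, hp = gbmHyperparams(), folds = 4, seed = 1,
                        selection = NULL) {
  labels <- SummarizedExperiment::colData(fm)$state
  fold <- .stratifiedFolds(labels, folds, seed)
  rows <- lapply(seq_len(folds), function(f)
    c(.evalFold(fm, which(fold != f), which(fold == f), hp, selection),
      rep = 1, fold = f))
  .cvResult("cross_clip", folds, 1, rows)
}

#' Cross-subject (subject-disjoint) cross-validation
#'
#' Subjects are partitioned into k disjoint groups per repeat; every epoch
#' of a subject stays in one fold, so test subjects are entirely unseen.
#' The whole scheme is repeated with different random groupings and
#' metrics are aggregated over all fold x repeat fits. Disjointness is
#' asserted, never assumed.
#'
#' @inheritParams crossClipCV
#' @param repeats number of random regroupings (default 5).
#' @return A [CVResult-class].
#' @export
crossSubjectCV <- function(fm, hp = gbmHyperparams(), folds = 4, repeats = 5,
                           seed = 1, selection = NULL) {
  cd <- SummarizedExperiment::colData(fm)
  subjects <- unique(cd$subject_id)
  if (length(subjects) < folds)
    stop(sprintf("%d subjects cannot fill %d disjoint folds",
                 length(subjects), folds), call. = FALSE)
  rows <- list()
  for (r in seq_len(repeats)) {
    set.seed(.deriveSeed(seed, r, 0, 30))
    grp <- rep_len(seq_len(folds), length(subjects))[sample.int(length(subjects))]
    for (f in seq_len(folds)) {
      testSub <- subjects[grp == f]
      testIdx <- which(cd$subject_id %in% testSub)
      trainIdx <- setdiff(seq_len(ncol(fm)), testIdx)
      stopifnot(!any(cd$subject_id[trainIdx] %in% testSub))  # disjointness
      rows[[length(rows) + 1L]] <-
        c(.evalFold(fm, trainIdx, testIdx, hp, selection), rep = r, fold = f)
    }
  }
  .cvResult("cross_subject", folds, repeats, rows)
}

#' Ablation over the six input conditions
#'
#' Evaluates the classifier under both CV schemes on: (1) all EEG
#' features, (2) EEG after ANOVA feature selection, (3) EEG after feature
#' and channel selection, (4) all ECG features, (5) ECG after feature
#' selection, (6) the multimodal fusion of (3) and (5). Conditions are
#' built from globally computed selection artifacts (whole-dataset
#' selection, as in the reference protocol).
#'
#' @param fm the full (unfused) normalized [FeatureSet-class].
#' @param report an [AnovaReport-class] from [anovaScreen()].
#' @param ranking a [ChannelRanking-class] with channels selected.
#' @param hp a [gbmHyperparams()].
#' @param folds,repeats,seed CV parameters (`repeats` applies to the
#'   cross-subject scheme only).
#' @return data.frame with 6 conditions x 2 schemes = 12 rows of mean/SD
#'   metrics, feature counts and training times.
#' @export
ablationSuite <- function(fm, report, ranking, hp = gbmHyperparams(),
                          folds = 4, repeats = 5, seed = 1) {
  rd <- SummarizedExperiment::rowData(fm)
  eegFS <- rd$modality == "EEG" & rd$feature %in% report@retainedEEG
  eegCS <- eegFS & rd$channel %in% selectedChannels(ranking)
  ecgFS <- rd$modality == "ECG" & rd$feature %in% report@retainedECG
  conditions <- list(
    "EEG (baseline)"    = rd$modality == "EEG",
    "EEG (w/ FS)"       = eegFS,
    "EEG (w/ FS and CS)" = eegCS,
    "ECG (baseline)"    = rd$modality == "ECG",
    "ECG (w/ FS)"       = ecgFS,
    "Multimodal fusion" = eegCS | ecgFS)
  out <- list()
  for (cn in names(conditions)) {
    keep <- conditions[[cn]]
    if (!any(keep)) {
      warning(sprintf("condition '%s' retained no features; using full modality", cn))
      keep <- if (grepl("^ECG", cn)) rd$modality == "ECG" else rd$modality == "EEG"
    }
    sub <- new("FeatureSet", fm[keep, ])
    for (scheme in c("cross_clip", "cross_subject")) {
      cv <- if (scheme == "cross_clip")
        crossClipCV(sub, hp, folds = folds, seed = seed)
      else crossSubjectCV(sub, hp, folds = folds, repeats = repeats, seed = seed)
      s <- cvSummary(cv)
      out[[length(out) + 1L]] <- data.frame(
        condition = cn, scheme = scheme, n_features = sum(keep),
        accuracy = s$mean[s$metric == "accuracy"],
        accuracy_sd = s$sd[s$metric == "accuracy"],
        precision = s$mean[s$metric == "precision"],
        recall = s$mean[s$metric == "recall"],
        F1 = s$mean[s$metric == "F1"],
        mean_train_time_s = mean(cv@perFold$train_time_s))
    }
  }
  do.call(rbind, out)
}

#' Write a CVResult or ablation table
#'
#' @param x a [CVResult-class] or the data.frame from [ablationSuite()].
#' @param path output path (`.json` for CVResult, `.tsv` for tables).
#' @return `path`, invisibly.
#' @export
writeCVResult <- function(x, path) {
  if (is(x, "CVResult")) {
    jsonlite::write_json(list(scheme = x@scheme, folds = x@folds,
                              repeats = x@repeats, per_fold = x@perFold,
                              summary = x@summary),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
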