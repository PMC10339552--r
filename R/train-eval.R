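#' Training configuration
#'
#' Optimization settings for [trainModel()]: mini-batch Adam on the
#' cross-entropy loss. With a positive `validationFraction` a stratified
#' validation split is held out and the weights from the epoch with the
#' lowest validation loss are returned; with 0 the final weights are
#' returned. Training is single-threaded per sample and reproducible for a
#' fixed (dataset order, seed).
#'
#' @param batchSize Mini-batch size N'.
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param seed Integer seed (weight init happens in [initModel()]; this seed
#'   drives shuffling and the validation split).
#' @param validationFraction Fraction of the training set held out for
#'   best-epoch checkpointing (0 disables).
#' @param variant Optional ablation variant; see [makeAblation()].
#' @return A named list of class `TrainConfig`.
#' @export
trainConfig <- function(batchSize = 64L, epochs = 50L, lr = 1e-3, seed = 1L,
                        validationFraction = 0.1, variant = NULL) {
  stopifnot(batchSize >= 1, epochs >= 1, lr > 0,
            validationFraction >= 0, validationFraction < 1)
  cfg <- list(batchSize = as.integer(batchSize), epochs = as.integer(epochs),
              lr = lr, seed = as.integer(seed),
              validationFraction = validationFraction, variant = variant)
  class(cfg) <- "TrainConfig"
  cfg
}

.labelsAsInt <- function(labels) as.integer(labels == "positive")

.embedAll <- function(ds, embedding) {
  lapply(as.character(sequences(ds)), embedSequence, embedding = embedding)
}

#' Train the network on a labeled dataset
#'
#' Minimizes the mean cross-entropy over shuffled mini-batches with Adam.
#' The embedding table is fixed during network training (it is trained
#' separately, on training sequences only; see [trainSkipgram()]).
#'
#' @param ds A labeled [SequenceDataset] with both classes present.
#' @param embedding A [KmerEmbedding].
#' @param config A [trainConfig()].
#' @param model Optional [DualScaleModel] template; when `NULL` one is
#'   initialized from `config$seed` with `filters` and `nFilters`.
#' @param filters,nFilters Architecture used when `model` is `NULL`.
#' @return A trained [DualScaleModel]; `metadata` holds the loss history
#'   (`trainLoss`, `valLoss`, `bestEpoch`) and the config echo.
#' @export
trainModel <- function(ds, embedding, config = trainConfig(), model = NULL,
                       filters = c(10L, 12L), nFilters = 1024L) {
  labs <- classLabels(ds)
  if (!length(labs)) stop("training requires a labeled dataset")
  if (length(unique(labs)) < 2L)
    stop("training requires both classes to be present")
  if (is.null(model))
    model <- initModel(embeddingDim = embeddingDim(embedding),
                       filters = filters, nFilters = nFilters,
                       seed = config$seed, variant = config$variant)
  else if (!is.null(config$variant))
    model <- makeAblation(model, config$variant, seed = config$seed)

  Es <- .embedAll(ds, embedding)
  y <- .labelsAsInt(labs)

  valIdx <- integer()
  if (config$validationFraction > 0) {
    set.seed(config$seed)
    for (cl in unique(y)) {
      idx <- which(y == cl)
      nv <- max(1L, round(length(idx) * config$validationFraction))
      valIdx <- c(valIdx, sample(idx, nv))
    }
    valIdx <- sort(valIdx)
  }
  trIdx <- setdiff(seq_along(y), valIdx)

  res <- .netTrain(Es[trIdx], y[trIdx], Es[valIdx], y[valIdx],
                   .modelToList(model),
                   list(batchSize = config$batchSize, epochs = config$epochs,
                        lr = config$lr, seed = config$seed))
  out <- .listToModel(model, res$model)
  out@metadata <- c(model@metadata,
                    list(trainLoss = as.numeric(res$trainLoss),
                         valLoss = as.numeric(res$valLoss),
                         bestEpoch = res$bestEpoch,
                         config = unclass(config)))
  out
}

#' Predict positive-class probabilities
#'
#' @param model A [DualScaleModel].
#' @param embedding The [KmerEmbedding] the model was trained with.
#' @param ds A [SequenceDataset] (labels optional).
#' @return Named numeric vector of positive-class probabilities.
#' @export
predictModel <- function(model, embedding, ds) {
  if (embeddingDim(embedding) != model@embeddingDim)
    stop("embedding dimension mismatch: model expects ", model@embeddingDim)
  Es <- .embedAll(ds, embedding)
  p <- .netForward(Es, .modelToList(model))
  setNames(p[, 2], names(sequences(ds)))
}

#' Tally a confusion matrix at a decision threshold
#'
#' Scores at or above the threshold predict the positive class (ties go to
#' positive).
#'
#' @param scores Positive-class probabilities.
#' @param labels True labels ("positive"/"negative" or a factor).
#' @param threshold Decision threshold (default 0.5).
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusionCounts <- function(scores, labels, threshold = 0.5) {
  if (!length(scores)) stop("empty input")
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  pos <- as.character(labels) == "positive"
  pred <- scores >= threshold
  c(TP = sum(pred & pos), FP = sum(pred & !pos),
    TN = sum(!pred & !pos), FN = sum(!pred & pos))
}

#' Classification metrics from confusion counts
#'
#' Exact evaluation of accuracy `(TP+TN)/(TP+FN+TN+FP)`, sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)` and the Matthews correlation
#' coefficient `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with
#' the convention MCC = 0 (and SN/SP = 0 with an empty class) when a
#' denominator factor vanishes.
#'
#' @param counts Named vector `c(TP, FP, TN, FN)`.
#' @return Named numeric vector `c(ACC, SN, SP, MCC)`; ACC/SN/SP are
#'   fractions in \[0, 1\].
#' @examples
#' classMetrics(c(TP = 159, FP = 29, TN = 171, FN = 41))
#' @export
classMetrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
  total <- tp + fp + tn + fn
  if (total <= 0) stop("empty confusion matrix")
  acc <- (tp + tn) / total
  sn <- if (tp + fn > 0) tp / (tp + fn) else 0
  sp <- if (tn + fp > 0) tn / (tn + fp) else 0
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
  c(ACC = acc, SN = sn, SP = sp, MCC = mcc)
}

#' Area under the ROC curve
#'
#' Trapezoidal rule over the empirical ROC curve; with tied scores the curve
#' takes the tie-group diagonal, so the value equals the Mann-Whitney
#' rank-sum statistic with ties counted one half.
#'
#' @param scores Positive-class scores.
#' @param labels True labels ("positive"/"negative" or a factor).
#' @return AUC in \[0, 1\].
#' @export
rocAuc <- function(scores, labels) {
  pos <- as.character(labels) == "positive"
  P <- sum(pos); N <- sum(!pos)
  if (P == 0 || N == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- pos[o]
  grp <- cumsum(rle(s)$lengths)  # last index of each distinct score
  tpr <- c(0, cumsum(y)[grp] / P)
  fpr <- c(0, cumsum(!y)[grp] / N)
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' Evaluate a trained model on a labeled dataset
#'
#' @inheritParams predictModel
#' @param threshold Decision threshold for the confusion counts.
#' @return An [EvalReport] with counts and ACC, SN, SP, MCC, AUC.
#' @export
evaluateModel <- function(model, embedding, ds, threshold = 0.5) {
  scores <- predictModel(model, embedding, ds)
  reportFromScores(scores, classLabels(ds), threshold = threshold,
                   config = list(threshold = threshold))
}

#' Build an [EvalReport] from scores and labels
#'
#' @param scores Positive-class probabilities.
#' @param labels True labels.
#' @param threshold Decision threshold.
#' @param config Optional config echo stored in the report.
#' @return An [EvalReport].
#' @export
reportFromScores <- function(scores, labels, threshold = 0.5, config = list()) {
  counts <- confusionCounts(scores, labels, threshold)
  m <- classMetrics(counts)
  auc <- if (length(unique(labels)) == 2L) rocAuc(scores, labels) else NA_real_
  new("EvalReport", counts = setNames(as.integer(counts), names(counts)),
      metrics = c(m, AUC = auc), scores = as.numeric(scores),
      labels = factor(as.character(labels), levels = c("negative", "positive")),
      config = config)
}

#' @rdname EvalReport-class
#' @export
setMethod("confusion", "EvalReport", function(x) x@counts)

#' @rdname EvalReport-class
#' @export
setMethod("metricValues", "EvalReport", function(x) x@metrics)

setMethod("show", "EvalReport", function(object) {
  m <- object@metrics
  cat("EvalReport on", sum(object@counts), "records\n")
  cat(sprintf("  TP=%d FP=%d TN=%d FN=%d\n", object@counts["TP"],
              object@counts["FP"], object@counts["TN"], object@counts["FN"]))
  cat(sprintf("  ACC %.2f%%  MCC %.3f  SN %.2f%%  SP %.2f%%  AUC %s\n",
              100 * m["ACC"], m["MCC"], 100 * m["SN"], 100 * m["SP"],
              if (is.na(m["AUC"])) "NA" else sprintf("%.2f%%", 100 * m["AUC"])))
})

#' Convert an [EvalReport] to a one-row data.frame
#'
#' @param report An [EvalReport].
#' @return data.frame with counts and metrics (percent scale for ACC/SN/SP/AUC).
#' @export
reportAsRow <- function(report) {
  m <- metricValues(report)
  cbind(as.data.frame(t(confusion(report))),
        data.frame(ACC = 100 * m[["ACC"]], MCC = m[["MCC"]],
                   SN = 100 * m[["SN"]], SP = 100 * m[["SP"]],
                   AUC = 100 * m[["AUC"]]))
}

#' k-fold cross-validation with leakage-safe embedding retraining
#'
#' For each fold the network *and* the word embedding are trained on the
#' other k - 1 parts only; the held-out part is embedded with that fold's
#' table and evaluated. Per-fold reports and the unweighted arithmetic mean
#' of each metric are returned.
#'
#' @param ds A labeled [SequenceDataset].
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold split; fold f trains with seed
#'   `seed + f`.
#' @param stratified Stratify the fold split by class.
#' @param config A [trainConfig()].
#' @param skipgram A [skipgramConfig()] for per-fold embedding training.
#' @param filters,nFilters Architecture parameters.
#' @return A [CVReport].
#' @export
crossValidate <- function(ds, k = 10L, seed = 1L, stratified = TRUE,
                          config = trainConfig(), skipgram = skipgramConfig(),
                          filters = c(10L, 12L), nFilters = 1024L) {
  fold <- splitFolds(ds, k = k, seed = seed, stratified = stratified)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    train <- ds[fold != f]
    test <- ds[fold == f]
    sg <- skipgram; sg$seed <- skipgram$seed + f
    emb <- trainSkipgram(train, sg)
    cfg <- config; cfg$seed <- config$seed + f
    model <- trainModel(train, emb, cfg, filters = filters,
                        nFilters = nFilters)
    reports[[f]] <- evaluateModel(model, emb, test)
    reports[[f]]@config <- list(fold = f, seed = cfg$seed)
  }
  mets <- do.call(rbind, lapply(reports, metricValues))
  new("CVReport", folds = reports, means = colMeans(mets),
      config = list(k = k, seed = seed, stratified = stratified))
}

#' @rdname CVReport-class
#' @export
setMethod("foldReports", "CVReport", function(x) x@folds)

#' @rdname CVReport-class
#' @export
setMethod("metricValues", "CVReport", function(x) x@means)

setMethod("show", "CVReport", function(object) {
  cat("CVReport over", length(object@folds), "folds\n")
  m <- object@means
  cat(sprintf("  mean ACC %.2f%%  MCC %.3f  SN %.2f%%  SP %.2f%%  AUC %.2f%%\n",
              100 * m["ACC"], m["MCC"], 100 * m["SN"], 100 * m["SP"],
              100 * m["AUC"]))
})

#' Multi-seed stability of independent-test performance
#'
#' Retrains the embedding and the network once per seed, evaluates each on
#' the same test set, and reports the mean and variance of ACC and MCC
#' across seeds (population variance by default, i.e. dividing by the
#' number of seeds; set `varType = "sample"` for the n-1 denominator).
#'
#' @param dsTrain,dsTest Labeled [SequenceDataset] objects.
#' @param seeds Integer vector of at least 2 seeds.
#' @param config A [trainConfig()] (its seed is replaced per run).
#' @param skipgram A [skipgramConfig()] (its seed is replaced per run).
#' @param filters,nFilters Architecture parameters.
#' @param varType "population" or "sample".
#' @return List with `perSeed` (data.frame of seed, ACC, MCC), `mean` and
#'   `variance` (named vectors over ACC and MCC, percent scale for ACC).
#' @export
seedStability <- function(dsTrain, dsTest, seeds, config = trainConfig(),
                          skipgram = skipgramConfig(),
                          filters = c(10L, 12L), nFilters = 1024L,
                          varType = c("population", "sample")) {
  varType <- match.arg(varType)
  if (length(seeds) < 2L) stop("at least 2 seeds required")
  rows <- lapply(seeds, function(s) {
    sg <- skipgram; sg$seed <- as.integer(s)
    emb <- trainSkipgram(dsTrain, sg)
    cfg <- config; cfg$seed <- as.integer(s)
    model <- trainModel(dsTrain, emb, cfg, filters = filters,
                        nFilters = nFilters)
    m <- metricValues(evaluateModel(model, emb, dsTest))
    data.frame(seed = s, ACC = 100 * m[["ACC"]], MCC = m[["MCC"]])
  })
  perSeed <- do.call(rbind, rows)
  popVar <- function(x) mean((x - mean(x))^2)
  vfun <- if (varType == "population") popVar else var
  list(perSeed = perSeed,
       mean = c(ACC = mean(perSeed$ACC), MCC = mean(perSeed$MCC)),
       variance = c(ACC = vfun(perSeed$ACC), MCC = vfun(perSeed$MCC)))
}

#' Two-layer prediction: cascade of identification and classification
#'
#' Classifier I (layer 1) gates: sequences predicted non-enhancer are
#' labeled as such and never reach classifier II. Sequences predicted
#' enhancer are passed to classifier II, which labels them strong or weak.
#' Evaluating each layer in isolation on its own labeled test set is done
#' with [evaluateModel()] directly.
#'
#' @param ds A [SequenceDataset] (labels ignored).
#' @param model1,model2 Trained [DualScaleModel] objects for layers 1 and 2.
#' @param embedding1,embedding2 The matching [KmerEmbedding] tables.
#' @param threshold Decision threshold for both layers.
#' @return Factor with levels `c("non-enhancer", "weak enhancer",
#'   "strong enhancer")`, named by record id.
#' @export
twoLayerPredict <- function(ds, model1, embedding1, model2, embedding2,
                            threshold = 0.5) {
  p1 <- predictModel(model1, embedding1, ds)
  out <- rep("non-enhancer", length(p1))
  isEnh <- p1 >= threshold
  if (any(isEnh)) {
    p2 <- predictModel(model2, embedding2, ds[which(isEnh)])
    out[which(isEnh)] <- ifelse(p2 >= threshold, "strong enhancer",
                                "weak enhancer")
  }
  setNames(factor(out, levels = c("non-enhancer", "weak enhancer",
                                  "strong enhancer")),
           names(sequences(ds)))
}
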