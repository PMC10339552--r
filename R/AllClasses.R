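#' Labeled DNA sequence dataset
#'
#' Container for a set of fixed-alphabet DNA sequences with optional binary
#' class labels. For layer 1 (enhancer identification) the positive class is
#' "enhancer"; for layer 2 (strength classification) it is "strong enhancer".
#' Class counts are always recomputed from the records, never cached.
#'
#' @slot sequences A [Biostrings::DNAStringSet] (names are record ids).
#' @slot labels A factor with levels `c("negative", "positive")`, one per
#'   sequence, or a zero-length factor for unlabeled data.
#' @slot layer Character scalar: `"identification"`, `"classification"` or
#'   `"none"`.
#'
#' @seealso [sequenceDataset()], [readFastaRecords()], [validateSequences()]
#' @exportClass SequenceDataset
setClass("SequenceDataset",
  representation(sequences = "DNAStringSet", labels = "factor",
                 layer = "character"),
  prototype(labels = factor(character(), levels = c("negative", "positive")),
            layer = "none"))

setValidity("SequenceDataset", function(object) {
  msg <- character()
  if (length(object@labels) &&
      length(object@labels) != length(object@sequences))
    msg <- c(msg, "labels must match sequences in length (or be empty)")
  if (!identical(levels(object@labels), c("negative", "positive")))
    msg <- c(msg, "label levels must be c('negative', 'positive')")
  if (!(object@layer %in% c("identification", "classification", "none")))
    msg <- c(msg, "layer must be 'identification', 'classification' or 'none'")
  if (length(msg)) msg else TRUE
})

#' 3-mer skip-gram embedding table
#'
#' Input and output (context) vector representations for every vocabulary
#' word, together with corpus counts and the training configuration. Input
#' vectors are the per-word embeddings used downstream; output vectors enter
#' the softmax word-prediction probability (see [skipgramProb()]).
#'
#' @slot input Numeric matrix, vocabulary words x dimensions (rownames are
#'   words); the input vector representations.
#' @slot output Numeric matrix of the same shape; the output/context vectors.
#' @slot counts Named integer vector of corpus counts per vocabulary word.
#' @slot config List echoing the [skipgramConfig()] used for training.
#'
#' @seealso [trainSkipgram()], [embedSequence()]
#' @exportClass KmerEmbedding
setClass("KmerEmbedding",
  representation(input = "matrix", output = "matrix", counts = "integer",
                 config = "list"))

setValidity("KmerEmbedding", function(object) {
  msg <- character()
  if (!identical(dim(object@input), dim(object@output)))
    msg <- c(msg, "input and output matrices must have identical dimensions")
  if (nrow(object@input) != length(object@counts))
    msg <- c(msg, "one count per vocabulary word required")
  if (!all(is.finite(object@input)) || !all(is.finite(object@output)))
    msg <- c(msg, "all embedding entries must be finite")
  if (is.null(rownames(object@input)))
    msg <- c(msg, "input matrix must have words as rownames")
  if (length(msg)) msg else TRUE
})

#' Dual-scale convolution + spatial attention model
#'
#' Weights of the dual-scale fusion branches (1D convolutions of kernel
#' widths 10 and 12 by default), the spatial attention convolution, and the
#' fully-connected softmax head, plus ablation flags. Branch weights are
#' stored as `M x C x k` arrays (filters x input channels x taps).
#'
#' When `bypass` is set (the variant with both convolutions and the attention
#' removed), the head consumes the per-channel spatial maximum of the raw
#' embedding, so its input dimension equals the embedding dimension.
#'
#' @slot branches List of branches, each `list(w = array(M, C, k), b, k)`.
#' @slot branchEnabled Logical vector, one flag per branch.
#' @slot attention `list(w = array(1, 2, 7), b)` (empty list when absent).
#' @slot useAttention Logical scalar.
#' @slot head `list(w = matrix(2, M), b = numeric(2))`; logits row order is
#'   (negative, positive).
#' @slot bypass Logical scalar.
#' @slot embeddingDim Integer, input channel count (embedding dimension d).
#' @slot nFilters Integer, filters per branch (M).
#' @slot metadata List for training history and provenance.
#'
#' @seealso [initModel()], [makeAblation()], [forwardPass()], [trainModel()]
#' @exportClass DualScaleModel
setClass("DualScaleModel",
  representation(branches = "list", branchEnabled = "logical",
                 attention = "list", useAttention = "logical",
                 head = "list", bypass = "logical",
                 embeddingDim = "integer", nFilters = "integer",
                 metadata = "list"),
  prototype(metadata = list()))

setValidity("DualScaleModel", function(object) {
  msg <- character()
  if (length(object@branches) != length(object@branchEnabled))
    msg <- c(msg, "one enabled flag per branch required")
  if (!object@bypass && !any(object@branchEnabled))
    msg <- c(msg, "at least one branch must be enabled (or bypass set)")
  headIn <- ncol(object@head$w)
  if (object@bypass) {
    if (headIn != object@embeddingDim)
      msg <- c(msg, "bypass head input dimension must equal embeddingDim")
  } else if (headIn != object@nFilters) {
    msg <- c(msg, "head input dimension must equal the filter count")
  }
  if (nrow(object@head$w) != 2L)
    msg <- c(msg, "head must produce 2 logits")
  for (b in object@branches) {
    dw <- dim(b$w)
    if (length(dw) != 3L || dw[1] != object@nFilters ||
        dw[2] != object@embeddingDim || dw[3] != b$k)
      msg <- c(msg, "branch weight array must be M x d x k")
    if (length(b$b) != object@nFilters)
      msg <- c(msg, "branch bias length must be M")
  }
  if (object@useAttention) {
    if (!length(object@attention))
      msg <- c(msg, "useAttention set but no attention weights")
    else if (dim(object@attention$w)[3] %% 2L == 0L)
      msg <- c(msg, "attention kernel width must be odd")
  }
  if (length(msg)) msg else TRUE
})

#' Evaluation report for one run
#'
#' Confusion counts at a fixed decision threshold together with the derived
#' metrics: accuracy (ACC), sensitivity (SN), specificity (SP), Matthews
#' correlation coefficient (MCC) and area under the ROC curve (AUC). ACC, SN,
#' SP and AUC are stored as fractions in \[0, 1\] and printed as percentages;
#' MCC lies in \[-1, 1\].
#'
#' @slot counts Named integer vector `c(TP, FP, TN, FN)`.
#' @slot metrics Named numeric vector `c(ACC, SN, SP, MCC, AUC)` (AUC may be
#'   `NA` when scores were unavailable).
#' @slot scores Numeric vector of positive-class probabilities (may be empty).
#' @slot labels Factor of true labels matching `scores`.
#' @slot config List echoing evaluation settings (threshold, seed, variant).
#'
#' @seealso [evaluateModel()], [classMetrics()], [confusionCounts()]
#' @exportClass EvalReport
setClass("EvalReport",
  representation(counts = "integer", metrics = "numeric", scores = "numeric",
                 labels = "factor", config = "list"),
  prototype(config = list()))

setValidity("EvalReport", function(object) {
  msg <- character()
  if (!all(c("TP", "FP", "TN", "FN") %in% names(object@counts)))
    msg <- c(msg, "counts must be named TP, FP, TN, FN")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be nonnegative")
  if (length(object@scores) &&
      sum(object@counts) != length(object@scores))
    msg <- c(msg, "counts must sum to the number of evaluated records")
  if (length(msg)) msg else TRUE
})

#' Cross-validation report
#'
#' Per-fold [EvalReport] objects plus the unweighted arithmetic mean of each
#' metric across folds.
#'
#' @slot folds List of [EvalReport] objects, one per fold.
#' @slot means Named numeric vector of metric means across folds.
#' @slot config List echoing the cross-validation settings.
#'
#' @seealso [crossValidate()]
#' @exportClass CVReport
setClass("CVReport",
  representation(folds = "list", means = "numeric", config = "list"),
  prototype(config = list()))

setValidity("CVReport", function(object) {
  ok <- all(vapply(object@folds, is, logical(1), class2 = "EvalReport"))
  if (!ok) "all folds must be EvalReport objects" else TRUE
})
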