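#' Initialize a dual-scale attention model
#'
#' Weights are drawn from a fan-in-scaled uniform distribution
#' U(-1/sqrt(fanIn), 1/sqrt(fanIn)), seeded; biases start at zero. The
#' default architecture has two convolution branches with kernel widths 10
#' and 12, 1024 filters each, a width-7 spatial attention convolution over
#' the 2-row channel-pooled descriptor, and a 2-way softmax head over the
#' globally max-pooled channels.
#'
#' @param embeddingDim Input channel count d (embedding dimension).
#' @param filters Integer vector of branch kernel widths.
#' @param nFilters Filters per branch (M).
#' @param attentionKernel Attention convolution width (odd).
#' @param seed Integer seed for weight initialization.
#' @param variant Optional ablation variant applied after initialization;
#'   see [makeAblation()].
#' @return A [DualScaleModel].
#' @examples
#' m <- initModel(embeddingDim = 4, nFilters = 8, seed = 1)
#' m
#' @export
initModel <- function(embeddingDim = 20L, filters = c(10L, 12L),
                      nFilters = 1024L, attentionKernel = 7L, seed = 1L,
                      variant = NULL) {
  d <- as.integer(embeddingDim); M <- as.integer(nFilters)
  if (attentionKernel %% 2L == 0L) stop("attention kernel width must be odd")
  set.seed(seed)
  branches <- lapply(as.integer(filters), function(k) {
    lim <- 1 / sqrt(d * k)
    list(w = array(runif(M * d * k, -lim, lim), dim = c(M, d, k)),
         b = numeric(M), k = k)
  })
  limA <- 1 / sqrt(2 * attentionKernel)
  attention <- list(w = array(runif(2 * attentionKernel, -limA, limA),
                              dim = c(1L, 2L, as.integer(attentionKernel))),
                    b = 0)
  limH <- 1 / sqrt(M)
  head <- list(w = matrix(runif(2 * M, -limH, limH), nrow = 2L), b = numeric(2))
  model <- new("DualScaleModel", branches = branches,
               branchEnabled = rep(TRUE, length(branches)),
               attention = attention, useAttention = TRUE, head = head,
               bypass = FALSE, embeddingDim = d, nFilters = M,
               metadata = list(seed = as.integer(seed)))
  if (!is.null(variant)) model <- makeAblation(model, variant, seed = seed)
  model
}

#' Derive an ablation variant of a model
#'
#' Variants mirror the ablation study: `"-SS1"` / `"-SS2"` disable the
#' first / second convolution branch; `"-SA"` disables spatial attention;
#' `"-SS1-SS2-SA"` bypasses both convolutions and the attention, so the head
#' consumes the per-channel spatial maximum of the raw embedding (head input
#' dimension becomes the embedding dimension, reinitialized with `seed`).
#'
#' @param model A [DualScaleModel].
#' @param variant One of "-SS1", "-SS2", "-SA", "-SS1-SS2-SA" (or "full").
#' @param seed Seed for head reinitialization in the bypass variant.
#' @return A [DualScaleModel].
#' @export
makeAblation <- function(model, variant, seed = 1L) {
  variant <- gsub(" ", "", variant)
  switch(variant,
    "full" = model,
    "-SS1" = { model@branchEnabled[1] <- FALSE; validObject(model); model },
    "-SS2" = { model@branchEnabled[2] <- FALSE; validObject(model); model },
    "-SA" = { model@useAttention <- FALSE; model },
    "-SS1-SS2-SA" = {
      d <- model@embeddingDim
      set.seed(seed)
      lim <- 1 / sqrt(d)
      model@head <- list(w = matrix(runif(2 * d, -lim, lim), nrow = 2L),
                         b = numeric(2))
      model@bypass <- TRUE
      model@useAttention <- FALSE
      model@branchEnabled[] <- FALSE
      model
    },
    stop("unknown ablation variant: ", variant))
}

setMethod("show", "DualScaleModel", function(object) {
  ks <- vapply(object@branches, `[[`, integer(1), "k")
  cat("DualScaleModel: d =", object@embeddingDim, ", M =", object@nFilters, "\n")
  if (object@bypass) {
    cat("  bypass variant: max-pooled embedding -> dense head\n")
  } else {
    cat("  branches (kernel widths):",
        paste0(ks, ifelse(object@branchEnabled, "", " [disabled]"),
               collapse = ", "), "\n")
    cat("  spatial attention:", if (object@useAttention) "on" else "off", "\n")
  }
})

# flatten an M x C x k weight array to the im2col layout M x (C*k),
# column index (j-1)*C + c
.flattenConvW <- function(w) {
  dw <- dim(w)
  t(matrix(aperm(w, c(2, 3, 1)), nrow = dw[2] * dw[3]))
}

# model -> plain list consumed by the C++ routines (enabled branches only)
.modelToList <- function(model) {
  branches <- list()
  for (i in seq_along(model@branches)) {
    if (!model@branchEnabled[i]) next
    b <- model@branches[[i]]
    branches[[length(branches) + 1L]] <-
      list(W = .flattenConvW(b$w), b = b$b, k = b$k)
  }
  useAtt <- model@useAttention && !model@bypass
  list(branches = branches, bypass = model@bypass, useAttention = useAtt,
       attW = if (useAtt) as.numeric(.flattenConvW(model@attention$w)) else numeric(),
       attB = if (useAtt) model@attention$b else 0,
       headW = model@head$w, headB = model@head$b)
}

# write a trained flat list back into the S4 model
.listToModel <- function(model, lst) {
  j <- 0L
  for (i in seq_along(model@branches)) {
    if (!model@branchEnabled[i]) next
    j <- j + 1L
    W <- lst$branches[[j]]$W
    d <- model@embeddingDim; k <- model@branches[[i]]$k
    model@branches[[i]]$w <- aperm(array(t(W), dim = c(d, k, nrow(W))), c(3, 1, 2))
    model@branches[[i]]$b <- as.numeric(lst$branches[[j]]$b)
  }
  if (model@useAttention && !model@bypass) {
    kA <- length(lst$attW) / 2L
    model@attention$w <- aperm(array(lst$attW, dim = c(2L, kA, 1L)), c(3, 1, 2))
    model@attention$b <- as.numeric(lst$attB)
  }
  model@head <- list(w = matrix(as.numeric(lst$headW), nrow = 2L),
                     b = as.numeric(lst$headB))
  model
}

#' Valid (unpadded) 1D convolution
#'
#' `out[m, t] = b[m] + sum_{c, j} w[m, c, j] * E[c, t + j - 1]`, stride 1,
#' no padding: a C x N input and width-k kernels give an M x (N - k + 1)
#' output, e.g. 20 x 198 -> 1024 x 189 for k = 10.
#'
#' @param E Numeric matrix, channels x positions.
#' @param w Weight array M x C x k.
#' @param b Bias vector of length M.
#' @return Numeric matrix M x (N - k + 1).
#' @export
conv1dValid <- function(E, w, b = NULL) {
  dw <- dim(w)
  if (length(dw) != 3L) stop("w must be an M x C x k array")
  M <- dw[1]; C <- dw[2]; k <- dw[3]
  if (nrow(E) != C) stop("channel mismatch: E has ", nrow(E), ", w expects ", C)
  N <- ncol(E)
  if (N < k) stop("input length ", N, " shorter than kernel width ", k)
  if (is.null(b)) b <- numeric(M)
  L <- N - k + 1L
  X <- matrix(0, C * k, L)
  for (j in seq_len(k))
    X[((j - 1L) * C + 1L):(j * C), ] <- E[, j:(j + L - 1L), drop = FALSE]
  .flattenConvW(w) %*% X + b
}

#' Dual-scale fusion of branch convolutions
#'
#' Applies each enabled convolution branch to the embedding, rectifies
#' (ReLU), and concatenates the branch outputs along the spatial axis in
#' branch order. The channel count (M) is preserved: a 20 x 198 input under
#' the default architecture yields a 1024 x 376 fused matrix (189 + 187).
#'
#' @param E Embedding matrix, d x N.
#' @param model A [DualScaleModel].
#' @return Fused feature matrix, M x sum of branch output lengths.
#' @export
dualScaleFusion <- function(E, model) {
  if (!any(model@branchEnabled)) stop("no enabled convolution branch")
  parts <- list()
  for (i in seq_along(model@branches)) {
    if (!model@branchEnabled[i]) next
    b <- model@branches[[i]]
    parts[[length(parts) + 1L]] <- pmax(conv1dValid(E, b$w, b$b), 0)
  }
  do.call(cbind, parts)
}

#' Spatial attention gate
#'
#' Builds the 2 x L descriptor stacking the per-position channel mean (row 1)
#' and channel max (row 2), convolves it with a width-7 kernel under
#' symmetric zero padding, applies the sigmoid to obtain the attention
#' vector S in (0, 1), and rescales every feature column:
#' `Fhat[m, t] = F[m, t] * S[t]` (broadcast along channels).
#'
#' @param F Fused feature matrix, M x L.
#' @param attention `list(w = array(1, 2, kA), b)`.
#' @return `list(score = 1 x L matrix, refined = M x L matrix)`.
#' @export
spatialAttention <- function(F, attention) {
  kA <- dim(attention$w)[3]
  pad <- (kA - 1L) / 2L
  L <- ncol(F)
  D <- rbind(colMeans(F), apply(F, 2, max))
  Dpad <- cbind(matrix(0, 2, pad), D, matrix(0, 2, pad))
  z <- conv1dValid(Dpad, attention$w, attention$b)
  S <- 1 / (1 + exp(-z))
  list(score = S, refined = sweep(F, 2, as.numeric(S), `*`))
}

#' Forward pass: embedding matrix to class probabilities
#'
#' Composes dual-scale fusion, spatial attention (when enabled), global
#' max-pooling along the spatial axis, the dense head, and the softmax. For
#' the bypass ablation the head consumes the per-channel maximum of the raw
#' embedding. This is the plain-R reference path; batch prediction uses the
#' compiled implementation (see [predictModel()]), and the two agree to
#' floating-point round-off.
#'
#' @param E Embedding matrix, d x N.
#' @param model A [DualScaleModel].
#' @return Named probability vector `c(positive =, negative =)`, summing to 1.
#' @export
forwardPass <- function(E, model) {
  if (model@bypass) {
    v <- apply(E, 1, max)
  } else {
    F <- dualScaleFusion(E, model)
    Fhat <- if (model@useAttention)
      spatialAttention(F, model@attention)$refined else F
    v <- apply(Fhat, 1, max)
  }
  logits <- as.numeric(model@head$w %*% v + model@head$b)
  ex <- exp(logits - max(logits))
  p <- ex / sum(ex)
  c(positive = p[2], negative = p[1])
}

#' Mean cross-entropy loss
#'
#' `-(1/N') sum_i log p_i[y_i]` over a batch of N' probability pairs.
#' Probabilities are clamped at 1e-12 (with a message) so a zero probability
#' at the true class yields a large finite loss.
#'
#' @param probs Numeric matrix with columns `positive`, `negative` (or an
#'   n x 2 matrix in that order), one row per sample.
#' @param labels Factor/character vector of true classes
#'   ("positive"/"negative").
#' @return Nonnegative scalar loss.
#' @examples
#' crossEntropy(matrix(0.5, 2, 2), c("positive", "negative"))  # log(2)
#' @export
crossEntropy <- function(probs, labels) {
  probs <- as.matrix(probs)
  if (is.null(colnames(probs))) colnames(probs) <- c("positive", "negative")
  if (!nrow(probs)) stop("empty batch")
  labels <- as.character(labels)
  pTrue <- probs[cbind(seq_len(nrow(probs)), match(labels, colnames(probs)))]
  if (anyNA(pTrue)) stop("labels must be 'positive' or 'negative'")
  if (any(pTrue < 1e-12)) {
    message("cross-entropy: clamped ", sum(pTrue < 1e-12),
            " probabilities at 1e-12")
    pTrue <- pmax(pTrue, 1e-12)
  }
  -mean(log(pTrue))
}

#' Write a model checkpoint
#'
#' A single self-describing JSON document holding every weight array at full
#' precision plus the architecture hyperparameters (kernel widths, filter
#' count, embedding dimension, ablation flags).
#'
#' @param model A [DualScaleModel].
#' @param path Output path (.json).
#' @return Invisibly, `path`.
#' @export
writeModel <- function(model, path) {
  obj <- list(
    class = "DualScaleModel",
    embeddingDim = model@embeddingDim,
    nFilters = model@nFilters,
    branchEnabled = model@branchEnabled,
    useAttention = model@useAttention,
    bypass = model@bypass,
    # weight arrays stored flat (column-major) with explicit dims
    branches = lapply(model@branches, function(b)
      list(k = b$k, w = as.numeric(b$w), b = b$b)),
    attention = if (length(model@attention))
      list(k = dim(model@attention$w)[3], w = as.numeric(model@attention$w),
           b = model@attention$b) else NULL,
    head = list(w = as.numeric(model@head$w), b = model@head$b))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a model checkpoint written by [writeModel()]
#'
#' @param path Path to the JSON checkpoint.
#' @return A [DualScaleModel].
#' @export
readModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  d <- as.integer(obj$embeddingDim); M <- as.integer(obj$nFilters)
  branches <- lapply(obj$branches, function(br) {
    k <- as.integer(br$k)
    list(w = array(as.numeric(unlist(br$w)), dim = c(M, d, k)),
         b = as.numeric(unlist(br$b)), k = k)
  })
  attention <- list()
  if (!is.null(obj$attention))
    attention <- list(w = array(as.numeric(unlist(obj$attention$w)),
                                dim = c(1L, 2L, as.integer(obj$attention$k))),
                      b = as.numeric(obj$attention$b))
  new("DualScaleModel", branches = branches,
      branchEnabled = as.logical(unlist(obj$branchEnabled)),
      attention = attention, useAttention = as.logical(obj$useAttention),
      head = list(w = matrix(as.numeric(unlist(obj$head$w)), nrow = 2L),
                  b = as.numeric(unlist(obj$head$b))),
      bypass = as.logical(obj$bypass), embeddingDim = d, nFilters = M,
      metadata = list(source = path))
}
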