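# Independent brute-force oracles and small fixture builders. These stay
# deliberately loop-based and separate from the package's vectorized /
# compiled code paths.

# direct triple-loop valid convolution: out[m, t] = b[m] + sum w[m,c,j] E[c,t+j-1]
oracleConv <- function(E, w, b) {
  M <- dim(w)[1]; C <- dim(w)[2]; k <- dim(w)[3]
  L <- ncol(E) - k + 1
  out <- matrix(0, M, L)
  for (m in seq_len(M)) for (t in seq_len(L)) {
    acc <- b[m]
    for (c in seq_len(C)) for (j in seq_len(k))
      acc <- acc + w[m, c, j] * E[c, t + j - 1]
    out[m, t] <- acc
  }
  out
}

# explicit per-position attention: mean/max descriptor, padded 7-tap conv,
# sigmoid, broadcast product
oracleAttention <- function(F, w, b) {
  kA <- dim(w)[3]; pad <- (kA - 1) / 2
  L <- ncol(F)
  D <- matrix(0, 2, L)
  for (t in seq_len(L)) {
    D[1, t] <- mean(F[, t])
    D[2, t] <- max(F[, t])
  }
  S <- numeric(L)
  for (t in seq_len(L)) {
    acc <- b
    for (j in seq_len(kA)) {
      tt <- t + j - 1 - pad
      if (tt >= 1 && tt <= L)
        acc <- acc + w[1, 1, j] * D[1, tt] + w[1, 2, j] * D[2, tt]
    }
    S[t] <- 1 / (1 + exp(-acc))
  }
  Fhat <- F
  for (m in seq_len(nrow(F))) for (t in seq_len(L)) Fhat[m, t] <- F[m, t] * S[t]
  list(score = S, refined = Fhat)
}

# full forward by composing the loop oracles plus explicit max-pool + softmax
oracleForward <- function(E, model) {
  if (model@bypass) {
    v <- apply(E, 1, max)
  } else {
    parts <- list()
    for (i in seq_along(model@branches)) {
      if (!model@branchEnabled[i]) next
      b <- model@branches[[i]]
      parts[[length(parts) + 1]] <- pmax(oracleConv(E, b$w, b$b), 0)
    }
    F <- do.call(cbind, parts)
    Fhat <- if (model@useAttention)
      oracleAttention(F, model@attention$w, model@attention$b)$refined else F
    v <- numeric(nrow(Fhat))
    for (m in seq_len(nrow(Fhat))) v[m] <- max(Fhat[m, ])
  }
  logits <- as.numeric(model@head$w %*% v + model@head$b)
  ex <- exp(logits - max(logits))
  p <- ex / sum(ex)
  c(positive = p[2], negative = p[1])
}

# O(n^2) rank-pair AUC: P(pos > neg) + 0.5 P(tie)
oracleAuc <- function(scores, labels) {
  pos <- which(as.character(labels) == "positive")
  neg <- which(as.character(labels) == "negative")
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

# scalar recomputation of the four confusion-matrix metrics
oracleMetrics <- function(tp, fp, tn, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  c(ACC = (tp + tn) / (tp + fp + tn + fn),
    SN = if (tp + fn > 0) tp / (tp + fn) else 0,
    SP = if (tn + fp > 0) tn / (tn + fp) else 0,
    MCC = if (den > 0) (tp * tn - fp * fn) / den else 0)
}

# random small model instance for oracle comparisons
randomModel <- function(d, filters, M, seed, variant = NULL) {
  initModel(embeddingDim = d, filters = filters, nFilters = M, seed = seed,
            variant = variant)
}

# a quick labeled dataset with an unmistakable class signal
separableDataset <- function(nPerClass = 20, seed = 1) {
  set.seed(seed)
  pos <- replicate(nPerClass,
                   paste0(strrep("A", 90), sampleBackground(20), strrep("A", 90)))
  neg <- replicate(nPerClass,
                   paste0(strrep("C", 90), sampleBackground(20), strrep("C", 90)))
  sequenceDataset(setNames(c(pos, neg), paste0("s", seq_len(2 * nPerClass))),
                  labels = rep(c("positive", "negative"), each = nPerClass))
}
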