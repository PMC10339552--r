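#' Tokenize a DNA sequence into overlapping n-mer words
#'
#' A sequence of K nucleotides yields all K - n + 1 overlapping n-mers in
#' order; with the default 3-mers, consecutive words overlap by two
#' nucleotides and a K-nt sequence gives N = K - 2 words (for example
#' "ATCGG" gives ATC, TCG, CGG).
#'
#' @param seq A single DNA string (character scalar).
#' @param n Word size in nucleotides (default 3).
#' @return Character vector of words.
#' @examples
#' tokenize("ATCGG")
#' @export
tokenize <- function(seq, n = 3L) {
  seq <- as.character(seq)
  K <- nchar(seq)
  if (K < n) stop("sequence shorter than the word size (", n, ")")
  starts <- seq_len(K - n + 1L)
  substring(seq, starts, starts + n - 1L)
}

#' Build a word vocabulary from a token corpus
#'
#' @param corpus List of token vectors (one per sequence/sentence), as
#'   produced by [tokenize()].
#' @param minCount Minimum corpus count for a word to be retained.
#' @return A data.frame with columns `word`, `index` (0-based, dense) and
#'   `count`, ordered by first appearance.
#' @export
buildVocab <- function(corpus, minCount = 1L) {
  if (!length(corpus)) stop("empty corpus")
  tokens <- unlist(corpus, use.names = FALSE)
  if (!length(tokens)) stop("empty corpus")
  counts <- table(factor(tokens, levels = unique(tokens)))
  keep <- counts >= minCount
  data.frame(word = names(counts)[keep],
             index = seq_len(sum(keep)) - 1L,
             count = as.integer(counts[keep]),
             stringsAsFactors = FALSE)
}

#' Skip-gram training configuration
#'
#' Defaults follow the reference training setup for the benchmark corpus:
#' 20-dimensional vectors, context window 5, minimum count 1, initial
#' learning rate 0.025 (decaying linearly to `lrMin`), 51 epochs, 5 negative
#' samples per positive pair, and a 1e-3 down-sampling threshold for
#' frequent words.
#'
#' @param vectorSize Embedding dimension d.
#' @param window Context window half-width c.
#' @param minCount Minimum corpus count to retain a word.
#' @param lr Initial learning rate.
#' @param lrMin Floor of the linear learning-rate decay.
#' @param epochs Training epochs.
#' @param negative Negative samples per positive pair.
#' @param sample Down-sampling threshold for frequent words.
#' @param seed Integer seed (training is single-threaded and bit-reproducible).
#' @return A named list of class `SkipgramConfig`.
#' @export
skipgramConfig <- function(vectorSize = 20L, window = 5L, minCount = 1L,
                           lr = 0.025, lrMin = 1e-4, epochs = 51L,
                           negative = 5L, sample = 1e-3, seed = 1L) {
  cfg <- list(vectorSize = as.integer(vectorSize), window = as.integer(window),
              minCount = as.integer(minCount), lr = lr, lrMin = lrMin,
              epochs = as.integer(epochs), negative = as.integer(negative),
              sample = sample, seed = as.integer(seed))
  stopifnot(cfg$vectorSize > 0, cfg$window > 0, cfg$minCount > 0, cfg$lr > 0,
            cfg$epochs >= 0, cfg$negative > 0, cfg$sample >= 0)
  # epochs = 0 returns the seeded initial table (useful as a baseline)
  class(cfg) <- "SkipgramConfig"
  cfg
}

.asTokenCorpus <- function(x, n = 3L) {
  if (is(x, "SequenceDataset")) x <- as.character(sequences(x))
  if (is.character(x)) x <- lapply(x, tokenize, n = n)
  if (!is.list(x)) stop("corpus must be a SequenceDataset, character vector or token list")
  x
}

#' Train a skip-gram word embedding on a sequence corpus
#'
#' Trains 3-mer word vectors by skip-gram with negative sampling. Each DNA
#' sequence is one sentence; context windows never span sequences. Training
#' is single-threaded and bit-reproducible for a fixed (corpus, config).
#'
#' @param x A [SequenceDataset], character vector of sequences, or list of
#'   token vectors.
#' @param config A [skipgramConfig()].
#' @param n Word size used when `x` must be tokenized.
#' @return A [KmerEmbedding].
#' @examples
#' emb <- trainSkipgram(c(strrep("ACGT", 10), strrep("TTAGC", 8)),
#'                      skipgramConfig(epochs = 2L))
#' dim(wordVectors(emb))
#' @export
trainSkipgram <- function(x, config = skipgramConfig(), n = 3L) {
  corpus <- .asTokenCorpus(x, n = n)
  if (!length(corpus)) stop("empty corpus")
  vocab <- buildVocab(corpus, minCount = config$minCount)
  idx <- setNames(vocab$index, vocab$word)
  sentences <- lapply(corpus, function(toks) {
    m <- idx[toks]
    as.integer(m[!is.na(m)])
  })
  res <- .sgnsTrain(sentences, vocab$count, config$vectorSize, config$window,
                    config$lr, config$lrMin, config$epochs, config$negative,
                    config$sample, config$seed)
  rownames(res$input) <- rownames(res$output) <- vocab$word
  new("KmerEmbedding", input = res$input, output = res$output,
      counts = setNames(vocab$count, vocab$word), config = unclass(config))
}

#' @rdname KmerEmbedding-class
#' @export
setMethod("wordVectors", "KmerEmbedding", function(x) x@input)

#' @rdname KmerEmbedding-class
#' @export
setMethod("contextVectors", "KmerEmbedding", function(x) x@output)

#' @rdname KmerEmbedding-class
#' @export
setMethod("vocabulary", "KmerEmbedding", function(x) {
  data.frame(word = rownames(x@input), index = seq_len(nrow(x@input)) - 1L,
             count = as.integer(x@counts), stringsAsFactors = FALSE)
})

#' @rdname KmerEmbedding-class
#' @export
setMethod("embeddingDim", "KmerEmbedding", function(x) ncol(x@input))

setMethod("show", "KmerEmbedding", function(object) {
  cat("KmerEmbedding:", nrow(object@input), "words x", ncol(object@input),
      "dimensions\n")
  cat("  corpus tokens:", sum(object@counts), "\n")
})

#' Softmax word-prediction probability under the skip-gram model
#'
#' The idealized skip-gram probability of observing `context` given
#' `center`: `exp(e'_context . e_center) / sum_j exp(e'_j . e_center)`,
#' where `e` are input vectors and `e'` output vectors. Training itself uses
#' negative sampling; this full softmax is exposed as a model query.
#'
#' @param center,context Vocabulary words.
#' @param embedding A [KmerEmbedding].
#' @return Probability in (0, 1); sums to 1 over all context words.
#' @export
skipgramProb <- function(center, context, embedding) {
  words <- rownames(wordVectors(embedding))
  if (!(center %in% words)) stop("out-of-vocabulary word: ", center)
  if (!(context %in% words)) stop("out-of-vocabulary word: ", context)
  scores <- as.numeric(contextVectors(embedding) %*% wordVectors(embedding)[center, ])
  scores <- scores - max(scores)
  p <- exp(scores) / sum(exp(scores))
  p[match(context, words)]
}

#' Embed a sequence as a d x N feature matrix
#'
#' Column i of the result is the input vector of the i-th word, so a 200-nt
#' sequence embeds as a 20 x 198 matrix under the defaults.
#'
#' @param x A DNA string or a token vector.
#' @param embedding A [KmerEmbedding].
#' @param n Word size used when `x` is a raw sequence.
#' @return Numeric matrix, dimensions x words.
#' @export
embedSequence <- function(x, embedding, n = 3L) {
  x <- as.character(x)
  toks <- if (length(x) == 1L && nchar(x) > n) tokenize(x, n = n) else x
  vecs <- wordVectors(embedding)
  m <- match(toks, rownames(vecs))
  if (anyNA(m)) stop("out-of-vocabulary token: ", toks[which(is.na(m))[1]])
  t(vecs[m, , drop = FALSE])
}

#' Write an embedding table in word2vec text format
#'
#' Header line "W d", then one line per word: the word followed by its d
#' input-vector components.
#'
#' @param embedding A [KmerEmbedding].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeWordVectors <- function(embedding, path) {
  vecs <- wordVectors(embedding)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(vecs), ncol(vecs)), con)
  writeLines(paste(rownames(vecs),
                   apply(vecs, 1, function(v) paste(format(v, digits = 17), collapse = " "))),
             con)
  invisible(path)
}

#' Read an embedding table in word2vec text format
#'
#' Output/context vectors are not part of the interchange format, so they are
#' restored as zeros; [skipgramProb()] on a read-back table is therefore the
#' uniform distribution.
#'
#' @param path Path to a word2vec text file.
#' @return A [KmerEmbedding].
#' @export
readWordVectors <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  W <- hdr[1]; d <- hdr[2]
  parts <- strsplit(trimws(lines[1 + seq_len(W)]), "\\s+")
  words <- vapply(parts, `[[`, character(1), 1)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  rownames(vecs) <- words
  zero <- matrix(0, W, d, dimnames = list(words, NULL))
  new("KmerEmbedding", input = vecs, output = zero,
      counts = setNames(rep(1L, W), words), config = list())
}
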