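#' Construct a labeled sequence dataset
#'
#' @param seqs A [Biostrings::DNAStringSet], or a named character vector of
#'   DNA sequences.
#' @param labels Optional factor/character vector with values "positive" /
#'   "negative" (or a logical vector, `TRUE` = positive), one per sequence.
#' @param layer `"identification"` (positive = enhancer),
#'   `"classification"` (positive = strong enhancer) or `"none"`.
#' @return A [SequenceDataset].
#' @examples
#' ds <- sequenceDataset(c(a = strrep("ACGT", 5)), labels = "positive")
#' classCounts(ds)
#' @export
sequenceDataset <- function(seqs, labels = NULL, layer = "none") {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)) && length(seqs))
    names(seqs) <- paste0("seq_", seq_along(seqs))
  if (is.null(labels)) {
    labels <- factor(character(), levels = c("negative", "positive"))
  } else {
    if (is.logical(labels))
      labels <- ifelse(labels, "positive", "negative")
    labels <- factor(as.character(labels), levels = c("negative", "positive"))
    if (anyNA(labels)) stop("labels must be 'positive' or 'negative'")
  }
  new("SequenceDataset", sequences = seqs, labels = labels, layer = layer)
}

#' @rdname SequenceDataset-class
#' @export
setMethod("sequences", "SequenceDataset", function(x) x@sequences)

#' @rdname SequenceDataset-class
#' @export
setMethod("classLabels", "SequenceDataset", function(x) x@labels)

#' @rdname SequenceDataset-class
#' @export
setMethod("layerType", "SequenceDataset", function(x) x@layer)

#' @rdname SequenceDataset-class
#' @export
setMethod("classCounts", "SequenceDataset", function(x) {
  if (!length(x@labels)) return(c(negative = 0L, positive = 0L))
  table(x@labels)
})

#' @rdname SequenceDataset-class
#' @export
setMethod("length", "SequenceDataset", function(x) length(x@sequences))

#' @rdname SequenceDataset-class
#' @param i Index vector.
#' @export
setMethod("[", "SequenceDataset", function(x, i) {
  lab <- if (length(x@labels)) x@labels[i, drop = FALSE] else x@labels
  new("SequenceDataset", sequences = x@sequences[i], labels = lab,
      layer = x@layer)
})

setMethod("show", "SequenceDataset", function(object) {
  cat("SequenceDataset with", length(object), "sequences",
      sprintf("(layer: %s)\n", object@layer))
  if (length(object)) {
    w <- BiocGenerics::width(object@sequences)
    cat("  widths:", min(w), "-", max(w), "nt\n")
  }
  cc <- classCounts(object)
  cat("  classes:", paste(names(cc), cc, sep = "=", collapse = ", "), "\n")
})

#' Read DNA sequences from a FASTA file
#'
#' One record per FASTA entry, in file order; the header token up to the
#' first whitespace becomes the record id. When `label` is given it is
#' applied to every record (the benchmark distributes one FASTA file per
#' class); otherwise a `label=positive|negative` token in the header is used
#' as a fallback, and records without one stay unlabeled.
#'
#' @param path Path to a FASTA file.
#' @param label Optional class for all records: "positive" or "negative".
#' @param layer Layer tag for the resulting dataset.
#' @return A [SequenceDataset].
#' @seealso [writeFastaRecords()], [validateSequences()]
#' @export
readFastaRecords <- function(path, label = NULL, layer = "none") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  labels <- NULL
  if (!is.null(label)) {
    label <- match.arg(label, c("positive", "negative"))
    if (length(seqs)) labels <- rep(label, length(seqs))
  } else if (length(seqs)) {
    m <- regmatches(headers, regexpr("label=(positive|negative)", headers))
    if (length(m) == length(headers) && all(nzchar(m)))
      labels <- sub("label=", "", m)
  }
  names(seqs) <- ids
  sequenceDataset(seqs, labels = labels, layer = layer)
}

#' Write a dataset to FASTA
#'
#' Standard FASTA with 60-column line wrapping; record ids are preserved, and
#' labels (when present) are appended as a `label=` header token so that a
#' read/write round trip is the identity.
#'
#' @param ds A [SequenceDataset].
#' @param path Output file path.
#' @param withLabels Append `label=` tokens to headers (default `TRUE` when
#'   the dataset is labeled).
#' @return Invisibly, `path`.
#' @export
writeFastaRecords <- function(ds, path, withLabels = length(classLabels(ds)) > 0) {
  seqs <- sequences(ds)
  if (withLabels && length(classLabels(ds))) {
    names(seqs) <- paste0(names(seqs), " label=", as.character(classLabels(ds)))
  }
  Biostrings::writeXStringSet(seqs, filepath = path, width = 60L)
  invisible(path)
}

#' Validate sequences against the ACGT alphabet
#'
#' Lower-case letters are upper-cased. Characters outside `{A, C, G, T}` are
#' rejected with an error naming the first offending record and position
#' (policy "reject"), or replaced by a uniformly drawn base (policy
#' "resample", seeded, reproducible). Sequences shorter than `minLength`
#' (default 14 nt, the shortest input the size-12 convolution branch can see
#' after tokenization) are always an error.
#'
#' @param ds A [SequenceDataset].
#' @param policy "reject" (default) or "resample".
#' @param seed Integer seed for the resampling policy.
#' @param minLength Minimum admissible sequence length in nt.
#' @return A validated [SequenceDataset].
#' @export
validateSequences <- function(ds, policy = c("reject", "resample"), seed = 1L,
                              minLength = 14L) {
  policy <- match.arg(policy)
  seqs <- toupper(as.character(sequences(ds)))
  w <- nchar(seqs)
  if (any(w < minLength))
    stop("sequence '", names(sequences(ds))[which(w < minLength)[1]],
         "' is shorter than ", minLength, " nt")
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    if (policy == "reject") {
      i <- which(bad)[1]
      pos <- regexpr("[^ACGT]", seqs[i])
      stop("non-ACGT character '", substr(seqs[i], pos, pos),
           "' in record '", names(sequences(ds))[i], "' at position ", pos)
    }
    set.seed(seed)
    for (i in which(bad)) {
      ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      j <- which(!ch %in% c("A", "C", "G", "T"))
      ch[j] <- sample(c("A", "C", "G", "T"), length(j), replace = TRUE)
      seqs[i] <- paste(ch, collapse = "")
    }
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(sequences(ds))
  new("SequenceDataset", sequences = out, labels = classLabels(ds),
      layer = layerType(ds))
}

#' Partition a dataset into k folds
#'
#' Deterministic, seeded assignment of records to `k` disjoint folds of
#' near-equal size. With `stratified = TRUE` (the default) the partition is
#' performed per class, so each fold's class balance deviates from the global
#' balance by at most one record per class.
#'
#' @param ds A [SequenceDataset] (or anything with a length).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @param stratified Stratify by class label (requires labels and every class
#'   to have at least `k` members).
#' @return Integer vector of fold ids in `1..k`, one per record.
#' @examples
#' ds <- sequenceDataset(setNames(rep(strrep("ACGT", 5), 20), paste0("s", 1:20)),
#'                       labels = rep(c("positive", "negative"), 10))
#' table(splitFolds(ds, k = 5, seed = 1))
#' @export
splitFolds <- function(ds, k, seed = 1L, stratified = TRUE) {
  n <- length(ds)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k larger than dataset size")
  set.seed(seed)
  fold <- integer(n)
  if (stratified) {
    labs <- classLabels(ds)
    if (!length(labs)) stop("stratified split requires labels")
    for (cl in levels(labs)) {
      idx <- which(labs == cl)
      if (!length(idx)) next
      if (length(idx) < k)
        stop("class '", cl, "' has fewer than k members")
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  fold
}
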