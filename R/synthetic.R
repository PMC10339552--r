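#' Motif specification for the synthetic generator
#'
#' A motif is a position-weight matrix (PWM): per-position nucleotide
#' probabilities over rows A, C, G, T. A consensus string plus a fidelity
#' gives the standard construction where each column puts `fidelity` on the
#' consensus base and splits the rest uniformly.
#'
#' @param name Motif name (appears in the ground-truth table).
#' @param consensus Consensus string over ACGT (ignored when `pwm` given).
#' @param pwm Optional 4 x L matrix with columns summing to 1 (rows A,C,G,T).
#' @param fidelity Consensus base probability per column (default 0.95).
#' @return A list of class `MotifSpec` with elements `name`, `pwm`,
#'   `consensus`, `length`.
#' @examples
#' m <- motifSpec("cre10", "TGACGTCATC")
#' m$length
#' @export
motifSpec <- function(name, consensus = NULL, pwm = NULL, fidelity = 0.95) {
  bases <- c("A", "C", "G", "T")
  if (is.null(pwm)) {
    if (is.null(consensus)) stop("either consensus or pwm required")
    ch <- strsplit(toupper(consensus), "")[[1]]
    if (!all(ch %in% bases)) stop("consensus must be over ACGT")
    pwm <- vapply(ch, function(b) {
      p <- rep((1 - fidelity) / 3, 4)
      p[match(b, bases)] <- fidelity
      p
    }, numeric(4))
    dimnames(pwm) <- list(bases, NULL)
  }
  if (nrow(pwm) != 4L) stop("pwm must have 4 rows (A, C, G, T)")
  if (ncol(pwm) < 4L) stop("motif length must be >= 4")
  if (any(abs(colSums(pwm) - 1) > 1e-8)) stop("pwm columns must sum to 1")
  if (is.null(rownames(pwm))) rownames(pwm) <- bases
  cons <- paste(bases[apply(pwm, 2, which.max)], collapse = "")
  structure(list(name = name, pwm = pwm, consensus = cons,
                 length = ncol(pwm)), class = "MotifSpec")
}

#' Flatten (add noise to) a motif PWM
#'
#' Mixes the PWM with the uniform distribution:
#' `(1 - alpha) * pwm + alpha * 1/4`. Used to make the weak-enhancer class
#' carry lower-fidelity motif instances.
#'
#' @param motif A [motifSpec()].
#' @param alpha Mixing weight in \[0, 1\].
#' @return A new `MotifSpec`.
#' @export
flattenPwm <- function(motif, alpha = 0.5) {
  motifSpec(paste0(motif$name, "_flat"),
            pwm = (1 - alpha) * motif$pwm + alpha * 0.25)
}

#' Built-in motif set
#'
#' Two TFBS-like consensus motifs of lengths 10 and 12 nt (within the
#' 5-30 nt range typical of transcription-factor binding motifs, average
#' ~11), matching the two convolution kernel widths of the default
#' architecture.
#'
#' @param fidelity Consensus base probability per column.
#' @return List of two [motifSpec()] objects.
#' @export
defaultMotifs <- function(fidelity = 0.95) {
  list(motifSpec("cre10", "TGACGTCATC", fidelity = fidelity),
       motifSpec("nfkb12", "GGGGATTTCCCC", fidelity = fidelity))
}

#' Read a PWM from a simple text matrix file
#'
#' Whitespace-separated numeric matrix, one row per base in A, C, G, T
#' order, one column per motif position; columns must sum to 1.
#'
#' @param path File path.
#' @param name Motif name (defaults to the file name).
#' @return A [motifSpec()].
#' @export
readPwm <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  m <- as.matrix(read.table(path))
  dimnames(m) <- NULL
  motifSpec(name, pwm = m)
}

#' Sample a background DNA sequence
#'
#' Independent draws from the given base composition, using the current R
#' random number stream (call `set.seed()` beforehand for reproducibility).
#'
#' @param L Sequence length (>= 1).
#' @param comp Base composition, probabilities over A, C, G, T summing to 1.
#' @return A DNA string of length `L`.
#' @export
sampleBackground <- function(L, comp = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (L < 1) stop("L must be >= 1")
  if (abs(sum(comp) - 1) > 1e-8 || any(comp < 0)) stop("invalid composition")
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = comp),
        collapse = "")
}

#' Plant a motif instance into a sequence
#'
#' Samples one motif instance column-wise from the PWM and writes it over a
#' contiguous window at a uniformly chosen admissible position. Everything
#' outside the window is untouched. Uses the current R random number stream.
#'
#' @param seq A DNA string.
#' @param motif A [motifSpec()].
#' @return `list(seq =, start =, end =)` with a 0-based half-open interval.
#' @export
plantMotif <- function(seq, motif) {
  L <- nchar(seq)
  len <- motif$length
  if (len > L) stop("motif longer than sequence")
  bases <- c("A", "C", "G", "T")
  inst <- paste(vapply(seq_len(len), function(j)
    sample(bases, 1L, prob = motif$pwm[, j]), character(1)), collapse = "")
  start <- sample.int(L - len + 1L, 1L)  # 1-based start
  out <- paste0(substr(seq, 1L, start - 1L), inst,
                substr(seq, start + len, L))
  list(seq = out, start = start - 1L, end = start - 1L + len)
}

# plant `count` motifs at non-overlapping positions; returns seq + intervals
.plantMany <- function(seq, motifs, count) {
  intervals <- data.frame(start = integer(), end = integer(),
                          motif = character())
  for (i in seq_len(count)) {
    m <- motifs[[if (length(motifs) == 1L) 1L else sample.int(length(motifs), 1L)]]
    for (try in 1:25) {
      res <- plantMotif(seq, m)
      ok <- !nrow(intervals) ||
        all(res$end <= intervals$start | res$start >= intervals$end)
      if (ok) break
    }
    seq <- res$seq
    intervals <- rbind(intervals,
                       data.frame(start = res$start, end = res$end,
                                  motif = m$name))
  }
  list(seq = seq, intervals = intervals)
}

#' Simulation configuration
#'
#' Defaults emulate the benchmark layout: balanced classes of 200-nt
#' sequences over a uniform background (1484 per class, the layer-1 training
#' size). Positives carry planted motif instances; negatives are pure
#' background (identification mode) or lower-dosage, lower-fidelity motif
#' carriers (classification mode, where positive = strong and negative =
#' weak enhancer).
#'
#' @param nPerClass Sequences per class.
#' @param seqLength Sequence length in nt.
#' @param background Base composition over A, C, G, T.
#' @param motifs List of [motifSpec()] objects for the positive class.
#' @param mode "identification" or "classification".
#' @param strongDosage Motif insertions per positive sequence (default 2).
#' @param weakDosage Insertions per weak sequence (classification mode).
#' @param weakFlatten PWM flattening weight for the weak class.
#' @param familySplit Assign motif families to disjoint halves of the
#'   positives (first half gets motif 1, second half motif 2) instead of
#'   sampling a family per insertion.
#' @param seed Integer seed; the generator is a pure function of this config.
#' @return A named list of class `SimConfig`.
#' @export
simConfig <- function(nPerClass = 1484L, seqLength = 200L,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                      motifs = defaultMotifs(),
                      mode = c("identification", "classification"),
                      strongDosage = 2L, weakDosage = 1L, weakFlatten = 0.25,
                      familySplit = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(nPerClass >= 1, seqLength >= 14, length(motifs) >= 1)
  cfg <- list(nPerClass = as.integer(nPerClass),
              seqLength = as.integer(seqLength), background = background,
              motifs = motifs, mode = mode,
              strongDosage = as.integer(strongDosage),
              weakDosage = as.integer(weakDosage), weakFlatten = weakFlatten,
              familySplit = isTRUE(familySplit), seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

#' Generate a labeled synthetic dataset with planted motifs
#'
#' Identification mode: positives ("enhancers") are background sequences
#' with `strongDosage` motif insertions; negatives are pure background.
#' Classification mode: positives are strong enhancers (`strongDosage`
#' insertions from the full-fidelity PWMs), negatives are weak enhancers
#' (`weakDosage` insertions from flattened PWMs). Classes are balanced and
#' the output is a pure function of the config (byte-identical FASTA for
#' identical configs).
#'
#' Ground truth is returned as a BED-like table (id, start, end, motif;
#' 0-based, half-open, forward strand). The exact-consensus leakage rate
#' into negatives is measured with a string search and attached.
#'
#' @param cfg A [simConfig()].
#' @return List with `dataset` (a labeled [SequenceDataset]), `truth`
#'   (data.frame), `leakage` (named count of exact consensus hits in
#'   negative sequences per motif) and `config`.
#' @examples
#' sim <- generateDataset(simConfig(nPerClass = 5, seed = 7))
#' classCounts(sim$dataset)
#' @export
generateDataset <- function(cfg) {
  if (!inherits(cfg, "SimConfig")) stop("cfg must come from simConfig()")
  set.seed(cfg$seed)
  n <- cfg$nPerClass
  L <- cfg$seqLength
  posPrefix <- if (cfg$mode == "identification") "enh" else "strong"
  negPrefix <- if (cfg$mode == "identification") "non" else "weak"

  truth <- list()
  posSeqs <- character(n)
  for (i in seq_len(n)) {
    bg <- sampleBackground(L, cfg$background)
    motifs <- if (cfg$familySplit)
      cfg$motifs[((i - 1L) * length(cfg$motifs)) %/% n + 1L] else cfg$motifs
    res <- .plantMany(bg, motifs, cfg$strongDosage)
    posSeqs[i] <- res$seq
    if (nrow(res$intervals))
      truth[[length(truth) + 1L]] <-
        cbind(id = paste0(posPrefix, "_", i), res$intervals)
  }

  negSeqs <- character(n)
  if (cfg$mode == "identification") {
    for (i in seq_len(n)) negSeqs[i] <- sampleBackground(L, cfg$background)
  } else {
    weakMotifs <- lapply(cfg$motifs, flattenPwm, alpha = cfg$weakFlatten)
    for (i in seq_len(n)) {
      bg <- sampleBackground(L, cfg$background)
      motifs <- if (cfg$familySplit)
        weakMotifs[((i - 1L) * length(weakMotifs)) %/% n + 1L] else weakMotifs
      res <- .plantMany(bg, motifs, cfg$weakDosage)
      negSeqs[i] <- res$seq
      if (nrow(res$intervals))
        truth[[length(truth) + 1L]] <-
          cbind(id = paste0(negPrefix, "_", i), res$intervals)
    }
  }

  seqs <- c(setNames(posSeqs, paste0(posPrefix, "_", seq_len(n))),
            setNames(negSeqs, paste0(negPrefix, "_", seq_len(n))))
  ds <- sequenceDataset(seqs,
                        labels = rep(c("positive", "negative"), each = n),
                        layer = cfg$mode)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(id = character(), start = integer(), end = integer(),
               motif = character())

  negSet <- Biostrings::DNAStringSet(negSeqs)
  leakage <- vapply(cfg$motifs, function(m)
    sum(Biostrings::vcountPattern(m$consensus, negSet)), integer(1))
  names(leakage) <- vapply(cfg$motifs, `[[`, character(1), "name")

  list(dataset = ds, truth = truth, leakage = leakage, config = cfg)
}

#' Write a ground-truth table as BED-like TSV
#'
#' Columns: id, start, end, motif (0-based, half-open intervals).
#'
#' @param truth The `truth` component of [generateDataset()] output.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeGroundTruth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
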