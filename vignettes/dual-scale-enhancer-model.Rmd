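---
title: "A dual-scale convolution and spatial attention model for enhancer prediction"
author: "enhancerScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dual-scale convolution and spatial attention model for enhancer prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Enhancers are short non-coding DNA elements that upregulate transcription,
sometimes across megabase distances. Sequence-based enhancer prediction is
usually posed as a two-layer classification task: layer 1 separates enhancers
from non-enhancers, and layer 2 — built on the same architecture — separates
strong from weak enhancers. The benchmark this package targets consists of
fixed-length 200-nt sequences with balanced classes (1484 enhancers and 1484
non-enhancers for training, the enhancers split 742/742 into strong and weak;
an independent test set of 100 strong, 100 weak and 200 non-enhancers).

`enhancerScan` implements the full predictor: feature representation by
3-mer skip-gram embedding, a dual-scale convolutional fusion network with a
spatial attention gate, training and evaluation protocols (independent test,
stratified k-fold cross-validation, multi-seed stability, ablations), plus a
synthetic planted-motif generator so the entire pipeline can be validated
without the external benchmark files.

# Model

## Feature representation

A DNA sequence of K nucleotides is segmented into overlapping 3-mer words
$S = \{w_1, \dots, w_N\}$ with $N = K - 2$ (a 200-nt sequence gives 198
words). Word vectors are learned by skip-gram: treating each sequence as a
sentence, the embedding maximizes the likelihood of context words within a
window of half-width $c$ around each center word,

$$\mathcal{L} = -\frac{1}{N}\sum_{n=1}^{N}\ \sum_{-c \le i \le c,\ i \ne 0}
\log p(w_{n+i} \mid w_n), \qquad
p(w_j \mid w_n) = \frac{\exp(e'^{\top}_{w_j} e_{w_n})}
{\sum_{l=1}^{W} \exp(e'^{\top}_{w_l} e_{w_n})},$$

with input vectors $e$, output (context) vectors $e'$ and vocabulary size
$W \le 64$. Training uses negative sampling rather than the full softmax;
the softmax form is exposed as a model query (`skipgramProb()`). The training
parameters are: vector size 20, window 5, minimum count 1, initial learning
rate 0.025, 51 epochs, 5 negative samples, down-sampling threshold $10^{-3}$.
The learning rate decays linearly with progress to a floor of $10^{-4}$
(the standard schedule; only the initial rate is prescribed). Embedding
training is single-threaded and bit-reproducible for a fixed seed; the corpus
is always the training split only, never test sequences — in cross-validation
the table is retrained inside every fold as a leakage guard.

A sequence is then embedded as the $d \times N$ matrix whose column $i$ is
the input vector of $w_i$ (20 × 198 for a 200-nt input).

## Dual-scale fusion

Transcription-factor binding motifs typically span 5–30 nt with an average
around 11, and one enhancer can harbor motifs of several lengths. A single
fixed-width convolution filter cannot capture this, so two parallel 1D
convolutions with kernel widths 10 and 12 (1024 filters each, stride 1, no
padding) run over the embedding and their rectified outputs are fused:

$$F(E_{\mathrm{in}}) = [\,\mathrm{ReLU}(f^{10}(E_{\mathrm{in}})),\
\mathrm{ReLU}(f^{12}(E_{\mathrm{in}}))\,].$$

The concatenation runs along the **spatial** axis: a 20 × 198 input yields
branch outputs 1024 × 189 and 1024 × 187 and a fused matrix 1024 × 376.
(The channel count is preserved — this orientation is forced by the published
layer shapes.) Kernel widths are configurable (`filters =`), so other
combinations of 8/10/12 can be explored; two branches are the default and
the optimized case.

## Spatial attention

Not every spatial position contributes equally. A channel-pooled descriptor
stacks the per-position mean and maximum over channels (2 × L); a width-7
1D convolution under symmetric zero padding followed by a sigmoid produces
the attention vector, which gates each column of the fused matrix:

$$S(F) = \sigma\!\big(f^{7}[\mathrm{AvgPool}(F), \mathrm{MaxPool}(F)]\big),
\qquad \hat F = F \odot S(F),$$

with $S$ broadcast along the channel dimension, so $\hat F$ keeps the
M × L shape. (A printed layer table gives the product shape as 1 × L; the
broadcast semantics govern here — anything else would make the following
max-pool degenerate.) Every attention value lies strictly in (0, 1), so
attention only ever shrinks features, never changes shapes.

## Head and loss

The refined matrix is globally max-pooled along the spatial axis to one
value per channel, and a single dense layer produces two logits and a
softmax probability pair. No hidden layer and no dropout are used by
default (the minimal head consistent with "a max-pooling layer and a
fully-connected layer"). Training minimizes the mean cross-entropy
$-\frac{1}{N'}\sum_i \ln p_i[y_i]$ over shuffled mini-batches with Adam.

Because convolutions are unpadded and pooling is global, the network is
fully convolutional in the spatial axis: any sequence of at least 14 nt
(12 words, the widest kernel) can be scored. The fixed 200-nt benchmark
length is a property of the data, not of the architecture; variable-length
scoring is an extension beyond the benchmark protocol.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `vectorSize` | 20 | embedding dimension (d) |
| `window` | 5 | skip-gram context half-width (words) |
| `epochs` (embedding) | 51 | skip-gram passes over the corpus |
| `negative` | 5 | negative samples per positive pair |
| `sample` | 1e-3 | down-sampling threshold for frequent words |
| `filters` | 10, 12 | convolution kernel widths (words) |
| `nFilters` | 1024 | filters per branch (M) |
| `attentionKernel` | 7 | attention convolution width (positions) |
| `batchSize` | 64 | mini-batch size N' |
| `epochs` (network) | 50 | Adam epochs |
| `lr` | 1e-3 | Adam learning rate |
| `validationFraction` | 0.1 | held-out fraction for best-epoch checkpointing |
| `threshold` | 0.5 | decision threshold on the positive-class probability |

The network optimizer settings (batch 64, 50 epochs, Adam at $10^{-3}$, 10 %
validation with best-epoch checkpointing) are defaults chosen here; the
reference protocol prescribes only the optimizer and the loss.

# Evaluation

Predictions at the 0.5 threshold (ties predict positive) are tallied into a
confusion matrix; accuracy, sensitivity, specificity and the Matthews
correlation coefficient are computed exactly, with MCC defined as 0 whenever
a denominator factor vanishes. AUC is the trapezoid rule over the empirical
ROC curve, which equals the Mann–Whitney rank statistic with ties counted
one half. Positive classes are: enhancer (layer 1) and strong enhancer
(layer 2).

Cross-validation splits stratified by class are the default (the literal
protocol — a plain random split into k parts — is available via
`stratified = FALSE`); fold metrics are aggregated as unweighted means.
Multi-seed stability retrains everything per seed and reports the mean and
population variance (divide by the number of seeds; sample variance is an
option) of ACC and MCC. The two-layer cascade gates on classifier I and
passes predicted enhancers to classifier II; evaluating each layer in
isolation on its own labeled test set is the benchmark's protocol and is
done with `evaluateModel()` directly.

# The synthetic benchmark generator

`generateDataset()` emulates the benchmark layout: balanced classes of
fixed-length (default 200 nt) sequences over a uniform background.
Positives carry motif instances sampled column-wise from position-weight
matrices and planted at uniformly random non-overlapping positions; ground
truth is emitted as a BED-like table (0-based, half-open, forward strand
only — reverse-complement planting is deliberately not modeled). The
built-in motifs are two TFBS-like consensi of lengths 10 and 12, matching
the two kernel widths, with per-column consensus probability 0.95.

Class design:

* **identification mode** — enhancers receive 2 insertions; non-enhancers
  are pure background. Exact-consensus leakage into negatives is measured
  by string search and reported (it is essentially always 0 for motifs of
  length ≥ 10 over a uniform background).
* **classification mode** — strong enhancers receive 2 insertions from the
  full-fidelity PWMs; weak enhancers receive 1 insertion from PWMs flattened
  toward uniform with weight 0.25. The flattening weight was chosen once so
  that weak enhancers remain genuine (detectable) enhancers while being
  clearly separable from strong ones; heavier flattening makes the weak
  class statistically indistinguishable from background best-matching
  windows, which contradicts the biology it stands in for.

The generator is a pure function of its configuration: identical configs
give byte-identical FASTA output.

What the generator does **not** emulate: real chromatin context,
dinucleotide composition bias, motif co-occurrence grammar, reverse-strand
sites, and redundancy structure between sequences. Passing tests on
synthetic data therefore demonstrate that the architecture, optimization
and evaluation machinery work end-to-end and that the dual-scale design
behaves as intended — they do not certify benchmark-level accuracy on real
enhancers, which requires the externally distributed benchmark FASTA
(supported through the command-line interface).

# Numerical choices

* All arithmetic is double precision (R's native numeric and Armadillo's
  default); independent brute-force oracles in the test suite agree with
  the vectorized/compiled paths to at least $10^{-9}$ relative error.
* Weight initialization is fan-in-scaled uniform
  $U(-1/\sqrt{\mathrm{fanIn}}, +1/\sqrt{\mathrm{fanIn}})$ with zero biases,
  seeded; any standard scheme would do, seedability is the requirement.
* ReLU derivative at exactly 0 is taken as 0; scores exactly at the decision
  threshold predict positive; probabilities are clamped at $10^{-12}$ inside
  the loss (with a message) so degenerate predictions stay finite.
* Training shuffles with an internal deterministic generator seeded from the
  configuration, so runs are bit-reproducible single-threaded; the skip-gram
  trainer similarly uses a self-contained linear-congruential stream.
* With a validation split, the weights returned are those of the epoch with
  the lowest validation loss; with `validationFraction = 0`, the final
  weights.
* Non-finite training loss aborts with a diagnostic rather than returning a
  corrupt model.

# Problem sizes used by the test suite

The packaged tests and the acceptance script validate the full M = 1024
architecture shape-wise, but train scaled-down instances: 64 filters per
branch for the main synthetic-recovery run (500 sequences per class,
default training configuration) and 32 filters for the five-seed ablation
comparison and the cascade demonstration. Filter count scales capacity,
not the architecture's structure, and the planted-motif task is saturated
well below 1024 filters; these sizes keep the suite fast while exercising
every code path. The benchmark-scale configuration is the package default
and is what the command-line interface uses unless told otherwise.

# Known limitations

* Global max-pooling is count-blind: it reports the best motif match, not
  how many there are. Distinguishing classes by motif dosage alone is
  therefore impossible for this architecture; the synthetic weak class
  accordingly differs in *fidelity*, and recovering weak enhancers behind
  the cascade is intrinsically the hard case (single lower-fidelity motif
  instances overlap the distribution of best background matches).
* Only n = 3 words are exercised; `n` is a parameter but untested beyond 3.
* CBOW embedding training is not implemented (skip-gram outperformed it in
  the reference experiments).
* One embedding table per layer is the default; whether the published model
  shared a table across layers is unstated, and sharing is available via
  the API by passing the same table.
* More than two convolution branches are permitted through `filters =` for
  exploration but are not an optimized configuration.
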