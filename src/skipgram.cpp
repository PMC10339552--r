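#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Deterministic linear-congruential generator (word2vec-style) so training is
// bit-reproducible regardless of R's RNG state and thread count (always 1).
static inline unsigned long long lcgNext(unsigned long long &s) {
  s = s * 25214903917ULL + 11ULL;
  return s;
}
static inline double lcgUnif(unsigned long long &s) {
  lcgNext(s);
  return ((s >> 16) & 0xFFFFULL) / 65536.0;
}

// Skip-gram with negative sampling over integer-coded sentences.
// sentences: list of integer vectors (0-based word indices); counts: corpus
// frequency per vocab word. Returns input (syn0) and output/context (syn1)
// vectors, W x d. Learning rate decays linearly with words processed from lr0
// to lrMin. Down-sampling of frequent words follows the classic
// (sqrt(f/(t*T)) + 1) * t*T/f keep-probability.
// [[Rcpp::export(name = ".sgnsTrain")]]
List sgnsTrain(List sentences, IntegerVector counts, int d, int window,
               double lr0, double lrMin, int epochs, int negative,
               double sample, int seed) {
  const int W = counts.size();
  double trainWords = 0.0;
  for (int i = 0; i < W; ++i) trainWords += counts[i];
  if (trainWords <= 0) stop("empty corpus");

  unsigned long long rng = (unsigned long long)(unsigned int)seed;

  NumericMatrix syn0(W, d), syn1(W, d);
  double *p0 = REAL(syn0), *p1 = REAL(syn1);
  // column-major: element (w, j) at p[j * W + w]
  for (int w = 0; w < W; ++w)
    for (int j = 0; j < d; ++j)
      p0[j * W + w] = (lcgUnif(rng) - 0.5) / d;
  // syn1 starts at zero (standard word2vec initialisation)

  // unigram^0.75 table for negative sampling
  const int tableSize = 100000;
  std::vector<int> table(tableSize);
  double z = 0.0;
  for (int i = 0; i < W; ++i) z += std::pow((double)counts[i], 0.75);
  int wi = 0;
  double cum = std::pow((double)counts[0], 0.75) / z;
  for (int a = 0; a < tableSize; ++a) {
    table[a] = wi;
    if ((double)(a + 1) / tableSize > cum && wi < W - 1) {
      ++wi;
      cum += std::pow((double)counts[wi], 0.75) / z;
    }
  }

  std::vector<double> neu1e(d);
  const double totalWords = trainWords * epochs;
  double wordsProcessed = 0.0;
  const int nSent = sentences.size();

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < nSent; ++s) {
      IntegerVector sent = sentences[s];
      const int len = sent.size();
      // down-sample frequent words; windows are formed on the kept words
      std::vector<int> kept;
      kept.reserve(len);
      for (int t = 0; t < len; ++t) {
        const int w = sent[t];
        wordsProcessed += 1.0;
        if (sample > 0) {
          const double f = counts[w];
          const double keep =
              (std::sqrt(f / (sample * trainWords)) + 1.0) *
              (sample * trainWords) / f;
          if (keep < lcgUnif(rng)) continue;
        }
        kept.push_back(w);
      }
      const int n = (int)kept.size();
      for (int t = 0; t < n; ++t) {
        double lr = lr0 * (1.0 - wordsProcessed / (totalWords + 1.0));
        if (lr < lrMin) lr = lrMin;
        lcgNext(rng);
        const int b = (int)((rng >> 16) % (unsigned long long)window);
        const int center = kept[t];
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          const int tc = t + off;
          if (tc < 0 || tc >= n) continue;
          const int ctx = kept[tc];
          for (int j = 0; j < d; ++j) neu1e[j] = 0.0;
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) {
              target = ctx;
              label = 1.0;
            } else {
              lcgNext(rng);
              target = table[(rng >> 16) % (unsigned long long)tableSize];
              if (target == ctx) continue;
              label = 0.0;
            }
            double dot = 0.0;
            for (int j = 0; j < d; ++j)
              dot += p0[j * W + center] * p1[j * W + target];
            const double pred = 1.0 / (1.0 + std::exp(-dot));
            const double g = (label - pred) * lr;
            for (int j = 0; j < d; ++j) {
              neu1e[j] += g * p1[j * W + target];
              p1[j * W + target] += g * p0[j * W + center];
            }
          }
          for (int j = 0; j < d; ++j) p0[j * W + center] += neu1e[j];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["input"] = syn0, _["output"] = syn1);
}
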