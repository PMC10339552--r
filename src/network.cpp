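// Dual-scale convolution + spatial attention network: forward pass,
// backpropagation and an Adam training loop. The architecture is fully
// convolutional along the spatial axis, so sequences of any length admitted
// by the largest kernel can be processed.
//
// Layout conventions (shared with the R reference implementation):
//  - embeddings E are C x N (channels x positions);
//  - branch conv weights are stored im2col-flattened as M x (C*k), with
//    column index (j-1)*C + c for tap j and channel c;
//  - the attention descriptor D is 2 x L with row 1 = channel mean,
//    row 2 = channel max; its conv kernel is flattened the same way (14);
//  - head logits are (negative, positive); class labels y are 0/1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::uvec;
using arma::uword;
using arma::vec;

struct Branch {
  mat W;  // M x (C*k)
  vec b;  // M
  int k;
};

struct Net {
  std::vector<Branch> br;
  bool useAtt;
  rowvec wA;  // 1 x (2*kA)
  double bA;
  int kA;
  mat Wh;  // 2 x M (or 2 x d when bypass)
  vec bh;  // 2
  bool bypass;
};

static Net parseNet(const List &m) {
  Net net;
  List brs = m["branches"];
  for (int i = 0; i < brs.size(); ++i) {
    List bi = brs[i];
    Branch B;
    B.W = as<mat>(bi["W"]);
    B.b = as<vec>(bi["b"]);
    B.k = as<int>(bi["k"]);
    net.br.push_back(B);
  }
  net.bypass = as<bool>(m["bypass"]);
  net.useAtt = as<bool>(m["useAttention"]);
  if (net.useAtt) {
    net.wA = as<rowvec>(m["attW"]);
    net.bA = as<double>(m["attB"]);
    net.kA = (int)(net.wA.n_elem / 2);
  } else {
    net.kA = 0;
    net.bA = 0.0;
  }
  net.Wh = as<mat>(m["headW"]);
  net.bh = as<vec>(m["headB"]);
  return net;
}

static List dumpNet(const Net &net) {
  List brs(net.br.size());
  for (size_t i = 0; i < net.br.size(); ++i) {
    brs[i] = List::create(_["W"] = net.br[i].W, _["b"] = net.br[i].b,
                          _["k"] = net.br[i].k);
  }
  List out = List::create(
      _["branches"] = brs, _["bypass"] = net.bypass,
      _["useAttention"] = net.useAtt, _["attW"] = net.useAtt ? wrap(net.wA) : R_NilValue,
      _["attB"] = net.bA, _["headW"] = net.Wh, _["headB"] = net.bh);
  return out;
}

static mat im2col(const mat &E, int k) {
  const int C = E.n_rows, N = E.n_cols;
  const int L = N - k + 1;
  mat X(C * k, L);
  for (int j = 0; j < k; ++j) X.rows(j * C, (j + 1) * C - 1) = E.cols(j, j + L - 1);
  return X;
}

struct Grad {
  std::vector<mat> dW;
  std::vector<vec> db;
  rowvec dwA;
  double dbA;
  mat dWh;
  vec dbh;
  void zerosLike(const Net &n) {
    dW.clear();
    db.clear();
    for (size_t i = 0; i < n.br.size(); ++i) {
      dW.push_back(mat(arma::size(n.br[i].W), arma::fill::zeros));
      db.push_back(vec(n.br[i].b.n_elem, arma::fill::zeros));
    }
    if (n.useAtt) dwA = rowvec(n.wA.n_elem, arma::fill::zeros);
    dbA = 0.0;
    dWh = mat(arma::size(n.Wh), arma::fill::zeros);
    dbh = vec(n.bh.n_elem, arma::fill::zeros);
  }
  void scale(double a) {
    for (size_t i = 0; i < dW.size(); ++i) {
      dW[i] *= a;
      db[i] *= a;
    }
    if (dwA.n_elem) dwA *= a;
    dbA *= a;
    dWh *= a;
    dbh *= a;
  }
};

// Forward (and optionally backward) for a single sequence. Returns the
// cross-entropy loss at true class y (ignored when y < 0); accumulates
// gradients into g when doGrad.
static double fwdOne(const mat &E, int y, const Net &net, Grad *g, bool doGrad,
                     vec *probsOut) {
  const int nb = (int)net.br.size();
  std::vector<mat> X(nb), Z(nb), Fb(nb);
  mat F, XA, Fhat;
  rowvec A;
  uvec argMaxCh;   // attention max-pool winner per position
  uvec argT;       // global max-pool winner per channel
  vec v;
  int Mch = 0, L = 0;

  if (net.bypass) {
    v = arma::max(E, 1);
  } else {
    for (int i = 0; i < nb; ++i) {
      if ((int)E.n_cols < net.br[i].k)
        stop("sequence too short for kernel width %d", net.br[i].k);
      X[i] = im2col(E, net.br[i].k);
      Z[i] = net.br[i].W * X[i];
      Z[i].each_col() += net.br[i].b;
      Fb[i] = arma::clamp(Z[i], 0.0, arma::datum::inf);  // ReLU
      F = (i == 0) ? Fb[i] : arma::join_rows(F, Fb[i]);
    }
    Mch = F.n_rows;
    L = F.n_cols;
    if (net.useAtt) {
      rowvec dAvg = arma::mean(F, 0);
      rowvec dMax(L);
      argMaxCh.set_size(L);
      for (int t = 0; t < L; ++t) {
        uword idx;
        dMax(t) = F.col(t).max(idx);
        argMaxCh(t) = idx;
      }
      mat D(2, L);
      D.row(0) = dAvg;
      D.row(1) = dMax;
      const int pad = (net.kA - 1) / 2;
      mat Dpad(2, L + 2 * pad, arma::fill::zeros);
      Dpad.cols(pad, pad + L - 1) = D;
      XA = im2col(Dpad, net.kA);  // (2*kA) x L
      rowvec zA = net.wA * XA + net.bA;
      A = 1.0 / (1.0 + arma::exp(-zA));
      Fhat = F;
      Fhat.each_row() %= A;
    } else {
      Fhat = F;
    }
    v.set_size(Mch);
    argT.set_size(Mch);
    for (int m = 0; m < Mch; ++m) {
      uword idx;
      v(m) = Fhat.row(m).max(idx);
      argT(m) = idx;
    }
  }

  vec logits = net.Wh * v + net.bh;
  const double mx = logits.max();
  vec ex = arma::exp(logits - mx);
  vec p = ex / arma::accu(ex);
  if (probsOut) *probsOut = p;
  double loss = NA_REAL;
  if (y >= 0) loss = -std::log(std::max(p(y), 1e-12));

  if (doGrad && y >= 0) {
    vec dlog = p;
    dlog(y) -= 1.0;
    g->dWh += dlog * v.t();
    g->dbh += dlog;
    vec dv = net.Wh.t() * dlog;
    if (!net.bypass) {
      mat dFhat(Mch, L, arma::fill::zeros);
      for (int m = 0; m < Mch; ++m) dFhat(m, argT(m)) += dv(m);
      mat dF;
      if (net.useAtt) {
        dF = dFhat;
        dF.each_row() %= A;
        rowvec dA = arma::sum(dFhat % F, 0);
        rowvec dzA = dA % A % (1.0 - A);
        g->dwA += dzA * XA.t();
        g->dbA += arma::accu(dzA);
        mat dXA = net.wA.t() * dzA;  // (2*kA) x L
        const int pad = (net.kA - 1) / 2;
        mat dDpad(2, L + 2 * pad, arma::fill::zeros);
        for (int j = 0; j < net.kA; ++j)
          dDpad.cols(j, j + L - 1) += dXA.rows(j * 2, j * 2 + 1);
        mat dD = dDpad.cols(pad, pad + L - 1);
        dF.each_row() += dD.row(0) / Mch;                    // mean path
        for (int t = 0; t < L; ++t) dF(argMaxCh(t), t) += dD(1, t);  // max path
      } else {
        dF = dFhat;
      }
      int c0 = 0;
      for (int i = 0; i < nb; ++i) {
        const int Li = Fb[i].n_cols;
        mat dFi = dF.cols(c0, c0 + Li - 1);
        c0 += Li;
        mat dZ = dFi % arma::conv_to<mat>::from(Z[i] > 0);
        g->dW[i] += dZ * X[i].t();
        g->db[i] += arma::sum(dZ, 1);
      }
    }
  }
  return loss;
}

// [[Rcpp::export(name = ".netForward")]]
NumericMatrix netForward(List Elist, List model) {
  Net net = parseNet(model);
  const int n = Elist.size();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    mat E = as<mat>(Elist[i]);
    vec p;
    fwdOne(E, -1, net, nullptr, false, &p);
    out(i, 0) = p(0);
    out(i, 1) = p(1);
  }
  return out;
}

// Loss and gradients for a (tiny) batch; used by finite-difference tests.
// [[Rcpp::export(name = ".netLossGrad")]]
List netLossGrad(List Elist, IntegerVector y, List model) {
  Net net = parseNet(model);
  Grad g;
  g.zerosLike(net);
  const int n = Elist.size();
  double loss = 0.0;
  for (int i = 0; i < n; ++i) {
    mat E = as<mat>(Elist[i]);
    loss += fwdOne(E, y[i], net, &g, true, nullptr);
  }
  loss /= n;
  g.scale(1.0 / n);
  List grads = List::create(
      _["dWh"] = g.dWh, _["dbh"] = g.dbh,
      _["dwA"] = net.useAtt ? wrap(g.dwA) : R_NilValue, _["dbA"] = g.dbA);
  List dbr(net.br.size());
  for (size_t i = 0; i < net.br.size(); ++i)
    dbr[i] = List::create(_["dW"] = g.dW[i], _["db"] = g.db[i]);
  grads["branches"] = dbr;
  return List::create(_["loss"] = loss, _["grad"] = grads);
}

struct AdamState {
  Grad m, v;
  long t = 0;
  void init(const Net &n) {
    m.zerosLike(n);
    v.zerosLike(n);
    t = 0;
  }
};

static void adamUpdate(mat &p, mat &m, mat &v, const mat &g, double lr,
                       double b1, double b2, double eps, double c1, double c2) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  p -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
}

static void adamStep(Net &net, AdamState &st, const Grad &g, double lr,
                     double b1, double b2, double eps) {
  st.t += 1;
  const double c1 = 1.0 - std::pow(b1, (double)st.t);
  const double c2 = 1.0 - std::pow(b2, (double)st.t);
  for (size_t i = 0; i < net.br.size(); ++i) {
    adamUpdate(net.br[i].W, st.m.dW[i], st.v.dW[i], g.dW[i], lr, b1, b2, eps, c1, c2);
    st.m.db[i] = b1 * st.m.db[i] + (1 - b1) * g.db[i];
    st.v.db[i] = b2 * st.v.db[i] + (1 - b2) * (g.db[i] % g.db[i]);
    net.br[i].b -= lr * (st.m.db[i] / c1) / (arma::sqrt(st.v.db[i] / c2) + eps);
  }
  if (net.useAtt) {
    st.m.dwA = b1 * st.m.dwA + (1 - b1) * g.dwA;
    st.v.dwA = b2 * st.v.dwA + (1 - b2) * (g.dwA % g.dwA);
    net.wA -= lr * (st.m.dwA / c1) / (arma::sqrt(st.v.dwA / c2) + eps);
    st.m.dbA = b1 * st.m.dbA + (1 - b1) * g.dbA;
    st.v.dbA = b2 * st.v.dbA + (1 - b2) * g.dbA * g.dbA;
    net.bA -= lr * (st.m.dbA / c1) / (std::sqrt(st.v.dbA / c2) + eps);
  }
  adamUpdate(net.Wh, st.m.dWh, st.v.dWh, g.dWh, lr, b1, b2, eps, c1, c2);
  st.m.dbh = b1 * st.m.dbh + (1 - b1) * g.dbh;
  st.v.dbh = b2 * st.v.dbh + (1 - b2) * (g.dbh % g.dbh);
  net.bh -= lr * (st.m.dbh / c1) / (arma::sqrt(st.v.dbh / c2) + eps);
}

static inline unsigned long long lcgNext(unsigned long long &s) {
  s = s * 25214903917ULL + 11ULL;
  return s;
}

// Mini-batch Adam training on cross-entropy. Deterministic: shuffling uses an
// internal LCG seeded by cfg$seed. When a validation set is supplied the
// weights with the lowest validation loss are returned, else the final ones.
// [[Rcpp::export(name = ".netTrain")]]
List netTrain(List Elist, IntegerVector y, List EvalList, IntegerVector yval,
              List model, List cfg) {
  Net net = parseNet(model);
  const int n = Elist.size();
  const int nVal = EvalList.size();
  const int batch = as<int>(cfg["batchSize"]);
  const int epochs = as<int>(cfg["epochs"]);
  const double lr = as<double>(cfg["lr"]);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  unsigned long long rng = (unsigned long long)(unsigned int)as<int>(cfg["seed"]);

  // pre-convert embeddings once
  std::vector<mat> Es(n), Ev(nVal);
  for (int i = 0; i < n; ++i) Es[i] = as<mat>(Elist[i]);
  for (int i = 0; i < nVal; ++i) Ev[i] = as<mat>(EvalList[i]);

  AdamState st;
  st.init(net);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;

  NumericVector trainLoss(epochs), valLoss(epochs);
  Net best = net;
  double bestVal = arma::datum::inf;
  int bestEpoch = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle
    for (int i = n - 1; i > 0; --i) {
      lcgNext(rng);
      const int j = (int)((rng >> 16) % (unsigned long long)(i + 1));
      std::swap(ord[i], ord[j]);
    }
    double epLoss = 0.0;
    int done = 0;
    while (done < n) {
      const int bEnd = std::min(done + batch, n);
      Grad g;
      g.zerosLike(net);
      double bl = 0.0;
      for (int i = done; i < bEnd; ++i)
        bl += fwdOne(Es[ord[i]], y[ord[i]], net, &g, true, nullptr);
      const int bs = bEnd - done;
      g.scale(1.0 / bs);
      epLoss += bl;
      if (!std::isfinite(bl))
        stop("training diverged: non-finite loss at epoch %d", ep + 1);
      adamStep(net, st, g, lr, b1, b2, eps);
      done = bEnd;
    }
    trainLoss[ep] = epLoss / n;
    if (nVal > 0) {
      double vl = 0.0;
      for (int i = 0; i < nVal; ++i)
        vl += fwdOne(Ev[i], yval[i], net, nullptr, false, nullptr);
      vl /= nVal;
      valLoss[ep] = vl;
      if (vl < bestVal) {
        bestVal = vl;
        best = net;
        bestEpoch = ep + 1;
      }
    } else {
      valLoss[ep] = NA_REAL;
    }
    Rcpp::checkUserInterrupt();
  }
  const Net &ret = (nVal > 0) ? best : net;
  return List::create(_["model"] = dumpNet(ret), _["trainLoss"] = trainLoss,
                      _["valLoss"] = valLoss,
                      _["bestEpoch"] = (nVal > 0) ? bestEpoch : epochs);
}
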