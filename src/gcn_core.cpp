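// Chebyshev spectral graph-convolutional regressor: forward pass, analytic
// backward pass, input gradients, and the Adam training loop.
//
// Per-subject graph structure is precomputed in R as the eigendecomposition
// of the scaled Laplacian Ltilde = U diag(lambda) U'.  Chebyshev filtering is
// applied in the spectral domain: T_k(Ltilde) H = U (t_k(lambda) . (U' H)),
// where t_k are the scalar Chebyshev values at the eigenvalues.  This costs
// two dense N x N x width products per hidden layer instead of K+1.
//
// Layer 1 consumes a precomputed basis Z = [T_0 X | ... | T_K X] because the
// input features X are fixed during training.

#include <RcppArmadillo.h>
#if defined(__SSE2__)
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Squared gradients in Adam's second moment fall below the single-precision
// normal range; flushing subnormals to zero avoids the hardware stall and is
// numerically irrelevant at that magnitude.
struct FlushSubnormals {
#if defined(__SSE2__)
  unsigned int ftz, daz;
  FlushSubnormals() : ftz(_MM_GET_FLUSH_ZERO_MODE()), daz(_MM_GET_DENORMALS_ZERO_MODE()) {
    _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
    _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
  }
  ~FlushSubnormals() {
    _MM_SET_FLUSH_ZERO_MODE(ftz);
    _MM_SET_DENORMALS_ZERO_MODE(daz);
  }
#endif
};

namespace {

template <typename T>
struct Subject {
  Mat<T> U;   // N x N eigenvectors of Ltilde
  Mat<T> tv;  // N x (K+1) Chebyshev values t_k(lambda_i)
  Mat<T> X;   // N x d input gradient features
  Mat<T> Z;   // N x (K+1)d precomputed layer-1 basis
};

template <typename T>
struct Net {
  std::vector<Mat<T>> Wg;        // GCN layers: ((K+1)*d_in) x d_out
  std::vector<Mat<T>> Wm;        // MLP layers: d_in x d_out
  std::vector<Col<T>> bm;        // MLP biases
};

template <typename T>
struct Cache {
  std::vector<Mat<T>> H;      // post-activation per GCN layer
  std::vector<Mat<T>> G;      // spectral transform of each hidden layer input
  std::vector<Col<T>> a;      // MLP layer inputs
  std::vector<Col<T>> z;      // MLP pre-activations
};

template <typename T>
Mat<T> as_tmat(Rcpp::NumericMatrix m) {
  mat d(m.begin(), m.nrow(), m.ncol(), false);
  return conv_to<Mat<T>>::from(d);
}

template <typename T>
std::vector<Subject<T>> read_subjects(const Rcpp::List& subjects) {
  std::vector<Subject<T>> out(subjects.size());
  for (int i = 0; i < subjects.size(); ++i) {
    Rcpp::List s = subjects[i];
    out[i].U  = as_tmat<T>(s["U"]);
    out[i].tv = as_tmat<T>(s["tv"]);
    out[i].X  = as_tmat<T>(s["X"]);
    out[i].Z  = as_tmat<T>(s["Z"]);
  }
  return out;
}

template <typename T>
Net<T> read_net(const Rcpp::List& Wg, const Rcpp::List& Wm, const Rcpp::List& bm) {
  Net<T> net;
  for (int l = 0; l < Wg.size(); ++l) net.Wg.push_back(as_tmat<T>(Wg[l]));
  for (int m = 0; m < Wm.size(); ++m) net.Wm.push_back(as_tmat<T>(Wm[m]));
  for (int m = 0; m < bm.size(); ++m) {
    Rcpp::NumericVector b = bm[m];
    vec bd(b.begin(), b.size(), false);
    net.bm.push_back(conv_to<Col<T>>::from(bd));
  }
  return net;
}

// Forward pass; fills cache when provided.
template <typename T>
T forward_one(const Subject<T>& s, const Net<T>& net, int K, Cache<T>* cache) {
  const size_t Lg = net.Wg.size();
  Mat<T> H = s.Z * net.Wg[0];
  H.transform([](T v) { return v > T(0) ? v : T(0); });
  if (cache) { cache->H.clear(); cache->G.clear(); cache->a.clear(); cache->z.clear(); }
  if (cache) cache->H.push_back(H);
  for (size_t l = 1; l < Lg; ++l) {
    const uword w_in = H.n_cols;
    Mat<T> G = s.U.t() * H;                 // N x w_in
    if (cache) cache->G.push_back(G);
    Mat<T> acc(s.U.n_rows, net.Wg[l].n_cols, fill::zeros);
    for (int k = 0; k <= K; ++k) {
      Mat<T> sG = G.each_col() % s.tv.col(k);
      acc += sG * net.Wg[l].rows(k * w_in, (k + 1) * w_in - 1);
    }
    H = s.U * acc;
    H.transform([](T v) { return v > T(0) ? v : T(0); });
    if (cache) cache->H.push_back(H);
  }
  Col<T> a = vectorise(H);
  const size_t Lm = net.Wm.size();
  T out = T(0);
  for (size_t m = 0; m < Lm; ++m) {
    if (cache) cache->a.push_back(a);
    Col<T> z = net.Wm[m].t() * a + net.bm[m];
    if (cache) cache->z.push_back(z);
    if (m + 1 < Lm) {
      a = z;
      a.transform([](T v) { return v > T(0) ? v : T(0); });
    } else {
      out = z(0);
    }
  }
  return out;
}

// Backward pass for parameter gradients, accumulating into grad net g.
// dpred is dLoss/dprediction for this subject.
template <typename T>
void backward_one(const Subject<T>& s, const Net<T>& net, int K,
                  const Cache<T>& cache, T dpred, Net<T>& g) {
  const size_t Lg = net.Wg.size();
  const size_t Lm = net.Wm.size();
  // MLP backward
  Col<T> delta(1);
  delta(0) = dpred;
  for (size_t m = Lm; m-- > 0;) {
    g.Wm[m] += cache.a[m] * delta.t();
    g.bm[m] += delta;
    Col<T> dprev = net.Wm[m] * delta;
    if (m > 0) {
      // derivative of the hidden relu
      const Col<T>& zm = cache.z[m - 1];
      delta = dprev;
      for (uword i = 0; i < delta.n_elem; ++i)
        if (zm(i) <= T(0)) delta(i) = T(0);
    } else {
      delta = dprev;  // = dv
    }
  }
  const uword N = s.U.n_rows;
  Mat<T> dH = reshape(delta, N, cache.H[Lg - 1].n_cols);
  // GCN layers
  for (size_t l = Lg; l-- > 1;) {
    Mat<T> dHpre = dH % conv_to<Mat<T>>::from(cache.H[l] > T(0));
    Mat<T> Ud = s.U.t() * dHpre;            // N x w_out
    const Mat<T>& G = cache.G[l - 1];
    const uword w_in = G.n_cols;
    Mat<T> dG(N, w_in, fill::zeros);
    for (int k = 0; k <= K; ++k) {
      Mat<T> sG = G.each_col() % s.tv.col(k);
      g.Wg[l].rows(k * w_in, (k + 1) * w_in - 1) += sG.t() * Ud;
      Mat<T> back = Ud * net.Wg[l].rows(k * w_in, (k + 1) * w_in - 1).t();
      dG += back.each_col() % s.tv.col(k);
    }
    dH = s.U * dG;
  }
  Mat<T> dHpre = dH % conv_to<Mat<T>>::from(cache.H[0] > T(0));
  g.Wg[0] += s.Z.t() * dHpre;
}

// Gradient of the prediction with respect to the input features X (N x d).
template <typename T>
Mat<T> input_grad_one(const Subject<T>& s, const Net<T>& net, int K) {
  Cache<T> cache;
  forward_one(s, net, K, &cache);
  const size_t Lg = net.Wg.size();
  const size_t Lm = net.Wm.size();
  Col<T> delta(1);
  delta(0) = T(1);
  for (size_t m = Lm; m-- > 0;) {
    Col<T> dprev = net.Wm[m] * delta;
    if (m > 0) {
      const Col<T>& zm = cache.z[m - 1];
      delta = dprev;
      for (uword i = 0; i < delta.n_elem; ++i)
        if (zm(i) <= T(0)) delta(i) = T(0);
    } else {
      delta = dprev;
    }
  }
  const uword N = s.U.n_rows;
  Mat<T> dH = reshape(delta, N, cache.H[Lg - 1].n_cols);
  for (size_t l = Lg; l-- > 1;) {
    Mat<T> dHpre = dH % conv_to<Mat<T>>::from(cache.H[l] > T(0));
    Mat<T> Ud = s.U.t() * dHpre;
    const Mat<T>& G = cache.G[l - 1];
    const uword w_in = G.n_cols;
    Mat<T> dG(N, w_in, fill::zeros);
    for (int k = 0; k <= K; ++k) {
      Mat<T> back = Ud * net.Wg[l].rows(k * w_in, (k + 1) * w_in - 1).t();
      dG += back.each_col() % s.tv.col(k);
    }
    dH = s.U * dG;
  }
  // through layer 1: Hpre1 = sum_k T_k X W_k
  Mat<T> dHpre = dH % conv_to<Mat<T>>::from(cache.H[0] > T(0));
  Mat<T> Ud = s.U.t() * dHpre;
  const uword d = s.X.n_cols;
  Mat<T> acc(N, d, fill::zeros);
  for (int k = 0; k <= K; ++k) {
    Mat<T> back = Ud * net.Wg[0].rows(k * d, (k + 1) * d - 1).t();
    acc += back.each_col() % s.tv.col(k);
  }
  return s.U * acc;
}

template <typename T>
Rcpp::List net_to_R(const Net<T>& net) {
  Rcpp::List Wg(net.Wg.size()), Wm(net.Wm.size()), bm(net.bm.size());
  for (size_t l = 0; l < net.Wg.size(); ++l)
    Wg[l] = Rcpp::wrap(conv_to<mat>::from(net.Wg[l]));
  for (size_t m = 0; m < net.Wm.size(); ++m)
    Wm[m] = Rcpp::wrap(conv_to<mat>::from(net.Wm[m]));
  for (size_t m = 0; m < net.bm.size(); ++m)
    bm[m] = Rcpp::wrap(conv_to<vec>::from(net.bm[m]));
  return Rcpp::List::create(Rcpp::Named("Wg") = Wg, Rcpp::Named("Wm") = Wm,
                            Rcpp::Named("bm") = bm);
}

template <typename T>
Net<T> zeros_like(const Net<T>& net) {
  Net<T> g;
  for (const auto& W : net.Wg) g.Wg.push_back(Mat<T>(W.n_rows, W.n_cols, fill::zeros));
  for (const auto& W : net.Wm) g.Wm.push_back(Mat<T>(W.n_rows, W.n_cols, fill::zeros));
  for (const auto& b : net.bm) g.bm.push_back(Col<T>(b.n_elem, fill::zeros));
  return g;
}

// fused single-pass Adam update over raw storage
template <typename T>
void adam_update(Mat<T>& W, const Mat<T>& gW, Mat<T>& mW, Mat<T>& vW,
                 T lr, T b1, T b2, T eps, T b1t, T b2t) {
  T* w = W.memptr();
  const T* g = gW.memptr();
  T* m = mW.memptr();
  T* v = vW.memptr();
  const T c1 = T(1) - b1, c2 = T(1) - b2;
  const T s1 = T(1) / (T(1) - b1t), s2 = T(1) / (T(1) - b2t);
  const uword nelem = W.n_elem;
  for (uword i = 0; i < nelem; ++i) {
    m[i] = b1 * m[i] + c1 * g[i];
    v[i] = b2 * v[i] + c2 * g[i] * g[i];
    w[i] -= lr * (m[i] * s1) / (std::sqrt(v[i] * s2) + eps);
  }
}

// GCN-only caches for the training loop (the MLP is batched across subjects)
template <typename T>
struct GcnCache {
  std::vector<Mat<T>> H;
  std::vector<Mat<T>> G;
};

template <typename T>
void gcn_forward_train(const Subject<T>& s, const Net<T>& net, int K,
                       GcnCache<T>& cache) {
  const size_t Lg = net.Wg.size();
  cache.H.resize(Lg);
  cache.G.resize(Lg > 0 ? Lg - 1 : 0);
  Mat<T>& H0 = cache.H[0];
  H0 = s.Z * net.Wg[0];
  H0.transform([](T v) { return v > T(0) ? v : T(0); });
  for (size_t l = 1; l < Lg; ++l) {
    const Mat<T>& Hin = cache.H[l - 1];
    const uword w_in = Hin.n_cols;
    Mat<T>& G = cache.G[l - 1];
    G = s.U.t() * Hin;
    Mat<T> acc(s.U.n_rows, net.Wg[l].n_cols, fill::zeros);
    for (int k = 0; k <= K; ++k) {
      Mat<T> sG = G.each_col() % s.tv.col(k);
      acc += sG * net.Wg[l].rows(k * w_in, (k + 1) * w_in - 1);
    }
    Mat<T>& H = cache.H[l];
    H = s.U * acc;
    H.transform([](T v) { return v > T(0) ? v : T(0); });
  }
}

template <typename T>
void gcn_backward_train(const Subject<T>& s, const Net<T>& net, int K,
                        const GcnCache<T>& cache, Mat<T> dH, Net<T>& g) {
  const size_t Lg = net.Wg.size();
  for (size_t l = Lg; l-- > 1;) {
    Mat<T> dHpre = dH % conv_to<Mat<T>>::from(cache.H[l] > T(0));
    Mat<T> Ud = s.U.t() * dHpre;
    const Mat<T>& G = cache.G[l - 1];
    const uword w_in = G.n_cols;
    Mat<T> dG(G.n_rows, w_in, fill::zeros);
    for (int k = 0; k <= K; ++k) {
      Mat<T> sG = G.each_col() % s.tv.col(k);
      g.Wg[l].rows(k * w_in, (k + 1) * w_in - 1) += sG.t() * Ud;
      Mat<T> back = Ud * net.Wg[l].rows(k * w_in, (k + 1) * w_in - 1).t();
      dG += back.each_col() % s.tv.col(k);
    }
    dH = s.U * dG;
  }
  Mat<T> dHpre = dH % conv_to<Mat<T>>::from(cache.H[0] > T(0));
  g.Wg[0] += s.Z.t() * dHpre;
}

template <typename T>
Rcpp::List train_impl(const Rcpp::List& subjects, const Rcpp::NumericVector& y,
                      const Rcpp::List& Wg, const Rcpp::List& Wm, const Rcpp::List& bm,
                      int K, int epochs, int batch_size,
                      const Rcpp::IntegerMatrix& order, double lr_,
                      double w_siamese_) {
  std::vector<Subject<T>> subs = read_subjects<T>(subjects);
  Net<T> net = read_net<T>(Wg, Wm, bm);
  Net<T> m = zeros_like(net), v = zeros_like(net), g = zeros_like(net);
  const int n = subs.size();
  const T lr = T(lr_), b1 = T(0.9), b2 = T(0.999), eps = T(1e-8);
  const T ws = T(w_siamese_);
  const size_t Lm = net.Wm.size();
  const uword N = subs[0].U.n_rows;
  const uword wlast = net.Wg.back().n_cols;
  const uword mlpIn = N * wlast;
  Rcpp::NumericVector epoch_loss(epochs);
  long step = 0;
  std::vector<GcnCache<T>> caches(batch_size);
  std::vector<Mat<T>> A(Lm), Zc(Lm);   // batched MLP activations
  Mat<T> V(mlpIn, batch_size);
  for (int e = 0; e < epochs; ++e) {
    T eloss = T(0);
    for (int start = 0; start < n; start += batch_size) {
      const int nb = std::min(batch_size, n - start);
      Col<T> yy(nb);
      for (int b = 0; b < nb; ++b) {
        int idx = order(e, start + b) - 1;
        gcn_forward_train(subs[idx], net, K, caches[b]);
        V.col(b) = vectorise(caches[b].H.back());
        yy(b) = T(y[idx]);
      }
      // batched MLP forward
      Mat<T> Ab = V.cols(0, nb - 1);
      for (size_t mm = 0; mm < Lm; ++mm) {
        A[mm] = Ab;
        Zc[mm] = net.Wm[mm].t() * Ab;
        Zc[mm].each_col() += net.bm[mm];
        if (mm + 1 < Lm) {
          Ab = Zc[mm];
          Ab.transform([](T v2) { return v2 > T(0) ? v2 : T(0); });
        }
      }
      Row<T> f = Zc[Lm - 1].row(0);
      Col<T> r = yy - f.t();
      T S = accu(r);
      T sumr2 = accu(r % r);
      T loss = sumr2 + ws * (T(2) * T(nb) * sumr2 - T(2) * S * S);
      eloss += loss;
      if (!std::isfinite(double(loss)))
        Rcpp::stop("non-finite training loss at epoch %d; consider lowering the learning rate", e + 1);
      // dLoss/dprediction for every subject in the batch
      Row<T> dpred(nb);
      for (int b = 0; b < nb; ++b)
        dpred(b) = -T(2) * r(b) - ws * (T(4) * T(nb) * r(b) - T(4) * S);
      // zero gradient accumulators
      for (auto& W : g.Wg) W.zeros();
      for (auto& W : g.Wm) W.zeros();
      for (auto& bvec : g.bm) bvec.zeros();
      // batched MLP backward
      Mat<T> Delta(1, nb);
      Delta.row(0) = dpred;
      for (size_t mm = Lm; mm-- > 0;) {
        g.Wm[mm] += A[mm] * Delta.t();
        g.bm[mm] += sum(Delta, 1);
        Mat<T> Prev = net.Wm[mm] * Delta;
        if (mm > 0) {
          Delta = Prev % conv_to<Mat<T>>::from(Zc[mm - 1] > T(0));
        } else {
          // Prev is dV
          for (int b = 0; b < nb; ++b) {
            int idx = order(e, start + b) - 1;
            Mat<T> dH = reshape(Prev.col(b), N, wlast);
            gcn_backward_train(subs[idx], net, K, caches[b], std::move(dH), g);
          }
        }
      }
      ++step;
      T b1t = std::pow(b1, T(step)), b2t = std::pow(b2, T(step));
      for (size_t l = 0; l < net.Wg.size(); ++l)
        adam_update(net.Wg[l], g.Wg[l], m.Wg[l], v.Wg[l], lr, b1, b2, eps, b1t, b2t);
      for (size_t l = 0; l < net.Wm.size(); ++l)
        adam_update(net.Wm[l], g.Wm[l], m.Wm[l], v.Wm[l], lr, b1, b2, eps, b1t, b2t);
      for (size_t l = 0; l < net.bm.size(); ++l) {
        Mat<T> gb(g.bm[l].memptr(), g.bm[l].n_elem, 1, false);
        Mat<T> mb(m.bm[l].memptr(), m.bm[l].n_elem, 1, false);
        Mat<T> vb(v.bm[l].memptr(), v.bm[l].n_elem, 1, false);
        Mat<T> Wb(net.bm[l].memptr(), net.bm[l].n_elem, 1, false);
        adam_update(Wb, gb, mb, vb, lr, b1, b2, eps, b1t, b2t);
      }
    }
    epoch_loss[e] = double(eloss);
  }
  Rcpp::List out = net_to_R(net);
  out["epoch_loss"] = epoch_loss;
  return out;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericVector gcn_forward_cpp(Rcpp::List subjects, Rcpp::List Wg,
                                    Rcpp::List Wm, Rcpp::List bm, int K) {
  std::vector<Subject<double>> subs = read_subjects<double>(subjects);
  Net<double> net = read_net<double>(Wg, Wm, bm);
  Rcpp::NumericVector out(subs.size());
  for (size_t i = 0; i < subs.size(); ++i)
    out[i] = forward_one<double>(subs[i], net, K, nullptr);
  return out;
}

// [[Rcpp::export]]
Rcpp::List gcn_input_grad_cpp(Rcpp::List subjects, Rcpp::List Wg,
                              Rcpp::List Wm, Rcpp::List bm, int K) {
  std::vector<Subject<double>> subs = read_subjects<double>(subjects);
  Net<double> net = read_net<double>(Wg, Wm, bm);
  Rcpp::List out(subs.size());
  for (size_t i = 0; i < subs.size(); ++i)
    out[i] = Rcpp::wrap(input_grad_one<double>(subs[i], net, K));
  return out;
}

// [[Rcpp::export]]
Rcpp::List gcn_param_grad_cpp(Rcpp::List subjects, Rcpp::NumericVector dpred,
                              Rcpp::List Wg, Rcpp::List Wm, Rcpp::List bm, int K) {
  std::vector<Subject<double>> subs = read_subjects<double>(subjects);
  Net<double> net = read_net<double>(Wg, Wm, bm);
  Net<double> g = zeros_like(net);
  Cache<double> cache;
  for (size_t i = 0; i < subs.size(); ++i) {
    forward_one<double>(subs[i], net, K, &cache);
    backward_one<double>(subs[i], net, K, cache, dpred[i], g);
  }
  return net_to_R(g);
}

// [[Rcpp::export]]
Rcpp::List gcn_train_cpp(Rcpp::List subjects, Rcpp::NumericVector y,
                         Rcpp::List Wg, Rcpp::List Wm, Rcpp::List bm,
                         int K, int epochs, int batch_size,
                         Rcpp::IntegerMatrix order, double lr,
                         double w_siamese, bool single_precision) {
  if (single_precision) {
    FlushSubnormals guard;
    return train_impl<float>(subjects, y, Wg, Wm, bm, K, epochs, batch_size,
                             order, lr, w_siamese);
  }
  return train_impl<double>(subjects, y, Wg, Wm, bm, K, epochs, batch_size,
                            order, lr, w_siamese);
}
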