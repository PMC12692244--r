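// Multi-task 1-D CNN + squeeze-and-excitation + Transformer-encoder network.
// Token layout: activations are (B*L) x C matrices, row index b*L + l, so the
// whole batch shares each GEMM while attention stays within one sample's rows.
// Double instantiations back the exported forward/gradient entry points
// (finite-difference checks need full precision); training runs in float.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <string>
#include <cstdint>

using namespace arma;

// ---------------------------------------------------------------- config ----

struct Cfg {
  int L, kernel, d_model, n_heads, n_layers, ffn_dim, se_red, K1, K2;
  std::vector<int> conv_channels;
  double dropout;
  bool has_cnn, has_se, has_encoder, has_task1, has_task2;
};

static Cfg parse_cfg(const Rcpp::List& cfg) {
  Cfg c;
  c.L = cfg["L"];
  c.kernel = cfg["kernel"];
  c.d_model = cfg["d_model"];
  c.n_heads = cfg["n_heads"];
  c.n_layers = cfg["n_layers"];
  c.ffn_dim = cfg["ffn_dim"];
  c.se_red = cfg["se_red"];
  c.K1 = cfg["K1"];
  c.K2 = cfg["K2"];
  c.dropout = cfg["dropout"];
  c.has_cnn = cfg["has_cnn"];
  c.has_se = cfg["has_se"];
  c.has_encoder = cfg["has_encoder"];
  c.has_task1 = cfg["has_task1"];
  c.has_task2 = cfg["has_task2"];
  Rcpp::IntegerVector ch = cfg["conv_channels"];
  c.conv_channels = std::vector<int>(ch.begin(), ch.end());
  if (c.has_cnn && c.conv_channels.empty())
    Rcpp::stop("has_cnn requires conv_channels");
  if (c.d_model % c.n_heads != 0) Rcpp::stop("d_model must be divisible by n_heads");
  if (c.kernel % 2 == 0) Rcpp::stop("conv kernel width must be odd");
  if (c.d_model % 2 != 0) Rcpp::stop("d_model must be even");
  return c;
}

struct Entry {
  std::string name;
  int rows, cols;   // cols == 0 -> bias/vector of length rows
  bool weight;      // participates in weight decay
  double init;      // constant init for vectors (ln gamma = 1), else 0
};

static std::vector<Entry> layout_entries(const Cfg& c) {
  std::vector<Entry> e;
  auto W = [&](std::string n, int r, int cc) { e.push_back({n, r, cc, true, 0.0}); };
  auto b = [&](std::string n, int r, double init = 0.0) {
    e.push_back({n, r, 0, false, init});
  };
  int cin = 1;
  if (c.has_cnn) {
    for (size_t i = 0; i < c.conv_channels.size(); ++i) {
      int cout = c.conv_channels[i];
      W("conv" + std::to_string(i + 1) + "_W", cin * c.kernel, cout);
      b("conv" + std::to_string(i + 1) + "_b", cout);
      cin = cout;
    }
  }
  W("lift_W", cin, c.d_model);
  b("lift_b", c.d_model);
  if (c.has_se) {
    int red = std::max(1, c.d_model / c.se_red);
    W("se_W1", c.d_model, red);
    W("se_W2", red, c.d_model);
  }
  if (c.has_encoder) {
    for (int l = 1; l <= c.n_layers; ++l) {
      std::string p = "enc" + std::to_string(l) + "_";
      W(p + "Wq", c.d_model, c.d_model); b(p + "bq", c.d_model);
      W(p + "Wk", c.d_model, c.d_model); b(p + "bk", c.d_model);
      W(p + "Wv", c.d_model, c.d_model); b(p + "bv", c.d_model);
      W(p + "Wo", c.d_model, c.d_model); b(p + "bo", c.d_model);
      b(p + "ln1_g", c.d_model, 1.0); b(p + "ln1_b", c.d_model);
      W(p + "ffn_W1", c.d_model, c.ffn_dim); b(p + "ffn_b1", c.ffn_dim);
      W(p + "ffn_W2", c.ffn_dim, c.d_model); b(p + "ffn_b2", c.d_model);
      b(p + "ln2_g", c.d_model, 1.0); b(p + "ln2_b", c.d_model);
    }
  }
  if (c.has_task1) { W("head1_W", c.d_model, c.K1); b("head1_b", c.K1); }
  if (c.has_task2) { W("head2_W", c.d_model, c.K2); b("head2_b", c.K2); }
  return e;
}

static int total_size(const std::vector<Entry>& es) {
  int n = 0;
  for (auto& en : es) n += en.rows * std::max(en.cols, 1);
  return n;
}

// ------------------------------------------------------------- rng ----------

struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

// ---------------------------------------------------------- parameters ------

template <typename T>
struct EncP {
  Mat<T> Wq, Wk, Wv, Wo, fW1, fW2;
  Col<T> bq, bk, bv, bo, ln1g, ln1b, fb1, fb2, ln2g, ln2b;
};

template <typename T>
struct Net {
  std::vector<Mat<T>> conv_W;
  std::vector<Col<T>> conv_b;
  Mat<T> lift_W, se_W1, se_W2, h1_W, h2_W;
  Col<T> lift_b, h1_b, h2_b;
  std::vector<EncP<T>> enc;
};

template <typename T>
static Net<T> unpack(const Cfg& c, const Col<T>& th) {
  Net<T> n;
  int off = 0;
  auto M = [&](int r, int cc) { Mat<T> m(&th[off], r, cc); off += r * cc; return m; };
  auto V = [&](int r) { Col<T> v(&th[off], r); off += r; return v; };
  if (c.has_cnn) {
    int cin = 1;
    for (size_t i = 0; i < c.conv_channels.size(); ++i) {
      int cout = c.conv_channels[i];
      n.conv_W.push_back(M(cin * c.kernel, cout));
      n.conv_b.push_back(V(cout));
      cin = cout;
    }
  }
  int cin = c.has_cnn ? c.conv_channels.back() : 1;
  n.lift_W = M(cin, c.d_model);
  n.lift_b = V(c.d_model);
  if (c.has_se) {
    int red = std::max(1, c.d_model / c.se_red);
    n.se_W1 = M(c.d_model, red);
    n.se_W2 = M(red, c.d_model);
  }
  if (c.has_encoder) {
    for (int l = 0; l < c.n_layers; ++l) {
      EncP<T> e;
      e.Wq = M(c.d_model, c.d_model); e.bq = V(c.d_model);
      e.Wk = M(c.d_model, c.d_model); e.bk = V(c.d_model);
      e.Wv = M(c.d_model, c.d_model); e.bv = V(c.d_model);
      e.Wo = M(c.d_model, c.d_model); e.bo = V(c.d_model);
      e.ln1g = V(c.d_model); e.ln1b = V(c.d_model);
      e.fW1 = M(c.d_model, c.ffn_dim); e.fb1 = V(c.ffn_dim);
      e.fW2 = M(c.ffn_dim, c.d_model); e.fb2 = V(c.d_model);
      e.ln2g = V(c.d_model); e.ln2b = V(c.d_model);
      n.enc.push_back(e);
    }
  }
  if (c.has_task1) { n.h1_W = M(c.d_model, c.K1); n.h1_b = V(c.K1); }
  if (c.has_task2) { n.h2_W = M(c.d_model, c.K2); n.h2_b = V(c.K2); }
  if (off != (int)th.n_elem) Rcpp::stop("parameter vector length mismatch");
  return n;
}

template <typename T>
static void pack_grad(const Cfg& c, const Net<T>& g, Col<T>& out) {
  int off = 0;
  auto M = [&](const Mat<T>& m) {
    std::copy(m.memptr(), m.memptr() + m.n_elem, out.memptr() + off);
    off += m.n_elem;
  };
  auto V = [&](const Col<T>& v) {
    std::copy(v.memptr(), v.memptr() + v.n_elem, out.memptr() + off);
    off += v.n_elem;
  };
  if (c.has_cnn)
    for (size_t i = 0; i < g.conv_W.size(); ++i) { M(g.conv_W[i]); V(g.conv_b[i]); }
  M(g.lift_W); V(g.lift_b);
  if (c.has_se) { M(g.se_W1); M(g.se_W2); }
  if (c.has_encoder)
    for (auto& e : g.enc) {
      M(e.Wq); V(e.bq); M(e.Wk); V(e.bk); M(e.Wv); V(e.bv); M(e.Wo); V(e.bo);
      V(e.ln1g); V(e.ln1b); M(e.fW1); V(e.fb1); M(e.fW2); V(e.fb2);
      V(e.ln2g); V(e.ln2b);
    }
  if (c.has_task1) { M(g.h1_W); V(g.h1_b); }
  if (c.has_task2) { M(g.h2_W); V(g.h2_b); }
}

template <typename T>
static Net<T> zero_like(const Cfg& c, const Net<T>& n) {
  Net<T> g = n;
  for (auto& m : g.conv_W) m.zeros();
  for (auto& v : g.conv_b) v.zeros();
  g.lift_W.zeros(); g.lift_b.zeros();
  if (c.has_se) { g.se_W1.zeros(); g.se_W2.zeros(); }
  for (auto& e : g.enc) {
    e.Wq.zeros(); e.bq.zeros(); e.Wk.zeros(); e.bk.zeros();
    e.Wv.zeros(); e.bv.zeros(); e.Wo.zeros(); e.bo.zeros();
    e.ln1g.zeros(); e.ln1b.zeros(); e.fW1.zeros(); e.fb1.zeros();
    e.fW2.zeros(); e.fb2.zeros(); e.ln2g.zeros(); e.ln2b.zeros();
  }
  if (c.has_task1) { g.h1_W.zeros(); g.h1_b.zeros(); }
  if (c.has_task2) { g.h2_W.zeros(); g.h2_b.zeros(); }
  return g;
}

// ------------------------------------------------------------ primitives ----

template <typename T>
static Mat<T> positional_encoding_mat(int L, int d) {
  Mat<T> pe(L, d);
  for (int pos = 0; pos < L; ++pos)
    for (int i = 0; i < d / 2; ++i) {
      double ang = pos / std::pow(10000.0, (2.0 * i) / d);
      pe(pos, 2 * i) = (T)std::sin(ang);
      pe(pos, 2 * i + 1) = (T)std::cos(ang);
    }
  return pe;
}

template <typename T>
static void softmax_rows(Mat<T>& m) {
  Col<T> mx = max(m, 1);
  m.each_col() -= mx;
  m = exp(m);
  Col<T> s = sum(m, 1);
  m.each_col() /= s;
}

static const double LN_EPS = 1e-5;

template <typename T>
struct LnCache { Mat<T> nhat; Col<T> invstd; };

template <typename T>
static Mat<T> ln_forward(const Mat<T>& X, const Col<T>& g, const Col<T>& b,
                         LnCache<T>& cache) {
  Col<T> mu = mean(X, 1);
  Mat<T> Xc = X.each_col() - mu;
  Col<T> v = mean(square(Xc), 1);
  cache.invstd = 1.0 / sqrt(v + (T)LN_EPS);
  cache.nhat = Xc.each_col() % cache.invstd;
  Mat<T> out = cache.nhat.each_row() % g.t();
  out.each_row() += b.t();
  return out;
}

template <typename T>
static void ln_backward(const Mat<T>& dOut, const LnCache<T>& cache,
                        const Col<T>& g, Col<T>& dg, Col<T>& db, Mat<T>& dX) {
  dg += sum(dOut % cache.nhat, 0).t();
  db += sum(dOut, 0).t();
  dX = dOut.each_row() % g.t();
  Col<T> m1 = mean(dX, 1);
  Col<T> m2 = mean(dX % cache.nhat, 1);
  dX.each_col() -= m1;
  dX -= cache.nhat.each_col() % m2;
  dX.each_col() %= cache.invstd;
}

// im2col for 1-D same-padded convolution over the (B*L) x C token matrix;
// column index c*k + j (channel-major blocks of kernel taps)
template <typename T>
static Mat<T> im2col(const Mat<T>& A, int B, int L, int k) {
  int C = A.n_cols, pad = (k - 1) / 2;
  Mat<T> M(A.n_rows, C * k, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < k; ++j) {
      int sh = j - pad;
      for (int b = 0; b < B; ++b) {
        int l0 = std::max(0, -sh), l1 = std::min(L, L - sh);
        for (int l = l0; l < l1; ++l)
          M(b * L + l, c * k + j) = A(b * L + l + sh, c);
      }
    }
  return M;
}

template <typename T>
static void col2im_add(const Mat<T>& dM, int B, int L, int k, Mat<T>& dA) {
  int C = dA.n_cols, pad = (k - 1) / 2;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < k; ++j) {
      int sh = j - pad;
      for (int b = 0; b < B; ++b) {
        int l0 = std::max(0, -sh), l1 = std::min(L, L - sh);
        for (int l = l0; l < l1; ++l)
          dA(b * L + l + sh, c) += dM(b * L + l, c * k + j);
      }
    }
}

// ------------------------------------------------------------ forward -------

template <typename T>
struct EncCache {
  Mat<T> Hin, Q, K, V, Ctx, mask1, mask2, N1, F1;
  Cube<T> Qc, Kc, Vc, Pc;      // per-(sample, head) slices; Pc = attention
  Mat<T> relu_mask_f;          // FFN relu mask
  LnCache<T> ln1, ln2;
};

// all members are assigned with `=` so a Cache instance can be reused across
// minibatches without reallocation (armadillo keeps same-size buffers)
template <typename T>
struct Cache {
  std::vector<Mat<T>> conv_M, conv_mask, conv_out;
  Mat<T> lift_in, H0;          // H0: lift output (pre-SE)
  Mat<T> se_z, se_h, se_s;     // SE: pooled input, hidden pre-relu, gates
  std::vector<EncCache<T>> enc;
  Mat<T> Hfinal, G, P1, P2;
};

template <typename T>
static void forward_pass(const Cfg& c, const Net<T>& n, const Mat<T>& X,
                         bool training, double dropout_p, SplitMix64* rng,
                         Cache<T>& K) {
  int B = X.n_rows, L = c.L, d = c.d_model;
  if ((int)X.n_cols != L) Rcpp::stop("input length mismatch");
  Mat<T> A(B * L, 1);
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < L; ++l) A(b * L + l, 0) = X(b, l);

  if (c.has_cnn) {
    size_t nc = n.conv_W.size();
    K.conv_M.resize(nc); K.conv_mask.resize(nc); K.conv_out.resize(nc);
    for (size_t i = 0; i < nc; ++i) {
      K.conv_M[i] = im2col(A, B, L, c.kernel);
      Mat<T> Z = K.conv_M[i] * n.conv_W[i];
      Z.each_row() += n.conv_b[i].t();
      K.conv_mask[i] = conv_to<Mat<T>>::from(Z > (T)0);
      A = Z % K.conv_mask[i];
      K.conv_out[i] = A;
    }
  }
  K.lift_in = A;
  Mat<T> H = A * n.lift_W;
  H.each_row() += n.lift_b.t();
  K.H0 = H;

  if (c.has_se) {
    Mat<T> Z(B, d);
    for (int b = 0; b < B; ++b) Z.row(b) = mean(H.rows(b * L, b * L + L - 1), 0);
    K.se_z = Z;
    K.se_h = Z * n.se_W1;
    Mat<T> hr = K.se_h % conv_to<Mat<T>>::from(K.se_h > (T)0);
    Mat<T> s = 1.0 / (1.0 + exp(-(hr * n.se_W2)));
    K.se_s = s;
    for (int b = 0; b < B; ++b)
      H.rows(b * L, b * L + L - 1).each_row() %= s.row(b);
  }

  if (c.has_encoder) {
    Mat<T> pe = positional_encoding_mat<T>(L, d);
    for (int b = 0; b < B; ++b) H.rows(b * L, b * L + L - 1) += pe;
    int nh = c.n_heads, dk = d / nh;
    T scale = (T)(1.0 / std::sqrt((double)dk));
    bool drop = training && dropout_p > 0;
    T keep = (T)(1.0 - dropout_p);
    // Bernoulli masks from four 16-bit lanes per RNG draw (threshold
    // quantised to 1/65536, indistinguishable from the nominal rate)
    uint64_t thr = (uint64_t)(dropout_p * 65536.0);
    auto make_mask = [&](int rows, int cols) {
      Mat<T> m(rows, cols);
      T inv = (T)1 / keep;
      uword nfull = m.n_elem - (m.n_elem % 4);
      for (uword idx = 0; idx < nfull; idx += 4) {
        uint64_t r = rng->next();
        m[idx] = ((r & 0xffff) < thr) ? (T)0 : inv;
        m[idx + 1] = (((r >> 16) & 0xffff) < thr) ? (T)0 : inv;
        m[idx + 2] = (((r >> 32) & 0xffff) < thr) ? (T)0 : inv;
        m[idx + 3] = (((r >> 48) & 0xffff) < thr) ? (T)0 : inv;
      }
      for (uword idx = nfull; idx < m.n_elem; ++idx)
        m[idx] = ((rng->next() & 0xffff) < thr) ? (T)0 : inv;
      return m;
    };
    K.enc.resize(c.n_layers);
    for (int l = 0; l < c.n_layers; ++l) {
      const EncP<T>& e = n.enc[l];
      EncCache<T>& ec = K.enc[l];
      ec.Hin = H;
      ec.Q = H * e.Wq; ec.Q.each_row() += e.bq.t();
      ec.K = H * e.Wk; ec.K.each_row() += e.bk.t();
      ec.V = H * e.Wv; ec.V.each_row() += e.bv.t();
      int ns = B * nh;
      ec.Qc.set_size(L, dk, ns); ec.Kc.set_size(L, dk, ns);
      ec.Vc.set_size(L, dk, ns); ec.Pc.set_size(L, L, ns);
      for (int b = 0; b < B; ++b)
        for (int h = 0; h < nh; ++h) {
          int s = b * nh + h;
          int r0 = b * L, r1 = b * L + L - 1;
          int c0 = h * dk, c1 = (h + 1) * dk - 1;
          ec.Qc.slice(s) = ec.Q.submat(r0, c0, r1, c1);
          ec.Kc.slice(s) = ec.K.submat(r0, c0, r1, c1);
          ec.Vc.slice(s) = ec.V.submat(r0, c0, r1, c1);
        }
      ec.Ctx.set_size(B * L, d);
      for (int s = 0; s < ns; ++s) {
        Mat<T>& Sl = ec.Pc.slice(s);
        Sl = ec.Qc.slice(s) * ec.Kc.slice(s).t();
        Sl *= scale;
        softmax_rows(Sl);
        int b = s / nh, h = s % nh;
        ec.Ctx.submat(b * L, h * dk, b * L + L - 1, (h + 1) * dk - 1) =
            Sl * ec.Vc.slice(s);
      }
      Mat<T> O = ec.Ctx * e.Wo;
      O.each_row() += e.bo.t();
      if (drop) { ec.mask1 = make_mask(B * L, d); O %= ec.mask1; }
      else ec.mask1.reset();
      Mat<T> R1 = ec.Hin + O;
      ec.N1 = ln_forward(R1, e.ln1g, e.ln1b, ec.ln1);
      Mat<T> Zf = ec.N1 * e.fW1;
      Zf.each_row() += e.fb1.t();
      ec.relu_mask_f = conv_to<Mat<T>>::from(Zf > (T)0);
      ec.F1 = Zf % ec.relu_mask_f;
      Mat<T> F2 = ec.F1 * e.fW2;
      F2.each_row() += e.fb2.t();
      if (drop) { ec.mask2 = make_mask(B * L, d); F2 %= ec.mask2; }
      else ec.mask2.reset();
      Mat<T> R2 = ec.N1 + F2;
      H = ln_forward(R2, e.ln2g, e.ln2b, ec.ln2);
    }
  }
  K.Hfinal = H;

  K.G.set_size(B, d);
  for (int b = 0; b < B; ++b) K.G.row(b) = mean(H.rows(b * L, b * L + L - 1), 0);

  if (c.has_task1) {
    K.P1 = K.G * n.h1_W;
    K.P1.each_row() += n.h1_b.t();
    softmax_rows(K.P1);
  }
  if (c.has_task2) {
    K.P2 = K.G * n.h2_W;
    K.P2.each_row() += n.h2_b.t();
    softmax_rows(K.P2);
  }
}

template <typename T>
static double ce_loss(const Mat<T>& P, const ivec& y) {
  double s = 0;
  for (uword i = 0; i < P.n_rows; ++i)
    s -= std::log(std::max((double)P(i, y[i] - 1), 1e-12));
  return s / P.n_rows;
}

// ------------------------------------------------------------ backward ------

// scratch buffers reused across minibatches (assigned with `=` only)
template <typename T>
struct BwdWs {
  Mat<T> dG, dH, dR2, dN1, dF2, dZf, dR1, dO, dCtx, dQ, dK, dV, dA;
};

template <typename T>
static void backward_pass(const Cfg& c, const Net<T>& n, const Cache<T>& K,
                          const ivec& y1, const ivec& y2, double alpha,
                          double beta, Net<T>& g, BwdWs<T>& w) {
  int B = K.G.n_rows, L = c.L, d = c.d_model;
  Mat<T>& dG = w.dG;
  dG.zeros(B, d);
  if (c.has_task1 && alpha != 0) {
    Mat<T> dl = K.P1;
    for (int i = 0; i < B; ++i) dl(i, y1[i] - 1) -= 1;
    dl *= (T)(alpha / B);
    g.h1_W += K.G.t() * dl;
    g.h1_b += sum(dl, 0).t();
    dG += dl * n.h1_W.t();
  }
  if (c.has_task2 && beta != 0) {
    Mat<T> dl = K.P2;
    for (int i = 0; i < B; ++i) dl(i, y2[i] - 1) -= 1;
    dl *= (T)(beta / B);
    g.h2_W += K.G.t() * dl;
    g.h2_b += sum(dl, 0).t();
    dG += dl * n.h2_W.t();
  }
  Mat<T>& dH = w.dH;
  dH.set_size(B * L, d);
  for (int b = 0; b < B; ++b)
    dH.rows(b * L, b * L + L - 1) = repmat(dG.row(b) / (T)L, L, 1);

  if (c.has_encoder) {
    int nh = c.n_heads, dk = d / nh;
    T scale = (T)(1.0 / std::sqrt((double)dk));
    for (int l = c.n_layers - 1; l >= 0; --l) {
      const EncP<T>& e = n.enc[l];
      EncP<T>& ge = g.enc[l];
      const EncCache<T>& ec = K.enc[l];
      ln_backward(dH, ec.ln2, e.ln2g, ge.ln2g, ge.ln2b, w.dR2);
      Mat<T>& dR2 = w.dR2;
      Mat<T>& dN1 = w.dN1;
      dN1 = dR2;
      Mat<T>& dF2 = w.dF2;
      dF2 = dR2;
      if (ec.mask2.n_elem > 0) dF2 %= ec.mask2;
      ge.fW2 += ec.F1.t() * dF2;
      ge.fb2 += sum(dF2, 0).t();
      w.dZf = (dF2 * e.fW2.t()) % ec.relu_mask_f;
      Mat<T>& dZf = w.dZf;
      ge.fW1 += ec.N1.t() * dZf;
      ge.fb1 += sum(dZf, 0).t();
      dN1 += dZf * e.fW1.t();
      ln_backward(dN1, ec.ln1, e.ln1g, ge.ln1g, ge.ln1b, w.dR1);
      Mat<T>& dR1 = w.dR1;
      Mat<T>& dO = w.dO;
      dO = dR1;
      if (ec.mask1.n_elem > 0) dO %= ec.mask1;
      ge.Wo += ec.Ctx.t() * dO;
      ge.bo += sum(dO, 0).t();
      w.dCtx = dO * e.Wo.t();
      Mat<T>& dCtx = w.dCtx;
      w.dQ.set_size(B * L, d); w.dK.set_size(B * L, d); w.dV.set_size(B * L, d);
      Mat<T>& dQ = w.dQ; Mat<T>& dK = w.dK; Mat<T>& dV = w.dV;
      Mat<T> dCtxb(L, dk), dP(L, L), dS(L, L);
      for (int b = 0; b < B; ++b) {
        int r0 = b * L, r1 = b * L + L - 1;
        for (int h = 0; h < nh; ++h) {
          int c0 = h * dk, c1 = (h + 1) * dk - 1;
          const Mat<T>& P = ec.Pc.slice(b * nh + h);
          dCtxb = dCtx.submat(r0, c0, r1, c1);
          dP = dCtxb * ec.Vc.slice(b * nh + h).t();
          dV.submat(r0, c0, r1, c1) = P.t() * dCtxb;
          dP %= P;
          dS = dP;
          dS -= P.each_col() % sum(dP, 1);
          dS *= scale;
          dQ.submat(r0, c0, r1, c1) = dS * ec.Kc.slice(b * nh + h);
          dK.submat(r0, c0, r1, c1) = dS.t() * ec.Qc.slice(b * nh + h);
        }
      }
      ge.Wq += ec.Hin.t() * dQ; ge.bq += sum(dQ, 0).t();
      ge.Wk += ec.Hin.t() * dK; ge.bk += sum(dK, 0).t();
      ge.Wv += ec.Hin.t() * dV; ge.bv += sum(dV, 0).t();
      dH = dR1 + dQ * e.Wq.t() + dK * e.Wk.t() + dV * e.Wv.t();
    }
  }

  // positional encoding is additive: gradient flows through unchanged
  if (c.has_se) {
    Mat<T> ds(B, d);
    Mat<T> dH0 = dH;
    for (int b = 0; b < B; ++b) {
      int r0 = b * L, r1 = b * L + L - 1;
      ds.row(b) = sum(dH.rows(r0, r1) % K.H0.rows(r0, r1), 0);
      dH0.rows(r0, r1).each_row() %= K.se_s.row(b);
    }
    Mat<T> dsig = ds % K.se_s % (1 - K.se_s);
    Mat<T> hr = K.se_h % conv_to<Mat<T>>::from(K.se_h > (T)0);
    g.se_W2 += hr.t() * dsig;
    Mat<T> dh = (dsig * n.se_W2.t()) % conv_to<Mat<T>>::from(K.se_h > (T)0);
    g.se_W1 += K.se_z.t() * dh;
    Mat<T> dz = dh * n.se_W1.t();
    for (int b = 0; b < B; ++b)
      dH0.rows(b * L, b * L + L - 1) += repmat(dz.row(b) / (T)L, L, 1);
    dH = dH0;
  }

  g.lift_W += K.lift_in.t() * dH;
  g.lift_b += sum(dH, 0).t();
  Mat<T> dA = dH * n.lift_W.t();

  if (c.has_cnn) {
    for (int i = (int)n.conv_W.size() - 1; i >= 0; --i) {
      Mat<T> dZ = dA % K.conv_mask[i];
      g.conv_W[i] += K.conv_M[i].t() * dZ;
      g.conv_b[i] += sum(dZ, 0).t();
      Mat<T> dM = dZ * n.conv_W[i].t();
      Mat<T> dPrev(dA.n_rows, i == 0 ? 1 : c.conv_channels[i - 1], fill::zeros);
      col2im_add(dM, (int)dA.n_rows / c.L, c.L, c.kernel, dPrev);
      dA = dPrev;
    }
  }
}

// --------------------------------------------------------- R entry points ---

// [[Rcpp::export]]
Rcpp::DataFrame cpp_param_layout(Rcpp::List cfg) {
  Cfg c = parse_cfg(cfg);
  auto es = layout_entries(c);
  int n = es.size();
  Rcpp::CharacterVector name(n);
  Rcpp::IntegerVector offset(n), rows(n), cols(n), size(n);
  Rcpp::LogicalVector weight(n);
  int off = 1;
  for (int i = 0; i < n; ++i) {
    name[i] = es[i].name;
    rows[i] = es[i].rows;
    cols[i] = es[i].cols;
    int sz = es[i].rows * std::max(es[i].cols, 1);
    size[i] = sz;
    offset[i] = off;
    off += sz;
    weight[i] = es[i].weight;
  }
  return Rcpp::DataFrame::create(
      Rcpp::Named("name") = name, Rcpp::Named("offset") = offset,
      Rcpp::Named("rows") = rows, Rcpp::Named("cols") = cols,
      Rcpp::Named("size") = size, Rcpp::Named("weight") = weight,
      Rcpp::Named("stringsAsFactors") = false);
}

// [[Rcpp::export]]
int cpp_param_count(Rcpp::List cfg) {
  return total_size(layout_entries(parse_cfg(cfg)));
}

// Glorot-normal init from a caller-supplied vector of standard normals (one
// draw per parameter; biases are zeroed, LayerNorm gains set to one).
// [[Rcpp::export]]
Rcpp::NumericVector cpp_init_params(Rcpp::List cfg, Rcpp::NumericVector z) {
  Cfg c = parse_cfg(cfg);
  auto es = layout_entries(c);
  int n = total_size(es);
  if ((int)z.size() != n) Rcpp::stop("z must have length %d", n);
  Rcpp::NumericVector out(n);
  int off = 0;
  for (auto& e : es) {
    int sz = e.rows * std::max(e.cols, 1);
    if (e.weight) {
      double sc = std::sqrt(2.0 / (e.rows + e.cols));
      for (int i = 0; i < sz; ++i) out[off + i] = sc * z[off + i];
    } else {
      for (int i = 0; i < sz; ++i) out[off + i] = e.init;
    }
    off += sz;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::LogicalVector cpp_decay_mask(Rcpp::List cfg) {
  Cfg c = parse_cfg(cfg);
  auto es = layout_entries(c);
  Rcpp::LogicalVector out(total_size(es));
  int off = 0;
  for (auto& e : es) {
    int sz = e.rows * std::max(e.cols, 1);
    for (int i = 0; i < sz; ++i) out[off + i] = e.weight;
    off += sz;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_forward(Rcpp::List cfg, Rcpp::NumericVector params,
                       Rcpp::NumericMatrix X) {
  Cfg c = parse_cfg(cfg);
  Col<double> th(params.begin(), params.size());
  Net<double> n = unpack(c, th);
  Mat<double> Xm(X.begin(), X.nrow(), X.ncol());
  Cache<double> K;
  forward_pass(c, n, Xm, false, 0.0, nullptr, K);
  Rcpp::List out;
  out["p1"] = c.has_task1 ? Rcpp::wrap(K.P1) : R_NilValue;
  out["p2"] = c.has_task2 ? Rcpp::wrap(K.P2) : R_NilValue;
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_loss_grad(Rcpp::List cfg, Rcpp::NumericVector params,
                         Rcpp::NumericMatrix X, Rcpp::IntegerVector y1,
                         Rcpp::IntegerVector y2, double alpha, double beta) {
  Cfg c = parse_cfg(cfg);
  Col<double> th(params.begin(), params.size());
  Net<double> n = unpack(c, th);
  Mat<double> Xm(X.begin(), X.nrow(), X.ncol());
  ivec y1v = Rcpp::as<ivec>(y1), y2v = Rcpp::as<ivec>(y2);
  Cache<double> K;
  forward_pass(c, n, Xm, false, 0.0, nullptr, K);
  double l1 = (c.has_task1 && alpha != 0) ? ce_loss(K.P1, y1v) : 0.0;
  double l2 = (c.has_task2 && beta != 0) ? ce_loss(K.P2, y2v) : 0.0;
  Net<double> g = zero_like(c, n);
  BwdWs<double> w;
  backward_pass(c, n, K, y1v, y2v, alpha, beta, g, w);
  Col<double> gflat(th.n_elem);
  pack_grad(c, g, gflat);
  return Rcpp::List::create(
      Rcpp::Named("loss") = alpha * l1 + beta * l2, Rcpp::Named("loss1") = l1,
      Rcpp::Named("loss2") = l2,
      Rcpp::Named("grad") = Rcpp::NumericVector(gflat.begin(), gflat.end()));
}

template <typename T>
static void eval_metrics(const Cfg& c, const Net<T>& n, const Mat<T>& X,
                         const ivec& y1, const ivec& y2, double alpha,
                         double beta, double& loss, double& acc1, double& acc2) {
  Cache<T> K;
  forward_pass(c, n, X, false, 0.0, nullptr, K);
  double l1 = 0, l2 = 0;
  acc1 = NA_REAL; acc2 = NA_REAL;
  if (c.has_task1) {
    l1 = ce_loss(K.P1, y1);
    int ok = 0;
    for (uword i = 0; i < K.P1.n_rows; ++i)
      if ((int)K.P1.row(i).index_max() + 1 == y1[i]) ++ok;
    acc1 = (double)ok / K.P1.n_rows;
  }
  if (c.has_task2) {
    l2 = ce_loss(K.P2, y2);
    int ok = 0;
    for (uword i = 0; i < K.P2.n_rows; ++i)
      if ((int)K.P2.row(i).index_max() + 1 == y2[i]) ++ok;
    acc2 = (double)ok / K.P2.n_rows;
  }
  loss = alpha * l1 + beta * l2;
}

// AdamW training loop with cosine-annealed learning rate and early stopping
// on the validation loss; single precision internally.
// [[Rcpp::export]]
Rcpp::List cpp_train(Rcpp::List cfg, Rcpp::NumericVector params,
                     Rcpp::NumericMatrix X, Rcpp::IntegerVector y1,
                     Rcpp::IntegerVector y2, Rcpp::NumericMatrix Xval,
                     Rcpp::IntegerVector yv1, Rcpp::IntegerVector yv2,
                     int epochs, int batch_size, double lr,
                     double weight_decay, double alpha, double beta,
                     int patience, double dropout_p, int shuffle_seed,
                     int dropout_seed) {
  Cfg c = parse_cfg(cfg);
  int np = params.size();
  fvec th = conv_to<fvec>::from(Col<double>(params.begin(), np));
  fmat Xm = conv_to<fmat>::from(Mat<double>(X.begin(), X.nrow(), X.ncol()));
  fmat Xv;
  bool has_val = Xval.nrow() > 0;
  if (has_val)
    Xv = conv_to<fmat>::from(Mat<double>(Xval.begin(), Xval.nrow(), Xval.ncol()));
  ivec y1v = Rcpp::as<ivec>(y1), y2v = Rcpp::as<ivec>(y2);
  ivec yv1v = Rcpp::as<ivec>(yv1), yv2v = Rcpp::as<ivec>(yv2);

  Rcpp::LogicalVector decay = cpp_decay_mask(cfg);
  fvec dmask(np);
  for (int i = 0; i < np; ++i) dmask[i] = decay[i] ? 1.0f : 0.0f;

  fvec m(np, fill::zeros), v(np, fill::zeros), gflat(np);
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  int n = Xm.n_rows;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<double> h_lr, h_train_loss, h_l1, h_l2, h_tacc1, h_tacc2,
      h_vloss, h_vacc1, h_vacc2;
  double best_val = datum::inf;
  fvec best_th = th;
  int best_epoch = 0, wait = 0;
  Cache<float> K;  // reused across minibatches
  BwdWs<float> W;

  for (int epoch = 1; epoch <= epochs; ++epoch) {
    double lr_e = lr * 0.5 * (1.0 + std::cos(M_PI * (epoch - 1) / (double)epochs));
    SplitMix64 shuf((uint64_t)shuffle_seed * 2654435761ULL + epoch);
    for (int i = n - 1; i > 0; --i) std::swap(order[i], order[shuf.below(i + 1)]);
    SplitMix64 drop((uint64_t)dropout_seed * 2654435761ULL + epoch);
    double ep_loss = 0, ep_l1 = 0, ep_l2 = 0;
    int n_batches = 0, ok1 = 0, ok2 = 0;
    for (int start = 0; start < n; start += batch_size) {
      int bsz = std::min(batch_size, n - start);
      fmat Xb(bsz, c.L);
      ivec y1b(bsz), y2b(bsz);
      for (int i = 0; i < bsz; ++i) {
        Xb.row(i) = Xm.row(order[start + i]);
        y1b[i] = y1v.n_elem ? y1v[order[start + i]] : 1;
        y2b[i] = y2v.n_elem ? y2v[order[start + i]] : 1;
      }
      Net<float> net = unpack(c, th);
      forward_pass(c, net, Xb, true, dropout_p, &drop, K);
      double l1 = (c.has_task1 && alpha != 0) ? ce_loss(K.P1, y1b) : 0.0;
      double l2 = (c.has_task2 && beta != 0) ? ce_loss(K.P2, y2b) : 0.0;
      if (c.has_task1)
        for (int i = 0; i < bsz; ++i)
          if ((int)K.P1.row(i).index_max() + 1 == y1b[i]) ++ok1;
      if (c.has_task2)
        for (int i = 0; i < bsz; ++i)
          if ((int)K.P2.row(i).index_max() + 1 == y2b[i]) ++ok2;
      Net<float> g = zero_like(c, net);
      backward_pass(c, net, K, y1b, y2b, alpha, beta, g, W);
      pack_grad(c, g, gflat);
      ++step;
      float bc1 = (float)(1.0 - std::pow(b1, (double)step));
      float bc2 = (float)(1.0 - std::pow(b2, (double)step));
      float fb1 = (float)b1, fb2 = (float)b2, flr = (float)lr_e,
            fwd_ = (float)weight_decay, feps = (float)eps;
      float* mp = m.memptr(); float* vp = v.memptr();
      float* gp = gflat.memptr(); float* tp = th.memptr();
      const float* dp = dmask.memptr();
      for (int j = 0; j < np; ++j) {
        mp[j] = fb1 * mp[j] + (1.0f - fb1) * gp[j];
        vp[j] = fb2 * vp[j] + (1.0f - fb2) * gp[j] * gp[j];
        tp[j] -= flr * ((mp[j] / bc1) / (std::sqrt(vp[j] / bc2) + feps) +
                        fwd_ * dp[j] * tp[j]);
      }
      ep_loss += alpha * l1 + beta * l2;
      ep_l1 += l1; ep_l2 += l2;
      ++n_batches;
    }
    h_lr.push_back(lr_e);
    h_train_loss.push_back(ep_loss / n_batches);
    h_l1.push_back(ep_l1 / n_batches);
    h_l2.push_back(ep_l2 / n_batches);
    h_tacc1.push_back(c.has_task1 ? (double)ok1 / n : NA_REAL);
    h_tacc2.push_back(c.has_task2 ? (double)ok2 / n : NA_REAL);
    if (has_val) {
      Net<float> net = unpack(c, th);
      double vl, va1, va2;
      eval_metrics(c, net, Xv, yv1v, yv2v, alpha, beta, vl, va1, va2);
      h_vloss.push_back(vl);
      h_vacc1.push_back(va1);
      h_vacc2.push_back(va2);
      if (vl < best_val - 1e-7) {
        best_val = vl; best_th = th; best_epoch = epoch; wait = 0;
      } else if (++wait >= patience) break;
    } else {
      h_vloss.push_back(NA_REAL);
      h_vacc1.push_back(NA_REAL);
      h_vacc2.push_back(NA_REAL);
      best_th = th; best_epoch = epoch;
    }
    Rcpp::checkUserInterrupt();
  }
  Col<double> out_th = conv_to<Col<double>>::from(best_th);
  int ne = h_lr.size();
  Rcpp::IntegerVector ep_idx(ne);
  for (int i = 0; i < ne; ++i) ep_idx[i] = i + 1;
  Rcpp::DataFrame hist = Rcpp::DataFrame::create(
      Rcpp::Named("epoch") = ep_idx, Rcpp::Named("lr") = h_lr,
      Rcpp::Named("train_loss") = h_train_loss, Rcpp::Named("loss_task1") = h_l1,
      Rcpp::Named("loss_task2") = h_l2, Rcpp::Named("train_acc1") = h_tacc1,
      Rcpp::Named("train_acc2") = h_tacc2, Rcpp::Named("val_loss") = h_vloss,
      Rcpp::Named("val_acc1") = h_vacc1, Rcpp::Named("val_acc2") = h_vacc2);
  return Rcpp::List::create(
      Rcpp::Named("params") = Rcpp::NumericVector(out_th.begin(), out_th.end()),
      Rcpp::Named("history") = hist, Rcpp::Named("best_epoch") = best_epoch);
}
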