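// Minimal sequence-model engine: 1-D convolution, max pooling, bidirectional
// LSTM/GRU, dense, dropout and activation layers with analytic backprop and
// Adam, in single precision on top of BLAS GEMM.  Layer semantics follow the
// standard gate formulations (classic GRU: candidate uses the reset-gated
// previous state).  All randomness (init, shuffling, dropout) comes from one
// std::mt19937 per entry point, so results are reproducible given a seed.
#include <RcppArmadillo.h>
#include <random>
#include <memory>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fcube;
using arma::fvec;

static inline fmat sigm(const fmat& x) { return 1.0f / (1.0f + arma::exp(-x)); }

struct Tensor {
  fcube c;   // (L, C, N) when is3d
  fmat  m;   // (N, D) otherwise
  bool  is3d = false;
};

struct Shape {
  bool is3d; int L; int C; int D;  // D used when !is3d
  int flat() const { return is3d ? L * C : D; }
};

// Glorot-uniform init, the Keras default for kernels.
static void glorot(fmat& W, double fan_in, double fan_out, std::mt19937& rng) {
  double lim = std::sqrt(6.0 / (fan_in + fan_out));
  std::uniform_real_distribution<double> U(-lim, lim);
  for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = (float)U(rng);
}

// Flatten a (L, C, N) cube to (N, L*C), time-major (position varies slowest
// within a row: index = pos*C + channel).
static fmat flatten_cube(const fcube& X) {
  int L = X.n_rows, C = X.n_cols, N = X.n_slices;
  fmat M(N, L * C);
  for (int n = 0; n < N; ++n) {
    const fmat& S = X.slice(n);
    for (int l = 0; l < L; ++l)
      for (int c = 0; c < C; ++c) M(n, l * C + c) = S(l, c);
  }
  return M;
}

static fcube unflatten_mat(const fmat& M, int L, int C) {
  int N = M.n_rows;
  fcube X(L, C, N);
  for (int n = 0; n < N; ++n)
    for (int l = 0; l < L; ++l)
      for (int c = 0; c < C; ++c) X(l, c, n) = M(n, l * C + c);
  return X;
}

struct Layer {
  std::string name;
  Shape out_shape;
  virtual ~Layer() {}
  virtual void init(std::mt19937&) {}
  virtual Tensor forward(const Tensor&, bool training, std::mt19937& rng) = 0;
  virtual Tensor backward(const Tensor&) = 0;
  virtual std::vector<fmat*> params() { return {}; }
  virtual std::vector<fmat*> grads() { return {}; }
  void zero_grads() { for (auto g : grads()) g->zeros(); }
};

// ---------------------------------------------------------------- Conv1D ----
struct Conv1D : Layer {
  int K, F, S, Lin, Cin, Lo;
  bool relu_act;
  fmat W, b, dW, db;        // W: (K*Cin) x F
  fmat X2, relu_mask;       // caches
  int Ncache = 0;

  Conv1D(const Shape& in, int filters, int kernel, int stride, bool relu,
         const std::string& nm) {
    if (!in.is3d) stop("conv1d '%s': input must be sequence-shaped", nm);
    K = kernel; F = filters; S = stride; Lin = in.L; Cin = in.C;
    relu_act = relu; name = nm;
    if (K > Lin)
      stop("layer '%s': kernel size %d exceeds input length %d", nm, K, Lin);
    Lo = (Lin - K) / S + 1;
    out_shape = {true, Lo, F, 0};
    W.set_size(K * Cin, F); b.set_size(1, F);
    dW.zeros(K * Cin, F); db.zeros(1, F);
  }
  void init(std::mt19937& rng) override {
    glorot(W, (double)K * Cin, (double)K * F, rng);
    b.zeros();
  }
  std::vector<fmat*> params() override { return {&W, &b}; }
  std::vector<fmat*> grads() override { return {&dW, &db}; }

  Tensor forward(const Tensor& in, bool, std::mt19937&) override {
    int N = in.c.n_slices; Ncache = N;
    X2.set_size((size_t)N * Lo, (size_t)K * Cin);
    if (S == 1) {
      for (int n = 0; n < N; ++n)
        for (int m = 0; m < K; ++m)
          X2.submat(n * Lo, m * Cin, n * Lo + Lo - 1, m * Cin + Cin - 1) =
              in.c.slice(n).rows(m, m + Lo - 1);
    } else {
      for (int n = 0; n < N; ++n)
        for (int i = 0; i < Lo; ++i)
          for (int m = 0; m < K; ++m)
            for (int c = 0; c < Cin; ++c)
              X2(n * Lo + i, m * Cin + c) = in.c(i * S + m, c, n);
    }
    fmat Y2 = X2 * W;
    Y2.each_row() += b;
    if (relu_act) {
      relu_mask = arma::conv_to<fmat>::from(Y2 > 0.0f);
      Y2 %= relu_mask;
    }
    Tensor out; out.is3d = true; out.c.set_size(Lo, F, N);
    for (int n = 0; n < N; ++n)
      out.c.slice(n) = Y2.rows(n * Lo, n * Lo + Lo - 1);
    return out;
  }

  Tensor backward(const Tensor& g) override {
    int N = Ncache;
    fmat dY2((size_t)N * Lo, F);
    for (int n = 0; n < N; ++n)
      dY2.rows(n * Lo, n * Lo + Lo - 1) = g.c.slice(n);
    if (relu_act) dY2 %= relu_mask;
    dW += X2.t() * dY2;
    db += arma::sum(dY2, 0);
    fmat dX2 = dY2 * W.t();
    Tensor out; out.is3d = true; out.c.zeros(Lin, Cin, N);
    if (S == 1) {
      for (int n = 0; n < N; ++n)
        for (int m = 0; m < K; ++m)
          out.c.slice(n).rows(m, m + Lo - 1) +=
              dX2.submat(n * Lo, m * Cin, n * Lo + Lo - 1, m * Cin + Cin - 1);
    } else {
      for (int n = 0; n < N; ++n)
        for (int i = 0; i < Lo; ++i)
          for (int m = 0; m < K; ++m)
            for (int c = 0; c < Cin; ++c)
              out.c(i * S + m, c, n) += dX2(n * Lo + i, m * Cin + c);
    }
    return out;
  }
};

// ------------------------------------------------------------- MaxPool1D ----
struct MaxPool1D : Layer {
  int P, S, Lin, C, Lo;
  arma::Cube<arma::uword> amax;  // (Lo, C, N): winning input position
  MaxPool1D(const Shape& in, int pool, int stride, const std::string& nm) {
    if (!in.is3d) stop("maxpool1d '%s': input must be sequence-shaped", nm);
    P = pool; S = stride; Lin = in.L; C = in.C; name = nm;
    if (P > Lin)
      stop("layer '%s': pool size %d exceeds input length %d", nm, P, Lin);
    Lo = (Lin - P) / S + 1;
    out_shape = {true, Lo, C, 0};
  }
  Tensor forward(const Tensor& in, bool, std::mt19937&) override {
    int N = in.c.n_slices;
    Tensor out; out.is3d = true; out.c.set_size(Lo, C, N);
    amax.set_size(Lo, C, N);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c)
        for (int i = 0; i < Lo; ++i) {
          int base = i * S; float best = in.c(base, c, n); int bi = base;
          for (int m = 1; m < P; ++m)
            if (in.c(base + m, c, n) > best) { best = in.c(base + m, c, n); bi = base + m; }
          out.c(i, c, n) = best; amax(i, c, n) = bi;
        }
    return out;
  }
  Tensor backward(const Tensor& g) override {
    int N = g.c.n_slices;
    Tensor out; out.is3d = true; out.c.zeros(Lin, C, N);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c)
        for (int i = 0; i < Lo; ++i)
          out.c(amax(i, c, n), c, n) += g.c(i, c, n);
    return out;
  }
};

// ------------------------------------------------------ recurrent helpers ---
// One direction of an LSTM.  Gate order in the stacked weight matrices is
// (i, f, c~, o); forget-gate bias initialised to 1.
struct LstmDir {
  int C, H, L;
  bool rev;
  fmat Wx, Wh, b, dWx, dWh, db;
  // caches, indexed by processing step
  std::vector<fmat> Xs, Is, Fs, Cts, Os, Cs, Th, Hs;

  void setup(int Cin, int units, int len, bool reverse) {
    C = Cin; H = units; L = len; rev = reverse;
    Wx.set_size(C, 4 * H); Wh.set_size(H, 4 * H); b.set_size(1, 4 * H);
    dWx.zeros(C, 4 * H); dWh.zeros(H, 4 * H); db.zeros(1, 4 * H);
  }
  void init(std::mt19937& rng) {
    glorot(Wx, C, 4.0 * H, rng);
    glorot(Wh, H, 4.0 * H, rng);
    b.zeros();
    b.cols(H, 2 * H - 1).fill(1.0f);  // forget gate bias
  }
  int idx(int s) const { return rev ? L - 1 - s : s; }

  // X: (L, C, N) input cube; fills Hs (h per step).
  void forward(const fcube& X) {
    int N = X.n_slices;
    Xs.assign(L, fmat()); Is.assign(L, fmat()); Fs.assign(L, fmat());
    Cts.assign(L, fmat()); Os.assign(L, fmat()); Cs.assign(L, fmat());
    Th.assign(L, fmat()); Hs.assign(L, fmat());
    fmat h(N, H, arma::fill::zeros), Cst(N, H, arma::fill::zeros);
    for (int s = 0; s < L; ++s) {
      int t = idx(s);
      fmat Xt(N, C);
      for (int n = 0; n < N; ++n) Xt.row(n) = X.slice(n).row(t);
      Xs[s] = Xt;
      fmat Z = Xt * Wx + h * Wh;
      Z.each_row() += b;
      fmat i = sigm(Z.cols(0, H - 1));
      fmat f = sigm(Z.cols(H, 2 * H - 1));
      fmat ct = arma::tanh(Z.cols(2 * H, 3 * H - 1));
      fmat o = sigm(Z.cols(3 * H, 4 * H - 1));
      Cst = f % Cst + i % ct;
      fmat th = arma::tanh(Cst);
      h = o % th;
      Is[s] = i; Fs[s] = f; Cts[s] = ct; Os[s] = o; Cs[s] = Cst;
      Th[s] = th; Hs[s] = h;
    }
  }
  // dH: per-step gradient on h (processing-step indexed); returns dX cube.
  fcube backward(const std::vector<fmat>& dH, int N) {
    fcube dX(L, C, N, arma::fill::zeros);
    fmat dh(N, H, arma::fill::zeros), dC(N, H, arma::fill::zeros);
    for (int s = L - 1; s >= 0; --s) {
      dh += dH[s];
      fmat d_o = dh % Th[s];
      fmat da_o = d_o % Os[s] % (1.0f - Os[s]);
      dC += dh % Os[s] % (1.0f - arma::square(Th[s]));
      fmat Cprev = (s == 0) ? fmat(N, H, arma::fill::zeros) : Cs[s - 1];
      fmat da_f = (dC % Cprev) % Fs[s] % (1.0f - Fs[s]);
      fmat da_i = (dC % Cts[s]) % Is[s] % (1.0f - Is[s]);
      fmat da_c = (dC % Is[s]) % (1.0f - arma::square(Cts[s]));
      fmat dA = arma::join_rows(da_i, da_f, da_c, da_o);
      fmat hprev = (s == 0) ? fmat(N, H, arma::fill::zeros) : Hs[s - 1];
      dWx += Xs[s].t() * dA;
      dWh += hprev.t() * dA;
      db += arma::sum(dA, 0);
      fmat dXt = dA * Wx.t();
      int t = idx(s);
      for (int n = 0; n < N; ++n) dX.slice(n).row(t) = dXt.row(n);
      dh = dA * Wh.t();
      dC %= Fs[s];
    }
    return dX;
  }
};

// One direction of a classic GRU: r, z gates then candidate
// h~ = tanh(Whh (r.h_prev) + Whx x + bh);  h = (1-z).h~ + z.h_prev.
struct GruDir {
  int C, H, L;
  bool rev;
  fmat Wx, Wh, b, dWx, dWh, db;  // stacked (r, z, h) blocks
  std::vector<fmat> Xs, Rs, Zs, Hts, Hs, RHs;

  void setup(int Cin, int units, int len, bool reverse) {
    C = Cin; H = units; L = len; rev = reverse;
    Wx.set_size(C, 3 * H); Wh.set_size(H, 3 * H); b.set_size(1, 3 * H);
    dWx.zeros(C, 3 * H); dWh.zeros(H, 3 * H); db.zeros(1, 3 * H);
  }
  void init(std::mt19937& rng) {
    glorot(Wx, C, 3.0 * H, rng);
    glorot(Wh, H, 3.0 * H, rng);
    b.zeros();
  }
  int idx(int s) const { return rev ? L - 1 - s : s; }

  void forward(const fcube& X) {
    int N = X.n_slices;
    Xs.assign(L, fmat()); Rs.assign(L, fmat()); Zs.assign(L, fmat());
    Hts.assign(L, fmat()); Hs.assign(L, fmat()); RHs.assign(L, fmat());
    fmat h(N, H, arma::fill::zeros);
    for (int s = 0; s < L; ++s) {
      int t = idx(s);
      fmat Xt(N, C);
      for (int n = 0; n < N; ++n) Xt.row(n) = X.slice(n).row(t);
      Xs[s] = Xt;
      fmat ar = Xt * Wx.cols(0, H - 1) + h * Wh.cols(0, H - 1);
      ar.each_row() += b.cols(0, H - 1);
      fmat az = Xt * Wx.cols(H, 2 * H - 1) + h * Wh.cols(H, 2 * H - 1);
      az.each_row() += b.cols(H, 2 * H - 1);
      fmat r = sigm(ar), z = sigm(az);
      fmat rh = r % h;
      fmat ah = Xt * Wx.cols(2 * H, 3 * H - 1) + rh * Wh.cols(2 * H, 3 * H - 1);
      ah.each_row() += b.cols(2 * H, 3 * H - 1);
      fmat ht = arma::tanh(ah);
      fmat hn = (1.0f - z) % ht + z % h;
      Rs[s] = r; Zs[s] = z; Hts[s] = ht; RHs[s] = rh; Hs[s] = hn;
      h = hn;
    }
  }
  fcube backward(const std::vector<fmat>& dH, int N) {
    fcube dX(L, C, N, arma::fill::zeros);
    fmat dh(N, H, arma::fill::zeros);
    for (int s = L - 1; s >= 0; --s) {
      dh += dH[s];
      fmat hprev = (s == 0) ? fmat(N, H, arma::fill::zeros) : Hs[s - 1];
      fmat dz = dh % (hprev - Hts[s]);
      fmat da_z = dz % Zs[s] % (1.0f - Zs[s]);
      fmat dht = dh % (1.0f - Zs[s]);
      fmat da_h = dht % (1.0f - arma::square(Hts[s]));
      fmat drh = da_h * Wh.cols(2 * H, 3 * H - 1).t();
      fmat dr = drh % hprev;
      fmat da_r = dr % Rs[s] % (1.0f - Rs[s]);
      dWx.cols(0, H - 1) += Xs[s].t() * da_r;
      dWx.cols(H, 2 * H - 1) += Xs[s].t() * da_z;
      dWx.cols(2 * H, 3 * H - 1) += Xs[s].t() * da_h;
      dWh.cols(0, H - 1) += hprev.t() * da_r;
      dWh.cols(H, 2 * H - 1) += hprev.t() * da_z;
      dWh.cols(2 * H, 3 * H - 1) += RHs[s].t() * da_h;
      db.cols(0, H - 1) += arma::sum(da_r, 0);
      db.cols(H, 2 * H - 1) += arma::sum(da_z, 0);
      db.cols(2 * H, 3 * H - 1) += arma::sum(da_h, 0);
      fmat dXt = da_r * Wx.cols(0, H - 1).t() + da_z * Wx.cols(H, 2 * H - 1).t() +
                 da_h * Wx.cols(2 * H, 3 * H - 1).t();
      int t = idx(s);
      for (int n = 0; n < N; ++n) dX.slice(n).row(t) = dXt.row(n);
      dh = dh % Zs[s] + drh % Rs[s] + da_z * Wh.cols(H, 2 * H - 1).t() +
           da_r * Wh.cols(0, H - 1).t();
    }
    return dX;
  }
};

template <class Dir>
struct BiRnn : Layer {
  int H, L, Cin;
  bool ret_seq;
  Dir fwd, bwd;
  int Ncache = 0;

  BiRnn(const Shape& in, int units, bool return_sequences, const std::string& nm) {
    if (!in.is3d) stop("recurrent layer '%s': input must be sequence-shaped", nm);
    H = units; L = in.L; Cin = in.C; ret_seq = return_sequences; name = nm;
    fwd.setup(Cin, H, L, false);
    bwd.setup(Cin, H, L, true);
    if (ret_seq) out_shape = {true, L, 2 * H, 0};
    else         out_shape = {false, 0, 0, 2 * H};
  }
  void init(std::mt19937& rng) override { fwd.init(rng); bwd.init(rng); }
  std::vector<fmat*> params() override {
    return {&fwd.Wx, &fwd.Wh, &fwd.b, &bwd.Wx, &bwd.Wh, &bwd.b};
  }
  std::vector<fmat*> grads() override {
    return {&fwd.dWx, &fwd.dWh, &fwd.db, &bwd.dWx, &bwd.dWh, &bwd.db};
  }

  Tensor forward(const Tensor& in, bool, std::mt19937&) override {
    int N = in.c.n_slices; Ncache = N;
    fwd.forward(in.c);
    bwd.forward(in.c);
    Tensor out;
    if (ret_seq) {
      out.is3d = true; out.c.set_size(L, 2 * H, N);
      for (int s = 0; s < L; ++s) {
        int tf = fwd.idx(s), tb = bwd.idx(s);
        for (int n = 0; n < N; ++n) {
          for (int hh = 0; hh < H; ++hh) {
            out.c(tf, hh, n) = fwd.Hs[s](n, hh);
            out.c(tb, H + hh, n) = bwd.Hs[s](n, hh);
          }
        }
      }
    } else {
      out.is3d = false;
      out.m = arma::join_rows(fwd.Hs[L - 1], bwd.Hs[L - 1]);
    }
    return out;
  }

  Tensor backward(const Tensor& g) override {
    int N = Ncache;
    std::vector<fmat> dHf(L), dHb(L);
    if (ret_seq) {
      for (int s = 0; s < L; ++s) {
        int tf = fwd.idx(s), tb = bwd.idx(s);
        fmat df(N, H), dbm(N, H);
        for (int n = 0; n < N; ++n)
          for (int hh = 0; hh < H; ++hh) {
            df(n, hh) = g.c(tf, hh, n);
            dbm(n, hh) = g.c(tb, H + hh, n);
          }
        dHf[s] = df; dHb[s] = dbm;
      }
    } else {
      for (int s = 0; s < L; ++s) {
        dHf[s] = fmat(N, H, arma::fill::zeros);
        dHb[s] = fmat(N, H, arma::fill::zeros);
      }
      dHf[L - 1] = g.m.cols(0, H - 1);
      dHb[L - 1] = g.m.cols(H, 2 * H - 1);
    }
    fcube dXf = fwd.backward(dHf, N);
    fcube dXb = bwd.backward(dHb, N);
    Tensor out; out.is3d = true; out.c = dXf + dXb;
    return out;
  }
};

// ----------------------------------------------------------------- Dense ----
struct Dense : Layer {
  int Din, U;
  int act;  // 0 linear, 1 relu, 2 sigmoid
  bool in3d; int Lin, Cin;
  fmat W, b, dW, db;
  fmat Xc, Yc, relu_mask;
  bool grad_is_preact = false;  // training loop sets this on the output layer

  Dense(const Shape& in, int units, int activation, const std::string& nm) {
    Din = in.flat(); U = units; act = activation; name = nm;
    in3d = in.is3d; Lin = in.L; Cin = in.C;
    W.set_size(Din, U); b.set_size(1, U);
    dW.zeros(Din, U); db.zeros(1, U);
    out_shape = {false, 0, 0, U};
  }
  void init(std::mt19937& rng) override { glorot(W, Din, U, rng); b.zeros(); }
  std::vector<fmat*> params() override { return {&W, &b}; }
  std::vector<fmat*> grads() override { return {&dW, &db}; }

  Tensor forward(const Tensor& in, bool, std::mt19937&) override {
    Xc = in.is3d ? flatten_cube(in.c) : in.m;
    fmat Y = Xc * W;
    Y.each_row() += b;
    if (act == 1) { relu_mask = arma::conv_to<fmat>::from(Y > 0.0f); Y %= relu_mask; }
    else if (act == 2) Y = sigm(Y);
    Yc = Y;
    Tensor out; out.is3d = false; out.m = Y;
    return out;
  }
  Tensor backward(const Tensor& g) override {
    fmat dY = g.m;
    if (!grad_is_preact) {
      if (act == 1) dY %= relu_mask;
      else if (act == 2) dY %= Yc % (1.0f - Yc);
    }
    dW += Xc.t() * dY;
    db += arma::sum(dY, 0);
    fmat dX = dY * W.t();
    Tensor out;
    if (in3d) { out.is3d = true; out.c = unflatten_mat(dX, Lin, Cin); }
    else { out.is3d = false; out.m = dX; }
    return out;
  }
};

// --------------------------------------------------------------- Dropout ----
struct Dropout : Layer {
  float rate;
  bool in3d;
  fcube mask3; fmat mask2;
  Dropout(const Shape& in, double r, const std::string& nm) {
    rate = (float)r; in3d = in.is3d; name = nm; out_shape = in;
  }
  Tensor forward(const Tensor& in, bool training, std::mt19937& rng) override {
    Tensor out = in;
    if (!training || rate <= 0.0f) { in3d = in.is3d; return out; }
    in3d = in.is3d;
    std::uniform_real_distribution<float> U(0.0f, 1.0f);
    float keep = 1.0f - rate;
    if (in.is3d) {
      mask3.set_size(arma::size(in.c));
      for (arma::uword i = 0; i < mask3.n_elem; ++i)
        mask3(i) = (U(rng) < keep) ? 1.0f / keep : 0.0f;
      out.c = in.c % mask3;
    } else {
      mask2.set_size(arma::size(in.m));
      for (arma::uword i = 0; i < mask2.n_elem; ++i)
        mask2(i) = (U(rng) < keep) ? 1.0f / keep : 0.0f;
      out.m = in.m % mask2;
    }
    return out;
  }
  Tensor backward(const Tensor& g) override {
    Tensor out = g;
    if (rate <= 0.0f) return out;
    if (g.is3d && mask3.n_elem == g.c.n_elem) out.c = g.c % mask3;
    else if (!g.is3d && mask2.n_elem == g.m.n_elem) out.m = g.m % mask2;
    return out;
  }
};

// ------------------------------------------------------------ Activation ----
struct Activation : Layer {
  int act;  // 1 relu, 2 sigmoid
  fmat m_mask; fcube c_mask; fmat Ym; fcube Yc;
  bool was3d = false;
  Activation(const Shape& in, int a, const std::string& nm) {
    act = a; name = nm; out_shape = in;
  }
  Tensor forward(const Tensor& in, bool, std::mt19937&) override {
    Tensor out = in; was3d = in.is3d;
    if (in.is3d) {
      if (act == 1) { c_mask = arma::conv_to<fcube>::from(in.c > 0.0f); out.c = in.c % c_mask; }
      else { out.c = 1.0f / (1.0f + arma::exp(-in.c)); Yc = out.c; }
    } else {
      if (act == 1) { m_mask = arma::conv_to<fmat>::from(in.m > 0.0f); out.m = in.m % m_mask; }
      else { out.m = sigm(in.m); Ym = out.m; }
    }
    return out;
  }
  Tensor backward(const Tensor& g) override {
    Tensor out = g;
    if (was3d) {
      if (act == 1) out.c = g.c % c_mask;
      else out.c = g.c % Yc % (1.0f - Yc);
    } else {
      if (act == 1) out.m = g.m % m_mask;
      else out.m = g.m % Ym % (1.0f - Ym);
    }
    return out;
  }
};

// --------------------------------------------------------------- Network ----
static int act_code(const std::string& a) {
  if (a == "linear") return 0;
  if (a == "relu") return 1;
  if (a == "sigmoid") return 2;
  stop("unknown activation '%s'", a);
  return -1;
}

struct Network {
  std::vector<std::unique_ptr<Layer>> layers;
  int Lin, Cin;

  Network(List spec, int L, int C) : Lin(L), Cin(C) {
    Shape cur = {true, L, C, 0};
    std::map<std::string, int> counts;
    for (int i = 0; i < spec.size(); ++i) {
      List ls = spec[i];
      std::string kind = as<std::string>(ls["kind"]);
      std::string nm;
      if (kind == "output") nm = "output";
      else nm = kind + "_" + std::to_string(++counts[kind]);
      Layer* lay = nullptr;
      if (kind == "conv1d") {
        int stride = ls.containsElementNamed("stride") ? as<int>(ls["stride"]) : 1;
        std::string a = ls.containsElementNamed("activation")
                            ? as<std::string>(ls["activation"]) : "relu";
        lay = new Conv1D(cur, as<int>(ls["filters"]), as<int>(ls["kernel_size"]),
                         stride, act_code(a) == 1, nm);
      } else if (kind == "maxpool1d") {
        int pool = as<int>(ls["pool_size"]);
        int stride = ls.containsElementNamed("stride") ? as<int>(ls["stride"]) : pool;
        lay = new MaxPool1D(cur, pool, stride, nm);
      } else if (kind == "bilstm") {
        bool rs = ls.containsElementNamed("return_sequences")
                      ? as<bool>(ls["return_sequences"]) : false;
        lay = new BiRnn<LstmDir>(cur, as<int>(ls["units"]), rs, nm);
      } else if (kind == "bigru") {
        bool rs = ls.containsElementNamed("return_sequences")
                      ? as<bool>(ls["return_sequences"]) : false;
        lay = new BiRnn<GruDir>(cur, as<int>(ls["units"]), rs, nm);
      } else if (kind == "dense") {
        std::string a = ls.containsElementNamed("activation")
                            ? as<std::string>(ls["activation"]) : "linear";
        lay = new Dense(cur, as<int>(ls["units"]), act_code(a), nm);
      } else if (kind == "output") {
        lay = new Dense(cur, 1, 2, nm);
      } else if (kind == "dropout") {
        lay = new Dropout(cur, as<double>(ls["rate"]), nm);
      } else if (kind == "activation") {
        std::string a = as<std::string>(ls["fun"]);
        lay = new Activation(cur, act_code(a), nm);
      } else {
        stop("unknown layer kind '%s'", kind);
      }
      cur = lay->out_shape;
      layers.emplace_back(lay);
    }
  }

  std::vector<fmat*> all_params() {
    std::vector<fmat*> out;
    for (auto& l : layers) for (auto p : l->params()) out.push_back(p);
    return out;
  }
  std::vector<fmat*> all_grads() {
    std::vector<fmat*> out;
    for (auto& l : layers) for (auto g : l->grads()) out.push_back(g);
    return out;
  }
  void zero_grads() { for (auto& l : layers) l->zero_grads(); }

  fvec forward_probs(const fcube& X, bool training, std::mt19937& rng) {
    Tensor t; t.is3d = true; t.c = X;
    for (auto& l : layers) t = l->forward(t, training, rng);
    if (t.is3d || t.m.n_cols != 1) stop("network does not end in a 1-unit output");
    return t.m.col(0);
  }
  void backward_from_output_grad(const fmat& G) {
    Tensor t; t.is3d = false; t.m = G;
    for (int i = (int)layers.size() - 1; i >= 0; --i) t = layers[i]->backward(t);
  }
};

// ------------------------------------------------------------ conversions ---
static fcube r_to_cube(NumericVector a) {
  IntegerVector d = a.attr("dim");
  if (d.size() != 3) stop("encoded input must be a 3-d array (N x L x C)");
  int N = d[0], L = d[1], C = d[2];
  fcube X(L, C, N);
  for (int c = 0; c < C; ++c)
    for (int l = 0; l < L; ++l)
      for (int n = 0; n < N; ++n)
        X(l, c, n) = (float)a[n + (size_t)N * l + (size_t)N * L * c];
  return X;
}

static List weights_to_r(Network& net) {
  List out;
  for (auto& l : net.layers) {
    auto ps = l->params();
    if (ps.empty()) continue;
    List wl;
    for (auto p : ps) {
      NumericMatrix M(p->n_rows, p->n_cols);
      for (arma::uword j = 0; j < p->n_cols; ++j)
        for (arma::uword i = 0; i < p->n_rows; ++i) M(i, j) = (*p)(i, j);
      wl.push_back(M);
    }
    out.push_back(wl, l->name);
  }
  return out;
}

static void weights_from_r(Network& net, List weights) {
  for (auto& l : net.layers) {
    auto ps = l->params();
    if (ps.empty()) continue;
    if (!weights.containsElementNamed(l->name.c_str()))
      stop("weights are missing layer '%s'", l->name);
    List wl = weights[l->name];
    if ((int)ps.size() != wl.size())
      stop("layer '%s': expected %d weight matrices, got %d",
           l->name, (int)ps.size(), (int)wl.size());
    for (size_t k = 0; k < ps.size(); ++k) {
      NumericMatrix M = wl[k];
      if ((arma::uword)M.nrow() != ps[k]->n_rows ||
          (arma::uword)M.ncol() != ps[k]->n_cols)
        stop("layer '%s': weight matrix %d has wrong shape", l->name, (int)k + 1);
      for (arma::uword j = 0; j < ps[k]->n_cols; ++j)
        for (arma::uword i = 0; i < ps[k]->n_rows; ++i)
          (*ps[k])(i, j) = (float)M(i, j);
    }
  }
}

static fcube subset_cube(const fcube& X, const std::vector<int>& idx) {
  fcube out(X.n_rows, X.n_cols, idx.size());
  for (size_t i = 0; i < idx.size(); ++i) out.slice(i) = X.slice(idx[i]);
  return out;
}

static double bce(const fvec& p, const fvec& y) {
  double s = 0;
  for (arma::uword i = 0; i < p.n_elem; ++i) {
    double pi = std::min(std::max((double)p(i), 1e-7), 1.0 - 1e-7);
    s += -(y(i) * std::log(pi) + (1.0 - y(i)) * std::log(1.0 - pi));
  }
  return s / p.n_elem;
}

static fvec predict_batched(Network& net, const fcube& X, int batch,
                            std::mt19937& rng) {
  int N = X.n_slices;
  fvec out(N);
  for (int s = 0; s < N; s += batch) {
    int e = std::min(N, s + batch);
    std::vector<int> idx;
    for (int i = s; i < e; ++i) idx.push_back(i);
    fvec p = net.forward_probs(subset_cube(X, idx), false, rng);
    out.subvec(s, e - 1) = p;
  }
  return out;
}

// ------------------------------------------------------------- exports ------

// [[Rcpp::export]]
List nn_init(List spec, IntegerVector input_shape, int seed) {
  Network net(spec, input_shape[0], input_shape[1]);
  std::mt19937 rng(seed);
  for (auto& l : net.layers) l->init(rng);
  return weights_to_r(net);
}

// [[Rcpp::export]]
CharacterVector nn_layer_names(List spec, IntegerVector input_shape) {
  Network net(spec, input_shape[0], input_shape[1]);
  CharacterVector out(net.layers.size());
  for (size_t i = 0; i < net.layers.size(); ++i) out[i] = net.layers[i]->name;
  return out;
}

// [[Rcpp::export]]
List nn_shapes(List spec, IntegerVector input_shape) {
  Network net(spec, input_shape[0], input_shape[1]);
  List out;
  for (auto& l : net.layers) {
    Shape s = l->out_shape;
    if (s.is3d)
      out.push_back(IntegerVector::create(s.L, s.C), l->name);
    else
      out.push_back(IntegerVector::create(s.D), l->name);
  }
  return out;
}

// [[Rcpp::export]]
List nn_train(List spec, IntegerVector input_shape, List weights,
              NumericVector x, NumericVector y,
              NumericVector xval, NumericVector yval,
              int epochs, int batch_size, double lr, int seed,
              bool shuffle, bool verbose,
              NumericVector sample_weights = NumericVector(0)) {
  Network net(spec, input_shape[0], input_shape[1]);
  weights_from_r(net, weights);
  fcube X = r_to_cube(x);
  fvec Y(y.size());
  for (int i = 0; i < y.size(); ++i) Y(i) = (float)y[i];
  bool has_val = xval.size() > 0;
  fcube Xv; fvec Yv;
  if (has_val) {
    Xv = r_to_cube(xval);
    Yv.set_size(yval.size());
    for (int i = 0; i < yval.size(); ++i) Yv(i) = (float)yval[i];
  }
  int N = X.n_slices;
  fvec W(N, arma::fill::ones);
  if (sample_weights.size() == N)
    for (int i = 0; i < N; ++i) W(i) = (float)sample_weights[i];
  std::mt19937 rng(seed);

  // mark the final sigmoid dense layer so BCE gradient enters pre-activation
  Dense* outlayer = dynamic_cast<Dense*>(net.layers.back().get());
  if (outlayer && outlayer->act == 2) outlayer->grad_is_preact = true;

  auto params = net.all_params();
  auto grads = net.all_grads();
  std::vector<fmat> m(params.size()), v(params.size());
  for (size_t i = 0; i < params.size(); ++i) {
    m[i].zeros(arma::size(*params[i]));
    v[i].zeros(arma::size(*params[i]));
  }
  double b1 = 0.9, b2 = 0.999, eps = 1e-7;
  long tstep = 0;

  NumericVector train_loss(epochs), val_loss(epochs);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    if (shuffle) std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0; int ep_n = 0;
    for (int s = 0; s < N; s += batch_size) {
      int e = std::min(N, s + batch_size);
      std::vector<int> idx(order.begin() + s, order.begin() + e);
      fcube Xb = subset_cube(X, idx);
      fvec Yb(e - s);
      for (int i = s; i < e; ++i) Yb(i - s) = Y(order[i]);
      fvec Wb(e - s);
      for (int i = s; i < e; ++i) Wb(i - s) = W(order[i]);
      float wsum = arma::accu(Wb);
      net.zero_grads();
      fvec p = net.forward_probs(Xb, true, rng);
      ep_loss += bce(p, Yb) * (e - s); ep_n += e - s;
      fmat G(e - s, 1);
      for (int i = 0; i < e - s; ++i)
        G(i, 0) = Wb(i) * (p(i) - Yb(i)) / wsum;
      net.backward_from_output_grad(G);
      ++tstep;
      double c1 = 1.0 - std::pow(b1, (double)tstep);
      double c2 = 1.0 - std::pow(b2, (double)tstep);
      for (size_t i = 0; i < params.size(); ++i) {
        m[i] = (float)b1 * m[i] + (float)(1 - b1) * (*grads[i]);
        v[i] = (float)b2 * v[i] + (float)(1 - b2) * arma::square(*grads[i]);
        *params[i] -= (float)(lr / c1) * m[i] /
                      (arma::sqrt(v[i] / (float)c2) + (float)eps);
      }
    }
    train_loss[ep] = ep_loss / ep_n;
    if (has_val) {
      fvec pv = predict_batched(net, Xv, 256, rng);
      val_loss[ep] = bce(pv, Yv);
    } else {
      val_loss[ep] = NA_REAL;
    }
    if (verbose)
      Rcpp::Rcout << "epoch " << (ep + 1) << "/" << epochs
                  << "  train_loss " << train_loss[ep]
                  << (has_val ? "  val_loss " : "")
                  << (has_val ? std::to_string(val_loss[ep]) : std::string())
                  << std::endl;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["weights"] = weights_to_r(net),
                      _["train_loss"] = train_loss,
                      _["val_loss"] = val_loss);
}

// [[Rcpp::export]]
NumericVector nn_predict(List spec, IntegerVector input_shape, List weights,
                         NumericVector x, int batch_size = 256,
                         bool return_logit = false) {
  Network net(spec, input_shape[0], input_shape[1]);
  weights_from_r(net, weights);
  if (return_logit) {
    // emit the output unit's pre-activation; callers apply the sigmoid in
    // double precision, which resolves saturated probabilities
    Dense* outlayer = dynamic_cast<Dense*>(net.layers.back().get());
    if (outlayer && outlayer->act == 2) outlayer->act = 0;
  }
  fcube X = r_to_cube(x);
  std::mt19937 rng(0);
  fvec p = predict_batched(net, X, batch_size, rng);
  NumericVector out(p.n_elem);
  for (arma::uword i = 0; i < p.n_elem; ++i) out[i] = p(i);
  return out;
}

// Flattened output of layer `layer_index` (1-based; 0 = the flattened input).
// [[Rcpp::export]]
NumericMatrix nn_layer_output(List spec, IntegerVector input_shape, List weights,
                              NumericVector x, int layer_index,
                              int batch_size = 256) {
  Network net(spec, input_shape[0], input_shape[1]);
  weights_from_r(net, weights);
  fcube X = r_to_cube(x);
  int N = X.n_slices;
  if (layer_index < 0 || layer_index > (int)net.layers.size())
    stop("layer index out of range");
  std::mt19937 rng(0);
  fmat acc;
  for (int s = 0; s < N; s += batch_size) {
    int e = std::min(N, s + batch_size);
    std::vector<int> idx;
    for (int i = s; i < e; ++i) idx.push_back(i);
    Tensor t; t.is3d = true; t.c = subset_cube(X, idx);
    for (int li = 0; li < layer_index; ++li)
      t = net.layers[li]->forward(t, false, rng);
    fmat flat = t.is3d ? flatten_cube(t.c) : t.m;
    acc = (acc.n_elem == 0) ? flat : arma::join_cols(acc, flat);
  }
  NumericMatrix out(acc.n_rows, acc.n_cols);
  for (arma::uword j = 0; j < acc.n_cols; ++j)
    for (arma::uword i = 0; i < acc.n_rows; ++i) out(i, j) = acc(i, j);
  return out;
}

// Loss and parameter gradients for one full batch (no update); used by the
// finite-difference gradient checks in the test suite.
// [[Rcpp::export]]
List nn_loss_grads(List spec, IntegerVector input_shape, List weights,
                   NumericVector x, NumericVector y) {
  Network net(spec, input_shape[0], input_shape[1]);
  weights_from_r(net, weights);
  fcube X = r_to_cube(x);
  int N = X.n_slices;
  fvec Y(y.size());
  for (int i = 0; i < y.size(); ++i) Y(i) = (float)y[i];
  Dense* outlayer = dynamic_cast<Dense*>(net.layers.back().get());
  if (outlayer && outlayer->act == 2) outlayer->grad_is_preact = true;
  std::mt19937 rng(0);
  net.zero_grads();
  fvec p = net.forward_probs(X, false, rng);
  double loss = bce(p, Y);
  fmat G(N, 1);
  for (int i = 0; i < N; ++i) G(i, 0) = (p(i) - Y(i)) / N;
  net.backward_from_output_grad(G);
  List gl;
  for (auto& l : net.layers) {
    auto gs = l->grads();
    if (gs.empty()) continue;
    List wl;
    for (auto g : gs) {
      NumericMatrix M(g->n_rows, g->n_cols);
      for (arma::uword j = 0; j < g->n_cols; ++j)
        for (arma::uword i = 0; i < g->n_rows; ++i) M(i, j) = (*g)(i, j);
      wl.push_back(M);
    }
    gl.push_back(wl, l->name);
  }
  return List::create(_["loss"] = loss, _["grads"] = gl);
}
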