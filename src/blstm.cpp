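// Stacked bidirectional LSTM with a linear readout at one window
// timestep, trained by minimizing mean-squared error against one-hot
// targets. This file implements the forward pass and full
// backpropagation through time; optimization (Adam) and the training
// loop live in R.
//
// Parameter layout (flat vector): for each layer l = 1..L, for each
// direction (forward, backward): W_x (4H x Din), W_h (4H x H), b (4H);
// then W_out (K x 2H), b_out (K). Din = D for layer 1, else 2H.
// Gate row order within 4H: input, forget, cell, output. Dropout masks
// (variational: one mask per unit per example, shared across time) are
// generated in R and applied to every layer's 2H-dim output.
//
// The input projection W_x * x_t is batched over all timesteps into a
// single GEMM per layer and direction (and likewise for its gradient),
// so only the recurrent H-sized products run inside the time loop.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct Dims {
  int D, H, L, K;
  int din(int l) const { return l == 0 ? D : 2 * H; }
  size_t block(int l, int d) const {
    size_t off = 0;
    for (int ll = 0; ll < l; ++ll)
      off += 2 * ((size_t)4 * H * din(ll) + 4 * H * H + 4 * H);
    off += d * ((size_t)4 * H * din(l) + 4 * H * H + 4 * H);
    return off;
  }
  size_t readout() const { return block(L, 0); }
  size_t total() const { return readout() + (size_t)K * 2 * H + K; }
};

// [[Rcpp::export]]
int cpp_blstm_n_params(int D, int H, int L, int K) {
  Dims dm{D, H, L, K};
  return (int)dm.total();
}

struct LayerCache {
  cube i, f, g, o, c, tc, h;  // each H x B x T
  void init(int H, int B, int T) {
    i.set_size(H, B, T); f.set_size(H, B, T); g.set_size(H, B, T);
    o.set_size(H, B, T); c.set_size(H, B, T); tc.set_size(H, B, T);
    h.set_size(H, B, T);
  }
};

// Workspaces reused across calls (R is single-threaded); set_size is a
// no-op when the shape is unchanged, so repeated same-shape batches
// skip tens of MB of allocation per call.
static std::vector<LayerCache> g_caches;
static std::vector<cube> g_inputs;
static cube g_dout, g_dz;
static std::vector<cube> g_din;

static const mat paramView(const vec& p, size_t off, int nr, int nc) {
  return mat(const_cast<double*>(p.memptr()) + off, nr, nc, false, true);
}

// One direction of one layer over the input cube (Din x B x T).
static void lstm_forward(const vec& params, const Dims& dm, int l, int d,
                         const cube& in, LayerCache& cc) {
  const int H = dm.H, B = in.n_cols, T = in.n_slices, Din = dm.din(l);
  size_t off = dm.block(l, d);
  const mat Wx = paramView(params, off, 4 * H, Din);
  const mat Wh = paramView(params, off + 4 * H * Din, 4 * H, H);
  const mat bm = paramView(params, off + 4 * H * Din + 4 * H * H, 4 * H, 1);
  cc.init(H, B, T);
  const mat inFlat(const_cast<double*>(in.memptr()), Din,
                   (size_t)B * T, false, true);
  mat Zx = Wx * inFlat;          // one GEMM for all timesteps
  Zx.each_col() += bm.col(0);
  mat h = zeros(H, B), c = zeros(H, B), z(4 * H, B);
  for (int step = 0; step < T; ++step) {
    int t = d == 0 ? step : T - 1 - step;
    z = Zx.cols((size_t)t * B, (size_t)t * B + B - 1) + Wh * h;
    // fused gate update, one pass per example column
    double* zp = z.memptr();
    double* ip = cc.i.slice_memptr(t); double* fp = cc.f.slice_memptr(t);
    double* gp = cc.g.slice_memptr(t); double* op = cc.o.slice_memptr(t);
    double* cp = cc.c.slice_memptr(t); double* tp = cc.tc.slice_memptr(t);
    double* hp = cc.h.slice_memptr(t);
    double* cprev = c.memptr(); double* hprev = h.memptr();
    for (int bcol = 0; bcol < B; ++bcol) {
      const double* zc = zp + (size_t)bcol * 4 * H;
      const size_t o0 = (size_t)bcol * H;
      for (int u = 0; u < H; ++u) {
        double gi = 1.0 / (1.0 + std::exp(-zc[u]));
        double gf = 1.0 / (1.0 + std::exp(-zc[H + u]));
        double gg = std::tanh(zc[2 * H + u]);
        double go = 1.0 / (1.0 + std::exp(-zc[3 * H + u]));
        double cn = gf * cprev[o0 + u] + gi * gg;
        double tc = std::tanh(cn);
        ip[o0 + u] = gi; fp[o0 + u] = gf; gp[o0 + u] = gg; op[o0 + u] = go;
        cp[o0 + u] = cn; tp[o0 + u] = tc;
        hp[o0 + u] = go * tc;
      }
    }
    c = cc.c.slice(t);
    h = cc.h.slice(t);
    (void)hprev;
  }
}

// Full forward pass; fills per-layer caches and the (possibly masked)
// inputs each layer actually saw. Returns readout scores K x B.
static mat forward_all(const vec& params, const Dims& dm, const cube& X,
                       int tstar, const cube* masks,
                       std::vector<LayerCache>& caches,
                       std::vector<cube>& inputs) {
  const int H = dm.H, L = dm.L, K = dm.K;
  const int B = X.n_cols, T = X.n_slices;
  caches.resize(2 * L);
  inputs.resize(L + 1);
  inputs[0] = X;
  for (int l = 0; l < L; ++l) {
    lstm_forward(params, dm, l, 0, inputs[l], caches[2 * l]);
    lstm_forward(params, dm, l, 1, inputs[l], caches[2 * l + 1]);
    cube& out = inputs[l + 1];
    out.set_size(2 * H, B, T);
    for (int t = 0; t < T; ++t) {
      out.slice(t).rows(0, H - 1) = caches[2 * l].h.slice(t);
      out.slice(t).rows(H, 2 * H - 1) = caches[2 * l + 1].h.slice(t);
      if (masks) out.slice(t) %= masks->slice(l);
    }
  }
  const mat Wout = paramView(params, dm.readout(), K, 2 * H);
  const mat bout = paramView(params, dm.readout() + (size_t)K * 2 * H, K, 1);
  mat y = Wout * inputs[L].slice(tstar);
  y.each_col() += bout.col(0);
  return y;
}

// [[Rcpp::export]]
arma::mat cpp_blstm_predict(const arma::vec& params, int D, int H, int L,
                            int K, const arma::cube& X, int tstar) {
  Dims dm{D, H, L, K};
  if (params.n_elem != dm.total())
    Rcpp::stop("parameter vector has wrong length");
  return forward_all(params, dm, X, tstar, nullptr, g_caches, g_inputs);
}

// [[Rcpp::export]]
Rcpp::List cpp_blstm_loss_grad(const arma::vec& params, int D, int H,
                               int L, int K, const arma::cube& X,
                               const arma::mat& Y, int tstar,
                               const arma::cube& masks, bool useMasks,
                               bool wantGrad) {
  Dims dm{D, H, L, K};
  if (params.n_elem != dm.total())
    Rcpp::stop("parameter vector has wrong length");
  const int B = X.n_cols, T = X.n_slices;
  std::vector<LayerCache>& caches = g_caches;
  std::vector<cube>& inputs = g_inputs;
  mat yhat = forward_all(params, dm, X, tstar,
                         useMasks ? &masks : nullptr, caches, inputs);
  mat diff = yhat - Y;
  double loss = accu(square(diff)) / ((double)B * K);
  if (!wantGrad)
    return Rcpp::List::create(Rcpp::Named("loss") = loss);

  vec grad(dm.total(), fill::zeros);
  size_t ro = dm.readout();
  const mat Wout = paramView(params, ro, K, 2 * H);
  mat dY = 2.0 * diff / ((double)B * K);
  mat dWout = dY * inputs[L].slice(tstar).t();
  vec dbout = sum(dY, 1);
  std::copy(dWout.memptr(), dWout.memptr() + dWout.n_elem,
            grad.memptr() + ro);
  std::copy(dbout.memptr(), dbout.memptr() + dbout.n_elem,
            grad.memptr() + ro + (size_t)K * 2 * H);

  // gradient w.r.t. each layer's (pre-mask) concatenated output
  cube& dout = g_dout;
  dout.set_size(2 * H, B, T);
  dout.zeros();
  mat dtop = Wout.t() * dY;
  if (useMasks) dtop %= masks.slice(L - 1);
  dout.slice(tstar) = dtop;

  const mat zeroHB = zeros(H, B);
  for (int l = dm.L - 1; l >= 0; --l) {
    const int Din = dm.din(l);
    const mat inFlat(const_cast<double*>(inputs[l].memptr()), Din,
                     (size_t)B * T, false, true);
    if ((int)g_din.size() < dm.L) g_din.resize(dm.L);
    cube& din = g_din[l];
    din.set_size(Din, B, T);
    din.zeros();
    mat dinFlat(din.memptr(), Din, (size_t)B * T, false, true);
    for (int d = 0; d < 2; ++d) {
      LayerCache& cc = caches[2 * l + d];
      size_t off = dm.block(l, d);
      const mat Wx = paramView(params, off, 4 * H, Din);
      const mat Wh = paramView(params, off + 4 * H * Din, 4 * H, H);
      const mat WhT = Wh.t();
      cube& dz = g_dz;
      dz.set_size(4 * H, B, T);
      mat dWh = zeros(4 * H, H);
      mat dh_carry = zeros(H, B), dc_carry = zeros(H, B);
      for (int step = T - 1; step >= 0; --step) {
        int t = d == 0 ? step : T - 1 - step;   // processing order
        bool first = (step == 0);
        int tprev = d == 0 ? t - 1 : t + 1;
        const mat& cprevM = first ? zeroHB : cc.c.slice(tprev);
        const mat& hprev = first ? zeroHB : cc.h.slice(tprev);
        // fused gate-gradient pass
        const double* dop = dout.slice_memptr(t);
        const double* dhc = dh_carry.memptr();
        double* dcc = dc_carry.memptr();
        const double* ip = cc.i.slice_memptr(t);
        const double* fp = cc.f.slice_memptr(t);
        const double* gp = cc.g.slice_memptr(t);
        const double* op = cc.o.slice_memptr(t);
        const double* tp = cc.tc.slice_memptr(t);
        const double* cprev = cprevM.memptr();
        mat dzt(dz.slice_memptr(t), 4 * H, B, false, true);
        double* dzp = dzt.memptr();
        for (int bcol = 0; bcol < B; ++bcol) {
          const size_t o0 = (size_t)bcol * H;
          const double* dob = dop + (size_t)bcol * 2 * H + d * H;
          double* dzb = dzp + (size_t)bcol * 4 * H;
          for (int u = 0; u < H; ++u) {
            double dh = dob[u] + dhc[o0 + u];
            double tc = tp[o0 + u];
            double dc = dcc[o0 + u] + dh * op[o0 + u] * (1.0 - tc * tc);
            double gi = ip[o0 + u], gf = fp[o0 + u];
            double gg = gp[o0 + u], go = op[o0 + u];
            dzb[u] = (dc * gg) * gi * (1.0 - gi);
            dzb[H + u] = (dc * cprev[o0 + u]) * gf * (1.0 - gf);
            dzb[2 * H + u] = (dc * gi) * (1.0 - gg * gg);
            dzb[3 * H + u] = (dh * tc) * go * (1.0 - go);
            dcc[o0 + u] = dc * gf;   // carry for the previous step
          }
        }
        dWh += dzt * hprev.t();
        dh_carry = WhT * dzt;
      }
      const mat dzFlat(dz.memptr(), 4 * H, (size_t)B * T, false, true);
      mat dWx = dzFlat * inFlat.t();           // one GEMM
      dinFlat += Wx.t() * dzFlat;              // one GEMM
      vec db = sum(dzFlat, 1);
      std::copy(dWx.memptr(), dWx.memptr() + dWx.n_elem,
                grad.memptr() + off);
      std::copy(dWh.memptr(), dWh.memptr() + dWh.n_elem,
                grad.memptr() + off + (size_t)4 * H * Din);
      std::copy(db.memptr(), db.memptr() + db.n_elem,
                grad.memptr() + off + (size_t)4 * H * Din +
                (size_t)4 * H * H);
    }
    if (l > 0) {
      for (int t = 0; t < T; ++t) {
        if (useMasks) din.slice(t) %= masks.slice(l - 1);
        dout.slice(t) = din.slice(t);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad);
}
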