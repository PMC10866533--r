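// Single-precision LSTM training engine. Mirrors the R reference
// implementation in R/lstm.R (same architectures, gate layout, training
// protocol); the R code is the readable specification and cross-check,
// this is the production path. Gate column blocks are ordered
// [input | forget | candidate | output]. All randomness comes from R's
// RNG so set.seed() on the R side governs initialization and shuffling.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

enum ActKind { ACT_RELU = 0, ACT_LINEAR = 1, ACT_TANH = 2 };

static inline fmat act_apply(const fmat& x, int act) {
  if (act == ACT_RELU) {
    fmat y = x;
    y.transform([](float v) { return v > 0.f ? v : 0.f; });
    return y;
  }
  if (act == ACT_TANH) return tanh(x);
  return x;
}

// derivative expressed through the activation value
static inline fmat act_deriv(const fmat& a, int act) {
  if (act == ACT_RELU) return conv_to<fmat>::from(a > 0.f);
  if (act == ACT_TANH) return 1.f - square(a);
  return fmat(a.n_rows, a.n_cols, fill::ones);
}

static inline fmat sigm(const fmat& x) { return 1.f / (1.f + exp(-x)); }

struct Cell {
  fmat Wx, Uh, b;          // d x 4H, H x 4H, 1 x 4H
  fmat pi, pf, po;         // 1 x H (peephole only)
  bool peep = false;
  int act = ACT_LINEAR;
  int H = 0, d = 0;
};

struct Layer {
  bool bidir = false;
  Cell f, bw;              // bw used iff bidir
};

struct Net {
  std::vector<Layer> layers;
  fmat Wd, bd;             // state_dim x p, 1 x p
};

struct CellCache {
  fcube GI, GF, GG, GO, CC, AC, HS;  // B x H x T
};

static void collect(Net& n, std::vector<fmat*>& out) {
  for (auto& ly : n.layers) {
    Cell* cs[2] = { &ly.f, ly.bidir ? &ly.bw : nullptr };
    for (Cell* c : cs) {
      if (!c) continue;
      out.push_back(&c->Wx); out.push_back(&c->Uh); out.push_back(&c->b);
      if (c->peep) {
        out.push_back(&c->pi); out.push_back(&c->pf); out.push_back(&c->po);
      }
    }
  }
  out.push_back(&n.Wd); out.push_back(&n.bd);
}

static fmat glorot(int nr, int nc) {
  double lim = std::sqrt(6.0 / (nr + nc));
  fmat m(nr, nc);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i)
      m(i, j) = (float)(R::unif_rand() * 2.0 * lim - lim);
  return m;
}

static Cell init_cell(int d, int H, bool peep, int act) {
  Cell c;
  c.d = d; c.H = H; c.peep = peep; c.act = act;
  // single glorot block split into input and recurrent parts, matching the
  // stacked (d+H) x 4H layout of the R reference
  fmat WU = glorot(d + H, 4 * H);
  c.Wx = WU.rows(0, d - 1);
  c.Uh = WU.rows(d, d + H - 1);
  c.b = fmat(1, 4 * H, fill::zeros);
  c.b.cols(H, 2 * H - 1).fill(1.f);     // open forget gate
  if (peep) {
    c.pi = glorot(1, H) * 0.f; c.pf = c.pi; c.po = c.pi;
    for (int k = 0; k < H; ++k) {
      c.pi(0, k) = (float)(R::unif_rand() * 0.1 - 0.05);
      c.pf(0, k) = (float)(R::unif_rand() * 0.1 - 0.05);
      c.po(0, k) = (float)(R::unif_rand() * 0.1 - 0.05);
    }
  }
  return c;
}

// forward one cell over a sequence; fills cache if given, returns final h
static fmat cell_forward(const Cell& c, const fcube& xs, bool reverse,
                         CellCache* K, fcube* hs_out) {
  const int T = xs.n_slices, B = xs.n_rows, H = c.H;
  fmat h(B, H, fill::zeros), cc(B, H, fill::zeros);
  if (K) {
    K->GI.set_size(B, H, T); K->GF.set_size(B, H, T);
    K->GG.set_size(B, H, T); K->GO.set_size(B, H, T);
    K->CC.set_size(B, H, T); K->AC.set_size(B, H, T);
    K->HS.set_size(B, H, T);
  }
  for (int s = 0; s < T; ++s) {
    const int t = reverse ? T - 1 - s : s;
    fmat z = xs.slice(t) * c.Wx + h * c.Uh;
    z.each_row() += c.b.row(0);
    fmat zi = z.cols(0, H - 1);
    fmat zf = z.cols(H, 2 * H - 1);
    fmat gg = act_apply(z.cols(2 * H, 3 * H - 1), c.act);
    fmat zo = z.cols(3 * H, 4 * H - 1);
    if (c.peep) {
      zi += cc.each_row() % c.pi.row(0);
      zf += cc.each_row() % c.pf.row(0);
    }
    fmat gi = sigm(zi), gf = sigm(zf);
    cc = gf % cc + gi % gg;
    if (c.peep) zo += cc.each_row() % c.po.row(0);
    fmat go = sigm(zo);
    fmat ac = act_apply(cc, c.act);
    h = go % ac;
    if (K) {
      K->GI.slice(t) = gi; K->GF.slice(t) = gf; K->GG.slice(t) = gg;
      K->GO.slice(t) = go; K->CC.slice(t) = cc; K->AC.slice(t) = ac;
      K->HS.slice(t) = h;
    }
    if (hs_out) hs_out->slice(t) = h;
  }
  return h;
}

// BPTT through one cell. dh_seq carries incoming gradients per time slice
// (zeros where none). Returns dx cube if want_dx.
static void cell_backward(const Cell& c, const fcube& xs, const CellCache& K,
                          const fcube& dh_seq, bool reverse, bool want_dx,
                          Cell& g, fcube* dx_out) {
  const int T = xs.n_slices, B = xs.n_rows, H = c.H;
  g.Wx.zeros(c.d, 4 * H); g.Uh.zeros(H, 4 * H); g.b.zeros(1, 4 * H);
  if (c.peep) { g.pi.zeros(1, H); g.pf.zeros(1, H); g.po.zeros(1, H); }
  fmat dh_next(B, H, fill::zeros), dc_next(B, H, fill::zeros);
  fmat WxT = c.Wx.t(), UhT = c.Uh.t();
  fmat dz(B, 4 * H);
  for (int s = T - 1; s >= 0; --s) {
    const int t = reverse ? T - 1 - s : s;
    const int t_prev = reverse ? T - s : s - 1;     // previous processed step
    const bool has_prev = s > 0;
    const fmat& gi = K.GI.slice(t); const fmat& gf = K.GF.slice(t);
    const fmat& gg = K.GG.slice(t); const fmat& go = K.GO.slice(t);
    const fmat& cc = K.CC.slice(t); const fmat& ac = K.AC.slice(t);
    fmat c_prev = has_prev ? K.CC.slice(t_prev) : fmat(B, H, fill::zeros);
    fmat h_prev = has_prev ? K.HS.slice(t_prev) : fmat(B, H, fill::zeros);
    fmat dh = dh_next + dh_seq.slice(t);
    fmat dc = dc_next + dh % go % act_deriv(ac, c.act);
    fmat dzo = (dh % ac) % go % (1.f - go);
    if (c.peep) dc += dzo.each_row() % c.po.row(0);
    fmat dzi = (dc % gg) % gi % (1.f - gi);
    fmat dzf = (dc % c_prev) % gf % (1.f - gf);
    fmat dzg = (dc % gi) % act_deriv(gg, c.act);
    dc_next = dc % gf;
    if (c.peep) {
      dc_next += dzi.each_row() % c.pi.row(0);
      dc_next += dzf.each_row() % c.pf.row(0);
      g.pi += sum(dzi % c_prev, 0);
      g.pf += sum(dzf % c_prev, 0);
      g.po += sum(dzo % cc, 0);
    }
    dz.cols(0, H - 1) = dzi;
    dz.cols(H, 2 * H - 1) = dzf;
    dz.cols(2 * H, 3 * H - 1) = dzg;
    dz.cols(3 * H, 4 * H - 1) = dzo;
    g.Wx += xs.slice(t).t() * dz;
    g.Uh += h_prev.t() * dz;
    g.b += sum(dz, 0);
    if (want_dx) dx_out->slice(t) = dz * WxT;
    dh_next = dz * UhT;
  }
}

struct FwdState {
  std::vector<fcube> inputs;          // input cube per layer
  std::vector<CellCache> cf, cb;      // caches per layer
  fmat state;                         // dense input
  fmat yhat;
};

static void net_forward(const Net& net, const fcube& X, bool train,
                        FwdState& F) {
  const int L = net.layers.size();
  F.inputs.assign(1, X);
  if (train) { F.cf.resize(L); F.cb.resize(L); }
  fmat state;
  for (int l = 0; l < L; ++l) {
    const Layer& ly = net.layers[l];
    const fcube& xs = F.inputs[l];
    const bool last = l == L - 1;
    const int B = xs.n_rows, T = xs.n_slices;
    CellCache* kf = train ? &F.cf[l] : nullptr;
    CellCache* kb = train ? &F.cb[l] : nullptr;
    if (ly.bidir) {
      fcube hsf, hsb;
      fcube* pf = nullptr; fcube* pb = nullptr;
      if (!last || train) {
        hsf.set_size(B, ly.f.H, T); hsb.set_size(B, ly.bw.H, T);
        pf = &hsf; pb = &hsb;
      }
      fmat hf = cell_forward(ly.f, xs, false, kf, pf);
      fmat hb = cell_forward(ly.bw, xs, true, kb, pb);
      state = join_rows(hf, hb);
      if (!last) {
        fcube nx(B, ly.f.H + ly.bw.H, T);
        for (int t = 0; t < T; ++t)
          nx.slice(t) = join_rows(hsf.slice(t), hsb.slice(t));
        F.inputs.push_back(nx);
      }
    } else {
      fcube hs;
      fcube* ph = nullptr;
      if (!last) { hs.set_size(B, ly.f.H, T); ph = &hs; }
      state = cell_forward(ly.f, xs, false, kf, ph);
      if (!last) F.inputs.push_back(hs);
    }
  }
  F.state = state;
  F.yhat = state * net.Wd;
  F.yhat.each_row() += net.bd.row(0);
}

static double net_loss_grads(const Net& net, const fcube& X, const fmat& Y,
                             Net& g) {
  FwdState F;
  net_forward(net, X, true, F);
  const int B = X.n_rows, p = Y.n_cols, L = net.layers.size();
  fmat err = F.yhat - Y;
  double loss = accu(square(err)) / (double)(B * p);
  fmat dy = err * (2.f / (float)(B * p));
  g.Wd = F.state.t() * dy;
  g.bd = sum(dy, 0);
  fmat dstate = dy * net.Wd.t();
  const int T = X.n_slices;
  fcube dh_above;                       // gradient cube for layer below
  for (int l = L - 1; l >= 0; --l) {
    const Layer& ly = net.layers[l];
    const bool last = l == L - 1;
    const fcube& xs = F.inputs[l];
    const int Bx = xs.n_rows;
    const bool want_dx = l > 0;
    fcube dxf, dxb;
    if (ly.bidir) {
      const int H = ly.f.H;
      fcube dh_f(Bx, H, T, fill::zeros), dh_b(Bx, H, T, fill::zeros);
      if (last) {
        dh_f.slice(T - 1) = dstate.cols(0, H - 1);
        dh_b.slice(0) = dstate.cols(H, 2 * H - 1);
      } else {
        for (int t = 0; t < T; ++t) {
          dh_f.slice(t) = dh_above.slice(t).cols(0, H - 1);
          dh_b.slice(t) = dh_above.slice(t).cols(H, 2 * H - 1);
        }
      }
      if (want_dx) {
        dxf.set_size(Bx, ly.f.d, T);
        dxb.set_size(Bx, ly.bw.d, T);
      }
      cell_backward(ly.f, xs, F.cf[l], dh_f, false, want_dx, g.layers[l].f,
                    &dxf);
      cell_backward(ly.bw, xs, F.cb[l], dh_b, true, want_dx, g.layers[l].bw,
                    &dxb);
      if (want_dx) dh_above = dxf + dxb;
    } else {
      fcube dh(Bx, ly.f.H, T, fill::zeros);
      if (last) dh.slice(T - 1) = dstate; else dh = dh_above;
      if (want_dx) dxf.set_size(Bx, ly.f.d, T);
      cell_backward(ly.f, xs, F.cf[l], dh, false, want_dx, g.layers[l].f,
                    &dxf);
      if (want_dx) dh_above = dxf;
    }
  }
  return loss;
}

// ---- construction from R descriptions ---------------------------------

static int act_code(const std::string& s) {
  if (s == "relu") return ACT_RELU;
  if (s == "linear") return ACT_LINEAR;
  if (s == "tanh") return ACT_TANH;
  stop("unknown activation '%s'", s);
}

static Net net_from_arch(List arch, int input_dim, int output_dim,
                         bool init) {
  Net net;
  int d = input_dim;
  for (int l = 0; l < arch.size(); ++l) {
    List ls = arch[l];
    Layer ly;
    ly.bidir = as<bool>(ls["bidirectional"]);
    int H = as<int>(ls["units"]);
    bool peep = as<bool>(ls["peephole"]);
    int act = act_code(as<std::string>(ls["activation"]));
    if (init) {
      ly.f = init_cell(d, H, peep, act);
      if (ly.bidir) ly.bw = init_cell(d, H, peep, act);
    } else {
      ly.f.d = d; ly.f.H = H; ly.f.peep = peep; ly.f.act = act;
      if (ly.bidir) { ly.bw = ly.f; }
    }
    net.layers.push_back(ly);
    d = ly.bidir ? 2 * H : H;
  }
  if (init) {
    net.Wd = glorot(d, output_dim);
    net.bd = fmat(1, output_dim, fill::zeros);
  }
  return net;
}

static NumericMatrix to_r(const fmat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i)
      out(i, j) = m(i, j);
  return out;
}

static fmat from_r(const NumericMatrix& m) {
  fmat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i)
      out(i, j) = (float)m(i, j);
  return out;
}

static List cell_to_r(const Cell& c) {
  // export the stacked (d+H) x 4H layout used by the R reference engine
  fmat WU = join_cols(c.Wx, c.Uh);
  List out = List::create(_["WU"] = to_r(WU),
                          _["b"] = NumericVector(to_r(c.b)));
  if (c.peep) {
    out["pi"] = NumericVector(to_r(c.pi));
    out["pf"] = NumericVector(to_r(c.pf));
    out["po"] = NumericVector(to_r(c.po));
  }
  return out;
}

static void cell_from_r(Cell& c, List par) {
  fmat WU = from_r(as<NumericMatrix>(par["WU"]));
  c.Wx = WU.rows(0, c.d - 1);
  c.Uh = WU.rows(c.d, c.d + c.H - 1);
  NumericVector b = par["b"];
  c.b = fmat(1, b.size());
  for (int i = 0; i < b.size(); ++i) c.b(0, i) = (float)b[i];
  if (c.peep) {
    NumericVector pi = par["pi"], pf = par["pf"], po = par["po"];
    c.pi = fmat(1, pi.size()); c.pf = fmat(1, pf.size());
    c.po = fmat(1, po.size());
    for (int i = 0; i < pi.size(); ++i) {
      c.pi(0, i) = (float)pi[i]; c.pf(0, i) = (float)pf[i];
      c.po(0, i) = (float)po[i];
    }
  }
}

static List net_to_r(const Net& net) {
  List out;
  for (size_t l = 0; l < net.layers.size(); ++l) {
    const Layer& ly = net.layers[l];
    std::string nm = "l" + std::to_string(l + 1);
    if (ly.bidir) {
      out[nm + ".f"] = cell_to_r(ly.f);
      out[nm + ".b"] = cell_to_r(ly.bw);
    } else out[nm] = cell_to_r(ly.f);
  }
  out["dense"] = List::create(_["W"] = to_r(net.Wd),
                              _["b"] = NumericVector(to_r(net.bd)));
  return out;
}

static void net_params_from_r(Net& net, List params) {
  for (size_t l = 0; l < net.layers.size(); ++l) {
    Layer& ly = net.layers[l];
    std::string nm = "l" + std::to_string(l + 1);
    if (ly.bidir) {
      cell_from_r(ly.f, params[nm + ".f"]);
      cell_from_r(ly.bw, params[nm + ".b"]);
    } else cell_from_r(ly.f, params[nm]);
  }
  List dn = params["dense"];
  net.Wd = from_r(as<NumericMatrix>(dn["W"]));
  NumericVector b = dn["b"];
  net.bd = fmat(1, b.size());
  for (int i = 0; i < b.size(); ++i) net.bd(0, i) = (float)b[i];
}

static fcube rows_to_cube(const fmat& X, const uvec& rows) {
  fcube out(rows.n_elem, 1, X.n_cols);
  for (uword t = 0; t < X.n_cols; ++t) {
    fmat col = X.col(t);
    out.slice(t) = col.rows(rows);
  }
  return out;
}

static double eval_mse(const Net& net, const fmat& X, const fmat& Y,
                       int chunk = 4096) {
  const int n = X.n_rows;
  double s = 0.0;
  for (int start = 0; start < n; start += chunk) {
    int end = std::min(n, start + chunk) - 1;
    uvec rows = regspace<uvec>(start, end);
    fcube xc = rows_to_cube(X, rows);
    FwdState F;
    net_forward(net, xc, false, F);
    fmat err = F.yhat - Y.rows(start, end);
    s += accu(square(err));
  }
  return s / ((double)n * Y.n_cols);
}

// [[Rcpp::export]]
List lstm_fit_cpp(List arch, NumericMatrix Xr, NumericMatrix Yr,
                  Nullable<NumericMatrix> Xvr, Nullable<NumericMatrix> Yvr,
                  int output_dim, double lr, int batch_size, int max_epochs,
                  double patience, bool shuffle, double clip_norm) {
  fmat X = from_r(Xr), Y = from_r(Yr);
  bool have_val = Xvr.isNotNull();
  fmat Xv, Yv;
  if (have_val) { Xv = from_r(Xvr.get()); Yv = from_r(Yvr.get()); }

  Net net = net_from_arch(arch, 1, output_dim, true);
  Net g = net_from_arch(arch, 1, output_dim, false);
  g.Wd.zeros(net.Wd.n_rows, net.Wd.n_cols);
  g.bd.zeros(1, net.bd.n_cols);
  Net m = net, v = net;                   // Adam moments, zeroed below
  std::vector<fmat*> pm, pg, pmm, pvv;
  collect(net, pm); collect(g, pg); collect(m, pmm); collect(v, pvv);
  for (auto* q : pmm) q->zeros();
  for (auto* q : pvv) q->zeros();

  const int n = X.n_rows;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;

  Net best = net;
  double best_val = R_PosInf;
  int best_epoch = 0, stall = 0, adam_t = 0;
  std::vector<double> hist_train, hist_val;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    if (shuffle) {
      for (int i = n - 1; i > 0; --i) {
        int j = (int)std::floor(R::unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(ord[i], ord[j]);
      }
    }
    double ep_loss = 0.0; int nb = 0;
    for (int start = 0; start < n; start += batch_size) {
      int end = std::min(n, start + batch_size);
      uvec rows(end - start);
      for (int i = start; i < end; ++i) rows(i - start) = ord[i];
      fcube xb = rows_to_cube(X, rows);
      fmat yb = Y.rows(rows);
      ep_loss += net_loss_grads(net, xb, yb, g);
      ++nb;
      // global-norm clip + Adam step
      double gn2 = 0.0;
      for (auto* q : pg) gn2 += accu(square(*q));
      double gn = std::sqrt(gn2);
      float scale = (std::isfinite(clip_norm) && gn > clip_norm)
                      ? (float)(clip_norm / gn) : 1.f;
      ++adam_t;
      const float c1 = (float)(1.0 - std::pow(b1, adam_t));
      const float c2 = (float)(1.0 - std::pow(b2, adam_t));
      for (size_t k = 0; k < pm.size(); ++k) {
        fmat gk = (*pg[k]) * scale;
        *pmm[k] = (float)b1 * (*pmm[k]) + (float)(1.0 - b1) * gk;
        *pvv[k] = (float)b2 * (*pvv[k]) + (float)(1.0 - b2) * square(gk);
        *pm[k] -= (float)lr * ((*pmm[k]) / c1) / (sqrt((*pvv[k]) / c2) + (float)eps);
      }
    }
    hist_train.push_back(ep_loss / nb);
    if (have_val) {
      double vl = eval_mse(net, Xv, Yv);
      hist_val.push_back(vl);
      if (vl < best_val) {
        best = net; best_val = vl; best_epoch = epoch; stall = 0;
      } else if (++stall >= patience) break;
    } else {
      best = net; best_val = hist_train.back(); best_epoch = epoch;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["params"] = net_to_r(best),
    _["history"] = List::create(_["train"] = hist_train, _["val"] = hist_val),
    _["epochs_run"] = (int)hist_train.size(),
    _["best_epoch"] = best_epoch,
    _["best_val"] = best_val);
}

// loss and gradients for one batch: cross-check hook against the R
// reference engine
// [[Rcpp::export]]
List lstm_grad_cpp(List arch, List params, NumericMatrix Xr,
                   NumericMatrix Yr, int output_dim) {
  fmat X = from_r(Xr), Y = from_r(Yr);
  Net net = net_from_arch(arch, 1, output_dim, false);
  net_params_from_r(net, params);
  Net g = net_from_arch(arch, 1, output_dim, false);
  g.Wd.zeros(net.Wd.n_rows, net.Wd.n_cols);
  g.bd.zeros(1, net.bd.n_cols);
  uvec rows = regspace<uvec>(0, X.n_rows - 1);
  fcube xc = rows_to_cube(X, rows);
  double loss = net_loss_grads(net, xc, Y, g);
  return List::create(_["loss"] = loss, _["grads"] = net_to_r(g));
}

// [[Rcpp::export]]
NumericMatrix lstm_predict_cpp(List arch, List params, NumericMatrix Xr,
                               int output_dim) {
  fmat X = from_r(Xr);
  Net net = net_from_arch(arch, 1, output_dim, false);
  net_params_from_r(net, params);
  const int n = X.n_rows;
  fmat out(n, output_dim);
  const int chunk = 4096;
  for (int start = 0; start < n; start += chunk) {
    int end = std::min(n, start + chunk) - 1;
    uvec rows = regspace<uvec>(start, end);
    fcube xc = rows_to_cube(X, rows);
    FwdState F;
    net_forward(net, xc, false, F);
    out.rows(start, end) = F.yhat;
  }
  return to_r(out);
}
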