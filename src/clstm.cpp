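// Numerical core of the contextual BiLSTM-CRF: coupled input/forget gate
// LSTM cells (the forget coefficient is 1 - i_t), context-window
// concatenation, the full sentence forward/backward pass, and the
// linear-chain CRF (forward algorithm, marginals, Viterbi).
//
// Matrices passed from R are borrowed (no copy); cpp_train_step updates the
// parameter matrices in place, which is why model parameters live in a list
// owned exclusively by the model object on the R side.

#include <RcppArmadillo.h>
#include <map>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Borrowed (no-copy) views over R memory. Relies on C++17 guaranteed copy
// elision so the advanced aux-memory constructor is the one that runs.
static inline mat bmat(SEXP s) {
  Rcpp::NumericMatrix m(s);
  return mat(m.begin(), m.nrow(), m.ncol(), false, true);
}
static inline vec bvec(SEXP s) {
  Rcpp::NumericVector v(s);
  return vec(v.begin(), v.size(), false, true);
}

static inline vec sigmoid(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

// ---------------------------------------------------------------------------
// LSTM parameters / gradients / cache. Gate row order in Wx, Wh, b: input
// gate i, candidate c, output gate o (3H rows total).

struct LstmP {
  mat Wx, Wh, Wci, Wco;
  vec b;
  explicit LstmP(Rcpp::List p)
    : Wx(bmat(p["Wx"])), Wh(bmat(p["Wh"])), Wci(bmat(p["Wci"])),
      Wco(bmat(p["Wco"])), b(bvec(p["b"])) {}
  int H() const { return Wh.n_cols; }
};

struct LstmG {
  mat Wx, Wh, Wci, Wco;
  vec b;
  void init(const LstmP& p) {
    Wx.zeros(p.Wx.n_rows, p.Wx.n_cols);
    Wh.zeros(p.Wh.n_rows, p.Wh.n_cols);
    Wci.zeros(p.Wci.n_rows, p.Wci.n_cols);
    Wco.zeros(p.Wco.n_rows, p.Wco.n_cols);
    b.zeros(p.b.n_elem);
  }
  double sqnorm() const {
    return accu(square(Wx)) + accu(square(Wh)) + accu(square(Wci)) +
           accu(square(Wco)) + accu(square(b));
  }
};

struct LstmCache {
  mat X;                 // input sequence (k x n), already contextualized
  mat I, G, O, C, Th, H; // gate activations, cell, tanh(cell), hidden (H x n)
};

// One step of the coupled-gate cell (Eqs.: i_t with peephole on c_{t-1};
// c_t = (1-i_t) (.) c_{t-1} + i_t (.) tanh(.); o_t with peephole on c_{t-1}).
static void cell_step(const LstmP& p, const vec& x, const vec& h0,
                      const vec& c0, vec& i, vec& g, vec& o, vec& c, vec& h) {
  const int H = p.H();
  vec a = p.Wx * x + p.Wh * h0 + p.b;
  i = sigmoid(a.rows(0, H - 1) + p.Wci * c0);
  g = tanh(a.rows(H, 2 * H - 1));
  c = (1.0 - i) % c0 + i % g;
  o = sigmoid(a.rows(2 * H, 3 * H - 1) + p.Wco * c0);
  h = o % tanh(c);
}

static void lstm_fwd(const LstmP& p, LstmCache& cc) {
  const int H = p.H();
  const int n = cc.X.n_cols;
  cc.I.set_size(H, n); cc.G.set_size(H, n); cc.O.set_size(H, n);
  cc.C.set_size(H, n); cc.Th.set_size(H, n); cc.H.set_size(H, n);
  if (n == 0) return;
  mat A = p.Wx * cc.X;           // batch the input projection
  A.each_col() += p.b;
  vec h(H, fill::zeros), c(H, fill::zeros);
  for (int t = 0; t < n; ++t) {
    vec a = A.col(t) + p.Wh * h;
    vec i = sigmoid(a.rows(0, H - 1) + p.Wci * c);
    vec g = tanh(a.rows(H, 2 * H - 1));
    vec cn = (1.0 - i) % c + i % g;
    vec o = sigmoid(a.rows(2 * H, 3 * H - 1) + p.Wco * c);
    vec th = tanh(cn);
    cc.I.col(t) = i; cc.G.col(t) = g; cc.O.col(t) = o;
    cc.C.col(t) = cn; cc.Th.col(t) = th;
    h = o % th; cc.H.col(t) = h;
    c = cn;
  }
}

// Backward through a (unidirectional) run. dH holds dLoss/dh_t per step in
// the cache's own time order. Returns dLoss/dX; accumulates weight grads.
static mat lstm_bwd(const LstmP& p, const LstmCache& cc, const mat& dH,
                    LstmG& g) {
  const int H = p.H();
  const int n = cc.X.n_cols;
  if (n == 0) return mat(cc.X.n_rows, 0);
  mat DA(3 * H, n);
  vec dh_rec(H, fill::zeros), dc_rec(H, fill::zeros);
  for (int t = n - 1; t >= 0; --t) {
    vec i = cc.I.col(t), gg = cc.G.col(t), o = cc.O.col(t), th = cc.Th.col(t);
    vec cprev = (t > 0) ? vec(cc.C.col(t - 1)) : vec(H, fill::zeros);
    vec dh = dH.col(t) + dh_rec;
    vec dc = dc_rec + dh % o % (1.0 - th % th);
    vec dao = (dh % th) % o % (1.0 - o);
    vec dai = (dc % (gg - cprev)) % i % (1.0 - i);
    vec dac = (dc % i) % (1.0 - gg % gg);
    dc_rec = dc % (1.0 - i) + p.Wci.t() * dai + p.Wco.t() * dao;
    vec da = join_cols(dai, join_cols(dac, dao));
    DA.col(t) = da;
    dh_rec = p.Wh.t() * da;
  }
  mat Hprev(H, n, fill::zeros), Cprev(H, n, fill::zeros);
  if (n > 1) {
    Hprev.cols(1, n - 1) = cc.H.cols(0, n - 2);
    Cprev.cols(1, n - 1) = cc.C.cols(0, n - 2);
  }
  g.Wx += DA * cc.X.t();
  g.Wh += DA * Hprev.t();
  g.Wci += DA.rows(0, H - 1) * Cprev.t();
  g.Wco += DA.rows(2 * H, 3 * H - 1) * Cprev.t();
  g.b += sum(DA, 1);
  return p.Wx.t() * DA;
}

// ---------------------------------------------------------------------------
// Context windows: pad with a shared padding vector, then concatenate the d
// neighboring columns centered at each original position.

static mat padmat(const mat& X, int d, const vec& pad) {
  const int h = d / 2;
  if (h == 0) return X;
  mat out(X.n_rows, X.n_cols + 2 * h);
  for (int j = 0; j < h; ++j) {
    out.col(j) = pad;
    out.col(out.n_cols - 1 - j) = pad;
  }
  if (X.n_cols > 0) out.cols(h, h + X.n_cols - 1) = X;
  return out;
}

static mat ctx(const mat& padded, int d) {
  const int h = d / 2;
  const int k = padded.n_rows;
  const int n = padded.n_cols - 2 * h;
  mat out(d * k, n);
  for (int j = 0; j < d; ++j)
    if (n > 0)
      out.rows(j * k, (j + 1) * k - 1) = padded.cols(j, j + n - 1);
  return out;
}

static mat unctx(const mat& dctx, int d, int k) {
  const int h = d / 2;
  const int n = dctx.n_cols;
  mat dp(k, n + 2 * h, fill::zeros);
  for (int j = 0; j < d; ++j)
    if (n > 0)
      dp.cols(j, j + n - 1) += dctx.rows(j * k, (j + 1) * k - 1);
  return dp;
}

// ---------------------------------------------------------------------------
// Full model.

struct Model {
  mat Ew, Ec;
  vec pad_w, pad_c;
  LstmP cf, cb, wf, wb;
  mat Wproj;
  vec bproj;
  mat T;
  int dw, dc;
  Model(Rcpp::List P, Rcpp::List cfg)
    : Ew(bmat(P["E_word"])), Ec(bmat(P["E_char"])),
      pad_w(bvec(P["pad_word"])), pad_c(bvec(P["pad_char"])),
      cf(P["char_f"]), cb(P["char_b"]), wf(P["word_f"]), wb(P["word_b"]),
      Wproj(bmat(P["W_proj"])), bproj(bvec(P["b_proj"])), T(bmat(P["T"])),
      dw(Rcpp::as<int>(cfg["d_word"])), dc(Rcpp::as<int>(cfg["d_char"])) {}
  int Hc() const { return cf.H(); }
  int Hw() const { return wf.H(); }
  int L() const { return Wproj.n_rows; }
};

struct SentCache {
  std::vector<LstmCache> cfw, cbw; // per-word char runs (cbw on reversed input)
  mat Win;                         // word input after dropout (Dwin x n)
  LstmCache wf, wb;                // word-level runs (wb on reversed input)
  mat H2;                          // 2Hw x n
  mat Pe;                          // L x n emissions
};

static std::vector<ivec> as_ivecs(Rcpp::List chars) {
  std::vector<ivec> out(chars.size());
  for (int i = 0; i < chars.size(); ++i)
    out[i] = Rcpp::as<ivec>(chars[i]);
  return out;
}

static void sentence_forward(const Model& M, const ivec& widx,
                             const std::vector<ivec>& chars,
                             const mat* dropmask, SentCache& S) {
  const int n = widx.n_elem;
  const int Hc = M.Hc(), Dec = M.Ec.n_cols, Dew = M.Ew.n_cols;
  const int Dwin = Dew + 2 * Hc;
  S.cfw.resize(n); S.cbw.resize(n);
  mat crep(2 * Hc, n);
  for (int w = 0; w < n; ++w) {
    const ivec& ci = chars[w];
    const int m = ci.n_elem;
    mat Xc(Dec, m);
    for (int j = 0; j < m; ++j) Xc.col(j) = M.Ec.row(ci[j] - 1).t();
    mat Xctx = ctx(padmat(Xc, M.dc, M.pad_c), M.dc);
    S.cfw[w].X = Xctx;
    lstm_fwd(M.cf, S.cfw[w]);
    S.cbw[w].X = fliplr(Xctx);
    lstm_fwd(M.cb, S.cbw[w]);
    crep.col(w) = join_cols(S.cfw[w].H.col(m - 1), S.cbw[w].H.col(m - 1));
  }
  S.Win.set_size(Dwin, n);
  for (int w = 0; w < n; ++w)
    S.Win.col(w).rows(0, Dew - 1) = M.Ew.row(widx[w] - 1).t();
  if (n > 0) S.Win.rows(Dew, Dwin - 1) = crep;
  if (dropmask) S.Win %= *dropmask;
  mat Wctx = ctx(padmat(S.Win, M.dw, M.pad_w), M.dw);
  S.wf.X = Wctx;
  lstm_fwd(M.wf, S.wf);
  S.wb.X = fliplr(Wctx);
  lstm_fwd(M.wb, S.wb);
  S.H2 = join_cols(S.wf.H, fliplr(S.wb.H));
  S.Pe = M.Wproj * S.H2;
  S.Pe.each_col() += M.bproj;
}

struct Grads {
  LstmG cf, cb, wf, wb;
  mat dWproj, dT;
  vec dbproj, dpad_w, dpad_c;
  std::map<int, vec> dEw, dEc; // sparse embedding-row grads (0-based rows)
  void init(const Model& M) {
    cf.init(M.cf); cb.init(M.cb); wf.init(M.wf); wb.init(M.wb);
    dWproj.zeros(M.Wproj.n_rows, M.Wproj.n_cols);
    dbproj.zeros(M.bproj.n_elem);
    dT.zeros(M.T.n_rows, M.T.n_cols);
    dpad_w.zeros(M.pad_w.n_elem);
    dpad_c.zeros(M.pad_c.n_elem);
  }
  double sqnorm() const {
    double s = cf.sqnorm() + cb.sqnorm() + wf.sqnorm() + wb.sqnorm() +
               accu(square(dWproj)) + accu(square(dbproj)) +
               accu(square(dT)) + accu(square(dpad_w)) + accu(square(dpad_c));
    for (auto& kv : dEw) s += accu(square(kv.second));
    for (auto& kv : dEc) s += accu(square(kv.second));
    return s;
  }
};

static void sentence_backward(const Model& M, const ivec& widx,
                              const std::vector<ivec>& chars,
                              const mat* dropmask, const SentCache& S,
                              const mat& dPe, Grads& G) {
  const int n = widx.n_elem;
  if (n == 0) return;
  const int Hc = M.Hc(), Hw = M.Hw();
  const int Dec = M.Ec.n_cols, Dew = M.Ew.n_cols;
  const int Dwin = Dew + 2 * Hc;
  G.dWproj += dPe * S.H2.t();
  G.dbproj += sum(dPe, 1);
  mat dH2 = M.Wproj.t() * dPe;
  mat dXctx = lstm_bwd(M.wf, S.wf, dH2.rows(0, Hw - 1), G.wf) +
              fliplr(lstm_bwd(M.wb, S.wb, fliplr(dH2.rows(Hw, 2 * Hw - 1)),
                              G.wb));
  mat dWp = unctx(dXctx, M.dw, Dwin);
  const int hw = M.dw / 2;
  for (int j = 0; j < hw; ++j)
    G.dpad_w += dWp.col(j) + dWp.col(dWp.n_cols - 1 - j);
  mat dWin = dWp.cols(hw, hw + n - 1);
  if (dropmask) dWin %= *dropmask;
  for (int w = 0; w < n; ++w) {
    auto it = G.dEw.find(widx[w] - 1);
    if (it == G.dEw.end())
      G.dEw[widx[w] - 1] = vec(dWin.col(w).rows(0, Dew - 1));
    else
      it->second += dWin.col(w).rows(0, Dew - 1);
  }
  const int hc = M.dc / 2;
  for (int w = 0; w < n; ++w) {
    const ivec& ci = chars[w];
    const int m = ci.n_elem;
    mat dHf(Hc, m, fill::zeros), dHb(Hc, m, fill::zeros);
    dHf.col(m - 1) = dWin.col(w).rows(Dew, Dew + Hc - 1);
    dHb.col(m - 1) = dWin.col(w).rows(Dew + Hc, Dwin - 1);
    mat dXc = lstm_bwd(M.cf, S.cfw[w], dHf, G.cf) +
              fliplr(lstm_bwd(M.cb, S.cbw[w], dHb, G.cb));
    mat dXp = unctx(dXc, M.dc, Dec);
    for (int j = 0; j < hc; ++j)
      G.dpad_c += dXp.col(j) + dXp.col(dXp.n_cols - 1 - j);
    for (int j = 0; j < m; ++j) {
      auto it = G.dEc.find(ci[j] - 1);
      if (it == G.dEc.end())
        G.dEc[ci[j] - 1] = vec(dXp.col(hc + j));
      else
        it->second += dXp.col(hc + j);
    }
  }
}

// ---------------------------------------------------------------------------
// Linear-chain CRF. Emissions Pe are L x n (one column per position); T is
// (L+2) x (L+2) with start = row/col L, end = row/col L+1 (0-based).
// Transitions into start and out of end are -Inf masks and never read.

static double lse(const vec& x) {
  double m = x.max();
  if (!std::isfinite(m)) return m;
  return m + std::log(accu(exp(x - m)));
}

static double crf_alpha(const mat& Pe, const mat& T, mat& alpha) {
  const int L = Pe.n_rows, n = Pe.n_cols;
  const int s = L, e = L + 1;
  alpha.set_size(L, n);
  alpha.col(0) = T.submat(s, 0, s, L - 1).t() + Pe.col(0);
  for (int t = 1; t < n; ++t)
    for (int j = 0; j < L; ++j)
      alpha(j, t) = Pe(j, t) + lse(alpha.col(t - 1) + T.submat(0, j, L - 1, j));
  return lse(alpha.col(n - 1) + T.submat(0, e, L - 1, e));
}

static void crf_beta(const mat& Pe, const mat& T, mat& beta) {
  const int L = Pe.n_rows, n = Pe.n_cols;
  const int e = L + 1;
  beta.set_size(L, n);
  beta.col(n - 1) = T.submat(0, e, L - 1, e);
  for (int t = n - 2; t >= 0; --t)
    for (int j = 0; j < L; ++j)
      beta(j, t) = lse(T.submat(j, 0, j, L - 1).t() + Pe.col(t + 1) +
                       beta.col(t + 1));
}

// NLL loss (= logZ - gold path score) and its gradients w.r.t. emissions
// and transitions. gold is 0-based.
static double crf_loss(const mat& Pe, const mat& T, const ivec& gold,
                       mat& dPe, mat& dT) {
  const int L = Pe.n_rows, n = Pe.n_cols;
  const int s = L, e = L + 1;
  mat alpha, beta;
  double logZ = crf_alpha(Pe, T, alpha);
  crf_beta(Pe, T, beta);
  dPe = exp(alpha + beta - logZ);   // unary marginals
  dT.zeros(L + 2, L + 2);
  for (int t = 0; t + 1 < n; ++t)
    for (int i = 0; i < L; ++i)
      for (int j = 0; j < L; ++j)
        dT(i, j) += std::exp(alpha(i, t) + T(i, j) + Pe(j, t + 1) +
                             beta(j, t + 1) - logZ);
  for (int j = 0; j < L; ++j) {
    dT(s, j) += dPe(j, 0);
    dT(j, e) += dPe(j, n - 1);
  }
  // subtract the gold indicator counts
  double score = T(s, gold[0]) + Pe(gold[0], 0);
  dPe(gold[0], 0) -= 1.0;
  dT(s, gold[0]) -= 1.0;
  for (int t = 1; t < n; ++t) {
    score += T(gold[t - 1], gold[t]) + Pe(gold[t], t);
    dPe(gold[t], t) -= 1.0;
    dT(gold[t - 1], gold[t]) -= 1.0;
  }
  score += T(gold[n - 1], e);
  dT(gold[n - 1], e) -= 1.0;
  return logZ - score;
}

// ---------------------------------------------------------------------------
// Exported kernels.

// [[Rcpp::export]]
Rcpp::List cpp_lstm_cell_step(SEXP x, SEXP h, SEXP c, Rcpp::List params) {
  LstmP p(params);
  vec xv = Rcpp::as<vec>(x), hv = Rcpp::as<vec>(h), cv = Rcpp::as<vec>(c);
  vec i, g, o, cn, hn;
  cell_step(p, xv, hv, cv, i, g, o, cn, hn);
  return Rcpp::List::create(Rcpp::Named("h") = hn, Rcpp::Named("c") = cn,
                            Rcpp::Named("i") = i, Rcpp::Named("forget") = 1.0 - i,
                            Rcpp::Named("o") = o);
}

// [[Rcpp::export]]
arma::mat cpp_lstm_run(SEXP X, Rcpp::List params, bool reverse) {
  LstmP p(params);
  LstmCache cc;
  mat Xm = Rcpp::as<mat>(X);
  cc.X = reverse ? mat(fliplr(Xm)) : Xm;
  lstm_fwd(p, cc);
  return reverse ? mat(fliplr(cc.H)) : cc.H;
}

// [[Rcpp::export]]
double cpp_crf_logZ(SEXP P, SEXP T) {
  mat Pe = Rcpp::as<mat>(P).t();
  mat Tm = Rcpp::as<mat>(T);
  mat alpha;
  return crf_alpha(Pe, Tm, alpha);
}

// [[Rcpp::export]]
double cpp_crf_path_score(SEXP P, SEXP T, SEXP y) {
  mat Pe = Rcpp::as<mat>(P).t();
  mat Tm = Rcpp::as<mat>(T);
  ivec yv = Rcpp::as<ivec>(y) - 1;
  const int L = Pe.n_rows, n = Pe.n_cols;
  double s = Tm(L, yv[0]) + Pe(yv[0], 0);
  for (int t = 1; t < n; ++t) s += Tm(yv[t - 1], yv[t]) + Pe(yv[t], t);
  s += Tm(yv[n - 1], L + 1);
  return s;
}

// [[Rcpp::export]]
Rcpp::List cpp_crf_viterbi(SEXP P, SEXP T) {
  mat Pe = Rcpp::as<mat>(P).t();
  mat Tm = Rcpp::as<mat>(T);
  const int L = Pe.n_rows, n = Pe.n_cols;
  const int s = L, e = L + 1;
  mat delta(L, n);
  imat bp(L, n);
  for (int j = 0; j < L; ++j) delta(j, 0) = Tm(s, j) + Pe(j, 0);
  for (int t = 1; t < n; ++t)
    for (int j = 0; j < L; ++j) {
      double best = -datum::inf;
      int arg = 0;
      for (int i = 0; i < L; ++i) {
        double v = delta(i, t - 1) + Tm(i, j);
        if (v > best) { best = v; arg = i; } // ties keep the lowest index
      }
      delta(j, t) = best + Pe(j, t);
      bp(j, t) = arg;
    }
  double best = -datum::inf;
  int arg = 0;
  for (int j = 0; j < L; ++j) {
    double v = delta(j, n - 1) + Tm(j, e);
    if (v > best) { best = v; arg = j; }
  }
  ivec path(n);
  path[n - 1] = arg;
  for (int t = n - 1; t > 0; --t) path[t - 1] = bp(path[t], t);
  return Rcpp::List::create(Rcpp::Named("path") = path + 1,
                            Rcpp::Named("score") = best);
}

// [[Rcpp::export]]
Rcpp::List cpp_crf_marginals(SEXP P, SEXP T) {
  mat Pe = Rcpp::as<mat>(P).t();
  mat Tm = Rcpp::as<mat>(T);
  mat alpha, beta;
  double logZ = crf_alpha(Pe, Tm, alpha);
  crf_beta(Pe, Tm, beta);
  mat marg = exp(alpha + beta - logZ);
  return Rcpp::List::create(Rcpp::Named("logZ") = logZ,
                            Rcpp::Named("unary") = marg.t());
}

// [[Rcpp::export]]
arma::mat cpp_emissions(Rcpp::List params, SEXP word_idx, Rcpp::List char_idx,
                        Rcpp::List cfg) {
  Model M(params, cfg);
  ivec widx = Rcpp::as<ivec>(word_idx);
  if (widx.n_elem == 0) return mat(0, M.L());
  std::vector<ivec> chars = as_ivecs(char_idx);
  SentCache S;
  sentence_forward(M, widx, chars, nullptr, S);
  return S.Pe.t();
}

// [[Rcpp::export]]
arma::vec cpp_char_rep(Rcpp::List params, SEXP char_idx_one, Rcpp::List cfg) {
  Model M(params, cfg);
  ivec ci = Rcpp::as<ivec>(char_idx_one);
  const int m = ci.n_elem, Dec = M.Ec.n_cols;
  mat Xc(Dec, m);
  for (int j = 0; j < m; ++j) Xc.col(j) = M.Ec.row(ci[j] - 1).t();
  mat Xctx = ctx(padmat(Xc, M.dc, M.pad_c), M.dc);
  LstmCache f, b;
  f.X = Xctx; lstm_fwd(M.cf, f);
  b.X = fliplr(Xctx); lstm_fwd(M.cb, b);
  return join_cols(f.H.col(m - 1), b.H.col(m - 1));
}

static Rcpp::List lstm_grads_out(const LstmG& g) {
  return Rcpp::List::create(
      Rcpp::Named("Wx") = g.Wx, Rcpp::Named("Wh") = g.Wh,
      Rcpp::Named("Wci") = g.Wci, Rcpp::Named("Wco") = g.Wco,
      Rcpp::Named("b") = g.b);
}

// Loss and (dense) gradients for one sentence; used by tests and the
// finite-difference gradient check. dropmask may be NULL.
// [[Rcpp::export]]
Rcpp::List cpp_loss_grads(Rcpp::List params, SEXP word_idx, Rcpp::List char_idx,
                          SEXP gold, Rcpp::List cfg, SEXP dropmask) {
  Model M(params, cfg);
  ivec widx = Rcpp::as<ivec>(word_idx);
  std::vector<ivec> chars = as_ivecs(char_idx);
  ivec y = Rcpp::as<ivec>(gold) - 1;
  mat dm;
  const mat* dmp = nullptr;
  if (!Rf_isNull(dropmask)) { dm = Rcpp::as<mat>(dropmask); dmp = &dm; }
  SentCache S;
  sentence_forward(M, widx, chars, dmp, S);
  mat dPe, dT;
  double loss = crf_loss(S.Pe, M.T, y, dPe, dT);
  Grads G;
  G.init(M);
  G.dT = dT;
  sentence_backward(M, widx, chars, dmp, S, dPe, G);
  mat dEw(M.Ew.n_rows, M.Ew.n_cols, fill::zeros);
  for (auto& kv : G.dEw) dEw.row(kv.first) = kv.second.t();
  mat dEc(M.Ec.n_rows, M.Ec.n_cols, fill::zeros);
  for (auto& kv : G.dEc) dEc.row(kv.first) = kv.second.t();
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("E_word") = dEw, Rcpp::Named("E_char") = dEc,
      Rcpp::Named("pad_word") = G.dpad_w, Rcpp::Named("pad_char") = G.dpad_c,
      Rcpp::Named("char_f") = lstm_grads_out(G.cf),
      Rcpp::Named("char_b") = lstm_grads_out(G.cb),
      Rcpp::Named("word_f") = lstm_grads_out(G.wf),
      Rcpp::Named("word_b") = lstm_grads_out(G.wb),
      Rcpp::Named("W_proj") = G.dWproj, Rcpp::Named("b_proj") = G.dbproj,
      Rcpp::Named("T") = dT);
}

static void sgd_lstm(LstmP& p, const LstmG& g, double lr) {
  p.Wx -= lr * g.Wx;
  p.Wh -= lr * g.Wh;
  p.Wci -= lr * g.Wci;
  p.Wco -= lr * g.Wco;
  p.b -= lr * g.b;
}

// One SGD step on one sentence; updates the parameter matrices in place and
// returns the NLL before the update. Gradients are rescaled when their
// global L2 norm exceeds `clip`.
// [[Rcpp::export]]
double cpp_train_step(Rcpp::List params, SEXP word_idx, Rcpp::List char_idx,
                      SEXP gold, Rcpp::List cfg, SEXP dropmask, double lr,
                      double clip) {
  Model M(params, cfg);
  ivec widx = Rcpp::as<ivec>(word_idx);
  std::vector<ivec> chars = as_ivecs(char_idx);
  ivec y = Rcpp::as<ivec>(gold) - 1;
  mat dm;
  const mat* dmp = nullptr;
  if (!Rf_isNull(dropmask)) { dm = Rcpp::as<mat>(dropmask); dmp = &dm; }
  SentCache S;
  sentence_forward(M, widx, chars, dmp, S);
  mat dPe, dT;
  double loss = crf_loss(S.Pe, M.T, y, dPe, dT);
  if (!std::isfinite(loss))
    Rcpp::stop("non-finite training loss");
  Grads G;
  G.init(M);
  G.dT = dT;
  sentence_backward(M, widx, chars, dmp, S, dPe, G);
  double nrm = std::sqrt(G.sqnorm());
  double eff = (clip > 0 && nrm > clip) ? lr * clip / nrm : lr;
  sgd_lstm(M.cf, G.cf, eff);
  sgd_lstm(M.cb, G.cb, eff);
  sgd_lstm(M.wf, G.wf, eff);
  sgd_lstm(M.wb, G.wb, eff);
  M.Wproj -= eff * G.dWproj;
  M.bproj -= eff * G.dbproj;
  M.T -= eff * G.dT;
  M.pad_w -= eff * G.dpad_w;
  M.pad_c -= eff * G.dpad_c;
  for (auto& kv : G.dEw) M.Ew.row(kv.first) -= eff * kv.second.t();
  for (auto& kv : G.dEc) M.Ec.row(kv.first) -= eff * kv.second.t();
  return loss;
}
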