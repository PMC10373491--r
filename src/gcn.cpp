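// Spectral graph-convolution regressor: a single graph-convolution-with-skip
// layer, MinCut-style soft pooling, and a dense readout with an 8-unit
// penultimate layer.  Forward, analytic backward and the Adam training loop
// live here; all shapes are small (N ~ 23 nodes) so everything is dense.
//
// Forward, per graph (X: N x F, At: normalized adjacency N x N):
//   X1 = relu(At * X * Wm + X * Ws + b1)              (N x H)
//   M  = X1 * Wp + bp ; S = row_softmax(M)            (N x K)
//   Xp = S' * X1                                      (K x H)
//   h8 = relu(Wr1' * vec(Xp) + br1)                   (8)
//   yhat = Wr2 . h8 + br2
// Auxiliary pooling losses (D = diag(rowsum(At))):
//   Lc = -tr(S' At S) / tr(S' D S)
//   Lo = || S'S / ||S'S||_F - I_K / sqrt(K) ||_F

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

struct Params {
  mat Wm, Ws, Wp, Wr0, Wr1;
  rowvec b1, bp, br0, br1;
  vec Wr2;
  double br2;
  bool has_hidden() const { return Wr0.n_elem > 0; }
};

static Params params_from_list(const List& l) {
  Params p;
  p.Wm  = Rcpp::as<mat>(l["Wm"]);
  p.Ws  = Rcpp::as<mat>(l["Ws"]);
  p.b1  = Rcpp::as<rowvec>(l["b1"]);
  p.Wp  = Rcpp::as<mat>(l["Wp"]);
  p.bp  = Rcpp::as<rowvec>(l["bp"]);
  if (l.containsElementNamed("Wr0")) {
    p.Wr0 = Rcpp::as<mat>(l["Wr0"]);
    p.br0 = Rcpp::as<rowvec>(l["br0"]);
  }
  p.Wr1 = Rcpp::as<mat>(l["Wr1"]);
  p.br1 = Rcpp::as<rowvec>(l["br1"]);
  p.Wr2 = Rcpp::as<vec>(l["Wr2"]);
  p.br2 = Rcpp::as<double>(l["br2"]);
  return p;
}

static List params_to_list(const Params& p) {
  List out = List::create(
    Named("Wm") = p.Wm, Named("Ws") = p.Ws, Named("b1") = p.b1,
    Named("Wp") = p.Wp, Named("bp") = p.bp,
    Named("Wr1") = p.Wr1, Named("br1") = p.br1,
    Named("Wr2") = p.Wr2, Named("br2") = p.br2);
  if (p.has_hidden()) {
    out["Wr0"] = p.Wr0;
    out["br0"] = p.br0;
  }
  return out;
}

static Params params_zero_like(const Params& p) {
  Params z;
  z.Wm = zeros<mat>(size(p.Wm));   z.Ws = zeros<mat>(size(p.Ws));
  z.b1 = zeros<rowvec>(p.b1.n_elem);
  z.Wp = zeros<mat>(size(p.Wp));   z.bp = zeros<rowvec>(p.bp.n_elem);
  z.Wr0 = zeros<mat>(size(p.Wr0)); z.br0 = zeros<rowvec>(p.br0.n_elem);
  z.Wr1 = zeros<mat>(size(p.Wr1)); z.br1 = zeros<rowvec>(p.br1.n_elem);
  z.Wr2 = zeros<vec>(p.Wr2.n_elem); z.br2 = 0.0;
  return z;
}

static void params_zero(Params& z) {
  z.Wm.zeros(); z.Ws.zeros(); z.b1.zeros();
  z.Wp.zeros(); z.bp.zeros();
  if (z.Wr0.n_elem) { z.Wr0.zeros(); z.br0.zeros(); }
  z.Wr1.zeros(); z.br1.zeros(); z.Wr2.zeros(); z.br2 = 0.0;
}

struct Cache {
  mat AX, Z1, X1, M, S, Xp, G, T;
  vec f;
  rowvec z0, a0, z2, h8;
  double yhat, Lc, Lo, a, bden, g;
  vec d;  // row sums of At
};

static mat row_softmax(const mat& M) {
  mat S = M;
  S.each_col() -= max(M, 1);
  S = exp(S);
  S.each_col() /= sum(S, 1);
  return S;
}

// act: 0 = relu, 1 = identity, 2 = tanh (convolution layer activation)
static void gcn_forward(const mat& X, const mat& At, const Params& p, Cache& c,
                        int act = 0) {
  c.AX = At * X;
  c.Z1 = c.AX * p.Wm + X * p.Ws;
  c.Z1.each_row() += p.b1;
  if (act == 0) c.X1 = clamp(c.Z1, 0.0, datum::inf);
  else if (act == 1) c.X1 = c.Z1;
  else c.X1 = tanh(c.Z1);
  c.M = c.X1 * p.Wp;
  c.M.each_row() += p.bp;
  c.S = row_softmax(c.M);
  c.Xp = c.S.t() * c.X1;
  c.f = vectorise(c.Xp);
  if (p.has_hidden()) {
    c.z0 = c.f.t() * p.Wr0 + p.br0;
    c.a0 = clamp(c.z0, 0.0, datum::inf);
    c.z2 = c.a0 * p.Wr1 + p.br1;
  } else {
    c.z2 = c.f.t() * p.Wr1 + p.br1;
  }
  c.h8 = clamp(c.z2, 0.0, datum::inf);
  c.yhat = dot(c.h8, p.Wr2) + p.br2;
  // auxiliary pooling losses
  c.d = sum(At, 1);
  mat AtS = At * c.S;
  c.a = accu(c.S % AtS);
  mat DS = c.S.each_col() % c.d;
  c.bden = accu(c.S % DS);
  c.Lc = (c.bden > 0) ? (-c.a / c.bden) : 0.0;
  const uword K = c.S.n_cols;
  c.G = c.S.t() * c.S;
  c.g = norm(c.G, "fro");
  c.T = c.G / c.g - eye<mat>(K, K) / std::sqrt((double)K);
  c.Lo = norm(c.T, "fro");
}

// dy = d(loss)/d(yhat); aux_w scales the pooling losses in the objective.
static void gcn_backward(const mat& X, const mat& At, const Params& p,
                         const Cache& c, double dy, double aux_w, Params& g,
                         int act = 0) {
  // readout
  g.Wr2 += dy * c.h8.t();
  g.br2 += dy;
  rowvec dh8 = dy * p.Wr2.t();
  rowvec dz2 = dh8 % conv_to<rowvec>::from(c.z2 > 0);
  vec df;
  if (p.has_hidden()) {
    g.Wr1 += c.a0.t() * dz2;
    g.br1 += dz2;
    rowvec da0 = dz2 * p.Wr1.t();
    rowvec dz0 = da0 % conv_to<rowvec>::from(c.z0 > 0);
    g.Wr0 += c.f * dz0;
    g.br0 += dz0;
    df = p.Wr0 * dz0.t();
  } else {
    g.Wr1 += c.f * dz2;
    g.br1 += dz2;
    df = p.Wr1 * dz2.t();
  }
  mat dXp = reshape(df, c.Xp.n_rows, c.Xp.n_cols);
  // pooling
  mat dX1 = c.S * dXp;
  mat dS = c.X1 * dXp.t();
  if (aux_w != 0.0) {
    // cut loss
    if (c.bden > 0) {
      mat AtS = At * c.S;
      mat DS = c.S.each_col() % c.d;
      dS += aux_w * (-(2.0 * AtS * c.bden - c.a * 2.0 * DS) / (c.bden * c.bden));
    }
    // orthogonality loss
    if (c.Lo > 1e-12) {
      mat U = c.T / c.Lo;
      mat dG = U / c.g - (accu(U % c.G) / (c.g * c.g * c.g)) * c.G;
      dS += aux_w * 2.0 * (c.S * dG);
    }
  }
  // softmax rows
  mat dM(size(dS));
  for (uword i = 0; i < dS.n_rows; ++i) {
    rowvec si = c.S.row(i);
    rowvec di = dS.row(i);
    dM.row(i) = si % (di - dot(di, si));
  }
  dX1 += dM * p.Wp.t();
  g.Wp += c.X1.t() * dM;
  g.bp += sum(dM, 0);
  // convolution
  mat dZ1;
  if (act == 0) dZ1 = dX1 % conv_to<mat>::from(c.Z1 > 0);
  else if (act == 1) dZ1 = dX1;
  else dZ1 = dX1 % (1.0 - square(c.X1));
  g.Wm += c.AX.t() * dZ1;
  g.Ws += X.t() * dZ1;
  g.b1 += sum(dZ1, 0);
}

// [[Rcpp::export]]
List cpp_gcn_forward(const arma::mat& X, const arma::mat& At, const List& params,
                     int act = 0) {
  Params p = params_from_list(params);
  Cache c;
  gcn_forward(X, At, p, c, act);
  return List::create(
    Named("yhat") = c.yhat, Named("h8") = c.h8, Named("S") = c.S,
    Named("Xpool") = c.Xp, Named("Lc") = c.Lc, Named("Lo") = c.Lo);
}

// [[Rcpp::export]]
List cpp_gcn_grads(const arma::mat& X, const arma::mat& At, const List& params,
                   double y, double aux_w, int act = 0) {
  Params p = params_from_list(params);
  Cache c;
  gcn_forward(X, At, p, c, act);
  Params g = params_zero_like(p);
  gcn_backward(X, At, p, c, 2.0 * (c.yhat - y), aux_w, g, act);
  double loss = (c.yhat - y) * (c.yhat - y) + aux_w * (c.Lc + c.Lo);
  List out = params_to_list(g);
  out["loss"] = loss;
  out["yhat"] = c.yhat;
  return out;
}

static void build_X(mat& X, const mat& X0, const umat& occ, const uvec& hot_idx,
                    const mat& props, uword i) {
  X = X0;
  for (uword h = 0; h < hot_idx.n_elem; ++h) {
    X.row(hot_idx(h) - 1) = props.row(occ(i, h) - 1);
  }
}

static double params_grad_norm(const Params& g) {
  double ss = accu(square(g.Wm)) + accu(square(g.Ws)) + accu(square(g.b1)) +
              accu(square(g.Wp)) + accu(square(g.bp)) +
              accu(square(g.Wr1)) + accu(square(g.br1)) +
              accu(square(g.Wr2)) + g.br2 * g.br2;
  if (g.Wr0.n_elem) ss += accu(square(g.Wr0)) + accu(square(g.br0));
  return std::sqrt(ss);
}

static void params_scale(Params& g, double f) {
  g.Wm *= f; g.Ws *= f; g.b1 *= f; g.Wp *= f; g.bp *= f;
  if (g.Wr0.n_elem) { g.Wr0 *= f; g.br0 *= f; }
  g.Wr1 *= f; g.br1 *= f; g.Wr2 *= f; g.br2 *= f;
}

struct Adam {
  Params m, v;
  double b1, b2, eps, lr, wd;
  long t;
  Adam(const Params& p, double lr_, double b1_, double b2_, double eps_,
       double wd_)
    : m(params_zero_like(p)), v(params_zero_like(p)),
      b1(b1_), b2(b2_), eps(eps_), lr(lr_), wd(wd_), t(0) {}
  template <class T>
  void upd(T& w, T& mw, T& vw, const T& gw, double a) {
    mw = b1 * mw + (1.0 - b1) * gw;
    vw = b2 * vw + (1.0 - b2) * (gw % gw);
    w -= a * (mw / (1.0 - std::pow(b1, (double)t))) /
         (sqrt(vw / (1.0 - std::pow(b2, (double)t))) + eps);
  }
  void step(Params& p, const Params& g) {
    ++t;
    double a = lr;
    if (wd > 0) {  // decoupled weight decay on the weight matrices only
      double f = 1.0 - lr * wd;
      p.Wm *= f; p.Ws *= f; p.Wp *= f;
      if (p.has_hidden()) p.Wr0 *= f;
      p.Wr1 *= f; p.Wr2 *= f;
    }
    upd(p.Wm, m.Wm, v.Wm, g.Wm, a);   upd(p.Ws, m.Ws, v.Ws, g.Ws, a);
    upd(p.b1, m.b1, v.b1, g.b1, a);
    upd(p.Wp, m.Wp, v.Wp, g.Wp, a);   upd(p.bp, m.bp, v.bp, g.bp, a);
    if (p.has_hidden()) {
      upd(p.Wr0, m.Wr0, v.Wr0, g.Wr0, a);
      upd(p.br0, m.br0, v.br0, g.br0, a);
    }
    upd(p.Wr1, m.Wr1, v.Wr1, g.Wr1, a); upd(p.br1, m.br1, v.br1, g.br1, a);
    upd(p.Wr2, m.Wr2, v.Wr2, g.Wr2, a);
    // scalar bias
    double mb = m.br2, vb = v.br2;
    mb = b1 * mb + (1.0 - b1) * g.br2;
    vb = b2 * vb + (1.0 - b2) * g.br2 * g.br2;
    m.br2 = mb; v.br2 = vb;
    p.br2 -= a * (mb / (1.0 - std::pow(b1, (double)t))) /
             (std::sqrt(vb / (1.0 - std::pow(b2, (double)t))) + eps);
  }
};

static double eval_mse(const umat& occ, const uvec& hot_idx, const mat& props,
                       const mat& X0, const mat& At, const Params& p,
                       const vec& y, const uvec& idx, int act,
                       vec* preds = nullptr) {
  mat X;
  Cache c;
  double ss = 0.0;
  for (uword k = 0; k < idx.n_elem; ++k) {
    uword i = idx(k) - 1;
    build_X(X, X0, occ, hot_idx, props, i);
    gcn_forward(X, At, p, c, act);
    double r = c.yhat - y(i);
    ss += r * r;
    if (preds) (*preds)(k) = c.yhat;
  }
  return ss / idx.n_elem;
}

// [[Rcpp::export]]
List cpp_gcn_train(const arma::umat& occ, const arma::uvec& hot_idx,
                   const arma::mat& props, const arma::mat& X0,
                   const arma::mat& At, const arma::vec& y,
                   const arma::uvec& train_idx, const arma::uvec& val_idx,
                   const List& params, int epochs, double lr, double beta1,
                   double beta2, double eps, int patience, double aux_w,
                   int seed, double weight_decay, double lr_decay,
                   int swa_start, int act = 0, double clip_norm = 0) {
  Params p = params_from_list(params);
  Adam opt(p, lr, beta1, beta2, eps, weight_decay);
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<uword> order(train_idx.n_elem);
  for (uword k = 0; k < train_idx.n_elem; ++k) order[k] = train_idx(k) - 1;

  Params best = p;
  double best_val = datum::inf;
  int best_epoch = 0, wait = 0, epochs_run = 0;
  std::vector<double> h_train, h_val, h_r2;
  // stochastic weight averaging over epochs >= swa_start (0 = off):
  // validation and the returned weights use the running average
  Params swa = params_zero_like(p);
  long swa_n = 0;

  const bool has_val = val_idx.n_elem > 0;
  double y_val_mean = 0.0, ss_tot = 0.0;
  if (has_val) {
    vec yv(val_idx.n_elem);
    for (uword k = 0; k < val_idx.n_elem; ++k) yv(k) = y(val_idx(k) - 1);
    y_val_mean = mean(yv);
    ss_tot = accu(square(yv - y_val_mean));
  }

  mat X;
  Cache c;
  Params g = params_zero_like(p);
  for (int ep = 1; ep <= epochs; ++ep) {
    opt.lr = lr * std::pow(lr_decay, ep - 1);
    std::shuffle(order.begin(), order.end(), rng);
    double tot = 0.0;
    for (uword k = 0; k < order.size(); ++k) {
      uword i = order[k];
      build_X(X, X0, occ, hot_idx, props, i);
      gcn_forward(X, At, p, c, act);
      params_zero(g);
      gcn_backward(X, At, p, c, 2.0 * (c.yhat - y(i)), aux_w, g, act);
      if (clip_norm > 0) {
        double gn = params_grad_norm(g);
        if (gn > clip_norm) params_scale(g, clip_norm / gn);
      }
      opt.step(p, g);
      double r = c.yhat - y(i);
      tot += r * r + aux_w * (c.Lc + c.Lo);
    }
    epochs_run = ep;
    h_train.push_back(tot / order.size());
    const bool use_swa = swa_start > 0 && ep >= swa_start;
    if (use_swa && swa_n == 0) {
      // restart the early-stopping baseline on the averaged sequence
      best_val = datum::inf;
      wait = 0;
    }
    if (use_swa) {
      double f = 1.0 / (double)(swa_n + 1);
      swa.Wm = swa.Wm * (1 - f) + p.Wm * f;
      swa.Ws = swa.Ws * (1 - f) + p.Ws * f;
      swa.b1 = swa.b1 * (1 - f) + p.b1 * f;
      swa.Wp = swa.Wp * (1 - f) + p.Wp * f;
      swa.bp = swa.bp * (1 - f) + p.bp * f;
      if (p.has_hidden()) {
        swa.Wr0 = swa.Wr0 * (1 - f) + p.Wr0 * f;
        swa.br0 = swa.br0 * (1 - f) + p.br0 * f;
      }
      swa.Wr1 = swa.Wr1 * (1 - f) + p.Wr1 * f;
      swa.br1 = swa.br1 * (1 - f) + p.br1 * f;
      swa.Wr2 = swa.Wr2 * (1 - f) + p.Wr2 * f;
      swa.br2 = swa.br2 * (1 - f) + p.br2 * f;
      ++swa_n;
    }
    const Params& eval_p = use_swa ? swa : p;
    if (has_val) {
      vec preds(val_idx.n_elem);
      double vmse = eval_mse(occ, hot_idx, props, X0, At, eval_p, y, val_idx,
                             act, &preds);
      h_val.push_back(vmse);
      double ss_res = vmse * val_idx.n_elem;
      h_r2.push_back(ss_tot > 0 ? 1.0 - ss_res / ss_tot : NA_REAL);
      if (vmse < best_val - 1e-12) {
        best_val = vmse;
        best = eval_p;
        best_epoch = ep;
        wait = 0;
      } else {
        ++wait;
        if (wait >= patience) break;
      }
    } else {
      h_val.push_back(NA_REAL);
      h_r2.push_back(NA_REAL);
      best = eval_p;
      best_epoch = ep;
    }
  }
  if (has_val) p = best;

  return List::create(
    Named("params") = params_to_list(p),
    Named("train_loss") = h_train,
    Named("val_loss") = h_val,
    Named("val_r2") = h_r2,
    Named("best_epoch") = best_epoch,
    Named("epochs_run") = epochs_run);
}

// [[Rcpp::export]]
List cpp_gcn_predict(const arma::umat& occ, const arma::uvec& hot_idx,
                     const arma::mat& props, const arma::mat& X0,
                     const arma::mat& At, const List& params, int act = 0) {
  Params p = params_from_list(params);
  const uword n = occ.n_rows;
  vec yhat(n);
  mat H8(n, p.br1.n_elem);
  mat X;
  Cache c;
  for (uword i = 0; i < n; ++i) {
    build_X(X, X0, occ, hot_idx, props, i);
    gcn_forward(X, At, p, c, act);
    yhat(i) = c.yhat;
    H8.row(i) = c.h8;
  }
  return List::create(Named("yhat") = yhat, Named("h8") = H8);
}
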