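// Embedding-fusion head: a small 2D-CNN reduces a per-sequence embedding
// matrix [L x D] to an 8-d vector (conv -> pool -> conv -> pool -> dense),
// which is concatenated with the frozen graph model's 8-d penultimate
// vector; a single dense layer maps the 16-d concatenation to the
// prediction.  Only the reducer and head weights are trainable; the graph
// model enters solely through its precomputed penultimate activations.
//
// Pooling uses window `pw` with ceiling partial windows; type 0 = average,
// 1 = max (argmax tracked for backprop).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

struct FParams {
  cube W1;   // 3 x 3 x C1
  vec b1;    // C1
  cube W2;   // 3 x 3 x (C1*C2), slice index c2*C1 + c1
  vec b2;    // C2
  mat Wd;    // flat x 8
  rowvec bd; // 8
  vec Wh;    // 16
  double bh;
};

static FParams fparams_from_list(const List& l) {
  FParams p;
  p.W1 = Rcpp::as<cube>(l["W1"]);
  p.b1 = Rcpp::as<vec>(l["b1"]);
  p.W2 = Rcpp::as<cube>(l["W2"]);
  p.b2 = Rcpp::as<vec>(l["b2"]);
  p.Wd = Rcpp::as<mat>(l["Wd"]);
  p.bd = Rcpp::as<rowvec>(l["bd"]);
  p.Wh = Rcpp::as<vec>(l["Wh"]);
  p.bh = Rcpp::as<double>(l["bh"]);
  return p;
}

static List fparams_to_list(const FParams& p) {
  return List::create(
    Named("W1") = p.W1, Named("b1") = p.b1, Named("W2") = p.W2,
    Named("b2") = p.b2, Named("Wd") = p.Wd, Named("bd") = p.bd,
    Named("Wh") = p.Wh, Named("bh") = p.bh);
}

static FParams fparams_zero_like(const FParams& p) {
  FParams z;
  z.W1 = zeros<cube>(size(p.W1)); z.b1 = zeros<vec>(p.b1.n_elem);
  z.W2 = zeros<cube>(size(p.W2)); z.b2 = zeros<vec>(p.b2.n_elem);
  z.Wd = zeros<mat>(size(p.Wd));  z.bd = zeros<rowvec>(p.bd.n_elem);
  z.Wh = zeros<vec>(p.Wh.n_elem); z.bh = 0.0;
  return z;
}

static mat conv_valid(const mat& X, const mat& K) {
  const uword kr = K.n_rows, kc = K.n_cols;
  const uword R = X.n_rows - kr + 1, C = X.n_cols - kc + 1;
  mat out(R, C, fill::zeros);
  for (uword u = 0; u < kr; ++u)
    for (uword v = 0; v < kc; ++v)
      out += K(u, v) * X.submat(u, v, u + R - 1, v + C - 1);
  return out;
}

// gradient of conv_valid wrt the kernel: corr(X, dOut)
static void conv_kernel_grad(const mat& X, const mat& dOut, mat& dK) {
  const uword R = dOut.n_rows, C = dOut.n_cols;
  for (uword u = 0; u < dK.n_rows; ++u)
    for (uword v = 0; v < dK.n_cols; ++v)
      dK(u, v) += accu(X.submat(u, v, u + R - 1, v + C - 1) % dOut);
}

// gradient of conv_valid wrt the input: full correlation of dOut with K
static void conv_input_grad(mat& dX, const mat& dOut, const mat& K) {
  const uword R = dOut.n_rows, C = dOut.n_cols;
  for (uword u = 0; u < K.n_rows; ++u)
    for (uword v = 0; v < K.n_cols; ++v)
      dX.submat(u, v, u + R - 1, v + C - 1) += K(u, v) * dOut;
}

static uword pooled_dim(uword n, uword pw) { return (n + pw - 1) / pw; }

static void pool_fwd(const mat& A, uword pw, int type, mat& P, umat& argmax) {
  const uword R = pooled_dim(A.n_rows, pw), C = pooled_dim(A.n_cols, pw);
  P.set_size(R, C);
  if (type == 1) argmax.set_size(R, C);
  for (uword r = 0; r < R; ++r) {
    for (uword c = 0; c < C; ++c) {
      uword r0 = r * pw, r1 = std::min(A.n_rows, r0 + pw) - 1;
      uword c0 = c * pw, c1 = std::min(A.n_cols, c0 + pw) - 1;
      mat w = A.submat(r0, c0, r1, c1);
      if (type == 0) {
        P(r, c) = accu(w) / w.n_elem;
      } else {
        uword im = w.index_max();
        P(r, c) = w(im);
        uword wr = im % w.n_rows, wc = im / w.n_rows;
        argmax(r, c) = (r0 + wr) + (c0 + wc) * A.n_rows;
      }
    }
  }
}

static void pool_bwd(mat& dA, const mat& dP, uword pw, int type,
                     const umat& argmax) {
  for (uword r = 0; r < dP.n_rows; ++r) {
    for (uword c = 0; c < dP.n_cols; ++c) {
      uword r0 = r * pw, r1 = std::min(dA.n_rows, r0 + pw) - 1;
      uword c0 = c * pw, c1 = std::min(dA.n_cols, c0 + pw) - 1;
      if (type == 0) {
        double n = (r1 - r0 + 1) * (c1 - c0 + 1);
        dA.submat(r0, c0, r1, c1) += dP(r, c) / n;
      } else {
        dA(argmax(r, c)) += dP(r, c);
      }
    }
  }
}

struct FCache {
  cube Z1, A1, P1, Z2, A2, P2;
  field<umat> am1, am2;
  vec f;
  rowvec r8;
  double yhat;
};

static void fusion_forward(const mat& H, const rowvec& hgcn, const FParams& p,
                           int pool_type, uword pw, FCache& c) {
  const uword C1 = p.b1.n_elem, C2 = p.b2.n_elem;
  const uword R1 = H.n_rows - 2, Q1 = H.n_cols - 2;
  c.Z1.set_size(R1, Q1, C1);
  for (uword k = 0; k < C1; ++k) {
    c.Z1.slice(k) = conv_valid(H, p.W1.slice(k)) + p.b1(k);
  }
  c.A1 = clamp(c.Z1, 0.0, datum::inf);
  const uword PR1 = pooled_dim(R1, pw), PC1 = pooled_dim(Q1, pw);
  c.P1.set_size(PR1, PC1, C1);
  c.am1.set_size(C1);
  for (uword k = 0; k < C1; ++k) {
    mat Pk; umat am;
    pool_fwd(c.A1.slice(k), pw, pool_type, Pk, am);
    c.P1.slice(k) = Pk;
    if (pool_type == 1) c.am1(k) = am;
  }
  const uword R2 = PR1 - 2, Q2 = PC1 - 2;
  c.Z2.set_size(R2, Q2, C2);
  for (uword k2 = 0; k2 < C2; ++k2) {
    mat z(R2, Q2, fill::value(p.b2(k2)));
    for (uword k1 = 0; k1 < C1; ++k1) {
      z += conv_valid(c.P1.slice(k1), p.W2.slice(k2 * C1 + k1));
    }
    c.Z2.slice(k2) = z;
  }
  c.A2 = clamp(c.Z2, 0.0, datum::inf);
  const uword PR2 = pooled_dim(R2, pw), PC2 = pooled_dim(Q2, pw);
  c.P2.set_size(PR2, PC2, C2);
  c.am2.set_size(C2);
  for (uword k = 0; k < C2; ++k) {
    mat Pk; umat am;
    pool_fwd(c.A2.slice(k), pw, pool_type, Pk, am);
    c.P2.slice(k) = Pk;
    if (pool_type == 1) c.am2(k) = am;
  }
  c.f = vectorise(c.P2);
  c.r8 = c.f.t() * p.Wd + p.bd;  // linear reducer output
  double acc = p.bh;
  for (uword j = 0; j < 8; ++j) acc += p.Wh(j) * hgcn(j);
  for (uword j = 0; j < 8; ++j) acc += p.Wh(8 + j) * c.r8(j);
  c.yhat = acc;
}

static void fusion_backward(const mat& H, const rowvec& hgcn, const FParams& p,
                            const FCache& c, int pool_type, uword pw,
                            double dy, FParams& g) {
  const uword C1 = p.b1.n_elem, C2 = p.b2.n_elem;
  for (uword j = 0; j < 8; ++j) {
    g.Wh(j) += dy * hgcn(j);
    g.Wh(8 + j) += dy * c.r8(j);
  }
  g.bh += dy;
  rowvec dr8(8);
  for (uword j = 0; j < 8; ++j) dr8(j) = dy * p.Wh(8 + j);
  g.Wd += c.f * dr8;
  g.bd += dr8;
  vec df = p.Wd * dr8.t();
  cube dP2(size(c.P2));
  std::memcpy(dP2.memptr(), df.memptr(), df.n_elem * sizeof(double));
  cube dA2(size(c.A2), fill::zeros);
  for (uword k = 0; k < C2; ++k) {
    mat dAk(size(c.A2.slice(k)), fill::zeros);
    pool_bwd(dAk, dP2.slice(k), pw, pool_type,
             pool_type == 1 ? c.am2(k) : umat());
    dA2.slice(k) = dAk;
  }
  cube dZ2 = dA2 % conv_to<cube>::from(c.Z2 > 0);
  cube dP1(size(c.P1), fill::zeros);
  for (uword k2 = 0; k2 < C2; ++k2) {
    g.b2(k2) += accu(dZ2.slice(k2));
    for (uword k1 = 0; k1 < C1; ++k1) {
      conv_kernel_grad(c.P1.slice(k1), dZ2.slice(k2), g.W2.slice(k2 * C1 + k1));
      conv_input_grad(dP1.slice(k1), dZ2.slice(k2), p.W2.slice(k2 * C1 + k1));
    }
  }
  cube dA1(size(c.A1), fill::zeros);
  for (uword k = 0; k < C1; ++k) {
    mat dAk(size(c.A1.slice(k)), fill::zeros);
    pool_bwd(dAk, dP1.slice(k), pw, pool_type,
             pool_type == 1 ? c.am1(k) : umat());
    dA1.slice(k) = dAk;
  }
  cube dZ1 = dA1 % conv_to<cube>::from(c.Z1 > 0);
  for (uword k = 0; k < C1; ++k) {
    g.b1(k) += accu(dZ1.slice(k));
    conv_kernel_grad(H, dZ1.slice(k), g.W1.slice(k));
  }
}

// [[Rcpp::export]]
List cpp_fusion_forward(const arma::mat& H, const arma::rowvec& hgcn,
                        const List& params, int pool_type, int pool_window) {
  FParams p = fparams_from_list(params);
  FCache c;
  fusion_forward(H, hgcn, p, pool_type, (uword)pool_window, c);
  return List::create(Named("yhat") = c.yhat, Named("r8") = c.r8);
}

// [[Rcpp::export]]
List cpp_fusion_grads(const arma::mat& H, const arma::rowvec& hgcn,
                      const List& params, double y, int pool_type,
                      int pool_window) {
  FParams p = fparams_from_list(params);
  FCache c;
  fusion_forward(H, hgcn, p, pool_type, (uword)pool_window, c);
  FParams g = fparams_zero_like(p);
  fusion_backward(H, hgcn, p, c, pool_type, (uword)pool_window,
                  2.0 * (c.yhat - y), g);
  List out = fparams_to_list(g);
  out["loss"] = (c.yhat - y) * (c.yhat - y);
  out["yhat"] = c.yhat;
  return out;
}

struct FAdam {
  FParams m, v;
  double b1, b2, eps, lr;
  long t;
  FAdam(const FParams& p, double lr_, double b1_, double b2_, double eps_)
    : m(fparams_zero_like(p)), v(fparams_zero_like(p)),
      b1(b1_), b2(b2_), eps(eps_), lr(lr_), t(0) {}
  template <class T>
  void upd(T& w, T& mw, T& vw, const T& gw) {
    mw = b1 * mw + (1.0 - b1) * gw;
    vw = b2 * vw + (1.0 - b2) * (gw % gw);
    w -= lr * (mw / (1.0 - std::pow(b1, (double)t))) /
         (sqrt(vw / (1.0 - std::pow(b2, (double)t))) + eps);
  }
  void step(FParams& p, const FParams& g) {
    ++t;
    upd(p.W1, m.W1, v.W1, g.W1); upd(p.b1, m.b1, v.b1, g.b1);
    upd(p.W2, m.W2, v.W2, g.W2); upd(p.b2, m.b2, v.b2, g.b2);
    upd(p.Wd, m.Wd, v.Wd, g.Wd); upd(p.bd, m.bd, v.bd, g.bd);
    upd(p.Wh, m.Wh, v.Wh, g.Wh);
    double mb = b1 * m.bh + (1.0 - b1) * g.bh;
    double vb = b2 * v.bh + (1.0 - b2) * g.bh * g.bh;
    m.bh = mb; v.bh = vb;
    p.bh -= lr * (mb / (1.0 - std::pow(b1, (double)t))) /
            (std::sqrt(vb / (1.0 - std::pow(b2, (double)t))) + eps);
  }
};

// [[Rcpp::export]]
List cpp_fusion_train(const arma::cube& Hcube, const arma::mat& Hgcn,
                      const arma::vec& y, const arma::uvec& train_idx,
                      const arma::uvec& val_idx, const List& params,
                      int epochs, double lr, double beta1, double beta2,
                      double eps, int patience, int seed, int pool_type,
                      int pool_window) {
  FParams p = fparams_from_list(params);
  FAdam opt(p, lr, beta1, beta2, eps);
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<uword> order(train_idx.n_elem);
  for (uword k = 0; k < train_idx.n_elem; ++k) order[k] = train_idx(k) - 1;

  FParams best = p;
  double best_val = datum::inf;
  int best_epoch = 0, wait = 0, epochs_run = 0;
  std::vector<double> h_train, h_val;
  FCache c;
  for (int ep = 1; ep <= epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double tot = 0.0;
    for (uword k = 0; k < order.size(); ++k) {
      uword i = order[k];
      fusion_forward(Hcube.slice(i), Hgcn.row(i), p, pool_type,
                     (uword)pool_window, c);
      FParams g = fparams_zero_like(p);
      fusion_backward(Hcube.slice(i), Hgcn.row(i), p, c, pool_type,
                      (uword)pool_window, 2.0 * (c.yhat - y(i)), g);
      opt.step(p, g);
      double r = c.yhat - y(i);
      tot += r * r;
    }
    epochs_run = ep;
    h_train.push_back(tot / order.size());
    if (val_idx.n_elem > 0) {
      double ss = 0.0;
      for (uword k = 0; k < val_idx.n_elem; ++k) {
        uword i = val_idx(k) - 1;
        fusion_forward(Hcube.slice(i), Hgcn.row(i), p, pool_type,
                       (uword)pool_window, c);
        double r = c.yhat - y(i);
        ss += r * r;
      }
      double vmse = ss / val_idx.n_elem;
      h_val.push_back(vmse);
      if (vmse < best_val - 1e-12) {
        best_val = vmse; best = p; best_epoch = ep; wait = 0;
      } else if (++wait >= patience) {
        break;
      }
    } else {
      h_val.push_back(NA_REAL);
      best = p; best_epoch = ep;
    }
  }
  if (val_idx.n_elem > 0) p = best;
  return List::create(
    Named("params") = fparams_to_list(p),
    Named("train_loss") = h_train,
    Named("val_loss") = h_val,
    Named("best_epoch") = best_epoch,
    Named("epochs_run") = epochs_run);
}

// [[Rcpp::export]]
List cpp_fusion_predict(const arma::cube& Hcube, const arma::mat& Hgcn,
                        const List& params, int pool_type, int pool_window) {
  FParams p = fparams_from_list(params);
  const uword n = Hcube.n_slices;
  vec yhat(n);
  mat R8(n, 8);
  FCache c;
  for (uword i = 0; i < n; ++i) {
    fusion_forward(Hcube.slice(i), Hgcn.row(i), p, pool_type,
                   (uword)pool_window, c);
    yhat(i) = c.yhat;
    R8.row(i) = c.r8;
  }
  return List::create(Named("yhat") = yhat, Named("r8") = R8);
}
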