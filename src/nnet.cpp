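// Minimal trainable conv-net engine (3x3 same-padding convs, 2x2 max-pool,
// nearest upsample, sigmoid heads) used for the small_cnn tile classifier and
// the small_unet segmenter. Parameters travel as one flat vector so the R side
// can run a generic Adam loop and numerical gradient checks.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// im2col for a 3x3 convolution with zero padding 1.
// X: H x W x C  ->  (H*W) x (9*C); pixel p = y + H*x (column-major, matches R).
static mat im2col3(const cube &X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  mat out(H * W, 9 * C, fill::zeros);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        double *o = out.colptr(col);
        for (int x = 0; x < W; ++x) {
          const int sx = x + dx;
          if (sx < 0 || sx >= W) continue;
          for (int y = 0; y < H; ++y) {
            const int sy = y + dy;
            if (sy < 0 || sy >= H) continue;
            o[y + H * x] = X(sy, sx, c);
          }
        }
        ++col;
      }
    }
  }
  return out;
}

// Adjoint of im2col3: dcol (H*W) x (9*C) -> dX H x W x C.
static cube col2im3(const mat &dcol, int H, int W, int C) {
  cube dX(H, W, C, fill::zeros);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        const double *o = dcol.colptr(col);
        for (int x = 0; x < W; ++x) {
          const int sx = x + dx;
          if (sx < 0 || sx >= W) continue;
          for (int y = 0; y < H; ++y) {
            const int sy = y + dy;
            if (sy < 0 || sy >= H) continue;
            dX(sy, sx, c) += o[y + H * x];
          }
        }
        ++col;
      }
    }
  }
  return dX;
}

static cube conv3_fwd(const cube &X, const mat &Wm, const rowvec &b) {
  const int H = X.n_rows, W = X.n_cols, Cout = Wm.n_cols;
  mat Y = im2col3(X) * Wm;
  Y.each_row() += b;
  cube out(H, W, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = reshape(Y.col(c), H, W);
  return out;
}

// Backward of conv3: given upstream dY, input X and weights Wm,
// accumulates dW, db and returns dX (skipped when want_dx is false).
static cube conv3_bwd(const cube &X, const mat &Wm, const cube &dY,
                      mat &dW, rowvec &db, bool want_dx) {
  const int H = X.n_rows, W = X.n_cols, Cin = X.n_slices, Cout = dY.n_slices;
  mat dYm(H * W, Cout);
  for (int c = 0; c < Cout; ++c)
    dYm.col(c) = vectorise(dY.slice(c));
  mat Xc = im2col3(X);
  dW += Xc.t() * dYm;
  db += sum(dYm, 0);
  if (!want_dx) return cube();
  return col2im3(dYm * Wm.t(), H, W, Cin);
}

static cube relu(const cube &X) { return clamp(X, 0.0, datum::inf); }

static cube relu_bwd(const cube &A, const cube &dR) {
  cube out = dR;
  out.elem(find(A <= 0)).zeros();
  return out;
}

// 2x2 max pool; records flat argmax indices for the backward pass.
static cube pool2_fwd(const cube &X, ucube &amax) {
  const int H = X.n_rows / 2, W = X.n_cols / 2, C = X.n_slices;
  cube out(H, W, C);
  amax.set_size(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        double best = -datum::inf;
        uword bi = 0;
        for (int dx = 0; dx < 2; ++dx)
          for (int dy = 0; dy < 2; ++dy) {
            const int sy = 2 * y + dy, sx = 2 * x + dx;
            const double v = X(sy, sx, c);
            if (v > best) { best = v; bi = sy + X.n_rows * sx; }
          }
        out(y, x, c) = best;
        amax(y, x, c) = bi;
      }
  return out;
}

static cube pool2_bwd(const cube &dP, const ucube &amax, int H, int W) {
  const int C = dP.n_slices;
  cube dX(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (uword x = 0; x < dP.n_cols; ++x)
      for (uword y = 0; y < dP.n_rows; ++y) {
        const uword bi = amax(y, x, c);
        dX(bi % H, bi / H, c) += dP(y, x, c);
      }
  return dX;
}

static cube upsample2_fwd(const cube &X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  cube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int x = 0; x < 2 * W; ++x)
      for (int y = 0; y < 2 * H; ++y)
        out(y, x, c) = X(y / 2, x / 2, c);
  return out;
}

static cube upsample2_bwd(const cube &dY) {
  const int H = dY.n_rows / 2, W = dY.n_cols / 2, C = dY.n_slices;
  cube dX(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (uword x = 0; x < dY.n_cols; ++x)
      for (uword y = 0; y < dY.n_rows; ++y)
        dX(y / 2, x / 2, c) += dY(y, x, c);
  return dX;
}

static cube concat_c(const cube &A, const cube &B) {
  return join_slices(A, B);
}

// ---- parameter packing -----------------------------------------------------

struct Slices {
  std::vector<uword> off, len;
  uword total = 0;
  void add(uword n) { off.push_back(total); len.push_back(n); total += n; }
};

static Slices cnn_slices(int c1, int c2, int c3) {
  Slices s;
  s.add(27 * c1); s.add(c1);          // W1, b1
  s.add(9 * c1 * c2); s.add(c2);      // W2, b2
  s.add(9 * c2 * c3); s.add(c3);      // W3, b3
  s.add(c3); s.add(1);                // W4, b4
  return s;
}

static Slices unet_slices(int c1, int c2, int c3) {
  Slices s;
  s.add(27 * c1); s.add(c1);                 // enc1
  s.add(9 * c1 * c2); s.add(c2);             // enc2
  s.add(9 * c2 * c3); s.add(c3);             // bottleneck
  s.add(9 * (c3 + c2) * c2); s.add(c2);      // dec2
  s.add(9 * (c2 + c1) * c1); s.add(c1);      // dec1
  s.add(c1); s.add(1);                       // 1x1 head
  return s;
}

static mat getW(const vec &th, const Slices &s, int i, int nrow) {
  return reshape(th.subvec(s.off[i], s.off[i] + s.len[i] - 1), nrow,
                 s.len[i] / nrow);
}
static rowvec getB(const vec &th, const Slices &s, int i) {
  return th.subvec(s.off[i], s.off[i] + s.len[i] - 1).t();
}
static void putW(vec &g, const Slices &s, int i, const mat &dW) {
  g.subvec(s.off[i], s.off[i] + s.len[i] - 1) += vectorise(dW);
}
static void putB(vec &g, const Slices &s, int i, const rowvec &db) {
  g.subvec(s.off[i], s.off[i] + s.len[i] - 1) += db.t();
}

// [[Rcpp::export]]
int cnn_theta_length(int c1, int c2, int c3) {
  return cnn_slices(c1, c2, c3).total;
}

// [[Rcpp::export]]
int unet_theta_length(int c1, int c2, int c3) {
  return unet_slices(c1, c2, c3).total;
}

// ---- small_cnn -------------------------------------------------------------

// Forward pass; when y/w are supplied (backward mode) also computes the
// weighted BCE loss, derives dz internally and accumulates gradients.
static double cnn_forward(const vec &th, const Slices &s, const cube &X,
                          int c1, int c2, int c3,
                          bool backward, double y, double w, double *loss,
                          vec *grad) {
  const mat W1 = getW(th, s, 0, 27);
  const mat W2 = getW(th, s, 2, 9 * c1);
  const mat W3 = getW(th, s, 4, 9 * c2);
  const vec W4 = th.subvec(s.off[6], s.off[6] + c3 - 1);
  const double b4 = th(s.off[7]);

  cube A1 = conv3_fwd(X, W1, getB(th, s, 1));
  cube R1 = relu(A1);
  ucube m1; cube P1 = pool2_fwd(R1, m1);
  cube A2 = conv3_fwd(P1, W2, getB(th, s, 3));
  cube R2 = relu(A2);
  ucube m2; cube P2 = pool2_fwd(R2, m2);
  cube A3 = conv3_fwd(P2, W3, getB(th, s, 5));
  cube R3 = relu(A3);
  const double npix = R3.n_rows * R3.n_cols;
  vec g(c3);
  for (int c = 0; c < c3; ++c) g(c) = accu(R3.slice(c)) / npix;
  const double z = dot(g, W4) + b4;
  if (!backward) return z;

  const double p = 1.0 / (1.0 + std::exp(-z));
  const double eps = 1e-12;
  *loss += -w * (y * std::log(p + eps) + (1 - y) * std::log(1 - p + eps));
  const double dz = w * (p - y);

  // backward
  vec dg = W4 * dz;
  vec dW4 = g * dz;
  grad->subvec(s.off[6], s.off[6] + c3 - 1) += dW4;
  (*grad)(s.off[7]) += dz;
  cube dR3(R3.n_rows, R3.n_cols, c3);
  for (int c = 0; c < c3; ++c) dR3.slice(c).fill(dg(c) / npix);
  cube dA3 = relu_bwd(A3, dR3);
  mat dW3(9 * c2, c3, fill::zeros); rowvec db3(c3, fill::zeros);
  cube dP2 = conv3_bwd(P2, W3, dA3, dW3, db3, true);
  cube dR2 = pool2_bwd(dP2, m2, R2.n_rows, R2.n_cols);
  cube dA2 = relu_bwd(A2, dR2);
  mat dW2(9 * c1, c2, fill::zeros); rowvec db2(c2, fill::zeros);
  cube dP1 = conv3_bwd(P1, W2, dA2, dW2, db2, true);
  cube dR1 = pool2_bwd(dP1, m1, R1.n_rows, R1.n_cols);
  cube dA1 = relu_bwd(A1, dR1);
  mat dW1(27, c1, fill::zeros); rowvec db1(c1, fill::zeros);
  conv3_bwd(X, W1, dA1, dW1, db1, false);
  putW(*grad, s, 0, dW1); putB(*grad, s, 1, db1);
  putW(*grad, s, 2, dW2); putB(*grad, s, 3, db2);
  putW(*grad, s, 4, dW3); putB(*grad, s, 5, db3);
  return z;
}

// Weighted binary cross-entropy loss + gradient over a batch of tiles.
// Xlist: list of H x W x 3 arrays; y in {0,1}; wts per-sample weights.
// [[Rcpp::export]]
Rcpp::List cnn_loss_grad(const arma::vec &theta, Rcpp::List Xlist,
                         const arma::vec &y, const arma::vec &wts,
                         int c1, int c2, int c3) {
  Slices s = cnn_slices(c1, c2, c3);
  vec grad(s.total, fill::zeros);
  double loss = 0, wsum = accu(wts);
  const int n = Xlist.size();
  for (int i = 0; i < n; ++i) {
    cube X = Rcpp::as<cube>(Xlist[i]);
    cnn_forward(theta, s, X, c1, c2, c3, true, y(i), wts(i), &loss, &grad);
  }
  loss /= wsum;
  grad /= wsum;
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad);
}

// [[Rcpp::export]]
arma::vec cnn_predict_cpp(const arma::vec &theta, Rcpp::List Xlist,
                          int c1, int c2, int c3) {
  Slices s = cnn_slices(c1, c2, c3);
  const int n = Xlist.size();
  vec out(n);
  for (int i = 0; i < n; ++i) {
    cube X = Rcpp::as<cube>(Xlist[i]);
    double z = cnn_forward(theta, s, X, c1, c2, c3, false, 0, 0, nullptr,
                           nullptr);
    out(i) = 1.0 / (1.0 + std::exp(-z));
  }
  return out;
}

// ---- small_unet ------------------------------------------------------------

// Forward pass; in backward mode (M supplied) computes the weighted
// per-pixel BCE loss against mask M, derives dZ internally (scaled by the
// caller's total weight wsum) and accumulates gradients.
static mat unet_forward(const vec &th, const Slices &s, const cube &X,
                        int c1, int c2, int c3,
                        bool backward, const mat *M, double wpos, double wsum,
                        double *loss, vec *grad) {
  const int H = X.n_rows, W = X.n_cols;
  const mat W1 = getW(th, s, 0, 27);
  const mat W2 = getW(th, s, 2, 9 * c1);
  const mat W3 = getW(th, s, 4, 9 * c2);
  const mat Wd2 = getW(th, s, 6, 9 * (c3 + c2));
  const mat Wd1 = getW(th, s, 8, 9 * (c2 + c1));
  const vec Wo = th.subvec(s.off[10], s.off[10] + c1 - 1);
  const double bo = th(s.off[11]);

  cube A1 = conv3_fwd(X, W1, getB(th, s, 1));
  cube E1 = relu(A1);
  ucube m1; cube P1 = pool2_fwd(E1, m1);
  cube A2 = conv3_fwd(P1, W2, getB(th, s, 3));
  cube E2 = relu(A2);
  ucube m2; cube P2 = pool2_fwd(E2, m2);
  cube A3 = conv3_fwd(P2, W3, getB(th, s, 5));
  cube BN = relu(A3);
  cube U2 = upsample2_fwd(BN);
  cube C2 = concat_c(U2, E2);
  cube Ad2 = conv3_fwd(C2, Wd2, getB(th, s, 7));
  cube D2 = relu(Ad2);
  cube U1 = upsample2_fwd(D2);
  cube C1 = concat_c(U1, E1);
  cube Ad1 = conv3_fwd(C1, Wd1, getB(th, s, 9));
  cube D1 = relu(Ad1);
  mat Z(H, W, fill::zeros);
  for (int c = 0; c < c1; ++c) Z += Wo(c) * D1.slice(c);
  Z += bo;
  if (!backward) return Z;

  const double eps = 1e-12;
  mat P = 1.0 / (1.0 + exp(-Z));
  mat Wt = (*M) * wpos + (1.0 - *M);
  *loss += accu(-Wt % ((*M) % log(P + eps) +
                       (1.0 - *M) % log(1.0 - P + eps)));
  mat dZ = (Wt % (P - *M)) / wsum;

  cube dD1(H, W, c1);
  vec dWo(c1);
  for (int c = 0; c < c1; ++c) {
    dD1.slice(c) = dZ * Wo(c);
    dWo(c) = accu(dZ % D1.slice(c));
  }
  grad->subvec(s.off[10], s.off[10] + c1 - 1) += dWo;
  (*grad)(s.off[11]) += accu(dZ);
  cube dAd1 = relu_bwd(Ad1, dD1);
  mat dWd1(9 * (c2 + c1), c1, fill::zeros); rowvec dbd1(c1, fill::zeros);
  cube dC1 = conv3_bwd(C1, Wd1, dAd1, dWd1, dbd1, true);
  cube dU1 = dC1.slices(0, c2 - 1);
  cube dE1a = dC1.slices(c2, c2 + c1 - 1);
  cube dD2 = upsample2_bwd(dU1);
  cube dAd2 = relu_bwd(Ad2, dD2);
  mat dWd2(9 * (c3 + c2), c2, fill::zeros); rowvec dbd2(c2, fill::zeros);
  cube dC2 = conv3_bwd(C2, Wd2, dAd2, dWd2, dbd2, true);
  cube dU2 = dC2.slices(0, c3 - 1);
  cube dE2a = dC2.slices(c3, c3 + c2 - 1);
  cube dBN = upsample2_bwd(dU2);
  cube dA3 = relu_bwd(A3, dBN);
  mat dW3(9 * c2, c3, fill::zeros); rowvec db3(c3, fill::zeros);
  cube dP2 = conv3_bwd(P2, W3, dA3, dW3, db3, true);
  cube dE2 = pool2_bwd(dP2, m2, E2.n_rows, E2.n_cols) + dE2a;
  cube dA2 = relu_bwd(A2, dE2);
  mat dW2(9 * c1, c2, fill::zeros); rowvec db2(c2, fill::zeros);
  cube dP1 = conv3_bwd(P1, W2, dA2, dW2, db2, true);
  cube dE1 = pool2_bwd(dP1, m1, E1.n_rows, E1.n_cols) + dE1a;
  cube dA1 = relu_bwd(A1, dE1);
  mat dW1(27, c1, fill::zeros); rowvec db1(c1, fill::zeros);
  conv3_bwd(X, W1, dA1, dW1, db1, false);
  putW(*grad, s, 0, dW1); putB(*grad, s, 1, db1);
  putW(*grad, s, 2, dW2); putB(*grad, s, 3, db2);
  putW(*grad, s, 4, dW3); putB(*grad, s, 5, db3);
  putW(*grad, s, 6, dWd2); putB(*grad, s, 7, dbd2);
  putW(*grad, s, 8, dWd1); putB(*grad, s, 9, dbd1);
  return Z;
}

// Per-pixel weighted BCE over a batch; Mlist are 0/1 masks (H x W matrices),
// positive pixels weighted wpos. Loss normalized by total pixel weight.
// [[Rcpp::export]]
Rcpp::List unet_loss_grad(const arma::vec &theta, Rcpp::List Xlist,
                          Rcpp::List Mlist, double wpos,
                          int c1, int c2, int c3) {
  Slices s = unet_slices(c1, c2, c3);
  vec grad(s.total, fill::zeros);
  double loss = 0, wsum = 0;
  const int n = Xlist.size();
  // first pass to get total weight (needed to scale gradients consistently)
  for (int i = 0; i < n; ++i) {
    mat M = Rcpp::as<mat>(Mlist[i]);
    wsum += accu(M) * wpos + (M.n_elem - accu(M));
  }
  for (int i = 0; i < n; ++i) {
    cube X = Rcpp::as<cube>(Xlist[i]);
    mat M = Rcpp::as<mat>(Mlist[i]);
    unet_forward(theta, s, X, c1, c2, c3, true, &M, wpos, wsum, &loss,
                 &grad);
  }
  loss /= wsum;
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad);
}

// [[Rcpp::export]]
Rcpp::List unet_predict_cpp(const arma::vec &theta, Rcpp::List Xlist,
                            int c1, int c2, int c3) {
  Slices s = unet_slices(c1, c2, c3);
  const int n = Xlist.size();
  Rcpp::List out(n);
  for (int i = 0; i < n; ++i) {
    cube X = Rcpp::as<cube>(Xlist[i]);
    mat Z = unet_forward(theta, s, X, c1, c2, c3, false, nullptr, 0, 0,
                         nullptr, nullptr);
    out[i] = Rcpp::wrap(mat(1.0 / (1.0 + exp(-Z))));
  }
  return out;
}
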