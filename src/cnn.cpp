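// Convolutional network for fixed-size sensor windows (T x C single-channel
// grids): conv(same padding, leaky ReLU) x3 with two 2x1 time max-pools,
// dense + dropout, softmax head, categorical cross-entropy, Adam.
//
// Layer activations are kept as (N*P) x channels matrices (P = T*C output
// positions per sample, position index t + T*c, samples stacked in blocks)
// so each convolution is a single im2col gather plus one BLAS matmul over
// the whole mini-batch. All randomness (shuffling, dropout) is drawn from
// R's RNG so that set.seed() in R fully determines training.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Gather the same-padded sliding-window view of one sample block.
// src rows [srow, srow + T*C) of A (channel per column) are read; dst rows
// [drow, drow + T*C) of col are written, columns (dt, dc, ch)-major.
static void im2col_block(const mat& A, uword srow, int T, int C,
                         int kh, int kw, mat& col, uword drow) {
  const int Cin = A.n_cols;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int ch = 0; ch < Cin; ++ch)
    for (int dc = 0; dc < kw; ++dc)
      for (int dt = 0; dt < kh; ++dt) {
        const int j = dt + kh * (dc + kw * ch);
        double* dst = col.colptr(j) + drow;
        const double* src = A.colptr(ch) + srow;
        for (int c = 0; c < C; ++c) {
          const int cc = c + dc - pw;
          if (cc < 0 || cc >= C) continue;
          const int t0 = std::max(0, ph - dt), t1 = std::min(T, T + ph - dt);
          const double* s = src + cc * T + (t0 + dt - ph);
          double* d = dst + c * T + t0;
          std::copy(s, s + (t1 - t0), d);
        }
      }
}

// Scatter-add adjoint of im2col_block.
static void col2im_block(const mat& dcol, uword drow, int T, int C,
                         int kh, int kw, mat& dA, uword srow) {
  const int Cin = dA.n_cols;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int ch = 0; ch < Cin; ++ch)
    for (int dc = 0; dc < kw; ++dc)
      for (int dt = 0; dt < kh; ++dt) {
        const int j = dt + kh * (dc + kw * ch);
        const double* src = dcol.colptr(j) + drow;
        double* dst = dA.colptr(ch) + srow;
        for (int c = 0; c < C; ++c) {
          const int cc = c + dc - pw;
          if (cc < 0 || cc >= C) continue;
          const int t0 = std::max(0, ph - dt), t1 = std::min(T, T + ph - dt);
          const double* s = src + c * T + t0;
          double* d = dst + cc * T + (t0 + dt - ph);
          for (int k = 0; k < t1 - t0; ++k) d[k] += s[k];
        }
      }
}

static mat conv_batch(const mat& A, int N, int T, int C, const mat& W,
                      const rowvec& b, int kh, int kw, mat* col_out) {
  const uword P = (uword)T * C;
  mat col(N * P, W.n_rows, fill::zeros);
  for (int i = 0; i < N; ++i)
    im2col_block(A, i * P, T, C, kh, kw, col, i * P);
  mat Z = col * W;
  Z.each_row() += b;
  if (col_out) *col_out = std::move(col);
  return Z;
}

static void leaky_inplace(mat& Z, double s) {
  double* p = Z.memptr();
  const uword n = Z.n_elem;
  for (uword i = 0; i < n; ++i)
    if (p[i] < 0) p[i] *= s;
}

// 2x1 max-pool over time within each sample block; mask holds the winning
// source row (global), ties to the earlier sample.
static mat pool_batch(const mat& A, int N, int T, int C, umat& mask) {
  const uword P = (uword)T * C, Q = P / 2;
  const int Th = T / 2;
  mat Y(N * Q, A.n_cols);
  mask.set_size(N * Q, A.n_cols);
  for (uword ch = 0; ch < A.n_cols; ++ch) {
    const double* src = A.colptr(ch);
    double* dst = Y.colptr(ch);
    uword* mk = mask.colptr(ch);
    for (int i = 0; i < N; ++i)
      for (int c = 0; c < C; ++c)
        for (int t = 0; t < Th; ++t) {
          const uword r0 = i * P + c * T + 2 * t;
          const uword q = i * Q + (uword)c * Th + t;
          if (src[r0] >= src[r0 + 1]) { dst[q] = src[r0]; mk[q] = r0; }
          else { dst[q] = src[r0 + 1]; mk[q] = r0 + 1; }
        }
  }
  return Y;
}

static mat pool_back(const mat& dY, const umat& mask, uword nrowUp) {
  mat dX(nrowUp, dY.n_cols, fill::zeros);
  for (uword ch = 0; ch < dY.n_cols; ++ch) {
    const double* s = dY.colptr(ch);
    const uword* mk = mask.colptr(ch);
    double* d = dX.colptr(ch);
    for (uword q = 0; q < dY.n_rows; ++q) d[mk[q]] = s[q];
  }
  return dX;
}

struct Net {
  mat W1, W2, W3, Wd, Wo;
  rowvec b1, b2, b3, bd, bo;
  int k1h, k1w, k2h, k2w, k3h, k3w;
  double slope;
};

static Net net_from_r(const Rcpp::List& w, const Rcpp::IntegerVector& kdims,
                      double slope) {
  Net n;
  n.W1 = Rcpp::as<mat>(w["W1"]); n.b1 = Rcpp::as<rowvec>(w["b1"]);
  n.W2 = Rcpp::as<mat>(w["W2"]); n.b2 = Rcpp::as<rowvec>(w["b2"]);
  n.W3 = Rcpp::as<mat>(w["W3"]); n.b3 = Rcpp::as<rowvec>(w["b3"]);
  n.Wd = Rcpp::as<mat>(w["Wd"]); n.bd = Rcpp::as<rowvec>(w["bd"]);
  n.Wo = Rcpp::as<mat>(w["Wo"]); n.bo = Rcpp::as<rowvec>(w["bo"]);
  n.k1h = kdims[0]; n.k1w = kdims[1]; n.k2h = kdims[2];
  n.k2w = kdims[3]; n.k3h = kdims[4]; n.k3w = kdims[5];
  n.slope = slope;
  return n;
}

static Rcpp::List net_to_r(const Net& n) {
  return Rcpp::List::create(
      Rcpp::Named("W1") = n.W1, Rcpp::Named("b1") = n.b1,
      Rcpp::Named("W2") = n.W2, Rcpp::Named("b2") = n.b2,
      Rcpp::Named("W3") = n.W3, Rcpp::Named("b3") = n.b3,
      Rcpp::Named("Wd") = n.Wd, Rcpp::Named("bd") = n.bd,
      Rcpp::Named("Wo") = n.Wo, Rcpp::Named("bo") = n.bo);
}

struct Cache {
  mat A0m;            // (N*T*C) x 1 input as channel matrix
  mat Z1, Z2, Z3;     // pre-activations
  mat P1, P2;         // pooled activations (post-leaky)
  umat M1, M2;        // pool argmax source rows
  mat F, Zd, Ad, Drop, Probs;
};

static mat leaky_mask_mult(const mat& dA, const mat& Z, double s) {
  mat dZ = dA;
  const double* z = Z.memptr();
  double* d = dZ.memptr();
  for (uword i = 0; i < dZ.n_elem; ++i)
    if (z[i] <= 0) d[i] *= s;
  return dZ;
}

// Forward pass over a batch held as a T x C x N cube.
static mat forward(const Net& n, const cube& Xb, bool training, double keep,
                   Cache* cc) {
  const int N = Xb.n_slices, T = Xb.n_rows, C = Xb.n_cols;
  const uword P = (uword)T * C;
  mat A0m(N * P, 1);
  for (int i = 0; i < N; ++i)
    std::copy(Xb.slice_memptr(i), Xb.slice_memptr(i) + P,
              A0m.colptr(0) + i * P);

  mat Z1 = conv_batch(A0m, N, T, C, n.W1, n.b1, n.k1h, n.k1w, nullptr);
  mat A1 = Z1; leaky_inplace(A1, n.slope);
  mat Z2 = conv_batch(A1, N, T, C, n.W2, n.b2, n.k2h, n.k2w, nullptr);
  mat A2 = Z2; leaky_inplace(A2, n.slope);
  umat M1;
  mat P1 = pool_batch(A2, N, T, C, M1);
  const int T2 = T / 2;
  mat Z3 = conv_batch(P1, N, T2, C, n.W3, n.b3, n.k3h, n.k3w, nullptr);
  mat A3 = Z3; leaky_inplace(A3, n.slope);
  umat M2;
  mat P2 = pool_batch(A3, N, T2, C, M2);
  const int T4 = T / 4;
  const uword Q = (uword)T4 * C;
  const int C3 = n.W3.n_cols;
  // flatten: F(i, q + Q*ch) = P2(i*Q + q, ch)
  mat F(N, Q * C3);
  for (int ch = 0; ch < C3; ++ch) {
    const double* src = P2.colptr(ch);
    for (uword q = 0; q < Q; ++q) {
      double* dst = F.colptr(ch * Q + q);
      for (int i = 0; i < N; ++i) dst[i] = src[i * Q + q];
    }
  }

  mat Zd = F * n.Wd;
  Zd.each_row() += n.bd;
  mat Ad = Zd; leaky_inplace(Ad, n.slope);
  mat Drop;
  if (training && keep < 1.0) {
    Drop.set_size(Ad.n_rows, Ad.n_cols);
    for (uword j = 0; j < Drop.n_elem; ++j)
      Drop(j) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
    Ad %= Drop;
  }
  mat Zo = Ad * n.Wo;
  Zo.each_row() += n.bo;
  mat Pm = exp(Zo.each_col() - max(Zo, 1));
  Pm.each_col() /= sum(Pm, 1);
  if (cc) {
    cc->A0m = std::move(A0m); cc->Z1 = std::move(Z1); cc->Z2 = std::move(Z2);
    cc->Z3 = std::move(Z3); cc->P1 = std::move(P1); cc->P2 = std::move(P2);
    cc->M1 = std::move(M1); cc->M2 = std::move(M2);
    cc->F = std::move(F); cc->Zd = std::move(Zd); cc->Ad = std::move(Ad);
    cc->Drop = std::move(Drop); cc->Probs = Pm;
  }
  return Pm;
}

struct Grads {
  mat W1, W2, W3, Wd, Wo;
  rowvec b1, b2, b3, bd, bo;
};

// Backward pass; dZo is the softmax + cross-entropy output gradient.
static Grads backward(const Net& n, const Cache& cc, const mat& dZo,
                      int N, int T, int C) {
  Grads g;
  g.Wo = cc.Ad.t() * dZo;
  g.bo = sum(dZo, 0);
  mat dAd = dZo * n.Wo.t();
  if (cc.Drop.n_elem > 0) dAd %= cc.Drop;
  mat dZd = leaky_mask_mult(dAd, cc.Zd, n.slope);
  g.Wd = cc.F.t() * dZd;
  g.bd = sum(dZd, 0);
  mat dF = dZd * n.Wd.t();

  const int T2 = T / 2, T4 = T / 4;
  const uword P = (uword)T * C, P2 = (uword)T2 * C, Q = (uword)T4 * C;
  const int C3 = n.W3.n_cols;
  // unflatten into pooled layout
  mat dP2(N * Q, C3);
  for (int ch = 0; ch < C3; ++ch) {
    double* dst = dP2.colptr(ch);
    for (uword q = 0; q < Q; ++q) {
      const double* src = dF.colptr(ch * Q + q);
      for (int i = 0; i < N; ++i) dst[i * Q + q] = src[i];
    }
  }
  mat dA3 = pool_back(dP2, cc.M2, N * P2);
  mat dZ3 = leaky_mask_mult(dA3, cc.Z3, n.slope);
  // conv3
  mat col3(N * P2, n.W3.n_rows, fill::zeros);
  for (int i = 0; i < N; ++i)
    im2col_block(cc.P1, i * P2, T2, C, n.k3h, n.k3w, col3, i * P2);
  g.W3 = col3.t() * dZ3;
  g.b3 = sum(dZ3, 0);
  mat dcol3 = dZ3 * n.W3.t();
  mat dP1(N * P2, n.W2.n_cols, fill::zeros);
  for (int i = 0; i < N; ++i)
    col2im_block(dcol3, i * P2, T2, C, n.k3h, n.k3w, dP1, i * P2);
  mat dA2 = pool_back(dP1, cc.M1, N * P);
  mat dZ2 = leaky_mask_mult(dA2, cc.Z2, n.slope);
  // conv2 (recompute A1 = leaky(Z1))
  mat A1 = cc.Z1; leaky_inplace(A1, n.slope);
  mat col2(N * P, n.W2.n_rows, fill::zeros);
  for (int i = 0; i < N; ++i)
    im2col_block(A1, i * P, T, C, n.k2h, n.k2w, col2, i * P);
  g.W2 = col2.t() * dZ2;
  g.b2 = sum(dZ2, 0);
  mat dcol2 = dZ2 * n.W2.t();
  mat dA1(N * P, n.W1.n_cols, fill::zeros);
  for (int i = 0; i < N; ++i)
    col2im_block(dcol2, i * P, T, C, n.k2h, n.k2w, dA1, i * P);
  mat dZ1 = leaky_mask_mult(dA1, cc.Z1, n.slope);
  // conv1 (no input gradient needed)
  mat col1(N * P, n.W1.n_rows, fill::zeros);
  for (int i = 0; i < N; ++i)
    im2col_block(cc.A0m, i * P, T, C, n.k1h, n.k1w, col1, i * P);
  g.W1 = col1.t() * dZ1;
  g.b1 = sum(dZ1, 0);
  return g;
}

struct AdamState { mat m, v; };

// fused single-pass Adam update
static void adam_step(double* W, AdamState& s, const double* g, uword n,
                      double lr, long t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  const double c1 = 1 - std::pow(b1, (double)t);
  const double c2 = 1 - std::pow(b2, (double)t);
  double* m = s.m.memptr();
  double* v = s.v.memptr();
  for (uword i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1 - b1) * g[i];
    v[i] = b2 * v[i] + (1 - b2) * g[i] * g[i];
    W[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}

// [[Rcpp::export]]
arma::mat cnn_forward_cpp(Rcpp::List weights, arma::cube Xb,
                          Rcpp::IntegerVector kdims, double slope) {
  Net n = net_from_r(weights, kdims, slope);
  return forward(n, Xb, false, 1.0, nullptr);
}

// [[Rcpp::export]]
Rcpp::List cnn_grad_cpp(Rcpp::List weights, arma::cube Xb, arma::ivec y,
                        Rcpp::IntegerVector kdims, double slope) {
  // loss and analytic gradients on one batch, dropout off (for testing)
  Net n = net_from_r(weights, kdims, slope);
  const int N = Xb.n_slices, T = Xb.n_rows, C = Xb.n_cols;
  Cache cc;
  mat P = forward(n, Xb, false, 1.0, &cc);
  double loss = 0;
  mat dZo = P;
  for (int i = 0; i < N; ++i) {
    loss -= std::log(std::max(P(i, y(i)), 1e-12));
    dZo(i, y(i)) -= 1.0;
  }
  loss /= N;
  dZo /= N;
  Grads g = backward(n, cc, dZo, N, T, C);
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("grads") = Rcpp::List::create(
          Rcpp::Named("W1") = g.W1, Rcpp::Named("b1") = g.b1,
          Rcpp::Named("W2") = g.W2, Rcpp::Named("b2") = g.b2,
          Rcpp::Named("W3") = g.W3, Rcpp::Named("b3") = g.b3,
          Rcpp::Named("Wd") = g.Wd, Rcpp::Named("bd") = g.bd,
          Rcpp::Named("Wo") = g.Wo, Rcpp::Named("bo") = g.bo));
}

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::List weights, arma::cube X, arma::ivec y,
                         int n_classes, Rcpp::IntegerVector kdims,
                         double slope, double lr, int epochs, int batch,
                         double dropout, int shift_aug, int verbose) {
  Rcpp::RNGScope rng;
  Net n = net_from_r(weights, kdims, slope);
  std::vector<mat*> Ws = {&n.W1, &n.W2, &n.W3, &n.Wd, &n.Wo};
  std::vector<rowvec*> bs = {&n.b1, &n.b2, &n.b3, &n.bd, &n.bo};
  std::vector<AdamState> sW(5), sb(5);
  for (int k = 0; k < 5; ++k) {
    sW[k].m = zeros(size(*Ws[k])); sW[k].v = sW[k].m;
    sb[k].m = zeros(1, bs[k]->n_elem); sb[k].v = sb[k].m;
  }
  const int N = X.n_slices, T = X.n_rows, C = X.n_cols;
  const double keep = 1.0 - dropout;
  std::vector<double> history;
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  long t = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = N - 1; i > 0; --i) {  // Fisher-Yates via R's RNG
      int j = (int)std::floor(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double ep_loss = 0.0;
    for (int start = 0; start < N; start += batch) {
      const int nb = std::min(batch, N - start);
      cube Xb(T, C, nb);
      ivec yb(nb);
      for (int i = 0; i < nb; ++i) {
        if (shift_aug) {
          // random circular time shift: streaming windows are never
          // phase-aligned with gesture onsets
          int k = (int)std::floor(R::unif_rand() * T);
          if (k >= T) k = T - 1;
          const cube& src = X;
          for (int c = 0; c < C; ++c) {
            const double* s = src.slice_colptr(idx[start + i], c);
            double* d = Xb.slice_colptr(i, c);
            std::copy(s + k, s + T, d);
            std::copy(s, s + k, d + (T - k));
          }
        } else {
          Xb.slice(i) = X.slice(idx[start + i]);
        }
        yb(i) = y(idx[start + i]);
      }
      Cache cc;
      mat P = forward(n, Xb, true, keep, &cc);
      mat dZo = P;
      for (int i = 0; i < nb; ++i) {
        ep_loss -= std::log(std::max(P(i, yb(i)), 1e-12));
        dZo(i, yb(i)) -= 1.0;
      }
      dZo /= nb;
      Grads g = backward(n, cc, dZo, nb, T, C);
      std::vector<mat*> gW = {&g.W1, &g.W2, &g.W3, &g.Wd, &g.Wo};
      std::vector<rowvec*> gb = {&g.b1, &g.b2, &g.b3, &g.bd, &g.bo};
      t += 1;
      for (int k = 0; k < 5; ++k) {
        adam_step(Ws[k]->memptr(), sW[k], gW[k]->memptr(),
                  Ws[k]->n_elem, lr, t);
        adam_step(bs[k]->memptr(), sb[k], gb[k]->memptr(),
                  bs[k]->n_elem, lr, t);
      }
      Rcpp::checkUserInterrupt();
    }
    history.push_back(ep_loss / N);
    if (verbose)
      Rcpp::Rcout << "epoch " << (ep + 1) << "/" << epochs
                  << " loss " << history.back() << std::endl;
  }
  return Rcpp::List::create(Rcpp::Named("weights") = net_to_r(n),
                            Rcpp::Named("loss") = history);
}
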