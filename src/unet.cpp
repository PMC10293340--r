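// Small 2D U-net: im2col convolutions, 2x2 max pooling, nearest-neighbour
// upsampling with skip concatenation, softmax cross-entropy, Adam.
// Feature maps are arma::cube (H x W x C); weights are (Cout x Cin*k) with
// column index c*9 + (dw*3 + dh) for the 3x3 kernels.
//
// Canonical parameter order for a net of depth D (levels 0..D-1, channels
// C_i = base * 2^i, input 1 channel, K output classes), stored as a flat
// list W1, b1, W2, b2, ...:
//   for i = 0..D-1:      enc_i conv1, enc_i conv2
//   for i = D-2..0:      up_i conv (3x3 after upsampling), dec_i conv1
//                        (input 2*C_i from skip concat), dec_i conv2
//   final 1x1 conv to K classes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static mat im2col3(const cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(C * 9, H * W);
  mat P(H + 2, W + 2, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    P.zeros();
    P.submat(1, 1, H, W) = x.slice(c);
    uword k = 0;
    for (uword dw = 0; dw < 3; ++dw)
      for (uword dh = 0; dh < 3; ++dh) {
        out.row(c * 9 + k) = vectorise(P.submat(dh, dw, dh + H - 1, dw + W - 1)).t();
        ++k;
      }
  }
  return out;
}

static cube conv3_fwd(const cube& x, const mat& Wm, const vec& b) {
  const uword H = x.n_rows, Wd = x.n_cols;
  mat cols = im2col3(x);
  mat o = Wm * cols;
  o.each_col() += b;
  cube out(H, Wd, Wm.n_rows);
  for (uword c = 0; c < Wm.n_rows; ++c)
    out.slice(c) = reshape(o.row(c), H, Wd);
  return out;
}

static cube conv3_bwd(const cube& x, const mat& Wm, const cube& dOut,
                      mat& dW, vec& db) {
  const uword H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices,
              Cout = Wm.n_rows;
  mat D(Cout, H * Wd);
  for (uword c = 0; c < Cout; ++c) D.row(c) = vectorise(dOut.slice(c)).t();
  mat cols = im2col3(x);
  dW = D * cols.t();
  db = sum(D, 1);
  mat dCols = Wm.t() * D;
  cube dX(H, Wd, Cin);
  mat dP(H + 2, Wd + 2);
  for (uword c = 0; c < Cin; ++c) {
    dP.zeros();
    uword k = 0;
    for (uword dw = 0; dw < 3; ++dw)
      for (uword dh = 0; dh < 3; ++dh) {
        dP.submat(dh, dw, dh + H - 1, dw + Wd - 1) +=
          reshape(dCols.row(c * 9 + k), H, Wd);
        ++k;
      }
    dX.slice(c) = dP.submat(1, 1, H, Wd);
  }
  return dX;
}

static cube conv1_fwd(const cube& x, const mat& Wm, const vec& b) {
  const uword H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  mat X(Cin, H * Wd);
  for (uword c = 0; c < Cin; ++c) X.row(c) = vectorise(x.slice(c)).t();
  mat o = Wm * X;
  o.each_col() += b;
  cube out(H, Wd, Wm.n_rows);
  for (uword c = 0; c < Wm.n_rows; ++c)
    out.slice(c) = reshape(o.row(c), H, Wd);
  return out;
}

static cube conv1_bwd(const cube& x, const mat& Wm, const cube& dOut,
                      mat& dW, vec& db) {
  const uword H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices,
              Cout = Wm.n_rows;
  mat D(Cout, H * Wd), X(Cin, H * Wd);
  for (uword c = 0; c < Cout; ++c) D.row(c) = vectorise(dOut.slice(c)).t();
  for (uword c = 0; c < Cin; ++c) X.row(c) = vectorise(x.slice(c)).t();
  dW = D * X.t();
  db = sum(D, 1);
  mat dXm = Wm.t() * D;
  cube dX(H, Wd, Cin);
  for (uword c = 0; c < Cin; ++c)
    dX.slice(c) = reshape(dXm.row(c), H, Wd);
  return dX;
}

static void relu_(cube& x) { x.transform([](double v) { return v > 0 ? v : 0.0; }); }

static void relu_bwd_(cube& d, const cube& act) {
  for (uword i = 0; i < d.n_elem; ++i) if (act(i) <= 0) d(i) = 0.0;
}

static cube pool2_fwd(const cube& x, ucube& idx) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube out(H / 2, W / 2, C);
  idx.set_size(H / 2, W / 2, C);
  for (uword c = 0; c < C; ++c) {
    const mat& s = x.slice(c);
    for (uword j = 0; j < W / 2; ++j)
      for (uword i = 0; i < H / 2; ++i) {
        uword r = 2 * i, q = 2 * j, br = r, bq = q;
        double best = s(r, q);
        if (s(r + 1, q) > best) { best = s(r + 1, q); br = r + 1; bq = q; }
        if (s(r, q + 1) > best) { best = s(r, q + 1); br = r; bq = q + 1; }
        if (s(r + 1, q + 1) > best) { best = s(r + 1, q + 1); br = r + 1; bq = q + 1; }
        out(i, j, c) = best;
        idx(i, j, c) = bq * H + br;
      }
  }
  return out;
}

static cube pool2_bwd(const cube& d, const ucube& idx, uword H, uword W) {
  const uword C = d.n_slices;
  cube dX(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    mat& s = dX.slice(c);
    for (uword j = 0; j < d.n_cols; ++j)
      for (uword i = 0; i < d.n_rows; ++i)
        s(idx(i, j, c)) += d(i, j, c);
  }
  return dX;
}

static cube upsample2(const cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube out(2 * H, 2 * W, C);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i) {
        double v = x(i, j, c);
        out(2 * i, 2 * j, c) = v;
        out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v;
        out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return out;
}

static cube upsample2_bwd(const cube& d) {
  const uword H = d.n_rows / 2, W = d.n_cols / 2, C = d.n_slices;
  cube out(H, W, C);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i)
        out(i, j, c) = d(2 * i, 2 * j, c) + d(2 * i + 1, 2 * j, c) +
                       d(2 * i, 2 * j + 1, c) + d(2 * i + 1, 2 * j + 1, c);
  return out;
}

static void unpack(const List& params, std::vector<mat>& W, std::vector<vec>& b) {
  int n = params.size() / 2;
  W.resize(n); b.resize(n);
  for (int i = 0; i < n; ++i) {
    W[i] = as<mat>(params[2 * i]);
    b[i] = as<vec>(params[2 * i + 1]);
  }
}

static List pack(const std::vector<mat>& W, const std::vector<vec>& b) {
  List out(2 * W.size());
  for (size_t i = 0; i < W.size(); ++i) {
    out[2 * i] = wrap(W[i]);
    out[2 * i + 1] = wrap(b[i]);
  }
  return out;
}

// Forward pass; if y has elements, also computes weighted cross-entropy loss
// and (when grads requested) parameter gradients by backprop.
static double unet_pass(const std::vector<mat>& W, const std::vector<vec>& b,
                        const mat& x, const imat& y, const vec& cw, int D,
                        std::vector<mat>* gW, std::vector<vec>* gb,
                        cube* probs_out) {
  const int nunit = (int)W.size();
  std::vector<cube> conv_in(nunit), act(nunit);
  std::vector<ucube> pidx(std::max(D - 1, 0));
  std::vector<cube> skips(std::max(D - 1, 0));

  cube a(x.n_rows, x.n_cols, 1);
  a.slice(0) = x;
  int u = 0;
  for (int i = 0; i < D; ++i) {
    conv_in[u] = a; a = conv3_fwd(a, W[u], b[u]); relu_(a); act[u] = a; ++u;
    conv_in[u] = a; a = conv3_fwd(a, W[u], b[u]); relu_(a); act[u] = a; ++u;
    if (i < D - 1) { skips[i] = a; a = pool2_fwd(a, pidx[i]); }
  }
  for (int i = D - 2; i >= 0; --i) {
    a = upsample2(a);
    conv_in[u] = a; a = conv3_fwd(a, W[u], b[u]); relu_(a); act[u] = a; ++u;
    a = join_slices(skips[i], a);
    conv_in[u] = a; a = conv3_fwd(a, W[u], b[u]); relu_(a); act[u] = a; ++u;
    conv_in[u] = a; a = conv3_fwd(a, W[u], b[u]); relu_(a); act[u] = a; ++u;
  }
  conv_in[u] = a;
  cube logits = conv1_fwd(a, W[u], b[u]);

  const uword H = logits.n_rows, Wd = logits.n_cols, K = logits.n_slices;
  mat L(K, H * Wd);
  for (uword c = 0; c < K; ++c) L.row(c) = vectorise(logits.slice(c)).t();
  rowvec mx = max(L, 0);
  L.each_row() -= mx;
  mat E = exp(L);
  rowvec Z = sum(E, 0);
  mat P = E;
  P.each_row() /= Z;

  cube probs(H, Wd, K);
  for (uword c = 0; c < K; ++c) probs.slice(c) = reshape(P.row(c), H, Wd);
  if (probs_out) *probs_out = probs;

  double loss = NA_REAL;
  if (y.n_elem > 0) {
    double wsum = 0.0, lsum = 0.0;
    for (uword px = 0; px < H * Wd; ++px) {
      int k = y(px);
      double w = cw(k);
      wsum += w;
      lsum += -w * std::log(std::max(P(k, px), 1e-12));
    }
    loss = lsum / wsum;
    if (gW) {
      mat dL = P;
      for (uword px = 0; px < H * Wd; ++px) {
        int k = y(px);
        double w = cw(k) / wsum;
        dL.col(px) *= w;
        dL(k, px) -= w;
      }
      cube d(H, Wd, K);
      for (uword c = 0; c < K; ++c) d.slice(c) = reshape(dL.row(c), H, Wd);

      std::vector<cube> dskip(std::max(D - 1, 0));
      int v = nunit - 1;
      d = conv1_bwd(conv_in[v], W[v], d, (*gW)[v], (*gb)[v]);
      --v;
      for (int i = 0; i <= D - 2; ++i) {
        relu_bwd_(d, act[v]);
        d = conv3_bwd(conv_in[v], W[v], d, (*gW)[v], (*gb)[v]); --v;
        relu_bwd_(d, act[v]);
        d = conv3_bwd(conv_in[v], W[v], d, (*gW)[v], (*gb)[v]); --v;
        uword Ci = skips[i].n_slices;
        dskip[i] = d.slices(0, Ci - 1);
        cube dup = d.slices(Ci, d.n_slices - 1);
        relu_bwd_(dup, act[v]);
        dup = conv3_bwd(conv_in[v], W[v], dup, (*gW)[v], (*gb)[v]); --v;
        d = upsample2_bwd(dup);
      }
      for (int i = D - 1; i >= 0; --i) {
        if (i < D - 1) {
          d = pool2_bwd(d, pidx[i], skips[i].n_rows, skips[i].n_cols);
          d += dskip[i];
        }
        relu_bwd_(d, act[v]);
        d = conv3_bwd(conv_in[v], W[v], d, (*gW)[v], (*gb)[v]); --v;
        relu_bwd_(d, act[v]);
        d = conv3_bwd(conv_in[v], W[v], d, (*gW)[v], (*gb)[v]); --v;
      }
    }
  }
  return loss;
}

// [[Rcpp::export]]
arma::cube cpp_unet_predict(List params, arma::mat x, int depth) {
  std::vector<mat> W; std::vector<vec> b;
  unpack(params, W, b);
  imat y;
  cube probs;
  vec cw;
  unet_pass(W, b, x, y, cw, depth, nullptr, nullptr, &probs);
  return probs;
}

// [[Rcpp::export]]
double cpp_unet_loss(List params, arma::mat x, arma::imat y, int depth,
                     arma::vec class_weights) {
  std::vector<mat> W; std::vector<vec> b;
  unpack(params, W, b);
  return unet_pass(W, b, x, y, class_weights, depth, nullptr, nullptr, nullptr);
}

// [[Rcpp::export]]
List cpp_unet_grad(List params, arma::mat x, arma::imat y, int depth,
                   arma::vec class_weights) {
  std::vector<mat> W; std::vector<vec> b;
  unpack(params, W, b);
  std::vector<mat> gW(W.size());
  std::vector<vec> gb(b.size());
  for (size_t i = 0; i < W.size(); ++i) {
    gW[i].zeros(W[i].n_rows, W[i].n_cols);
    gb[i].zeros(b[i].n_elem);
  }
  double loss = unet_pass(W, b, x, y, class_weights, depth, &gW, &gb, nullptr);
  return List::create(_["loss"] = loss, _["grads"] = pack(gW, gb));
}

// One pass over the supplied slices with mini-batch Adam updates.
// [[Rcpp::export]]
List cpp_unet_train(List params, List m_, List v_, int t, List xs, List ys,
                    int depth, double lr, double beta1, double beta2,
                    double eps, int batch_size, arma::vec class_weights) {
  std::vector<mat> W, M, V;
  std::vector<vec> b, mb, vb;
  unpack(params, W, b);
  unpack(m_, M, mb);
  unpack(v_, V, vb);
  const size_t np = W.size();
  std::vector<mat> gW(np), accW(np);
  std::vector<vec> gb(np), accb(np);
  for (size_t i = 0; i < np; ++i) {
    gW[i].zeros(W[i].n_rows, W[i].n_cols);
    gb[i].zeros(b[i].n_elem);
    accW[i] = gW[i];
    accb[i] = gb[i];
  }
  const int n = xs.size();
  vec losses(n);
  int in_batch = 0;
  for (int s = 0; s < n; ++s) {
    mat x = as<mat>(xs[s]);
    imat y = as<imat>(ys[s]);
    losses(s) = unet_pass(W, b, x, y, class_weights, depth, &gW, &gb, nullptr);
    for (size_t i = 0; i < np; ++i) { accW[i] += gW[i]; accb[i] += gb[i]; }
    ++in_batch;
    if (in_batch == batch_size || s == n - 1) {
      ++t;
      double c1 = 1.0 - std::pow(beta1, t), c2 = 1.0 - std::pow(beta2, t);
      for (size_t i = 0; i < np; ++i) {
        mat g = accW[i] / in_batch;
        M[i] = beta1 * M[i] + (1 - beta1) * g;
        V[i] = beta2 * V[i] + (1 - beta2) * (g % g);
        W[i] -= lr * (M[i] / c1) / (sqrt(V[i] / c2) + eps);
        vec gv = accb[i] / in_batch;
        mb[i] = beta1 * mb[i] + (1 - beta1) * gv;
        vb[i] = beta2 * vb[i] + (1 - beta2) * (gv % gv);
        b[i] -= lr * (mb[i] / c1) / (sqrt(vb[i] / c2) + eps);
        accW[i].zeros();
        accb[i].zeros();
      }
      in_batch = 0;
    }
  }
  return List::create(_["params"] = pack(W, b), _["m"] = pack(M, mb),
                      _["v"] = pack(V, vb), _["t"] = t,
                      _["losses"] = losses);
}

// Forward-only evaluation: per-slice loss plus per-class overlap counts of
// the argmax prediction against ground truth (for slice-pooled Dice).
// [[Rcpp::export]]
List cpp_unet_eval(List params, List xs, List ys, int depth,
                   arma::vec class_weights) {
  std::vector<mat> W; std::vector<vec> b;
  unpack(params, W, b);
  const int n = xs.size();
  const int K = (int)class_weights.n_elem;
  vec losses(n);
  vec inter(K, fill::zeros), npred(K, fill::zeros), ntrue(K, fill::zeros);
  for (int s = 0; s < n; ++s) {
    mat x = as<mat>(xs[s]);
    imat y = as<imat>(ys[s]);
    cube probs;
    losses(s) = unet_pass(W, b, x, y, class_weights, depth, nullptr, nullptr,
                          &probs);
    for (uword j = 0; j < probs.n_cols; ++j)
      for (uword i = 0; i < probs.n_rows; ++i) {
        int best = 0;
        double bv = probs(i, j, 0);
        for (int k = 1; k < K; ++k)
          if (probs(i, j, k) > bv) { bv = probs(i, j, k); best = k; }
        npred(best) += 1;
        ntrue(y(i, j)) += 1;
        if (best == y(i, j)) inter(best) += 1;
      }
  }
  return List::create(_["losses"] = losses, _["intersection"] = inter,
                      _["n_pred"] = npred, _["n_true"] = ntrue);
}
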