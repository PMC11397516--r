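// Compact encoder-decoder convolutional network for artificial image
// objects.  Fixed topology (sizes inferred from the weight list):
//
//   conv3x3(3->c1)+ReLU -> maxpool2 -> conv3x3(c1->c2)+ReLU -> maxpool2
//   -> conv3x3(c2->c3)+ReLU                         [encoder output]
//   -> tconv2x2(c3->c2)+ReLU -> concat(skip conv2) -> conv3x3(2c2->c2)+ReLU
//   -> tconv2x2(c2->c1)+ReLU -> concat(skip conv1) -> conv3x3(2c1->d)+ReLU
//                                                     [decoder output, d ch]
//   -> GAP(d) ++ numeric features -> dense(h)+ReLU -> dense(1)
//
// Convolutions use 'same' zero padding and are evaluated as im2col matrix
// products so the heavy lifting lands in BLAS.  The backward pass returns
// analytic gradients for all weights and, on request, for the input image
// (used for saliency / attention maps).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

// im2col for a 3x3 'same' convolution: (H*W) x (9*C), column c*9+k where k
// enumerates kernel offsets (di,dj) in column-major order di fastest.
static mat im2col3(const cube& X) {
  const uword H = X.n_rows, W = X.n_cols, C = X.n_slices;
  mat M(H * W, 9 * C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const mat& S = X.slice(c);
    uword k = 0;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di, ++k) {
        const uword col = c * 9 + k;
        const uword i0 = (di < 0) ? 1u : 0u;
        const uword i1 = (di > 0) ? H - 1 : H;   // out rows [i0, i1)
        const uword j0 = (dj < 0) ? 1u : 0u;
        const uword j1 = (dj > 0) ? W - 1 : W;
        for (uword j = j0; j < j1; ++j) {
          M(span(i0 + j * H, i1 - 1 + j * H), span(col, col)) =
            S(span(i0 + di, i1 - 1 + di), span(j + dj, j + dj));
        }
      }
    }
  }
  return M;
}

static cube col2im3(const mat& M, uword H, uword W, uword C) {
  cube X(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    mat& S = X.slice(c);
    uword k = 0;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di, ++k) {
        const uword col = c * 9 + k;
        const uword i0 = (di < 0) ? 1u : 0u;
        const uword i1 = (di > 0) ? H - 1 : H;
        const uword j0 = (dj < 0) ? 1u : 0u;
        const uword j1 = (dj > 0) ? W - 1 : W;
        for (uword j = j0; j < j1; ++j) {
          S(span(i0 + di, i1 - 1 + di), span(j + dj, j + dj)) +=
            M(span(i0 + j * H, i1 - 1 + j * H), span(col, col));
        }
      }
    }
  }
  return X;
}

static mat cube2mat(const cube& X) {       // (H*W) x C view copy
  const uword HW = X.n_rows * X.n_cols, C = X.n_slices;
  mat M(HW, C);
  for (uword c = 0; c < C; ++c) M.col(c) = vectorise(X.slice(c));
  return M;
}

static cube mat2cube(const mat& M, uword H, uword W) {
  cube X(H, W, M.n_cols);
  for (uword c = 0; c < M.n_cols; ++c) X.slice(c) = reshape(M.col(c), H, W);
  return X;
}

static cube conv_fw(const cube& X, const mat& Wt, const rowvec& b) {
  mat O = im2col3(X) * Wt;
  O.each_row() += b;
  return mat2cube(O, X.n_rows, X.n_cols);
}

// gradient wrt weights/bias accumulated in dW/db; returns gradient wrt X
static cube conv_bw(const cube& X, const mat& Wt, const cube& dOut,
                    mat& dW, rowvec& db, bool want_dx) {
  const mat dOm = cube2mat(dOut);
  const mat Mi = im2col3(X);
  dW += Mi.t() * dOm;
  db += sum(dOm, 0);
  if (!want_dx) return cube();
  return col2im3(dOm * Wt.t(), X.n_rows, X.n_cols, X.n_slices);
}

static cube relu(const cube& Z) { return clamp(Z, 0.0, datum::inf); }

static cube maxpool2(const cube& A, ucube& idx) {
  const uword H = A.n_rows, W = A.n_cols, C = A.n_slices;
  cube P(H / 2, W / 2, C);
  idx.set_size(H / 2, W / 2, C);
  for (uword c = 0; c < C; ++c) {
    const mat& S = A.slice(c);
    for (uword j = 0; j < W / 2; ++j) {
      for (uword i = 0; i < H / 2; ++i) {
        uword bi = 2 * i, bj = 2 * j, am = bi + bj * H;
        double m = S(bi, bj);
        if (S(bi + 1, bj) > m)     { m = S(bi + 1, bj);     am = bi + 1 + bj * H; }
        if (S(bi, bj + 1) > m)     { m = S(bi, bj + 1);     am = bi + (bj + 1) * H; }
        if (S(bi + 1, bj + 1) > m) { m = S(bi + 1, bj + 1); am = bi + 1 + (bj + 1) * H; }
        P(i, j, c) = m;
        idx(i, j, c) = am;
      }
    }
  }
  return P;
}

static cube maxpool2_bw(const cube& dP, const ucube& idx, uword H, uword W) {
  cube dA(H, W, dP.n_slices, fill::zeros);
  for (uword c = 0; c < dP.n_slices; ++c) {
    mat& S = dA.slice(c);
    for (uword j = 0; j < dP.n_cols; ++j)
      for (uword i = 0; i < dP.n_rows; ++i)
        S(idx(i, j, c)) += dP(i, j, c);
  }
  return dA;
}

// transpose convolution, 2x2 kernel, stride 2; T is (Ci x 4*Co), column
// co*4 + k with k enumerating output offsets (di,dj), di fastest.
static cube tconv_fw(const cube& X, const mat& T, const rowvec& b) {
  const uword h = X.n_rows, w = X.n_cols;
  const uword Co = T.n_cols / 4;
  const mat O = cube2mat(X) * T;           // (hw x 4Co)
  cube Y(2 * h, 2 * w, Co);
  for (uword co = 0; co < Co; ++co) {
    mat& S = Y.slice(co);
    S.fill(b(co));
    uword k = 0;
    for (uword dj = 0; dj <= 1; ++dj) {
      for (uword di = 0; di <= 1; ++di, ++k) {
        const vec v = O.col(co * 4 + k);
        for (uword j = 0; j < w; ++j)
          for (uword i = 0; i < h; ++i)
            S(2 * i + di, 2 * j + dj) += v(i + j * h);
      }
    }
  }
  return Y;
}

static cube tconv_bw(const cube& X, const mat& T, const cube& dY,
                     mat& dT, rowvec& db) {
  const uword h = X.n_rows, w = X.n_cols;
  const uword Co = T.n_cols / 4;
  mat dO(h * w, 4 * Co);
  for (uword co = 0; co < Co; ++co) {
    const mat& S = dY.slice(co);
    db(co) += accu(S);
    uword k = 0;
    for (uword dj = 0; dj <= 1; ++dj) {
      for (uword di = 0; di <= 1; ++di, ++k) {
        vec v(h * w);
        for (uword j = 0; j < w; ++j)
          for (uword i = 0; i < h; ++i)
            v(i + j * h) = S(2 * i + di, 2 * j + dj);
        dO.col(co * 4 + k) = v;
      }
    }
  }
  dT += cube2mat(X).t() * dO;
  return mat2cube(dO * T.t(), h, w);
}

static cube concat_ch(const cube& A, const cube& B) {
  cube C(A.n_rows, A.n_cols, A.n_slices + B.n_slices);
  C.slices(0, A.n_slices - 1) = A;
  C.slices(A.n_slices, C.n_slices - 1) = B;
  return C;
}

struct Weights {
  mat W1, W2, W3, T1, W4, T2, W5, Wd1, Wd2;
  rowvec b1, b2, b3, bt1, b4, bt2, b5;
  vec bd1;
  double bd2;
};

static Weights unpack(const List& L) {
  Weights w;
  w.W1 = Rcpp::as<mat>(L["W1"]);   w.b1  = Rcpp::as<rowvec>(L["b1"]);
  w.W2 = Rcpp::as<mat>(L["W2"]);   w.b2  = Rcpp::as<rowvec>(L["b2"]);
  w.W3 = Rcpp::as<mat>(L["W3"]);   w.b3  = Rcpp::as<rowvec>(L["b3"]);
  w.T1 = Rcpp::as<mat>(L["T1"]);   w.bt1 = Rcpp::as<rowvec>(L["bt1"]);
  w.W4 = Rcpp::as<mat>(L["W4"]);   w.b4  = Rcpp::as<rowvec>(L["b4"]);
  w.T2 = Rcpp::as<mat>(L["T2"]);   w.bt2 = Rcpp::as<rowvec>(L["bt2"]);
  w.W5 = Rcpp::as<mat>(L["W5"]);   w.b5  = Rcpp::as<rowvec>(L["b5"]);
  w.Wd1 = Rcpp::as<mat>(L["Wd1"]); w.bd1 = Rcpp::as<vec>(L["bd1"]);
  w.Wd2 = Rcpp::as<mat>(L["Wd2"]); w.bd2 = Rcpp::as<double>(L["bd2"]);
  return w;
}

struct Cache {
  cube X, Z1, A1, P1, Z2, A2, P2, Z3, A3, ZU1, Z4, A4, ZU2, C1, C2, Z5, A5;
  ucube idx1, idx2;
  vec v, zH, Hh;
  double y;
};

static void forward(const cube& X, const vec& f, const Weights& w, Cache& c) {
  c.X = X;
  c.Z1 = conv_fw(X, w.W1, w.b1);              c.A1 = relu(c.Z1);
  c.P1 = maxpool2(c.A1, c.idx1);
  c.Z2 = conv_fw(c.P1, w.W2, w.b2);           c.A2 = relu(c.Z2);
  c.P2 = maxpool2(c.A2, c.idx2);
  c.Z3 = conv_fw(c.P2, w.W3, w.b3);           c.A3 = relu(c.Z3);
  c.ZU1 = tconv_fw(c.A3, w.T1, w.bt1);
  c.C1 = concat_ch(relu(c.ZU1), c.A2);
  c.Z4 = conv_fw(c.C1, w.W4, w.b4);           c.A4 = relu(c.Z4);
  c.ZU2 = tconv_fw(c.A4, w.T2, w.bt2);
  c.C2 = concat_ch(relu(c.ZU2), c.A1);
  c.Z5 = conv_fw(c.C2, w.W5, w.b5);           c.A5 = relu(c.Z5);
  const uword d = c.A5.n_slices, HW = c.A5.n_rows * c.A5.n_cols;
  vec g(d);
  for (uword k = 0; k < d; ++k) g(k) = accu(c.A5.slice(k)) / double(HW);
  c.v = join_cols(g, f);
  c.zH = w.Wd1.t() * c.v + w.bd1;
  c.Hh = clamp(c.zH, 0.0, datum::inf);
  c.y = as_scalar(w.Wd2.t() * c.Hh) + w.bd2;
}

struct Grads {
  mat W1, W2, W3, T1, W4, T2, W5, Wd1, Wd2;
  rowvec b1, b2, b3, bt1, b4, bt2, b5;
  vec bd1;
  double bd2 = 0.0;
  void init(const Weights& w) {
    W1.zeros(size(w.W1)); W2.zeros(size(w.W2)); W3.zeros(size(w.W3));
    T1.zeros(size(w.T1)); W4.zeros(size(w.W4)); T2.zeros(size(w.T2));
    W5.zeros(size(w.W5)); Wd1.zeros(size(w.Wd1)); Wd2.zeros(size(w.Wd2));
    b1.zeros(w.b1.n_elem); b2.zeros(w.b2.n_elem); b3.zeros(w.b3.n_elem);
    bt1.zeros(w.bt1.n_elem); b4.zeros(w.b4.n_elem); bt2.zeros(w.bt2.n_elem);
    b5.zeros(w.b5.n_elem); bd1.zeros(w.bd1.n_elem); bd2 = 0.0;
  }
};

// backward for one sample; dy = dLoss/dy.  Fills g; returns input gradient
// (empty unless want_dx).  If dA5_out is non-null, stores dLoss/dA5 there
// (gradient wrt decoder activations, used by the layer-CAM style maps).
static cube backward(const Cache& c, const Weights& w, double dy, Grads& g,
                     bool want_dx, cube* dA5_out = nullptr) {
  const uword d = c.A5.n_slices, HW = c.A5.n_rows * c.A5.n_cols;
  vec dH = w.Wd2 * dy;
  g.Wd2 += c.Hh * dy;
  g.bd2 += dy;
  vec dzH = dH % conv_to<vec>::from(c.zH > 0);
  g.Wd1 += c.v * dzH.t();
  g.bd1 += dzH;
  vec dv = w.Wd1 * dzH;
  cube dA5(c.A5.n_rows, c.A5.n_cols, d);
  for (uword k = 0; k < d; ++k) dA5.slice(k).fill(dv(k) / double(HW));
  if (dA5_out) *dA5_out = dA5;
  cube dZ5 = dA5 % conv_to<cube>::from(c.Z5 > 0);
  cube dC2 = conv_bw(c.C2, w.W5, dZ5, g.W5, g.b5, true);
  const uword c1 = c.A1.n_slices, c2 = c.A2.n_slices;
  cube dU2 = dC2.slices(0, c1 - 1);
  cube dA1 = dC2.slices(c1, 2 * c1 - 1);
  cube dZU2 = dU2 % conv_to<cube>::from(c.ZU2 > 0);
  cube dA4 = tconv_bw(c.A4, w.T2, dZU2, g.T2, g.bt2);
  cube dZ4 = dA4 % conv_to<cube>::from(c.Z4 > 0);
  cube dC1 = conv_bw(c.C1, w.W4, dZ4, g.W4, g.b4, true);
  cube dU1 = dC1.slices(0, c2 - 1);
  cube dA2 = dC1.slices(c2, 2 * c2 - 1);
  cube dZU1 = dU1 % conv_to<cube>::from(c.ZU1 > 0);
  cube dA3 = tconv_bw(c.A3, w.T1, dZU1, g.T1, g.bt1);
  cube dZ3 = dA3 % conv_to<cube>::from(c.Z3 > 0);
  cube dP2 = conv_bw(c.P2, w.W3, dZ3, g.W3, g.b3, true);
  dA2 += maxpool2_bw(dP2, c.idx2, c.A2.n_rows, c.A2.n_cols);
  cube dZ2 = dA2 % conv_to<cube>::from(c.Z2 > 0);
  cube dP1 = conv_bw(c.P1, w.W2, dZ2, g.W2, g.b2, true);
  dA1 += maxpool2_bw(dP1, c.idx1, c.A1.n_rows, c.A1.n_cols);
  cube dZ1 = dA1 % conv_to<cube>::from(c.Z1 > 0);
  return conv_bw(c.X, w.W1, dZ1, g.W1, g.b1, want_dx);
}

static List grads_to_list(const Grads& g) {
  return List::create(
    Named("W1") = g.W1, Named("b1") = g.b1, Named("W2") = g.W2,
    Named("b2") = g.b2, Named("W3") = g.W3, Named("b3") = g.b3,
    Named("T1") = g.T1, Named("bt1") = g.bt1, Named("W4") = g.W4,
    Named("b4") = g.b4, Named("T2") = g.T2, Named("bt2") = g.bt2,
    Named("W5") = g.W5, Named("b5") = g.b5, Named("Wd1") = g.Wd1,
    Named("bd1") = g.bd1, Named("Wd2") = g.Wd2, Named("bd2") = g.bd2);
}

// [[Rcpp::export(name = ".cnn_predict_batch")]]
List cnn_predict_batch(List images, const arma::mat& feats, List weights) {
  const Weights w = unpack(weights);
  const int n = images.size();
  vec y(n);
  mat gap(n, w.W5.n_cols);
  Cache c;
  for (int i = 0; i < n; ++i) {
    forward(Rcpp::as<cube>(images[i]), feats.row(i).t(), w, c);
    y(i) = c.y;
    gap.row(i) = c.v.head(w.W5.n_cols).t();
  }
  return List::create(Named("y") = y, Named("gap") = gap);
}

// mean-absolute-error training step: returns loss and weight gradients
// (of the mean loss over the batch)
// [[Rcpp::export(name = ".cnn_grad_batch")]]
List cnn_grad_batch(List images, const arma::mat& feats, List weights,
                    const arma::vec& targets) {
  const Weights w = unpack(weights);
  const int n = images.size();
  Grads g;
  g.init(w);
  double loss = 0.0;
  Cache c;
  for (int i = 0; i < n; ++i) {
    forward(Rcpp::as<cube>(images[i]), feats.row(i).t(), w, c);
    const double r = c.y - targets(i);
    loss += std::abs(r);
    const double dy = ((r > 0) - (r < 0)) / double(n);
    backward(c, w, dy, g, false);
  }
  List out = grads_to_list(g);
  return List::create(Named("loss") = loss / n, Named("grads") = out);
}

// gradients of the regression output wrt the input image (saliency) and wrt
// the decoder activations (for layer-CAM style maps)
// [[Rcpp::export(name = ".cnn_saliency")]]
List cnn_saliency(const arma::cube& image, const arma::vec& feat,
                  List weights) {
  const Weights w = unpack(weights);
  Cache c;
  forward(image, feat, w, c);
  Grads g;
  g.init(w);
  cube dA5;
  cube dx = backward(c, w, 1.0, g, true, &dA5);
  return List::create(Named("y") = c.y, Named("dx") = dx,
                      Named("dec") = c.A5, Named("ddec") = dA5);
}

// activation shapes observed on a real forward pass (height, width, channels)
// [[Rcpp::export(name = ".cnn_shapes_observed")]]
List cnn_shapes_observed(const arma::cube& image, const arma::vec& feat,
                         List weights) {
  const Weights w = unpack(weights);
  Cache c;
  forward(image, feat, w, c);
  auto dim3 = [](const cube& A) {
    return Rcpp::IntegerVector::create(A.n_rows, A.n_cols, A.n_slices);
  };
  return List::create(Named("encoder") = dim3(c.A3),
                      Named("decoder") = dim3(c.A5),
                      Named("gap_len") = (int)w.W5.n_cols,
                      Named("combined_len") = (int)c.v.n_elem,
                      Named("y") = c.y);
}
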