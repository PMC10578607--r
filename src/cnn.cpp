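// Small convolutional classifier: conv(6,5x5)+ReLU -> maxpool 2x2 ->
// conv(16,5x5)+ReLU -> maxpool 2x2 -> dense 128 ReLU -> dense 64 ReLU ->
// K softmax. Trained with Adam on categorical cross-entropy; 50% inverted
// dropout after both pooling stages and both hidden dense layers (training
// only). He-normal init everywhere except the output layer (Glorot uniform).
// All randomness (init, shuffling, dropout) comes from R's RNG so runs are
// exactly reproducible under set.seed(). Arithmetic is single precision,
// which is ample for a classifier of this size.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

typedef arma::fmat fm;
typedef arma::fvec fv;

struct Dims {
  int H, W, K;
  int H1, W1, P1, Q1, H2, W2, P2, Q2, F;
};

Dims make_dims(int H, int W, int K) {
  Dims d;
  d.H = H; d.W = W; d.K = K;
  d.H1 = H - 4; d.W1 = W - 4;
  if (d.H1 < 2 || d.W1 < 2 || d.H1 % 2 || d.W1 % 2)
    stop("image size incompatible with architecture (first conv/pool stage)");
  d.P1 = d.H1 / 2; d.Q1 = d.W1 / 2;
  d.H2 = d.P1 - 4; d.W2 = d.Q1 - 4;
  if (d.H2 < 2 || d.W2 < 2 || d.H2 % 2 || d.W2 % 2)
    stop("image size incompatible with architecture (second conv/pool stage)");
  d.P2 = d.H2 / 2; d.Q2 = d.W2 / 2;
  d.F = d.P2 * d.Q2 * 16;
  return d;
}

// im2col for 5x5 valid convolution over C channel maps stored as a
// (C x B*Hin*Win) matrix (positions col-major per image)
fm im2col5(const fm& maps, int C, int B, int Hin, int Win, int Ho, int Wo) {
  fm out(C * 25, (arma::uword)B * Ho * Wo);
  const int in_per_img = Hin * Win, out_per_img = Ho * Wo;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        float* dst = out.colptr((arma::uword)b * out_per_img + c * Ho + r);
        for (int ch = 0; ch < C; ++ch) {
          const float* src = maps.memptr() +
            ((arma::uword)b * in_per_img + c * Hin + r) * maps.n_rows + ch;
          // walk the 5x5 patch; maps is column-major with C rows
          for (int kc = 0; kc < 5; ++kc)
            for (int kr = 0; kr < 5; ++kr)
              dst[ch * 25 + kc * 5 + kr] = src[(kc * Hin + kr) * maps.n_rows];
        }
      }
    }
  }
  return out;
}

// scatter-add counterpart of im2col5
void col2im5(const fm& dcol, fm& dmaps, int C, int B, int Hin, int Win,
             int Ho, int Wo) {
  const int in_per_img = Hin * Win, out_per_img = Ho * Wo;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        const float* src = dcol.colptr((arma::uword)b * out_per_img + c * Ho + r);
        for (int ch = 0; ch < C; ++ch) {
          float* dst = dmaps.memptr() +
            ((arma::uword)b * in_per_img + c * Hin + r) * dmaps.n_rows + ch;
          for (int kc = 0; kc < 5; ++kc)
            for (int kr = 0; kr < 5; ++kr)
              dst[(kc * Hin + kr) * dmaps.n_rows] += src[ch * 25 + kc * 5 + kr];
        }
      }
    }
  }
}

// 2x2 max pooling, stride 2; records the argmax source column per cell
void maxpool2(const fm& in, int C, int B, int Hin, int Win,
              fm& out, arma::umat& idx) {
  const int Ho = Hin / 2, Wo = Win / 2;
  const int in_per_img = Hin * Win, out_per_img = Ho * Wo;
  out.set_size(C, (arma::uword)B * out_per_img);
  idx.set_size(C, (arma::uword)B * out_per_img);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        const arma::uword col = (arma::uword)b * out_per_img + c * Ho + r;
        for (int ch = 0; ch < C; ++ch) {
          float best = -std::numeric_limits<float>::infinity();
          arma::uword bi = 0;
          for (int dc = 0; dc < 2; ++dc) {
            for (int dr = 0; dr < 2; ++dr) {
              const arma::uword src =
                (arma::uword)b * in_per_img + (2 * c + dc) * Hin + 2 * r + dr;
              const float val = in(ch, src);
              if (val > best) { best = val; bi = src; }
            }
          }
          out(ch, col) = best;
          idx(ch, col) = bi;
        }
      }
    }
  }
}

void relu_inplace(fm& z) {
  float* p = z.memptr();
  for (arma::uword j = 0; j < z.n_elem; ++j) if (p[j] < 0.f) p[j] = 0.f;
}

// dA *= (act > 0), where act is the pre-dropout ReLU output
void relu_backward(fm& dA, const fm& act) {
  float* p = dA.memptr();
  const float* a = act.memptr();
  for (arma::uword j = 0; j < dA.n_elem; ++j) if (a[j] <= 0.f) p[j] = 0.f;
}

fm dropout_mask(arma::uword nr, arma::uword nc, double p) {
  fm m(nr, nc);
  const double keep = 1.0 - p;
  const float inv = (float)(1.0 / keep);
  float* q = m.memptr();
  for (arma::uword j = 0; j < m.n_elem; ++j)
    q[j] = (unif_rand() < keep) ? inv : 0.f;
  return m;
}

fm he_normal(arma::uword nr, arma::uword nc, double fan_in) {
  fm w(nr, nc);
  const double sd = std::sqrt(2.0 / fan_in);
  float* p = w.memptr();
  for (arma::uword j = 0; j < w.n_elem; ++j) p[j] = (float)(sd * norm_rand());
  return w;
}

void softmax_cols(fm& Z) {
  for (arma::uword j = 0; j < Z.n_cols; ++j) {
    fv z = Z.col(j);
    z -= z.max();
    z = arma::exp(z);
    Z.col(j) = z / arma::accu(z);
  }
}

struct Params {
  fm W1, W2, W3, W4, W5;
  fv b1, b2, b3, b4, b5;
};

Params params_from_list(const List& w) {
  Params p;
  p.W1 = arma::conv_to<fm>::from(as<arma::mat>(w["W1"]));
  p.W2 = arma::conv_to<fm>::from(as<arma::mat>(w["W2"]));
  p.W3 = arma::conv_to<fm>::from(as<arma::mat>(w["W3"]));
  p.W4 = arma::conv_to<fm>::from(as<arma::mat>(w["W4"]));
  p.W5 = arma::conv_to<fm>::from(as<arma::mat>(w["W5"]));
  p.b1 = arma::conv_to<fv>::from(as<arma::vec>(w["b1"]));
  p.b2 = arma::conv_to<fv>::from(as<arma::vec>(w["b2"]));
  p.b3 = arma::conv_to<fv>::from(as<arma::vec>(w["b3"]));
  p.b4 = arma::conv_to<fv>::from(as<arma::vec>(w["b4"]));
  p.b5 = arma::conv_to<fv>::from(as<arma::vec>(w["b5"]));
  return p;
}

List params_to_list(const Params& p, int H, int W, int K) {
  return List::create(
    _["W1"] = arma::conv_to<arma::mat>::from(p.W1),
    _["b1"] = arma::conv_to<arma::vec>::from(p.b1),
    _["W2"] = arma::conv_to<arma::mat>::from(p.W2),
    _["b2"] = arma::conv_to<arma::vec>::from(p.b2),
    _["W3"] = arma::conv_to<arma::mat>::from(p.W3),
    _["b3"] = arma::conv_to<arma::vec>::from(p.b3),
    _["W4"] = arma::conv_to<arma::mat>::from(p.W4),
    _["b4"] = arma::conv_to<arma::vec>::from(p.b4),
    _["W5"] = arma::conv_to<arma::mat>::from(p.W5),
    _["b5"] = arma::conv_to<arma::vec>::from(p.b5),
    _["H"] = H, _["W"] = W, _["K"] = K);
}

// copy selected image columns of X into the (1 x B*H*W) channel-map layout
fm gather_inputs(const fm& X, const std::vector<int>& sel) {
  const arma::uword HW = X.n_rows, B = sel.size();
  fm maps(1, B * HW);
  for (arma::uword b = 0; b < B; ++b)
    std::copy(X.colptr(sel[b]), X.colptr(sel[b]) + HW, maps.memptr() + b * HW);
  return maps;
}

struct Adam {
  fm m, v;
  Adam(arma::uword r, arma::uword c) : m(r, c, arma::fill::zeros),
                                       v(r, c, arma::fill::zeros) {}
  void step(fm& W, const fm& g, double lr, int t) {
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    const float c1 = (float)(lr / (1.0 - std::pow((double)b1, t)));
    const float c2 = (float)(1.0 / (1.0 - std::pow((double)b2, t)));
    float* mp = m.memptr(); float* vp = v.memptr();
    float* wp = W.memptr(); const float* gp = g.memptr();
    for (arma::uword j = 0; j < W.n_elem; ++j) {
      mp[j] = b1 * mp[j] + (1.f - b1) * gp[j];
      vp[j] = b2 * vp[j] + (1.f - b2) * gp[j] * gp[j];
      wp[j] -= c1 * mp[j] / (std::sqrt(c2 * vp[j]) + eps);
    }
  }
  void step_vec(fv& b, const fv& g, double lr, int t) {
    fm bw(b); fm gw(g);
    step(bw, gw, lr, t);
    b = bw.col(0);
  }
};

struct Forward {
  fm M1, Z1p, P1d, M2, Z2p, P2d, Fmat, A3, A4, P;
  fm D1, D2, D3, D4;
  arma::umat I1, I2;
};

// forward pass over one batch; training = true applies dropout and keeps
// everything the backward pass needs
void forward_batch(const Params& p, const Dims& d, const fm& X,
                   const std::vector<int>& sel, double dropout, bool training,
                   Forward& f) {
  const int B = sel.size();
  fm X0 = gather_inputs(X, sel);
  f.M1 = im2col5(X0, 1, B, d.H, d.W, d.H1, d.W1);
  fm Z1 = p.W1 * f.M1; Z1.each_col() += p.b1;
  relu_inplace(Z1);
  fm P1out; maxpool2(Z1, 6, B, d.H1, d.W1, P1out, f.I1);
  f.Z1p = std::move(Z1);
  if (training) {
    f.D1 = dropout_mask(P1out.n_rows, P1out.n_cols, dropout);
    f.P1d = P1out % f.D1;
  } else f.P1d = std::move(P1out);

  f.M2 = im2col5(f.P1d, 6, B, d.P1, d.Q1, d.H2, d.W2);
  fm Z2 = p.W2 * f.M2; Z2.each_col() += p.b2;
  relu_inplace(Z2);
  fm P2out; maxpool2(Z2, 16, B, d.H2, d.W2, P2out, f.I2);
  f.Z2p = std::move(Z2);
  if (training) {
    f.D2 = dropout_mask(P2out.n_rows, P2out.n_cols, dropout);
    f.P2d = P2out % f.D2;
  } else f.P2d = std::move(P2out);

  // flatten: feature index = pos + P2*Q2*ch (pos col-major within map)
  const int per_img2 = d.P2 * d.Q2;
  f.Fmat.set_size(d.F, B);
  for (int b = 0; b < B; ++b)
    for (int ch = 0; ch < 16; ++ch)
      for (int pos = 0; pos < per_img2; ++pos)
        f.Fmat(pos + per_img2 * ch, b) = f.P2d(ch, (arma::uword)b * per_img2 + pos);

  fm Z3 = p.W3 * f.Fmat; Z3.each_col() += p.b3;
  relu_inplace(Z3);
  if (training) {
    f.D3 = dropout_mask(Z3.n_rows, Z3.n_cols, dropout);
    f.A3 = Z3 % f.D3;
  } else f.A3 = Z3;
  fm Z4 = p.W4 * f.A3; Z4.each_col() += p.b4;
  relu_inplace(Z4);
  if (training) {
    f.D4 = dropout_mask(Z4.n_rows, Z4.n_cols, dropout);
    f.A4 = Z4 % f.D4;
  } else f.A4 = Z4;
  f.P = p.W5 * f.A4; f.P.each_col() += p.b5;
  softmax_cols(f.P);
}

}  // namespace

// [[Rcpp::export]]
List cnn_init_cpp(int H, int W, int K) {
  Dims d = make_dims(H, W, K);
  Params p;
  p.W1 = he_normal(6, 25, 25.0);
  p.W2 = he_normal(16, 150, 150.0);
  p.W3 = he_normal(128, d.F, d.F);
  p.W4 = he_normal(64, 128, 128.0);
  const double lim = std::sqrt(6.0 / (64.0 + K));
  p.W5.set_size(K, 64);
  for (arma::uword j = 0; j < p.W5.n_elem; ++j)
    p.W5[j] = (float)((2.0 * unif_rand() - 1.0) * lim);
  p.b1.zeros(6); p.b2.zeros(16); p.b3.zeros(128); p.b4.zeros(64); p.b5.zeros(K);
  return params_to_list(p, H, W, K);
}

// [[Rcpp::export]]
List cnn_train_cpp(List weights, const arma::mat& Xin, const IntegerVector& y,
                   int epochs, int batch_size, double lr, double dropout) {
  Params p = params_from_list(weights);
  const int H = as<int>(weights["H"]), W = as<int>(weights["W"]),
            K = as<int>(weights["K"]);
  Dims d = make_dims(H, W, K);
  const fm X = arma::conv_to<fm>::from(Xin);
  const int n = X.n_cols;
  if ((int)X.n_rows != H * W) stop("image size incompatible with weights");
  for (int i = 0; i < n; ++i)
    if (y[i] < 0 || y[i] >= K) stop("label outside 0..K-1");

  Adam aW1(6, 25), aW2(16, 150), aW3(128, d.F), aW4(64, 128), aW5(K, 64);
  Adam ab1(6, 1), ab2(16, 1), ab3(128, 1), ab4(64, 1), ab5(K, 1);
  int t = 0;

  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  Forward f;
  const int per_img2 = d.P2 * d.Q2;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = n - 1; i > 0; --i) {          // Fisher-Yates with R's RNG
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    for (int start = 0; start < n; start += batch_size) {
      const int B = std::min(batch_size, n - start);
      std::vector<int> sel(perm.begin() + start, perm.begin() + start + B);
      forward_batch(p, d, X, sel, dropout, true, f);

      fm dZ5 = f.P;
      for (int i = 0; i < B; ++i) dZ5(y[sel[i]], i) -= 1.f;
      dZ5 /= (float)B;

      fm dW5 = dZ5 * f.A4.t();
      fv db5 = arma::sum(dZ5, 1);
      fm dA4 = (p.W5.t() * dZ5) % f.D4;
      relu_backward(dA4, f.A4);                // A4 = relu(Z4) % D4; D4 >= 0

      fm dW4 = dA4 * f.A3.t();
      fv db4 = arma::sum(dA4, 1);
      fm dA3 = (p.W4.t() * dA4) % f.D3;
      relu_backward(dA3, f.A3);

      fm dW3 = dA3 * f.Fmat.t();
      fv db3 = arma::sum(dA3, 1);
      fm dF = p.W3.t() * dA3;

      fm dP2d(16, f.P2d.n_cols);
      for (int b = 0; b < B; ++b)
        for (int ch = 0; ch < 16; ++ch)
          for (int pos = 0; pos < per_img2; ++pos)
            dP2d(ch, (arma::uword)b * per_img2 + pos) = dF(pos + per_img2 * ch, b);
      dP2d %= f.D2;

      fm dA2(16, f.Z2p.n_cols, arma::fill::zeros);
      for (arma::uword j = 0; j < dP2d.n_cols; ++j)
        for (int ch = 0; ch < 16; ++ch)
          dA2(ch, f.I2(ch, j)) += dP2d(ch, j);
      relu_backward(dA2, f.Z2p);

      fm dW2 = dA2 * f.M2.t();
      fv db2 = arma::sum(dA2, 1);
      fm dM2 = p.W2.t() * dA2;
      fm dP1d(6, f.P1d.n_cols, arma::fill::zeros);
      col2im5(dM2, dP1d, 6, B, d.P1, d.Q1, d.H2, d.W2);
      dP1d %= f.D1;

      fm dA1(6, f.Z1p.n_cols, arma::fill::zeros);
      for (arma::uword j = 0; j < dP1d.n_cols; ++j)
        for (int ch = 0; ch < 6; ++ch)
          dA1(ch, f.I1(ch, j)) += dP1d(ch, j);
      relu_backward(dA1, f.Z1p);

      fm dW1 = dA1 * f.M1.t();
      fv db1 = arma::sum(dA1, 1);

      ++t;
      aW1.step(p.W1, dW1, lr, t); aW2.step(p.W2, dW2, lr, t);
      aW3.step(p.W3, dW3, lr, t); aW4.step(p.W4, dW4, lr, t);
      aW5.step(p.W5, dW5, lr, t);
      ab1.step_vec(p.b1, db1, lr, t); ab2.step_vec(p.b2, db2, lr, t);
      ab3.step_vec(p.b3, db3, lr, t); ab4.step_vec(p.b4, db4, lr, t);
      ab5.step_vec(p.b5, db5, lr, t);
    }
    if (ep % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return params_to_list(p, H, W, K);
}

// [[Rcpp::export]]
arma::mat cnn_predict_cpp(List weights, const arma::mat& Xin) {
  Params p = params_from_list(weights);
  const int H = as<int>(weights["H"]), W = as<int>(weights["W"]),
            K = as<int>(weights["K"]);
  Dims d = make_dims(H, W, K);
  const fm X = arma::conv_to<fm>::from(Xin);
  const int n = X.n_cols;
  if ((int)X.n_rows != H * W) stop("image size incompatible with weights");
  arma::mat probs(n, K);
  const int chunk = 256;
  Forward f;
  for (int start = 0; start < n; start += chunk) {
    const int B = std::min(chunk, n - start);
    std::vector<int> sel(B);
    for (int i = 0; i < B; ++i) sel[i] = start + i;
    forward_batch(p, d, X, sel, 0.0, false, f);
    probs.rows(start, start + B - 1) =
      arma::conv_to<arma::mat>::from(f.P.t());
  }
  return probs;
}
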