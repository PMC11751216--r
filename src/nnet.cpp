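// Minimal single-precision training/inference engine for the two fixed
// architectures used as deep feature extractors: a CNN-LSTM over 19x300 EEG
// windows and a LeNet-5 over 64x64 gaze plots. Feature maps are stored as
// (channels x H*W) matrices with column-major spatial indexing s = i + j*H.
// All randomness (weight init, shuffling) happens on the R side; these
// routines are deterministic given their inputs.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#if defined(__SSE2__) || defined(__x86_64__)
#include <xmmintrin.h>
#include <pmmintrin.h>
// Vanishing gradients over the 14,016-step BPTT reach float denormal range,
// where x86 arithmetic is ~100x slower; flush them to zero for the duration
// of a call and restore the caller's FP mode afterwards.
struct FlushDenormals {
  unsigned int saved;
  FlushDenormals() : saved(_mm_getcsr()) { _mm_setcsr(saved | 0x8040); }
  ~FlushDenormals() { _mm_setcsr(saved); }
};
#else
struct FlushDenormals {};
#endif
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

namespace {

inline fmat as_f(Rcpp::NumericMatrix m) {
  mat d(m.begin(), m.nrow(), m.ncol(), false);
  return conv_to<fmat>::from(d);
}

inline Rcpp::NumericMatrix as_r(const fmat& f) {
  mat d = conv_to<mat>::from(f);
  return Rcpp::wrap(d);
}

// im2col for valid KxK stride-1 convolution; fm is C x (H*W).
fmat im2col(const fmat& fm, int C, int H, int W, int K) {
  const int oH = H - K + 1, oW = W - K + 1;
  fmat out(C * K * K, oH * oW);
  for (int j = 0; j < oW; ++j) {
    for (int i = 0; i < oH; ++i) {
      const int col = i + j * oH;
      for (int kj = 0; kj < K; ++kj) {
        for (int ki = 0; ki < K; ++ki) {
          const int s = (i + ki) + (j + kj) * H;
          const int r0 = (ki + kj * K) * C;
          for (int c = 0; c < C; ++c) out(r0 + c, col) = fm(c, s);
        }
      }
    }
  }
  return out;
}

// accumulate columns of `cols` back into a C x (H*W) map (adjoint of im2col)
fmat col2im(const fmat& cols, int C, int H, int W, int K) {
  const int oH = H - K + 1, oW = W - K + 1;
  fmat fm(C, H * W, fill::zeros);
  for (int j = 0; j < oW; ++j) {
    for (int i = 0; i < oH; ++i) {
      const int col = i + j * oH;
      for (int kj = 0; kj < K; ++kj) {
        for (int ki = 0; ki < K; ++ki) {
          const int s = (i + ki) + (j + kj) * H;
          const int r0 = (ki + kj * K) * C;
          for (int c = 0; c < C; ++c) fm(c, s) += cols(r0 + c, col);
        }
      }
    }
  }
  return fm;
}

// 2x2 stride-2 max pooling (floor mode); records argmax spatial index
void maxpool(const fmat& fm, int C, int H, int W, fmat& out, umat& idx) {
  const int oH = H / 2, oW = W / 2;
  out.set_size(C, oH * oW);
  idx.set_size(C, oH * oW);
  for (int j = 0; j < oW; ++j) {
    for (int i = 0; i < oH; ++i) {
      const int o = i + j * oH;
      const int s00 = 2 * i + 2 * j * H;
      const int cand[4] = {s00, s00 + 1, s00 + H, s00 + H + 1};
      for (int c = 0; c < C; ++c) {
        float best = fm(c, cand[0]); int bs = cand[0];
        for (int k = 1; k < 4; ++k)
          if (fm(c, cand[k]) > best) { best = fm(c, cand[k]); bs = cand[k]; }
        out(c, o) = best; idx(c, o) = bs;
      }
    }
  }
}

fmat maxpool_back(const fmat& dout, const umat& idx, int C, int HW) {
  fmat din(C, HW, fill::zeros);
  for (uword o = 0; o < dout.n_cols; ++o)
    for (int c = 0; c < C; ++c) din(c, idx(c, o)) += dout(c, o);
  return din;
}

inline fmat sigmf(const fmat& z) { return 1.0f / (1.0f + exp(-z)); }

struct Adam {
  std::vector<fmat> m, v;
  float b1, b2, lr, eps;
  long t = 0;
  void init(const std::vector<fmat*>& ws, float lr_, float b1_, float b2_, float eps_) {
    lr = lr_; b1 = b1_; b2 = b2_; eps = eps_;
    for (auto* w : ws) { m.emplace_back(size(*w), fill::zeros); v.emplace_back(size(*w), fill::zeros); }
  }
  void step(std::vector<fmat*>& ws, const std::vector<fmat*>& gs) {
    ++t;
    const float c1 = 1.0f - std::pow(b1, (float)t), c2 = 1.0f - std::pow(b2, (float)t);
    for (size_t k = 0; k < ws.size(); ++k) {
      m[k] = b1 * m[k] + (1.0f - b1) * (*gs[k]);
      v[k] = b2 * v[k] + (1.0f - b2) * square(*gs[k]);
      *ws[k] -= lr * (m[k] / c1) / (sqrt(v[k] / c2) + eps);
    }
  }
};

// ---------------- CNN-LSTM (EEG) ----------------
// input 19x300x1 -> conv 3x3x32 -> pool -> conv 3x3x64 -> pool ->
// flatten 14016 -> reshape (14016,1) -> LSTM 64 -> dense 128 -> dense 64 -> sigmoid

struct CnnLstm {
  fmat W1, W2, Wx, Wh, Wf1, Wf2, Wo;     // conv1 32x9, conv2 64x288, lstm, dense
  fvec b1, b2, bl, bf1, bf2, bo;
  static const int H1 = 19, W1d = 300;
  static const int oH1 = 17, oW1 = 298, pH1 = 8, pW1 = 149;
  static const int oH2 = 6, oW2 = 147, pH2 = 3, pW2 = 73;
  static const int T = 64 * pH2 * pW2;   // 14016
  static const int HU = 64;              // LSTM units

  void load(const List& w) {
    W1 = as_f(w["conv1_W"]); b1 = conv_to<fvec>::from(as_f(w["conv1_b"]));
    W2 = as_f(w["conv2_W"]); b2 = conv_to<fvec>::from(as_f(w["conv2_b"]));
    Wx = as_f(w["lstm_Wx"]); Wh = as_f(w["lstm_Wh"]); bl = conv_to<fvec>::from(as_f(w["lstm_b"]));
    Wf1 = as_f(w["fc1_W"]); bf1 = conv_to<fvec>::from(as_f(w["fc1_b"]));
    Wf2 = as_f(w["fc2_W"]); bf2 = conv_to<fvec>::from(as_f(w["fc2_b"]));
    Wo = as_f(w["out_W"]); bo = conv_to<fvec>::from(as_f(w["out_b"]));
  }
  List dump() const {
    return List::create(
      Named("conv1_W") = as_r(W1), Named("conv1_b") = as_r(fmat(b1)),
      Named("conv2_W") = as_r(W2), Named("conv2_b") = as_r(fmat(b2)),
      Named("lstm_Wx") = as_r(Wx), Named("lstm_Wh") = as_r(Wh), Named("lstm_b") = as_r(fmat(bl)),
      Named("fc1_W") = as_r(Wf1), Named("fc1_b") = as_r(fmat(bf1)),
      Named("fc2_W") = as_r(Wf2), Named("fc2_b") = as_r(fmat(bf2)),
      Named("out_W") = as_r(Wo), Named("out_b") = as_r(fmat(bo)));
  }

  // conv stack for one sample; returns flatten vector, optionally caches
  fvec conv_forward(const fmat& x, fmat* P1c, fmat* A1c, umat* I1c,
                    fmat* P2c, fmat* A2c, umat* I2c) const {
    fmat fm0 = reshape(x, 1, H1 * W1d);           // 1 x (19*300), s = i + j*19
    fmat P1 = im2col(fm0, 1, H1, W1d, 3);
    fmat A1 = W1 * P1; A1.each_col() += b1;       // 32 x 5066
    fmat R1 = clamp(A1, 0.0f, fdatum::inf);
    fmat pooled1; umat idx1;
    maxpool(R1, 32, oH1, oW1, pooled1, idx1);     // 32 x 1192
    fmat P2 = im2col(pooled1, 32, pH1, pW1, 3);
    fmat A2 = W2 * P2; A2.each_col() += b2;       // 64 x 882
    fmat R2 = clamp(A2, 0.0f, fdatum::inf);
    fmat pooled2; umat idx2;
    maxpool(R2, 64, oH2, oW2, pooled2, idx2);     // 64 x 219
    if (P1c) { *P1c = P1; *A1c = A1; *I1c = idx1; *P2c = P2; *A2c = A2; *I2c = idx2; }
    return vectorise(pooled2);                    // 14016, channel-fastest
  }

  // full forward for a batch (columns of Xseq are per-sample flatten vectors)
  // returns sigmoid outputs; caches LSTM internals when train = true
  frowvec head_forward(const fmat& Xseq, bool train,
                       fcube* G, fcube* Hs, fcube* Cs,
                       fmat* H1a, fmat* H2a) const {
    const int B = Xseq.n_cols;
    fmat h(HU, B, fill::zeros), c(HU, B, fill::zeros);
    fmat z(4 * HU, B), gates(4 * HU, B);
    if (train) { G->set_size(4 * HU, B, T); Hs->set_size(HU, B, T); Cs->set_size(HU, B, T); }
    for (int t = 0; t < T; ++t) {
      z = Wh * h;
      z += Wx * Xseq.row(t);
      z.each_col() += bl;
      gates.rows(0, 2 * HU - 1) = 1.0f / (1.0f + exp(-z.rows(0, 2 * HU - 1)));
      gates.rows(2 * HU, 3 * HU - 1) = tanh(z.rows(2 * HU, 3 * HU - 1));
      gates.rows(3 * HU, 4 * HU - 1) = 1.0f / (1.0f + exp(-z.rows(3 * HU, 4 * HU - 1)));
      c = gates.rows(HU, 2 * HU - 1) % c +
          gates.rows(0, HU - 1) % gates.rows(2 * HU, 3 * HU - 1);
      h = gates.rows(3 * HU, 4 * HU - 1) % tanh(c);
      if (train) {
        G->slice(t) = gates;
        Hs->slice(t) = h; Cs->slice(t) = c;
      }
    }
    fmat a1 = Wf1 * h; a1.each_col() += bf1; fmat h1 = clamp(a1, 0.0f, fdatum::inf);
    fmat a2 = Wf2 * h1; a2.each_col() += bf2; fmat h2 = clamp(a2, 0.0f, fdatum::inf);
    fmat zo = Wo * h2; zo.each_col() += bo;
    if (H1a) { *H1a = h1; *H2a = h2; }
    return sigmf(zo).row(0);
  }
};

// ---------------- LeNet-5 (gaze plots) ----------------
struct LeNet {
  fmat W1, W2, Wf1, Wf2, Wo;
  fvec b1, b2, bf1, bf2, bo;
  static const int Hin = 64;
  static const int oH1 = 60, pH1 = 30, oH2 = 26, pH2 = 13;
  static const int FD = 16 * pH2 * pH2;  // 2704

  void load(const List& w) {
    W1 = as_f(w["conv1_W"]); b1 = conv_to<fvec>::from(as_f(w["conv1_b"]));
    W2 = as_f(w["conv2_W"]); b2 = conv_to<fvec>::from(as_f(w["conv2_b"]));
    Wf1 = as_f(w["fc1_W"]); bf1 = conv_to<fvec>::from(as_f(w["fc1_b"]));
    Wf2 = as_f(w["fc2_W"]); bf2 = conv_to<fvec>::from(as_f(w["fc2_b"]));
    Wo = as_f(w["out_W"]); bo = conv_to<fvec>::from(as_f(w["out_b"]));
  }
  List dump() const {
    return List::create(
      Named("conv1_W") = as_r(W1), Named("conv1_b") = as_r(fmat(b1)),
      Named("conv2_W") = as_r(W2), Named("conv2_b") = as_r(fmat(b2)),
      Named("fc1_W") = as_r(Wf1), Named("fc1_b") = as_r(fmat(bf1)),
      Named("fc2_W") = as_r(Wf2), Named("fc2_b") = as_r(fmat(bf2)),
      Named("out_W") = as_r(Wo), Named("out_b") = as_r(fmat(bo)));
  }

  fvec conv_forward(const fmat& x, fmat* P1c, fmat* A1c, umat* I1c,
                    fmat* P2c, fmat* A2c, umat* I2c) const {
    fmat fm0 = reshape(x, 1, Hin * Hin);
    fmat P1 = im2col(fm0, 1, Hin, Hin, 5);
    fmat A1 = W1 * P1; A1.each_col() += b1;
    fmat R1 = clamp(A1, 0.0f, fdatum::inf);
    fmat pooled1; umat idx1;
    maxpool(R1, 6, oH1, oH1, pooled1, idx1);
    fmat P2 = im2col(pooled1, 6, pH1, pH1, 5);
    fmat A2 = W2 * P2; A2.each_col() += b2;
    fmat R2 = clamp(A2, 0.0f, fdatum::inf);
    fmat pooled2; umat idx2;
    maxpool(R2, 16, oH2, oH2, pooled2, idx2);
    if (P1c) { *P1c = P1; *A1c = A1; *I1c = idx1; *P2c = P2; *A2c = A2; *I2c = idx2; }
    return vectorise(pooled2);
  }
};

fcube load_cube(const Rcpp::NumericVector& X) {
  Rcpp::IntegerVector dm = X.attr("dim");
  fcube f(dm[0], dm[1], dm[2]);
  const double* p = X.begin();
  float* q = f.memptr();
  for (uword i = 0; i < f.n_elem; ++i) q[i] = (float)p[i];
  return f;
}

}  // namespace

// [[Rcpp::export]]
List cnnlstm_train_cpp(List weights, Rcpp::NumericVector X, Rcpp::NumericVector y,
                       Rcpp::IntegerMatrix order, int batch, double lr,
                       double beta1, double beta2, double eps, int loss_type) {
  FlushDenormals ftz;
  CnnLstm net; net.load(weights);
  fcube Xs = load_cube(X);
  const int n = Xs.n_slices, epochs = order.nrow();
  std::vector<fmat*> ws; std::vector<fmat> bs_as_mat;
  // treat biases as 1-col matrices so Adam can handle a uniform list
  fmat b1m(net.b1), b2m(net.b2), blm(net.bl), bf1m(net.bf1), bf2m(net.bf2), bom(net.bo);
  ws = { &net.W1, &b1m, &net.W2, &b2m, &net.Wx, &net.Wh, &blm,
         &net.Wf1, &bf1m, &net.Wf2, &bf2m, &net.Wo, &bom };
  Adam opt; opt.init(ws, (float)lr, (float)beta1, (float)beta2, (float)eps);
  Rcpp::NumericVector loss_hist(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0.0; int n_batches = 0;
    for (int start = 0; start < n; start += batch) {
      const int B = std::min(batch, n - start);
      // conv forward per sample (with caches)
      fmat Xseq(CnnLstm::T, B);
      std::vector<fmat> P1(B), A1(B), P2(B), A2(B);
      std::vector<umat> I1(B), I2(B);
      fvec yb(B);
      for (int b = 0; b < B; ++b) {
        const int s = order(ep, start + b) - 1;
        Xseq.col(b) = net.conv_forward(Xs.slice(s), &P1[b], &A1[b], &I1[b], &P2[b], &A2[b], &I2[b]);
        yb(b) = (float)y[s];
      }
      fcube G, Hs, Cs; fmat h1, h2;
      frowvec p = net.head_forward(Xseq, true, &G, &Hs, &Cs, &h1, &h2);
      fvec pv = p.t();
      double L;
      fmat dzo(1, B);
      if (loss_type == 0) {  // MSE on sigmoid output
        L = accu(square(yb - pv)) / B;
        dzo.row(0) = (2.0f / B) * ((pv - yb) % pv % (1.0f - pv)).t();
      } else {               // binary cross-entropy
        fvec pc = clamp(pv, 1e-7f, 1.0f - 1e-7f);
        L = -accu(yb % log(pc) + (1.0f - yb) % log(1.0f - pc)) / B;
        dzo.row(0) = ((pv - yb) / B).t();
      }
      ep_loss += L; ++n_batches;
      // dense backward
      fmat dWo = dzo * h2.t(); fmat dbo(sum(dzo, 1));
      fmat dh2 = net.Wo.t() * dzo; dh2 %= conv_to<fmat>::from(h2 > 0.0f);
      fmat dWf2 = dh2 * h1.t(); fmat dbf2(sum(dh2, 1));
      fmat dh1 = net.Wf2.t() * dh2; dh1 %= conv_to<fmat>::from(h1 > 0.0f);
      fmat dWf1 = dh1 * Hs.slice(CnnLstm::T - 1).t(); fmat dbf1(sum(dh1, 1));
      fmat dh = net.Wf1.t() * dh1;
      // LSTM BPTT (buffers preallocated; per-t work is elementwise + 2 gemms)
      const int HU = CnnLstm::HU, T = CnnLstm::T;
      fmat dc(HU, B, fill::zeros);
      fmat dWx(size(net.Wx), fill::zeros), dWh(size(net.Wh), fill::zeros);
      fvec dbl(4 * HU, fill::zeros);
      fmat dXseq(T, B);
      fmat gi(HU, B), gf(HU, B), gg(HU, B), go(HU, B);
      fmat tc(HU, B), dz(4 * HU, B), dxt(1, B);
      for (int t = T - 1; t >= 0; --t) {
        const fmat& Gt = G.slice(t);
        gi = Gt.rows(0, HU - 1); gf = Gt.rows(HU, 2 * HU - 1);
        gg = Gt.rows(2 * HU, 3 * HU - 1); go = Gt.rows(3 * HU, 4 * HU - 1);
        tc = tanh(Cs.slice(t));
        dc += dh % go % (1.0f - tc % tc);
        dz.rows(0, HU - 1) = dc % gg % gi % (1.0f - gi);
        if (t > 0)
          dz.rows(HU, 2 * HU - 1) = dc % Cs.slice(t - 1) % gf % (1.0f - gf);
        else
          dz.rows(HU, 2 * HU - 1).zeros();
        dz.rows(2 * HU, 3 * HU - 1) = dc % gi % (1.0f - gg % gg);
        dz.rows(3 * HU, 4 * HU - 1) = dh % tc % go % (1.0f - go);
        dWx += dz * Xseq.row(t).t();
        dbl += sum(dz, 1);
        if (t > 0) {
          dWh += dz * Hs.slice(t - 1).t();
          dh = net.Wh.t() * dz;
          dc %= gf;
        }
        dxt = net.Wx.t() * dz;
        dXseq.row(t) = dxt;
      }
      // conv backward per sample
      fmat dW1(size(net.W1), fill::zeros), dW2(size(net.W2), fill::zeros);
      fvec db1(32, fill::zeros), db2(64, fill::zeros);
      for (int b = 0; b < B; ++b) {
        fmat dP2out = reshape(dXseq.col(b), 64, CnnLstm::pH2 * CnnLstm::pW2);
        fmat dR2 = maxpool_back(dP2out, I2[b], 64, CnnLstm::oH2 * CnnLstm::oW2);
        dR2 %= conv_to<fmat>::from(A2[b] > 0.0f);
        dW2 += dR2 * P2[b].t(); db2 += sum(dR2, 1);
        fmat dP2cols = net.W2.t() * dR2;
        fmat dPool1 = col2im(dP2cols, 32, CnnLstm::pH1, CnnLstm::pW1, 3);
        fmat dR1 = maxpool_back(dPool1, I1[b], 32, CnnLstm::oH1 * CnnLstm::oW1);
        dR1 %= conv_to<fmat>::from(A1[b] > 0.0f);
        dW1 += dR1 * P1[b].t(); db1 += sum(dR1, 1);
      }
      fmat db1m(db1), db2m(db2), dblm(dbl);
      std::vector<fmat*> gs = { &dW1, &db1m, &dW2, &db2m, &dWx, &dWh, &dblm,
                                &dWf1, &dbf1, &dWf2, &dbf2, &dWo, &dbo };
      opt.step(ws, gs);
      // biases live in the net as vectors; sync the optimized copies back
      net.b1 = b1m.col(0); net.b2 = b2m.col(0); net.bl = blm.col(0);
      net.bf1 = bf1m.col(0); net.bf2 = bf2m.col(0); net.bo = bom.col(0);
    }
    loss_hist[ep] = ep_loss / std::max(n_batches, 1);
    Rcpp::checkUserInterrupt();
  }
  net.b1 = b1m.col(0); net.b2 = b2m.col(0); net.bl = blm.col(0);
  net.bf1 = bf1m.col(0); net.bf2 = bf2m.col(0); net.bo = bom.col(0);
  return List::create(Named("weights") = net.dump(), Named("loss") = loss_hist);
}

// layer: 0 = flatten (14016), 1 = last dense (64), 2 = sigmoid output
// [[Rcpp::export]]
Rcpp::NumericMatrix cnnlstm_features_cpp(List weights, Rcpp::NumericVector X, int layer) {
  FlushDenormals ftz;
  CnnLstm net; net.load(weights);
  fcube Xs = load_cube(X);
  const int n = Xs.n_slices;
  if (layer == 0) {
    fmat out(CnnLstm::T, n);
    for (int s = 0; s < n; ++s)
      out.col(s) = net.conv_forward(Xs.slice(s), nullptr, nullptr, nullptr, nullptr, nullptr, nullptr);
    return as_r(out.t());
  }
  const int batch = 32;
  fmat out(layer == 2 ? 1 : 64, n);
  for (int start = 0; start < n; start += batch) {
    const int B = std::min(batch, n - start);
    fmat Xseq(CnnLstm::T, B);
    for (int b = 0; b < B; ++b)
      Xseq.col(b) = net.conv_forward(Xs.slice(start + b), nullptr, nullptr, nullptr, nullptr, nullptr, nullptr);
    fmat h1, h2;
    frowvec p = net.head_forward(Xseq, false, nullptr, nullptr, nullptr, &h1, &h2);
    if (layer == 2) out.cols(start, start + B - 1) = fmat(p);
    else out.cols(start, start + B - 1) = h2;
    Rcpp::checkUserInterrupt();
  }
  return as_r(out.t());
}

// [[Rcpp::export]]
List lenet_train_cpp(List weights, Rcpp::NumericVector X, Rcpp::NumericVector y,
                     Rcpp::IntegerMatrix order, int batch, double lr,
                     double beta1, double beta2, double eps, int loss_type) {
  FlushDenormals ftz;
  LeNet net; net.load(weights);
  fcube Xs = load_cube(X);
  const int n = Xs.n_slices, epochs = order.nrow();
  fmat b1m(net.b1), b2m(net.b2), bf1m(net.bf1), bf2m(net.bf2), bom(net.bo);
  std::vector<fmat*> ws = { &net.W1, &b1m, &net.W2, &b2m,
                            &net.Wf1, &bf1m, &net.Wf2, &bf2m, &net.Wo, &bom };
  Adam opt; opt.init(ws, (float)lr, (float)beta1, (float)beta2, (float)eps);
  Rcpp::NumericVector loss_hist(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0.0; int n_batches = 0;
    for (int start = 0; start < n; start += batch) {
      const int B = std::min(batch, n - start);
      fmat F(LeNet::FD, B); fvec yb(B);
      std::vector<fmat> P1(B), A1(B), P2(B), A2(B);
      std::vector<umat> I1(B), I2(B);
      for (int b = 0; b < B; ++b) {
        const int s = order(ep, start + b) - 1;
        F.col(b) = net.conv_forward(Xs.slice(s), &P1[b], &A1[b], &I1[b], &P2[b], &A2[b], &I2[b]);
        yb(b) = (float)y[s];
      }
      fmat a1 = net.Wf1 * F; a1.each_col() += net.bf1; fmat h1 = clamp(a1, 0.0f, fdatum::inf);
      fmat a2 = net.Wf2 * h1; a2.each_col() += net.bf2; fmat h2 = clamp(a2, 0.0f, fdatum::inf);
      fmat zo = net.Wo * h2; zo.each_col() += net.bo;
      fvec pv = sigmf(zo).row(0).t();
      double L;
      fmat dzo(1, B);
      if (loss_type == 0) {
        L = accu(square(yb - pv)) / B;
        dzo.row(0) = (2.0f / B) * ((pv - yb) % pv % (1.0f - pv)).t();
      } else {
        fvec pc = clamp(pv, 1e-7f, 1.0f - 1e-7f);
        L = -accu(yb % log(pc) + (1.0f - yb) % log(1.0f - pc)) / B;
        dzo.row(0) = ((pv - yb) / B).t();
      }
      ep_loss += L; ++n_batches;
      fmat dWo = dzo * h2.t(); fmat dbo(sum(dzo, 1));
      fmat dh2 = net.Wo.t() * dzo; dh2 %= conv_to<fmat>::from(h2 > 0.0f);
      fmat dWf2 = dh2 * h1.t(); fmat dbf2(sum(dh2, 1));
      fmat dh1 = net.Wf2.t() * dh2; dh1 %= conv_to<fmat>::from(h1 > 0.0f);
      fmat dWf1 = dh1 * F.t(); fmat dbf1(sum(dh1, 1));
      fmat dF = net.Wf1.t() * dh1;
      fmat dW1(size(net.W1), fill::zeros), dW2(size(net.W2), fill::zeros);
      fvec db1(6, fill::zeros), db2(16, fill::zeros);
      for (int b = 0; b < B; ++b) {
        fmat dP2out = reshape(dF.col(b), 16, LeNet::pH2 * LeNet::pH2);
        fmat dR2 = maxpool_back(dP2out, I2[b], 16, LeNet::oH2 * LeNet::oH2);
        dR2 %= conv_to<fmat>::from(A2[b] > 0.0f);
        dW2 += dR2 * P2[b].t(); db2 += sum(dR2, 1);
        fmat dP2cols = net.W2.t() * dR2;
        fmat dPool1 = col2im(dP2cols, 6, LeNet::pH1, LeNet::pH1, 5);
        fmat dR1 = maxpool_back(dPool1, I1[b], 6, LeNet::oH1 * LeNet::oH1);
        dR1 %= conv_to<fmat>::from(A1[b] > 0.0f);
        dW1 += dR1 * P1[b].t(); db1 += sum(dR1, 1);
      }
      fmat db1m2(db1), db2m2(db2);
      std::vector<fmat*> gs = { &dW1, &db1m2, &dW2, &db2m2,
                                &dWf1, &dbf1, &dWf2, &dbf2, &dWo, &dbo };
      opt.step(ws, gs);
      net.b1 = b1m.col(0); net.b2 = b2m.col(0);
      net.bf1 = bf1m.col(0); net.bf2 = bf2m.col(0); net.bo = bom.col(0);
    }
    loss_hist[ep] = ep_loss / std::max(n_batches, 1);
    Rcpp::checkUserInterrupt();
  }
  net.b1 = b1m.col(0); net.b2 = b2m.col(0);
  net.bf1 = bf1m.col(0); net.bf2 = bf2m.col(0); net.bo = bom.col(0);
  return List::create(Named("weights") = net.dump(), Named("loss") = loss_hist);
}

// layer: 0 = flatten (2704), 1 = last dense (84), 2 = sigmoid output
// [[Rcpp::export]]
Rcpp::NumericMatrix lenet_features_cpp(List weights, Rcpp::NumericVector X, int layer) {
  FlushDenormals ftz;
  LeNet net; net.load(weights);
  fcube Xs = load_cube(X);
  const int n = Xs.n_slices;
  fmat F(LeNet::FD, n);
  for (int s = 0; s < n; ++s)
    F.col(s) = net.conv_forward(Xs.slice(s), nullptr, nullptr, nullptr, nullptr, nullptr, nullptr);
  if (layer == 0) return as_r(F.t());
  fmat a1 = net.Wf1 * F; a1.each_col() += net.bf1; fmat h1 = clamp(a1, 0.0f, fdatum::inf);
  fmat a2 = net.Wf2 * h1; a2.each_col() += net.bf2; fmat h2 = clamp(a2, 0.0f, fdatum::inf);
  if (layer == 1) return as_r(h2.t());
  fmat zo = net.Wo * h2; zo.each_col() += net.bo;
  return as_r(fmat(sigmf(zo)).t());
}
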