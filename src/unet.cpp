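// Reduced U-Net heatmap regressor: forward/backward pass, binary
// cross-entropy loss and SGD+Nesterov updates. Single precision
// internally; double at the R interface. All randomness (shuffling,
// initialization, augmentation) lives on the R side, so these routines
// are deterministic given their inputs.
#include <RcppArmadillo.h>
#include <cfloat>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fcube;
using arma::fmat;
using arma::fvec;

namespace {

// Layer spec row: in_ch, out_ch, kernel (odd), relu flag.
struct ConvSpec {
  int in_ch, out_ch, k;
  bool relu;
};

struct Net {
  int depth;
  std::vector<ConvSpec> spec;
  std::vector<fmat> W;  // (in_ch * k * k) x out_ch
  std::vector<fvec> b;  // out_ch
};

fcube as_fcube(SEXP s) {
  NumericVector v(s);
  IntegerVector d = v.attr("dim");
  if (d.size() == 2) {  // single-channel matrix
    fcube A(d[0], d[1], 1);
    std::copy(v.begin(), v.end(), A.memptr());
    return A;
  }
  fcube A(d[0], d[1], d[2]);
  std::copy(v.begin(), v.end(), A.memptr());
  return A;
}

fmat as_fmat(SEXP s) {
  NumericMatrix m(s);
  fmat A(m.nrow(), m.ncol());
  std::copy(m.begin(), m.end(), A.memptr());
  return A;
}

Net build_net(List spec_list, List params) {
  Net net;
  net.depth = as<int>(spec_list["depth"]);
  IntegerMatrix sm = spec_list["layers"];  // L x 4
  int L = sm.nrow();
  List pl = params;
  if (pl.size() != L) stop("parameter list length does not match layer spec");
  for (int i = 0; i < L; ++i) {
    ConvSpec cs{sm(i, 0), sm(i, 1), sm(i, 2), sm(i, 3) != 0};
    net.spec.push_back(cs);
    List p = pl[i];
    fmat W = as_fmat(p["W"]);
    NumericVector bv = p["b"];
    fvec b(bv.size());
    std::copy(bv.begin(), bv.end(), b.memptr());
    if ((int)W.n_rows != cs.in_ch * cs.k * cs.k || (int)W.n_cols != cs.out_ch)
      stop("weight matrix %d has wrong shape", i + 1);
    net.W.push_back(std::move(W));
    net.b.push_back(std::move(b));
  }
  return net;
}

// im2col with zero padding: (H x W x C) -> (H*W) x (C*k*k), column-major
// pixel order matching the cube's slice memory layout.
fmat im2col(const fcube& A, int k) {
  const int H = A.n_rows, W = A.n_cols, C = A.n_slices, p = k / 2;
  fmat out(H * W, C * k * k, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const fmat& S = A.slice(c);
    for (int dx = -p; dx <= p; ++dx) {
      for (int dy = -p; dy <= p; ++dy) {
        const int col = c * k * k + (dx + p) * k + (dy + p);
        const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
        const int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
        float* dst = out.colptr(col);
        for (int x = x0; x < x1; ++x)
          std::memcpy(dst + (size_t)x * H + y0, S.colptr(x + dx) + y0 + dy,
                      sizeof(float) * (y1 - y0));
      }
    }
  }
  return out;
}

fcube col2im(const fmat& dcols, int H, int W, int C, int k) {
  const int p = k / 2;
  fcube dA(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    fmat& S = dA.slice(c);
    for (int dx = -p; dx <= p; ++dx) {
      for (int dy = -p; dy <= p; ++dy) {
        const int col = c * k * k + (dx + p) * k + (dy + p);
        const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
        const int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
        const float* src = dcols.colptr(col);
        for (int x = x0; x < x1; ++x) {
          float* dst = S.colptr(x + dx) + y0 + dy;
          const float* s = src + (size_t)x * H + y0;
          for (int y = 0; y < y1 - y0; ++y) dst[y] += s[y];
        }
      }
    }
  }
  return dA;
}

fcube mat_to_cube(fmat&& Y, int H, int W) {
  fcube out(H, W, Y.n_cols);
  std::memcpy(out.memptr(), Y.memptr(), sizeof(float) * Y.n_elem);
  return out;
}

fcube maxpool(const fcube& A, arma::Cube<arma::u8>& idx) {
  const int H = A.n_rows / 2, W = A.n_cols / 2, C = A.n_slices;
  fcube out(H, W, C);
  idx.set_size(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        float best = -FLT_MAX;
        int bi = 0;
        for (int j = 0; j < 2; ++j)
          for (int i = 0; i < 2; ++i) {
            const float v = A(2 * y + i, 2 * x + j, c);
            if (v > best) { best = v; bi = j * 2 + i; }
          }
        out(y, x, c) = best;
        idx(y, x, c) = (arma::u8)bi;
      }
  return out;
}

fcube maxpool_back(const fcube& dout, const arma::Cube<arma::u8>& idx) {
  const int H = dout.n_rows * 2, W = dout.n_cols * 2, C = dout.n_slices;
  fcube dA(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int x = 0; x < (int)dout.n_cols; ++x)
      for (int y = 0; y < (int)dout.n_rows; ++y) {
        const int bi = idx(y, x, c);
        dA(2 * y + bi % 2, 2 * x + bi / 2, c) = dout(y, x, c);
      }
  return dA;
}

fcube upsample2(const fcube& A) {
  const int H = A.n_rows, W = A.n_cols, C = A.n_slices;
  fcube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        const float v = A(y, x, c);
        out(2 * y, 2 * x, c) = v;
        out(2 * y + 1, 2 * x, c) = v;
        out(2 * y, 2 * x + 1, c) = v;
        out(2 * y + 1, 2 * x + 1, c) = v;
      }
  return out;
}

fcube upsample2_back(const fcube& dout) {
  const int H = dout.n_rows / 2, W = dout.n_cols / 2, C = dout.n_slices;
  fcube dA(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y)
        dA(y, x, c) = dout(2 * y, 2 * x, c) + dout(2 * y + 1, 2 * x, c) +
                      dout(2 * y, 2 * x + 1, c) + dout(2 * y + 1, 2 * x + 1, c);
  return dA;
}

struct ConvState {
  fmat cols;   // im2col of the layer input
  fcube out;   // post-activation output (for the ReLU mask)
};

fcube conv_forward(const Net& net, int li, const fcube& A, ConvState* st) {
  const ConvSpec& cs = net.spec[li];
  fmat cols = (cs.k == 1)
                  ? fmat(const_cast<float*>(A.memptr()), A.n_rows * A.n_cols,
                         A.n_slices)  // 1x1 conv: plain reshape (copy)
                  : im2col(A, cs.k);
  fmat Y = cols * net.W[li];
  Y.each_row() += net.b[li].t();
  if (cs.relu) Y.transform([](float v) { return v > 0.f ? v : 0.f; });
  fcube out = mat_to_cube(std::move(Y), A.n_rows, A.n_cols);
  if (st) {
    st->cols = std::move(cols);
    st->out = out;
  }
  return out;
}

// Backward through conv layer li. dout is gradient w.r.t. this layer's
// (post-activation) output; returns gradient w.r.t. its input.
fcube conv_backward(const Net& net, int li, const ConvState& st,
                    const fcube& dout, fmat& gW, fvec& gb) {
  const ConvSpec& cs = net.spec[li];
  const int H = dout.n_rows, W = dout.n_cols;
  fmat dY(const_cast<float*>(dout.memptr()), (size_t)H * W, cs.out_ch);
  fmat dYm = dY;  // copy: we may mask it
  if (cs.relu) {
    const fmat Ym(const_cast<float*>(st.out.memptr()), (size_t)H * W, cs.out_ch);
    dYm %= arma::conv_to<fmat>::from(Ym > 0.f);
  }
  gW += st.cols.t() * dYm;
  gb += arma::sum(dYm, 0).t();
  fmat dcols = dYm * net.W[li].t();
  if (cs.k == 1) return mat_to_cube(std::move(dcols), H, W);
  return col2im(dcols, H, W, cs.in_ch, cs.k);
}

double sigmoid_bce(const fcube& logits, const fmat& y, fmat& p, fmat& dlogit) {
  const int H = logits.n_rows, W = logits.n_cols;
  p.set_size(H, W);
  dlogit.set_size(H, W);
  double loss = 0.0;
  const double n = (double)H * W;
  for (int x = 0; x < W; ++x)
    for (int yy = 0; yy < H; ++yy) {
      const double z = logits(yy, x, 0);
      double pr = 1.0 / (1.0 + std::exp(-z));
      pr = std::min(1.0 - 1e-6, std::max(1e-6, pr));
      const double t = y(yy, x);
      loss += -(t * std::log(pr) + (1.0 - t) * std::log(1.0 - pr));
      p(yy, x) = (float)pr;
      dlogit(yy, x) = (float)((pr - t) / n);
    }
  return loss / n;
}

// Forward + (optionally) backward for one sample. Gradients accumulate
// into gW/gb. Returns the mean-pixel BCE loss; fills `pred` with the
// sigmoid heatmap.
double run_sample(const Net& net, const fcube& x, const fmat* y, fmat& pred,
                  std::vector<fmat>* gW, std::vector<fvec>* gb) {
  const int d = net.depth;
  const int L = (int)net.spec.size();
  const bool train = gW != nullptr;
  std::vector<ConvState> st(L);
  std::vector<fcube> skips(d);
  std::vector<arma::Cube<arma::u8>> pidx(d);
  std::vector<int> up_ch(d);

  fcube cur = x;
  int li = 0;
  for (int i = 0; i < d; ++i) {  // encoder
    cur = conv_forward(net, li, cur, train ? &st[li] : nullptr); ++li;
    cur = conv_forward(net, li, cur, train ? &st[li] : nullptr); ++li;
    skips[i] = cur;
    cur = maxpool(cur, pidx[i]);
  }
  cur = conv_forward(net, li, cur, train ? &st[li] : nullptr); ++li;  // bottleneck
  cur = conv_forward(net, li, cur, train ? &st[li] : nullptr); ++li;
  for (int i = d - 1; i >= 0; --i) {  // decoder
    fcube up = upsample2(cur);
    up_ch[i] = up.n_slices;
    cur = arma::join_slices(up, skips[i]);
    cur = conv_forward(net, li, cur, train ? &st[li] : nullptr); ++li;
    cur = conv_forward(net, li, cur, train ? &st[li] : nullptr); ++li;
  }
  fcube logits = conv_forward(net, li, cur, train ? &st[li] : nullptr);

  fmat dlogit;
  double loss = NA_REAL;
  if (y) {
    loss = sigmoid_bce(logits, *y, pred, dlogit);
  } else {
    pred.set_size(logits.n_rows, logits.n_cols);
    for (arma::uword j = 0; j < logits.n_cols; ++j)
      for (arma::uword i2 = 0; i2 < logits.n_rows; ++i2)
        pred(i2, j) = 1.0f / (1.0f + std::exp(-logits(i2, j, 0)));
  }
  if (!train) return loss;

  // backward
  li = L - 1;
  fcube dcur(dlogit.n_rows, dlogit.n_cols, 1);
  std::memcpy(dcur.memptr(), dlogit.memptr(), sizeof(float) * dlogit.n_elem);
  dcur = conv_backward(net, li, st[li], dcur, (*gW)[li], (*gb)[li]); --li;
  std::vector<fcube> dskips(d);
  for (int i = 0; i < d; ++i) {  // decoder levels, shallow to deep
    dcur = conv_backward(net, li, st[li], dcur, (*gW)[li], (*gb)[li]); --li;
    dcur = conv_backward(net, li, st[li], dcur, (*gW)[li], (*gb)[li]); --li;
    const int cu = up_ch[i];
    dskips[i] = dcur.slices(cu, dcur.n_slices - 1);
    dcur = upsample2_back(dcur.slices(0, cu - 1));
  }
  dcur = conv_backward(net, li, st[li], dcur, (*gW)[li], (*gb)[li]); --li;  // bottleneck
  dcur = conv_backward(net, li, st[li], dcur, (*gW)[li], (*gb)[li]); --li;
  for (int i = d - 1; i >= 0; --i) {  // encoder, deep to shallow
    fcube dsk = maxpool_back(dcur, pidx[i]);
    dsk += dskips[i];
    dsk = conv_backward(net, li, st[li], dsk, (*gW)[li], (*gb)[li]); --li;
    dcur = conv_backward(net, li, st[li], dsk, (*gW)[li], (*gb)[li]); --li;
  }
  return loss;
}

List params_out(const Net& net) {
  List out(net.W.size());
  for (size_t i = 0; i < net.W.size(); ++i) {
    const fmat& W = net.W[i];
    NumericMatrix Wm(W.n_rows, W.n_cols);
    std::copy(W.begin(), W.end(), Wm.begin());
    NumericVector bv(net.b[i].n_elem);
    std::copy(net.b[i].begin(), net.b[i].end(), bv.begin());
    out[i] = List::create(_["W"] = Wm, _["b"] = bv);
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_unet_predict(List spec, List params, SEXP x) {
  Net net = build_net(spec, params);
  fcube A = as_fcube(x);
  fmat pred;
  run_sample(net, A, nullptr, pred, nullptr, nullptr);
  NumericMatrix out(pred.n_rows, pred.n_cols);
  std::copy(pred.begin(), pred.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
double cpp_unet_mean_loss(List spec, List params, List X, List Y) {
  Net net = build_net(spec, params);
  double tot = 0.0;
  fmat pred;
  for (int i = 0; i < X.size(); ++i) {
    fcube x = as_fcube(X[i]);
    fmat y = as_fmat(Y[i]);
    tot += run_sample(net, x, &y, pred, nullptr, nullptr);
  }
  return tot / X.size();
}

// Loss and gradients for one sample; used by the finite-difference
// gradient check in the test suite.
// [[Rcpp::export]]
List cpp_unet_sample_grad(List spec, List params, SEXP x, SEXP y) {
  Net net = build_net(spec, params);
  const int L = (int)net.spec.size();
  std::vector<fmat> gW(L);
  std::vector<fvec> gb(L);
  for (int i = 0; i < L; ++i) {
    gW[i].zeros(net.W[i].n_rows, net.W[i].n_cols);
    gb[i].zeros(net.b[i].n_elem);
  }
  fcube xc = as_fcube(x);
  fmat ym = as_fmat(y);
  fmat pred;
  double loss = run_sample(net, xc, &ym, pred, &gW, &gb);
  List grads(L);
  for (int i = 0; i < L; ++i) {
    NumericMatrix Wm(gW[i].n_rows, gW[i].n_cols);
    std::copy(gW[i].begin(), gW[i].end(), Wm.begin());
    NumericVector bv(gb[i].n_elem);
    std::copy(gb[i].begin(), gb[i].end(), bv.begin());
    grads[i] = List::create(_["W"] = Wm, _["b"] = bv);
  }
  return List::create(_["loss"] = loss, _["grads"] = grads);
}

// One epoch of minibatch SGD with Nesterov momentum. `order` is a
// 0-based permutation of samples computed (seeded) on the R side.
// [[Rcpp::export]]
List cpp_unet_train_epoch(List spec, List params, List velocity, List X,
                          List Y, IntegerVector order, int batch_size,
                          double lr, double momentum) {
  Net net = build_net(spec, params);
  const int L = (int)net.spec.size();
  std::vector<fmat> vW(L);
  std::vector<fvec> vb(L);
  List vl = velocity;
  for (int i = 0; i < L; ++i) {
    List v = vl[i];
    vW[i] = as_fmat(v["W"]);
    fvec b(((NumericVector)v["b"]).size());
    NumericVector bv = v["b"];
    std::copy(bv.begin(), bv.end(), b.memptr());
    vb[i] = b;
  }
  const int n = order.size();
  double tot_loss = 0.0;
  int n_batches = 0;
  std::vector<fmat> gW(L);
  std::vector<fvec> gb(L);
  fmat pred;
  for (int s = 0; s < n; s += batch_size) {
    const int e = std::min(n, s + batch_size);
    for (int i = 0; i < L; ++i) {
      gW[i].zeros(net.W[i].n_rows, net.W[i].n_cols);
      gb[i].zeros(net.b[i].n_elem);
    }
    double bl = 0.0;
    for (int j = s; j < e; ++j) {
      fcube x = as_fcube(X[order[j]]);
      fmat y = as_fmat(Y[order[j]]);
      bl += run_sample(net, x, &y, pred, &gW, &gb);
    }
    const float inv = 1.0f / (e - s);
    for (int i = 0; i < L; ++i) {
      gW[i] *= inv;
      gb[i] *= inv;
      // Nesterov: v <- m v - lr g ; theta <- theta + m v - lr g
      vW[i] = (float)momentum * vW[i] - (float)lr * gW[i];
      vb[i] = (float)momentum * vb[i] - (float)lr * gb[i];
      net.W[i] += (float)momentum * vW[i] - (float)lr * gW[i];
      net.b[i] += (float)momentum * vb[i] - (float)lr * gb[i];
    }
    tot_loss += bl / (e - s);
    ++n_batches;
  }
  List vout(L);
  for (int i = 0; i < L; ++i) {
    NumericMatrix Wm(vW[i].n_rows, vW[i].n_cols);
    std::copy(vW[i].begin(), vW[i].end(), Wm.begin());
    NumericVector bv(vb[i].n_elem);
    std::copy(vb[i].begin(), vb[i].end(), bv.begin());
    vout[i] = List::create(_["W"] = Wm, _["b"] = bv);
  }
  return List::create(_["params"] = params_out(net), _["velocity"] = vout,
                      _["train_loss"] = tot_loss / std::max(1, n_batches));
}
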