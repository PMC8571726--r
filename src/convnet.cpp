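// Compiled kernels for the convolutional network and the stimulus audit.
//
// Convolutions are implemented as im2col + GEMM in single precision (the
// network is evaluated, not differentiated, in bulk; gradients for the small
// training pathway are accumulated in double where it matters numerically).
// All arrays use R's column-major layout: images are (H, W, C), kernels are
// (kh, kw, Cin, Cout).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void get_dim3(const NumericVector& x, int& H, int& W, int& C) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array (H, W, C)");
  H = d[0]; W = d[1]; C = d[2];
}

// Build the transposed im2col matrix: rows index output pixels (H*W, column
// major over (i,j)), columns index kernel taps (dh, dw, c). Zero-padded.
static arma::fmat im2col_t(const double* x, int H, int W, int C,
                           int kh, int kw, int pad) {
  const int K = kh * kw * C;
  arma::fmat colT(static_cast<arma::uword>(H) * W, K, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* plane = x + static_cast<size_t>(c) * H * W;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * dw + kh * kw * c;
        float* dst = colT.colptr(r);
        for (int j = 0; j < W; ++j) {
          const int jj = j + dw - pad;
          if (jj < 0 || jj >= W) continue;
          int i0 = std::max(0, pad - dh);
          int i1 = std::min(H, H + pad - dh);  // exclusive
          const double* src = plane + static_cast<size_t>(jj) * H + (i0 + dh - pad);
          float* out = dst + static_cast<size_t>(j) * H + i0;
          for (int i = i0; i < i1; ++i) *out++ = static_cast<float>(*src++);
        }
      }
    }
  }
  return colT;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, NumericVector b,
                         int pad) {
  int H, W, C;
  get_dim3(x, H, W, C);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("kernel must be a 4-d array (kh, kw, Cin, Cout)");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("kernel input channels do not match image channels");
  if (b.size() != Cout) stop("bias length must equal the output channel count");

  arma::fmat colT = im2col_t(REAL(x), H, W, C, kh, kw, pad);
  arma::fmat Wm(kh * kw * Cin, Cout);
  for (size_t t = 0; t < Wm.n_elem; ++t) Wm[t] = static_cast<float>(w[t]);

  arma::fmat Y = colT * Wm;  // (H*W) x Cout
  NumericVector out(static_cast<R_xlen_t>(H) * W * Cout);
  out.attr("dim") = IntegerVector::create(H, W, Cout);
  double* po = REAL(out);
  for (int o = 0; o < Cout; ++o) {
    const float* col = Y.colptr(o);
    const double bo = b[o];
    const size_t n = static_cast<size_t>(H) * W;
    for (size_t t = 0; t < n; ++t) po[t] = static_cast<double>(col[t]) + bo;
    po += n;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int pad) {
  int H, W, C;
  get_dim3(x, H, W, C);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const size_t npix = static_cast<size_t>(H) * W;

  arma::fmat colT = im2col_t(REAL(x), H, W, C, kh, kw, pad);
  arma::fmat DY(npix, Cout);
  const double* pdy = REAL(dy);
  for (size_t t = 0; t < npix * Cout; ++t) DY[t] = static_cast<float>(pdy[t]);

  // weight and bias gradients
  arma::fmat dWm = colT.t() * DY;  // K x Cout
  NumericVector dw(static_cast<R_xlen_t>(kh) * kw * Cin * Cout);
  dw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  for (size_t t = 0; t < dWm.n_elem; ++t) dw[t] = dWm[t];
  NumericVector db(Cout);
  for (int o = 0; o < Cout; ++o) {
    double s = 0;
    const float* col = DY.colptr(o);
    for (size_t t = 0; t < npix; ++t) s += col[t];
    db[o] = s;
  }

  // input gradient: dcolT = DY * Wm', then scatter-add (col2im)
  arma::fmat Wm(kh * kw * Cin, Cout);
  for (size_t t = 0; t < Wm.n_elem; ++t) Wm[t] = static_cast<float>(w[t]);
  arma::fmat dcolT = DY * Wm.t();  // npix x K

  NumericVector dx(static_cast<R_xlen_t>(npix) * C);
  dx.attr("dim") = IntegerVector::create(H, W, C);
  double* pdx = REAL(dx);
  for (int c = 0; c < C; ++c) {
    double* plane = pdx + static_cast<size_t>(c) * npix;
    for (int dw2 = 0; dw2 < kw; ++dw2) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * dw2 + kh * kw * c;
        const float* src = dcolT.colptr(r);
        for (int j = 0; j < W; ++j) {
          const int jj = j + dw2 - pad;
          if (jj < 0 || jj >= W) continue;
          int i0 = std::max(0, pad - dh);
          int i1 = std::min(H, H + pad - dh);
          double* out = plane + static_cast<size_t>(jj) * H + (i0 + dh - pad);
          const float* in = src + static_cast<size_t>(j) * H + i0;
          for (int i = i0; i < i1; ++i) *out++ += static_cast<double>(*in++);
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Non-overlapping 2x2 max pooling; argmax indices (1-based, into x) are
// returned so the training pathway can route gradients.
// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x) {
  int H, W, C;
  get_dim3(x, H, W, C);
  if (H % 2 || W % 2) stop("spatial size must be even for 2x2 pooling");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C);
  IntegerVector amax(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  const double* px = REAL(x);
  double* py = REAL(y);
  R_xlen_t t = 0;
  for (int c = 0; c < C; ++c) {
    const size_t off = static_cast<size_t>(c) * H * W;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i, ++t) {
        size_t base = off + static_cast<size_t>(2 * j) * H + 2 * i;
        size_t idx = base;
        double best = px[base];
        if (px[base + 1] > best) { best = px[base + 1]; idx = base + 1; }
        if (px[base + H] > best) { best = px[base + H]; idx = base + H; }
        if (px[base + H + 1] > best) { best = px[base + H + 1]; idx = base + H + 1; }
        py[t] = best;
        amax[t] = static_cast<int>(idx) + 1;
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector dy, IntegerVector amax,
                                    IntegerVector in_dim) {
  NumericVector dx(static_cast<R_xlen_t>(in_dim[0]) * in_dim[1] * in_dim[2]);
  dx.attr("dim") = in_dim;
  for (R_xlen_t t = 0; t < dy.size(); ++t) dx[amax[t] - 1] += dy[t];
  return dx;
}

// Local response normalization across feature maps at each spatial location:
//   b_i = a_i / (k + alpha * sum_{j in [i-n/2, i+n/2]} max(0, a_j)^2)^beta
// with the neighborhood clipped to [0, N-1] and half-width floor(n/2).
// [[Rcpp::export]]
NumericVector cpp_lrn(NumericVector x, double k, double alpha, double beta,
                      int n) {
  int H, W, C;
  get_dim3(x, H, W, C);
  if (k <= 0 || beta < 0) stop("LRN requires k > 0 and beta >= 0");
  const int half = n / 2;
  const size_t npix = static_cast<size_t>(H) * W;
  const double* px = REAL(x);

  // squared rectified responses, then per-pixel sliding-window sums over maps
  std::vector<double> sq(npix * C);
  for (size_t t = 0; t < npix * C; ++t) {
    double v = px[t] > 0 ? px[t] : 0.0;
    sq[t] = v * v;
  }
  NumericVector y(x.size());
  y.attr("dim") = IntegerVector::create(H, W, C);
  double* py = REAL(y);
  std::vector<double> acc(npix);
  // initial window for channel 0: maps 0..min(C-1, half)
  std::fill(acc.begin(), acc.end(), 0.0);
  for (int j = 0; j <= std::min(C - 1, half); ++j) {
    const double* s = sq.data() + static_cast<size_t>(j) * npix;
    for (size_t t = 0; t < npix; ++t) acc[t] += s[t];
  }
  for (int i = 0; i < C; ++i) {
    const double* xi = px + static_cast<size_t>(i) * npix;
    double* yi = py + static_cast<size_t>(i) * npix;
    for (size_t t = 0; t < npix; ++t)
      yi[t] = xi[t] / std::pow(k + alpha * acc[t], beta);
    // slide window: drop i-half, add i+1+half
    const int drop = i - half, add = i + 1 + half;
    if (drop >= 0) {
      const double* s = sq.data() + static_cast<size_t>(drop) * npix;
      for (size_t t = 0; t < npix; ++t) acc[t] -= s[t];
    }
    if (add < C) {
      const double* s = sq.data() + static_cast<size_t>(add) * npix;
      for (size_t t = 0; t < npix; ++t) acc[t] += s[t];
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_lrn_backward(NumericVector x, NumericVector dy, double k,
                               double alpha, double beta, int n) {
  int H, W, C;
  get_dim3(x, H, W, C);
  const int half = n / 2;
  const size_t npix = static_cast<size_t>(H) * W;
  const double* px = REAL(x);
  const double* pdy = REAL(dy);

  std::vector<double> sq(npix * C), d(npix * C), u(npix * C);
  for (size_t t = 0; t < npix * C; ++t) {
    double v = px[t] > 0 ? px[t] : 0.0;
    sq[t] = v * v;
  }
  // d_i = k + alpha * window sum of sq
  std::vector<double> acc(npix, 0.0);
  for (int j = 0; j <= std::min(C - 1, half); ++j)
    for (size_t t = 0; t < npix; ++t) acc[t] += sq[j * npix + t];
  for (int i = 0; i < C; ++i) {
    for (size_t t = 0; t < npix; ++t) d[i * npix + t] = k + alpha * acc[t];
    const int drop = i - half, add = i + 1 + half;
    if (drop >= 0)
      for (size_t t = 0; t < npix; ++t) acc[t] -= sq[drop * npix + t];
    if (add < C)
      for (size_t t = 0; t < npix; ++t) acc[t] += sq[add * npix + t];
  }
  // u_i = dy_i * x_i * d_i^(-beta-1); T_m = window sum of u around m
  for (size_t t = 0; t < npix * C; ++t)
    u[t] = pdy[t] * px[t] * std::pow(d[t], -beta - 1.0);

  NumericVector dx(x.size());
  dx.attr("dim") = IntegerVector::create(H, W, C);
  double* pdx = REAL(dx);
  std::fill(acc.begin(), acc.end(), 0.0);
  for (int j = 0; j <= std::min(C - 1, half); ++j)
    for (size_t t = 0; t < npix; ++t) acc[t] += u[j * npix + t];
  for (int m = 0; m < C; ++m) {
    const double* xm = px + static_cast<size_t>(m) * npix;
    const double* dym = pdy + static_cast<size_t>(m) * npix;
    const double* dm = d.data() + static_cast<size_t>(m) * npix;
    double* out = pdx + static_cast<size_t>(m) * npix;
    for (size_t t = 0; t < npix; ++t) {
      double cm = xm[t] > 0 ? xm[t] : 0.0;
      out[t] = dym[t] * std::pow(dm[t], -beta) -
               2.0 * alpha * beta * cm * acc[t];
    }
    const int drop = m - half, add = m + 1 + half;
    if (drop >= 0)
      for (size_t t = 0; t < npix; ++t) acc[t] -= u[drop * npix + t];
    if (add < C)
      for (size_t t = 0; t < npix; ++t) acc[t] += u[add * npix + t];
  }
  return dx;
}

// 8-connected component labelling of a binary mask (stimulus audit oracle).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.push_back(i + j * H);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % H, pj = p / H;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
            if (mask(qi, qj) && !lab(qi, qj)) {
              lab(qi, qj) = next;
              stack.push_back(qi + qj * H);
            }
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// Whole-network inference path. Weights are converted to single precision
// once and held behind an external pointer so that bulk stimulus presentation
// avoids per-call conversion and R-side allocation. Batch normalization is
// folded into a per-map scale/offset (evaluation mode, running statistics).

struct NzConv {
  arma::fmat Wm;            // (kh*kw*cin) x cout
  arma::fvec bias, bn_scale, bn_off;
  int kh, kw, cin, cout, pad;
  arma::fmat colT, Y;       // persistent workspaces, sized on first use
};

struct NzNet {
  std::vector<int> role;    // 0 input, 1 conv, 2 maxpool, 3 avgpool, 4 softmax
  std::vector<int> index;   // layer index per row
  std::vector<int> conv_of; // row -> position in convs, or -1
  std::vector<NzConv> convs;
  arma::fmat fcW;           // nclass x nfeat
  arma::fvec fcb;
  float lrn_k, lrn_alpha, lrn_beta;
  int lrn_n, in_size;
  std::vector<arma::fmat> buf;  // persistent per-row output workspaces
};

static void im2col_t_f(const float* x, int H, int W, int C, int kh, int kw,
                       int pad, arma::fmat& colT) {
  const arma::uword npix = static_cast<arma::uword>(H) * W;
  const arma::uword K = static_cast<arma::uword>(kh) * kw * C;
  // padding slots are zero and never touched afterwards, so a persistent
  // workspace only needs zeroing when (re)allocated
  if (colT.n_rows != npix || colT.n_cols != K) colT.zeros(npix, K);
  for (int c = 0; c < C; ++c) {
    const float* plane = x + static_cast<size_t>(c) * H * W;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * dw + kh * kw * c;
        float* dst = colT.colptr(r);
        for (int j = 0; j < W; ++j) {
          const int jj = j + dw - pad;
          if (jj < 0 || jj >= W) continue;
          int i0 = std::max(0, pad - dh);
          int i1 = std::min(H, H + pad - dh);
          const float* src = plane + static_cast<size_t>(jj) * H + (i0 + dh - pad);
          float* out = dst + static_cast<size_t>(j) * H + i0;
          std::copy(src, src + (i1 - i0), out);
        }
      }
    }
  }
}

static void lrn_f(float* x, size_t npix, int C, float k, float alpha,
                  float beta, int n) {
  const int half = n / 2;
  std::vector<float> sq(npix * C);
  for (size_t t = 0; t < npix * C; ++t) {
    float v = x[t] > 0 ? x[t] : 0.0f;
    sq[t] = v * v;
  }
  std::vector<float> acc(npix, 0.0f);
  for (int j = 0; j <= std::min(C - 1, half); ++j)
    for (size_t t = 0; t < npix; ++t) acc[t] += sq[j * npix + t];
  for (int i = 0; i < C; ++i) {
    float* xi = x + static_cast<size_t>(i) * npix;
    for (size_t t = 0; t < npix; ++t)
      xi[t] = xi[t] / std::pow(k + alpha * acc[t], beta);
    const int drop = i - half, add = i + 1 + half;
    if (drop >= 0)
      for (size_t t = 0; t < npix; ++t) acc[t] -= sq[drop * npix + t];
    if (add < C)
      for (size_t t = 0; t < npix; ++t) acc[t] += sq[add * npix + t];
  }
}

// [[Rcpp::export]]
SEXP cpp_net_create(List spec) {
  NzNet* net = new NzNet();
  IntegerVector role = spec["role"], index = spec["index"];
  net->role.assign(role.begin(), role.end());
  net->index.assign(index.begin(), index.end());
  net->in_size = as<int>(spec["in_size"]);
  NumericVector lrn = spec["lrn"];
  net->lrn_k = lrn[0]; net->lrn_alpha = lrn[1]; net->lrn_beta = lrn[2];
  net->lrn_n = static_cast<int>(lrn[3]);
  List convs = spec["convs"];
  net->conv_of.assign(net->role.size(), -1);
  int ci = 0;
  for (size_t r = 0; r < net->role.size(); ++r) {
    if (net->role[r] != 1) continue;
    List cl = convs[ci];
    NumericVector w = cl["w"];
    IntegerVector wd = w.attr("dim");
    NzConv c;
    c.kh = wd[0]; c.kw = wd[1]; c.cin = wd[2]; c.cout = wd[3];
    c.pad = as<int>(cl["pad"]);
    c.Wm.set_size(static_cast<arma::uword>(c.kh) * c.kw * c.cin, c.cout);
    for (size_t t = 0; t < c.Wm.n_elem; ++t) c.Wm[t] = static_cast<float>(w[t]);
    NumericVector b = cl["b"], sc = cl["bn_scale"], of = cl["bn_off"];
    c.bias = arma::conv_to<arma::fvec>::from(as<arma::vec>(b));
    c.bn_scale = arma::conv_to<arma::fvec>::from(as<arma::vec>(sc));
    c.bn_off = arma::conv_to<arma::fvec>::from(as<arma::vec>(of));
    net->conv_of[r] = ci++;
    net->convs.push_back(std::move(c));
  }
  if (spec.containsElementNamed("fcW") && !Rf_isNull(spec["fcW"])) {
    NumericMatrix fw = spec["fcW"];
    NumericVector fb = spec["fcb"];
    net->fcW.set_size(fw.nrow(), fw.ncol());
    for (size_t t = 0; t < net->fcW.n_elem; ++t) net->fcW[t] = static_cast<float>(fw[t]);
    net->fcb = arma::conv_to<arma::fvec>::from(as<arma::vec>(fb));
  }
  XPtr<NzNet> ptr(net, true);
  return ptr;
}

// Forward one image; record >= 0 returns that layer's activation stack,
// record < 0 returns the softmax probabilities.
// [[Rcpp::export]]
NumericVector cpp_net_forward(SEXP ptr, NumericVector img, int record,
                              bool noise_on, double mu, double sigma,
                              int noise_seed) {
  XPtr<NzNet> net(ptr);
  IntegerVector d = img.attr("dim");
  int H = d[0], W = d[1], C = d.size() == 3 ? d[2] : 1;
  if (net->buf.size() != net->role.size()) net->buf.resize(net->role.size());
  arma::fmat& inbuf = net->buf[0];
  inbuf.set_size(static_cast<arma::uword>(H) * W, C);
  for (size_t t = 0; t < inbuf.n_elem; ++t) inbuf[t] = static_cast<float>(img[t]);
  arma::fmat* cur = &inbuf;

  std::mt19937 gen(static_cast<uint32_t>(noise_seed));
  const bool degenerate = sigma <= 0;  // N(mu, 0) is the constant mu
  std::normal_distribution<float> ndist(static_cast<float>(mu),
                                        degenerate ? 1.0f
                                                   : static_cast<float>(sigma));
  for (size_t r = 1; r < net->role.size(); ++r) {
    const int role = net->role[r];
    if (role == 1) {
      NzConv& c = net->convs[net->conv_of[r]];
      im2col_t_f(cur->memptr(), H, W, C, c.kh, c.kw, c.pad, c.colT);
      c.Y = c.colT * c.Wm;
      const size_t npix = static_cast<size_t>(H) * W;
      for (int o = 0; o < c.cout; ++o) {
        float* col = c.Y.colptr(o);
        const float a = c.bn_scale[o];
        const float b = c.bias[o] * a + c.bn_off[o];
        for (size_t t = 0; t < npix; ++t) {
          float v = col[t] * a + b;
          col[t] = v > 0 ? v : 0.0f;
        }
      }
      lrn_f(c.Y.memptr(), npix, c.cout, net->lrn_k, net->lrn_alpha,
            net->lrn_beta, net->lrn_n);
      if (noise_on) {
        float* p = c.Y.memptr();
        const size_t nel = npix * c.cout;
        if (degenerate) {
          const float m = static_cast<float>(mu);
          for (size_t t = 0; t < nel; ++t) p[t] *= m;
        } else {
          for (size_t t = 0; t < nel; ++t) p[t] *= ndist(gen);
        }
      }
      cur = &c.Y;
      C = c.cout;
    } else if (role == 2) {
      const int Ho = H / 2, Wo = W / 2;
      arma::fmat& out = net->buf[r];
      out.set_size(static_cast<arma::uword>(Ho) * Wo, C);
      for (int c2 = 0; c2 < C; ++c2) {
        const float* px = cur->colptr(c2);
        float* py = out.colptr(c2);
        for (int j = 0; j < Wo; ++j)
          for (int i = 0; i < Ho; ++i) {
            const float* b = px + static_cast<size_t>(2 * j) * H + 2 * i;
            float m = b[0];
            if (b[1] > m) m = b[1];
            if (b[H] > m) m = b[H];
            if (b[H + 1] > m) m = b[H + 1];
            py[i + static_cast<size_t>(j) * Ho] = m;
          }
      }
      cur = &out;
      H = Ho; W = Wo;
    } else if (role == 3) {
      // global average pooling: one pixel, C channels
      net->buf[r] = arma::fmat(arma::mean(*cur, 0));
      cur = &net->buf[r];
      H = 1; W = 1;
    } else if (role == 4) {
      arma::fvec feat = cur->row(0).t();
      arma::fvec z = net->fcW * feat + net->fcb;
      float zmax = z.max();
      arma::fvec e = arma::exp(z - zmax);
      arma::fvec p = e / arma::accu(e);
      NumericVector out(p.n_elem);
      for (size_t t = 0; t < p.n_elem; ++t) out[t] = p[t];
      return out;
    }
    if (record >= 0 && net->index[r] == record) {
      NumericVector out(cur->n_elem);
      for (size_t t = 0; t < cur->n_elem; ++t) out[t] = (*cur)[t];
      out.attr("dim") = IntegerVector::create(H, W, C);
      return out;
    }
  }
  NumericVector out(cur->n_elem);
  for (size_t t = 0; t < cur->n_elem; ++t) out[t] = (*cur)[t];
  return out;
}

// [[Rcpp::export]]
bool cpp_xptr_valid(SEXP ptr) {
  return R_ExternalPtrAddr(ptr) != nullptr;
}
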