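// Compact CNN point-estimator for projective-line orientation, trained with
// a cross-entropy loss on two-hot targets, plus the O(2) image transforms
// (rotation/reflection) used for augmentation and group averaging.
//
// Layout conventions (must stay in sync with the R level):
//   * images are square S x S depth grids, normalized, stored as cube(S,S,n),
//     rows = image rows (top row = largest y), cols = x rightward;
//   * angles are measured from +y, counterclockwise positive, and wrapped to
//     the projective line (-pi/2, pi/2];
//   * activations are mat(C, Ho*Wo*n) with pixel index p = col*H + row and
//     image blocks contiguous;
//   * conv weights are mat(Cout, Cin*9), kernel index k = ch*9 + kc*3 + kr.
//
// All randomness goes through R's RNG so set.seed() at the R level makes
// training and augmentation fully reproducible (single-threaded).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static const double PI_ = 3.141592653589793238462643383279502884;

static inline double wrap_p1_cpp(double x) {
  double w = x - PI_ * std::floor(x / PI_);  // [0, pi)
  return (w > PI_ / 2) ? w - PI_ : w;
}

// exact-inverse two-hot weights (see R two_hot_encode)
static void two_hot_col(double theta, int B, double* out) {
  std::fill(out, out + B, 0.0);
  double binw = PI_ / B;
  double u = (wrap_p1_cpp(theta) + PI_ / 2) / binw - 0.5;
  double i0 = std::floor(u);
  double frac = u - i0;
  int lo = ((int)i0 % B + B) % B;
  int hi = ((int)(i0 + 1) % B + B) % B;
  if (frac < 1e-12) {
    out[lo] = 1.0;
  } else if (frac > 1 - 1e-12) {
    out[hi] = 1.0;
  } else {
    double w_lo = std::sin(2 * (1 - frac) * binw);
    double w_hi = std::sin(2 * frac * binw);
    double s = w_lo + w_hi;
    out[lo] = w_lo / s;
    out[hi] = w_hi / s;
  }
}

// rotate content CCW by alpha about the image center (bilinear, fill), then
// optionally mirror left-right (x -> -x).
static void rotate_flip_one(const mat& in, mat& out, double alpha, bool flip,
                            double fill) {
  const int S = in.n_rows;
  const double c0 = (S - 1) / 2.0;
  const double ca = std::cos(alpha), sa = std::sin(alpha);
  for (int j = 0; j < S; ++j) {      // output column (x)
    for (int i = 0; i < S; ++i) {    // output row (y down)
      double x = j - c0;
      double y = c0 - i;
      // source position = R(-alpha) * (x, y)
      double xs = ca * x + sa * y;
      double ys = -sa * x + ca * y;
      double cs = xs + c0;
      double rs = c0 - ys;
      double val = fill;
      int r0 = (int)std::floor(rs), cc0 = (int)std::floor(cs);
      if (r0 >= -1 && r0 <= S - 1 && cc0 >= -1 && cc0 <= S - 1) {
        double fr = rs - r0, fc = cs - cc0;
        auto px = [&](int r, int c) -> double {
          if (r < 0 || r >= S || c < 0 || c >= S) return fill;
          return in(r, c);
        };
        val = (1 - fr) * (1 - fc) * px(r0, cc0) +
              (1 - fr) * fc * px(r0, cc0 + 1) +
              fr * (1 - fc) * px(r0 + 1, cc0) +
              fr * fc * px(r0 + 1, cc0 + 1);
      }
      int jo = flip ? (S - 1 - j) : j;
      out(i, jo) = val;
    }
  }
}

// [[Rcpp::export]]
arma::cube rotate_flip_batch(const arma::cube& imgs, const arma::vec& alphas,
                             const arma::uvec& flips, double fill) {
  const int n = imgs.n_slices;
  if ((int)alphas.n_elem != n || (int)flips.n_elem != n)
    Rcpp::stop("alphas/flips length must match the number of images");
  cube out(imgs.n_rows, imgs.n_cols, n);
  mat tmp(imgs.n_rows, imgs.n_cols);
  for (int b = 0; b < n; ++b) {
    rotate_flip_one(imgs.slice(b), tmp, alphas(b), flips(b) != 0, fill);
    out.slice(b) = tmp;
  }
  return out;
}

// ---------------------------------------------------------------------------
// network plumbing

struct NetCfg {
  int S;                 // input size
  std::vector<int> convC;
  std::vector<int> dense; // hidden widths (may be empty)
  int B;                 // output bins
  std::vector<int> hs;   // spatial size after each conv block
};

static NetCfg parse_cfg(const Rcpp::List& cfg) {
  NetCfg c;
  c.S = Rcpp::as<int>(cfg["input_size"]);
  c.convC = Rcpp::as<std::vector<int>>(cfg["conv_channels"]);
  c.dense = Rcpp::as<std::vector<int>>(cfg["dense_widths"]);
  c.B = Rcpp::as<int>(cfg["bins"]);
  int h = c.S;
  for (size_t l = 0; l < c.convC.size(); ++l) {
    h = (h + 2 - 3) / 2 + 1;  // kernel 3, stride 2, pad 1
    c.hs.push_back(h);
  }
  return c;
}

// im2col for 3x3 / stride 2 / pad 1.
// A: (Cin, Hi*Wi*nb) activations; col: (Cin*9, Ho*Wo*nb)
static void im2col(const mat& A, int Cin, int Hi, int Ho, int nb, mat& col) {
  const int npix_i = Hi * Hi, npix_o = Ho * Ho;
  for (int b = 0; b < nb; ++b) {
    const int off_i = b * npix_i, off_o = b * npix_o;
    for (int co = 0; co < Ho; ++co) {
      for (int ro = 0; ro < Ho; ++ro) {
        const int q = off_o + co * Ho + ro;
        double* dst = col.colptr(q);
        for (int kc = 0; kc < 3; ++kc) {
          const int ci = 2 * co + kc - 1;
          for (int kr = 0; kr < 3; ++kr) {
            const int ri = 2 * ro + kr - 1;
            const int k = kc * 3 + kr;
            if (ri < 0 || ri >= Hi || ci < 0 || ci >= Hi) {
              for (int ch = 0; ch < Cin; ++ch) dst[ch * 9 + k] = 0.0;
            } else {
              const double* src = A.colptr(off_i + ci * Hi + ri);
              for (int ch = 0; ch < Cin; ++ch) dst[ch * 9 + k] = src[ch];
            }
          }
        }
      }
    }
  }
}

// adjoint of im2col: scatter col-gradients back onto activation grid
static void col2im(const mat& dcol, int Cin, int Hi, int Ho, int nb, mat& dA) {
  dA.zeros();
  const int npix_i = Hi * Hi, npix_o = Ho * Ho;
  for (int b = 0; b < nb; ++b) {
    const int off_i = b * npix_i, off_o = b * npix_o;
    for (int co = 0; co < Ho; ++co) {
      for (int ro = 0; ro < Ho; ++ro) {
        const int q = off_o + co * Ho + ro;
        const double* src = dcol.colptr(q);
        for (int kc = 0; kc < 3; ++kc) {
          const int ci = 2 * co + kc - 1;
          if (ci < 0 || ci >= Hi) continue;
          for (int kr = 0; kr < 3; ++kr) {
            const int ri = 2 * ro + kr - 1;
            if (ri < 0 || ri >= Hi) continue;
            const int k = kc * 3 + kr;
            double* dst = dA.colptr(off_i + ci * Hi + ri);
            for (int ch = 0; ch < Cin; ++ch) dst[ch] += src[ch * 9 + k];
          }
        }
      }
    }
  }
}

struct Params {
  std::vector<mat> W;
  std::vector<vec> b;
};

static Params params_from_list(const Rcpp::List& wl) {
  Params p;
  Rcpp::List Ws = wl["W"], bs = wl["b"];
  for (int i = 0; i < Ws.size(); ++i) {
    p.W.push_back(Rcpp::as<mat>(Ws[i]));
    p.b.push_back(Rcpp::as<vec>(bs[i]));
  }
  return p;
}

static Rcpp::List params_to_list(const Params& p) {
  Rcpp::List Ws(p.W.size()), bs(p.b.size());
  for (size_t i = 0; i < p.W.size(); ++i) {
    Ws[i] = p.W[i];
    bs[i] = p.b[i];
  }
  return Rcpp::List::create(Rcpp::Named("W") = Ws, Rcpp::Named("b") = bs);
}

static Params init_params(const NetCfg& c) {
  // He-normal init through R's RNG (reproducible under set.seed)
  Params p;
  int cin = 1;
  for (size_t l = 0; l < c.convC.size(); ++l) {
    int fan_in = cin * 9;
    mat W(c.convC[l], fan_in);
    double sd = std::sqrt(2.0 / fan_in);
    for (uword i = 0; i < W.n_elem; ++i) W(i) = R::norm_rand() * sd;
    p.W.push_back(W);
    p.b.push_back(vec(c.convC[l], fill::zeros));
    cin = c.convC[l];
  }
  int in = cin;  // after global average pool
  for (size_t l = 0; l < c.dense.size(); ++l) {
    mat W(c.dense[l], in);
    double sd = std::sqrt(2.0 / in);
    for (uword i = 0; i < W.n_elem; ++i) W(i) = R::norm_rand() * sd;
    p.W.push_back(W);
    p.b.push_back(vec(c.dense[l], fill::zeros));
    in = c.dense[l];
  }
  mat W(c.B, in);
  double sd = std::sqrt(1.0 / in);
  for (uword i = 0; i < W.n_elem; ++i) W(i) = R::norm_rand() * sd;
  p.W.push_back(W);
  p.b.push_back(vec(c.B, fill::zeros));
  return p;
}

struct Cache {
  std::vector<mat> conv_out;  // post-relu conv activations
  std::vector<mat> cols;      // im2col matrices
  mat G;                      // pooled features (C_last, nb)
  std::vector<mat> dense_out; // post-relu dense activations
  mat P;                      // softmax probs (B, nb)
};

// forward pass over one batch; X: (1, S*S*nb)
static void forward(const Params& p, const NetCfg& c, const mat& X, int nb,
                    Cache& K, bool keep_cols) {
  int nconv = c.convC.size();
  mat A = X;
  int cin = 1, Hi = c.S;
  K.conv_out.assign(nconv, mat());
  K.cols.assign(nconv, mat());
  for (int l = 0; l < nconv; ++l) {
    int Ho = c.hs[l];
    mat col(cin * 9, Ho * Ho * nb);
    im2col(A, cin, Hi, Ho, nb, col);
    mat Y = p.W[l] * col;
    Y.each_col() += p.b[l];
    Y.transform([](double v) { return v > 0 ? v : 0.0; });
    if (keep_cols) K.cols[l] = std::move(col);
    K.conv_out[l] = std::move(Y);
    A = K.conv_out[l];
    cin = c.convC[l];
    Hi = Ho;
  }
  // global average pool
  const int npix = Hi * Hi;
  K.G.set_size(cin, nb);
  for (int b = 0; b < nb; ++b)
    K.G.col(b) = mean(A.cols(b * npix, (b + 1) * npix - 1), 1);
  // dense stack
  int nd = c.dense.size();
  K.dense_out.assign(nd, mat());
  mat H = K.G;
  for (int l = 0; l < nd; ++l) {
    mat Y = p.W[nconv + l] * H;
    Y.each_col() += p.b[nconv + l];
    Y.transform([](double v) { return v > 0 ? v : 0.0; });
    K.dense_out[l] = std::move(Y);
    H = K.dense_out[l];
  }
  mat logits = p.W[nconv + nd] * H;
  logits.each_col() += p.b[nconv + nd];
  logits.each_row() -= max(logits, 0);
  K.P = exp(logits);
  K.P.each_row() /= sum(K.P, 0);
}

// [[Rcpp::export]]
Rcpp::List cnn_train(const arma::cube& imgs, const arma::vec& labels,
                     const Rcpp::List& net_cfg, const Rcpp::List& opt_cfg) {
  NetCfg c = parse_cfg(net_cfg);
  const int n = imgs.n_slices;
  if ((int)labels.n_elem != n) Rcpp::stop("labels length mismatch");
  if ((int)imgs.n_rows != c.S || (int)imgs.n_cols != c.S)
    Rcpp::stop("imagelet size does not match network input size");

  const int epochs = Rcpp::as<int>(opt_cfg["epochs"]);
  const int batch = Rcpp::as<int>(opt_cfg["batch_size"]);
  const double lr = Rcpp::as<double>(opt_cfg["learning_rate"]);
  const bool augment = Rcpp::as<bool>(opt_cfg["augment"]);
  const double fill = Rcpp::as<double>(opt_cfg["fill"]);

  Params p = init_params(c);
  const int nmat = p.W.size();
  std::vector<mat> mW(nmat), vW(nmat);
  std::vector<vec> mb(nmat), vb(nmat);
  for (int i = 0; i < nmat; ++i) {
    mW[i] = zeros(size(p.W[i]));
    vW[i] = zeros(size(p.W[i]));
    mb[i] = zeros(size(p.b[i]));
    vb[i] = zeros(size(p.b[i]));
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  const int nconv = c.convC.size(), nd = c.dense.size();
  std::vector<double> loss_hist;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  mat X(1, 0);
  mat img_tmp(c.S, c.S);
  Cache K;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle via R RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double ep_loss = 0.0;
    long ep_count = 0;
    for (int start = 0; start < n; start += batch) {
      const int nb = std::min(batch, n - start);
      X.set_size(1, c.S * c.S * nb);
      mat T(c.B, nb);
      for (int k = 0; k < nb; ++k) {
        const int s = idx[start + k];
        double lab = labels(s);
        if (augment) {
          double alpha = unif_rand() * 2 * PI_;
          bool flip = unif_rand() < 0.5;
          rotate_flip_one(imgs.slice(s), img_tmp, alpha, flip, fill);
          lab = wrap_p1_cpp((lab + alpha) * (flip ? -1.0 : 1.0));
          std::memcpy(X.colptr(k * c.S * c.S), img_tmp.memptr(),
                      sizeof(double) * c.S * c.S);
        } else {
          std::memcpy(X.colptr(k * c.S * c.S), imgs.slice(s).memptr(),
                      sizeof(double) * c.S * c.S);
        }
        two_hot_col(lab, c.B, T.colptr(k));
      }

      forward(p, c, X, nb, K, true);

      // loss
      for (int k = 0; k < nb; ++k)
        for (int j = 0; j < c.B; ++j)
          if (T(j, k) > 0)
            ep_loss -= T(j, k) * std::log(std::max(K.P(j, k), 1e-12));
      ep_count += nb;

      // backward
      std::vector<mat> dW(nmat);
      std::vector<vec> db(nmat);
      mat dH = (K.P - T) / nb;  // dlogits
      // output layer
      {
        const mat& Hin = nd > 0 ? K.dense_out[nd - 1] : K.G;
        dW[nconv + nd] = dH * Hin.t();
        db[nconv + nd] = sum(dH, 1);
        dH = p.W[nconv + nd].t() * dH;
      }
      for (int l = nd - 1; l >= 0; --l) {
        dH %= conv_to<mat>::from(K.dense_out[l] > 0);
        const mat& Hin = l > 0 ? K.dense_out[l - 1] : K.G;
        dW[nconv + l] = dH * Hin.t();
        db[nconv + l] = sum(dH, 1);
        dH = p.W[nconv + l].t() * dH;
      }
      // un-pool: spread dG uniformly over the last conv map
      const int Hl = c.hs[nconv - 1];
      const int npix = Hl * Hl;
      mat dY(c.convC[nconv - 1], npix * nb);
      for (int b = 0; b < nb; ++b) {
        vec g = dH.col(b) / npix;
        for (int q = 0; q < npix; ++q) dY.col(b * npix + q) = g;
      }
      for (int l = nconv - 1; l >= 0; --l) {
        dY %= conv_to<mat>::from(K.conv_out[l] > 0);
        dW[l] = dY * K.cols[l].t();
        db[l] = sum(dY, 1);
        if (l > 0) {
          const int cin_l = c.convC[l - 1];
          const int Hi = c.hs[l - 1];
          mat dcol = p.W[l].t() * dY;
          mat dA(cin_l, Hi * Hi * nb);
          col2im(dcol, cin_l, Hi, c.hs[l], nb, dA);
          dY = std::move(dA);
        }
      }

      // Adam step
      ++step;
      const double corr1 = 1 - std::pow(b1, (double)step);
      const double corr2 = 1 - std::pow(b2, (double)step);
      for (int i = 0; i < nmat; ++i) {
        mW[i] = b1 * mW[i] + (1 - b1) * dW[i];
        vW[i] = b2 * vW[i] + (1 - b2) * square(dW[i]);
        p.W[i] -= lr * (mW[i] / corr1) / (sqrt(vW[i] / corr2) + eps);
        mb[i] = b1 * mb[i] + (1 - b1) * db[i];
        vb[i] = b2 * vb[i] + (1 - b2) * square(db[i]);
        p.b[i] -= lr * (mb[i] / corr1) / (sqrt(vb[i] / corr2) + eps);
      }
    }
    double mloss = ep_loss / ep_count;
    if (!std::isfinite(mloss))
      Rcpp::stop("training diverged: non-finite loss at epoch %d", ep + 1);
    loss_hist.push_back(mloss);
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("weights") = params_to_list(p),
      Rcpp::Named("loss_history") = loss_hist);
}

// [[Rcpp::export]]
arma::mat cnn_forward(const Rcpp::List& weights, const Rcpp::List& net_cfg,
                      const arma::cube& imgs, int batch = 256) {
  NetCfg c = parse_cfg(net_cfg);
  Params p = params_from_list(weights);
  const int n = imgs.n_slices;
  if ((int)imgs.n_rows != c.S || (int)imgs.n_cols != c.S)
    Rcpp::stop("imagelet size does not match network input size");
  mat out(n, c.B);
  Cache K;
  mat X;
  for (int start = 0; start < n; start += batch) {
    const int nb = std::min(batch, n - start);
    X.set_size(1, c.S * c.S * nb);
    for (int k = 0; k < nb; ++k)
      std::memcpy(X.colptr(k * c.S * c.S), imgs.slice(start + k).memptr(),
                  sizeof(double) * c.S * c.S);
    forward(p, c, X, nb, K, false);
    out.rows(start, start + nb - 1) = K.P.t();
  }
  return out;
}

// [[Rcpp::export]]
int cnn_param_count(const Rcpp::List& net_cfg) {
  NetCfg c = parse_cfg(net_cfg);
  int n = 0, cin = 1;
  for (size_t l = 0; l < c.convC.size(); ++l) {
    n += c.convC[l] * cin * 9 + c.convC[l];
    cin = c.convC[l];
  }
  for (size_t l = 0; l < c.dense.size(); ++l) {
    n += c.dense[l] * cin + c.dense[l];
    cin = c.dense[l];
  }
  n += c.B * cin + c.B;
  return n;
}
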