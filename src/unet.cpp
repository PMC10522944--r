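// Self-contained 2D U-Net: encoder/decoder with skip concatenations,
// 3x3 (configurable) same-padding convolutions + ReLU, 2x2 max-pooling,
// 2x2 stride-2 up-convolutions, and a 1x1 output head (softmax
// cross-entropy for the 4-class head, sigmoid BCE for the 1-channel
// binary head). Training uses Adam on class-weighted pixel losses.
// Everything is single-threaded and seeded (std::mt19937), so training
// is bit-reproducible for a given (spec, data, seed).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;

namespace {

struct ConvDef {
  int k, cin, cout;
  size_t woff, boff;
};

struct Net {
  int S, C, F, K, OC;
  std::vector<ConvDef> enc, bott, up, dec;
  ConvDef fin;
  size_t nparam;
};

Net build_net(const List& spec) {
  Net n;
  n.S = as<int>(spec["n_encoding_stages"]);
  n.C = as<int>(spec["convs_per_stage"]);
  n.F = as<int>(spec["base_features"]);
  n.K = as<int>(spec["kernel_size"]);
  n.OC = as<int>(spec["out_channels"]);
  size_t off = 0;
  auto add = [&off](int k, int cin, int cout) {
    ConvDef d;
    d.k = k; d.cin = cin; d.cout = cout;
    d.woff = off;
    d.boff = off + (size_t)k * k * cin * cout;
    off += (size_t)k * k * cin * cout + cout;
    return d;
  };
  int ch = 1;
  for (int s = 0; s < n.S; ++s) {
    int f = n.F << s;
    n.enc.push_back(add(n.K, ch, f));
    ch = f;
    for (int c = 1; c < n.C; ++c) n.enc.push_back(add(n.K, f, f));
  }
  int fb = n.F << n.S;
  n.bott.push_back(add(n.K, ch, fb));
  for (int c = 1; c < n.C; ++c) n.bott.push_back(add(n.K, fb, fb));
  ch = fb;
  for (int s = n.S - 1; s >= 0; --s) {
    int f = n.F << s;
    n.up.push_back(add(2, ch, f)); // up-convolution 2x2 stride 2
    n.dec.push_back(add(n.K, 2 * f, f));
    for (int c = 1; c < n.C; ++c) n.dec.push_back(add(n.K, f, f));
    ch = f;
  }
  n.fin = add(1, ch, n.OC);
  n.nparam = off;
  return n;
}

// ---- primitive layers -------------------------------------------------

void im2col(const cube& x, int k, mat& cols) {
  const int H = x.n_rows, W = x.n_cols, cin = x.n_slices;
  const int pad = k / 2, kk = k * k;
  cols.zeros((size_t)kk * cin, (size_t)H * W);
  for (int c = 0; c < cin; ++c) {
    const mat& xc = x.slice(c);
    for (int dy = 0; dy < k; ++dy)
      for (int dx = 0; dx < k; ++dx) {
        const int r = c * kk + dy * k + dx;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dx - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + dy - pad;
            if (si < 0 || si >= H) continue;
            cols(r, (size_t)i + (size_t)H * j) = xc(si, sj);
          }
        }
      }
  }
}

void col2im(const mat& dcols, int k, cube& gx) {
  const int H = gx.n_rows, W = gx.n_cols, cin = gx.n_slices;
  const int pad = k / 2, kk = k * k;
  for (int c = 0; c < cin; ++c) {
    mat& gc = gx.slice(c);
    for (int dy = 0; dy < k; ++dy)
      for (int dx = 0; dx < k; ++dx) {
        const int r = c * kk + dy * k + dx;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dx - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + dy - pad;
            if (si < 0 || si >= H) continue;
            gc(si, sj) += dcols(r, (size_t)i + (size_t)H * j);
          }
        }
      }
  }
}

struct ConvCache {
  mat cols;     // im2col of the layer input
  cube out;     // post-activation output (ReLU mask / next input)
  int H, W;
};

cube conv_forward(const double* params, const ConvDef& d, const cube& x,
                  bool relu, ConvCache& cc) {
  const int H = x.n_rows, W = x.n_cols;
  im2col(x, d.k, cc.cols);
  const mat Wm(const_cast<double*>(params + d.woff), d.cout,
               (size_t)d.k * d.k * d.cin, false, true);
  mat out = Wm * cc.cols; // cout x HW
  for (int c = 0; c < d.cout; ++c) out.row(c) += params[d.boff + c];
  if (relu) out.transform([](double v) { return v > 0 ? v : 0.0; });
  cube y(H, W, d.cout);
  for (int c = 0; c < d.cout; ++c) {
    double* dst = y.slice(c).memptr();
    for (size_t p = 0; p < (size_t)H * W; ++p) dst[p] = out(c, p);
  }
  cc.out = y;
  cc.H = H; cc.W = W;
  return y;
}

// gout: gradient wrt layer output (post-activation); returns grad wrt input
cube conv_backward(const double* params, double* grad, const ConvDef& d,
                   const ConvCache& cc, cube gout, bool relu) {
  const int H = cc.H, W = cc.W;
  if (relu) {
    for (int c = 0; c < d.cout; ++c)
      gout.slice(c) %= arma::conv_to<mat>::from(cc.out.slice(c) > 0);
  }
  mat gm(d.cout, (size_t)H * W);
  for (int c = 0; c < d.cout; ++c) {
    const double* src = gout.slice(c).memptr();
    for (size_t p = 0; p < (size_t)H * W; ++p) gm(c, p) = src[p];
  }
  const mat Wm(const_cast<double*>(params + d.woff), d.cout,
               (size_t)d.k * d.k * d.cin, false, true);
  mat dW = gm * cc.cols.t();
  const double* dWp = dW.memptr();
  for (size_t i = 0; i < dW.n_elem; ++i) grad[d.woff + i] += dWp[i];
  for (int c = 0; c < d.cout; ++c) grad[d.boff + c] += arma::accu(gm.row(c));
  mat dcols = Wm.t() * gm;
  cube gx(H, W, d.cin, arma::fill::zeros);
  col2im(dcols, d.k, gx);
  return gx;
}

cube maxpool_forward(const cube& x, arma::ucube& argidx) {
  const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  cube y(H, W, C);
  argidx.set_size(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double best = -1e300;
        arma::uword barg = 0;
        for (int b = 0; b < 2; ++b)
          for (int a = 0; a < 2; ++a) {
            const int ii = 2 * i + a, jj = 2 * j + b;
            const double v = x(ii, jj, c);
            if (v > best) { best = v; barg = (arma::uword)ii + (arma::uword)x.n_rows * jj; }
          }
        y(i, j, c) = best;
        argidx(i, j, c) = barg;
      }
  return y;
}

cube maxpool_backward(const cube& gout, const arma::ucube& argidx,
                      int Hin, int Win) {
  const int H = gout.n_rows, W = gout.n_cols, C = gout.n_slices;
  cube gx(Hin, Win, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        gx.slice(c)(argidx(i, j, c)) += gout(i, j, c);
  return gx;
}

// 2x2 stride-2 transposed convolution; weight matrix (4*cout, cin),
// row index = c*4 + pos with pos = dy + 2*dx.
struct UpCache { mat in_mat; int h, w; cube out; };

cube upconv_forward(const double* params, const ConvDef& d, const cube& x,
                    UpCache& uc) {
  const int h = x.n_rows, w = x.n_cols;
  uc.in_mat.set_size(d.cin, (size_t)h * w);
  for (int c = 0; c < d.cin; ++c) {
    const double* src = x.slice(c).memptr();
    for (size_t p = 0; p < (size_t)h * w; ++p) uc.in_mat(c, p) = src[p];
  }
  const mat Wm(const_cast<double*>(params + d.woff), 4 * d.cout, d.cin,
               false, true);
  mat o4 = Wm * uc.in_mat; // (4*cout) x (h*w)
  cube y(2 * h, 2 * w, d.cout);
  for (int c = 0; c < d.cout; ++c) {
    mat& yc = y.slice(c);
    const double b = params[d.boff + c];
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        const size_t p = (size_t)i + (size_t)h * j;
        yc(2 * i, 2 * j) = o4(c * 4 + 0, p) + b;
        yc(2 * i + 1, 2 * j) = o4(c * 4 + 1, p) + b;
        yc(2 * i, 2 * j + 1) = o4(c * 4 + 2, p) + b;
        yc(2 * i + 1, 2 * j + 1) = o4(c * 4 + 3, p) + b;
      }
  }
  // ReLU after up-convolution (activation follows every convolution)
  y.transform([](double v) { return v > 0 ? v : 0.0; });
  uc.out = y;
  uc.h = h; uc.w = w;
  return y;
}

cube upconv_backward(const double* params, double* grad, const ConvDef& d,
                     const UpCache& uc, cube gout) {
  const int h = uc.h, w = uc.w;
  for (int c = 0; c < d.cout; ++c)
    gout.slice(c) %= arma::conv_to<mat>::from(uc.out.slice(c) > 0);
  mat g4(4 * d.cout, (size_t)h * w);
  for (int c = 0; c < d.cout; ++c) {
    const mat& gc = gout.slice(c);
    double bsum = 0;
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        const size_t p = (size_t)i + (size_t)h * j;
        g4(c * 4 + 0, p) = gc(2 * i, 2 * j);
        g4(c * 4 + 1, p) = gc(2 * i + 1, 2 * j);
        g4(c * 4 + 2, p) = gc(2 * i, 2 * j + 1);
        g4(c * 4 + 3, p) = gc(2 * i + 1, 2 * j + 1);
      }
    bsum = arma::accu(gc);
    grad[d.boff + c] += bsum;
  }
  mat dW = g4 * uc.in_mat.t();
  const double* dWp = dW.memptr();
  for (size_t i = 0; i < dW.n_elem; ++i) grad[d.woff + i] += dWp[i];
  const mat Wm(const_cast<double*>(params + d.woff), 4 * d.cout, d.cin,
               false, true);
  mat din = Wm.t() * g4;
  cube gx(h, w, d.cin);
  for (int c = 0; c < d.cin; ++c) {
    double* dst = gx.slice(c).memptr();
    for (size_t p = 0; p < (size_t)h * w; ++p) dst[p] = din(c, p);
  }
  return gx;
}

// ---- full network -----------------------------------------------------

struct ForwardCache {
  std::vector<ConvCache> enc, bott, dec;
  ConvCache fin;
  std::vector<UpCache> up;
  std::vector<arma::ucube> poolarg;
  std::vector<cube> skips;
  std::vector<std::pair<int, int>> pool_insize;
};

cube net_forward(const Net& n, const double* params, const mat& input,
                 ForwardCache& fc) {
  cube cur(input.n_rows, input.n_cols, 1);
  cur.slice(0) = input;
  fc.enc.resize(n.enc.size());
  fc.bott.resize(n.bott.size());
  fc.dec.resize(n.dec.size());
  fc.up.resize(n.up.size());
  fc.poolarg.resize(n.S);
  fc.skips.resize(n.S);
  fc.pool_insize.resize(n.S);
  size_t ei = 0;
  for (int s = 0; s < n.S; ++s) {
    for (int c = 0; c < n.C; ++c, ++ei)
      cur = conv_forward(params, n.enc[ei], cur, true, fc.enc[ei]);
    fc.skips[s] = cur;
    fc.pool_insize[s] = {(int)cur.n_rows, (int)cur.n_cols};
    cur = maxpool_forward(cur, fc.poolarg[s]);
  }
  for (size_t c = 0; c < n.bott.size(); ++c)
    cur = conv_forward(params, n.bott[c], cur, true, fc.bott[c]);
  size_t di = 0;
  for (int s = n.S - 1; s >= 0; --s) {
    const int ui = n.S - 1 - s;
    cur = upconv_forward(params, n.up[ui], cur, fc.up[ui]);
    const cube& skip = fc.skips[s];
    cube cat(cur.n_rows, cur.n_cols, cur.n_slices + skip.n_slices);
    for (size_t c = 0; c < cur.n_slices; ++c) cat.slice(c) = cur.slice(c);
    for (size_t c = 0; c < skip.n_slices; ++c)
      cat.slice(cur.n_slices + c) = skip.slice(c);
    cur = cat;
    for (int c = 0; c < n.C; ++c, ++di)
      cur = conv_forward(params, n.dec[di], cur, true, fc.dec[di]);
  }
  return conv_forward(params, n.fin, cur, false, fc.fin);
}

void net_backward(const Net& n, const double* params, double* grad,
                  ForwardCache& fc, cube g) {
  g = conv_backward(params, grad, n.fin, fc.fin, g, false);
  size_t di = n.dec.size();
  std::vector<cube> skip_grads(n.S);
  for (int s = 0; s < n.S; ++s) {
    for (int c = n.C - 1; c >= 0; --c) {
      --di;
      g = conv_backward(params, grad, n.dec[di], fc.dec[di], g, true);
    }
    const int ui = n.S - 1 - s; // decoder block index (top of loop = deepest? )
    // g now has 2*f channels: first f from upconv path, rest from skip
    const int f = n.up[ui].cout;
    cube gup(g.n_rows, g.n_cols, f);
    cube gskip(g.n_rows, g.n_cols, f);
    for (int c = 0; c < f; ++c) gup.slice(c) = g.slice(c);
    for (int c = 0; c < f; ++c) gskip.slice(c) = g.slice(f + c);
    skip_grads[s] = gskip;
    g = upconv_backward(params, grad, n.up[ui], fc.up[ui], gup);
  }
  for (size_t c = n.bott.size(); c-- > 0;)
    g = conv_backward(params, grad, n.bott[c], fc.bott[c], g, true);
  size_t ei = n.enc.size();
  for (int s = n.S - 1; s >= 0; --s) {
    g = maxpool_backward(g, fc.poolarg[s], fc.pool_insize[s].first,
                         fc.pool_insize[s].second);
    g += skip_grads[s];
    for (int c = n.C - 1; c >= 0; --c) {
      --ei;
      g = conv_backward(params, grad, n.enc[ei], fc.enc[ei], g, true);
    }
  }
}

// loss + gradient wrt logits; labels in 0..OC-1 (multiclass) or 0/1 (binary)
double loss_grad(const cube& logits, const IntegerMatrix& lab,
                 const NumericVector& cw, cube& dlogits) {
  const int H = logits.n_rows, W = logits.n_cols, OC = logits.n_slices;
  dlogits.set_size(H, W, OC);
  double loss = 0, wsum = 0;
  if (OC == 1) {
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const int y = lab(i, j);
        const double w = cw[y];
        const double z = logits(i, j, 0);
        const double p = 1.0 / (1.0 + std::exp(-z));
        const double pc = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
        loss += -w * (y ? std::log(pc) : std::log(1.0 - pc));
        dlogits(i, j, 0) = w * (p - y);
        wsum += w;
      }
  } else {
    std::vector<double> pr(OC);
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double mx = -1e300;
        for (int c = 0; c < OC; ++c) mx = std::max(mx, logits(i, j, c));
        double den = 0;
        for (int c = 0; c < OC; ++c) { pr[c] = std::exp(logits(i, j, c) - mx); den += pr[c]; }
        for (int c = 0; c < OC; ++c) pr[c] /= den;
        const int y = lab(i, j);
        const double w = cw[y];
        loss += -w * std::log(std::max(pr[y], 1e-12));
        for (int c = 0; c < OC; ++c)
          dlogits(i, j, c) = w * (pr[c] - (c == y ? 1.0 : 0.0));
        wsum += w;
      }
  }
  if (wsum > 0) {
    loss /= wsum;
    dlogits /= wsum;
  }
  return loss;
}

} // namespace

// loss and analytic gradient for one labelled patch (gradient-check hook)
// [[Rcpp::export]]
List cpp_unet_loss_grad(NumericVector params_in, NumericMatrix grey,
                        IntegerMatrix lab, List spec,
                        NumericVector class_weights) {
  Net n = build_net(spec);
  if ((size_t)params_in.size() != n.nparam)
    stop("parameter vector length does not match the architecture");
  mat X(grey.begin(), grey.nrow(), grey.ncol());
  ForwardCache fc;
  cube logits = net_forward(n, params_in.begin(), X, fc);
  cube dlog;
  double loss = loss_grad(logits, lab, class_weights, dlog);
  NumericVector grad((R_xlen_t)n.nparam);
  net_backward(n, params_in.begin(), grad.begin(), fc, dlog);
  return List::create(_["loss"] = loss, _["grad"] = grad);
}

// [[Rcpp::export]]
double cpp_unet_param_count(List spec) {
  Net n = build_net(spec);
  return (double)n.nparam;
}

// [[Rcpp::export]]
NumericVector cpp_unet_init(List spec, int seed) {
  Net n = build_net(spec);
  NumericVector params((R_xlen_t)n.nparam);
  std::mt19937 rng((unsigned)seed);
  auto init_conv = [&](const ConvDef& d, int fanin_k) {
    const double sd = std::sqrt(2.0 / ((double)fanin_k * fanin_k * d.cin));
    std::normal_distribution<double> nd(0.0, sd);
    const size_t nw = (size_t)d.k * d.k * d.cin * d.cout;
    for (size_t i = 0; i < nw; ++i) params[d.woff + i] = nd(rng);
    for (int c = 0; c < d.cout; ++c) params[d.boff + c] = 0.0;
  };
  for (const auto& d : n.enc) init_conv(d, d.k);
  for (const auto& d : n.bott) init_conv(d, d.k);
  for (const auto& d : n.up) init_conv(d, 2);
  for (const auto& d : n.dec) init_conv(d, d.k);
  init_conv(n.fin, 1);
  return params;
}

// [[Rcpp::export]]
List cpp_unet_train(NumericVector params_in, List greys, List labels,
                    List spec, NumericVector class_weights, double lr,
                    int epochs, int batch_size, int seed) {
  Net n = build_net(spec);
  if ((size_t)params_in.size() != n.nparam)
    stop("parameter vector length does not match the architecture");
  std::vector<double> params(params_in.begin(), params_in.end());
  const int N = greys.size();
  std::vector<mat> X(N);
  std::vector<IntegerMatrix> Y(N);
  for (int i = 0; i < N; ++i) {
    NumericMatrix g = greys[i];
    X[i] = mat(g.begin(), g.nrow(), g.ncol());
    Y[i] = as<IntegerMatrix>(labels[i]);
  }
  std::vector<double> m(n.nparam, 0.0), v(n.nparam, 0.0);
  std::vector<double> grad(n.nparam, 0.0);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  std::mt19937 rng((unsigned)seed);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  NumericVector loss_hist(epochs);
  ForwardCache fc;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0;
    int done = 0;
    while (done < N) {
      const int bs = std::min(batch_size, N - done);
      std::fill(grad.begin(), grad.end(), 0.0);
      double bloss = 0;
      for (int b = 0; b < bs; ++b) {
        const int i = order[done + b];
        cube logits = net_forward(n, params.data(), X[i], fc);
        cube dlog;
        bloss += loss_grad(logits, Y[i], class_weights, dlog);
        net_backward(n, params.data(), grad.data(), fc, dlog);
      }
      for (size_t p = 0; p < n.nparam; ++p) grad[p] /= bs;
      bloss /= bs;
      ep_loss += bloss * bs;
      ++step;
      const double bc1 = 1.0 - std::pow(b1, (double)step);
      const double bc2 = 1.0 - std::pow(b2, (double)step);
      for (size_t p = 0; p < n.nparam; ++p) {
        m[p] = b1 * m[p] + (1 - b1) * grad[p];
        v[p] = b2 * v[p] + (1 - b2) * grad[p] * grad[p];
        params[p] -= lr * (m[p] / bc1) / (std::sqrt(v[p] / bc2) + eps);
      }
      done += bs;
      Rcpp::checkUserInterrupt();
    }
    loss_hist[ep] = ep_loss / N;
  }
  NumericVector out((R_xlen_t)n.nparam);
  std::copy(params.begin(), params.end(), out.begin());
  return List::create(_["params"] = out, _["loss"] = loss_hist);
}

// [[Rcpp::export]]
NumericVector cpp_unet_predict(NumericVector params_in, NumericMatrix grey,
                               List spec) {
  Net n = build_net(spec);
  if ((size_t)params_in.size() != n.nparam)
    stop("parameter vector length does not match the architecture");
  mat X(grey.begin(), grey.nrow(), grey.ncol());
  ForwardCache fc;
  cube logits = net_forward(n, params_in.begin(), X, fc);
  const int H = logits.n_rows, W = logits.n_cols, OC = logits.n_slices;
  NumericVector out((R_xlen_t)H * W * OC);
  if (OC == 1) {
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        out[(R_xlen_t)i + (R_xlen_t)H * j] =
            1.0 / (1.0 + std::exp(-logits(i, j, 0)));
  } else {
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double mx = -1e300;
        for (int c = 0; c < OC; ++c) mx = std::max(mx, logits(i, j, c));
        double den = 0;
        for (int c = 0; c < OC; ++c) den += std::exp(logits(i, j, c) - mx);
        for (int c = 0; c < OC; ++c)
          out[(R_xlen_t)i + (R_xlen_t)H * j + (R_xlen_t)H * W * c] =
              std::exp(logits(i, j, c) - mx) / den;
      }
  }
  out.attr("dim") = IntegerVector::create(H, W, OC);
  return out;
}
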