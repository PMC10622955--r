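// 3D convolutional age regressor: im2col + BLAS GEMM forward/backward and a
// plain SGD (momentum + inverse-time learning-rate decay) training loop with
// on-the-fly rigid augmentation. MAE cost throughout. Single precision is not
// used: doubles keep the R round-trip exact and the grids are small.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include "sampling.h"
#include <random>
using namespace Rcpp;

struct BlockDims {
  int c_in, c_out, k, s, pad;
  int nxi, nyi, nzi, nxo, nyo, nzo;
  int n_in()  const { return nxi * nyi * nzi; }
  int n_out() const { return nxo * nyo * nzo; }
  int patch() const { return c_in * k * k * k; }
};

static int out_len(int n, int k, int s) { return (n + 2 * (k / 2) - k) / s + 1; }

static std::vector<BlockDims> plan_blocks(const arma::imat& blocks,
                                          int nx, int ny, int nz) {
  std::vector<BlockDims> out;
  int c = 1;
  for (arma::uword l = 0; l < blocks.n_rows; ++l) {
    BlockDims d;
    d.c_in = c; d.c_out = (int)blocks(l, 0);
    d.k = (int)blocks(l, 1); d.s = (int)blocks(l, 2);
    d.pad = d.k / 2;
    d.nxi = nx; d.nyi = ny; d.nzi = nz;
    d.nxo = out_len(nx, d.k, d.s);
    d.nyo = out_len(ny, d.k, d.s);
    d.nzo = out_len(nz, d.k, d.s);
    out.push_back(d);
    nx = d.nxo; ny = d.nyo; nz = d.nzo; c = d.c_out;
  }
  return out;
}

// Gather conv patches: P is (n_out x c_in*k^3); feature map F is (n_in x c_in),
// voxels in x-fastest order. Zero padding outside the grid.
static void im2col(const arma::mat& F, const BlockDims& d, arma::mat& P) {
  P.zeros(d.n_out(), d.patch());
  for (int c = 0; c < d.c_in; ++c) {
    const double* col = F.colptr(c);
    for (int kz = 0; kz < d.k; ++kz)
      for (int ky = 0; ky < d.k; ++ky)
        for (int kx = 0; kx < d.k; ++kx) {
          int pc = ((c * d.k + kz) * d.k + ky) * d.k + kx;
          double* dst = P.colptr(pc);
          for (int zo = 0; zo < d.nzo; ++zo) {
            int zi = zo * d.s - d.pad + kz;
            if (zi < 0 || zi >= d.nzi) continue;
            for (int yo = 0; yo < d.nyo; ++yo) {
              int yi = yo * d.s - d.pad + ky;
              if (yi < 0 || yi >= d.nyi) continue;
              std::size_t rbase = (std::size_t)d.nxo * (yo + (std::size_t)d.nyo * zo);
              std::size_t ibase = (std::size_t)d.nxi * (yi + (std::size_t)d.nyi * zi);
              for (int xo = 0; xo < d.nxo; ++xo) {
                int xi = xo * d.s - d.pad + kx;
                if (xi < 0 || xi >= d.nxi) continue;
                dst[rbase + xo] = col[ibase + xi];
              }
            }
          }
        }
  }
}

// Scatter-add of patch-space gradients back onto the input feature map.
static void col2im(const arma::mat& dP, const BlockDims& d, arma::mat& dF) {
  dF.zeros(d.n_in(), d.c_in);
  for (int c = 0; c < d.c_in; ++c) {
    double* col = dF.colptr(c);
    for (int kz = 0; kz < d.k; ++kz)
      for (int ky = 0; ky < d.k; ++ky)
        for (int kx = 0; kx < d.k; ++kx) {
          int pc = ((c * d.k + kz) * d.k + ky) * d.k + kx;
          const double* src = dP.colptr(pc);
          for (int zo = 0; zo < d.nzo; ++zo) {
            int zi = zo * d.s - d.pad + kz;
            if (zi < 0 || zi >= d.nzi) continue;
            for (int yo = 0; yo < d.nyo; ++yo) {
              int yi = yo * d.s - d.pad + ky;
              if (yi < 0 || yi >= d.nyi) continue;
              std::size_t rbase = (std::size_t)d.nxo * (yo + (std::size_t)d.nyo * zo);
              std::size_t ibase = (std::size_t)d.nxi * (yi + (std::size_t)d.nyi * zi);
              for (int xo = 0; xo < d.nxo; ++xo) {
                int xi = xo * d.s - d.pad + kx;
                if (xi < 0 || xi >= d.nxi) continue;
                col[ibase + xi] += src[rbase + xo];
              }
            }
          }
        }
  }
}

struct Net {
  std::vector<BlockDims> dims;
  std::vector<arma::mat> W;   // (patch x c_out)
  std::vector<arma::vec> b;   // (c_out)
  arma::vec w_head;           // (c_last)
  double b_head;
  // per-channel normalization of the pooled features. During training the
  // statistics are tracked as exponential moving averages (stop-gradient,
  // BatchNorm-style without learnable affine - the head provides those);
  // at inference they are frozen. feat_var is the EMA of squared deviation.
  arma::rowvec feat_mean, feat_sd, feat_var;
  bool track_stats = false;
  double stats_momentum = 0.99;
  // workspaces kept across samples
  std::vector<arma::mat> P, A, mask;
  arma::rowvec feat; // standardized

  void init_ws() {
    P.resize(dims.size()); A.resize(dims.size()); mask.resize(dims.size());
  }

  // floor near-constant channels relative to the median spread so the
  // backward scale w/sd stays bounded
  static arma::rowvec floored_sd(const arma::rowvec& sd) {
    arma::rowvec pos = sd(arma::find(sd > 0)).t();
    double fl = pos.n_elem > 0 ? 0.05 * arma::median(pos) : 1.0;
    if (fl <= 0) fl = 1.0;
    arma::rowvec out = sd;
    out.transform([fl](double v) { return v < fl ? fl : v; });
    return out;
  }

  void update_stats(const arma::rowvec& raw) {
    double r = stats_momentum;
    feat_mean = r * feat_mean + (1 - r) * raw;
    feat_var = r * feat_var + (1 - r) * arma::square(raw - feat_mean);
    feat_sd = floored_sd(arma::sqrt(feat_var));
  }

  // Global-average-pooled features, pre-standardization.
  arma::rowvec raw_features(const arma::mat& x, bool store) {
    arma::mat cur = x; // (n_vox x 1)
    for (std::size_t l = 0; l < dims.size(); ++l) {
      im2col(cur, dims[l], P[l]);
      arma::mat O = P[l] * W[l];
      O.each_row() += b[l].t();
      if (store) mask[l] = arma::conv_to<arma::mat>::from(O > 0);
      A[l] = arma::clamp(O, 0.0, arma::datum::inf);
      cur = A[l];
    }
    return arma::mean(A.back(), 0);
  }

  // Forward; when `store`, keep patches/masks for backward.
  double forward(const arma::mat& x, bool store) {
    arma::rowvec raw = raw_features(x, store);
    if (track_stats) update_stats(raw);
    feat = (raw - feat_mean) / feat_sd;
    return arma::dot(feat, w_head) + b_head;
  }

  void backward(double dpred, std::vector<arma::mat>& gW,
                std::vector<arma::vec>& gb, arma::vec& gw_head,
                double& gb_head) {
    gw_head += dpred * feat.t();
    gb_head += dpred;
    int nL = dims.back().n_out();
    arma::rowvec dfeat_raw = dpred * (w_head.t() / feat_sd);
    arma::mat dA = arma::repmat(dfeat_raw / nL, nL, 1);
    for (int l = (int)dims.size() - 1; l >= 0; --l) {
      arma::mat dO = dA % mask[l];
      gW[l] += P[l].t() * dO;
      gb[l] += arma::sum(dO, 0).t();
      if (l > 0) {
        arma::mat dP = dO * W[l].t();
        col2im(dP, dims[l], dA);
      }
    }
  }
};

static Net build_net(IntegerVector dim, const arma::imat& blocks,
                     List W0, List b0, arma::vec w_head0, double b_head0,
                     arma::rowvec feat_mean, arma::rowvec feat_sd) {
  Net net;
  net.dims = plan_blocks(blocks, dim[0], dim[1], dim[2]);
  for (std::size_t l = 0; l < net.dims.size(); ++l) {
    net.W.push_back(as<arma::mat>(W0[l]));
    net.b.push_back(as<arma::vec>(b0[l]));
    if ((int)net.W[l].n_rows != net.dims[l].patch() ||
        (int)net.W[l].n_cols != net.dims[l].c_out)
      stop("weight matrix %d has wrong shape", (int)l + 1);
  }
  net.w_head = w_head0; net.b_head = b_head0;
  net.feat_mean = feat_mean; net.feat_sd = feat_sd;
  net.init_ws();
  return net;
}

// [[Rcpp::export]]
List cpp_cnn_train(const arma::mat& X, const arma::vec& y, IntegerVector dim,
                   const arma::imat& blocks, List W0, List b0,
                   arma::vec w_head0, double b_head0,
                   double lr, double momentum, double decay,
                   int batch_size, int epochs,
                   double max_translation, double max_rotation, bool augment,
                   int seed, double clip_norm) {
  int n = (int)X.n_cols;
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int c_last = (int)blocks(blocks.n_rows - 1, 0);
  Net net = build_net(dim, blocks, W0, b0, w_head0, b_head0,
                      arma::rowvec(c_last, arma::fill::zeros),
                      arma::rowvec(c_last, arma::fill::ones));
  std::size_t L = net.dims.size();

  // initialize the normalization statistics over the (un-augmented)
  // training volumes with the initial weights; they are EMA-tracked during
  // training thereafter
  {
    arma::mat feats(n, c_last);
    for (int i = 0; i < n; ++i) {
      arma::mat xin(const_cast<double*>(X.colptr(i)), X.n_rows, 1, false, true);
      feats.row(i) = net.raw_features(xin, false);
    }
    net.feat_mean = arma::mean(feats, 0);
    net.feat_var = arma::var(feats, 0, 0);
    net.feat_sd = Net::floored_sd(arma::sqrt(net.feat_var));
  }
  net.track_stats = true;

  std::vector<arma::mat> gW(L), vW(L);
  std::vector<arma::vec> gb(L), vb(L);
  for (std::size_t l = 0; l < L; ++l) {
    gW[l].zeros(arma::size(net.W[l])); vW[l].zeros(arma::size(net.W[l]));
    gb[l].zeros(net.dims[l].c_out);    vb[l].zeros(net.dims[l].c_out);
  }
  arma::vec gw_head(net.w_head.n_elem), vw_head(net.w_head.n_elem, arma::fill::zeros);
  double gb_head = 0.0, vb_head = 0.0;

  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> u01(0.0, 1.0);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  arma::vec aug_buf(X.n_rows);
  NumericVector history(epochs);
  long step = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double abs_err = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      int bn = std::min(batch_size, n - start);
      for (std::size_t l = 0; l < L; ++l) { gW[l].zeros(); gb[l].zeros(); }
      gw_head.zeros(); gb_head = 0.0;
      for (int bi = 0; bi < bn; ++bi) {
        int i = order[start + bi];
        const double* src = X.colptr(i);
        const double* use = src;
        if (augment && (max_translation > 0 || max_rotation > 0)) {
          int axis = (int)(u01(rng) * 3.0); if (axis > 2) axis = 2;
          double ang = (2.0 * u01(rng) - 1.0) * max_rotation * M_PI / 180.0;
          double tx = (2.0 * u01(rng) - 1.0) * max_translation;
          double ty = (2.0 * u01(rng) - 1.0) * max_translation;
          double tz = (2.0 * u01(rng) - 1.0) * max_translation;
          rigid_resample(src, aug_buf.memptr(), nx, ny, nz, ang, axis, tx, ty, tz);
          use = aug_buf.memptr();
        }
        arma::mat xin(const_cast<double*>(use), X.n_rows, 1, false, true);
        double pred = net.forward(xin, true);
        double err = pred - y(i);
        abs_err += std::fabs(err);
        double dpred = (err > 0 ? 1.0 : (err < 0 ? -1.0 : 0.0)) / bn;
        net.backward(dpred, gW, gb, gw_head, gb_head);
      }
      ++step;
      // clip the global gradient norm: MAE gradients do not shrink near the
      // optimum, so an occasional steep batch would otherwise knock the conv
      // features away from their head calibration
      if (clip_norm > 0) {
        double sq = arma::dot(gw_head, gw_head) + gb_head * gb_head;
        for (std::size_t l = 0; l < L; ++l)
          sq += arma::accu(gW[l] % gW[l]) + arma::dot(gb[l], gb[l]);
        double gn = std::sqrt(sq);
        if (gn > clip_norm) {
          double sc = clip_norm / gn;
          for (std::size_t l = 0; l < L; ++l) { gW[l] *= sc; gb[l] *= sc; }
          gw_head *= sc; gb_head *= sc;
        }
      }
      double lr_t = lr / (1.0 + decay * step);
      for (std::size_t l = 0; l < L; ++l) {
        vW[l] = momentum * vW[l] - lr_t * gW[l];
        net.W[l] += vW[l];
        vb[l] = momentum * vb[l] - lr_t * gb[l];
        net.b[l] += vb[l];
      }
      vw_head = momentum * vw_head - lr_t * gw_head;
      net.w_head += vw_head;
      vb_head = momentum * vb_head - lr_t * gb_head;
      net.b_head += vb_head;
      if (!arma::is_finite(net.w_head))
        stop("non-finite parameters at step %ld: training diverged", step);
    }
    history[ep] = abs_err / n;
    if (ep % 10 == 0) Rcpp::checkUserInterrupt();
  }

  List Wout(L), bout(L);
  for (std::size_t l = 0; l < L; ++l) { Wout[l] = net.W[l]; bout[l] = net.b[l]; }
  return List::create(_["W"] = Wout, _["b"] = bout,
                      _["w_head"] = net.w_head, _["b_head"] = net.b_head,
                      _["feat_mean"] = net.feat_mean,
                      _["feat_sd"] = net.feat_sd,
                      _["history"] = history);
}

// [[Rcpp::export]]
arma::vec cpp_cnn_predict(const arma::mat& X, IntegerVector dim,
                          const arma::imat& blocks, List W, List b,
                          arma::vec w_head, double b_head,
                          arma::rowvec feat_mean, arma::rowvec feat_sd) {
  Net net = build_net(dim, blocks, W, b, w_head, b_head, feat_mean, feat_sd);
  arma::vec out(X.n_cols);
  for (arma::uword i = 0; i < X.n_cols; ++i) {
    arma::mat xin(const_cast<double*>(X.colptr(i)), X.n_rows, 1, false, true);
    out(i) = net.forward(xin, false);
  }
  return out;
}
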