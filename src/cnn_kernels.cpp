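// Compiled kernels for the multi-trait convolutional regression network.
//
// Layout conventions (match R's column-major arrays):
//   - an image batch arrives as a numeric array [H, W, C, N]
//   - a conv activation for one image is an arma::cube (H x W x C)
//   - conv weights are stored as a matrix (out_c x in_c*9); the row index of
//     the unrolled patch is c*9 + (di+1)*3 + (dj+1) for offsets di, dj in
//     {-1,0,1} (3x3 kernels, stride 1, zero padding 1)
//   - fully connected weights are (in x out); the head is (feature_dim x 5)
//
// Batch normalization uses biased batch variance both for normalization and
// for the running estimate; inference uses the running statistics.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static const double BN_EPS = 1e-5;

// Unroll 3x3 zero-padded patches: (C*9) x (H*W), output pixel (i,j) -> col j*H+i.
static mat im2col3(const cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat col(C * 9, H * W, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    for (int di = -1; di <= 1; ++di) {
      for (int dj = -1; dj <= 1; ++dj) {
        const uword r = c * 9 + (uword)(di + 1) * 3 + (uword)(dj + 1);
        for (uword j = 0; j < W; ++j) {
          const int sj = (int)j + dj;
          if (sj < 0 || sj >= (int)W) continue;
          for (uword i = 0; i < H; ++i) {
            const int si = (int)i + di;
            if (si < 0 || si >= (int)H) continue;
            col(r, j * H + i) = x(si, sj, c);
          }
        }
      }
    }
  }
  return col;
}

// Adjoint of im2col3: scatter-add patch gradients back onto the input grid.
static void col2im3_add(const mat& dcol, cube& dx) {
  const uword H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  for (uword c = 0; c < C; ++c) {
    for (int di = -1; di <= 1; ++di) {
      for (int dj = -1; dj <= 1; ++dj) {
        const uword r = c * 9 + (uword)(di + 1) * 3 + (uword)(dj + 1);
        for (uword j = 0; j < W; ++j) {
          const int sj = (int)j + dj;
          if (sj < 0 || sj >= (int)W) continue;
          for (uword i = 0; i < H; ++i) {
            const int si = (int)i + di;
            if (si < 0 || si >= (int)H) continue;
            dx(si, sj, c) += dcol(r, j * H + i);
          }
        }
      }
    }
  }
}

static cube conv3_forward(const cube& x, const mat& W, const vec& b) {
  const uword H = x.n_rows, Wd = x.n_cols;
  mat col = im2col3(x);
  mat Y = W * col;          // out_c x (H*W)
  Y.each_col() += b;
  cube z(H, Wd, W.n_rows);
  for (uword c = 0; c < W.n_rows; ++c)
    z.slice(c) = reshape(Y.row(c).t(), H, Wd);
  return z;
}

// 2x2 max pooling, stride 2; records the within-slice linear argmax index.
static cube pool2_forward(const cube& x, ucube& idx) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube out(H / 2, W / 2, C);
  idx.set_size(H / 2, W / 2, C);
  for (uword c = 0; c < C; ++c) {
    for (uword j = 0; j < W / 2; ++j) {
      for (uword i = 0; i < H / 2; ++i) {
        uword bi = 2 * i, bj = 2 * j, best = bj * H + bi;
        double bv = x(bi, bj, c);
        for (uword dj = 0; dj < 2; ++dj)
          for (uword di = 0; di < 2; ++di) {
            const double v = x(bi + di, bj + dj, c);
            if (v > bv) { bv = v; best = (bj + dj) * H + (bi + di); }
          }
        out(i, j, c) = bv;
        idx(i, j, c) = best;
      }
    }
  }
  return out;
}

static cube pool2_backward(const cube& dout, const ucube& idx,
                           uword H, uword W) {
  cube dx(H, W, dout.n_slices, fill::zeros);
  for (uword c = 0; c < dout.n_slices; ++c) {
    mat& sl = dx.slice(c);
    for (uword j = 0; j < dout.n_cols; ++j)
      for (uword i = 0; i < dout.n_rows; ++i)
        sl(idx(i, j, c)) += dout(i, j, c);
  }
  return dx;
}

struct BlockCache {
  std::vector<cube> input;   // conv input per image
  std::vector<cube> xhat;    // normalized pre-activation per image
  std::vector<cube> mask;    // relu mask per image (0/1)
  std::vector<ucube> pidx;   // pool argmax per image
  vec batch_mean, batch_var; // per-channel batch stats
};

// Full forward (and optionally backward) pass over one batch.
//
// params: conv_W, conv_b, bn_gamma, bn_beta, bn_rmean, bn_rvar (lists per
//         block), fc_W, fc_b (lists; last entry is the linear feature layer),
//         feat_rmean, feat_rvar, head_W, head_b.
// spec:   n_blocks, use_batchnorm, bn_momentum.
// x:      numeric array [H, W, C, N]; y: N x out_dim targets (may be empty
//         when want_grads = false).
// [[Rcpp::export]]
List cnn_batch_cpp(List params, List spec, NumericVector x, arma::mat y,
                   bool training, bool want_grads, double dropout) {
  IntegerVector xdim = x.attr("dim");
  if (xdim.size() != 4) stop("input must be a 4-d array [H, W, C, N]");
  const uword H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int n_blocks = as<int>(spec["n_blocks"]);
  const bool use_bn = as<bool>(spec["use_batchnorm"]);
  const double mom = as<double>(spec["bn_momentum"]);

  List conv_W = params["conv_W"], conv_b = params["conv_b"];
  List bn_gamma = params["bn_gamma"], bn_beta = params["bn_beta"];
  List bn_rmean = params["bn_rmean"], bn_rvar = params["bn_rvar"];
  List fc_W = params["fc_W"], fc_b = params["fc_b"];
  vec feat_rmean = as<vec>(params["feat_rmean"]);
  vec feat_rvar = as<vec>(params["feat_rvar"]);
  mat head_W = as<mat>(params["head_W"]);
  vec head_b = as<vec>(params["head_b"]);
  const int n_fc = fc_W.size();            // hidden fc layers + feature layer

  std::vector<BlockCache> caches(n_blocks);
  List bn_mean_new(n_blocks), bn_var_new(n_blocks);

  // ---- conv trunk ----
  std::vector<cube> act(N);
  for (uword n = 0; n < N; ++n) {
    act[n] = cube(const_cast<double*>(x.begin()) + n * H * W * C, H, W, C,
                  /*copy*/ true);
  }
  uword curH = H, curW = W;
  for (int l = 0; l < n_blocks; ++l) {
    mat Wl = as<mat>(conv_W[l]);
    vec bl = as<vec>(conv_b[l]);
    const uword oc = Wl.n_rows;
    if (as<mat>(conv_W[l]).n_cols != act[0].n_slices * 9)
      stop("conv block %d: weight shape does not match %d input channels",
           l + 1, (int)act[0].n_slices);
    if (curH % 2 != 0 || curW % 2 != 0)
      stop("pool layer in block %d: spatial size %dx%d is not even",
           l + 1, (int)curH, (int)curW);
    BlockCache& cc = caches[l];
    cc.input.resize(N); cc.xhat.resize(N); cc.mask.resize(N); cc.pidx.resize(N);

    std::vector<cube> z(N);
    for (uword n = 0; n < N; ++n) {
      cc.input[n] = act[n];
      z[n] = conv3_forward(act[n], Wl, bl);
    }

    vec gam = as<vec>(bn_gamma[l]), bet = as<vec>(bn_beta[l]);
    vec mu(oc), va(oc);
    if (use_bn) {
      if (training) {
        const double M = (double)N * curH * curW;
        for (uword c = 0; c < oc; ++c) {
          double s = 0, s2 = 0;
          for (uword n = 0; n < N; ++n) {
            s += accu(z[n].slice(c));
            s2 += accu(square(z[n].slice(c)));
          }
          mu(c) = s / M;
          va(c) = s2 / M - mu(c) * mu(c);
          if (va(c) < 0) va(c) = 0;
        }
        vec rm = as<vec>(bn_rmean[l]), rv = as<vec>(bn_rvar[l]);
        bn_mean_new[l] = wrap((1 - mom) * rm + mom * mu);
        bn_var_new[l] = wrap((1 - mom) * rv + mom * va);
      } else {
        mu = as<vec>(bn_rmean[l]);
        va = as<vec>(bn_rvar[l]);
      }
    }
    cc.batch_mean = mu; cc.batch_var = va;

    for (uword n = 0; n < N; ++n) {
      cube yb;
      if (use_bn) {
        cc.xhat[n].set_size(curH, curW, oc);
        yb.set_size(curH, curW, oc);
        for (uword c = 0; c < oc; ++c) {
          const double s = std::sqrt(va(c) + BN_EPS);
          cc.xhat[n].slice(c) = (z[n].slice(c) - mu(c)) / s;
          yb.slice(c) = gam(c) * cc.xhat[n].slice(c) + bet(c);
        }
      } else {
        yb = z[n];
      }
      cc.mask[n] = conv_to<cube>::from(yb > 0);
      yb %= cc.mask[n];
      act[n] = pool2_forward(yb, cc.pidx[n]);
    }
    curH /= 2; curW /= 2;
  }

  // ---- flatten + fc trunk ----
  const uword flat = curH * curW * act[0].n_slices;
  mat F0(N, flat);
  for (uword n = 0; n < N; ++n) F0.row(n) = vectorise(act[n]).t();

  std::vector<mat> fc_in(n_fc), fc_mask(n_fc), drop_mask(n_fc);
  mat cur = F0;
  for (int l = 0; l < n_fc; ++l) {
    fc_in[l] = cur;
    mat Wl = as<mat>(fc_W[l]);
    rowvec bl = as<rowvec>(fc_b[l]);
    cur = cur * Wl;
    cur.each_row() += bl;
    if (l < n_fc - 1) {                    // hidden layers: relu + dropout
      fc_mask[l] = conv_to<mat>::from(cur > 0);
      cur %= fc_mask[l];
      if (training && dropout > 0) {
        drop_mask[l].set_size(cur.n_rows, cur.n_cols);
        for (uword k = 0; k < cur.n_elem; ++k)
          drop_mask[l](k) = (R::unif_rand() > dropout) ? 1.0 / (1 - dropout) : 0.0;
        cur %= drop_mask[l];
      }
    }
  }
  mat feat_raw = cur;                      // N x feature_dim, pre-BN

  // ---- non-affine feature batch norm ----
  vec fmu, fva;
  if (training) {
    fmu = mean(feat_raw, 0).t();
    fva = var(feat_raw, 1, 0).t();        // biased
  } else {
    fmu = feat_rmean; fva = feat_rvar;
  }
  mat fhat = feat_raw;
  fhat.each_row() -= fmu.t();
  fhat.each_row() /= sqrt(fva.t() + BN_EPS);

  mat preds = fhat * head_W;
  preds.each_row() += head_b.t();

  double loss = NA_REAL;
  if (y.n_elem > 0) loss = accu(square(preds - y)) / (double)(preds.n_elem);

  List out = List::create(
    _["loss"] = loss,
    _["preds"] = preds,
    _["features"] = fhat);

  if (training) {
    out["feat_rmean"] = wrap((1 - mom) * feat_rmean + mom * fmu);
    out["feat_rvar"] = wrap((1 - mom) * feat_rvar + mom * fva);
    out["bn_rmean"] = bn_mean_new;
    out["bn_rvar"] = bn_var_new;
  }
  if (!want_grads) return out;

  // ================= backward =================
  mat dP = 2.0 * (preds - y) / (double)(preds.n_elem);
  mat d_head_W = fhat.t() * dP;
  rowvec d_head_b = sum(dP, 0);
  mat dfhat = dP * head_W.t();

  // non-affine BN backward over rows (M = N)
  mat dfeat(N, feat_raw.n_cols);
  {
    const double M = (double)N;
    rowvec s = sqrt(fva.t() + BN_EPS);
    rowvec sum_dy = sum(dfhat, 0);
    rowvec sum_dyx = sum(dfhat % fhat, 0);
    dfeat = dfhat;
    dfeat.each_row() -= sum_dy / M;
    dfeat -= fhat % repmat(sum_dyx / M, N, 1);
    dfeat.each_row() /= s;
  }

  List d_fc_W(n_fc), d_fc_b(n_fc);
  mat dcur = dfeat;
  for (int l = n_fc - 1; l >= 0; --l) {
    if (l < n_fc - 1) {
      if (training && dropout > 0 && drop_mask[l].n_elem > 0) dcur %= drop_mask[l];
      dcur %= fc_mask[l];
    }
    mat Wl = as<mat>(fc_W[l]);
    d_fc_W[l] = wrap(fc_in[l].t() * dcur);
    d_fc_b[l] = wrap(sum(dcur, 0));
    dcur = dcur * Wl.t();
  }

  // unflatten
  curH = H >> n_blocks; curW = W >> n_blocks;
  std::vector<cube> dact(N);
  for (uword n = 0; n < N; ++n) {
    vec v = dcur.row(n).t();
    dact[n] = cube(v.memptr(), curH, curW, act[0].n_slices, /*copy*/ true);
  }

  List d_conv_W(n_blocks), d_conv_b(n_blocks), d_gam(n_blocks), d_bet(n_blocks);
  for (int l = n_blocks - 1; l >= 0; --l) {
    BlockCache& cc = caches[l];
    mat Wl = as<mat>(conv_W[l]);
    const uword oc = Wl.n_rows;
    const uword bh = cc.mask[0].n_rows, bw = cc.mask[0].n_cols;

    std::vector<cube> dz(N);
    vec dgam(oc, fill::zeros), dbet(oc, fill::zeros);
    if (use_bn) {
      vec gam = as<vec>(bn_gamma[l]);
      // accumulate per-channel sums for BN backward
      std::vector<cube> dy(N);
      vec sum_dy(oc, fill::zeros), sum_dyx(oc, fill::zeros);
      for (uword n = 0; n < N; ++n) {
        dy[n] = pool2_backward(dact[n], cc.pidx[n], bh, bw);
        dy[n] %= cc.mask[n];
        for (uword c = 0; c < oc; ++c) {
          dgam(c) += accu(dy[n].slice(c) % cc.xhat[n].slice(c));
          dbet(c) += accu(dy[n].slice(c));
        }
      }
      if (training) {
        const double M = (double)N * bh * bw;
        for (uword n = 0; n < N; ++n) {
          dz[n].set_size(bh, bw, oc);
          for (uword c = 0; c < oc; ++c) {
            const double s = std::sqrt(cc.batch_var(c) + BN_EPS);
            // dxhat = dy*gamma; mean(dxhat) = gamma*dbeta/M,
            // mean(dxhat*xhat) = gamma*dgamma/M
            dz[n].slice(c) =
              (gam(c) / s) * (dy[n].slice(c) - dbet(c) / M -
                              cc.xhat[n].slice(c) * (dgam(c) / M));
          }
        }
      } else {
        for (uword n = 0; n < N; ++n) {
          dz[n].set_size(bh, bw, oc);
          for (uword c = 0; c < oc; ++c) {
            const double s = std::sqrt(cc.batch_var(c) + BN_EPS);
            dz[n].slice(c) = dy[n].slice(c) * (gam(c) / s);
          }
        }
      }
    } else {
      for (uword n = 0; n < N; ++n) {
        dz[n] = pool2_backward(dact[n], cc.pidx[n], bh, bw);
        dz[n] %= cc.mask[n];
      }
    }

    mat dW(size(Wl), fill::zeros);
    vec db(oc, fill::zeros);
    for (uword n = 0; n < N; ++n) {
      mat dY(oc, bh * bw);
      for (uword c = 0; c < oc; ++c) dY.row(c) = vectorise(dz[n].slice(c)).t();
      mat col = im2col3(cc.input[n]);
      dW += dY * col.t();
      db += sum(dY, 1);
      mat dcol = Wl.t() * dY;
      cube dxn(cc.input[n].n_rows, cc.input[n].n_cols, cc.input[n].n_slices,
               fill::zeros);
      col2im3_add(dcol, dxn);
      dact[n] = dxn;
    }
    d_conv_W[l] = wrap(dW);
    d_conv_b[l] = wrap(db);
    d_gam[l] = wrap(dgam);
    d_bet[l] = wrap(dbet);
  }

  out["grads"] = List::create(
    _["conv_W"] = d_conv_W, _["conv_b"] = d_conv_b,
    _["bn_gamma"] = d_gam, _["bn_beta"] = d_bet,
    _["fc_W"] = d_fc_W, _["fc_b"] = d_fc_b,
    _["head_W"] = d_head_W, _["head_b"] = wrap(d_head_b));
  return out;
}

// Reference-path single-image convolution, exposed for kernel tests.
// [[Rcpp::export]]
arma::cube conv3x3_forward_cpp(arma::cube x, arma::mat W, arma::vec b) {
  return conv3_forward(x, W, b);
}
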