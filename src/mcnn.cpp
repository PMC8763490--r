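// Multilayer CNN engine: blocks of [3x3 conv (same padding) -> ReLU ->
// 2x2 max-pool], then flatten -> dropout -> FC -> ReLU -> FC -> softmax.
// Spatial tensors are held as (channels x H*W) matrices with pixel linear
// index i + j*H (column-major, matching R arrays). Convolutions run per
// sample via im2col + GEMM; the fully connected head is batched so its
// large weight matrices stream through memory once per minibatch. All
// stochastic inputs (sample order, dropout masks) are generated on the R
// side so training is bit-reproducible for a fixed R seed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::mat;
using arma::vec;

static void im2col3(const mat& A, int H, int W, mat& cols) {
  const int C = A.n_rows;
  cols.set_size(9 * C, H * W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const int col = i + j * H;
      int r = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          const int ii = i + di, jj = j + dj;
          if (ii >= 0 && ii < H && jj >= 0 && jj < W) {
            const int src = ii + jj * H;
            for (int c = 0; c < C; ++c) cols(r + c, col) = A(c, src);
          } else {
            for (int c = 0; c < C; ++c) cols(r + c, col) = 0.0;
          }
          r += C;
        }
      }
    }
  }
}

// adjoint of im2col3: scatter-add column gradients back to the image grid
static void col2im3(const mat& dcols, int H, int W, int C, mat& dA) {
  dA.zeros(C, H * W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const int col = i + j * H;
      int r = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          const int ii = i + di, jj = j + dj;
          if (ii >= 0 && ii < H && jj >= 0 && jj < W) {
            const int src = ii + jj * H;
            for (int c = 0; c < C; ++c) dA(c, src) += dcols(r + c, col);
          }
          r += C;
        }
      }
    }
  }
}

// 2x2 stride-2 max pool; records the argmax pixel index for the backward pass
static void maxpool2(const mat& A, int H, int W, mat& P, arma::umat& idx) {
  const int C = A.n_rows, Ho = H / 2, Wo = W / 2;
  P.set_size(C, Ho * Wo);
  idx.set_size(C, Ho * Wo);
  for (int jo = 0; jo < Wo; ++jo) {
    for (int io = 0; io < Ho; ++io) {
      const int col = io + jo * Ho;
      const int p00 = 2 * io + (2 * jo) * H;
      const int cand[4] = {p00, p00 + 1, p00 + H, p00 + H + 1};
      for (int c = 0; c < C; ++c) {
        double best = A(c, cand[0]);
        int bi = cand[0];
        for (int t = 1; t < 4; ++t) {
          if (A(c, cand[t]) > best) { best = A(c, cand[t]); bi = cand[t]; }
        }
        P(c, col) = best;
        idx(c, col) = bi;
      }
    }
  }
}

struct Net {
  int H, W, C0, nblocks, nclasses;
  std::vector<mat> convW;   // (C_out x 9*C_in)
  std::vector<vec> convB;
  mat fc1W, fc2W;           // (fc_units x F), (nclasses x fc_units)
  vec fc1B, fc2B;
};

// wrap R-side matrices without copying so updates happen in place
static Net wrap_net(Rcpp::List convW, Rcpp::List convB,
                    Rcpp::List fcW, Rcpp::List fcB, int H, int W, int C0) {
  Net net;
  net.H = H; net.W = W; net.C0 = C0;
  net.nblocks = convW.size();
  // reserve up front: vector reallocation would copy the aux-memory
  // matrices and silently detach them from the R-side storage
  net.convW.reserve(net.nblocks);
  net.convB.reserve(net.nblocks);
  for (int k = 0; k < net.nblocks; ++k) {
    Rcpp::NumericMatrix w = convW[k];
    Rcpp::NumericVector b = convB[k];
    net.convW.emplace_back(w.begin(), w.nrow(), w.ncol(), false, true);
    net.convB.emplace_back(b.begin(), b.size(), false, true);
  }
  Rcpp::NumericMatrix w1 = fcW[0], w2 = fcW[1];
  Rcpp::NumericVector b1 = fcB[0], b2 = fcB[1];
  net.fc1W = mat(w1.begin(), w1.nrow(), w1.ncol(), false, true);
  net.fc2W = mat(w2.begin(), w2.nrow(), w2.ncol(), false, true);
  net.fc1B = vec(b1.begin(), b1.size(), false, true);
  net.fc2B = vec(b2.begin(), b2.size(), false, true);
  net.nclasses = w2.nrow();
  return net;
}

// per-sample convolutional caches for one minibatch
struct ConvCache {
  std::vector<mat> cols, Z;
  std::vector<arma::umat> poolidx;
};

// conv stack forward for one sample; returns the flattened deepest features
static vec conv_forward(const Net& net, const double* xptr, ConvCache* cc) {
  int H = net.H, W = net.W;
  // R array layout (H, W, C, N): channel planes are contiguous, so the raw
  // sample is an (H*W x C) matrix; transpose into the internal (C x H*W)
  mat At(const_cast<double*>(xptr), (size_t)H * W, net.C0, false, true);
  mat cur = At.t();
  if (cc) {
    cc->cols.resize(net.nblocks);
    cc->Z.resize(net.nblocks);
    cc->poolidx.resize(net.nblocks);
  }
  mat cols, Z, P;
  arma::umat idx;
  for (int k = 0; k < net.nblocks; ++k) {
    im2col3(cur, H, W, cols);
    Z = net.convW[k] * cols;
    Z.each_col() += net.convB[k];
    mat Ar = Z;
    Ar.elem(arma::find(Ar < 0)).zeros();
    maxpool2(Ar, H, W, P, idx);
    if (cc) { cc->cols[k] = cols; cc->Z[k] = Z; cc->poolidx[k] = idx; }
    cur = P;
    H /= 2; W /= 2;
  }
  return arma::vectorise(cur);
}

// conv stack backward for one sample, given the gradient at the flatten
static void conv_backward(const Net& net, const ConvCache& cc, const vec& da,
                          std::vector<mat>& gW, std::vector<vec>& gB) {
  int H = net.H >> net.nblocks, W = net.W >> net.nblocks;
  int C = net.convW[net.nblocks - 1].n_rows;
  mat dP = arma::reshape(da, C, H * W);
  mat dA, dZ, dcols;
  for (int k = net.nblocks - 1; k >= 0; --k) {
    const int Hk = net.H >> k, Wk = net.W >> k;   // pre-pool grid of block k
    const int Ck = net.convW[k].n_rows;
    dA.zeros(Ck, (size_t)Hk * Wk);
    const arma::umat& idx = cc.poolidx[k];
    for (arma::uword col = 0; col < idx.n_cols; ++col) {
      for (int c = 0; c < Ck; ++c) dA(c, idx(c, col)) += dP(c, col);
    }
    dZ = dA % arma::conv_to<mat>::from(cc.Z[k] > 0);
    gW[k] += dZ * cc.cols[k].t();
    gB[k] += arma::sum(dZ, 1);
    if (k > 0) {  // no input gradient needed below the first block
      dcols = net.convW[k].t() * dZ;
      const int Cin = net.convW[k - 1].n_rows;
      col2im3(dcols, Hk, Wk, Cin, dP);
    }
  }
}

// one epoch of momentum SGD; weights and velocities are updated in place.
// Returns running mean loss and accuracy over the training pass.
// [[Rcpp::export]]
Rcpp::NumericVector mcnn_epoch_cpp(Rcpp::NumericVector X,
                                   Rcpp::IntegerVector dimX,
                                   Rcpp::IntegerVector y,
                                   Rcpp::List convW, Rcpp::List convB,
                                   Rcpp::List fcW, Rcpp::List fcB,
                                   Rcpp::List velW, Rcpp::List velB,
                                   Rcpp::List velFW, Rcpp::List velFB,
                                   Rcpp::IntegerVector order,
                                   Rcpp::NumericMatrix dropmask,
                                   int batch_size, double lr, double momentum,
                                   double dropout, double clip_norm) {
  const int H = dimX[0], W = dimX[1], C = dimX[2];
  const size_t sampsz = (size_t)H * W * C;
  Net net = wrap_net(convW, convB, fcW, fcB, H, W, C);
  Net vel = wrap_net(velW, velB, velFW, velFB, H, W, C);
  const int F = net.fc1W.n_cols;

  const int ntrain = order.size();
  std::vector<ConvCache> caches(batch_size);
  std::vector<mat> gW(net.nblocks);
  std::vector<vec> gB(net.nblocks);
  mat gfc1W, gfc2W;
  vec gfc1B, gfc2B;

  double loss = 0.0;
  int correct = 0;
  int pos = 0;
  while (pos < ntrain) {
    const int bs = std::min(batch_size, ntrain - pos);
    for (int k = 0; k < net.nblocks; ++k) {
      gW[k].zeros(net.convW[k].n_rows, net.convW[k].n_cols);
      gB[k].zeros(net.convB[k].n_elem);
    }
    gfc1W.zeros(net.fc1W.n_rows, net.fc1W.n_cols);
    gfc2W.zeros(net.fc2W.n_rows, net.fc2W.n_cols);
    gfc1B.zeros(net.fc1B.n_elem);
    gfc2B.zeros(net.fc2B.n_elem);

    // conv stacks per sample, flatten into a batch matrix
    mat Aflat(F, bs), M(F, bs, arma::fill::ones);
    for (int b = 0; b < bs; ++b) {
      const int s = order[pos + b] - 1;   // R-side 1-based
      Aflat.col(b) = conv_forward(net, X.begin() + sampsz * s, &caches[b]);
      if (dropout > 0) {
        M.col(b) = vec(&dropmask(0, pos + b), F) / (1.0 - dropout);
      }
    }
    mat Adrop = Aflat % M;

    // batched fully connected head
    mat Z1 = net.fc1W * Adrop;
    Z1.each_col() += net.fc1B;
    mat H1 = Z1;
    H1.elem(arma::find(H1 < 0)).zeros();
    mat Z2 = net.fc2W * H1;
    Z2.each_col() += net.fc2B;
    mat P = Z2;
    P.each_row() -= arma::max(Z2, 0);
    P = arma::exp(P);
    P.each_row() /= arma::sum(P, 0);

    mat dZ2 = P;
    for (int b = 0; b < bs; ++b) {
      const int s = order[pos + b] - 1;
      const int yy = y[s];
      loss += -std::log(std::max(P(yy, b), 1e-12));
      if (P.col(b).index_max() == (arma::uword)yy) ++correct;
      dZ2(yy, b) -= 1.0;
    }
    gfc2W += dZ2 * H1.t();
    gfc2B += arma::sum(dZ2, 1);
    mat dH1 = net.fc2W.t() * dZ2;
    mat dZ1 = dH1 % arma::conv_to<mat>::from(Z1 > 0);
    gfc1W += dZ1 * Adrop.t();
    gfc1B += arma::sum(dZ1, 1);
    mat dA = (net.fc1W.t() * dZ1) % M;

    for (int b = 0; b < bs; ++b) {
      conv_backward(net, caches[b], dA.col(b), gW, gB);
    }

    // global gradient-norm clipping (on the mean-over-batch gradient):
    // one oversized early step, amplified by momentum, can push every
    // hidden unit into the dead half of the ReLU and freeze training
    double scale = lr / bs;
    if (clip_norm > 0) {
      double sq = arma::dot(gfc1W, gfc1W) + arma::dot(gfc2W, gfc2W) +
                  arma::dot(gfc1B, gfc1B) + arma::dot(gfc2B, gfc2B);
      for (int k = 0; k < net.nblocks; ++k) {
        sq += arma::dot(gW[k], gW[k]) + arma::dot(gB[k], gB[k]);
      }
      const double gnorm = std::sqrt(sq) / bs;
      if (gnorm > clip_norm) scale *= clip_norm / gnorm;
    }
    for (int k = 0; k < net.nblocks; ++k) {
      vel.convW[k] = momentum * vel.convW[k] - scale * gW[k];
      net.convW[k] += vel.convW[k];
      vel.convB[k] = momentum * vel.convB[k] - scale * gB[k];
      net.convB[k] += vel.convB[k];
    }
    vel.fc1W = momentum * vel.fc1W - scale * gfc1W;  net.fc1W += vel.fc1W;
    vel.fc2W = momentum * vel.fc2W - scale * gfc2W;  net.fc2W += vel.fc2W;
    vel.fc1B = momentum * vel.fc1B - scale * gfc1B;  net.fc1B += vel.fc1B;
    vel.fc2B = momentum * vel.fc2B - scale * gfc2B;  net.fc2B += vel.fc2B;
    pos += bs;
  }
  return Rcpp::NumericVector::create(loss / ntrain,
                                     (double)correct / ntrain);
}

// forward pass over a batch of samples: returns (n_classes x N)
// probabilities; conv stacks run per sample, the FC head in chunks
// [[Rcpp::export]]
Rcpp::NumericMatrix mcnn_predict_cpp(Rcpp::NumericVector X,
                                     Rcpp::IntegerVector dimX,
                                     Rcpp::List convW, Rcpp::List convB,
                                     Rcpp::List fcW, Rcpp::List fcB) {
  const int H = dimX[0], W = dimX[1], C = dimX[2], N = dimX[3];
  const size_t sampsz = (size_t)H * W * C;
  Net net = wrap_net(convW, convB, fcW, fcB, H, W, C);
  const int F = net.fc1W.n_cols;
  Rcpp::NumericMatrix out(net.nclasses, N);
  const int chunk = 64;
  for (int s0 = 0; s0 < N; s0 += chunk) {
    const int bs = std::min(chunk, N - s0);
    mat Aflat(F, bs);
    for (int b = 0; b < bs; ++b) {
      Aflat.col(b) = conv_forward(net, X.begin() + sampsz * (s0 + b),
                                  nullptr);
    }
    mat Z1 = net.fc1W * Aflat;
    Z1.each_col() += net.fc1B;
    Z1.elem(arma::find(Z1 < 0)).zeros();
    mat Z2 = net.fc2W * Z1;
    Z2.each_col() += net.fc2B;
    Z2.each_row() -= arma::max(Z2, 0);
    Z2 = arma::exp(Z2);
    Z2.each_row() /= arma::sum(Z2, 0);
    for (int b = 0; b < bs; ++b) {
      for (int c = 0; c < net.nclasses; ++c) out(c, s0 + b) = Z2(c, b);
    }
  }
  return out;
}
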