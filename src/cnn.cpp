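// Minimal CNN engine for 4-class patch classification.
//
// Layer sequence (fixed topology, configurable widths):
//   [conv3x3 same + ReLU, conv3x3 same + ReLU, maxpool 2x2, dropout] x nBlocks
//   flatten -> dense + ReLU + dropout -> dense + softmax
//
// Feature maps are stored as (channels x H*W) matrices with pixel column
// index j = r + c*H (column-major in the spatial grid). Convolutions use
// im2col with kernel-major row blocks: row block k*C..k*C+C-1 holds the
// input shifted by kernel offset k = (kr+1) + (kc+1)*3, zero padded.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

static void im2col3(const mat& X, int H, int W, mat& K) {
  const int C = X.n_rows;
  K.zeros(9 * C, H * W);
  for (int kc = -1; kc <= 1; ++kc) {
    for (int kr = -1; kr <= 1; ++kr) {
      const int k = (kr + 1) + (kc + 1) * 3;
      const int r0 = std::max(0, -kr), r1 = std::min(H - 1, H - 1 - kr);
      if (r1 < r0) continue;
      for (int c = 0; c < W; ++c) {
        const int cc = c + kc;
        if (cc < 0 || cc >= W) continue;
        // output rows r0..r1 at column block of c map to input rows r0+kr..
        K.submat(k * C, c * H + r0, k * C + C - 1, c * H + r1) =
          X.submat(0, cc * H + r0 + kr, C - 1, cc * H + r1 + kr);
      }
    }
  }
}

static void col2im3(const mat& dK, int H, int W, mat& dX) {
  const int C = dX.n_rows; // dX must be pre-zeroed C x H*W
  for (int kc = -1; kc <= 1; ++kc) {
    for (int kr = -1; kr <= 1; ++kr) {
      const int k = (kr + 1) + (kc + 1) * 3;
      const int r0 = std::max(0, -kr), r1 = std::min(H - 1, H - 1 - kr);
      if (r1 < r0) continue;
      for (int c = 0; c < W; ++c) {
        const int cc = c + kc;
        if (cc < 0 || cc >= W) continue;
        dX.submat(0, cc * H + r0 + kr, C - 1, cc * H + r1 + kr) +=
          dK.submat(k * C, c * H + r0, k * C + C - 1, c * H + r1);
      }
    }
  }
}

static void maxpool2(const mat& A, int H, int W, mat& P, arma::umat& idx) {
  const int C = A.n_rows, Ho = H / 2, Wo = W / 2;
  P.set_size(C, Ho * Wo);
  idx.set_size(C, Ho * Wo);
  for (int c = 0; c < Wo; ++c) {
    for (int r = 0; r < Ho; ++r) {
      const int jo = r + c * Ho;
      const int j00 = 2 * r + 2 * c * H;
      const int cand[4] = {j00, j00 + 1, j00 + H, j00 + H + 1};
      for (int ch = 0; ch < C; ++ch) {
        double best = A(ch, cand[0]);
        int bi = cand[0];
        for (int q = 1; q < 4; ++q)
          if (A(ch, cand[q]) > best) { best = A(ch, cand[q]); bi = cand[q]; }
        P(ch, jo) = best;
        idx(ch, jo) = bi;
      }
    }
  }
}

struct DropMask {
  mat m;
  void fill(int nr, int nc, double rate, std::mt19937& gen) {
    m.set_size(nr, nc);
    if (rate <= 0.0) { m.ones(); return; }
    std::uniform_real_distribution<double> U(0.0, 1.0);
    const double keep = 1.0 - rate;
    for (arma::uword i = 0; i < m.n_elem; ++i)
      m(i) = (U(gen) < keep) ? 1.0 / keep : 0.0;
  }
};

struct LayerCache {
  mat K;        // im2col matrix
  mat Z;        // pre-activation
  mat P;        // post-pool (only for even layers)
  arma::umat poolIdx;
  DropMask drop;
  int H, W;     // spatial dims at layer input
};

// Extract sample n from the R array (N, s, s, 3) into X (3 x s*s).
static void sampleToMat(const double* x, int n, int N, int s, mat& X) {
  X.set_size(3, s * s);
  for (int ch = 0; ch < 3; ++ch)
    for (int c = 0; c < s; ++c)
      for (int r = 0; r < s; ++r)
        X(ch, r + c * s) = x[n + N * (r + s * (c + s * ch))] / 255.0;
}

struct Net {
  std::vector<mat> convW;
  std::vector<vec> convB;
  mat d1W; vec d1B;
  mat d2W; vec d2B;
  int nBlocks;
  std::vector<double> blockDrop;
  double denseDrop;
  int H0;
};

static Net unpack(const List& weights, const List& meta) {
  Net net;
  List conv = weights["conv"];
  net.nBlocks = as<int>(meta["nBlocks"]);
  for (int l = 0; l < conv.size(); ++l) {
    List wl = conv[l];
    net.convW.push_back(as<mat>(wl["W"]));
    net.convB.push_back(as<vec>(wl["b"]));
  }
  List d1 = weights["dense1"], d2 = weights["dense2"];
  net.d1W = as<mat>(d1["W"]); net.d1B = as<vec>(d1["b"]);
  net.d2W = as<mat>(d2["W"]); net.d2B = as<vec>(d2["b"]);
  net.blockDrop = as<std::vector<double>>(meta["blockDrop"]);
  net.denseDrop = as<double>(meta["denseDrop"]);
  net.H0 = as<int>(meta["inputSide"]);
  return net;
}

// Forward one sample; fills caches when caching = true.
static vec forwardOne(const Net& net, mat X, bool training, std::mt19937& gen,
                      std::vector<LayerCache>& caches, DropMask& denseMask,
                      vec& flat, vec& h1, vec& z1, bool caching) {
  int H = net.H0, W = net.H0;
  const int nConv = net.convW.size();
  for (int l = 0; l < nConv; ++l) {
    LayerCache& cc = caches[l];
    cc.H = H; cc.W = W;
    im2col3(X, H, W, cc.K);
    cc.Z = net.convW[l] * cc.K;
    cc.Z.each_col() += net.convB[l];
    mat A = arma::max(cc.Z, arma::zeros<mat>(cc.Z.n_rows, cc.Z.n_cols));
    if (l % 2 == 1) { // end of block: pool then dropout
      mat P;
      maxpool2(A, H, W, P, cc.poolIdx);
      H /= 2; W /= 2;
      const double rate = training ? net.blockDrop[l / 2] : 0.0;
      cc.drop.fill(P.n_rows, P.n_cols, rate, gen);
      cc.P = P % cc.drop.m;
      X = cc.P;
    } else {
      X = A;
    }
    if (!caching) { cc.K.reset(); cc.Z.reset(); }
  }
  flat = arma::vectorise(X);
  z1 = net.d1W * flat + net.d1B;
  h1 = arma::max(z1, arma::zeros<vec>(z1.n_elem));
  denseMask.fill(h1.n_elem, 1, training ? net.denseDrop : 0.0, gen);
  vec hd = h1 % denseMask.m.col(0);
  vec z2 = net.d2W * hd + net.d2B;
  z2 -= z2.max();
  vec e = arma::exp(z2);
  return e / arma::accu(e);
}

// [[Rcpp::export]]
NumericMatrix cnn_forward(List weights, NumericVector x, IntegerVector dims,
                          List meta, bool training, int seed) {
  Net net = unpack(weights, meta);
  const int N = dims[0], s = dims[1];
  std::mt19937 gen(seed);
  std::vector<LayerCache> caches(net.convW.size());
  DropMask dm; vec flat, h1, z1;
  const int K = net.d2W.n_rows;
  NumericMatrix probs(N, K);
  mat X;
  for (int n = 0; n < N; ++n) {
    sampleToMat(REAL(x), n, N, s, X);
    vec p = forwardOne(net, X, training, gen, caches, dm, flat, h1, z1, false);
    for (int k = 0; k < K; ++k) probs(n, k) = p(k);
  }
  return probs;
}

// [[Rcpp::export]]
List cnn_grad(List weights, NumericVector x, IntegerVector dims,
              IntegerVector ycode, List meta, int seed) {
  Net net = unpack(weights, meta);
  const int N = dims[0], s = dims[1];
  const int nConv = net.convW.size();
  const int K = net.d2W.n_rows;
  std::mt19937 gen(seed);

  std::vector<mat> gConvW(nConv);
  std::vector<vec> gConvB(nConv);
  for (int l = 0; l < nConv; ++l) {
    gConvW[l].zeros(net.convW[l].n_rows, net.convW[l].n_cols);
    gConvB[l].zeros(net.convB[l].n_elem);
  }
  mat gD1W(net.d1W.n_rows, net.d1W.n_cols, arma::fill::zeros);
  vec gD1B(net.d1B.n_elem, arma::fill::zeros);
  mat gD2W(net.d2W.n_rows, net.d2W.n_cols, arma::fill::zeros);
  vec gD2B(net.d2B.n_elem, arma::fill::zeros);

  std::vector<LayerCache> caches(nConv);
  DropMask denseMask;
  vec flat, h1, z1;
  double loss = 0.0;
  NumericMatrix probs(N, K);
  mat X;

  for (int n = 0; n < N; ++n) {
    sampleToMat(REAL(x), n, N, s, X);
    vec p = forwardOne(net, X, true, gen, caches, denseMask, flat, h1, z1, true);
    for (int k = 0; k < K; ++k) probs(n, k) = p(k);
    const int yi = ycode[n];
    loss += -std::log(std::max(p(yi), 1e-12));

    // output layer
    vec dz2 = p;
    dz2(yi) -= 1.0;
    vec hd = h1 % denseMask.m.col(0);
    gD2W += dz2 * hd.t();
    gD2B += dz2;
    vec dhd = net.d2W.t() * dz2;
    vec dz1 = (dhd % denseMask.m.col(0)) % arma::conv_to<vec>::from(z1 > 0);
    gD1W += dz1 * flat.t();
    gD1B += dz1;
    vec dflat = net.d1W.t() * dz1;

    // back through conv blocks
    mat dX(arma::size(caches[nConv - 1].P));
    std::copy(dflat.begin(), dflat.end(), dX.begin());
    for (int l = nConv - 1; l >= 0; --l) {
      LayerCache& cc = caches[l];
      mat dA;
      if (l % 2 == 1) {
        // dropout backward then unpool to pre-pool size
        mat dP = dX % cc.drop.m;
        dA.zeros(cc.Z.n_rows, cc.H * cc.W);
        for (arma::uword ch = 0; ch < dP.n_rows; ++ch)
          for (arma::uword j = 0; j < dP.n_cols; ++j)
            dA(ch, cc.poolIdx(ch, j)) += dP(ch, j);
      } else {
        dA = dX;
      }
      mat dZ = dA % arma::conv_to<mat>::from(cc.Z > 0);
      gConvW[l] += dZ * cc.K.t();
      gConvB[l] += arma::sum(dZ, 1);
      if (l > 0) {
        mat dK = net.convW[l].t() * dZ;
        const int Cin = net.convW[l].n_cols / 9;
        dX.zeros(Cin, cc.H * cc.W);
        col2im3(dK, cc.H, cc.W, dX);
      }
    }
  }

  const double inv = 1.0 / N;
  List gConv(nConv);
  for (int l = 0; l < nConv; ++l)
    gConv[l] = List::create(_["W"] = wrap(mat(gConvW[l] * inv)),
                            _["b"] = wrap(vec(gConvB[l] * inv)));
  return List::create(
    _["loss"] = loss * inv,
    _["probs"] = probs,
    _["grads"] = List::create(
      _["conv"] = gConv,
      _["dense1"] = List::create(_["W"] = wrap(mat(gD1W * inv)),
                                 _["b"] = wrap(vec(gD1B * inv))),
      _["dense2"] = List::create(_["W"] = wrap(mat(gD2W * inv)),
                                 _["b"] = wrap(vec(gD2B * inv)))));
}
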