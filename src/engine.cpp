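// Multitask 3D CNN engine: forward, backprop, Adam, and input gradients.
//
// Layer stack (fixed topology, configurable widths):
//   per block:  batch-norm -> conv 3x3x3 (same padding, ReLU) -> max-pool 3x3x3 stride 2 (same)
//   then:       flatten -> dropout -> dense (ReLU) -> three heads
//   per head:   dense (ReLU) -> batch-norm -> dense(1) -> sigmoid (gender/diagnosis) or identity (age)
//
// Data layout: one sample is a column vector of length nvox*channels,
// voxel-major (x fastest, then y, z) with the channel index slowest, matching
// the column-major flattening of an R array dim c(nx, ny, nz, C).
// All heavy arithmetic is single precision; parameters cross the R boundary
// as doubles (float -> double -> float is exact).

#include <RcppArmadillo.h>
#include <random>
#include <array>
#include <limits>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const float BN_EPS = 1e-5f;
static const double BCE_EPS = 1e-7;

typedef std::array<int, 3> dim3;

static inline int ceil_div2(int n) { return (n + 1) / 2; }

struct DataSet {
  fmat X;          // D x N
  fvec age;
  fvec gender;
  fvec diagnosis;
};

// ---------------------------------------------------------------------------
// geometry helpers

struct ConvGeom {
  dim3 dim;        // spatial dims (conv keeps them; same padding)
  int cin, cout;
};

// im2col (transposed layout) for 3x3x3 same-padded convolution:
// colsT is nvox x (27*cin), column r = c*27 + o with offset index
// o = (dx+1) + 3*(dy+1) + 9*(dz+1). Writes are contiguous runs along x, so
// the buffer streams through cache; out-of-range (padding) entries are
// zeroed once at allocation and never touched again (the in-range region of
// every column is identical across samples).
static void im2col3(const float* x, const dim3& d, int cin, fmat& colsT) {
  const int nx = d[0], ny = d[1], nz = d[2];
  const int nvox = nx * ny * nz;
  for (int c = 0; c < cin; ++c) {
    const float* xc = x + (size_t)c * nvox;
    for (int o = 0; o < 27; ++o) {
      const int dx = o % 3 - 1, dy = (o / 3) % 3 - 1, dz = o / 9 - 1;
      float* col = colsT.colptr(c * 27 + o);
      for (int k = 0; k < nz; ++k) {
        const int ks = k + dz;
        if (ks < 0 || ks >= nz) continue;
        for (int j = 0; j < ny; ++j) {
          const int js = j + dy;
          if (js < 0 || js >= ny) continue;
          const int i0 = std::max(0, -dx), i1 = std::min(nx, nx - dx);
          const float* src = xc + (size_t)(ks * ny + js) * nx + dx;
          float* dst = col + (size_t)(k * ny + j) * nx;
          std::copy(src + i0, src + i1, dst + i0);
        }
      }
    }
  }
}

// scatter-add transpose of im2col: dx += col2im(dcolsT)
static void col2im3(const fmat& dcolsT, const dim3& d, int cin, float* dx) {
  const int nx = d[0], ny = d[1], nz = d[2];
  const int nvox = nx * ny * nz;
  for (int c = 0; c < cin; ++c) {
    float* xc = dx + (size_t)c * nvox;
    for (int o = 0; o < 27; ++o) {
      const int dxo = o % 3 - 1, dy = (o / 3) % 3 - 1, dz = o / 9 - 1;
      const float* col = dcolsT.colptr(c * 27 + o);
      for (int k = 0; k < nz; ++k) {
        const int ks = k + dz;
        if (ks < 0 || ks >= nz) continue;
        for (int j = 0; j < ny; ++j) {
          const int js = j + dy;
          if (js < 0 || js >= ny) continue;
          const int i0 = std::max(0, -dxo), i1 = std::min(nx, nx - dxo);
          float* dst = xc + (size_t)(ks * ny + js) * nx + dxo;
          const float* src = col + (size_t)(k * ny + j) * nx;
          for (int i = i0; i < i1; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// max-pool 3x3x3 stride 2 with TensorFlow-style SAME padding
// (output dim = ceil(n/2); when total padding is odd the extra plane is on
// the high side). argmax stores, per output element, the linear input index.
static void pool_geom(int n, int& out, int& pad_lo) {
  out = ceil_div2(n);
  int pad_total = std::max((out - 1) * 2 + 3 - n, 0);
  pad_lo = pad_total / 2;
}

static void maxpool_fwd(const float* x, const dim3& d, int ch, const dim3& od,
                        float* y, unsigned int* argmax) {
  const int nx = d[0], ny = d[1], nz = d[2];
  const int ox = od[0], oy = od[1], oz = od[2];
  int plx, ply, plz, tmp;
  pool_geom(nx, tmp, plx);
  pool_geom(ny, tmp, ply);
  pool_geom(nz, tmp, plz);
  const size_t nvox_in = (size_t)nx * ny * nz;
  const size_t nvox_out = (size_t)ox * oy * oz;
  for (int c = 0; c < ch; ++c) {
    const float* xc = x + c * nvox_in;
    float* yc = y + c * nvox_out;
    unsigned int* ac = argmax + c * nvox_out;
    for (int k = 0; k < oz; ++k) {
      const int z0 = std::max(0, 2 * k - plz), z1 = std::min(nz, 2 * k - plz + 3);
      for (int j = 0; j < oy; ++j) {
        const int y0 = std::max(0, 2 * j - ply), y1 = std::min(ny, 2 * j - ply + 3);
        for (int i = 0; i < ox; ++i) {
          const int x0 = std::max(0, 2 * i - plx), x1 = std::min(nx, 2 * i - plx + 3);
          float best = -std::numeric_limits<float>::infinity();
          size_t besti = 0;
          for (int zz = z0; zz < z1; ++zz)
            for (int yy = y0; yy < y1; ++yy)
              for (int xx = x0; xx < x1; ++xx) {
                const size_t idx = (size_t)(zz * ny + yy) * nx + xx;
                if (xc[idx] > best) { best = xc[idx]; besti = idx; }
              }
          const size_t oidx = (size_t)(k * oy + j) * ox + i;
          yc[oidx] = best;
          ac[oidx] = (unsigned int)(besti + c * nvox_in);
        }
      }
    }
  }
}

static void maxpool_bwd(const float* dy, int ch, size_t nvox_out,
                        const unsigned int* argmax, float* dx) {
  for (size_t t = 0; t < (size_t)ch * nvox_out; ++t) dx[argmax[t]] += dy[t];
}

// ---------------------------------------------------------------------------
// batch norm over a (nvox*C) x B matrix, nvox rows per channel

struct BNParam {
  fvec gamma, beta, rmean, rvar;
  fvec dgamma, dbeta;
  void init(int C) {
    gamma.ones(C); beta.zeros(C); rmean.zeros(C); rvar.ones(C);
    dgamma.zeros(C); dbeta.zeros(C);
  }
};

struct BNCache {
  fmat xhat;       // normalized input
  fvec mean, invstd;
};

static void bn_fwd(const fmat& X, int nvox, int C, BNParam& p, bool train,
                   float momentum, fmat& Y, BNCache& cache) {
  const int B = X.n_cols;
  const size_t n = (size_t)nvox * B;
  Y.set_size(X.n_rows, B);
  if (train) {
    cache.xhat.set_size(X.n_rows, B);
    cache.mean.set_size(C);
    cache.invstd.set_size(C);
  }
  for (int c = 0; c < C; ++c) {
    const int r0 = c * nvox;
    float mu, var;
    if (train) {
      double s = 0, s2 = 0;
      for (int b = 0; b < B; ++b) {
        const float* col = X.colptr(b) + r0;
        for (int i = 0; i < nvox; ++i) { s += col[i]; s2 += (double)col[i] * col[i]; }
      }
      mu = (float)(s / n);
      var = (float)(s2 / n - (double)mu * mu);
      if (var < 0) var = 0;
      p.rmean(c) = momentum * p.rmean(c) + (1 - momentum) * mu;
      p.rvar(c) = momentum * p.rvar(c) + (1 - momentum) * var;
    } else {
      mu = p.rmean(c);
      var = p.rvar(c);
    }
    const float invstd = 1.0f / std::sqrt(var + BN_EPS);
    const float g = p.gamma(c), bb = p.beta(c);
    for (int b = 0; b < B; ++b) {
      const float* col = X.colptr(b) + r0;
      float* out = Y.colptr(b) + r0;
      if (train) {
        float* xh = cache.xhat.colptr(b) + r0;
        for (int i = 0; i < nvox; ++i) {
          xh[i] = (col[i] - mu) * invstd;
          out[i] = g * xh[i] + bb;
        }
      } else {
        for (int i = 0; i < nvox; ++i) out[i] = g * (col[i] - mu) * invstd + bb;
      }
    }
    if (train) { cache.mean(c) = mu; cache.invstd(c) = invstd; }
  }
}

static void bn_bwd(const fmat& dY, int nvox, int C, BNParam& p,
                   const BNCache& cache, fmat& dX) {
  const int B = dY.n_cols;
  const double n = (double)nvox * B;
  dX.set_size(dY.n_rows, B);
  for (int c = 0; c < C; ++c) {
    const int r0 = c * nvox;
    double sum_dy = 0, sum_dy_xh = 0;
    for (int b = 0; b < B; ++b) {
      const float* dyc = dY.colptr(b) + r0;
      const float* xh = cache.xhat.colptr(b) + r0;
      for (int i = 0; i < nvox; ++i) { sum_dy += dyc[i]; sum_dy_xh += (double)dyc[i] * xh[i]; }
    }
    p.dgamma(c) += (float)sum_dy_xh;
    p.dbeta(c) += (float)sum_dy;
    const float g = p.gamma(c), invstd = cache.invstd(c);
    const float k1 = (float)(sum_dy / n), k2 = (float)(sum_dy_xh / n);
    for (int b = 0; b < B; ++b) {
      const float* dyc = dY.colptr(b) + r0;
      const float* xh = cache.xhat.colptr(b) + r0;
      float* dxc = dX.colptr(b) + r0;
      for (int i = 0; i < nvox; ++i) {
        dxc[i] = g * invstd * (dyc[i] - k1 - xh[i] * k2);
      }
    }
  }
}

// eval-mode BN is a fixed affine map; its backward is elementwise scaling
static void bn_bwd_eval(const fmat& dY, int nvox, int C, const BNParam& p, fmat& dX) {
  const int B = dY.n_cols;
  dX.set_size(dY.n_rows, B);
  for (int c = 0; c < C; ++c) {
    const float s = p.gamma(c) / std::sqrt(p.rvar(c) + BN_EPS);
    const int r0 = c * nvox;
    for (int b = 0; b < B; ++b) {
      const float* dyc = dY.colptr(b) + r0;
      float* dxc = dX.colptr(b) + r0;
      for (int i = 0; i < nvox; ++i) dxc[i] = s * dyc[i];
    }
  }
}

// ---------------------------------------------------------------------------

struct Block {
  BNParam bn;
  fmat W;          // (27*cin) x cout
  fvec b;
  fmat dW; fvec db;
  ConvGeom geom;
  dim3 pool_dim;   // dims after pooling
};

struct Head {
  fmat W1; fvec b1;
  BNParam bn;
  fmat W2; fvec b2;     // head_units x 1
  fmat dW1; fvec db1; fmat dW2; fvec db2;
};

struct AdamSlot { fmat m, v; };

struct Engine {
  dim3 input_dim;
  int channels;
  std::vector<Block> blocks;
  int flat_dim, dense_units, head_units;
  fmat dense_W; fvec dense_b;
  fmat d_dense_W; fvec d_dense_b;
  Head heads[3];                       // 0 = age, 1 = gender, 2 = diagnosis
  float dropout_rate, l2, bn_momentum;
  std::vector<fmat> colsT_buf, dcolsT_buf;  // per-block im2col workspaces
  std::mt19937 rng;
  // Adam state
  std::vector<AdamSlot> adam;
  long adam_t = 0;

  // registries built once: pointers to every trainable tensor + its gradient
  std::vector<fmat*> par_m; std::vector<fmat*> grad_m;
  std::vector<fvec*> par_v; std::vector<fvec*> grad_v;
  std::vector<bool> m_is_weight;

  void register_params() {
    par_m.clear(); grad_m.clear(); par_v.clear(); grad_v.clear(); m_is_weight.clear();
    for (auto& bl : blocks) {
      par_m.push_back(&bl.W); grad_m.push_back(&bl.dW); m_is_weight.push_back(true);
      par_v.push_back(&bl.b); grad_v.push_back(&bl.db);
      par_v.push_back(&bl.bn.gamma); grad_v.push_back(&bl.bn.dgamma);
      par_v.push_back(&bl.bn.beta); grad_v.push_back(&bl.bn.dbeta);
    }
    par_m.push_back(&dense_W); grad_m.push_back(&d_dense_W); m_is_weight.push_back(true);
    par_v.push_back(&dense_b); grad_v.push_back(&d_dense_b);
    for (int t = 0; t < 3; ++t) {
      Head& h = heads[t];
      par_m.push_back(&h.W1); grad_m.push_back(&h.dW1); m_is_weight.push_back(true);
      par_m.push_back(&h.W2); grad_m.push_back(&h.dW2); m_is_weight.push_back(true);
      par_v.push_back(&h.b1); grad_v.push_back(&h.db1);
      par_v.push_back(&h.b2); grad_v.push_back(&h.db2);
      par_v.push_back(&h.bn.gamma); grad_v.push_back(&h.bn.dgamma);
      par_v.push_back(&h.bn.beta); grad_v.push_back(&h.bn.dbeta);
    }
    adam.assign(par_m.size() + par_v.size(), AdamSlot());
    size_t k = 0;
    for (auto* p : par_m) { adam[k].m.zeros(p->n_rows, p->n_cols); adam[k].v.zeros(p->n_rows, p->n_cols); ++k; }
    for (auto* p : par_v) { adam[k].m.zeros(p->n_elem, 1); adam[k].v.zeros(p->n_elem, 1); ++k; }
    adam_t = 0;
  }

  void zero_grads() {
    for (auto* g : grad_m) g->zeros();
    for (auto* g : grad_v) g->zeros();
    for (auto& bl : blocks) { bl.bn.dgamma.zeros(); bl.bn.dbeta.zeros(); }
    for (int t = 0; t < 3; ++t) { heads[t].bn.dgamma.zeros(); heads[t].bn.dbeta.zeros(); }
  }
};

// forward caches for one batch
struct FwdCache {
  std::vector<BNCache> bn;           // per block
  std::vector<fmat> conv_in;         // post-BN input to conv (needed for dW)
  std::vector<std::vector<fmat>> cols_cache; // per block, per sample im2col
  bool cols_cached = false;
  std::vector<fmat> conv_out;        // post-ReLU conv output
  std::vector<fmat> pool_out;
  std::vector<Mat<u32>> argmax;
  fmat drop_mask;
  fmat flat_dropped;
  fmat dense_out;                    // post-ReLU
  fmat head_a1[3];                   // post-ReLU
  BNCache head_bn[3];
  fmat head_n1[3];                   // post-BN
  frowvec z2[3];                     // final pre-activation
  frowvec out[3];                    // head output (after sigmoid/identity)
};

static void engine_forward(Engine& E, const fmat& X, bool train, FwdCache& C) {
  const int B = X.n_cols;
  const int nb = E.blocks.size();
  C.bn.resize(nb); C.conv_in.resize(nb); C.conv_out.resize(nb);
  C.pool_out.resize(nb); C.argmax.resize(nb);
  // when training (a backward pass follows) cache each sample's im2col
  // matrix for reuse in the weight-gradient GEMM, if that fits in ~256 MB
  size_t cols_bytes = 0;
  for (int b = 0; b < nb; ++b) {
    const Block& bl = E.blocks[b];
    cols_bytes += (size_t)bl.geom.dim[0] * bl.geom.dim[1] * bl.geom.dim[2] *
      27 * bl.geom.cin * sizeof(float) * B;
  }
  C.cols_cached = train && cols_bytes < (size_t)256 * 1024 * 1024;
  if (C.cols_cached) C.cols_cache.resize(nb);
  const fmat* cur = &X;
  for (int b = 0; b < nb; ++b) {
    Block& bl = E.blocks[b];
    const int nvox = bl.geom.dim[0] * bl.geom.dim[1] * bl.geom.dim[2];
    bn_fwd(*cur, nvox, bl.geom.cin, bl.bn, train, E.bn_momentum, C.conv_in[b], C.bn[b]);
    // conv + bias + ReLU, sample by sample
    if (C.cols_cached) C.cols_cache[b].resize(B);
    C.conv_out[b].set_size((size_t)nvox * bl.geom.cout, B);
    for (int s = 0; s < B; ++s) {
      fmat* colsT;
      if (C.cols_cached) {
        fmat& cc = C.cols_cache[b][s];
        if ((int)cc.n_rows != nvox || (int)cc.n_cols != 27 * bl.geom.cin) {
          cc.zeros(nvox, 27 * bl.geom.cin); // padding entries stay 0 thereafter
        }
        colsT = &cc;
      } else {
        colsT = &E.colsT_buf[b];
      }
      im2col3(C.conv_in[b].colptr(s), bl.geom.dim, bl.geom.cin, *colsT);
      fmat Yv(C.conv_out[b].colptr(s), nvox, bl.geom.cout, false, true);
      Yv = (*colsT) * bl.W;              // nvox x cout, voxel-major flatten
      Yv.each_row() += bl.b.t();
      Yv.transform([](float v) { return v > 0 ? v : 0.0f; });
    }
    // max pool
    const int onv = bl.pool_dim[0] * bl.pool_dim[1] * bl.pool_dim[2];
    C.pool_out[b].set_size((size_t)onv * bl.geom.cout, B);
    C.argmax[b].set_size((size_t)onv * bl.geom.cout, B);
    for (int s = 0; s < B; ++s) {
      maxpool_fwd(C.conv_out[b].colptr(s), bl.geom.dim, bl.geom.cout, bl.pool_dim,
                  C.pool_out[b].colptr(s), C.argmax[b].colptr(s));
    }
    cur = &C.pool_out[b];
  }
  // flatten -> dropout -> dense -> ReLU
  if (train && E.dropout_rate > 0) {
    std::uniform_real_distribution<float> U(0.0f, 1.0f);
    C.drop_mask.set_size(cur->n_rows, B);
    const float keep = 1.0f - E.dropout_rate;
    for (size_t i = 0; i < C.drop_mask.n_elem; ++i) {
      C.drop_mask(i) = U(E.rng) < keep ? 1.0f / keep : 0.0f;
    }
    C.flat_dropped = (*cur) % C.drop_mask;
  } else {
    C.flat_dropped = *cur;
  }
  C.dense_out = E.dense_W.t() * C.flat_dropped;
  C.dense_out.each_col() += E.dense_b;
  C.dense_out.transform([](float v) { return v > 0 ? v : 0.0f; });
  for (int t = 0; t < 3; ++t) {
    Head& h = E.heads[t];
    C.head_a1[t] = h.W1.t() * C.dense_out;
    C.head_a1[t].each_col() += h.b1;
    C.head_a1[t].transform([](float v) { return v > 0 ? v : 0.0f; });
    bn_fwd(C.head_a1[t], 1, E.head_units, h.bn, train, E.bn_momentum,
           C.head_n1[t], C.head_bn[t]);
    C.z2[t] = h.W2.t() * C.head_n1[t] + h.b2(0);
    C.out[t] = C.z2[t];
    if (t != 0) {
      C.out[t].transform([](float z) { return 1.0f / (1.0f + std::exp(-z)); });
    }
  }
}

// backward from per-head dz2 (gradients w.r.t. final pre-activations).
// If want_input_grad, returns gradient w.r.t. the input batch in dX.
static void engine_backward(Engine& E, const fmat& X, FwdCache& C,
                            const frowvec dz2[3], bool train,
                            bool want_input_grad, fmat* dX) {
  const int B = X.n_cols;
  fmat dh(E.dense_units, B, fill::zeros);
  for (int t = 0; t < 3; ++t) {
    Head& h = E.heads[t];
    // z2 = W2' n1 + b2
    h.dW2 += C.head_n1[t] * dz2[t].t();
    h.db2(0) += accu(dz2[t]);
    fmat dn1 = h.W2 * dz2[t];
    fmat dr1;
    if (train) bn_bwd(dn1, 1, E.head_units, h.bn, C.head_bn[t], dr1);
    else bn_bwd_eval(dn1, 1, E.head_units, h.bn, dr1);
    dr1 %= conv_to<fmat>::from(C.head_a1[t] > 0);
    h.dW1 += C.dense_out * dr1.t();
    h.db1 += sum(dr1, 1);
    dh += h.W1 * dr1;
  }
  dh %= conv_to<fmat>::from(C.dense_out > 0);
  E.d_dense_W += C.flat_dropped * dh.t();
  E.d_dense_b += sum(dh, 1);
  fmat dflat = E.dense_W * dh;
  if (train && E.dropout_rate > 0) dflat %= C.drop_mask;

  const int nb = E.blocks.size();
  fmat dcur = dflat;
  for (int b = nb - 1; b >= 0; --b) {
    Block& bl = E.blocks[b];
    const int nvox = bl.geom.dim[0] * bl.geom.dim[1] * bl.geom.dim[2];
    const size_t onv = (size_t)bl.pool_dim[0] * bl.pool_dim[1] * bl.pool_dim[2];
    // pool backward
    fmat dconv((size_t)nvox * bl.geom.cout, B, fill::zeros);
    for (int s = 0; s < B; ++s) {
      maxpool_bwd(dcur.colptr(s), bl.geom.cout, onv, C.argmax[b].colptr(s), dconv.colptr(s));
    }
    // ReLU mask, in place
    {
      const float* act = C.conv_out[b].memptr();
      float* g = dconv.memptr();
      const size_t n = dconv.n_elem;
      for (size_t i = 0; i < n; ++i) if (act[i] <= 0) g[i] = 0;
    }
    // conv backward (the gradient into the block's BN is always needed,
    // because the BN scale/shift of every block is trainable)
    fmat& dcolsT = E.dcolsT_buf[b];
    fmat dpre((size_t)nvox * bl.geom.cin, B, fill::zeros);
    for (int s = 0; s < B; ++s) {
      const fmat G(const_cast<float*>(dconv.colptr(s)), nvox, bl.geom.cout, false, true);
      fmat* colsT;
      if (C.cols_cached) {
        colsT = &C.cols_cache[b][s];
      } else {
        colsT = &E.colsT_buf[b];
        im2col3(C.conv_in[b].colptr(s), bl.geom.dim, bl.geom.cin, *colsT);
      }
      bl.dW += colsT->t() * G;
      bl.db += sum(G, 0).t();
      dcolsT = G * bl.W.t();  // nvox x (27*cin)
      col2im3(dcolsT, bl.geom.dim, bl.geom.cin, dpre.colptr(s));
    }
    // BN backward
    fmat dbn;
    if (train) bn_bwd(dpre, nvox, bl.geom.cin, bl.bn, C.bn[b], dbn);
    else bn_bwd_eval(dpre, nvox, bl.geom.cin, bl.bn, dbn);
    if (b == 0) {
      if (want_input_grad) *dX = dbn;
    } else {
      dcur = dbn;
    }
  }
}

// joint objective on one batch: w_age*MSE + w_gender*BCE + w_diag*BCE
// (batch means; probabilities clamped at 1e-7 in double precision).
static double batch_loss_and_dz(const FwdCache& C, const fvec& y_age,
                                const fvec& y_gender, const fvec& y_diag,
                                double w1, double w2, double w3,
                                frowvec dz2[3], double per_task[3]) {
  const int B = C.out[0].n_elem;
  double mse = 0, bce_g = 0, bce_d = 0;
  dz2[0].set_size(B); dz2[1].set_size(B); dz2[2].set_size(B);
  for (int s = 0; s < B; ++s) {
    const double e = (double)C.out[0](s) - y_age(s);
    mse += e * e;
    dz2[0](s) = (float)(w1 * 2.0 * e / B);
    for (int t = 1; t < 3; ++t) {
      const double y = (t == 1) ? y_gender(s) : y_diag(s);
      double p = std::min(1.0 - BCE_EPS, std::max(BCE_EPS, (double)C.out[t](s)));
      const double l = -(y * std::log(p) + (1 - y) * std::log(1 - p));
      if (t == 1) bce_g += l; else bce_d += l;
      const double w = (t == 1) ? w2 : w3;
      dz2[t](s) = (float)(w * ((double)C.out[t](s) - y) / B);
    }
  }
  per_task[0] = mse / B; per_task[1] = bce_g / B; per_task[2] = bce_d / B;
  return w1 * per_task[0] + w2 * per_task[1] + w3 * per_task[2];
}

static double l2_penalty(const Engine& E) {
  double s = 0;
  for (size_t k = 0; k < E.par_m.size(); ++k) {
    if (E.m_is_weight[k]) s += accu(square(conv_to<mat>::from(*E.par_m[k])));
  }
  return E.l2 * s;
}

static void adam_step(Engine& E, double lr, double beta1, double beta2, double eps) {
  E.adam_t += 1;
  const double bc1 = 1.0 - std::pow(beta1, (double)E.adam_t);
  const double bc2 = 1.0 - std::pow(beta2, (double)E.adam_t);
  size_t k = 0;
  for (size_t i = 0; i < E.par_m.size(); ++i, ++k) {
    fmat g = *E.grad_m[i];
    if (E.m_is_weight[i]) g += 2.0f * E.l2 * (*E.par_m[i]);
    E.adam[k].m = (float)beta1 * E.adam[k].m + (float)(1 - beta1) * g;
    E.adam[k].v = (float)beta2 * E.adam[k].v + (float)(1 - beta2) * square(g);
    *E.par_m[i] -= (float)(lr / bc1) * E.adam[k].m /
      (sqrt(E.adam[k].v / (float)bc2) + (float)eps);
  }
  for (size_t i = 0; i < E.par_v.size(); ++i, ++k) {
    fmat g(E.grad_v[i]->memptr(), E.grad_v[i]->n_elem, 1, false, true);
    E.adam[k].m = (float)beta1 * E.adam[k].m + (float)(1 - beta1) * g;
    E.adam[k].v = (float)beta2 * E.adam[k].v + (float)(1 - beta2) * square(g);
    fmat upd = (float)(lr / bc1) * E.adam[k].m /
      (sqrt(E.adam[k].v / (float)bc2) + (float)eps);
    *E.par_v[i] -= fvec(upd.memptr(), upd.n_elem);
  }
}

// ---------------------------------------------------------------------------
// R interface

static dim3 as_dim3(const Rcpp::IntegerVector& v) {
  return dim3{v[0], v[1], v[2]};
}

// [[Rcpp::export]]
SEXP cpp_engine_create(Rcpp::List config, int seed) {
  Engine* E = new Engine();
  Rcpp::IntegerVector shape = config["shape"];
  E->input_dim = as_dim3(shape);
  E->channels = Rcpp::as<int>(config["channels"]);
  Rcpp::IntegerVector filters = config["filters"];
  E->dense_units = Rcpp::as<int>(config["dense_units"]);
  E->head_units = Rcpp::as<int>(config["head_units"]);
  E->dropout_rate = Rcpp::as<double>(config["dropout_rate"]);
  E->l2 = Rcpp::as<double>(config["l2_coefficient"]);
  E->bn_momentum = 0.9f;
  E->rng.seed((unsigned int)seed);

  std::mt19937 init_rng((unsigned int)seed);
  std::normal_distribution<float> N(0.0f, 1.0f);
  auto he_fill = [&](fmat& W, int fan_in) {
    const float s = std::sqrt(2.0f / fan_in);
    for (size_t i = 0; i < W.n_elem; ++i) W(i) = s * N(init_rng);
  };

  dim3 d = E->input_dim;
  int cin = E->channels;
  for (int b = 0; b < filters.size(); ++b) {
    Block bl;
    bl.geom.dim = d;
    bl.geom.cin = cin;
    bl.geom.cout = filters[b];
    int tmp;
    for (int a = 0; a < 3; ++a) pool_geom(d[a], bl.pool_dim[a], tmp);
    bl.bn.init(cin);
    bl.W.set_size(27 * cin, bl.geom.cout);
    he_fill(bl.W, 27 * cin);
    bl.b.zeros(bl.geom.cout);
    bl.dW.zeros(size(bl.W)); bl.db.zeros(bl.geom.cout);
    E->blocks.push_back(std::move(bl));
    d = E->blocks.back().pool_dim;
    cin = filters[b];
  }
  E->colsT_buf.resize(E->blocks.size());
  E->dcolsT_buf.resize(E->blocks.size());
  for (size_t b = 0; b < E->blocks.size(); ++b) {
    const Block& bl = E->blocks[b];
    const int nvox = bl.geom.dim[0] * bl.geom.dim[1] * bl.geom.dim[2];
    E->colsT_buf[b].zeros(nvox, 27 * bl.geom.cin);
    E->dcolsT_buf[b].set_size(nvox, 27 * bl.geom.cin);
  }
  E->flat_dim = d[0] * d[1] * d[2] * cin;
  E->dense_W.set_size(E->flat_dim, E->dense_units);
  he_fill(E->dense_W, E->flat_dim);
  E->dense_b.zeros(E->dense_units);
  E->d_dense_W.zeros(size(E->dense_W)); E->d_dense_b.zeros(E->dense_units);
  for (int t = 0; t < 3; ++t) {
    Head& h = E->heads[t];
    h.W1.set_size(E->dense_units, E->head_units);
    he_fill(h.W1, E->dense_units);
    h.b1.zeros(E->head_units);
    h.bn.init(E->head_units);
    h.W2.set_size(E->head_units, 1);
    he_fill(h.W2, E->head_units);
    h.b2.zeros(1);
    h.dW1.zeros(size(h.W1)); h.db1.zeros(E->head_units);
    h.dW2.zeros(size(h.W2)); h.db2.zeros(1);
  }
  E->register_params();
  return Rcpp::XPtr<Engine>(E, true);
}

// [[Rcpp::export]]
SEXP cpp_data_create(Rcpp::NumericMatrix X, Rcpp::NumericVector age,
                     Rcpp::NumericVector gender, Rcpp::NumericVector diagnosis) {
  DataSet* D = new DataSet();
  D->X = conv_to<fmat>::from(Rcpp::as<mat>(X));
  D->age = conv_to<fvec>::from(Rcpp::as<vec>(age));
  D->gender = conv_to<fvec>::from(Rcpp::as<vec>(gender));
  D->diagnosis = conv_to<fvec>::from(Rcpp::as<vec>(diagnosis));
  return Rcpp::XPtr<DataSet>(D, true);
}

static const char* PAR_TASKS[3] = {"age", "gender", "diagnosis"};

// [[Rcpp::export]]
Rcpp::List cpp_engine_get_params(SEXP ptr) {
  Rcpp::XPtr<Engine> E(ptr);
  Rcpp::List out;
  auto put_m = [&](const std::string& nm, const fmat& M) {
    out[nm] = Rcpp::wrap(conv_to<mat>::from(M));
  };
  auto put_v = [&](const std::string& nm, const fvec& V) {
    out[nm] = Rcpp::wrap(conv_to<vec>::from(V));
  };
  for (size_t b = 0; b < E->blocks.size(); ++b) {
    const std::string p = "block" + std::to_string(b + 1);
    const Block& bl = E->blocks[b];
    put_v(p + "_bn_gamma", bl.bn.gamma); put_v(p + "_bn_beta", bl.bn.beta);
    put_v(p + "_bn_rmean", bl.bn.rmean); put_v(p + "_bn_rvar", bl.bn.rvar);
    put_m(p + "_conv_W", bl.W); put_v(p + "_conv_b", bl.b);
  }
  put_m("dense_W", E->dense_W); put_v("dense_b", E->dense_b);
  for (int t = 0; t < 3; ++t) {
    const std::string p = std::string("head_") + PAR_TASKS[t];
    const Head& h = E->heads[t];
    put_m(p + "_W1", h.W1); put_v(p + "_b1", h.b1);
    put_v(p + "_bn_gamma", h.bn.gamma); put_v(p + "_bn_beta", h.bn.beta);
    put_v(p + "_bn_rmean", h.bn.rmean); put_v(p + "_bn_rvar", h.bn.rvar);
    put_m(p + "_W2", h.W2); put_v(p + "_b2", h.b2);
  }
  return out;
}

// [[Rcpp::export]]
void cpp_engine_set_params(SEXP ptr, Rcpp::List params) {
  Rcpp::XPtr<Engine> E(ptr);
  auto get_m = [&](const std::string& nm, fmat& M) {
    M = conv_to<fmat>::from(Rcpp::as<mat>(params[nm]));
  };
  auto get_v = [&](const std::string& nm, fvec& V) {
    V = conv_to<fvec>::from(Rcpp::as<vec>(params[nm]));
  };
  for (size_t b = 0; b < E->blocks.size(); ++b) {
    const std::string p = "block" + std::to_string(b + 1);
    Block& bl = E->blocks[b];
    get_v(p + "_bn_gamma", bl.bn.gamma); get_v(p + "_bn_beta", bl.bn.beta);
    get_v(p + "_bn_rmean", bl.bn.rmean); get_v(p + "_bn_rvar", bl.bn.rvar);
    get_m(p + "_conv_W", bl.W); get_v(p + "_conv_b", bl.b);
  }
  get_m("dense_W", E->dense_W); get_v("dense_b", E->dense_b);
  for (int t = 0; t < 3; ++t) {
    const std::string p = std::string("head_") + PAR_TASKS[t];
    Head& h = E->heads[t];
    get_m(p + "_W1", h.W1); get_v(p + "_b1", h.b1);
    get_v(p + "_bn_gamma", h.bn.gamma); get_v(p + "_bn_beta", h.bn.beta);
    get_v(p + "_bn_rmean", h.bn.rmean); get_v(p + "_bn_rvar", h.bn.rvar);
    get_m(p + "_W2", h.W2); get_v(p + "_b2", h.b2);
  }
}

// [[Rcpp::export]]
double cpp_engine_train_epoch(SEXP eptr, SEXP dptr, Rcpp::IntegerVector order,
                              int batch_size, double lr, double beta1,
                              double beta2, double adam_eps,
                              Rcpp::NumericVector loss_weights,
                              int dropout_seed) {
  Rcpp::XPtr<Engine> E(eptr);
  Rcpp::XPtr<DataSet> D(dptr);
  E->rng.seed((unsigned int)dropout_seed);
  const int n = order.size();
  double total = 0;
  int nb = 0;
  FwdCache C;
  for (int start = 0; start < n; start += batch_size) {
    const int bs = std::min(batch_size, n - start);
    fmat X(D->X.n_rows, bs);
    fvec ya(bs), yg(bs), yd(bs);
    for (int s = 0; s < bs; ++s) {
      const int idx = order[start + s];
      X.col(s) = D->X.col(idx);
      ya(s) = D->age(idx); yg(s) = D->gender(idx); yd(s) = D->diagnosis(idx);
    }
    engine_forward(*E, X, true, C);
    frowvec dz2[3];
    double per_task[3];
    double loss = batch_loss_and_dz(C, ya, yg, yd, loss_weights[0],
                                    loss_weights[1], loss_weights[2], dz2, per_task);
    if (!std::isfinite(loss)) Rcpp::stop("non-finite training loss in batch %d", nb + 1);
    E->zero_grads();
    engine_backward(*E, X, C, dz2, true, false, nullptr);
    adam_step(*E, lr, beta1, beta2, adam_eps);
    total += loss + l2_penalty(*E);
    nb += 1;
  }
  return total / nb;
}

// [[Rcpp::export]]
Rcpp::List cpp_engine_eval(SEXP eptr, SEXP dptr, Rcpp::IntegerVector idx,
                           int batch_size) {
  Rcpp::XPtr<Engine> E(eptr);
  Rcpp::XPtr<DataSet> D(dptr);
  const int n = idx.size();
  Rcpp::NumericVector pred_age(n), pred_gender(n), pred_diag(n);
  double mse = 0, bce_g = 0, bce_d = 0;
  FwdCache C;
  for (int start = 0; start < n; start += batch_size) {
    const int bs = std::min(batch_size, n - start);
    fmat X(D->X.n_rows, bs);
    for (int s = 0; s < bs; ++s) X.col(s) = D->X.col(idx[start + s]);
    engine_forward(*E, X, false, C);
    for (int s = 0; s < bs; ++s) {
      const int i = idx[start + s];
      pred_age[start + s] = C.out[0](s);
      pred_gender[start + s] = C.out[1](s);
      pred_diag[start + s] = C.out[2](s);
      const double e = (double)C.out[0](s) - D->age(i);
      mse += e * e;
      double pg = std::min(1.0 - BCE_EPS, std::max(BCE_EPS, (double)C.out[1](s)));
      double pd = std::min(1.0 - BCE_EPS, std::max(BCE_EPS, (double)C.out[2](s)));
      bce_g += -(D->gender(i) * std::log(pg) + (1 - D->gender(i)) * std::log(1 - pg));
      bce_d += -(D->diagnosis(i) * std::log(pd) + (1 - D->diagnosis(i)) * std::log(1 - pd));
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("pred_age") = pred_age,
    Rcpp::Named("pred_gender") = pred_gender,
    Rcpp::Named("pred_diagnosis") = pred_diag,
    Rcpp::Named("losses") = Rcpp::NumericVector::create(
      Rcpp::Named("age") = mse / n, Rcpp::Named("gender") = bce_g / n,
      Rcpp::Named("diagnosis") = bce_d / n));
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_engine_input_grad(SEXP eptr, Rcpp::NumericMatrix Xr, int task) {
  Rcpp::XPtr<Engine> E(eptr);
  if (task < 0 || task > 2) Rcpp::stop("task index out of range");
  fmat X = conv_to<fmat>::from(Rcpp::as<mat>(Xr));
  FwdCache C;
  engine_forward(*E, X, false, C);
  frowvec dz2[3];
  const int B = X.n_cols;
  for (int t = 0; t < 3; ++t) dz2[t].zeros(B);
  if (task == 0) {
    dz2[0].ones(B);                       // d(age output)/dz2 = 1
  } else {
    dz2[task] = C.out[task] % (1.0f - C.out[task]);  // sigmoid derivative
  }
  E->zero_grads();
  fmat dX;
  engine_backward(*E, X, C, dz2, false, true, &dX);
  if (!dX.is_finite()) Rcpp::stop("non-finite input gradient");
  return Rcpp::wrap(conv_to<mat>::from(dX));
}

// Debug/testing hook: data loss (no L2) and its analytic parameter gradients
// on one batch, in train or eval mode, with dropout disabled.
// [[Rcpp::export]]
Rcpp::List cpp_engine_loss_grads(SEXP eptr, Rcpp::NumericMatrix Xr,
                                 Rcpp::NumericVector age, Rcpp::NumericVector gender,
                                 Rcpp::NumericVector diagnosis,
                                 Rcpp::NumericVector loss_weights, bool train) {
  Rcpp::XPtr<Engine> E(eptr);
  const float saved_dropout = E->dropout_rate;
  E->dropout_rate = 0.0f;
  fmat X = conv_to<fmat>::from(Rcpp::as<mat>(Xr));
  fvec ya = conv_to<fvec>::from(Rcpp::as<vec>(age));
  fvec yg = conv_to<fvec>::from(Rcpp::as<vec>(gender));
  fvec yd = conv_to<fvec>::from(Rcpp::as<vec>(diagnosis));
  // train-mode BN updates running stats; preserve them so this stays read-only
  std::vector<fvec> saved;
  for (auto& bl : E->blocks) { saved.push_back(bl.bn.rmean); saved.push_back(bl.bn.rvar); }
  for (int t = 0; t < 3; ++t) { saved.push_back(E->heads[t].bn.rmean); saved.push_back(E->heads[t].bn.rvar); }
  FwdCache C;
  engine_forward(*E, X, train, C);
  frowvec dz2[3];
  double per_task[3];
  double loss = batch_loss_and_dz(C, ya, yg, yd, loss_weights[0], loss_weights[1],
                                  loss_weights[2], dz2, per_task);
  E->zero_grads();
  engine_backward(*E, X, C, dz2, train, false, nullptr);
  size_t si = 0;
  for (auto& bl : E->blocks) { bl.bn.rmean = saved[si++]; bl.bn.rvar = saved[si++]; }
  for (int t = 0; t < 3; ++t) { E->heads[t].bn.rmean = saved[si++]; E->heads[t].bn.rvar = saved[si++]; }
  E->dropout_rate = saved_dropout;
  Rcpp::List grads;
  auto put_m = [&](const std::string& nm, const fmat& M) {
    grads[nm] = Rcpp::wrap(conv_to<mat>::from(M));
  };
  auto put_v = [&](const std::string& nm, const fvec& V) {
    grads[nm] = Rcpp::wrap(conv_to<vec>::from(V));
  };
  for (size_t b = 0; b < E->blocks.size(); ++b) {
    const std::string p = "block" + std::to_string(b + 1);
    put_m(p + "_conv_W", E->blocks[b].dW); put_v(p + "_conv_b", E->blocks[b].db);
    put_v(p + "_bn_gamma", E->blocks[b].bn.dgamma); put_v(p + "_bn_beta", E->blocks[b].bn.dbeta);
  }
  put_m("dense_W", E->d_dense_W); put_v("dense_b", E->d_dense_b);
  for (int t = 0; t < 3; ++t) {
    const std::string p = std::string("head_") + PAR_TASKS[t];
    const Head& h = E->heads[t];
    put_m(p + "_W1", h.dW1); put_v(p + "_b1", h.db1);
    put_v(p + "_bn_gamma", h.bn.dgamma); put_v(p + "_bn_beta", h.bn.dbeta);
    put_m(p + "_W2", h.dW2); put_v(p + "_b2", h.db2);
  }
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("per_task") = Rcpp::NumericVector::create(per_task[0], per_task[1], per_task[2]),
    Rcpp::Named("grads") = grads);
}

// [[Rcpp::export]]
Rcpp::List cpp_engine_predict(SEXP eptr, Rcpp::NumericMatrix Xr, int batch_size) {
  Rcpp::XPtr<Engine> E(eptr);
  mat Xd = Rcpp::as<mat>(Xr);
  const int n = Xd.n_cols;
  Rcpp::NumericVector pred_age(n), pred_gender(n), pred_diag(n);
  FwdCache C;
  for (int start = 0; start < n; start += batch_size) {
    const int bs = std::min(batch_size, n - start);
    fmat X = conv_to<fmat>::from(Xd.cols(start, start + bs - 1));
    engine_forward(*E, X, false, C);
    for (int s = 0; s < bs; ++s) {
      pred_age[start + s] = C.out[0](s);
      pred_gender[start + s] = C.out[1](s);
      pred_diag[start + s] = C.out[2](s);
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("age") = pred_age, Rcpp::Named("gender") = pred_gender,
    Rcpp::Named("diagnosis") = pred_diag);
}
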