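// Dedicated trainer for the 1D-CNN on raw audio. The six convolution
// blocks (conv k=9 'same' -> batch norm -> ReLU -> max pool
// 8,8,8,8,4,none; channels 1,16,32,64,128,256,256) followed by dense
// 1536 -> 100 -> 50 -> 2 are unrolled here with all workspaces
// allocated once per fit and every matrix product running through BLAS
// dgemm straight into preallocated buffers. Initial weights and the
// per-epoch shuffle orders come from R, so a fit is bit-reproducible
// for a fixed seed. The generic R engine implements the same forward
// pass and is used as an independent cross-check in the tests.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif

#include <vector>
#include <memory>
#include <cstring>
#include <cmath>
#include <algorithm>

using Rcpp::List;
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;
using Rcpp::IntegerMatrix;
using Rcpp::IntegerVector;

namespace {

const int KW = 9;                     // conv kernel width
const int NBLK = 6;

struct Dims {
  int c_in[NBLK] = {1, 16, 32, 64, 128, 256};
  int c_out[NBLK] = {16, 32, 64, 128, 256, 256};
  int pool[NBLK] = {8, 8, 8, 8, 4, 1};
  int p_in[NBLK];                     // positions entering each block
  int p_last;                         // positions after the last block
  int flat;                           // flattened feature width
  int d_in[3], d_out[3];              // dense head
  Dims(int input_len) {
    int p = input_len;
    for (int i = 0; i < NBLK; ++i) {
      p_in[i] = p;
      p /= pool[i];
    }
    p_last = p;
    flat = p * c_out[NBLK - 1];
    d_in[0] = flat; d_out[0] = 100;
    d_in[1] = 100;  d_out[1] = 50;
    d_in[2] = 50;   d_out[2] = 2;
  }
};

typedef std::vector<double> Buf;

inline void gemm(char ta, char tb, int m, int n, int k, const double* a,
                 int lda, const double* b, int ldb, double beta, double* c,
                 int ldc) {
  const double one = 1.0;
  F77_CALL(dgemm)(&ta, &tb, &m, &n, &k, &one, a, &lda, b, &ldb, &beta, c,
                  &ldc FCONE FCONE);
}

// parameter with Adam state
struct Par {
  Buf v, m, s;
  void init(const NumericVector& x) {
    v.assign(x.begin(), x.end());
    m.assign(v.size(), 0.0);
    s.assign(v.size(), 0.0);
  }
  void step(const double* g, double lr, int t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
    for (size_t i = 0; i < v.size(); ++i) {
      m[i] = b1 * m[i] + (1 - b1) * g[i];
      s[i] = b2 * s[i] + (1 - b2) * g[i] * g[i];
      v[i] -= lr * (m[i] / c1) / (std::sqrt(s[i] / c2) + eps);
    }
  }
};

struct Net {
  Dims dm;
  Par convW[NBLK], convB[NBLK];
  Par gamma[NBLK], beta[NBLK];
  Buf rmean[NBLK], rvar[NBLK];
  Par denseW[3], denseB[3];
  int t_adam = 0;

  explicit Net(int input_len, const List& w) : dm(input_len) {
    List cw = w["conv_w"], cb = w["conv_b"], gg = w["bn_gamma"],
         bb = w["bn_beta"], rm = w["bn_rmean"], rv = w["bn_rvar"],
         dw = w["dense_w"], db = w["dense_b"];
    for (int i = 0; i < NBLK; ++i) {
      convW[i].init(cw[i]);
      convB[i].init(cb[i]);
      gamma[i].init(gg[i]);
      beta[i].init(bb[i]);
      NumericVector r1 = rm[i], r2 = rv[i];
      rmean[i].assign(r1.begin(), r1.end());
      rvar[i].assign(r2.begin(), r2.end());
    }
    for (int j = 0; j < 3; ++j) {
      denseW[j].init(dw[j]);
      denseB[j].init(db[j]);
    }
  }

  List export_weights() const {
    List cw(NBLK), cb(NBLK), gg(NBLK), bb(NBLK), rm(NBLK), rv(NBLK);
    for (int i = 0; i < NBLK; ++i) {
      NumericMatrix W(KW * dm.c_in[i], dm.c_out[i]);
      std::copy(convW[i].v.begin(), convW[i].v.end(), W.begin());
      cw[i] = W;
      cb[i] = NumericVector(convB[i].v.begin(), convB[i].v.end());
      gg[i] = NumericVector(gamma[i].v.begin(), gamma[i].v.end());
      bb[i] = NumericVector(beta[i].v.begin(), beta[i].v.end());
      rm[i] = NumericVector(rmean[i].begin(), rmean[i].end());
      rv[i] = NumericVector(rvar[i].begin(), rvar[i].end());
    }
    List dw(3), db(3);
    for (int j = 0; j < 3; ++j) {
      NumericMatrix W(dm.d_in[j], dm.d_out[j]);
      std::copy(denseW[j].v.begin(), denseW[j].v.end(), W.begin());
      dw[j] = W;
      db[j] = NumericVector(denseB[j].v.begin(), denseB[j].v.end());
    }
    return List::create(
        Rcpp::Named("conv_w") = cw, Rcpp::Named("conv_b") = cb,
        Rcpp::Named("bn_gamma") = gg, Rcpp::Named("bn_beta") = bb,
        Rcpp::Named("bn_rmean") = rm, Rcpp::Named("bn_rvar") = rv,
        Rcpp::Named("dense_w") = dw, Rcpp::Named("dense_b") = db);
  }
};

// per-fit workspaces sized for the largest batch
struct Work {
  int nb;                             // max batch
  Buf x[NBLK + 1];                    // block inputs (x[0] = raw audio)
  Buf xc[NBLK];                       // im2col buffers
  Buf y[NBLK];                        // conv outputs
  Buf xhat[NBLK];                     // batch-norm normalized
  Buf act[NBLK];                      // post-ReLU activations
  std::vector<int> sel[NBLK];         // pool argmax (flat index into act)
  Buf flat;                           // nb x 1536
  Buf z[3];                           // dense outputs (post-ReLU for 0,1)
  Buf prob;                           // nb x 2
  // gradients: the backward pass reuses y (for dL/dy), xc (for dL/dxc)
  // and x (for dL/dx) once their forward contents have served their last
  // read, so only the small dense-head gradients need their own buffers
  Buf gflat, gz[3];
  Buf dW[NBLK], dB[NBLK], dG[NBLK], dBt[NBLK];
  Buf dDW[3], dDB[3];
  Buf bn_isd[NBLK];                   // batch inv_sd stash for backward

  Work(const Dims& dm, int nb_) : nb(nb_) {
    for (int i = 0; i < NBLK; ++i) {
      size_t rows = (size_t)nb * dm.p_in[i];
      x[i].assign(rows * dm.c_in[i], 0.0);
      xc[i].assign(rows * KW * dm.c_in[i], 0.0);
      y[i].assign(rows * dm.c_out[i], 0.0);
      xhat[i].assign(rows * dm.c_out[i], 0.0);
      act[i].assign(rows * dm.c_out[i], 0.0);
      sel[i].assign(rows / dm.pool[i] * dm.c_out[i], 0);
      dW[i].assign((size_t)KW * dm.c_in[i] * dm.c_out[i], 0.0);
      dB[i].assign(dm.c_out[i], 0.0);
      dG[i].assign(dm.c_out[i], 0.0);
      dBt[i].assign(dm.c_out[i], 0.0);
    }
    x[NBLK].assign((size_t)nb * dm.p_last * dm.c_out[NBLK - 1], 0.0);
    flat.assign((size_t)nb * dm.flat, 0.0);
    gflat.assign(flat.size(), 0.0);
    for (int j = 0; j < 3; ++j) {
      z[j].assign((size_t)nb * dm.d_out[j], 0.0);
      gz[j].assign(z[j].size(), 0.0);
      dDW[j].assign((size_t)dm.d_in[j] * dm.d_out[j], 0.0);
      dDB[j].assign(dm.d_out[j], 0.0);
    }
    prob.assign((size_t)nb * 2, 0.0);
    for (int i = 0; i < NBLK; ++i) bn_isd[i].assign(dm.c_out[i], 0.0);
  }
};

// im2col with 'same' padding; dst column block o holds src shifted by
// o - KW/2 within each example. ld is the allocated column stride of
// both buffers (nb * p), which may exceed the used rows n * p.
void im2col(const double* src, double* dst, int n, int p, int c_in,
            size_t ld) {
  const int half = (KW - 1) / 2;
  for (int o = 0; o < KW; ++o) {
    const int d = o - half;
    const int t0 = std::max(0, -d);
    const int t1 = std::min(p - 1, p - 1 - d);
    for (int c = 0; c < c_in; ++c) {
      const double* sc = src + (size_t)c * ld;
      double* dc = dst + ((size_t)o * c_in + c) * ld;
      for (int s = 0; s < n; ++s) {
        double* db = dc + (size_t)s * p;
        const double* sb = sc + (size_t)s * p;
        for (int t = 0; t < t0; ++t) db[t] = 0.0;
        std::memcpy(db + t0, sb + t0 + d, (size_t)(t1 - t0 + 1) * sizeof(double));
        for (int t = t1 + 1; t < p; ++t) db[t] = 0.0;
      }
    }
  }
}

void col2im_add(const double* dcol, double* dx, int n, int p, int c_in,
                size_t ld) {
  const int half = (KW - 1) / 2;
  for (int c = 0; c < c_in; ++c) {
    std::memset(dx + (size_t)c * ld, 0, (size_t)n * p * sizeof(double));
  }
  for (int o = 0; o < KW; ++o) {
    const int d = o - half;
    const int t0 = std::max(0, -d);
    const int t1 = std::min(p - 1, p - 1 - d);
    for (int c = 0; c < c_in; ++c) {
      const double* sc = dcol + ((size_t)o * c_in + c) * ld;
      double* dc = dx + (size_t)c * ld;
      for (int s = 0; s < n; ++s) {
        const double* sb = sc + (size_t)s * p + t0;
        double* db = dc + (size_t)s * p + t0 + d;
        for (int t = 0; t <= t1 - t0; ++t) db[t] += sb[t];
      }
    }
  }
}

// forward through the conv blocks + dense head for `n` examples already
// copied into w.x[0]; training toggles batch statistics
void forward(Net& net, Work& w, int n, bool training) {
  const Dims& dm = net.dm;
  const double mom = 0.9, eps = 1e-5;
  for (int i = 0; i < NBLK; ++i) {
    const size_t rows = (size_t)n * dm.p_in[i];
    im2col(w.x[i].data(), w.xc[i].data(), n, dm.p_in[i], dm.c_in[i],
           (size_t)w.nb * dm.p_in[i]);
    // y = xc * W  (ld of xc is the allocated row count)
    const int ldxc = w.nb * dm.p_in[i];
    gemm('N', 'N', (int)rows, dm.c_out[i], KW * dm.c_in[i],
         w.xc[i].data(), ldxc, net.convW[i].v.data(), KW * dm.c_in[i],
         0.0, w.y[i].data(), w.nb * dm.p_in[i]);
    const int ldy = w.nb * dm.p_in[i];
    // bias + batch norm + ReLU, one pass per channel
    for (int c = 0; c < dm.c_out[i]; ++c) {
      double* yc = w.y[i].data() + (size_t)c * ldy;
      const double bc = net.convB[i].v[c];
      for (size_t r = 0; r < rows; ++r) yc[r] += bc;
      double m_, v_;
      if (training) {
        double s1 = 0.0, s2 = 0.0;
        for (size_t r = 0; r < rows; ++r) { s1 += yc[r]; s2 += yc[r] * yc[r]; }
        m_ = s1 / rows;
        v_ = s2 / rows - m_ * m_;
        net.rmean[i][c] = mom * net.rmean[i][c] + (1 - mom) * m_;
        net.rvar[i][c] = mom * net.rvar[i][c] + (1 - mom) * v_;
      } else {
        m_ = net.rmean[i][c];
        v_ = net.rvar[i][c];
      }
      const double isd = 1.0 / std::sqrt(v_ + eps);
      const double g_ = net.gamma[i].v[c], b_ = net.beta[i].v[c];
      double* xh = w.xhat[i].data() + (size_t)c * ldy;
      double* ac = w.act[i].data() + (size_t)c * ldy;
      for (size_t r = 0; r < rows; ++r) {
        const double h = (yc[r] - m_) * isd;
        xh[r] = h;
        const double a = g_ * h + b_;
        ac[r] = a > 0.0 ? a : 0.0;
      }
      w.bn_isd[i][c] = isd;
    }
    // max pool into the next block input
    const int pl = dm.pool[i];
    const int p_out = dm.p_in[i] / pl;
    double* nx = (i + 1 < NBLK) ? w.x[i + 1].data() : w.x[NBLK].data();
    const int ldnx = w.nb * p_out;
    for (int c = 0; c < dm.c_out[i]; ++c) {
      const double* ac = w.act[i].data() + (size_t)c * ldy;
      double* ox = nx + (size_t)c * ldnx;
      int* se = w.sel[i].data() + (size_t)c * ((size_t)w.nb * p_out);
      for (size_t q = 0; q < (size_t)n * p_out; ++q) {
        const double* blk = ac + q * pl;
        int wbest = 0;
        double best = blk[0];
        for (int u = 1; u < pl; ++u) {
          if (blk[u] > best) { best = blk[u]; wbest = u; }
        }
        ox[q] = best;
        // negative marks a block whose max is 0, i.e. ReLU blocks the
        // gradient; the winner index is then irrelevant
        se[q] = best > 0.0 ? (int)(q * pl) + wbest : -1;
      }
    }
  }
  // flatten: feature f = pos + ch * p_last (column-major over (pos, ch))
  const int pl = dm.p_last;
  const int ldl = w.nb * pl;
  for (int c = 0; c < dm.c_out[NBLK - 1]; ++c) {
    const double* xc_ = w.x[NBLK].data() + (size_t)c * ldl;
    for (int s = 0; s < n; ++s) {
      for (int q = 0; q < pl; ++q) {
        w.flat[(size_t)(q + c * pl) * w.nb + s] = xc_[(size_t)s * pl + q];
      }
    }
  }
  // dense head (flat is nb x 1536 with ld = nb)
  const double* in = w.flat.data();
  int ld_in = w.nb;
  for (int j = 0; j < 3; ++j) {
    gemm('N', 'N', n, dm.d_out[j], dm.d_in[j], in, ld_in,
         net.denseW[j].v.data(), dm.d_in[j], 0.0, w.z[j].data(), w.nb);
    for (int c = 0; c < dm.d_out[j]; ++c) {
      double* zc = w.z[j].data() + (size_t)c * w.nb;
      const double bc = net.denseB[j].v[c];
      for (int s = 0; s < n; ++s) {
        double v = zc[s] + bc;
        if (j < 2 && v < 0.0) v = 0.0;  // ReLU on the hidden layers
        zc[s] = v;
      }
    }
    in = w.z[j].data();
    ld_in = w.nb;
  }
  // softmax
  for (int s = 0; s < n; ++s) {
    const double a = w.z[2][s], b = w.z[2][(size_t)w.nb + s];
    const double mx = std::max(a, b);
    const double ea = std::exp(a - mx), eb = std::exp(b - mx);
    w.prob[s] = ea / (ea + eb);
    w.prob[(size_t)w.nb + s] = eb / (ea + eb);
  }
}

// backward + Adam update; y1 holds 1-based class labels (1 = normal,
// 2 = pathological); returns the batch loss
double backward_step(Net& net, Work& w, int n, const int* y1, double lr) {
  const Dims& dm = net.dm;
  double loss = 0.0;
  // dlogits into gz[2]
  for (int s = 0; s < n; ++s) {
    const double p2 = w.prob[(size_t)w.nb + s];
    const double py = (y1[s] == 2) ? p2 : (1.0 - p2);
    loss -= std::log(std::max(py, 1e-12));
    w.gz[2][s] = (w.prob[s] - (y1[s] == 1 ? 1.0 : 0.0)) / n;
    w.gz[2][(size_t)w.nb + s] =
        (p2 - (y1[s] == 2 ? 1.0 : 0.0)) / n;
  }
  loss /= n;

  net.t_adam += 1;
  const int t = net.t_adam;

  // dense head backward
  for (int j = 2; j >= 0; --j) {
    const double* in = (j == 0) ? w.flat.data() : w.z[j - 1].data();
    const int ld_in = w.nb;
    // dW = in' * gz
    gemm('T', 'N', dm.d_in[j], dm.d_out[j], n, in, ld_in,
         w.gz[j].data(), w.nb, 0.0, w.dDW[j].data(), dm.d_in[j]);
    for (int c = 0; c < dm.d_out[j]; ++c) {
      double s_ = 0.0;
      const double* gc = w.gz[j].data() + (size_t)c * w.nb;
      for (int s = 0; s < n; ++s) s_ += gc[s];
      w.dDB[j][c] = s_;
    }
    double* gin = (j == 0) ? w.gflat.data() : w.gz[j - 1].data();
    gemm('N', 'T', n, dm.d_in[j], dm.d_out[j], w.gz[j].data(), w.nb,
         net.denseW[j].v.data(), dm.d_in[j], 0.0, gin, w.nb);
    if (j > 0) {                      // ReLU gradient (z holds the output)
      for (int c = 0; c < dm.d_in[j]; ++c) {
        double* gc = gin + (size_t)c * w.nb;
        const double* zc = w.z[j - 1].data() + (size_t)c * w.nb;
        for (int s = 0; s < n; ++s) {
          if (zc[s] <= 0.0) gc[s] = 0.0;
        }
      }
    }
    net.denseW[j].step(w.dDW[j].data(), lr, t);
    net.denseB[j].step(w.dDB[j].data(), lr, t);
  }

  // unflatten gflat into x[NBLK] (forward contents already consumed)
  const int plast = dm.p_last;
  const int ldl = w.nb * plast;
  for (int c = 0; c < dm.c_out[NBLK - 1]; ++c) {
    double* gc = w.x[NBLK].data() + (size_t)c * ldl;
    for (int s = 0; s < n; ++s) {
      for (int q = 0; q < plast; ++q) {
        gc[(size_t)s * plast + q] = w.gflat[(size_t)(q + c * plast) * w.nb + s];
      }
    }
  }

  for (int i = NBLK - 1; i >= 0; --i) {
    const size_t rows = (size_t)n * dm.p_in[i];
    const int ldy = w.nb * dm.p_in[i];
    const int pl = dm.pool[i];
    const int p_out = dm.p_in[i] / pl;
    const int ldo = w.nb * p_out;
    const double* gup = (i + 1 < NBLK) ? w.x[i + 1].data()
                                       : w.x[NBLK].data();
    // pool + ReLU backward scatter into act, then BN backward into y;
    // both forward buffers have served their last read for this block
    for (int c = 0; c < dm.c_out[i]; ++c) {
      double* ga = w.act[i].data() + (size_t)c * ldy;
      std::memset(ga, 0, rows * sizeof(double));
      const double* gu = gup + (size_t)c * ldo;
      const int* se = w.sel[i].data() + (size_t)c * ((size_t)w.nb * p_out);
      for (size_t q = 0; q < (size_t)n * p_out; ++q) {
        if (se[q] >= 0) ga[se[q]] = gu[q];
      }
      double s_g = 0.0, s_gx = 0.0;
      const double* xh = w.xhat[i].data() + (size_t)c * ldy;
      for (size_t r = 0; r < rows; ++r) {
        s_g += ga[r];
        s_gx += ga[r] * xh[r];
      }
      w.dG[i][c] = s_gx;
      w.dBt[i][c] = s_g;
      const double a = net.gamma[i].v[c] * w.bn_isd[i][c];
      const double k1 = a * s_gx / rows, k2 = a * s_g / rows;
      double* gyc = w.y[i].data() + (size_t)c * ldy;
      for (size_t r = 0; r < rows; ++r) {
        gyc[r] = a * ga[r] - xh[r] * k1 - k2;
      }
      // conv bias gradient = column sum of gy
      double sb = 0.0;
      for (size_t r = 0; r < rows; ++r) sb += gyc[r];
      w.dB[i][c] = sb;
    }
    // dW = xc' * gy, then gxc overwrites xc, and dx overwrites x
    gemm('T', 'N', KW * dm.c_in[i], dm.c_out[i], (int)rows,
         w.xc[i].data(), ldy, w.y[i].data(), ldy, 0.0, w.dW[i].data(),
         KW * dm.c_in[i]);
    gemm('N', 'T', (int)rows, KW * dm.c_in[i], dm.c_out[i],
         w.y[i].data(), ldy, net.convW[i].v.data(), KW * dm.c_in[i],
         0.0, w.xc[i].data(), ldy);
    col2im_add(w.xc[i].data(), w.x[i].data(), n, dm.p_in[i], dm.c_in[i],
               (size_t)w.nb * dm.p_in[i]);
    net.convW[i].step(w.dW[i].data(), lr, t);
    net.convB[i].step(w.dB[i].data(), lr, t);
    net.gamma[i].step(w.dG[i].data(), lr, t);
    net.beta[i].step(w.dBt[i].data(), lr, t);
  }
  return loss;
}

// workspaces survive across fits/predictions in one session: the page
// faults of a fresh ~0.5 GB arena are far more expensive than the
// compute on some virtualized hosts, and every buffer is fully
// (re)written before use in each step
Work& shared_work(const Dims& dm, int input_len, int nb) {
  static std::unique_ptr<Work> ws;
  static int cur_len = -1, cur_nb = -1;
  if (!ws || cur_len != input_len || cur_nb < nb) {
    ws.reset(new Work(dm, nb));
    cur_len = input_len;
    cur_nb = nb;
  }
  return *ws;
}

void copy_in(const NumericMatrix& X, const IntegerVector& idx, Work& w,
             int input_len) {
  const int n = idx.size();
  for (int s = 0; s < n; ++s) {
    const double* src = &X(0, idx[s] - 1);
    std::memcpy(w.x[0].data() + (size_t)s * input_len, src,
                input_len * sizeof(double));
  }
}

}  // namespace

// X: input_len x N matrix (one recording per column); y: labels 1/2;
// orders: N x epochs matrix of 1-based shuffle orders; returns trained
// weights plus the per-epoch training-loss history.
// [[Rcpp::export]]
Rcpp::List cpp_cnn1d_fit(const Rcpp::NumericMatrix& X,
                         const Rcpp::IntegerVector& y,
                         const Rcpp::List& weights,
                         const Rcpp::IntegerMatrix& orders,
                         int batch_size, double lr) {
  const int input_len = X.nrow();
  const int n_all = X.ncol();
  const int epochs = orders.ncol();
  Net net(input_len, weights);
  const int bsz = std::min(batch_size, n_all);
  Work& w = shared_work(net.dm, input_len, bsz);
  NumericVector history(epochs);
  std::vector<int> yb(bsz);
  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0.0;
    int n_batches = 0;
    for (int b0 = 0; b0 < n_all; b0 += bsz) {
      const int nb = std::min(bsz, n_all - b0);
      IntegerVector idx(nb);
      for (int s = 0; s < nb; ++s) {
        idx[s] = orders(b0 + s, ep);
        yb[s] = y[idx[s] - 1];
      }
      copy_in(X, idx, w, input_len);
      forward(net, w, nb, true);
      ep_loss += backward_step(net, w, nb, yb.data(), lr);
      ++n_batches;
      Rcpp::checkUserInterrupt();
    }
    history[ep] = ep_loss / n_batches;
    if (!std::isfinite(history[ep])) {
      Rcpp::stop("cpp_cnn1d_fit: NaN loss at epoch %d", ep + 1);
    }
  }
  List out = net.export_weights();
  out["history"] = history;
  return out;
}

// eval-mode forward; returns N x 2 class probabilities
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_cnn1d_predict(const Rcpp::NumericMatrix& X,
                                      const Rcpp::List& weights) {
  const int input_len = X.nrow();
  const int n_all = X.ncol();
  Net net(input_len, weights);
  const int nb_max = std::min(8, n_all);
  Work& w = shared_work(net.dm, input_len, nb_max);
  NumericMatrix out(n_all, 2);
  for (int b0 = 0; b0 < n_all; b0 += nb_max) {
    const int nb = std::min(nb_max, n_all - b0);
    IntegerVector idx(nb);
    for (int s = 0; s < nb; ++s) idx[s] = b0 + s + 1;
    copy_in(X, idx, w, input_len);
    forward(net, w, nb, false);
    for (int s = 0; s < nb; ++s) {
      out(b0 + s, 0) = w.prob[s];
      out(b0 + s, 1) = w.prob[(size_t)w.nb + s];
    }
  }
  return out;
}
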