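// Compute kernels for the conv-net engine and connected-component labeling.
//
// Feature-map batches are passed as (B*H*W) x C matrices: image b occupies
// rows [b*H*W, (b+1)*H*W), pixels in column-major order within the frame
// (index = c*H + r, 0-based).  3x3 convolutions use the "valid" definition
// embedded in a fixed frame: outputs are written at the same coordinates as
// their window centre and the 1-px frame border (where the window would
// leave the frame) is set to zero.  Weights are (9*Cin) x Cout with row
// layout cin*9 + (dc+1)*3 + (dr+1), dr/dc in {-1,0,1}.
//
// Arithmetic is single precision internally (weights and activations cross
// the R boundary as doubles); bias addition and the optional rectifier are
// fused into the kernels.  The stride-2 transposed convolution is computed
// by output-parity decomposition, which touches only the taps that can be
// non-zero for each parity class (2.25 of 9 on average).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

typedef arma::fmat fmat;

static fmat to_f(const arma::mat& X) { return arma::conv_to<fmat>::from(X); }
static arma::mat to_d(const fmat& X) { return arma::conv_to<arma::mat>::from(X); }

static void im2col3(const fmat& X, int b, int H, int W, fmat& cols) {
  const int HW = H * W, Cin = X.n_cols;
  for (int c = 0; c < Cin; ++c) {
    const float* src = X.colptr(c) + (size_t)b * HW;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        float* dst = cols.colptr(c * 9 + (dc + 1) * 3 + (dr + 1));
        for (int j = 0; j < W; ++j) {
          int js = j + dc;
          if (js < 0 || js >= W) {
            std::fill(dst + (size_t)j * H, dst + (size_t)(j + 1) * H, 0.0f);
            continue;
          }
          const float* s = src + (size_t)js * H;
          float* d = dst + (size_t)j * H;
          for (int i = 0; i < H; ++i) {
            int is = i + dr;
            d[i] = (is < 0 || is >= H) ? 0.0f : s[is];
          }
        }
      }
    }
  }
}

static void col2im3(const fmat& dcols, int b, int H, int W, fmat& dX) {
  const int HW = H * W, Cin = dX.n_cols;
  for (int c = 0; c < Cin; ++c) {
    float* dst = dX.colptr(c) + (size_t)b * HW;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const float* src = dcols.colptr(c * 9 + (dc + 1) * 3 + (dr + 1));
        for (int j = 0; j < W; ++j) {
          int js = j + dc;
          if (js < 0 || js >= W) continue;
          const float* s = src + (size_t)j * H;
          float* d = dst + (size_t)js * H;
          for (int i = 0; i < H; ++i) {
            int is = i + dr;
            if (is >= 0 && is < H) d[is] += s[i];
          }
        }
      }
    }
  }
}

static void finish_block(fmat& Yb, const arma::vec& bias, int H, int W, bool relu) {
  // bias add, 1-px border zeroing and optional rectifier on one image block
  for (unsigned int c = 0; c < Yb.n_cols; ++c) {
    float bc = (float)bias[c];
    float* y = Yb.colptr(c);
    for (int j = 0; j < W; ++j) {
      float* col = y + (size_t)j * H;
      if (j == 0 || j == W - 1) { std::fill(col, col + H, 0.0f); continue; }
      col[0] = 0.0f; col[H - 1] = 0.0f;
      for (int i = 1; i < H - 1; ++i) {
        float v = col[i] + bc;
        col[i] = (relu && v < 0.0f) ? 0.0f : v;
      }
    }
  }
}

// zero border of a gradient block and apply rectifier mask from the stored
// (post-activation) output
static void mask_block(fmat& dYb, const fmat& Y, size_t row0, int H, int W, bool relu) {
  for (unsigned int c = 0; c < dYb.n_cols; ++c) {
    float* g = dYb.colptr(c);
    const float* y = Y.colptr(c) + row0;
    for (int j = 0; j < W; ++j) {
      float* col = g + (size_t)j * H;
      if (j == 0 || j == W - 1) { std::fill(col, col + H, 0.0f); continue; }
      col[0] = 0.0f; col[H - 1] = 0.0f;
      if (relu) {
        const float* yc = y + (size_t)j * H;
        for (int i = 1; i < H - 1; ++i)
          if (yc[i] <= 0.0f) col[i] = 0.0f;
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv_fwd(const arma::mat& X, const arma::mat& Wt,
                       const arma::vec& b, int H, int W, int B, bool relu) {
  const int HW = H * W;
  fmat Xf = to_f(X), Wf = to_f(Wt);
  fmat Y((size_t)B * HW, Wt.n_cols);
  fmat cols(HW, Wt.n_rows);
  for (int bb = 0; bb < B; ++bb) {
    im2col3(Xf, bb, H, W, cols);
    fmat Yb = cols * Wf;
    finish_block(Yb, b, H, W, relu);
    Y.rows((size_t)bb * HW, (size_t)(bb + 1) * HW - 1) = Yb;
  }
  return to_d(Y);
}

// [[Rcpp::export]]
List cpp_conv_bwd(const arma::mat& X, const arma::mat& Wt, const arma::mat& Y,
                  const arma::mat& dY, int H, int W, int B, bool relu) {
  const int HW = H * W;
  fmat Xf = to_f(X), Wf = to_f(Wt), Yf = to_f(Y), dYf = to_f(dY);
  fmat dX(arma::size(Xf), arma::fill::zeros);
  fmat dW(arma::size(Wf), arma::fill::zeros);
  arma::fvec db(Wt.n_cols, arma::fill::zeros);
  fmat cols(HW, Wt.n_rows);
  for (int bb = 0; bb < B; ++bb) {
    size_t r0 = (size_t)bb * HW;
    fmat dYb = dYf.rows(r0, r0 + HW - 1);
    mask_block(dYb, Yf, r0, H, W, relu);
    im2col3(Xf, bb, H, W, cols);
    dW += cols.t() * dYb;
    db += arma::sum(dYb, 0).t();
    fmat dcols = dYb * Wf.t();
    col2im3(dcols, bb, H, W, dX);
  }
  return List::create(_["dX"] = to_d(dX), _["dW"] = to_d(dW),
                      _["db"] = arma::conv_to<arma::vec>::from(db));
}

// ---- stride-2 3x3 transposed convolution, parity decomposed ---------------
//
// Output Y(2a+pr, 2b+pc) with parity (pr, pc) reads input X(a+di, b+dj)
// through tap (dr, dc) = (2*di - pr, 2*dj - pc).  Shift/tap pairs per
// parity: pr=0 -> di=0 (dr=0); pr=1 -> di in {0,1} (dr in {-1,+1}).

struct Parity {
  int pr, pc, nshift;
  int di[4], dj[4], tap[4];
};

static void parity_tables(Parity par[4]) {
  int idx = 0;
  for (int pc = 0; pc <= 1; ++pc) {
    for (int pr = 0; pr <= 1; ++pr) {
      Parity& p = par[idx++];
      p.pr = pr; p.pc = pc; p.nshift = 0;
      for (int dj = 0; dj <= (pc ? 1 : 0); ++dj) {
        for (int di = 0; di <= (pr ? 1 : 0); ++di) {
          int dr = 2 * di - pr, dc = 2 * dj - pc;
          p.di[p.nshift] = di; p.dj[p.nshift] = dj;
          p.tap[p.nshift] = (dc + 1) * 3 + (dr + 1);
          ++p.nshift;
        }
      }
    }
  }
}

// gather shifted copy of image block (a+di, b+dj), zero outside
static void shifted_copy(const fmat& X, int b, int H, int W, int c,
                         int di, int dj, float* dst) {
  const float* src = X.colptr(c) + (size_t)b * H * W;
  for (int j = 0; j < W; ++j) {
    int js = j + dj;
    if (js < 0 || js >= W) { std::fill(dst + (size_t)j * H, dst + (size_t)(j + 1) * H, 0.0f); continue; }
    const float* s = src + (size_t)js * H;
    float* d = dst + (size_t)j * H;
    for (int i = 0; i < H; ++i) {
      int is = i + di;
      d[i] = (is < 0 || is >= H) ? 0.0f : s[is];
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_tconv_fwd(const arma::mat& X, const arma::mat& Wt,
                        const arma::vec& b, int H, int W, int B, bool relu) {
  const int HW = H * W, Ho = 2 * H, Wo = 2 * W, HWo = Ho * Wo;
  const int Cin = X.n_cols, Cout = Wt.n_cols;
  fmat Xf = to_f(X), Wf = to_f(Wt);
  Parity par[4]; parity_tables(par);
  fmat Wsub[4], cols[4];
  for (int p = 0; p < 4; ++p) {
    Wsub[p].set_size(par[p].nshift * Cin, Cout);
    for (int c = 0; c < Cin; ++c)
      for (int q = 0; q < par[p].nshift; ++q)
        Wsub[p].row(c * par[p].nshift + q) = Wf.row(c * 9 + par[p].tap[q]);
    cols[p].set_size(HW, par[p].nshift * Cin);
  }
  fmat Y((size_t)B * HWo, Cout);
  for (int bb = 0; bb < B; ++bb) {
    fmat Yb(HWo, Cout);
    for (int p = 0; p < 4; ++p) {
      const Parity& pp = par[p];
      for (int c = 0; c < Cin; ++c)
        for (int q = 0; q < pp.nshift; ++q)
          shifted_copy(Xf, bb, H, W, c, pp.di[q], pp.dj[q],
                       cols[p].colptr(c * pp.nshift + q));
      fmat Yp = cols[p] * Wsub[p];
      // scatter into the full frame at stride 2
      for (int c = 0; c < Cout; ++c) {
        const float* s = Yp.colptr(c);
        float* d = Yb.colptr(c);
        for (int j = 0; j < W; ++j) {
          const float* sc = s + (size_t)j * H;
          float* dc_ = d + (size_t)(2 * j + pp.pc) * Ho + pp.pr;
          for (int i = 0; i < H; ++i) dc_[2 * i] = sc[i];
        }
      }
    }
    finish_block(Yb, b, Ho, Wo, relu);
    Y.rows((size_t)bb * HWo, (size_t)(bb + 1) * HWo - 1) = Yb;
  }
  return to_d(Y);
}

// [[Rcpp::export]]
List cpp_tconv_bwd(const arma::mat& X, const arma::mat& Wt, const arma::mat& Y,
                   const arma::mat& dY, int H, int W, int B, bool relu) {
  const int HW = H * W, Ho = 2 * H, Wo = 2 * W, HWo = Ho * Wo;
  const int Cin = X.n_cols, Cout = Wt.n_cols;
  fmat Xf = to_f(X), Wf = to_f(Wt), Yf = to_f(Y), dYf = to_f(dY);
  Parity par[4]; parity_tables(par);
  fmat Wsub[4], cols[4];
  for (int p = 0; p < 4; ++p) {
    Wsub[p].set_size(par[p].nshift * Cin, Cout);
    for (int c = 0; c < Cin; ++c)
      for (int q = 0; q < par[p].nshift; ++q)
        Wsub[p].row(c * par[p].nshift + q) = Wf.row(c * 9 + par[p].tap[q]);
    cols[p].set_size(HW, par[p].nshift * Cin);
  }
  fmat dX(arma::size(Xf), arma::fill::zeros);
  fmat dWsub[4];
  for (int p = 0; p < 4; ++p) dWsub[p].zeros(par[p].nshift * Cin, Cout);
  arma::fvec db(Cout, arma::fill::zeros);
  fmat dYp(HW, Cout);
  for (int bb = 0; bb < B; ++bb) {
    size_t r0 = (size_t)bb * HWo;
    fmat dYb = dYf.rows(r0, r0 + HWo - 1);
    mask_block(dYb, Yf, r0, Ho, Wo, relu);
    db += arma::sum(dYb, 0).t();
    for (int p = 0; p < 4; ++p) {
      const Parity& pp = par[p];
      // gather strided gradient for this parity
      for (int c = 0; c < Cout; ++c) {
        const float* s = dYb.colptr(c);
        float* d = dYp.colptr(c);
        for (int j = 0; j < W; ++j) {
          const float* sc = s + (size_t)(2 * j + pp.pc) * Ho + pp.pr;
          float* dc_ = d + (size_t)j * H;
          for (int i = 0; i < H; ++i) dc_[i] = sc[2 * i];
        }
      }
      for (int c = 0; c < Cin; ++c)
        for (int q = 0; q < pp.nshift; ++q)
          shifted_copy(Xf, bb, H, W, c, pp.di[q], pp.dj[q],
                       cols[p].colptr(c * pp.nshift + q));
      dWsub[p] += cols[p].t() * dYp;
      fmat dcols = dYp * Wsub[p].t();
      // scatter-add dcols back to dX with the reverse shifts
      for (int c = 0; c < Cin; ++c) {
        float* d = dX.colptr(c) + (size_t)bb * HW;
        for (int q = 0; q < pp.nshift; ++q) {
          const float* s = dcols.colptr(c * pp.nshift + q);
          for (int j = 0; j < W; ++j) {
            int js = j + pp.dj[q];
            if (js < 0 || js >= W) continue;
            const float* sc = s + (size_t)j * H;
            float* dc_ = d + (size_t)js * H;
            for (int i = 0; i < H; ++i) {
              int is = i + pp.di[q];
              if (is >= 0 && is < H) dc_[is] += sc[i];
            }
          }
        }
      }
    }
  }
  fmat dW(arma::size(Wf), arma::fill::zeros);
  for (int p = 0; p < 4; ++p)
    for (int c = 0; c < Cin; ++c)
      for (int q = 0; q < par[p].nshift; ++q)
        dW.row(c * 9 + par[p].tap[q]) += dWsub[p].row(c * par[p].nshift + q);
  return List::create(_["dX"] = to_d(dX), _["dW"] = to_d(dW),
                      _["db"] = arma::conv_to<arma::vec>::from(db));
}

// [[Rcpp::export]]
List cpp_pool_fwd(const arma::mat& X, int H, int W, int B) {
  const int H2 = H / 2, W2 = W / 2, HW = H * W, HW2 = H2 * W2;
  const int C = X.n_cols;
  arma::mat Y((size_t)B * HW2, C);
  IntegerMatrix idx(B * HW2, C);  // 0..3 code: di + 2*dj
  for (int bb = 0; bb < B; ++bb) {
    for (int c = 0; c < C; ++c) {
      const double* src = X.colptr(c) + (size_t)bb * HW;
      double* dst = Y.colptr(c) + (size_t)bb * HW2;
      for (int j = 0; j < W2; ++j) {
        for (int i = 0; i < H2; ++i) {
          double best = -1e300; int code = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              double v = src[(size_t)(2 * j + dj) * H + 2 * i + di];
              if (v > best) { best = v; code = di + 2 * dj; }
            }
          dst[(size_t)j * H2 + i] = best;
          idx((size_t)bb * HW2 + (size_t)j * H2 + i, c) = code;
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::mat cpp_pool_bwd(const arma::mat& dY, const IntegerMatrix& idx,
                       int H, int W, int B) {
  const int H2 = H / 2, W2 = W / 2, HW = H * W, HW2 = H2 * W2;
  const int C = dY.n_cols;
  arma::mat dX((size_t)B * HW, C, arma::fill::zeros);
  for (int bb = 0; bb < B; ++bb) {
    for (int c = 0; c < C; ++c) {
      const double* src = dY.colptr(c) + (size_t)bb * HW2;
      double* dst = dX.colptr(c) + (size_t)bb * HW;
      for (int j = 0; j < W2; ++j) {
        for (int i = 0; i < H2; ++i) {
          int code = idx((size_t)bb * HW2 + (size_t)j * H2 + i, c);
          int di = code % 2, dj = code / 2;
          dst[(size_t)(2 * j + dj) * H + 2 * i + di] += src[(size_t)j * H2 + i];
        }
      }
    }
  }
  return dX;
}

// [[Rcpp::export]]
IntegerMatrix cpp_cc_label(const IntegerMatrix& bin, int connectivity) {
  // connected components of 1-pixels; labels assigned in raster (row-major)
  // order of each component's first pixel
  const int H = bin.nrow(), W = bin.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int,int> > stack;
  int next = 0;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (bin(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        std::pair<int,int> p = stack.back(); stack.pop_back();
        for (int k = 0; k < nn; ++k) {
          int rr = p.first + dr8[k], cc = p.second + dc8[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (bin(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  lab.attr("count") = next;
  return lab;
}
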