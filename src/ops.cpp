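#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Volumetric arrays are stored channel-first, column-major: dim (C, D, H, W),
// i.e. linear index c + C*(d + D*(h + H*w)), all 0-based here.

// Unfold a (C, D, H, W) volume into a (C*kd*kh*kw) x (Do*Ho*Wo) matrix whose
// column j holds the receptive field of output voxel j (d fastest). Row index
// is c + C*(kx + kd*(ky + kh*kz)). Out-of-bounds taps are zero (zero padding).
// [[Rcpp::export(name = ".im2col3")]]
NumericMatrix im2col3(NumericVector x, int C, int D, int H, int W,
                      int kd, int kh, int kw, int stride, int pad) {
  const int Do = (D + 2 * pad - kd) / stride + 1;
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int K = kd * kh * kw;
  NumericMatrix out(C * K, Do * Ho * Wo);
  const double* xp = x.begin();
  double* op = out.begin();
  const R_xlen_t nrow = (R_xlen_t)C * K;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int d0 = 0; d0 < Do; ++d0) {
        const R_xlen_t col = (R_xlen_t)d0 + (R_xlen_t)Do * (ho + (R_xlen_t)Ho * wo);
        double* oc = op + col * nrow;
        for (int kz = 0; kz < kw; ++kz) {
          const int wz = wo * stride - pad + kz;
          for (int ky = 0; ky < kh; ++ky) {
            const int hy = ho * stride - pad + ky;
            for (int kx = 0; kx < kd; ++kx) {
              const int dx = d0 * stride - pad + kx;
              const int k = kx + kd * (ky + kh * kz);
              double* dst = oc + (R_xlen_t)C * k;
              if (dx >= 0 && dx < D && hy >= 0 && hy < H && wz >= 0 && wz < W) {
                const double* src =
                  xp + (R_xlen_t)C * (dx + (R_xlen_t)D * (hy + (R_xlen_t)H * wz));
                for (int c = 0; c < C; ++c) dst[c] = src[c];
              }
              // else: matrix is zero-initialised
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3: fold a (C*kd*kh*kw) x (Do*Ho*Wo) matrix of column
// gradients back into a (C, D, H, W) volume, accumulating overlaps.
// [[Rcpp::export(name = ".col2im3")]]
NumericVector col2im3(NumericMatrix cols, int C, int D, int H, int W,
                      int kd, int kh, int kw, int stride, int pad) {
  const int Do = (D + 2 * pad - kd) / stride + 1;
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector out((R_xlen_t)C * D * H * W);
  double* op = out.begin();
  const double* cp = cols.begin();
  const R_xlen_t nrow = (R_xlen_t)C * kd * kh * kw;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int d0 = 0; d0 < Do; ++d0) {
        const R_xlen_t col = (R_xlen_t)d0 + (R_xlen_t)Do * (ho + (R_xlen_t)Ho * wo);
        const double* cc = cp + col * nrow;
        for (int kz = 0; kz < kw; ++kz) {
          const int wz = wo * stride - pad + kz;
          if (wz < 0 || wz >= W) continue;
          for (int ky = 0; ky < kh; ++ky) {
            const int hy = ho * stride - pad + ky;
            if (hy < 0 || hy >= H) continue;
            for (int kx = 0; kx < kd; ++kx) {
              const int dx = d0 * stride - pad + kx;
              if (dx < 0 || dx >= D) continue;
              const int k = kx + kd * (ky + kh * kz);
              const double* src = cc + (R_xlen_t)C * k;
              double* dst = op + (R_xlen_t)C * (dx + (R_xlen_t)D * (hy + (R_xlen_t)H * wz));
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
          }
        }
      }
    }
  }
  return out;
}

// Label the 18-connected components of a binary 3D mask (dim D x H x W,
// values 0/1). Neighbours share a face or an edge (offsets with at most two
// nonzero coordinates); pure corner contacts do not connect. Returns an
// integer array of labels, background 0, components numbered from 1.
// [[Rcpp::export(name = ".cc18_label")]]
IntegerVector cc18_label(IntegerVector mask, int D, int H, int W) {
  IntegerVector lab((R_xlen_t)D * H * W);
  // 18-neighbourhood: all |dd|,|dh|,|dw| <= 1 offsets with 1 or 2 nonzeros
  int off[18][3];
  int m = 0;
  for (int dw = -1; dw <= 1; ++dw)
    for (int dh = -1; dh <= 1; ++dh)
      for (int dd = -1; dd <= 1; ++dd) {
        int nz = (dd != 0) + (dh != 0) + (dw != 0);
        if (nz == 1 || nz == 2) {
          off[m][0] = dd; off[m][1] = dh; off[m][2] = dw; ++m;
        }
      }
  int next = 0;
  std::queue<int> q;
  for (R_xlen_t s = 0; s < lab.size(); ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    q.push((int)s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      int d = v % D, rest = v / D, h = rest % H, w = rest / H;
      for (int i = 0; i < 18; ++i) {
        int nd = d + off[i][0], nh = h + off[i][1], nw = w + off[i][2];
        if (nd < 0 || nd >= D || nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
        R_xlen_t u = (R_xlen_t)nd + (R_xlen_t)D * (nh + (R_xlen_t)H * nw);
        if (mask[u] != 0 && lab[u] == 0) {
          lab[u] = next;
          q.push((int)u);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
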