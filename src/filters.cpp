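#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
using namespace Rcpp;

// Median over a disk neighbourhood of the given pixel radius. Pixels outside
// the image are excluded (shrinking neighbourhood at borders, as in common
// GUI implementations). Ties at even counts average the two middle values,
// matching stats::median().
// [[Rcpp::export]]
NumericMatrix median_filter_disk_cpp(NumericMatrix x, int radius) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  const double *px = x.begin();
  double *po = out.begin();
  std::vector<long> off;          // linear offsets of the disk (column-major)
  std::vector<int> dr, dc;
  for (int b = -radius; b <= radius; ++b)
    for (int a = -radius; a <= radius; ++a)
      if (a * a + b * b <= radius * radius) {
        dr.push_back(a); dc.push_back(b);
        off.push_back((long) b * nr + a);
      }
  int K = (int) off.size();
  std::vector<double> buf(K);
  int h = K / 2;                  // K is odd for a centred disk
  for (int j = 0; j < nc; ++j) {
    bool cedge = j < radius || j >= nc - radius;
    for (int i = 0; i < nr; ++i) {
      if (!cedge && i >= radius && i < nr - radius) {
        const double *base = px + (long) j * nr + i;
        for (int k = 0; k < K; ++k) buf[k] = base[off[k]];
        std::nth_element(buf.begin(), buf.begin() + h, buf.end());
        po[(long) j * nr + i] = buf[h];
      } else {
        int n = 0;
        for (int k = 0; k < K; ++k) {
          int r = i + dr[k], c = j + dc[k];
          if (r >= 0 && r < nr && c >= 0 && c < nc)
            buf[n++] = px[(long) c * nr + r];
        }
        int hh = n / 2;
        std::nth_element(buf.begin(), buf.begin() + hh, buf.begin() + n);
        double med = buf[hh];
        if (n % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + hh);
          med = 0.5 * (med + lo);
        }
        po[(long) j * nr + i] = med;
      }
    }
  }
  return out;
}

static inline int wrap(int i, int n) {
  i %= n;
  return i < 0 ? i + n : i;
}

// Separable 2D convolution with a 1D kernel applied along rows then columns,
// circular (wrap-around) boundary. A unit-sum kernel conserves the image sum
// exactly under this boundary rule.
// [[Rcpp::export]]
NumericMatrix conv_sep_circular_cpp(NumericMatrix x, NumericVector kernel) {
  int nr = x.nrow(), nc = x.ncol(), K = kernel.size();
  int half = K / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  const double *kp = kernel.begin();
  const double *px = x.begin();
  double *pt = tmp.begin(), *po = out.begin();
  for (int j = 0; j < nc; ++j) {        // vertical pass (within columns)
    const double *col = px + (long) j * nr;
    double *tcol = pt + (long) j * nr;
    for (int i = 0; i < half && i < nr; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += kp[k] * col[wrap(i + k - half, nr)];
      tcol[i] = s;
    }
    for (int i = half; i < nr - half; ++i) {
      double s = 0.0;
      const double *base = col + i - half;
      for (int k = 0; k < K; ++k) s += kp[k] * base[k];
      tcol[i] = s;
    }
    for (int i = std::max(half, nr - half); i < nr; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += kp[k] * col[wrap(i + k - half, nr)];
      tcol[i] = s;
    }
  }
  for (int j = 0; j < nc; ++j) {        // horizontal pass (across columns)
    double *ocol = po + (long) j * nr;
    if (j >= half && j < nc - half) {
      const double *base = pt + (long) (j - half) * nr;
      for (int i = 0; i < nr; ++i) {
        double s = 0.0;
        for (int k = 0; k < K; ++k) s += kp[k] * base[(long) k * nr + i];
        ocol[i] = s;
      }
    } else {
      for (int i = 0; i < nr; ++i) {
        double s = 0.0;
        for (int k = 0; k < K; ++k)
          s += kp[k] * pt[(long) wrap(j + k - half, nc) * nr + i];
        ocol[i] = s;
      }
    }
  }
  return out;
}

// Connected-component labelling of a 3D logical array (dims ny, nx, nt) with
// 26-connectivity (all neighbours differing by at most 1 in each index).
// Returns an integer array of labels, 0 = background.
// [[Rcpp::export]]
IntegerVector label3d26_cpp(LogicalVector mask, IntegerVector dims) {
  int ny = dims[0], nx = dims[1], nt = dims[2];
  R_xlen_t n = (R_xlen_t) ny * nx * nt;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int t = (int)(cur / ((R_xlen_t) ny * nx));
      int rem = (int)(cur % ((R_xlen_t) ny * nx));
      int xx = rem / ny, yy = rem % ny;
      for (int dt = -1; dt <= 1; ++dt)
        for (int dxp = -1; dxp <= 1; ++dxp)
          for (int dyp = -1; dyp <= 1; ++dyp) {
            if (!dt && !dxp && !dyp) continue;
            int y2 = yy + dyp, x2 = xx + dxp, t2 = t + dt;
            if (y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx || t2 < 0 || t2 >= nt)
              continue;
            R_xlen_t idx = (R_xlen_t) t2 * ny * nx + (R_xlen_t) x2 * ny + y2;
            if (mask[idx] && lab[idx] == 0) { lab[idx] = next; q.push(idx); }
          }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}
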