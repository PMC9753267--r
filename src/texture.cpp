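// Sliding-window GLCM texture panel.
//
// For every pixel whose centre lies in the mask, a window x window
// neighbourhood (mirror-padded at image borders) is scanned; symmetric
// co-occurrence counts are accumulated at unit distance for the four
// standard orientations (0, 45, 90, 135 degrees) and the 17 Haralick
// statistics are computed per offset and averaged, or computed once from
// the offset-pooled matrix. The per-centre panels are then averaged over
// the mask. Gray levels arrive already quantized to 0..nlevels-1.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline int reflect(int i, int n) {
  // mirror without edge repetition; loops for windows larger than the image
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// 17 statistics from a dense probability matrix P (G x G, column-major),
// touched = indices of possibly non-zero cells. Levels are valued 1..G.
static void haralick17(const std::vector<double> &P,
                       const std::vector<int> &touched, int G, double *out) {
  std::vector<double> px(G, 0.0), py(G, 0.0);
  std::vector<double> psum(2 * G - 1, 0.0), pdiff(G, 0.0);
  double autoc = 0, contrast = 0, dissim = 0, energy = 0, entropy = 0,
         maxp = 0, homog = 0;
  for (int t : touched) {
    double p = P[t];
    if (p <= 0) continue;
    int i = t % G, j = t / G; // 0-based
    double vi = i + 1.0, vj = j + 1.0, d = vi - vj, ad = std::fabs(d);
    px[i] += p; py[j] += p;
    psum[i + j] += p; pdiff[(int)ad] += p;
    autoc += vi * vj * p;
    contrast += d * d * p;
    dissim += ad * p;
    energy += p * p;
    entropy -= p * std::log(p);
    homog += p / (1.0 + ad);
    if (p > maxp) maxp = p;
  }
  double mux = 0, muy = 0;
  for (int i = 0; i < G; ++i) { mux += (i + 1.0) * px[i]; muy += (i + 1.0) * py[i]; }
  double vx = 0, vy = 0, hx = 0, hy = 0;
  for (int i = 0; i < G; ++i) {
    vx += (i + 1.0 - mux) * (i + 1.0 - mux) * px[i];
    vy += (i + 1.0 - muy) * (i + 1.0 - muy) * py[i];
    if (px[i] > 0) hx -= px[i] * std::log(px[i]);
    if (py[i] > 0) hy -= py[i] * std::log(py[i]);
  }
  double shade = 0, prom = 0, ssvar = 0, hxy1 = 0;
  for (int t : touched) {
    double p = P[t];
    if (p <= 0) continue;
    int i = t % G, j = t / G;
    double s = (i + 1.0) + (j + 1.0) - mux - muy;
    shade += s * s * s * p;
    prom += s * s * s * s * p;
    ssvar += (i + 1.0 - mux) * (i + 1.0 - mux) * p;
    hxy1 -= p * std::log(px[i] * py[j]);
  }
  double hxy2 = 0;
  for (int i = 0; i < G; ++i) {
    if (px[i] <= 0) continue;
    for (int j = 0; j < G; ++j) {
      if (py[j] <= 0) continue;
      double q = px[i] * py[j];
      hxy2 -= q * std::log(q);
    }
  }
  double sa = 0, se = 0;
  for (int k = 0; k < 2 * G - 1; ++k) {
    double p = psum[k];
    if (p <= 0) continue;
    sa += (k + 2.0) * p;
    se -= p * std::log(p);
  }
  double sv = 0;
  for (int k = 0; k < 2 * G - 1; ++k) {
    double p = psum[k];
    if (p <= 0) continue;
    sv += (k + 2.0 - sa) * (k + 2.0 - sa) * p;
  }
  double de = 0;
  for (int k = 0; k < G; ++k)
    if (pdiff[k] > 0) de -= pdiff[k] * std::log(pdiff[k]);
  double sx = std::sqrt(vx), sy = std::sqrt(vy);
  double corr = (sx > 1e-12 && sy > 1e-12) ? (autoc - mux * muy) / (sx * sy) : 0.0;
  double hmax = std::max(hx, hy);
  double imc1 = (hmax > 1e-12) ? (entropy - hxy1) / hmax : 0.0;
  double a2 = 1.0 - std::exp(-2.0 * (hxy2 - entropy));
  double imc2 = (a2 > 0) ? std::sqrt(a2) : 0.0;
  out[0] = autoc;   out[1] = prom;   out[2] = shade;  out[3] = contrast;
  out[4] = corr;    out[5] = de;     out[6] = dissim; out[7] = energy;
  out[8] = entropy; out[9] = imc1;   out[10] = imc2;  out[11] = maxp;
  out[12] = sa;     out[13] = se;    out[14] = ssvar; out[15] = sv;
  out[16] = homog;
}

// [[Rcpp::export]]
NumericVector cpp_texture_panel(IntegerMatrix q, LogicalMatrix mask,
                                int window, int nlevels, bool avg_matrices) {
  int nr = q.nrow(), nc = q.ncol(), G = nlevels;
  if (window < 3 || window % 2 == 0) stop("window must be odd and >= 3");
  int h = window / 2;
  // offsets at distance 1: 0, 45, 90, 135 degrees (rows grow downward)
  const int odr[4] = {0, -1, -1, -1};
  const int odc[4] = {1, 1, 0, -1};
  std::vector<double> P((size_t)G * G, 0.0);
  std::vector<int> touched;
  std::vector<int> win((size_t)window * window);
  double acc[17], f[17], tot[17];
  for (int k = 0; k < 17; ++k) tot[k] = 0;
  long ncentres = 0;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      // extract mirror-padded window
      for (int wc = 0; wc < window; ++wc) {
        int jj = reflect(j - h + wc, nc);
        for (int wr = 0; wr < window; ++wr)
          win[wr + wc * window] = q(reflect(i - h + wr, nr), jj);
      }
      for (int k = 0; k < 17; ++k) acc[k] = 0;
      if (!avg_matrices) {
        for (int o = 0; o < 4; ++o) {
          int dr = odr[o], dc = odc[o];
          for (int t : touched) P[t] = 0;
          touched.clear();
          double n = 0;
          int r0 = std::max(0, -dr), r1 = window - std::max(0, dr);
          int c0 = std::max(0, -dc), c1 = window - std::max(0, dc);
          for (int wc = c0; wc < c1; ++wc) {
            for (int wr = r0; wr < r1; ++wr) {
              int a = win[wr + wc * window];
              int b = win[(wr + dr) + (wc + dc) * window];
              int ia = a + b * G, ib = b + a * G;
              if (P[ia] == 0) touched.push_back(ia);
              if (ia != ib && P[ib] == 0) touched.push_back(ib);
              P[ia] += 1.0; P[ib] += 1.0;
              n += 2.0;
            }
          }
          for (int t : touched) P[t] /= n;
          haralick17(P, touched, G, f);
          for (int k = 0; k < 17; ++k) acc[k] += f[k] / 4.0;
        }
      } else {
        for (int t : touched) P[t] = 0;
        touched.clear();
        double n = 0;
        for (int o = 0; o < 4; ++o) {
          int dr = odr[o], dc = odc[o];
          int r0 = std::max(0, -dr), r1 = window - std::max(0, dr);
          int c0 = std::max(0, -dc), c1 = window - std::max(0, dc);
          for (int wc = c0; wc < c1; ++wc) {
            for (int wr = r0; wr < r1; ++wr) {
              int a = win[wr + wc * window];
              int b = win[(wr + dr) + (wc + dc) * window];
              int ia = a + b * G, ib = b + a * G;
              if (P[ia] == 0) touched.push_back(ia);
              if (ia != ib && P[ib] == 0) touched.push_back(ib);
              P[ia] += 1.0; P[ib] += 1.0;
              n += 2.0;
            }
          }
        }
        for (int t : touched) P[t] /= n;
        haralick17(P, touched, G, acc);
      }
      for (int k = 0; k < 17; ++k) tot[k] += acc[k];
      ++ncentres;
    }
  }
  if (ncentres == 0) stop("mask is empty");
  NumericVector out(17);
  for (int k = 0; k < 17; ++k) out[k] = tot[k] / ncentres;
  return out;
}
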