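// Sliding-window GLCM / run-length texture feature maps.
//
// Computes, for every pixel whose window x window neighborhood lies fully
// inside the image and contains no masked pixel (level < 0), the 28 texture
// features in the package's published order: 8 simple GLCM, 10 advanced
// GLCM, 10 gray-level run-length. Conventions mirror the R reference
// functions exactly (0-based levels, natural log, 0*log(0) = 0, run-length
// gray weights (g+1)^2, symmetric GLCM at one offset).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double xlogx(double p) { return p > 0.0 ? p * std::log(p) : 0.0; }

// [[Rcpp::export]]
NumericVector texture_maps_cpp(IntegerMatrix q, int G, int window,
                               int offr, int offc) {
  const int H = q.nrow(), W = q.ncol();
  const int half = window / 2;
  const int NF = 28;
  NumericVector out(static_cast<R_xlen_t>(H) * W * NF, NA_REAL);
  out.attr("dim") = Dimension(H, W, NF);

  std::vector<double> p(G * G);
  std::vector<double> px(G), py(G), psum(2 * G - 1), pdiff(G);
  const int lmax = window;
  std::vector<double> rl(G * lmax);
  std::vector<double> feat(NF);

  for (int c = half; c < W - half; ++c) {
    for (int r = half; r < H - half; ++r) {
      // validity scan
      bool ok = true;
      for (int wc = c - half; wc <= c + half && ok; ++wc)
        for (int wr = r - half; wr <= r + half; ++wr)
          if (q(wr, wc) < 0) { ok = false; break; }
      if (!ok) continue;

      // ---- GLCM (symmetric, one offset), normalized ----
      std::fill(p.begin(), p.end(), 0.0);
      double npairs = 0.0;
      for (int wc = c - half; wc <= c + half; ++wc) {
        int c2 = wc + offc;
        if (c2 < c - half || c2 > c + half) continue;
        for (int wr = r - half; wr <= r + half; ++wr) {
          int r2 = wr + offr;
          if (r2 < r - half || r2 > r + half) continue;
          int i = q(wr, wc), j = q(r2, c2);
          p[i + G * j] += 1.0;
          p[j + G * i] += 1.0;
          npairs += 2.0;
        }
      }
      if (npairs == 0.0) continue;
      for (int k = 0; k < G * G; ++k) p[k] /= npairs;

      // marginals
      std::fill(px.begin(), px.end(), 0.0);
      std::fill(py.begin(), py.end(), 0.0);
      std::fill(psum.begin(), psum.end(), 0.0);
      std::fill(pdiff.begin(), pdiff.end(), 0.0);
      for (int j = 0; j < G; ++j)
        for (int i = 0; i < G; ++i) {
          double v = p[i + G * j];
          if (v == 0.0) continue;
          px[i] += v; py[j] += v;
          psum[i + j] += v;
          pdiff[i > j ? i - j : j - i] += v;
        }
      double mux = 0, muy = 0;
      for (int i = 0; i < G; ++i) { mux += i * px[i]; muy += i * py[i]; }
      double vx = 0, vy = 0;
      for (int i = 0; i < G; ++i) {
        vx += (i - mux) * (i - mux) * px[i];
        vy += (i - muy) * (i - muy) * py[i];
      }
      double sdx = std::sqrt(vx), sdy = std::sqrt(vy);

      // ---- simple (8) ----
      double energy = 0, entropy = 0, corr_num = 0, idm = 0, inertia = 0;
      double shade = 0, prom = 0, sij = 0, mean_f = 0, variance = 0, dissim = 0;
      double hxy1 = 0;
      for (int j = 0; j < G; ++j)
        for (int i = 0; i < G; ++i) {
          double v = p[i + G * j];
          if (v == 0.0) continue;
          energy += v * v;
          entropy -= xlogx(v);
          corr_num += (i - mux) * (j - muy) * v;
          double dij = i - j;
          idm += v / (1.0 + dij * dij);
          inertia += dij * dij * v;
          double s = i + j - mux - muy;
          shade += s * s * s * v;
          prom += s * s * s * s * v;
          sij += double(i) * double(j) * v;
          mean_f += i * v;
          dissim += std::fabs(dij) * v;
          double pp = px[i] * py[j];
          if (pp > 0) hxy1 -= v * std::log(pp);
        }
      bool degen = (sdx < 1e-12 || sdy < 1e-12);
      double correlation = degen ? 0.0 : corr_num / (sdx * sdy);
      double hcorr = degen ? 0.0 : (sij - mux * mux) / vx;
      for (int j = 0; j < G; ++j)
        for (int i = 0; i < G; ++i) {
          double v = p[i + G * j];
          if (v == 0.0) continue;
          variance += (i - mean_f) * (i - mean_f) * v;
        }

      // ---- advanced (10) ----
      double sum_avg = 0, sum_var = 0, sum_ent = 0;
      for (int k = 0; k < 2 * G - 1; ++k) sum_avg += k * psum[k];
      for (int k = 0; k < 2 * G - 1; ++k) {
        sum_var += (k - sum_avg) * (k - sum_avg) * psum[k];
        sum_ent -= xlogx(psum[k]);
      }
      double diff_avg = 0, diff_var = 0, diff_ent = 0;
      for (int k = 0; k < G; ++k) diff_avg += k * pdiff[k];
      for (int k = 0; k < G; ++k) {
        diff_var += (k - diff_avg) * (k - diff_avg) * pdiff[k];
        diff_ent -= xlogx(pdiff[k]);
      }
      double hx = 0, hy = 0, hxy2 = 0;
      for (int i = 0; i < G; ++i) { hx -= xlogx(px[i]); hy -= xlogx(py[i]); }
      for (int j = 0; j < G; ++j)
        for (int i = 0; i < G; ++i) hxy2 -= xlogx(px[i] * py[j]);
      double hmax = hx > hy ? hx : hy;
      double ic1 = hmax < 1e-12 ? 0.0 : (entropy - hxy1) / hmax;
      double ic2arg = 1.0 - std::exp(-2.0 * (hxy2 - entropy));
      double ic2 = std::sqrt(ic2arg > 0.0 ? ic2arg : 0.0);

      // ---- run-length matrix along 45-degree diagonals ----
      std::fill(rl.begin(), rl.end(), 0.0);
      for (int s = 0; s < 2 * window - 1; ++s) {
        // local window coords: wr in [0, window), wc = s - wr
        int wr_hi = s < window ? s : window - 1;
        int wr_lo = s - (window - 1) > 0 ? s - (window - 1) : 0;
        int lev = -1, len = 0;
        for (int wr = wr_hi; wr >= wr_lo; --wr) {   // bottom-left -> top-right
          int v = q(r - half + wr, c - half + (s - wr));
          if (lev >= 0 && v == lev) {
            ++len;
          } else {
            if (len > 0) rl[lev + G * (len - 1)] += 1.0;
            lev = v; len = 1;
          }
        }
        if (len > 0) rl[lev + G * (len - 1)] += 1.0;
      }
      double Nr = 0;
      for (int k = 0; k < G * lmax; ++k) Nr += rl[k];
      double sre = 0, lre = 0, lgre = 0, hgre = 0, srlge = 0, srhge = 0, lrlge = 0;
      double gln = 0, rln = 0;
      for (int g = 0; g < G; ++g) {
        double rowsum = 0;
        for (int l = 1; l <= lmax; ++l) {
          double v = rl[g + G * (l - 1)];
          if (v == 0.0) continue;
          rowsum += v;
          double l2 = double(l) * l, g2 = double(g + 1) * (g + 1);
          sre += v / l2; lre += v * l2;
          lgre += v / g2; hgre += v * g2;
          srlge += v / (g2 * l2); srhge += v * g2 / l2;
          lrlge += v * l2 / g2;
        }
        gln += rowsum * rowsum;
      }
      for (int l = 0; l < lmax; ++l) {
        double colsum = 0;
        for (int g = 0; g < G; ++g) colsum += rl[g + G * l];
        rln += colsum * colsum;
      }
      double Np = double(window) * window;

      feat[0] = energy; feat[1] = entropy; feat[2] = correlation;
      feat[3] = idm; feat[4] = inertia; feat[5] = shade; feat[6] = prom;
      feat[7] = hcorr;
      feat[8] = mean_f; feat[9] = variance; feat[10] = dissim;
      feat[11] = sum_avg; feat[12] = sum_var; feat[13] = sum_ent;
      feat[14] = diff_var; feat[15] = diff_ent; feat[16] = ic1; feat[17] = ic2;
      feat[18] = sre / Nr; feat[19] = lre / Nr; feat[20] = gln / Nr;
      feat[21] = rln / Nr; feat[22] = Nr / Np; feat[23] = lgre / Nr;
      feat[24] = hgre / Nr; feat[25] = srlge / Nr; feat[26] = srhge / Nr;
      feat[27] = lrlge / Nr;

      for (int k = 0; k < NF; ++k)
        out[r + static_cast<R_xlen_t>(H) * (c + static_cast<R_xlen_t>(W) * k)] = feat[k];
    }
  }
  return out;
}
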