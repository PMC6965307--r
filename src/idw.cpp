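#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Inverse-distance-weighted interpolation at arbitrary query points from
// the k nearest samples, w = d^(-power).  A query within eps of a sample
// takes that sample's value exactly.  Neighbour search uses a uniform
// bin grid over the sample bounding box with an expanding ring sweep, so
// cost is near-linear in queries for evenly spread samples.
// [[Rcpp::export]]
NumericVector cpp_idw(NumericVector sx, NumericVector sy, NumericVector sv,
                      NumericVector qx, NumericVector qy,
                      double power, int k, double eps) {
  const int ns = sx.size();
  const R_xlen_t nq = qx.size();
  NumericVector out(nq);
  if (ns == 0) stop("no samples");
  if (k > ns) k = ns;

  // bin grid sized for ~2 samples per bin
  double xmin = sx[0], xmax = sx[0], ymin = sy[0], ymax = sy[0];
  for (int i = 1; i < ns; ++i) {
    xmin = std::min(xmin, sx[i]); xmax = std::max(xmax, sx[i]);
    ymin = std::min(ymin, sy[i]); ymax = std::max(ymax, sy[i]);
  }
  int nb = std::max(1, (int)std::floor(std::sqrt(ns / 2.0)));
  double spanx = std::max(xmax - xmin, 1e-12), spany = std::max(ymax - ymin, 1e-12);
  double bx = spanx / nb, by = spany / nb;
  std::vector<std::vector<int>> bins((size_t)nb * nb);
  auto binof = [&](double x, double y) {
    int ix = (int)((x - xmin) / bx); if (ix < 0) ix = 0; if (ix >= nb) ix = nb - 1;
    int iy = (int)((y - ymin) / by); if (iy < 0) iy = 0; if (iy >= nb) iy = nb - 1;
    return std::make_pair(ix, iy);
  };
  for (int i = 0; i < ns; ++i) {
    auto b = binof(sx[i], sy[i]);
    bins[(size_t)b.second * nb + b.first].push_back(i);
  }

  std::vector<double> bd(k);
  std::vector<int> bi(k);
  const double bmin = std::min(bx, by);

  for (R_xlen_t q = 0; q < nq; ++q) {
    int have = 0;
    double worst = R_PosInf;
    auto consider = [&](int i) {
      double dx = sx[i] - qx[q], dy = sy[i] - qy[q];
      double d2 = dx * dx + dy * dy;
      if (have < k) {
        bd[have] = d2; bi[have] = i; ++have;
        if (have == k) {
          worst = *std::max_element(bd.begin(), bd.end());
        }
      } else if (d2 < worst) {
        int wi = (int)(std::max_element(bd.begin(), bd.end()) - bd.begin());
        bd[wi] = d2; bi[wi] = i;
        worst = *std::max_element(bd.begin(), bd.end());
      }
    };
    int cx, cy;
    {
      auto b = binof(qx[q], qy[q]);
      cx = b.first; cy = b.second;
    }
    for (int ring = 0; ring < 2 * nb; ++ring) {
      int x0 = cx - ring, x1 = cx + ring, y0 = cy - ring, y1 = cy + ring;
      bool any = false;
      for (int iy = std::max(0, y0); iy <= std::min(nb - 1, y1); ++iy) {
        for (int ix = std::max(0, x0); ix <= std::min(nb - 1, x1); ++ix) {
          if (ring > 0 && ix > x0 && ix < x1 && iy > y0 && iy < y1) continue;
          any = true;
          for (int i : bins[(size_t)iy * nb + ix]) consider(i);
        }
      }
      // once k found, stop when the ring's guaranteed minimum distance
      // exceeds the current worst neighbour
      if (have == k) {
        double safe = ring * bmin;  // conservative lower bound for next rings
        if (safe * safe > worst) break;
      }
      if (!any && ring >= nb) break;
    }
    // exact hit?
    int hit = -1;
    for (int j = 0; j < have; ++j)
      if (bd[j] <= eps * eps) { hit = bi[j]; break; }
    if (hit >= 0) { out[q] = sv[hit]; continue; }
    double wsum = 0.0, vsum = 0.0;
    for (int j = 0; j < have; ++j) {
      double w = std::pow(std::sqrt(bd[j]), -power);
      wsum += w; vsum += w * sv[bi[j]];
    }
    out[q] = vsum / wsum;
  }
  return out;
}
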