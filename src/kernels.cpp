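#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a 0/1 mask. conn is 4 or 8.
// Labels are assigned in row-major discovery order starting at 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label(IntegerMatrix mask, int conn) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(1024);
  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = (conn == 8) ? 8 : 4;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < nnb; ++k) {
          int qi = pi + di8[k], qj = pj + dj8[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Fill holes: background is flood-filled (4-connectivity) from the image
// border; any background pixel not reached is interior and becomes 1.
// [[Rcpp::export]]
IntegerMatrix cpp_fill_holes(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  std::vector<char> seen((size_t)nr * nc, 0);
  std::vector<int> stack;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if ((i == 0 || i == nr - 1 || j == 0 || j == nc - 1) &&
          mask(i, j) == 0 && !seen[i + (size_t)j * nr]) {
        seen[i + (size_t)j * nr] = 1;
        stack.push_back(i + j * nr);
        while (!stack.empty()) {
          int p = stack.back(); stack.pop_back();
          int pi = p % nr, pj = p / nr;
          const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
          for (int k = 0; k < 4; ++k) {
            int qi = pi + di[k], qj = pj + dj[k];
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (mask(qi, qj) == 0 && !seen[qi + (size_t)qj * nr]) {
              seen[qi + (size_t)qj * nr] = 1;
              stack.push_back(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = (mask(i, j) != 0 || !seen[i + (size_t)j * nr]) ? 1 : 0;
  return out;
}

// Gradient circular Hough transform, two-stage variant.  Voting pixels
// (weight > 0) vote along the gradient direction (toward brighter
// intensity, i.e. toward the centre of a bright disk) at every integer
// radius of the band, each vote weighted by the pixel's normalised
// gradient magnitude.  Stage 1 sums the accumulators over all radii: an
// irregular (spiculated) boundary still concentrates its vote mass at the
// centre even though it spreads across radii.  Stage 2 re-votes per radius
// and assigns each centre the radius with the highest normalised score
// (3x3 box sum divided by the ideal circumference 2*pi*r).  Local maxima
// whose best score reaches scoreThresh and whose centre lies in centerMask
// are returned as rows (row, col, radius, score), 1-based coordinates.
// [[Rcpp::export]]
NumericMatrix cpp_cht(NumericMatrix gx, NumericMatrix gy,
                      NumericMatrix weight, IntegerMatrix centerMask,
                      IntegerVector radii, double scoreThresh) {
  int nr = gx.nrow(), nc = gx.ncol();
  std::vector<int> ei, ej;
  std::vector<double> ux, uy, wv;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (weight(i, j) > 0) {
        double m = std::sqrt(gx(i, j) * gx(i, j) + gy(i, j) * gy(i, j));
        if (m > 0) {
          ei.push_back(i); ej.push_back(j);
          ux.push_back(gx(i, j) / m); uy.push_back(gy(i, j) / m);
          wv.push_back(weight(i, j));
        }
      }
    }
  }
  int nrad = radii.size();
  std::vector<double> accSum((size_t)nr * nc, 0.0);
  for (int ri = 0; ri < nrad; ++ri) {
    int r = radii[ri];
    for (size_t k = 0; k < ei.size(); ++k) {
      int ci = (int)std::lround(ei[k] + r * ux[k]);
      int cj = (int)std::lround(ej[k] + r * uy[k]);
      if (ci >= 0 && ci < nr && cj >= 0 && cj < nc)
        accSum[ci + (size_t)cj * nr] += wv[k];
    }
  }
  // 3x3 box smoothing of the summed accumulator
  std::vector<double> sm((size_t)nr * nc, 0.0);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double sum = 0;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          int qi = i + di, qj = j + dj;
          if (qi >= 0 && qi < nr && qj >= 0 && qj < nc)
            sum += accSum[qi + (size_t)qj * nr];
        }
      sm[i + (size_t)j * nr] = sum;
    }
  }
  // stage-1 peaks: local maxima with at least the smallest circle's
  // worth of vote mass, centres inside the mask
  double minMass = scoreThresh * 2.0 * M_PI * radii[0];
  std::vector<int> pi, pj;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = sm[i + (size_t)j * nr];
      if (v < minMass || centerMask(i, j) == 0) continue;
      bool ismax = true;
      for (int dj = -1; dj <= 1 && ismax; ++dj) {
        for (int di = -1; di <= 1 && ismax; ++di) {
          if (di == 0 && dj == 0) continue;
          int qi = i + di, qj = j + dj;
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          double w = sm[qi + (size_t)qj * nr];
          // break plateau ties toward the earlier pixel (column-major)
          bool earlier = (qj < j) || (qj == j && qi < i);
          if (earlier ? (w >= v) : (w > v)) ismax = false;
        }
      }
      if (ismax) { pi.push_back(i); pj.push_back(j); }
    }
  }
  // stage 2: per-radius normalised score at each stage-1 centre
  size_t np = pi.size();
  std::vector<double> bestScore(np, 0.0);
  std::vector<int> bestR(np, radii[0]);
  std::vector<double> acc((size_t)nr * nc);
  for (int ri = 0; ri < nrad; ++ri) {
    int r = radii[ri];
    std::fill(acc.begin(), acc.end(), 0.0);
    for (size_t k = 0; k < ei.size(); ++k) {
      int ci = (int)std::lround(ei[k] + r * ux[k]);
      int cj = (int)std::lround(ej[k] + r * uy[k]);
      if (ci >= 0 && ci < nr && cj >= 0 && cj < nc)
        acc[ci + (size_t)cj * nr] += wv[k];
    }
    double norm = 2.0 * M_PI * r;
    for (size_t p = 0; p < np; ++p) {
      double sum = 0;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          int qi = pi[p] + di, qj = pj[p] + dj;
          if (qi >= 0 && qi < nr && qj >= 0 && qj < nc)
            sum += acc[qi + (size_t)qj * nr];
        }
      double sc = sum / norm;
      if (sc > bestScore[p]) { bestScore[p] = sc; bestR[p] = r; }
    }
  }
  std::vector<size_t> keep;
  for (size_t p = 0; p < np; ++p)
    if (bestScore[p] >= scoreThresh) keep.push_back(p);
  NumericMatrix out(keep.size(), 4);
  for (size_t k = 0; k < keep.size(); ++k) {
    size_t p = keep[k];
    out(k, 0) = pi[p] + 1; out(k, 1) = pj[p] + 1;
    out(k, 2) = bestR[p]; out(k, 3) = bestScore[p];
  }
  colnames(out) = CharacterVector::create("row", "col", "radius_px", "score");
  return out;
}

// Online 1D-chain self-organizing map.  X is n x d (samples in rows),
// initIdx / order are 1-based index vectors prepared (seeded) in R so the
// whole run is deterministic.  Learning rate and neighbourhood radius decay
// exponentially from their initial to final values over all steps.
// [[Rcpp::export]]
NumericMatrix cpp_som_train(NumericMatrix X, int nNodes, IntegerVector initIdx,
                            IntegerVector order, double lr0, double lr1,
                            double nbr0, double nbr1) {
  int d = X.ncol();
  NumericMatrix W(nNodes, d);
  for (int k = 0; k < nNodes; ++k)
    for (int c = 0; c < d; ++c) W(k, c) = X(initIdx[k] - 1, c);
  R_xlen_t T = order.size();
  for (R_xlen_t t = 0; t < T; ++t) {
    double frac = (T > 1) ? (double)t / (double)(T - 1) : 0.0;
    double lr = lr0 * std::pow(lr1 / lr0, frac);
    double nbr = nbr0 * std::pow(nbr1 / nbr0, frac);
    int s = order[t] - 1;
    int win = 0; double best = R_PosInf;
    for (int k = 0; k < nNodes; ++k) {
      double dd = 0;
      for (int c = 0; c < d; ++c) {
        double e = X(s, c) - W(k, c); dd += e * e;
      }
      if (dd < best) { best = dd; win = k; }
    }
    for (int k = 0; k < nNodes; ++k) {
      double h = std::exp(-0.5 * (k - win) * (k - win) / (nbr * nbr));
      double a = lr * h;
      if (a < 1e-8) continue;
      for (int c = 0; c < d; ++c) W(k, c) += a * (X(s, c) - W(k, c));
    }
  }
  return W;
}
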