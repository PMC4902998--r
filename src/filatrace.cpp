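#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

// 8 neighbours: row offsets / col offsets, axial first
static const int DR8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DC8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
static const int DR4[4] = {-1, 1, 0, 0};
static const int DC4[4] = {0, 0, -1, 1};

// Connected-component labelling by flood fill. connectivity = 4 or 8.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int *dr = (connectivity == 8) ? DR8 : DR4;
  const int *dc = (connectivity == 8) ? DC8 : DC4;
  int nn = (connectivity == 8) ? 8 : 4;
  int next_label = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next_label;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next_label;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int ni = ci + dr[k], nj = cj + dc[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next_label;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  }
  return lab;
}

static inline int getpix(const LogicalMatrix &m, int i, int j) {
  if (i < 0 || i >= m.nrow() || j < 0 || j >= m.ncol()) return 0;
  return m(i, j) ? 1 : 0;
}

// Neighbours p2..p9 clockwise from north (p2 = (i-1,j)).
static inline void neighbours(const LogicalMatrix &m, int i, int j, int p[10]) {
  p[2] = getpix(m, i - 1, j);
  p[3] = getpix(m, i - 1, j + 1);
  p[4] = getpix(m, i, j + 1);
  p[5] = getpix(m, i + 1, j + 1);
  p[6] = getpix(m, i + 1, j);
  p[7] = getpix(m, i + 1, j - 1);
  p[8] = getpix(m, i, j - 1);
  p[9] = getpix(m, i - 1, j - 1);
}

// Hilditch crossing number: 1 iff the pixel is 8-simple.
static inline int crossing(const int p[10]) {
  return ((!p[2]) && (p[3] || p[4])) + ((!p[4]) && (p[5] || p[6])) +
         ((!p[6]) && (p[7] || p[8])) + ((!p[8]) && (p[9] || p[2]));
}

// Guo-Hall homotopic thinning to a one-pixel-wide, 8-connected skeleton.
// A final cleanup removes simple pixels still sitting in 2x2 solid blocks.
// [[Rcpp::export(name = ".thin_cpp")]]
LogicalMatrix thin_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix m = clone(mask);
  int p[10];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int iter = 0; iter < 2; ++iter) {
      std::vector<int> kill;
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!m(i, j)) continue;
          neighbours(m, i, j, p);
          int C = crossing(p);
          int N1 = (p[9] || p[2]) + (p[3] || p[4]) + (p[5] || p[6]) + (p[7] || p[8]);
          int N2 = (p[2] || p[3]) + (p[4] || p[5]) + (p[6] || p[7]) + (p[8] || p[9]);
          int N = N1 < N2 ? N1 : N2;
          int cm = (iter == 0) ? ((p[6] || p[7] || !p[9]) && p[8])
                               : ((p[2] || p[3] || !p[5]) && p[4]);
          if (C == 1 && N >= 2 && N <= 3 && cm == 0)
            kill.push_back(i + j * nr);
        }
      }
      for (size_t k = 0; k < kill.size(); ++k)
        m(kill[k] % nr, kill[k] / nr) = false;
      if (!kill.empty()) changed = true;
    }
  }
  // break residual 2x2 solid blocks without changing topology
  changed = true;
  while (changed) {
    changed = false;
    for (int j = 0; j < nc - 1 && !changed; ++j) {
      for (int i = 0; i < nr - 1 && !changed; ++i) {
        if (!(m(i, j) && m(i + 1, j) && m(i, j + 1) && m(i + 1, j + 1))) continue;
        int ci[4] = {i, i + 1, i, i + 1};
        int cj[4] = {j, j, j + 1, j + 1};
        for (int k = 0; k < 4; ++k) {
          neighbours(m, ci[k], cj[k], p);
          int B = p[2] + p[3] + p[4] + p[5] + p[6] + p[7] + p[8] + p[9];
          if (crossing(p) == 1 && B >= 2) {
            m(ci[k], cj[k]) = false;
            changed = true;
            break;
          }
        }
      }
    }
  }
  return m;
}

// Geodesic distance over the skeleton pixels with quasi-euclidean steps:
// cost 1 for axial moves, sqrt(2) for diagonal moves. Dijkstra from origin
// (0-based row/col). Off-skeleton and unreachable pixels get +Inf.
// [[Rcpp::export(name = ".geodesic_cpp")]]
NumericMatrix geodesic_cpp(LogicalMatrix mask, int origin_row, int origin_col) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix dist(nr, nc);
  std::fill(dist.begin(), dist.end(), R_PosInf);
  if (origin_row < 0 || origin_row >= nr || origin_col < 0 || origin_col >= nc ||
      !mask(origin_row, origin_col))
    stop("origin must lie on the skeleton");
  const double SQRT2 = std::sqrt(2.0);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  dist(origin_row, origin_col) = 0.0;
  pq.push(QE(0.0, origin_row + origin_col * nr));
  while (!pq.empty()) {
    double d = pq.top().first;
    int idx = pq.top().second;
    pq.pop();
    int i = idx % nr, j = idx / nr;
    if (d > dist(i, j)) continue;
    for (int k = 0; k < 8; ++k) {
      int ni = i + DR8[k], nj = j + DC8[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc || !mask(ni, nj)) continue;
      double nd = d + (k < 4 ? 1.0 : SQRT2);
      if (nd < dist(ni, nj)) {
        dist(ni, nj) = nd;
        pq.push(QE(nd, ni + nj * nr));
      }
    }
  }
  return dist;
}

// Count of 8-neighbours for every true pixel (0 elsewhere); endpoints have 1.
// [[Rcpp::export(name = ".neighbour_count_cpp")]]
IntegerMatrix neighbour_count_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix cnt(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int b = 0;
      for (int k = 0; k < 8; ++k)
        b += getpix(mask, i + DR8[k], j + DC8[k]);
      cnt(i, j) = b;
    }
  return cnt;
}
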