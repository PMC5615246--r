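#include <Rcpp.h>

#include <algorithm>
#include <cmath>
#include <deque>
#include <vector>

using namespace Rcpp;

namespace {

// One rectangle of the adaptive partition: half-open [xlo,xhi) x [ylo,yhi)
// in 0-based rank coordinates, plus the indices of the points it contains.
struct Rect {
  int xlo, xhi, ylo, yhi;
  std::vector<int> pts;
};

// Breadth-first adaptive partitioning of the 2-D rank plane.
//
// A FIFO queue replaces the usual recursion: rectangles are popped,
// chi-square tested against local uniformity, and either split at the
// integer midpoints of their rank intervals or scored as leaves.  Empty
// quadrants are dropped immediately (their contribution is zero), which is
// what keeps the queue within its M - 3 bound.
//
// Leaf contributions are collected and sorted before summation so the
// estimate is exactly invariant under swapping the two variables (the leaf
// multiset is symmetric under the axis swap; only the traversal order is
// not).
double apmi_core(const std::vector<int>& xr, const std::vector<int>& yr,
                 double chi2_crit, int min_points, int* max_queue) {
  const int M = static_cast<int>(xr.size());
  std::deque<Rect> queue;
  Rect root;
  root.xlo = 0; root.xhi = M; root.ylo = 0; root.yhi = M;
  root.pts.resize(M);
  for (int i = 0; i < M; ++i) root.pts[i] = i;
  queue.push_back(std::move(root));
  size_t maxq = 1;

  std::vector<double> leaf_terms;
  while (!queue.empty()) {
    Rect rect = std::move(queue.front());
    queue.pop_front();
    const int n = static_cast<int>(rect.pts.size());
    const int wx = rect.xhi - rect.xlo;
    const int wy = rect.yhi - rect.ylo;

    bool split = false;
    if (n >= min_points && wx >= 2 && wy >= 2) {
      const int xm = (rect.xlo + rect.xhi) / 2;
      const int ym = (rect.ylo + rect.yhi) / 2;
      std::vector<int> qpts[4];
      for (int id : rect.pts) {
        const int qx = (xr[id] < xm) ? 0 : 1;
        const int qy = (yr[id] < ym) ? 0 : 1;
        qpts[qy * 2 + qx].push_back(id);
      }
      const double expected = n / 4.0;
      double T = 0.0;
      for (int q = 0; q < 4; ++q) {
        const double d = static_cast<double>(qpts[q].size()) - expected;
        T += d * d / expected;
      }
      if (T > chi2_crit) {
        split = true;
        const int xb[4] = {rect.xlo, xm, rect.xlo, xm};
        const int xe[4] = {xm, rect.xhi, xm, rect.xhi};
        const int yb[4] = {rect.ylo, rect.ylo, ym, ym};
        const int ye[4] = {ym, ym, rect.yhi, rect.yhi};
        for (int q = 0; q < 4; ++q) {
          if (qpts[q].empty()) continue;
          Rect child;
          child.xlo = xb[q]; child.xhi = xe[q];
          child.ylo = yb[q]; child.yhi = ye[q];
          child.pts = std::move(qpts[q]);
          queue.push_back(std::move(child));
        }
        if (queue.size() > maxq) maxq = queue.size();
      }
    }

    if (!split && n > 0) {
      leaf_terms.push_back((static_cast<double>(n) / M) *
                           std::log(static_cast<double>(n) * M /
                                    (static_cast<double>(wx) * wy)));
    }
  }

  std::sort(leaf_terms.begin(), leaf_terms.end());
  double mi = 0.0;
  for (double t : leaf_terms) mi += t;
  if (max_queue) *max_queue = static_cast<int>(maxq);
  return mi < 0.0 ? 0.0 : mi;
}

}  // namespace

// [[Rcpp::export(name = ".apmi_pair_cpp")]]
List apmi_pair_cpp(IntegerVector x, IntegerVector y, double chi2_crit,
                   int min_points) {
  std::vector<int> xr(x.begin(), x.end());
  std::vector<int> yr(y.begin(), y.end());
  int maxq = 0;
  const double mi = apmi_core(xr, yr, chi2_crit, min_points, &maxq);
  return List::create(_["mi"] = mi, _["max_queue_length"] = maxq);
}

// Batch evaluation over pairs of rows of a rank matrix (genes x samples),
// used for the candidate MI matrix and for null-model sampling where the
// per-call overhead of an R loop would dominate.
// [[Rcpp::export(name = ".apmi_batch_cpp")]]
NumericVector apmi_batch_cpp(IntegerMatrix ranks, IntegerVector rows_x,
                             IntegerVector rows_y, double chi2_crit,
                             int min_points) {
  const int M = ranks.ncol();
  const int npair = rows_x.size();
  if (rows_y.size() != npair) stop("rows_x and rows_y differ in length");
  NumericVector out(npair);
  std::vector<int> xr(M), yr(M);
  for (int p = 0; p < npair; ++p) {
    const int rx = rows_x[p] - 1;
    const int ry = rows_y[p] - 1;
    if (rx < 0 || rx >= ranks.nrow() || ry < 0 || ry >= ranks.nrow())
      stop("row index out of range");
    for (int j = 0; j < M; ++j) {
      xr[j] = ranks(rx, j);
      yr[j] = ranks(ry, j);
    }
    out[p] = apmi_core(xr, yr, chi2_crit, min_points, nullptr);
  }
  return out;
}
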