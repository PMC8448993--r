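// Exact weighted simple quantile regression.
//
// Minimises the weighted check (pinball) loss
//     L(a, b) = sum_i w_i * rho_tau(y_i - a - b x_i),
//     rho_tau(u) = u * (tau - 1{u < 0}),
// over intercept a and slope b for a single covariate.  The objective is
// piecewise-linear convex; an optimum is attained at a vertex where the
// fitted line interpolates two observations.  The solver pivots between
// vertices: a rotation about an interpolated point is an exact line search
// whose minimiser is a weighted quantile of the pairwise slopes through
// that point, computed by O(n) quickselect.  Pivoting stops when rotations
// about both interpolated points fail to improve; for a piecewise-linear
// convex function in two variables whose only kinks at the vertex are the
// two zero-residual observations this certifies global optimality.  Among
// equal-loss vertices the move rule prefers the smaller slope, so ties
// resolve to the lexicographically smallest-slope optimal vertex.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Cand {
  double s;  // candidate slope (or intercept-step value)
  double u;  // positive weight attached to the breakpoint
  int idx;   // index of the generating observation
};

// Smallest value s* in c such that sum of u over { s <= s* } >= t.
// Three-way-partition quickselect, expected O(n).  c is permuted.
const Cand &wq_select(std::vector<Cand> &c, double t) {
  size_t lo = 0, hi = c.size();
  double acc = 0.0;
  while (hi - lo > 1) {
    const double a0 = c[lo].s, a1 = c[lo + (hi - lo) / 2].s, a2 = c[hi - 1].s;
    const double p = std::max(std::min(a0, a1), std::min(std::max(a0, a1), a2));
    size_t i = lo, lt = lo, gt = hi;
    double w_less = 0.0, w_eq = 0.0;
    while (i < gt) {
      if (c[i].s < p) {
        std::swap(c[i], c[lt]);
        w_less += c[lt].u;
        ++lt;
        ++i;
      } else if (c[i].s > p) {
        --gt;
        std::swap(c[i], c[gt]);
      } else {
        w_eq += c[i].u;
        ++i;
      }
    }
    if (acc + w_less >= t && lt > lo) {
      hi = lt;
    } else if (acc + w_less + w_eq >= t || gt >= hi) {
      return c[lt];  // an element of the equal-to-pivot block
    } else {
      acc += w_less + w_eq;
      lo = gt;
    }
  }
  return c[lo];
}

double check_loss(int n, const double *x, const double *y, const double *w,
                  double tau, double a, double b) {
  double loss = 0.0;
  for (int i = 0; i < n; ++i) {
    const double u = y[i] - a - b * x[i];
    loss += w[i] * (u >= 0 ? tau * u : (tau - 1.0) * u);
  }
  return loss;
}

struct Workspace {
  std::vector<Cand> cand;
};

// Exact line search over lines through observation `pivot`: returns the
// minimising slope and the second interpolated observation.  Returns false
// when every x equals x[pivot] (rotation undefined).
bool rotate(int n, const double *x, const double *y, const double *w,
            double tau, int pivot, Workspace &ws, double &b_out, int &j_out) {
  const double x0 = x[pivot], y0 = y[pivot];
  ws.cand.clear();
  double sum_wd = 0.0, sum_neg = 0.0;
  for (int i = 0; i < n; ++i) {
    const double d = x[i] - x0;
    if (d == 0.0) continue;
    const double e = y[i] - y0;
    const double uw = w[i] * std::fabs(d);
    sum_wd += w[i] * d;
    if (d < 0.0) sum_neg += uw;
    ws.cand.push_back(Cand{e / d, uw, i});
  }
  if (ws.cand.empty()) return false;
  double t = tau * sum_wd + sum_neg;
  double tot = 0.0;
  for (const Cand &c : ws.cand) tot += c.u;
  // Nudge toward the lower end of any flat optimal interval.
  t -= 1e-9 * tot;
  if (t <= 0.0) t = 1e-12 * tot;
  if (t > tot) t = tot;
  const Cand &sel = wq_select(ws.cand, t);
  b_out = sel.s;
  j_out = sel.idx;
  return true;
}

}  // namespace

// Fit one quantile.  b_init seeds the search (e.g. the OLS slope or the
// solution at a neighbouring quantile).  Returns a, b, loss, converged,
// iterations.
// [[Rcpp::export(name = ".qr_fit_cpp")]]
List qr_fit_cpp(NumericVector x, NumericVector y, NumericVector w, double tau,
                double b_init, int max_iter = 200) {
  const int n = x.size();
  if (n < 2) stop("need at least 2 observations");
  if (y.size() != n || w.size() != n) stop("length mismatch");
  if (!(tau > 0.0 && tau < 1.0)) stop("tau must be in (0, 1)");
  const double *px = REAL(x), *py = REAL(y), *pw = REAL(w);

  Workspace ws;
  ws.cand.reserve(n);

  // Initial intercept: weighted tau-quantile of y - b_init * x.
  double wtot = 0.0;
  for (int i = 0; i < n; ++i) wtot += pw[i];
  ws.cand.clear();
  for (int i = 0; i < n; ++i)
    ws.cand.push_back(Cand{py[i] - b_init * px[i], pw[i], i});
  double t0 = tau * wtot - 1e-9 * wtot;
  if (t0 <= 0.0) t0 = 1e-12 * wtot;
  const Cand &c0 = wq_select(ws.cand, t0);
  int pivot = c0.idx;
  double b = b_init;
  double a = py[pivot] - b * px[pivot];

  double best = check_loss(n, px, py, pw, tau, a, b);
  const double ltol = 1e-12 * std::max(1.0, best);
  int other = -1;
  int fails = 0;
  bool converged = false;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    double b_new;
    int j;
    if (!rotate(n, px, py, pw, tau, pivot, ws, b_new, j)) {
      stop("degenerate design: covariate has zero variance");
    }
    const double a_new = py[pivot] - b_new * px[pivot];
    const double L = check_loss(n, px, py, pw, tau, a_new, b_new);
    const bool improves = L < best - ltol;
    const bool tie_smaller = (L < best + ltol) && (b_new < b - 1e-12);
    if (improves || tie_smaller) {
      a = a_new;
      b = b_new;
      if (L < best) best = L;
      other = pivot;
      pivot = j;
      fails = 0;
    } else {
      ++fails;
      if (other < 0 || fails >= 2) {
        converged = true;
        break;
      }
      std::swap(pivot, other);
    }
  }
  return List::create(_["intercept"] = a, _["slope"] = b, _["loss"] = best,
                      _["converged"] = converged, _["iterations"] = iter);
}

// Fit a whole grid of quantiles on one data set, warm-starting each fit
// from the previous quantile's slope.  Returns a matrix with columns
// intercept, slope, loss, converged.
// [[Rcpp::export(name = ".qr_fit_grid_cpp")]]
NumericMatrix qr_fit_grid_cpp(NumericVector x, NumericVector y,
                              NumericVector w, NumericVector taus,
                              double b_init, int max_iter = 200) {
  const int m = taus.size();
  NumericMatrix out(m, 4);
  colnames(out) = CharacterVector::create("intercept", "slope", "loss",
                                          "converged");
  double b_prev = b_init;
  for (int k = 0; k < m; ++k) {
    List f = qr_fit_cpp(x, y, w, taus[k], b_prev, max_iter);
    out(k, 0) = as<double>(f["intercept"]);
    out(k, 1) = as<double>(f["slope"]);
    out(k, 2) = as<double>(f["loss"]);
    out(k, 3) = as<bool>(f["converged"]) ? 1.0 : 0.0;
    b_prev = out(k, 1);
  }
  return out;
}
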