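// Compiled kernels: Gaussian-atom density synthesis, footprint mask
// enumeration, RMSD-threshold deduplication, and the exact subset-
// enumeration MIQP used for cardinality-constrained occupancy selection.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Density of a sum of isotropic Gaussian atoms at arbitrary points.
// rho_a(r) = Z * (4*pi/B)^{3/2} * exp(-4*pi^2 r^2 / B), B = B_atom + B_blur.
// Each atom integrates to Z electrons.
// [[Rcpp::export]]
NumericVector cpp_atom_density(NumericMatrix points, NumericMatrix coords,
                               NumericVector zel, NumericVector beff) {
  const int m = points.nrow(), n = coords.nrow();
  const double fourpi = 4.0 * M_PI;
  const double fourpi2 = 4.0 * M_PI * M_PI;
  NumericVector out(m);
  std::vector<double> amp(n), k(n), rcut2(n);
  for (int a = 0; a < n; ++a) {
    const double b = beff[a];
    amp[a] = zel[a] * std::pow(fourpi / b, 1.5);
    k[a] = fourpi2 / b;
    rcut2[a] = 18.42 / k[a];  // exp(-18.42) ~ 1e-8: negligible beyond
  }
  for (int a = 0; a < n; ++a) {
    const double xa = coords(a, 0), ya = coords(a, 1), za = coords(a, 2);
    const double ka = k[a], am = amp[a], rc = rcut2[a];
    for (int p = 0; p < m; ++p) {
      const double dx = points(p, 0) - xa;
      const double dy = points(p, 1) - ya;
      const double dz = points(p, 2) - za;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < rc) out[p] += am * std::exp(-ka * d2);
    }
  }
  return out;
}

// Linear indices (1-based) of voxels whose center lies within `radius` of
// any atom. dim/spacing/origin define the grid; duplicates possible.
// [[Rcpp::export]]
IntegerVector cpp_mask_indices(NumericMatrix coords, IntegerVector dim,
                               NumericVector spacing, NumericVector origin,
                               double radius) {
  std::vector<int> idx;
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double r2 = radius * radius;
  for (int a = 0; a < coords.nrow(); ++a) {
    const double xa = coords(a, 0), ya = coords(a, 1), za = coords(a, 2);
    int i0 = (int)std::ceil((xa - radius - origin[0]) / spacing[0]);
    int i1 = (int)std::floor((xa + radius - origin[0]) / spacing[0]);
    int j0 = (int)std::ceil((ya - radius - origin[1]) / spacing[1]);
    int j1 = (int)std::floor((ya + radius - origin[1]) / spacing[1]);
    int k0 = (int)std::ceil((za - radius - origin[2]) / spacing[2]);
    int k1 = (int)std::floor((za + radius - origin[2]) / spacing[2]);
    i0 = std::max(i0, 0); i1 = std::min(i1, nx - 1);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);
    k0 = std::max(k0, 0); k1 = std::min(k1, nz - 1);
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * spacing[2] - za;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * spacing[1] - ya;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * spacing[0] - xa;
          if (dx * dx + dy * dy + dz * dz <= r2)
            idx.push_back(1 + i + nx * (j + ny * k));
        }
      }
    }
  }
  return wrap(idx);
}

// Greedy RMSD deduplication: rows of X are flattened conformers in
// processing order; keep a row iff its in-place RMSD to every previously
// kept row is >= thresh.
// [[Rcpp::export]]
LogicalVector cpp_dedup_keep(NumericMatrix X, double thresh) {
  const int n = X.nrow(), m = X.ncol();
  const int natom = m / 3;
  const double lim = thresh * thresh * natom;  // sum of squared diffs
  LogicalVector keep(n);
  std::vector<int> kept;
  for (int i = 0; i < n; ++i) {
    bool ok = true;
    for (size_t q = 0; q < kept.size() && ok; ++q) {
      const int j = kept[q];
      double s = 0.0;
      for (int c = 0; c < m; ++c) {
        const double d = X(i, c) - X(j, c);
        s += d * d;
        if (s >= lim) break;
      }
      if (s < lim) ok = false;
    }
    keep[i] = ok;
    if (ok) kept.push_back(i);
  }
  return keep;
}

// ---- exact small QP and subset-enumeration MIQP --------------------------
//
// Objective: rss(w) = w' G w - 2 c' w + bsq, G = M M' (conformer maps),
// c = M rho_obs. MIQP constraints: at most `card` nonzero weights, each in
// [tmin, 1], sum(w) <= 1. Solved exactly by enumerating supports of size
// <= card and, per support, enumerating KKT active sets of the small box-
// and-sum-constrained QP (<= 3^k states x sum on/off, k <= card).

static bool solve_linear(std::vector<double>& A, std::vector<double>& rhs,
                         int n) {
  // Gaussian elimination with partial pivoting; A is n x n row-major.
  for (int col = 0; col < n; ++col) {
    int piv = col;
    double best = std::fabs(A[col * n + col]);
    for (int r = col + 1; r < n; ++r) {
      const double v = std::fabs(A[r * n + col]);
      if (v > best) { best = v; piv = r; }
    }
    if (best < 1e-12) return false;
    if (piv != col) {
      for (int cc = 0; cc < n; ++cc) std::swap(A[col * n + cc], A[piv * n + cc]);
      std::swap(rhs[col], rhs[piv]);
    }
    for (int r = col + 1; r < n; ++r) {
      const double f = A[r * n + col] / A[col * n + col];
      if (f == 0.0) continue;
      for (int cc = col; cc < n; ++cc) A[r * n + cc] -= f * A[col * n + cc];
      rhs[r] -= f * rhs[col];
    }
  }
  for (int r = n - 1; r >= 0; --r) {
    double s = rhs[r];
    for (int cc = r + 1; cc < n; ++cc) s -= A[r * n + cc] * rhs[cc];
    rhs[r] = s / A[r * n + r];
  }
  return true;
}

// Exact minimizer of w' G w - 2 c' w over {tmin <= w_i <= 1, sum w <= 1}
// for k <= 8 variables by KKT active-set enumeration. Returns objective
// (without bsq) and fills w; returns false if infeasible (k * tmin > 1).
static bool small_box_qp(const std::vector<double>& G,
                         const std::vector<double>& c, int k, double tmin,
                         std::vector<double>& w, double& obj) {
  if (k * tmin > 1.0 + 1e-12) return false;
  const double eps = 1e-9;
  double best = R_PosInf;
  std::vector<double> wbest(k, tmin);
  bool found = false;
  std::vector<int> state(k);  // 0 = at tmin, 1 = at 1, 2 = free
  int nstates = 1;
  for (int i = 0; i < k; ++i) nstates *= 3;
  for (int sum_active = 0; sum_active <= 1; ++sum_active) {
    for (int s = 0; s < nstates; ++s) {
      int t = s;
      for (int i = 0; i < k; ++i) { state[i] = t % 3; t /= 3; }
      std::vector<int> freev;
      std::vector<double> wtry(k);
      double fixed_sum = 0.0;
      for (int i = 0; i < k; ++i) {
        if (state[i] == 0) { wtry[i] = tmin; fixed_sum += tmin; }
        else if (state[i] == 1) { wtry[i] = 1.0; fixed_sum += 1.0; }
        else freev.push_back(i);
      }
      const int nf = (int)freev.size();
      const int dim = nf + sum_active;
      double lambda = 0.0;
      if (dim > 0) {
        // KKT: 2 G_FF w_F + lambda 1 = 2 c_F - 2 G_FB w_B ; [1' w = 1]
        std::vector<double> A(dim * dim, 0.0), rhs(dim, 0.0);
        for (int r = 0; r < nf; ++r) {
          const int i = freev[r];
          for (int cc = 0; cc < nf; ++cc)
            A[r * dim + cc] = 2.0 * G[i * k + freev[cc]];
          if (sum_active) A[r * dim + nf] = 1.0;
          double b = 2.0 * c[i];
          for (int j = 0; j < k; ++j)
            if (state[j] != 2) b -= 2.0 * G[i * k + j] * wtry[j];
          rhs[r] = b;
        }
        if (sum_active) {
          for (int cc = 0; cc < nf; ++cc) A[nf * dim + cc] = 1.0;
          rhs[nf] = 1.0 - fixed_sum;
        }
        if (!solve_linear(A, rhs, dim)) continue;
        for (int r = 0; r < nf; ++r) wtry[freev[r]] = rhs[r];
        if (sum_active) lambda = rhs[nf];
      } else if (sum_active) {
        if (std::fabs(fixed_sum - 1.0) > eps) continue;
        // no free variables: lambda lives in the interval allowed by the
        // bound multipliers; pick the smallest nonnegative feasible value
        double lo = 0.0, hi = R_PosInf;
        for (int i = 0; i < k; ++i) {
          double gi0 = -2.0 * c[i];
          for (int j = 0; j < k; ++j) gi0 += 2.0 * G[i * k + j] * wtry[j];
          if (state[i] == 0) lo = std::max(lo, -gi0);
          else hi = std::min(hi, -gi0);
        }
        if (lo > hi + 1e-7) continue;
        lambda = lo;
      }
      // primal feasibility
      bool ok = true;
      double tot = 0.0;
      for (int i = 0; i < k && ok; ++i) {
        if (wtry[i] < tmin - eps || wtry[i] > 1.0 + eps) ok = false;
        tot += wtry[i];
      }
      if (!ok) continue;
      if (!sum_active && tot > 1.0 + eps) continue;
      if (sum_active && lambda < -eps) continue;
      // dual feasibility at the bounds: g_i = 2(Gw - c)_i + lambda
      for (int i = 0; i < k && ok; ++i) {
        double gi = lambda;
        for (int j = 0; j < k; ++j) gi += 2.0 * G[i * k + j] * wtry[j];
        gi -= 2.0 * c[i];
        if (state[i] == 0 && gi < -1e-7) ok = false;       // at tmin
        else if (state[i] == 1 && gi > 1e-7) ok = false;   // at 1
      }
      if (!ok) continue;
      double f = 0.0;
      for (int i = 0; i < k; ++i) {
        double gw = 0.0;
        for (int j = 0; j < k; ++j) gw += G[i * k + j] * wtry[j];
        f += wtry[i] * gw - 2.0 * c[i] * wtry[i];
      }
      if (f < best - 1e-12) { best = f; wbest = wtry; found = true; }
    }
  }
  if (!found) return false;
  w = wbest;
  obj = best;
  return true;
}

// [[Rcpp::export]]
List cpp_miqp_enum(NumericMatrix G, NumericVector c, double bsq,
                   double tmin, int card) {
  const int n = G.nrow();
  card = std::min(card, n);
  // baseline: empty selection, w = 0, rss = |rho_obs|^2
  double best = bsq;
  std::vector<int> best_sel;
  std::vector<double> best_w;
  std::vector<int> sel(card);
  std::vector<double> Gs, cs, w;
  // enumerate supports in size order, lexicographic within each size, and
  // accept strict improvements only -> lexicographically smallest optimum.
  for (int k = 1; k <= card; ++k) {
    std::vector<int> comb(k);
    for (int i = 0; i < k; ++i) comb[i] = i;
    while (true) {
      Gs.assign(k * k, 0.0);
      cs.assign(k, 0.0);
      for (int r = 0; r < k; ++r) {
        cs[r] = c[comb[r]];
        for (int cc = 0; cc < k; ++cc)
          Gs[r * k + cc] = G(comb[r], comb[cc]);
      }
      double obj;
      if (small_box_qp(Gs, cs, k, tmin, w, obj)) {
        const double rss = obj + bsq;
        if (rss < best - 1e-12) {
          best = rss;
          best_sel.assign(comb.begin(), comb.end());
          best_w = w;
        }
      }
      // next combination
      int pos = k - 1;
      while (pos >= 0 && comb[pos] == n - k + pos) --pos;
      if (pos < 0) break;
      ++comb[pos];
      for (int i = pos + 1; i < k; ++i) comb[i] = comb[i - 1] + 1;
      Rcpp::checkUserInterrupt();
    }
  }
  NumericVector wfull(n);
  for (size_t i = 0; i < best_sel.size(); ++i)
    wfull[best_sel[i]] = best_w[i];
  IntegerVector selR(best_sel.begin(), best_sel.end());
  return List::create(_["weights"] = wfull, _["selected"] = selR + 1,
                      _["objective"] = best);
}
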