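// Sparse iterative solver and point-correspondence kernels.
// Kept in C++ because they dominate the run time of the FEM registration.
// The solver works directly on the CSC slots (p, i, x) of a Matrix::dgCMatrix,
// avoiding any copy or index-width conversion.

#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

static inline void csc_matvec(const IntegerVector& Ap, const IntegerVector& Ai,
                              const NumericVector& Ax,
                              const std::vector<double>& x,
                              std::vector<double>& y) {
  const int n = static_cast<int>(x.size());
  std::fill(y.begin(), y.end(), 0.0);
  for (int col = 0; col < n; ++col) {
    const double xc = x[col];
    if (xc == 0.0) continue;
    const int start = Ap[col], end = Ap[col + 1];
    for (int k = start; k < end; ++k) y[Ai[k]] += Ax[k] * xc;
  }
}

static inline double nrm2(const std::vector<double>& v) {
  double s = 0.0;
  for (double q : v) s += q * q;
  return std::sqrt(s);
}

static inline double dot(const std::vector<double>& a,
                         const std::vector<double>& b) {
  double s = 0.0;
  for (size_t k = 0; k < a.size(); ++k) s += a[k] * b[k];
  return s;
}

// Incomplete Cholesky IC(0) on the lower triangle of a symmetric CSC matrix.
// Factor stored CSC by column, rows sorted ascending (diagonal first).
struct IC0 {
  int n = 0;
  bool ok = false;
  std::vector<int> p, i;     // CSC of L (lower, incl. diagonal)
  std::vector<double> x;
};

static bool ic0_factor(const IntegerVector& Ap, const IntegerVector& Ai,
                       const NumericVector& Ax, double shift, IC0& L) {
  const int n = L.n;
  L.p.assign(n + 1, 0);
  L.i.clear();
  L.x.clear();
  // extract lower triangle (column-sorted input assumed: dgCMatrix rows are
  // sorted within each column)
  for (int j = 0; j < n; ++j) {
    for (int k = Ap[j]; k < Ap[j + 1]; ++k)
      if (Ai[k] >= j) ++L.p[j + 1];
  }
  for (int j = 0; j < n; ++j) L.p[j + 1] += L.p[j];
  L.i.resize(L.p[n]);
  L.x.resize(L.p[n]);
  {
    std::vector<int> pos(n);
    for (int j = 0; j < n; ++j) pos[j] = L.p[j];
    for (int j = 0; j < n; ++j) {
      for (int k = Ap[j]; k < Ap[j + 1]; ++k) {
        const int r = Ai[k];
        if (r >= j) {
          L.i[pos[j]] = r;
          L.x[pos[j]] = (r == j) ? Ax[k] * (1.0 + shift) : Ax[k];
          ++pos[j];
        }
      }
    }
  }
  // Left-looking IC(0): for each column j, subtract the contributions of
  // every earlier column k that has a nonzero in row j, restricted to the
  // sparsity pattern of column j (marker array enforces the restriction).
  // first[k] tracks the next unused row of column k; head/next thread the
  // columns whose current row equals the column being processed.
  std::vector<int> first(n), head(n, -1), next(n, -1), marker(n, -1);
  std::vector<double> work(n, 0.0);
  for (int j = 0; j < n; ++j) {
    for (int q = L.p[j]; q < L.p[j + 1]; ++q) {
      work[L.i[q]] = L.x[q];
      marker[L.i[q]] = j;
    }
    for (int k = head[j]; k != -1; ) {
      const int knext = next[k];
      const int q0 = first[k];
      const double ljk = L.x[q0];
      for (int q = q0; q < L.p[k + 1]; ++q) {
        const int r = L.i[q];
        if (marker[r] == j) work[r] -= ljk * L.x[q];
      }
      if (q0 + 1 < L.p[k + 1]) {
        first[k] = q0 + 1;
        const int r = L.i[q0 + 1];
        next[k] = head[r];
        head[r] = k;
      }
      k = knext;
    }
    const double dj = work[j];
    if (!(dj > 0.0)) return false;  // breakdown; caller retries with a shift
    const double lj = std::sqrt(dj);
    L.x[L.p[j]] = lj;
    for (int q = L.p[j] + 1; q < L.p[j + 1]; ++q)
      L.x[q] = work[L.i[q]] / lj;
    if (L.p[j] + 1 < L.p[j + 1]) {
      const int r = L.i[L.p[j] + 1];
      first[j] = L.p[j] + 1;
      next[j] = head[r];
      head[r] = j;
    }
  }
  return true;
}

// forward solve L y = r, then backward solve L^T z = y; L in CSC lower form
static inline void ic0_solve(const IC0& L, const std::vector<double>& r,
                             std::vector<double>& y, std::vector<double>& z) {
  const int n = L.n;
  y = r;
  for (int j = 0; j < n; ++j) {
    const double yj = y[j] / L.x[L.p[j]];
    y[j] = yj;
    for (int q = L.p[j] + 1; q < L.p[j + 1]; ++q) y[L.i[q]] -= L.x[q] * yj;
  }
  z = y;
  for (int j = n - 1; j >= 0; --j) {
    double s = z[j];
    for (int q = L.p[j] + 1; q < L.p[j + 1]; ++q) s -= L.x[q] * z[L.i[q]];
    z[j] = s / L.x[L.p[j]];
  }
}

// Biconjugate gradient stabilized solve of A x = b, preconditioned with
// IC(0) (falling back to Jacobi if the incomplete factorization breaks down
// repeatedly). A is given by its dgCMatrix slots. Convergence when
// ||b - A x|| / max(||b||, eps) <= tol.
// [[Rcpp::export(name = ".cpp_bicgstab")]]
List cpp_bicgstab(IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                  NumericVector b, NumericVector x0, double tol,
                  int max_iter, bool use_ic = true) {
  const int n = b.size();
  std::vector<double> x(x0.begin(), x0.end());
  // Jacobi fallback data
  std::vector<double> dinv(n, 1.0);
  for (int col = 0; col < n; ++col) {
    for (int k = Ap[col]; k < Ap[col + 1]; ++k) {
      if (Ai[k] == col) {
        double d = std::fabs(Ax[k]);
        dinv[col] = 1.0 / (d > 1e-300 ? d : 1e-300);
        break;
      }
    }
  }
  IC0 L;
  L.n = n;
  bool have_ic = false;
  if (use_ic) {
    double shift = 0.0;
    for (int attempt = 0; attempt < 4 && !have_ic; ++attempt) {
      have_ic = ic0_factor(Ap, Ai, Ax, shift, L);
      shift = (shift == 0.0) ? 0.01 : shift * 10.0;
    }
  }
  std::vector<double> w1(n), w2(n);
  auto precond = [&](const std::vector<double>& r, std::vector<double>& out) {
    if (have_ic) {
      ic0_solve(L, r, w1, out);
    } else {
      for (int k = 0; k < n; ++k) out[k] = dinv[k] * r[k];
    }
  };
  std::vector<double> r(n), rhat(n), v(n, 0.0), p(n, 0.0), phat(n), s(n),
      shat(n), t(n), tmp(n);
  csc_matvec(Ap, Ai, Ax, x, tmp);
  for (int k = 0; k < n; ++k) r[k] = b[k] - tmp[k];
  rhat = r;
  const double bnorm = std::max(nrm2(std::vector<double>(b.begin(), b.end())),
                                1e-300);
  double rho = 1.0, alpha = 1.0, omega = 1.0;
  double relres = nrm2(r) / bnorm;
  int it = 0;
  while (relres > tol && it < max_iter) {
    ++it;
    const double rho1 = dot(rhat, r);
    if (std::fabs(rho1) < 1e-300) break;  // breakdown; return best effort
    if (it == 1) {
      p = r;
    } else {
      const double beta = (rho1 / rho) * (alpha / omega);
      for (int k = 0; k < n; ++k) p[k] = r[k] + beta * (p[k] - omega * v[k]);
    }
    rho = rho1;
    precond(p, phat);
    csc_matvec(Ap, Ai, Ax, phat, v);
    alpha = rho1 / dot(rhat, v);
    for (int k = 0; k < n; ++k) s[k] = r[k] - alpha * v[k];
    if (nrm2(s) / bnorm <= tol) {
      for (int k = 0; k < n; ++k) x[k] += alpha * phat[k];
      r = s;
      relres = nrm2(r) / bnorm;
      break;
    }
    precond(s, shat);
    csc_matvec(Ap, Ai, Ax, shat, t);
    const double tt = dot(t, t);
    if (tt < 1e-300) {
      for (int k = 0; k < n; ++k) x[k] += alpha * phat[k];
      r = s;
      relres = nrm2(r) / bnorm;
      break;
    }
    omega = dot(t, s) / tt;
    for (int k = 0; k < n; ++k) {
      x[k] += alpha * phat[k] + omega * shat[k];
      r[k] = s[k] - omega * t[k];
    }
    relres = nrm2(r) / bnorm;
    if (std::fabs(omega) < 1e-300) break;
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["iterations"] = it, _["relres"] = relres,
                      _["converged"] = relres <= tol,
                      _["preconditioner"] = have_ic ? "ic0" : "jacobi");
}

// For each row of `query` (n x 3), the 1-based row index of the nearest row
// of `ref` (m x 3) in Euclidean distance. Brute force; the point sets here
// are surface clouds of a few thousand points, so O(n*m) is cheap and exact.
// [[Rcpp::export(name = ".cpp_nearest_index")]]
IntegerVector cpp_nearest_index(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  IntegerVector out(nq);
  std::vector<double> rx(nr), ry(nr), rz(nr);
  for (int j = 0; j < nr; ++j) {
    rx[j] = ref(j, 0);
    ry[j] = ref(j, 1);
    rz[j] = ref(j, 2);
  }
  for (int i = 0; i < nq; ++i) {
    double best = std::numeric_limits<double>::max();
    int bj = 0;
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    for (int j = 0; j < nr; ++j) {
      const double dx = qx - rx[j], dy = qy - ry[j], dz = qz - rz[j];
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bj = j; }
    }
    out[i] = bj + 1;
  }
  return out;
}
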