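// Time-stepping inner loops.  Each step of the propagation method is one
// sparse matrix/vector product (CSC layout, as stored by Matrix::dgCMatrix)
// plus a source-vector update; long validation runs (up to 1e6 steps) compare
// against the closed-form profiles every step, so these loops live in C++.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline void spmv(const IntegerVector &p, const IntegerVector &i,
                        const NumericVector &x, const std::vector<double> &v,
                        std::vector<double> &out) {
  std::fill(out.begin(), out.end(), 0.0);
  int ncol = p.size() - 1;
  for (int j = 0; j < ncol; ++j) {
    double vj = v[j];
    if (vj == 0.0) continue;
    for (int k = p[j]; k < p[j + 1]; ++k) out[i[k]] += x[k] * vj;
  }
}

// rho_{n+1} = react_factor * (W rho_n) + chi_n * F_n * s + react_add.
// Row 0 of W is empty and s[0] = 1, so the origin value comes out as
// chi_n * F_n — the exact point-source limit rho(0) = lim R c.
// Records every record_every steps.
// [[Rcpp::export]]
List cpp_propagate(IntegerVector Wp, IntegerVector Wi, NumericVector Wx,
                   NumericVector s, NumericVector rho0, IntegerVector chi,
                   NumericVector Fvec, double react_factor,
                   NumericVector react_add, int record_every,
                   double div_threshold) {
  int I = rho0.size();
  int n_steps = chi.size();
  std::vector<double> rho(rho0.begin(), rho0.end());
  std::vector<double> tmp(I);
  int nrec = record_every > 0 ? n_steps / record_every : 0;
  NumericMatrix rec(nrec, I);
  IntegerVector rec_steps(nrec);
  bool diverged = false;
  int bad_step = NA_INTEGER;
  int r = 0;
  for (int n = 0; n < n_steps; ++n) {
    spmv(Wp, Wi, Wx, rho, tmp);
    double src = chi[n] ? Fvec[n] : 0.0;
    double mx = 0.0;
    for (int k = 0; k < I; ++k) {
      double v = react_factor * tmp[k] + src * s[k] + react_add[k];
      rho[k] = v;
      double av = std::fabs(v);
      if (av > mx) mx = av;
    }
    if (!std::isfinite(mx) || mx > div_threshold) {
      diverged = true;
      bad_step = n + 1;
      break;
    }
    if (record_every > 0 && (n + 1) % record_every == 0 && r < nrec) {
      for (int k = 0; k < I; ++k) rec(r, k) = rho[k];
      rec_steps[r] = n + 1;
      ++r;
    }
  }
  return List::create(_["rho"] = NumericVector(rho.begin(), rho.end()),
                      _["recorded"] = rec, _["rec_steps"] = rec_steps,
                      _["n_recorded"] = r, _["diverged"] = diverged,
                      _["step"] = bad_step);
}

// Always-on protocol in nondimensional units (F = 1): after k on-steps from
// rho = 0 the exact profile is erfc(R/sqrt(k)); eps_k = max_i |rho - exact|.
// [[Rcpp::export]]
List cpp_always_on_error(IntegerVector Wp, IntegerVector Wi, NumericVector Wx,
                         NumericVector s, NumericVector Rg, int n_steps,
                         double div_threshold) {
  int I = s.size();
  std::vector<double> rho(I, 0.0), tmp(I);
  NumericVector eps(n_steps);
  bool diverged = false;
  int bad_step = NA_INTEGER;
  for (int n = 0; n < n_steps; ++n) {
    spmv(Wp, Wi, Wx, rho, tmp);
    for (int k = 0; k < I; ++k) rho[k] = tmp[k] + s[k];
    double rk = std::sqrt((double)(n + 1));
    double e = 0.0, mx = 0.0;
    for (int k = 0; k < I; ++k) {
      double ex = std::erfc(Rg[k] / rk); // at R = 0 this is 1 = chi F, exact
      double d = std::fabs(rho[k] - ex);
      if (d > e) e = d;
      double av = std::fabs(rho[k]);
      if (av > mx) mx = av;
    }
    eps[n] = e;
    if (!std::isfinite(mx) || mx > div_threshold) {
      diverged = true;
      bad_step = n + 1;
      eps[n] = R_PosInf;
      for (int m = n + 1; m < n_steps; ++m) eps[m] = NA_REAL;
      break;
    }
  }
  return List::create(_["eps"] = eps, _["diverged"] = diverged,
                      _["step"] = bad_step);
}

// Random-on protocol (F = 1): chi is the realized 0/1 history.  The exact
// profile is the history sum of e_m basis functions; contiguous on-runs
// telescope to erf(R/sqrt(n-k2)) - erf(R/sqrt(n-k1+1)) (erf(R/sqrt(0)) := 1),
// evaluated from a cached erf(R_i/sqrt(m)) table.  Cost is O(runs * I) per
// evaluated step, so the error is evaluated every check_every steps.
// [[Rcpp::export]]
List cpp_random_on_error(IntegerVector Wp, IntegerVector Wi, NumericVector Wx,
                         NumericVector s, NumericVector Rg, IntegerVector chi,
                         int check_every, double div_threshold) {
  int I = s.size();
  int n_steps = chi.size();
  std::vector<double> rho(I, 0.0), tmp(I);
  // erf table: T[m*I + i] = erf(Rg[i]/sqrt(m)), m = 1..n_steps; m = 0 -> 1
  std::vector<double> T((size_t)(n_steps + 1) * I);
  for (int i = 0; i < I; ++i) T[i] = 1.0;
  for (int m = 1; m <= n_steps; ++m) {
    double rm = std::sqrt((double)m);
    for (int i = 0; i < I; ++i) T[(size_t)m * I + i] = std::erf(Rg[i] / rm);
  }
  std::vector<int> run_start, run_end; // inclusive step indices (0-based)
  bool in_run = false;
  std::vector<double> exact(I);
  std::vector<int> ck_steps;
  std::vector<double> ck_eps;
  bool diverged = false;
  int bad_step = NA_INTEGER;
  for (int n = 0; n < n_steps; ++n) {
    spmv(Wp, Wi, Wx, rho, tmp);
    double src = chi[n] ? 1.0 : 0.0;
    for (int k = 0; k < I; ++k) rho[k] = tmp[k] + src * s[k];
    if (chi[n]) {
      if (in_run) run_end.back() = n;
      else { run_start.push_back(n); run_end.push_back(n); in_run = true; }
    } else {
      in_run = false;
    }
    double mx = 0.0;
    for (int k = 0; k < I; ++k) {
      double av = std::fabs(rho[k]);
      if (av > mx) mx = av;
    }
    if (!std::isfinite(mx) || mx > div_threshold) {
      diverged = true;
      bad_step = n + 1;
      break;
    }
    if ((n + 1) % check_every == 0 || n == n_steps - 1) {
      std::fill(exact.begin(), exact.end(), 0.0);
      for (size_t rr = 0; rr < run_start.size(); ++rr) {
        int m_lo = n - run_end[rr];      // >= 0
        int m_hi = n - run_start[rr] + 1; // >= 1
        const double *Tlo = &T[(size_t)m_lo * I];
        const double *Thi = &T[(size_t)m_hi * I];
        for (int i = 0; i < I; ++i) exact[i] += Tlo[i] - Thi[i];
      }
      double e = 0.0;
      for (int i = 0; i < I; ++i) {
        double d = std::fabs(rho[i] - exact[i]);
        if (d > e) e = d;
      }
      ck_steps.push_back(n + 1);
      ck_eps.push_back(e);
    }
  }
  return List::create(_["steps"] = IntegerVector(ck_steps.begin(), ck_steps.end()),
                      _["eps"] = NumericVector(ck_eps.begin(), ck_eps.end()),
                      _["diverged"] = diverged, _["step"] = bad_step);
}

// Crank-Nicolson baseline on a uniform radial grid, solved in u = r c
// (du/dt = D u_rr).  The point source enters as the inner Dirichlet value
// u(0) = chi_n j/(4 pi D) (the quasi-steady near-field of a point source);
// outer boundary u(L) = 0.  Thomas solve per step.
// [[Rcpp::export]]
List cpp_crank_nicolson(double D, double dt, double dr, int Nr,
                        IntegerVector chi, double j_flux,
                        IntegerVector record_steps) {
  int n_steps = chi.size();
  double lam = D * dt / (dr * dr);
  int Ni = Nr - 1; // interior nodes 1..Nr-1
  std::vector<double> u(Nr + 1, 0.0), rhs(Ni), cp(Ni), dp(Ni), unew(Nr + 1, 0.0);
  double u0_on = j_flux / (4.0 * M_PI * D);
  double a = -lam / 2.0, b = 1.0 + lam, c = -lam / 2.0;
  NumericMatrix rec(record_steps.size(), Nr + 1);
  int ri = 0;
  for (int n = 0; n < n_steps; ++n) {
    double u0_new = chi[n] ? u0_on : 0.0;
    // rhs: (I + lam/2 D2) u^n with boundary terms of u^{n+1}
    for (int k = 1; k <= Ni; ++k) {
      double lap = u[k - 1] - 2.0 * u[k] + u[k + 1];
      rhs[k - 1] = u[k] + 0.5 * lam * lap;
    }
    rhs[0] -= a * u0_new;
    // Thomas
    cp[0] = c / b;
    dp[0] = rhs[0] / b;
    for (int k = 1; k < Ni; ++k) {
      double mden = b - a * cp[k - 1];
      cp[k] = c / mden;
      dp[k] = (rhs[k] - a * dp[k - 1]) / mden;
    }
    unew[Ni] = dp[Ni - 1];
    for (int k = Ni - 1; k >= 1; --k)
      unew[k] = dp[k - 1] - cp[k - 1] * unew[k + 1];
    unew[0] = u0_new;
    unew[Nr] = 0.0;
    u = unew;
    for (int k = 0; k <= Nr; ++k) {
      if (!std::isfinite(u[k])) stop("Crank-Nicolson solution became non-finite");
    }
    if (ri < record_steps.size() && record_steps[ri] == n + 1) {
      for (int k = 0; k <= Nr; ++k) rec(ri, k) = u[k];
      ++ri;
    }
  }
  return List::create(_["u"] = rec, _["u_final"] = NumericVector(u.begin(), u.end()));
}
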