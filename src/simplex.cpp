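// Two-phase dense simplex for the steady-state extraction LP:
//
//   min  c'x   s.t.  A x = b,  x >= 0
//
// Bland's smallest-index rule in both phases: the flux cone S v = 0 makes
// every basic feasible solution degenerate, so an anti-cycling rule is not
// optional here.  The solver is fully deterministic — identical inputs give
// identical vertices — which the extraction protocol relies on.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// One simplex phase on an explicit tableau.
//   T      : m x (ncols+1) tableau, last column = rhs (kept >= 0)
//   cost   : reduced-cost row, length ncols + 1 (last entry = -objective)
//   basis  : length m, current basic column per row
//   active : columns eligible to enter (phase 1 keeps artificials out)
// Returns false only if the iteration cap is hit (never in practice:
// Bland's rule precludes cycling).
bool run_phase(mat& T, rowvec& cost, uvec& basis,
               const std::vector<bool>& active, double tol)
{
    const uword m = T.n_rows, ncols = T.n_cols - 1;
    const uword max_iter = 50000 + 200 * (m + ncols);
    for (uword it = 0; it < max_iter; ++it) {
        // Bland: entering = smallest-index active column with cbar < -tol
        uword enter = ncols;
        for (uword j = 0; j < ncols; ++j) {
            if (active[j] && cost[j] < -tol) { enter = j; break; }
        }
        if (enter == ncols) return true;  // optimal

        // ratio test; ties broken by smallest basis label (Bland)
        uword leave = m;
        double best = datum::inf;
        for (uword i = 0; i < m; ++i) {
            double a = T(i, enter);
            if (a > tol) {
                double ratio = T(i, ncols) / a;
                if (ratio < best - tol ||
                    (ratio < best + tol && (leave == m || basis[i] < basis[leave]))) {
                    best = ratio;
                    leave = i;
                }
            }
        }
        if (leave == m) return true;  // unbounded direction; cannot occur with c > 0

        // pivot on (leave, enter)
        T.row(leave) /= T(leave, enter);
        for (uword i = 0; i < m; ++i) {
            if (i != leave && std::abs(T(i, enter)) > 0.0)
                T.row(i) -= T(i, enter) * T.row(leave);
        }
        cost -= cost[enter] * T.row(leave);
        basis[leave] = enter;
    }
    return false;
}

}  // namespace

// [[Rcpp::export(name = ".simplex_core")]]
Rcpp::List simplex_core(const arma::mat& A, const arma::vec& b,
                        const arma::vec& cobj, double tol = 1e-9)
{
    const uword m = A.n_rows, n = A.n_cols;

    // tableau with artificial columns n..n+m-1; rhs made nonnegative
    mat T(m, n + m + 1, fill::zeros);
    T.cols(0, n - 1) = A;
    T.col(n + m) = b;
    for (uword i = 0; i < m; ++i) {
        if (T(i, n + m) < 0) T.row(i) *= -1.0;
        T(i, n + i) = 1.0;
    }
    uvec basis(m);
    for (uword i = 0; i < m; ++i) basis[i] = n + i;

    // phase 1: minimize sum of artificials; price the artificial basis out
    // of the cost row (c_art = 1) and bar artificials from re-entering
    rowvec cost(n + m + 1, fill::zeros);
    for (uword j = n; j < n + m; ++j) cost[j] = 1.0;
    for (uword i = 0; i < m; ++i) cost -= T.row(i);
    std::vector<bool> active(n + m, true);
    for (uword j = n; j < n + m; ++j) active[j] = false;
    if (!run_phase(T, cost, basis, active, tol))
        return Rcpp::List::create(Rcpp::Named("status") = 2);

    double phase1_obj = -cost[n + m];
    if (phase1_obj > std::sqrt(tol))
        return Rcpp::List::create(Rcpp::Named("status") = 1);  // infeasible

    // drive remaining artificials out of the basis (degenerate rows)
    for (uword i = 0; i < m; ++i) {
        if (basis[i] >= n) {
            uword piv = n;
            for (uword j = 0; j < n; ++j)
                if (std::abs(T(i, j)) > std::sqrt(tol)) { piv = j; break; }
            if (piv == n) {
                T.row(i).zeros();  // redundant constraint row
                continue;
            }
            T.row(i) /= T(i, piv);
            for (uword k = 0; k < m; ++k)
                if (k != i && std::abs(T(k, piv)) > 0.0)
                    T.row(k) -= T(k, piv) * T.row(i);
            basis[i] = piv;
        }
    }

    // phase 2: real objective
    rowvec cost2(n + m + 1, fill::zeros);
    cost2.subvec(0, n - 1) = cobj.t();
    for (uword i = 0; i < m; ++i) {
        if (basis[i] < n && std::abs(cost2[basis[i]]) > 0.0)
            cost2 -= cost2[basis[i]] * T.row(i);
    }
    if (!run_phase(T, cost2, basis, active, tol))
        return Rcpp::List::create(Rcpp::Named("status") = 2);

    vec x(n, fill::zeros);
    for (uword i = 0; i < m; ++i)
        if (basis[i] < n) x[basis[i]] = T(i, n + m);
    x.clamp(0.0, datum::inf);  // clip the roundoff negatives

    return Rcpp::List::create(
        Rcpp::Named("status") = 0,
        Rcpp::Named("x") = x,
        Rcpp::Named("objective") = dot(cobj, x));
}
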