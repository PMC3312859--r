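#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// EGFR network right-hand side. State layout: x[0..10] = X0..X10 where
// X0 glucose (inert), X1 TGFa, X2 EGFR, X3 TGFa-EGFR, X4 (TGFa-EGFR)^2,
// X5 TGFa-EGFR-P, X6 PLCg, X7 TGFa-EGFR-PLCg, X8 TGFa-EGFR-PLCg-P,
// X9 PLCg-P, X10 PLCg-P-I.
// Parameter layout: p[0..17] =
// k1, km1, k2, km2, k3, km3, K4, V4, k5, km5, k6, km6, k7, km7, K8, V8, k9, km9.
static inline void egfr_derivs(const double *x, const double *p, double *dx) {
    const double v1 = p[0] * x[1] * x[2] - p[1] * x[3];
    const double v2 = p[2] * x[3] * x[3] - p[3] * x[4];
    const double v3 = p[4] * x[4] - p[5] * x[5];
    const double v4 = p[7] * x[5] / (p[6] + x[5]);
    const double v5 = p[8] * x[5] * x[6] - p[9] * x[7];
    const double v6 = p[10] * x[7] - p[11] * x[8];
    const double v7 = p[12] * x[8] - p[13] * x[5] * x[9];
    const double v8 = p[15] * x[9] / (p[14] + x[9]);
    const double v9 = p[16] * x[9] - p[17] * x[10];

    dx[0] = 0.0;                    // glucose carried as an inert variable
    dx[1] = -v1;
    dx[2] = -v1;
    dx[3] = v1 - 2.0 * v2;
    dx[4] = v2 + v4 - v3;
    dx[5] = v3 + v7 - v4 - v5;
    dx[6] = v8 - v5;
    dx[7] = v5 - v6;
    dx[8] = v6 - v7;
    dx[9] = v7 - v8 - v9;
    dx[10] = v9;
}

// One classical RK4 step of size h, in place. Work arrays supplied by caller.
static inline void rk4_step(double *x, const double *p, double h,
                            double *k1, double *k2, double *k3, double *k4,
                            double *tmp) {
    egfr_derivs(x, p, k1);
    for (int i = 0; i < 11; ++i) tmp[i] = x[i] + 0.5 * h * k1[i];
    egfr_derivs(tmp, p, k2);
    for (int i = 0; i < 11; ++i) tmp[i] = x[i] + 0.5 * h * k2[i];
    egfr_derivs(tmp, p, k3);
    for (int i = 0; i < 11; ++i) tmp[i] = x[i] + h * k3[i];
    egfr_derivs(tmp, p, k4);
    for (int i = 0; i < 11; ++i)
        x[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// Integrates one cell state for n_steps steps of size dt. Negative
// overshoot within clamp_tol is clamped to zero (counted); a larger
// undershoot or a non-finite value aborts: both indicate dt is too large
// for the current stiffness.
static int integrate_one(double *x, const double *p, long n_steps, double dt,
                         double clamp_tol, std::string &err) {
    double k1[11], k2[11], k3[11], k4[11], tmp[11];
    int n_clamped = 0;
    for (long s = 0; s < n_steps; ++s) {
        rk4_step(x, p, dt, k1, k2, k3, k4, tmp);
        for (int i = 0; i < 11; ++i) {
            const double xi = x[i];
            if (!std::isfinite(xi)) {
                err = "non-finite concentration during integration; the system is too stiff for this dt, reduce dt";
                return -1;
            }
            if (xi < 0.0) {
                if (xi >= -clamp_tol) {
                    x[i] = 0.0;
                    ++n_clamped;
                } else {
                    err = "concentration undershoot below -clamp_tol during integration; reduce dt";
                    return -1;
                }
            }
        }
    }
    return n_clamped;
}

// [[Rcpp::export]]
List rk4_pathway_cpp(NumericVector state, NumericVector params,
                     double n_steps, double dt, double clamp_tol) {
    if (state.size() != 11) stop("state must have 11 species");
    if (params.size() != 18) stop("params must have 18 entries");
    double x[11];
    for (int i = 0; i < 11; ++i) x[i] = state[i];
    std::string err;
    long ns = (long)n_steps;
    int ncl = integrate_one(x, REAL(params), ns, dt, clamp_tol, err);
    if (ncl < 0) stop(err);
    NumericVector out(11);
    for (int i = 0; i < 11; ++i) out[i] = x[i];
    return List::create(_["state"] = out, _["n_clamped"] = ncl);
}

// Batch version: states is n_cells x 11, processed cell by cell so that the
// result is bitwise identical to looping over rk4_pathway_cpp.
// [[Rcpp::export]]
List rk4_pathway_batch_cpp(NumericMatrix states, NumericVector params,
                           double n_steps, double dt, double clamp_tol) {
    if (states.ncol() != 11) stop("states must have 11 columns (X0..X10)");
    if (params.size() != 18) stop("params must have 18 entries");
    const int n = states.nrow();
    NumericMatrix out(n, 11);
    IntegerVector ncl(n);
    const double *p = REAL(params);
    long ns = (long)n_steps;
    double x[11];
    std::string err;
    for (int c = 0; c < n; ++c) {
        for (int i = 0; i < 11; ++i) x[i] = states(c, i);
        int r = integrate_one(x, p, ns, dt, clamp_tol, err);
        if (r < 0) stop("cell %d: %s", c + 1, err.c_str());
        ncl[c] = r;
        for (int i = 0; i < 11; ++i) out(c, i) = x[i];
    }
    return List::create(_["states"] = out, _["n_clamped"] = ncl);
}
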