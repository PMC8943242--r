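#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Implicit-Euler stepper for the time-domain diffusion equation
//
//   (1/c) dPhi/dt = div(kappa grad Phi) - mua Phi,
//   Phi + 2 A kappa dPhi/dn = 0 on the boundary (Robin),
//
// discretized with cell-centered finite volumes on an isotropic voxel grid:
// harmonic averaging of kappa at interior faces, and a boundary-face
// conductance g = kappa / ((h/2 + 2 A kappa) h) derived from the Robin
// condition with a linear profile between the cell center and the face.
//
// Each step solves (I + dt c (K + mua)) phi_{n+1} = phi_n with a
// Jacobi-preconditioned conjugate-gradient iteration warm-started from a
// linear extrapolation of the two previous fields. The system matrix is SPD
// and constant over steps. Work vectors are padded by one z-plane on both
// sides so the 7-point stencil needs no boundary branches (out-of-range
// reads are multiplied by zero face weights).

struct Stencil {
    int n1, n2, n3, n, pad;
    // padded length n + 2*pad; index i lives at [i + pad]
    std::vector<double> diag, wx, wy, wz;
};

typedef std::vector<double> vec;

static inline void matvec(const Stencil &S, const double *x, double *y) {
    const int n = S.n, sx = 1, sy = S.n1, sz = S.n1 * S.n2;
    const double *diag = S.diag.data() + S.pad;
    const double *wx = S.wx.data() + S.pad;
    const double *wy = S.wy.data() + S.pad;
    const double *wz = S.wz.data() + S.pad;
    for (int i = 0; i < n; ++i) {
        y[i] = diag[i] * x[i]
            - wx[i] * x[i + sx] - wx[i - sx] * x[i - sx]
            - wy[i] * x[i + sy] - wy[i - sy] * x[i - sy]
            - wz[i] * x[i + sz] - wz[i - sz] * x[i - sz];
    }
}

// Solve S x = b by Jacobi-preconditioned CG; x holds the warm start.
// Returns the number of iterations used.
static int cg_solve(const Stencil &S, const double *b, double *x,
                    double tol, int maxit, vec &r, vec &p, vec &q, vec &z) {
    const int n = S.n;
    const double *diag = S.diag.data() + S.pad;
    double *pp = p.data() + S.pad;
    double *zp = z.data();
    double bnorm2 = 0.0;
    for (int i = 0; i < n; ++i) bnorm2 += b[i] * b[i];
    if (bnorm2 == 0.0) { std::fill(x, x + n, 0.0); return 0; }
    const double target2 = tol * tol * bnorm2;

    matvec(S, x, q.data());
    double rnorm2 = 0.0;
    for (int i = 0; i < n; ++i) { r[i] = b[i] - q[i]; rnorm2 += r[i] * r[i]; }
    if (rnorm2 <= target2) return 0;

    double rho_old = 0.0;
    int it = 0;
    for (; it < maxit; ++it) {
        double rho = 0.0;
        for (int i = 0; i < n; ++i) { zp[i] = r[i] / diag[i]; rho += r[i] * zp[i]; }
        if (it == 0)
            for (int i = 0; i < n; ++i) pp[i] = zp[i];
        else {
            const double beta = rho / rho_old;
            for (int i = 0; i < n; ++i) pp[i] = zp[i] + beta * pp[i];
        }
        matvec(S, pp, q.data());
        double pq = 0.0;
        for (int i = 0; i < n; ++i) pq += pp[i] * q[i];
        const double alpha = rho / pq;
        rnorm2 = 0.0;
        for (int i = 0; i < n; ++i) {
            x[i] += alpha * pp[i];
            r[i] -= alpha * q[i];
            rnorm2 += r[i] * r[i];
        }
        rho_old = rho;
        if (rnorm2 <= target2) { ++it; break; }
    }
    return it;
}

// phi_ref: optional reference field trajectory (n rows, nsteps*nsrc columns,
// column t + nsteps*s) from a nearby parameter set; used to warm-start each
// step's CG solve as ref_t + (phi_{t-1} - ref_{t-1}), which makes repeated
// solves at slightly perturbed coefficients (finite-difference Jacobians)
// converge in a couple of iterations. return_fields asks for the full
// trajectory back.
// [[Rcpp::export(name = ".td_diffusion_cpp")]]
List td_diffusion_cpp(NumericVector kappa, NumericVector mua,
                      IntegerVector dims, double h, double dt, int nsteps,
                      double cspeed, double arobin, bool robin,
                      NumericMatrix src, NumericMatrix detw,
                      bool movie = false, double tol = 1e-7, int maxit = 1000,
                      Nullable<NumericMatrix> phi_ref = R_NilValue,
                      bool return_fields = false) {
    Stencil S;
    S.n1 = dims[0]; S.n2 = dims[1]; S.n3 = dims[2];
    S.n = S.n1 * S.n2 * S.n3;
    S.pad = S.n1 * S.n2;
    const int n = S.n, pad = S.pad;
    if (kappa.size() != n || mua.size() != n)
        stop("kappa/mua size does not match dims");
    if (src.nrow() != n) stop("src rows must equal prod(dims)");
    if (detw.ncol() > 0 && detw.nrow() != n) stop("detw rows must equal prod(dims)");
    for (int i = 0; i < n; ++i)
        if (!(kappa[i] > 0.0) || mua[i] < 0.0)
            stop("optical coefficients must be positive (kappa) and non-negative (mua)");

    const double a = dt * cspeed;
    const double h2 = h * h;
    S.diag.assign(n + 2 * pad, 1.0);  // padding diag = 1 avoids div-by-zero
    S.wx.assign(n + 2 * pad, 0.0);
    S.wy.assign(n + 2 * pad, 0.0);
    S.wz.assign(n + 2 * pad, 0.0);
    double *diag = S.diag.data() + pad;
    double *wx = S.wx.data() + pad;
    double *wy = S.wy.data() + pad;
    double *wz = S.wz.data() + pad;

    const int sx = 1, sy = S.n1, sz = S.n1 * S.n2;
    for (int k = 0; k < S.n3; ++k)
        for (int j = 0; j < S.n2; ++j)
            for (int i = 0; i < S.n1; ++i) {
                int id = i + S.n1 * (j + S.n2 * k);
                double kap = kappa[id];
                if (i < S.n1 - 1)
                    wx[id] = a * 2.0 * kap * kappa[id + sx] / (kap + kappa[id + sx]) / h2;
                if (j < S.n2 - 1)
                    wy[id] = a * 2.0 * kap * kappa[id + sy] / (kap + kappa[id + sy]) / h2;
                if (k < S.n3 - 1)
                    wz[id] = a * 2.0 * kap * kappa[id + sz] / (kap + kappa[id + sz]) / h2;
            }
    for (int k = 0; k < S.n3; ++k)
        for (int j = 0; j < S.n2; ++j)
            for (int i = 0; i < S.n1; ++i) {
                int id = i + S.n1 * (j + S.n2 * k);
                double dd = 1.0 + a * mua[id];
                dd += wx[id] + wx[id - sx] + wy[id] + wy[id - sy]
                    + wz[id] + wz[id - sz];
                if (robin) {
                    double kap = kappa[id];
                    double g = a * kap / ((0.5 * h + 2.0 * arobin * kap) * h);
                    int nb = (i == 0) + (i == S.n1 - 1) + (j == 0) +
                             (j == S.n2 - 1) + (k == 0) + (k == S.n3 - 1);
                    dd += nb * g;
                }
                diag[id] = dd;
            }

    const int nsrc = src.ncol();
    const int ndet = detw.ncol();
    NumericVector tpsf(Dimension(std::max(ndet, 1), nsteps, nsrc));
    if (ndet == 0) std::fill(tpsf.begin(), tpsf.end(), 0.0);
    NumericMatrix mov;
    if (movie) mov = NumericMatrix(n, nsteps);
    NumericMatrix fields;
    if (return_fields) fields = NumericMatrix(n, nsteps * nsrc);
    NumericMatrix ref;
    bool have_ref = phi_ref.isNotNull();
    if (have_ref) {
        ref = NumericMatrix(phi_ref);
        if (ref.nrow() != n || ref.ncol() != nsteps * nsrc) have_ref = false;
    }

    vec phi(n + 2 * pad, 0.0), prev(n), b(n), r(n), p(n + 2 * pad, 0.0), q(n),
        z(n, 0.0);
    long total_iters = 0;

    for (int s = 0; s < nsrc; ++s) {
        double *x = phi.data() + pad;
        std::fill(phi.begin(), phi.end(), 0.0);
        for (int i = 0; i < n; ++i) x[i] = src(i, s);
        bool have_prev = false;
        for (int t = 0; t < nsteps; ++t) {
            std::copy(x, x + n, b.begin());
            if (have_ref) {
                const double *rt = &ref(0, t + nsteps * s);
                if (t == 0) {
                    for (int i = 0; i < n; ++i) x[i] = rt[i];
                } else {
                    const double *rp = &ref(0, t - 1 + nsteps * s);
                    for (int i = 0; i < n; ++i) x[i] = rt[i] + (b[i] - rp[i]);
                }
            } else if (have_prev) {  // linear extrapolation warm start
                for (int i = 0; i < n; ++i) {
                    double g = 2.0 * b[i] - prev[i];
                    prev[i] = b[i];
                    x[i] = g > 0.0 ? g : 0.0;
                }
            } else {
                std::copy(b.begin(), b.end(), prev.begin());
                have_prev = true;
            }
            total_iters += cg_solve(S, b.data(), x, tol, maxit, r, p, q, z);
            for (int d = 0; d < ndet; ++d) {
                double acc = 0.0;
                const double *w = &detw(0, d);
                for (int i = 0; i < n; ++i) acc += w[i] * x[i];
                tpsf[d + ndet * (t + nsteps * s)] = acc;
            }
            if (movie && s == 0)
                for (int i = 0; i < n; ++i) mov(i, t) = x[i];
            if (return_fields) {
                double *fc = &fields(0, t + nsteps * s);
                std::copy(x, x + n, fc);
            }
        }
        Rcpp::checkUserInterrupt();
    }

    List out = List::create(_["tpsf"] = tpsf,
                            _["cg_iterations"] = (double)total_iters);
    if (movie) out["movie"] = mov;
    if (return_fields) out["fields"] = fields;
    return out;
}
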