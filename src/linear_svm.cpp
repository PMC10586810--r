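#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Linear L1-hinge SVM trained by dual coordinate descent
// (Hsieh et al., ICML 2008). The bias is handled as an augmented,
// regularized constant feature; for the small, whitened pseudotrial
// problems this pipeline solves the difference from an unregularized
// bias is negligible. Deterministic: fixed cyclic sweep order, no RNG.
//
// X: n x d row-major buffer, y: +1/-1 labels. Returns weight vector of
// length d+1; the last entry is the bias.
static std::vector<double> dcd_train(const double* X, const int* y,
                                     int n, int d, double C,
                                     double tol, int max_sweeps) {
    const int da = d + 1;                     // augmented dimension
    std::vector<double> w(da, 0.0), alpha(n, 0.0), qii(n);
    for (int i = 0; i < n; ++i) {
        double s = 1.0;                       // augmented bias feature
        const double* xi = X + (std::size_t)i * d;
        for (int j = 0; j < d; ++j) s += xi[j] * xi[j];
        qii[i] = s;
    }
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
        double max_pg = 0.0;
        for (int i = 0; i < n; ++i) {
            const double* xi = X + (std::size_t)i * d;
            double wx = w[d];                 // bias term
            for (int j = 0; j < d; ++j) wx += w[j] * xi[j];
            double G = y[i] * wx - 1.0;
            double PG = G;
            if (alpha[i] <= 0.0)      PG = (G < 0.0) ? G : 0.0;
            else if (alpha[i] >= C)   PG = (G > 0.0) ? G : 0.0;
            if (std::fabs(PG) > max_pg) max_pg = std::fabs(PG);
            if (std::fabs(PG) > 1e-12) {
                double a_old = alpha[i];
                double a_new = a_old - G / qii[i];
                if (a_new < 0.0) a_new = 0.0;
                if (a_new > C)   a_new = C;
                double delta = (a_new - a_old) * y[i];
                if (delta != 0.0) {
                    for (int j = 0; j < d; ++j) w[j] += delta * xi[j];
                    w[d] += delta;
                    alpha[i] = a_new;
                }
            }
        }
        if (max_pg < tol) break;
    }
    return w;
}

// Copy an (n x d) slice at time t out of an (n x d x T) column-major
// array into a row-major buffer.
static void slice_rowmajor(const double* A, int n, int d, int t,
                           std::vector<double>& out) {
    const double* base = A + (std::size_t)t * n * d;
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < d; ++j)
            out[(std::size_t)i * d + j] = base[(std::size_t)j * n + i];
}

// Midpoint of the two class means. Centering the data here before
// training makes the zero threshold of the regularized-bias formulation
// coincide with libsvm's KKT bias even when every dual variable sits at
// the bound C (weak-signal regime).
static std::vector<double> class_midpoint(const double* X, const int* y,
                                          int n, int d) {
    std::vector<double> mp(d, 0.0), mneg(d, 0.0);
    int npos = 0, nneg = 0;
    for (int i = 0; i < n; ++i) {
        const double* xi = X + (std::size_t)i * d;
        if (y[i] > 0) { ++npos; for (int j = 0; j < d; ++j) mp[j] += xi[j]; }
        else          { ++nneg; for (int j = 0; j < d; ++j) mneg[j] += xi[j]; }
    }
    for (int j = 0; j < d; ++j)
        mp[j] = 0.5 * (mp[j] / std::max(npos, 1) +
                       mneg[j] / std::max(nneg, 1));
    return mp;
}

static void center_rows(std::vector<double>& X, int n, int d,
                        const std::vector<double>& mu) {
    for (int i = 0; i < n; ++i) {
        double* xi = X.data() + (std::size_t)i * d;
        for (int j = 0; j < d; ++j) xi[j] -= mu[j];
    }
}

//' @noRd
// [[Rcpp::export(name = ".lsvm_fit")]]
List lsvm_fit(NumericMatrix X, IntegerVector y, double C,
              double tol = 1e-6, int max_sweeps = 2000) {
    int n = X.nrow(), d = X.ncol();
    std::vector<double> Xr((std::size_t)n * d);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < d; ++j)
            Xr[(std::size_t)i * d + j] = X(i, j);
    std::vector<double> mu = class_midpoint(Xr.data(), INTEGER(y), n, d);
    center_rows(Xr, n, d, mu);
    std::vector<double> w = dcd_train(Xr.data(), INTEGER(y), n, d, C,
                                      tol, max_sweeps);
    NumericVector wv(d);
    double b = w[d];
    for (int j = 0; j < d; ++j) { wv[j] = w[j]; b -= w[j] * mu[j]; }
    return List::create(_["w"] = wv, _["b"] = b);
}

// Train one classifier per time slice of Xtr (ntr x d x T) and return
// decision values for the matching slices of Xte (nte x d x T) as an
// (nte x T) matrix.
//' @noRd
// [[Rcpp::export(name = ".lsvm_decode_batch")]]
NumericMatrix lsvm_decode_batch(NumericVector Xtr, IntegerVector ytr,
                                NumericVector Xte, double C,
                                double tol = 1e-6, int max_sweeps = 2000) {
    IntegerVector dtr = Xtr.attr("dim"), dte = Xte.attr("dim");
    if (dtr.size() != 3 || dte.size() != 3)
        stop("Xtr and Xte must be 3-d arrays (samples x features x time)");
    int ntr = dtr[0], d = dtr[1], T = dtr[2];
    int nte = dte[0];
    if (dte[1] != d || dte[2] != T)
        stop("train and test arrays disagree in features or time points");
    if (ytr.size() != ntr) stop("label length does not match training rows");

    NumericMatrix dv(nte, T);
    std::vector<double> Xr((std::size_t)ntr * d), Er((std::size_t)nte * d);
    const double* ptr_tr = REAL(Xtr);
    const double* ptr_te = REAL(Xte);
    for (int t = 0; t < T; ++t) {
        slice_rowmajor(ptr_tr, ntr, d, t, Xr);
        slice_rowmajor(ptr_te, nte, d, t, Er);
        std::vector<double> mu = class_midpoint(Xr.data(), INTEGER(ytr),
                                                ntr, d);
        center_rows(Xr, ntr, d, mu);
        center_rows(Er, nte, d, mu);
        std::vector<double> w = dcd_train(Xr.data(), INTEGER(ytr), ntr, d,
                                          C, tol, max_sweeps);
        for (int i = 0; i < nte; ++i) {
            double s = w[d];
            const double* xi = Er.data() + (std::size_t)i * d;
            for (int j = 0; j < d; ++j) s += w[j] * xi[j];
            dv(i, t) = s;
        }
    }
    return dv;
}
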