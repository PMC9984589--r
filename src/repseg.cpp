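#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
using namespace Rcpp;

// Directed Hausdorff helper: for every point of A, nearest squared distance to
// a point of B, using B sorted along the first coordinate with an early-exit
// window (|dx|^2 already exceeding the running minimum prunes the scan).
// Exact: returns the same min/max as the all-pairs computation.
static double directedMaxMin2(const NumericMatrix &A,
                              const std::vector<double> &bx,
                              const std::vector<double> &by,
                              const std::vector<double> &bz) {
    const int na = A.nrow(), nb = (int) bx.size();
    double worst = 0.0;
    for (int i = 0; i < na; ++i) {
        const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
        // first element of bx not less than ax
        int lo = (int) (std::lower_bound(bx.begin(), bx.end(), ax) - bx.begin());
        int up = lo, dn = lo - 1;
        double best = R_PosInf;
        while (up < nb || dn >= 0) {
            bool advanced = false;
            if (up < nb) {
                double dx = bx[up] - ax;
                if (dx * dx < best) {
                    double dy = by[up] - ay, dz = bz[up] - az;
                    double d2 = dx * dx + dy * dy + dz * dz;
                    if (d2 < best) best = d2;
                    ++up;
                    advanced = true;
                } else up = nb;
            }
            if (dn >= 0) {
                double dx = bx[dn] - ax;
                if (dx * dx < best) {
                    double dy = by[dn] - ay, dz = bz[dn] - az;
                    double d2 = dx * dx + dy * dy + dz * dz;
                    if (d2 < best) best = d2;
                    --dn;
                    advanced = true;
                } else dn = -1;
            }
            if (!advanced) break;
        }
        if (best > worst) worst = best;
    }
    return worst;
}

static void sortedCols(const NumericMatrix &B, std::vector<double> &x,
                       std::vector<double> &y, std::vector<double> &z) {
    const int n = B.nrow();
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&B](int a, int b) { return B(a, 0) < B(b, 0); });
    x.resize(n); y.resize(n); z.resize(n);
    for (int i = 0; i < n; ++i) {
        x[i] = B(ord[i], 0);
        y[i] = B(ord[i], 1);
        z[i] = B(ord[i], 2);
    }
}

// [[Rcpp::export(name = "cppHausdorffMax")]]
double cppHausdorffMax(NumericMatrix A, NumericMatrix B) {
    if (A.nrow() == 0 || B.nrow() == 0)
        stop("empty point set");
    std::vector<double> x, y, z;
    sortedCols(B, x, y, z);
    double d2 = directedMaxMin2(A, x, y, z);
    sortedCols(A, x, y, z);
    double e2 = directedMaxMin2(B, x, y, z);
    return std::sqrt(d2 > e2 ? d2 : e2);
}

// 6-connected component labelling of a 3D logical array (column-major dims).
// Labels are 1..ncomp in discovery order; background stays 0.
// [[Rcpp::export(name = "cppLabelComponents")]]
IntegerVector cppLabelComponents(LogicalVector vox, IntegerVector dim) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t) nx * ny * nz;
    if (vox.size() != n) stop("dim does not match array length");
    IntegerVector lab(n, 0);
    int next = 0;
    std::queue<R_xlen_t> q;
    const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t) nx * ny;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (!vox[s] || lab[s] != 0) continue;
        ++next;
        lab[s] = next;
        q.push(s);
        while (!q.empty()) {
            R_xlen_t c = q.front(); q.pop();
            int k = (int) (c / sz);
            int r = (int) (c % sz);
            int j = r / nx, i = r % nx;
            R_xlen_t nb[6];
            int nn = 0;
            if (i > 0)      nb[nn++] = c - sx;
            if (i < nx - 1) nb[nn++] = c + sx;
            if (j > 0)      nb[nn++] = c - sy;
            if (j < ny - 1) nb[nn++] = c + sy;
            if (k > 0)      nb[nn++] = c - sz;
            if (k < nz - 1) nb[nn++] = c + sz;
            for (int t = 0; t < nn; ++t) {
                R_xlen_t u = nb[t];
                if (vox[u] && lab[u] == 0) {
                    lab[u] = next;
                    q.push(u);
                }
            }
        }
    }
    lab.attr("ncomp") = next;
    return lab;
}
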