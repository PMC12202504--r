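#include <Rcpp.h>
#include <vector>
#include <limits>

// Exact Euclidean distance transform on a 3-D lattice with anisotropic
// voxel spacing, via the separable lower-envelope-of-parabolas algorithm
// applied axis by axis to squared distances. Distances are measured in
// physical units (mm) between voxel centers.

static const double INF = std::numeric_limits<double>::infinity();

// 1-D squared-distance transform of sampled function f at positions i*w.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n, double w) {
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; ++q) {
        if (f[q] == INF && f[v[k]] == INF) {
            // both parabolas at infinity: keep the later one as vertex
            if (k == 0) { v[0] = q; continue; }
        }
        double xq = q * w, s;
        for (;;) {
            double xv = v[k] * w;
            if (f[q] == INF) { s = INF; }
            else if (f[v[k]] == INF) { s = -INF; }
            else s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
            if (k > 0 && s <= z[k]) { --k; } else break;
        }
        if (s == INF) continue;  // new parabola never wins
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        double xq = q * w;
        while (z[k + 1] < xq) ++k;
        double xv = v[k] * w;
        double fv = f[v[k]];
        d[q] = (fv == INF) ? INF : (xq - xv) * (xq - xv) + fv;
    }
}

// [[Rcpp::export(name = ".edt_mm")]]
Rcpp::NumericVector edt_mm(Rcpp::LogicalVector mask, Rcpp::IntegerVector dim,
                           Rcpp::NumericVector spacing) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    std::vector<double> g(n);
    for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : INF;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // axis 1 (x): stride 1
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
            R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
            for (int i = 0; i < nx; ++i) f[i] = g[base + i];
            dt1d(f, d, v, z, nx, spacing[0]);
            for (int i = 0; i < nx; ++i) g[base + i] = d[i];
        }
    // axis 2 (y): stride nx
    for (int k = 0; k < nz; ++k)
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = (R_xlen_t)k * nx * ny + i;
            for (int j = 0; j < ny; ++j) f[j] = g[base + (R_xlen_t)j * nx];
            dt1d(f, d, v, z, ny, spacing[1]);
            for (int j = 0; j < ny; ++j) g[base + (R_xlen_t)j * nx] = d[j];
        }
    // axis 3 (z): stride nx*ny
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = (R_xlen_t)j * nx + i;
            for (int k = 0; k < nz; ++k) f[k] = g[base + (R_xlen_t)k * nx * ny];
            dt1d(f, d, v, z, nz, spacing[2]);
            for (int k = 0; k < nz; ++k) g[base + (R_xlen_t)k * nx * ny] = d[k];
        }

    Rcpp::NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = (g[i] == INF) ? R_PosInf : std::sqrt(g[i]);
    out.attr("dim") = dim;
    return out;
}
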