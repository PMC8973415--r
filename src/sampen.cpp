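#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Count SampEn template matches on x[from, from+len) with absolute tolerance r.
// Templates x_m(i), i = 0..len-m-1 (only indices whose (m+1)-extension exists,
// so A and B count the same pair set). Pairs i < j, Chebyshev distance
// strictly < r. Returns {B (length-m matches), A (length-(m+1) matches)}.
static inline void count_matches(const double *x, int len, int m, double r,
                                 long long &B, long long &A) {
    B = 0; A = 0;
    const int nt = len - m; // number of templates
    for (int i = 0; i < nt - 1; ++i) {
        for (int j = i + 1; j < nt; ++j) {
            double dmax = 0.0;
            bool match = true;
            for (int k = 0; k < m; ++k) {
                double d = std::fabs(x[i + k] - x[j + k]);
                if (d > dmax) dmax = d;
                if (dmax >= r) { match = false; break; }
            }
            if (!match) continue;
            ++B;
            double d = std::fabs(x[i + m] - x[j + m]);
            if (d > dmax) dmax = d;
            if (dmax < r) ++A;
        }
    }
}

static inline double series_sd(const double *x, int len) {
    double mean = 0.0;
    for (int t = 0; t < len; ++t) mean += x[t];
    mean /= len;
    double ss = 0.0;
    for (int t = 0; t < len; ++t) {
        double d = x[t] - mean;
        ss += d * d;
    }
    return std::sqrt(ss / (len - 1)); // sample convention
}

// [[Rcpp::export]]
List sampen_counts_cpp(NumericVector x, int m, double r) {
    long long B, A;
    count_matches(x.begin(), x.size(), m, r, B, A);
    return List::create(Named("B") = (double)B, Named("A") = (double)A);
}

// [[Rcpp::export]]
double sampen_cpp(NumericVector x, int m, double r_factor) {
    const int len = x.size();
    double sd = series_sd(x.begin(), len);
    if (!(sd > 0.0)) return NA_REAL;
    long long B, A;
    count_matches(x.begin(), len, m, r_factor * sd, B, A);
    if (B == 0 || A == 0) return NA_REAL;
    return -std::log((double)A / (double)B);
}

// Sliding-window SampEn for many series at once.
// series: T x V matrix (time by voxel); starts: 0-based window starts.
// Returns M x V matrix of per-window entropies (NA where undefined).
// [[Rcpp::export]]
NumericMatrix sampen_map_cpp(NumericMatrix series, IntegerVector starts,
                             int len, int m, double r_factor) {
    const int M = starts.size();
    const int V = series.ncol();
    NumericMatrix out(M, V);
    for (int v = 0; v < V; ++v) {
        const double *col = &series(0, v);
        for (int w = 0; w < M; ++w) {
            const double *x = col + starts[w];
            double sd = series_sd(x, len);
            if (!(sd > 0.0)) { out(w, v) = NA_REAL; continue; }
            long long B, A;
            count_matches(x, len, m, r_factor * sd, B, A);
            out(w, v) = (B == 0 || A == 0) ? NA_REAL
                                           : -std::log((double)A / (double)B);
        }
    }
    return out;
}

// Connected-component labelling of a 3D logical array under a 6/18/26
// neighbourhood. Returns an integer array: 0 background, 1..k components.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector fg, IntegerVector dim,
                                   int connectivity) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const int n = nx * ny * nz;
    IntegerVector labels(n, 0);

    // neighbour offsets
    std::vector<int> dxs, dys, dzs;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int nn = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (nn == 0) continue;
                if (connectivity == 6 && nn > 1) continue;
                if (connectivity == 18 && nn > 2) continue;
                dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
            }

    int next = 0;
    std::vector<int> stack;
    for (int idx = 0; idx < n; ++idx) {
        if (!fg[idx] || labels[idx] != 0) continue;
        ++next;
        labels[idx] = next;
        stack.clear();
        stack.push_back(idx);
        while (!stack.empty()) {
            int cur = stack.back(); stack.pop_back();
            int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
            for (size_t k = 0; k < dxs.size(); ++k) {
                int x = cx + dxs[k], y = cy + dys[k], z = cz + dzs[k];
                if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
                    continue;
                int nb = x + nx * (y + ny * z);
                if (fg[nb] && labels[nb] == 0) {
                    labels[nb] = next;
                    stack.push_back(nb);
                }
            }
        }
    }
    labels.attr("dim") = dim;
    return labels;
}
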