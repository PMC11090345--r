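// Grid search for the maximal information coefficient.
//
// All partitions are rank-based: cut points are placed only between distinct
// consecutive order statistics of an axis, so tied values never straddle a
// bin boundary and the score is invariant under strictly monotone transforms.
//
// Three search routines share one mutual-information kernel:
//   * exhaustive 2x2 search over every legal (x-cut, y-cut) pair, O(n^2),
//     via a cumulative 2-D count table;
//   * general exhaustive enumeration of all cut placements at a given shape
//     (combinatorial; intended for small n where it is the verification
//     default);
//   * an equipartition + dynamic-programming heuristic in the spirit of the
//     MINE ApproxMaxMI search: fix an equifrequency partition on one axis,
//     optimise the other axis by DP over candidate boundaries, and take the
//     better of the two orientations.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

const double LOG2E = 1.4426950408889634074; // 1/ln(2)

// lg[k] = log2(k) for integer counts 0..n (lg[0] unused); shared across the
// whole grid search so the hot loops never call log()
typedef std::vector<double> LogTab;

LogTab make_logtab(int n)
{
    LogTab lg(n + 1, 0.0);
    for (int k = 1; k <= n; ++k) lg[k] = std::log((double)k) * LOG2E;
    return lg;
}

inline double xlg(int c, const LogTab &lg) { return c > 0 ? c * lg[c] : 0.0; }

// I in bits from an nx-by-ny count grid (row-major), total n.
double mi_counts(const std::vector<int> &cnt, int nx, int ny, int n,
                 const LogTab &lg)
{
    std::vector<int> row(nx, 0), col(ny, 0);
    double cell = 0.0;
    for (int i = 0; i < nx; ++i)
        for (int j = 0; j < ny; ++j) {
            int c = cnt[i * ny + j];
            row[i] += c;
            col[j] += c;
            cell += xlg(c, lg);
        }
    double r = 0.0, s = 0.0;
    for (int i = 0; i < nx; ++i) r += xlg(row[i], lg);
    for (int j = 0; j < ny; ++j) s += xlg(col[j], lg);
    double I = (cell - r - s) / n + lg[n];
    return I > 0.0 ? I : 0.0; // guard fp negatives
}

// indices 0..n-1 ordered by v (stable)
std::vector<int> order_of(const NumericVector &v)
{
    int n = v.size();
    std::vector<int> o(n);
    for (int i = 0; i < n; ++i) o[i] = i;
    std::stable_sort(o.begin(), o.end(),
                     [&](int a, int b) { return v[a] < v[b]; });
    return o;
}

// legal cut positions: p means "cut after the p-th point in sort order"
// (1-based prefix length), allowed only between distinct values.
std::vector<int> boundaries(const NumericVector &v, const std::vector<int> &o)
{
    std::vector<int> b;
    int n = v.size();
    for (int p = 1; p < n; ++p)
        if (v[o[p - 1]] != v[o[p]]) b.push_back(p);
    return b;
}

// Map each point to its bin given sorted order o and chosen prefix cuts.
std::vector<int> bins_from_cuts(const std::vector<int> &o,
                                const std::vector<int> &cuts)
{
    int n = o.size();
    std::vector<int> bin(n);
    int b = 0;
    size_t ci = 0;
    for (int p = 0; p < n; ++p) {
        while (ci < cuts.size() && p >= cuts[ci]) { ++b; ++ci; }
        bin[o[p]] = b;
    }
    return bin;
}

// ---------------------------------------------------------------- exhaustive

// all placements of k cuts among candidate boundaries; returns max MI
double exhaustive_shape(const NumericVector &x, const NumericVector &y,
                        int nx, int ny, const LogTab &lg)
{
    int n = x.size();
    std::vector<int> ox = order_of(x), oy = order_of(y);
    std::vector<int> bx = boundaries(x, ox), by = boundaries(y, oy);
    if ((int)bx.size() < nx - 1 || (int)by.size() < ny - 1) return 0.0;

    double best = 0.0;
    std::vector<int> xc(nx - 1), yc(ny - 1);
    // enumerate combinations by index vectors
    std::vector<int> xi(nx - 1), yi(ny - 1);
    for (int i = 0; i < nx - 1; ++i) xi[i] = i;
    bool morex = true;
    while (morex) {
        for (int i = 0; i < nx - 1; ++i) xc[i] = bx[xi[i]];
        std::vector<int> xbin = bins_from_cuts(ox, xc);

        for (int i = 0; i < ny - 1; ++i) yi[i] = i;
        bool morey = true;
        while (morey) {
            for (int i = 0; i < ny - 1; ++i) yc[i] = by[yi[i]];
            std::vector<int> ybin = bins_from_cuts(oy, yc);
            std::vector<int> cnt(nx * ny, 0);
            for (int p = 0; p < n; ++p) cnt[xbin[p] * ny + ybin[p]]++;
            double I = mi_counts(cnt, nx, ny, n, lg);
            if (I > best) best = I;
            // next y combination
            int k = ny - 2;
            while (k >= 0 && yi[k] == (int)by.size() - (ny - 1) + k) --k;
            if (k < 0) morey = false;
            else { ++yi[k]; for (int j = k + 1; j < ny - 1; ++j) yi[j] = yi[j - 1] + 1; }
        }
        int k = nx - 2;
        while (k >= 0 && xi[k] == (int)bx.size() - (nx - 1) + k) --k;
        if (k < 0) morex = false;
        else { ++xi[k]; for (int j = k + 1; j < nx - 1; ++j) xi[j] = xi[j - 1] + 1; }
    }
    return best;
}

// fast O(n^2) exhaustive search restricted to 2x2 grids
double exhaustive_2x2(const NumericVector &x, const NumericVector &y,
                      const LogTab &lg)
{
    int n = x.size();
    std::vector<int> ox = order_of(x), oy = order_of(y);
    std::vector<int> bx = boundaries(x, ox), by = boundaries(y, oy);
    if (bx.empty() || by.empty()) return 0.0;

    // y level (distinct-value index) per point
    std::vector<int> ylev(n);
    int lev = 0;
    for (int p = 0; p < n; ++p) {
        if (p > 0 && y[oy[p]] != y[oy[p - 1]]) ++lev;
        ylev[oy[p]] = lev;
    }
    int dy = lev + 1;
    // cum[p][t] = #ylev <= t among first p points in x order; store flat
    std::vector<int> cum((n + 1) * dy, 0);
    for (int p = 1; p <= n; ++p) {
        int l = ylev[ox[p - 1]];
        for (int t = 0; t < dy; ++t)
            cum[p * dy + t] = cum[(p - 1) * dy + t] + (l <= t ? 1 : 0);
    }
    double best = 0.0;
    for (size_t a = 0; a < bx.size(); ++a) {
        int i = bx[a]; // left block size
        double rterm = xlg(i, lg) + xlg(n - i, lg);
        for (size_t b = 0; b < by.size(); ++b) {
            int t = ylev[oy[by[b] - 1]]; // highest level in the low block
            int n11 = cum[i * dy + t];
            int ncol1 = cum[n * dy + t];
            int n12 = i - n11, n21 = ncol1 - n11;
            int n22 = n - i - n21;
            double I = (xlg(n11, lg) + xlg(n12, lg) + xlg(n21, lg) +
                        xlg(n22, lg) - rterm - xlg(ncol1, lg) -
                        xlg(n - ncol1, lg)) / n + lg[n];
            if (I > best) best = I;
        }
    }
    return best > 0.0 ? best : 0.0;
}

// ----------------------------------------------------------------- heuristic

// nearest-candidate equifrequency cuts: nx bins over candidates b
std::vector<int> equifreq_cuts(const std::vector<int> &b, int n, int nx)
{
    std::vector<int> cuts;
    for (int i = 1; i < nx; ++i) {
        double target = (double)i * n / nx;
        int bestp = -1;
        double bestd = 1e18;
        for (size_t j = 0; j < b.size(); ++j) {
            double d = std::fabs(b[j] - target);
            if (d < bestd) { bestd = d; bestp = b[j]; }
        }
        if (bestp >= 0 && (cuts.empty() || bestp > cuts.back()))
            cuts.push_back(bestp);
    }
    return cuts;
}

// fix x partition (xbin over nx bins), DP-optimise up to ny bins on y
double dp_y_axis(const NumericVector &y, const std::vector<int> &xbin,
                 int nx, int ny, int n, const LogTab &lg)
{
    std::vector<int> oy = order_of(y);
    std::vector<int> by = boundaries(y, oy);
    // candidate boundary prefix lengths, plus the full prefix n
    std::vector<int> q(by);
    q.push_back(n);
    int T = q.size();
    if (T == 1) return 0.0; // constant y

    std::vector<int> rowx(nx, 0);
    for (int p = 0; p < n; ++p) rowx[xbin[p]]++;

    // cumx[t][b]: counts of x-bin b among first q[t] points in y order
    std::vector<int> cumx((T + 1) * nx, 0); // index 0 == empty prefix
    {
        int p = 0;
        std::vector<int> acc(nx, 0);
        for (int t = 0; t < T; ++t) {
            while (p < q[t]) { acc[xbin[oy[p]]]++; ++p; }
            for (int b = 0; b < nx; ++b) cumx[(t + 1) * nx + b] = acc[b];
        }
    }
    auto contrib = [&](int a, int b2) {
        // y bin spanning prefix indices (a, b2]; a,b2 in 0..T (0 = empty)
        int lo = (a == 0) ? 0 : q[a - 1];
        int hi = q[b2 - 1];
        int tot = hi - lo;
        double s = 0.0;
        for (int bb = 0; bb < nx; ++bb) {
            int c = cumx[b2 * nx + bb] - cumx[a * nx + bb];
            if (c > 0)
                s += c * (lg[c] + lg[n] - lg[rowx[bb]] - lg[tot]);
        }
        return s / n;
    };

    const double NEG = -1e18;
    // D[t][k]: best sum using first q[t-1] ... use 1-based prefix index t=1..T
    std::vector<double> prev(T + 1, NEG), cur(T + 1, NEG);
    for (int t = 1; t <= T; ++t) prev[t] = contrib(0, t); // one bin
    double best = prev[T];
    int kmax = std::min(ny, T);
    for (int k = 2; k <= kmax; ++k) {
        std::fill(cur.begin(), cur.end(), NEG);
        for (int t = k; t <= T; ++t) {
            double m = NEG;
            for (int j = k - 1; j < t; ++j) {
                if (prev[j] <= NEG / 2) continue;
                double v = prev[j] + contrib(j, t);
                if (v > m) m = v;
            }
            cur[t] = m;
        }
        if (cur[T] > best) best = cur[T];
        std::swap(prev, cur);
    }
    return best > 0.0 ? best : 0.0;
}

double heuristic_shape(const NumericVector &x, const NumericVector &y,
                       int nx, int ny, const LogTab &lg)
{
    int n = x.size();
    std::vector<int> ox = order_of(x), oy = order_of(y);
    std::vector<int> bx = boundaries(x, ox), by = boundaries(y, oy);
    if (bx.empty() || by.empty()) return 0.0;

    double best = 0.0;
    { // equipartition x, optimise y
        std::vector<int> cuts = equifreq_cuts(bx, n, nx);
        if (!cuts.empty()) {
            std::vector<int> xbin = bins_from_cuts(ox, cuts);
            double I = dp_y_axis(y, xbin, (int)cuts.size() + 1, ny, n, lg);
            if (I > best) best = I;
        }
    }
    { // transpose orientation
        std::vector<int> cuts = equifreq_cuts(by, n, ny);
        if (!cuts.empty()) {
            std::vector<int> ybin = bins_from_cuts(oy, cuts);
            double I = dp_y_axis(x, ybin, (int)cuts.size() + 1, nx, n, lg);
            if (I > best) best = I;
        }
    }
    return best;
}

bool is_constant(const NumericVector &v)
{
    for (int i = 1; i < v.size(); ++i)
        if (v[i] != v[0]) return false;
    return true;
}

// mode: 0 auto (exhaustive where affordable), 1 always exhaustive,
//       2 heuristic search only
double shape_mi(const NumericVector &x, const NumericVector &y,
                int nx, int ny, int mode, const LogTab &lg)
{
    int n = x.size();
    if (mode == 1 || (mode == 0 && n <= 20)) {
        if (nx == 2 && ny == 2) return exhaustive_2x2(x, y, lg);
        return exhaustive_shape(x, y, nx, ny, lg);
    }
    // 2x2 exhaustive costs only O(n^2): keep it exact where affordable
    if (mode == 0 && nx == 2 && ny == 2 && n <= 200)
        return exhaustive_2x2(x, y, lg);
    return heuristic_shape(x, y, nx, ny, lg);
}

} // namespace

// [[Rcpp::export]]
double cpp_max_grid_mi(NumericVector x, NumericVector y, int nx, int ny,
                       int mode)
{
    if (x.size() != y.size()) stop("x and y must have equal length");
    if (is_constant(x) || is_constant(y)) return 0.0;
    LogTab lg = make_logtab(x.size());
    return shape_mi(x, y, nx, ny, mode, lg);
}

// [[Rcpp::export]]
IntegerMatrix cpp_admissible_shapes(int n)
{
    double B = std::pow((double)n, 0.6);
    std::vector<int> xs, ys;
    for (int nx = 2; (double)nx * 2 < B; ++nx)
        for (int ny = 2; (double)nx * ny < B; ++ny) {
            xs.push_back(nx);
            ys.push_back(ny);
        }
    IntegerMatrix out(xs.size(), 2);
    for (size_t i = 0; i < xs.size(); ++i) {
        out(i, 0) = xs[i];
        out(i, 1) = ys[i];
    }
    return out;
}

// mode: 0 auto (exhaustive where affordable), 1 always exhaustive,
//       2 heuristic search only
// [[Rcpp::export]]
double cpp_mic_score(NumericVector x, NumericVector y, int mode)
{
    int n = x.size();
    if (is_constant(x) || is_constant(y)) return 0.0;
    LogTab lg = make_logtab(n);
    double B = std::pow((double)n, 0.6);
    double best = 0.0;
    for (int nx = 2; (double)nx * 2 < B; ++nx)
        for (int ny = 2; (double)nx * ny < B; ++ny) {
            double I = shape_mi(x, y, nx, ny, mode, lg);
            double denom = std::log((double)std::min(nx, ny)) * LOG2E;
            double s = I / denom;
            if (s > best) best = s;
        }
    if (best > 1.0 && best < 1.0 + 1e-12) best = 1.0;
    return best;
}

// [[Rcpp::export]]
NumericVector cpp_mic_profile(NumericMatrix blood, NumericMatrix cancer,
                              int mode)
{
    int m = blood.ncol();
    NumericVector out(m);
    for (int j = 0; j < m; ++j) {
        NumericVector b = blood(_, j), c = cancer(_, j);
        out[j] = cpp_mic_score(b, c, mode);
    }
    return out;
}
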