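#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Sliding sorted buffer. Windows here are small relative to trace length
// (10 for phred seeds, 250 for squiggles, 1000 for profiles), so O(n*w)
// insert/erase with memmove beats heap bookkeeping in practice.

static inline double buf_median(const std::vector<double>& b) {
    const size_t m = b.size();
    if (m % 2 == 1) return b[m / 2];
    return 0.5 * (b[m / 2 - 1] + b[m / 2]);
}

static inline void buf_insert(std::vector<double>& b, double v) {
    b.insert(std::upper_bound(b.begin(), b.end(), v), v);
}

static inline void buf_remove(std::vector<double>& b, double v) {
    b.erase(std::lower_bound(b.begin(), b.end(), v));
}

// Centered window of width w around position i: offsets -((w-1)/2) .. +(w/2),
// truncated at both sequence edges. Even w gives the mean of the two central
// order statistics.
// [[Rcpp::export]]
NumericVector roll_median_center(NumericVector x, int w) {
    const int n = x.size();
    NumericVector out(n);
    if (n == 0) return out;
    if (w < 1) stop("window must be >= 1");
    const int left = (w - 1) / 2, right = w / 2;
    std::vector<double> buf;
    buf.reserve(std::min(n, w));
    int lo = 0, hi = -1; // current inclusive window [lo, hi]
    for (int i = 0; i < n; ++i) {
        const int nlo = std::max(0, i - left);
        const int nhi = std::min(n - 1, i + right);
        while (hi < nhi) buf_insert(buf, x[++hi]);
        while (lo < nlo) buf_remove(buf, x[lo++]);
        out[i] = buf_median(buf);
    }
    return out;
}

// Trailing window starting at i, length min(w, n - i): used for the rolling
// phred profile, where the window anchors at the position and shrinks at the
// read end.
// [[Rcpp::export]]
NumericVector roll_median_left(NumericVector x, int w) {
    const int n = x.size();
    NumericVector out(n);
    if (n == 0) return out;
    if (w < 1) stop("window must be >= 1");
    std::vector<double> buf;
    buf.reserve(std::min(n, w));
    for (int i = n - 1; i >= 0; --i) {
        buf_insert(buf, x[i]);
        if (i + w <= n - 1) buf_remove(buf, x[i + w]);
        out[i] = buf_median(buf);
    }
    return out;
}
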