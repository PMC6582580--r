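#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -1e30;

// One-sided gapped extension with X-drop termination, anchored at the origin.
// q, t: 0-based residue indices into `mat` for the sequence parts to extend
// into (already oriented away from the seed).  A gap of length L costs
// go + L*ge (NCBI convention with go=11, ge=1).  Returns the best
// origin-anchored prefix-alignment score (>= 0) and the (i, j) lengths
// consumed at the optimum.
static void xdrop_one_side(const std::vector<int>& q, const std::vector<int>& t,
                           const NumericMatrix& mat, double go, double ge,
                           double xdrop, double& best, int& bi, int& bj) {
    const int n = q.size(), m = t.size();
    best = 0.0; bi = 0; bj = 0;
    if (n == 0 || m == 0) return;
    // rows over i (query), columns j (target); band of live cells per row
    std::vector<double> H(m + 1, NEG_INF), E(m + 1, NEG_INF);
    std::vector<double> Hn(m + 1), En(m + 1);
    H[0] = 0.0;
    int lo = 0, hi = 0;  // inclusive live range of j in current row i=0
    // row 0: gaps in query only
    for (int j = 1; j <= m; ++j) {
        double s = -go - ge * j;
        if (s < best - xdrop) break;
        H[j] = s;
        hi = j;
    }
    for (int i = 1; i <= n; ++i) {
        int nlo = -1, nhi = -1;
        std::fill(Hn.begin(), Hn.end(), NEG_INF);
        std::fill(En.begin(), En.end(), NEG_INF);
        double F = NEG_INF;  // gap in target, running along the row
        int jmax = std::min(m, hi + 1);
        for (int j = std::max(0, lo); j <= jmax; ++j) {
            double h = NEG_INF, e = NEG_INF;
            if (j > 0 && H[j - 1] > NEG_INF / 2)
                h = H[j - 1] + mat(q[i - 1], t[j - 1]);
            if (H[j] > NEG_INF / 2)
                e = H[j] - go - ge;
            if (E[j] > NEG_INF / 2)
                e = std::max(e, E[j] - ge);
            double f = NEG_INF;
            if (j > 0) {
                if (Hn[j - 1] > NEG_INF / 2) f = Hn[j - 1] - go - ge;
                if (F > NEG_INF / 2) f = std::max(f, F - ge);
            }
            double val = std::max(h, std::max(e, f));
            if (val < best - xdrop) val = NEG_INF;  // X-drop prune
            Hn[j] = val; En[j] = e < best - xdrop ? NEG_INF : e; F = f;
            if (val > NEG_INF / 2) {
                if (nlo < 0) nlo = j;
                nhi = j;
                if (val > best) { best = val; bi = i; bj = j; }
            }
        }
        if (nlo < 0) break;  // whole row pruned
        lo = nlo; hi = nhi;
        std::swap(H, Hn); std::swap(E, En);
    }
}

// Gapped X-drop extension of a word seed.  qidx/tidx are full sequences as
// 0-based residue indices; qs/ts are 0-based word start positions, wlen the
// word length.  Returns raw score (word + both extensions) and the 0-based
// half-open extents of the HSP on query and target.
// [[Rcpp::export]]
List cpp_xdrop_extend(IntegerVector qidx, IntegerVector tidx, int qs, int ts,
                      int wlen, NumericMatrix mat, double gap_open,
                      double gap_extend, double xdrop) {
    // anchor the extension at the best-scoring residue pair of the word:
    // anchoring on the whole word would force any negative word-edge pair
    // into the HSP and cap the attainable score
    int ka = 0; double anchor = mat(qidx[qs], tidx[ts]);
    for (int k = 1; k < wlen; ++k) {
        double s = mat(qidx[qs + k], tidx[ts + k]);
        if (s > anchor) { anchor = s; ka = k; }
    }
    const int qa = qs + ka, ta = ts + ka;
    // right side
    std::vector<int> qr, tr;
    for (int i = qa + 1; i < qidx.size(); ++i) qr.push_back(qidx[i]);
    for (int j = ta + 1; j < tidx.size(); ++j) tr.push_back(tidx[j]);
    double rbest; int rbi, rbj;
    xdrop_one_side(qr, tr, mat, gap_open, gap_extend, xdrop, rbest, rbi, rbj);
    // left side (reversed prefixes)
    std::vector<int> ql, tl;
    for (int i = qa - 1; i >= 0; --i) ql.push_back(qidx[i]);
    for (int j = ta - 1; j >= 0; --j) tl.push_back(tidx[j]);
    double lbest; int lbi, lbj;
    xdrop_one_side(ql, tl, mat, gap_open, gap_extend, xdrop, lbest, lbi, lbj);
    return List::create(
        _["score"] = anchor + rbest + lbest,
        _["q_start"] = qa - lbi, _["q_end"] = qa + 1 + rbi,
        _["t_start"] = ta - lbj, _["t_end"] = ta + 1 + rbj);
}

// Global (Needleman-Wunsch) alignment with affine gaps over a precomputed
// column-score matrix S (rows = columns of profile A, cols = profile B).
// Returns aligned column indices (1-based; 0 marks a gap) for both profiles.
// [[Rcpp::export]]
List cpp_profile_align(NumericMatrix S, double gap_open, double gap_extend) {
    const int n = S.nrow(), m = S.ncol();
    NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
    IntegerMatrix TB(n + 1, m + 1);  // 0 diag, 1 up (gap in B), 2 left (gap in A)
    for (int j = 0; j <= m; ++j) { E(0, j) = NEG_INF; }
    for (int i = 0; i <= n; ++i) { F(i, 0) = NEG_INF; }
    H(0, 0) = 0;
    for (int i = 1; i <= n; ++i) {
        E(i, 0) = std::max(H(i - 1, 0) - gap_open - gap_extend,
                           E(i - 1, 0) - gap_extend);
        H(i, 0) = E(i, 0); TB(i, 0) = 1;
    }
    for (int j = 1; j <= m; ++j) {
        F(0, j) = std::max(H(0, j - 1) - gap_open - gap_extend,
                           F(0, j - 1) - gap_extend);
        H(0, j) = F(0, j); TB(0, j) = 2;
    }
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            E(i, j) = std::max(H(i - 1, j) - gap_open - gap_extend,
                               E(i - 1, j) - gap_extend);
            F(i, j) = std::max(H(i, j - 1) - gap_open - gap_extend,
                               F(i, j - 1) - gap_extend);
            double d = H(i - 1, j - 1) + S(i - 1, j - 1);
            double best = d; int tb = 0;
            if (E(i, j) > best) { best = E(i, j); tb = 1; }
            if (F(i, j) > best) { best = F(i, j); tb = 2; }
            H(i, j) = best; TB(i, j) = tb;
        }
    }
    std::vector<int> a, b;
    int i = n, j = m;
    while (i > 0 || j > 0) {
        int tb = TB(i, j);
        if (i > 0 && (j == 0 || tb == 1)) { a.push_back(i); b.push_back(0); --i; }
        else if (j > 0 && (i == 0 || tb == 2)) { a.push_back(0); b.push_back(j); --j; }
        else { a.push_back(i); b.push_back(j); --i; --j; }
    }
    std::reverse(a.begin(), a.end());
    std::reverse(b.begin(), b.end());
    return List::create(_["score"] = H(n, m),
                        _["a"] = IntegerVector(a.begin(), a.end()),
                        _["b"] = IntegerVector(b.begin(), b.end()));
}
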