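#include <Rcpp.h>
#include <cstring>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP) with a fixed,
// deterministic tie-break order: diagonal, then up (gap in the second
// sequence), then left (gap in the first sequence).  A gap of length L
// scores gapOpen + L * gapExtend.  Modes: 0 = global, 1 = semiglobal
// (leading and trailing gaps in either sequence are free), 2 = local
// (Smith-Waterman; only the match state may restart at zero).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double subscore(char x, char y, double match, double mismatch) {
    if (x == 'N' || y == 'N') return 0.0;
    return (x == y) ? match : mismatch;
}

// state codes: 0 = M (diagonal), 1 = X (up, consumes a), 2 = Y (left, consumes b)
// pointer codes per cell/state: predecessor state 0..2, 3 = start/stop marker

// [[Rcpp::export]]
List cpp_align_pair(std::string a, std::string b,
                    double match, double mismatch,
                    double gapOpen, double gapExtend,
                    int mode) {
    const int n = (int) a.size();
    const int m = (int) b.size();
    if (n == 0 || m == 0)
        stop("cpp_align_pair: empty sequence");
    const R_xlen_t ncell = (R_xlen_t)(n + 1) * (R_xlen_t)(m + 1);
    if (ncell > (R_xlen_t) 3e8)
        stop("cpp_align_pair: DP matrix too large (%d x %d)", n, m);

    std::vector<double> M(ncell, NEG_INF), X(ncell, NEG_INF), Y(ncell, NEG_INF);
    std::vector<unsigned char> pM(ncell, 3), pX(ncell, 3), pY(ncell, 3);
    const R_xlen_t W = m + 1;
#define IDX(i, j) ((R_xlen_t)(i) * W + (j))

    const bool freeEnds = (mode == 1);
    const bool local = (mode == 2);

    M[IDX(0, 0)] = 0.0;
    for (int i = 1; i <= n; ++i) {
        if (freeEnds || local) {
            X[IDX(i, 0)] = 0.0;      // free leading gap / local start
            pX[IDX(i, 0)] = 3;
        } else {
            X[IDX(i, 0)] = gapOpen + i * gapExtend;
            pX[IDX(i, 0)] = (i == 1) ? 0 : 1;
        }
        if (local) { M[IDX(i, 0)] = 0.0; pM[IDX(i, 0)] = 3; }
    }
    for (int j = 1; j <= m; ++j) {
        if (freeEnds || local) {
            Y[IDX(0, j)] = 0.0;
            pY[IDX(0, j)] = 3;
        } else {
            Y[IDX(0, j)] = gapOpen + j * gapExtend;
            pY[IDX(0, j)] = (j == 1) ? 0 : 2;
        }
        if (local) { M[IDX(0, j)] = 0.0; pM[IDX(0, j)] = 3; }
    }

    for (int i = 1; i <= n; ++i) {
        const char ai = a[i - 1];
        for (int j = 1; j <= m; ++j) {
            const R_xlen_t here = IDX(i, j), dg = IDX(i - 1, j - 1),
                           up = IDX(i - 1, j), lf = IDX(i, j - 1);
            // M: tie-break prefers predecessor M, then X, then Y
            double s = subscore(ai, b[j - 1], match, mismatch);
            double best = M[dg]; unsigned char bp = 0;
            if (X[dg] > best) { best = X[dg]; bp = 1; }
            if (Y[dg] > best) { best = Y[dg]; bp = 2; }
            double mv = (best == NEG_INF) ? NEG_INF : best + s;
            if (local && mv < 0.0) { mv = 0.0; bp = 3; }
            M[here] = mv; pM[here] = bp;
            // X: gap in b (consume a)
            double xo = (M[up] == NEG_INF) ? NEG_INF : M[up] + gapOpen + gapExtend;
            double xx = (X[up] == NEG_INF) ? NEG_INF : X[up] + gapExtend;
            double xy = (Y[up] == NEG_INF) ? NEG_INF : Y[up] + gapOpen + gapExtend;
            best = xo; bp = 0;
            if (xx > best) { best = xx; bp = 1; }
            if (xy > best) { best = xy; bp = 2; }
            X[here] = best; pX[here] = bp;
            // Y: gap in a (consume b)
            double yo = (M[lf] == NEG_INF) ? NEG_INF : M[lf] + gapOpen + gapExtend;
            double yx = (X[lf] == NEG_INF) ? NEG_INF : X[lf] + gapOpen + gapExtend;
            double yy = (Y[lf] == NEG_INF) ? NEG_INF : Y[lf] + gapExtend;
            best = yo; bp = 0;
            if (yx > best) { best = yx; bp = 1; }
            if (yy > best) { best = yy; bp = 2; }
            Y[here] = best; pY[here] = bp;
        }
    }

    // locate the terminus
    int ei = n, ej = m, estate = 0;
    double score;
    if (mode == 0) {
        score = M[IDX(n, m)]; estate = 0;
        if (X[IDX(n, m)] > score) { score = X[IDX(n, m)]; estate = 1; }
        if (Y[IDX(n, m)] > score) { score = Y[IDX(n, m)]; estate = 2; }
    } else if (freeEnds) {
        // best cell on last row or last column, any state; prefer M then X
        // then Y, larger i+j first for determinism; i = 0 / j = 0 border
        // cells admit the zero-overlap alignment
        score = NEG_INF; estate = 0;
        for (int i = n; i >= 0; --i) {
            const R_xlen_t c = IDX(i, m);
            if (M[c] > score) { score = M[c]; ei = i; ej = m; estate = 0; }
            if (X[c] > score) { score = X[c]; ei = i; ej = m; estate = 1; }
            if (Y[c] > score) { score = Y[c]; ei = i; ej = m; estate = 2; }
        }
        for (int j = m; j >= 0; --j) {
            const R_xlen_t c = IDX(n, j);
            if (M[c] > score) { score = M[c]; ei = n; ej = j; estate = 0; }
            if (X[c] > score) { score = X[c]; ei = n; ej = j; estate = 1; }
            if (Y[c] > score) { score = Y[c]; ei = n; ej = j; estate = 2; }
        }
    } else {
        score = 0.0; estate = 0; ei = 0; ej = 0;
        for (int i = 1; i <= n; ++i)
            for (int j = 1; j <= m; ++j) {
                const R_xlen_t c = IDX(i, j);
                if (M[c] > score) { score = M[c]; ei = i; ej = j; }
            }
    }

    // traceback; pointer value 3 marks a start cell (origin, free border, or
    // local restart) and is never consumed as a move
    std::string ra, rb;
    ra.reserve(n + m); rb.reserve(n + m);
    int i = ei, j = ej, st = estate;
    while (!(i == 0 && j == 0)) {
        unsigned char prev;
        if (st == 0) {
            prev = pM[IDX(i, j)];
            if (prev == 3) break;
            ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
            --i; --j;
        } else if (st == 1) {
            prev = pX[IDX(i, j)];
            if (prev == 3) break;
            ra.push_back(a[i - 1]); rb.push_back('-');
            --i;
        } else {
            prev = pY[IDX(i, j)];
            if (prev == 3) break;
            ra.push_back('-'); rb.push_back(b[j - 1]);
            --j;
        }
        st = prev;
    }
    int si = i, sj = j;  // alignment starts after (si, sj)
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());

    if (mode == 0 || freeEnds) {
        // pad unaligned ends (global should already be at origin; semiglobal pads)
        std::string pa, pb;
        for (int k = 0; k < si; ++k) { pa.push_back(a[k]); pb.push_back('-'); }
        for (int k = 0; k < sj; ++k) { pa.push_back('-'); pb.push_back(b[k]); }
        ra = pa + ra; rb = pb + rb;
        std::string sa, sb;
        for (int k = ei; k < n; ++k) { sa.push_back(a[k]); sb.push_back('-'); }
        for (int k = ej; k < m; ++k) { sa.push_back('-'); sb.push_back(b[k]); }
        ra += sa; rb += sb;
    }

    return List::create(
        _["a"] = ra, _["b"] = rb, _["score"] = score,
        _["start_a"] = si + 1, _["end_a"] = ei,
        _["start_b"] = sj + 1, _["end_b"] = ej);
#undef IDX
}

// Profile-profile global alignment used by the progressive aligner.
// A and B are 5 x L frequency matrices over (A, C, G, T, gap).  Column
// score sums residue-pair scores weighted by frequencies; gap columns in
// a profile are neutral.  Returns the merge path: 0 = take both, 1 =
// take A only (gap column inserted into B), 2 = take B only.

// [[Rcpp::export]]
IntegerVector cpp_align_profiles(NumericMatrix A, NumericMatrix B,
                                 double match, double mismatch,
                                 double gapOpen, double gapExtend) {
    const int n = A.ncol(), m = B.ncol();
    if (A.nrow() != 5 || B.nrow() != 5)
        stop("profiles must have 5 rows (A,C,G,T,-)");
    const R_xlen_t W = m + 1, ncell = (R_xlen_t)(n + 1) * W;
    std::vector<double> M(ncell, NEG_INF), X(ncell, NEG_INF), Y(ncell, NEG_INF);
    std::vector<unsigned char> pM(ncell, 3), pX(ncell, 3), pY(ncell, 3);
#define IDX(i, j) ((R_xlen_t)(i) * W + (j))
    M[IDX(0, 0)] = 0.0;
    for (int i = 1; i <= n; ++i) {
        X[IDX(i, 0)] = gapOpen + i * gapExtend;
        pX[IDX(i, 0)] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= m; ++j) {
        Y[IDX(0, j)] = gapOpen + j * gapExtend;
        pY[IDX(0, j)] = (j == 1) ? 0 : 2;
    }
    // residue fractions (gap row excluded; renormalised by residue mass)
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            const R_xlen_t here = IDX(i, j), dg = IDX(i - 1, j - 1),
                           up = IDX(i - 1, j), lf = IDX(i, j - 1);
            double s = 0.0;
            for (int x = 0; x < 4; ++x) {
                const double fa = A(x, i - 1);
                if (fa == 0.0) continue;
                for (int y = 0; y < 4; ++y) {
                    const double fb = B(y, j - 1);
                    if (fb == 0.0) continue;
                    s += fa * fb * ((x == y) ? match : mismatch);
                }
            }
            double best = M[dg]; unsigned char bp = 0;
            if (X[dg] > best) { best = X[dg]; bp = 1; }
            if (Y[dg] > best) { best = Y[dg]; bp = 2; }
            M[here] = (best == NEG_INF) ? NEG_INF : best + s; pM[here] = bp;

            double xo = (M[up] == NEG_INF) ? NEG_INF : M[up] + gapOpen + gapExtend;
            double xx = (X[up] == NEG_INF) ? NEG_INF : X[up] + gapExtend;
            double xy = (Y[up] == NEG_INF) ? NEG_INF : Y[up] + gapOpen + gapExtend;
            best = xo; bp = 0;
            if (xx > best) { best = xx; bp = 1; }
            if (xy > best) { best = xy; bp = 2; }
            X[here] = best; pX[here] = bp;

            double yo = (M[lf] == NEG_INF) ? NEG_INF : M[lf] + gapOpen + gapExtend;
            double yx = (X[lf] == NEG_INF) ? NEG_INF : X[lf] + gapOpen + gapExtend;
            double yy = (Y[lf] == NEG_INF) ? NEG_INF : Y[lf] + gapExtend;
            best = yo; bp = 0;
            if (yx > best) { best = yx; bp = 1; }
            if (yy > best) { best = yy; bp = 2; }
            Y[here] = best; pY[here] = bp;
        }
    }
    int st = 0;
    double sc = M[IDX(n, m)];
    if (X[IDX(n, m)] > sc) { sc = X[IDX(n, m)]; st = 1; }
    if (Y[IDX(n, m)] > sc) { sc = Y[IDX(n, m)]; st = 2; }
    std::vector<int> path;
    int i = n, j = m;
    while (i > 0 || j > 0) {
        if (i == 0) { path.push_back(2); --j; continue; }
        if (j == 0) { path.push_back(1); --i; continue; }
        unsigned char prev;
        if (st == 0) { prev = pM[IDX(i, j)]; path.push_back(0); --i; --j; }
        else if (st == 1) { prev = pX[IDX(i, j)]; path.push_back(1); --i; }
        else { prev = pY[IDX(i, j)]; path.push_back(2); --j; }
        st = prev;
    }
    std::reverse(path.begin(), path.end());
    return wrap(path);
#undef IDX
}
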