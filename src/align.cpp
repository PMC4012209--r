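#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman / Gotoh).
// Sequences arrive as 0-based integer codes indexing the substitution
// matrix; a gap of length L costs gapOpen1 + (L - 1) * gapExt, so the
// BLAST convention "open 11 / extend 1" corresponds to gapOpen1 = 12,
// gapExt = 1.

// Best ungapped local segment score over all diagonals.  The recurrence
// H[i][j] = max(0, H[i-1][j-1] + s(a_i, b_j)) carries no dependency
// along a row, so the inner loop vectorizes.
static int ungapped_max(const int* a, int la, const int* b, int lb,
                        const int* sub, int ncol) {
    std::vector<int> prev(lb + 1, 0), cur(lb + 1, 0);
    int best = 0;
    for (int i = 0; i < la; ++i) {
        const int* srow = sub + (size_t)a[i] * ncol;
        const int* p = prev.data();
        int* c = cur.data() + 1;
        int rowbest = 0;
        for (int j = 0; j < lb; ++j) {
            int h = p[j] + srow[b[j]];
            h = h > 0 ? h : 0;
            c[j] = h;
            rowbest = h > rowbest ? h : rowbest;
        }
        best = rowbest > best ? rowbest : best;
        std::swap(prev, cur);
        cur[0] = 0;
    }
    return best;
}

// Score-only Gotoh.
static int sw_score(const int* a, int la, const int* b, int lb,
                    const int* sub, int ncol, int gapo1, int gape) {
    const int NEG = -1000000000;
    std::vector<int> H(lb + 1, 0), F(lb + 1, NEG);
    int best = 0;
    for (int i = 0; i < la; ++i) {
        const int* srow = sub + (size_t)a[i] * ncol;
        int hdiag = 0;   // H[i-1][j-1]
        int e = NEG;     // gap in a (horizontal)
        int hleft = 0;   // H[i][j-1]
        for (int j = 1; j <= lb; ++j) {
            int eo = hleft - gapo1, ee = e - gape;
            e = eo > ee ? eo : ee;
            int fo = H[j] - gapo1, fe = F[j] - gape;
            int f = fo > fe ? fo : fe;
            F[j] = f;
            int h = hdiag + srow[b[j - 1]];
            h = h > e ? h : e;
            h = h > f ? h : f;
            h = h > 0 ? h : 0;
            hdiag = H[j];
            H[j] = h;
            hleft = h;
            best = h > best ? h : best;
        }
    }
    return best;
}

struct SwFull {
    int score, sa, ea, sb, eb, cols;
};

// Full Gotoh with alignment-start and column-count propagation, so the
// optimal local alignment's spans and column count (gap columns
// included) come out without a traceback matrix.  Tie preference:
// diagonal, then horizontal gap, then vertical gap.
static SwFull sw_full(const int* a, int la, const int* b, int lb,
                      const int* sub, int ncol, int gapo1, int gape) {
    const int NEG = -1000000000;
    struct Cell { int h, sa, sb, cols; };
    std::vector<Cell> H(lb + 1), Hprev(lb + 1);
    struct GCell { int v, sa, sb, cols; };
    std::vector<GCell> F(lb + 1);
    for (int j = 0; j <= lb; ++j) {
        Hprev[j] = {0, 0, 0, 0};
        F[j] = {NEG, 0, 0, 0};
    }
    SwFull best = {0, 0, 0, 0, 0, 0};
    for (int i = 1; i <= la; ++i) {
        const int* srow = sub + (size_t)a[i - 1] * ncol;
        H[0] = {0, 0, 0, 0};
        GCell E = {NEG, 0, 0, 0};
        for (int j = 1; j <= lb; ++j) {
            // E: gap in a, consuming b[j]
            int eo = H[j - 1].h - gapo1, ee = E.v - gape;
            if (eo >= ee) E = {eo, H[j - 1].sa, H[j - 1].sb, H[j - 1].cols + 1};
            else          E = {ee, E.sa, E.sb, E.cols + 1};
            // F: gap in b, consuming a[i]
            int fo = Hprev[j].h - gapo1, fe = F[j].v - gape;
            if (fo >= fe) F[j] = {fo, Hprev[j].sa, Hprev[j].sb, Hprev[j].cols + 1};
            else          F[j] = {fe, F[j].sa, F[j].sb, F[j].cols + 1};
            int d = Hprev[j - 1].h + srow[b[j - 1]];
            Cell cur;
            if (d >= E.v && d >= F[j].v && d > 0) {
                if (Hprev[j - 1].h == 0 && Hprev[j - 1].cols == 0)
                    cur = {d, i, j, 1};       // fresh start
                else
                    cur = {d, Hprev[j - 1].sa, Hprev[j - 1].sb,
                           Hprev[j - 1].cols + 1};
            } else if (E.v >= F[j].v && E.v > 0) {
                cur = {E.v, E.sa, E.sb, E.cols};
            } else if (F[j].v > 0) {
                cur = {F[j].v, F[j].sa, F[j].sb, F[j].cols};
            } else {
                cur = {0, 0, 0, 0};
            }
            H[j] = cur;
            if (cur.h > best.score) {
                best = {cur.h, cur.sa, i, cur.sb, j, cur.cols};
            }
        }
        std::swap(H, Hprev);
    }
    return best;
}

// [[Rcpp::export(name = ".cppUngappedMax")]]
int cpp_ungapped_max(IntegerVector a, IntegerVector b, IntegerMatrix sub) {
    return ungapped_max(INTEGER(a), a.size(), INTEGER(b), b.size(),
                        INTEGER(sub), sub.ncol());
}

// [[Rcpp::export(name = ".cppSwScore")]]
int cpp_sw_score(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                 int gapOpen1, int gapExt) {
    return sw_score(INTEGER(a), a.size(), INTEGER(b), b.size(),
                    INTEGER(sub), sub.ncol(), gapOpen1, gapExt);
}

// [[Rcpp::export(name = ".cppSwFull")]]
List cpp_sw_full(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                 int gapOpen1, int gapExt) {
    SwFull r = sw_full(INTEGER(a), a.size(), INTEGER(b), b.size(),
                       INTEGER(sub), sub.ncol(), gapOpen1, gapExt);
    return List::create(_["score"] = r.score,
                        _["startA"] = r.sa, _["endA"] = r.ea,
                        _["startB"] = r.sb, _["endB"] = r.eb,
                        _["cols"] = r.cols);
}

// All-pairs linkage under joint length-coverage and score-density
// thresholds.  For each unordered pair: an optional ungapped pre-screen
// (exact segment score; a pair below `screenMin` cannot be linked under
// the generator's substitution-only families, see package vignette),
// then a score-only pass against the minimum raw score any linked pair
// must reach, then the full pass for spans and column counts.
// [[Rcpp::export(name = ".cppLinkedPairs")]]
IntegerMatrix cpp_linked_pairs(List seqs, IntegerMatrix sub,
                               int gapOpen1, int gapExt,
                               double lengthCov, double scoreDensity,
                               double lambda, double lnK,
                               int screenMin, int screenLenMin) {
    int n = seqs.size();
    std::vector<const int*> ptr(n);
    std::vector<int> len(n);
    std::vector<IntegerVector> keep(n);
    for (int i = 0; i < n; ++i) {
        keep[i] = seqs[i];
        ptr[i] = INTEGER(keep[i]);
        len[i] = keep[i].size();
    }
    const int ncol = sub.ncol();
    const int* S = INTEGER(sub);
    const double ln2 = 0.6931471805599453;
    std::vector<int> ei, ej;
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            int la = len[i], lb = len[j];
            int maxlen = la > lb ? la : lb;
            int minlen = la < lb ? la : lb;
            // minimum alignment columns any linked pair can have
            int mincols = (int)std::ceil(lengthCov * maxlen - 1e-9);
            if (mincols < 1) mincols = 1;
            // minimum raw score: density and column bound
            double treq = (scoreDensity * ln2 * mincols + lnK) / lambda;
            // composition-free cap: matched columns <= minlen, max entry 11
            if (11.0 * minlen < treq) continue;
            if (screenMin > 0 && minlen >= screenLenMin) {
                int m = ungapped_max(ptr[i], la, ptr[j], lb, S, ncol);
                if (m < screenMin) continue;
            }
            int sc = sw_score(ptr[i], la, ptr[j], lb, S, ncol,
                              gapOpen1, gapExt);
            if ((double)sc < treq) continue;
            SwFull r = sw_full(ptr[i], la, ptr[j], lb, S, ncol,
                               gapOpen1, gapExt);
            if (r.cols <= 0) continue;
            double covA = (double)(r.ea - r.sa + 1) / la;
            double covB = (double)(r.eb - r.sb + 1) / lb;
            if (covA < lengthCov || covB < lengthCov) continue;
            double bits = (lambda * r.score - lnK) / ln2;
            if (bits / r.cols < scoreDensity) continue;
            ei.push_back(i + 1);
            ej.push_back(j + 1);
        }
        Rcpp::checkUserInterrupt();
    }
    IntegerMatrix out(ei.size(), 2);
    for (size_t k = 0; k < ei.size(); ++k) {
        out(k, 0) = ei[k];
        out(k, 1) = ej[k];
    }
    return out;
}
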