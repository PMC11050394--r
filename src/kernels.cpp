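#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Base codes used throughout the package: a=0, t=1, c=2, g=3, N=4
// (the let() order of the dinucleotide row index, zero-based).
// Dinucleotide row for (prev, cur): n = prev + 4*cur  (0..15); a virtual
// row 16 of zeros stands for "no context" (window start, N base, gap).

static const int NO_ROW = 16;

// Multi-version the hot loops for wider SIMD units when the CPU has them;
// the binary stays portable (runtime dispatch, baseline fallback).
#if defined(__x86_64__) && defined(__GNUC__) && !defined(__clang__)
#define IP_HOT __attribute__((target_clones("arch=x86-64-v4", "arch=x86-64-v3", "default")))
#else
#define IP_HOT
#endif

// Flatten a 16 x L weight matrix to rows of length L plus a 17th zero row,
// so the inner DP loop reads one contiguous row per window position.
static std::vector<float> flatten_weights(const NumericMatrix& W) {
    const int L = W.ncol();
    std::vector<float> wf(17 * (size_t)L, 0.0f);
    for (int n = 0; n < 16; ++n)
        for (int j = 0; j < L; ++j)
            wf[(size_t)n * L + j] = (float)W(n, j);
    return wf;
}

static std::vector<double> flatten_weights_d(const NumericMatrix& W) {
    const int L = W.ncol();
    std::vector<double> wf(17 * (size_t)L, 0.0);
    for (int n = 0; n < 16; ++n)
        for (int j = 0; j < L; ++j)
            wf[(size_t)n * L + j] = W(n, j);
    return wf;
}

// Dinucleotide row per window position (0-based local index).
// Position 0 has no predecessor inside the window -> neutral row.
static inline void window_rows(const int* seq, int start, int len, int* rows) {
    rows[0] = NO_ROW;
    for (int i = 1; i < len; ++i) {
        const int prev = seq[start + i - 1], cur = seq[start + i];
        rows[i] = (prev < 4 && cur < 4) ? prev + 4 * cur : NO_ROW;
    }
}

// Score-only Smith-Waterman style local DP between a PWM (columns) and a
// window; linear gap penalty g on both sides.  Returns the best cell.
//
// Row update in vectorizable passes.  Pass 1 applies the diagonal (match)
// and vertical (base-only) moves, giving provisional values v(j).  The
// horizontal (column-only) gap carry is
//     c(j) = max_{k<j} [ v(k) - (j-k) g ] = max_{k<j} [ v(k) + k g ] - j g,
// a prefix maximum of B(j) = v(j) + j g, computed by ping-pong log-step
// doubling so every loop is dependence-free.  The carry is always an
// earlier cell minus g, so it never sets a new global maximum; the global
// maximum is collected in pass 1.

IP_HOT
static float dp_pass1(const float* __restrict__ Hp,
                      const float* __restrict__ wrow,
                      float* __restrict__ Hc, float* __restrict__ B,
                      const float* __restrict__ jg, int L, float gf) {
    float rowbest = 0.0f;
    for (int j = 0; j < L; ++j) {
        float v = Hp[j] + wrow[j];
        const float up = Hp[j + 1] - gf;
        v = v > up ? v : up;
        v = v > 0.0f ? v : 0.0f;
        Hc[j + 1] = v;
        B[j + 1] = v + jg[j + 1];
        rowbest = rowbest > v ? rowbest : v;
    }
    return rowbest;
}

IP_HOT
static void dp_prefmax(float* __restrict__ A, float* __restrict__ T, int L) {
    for (int s = 1; s < L; s <<= 1) {
        for (int j = 1; j <= L; ++j) {
            float a = A[j];
            if (j - s >= 1) {
                const float b = A[j - s];
                a = a > b ? a : b;
            }
            T[j] = a;
        }
        std::swap(A, T);
    }
}

IP_HOT
static void dp_combine(float* __restrict__ Hc, const float* __restrict__ pm,
                       const float* __restrict__ jg, int L) {
    for (int j = 2; j <= L; ++j) {
        const float c = pm[j - 1] - jg[j];
        Hc[j] = Hc[j] > c ? Hc[j] : c;
    }
}

struct DpBuffers {
    std::vector<float> Hp, Hc, jg, B, T;
    int levels;
    DpBuffers(int L, double g)
        : Hp(L + 1), Hc(L + 1), jg(L + 1), B(L + 1), T(L + 1) {
        for (int j = 0; j <= L; ++j) jg[j] = (float)(g * j);
        B[0] = T[0] = -1e30f;
        levels = 0;
        for (int s = 1; s < L; s <<= 1) ++levels;
    }
};

static double dp_score(const int* rows, int len, const float* wf, int L,
                       double g, DpBuffers& buf) {
    float best = 0.0f;
    const float gf = (float)g;
    float* Hp = buf.Hp.data();
    float* Hc = buf.Hc.data();
    std::memset(Hp, 0, sizeof(float) * (size_t)(L + 1));
    Hc[0] = 0.0f;
    for (int i = 0; i < len; ++i) {
        const float* wrow = wf + (size_t)rows[i] * L;
        const float rb = dp_pass1(Hp, wrow, Hc, buf.B.data(), buf.jg.data(),
                                  L, gf);
        if (rb > best) best = rb;
        dp_prefmax(buf.B.data(), buf.T.data(), L);
        const float* pm = (buf.levels % 2 == 1) ? buf.T.data() : buf.B.data();
        dp_combine(Hc, pm, buf.jg.data(), L);
        std::swap(Hp, Hc);
    }
    return (double)best;
}

// Anchored-fit pass 1: no local floor; the row starts from the paid
// leading-gap state Hc[0].
IP_HOT
static void dp_pass1_anch(const float* __restrict__ Hp,
                          const float* __restrict__ wrow,
                          float* __restrict__ Hc, float* __restrict__ B,
                          const float* __restrict__ jg, int L, float gf) {
    for (int j = 0; j < L; ++j) {
        float v = Hp[j] + wrow[j];
        const float up = Hp[j + 1] - gf;
        v = v > up ? v : up;
        Hc[j + 1] = v;
        B[j + 1] = v + jg[j + 1];
    }
}

// Anchored fit score: every matrix column is consumed (column gaps cost
// g, including leading/trailing ones), the alignment starts at the first
// window base (leading window bases are paid as gaps), trailing window
// bases are free.  The score is the best over all sequence end positions
// of the full-column alignment; it peaks sharply where a matrix-like
// element begins exactly at the window start.
static double dp_score_anchored(const int* rows, int len, const float* wf,
                                int L, double g, DpBuffers& buf) {
    const float gf = (float)g;
    float* Hp = buf.Hp.data();
    float* Hc = buf.Hc.data();
    for (int j = 0; j <= L; ++j) Hp[j] = -gf * j;
    double best = (double)Hp[L];
    for (int i = 0; i < len; ++i) {
        const float* wrow = wf + (size_t)rows[i] * L;
        Hc[0] = -gf * (float)(i + 1);
        buf.B[0] = Hc[0];
        dp_pass1_anch(Hp, wrow, Hc, buf.B.data(), buf.jg.data(), L, gf);
        dp_prefmax(buf.B.data(), buf.T.data(), L);
        const float* pm = (buf.levels % 2 == 1) ? buf.T.data() : buf.B.data();
        dp_combine(Hc, pm, buf.jg.data(), L);
        // carry from the leading-gap state
        const float c0 = buf.B[0] - buf.jg[1];
        if (L >= 1 && c0 > Hc[1]) {
            // re-propagate is unnecessary beyond j=1: pm already includes
            // B[1..]; only the j=1 cell can be improved by the j=0 state
            float c = c0;
            for (int j = 1; j <= L; ++j) {
                if (c > Hc[j]) Hc[j] = c;
                else break;
                c = Hc[j] - gf;
            }
        }
        if ((double)Hc[L] > best) best = (double)Hc[L];
        std::swap(Hp, Hc);
    }
    return best;
}

// [[Rcpp::export(name = ".cpp_align_score")]]
double cpp_align_score(IntegerVector window, NumericMatrix W, double gap) {
    const int len = window.size(), L = W.ncol();
    if (W.nrow() != 16) stop("weight matrix must have 16 rows");
    if (len < 2) return 0.0;
    std::vector<float> wf = flatten_weights(W);
    std::vector<int> rows(len);
    std::vector<int> seq(window.begin(), window.end());
    window_rows(seq.data(), 0, len, rows.data());
    DpBuffers buf(L, gap);
    return dp_score(rows.data(), len, wf.data(), L, gap, buf);
}

// Scan many windows of a coded genome.  starts0 are 0-based window start
// offsets.  Windows containing any masked base, or more than maxNfrac
// ambiguous bases, are flagged and given F = 0 without alignment.
// [[Rcpp::export(name = ".cpp_scan")]]
List cpp_scan(IntegerVector seq, LogicalVector mask, NumericMatrix W,
              double gap, int window, NumericVector maxNfrac,
              IntegerVector starts0, bool anchored) {
    const int L = W.ncol();
    const R_xlen_t n = seq.size();
    if (W.nrow() != 16) stop("weight matrix must have 16 rows");
    std::vector<float> wf = flatten_weights(W);
    // prefix counts of masked and ambiguous bases
    std::vector<int> pmask(n + 1, 0), pN(n + 1, 0);
    const int* sp = INTEGER(seq);
    const int* mp = LOGICAL(mask);
    for (R_xlen_t i = 0; i < n; ++i) {
        pmask[i + 1] = pmask[i] + (mp[i] == TRUE ? 1 : 0);
        pN[i + 1] = pN[i] + (sp[i] >= 4 ? 1 : 0);
    }
    const int nw = starts0.size();
    NumericVector F(nw);
    LogicalVector flagged(nw);
    std::vector<int> rows(window);
    DpBuffers buf(L, gap);
    const double nfrac = maxNfrac[0];
    for (int k = 0; k < nw; ++k) {
        const int x = starts0[k];
        if (x < 0 || x + window > n) stop("window out of range");
        if (pmask[x + window] - pmask[x] > 0 ||
            pN[x + window] - pN[x] >= nfrac * window) {
            F[k] = 0.0;
            flagged[k] = true;
            continue;
        }
        window_rows(sp, x, window, rows.data());
        F[k] = anchored
            ? dp_score_anchored(rows.data(), window, wf.data(), L, gap, buf)
            : dp_score(rows.data(), window, wf.data(), L, gap, buf);
        flagged[k] = false;
        if (k % 4096 == 0) Rcpp::checkUserInterrupt();
    }
    return List::create(_["F"] = F, _["flagged"] = flagged);
}

// Full DP with traceback for one window.  Returns the optimal local
// alignment trace: s1 = base codes with NA at deletions (column consumed,
// no base), s2 = 1-based matrix columns with NA where a base is aligned to
// no column, plus the window-local 1-based span of aligned bases.
// Backtracking ties prefer diagonal > up (base, no column) > left.
// [[Rcpp::export(name = ".cpp_align_trace")]]
List cpp_align_trace(IntegerVector window, NumericMatrix W, double gap) {
    const int len = window.size(), L = W.ncol();
    if (W.nrow() != 16) stop("weight matrix must have 16 rows");
    if (len < 2) {
        return List::create(_["score"] = 0.0,
                            _["s1"] = IntegerVector(0),
                            _["s2"] = IntegerVector(0),
                            _["first"] = NA_INTEGER, _["last"] = NA_INTEGER);
    }
    std::vector<double> wf = flatten_weights_d(W);
    std::vector<int> seq(window.begin(), window.end());
    std::vector<int> rows(len);
    window_rows(seq.data(), 0, len, rows.data());
    // full H matrix ((len+1) x (L+1)) and move matrix
    // moves: 0 = local start, 1 = diag, 2 = up (consume base), 3 = left
    const size_t W1 = (size_t)L + 1;
    std::vector<double> H((size_t)(len + 1) * W1, 0.0);
    std::vector<unsigned char> mv((size_t)(len + 1) * W1, 0);
    double best = 0.0;
    int bi = 0, bj = 0;
    for (int i = 1; i <= len; ++i) {
        const double* wrow = wf.data() + (size_t)rows[i - 1] * L;
        double* h = &H[(size_t)i * W1];
        const double* hp = &H[(size_t)(i - 1) * W1];
        unsigned char* m = &mv[(size_t)i * W1];
        for (int j = 1; j <= L; ++j) {
            const double diag = hp[j - 1] + wrow[j - 1];
            const double up = hp[j] - gap;
            const double lf = h[j - 1] - gap;
            double v = diag;
            unsigned char mm = 1;
            if (up > v) { v = up; mm = 2; }
            if (lf > v) { v = lf; mm = 3; }
            if (v <= 0.0) { v = 0.0; mm = 0; }
            h[j] = v;
            m[j] = mm;
            if (v > best) { best = v; bi = i; bj = j; }
        }
    }
    std::vector<int> s1r, s2r;
    int i = bi, j = bj, first = NA_INTEGER, last = NA_INTEGER;
    if (best > 0.0) {
        last = bi;
        while (i > 0 && j > 0) {
            const unsigned char mm = mv[(size_t)i * W1 + j];
            if (mm == 0) break;
            if (mm == 1) {
                s1r.push_back(seq[i - 1]);
                s2r.push_back(j);
                first = i;
                --i; --j;
            } else if (mm == 2) {           // base aligned to no column
                s1r.push_back(seq[i - 1]);
                s2r.push_back(NA_INTEGER);
                first = i;
                --i;
            } else {                         // column consumed, no base
                s1r.push_back(NA_INTEGER);
                s2r.push_back(j);
                --j;
            }
        }
    }
    const int k = (int)s1r.size();
    IntegerVector s1(k), s2(k);
    for (int t = 0; t < k; ++t) {
        s1[t] = s1r[k - 1 - t];
        s2[t] = s2r[k - 1 - t];
    }
    return List::create(_["score"] = best, _["s1"] = s1, _["s2"] = s2,
                        _["first"] = first, _["last"] = last);
}

// Fit alignment with traceback: every matrix column is consumed (interior
// and terminal column gaps cost g per column), while window bases before
// and after the aligned region are free.  Used to re-estimate the
// frequency matrix from the maxima windows: anchoring all columns keeps
// the member traces in a common register.
// [[Rcpp::export(name = ".cpp_align_fit")]]
List cpp_align_fit(IntegerVector window, NumericMatrix W, double gap,
                   bool anchored) {
    const int len = window.size(), L = W.ncol();
    if (W.nrow() != 16) stop("weight matrix must have 16 rows");
    if (len < 2 || L < 1)
        return List::create(_["score"] = 0.0,
                            _["s1"] = IntegerVector(0),
                            _["s2"] = IntegerVector(0),
                            _["first"] = NA_INTEGER, _["last"] = NA_INTEGER);
    std::vector<double> wf = flatten_weights_d(W);
    std::vector<int> seq(window.begin(), window.end());
    std::vector<int> rows(len);
    window_rows(seq.data(), 0, len, rows.data());
    const size_t W1 = (size_t)L + 1;
    const double NEG = -1e30;
    std::vector<double> H((size_t)(len + 1) * W1);
    std::vector<unsigned char> mv((size_t)(len + 1) * W1, 0);
    // moves: 1 = diag, 2 = up (base, no column), 3 = left (column gap),
    // 0 = start of the aligned region (free leading bases)
    for (int j = 0; j <= L; ++j) {
        H[j] = -gap * j;               // leading column gaps are paid
        mv[j] = j > 0 ? 3 : 0;
    }
    for (int i = 1; i <= len; ++i) {
        double* h = &H[(size_t)i * W1];
        const double* hp = &H[(size_t)(i - 1) * W1];
        unsigned char* m = &mv[(size_t)i * W1];
        if (anchored) {                // leading window bases are paid
            h[0] = -gap * i;
            m[0] = 2;
        } else {
            h[0] = 0.0;                // free leading sequence
            m[0] = 0;
        }
        const double* wrow = wf.data() + (size_t)rows[i - 1] * L;
        for (int j = 1; j <= L; ++j) {
            double v = hp[j - 1] + wrow[j - 1];
            unsigned char mm = 1;
            const double up = hp[j] - gap;
            if (up > v) { v = up; mm = 2; }
            const double lf = h[j - 1] - gap;
            if (lf > v) { v = lf; mm = 3; }
            if (v < NEG) v = NEG;
            h[j] = v;
            m[j] = mm;
        }
    }
    // best full-column alignment over all sequence end positions
    double best = H[L];
    int bi = 0;
    for (int i = 1; i <= len; ++i)
        if (H[(size_t)i * W1 + L] > best) { best = H[(size_t)i * W1 + L]; bi = i; }
    std::vector<int> s1r, s2r;
    int i = bi, j = L, first = NA_INTEGER, last = NA_INTEGER;
    while (j > 0 || (i > 0 && mv[(size_t)i * W1 + j] != 0)) {
        const unsigned char mm = mv[(size_t)i * W1 + j];
        if (mm == 0) break;
        if (mm == 1) {
            s1r.push_back(seq[i - 1]);
            s2r.push_back(j);
            first = i;
            if (last == NA_INTEGER) last = i;
            --i; --j;
        } else if (mm == 2) {
            s1r.push_back(seq[i - 1]);
            s2r.push_back(NA_INTEGER);
            first = i;
            if (last == NA_INTEGER) last = i;
            --i;
        } else {
            s1r.push_back(NA_INTEGER);
            s2r.push_back(j);
            --j;
        }
    }
    const int k = (int)s1r.size();
    IntegerVector s1(k), s2(k);
    for (int t = 0; t < k; ++t) {
        s1[t] = s1r[k - 1 - t];
        s2[t] = s2r[k - 1 - t];
    }
    return List::create(_["score"] = best, _["s1"] = s1, _["s2"] = s2,
                        _["first"] = first, _["last"] = last);
}

// Running max of x over a centred window of half-width h; out-of-range
// neighbours cannot veto, i.e. are treated as -Inf.
// [[Rcpp::export(name = ".cpp_run_max")]]
NumericVector cpp_run_max(NumericVector x, int h) {
    const R_xlen_t n = x.size();
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        const R_xlen_t lo = i - h < 0 ? 0 : i - h;
        const R_xlen_t hi = i + h >= n ? n - 1 : i + h;
        double m = R_NegInf;
        for (R_xlen_t k = lo; k <= hi; ++k)
            if (x[k] > m) m = x[k];
        out[i] = m;
    }
    return out;
}
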