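#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Words of the occurrence bit-vector I are stored in R integer vectors and
// reinterpreted as unsigned 32-bit words here. Group words use only the low
// w bits (w <= 32), one R integer per group.

static inline int popcnt32(uint32_t x) { return __builtin_popcount(x); }

static inline int get_S(const int *S, const uint32_t *I, bool half, uint64_t i) {
    if (!half) return S[i];
    if ((i & 1) == 0) return S[i >> 1];
    return S[(i - 1) >> 1] + popcnt32(I[i - 1]);
}

// [[Rcpp::export]]
IntegerVector bits_popcount_cpp(IntegerVector words) {
    R_xlen_t n = words.size();
    IntegerVector out(n);
    const uint32_t *w = (const uint32_t *)INTEGER(words);
    for (R_xlen_t i = 0; i < n; ++i) out[i] = popcnt32(w[i]);
    return out;
}

// Build the four arrays (I, S, S', O) over a 2-bit encoded text.
// codes: values in 0..3; valid: logical, one entry per q-gram start position
// (length len - q + 1), FALSE where the window overlaps a skipped region.
// Positions in O are 0-based. S is the exclusive prefix sum of popcounts of
// I with a terminal sentinel; when half_sample is TRUE only entries of S at
// even group indices are returned (odd entries are reconstructed at query
// time from one extra popcount).
// [[Rcpp::export]]
List qgi_build_cpp(IntegerVector codes, LogicalVector valid, int q, int w,
                   bool half_sample) {
    if (w < 1 || w > 32) stop("word size w must be in 1..32");
    if (q < 1 || 2 * q > 32) stop("q must satisfy 1 <= q <= 16 (2q bits per word)");
    R_xlen_t n = codes.size();
    R_xlen_t npos = n - q + 1;
    if (npos < 0) npos = 0;
    if (valid.size() != npos) stop("valid mask has wrong length");

    uint64_t nQ = 1ULL << (2 * q);
    uint64_t nGroups = (nQ + (uint64_t)w - 1) / (uint64_t)w;
    uint64_t mask = nQ - 1;

    IntegerVector I((R_xlen_t)nGroups); // zero-initialised by R
    uint32_t *Ip = (uint32_t *)INTEGER(I);
    const int *cd = INTEGER(codes);

    uint64_t g = 0;
    for (R_xlen_t pos = 0; pos < n; ++pos) {
        int c = cd[pos];
        if (c < 0 || c > 3) stop("codes must be in 0..3");
        g = ((g << 2) | (uint32_t)c) & mask;
        R_xlen_t start = pos - q + 1;
        if (start >= 0 && valid[start]) Ip[g / w] |= (1u << (g % w));
    }

    IntegerVector S((R_xlen_t)nGroups + 1);
    int *Sp = INTEGER(S);
    int64_t acc = 0;
    Sp[0] = 0;
    for (uint64_t i = 0; i < nGroups; ++i) {
        acc += popcnt32(Ip[i]);
        Sp[i + 1] = (int)acc;
    }
    int nDistinct = (int)acc;

    std::vector<int> counts((size_t)nDistinct, 0);
    g = 0;
    for (R_xlen_t pos = 0; pos < n; ++pos) {
        g = ((g << 2) | (uint32_t)cd[pos]) & mask;
        R_xlen_t start = pos - q + 1;
        if (start >= 0 && valid[start]) {
            uint64_t i = g / w;
            uint32_t j = (uint32_t)(g % w);
            int jp = popcnt32(Ip[i] & ((1u << j) - 1u));
            counts[(size_t)(Sp[i] + jp)]++;
        }
    }

    IntegerVector Sprime(nDistinct + 1);
    int *S2 = INTEGER(Sprime);
    acc = 0;
    S2[0] = 0;
    for (int k = 0; k < nDistinct; ++k) {
        acc += counts[(size_t)k];
        S2[k + 1] = (int)acc;
    }

    IntegerVector O((R_xlen_t)acc);
    int *Op = INTEGER(O);
    std::vector<int> cursor(S2, S2 + nDistinct);
    g = 0;
    for (R_xlen_t pos = 0; pos < n; ++pos) {
        g = ((g << 2) | (uint32_t)cd[pos]) & mask;
        R_xlen_t start = pos - q + 1;
        if (start >= 0 && valid[start]) {
            uint64_t i = g / w;
            uint32_t j = (uint32_t)(g % w);
            int jp = popcnt32(Ip[i] & ((1u << j) - 1u));
            Op[cursor[(size_t)(Sp[i] + jp)]++] = (int)start;
        }
    }

    if (half_sample) {
        uint64_t nHalf = nGroups / 2 + 1; // entries 0, 2, 4, ...
        IntegerVector Shalf((R_xlen_t)nHalf);
        for (uint64_t t = 0; t < nHalf; ++t) Shalf[t] = Sp[2 * t];
        return List::create(_["I"] = I, _["S"] = Shalf, _["S_prime"] = Sprime,
                            _["O"] = O);
    }
    return List::create(_["I"] = I, _["S"] = S, _["S_prime"] = Sprime,
                        _["O"] = O);
}

// Indexpair(g): the half-open interval [k_start, k_end) of O holding the
// occurrence positions of q-gram g, or c(-1, -1) when g does not occur.
// [[Rcpp::export]]
IntegerVector qgi_indexpair_cpp(IntegerVector I, IntegerVector S,
                                IntegerVector Sprime, bool half, int w,
                                double g_) {
    uint64_t g = (uint64_t)g_;
    const uint32_t *Ip = (const uint32_t *)INTEGER(I);
    uint64_t i = g / (uint64_t)w;
    uint32_t j = (uint32_t)(g % (uint64_t)w);
    if (i >= (uint64_t)I.size()) stop("q-gram code out of range");
    if (!(Ip[i] & (1u << j))) return IntegerVector::create(-1, -1);
    int jp = popcnt32(Ip[i] & ((1u << j) - 1u));
    int base = get_S(INTEGER(S), Ip, half, i);
    return IntegerVector::create(Sprime[base + jp], Sprime[base + jp + 1]);
}

// Stream the sorted reference pairs (g, position) against a q-group index
// built over concatenated read slots. Two passes in the count / exclusive
// prefix sum / scatter style: the first pass stores per-pair hit counts in
// C, the scan assigns each pair its output interval, the second pass writes
// (read id, diagonal) into that interval. Output capacity equals sum(C).
// read_id is 0-based; diagonal = reference position - in-read offset (may
// be negative near the contig start).
// [[Rcpp::export]]
List qgi_stream_cpp(IntegerVector I, IntegerVector S, IntegerVector Sprime,
                    IntegerVector O, bool half, int w, NumericVector P_g,
                    IntegerVector P_pos, int slot_len) {
    R_xlen_t m = P_g.size();
    if (P_pos.size() != m) stop("P arrays differ in length");
    const uint32_t *Ip = (const uint32_t *)INTEGER(I);
    const int *Sp = INTEGER(S);
    const int *S2 = INTEGER(Sprime);
    const int *Op = INTEGER(O);

    std::vector<int> C((size_t)m, 0);
    std::vector<int> kstart((size_t)m, -1);
    for (R_xlen_t t = 0; t < m; ++t) {
        uint64_t g = (uint64_t)P_g[t];
        uint64_t i = g / (uint64_t)w;
        uint32_t j = (uint32_t)(g % (uint64_t)w);
        if (!(Ip[i] & (1u << j))) continue;
        int jp = popcnt32(Ip[i] & ((1u << j) - 1u));
        int base = get_S(Sp, Ip, half, i);
        kstart[(size_t)t] = S2[base + jp];
        C[(size_t)t] = S2[base + jp + 1] - S2[base + jp];
    }

    std::vector<int64_t> off((size_t)m + 1, 0); // exclusive prefix sum of C
    for (R_xlen_t t = 0; t < m; ++t) off[(size_t)t + 1] = off[(size_t)t] + C[(size_t)t];
    int64_t total = off[(size_t)m];

    IntegerVector read_id((R_xlen_t)total), diag((R_xlen_t)total);
    int *rid = INTEGER(read_id);
    int *dg = INTEGER(diag);
    for (R_xlen_t t = 0; t < m; ++t) {
        int c = C[(size_t)t];
        if (c == 0) continue;
        int ks = kstart[(size_t)t];
        int p = P_pos[t];
        int64_t o = off[(size_t)t];
        for (int k = 0; k < c; ++k) {
            int occ = Op[ks + k];
            rid[o + k] = occ / slot_len;
            dg[o + k] = p - (occ % slot_len);
        }
    }
    return List::create(_["read_id"] = read_id, _["diagonal"] = diag);
}

// ---------------------------------------------------------------------------
// Bit-parallel semi-global edit distance (Myers' algorithm, blocked for
// reads longer than one machine word). The read is global, the text window
// local: column j of the implicit edit matrix holds the minimal distance of
// the whole read against any window substring ending at j. The band of the
// computation is realised through the extent of the window itself: a window
// of length |r| + 2*pad admits no alignment whose diagonal excursion
// exceeds pad.

struct MyersState {
    int m, nb;
    std::vector<uint64_t> Peq; // 4 * nb
    std::vector<uint64_t> VP, VN;
    uint64_t last_high; // bit of row m-1 inside the last block
    int score;
};

static void myers_init(MyersState &st, const int *read, int m) {
    st.m = m;
    st.nb = (m + 63) / 64;
    st.Peq.assign((size_t)(4 * st.nb), 0);
    for (int i = 0; i < m; ++i)
        st.Peq[(size_t)(read[i] * st.nb + i / 64)] |= 1ULL << (i % 64);
    st.VP.assign((size_t)st.nb, ~0ULL);
    st.VN.assign((size_t)st.nb, 0);
    st.last_high = 1ULL << ((m - 1) % 64);
    st.score = m;
}

// Advance one text column; returns the new score at the bottom row.
static int myers_column(MyersState &st, int c) {
    int hin = 0;
    for (int b = 0; b < st.nb; ++b) {
        uint64_t Pv = st.VP[(size_t)b], Mv = st.VN[(size_t)b];
        uint64_t Eq = st.Peq[(size_t)(c * st.nb + b)];
        uint64_t X = Eq;
        if (hin < 0) X |= 1ULL;
        uint64_t Xv = Eq | Mv;
        uint64_t Xh = (((X & Pv) + Pv) ^ Pv) | X;
        uint64_t Ph = Mv | ~(Xh | Pv);
        uint64_t Mh = Pv & Xh;
        uint64_t high = (b == st.nb - 1) ? st.last_high : (1ULL << 63);
        int hout = 0;
        if (Ph & high) hout = 1;
        else if (Mh & high) hout = -1;
        Ph <<= 1;
        Mh <<= 1;
        if (hin < 0) Mh |= 1ULL;
        else if (hin > 0) Ph |= 1ULL;
        st.VP[(size_t)b] = Mh | ~(Xv | Ph);
        st.VN[(size_t)b] = Ph & Xv;
        hin = hout;
    }
    st.score += hin;
    return st.score;
}

// Minimal semi-global edit distance of read vs window, plus the smallest
// half-open window end position attaining it. Empty window: k = |read|.
// [[Rcpp::export]]
List myers_semiglobal_cpp(IntegerVector read, IntegerVector window) {
    int m = read.size(), n = window.size();
    if (m == 0) return List::create(_["k"] = 0, _["end"] = 0);
    MyersState st;
    myers_init(st, INTEGER(read), m);
    int best = m, best_end = 0;
    const int *win = INTEGER(window);
    for (int j = 0; j < n; ++j) {
        int sc = myers_column(st, win[j]);
        if (sc < best) {
            best = sc;
            best_end = j + 1;
        }
    }
    return List::create(_["k"] = best, _["end"] = best_end);
}

// Column-wise scores at the bottom row for every window prefix end
// (used by tests to compare whole score profiles against the DP oracle).
// [[Rcpp::export]]
IntegerVector myers_profile_cpp(IntegerVector read, IntegerVector window) {
    int m = read.size(), n = window.size();
    IntegerVector out(n);
    if (m == 0) return out;
    MyersState st;
    myers_init(st, INTEGER(read), m);
    const int *win = INTEGER(window);
    for (int j = 0; j < n; ++j) out[j] = myers_column(st, win[j]);
    return out;
}

// Global unit-cost alignment with traceback between a read and the exact
// reference segment located for its hit. Op codes: 0 = match, 1 = mismatch,
// 2 = insertion (read base absent from reference), 3 = deletion (reference
// base absent from read). Deterministic tie-break: diagonal, then deletion,
// then insertion.
// [[Rcpp::export]]
List edit_traceback_cpp(IntegerVector read, IntegerVector seg) {
    int m = read.size(), n = seg.size();
    std::vector<int> D((size_t)((m + 1) * (n + 1)));
    auto at = [&](int i, int j) -> int & { return D[(size_t)(i * (n + 1) + j)]; };
    for (int j = 0; j <= n; ++j) at(0, j) = j;
    for (int i = 1; i <= m; ++i) {
        at(i, 0) = i;
        for (int j = 1; j <= n; ++j) {
            int sub = at(i - 1, j - 1) + (read[i - 1] == seg[j - 1] ? 0 : 1);
            int del = at(i, j - 1) + 1;
            int ins = at(i - 1, j) + 1;
            int v = sub;
            if (del < v) v = del;
            if (ins < v) v = ins;
            at(i, j) = v;
        }
    }
    int k = at(m, n);
    std::vector<int> ops;
    ops.reserve((size_t)(m + n));
    int i = m, j = n;
    while (i > 0 || j > 0) {
        if (i > 0 && j > 0) {
            int c = (read[i - 1] == seg[j - 1]) ? 0 : 1;
            if (at(i, j) == at(i - 1, j - 1) + c) {
                ops.push_back(c);
                --i;
                --j;
                continue;
            }
        }
        if (j > 0 && at(i, j) == at(i, j - 1) + 1) {
            ops.push_back(3);
            --j;
            continue;
        }
        ops.push_back(2);
        --i;
    }
    std::reverse(ops.begin(), ops.end());
    return List::create(_["k"] = k, _["ops"] = IntegerVector(ops.begin(), ops.end()));
}
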