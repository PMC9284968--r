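#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
#include <algorithm>
using namespace Rcpp;

// Affine-gap local (Smith-Waterman) alignment.
// Scoring convention: a gap of length L costs -(open + L * extend), i.e. the
// first gapped base pays open + extend. Non-ACGT characters (used as masking
// sentinels) score a large negative value against everything so masked spans
// can never be traversed.

static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
    }
}

static const int MASK_PENALTY = -1000000;

static inline int pair_score(int a, int b, int match, int mismatch) {
    if (a == 4 || b == 4) return MASK_PENALTY;
    return (a == b) ? match : mismatch;
}

// Full DP with traceback. query indexes rows (i), subject columns (j).
// CIGAR ops are relative to the query: M consumes both, I consumes query
// only (insertion in query / gap in subject), D consumes subject only.
// [[Rcpp::export]]
List sw_align_cpp(std::string query, std::string subject,
                  int match = 2, int mismatch = -4,
                  int gap_open = -4, int gap_extend = -2) {
    const int n = (int) query.size();
    const int m = (int) subject.size();
    if (n == 0 || m == 0) stop("empty sequence");

    std::vector<int> q(n), s(m);
    for (int i = 0; i < n; ++i) q[i] = base_code(query[i]);
    for (int j = 0; j < m; ++j) s[j] = base_code(subject[j]);

    const size_t W = (size_t) m + 1;
    // rolling score rows; full matrices only for the byte-sized traceback
    std::vector<int> Hprev(W, 0), Hcur(W, 0), Fcol(W, INT_MIN / 2);
    // traceback state per cell, packed: bits 0-1 H-state (0 stop, 1 diag,
    // 2 from E, 3 from F), bit 2 E-extends, bit 3 F-extends
    std::vector<unsigned char> TB((size_t)(n + 1) * W, 0);

    int best = 0, bi = 0, bj = 0;
    const int go = gap_open + gap_extend;
    for (int i = 1; i <= n; ++i) {
        size_t row = (size_t) i * W;
        int e = INT_MIN / 2;
        const int qi = q[i - 1];
        Hcur[0] = 0;
        for (int j = 1; j <= m; ++j) {
            unsigned char tb = 0;
            int e_open = Hcur[j - 1] + go;
            if (e + gap_extend > e_open) { e += gap_extend; tb |= 4; }
            else e = e_open;

            int f_open = Hprev[j] + go;
            if (Fcol[j] + gap_extend > f_open) { Fcol[j] += gap_extend; tb |= 8; }
            else Fcol[j] = f_open;

            int diag = Hprev[j - 1] + pair_score(qi, s[j - 1], match, mismatch);
            int h = 0; unsigned char t = 0;
            if (diag > h) { h = diag; t = 1; }
            if (e > h) { h = e; t = 2; }
            if (Fcol[j] > h) { h = Fcol[j]; t = 3; }
            Hcur[j] = h; TB[row + j] = tb | t;
            if (h > best) { best = h; bi = i; bj = j; }
        }
        std::swap(Hprev, Hcur);
    }

    // traceback
    int i = bi, j = bj;
    int matches = 0, columns = 0;
    std::string ops; // reversed op chars
    int state = 0;   // 0 = in H
    while (i > 0 && j > 0) {
        unsigned char tb = TB[(size_t) i * W + j];
        if (state == 0) {
            unsigned char t = tb & 3;
            if (t == 0) break;
            if (t == 1) {
                ops.push_back('M');
                ++columns;
                if (q[i - 1] == s[j - 1] && q[i - 1] != 4) ++matches;
                --i; --j;
            } else if (t == 2) state = 2;
            else state = 3;
        } else if (state == 2) { // E: D op, consumes subject
            ops.push_back('D'); ++columns;
            if (!(tb & 4)) state = 0;
            --j;
        } else { // F: I op, consumes query
            ops.push_back('I'); ++columns;
            if (!(tb & 8)) state = 0;
            --i;
        }
    }
    std::reverse(ops.begin(), ops.end());

    // compact cigar
    std::string cigar;
    size_t k = 0;
    while (k < ops.size()) {
        size_t k2 = k;
        while (k2 < ops.size() && ops[k2] == ops[k]) ++k2;
        cigar += std::to_string(k2 - k);
        cigar.push_back(ops[k]);
        k = k2;
    }

    return List::create(
        _["score"] = best,
        _["q_start"] = i, _["q_end"] = bi,
        _["s_start"] = j, _["s_end"] = bj,
        _["matches"] = matches, _["columns"] = columns,
        _["cigar"] = cigar);
}

// Linear-memory forward pass: best score and (exclusive) end coordinates.
static void sw_end(const std::vector<int>& q, const std::vector<int>& s,
                   int match, int mismatch, int go, int ge,
                   int& best, int& bi, int& bj) {
    const int n = (int) q.size(), m = (int) s.size();
    std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0);
    std::vector<int> Fcol(m + 1, INT_MIN / 2);
    best = 0; bi = 0; bj = 0;
    for (int i = 1; i <= n; ++i) {
        int e = INT_MIN / 2;
        Hcur[0] = 0;
        for (int j = 1; j <= m; ++j) {
            e = std::max(Hcur[j - 1] + go + ge, e + ge);
            Fcol[j] = std::max(Hprev[j] + go + ge, Fcol[j] + ge);
            int h = Hprev[j - 1] + pair_score(q[i - 1], s[j - 1], match, mismatch);
            h = std::max(std::max(h, 0), std::max(e, Fcol[j]));
            Hcur[j] = h;
            if (h > best) { best = h; bi = i; bj = j; }
        }
        std::swap(Hprev, Hcur);
    }
}

// Locate the best local alignment without a traceback matrix (O(m) memory):
// forward pass finds the end, a reverse pass on the reversed prefixes finds
// the start. Suitable for long subjects (background contigs).
// [[Rcpp::export]]
List sw_locate_cpp(std::string query, std::string subject,
                   int match = 2, int mismatch = -4,
                   int gap_open = -4, int gap_extend = -2) {
    const int n = (int) query.size();
    const int m = (int) subject.size();
    if (n == 0 || m == 0) stop("empty sequence");
    std::vector<int> q(n), s(m);
    for (int i = 0; i < n; ++i) q[i] = base_code(query[i]);
    for (int j = 0; j < m; ++j) s[j] = base_code(subject[j]);

    int best, bi, bj;
    sw_end(q, s, match, mismatch, gap_open, gap_extend, best, bi, bj);
    if (best <= 0)
        return List::create(_["score"] = 0, _["q_start"] = 0, _["q_end"] = 0,
                            _["s_start"] = 0, _["s_end"] = 0);

    std::vector<int> qr(q.begin(), q.begin() + bi);
    std::vector<int> sr(s.begin(), s.begin() + bj);
    std::reverse(qr.begin(), qr.end());
    std::reverse(sr.begin(), sr.end());
    int best2, ri, rj;
    sw_end(qr, sr, match, mismatch, gap_open, gap_extend, best2, ri, rj);

    return List::create(
        _["score"] = best,
        _["q_start"] = bi - ri, _["q_end"] = bi,
        _["s_start"] = bj - rj, _["s_end"] = bj);
}
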