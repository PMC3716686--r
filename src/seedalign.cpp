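#include <Rcpp.h>
#include <climits>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const int NEG = INT_MIN / 4;

static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4; // N and anything else: never seeds, scores as mismatch
    }
}

static std::vector<uint8_t> encode_seq(const std::string &s) {
    std::vector<uint8_t> v(s.size());
    for (size_t i = 0; i < s.size(); ++i) v[i] = (uint8_t)base_code(s[i]);
    return v;
}

static inline int pair_score(uint8_t a, uint8_t b, int match, int mismatch) {
    if (a > 3 || b > 3) return mismatch;
    return a == b ? match : mismatch;
}

// ---------------------------------------------------------------------------
// Ungapped X-drop extension along one diagonal, one direction.
// Returns (score gained, bases consumed) starting just outside the seed.
static void ungapped_extend_dir(const std::vector<uint8_t> &q,
                                const std::vector<uint8_t> &s,
                                long qi, long si, int dir,
                                int match, int mismatch, int xdrop,
                                int &best_gain, long &best_len) {
    long nq = (long)q.size(), ns = (long)s.size();
    int run = 0, best = 0;
    long len = 0, blen = 0;
    while (true) {
        long a = qi + dir * len, b = si + dir * len;
        if (a < 0 || b < 0 || a >= nq || b >= ns) break;
        run += pair_score(q[a], s[b], match, mismatch);
        ++len;
        if (run > best) { best = run; blen = len; }
        if (run < best - xdrop) break;
    }
    best_gain = best;
    best_len = blen;
}

// ---------------------------------------------------------------------------
// Gapped X-drop extension (affine, Gotoh) in one direction from an anchor.
// Aligns q[qi0 + dir*k] vs s[si0 + dir*k] for k = 0,1,...; the anchor cell
// itself is NOT consumed here (caller splits the anchor between directions).
// Returns best score and the number of query/subject bases consumed.
static void gapped_extend_dir(const std::vector<uint8_t> &q,
                              const std::vector<uint8_t> &s,
                              long qi0, long si0, int dir,
                              int match, int mismatch,
                              int gap_open, int gap_extend, int xdrop,
                              int &best_score, long &best_qlen, long &best_slen) {
    long nq, ns;
    if (dir > 0) { nq = (long)q.size() - qi0; ns = (long)s.size() - si0; }
    else         { nq = qi0 + 1;              ns = si0 + 1; }
    if (nq < 0) nq = 0;
    if (ns < 0) ns = 0;

    best_score = 0; best_qlen = 0; best_slen = 0;
    if (nq == 0 || ns == 0) return;

    // H[j]: best score of q-prefix (i rows) vs s-prefix (j cols), band-pruned
    std::vector<int> H(ns + 1, NEG), E(ns + 1, NEG), Hn(ns + 1, NEG), En(ns + 1, NEG);
    long lo = 0, hi = 0; // inclusive column band of finite cells in current row
    H[0] = 0;
    for (long j = 1; j <= ns; ++j) {
        int v = -(gap_open + (int)j * gap_extend);
        if (v < best_score - xdrop) break;
        H[j] = v;
        hi = j;
    }
    int best = 0; long bq = 0, bs = 0;

    for (long i = 1; i <= nq; ++i) {
        long nlo = -1, nhi = -1;
        std::fill(Hn.begin() + std::max(0L, lo - 1), Hn.begin() + std::min(ns, hi + 1) + 1, NEG);
        std::fill(En.begin() + std::max(0L, lo - 1), En.begin() + std::min(ns, hi + 1) + 1, NEG);
        int rowE = NEG; // horizontal gap state within the new row
        long jstart = lo, jend = std::min(ns, hi + 1);
        for (long j = jstart; j <= jend; ++j) {
            int h = NEG;
            if (j >= 1 && H[j - 1] > NEG) {
                long a = qi0 + dir * (i - 1), b = si0 + dir * (j - 1);
                int d = H[j - 1] + pair_score(q[a], s[b], match, mismatch);
                if (d > h) h = d;
            }
            // vertical: gap in subject (consume query)
            int f = NEG;
            if (H[j] > NEG) f = H[j] - gap_open - gap_extend;
            if (E[j] > NEG && E[j] - gap_extend > f) f = E[j] - gap_extend; // E doubles as vertical state
            if (f > h) h = f;
            // horizontal: gap in query (consume subject)
            if (rowE > h) h = rowE;
            if (h < best - xdrop) h = NEG;
            Hn[j] = h;
            En[j] = f; // store vertical state for next row
            int e2 = NEG;
            if (h > NEG) e2 = h - gap_open - gap_extend;
            if (rowE > NEG && rowE - gap_extend > e2) e2 = rowE - gap_extend;
            rowE = e2;
            if (h > NEG) {
                if (nlo < 0) nlo = j;
                nhi = j;
                if (h > best) { best = h; bq = i; bs = j; }
            }
        }
        if (nlo < 0) break; // band extinguished
        std::swap(H, Hn);
        std::swap(E, En);
        lo = nlo;
        hi = nhi;
        if (lo == 0) lo = 1; // column 0 only valid in row 0
    }
    best_score = best; best_qlen = bq; best_slen = bs;
}

// ---------------------------------------------------------------------------
// Banded global alignment (Gotoh, affine) of q[qs..qe) vs s[ss..se) with
// traceback; fills alignment-column statistics. Score returned.
struct AlnStats {
    int score;
    long columns, nident, nmismatch, ngapopen, ngaps;
};

static AlnStats banded_global(const std::vector<uint8_t> &q, long qs, long qe,
                              const std::vector<uint8_t> &s, long ss, long se,
                              int match, int mismatch, int gap_open, int gap_extend) {
    long m = qe - qs, n = se - ss;
    long w = std::max(32L, std::labs(m - n) + 32L); // half band width
    // band: for row i, columns [ci - w, ci + w], ci = i*n/m (straight line)
    auto center = [&](long i) { return m > 0 ? (i * n) / m : 0; };
    auto lo_of = [&](long i) { long c = center(i) - w; return c < 0 ? 0 : c; };
    auto hi_of = [&](long i) { long c = center(i) + w; return c > n ? n : c; };
    long bw = 2 * w + 1;

    std::vector<int> H((m + 1) * bw, NEG), E((m + 1) * bw, NEG), F((m + 1) * bw, NEG);
    std::vector<uint8_t> TB((m + 1) * bw, 0);
    // TB bits: 0-1 H-source (0 diag, 1 from E[horiz], 2 from F[vert]),
    //          2 E extends E, 3 F extends F
    auto idx = [&](long i, long j) { return i * bw + (j - lo_of(i)); };
    auto inband = [&](long i, long j) { return j >= lo_of(i) && j <= hi_of(i); };

    H[idx(0, 0)] = 0;
    for (long j = 1; j <= hi_of(0); ++j) {
        E[idx(0, j)] = -(gap_open + (int)j * gap_extend);
        H[idx(0, j)] = E[idx(0, j)];
        TB[idx(0, j)] = 1 | (j > 1 ? 4 : 0);
    }
    for (long i = 1; i <= m; ++i) {
        long jlo = lo_of(i), jhi = hi_of(i);
        for (long j = jlo; j <= jhi; ++j) {
            long k = idx(i, j);
            int e = NEG, f = NEG, h = NEG;
            uint8_t tb = 0;
            if (j >= 1 && inband(i, j - 1)) {
                long kk = idx(i, j - 1);
                int open_e = H[kk] > NEG ? H[kk] - gap_open - gap_extend : NEG;
                int ext_e = E[kk] > NEG ? E[kk] - gap_extend : NEG;
                e = std::max(open_e, ext_e);
                if (ext_e > open_e) tb |= 4;
            }
            if (inband(i - 1, j)) {
                long kk = idx(i - 1, j);
                int open_f = H[kk] > NEG ? H[kk] - gap_open - gap_extend : NEG;
                int ext_f = F[kk] > NEG ? F[kk] - gap_extend : NEG;
                f = std::max(open_f, ext_f);
                if (ext_f > open_f) tb |= 8;
            }
            if (j >= 1 && inband(i - 1, j - 1)) {
                long kk = idx(i - 1, j - 1);
                if (H[kk] > NEG)
                    h = H[kk] + pair_score(q[qs + i - 1], s[ss + j - 1], match, mismatch);
            }
            int hv = h; uint8_t src = 0;
            if (e > hv) { hv = e; src = 1; }
            if (f > hv) { hv = f; src = 2; }
            E[k] = e; F[k] = f; H[k] = hv; TB[k] = tb | src;
        }
    }

    AlnStats st; st.score = H[idx(m, n)];
    st.columns = st.nident = st.nmismatch = st.ngapopen = st.ngaps = 0;
    if (st.score <= NEG / 2) return st; // no in-band path; caller discards
    long i = m, j = n;
    int state = 0; // 0 = H, 1 = E, 2 = F
    while (i > 0 || j > 0) {
        long k = idx(i, j);
        uint8_t tb = TB[k];
        if (state == 0) state = tb & 3;
        if (i == 0) state = 1;
        else if (j == 0) state = 2;
        if (state == 0) {
            ++st.columns;
            if (q[qs + i - 1] <= 3 && q[qs + i - 1] == s[ss + j - 1]) ++st.nident;
            else ++st.nmismatch;
            --i; --j;
        } else if (state == 1) { // gap in query: consume subject
            ++st.columns; ++st.ngaps;
            bool ext = tb & 4;
            --j;
            if (!ext) { ++st.ngapopen; state = 0; }
        } else { // gap in subject: consume query
            ++st.columns; ++st.ngaps;
            bool ext = tb & 8;
            --i;
            if (!ext) { ++st.ngapopen; state = 0; }
        }
    }
    return st;
}

// ---------------------------------------------------------------------------
// [[Rcpp::export]]
DataFrame cpp_seed_extend(std::string query, std::string subject,
                          int match, int mismatch,
                          int gap_open, int gap_extend,
                          int word_size, int xdrop_ungapped, int xdrop_gapped,
                          int min_ungapped, int min_report) {
    std::vector<uint8_t> q = encode_seq(query), s = encode_seq(subject);
    long nq = (long)q.size(), ns = (long)s.size();

    std::vector<long> hqs, hqe, hss, hse, hlen, hid, hmm, hgo, hgp;
    std::vector<int> hsc;

    if (nq >= word_size && ns >= word_size && word_size >= 1) {
        // index query words (2 bits/base; words containing N skipped)
        uint32_t mask = (word_size >= 16) ? 0xFFFFFFFFu
                                          : ((1u << (2 * word_size)) - 1u);
        std::unordered_map<uint32_t, std::vector<int> > widx;
        {
            uint32_t code = 0; int valid = 0;
            for (long i = 0; i < nq; ++i) {
                if (q[i] > 3) { valid = 0; code = 0; continue; }
                code = ((code << 2) | q[i]) & mask;
                if (++valid >= word_size)
                    widx[code].push_back((int)(i - word_size + 1));
            }
        }
        std::vector<long> diag_last(nq + ns + 1, -1);

        uint32_t code = 0; int valid = 0;
        for (long sp = 0; sp < ns; ++sp) {
            if (s[sp] > 3) { valid = 0; code = 0; continue; }
            code = ((code << 2) | s[sp]) & mask;
            if (++valid < word_size) continue;
            long spos = sp - word_size + 1;
            auto it = widx.find(code);
            if (it == widx.end()) continue;
            for (int qpos : it->second) {
                long diag = spos - (long)qpos + nq;
                if (spos <= diag_last[diag]) continue;

                // ungapped X-drop out from the seed word
                int lg, rg; long ll, rl;
                ungapped_extend_dir(q, s, qpos - 1, spos - 1, -1, match,
                                    mismatch, xdrop_ungapped, lg, ll);
                ungapped_extend_dir(q, s, qpos + word_size, spos + word_size,
                                    +1, match, mismatch, xdrop_ungapped, rg, rl);
                long uqs = qpos - ll, uqe = qpos + word_size + rl;
                long uss = spos - ll;
                diag_last[diag] = uss + (uqe - uqs) - 1;
                // two-stage cutoff: weak ungapped seeds skip the gapped stage
                if (lg + rg + word_size * match < min_ungapped) continue;

                // gapped X-drop from the midpoint of the ungapped segment
                long mid = (uqe - uqs) / 2;
                long qa = uqs + mid, sa = uss + mid; // anchor, consumed rightward
                int lsc, rsc; long lql, lsl, rql, rsl;
                gapped_extend_dir(q, s, qa - 1, sa - 1, -1, match, mismatch,
                                  gap_open, gap_extend, xdrop_gapped,
                                  lsc, lql, lsl);
                gapped_extend_dir(q, s, qa, sa, +1, match, mismatch,
                                  gap_open, gap_extend, xdrop_gapped,
                                  rsc, rql, rsl);
                long gqs = qa - lql, gqe = qa + rql;
                long gss = sa - lsl, gse = sa + rsl;
                if (gqe - gqs <= 0 || gse - gss <= 0) continue;

                AlnStats st = banded_global(q, gqs, gqe, s, gss, gse,
                                            match, mismatch, gap_open, gap_extend);
                if (st.score <= 0 || st.score < min_report) continue;
                hqs.push_back(gqs + 1); hqe.push_back(gqe);
                hss.push_back(gss + 1); hse.push_back(gse);
                hsc.push_back(st.score);
                hlen.push_back(st.columns); hid.push_back(st.nident);
                hmm.push_back(st.nmismatch); hgo.push_back(st.ngapopen);
                hgp.push_back(st.ngaps);
            }
        }
    }

    // dedup: drop hits (near-)contained in a higher-scoring hit
    size_t nh = hsc.size();
    std::vector<size_t> ord(nh);
    for (size_t i = 0; i < nh; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
        if (hsc[a] != hsc[b]) return hsc[a] > hsc[b];
        if (hss[a] != hss[b]) return hss[a] < hss[b];
        return hqs[a] < hqs[b];
    });
    const long pad = 4;
    std::vector<size_t> keep;
    for (size_t oi : ord) {
        bool contained = false;
        for (size_t ki : keep) {
            if (hqs[oi] >= hqs[ki] - pad && hqe[oi] <= hqe[ki] + pad &&
                hss[oi] >= hss[ki] - pad && hse[oi] <= hse[ki] + pad) {
                contained = true; break;
            }
        }
        if (!contained) keep.push_back(oi);
    }

    size_t nk = keep.size();
    IntegerVector oqs(nk), oqe(nk), oss(nk), ose(nk), osc(nk), olen(nk),
        oid(nk), omm(nk), ogo(nk), ogp(nk);
    for (size_t i = 0; i < nk; ++i) {
        size_t k = keep[i];
        oqs[i] = (int)hqs[k]; oqe[i] = (int)hqe[k];
        oss[i] = (int)hss[k]; ose[i] = (int)hse[k];
        osc[i] = hsc[k]; olen[i] = (int)hlen[k]; oid[i] = (int)hid[k];
        omm[i] = (int)hmm[k]; ogo[i] = (int)hgo[k]; ogp[i] = (int)hgp[k];
    }
    return DataFrame::create(
        _["qstart"] = oqs, _["qend"] = oqe,
        _["sstart"] = oss, _["send"] = ose,
        _["score"] = osc, _["length"] = olen, _["nident"] = oid,
        _["mismatch"] = omm, _["gapopen"] = ogo, _["gaps"] = ogp);
}

// ---------------------------------------------------------------------------
// Best ungapped local alignment score over all diagonals (Kadane); used for
// Monte-Carlo calibration of the Karlin-Altschul K parameter.
// [[Rcpp::export]]
int cpp_best_local_ungapped(std::string a, std::string b,
                            int match, int mismatch) {
    std::vector<uint8_t> x = encode_seq(a), y = encode_seq(b);
    long m = (long)x.size(), n = (long)y.size();
    int best = 0;
    for (long d = -(m - 1); d <= n - 1; ++d) {
        long i0 = d < 0 ? -d : 0, j0 = d < 0 ? 0 : d;
        int run = 0;
        for (long i = i0, j = j0; i < m && j < n; ++i, ++j) {
            run += pair_score(x[i], y[j], match, mismatch);
            if (run < 0) run = 0;
            if (run > best) best = run;
        }
    }
    return best;
}
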