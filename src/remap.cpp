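#include <Rcpp.h>
#include <string>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// k-mer seed + banded Smith-Waterman local extension, the stand-in for an
// external BLAT-like aligner.  Scoring: match +1, mismatch -1, gap -2.
// Identity = matches / alignment columns (gaps count against identity).

static std::string revcomp2(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (char& c : r) {
        switch (c) {
        case 'A': c = 'T'; break;
        case 'C': c = 'G'; break;
        case 'G': c = 'C'; break;
        case 'T': c = 'A'; break;
        default:  c = 'N';
        }
    }
    return r;
}

struct Hit {
    int ref_start, ref_end;  // 0-based half-open on the reference
    int score;
    double identity;
    int strand;              // +1 / -1
};

// Banded local alignment of `read` against ref[win_start, win_end), band
// centred on the supplied diagonal (diag = refpos - readpos).  Tracks the
// number of matched columns and total alignment columns alongside the score
// so identity can be reported without a traceback.
static bool banded_sw(const std::string& read, const std::string& ref,
                      int win_start, int win_end, int diag, int band,
                      Hit& out) {
    const int m = read.size();
    const int lo = std::max(0, win_start), hi = std::min((int)ref.size(), win_end);
    const int n = hi - lo;
    if (n <= 0) return false;
    const int W = 2 * band + 1;
    // cell (i, j): read pos i (1..m), ref offset j (1..n); banded on j - i ~ (diag - lo)
    const int dcen = diag - lo;
    std::vector<int> sc(W, 0), nsc(W, 0);
    std::vector<int> mt(W, 0), nmt(W, 0);   // matched columns
    std::vector<int> al(W, 0), nal(W, 0);   // alignment columns
    std::vector<int> st(W, 0), nst(W, 0);   // ref offset where local aln started
    int best = 0, best_mt = 0, best_al = 0, best_j = -1, best_st = 0;
    // initialise row i = 0: score 0 everywhere (local)
    for (int w = 0; w < W; ++w) { sc[w] = 0; mt[w] = 0; al[w] = 0; }
    for (int i = 1; i <= m; ++i) {
        const char rc = read[i - 1];
        for (int w = 0; w < W; ++w) {
            const int j = i + dcen + (w - band);  // ref offset (1-based within window)
            if (j < 1 || j > n) { nsc[w] = 0; nmt[w] = 0; nal[w] = 0; nst[w] = (j >= 0 ? j : 0); continue; }
            const char gc = ref[lo + j - 1];
            const bool is_match = (rc == gc && rc != 'N');
            const int subsc = is_match ? 1 : -1;
            // diagonal predecessor: same w in previous row
            int s_diag = sc[w] + subsc;
            int m_diag = mt[w] + (is_match ? 1 : 0);
            int a_diag = al[w] + 1;
            int t_diag = (al[w] == 0) ? j - 1 : st[w];
            // up (i-1, j): consumes a read base, gap in the reference => w + 1
            // in the previous row under this band parameterisation
            int s_up = INT_MIN, m_up = 0, a_up = 0, t_up = 0;
            if (w + 1 < W) { s_up = sc[w + 1] - 2; m_up = mt[w + 1]; a_up = al[w + 1] + 1; t_up = (al[w + 1] == 0) ? j : st[w + 1]; }
            // left (i, j-1): consumes a reference base, gap in the read => w - 1
            // in the current row
            int s_left = INT_MIN, m_left = 0, a_left = 0, t_left = 0;
            if (w - 1 >= 0) { s_left = nsc[w - 1] - 2; m_left = nmt[w - 1]; a_left = nal[w - 1] + 1; t_left = (nal[w - 1] == 0) ? j - 1 : nst[w - 1]; }
            int s = s_diag, mm = m_diag, aa = a_diag, tt = t_diag;
            if (s_up > s)   { s = s_up;   mm = m_up;   aa = a_up;   tt = t_up; }
            if (s_left > s) { s = s_left; mm = m_left; aa = a_left; tt = t_left; }
            if (s <= 0) { s = 0; mm = 0; aa = 0; tt = j; }
            nsc[w] = s; nmt[w] = mm; nal[w] = aa; nst[w] = tt;
            if (s > best) { best = s; best_mt = mm; best_al = aa; best_j = j; best_st = tt; }
        }
        std::swap(sc, nsc); std::swap(mt, nmt); std::swap(al, nal); std::swap(st, nst);
    }
    if (best <= 0 || best_al == 0) return false;
    out.score = best;
    out.identity = (double)best_mt / (double)best_al;
    out.ref_start = lo + best_st;
    out.ref_end = lo + best_j;
    return true;
}

//' @noRd
// [[Rcpp::export]]
DataFrame cpp_remap(CharacterVector reads, std::string reference,
                    int k, int band) {
    const std::string& ref = reference;
    const int rn = ref.size();
    // k-mer index of the reference (forward strand only; reads are searched
    // on both strands instead)
    std::unordered_map<std::string, std::vector<int> > index;
    index.reserve(rn);
    for (int p = 0; p + k <= rn; ++p) {
        std::string km = ref.substr(p, k);
        if (km.find('N') != std::string::npos) continue;
        index[km].push_back(p);
    }
    std::vector<int> o_read, o_start, o_end, o_score;
    std::vector<double> o_ident;
    std::vector<std::string> o_strand;
    for (int r = 0; r < reads.size(); ++r) {
        const std::string fwd = as<std::string>(reads[r]);
        for (int sdir = 0; sdir < 2; ++sdir) {
            const std::string rd = sdir == 0 ? fwd : revcomp2(fwd);
            const int m = rd.size();
            if (m < k) continue;
            // collect seed diagonals
            std::vector<int> diags;
            for (int p = 0; p + k <= m; p += 1) {
                std::string km = rd.substr(p, k);
                auto it = index.find(km);
                if (it == index.end()) continue;
                for (int rp : it->second) diags.push_back(rp - p);
            }
            if (diags.empty()) continue;
            std::sort(diags.begin(), diags.end());
            // cluster nearby diagonals, one banded alignment per cluster
            std::vector<Hit> hits;
            size_t i0 = 0;
            for (size_t i = 1; i <= diags.size(); ++i) {
                if (i == diags.size() || diags[i] - diags[i - 1] > band) {
                    const int dlo = diags[i0], dhi = diags[i - 1];
                    const int dmid = (dlo + dhi) / 2;
                    const int bw = std::max(band, (dhi - dlo) / 2 + band / 2);
                    Hit h;
                    if (banded_sw(rd, ref, dmid - bw, dmid + m + bw, dmid, bw, h)) {
                        h.strand = (sdir == 0) ? 1 : -1;
                        hits.push_back(h);
                    }
                    i0 = i;
                }
            }
            // merge hits overlapping on the reference, keep the best-scoring
            std::sort(hits.begin(), hits.end(),
                      [](const Hit& a, const Hit& b) { return a.ref_start < b.ref_start; });
            std::vector<Hit> kept;
            for (const Hit& h : hits) {
                if (!kept.empty() && h.ref_start < kept.back().ref_end) {
                    if (h.score > kept.back().score) kept.back() = h;
                } else {
                    kept.push_back(h);
                }
            }
            for (const Hit& h : kept) {
                o_read.push_back(r + 1);
                o_start.push_back(h.ref_start);
                o_end.push_back(h.ref_end);
                o_score.push_back(h.score);
                o_ident.push_back(h.identity);
                o_strand.push_back(h.strand > 0 ? "+" : "-");
            }
        }
    }
    return DataFrame::create(_["read"] = wrap(o_read),
                             _["ref_start"] = wrap(o_start),
                             _["ref_end"] = wrap(o_end),
                             _["score"] = wrap(o_score),
                             _["identity"] = wrap(o_ident),
                             _["strand"] = wrap(o_strand),
                             _["stringsAsFactors"] = false);
}
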