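#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Reverse complement; any non-ACGT base maps to 'N'.
static std::string revcomp(const std::string& s) {
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

// Minimum edit distance between `pat` (aligned end to end) and any substring
// of `txt` (semi-global DP: free start and end in the text).  'N' never
// matches, per the convention that ambiguous read bases count as mismatches.
static int semiglobal_dist(const std::string& pat, const std::string& txt, int k) {
    const int m = pat.size(), n = txt.size();
    if (m == 0) return 0;
    std::vector<int> col(m + 1), ncol(m + 1);
    for (int i = 0; i <= m; ++i) col[i] = i;
    int best = m;
    for (int j = 1; j <= n; ++j) {
        ncol[0] = 0;  // free start anywhere in the text
        const char tc = txt[j - 1];
        for (int i = 1; i <= m; ++i) {
            const char pc = pat[i - 1];
            const int sub = (pc == tc && pc != 'N') ? 0 : 1;
            int v = col[i - 1] + sub;
            v = std::min(v, col[i] + 1);
            v = std::min(v, ncol[i - 1] + 1);
            ncol[i] = v;
        }
        best = std::min(best, ncol[m]);
        if (best == 0) return 0;
        std::swap(col, ncol);
    }
    (void)k;
    return best;
}

// Exact substring presence (k = 0 fast path).
static bool exact_contains(const std::string& pat, const std::string& txt) {
    return txt.find(pat) != std::string::npos;
}

//' @noRd
// [[Rcpp::export]]
List cpp_fuzzy_match(std::string query, CharacterVector reads, int max_edits) {
    const std::string q = query;
    const std::string qrc = revcomp(q);
    const bool palindrome = (q == qrc);
    std::vector<int> idx;
    std::vector<int> dist;
    std::vector<std::string> strand;
    const int n = reads.size();
    for (int r = 0; r < n; ++r) {
        const std::string txt = as<std::string>(reads[r]);
        if ((int)txt.size() < (int)q.size()) continue;
        int dplus, dminus;
        if (max_edits == 0) {
            dplus  = exact_contains(q, txt) ? 0 : 1;
            dminus = palindrome ? dplus : (exact_contains(qrc, txt) ? 0 : 1);
            if (dplus > 0 && dminus > 0) continue;
        } else {
            dplus  = semiglobal_dist(q, txt, max_edits);
            dminus = palindrome ? dplus : semiglobal_dist(qrc, txt, max_edits);
            if (std::min(dplus, dminus) > max_edits) continue;
        }
        idx.push_back(r + 1);
        if (dplus <= dminus) {
            dist.push_back(dplus);
            strand.push_back("+");
        } else {
            dist.push_back(dminus);
            strand.push_back("-");
        }
    }
    return List::create(_["index"] = wrap(idx),
                        _["edit_distance"] = wrap(dist),
                        _["strand"] = wrap(strand));
}
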