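#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static inline bool can_pair(char a, char b) {
    return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
           (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
           (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Maximum nested base pairing (AU/GC/GU) with a minimum hairpin loop size.
// `forbid` lists 0-based positions that must stay unpaired.
// Traceback prefers pairing the right end with the most distant partner at
// equal score, which keeps designed terminal stems intact in reported
// structures.
// [[Rcpp::export(name = ".nussinov_cpp")]]
List nussinov_cpp(std::string seq, int min_loop, IntegerVector forbid) {
    int n = seq.size();
    std::vector<bool> blocked(n, false);
    for (int f = 0; f < forbid.size(); ++f) {
        int p = forbid[f];
        if (p < 0 || p >= n) stop("forbidden position out of range");
        blocked[p] = true;
    }
    if (n == 0)
        return List::create(_["pairs"] = 0, _["structure"] = "");
    std::vector<int> dp((size_t)n * n, 0);
    #define DP(i, j) dp[(size_t)(i) * n + (j)]
    for (int span = min_loop + 1; span < n; ++span) {
        for (int i = 0; i + span < n; ++i) {
            int j = i + span;
            int best = DP(i, j - 1);
            if (!blocked[j]) {
                for (int k = i; k <= j - min_loop - 1; ++k) {
                    if (blocked[k] || !can_pair(seq[k], seq[j])) continue;
                    int cand = 1 + DP(k + 1, j - 1);
                    if (k > i) cand += DP(i, k - 1);
                    if (cand > best) best = cand;
                }
            }
            DP(i, j) = best;
        }
    }
    std::string db(n, '.');
    std::vector<std::pair<int, int> > stack;
    stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (i >= j || j - i <= min_loop) continue;
        bool done = false;
        if (!blocked[j]) {
            for (int k = i; k <= j - min_loop - 1 && !done; ++k) {
                if (blocked[k] || !can_pair(seq[k], seq[j])) continue;
                int cand = 1 + DP(k + 1, j - 1);
                if (k > i) cand += DP(i, k - 1);
                if (cand == DP(i, j)) {
                    db[k] = '(';
                    db[j] = ')';
                    if (k > i) stack.push_back(std::make_pair(i, k - 1));
                    stack.push_back(std::make_pair(k + 1, j - 1));
                    done = true;
                }
            }
        }
        if (!done) stack.push_back(std::make_pair(i, j - 1));
    }
    int total = (n > 1) ? DP(0, n - 1) : 0;
    #undef DP
    return List::create(_["pairs"] = total, _["structure"] = db);
}
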