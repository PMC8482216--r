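#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps.
// A gap of length L costs gap_open + L * gap_extend (both penalties are
// supplied as negative numbers), i.e. opening a 1-base gap costs
// gap_open + gap_extend. Traceback is a full three-state (match/insert/
// delete) walk so gap runs and identity are reported exactly.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string subject,
                  int match, int mismatch, int gap_open, int gap_extend) {
    int n = query.size(), m = subject.size();
    if (n == 0 || m == 0) stop("empty sequence");
    const int NEG = -1000000000;
    size_t W = (size_t)m + 1;
    std::vector<int> H((size_t)(n + 1) * W, 0), E((size_t)(n + 1) * W, NEG),
        F((size_t)(n + 1) * W, NEG);
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            size_t c = (size_t)i * W + j;
            int e = std::max(H[c - 1] + gap_open + gap_extend,
                             E[c - 1] + gap_extend);
            int f = std::max(H[c - W] + gap_open + gap_extend,
                             F[c - W] + gap_extend);
            int s = (query[i - 1] == subject[j - 1]) ? match : mismatch;
            int d = H[c - W - 1] + s;
            int h = 0;
            if (d > h) h = d;
            if (f > h) h = f;
            if (e > h) h = e;
            H[c] = h; E[c] = e; F[c] = f;
            if (h > best) { best = h; bi = i; bj = j; }
        }
    }
    int i = bi, j = bj, matches = 0, columns = 0;
    int state = 0; // 0 = H, 1 = E (gap in query), 2 = F (gap in subject)
    while (i > 0 && j > 0) {
        size_t c = (size_t)i * W + j;
        if (state == 0) {
            if (H[c] == 0) break;
            int s = (query[i - 1] == subject[j - 1]) ? match : mismatch;
            if (H[c] == H[c - W - 1] + s) {
                ++columns;
                if (query[i - 1] == subject[j - 1]) ++matches;
                --i; --j;
            } else if (H[c] == F[c]) {
                state = 2;
            } else if (H[c] == E[c]) {
                state = 1;
            } else {
                break; // unreachable
            }
        } else if (state == 1) {
            ++columns; // subject base aligned to a gap
            if (E[c] == H[c - 1] + gap_open + gap_extend) state = 0;
            --j;
        } else {
            ++columns; // query base aligned to a gap
            if (F[c] == H[c - W] + gap_open + gap_extend) state = 0;
            --i;
        }
    }
    double identity = columns > 0 ? (double)matches / columns : 0.0;
    return List::create(
        _["score"] = best,
        _["query_start"] = i, _["query_end"] = bi,
        _["subject_start"] = j, _["subject_end"] = bj,
        _["matches"] = matches, _["columns"] = columns,
        _["identity"] = identity);
}
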