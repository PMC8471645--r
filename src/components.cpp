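#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// 3D connected-component labelling of a logical array under 6-, 18- or
// 26-connectivity (face / face+edge / face+edge+corner neighbours).
// Components are numbered from 1 in scan order; 0 is background.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, int connectivity) {
    IntegerVector dims = mask.attr("dim");
    if (dims.size() != 3) stop("mask must be a 3D array");
    const int ns = dims[0], nr = dims[1], nc = dims[2];
    const int64_t n = (int64_t)ns * nr * nc;
    const int *m = LOGICAL(mask);

    // neighbour offsets
    std::vector<std::array<int,3>> nb;
    for (int ds = -1; ds <= 1; ++ds)
        for (int dr = -1; dr <= 1; ++dr)
            for (int dc = -1; dc <= 1; ++dc) {
                int nz = std::abs(ds) + std::abs(dr) + std::abs(dc);
                if (nz == 0) continue;
                if (connectivity == 6 && nz > 1) continue;
                if (connectivity == 18 && nz > 2) continue;
                nb.push_back({ds, dr, dc});
            }

    IntegerVector labels(n, 0);
    labels.attr("dim") = dims;
    int *lab = INTEGER(labels);
    std::vector<int64_t> stack;
    int next = 0;

    for (int64_t i = 0; i < n; ++i) {
        if (!m[i] || lab[i]) continue;
        ++next;
        lab[i] = next;
        stack.push_back(i);
        while (!stack.empty()) {
            int64_t cur = stack.back(); stack.pop_back();
            int s = (int)(cur % ns);
            int64_t t = cur / ns;
            int r = (int)(t % nr), c = (int)(t / nr);
            for (const auto &o : nb) {
                int s2 = s + o[0], r2 = r + o[1], c2 = c + o[2];
                if (s2 < 0 || s2 >= ns || r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc)
                    continue;
                int64_t j = (int64_t)s2 + (int64_t)ns * ((int64_t)r2 + (int64_t)nr * c2);
                if (m[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
            }
        }
    }
    labels.attr("n_components") = next;
    return labels;
}
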