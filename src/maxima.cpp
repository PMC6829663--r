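#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Prominence-based local maxima by topological persistence.
//
// Pixels are processed in decreasing intensity order while connected
// components (8-neighbourhood) are grown with a union-find structure. Each
// component is born at a local maximum; when two components meet, the one
// with the lower peak dies and its persistence is (peak height - merge
// level), i.e. the height of the peak above the highest saddle connecting
// it to a higher peak. This reproduces the noise-tolerance semantics of the
// ImageJ "find maxima" routine: a maximum is reported iff its persistence
// is >= the tolerance. Ties in intensity are broken by pixel index so the
// result is deterministic.

static int uf_find(std::vector<int>& parent, int i) {
    while (parent[i] != i) {
        parent[i] = parent[parent[i]];
        i = parent[i];
    }
    return i;
}

// [[Rcpp::export(name = ".find_maxima_cpp")]]
DataFrame find_maxima_cpp(NumericMatrix img, double tolerance) {
    const int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) order[i] = i;
    const double* v = img.begin();
    std::stable_sort(order.begin(), order.end(),
                     [&](int a, int b) { return v[a] > v[b]; });

    std::vector<int> parent(n, -1);       // -1 = not yet processed
    std::vector<int> comp_peak(n, -1);    // representative -> peak pixel
    std::vector<int> peaks;
    std::vector<double> prominence;

    const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
    const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

    for (int k = 0; k < n; ++k) {
        int p = order[k];
        int r = p % nr, c = p / nr;
        double level = v[p];
        parent[p] = p;
        comp_peak[p] = p;
        for (int j = 0; j < 8; ++j) {
            int rr = r + dr[j], cc = c + dc[j];
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            int q = rr + cc * nr;
            if (parent[q] < 0) continue;  // neighbour not yet flooded
            int ra = uf_find(parent, p);
            int rb = uf_find(parent, q);
            if (ra == rb) continue;
            int pa = comp_peak[ra], pb = comp_peak[rb];
            // the component with the lower peak dies at this saddle
            bool a_dies = (v[pa] < v[pb]) || (v[pa] == v[pb] && pa > pb);
            int dies = a_dies ? pa : pb;
            double pers = v[dies] - level;
            if (pers >= tolerance && v[dies] > level) {
                peaks.push_back(dies);
                prominence.push_back(pers);
            }
            // merge: survivor's peak is kept
            int surv_peak = a_dies ? pb : pa;
            parent[ra] = rb;
            comp_peak[rb] = surv_peak;
            comp_peak[ra] = surv_peak;
        }
    }
    // the global maximum never merges into anything: persistence = range
    if (n > 0) {
        int root = uf_find(parent, order[0]);
        int gp = comp_peak[root];
        double pers = v[gp] - v[order[n - 1]];
        if (pers >= tolerance) {
            peaks.push_back(gp);
            prominence.push_back(pers);
        }
    }

    int m = (int)peaks.size();
    IntegerVector row(m), col(m);
    NumericVector val(m), prom(m);
    for (int i = 0; i < m; ++i) {
        row[i] = peaks[i] % nr + 1;   // 1-based for R
        col[i] = peaks[i] / nr + 1;
        val[i] = v[peaks[i]];
        prom[i] = prominence[i];
    }
    return DataFrame::create(_["row"] = row, _["col"] = col,
                             _["value"] = val, _["prominence"] = prom);
}
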