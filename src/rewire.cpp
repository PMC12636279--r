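#include <Rcpp.h>
using namespace Rcpp;

// Degree-preserving double-edge swaps on a weighted undirected graph.
// Edges carry their weights through swaps, so the binary degree sequence and
// the edge-weight multiset are both preserved exactly.  Uses R's RNG, so the
// result is deterministic under set.seed().
//
// w:     symmetric nonnegative adjacency with zero diagonal (0 = no edge)
// nAttempts: number of attempted swaps
// [[Rcpp::export(name = ".rewire_swaps")]]
NumericMatrix rewire_swaps(NumericMatrix w, int nAttempts) {
    int n = w.nrow();
    std::vector<int> ei, ej;
    std::vector<double> ew;
    for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j)
            if (w(i, j) > 0) {
                ei.push_back(i);
                ej.push_back(j);
                ew.push_back(w(i, j));
            }
    int m = (int) ei.size();
    NumericMatrix out(n, n);
    if (m < 2) {
        for (int i = 0; i < n; ++i)
            for (int j = 0; j < n; ++j) out(i, j) = w(i, j);
        return out;
    }
    // boolean adjacency for O(1) duplicate checks
    std::vector<char> adj((size_t) n * n, 0);
    for (int e = 0; e < m; ++e) {
        adj[(size_t) ei[e] * n + ej[e]] = 1;
        adj[(size_t) ej[e] * n + ei[e]] = 1;
    }
    for (int t = 0; t < nAttempts; ++t) {
        int e1 = (int) (unif_rand() * m);
        int e2 = (int) (unif_rand() * m);
        if (e1 >= m) e1 = m - 1;
        if (e2 >= m) e2 = m - 1;
        if (e1 == e2) continue;
        int a = ei[e1], b = ej[e1], c = ei[e2], d = ej[e2];
        if (unif_rand() < 0.5) std::swap(c, d);  // both swap pairings reachable
        // propose (a,b),(c,d) -> (a,d),(c,b)
        if (a == d || c == b) continue;                    // self-loop
        if (adj[(size_t) a * n + d] || adj[(size_t) c * n + b]) continue;
        adj[(size_t) a * n + b] = adj[(size_t) b * n + a] = 0;
        adj[(size_t) c * n + d] = adj[(size_t) d * n + c] = 0;
        adj[(size_t) a * n + d] = adj[(size_t) d * n + a] = 1;
        adj[(size_t) c * n + b] = adj[(size_t) b * n + c] = 1;
        ei[e1] = a < d ? a : d;
        ej[e1] = a < d ? d : a;
        ei[e2] = c < b ? c : b;
        ej[e2] = c < b ? b : c;
    }
    for (int e = 0; e < m; ++e) {
        out(ei[e], ej[e]) = ew[e];
        out(ej[e], ei[e]) = ew[e];
    }
    return out;
}
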