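#include <Rcpp.h>
#include <array>
#include <cstdint>
#include <vector>

// Brute-force maximum of the first Betti number of the clique complex over
// all simple graphs on n labelled vertices. For a graph G with E edges, n
// vertices and c components, beta1 of the clique complex X(G) is
//   E - n + c - rank_GF2(boundary of the triangles of G),
// since H1 of a clique complex only depends on the 2-skeleton and its
// 2-simplices are exactly the triangles of G. Enumeration is over all
// 2^C(n,2) edge subsets; feasible for n <= 7 (2^21 graphs).

// [[Rcpp::export]]
int brute_force_max_betti1_cpp(int n) {
    if (n < 1 || n > 7) Rcpp::stop("n must be in 1..7");
    const int m = n * (n - 1) / 2;
    std::vector<int> eu(m), ev(m);
    {
        int k = 0;
        for (int i = 0; i < n; ++i)
            for (int j = i + 1; j < n; ++j) { eu[k] = i; ev[k] = j; ++k; }
    }
    // edge index lookup
    int eid[7][7];
    for (int k = 0; k < m; ++k) { eid[eu[k]][ev[k]] = k; eid[ev[k]][eu[k]] = k; }
    // all triangles as edge-index triples
    std::vector<std::array<int, 3>> tris;
    for (int a = 0; a < n; ++a)
        for (int b = a + 1; b < n; ++b)
            for (int c = b + 1; c < n; ++c)
                tris.push_back({eid[a][b], eid[a][c], eid[b][c]});

    int best = 0;
    const uint32_t total = 1u << m;
    std::vector<uint32_t> pivots; pivots.reserve(32);
    for (uint32_t mask = 0; mask < total; ++mask) {
        const int E = __builtin_popcount(mask);
        // beta1 <= E - n + c and c <= n - (edges can only reduce c);
        // cheap prune: even with rank 0 and max possible c.
        // c >= n - E, c <= n; upper bound beta1 <= E - n + n = E.
        if (E <= best) continue;
        // components via union-find
        int parent[7];
        for (int i = 0; i < n; ++i) parent[i] = i;
        for (int k = 0; k < m; ++k) {
            if (!(mask & (1u << k))) continue;
            int a = eu[k], b = ev[k];
            while (parent[a] != a) a = parent[a] = parent[parent[a]];
            while (parent[b] != b) b = parent[b] = parent[parent[b]];
            if (a != b) parent[a] = b;
        }
        int c = 0;
        for (int i = 0; i < n; ++i) if (parent[i] == i) ++c;
        int cycles = E - n + c;
        if (cycles <= best) continue;
        // GF(2) rank of the triangle boundary rows over the edge space
        pivots.clear();
        int rank = 0;
        for (const auto& t : tris) {
            const uint32_t need = (1u << t[0]) | (1u << t[1]) | (1u << t[2]);
            if ((mask & need) != need) continue;   // triangle not in G
            uint32_t row = need;
            for (uint32_t p : pivots) {
                const uint32_t pb = 1u << (31 - __builtin_clz(p));
                if (row & pb) row ^= p;
            }
            if (row) { pivots.push_back(row); ++rank; }
        }
        const int b1 = cycles - rank;
        if (b1 > best) best = b1;
    }
    return best;
}
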