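#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path compression + union by root index.
static int uf_find(std::vector<int>& parent, int i) {
    int root = i;
    while (parent[root] != root) root = parent[root];
    while (parent[i] != root) { int nxt = parent[i]; parent[i] = root; i = nxt; }
    return root;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
    int ra = uf_find(parent, a), rb = uf_find(parent, b);
    if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

//' Two-pass connected-component labeling (internal kernel).
//'
//' Labels are assigned 1..K in row-major order of each component's first
//' pixel, so the output is deterministic for a given mask and connectivity.
//'
//' @param mask logical matrix (TRUE = foreground)
//' @param connectivity 4 or 8
//' @return integer matrix of component labels, 0 for background
//' @keywords internal
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
    if (connectivity != 4 && connectivity != 8)
        stop("connectivity must be 4 or 8");
    const int nr = mask.nrow(), nc = mask.ncol();
    std::vector<int> parent(static_cast<size_t>(nr) * nc, -1);

    // first pass: column-major scan, union with previously visited neighbours
    for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
            if (!mask(r, c)) continue;
            const int idx = r + c * nr;
            parent[idx] = idx;
            if (r > 0 && mask(r - 1, c)) uf_union(parent, idx, idx - 1);
            if (c > 0 && mask(r, c - 1)) uf_union(parent, idx, idx - nr);
            if (connectivity == 8 && c > 0) {
                if (r > 0 && mask(r - 1, c - 1)) uf_union(parent, idx, idx - nr - 1);
                if (r < nr - 1 && mask(r + 1, c - 1)) uf_union(parent, idx, idx - nr + 1);
            }
        }
    }

    // second pass: relabel so that components are numbered by the row-major
    // position of their first pixel
    IntegerMatrix out(nr, nc);
    std::vector<int> label_of_root(static_cast<size_t>(nr) * nc, 0);
    int next = 0;
    for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
            if (!mask(r, c)) continue;
            const int root = uf_find(parent, r + c * nr);
            if (label_of_root[root] == 0) label_of_root[root] = ++next;
            out(r, c) = label_of_root[root];
        }
    }
    return out;
}
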