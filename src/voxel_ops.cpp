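#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Arrays are stored in R's column-major order with dims = (nz, ny, nx):
// linear index i = z + nz*(y + ny*x), 0-based internally.

static inline void idx_to_zyx(int i, int nz, int ny, int &z, int &y, int &x) {
    z = i % nz;
    int r = i / nz;
    y = r % ny;
    x = r / ny;
}

// lexicographic (z,y,x) tie-break key: z most significant
static inline double lex_key(int z, int y, int x, int ny, int nx) {
    return ((double)z * ny + y) * nx + x;
}

struct UF {
    std::vector<int> parent;
    UF(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
    int find(int a) {
        while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
        return a;
    }
};

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
    int nz = dims[0], ny = dims[1], nx = dims[2];
    int n = nz * ny * nx;
    IntegerVector labels(n, 0);
    std::vector<int> stack;
    int next_label = 0;
    for (int start = 0; start < n; ++start) {
        if (!mask[start] || labels[start] != 0) continue;
        ++next_label;
        labels[start] = next_label;
        stack.push_back(start);
        while (!stack.empty()) {
            int v = stack.back(); stack.pop_back();
            int z, y, x; idx_to_zyx(v, nz, ny, z, y, x);
            for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                if (dz == 0 && dy == 0 && dx == 0) continue;
                if (connectivity == 6 && std::abs(dz) + std::abs(dy) + std::abs(dx) > 1)
                    continue;
                int z2 = z + dz, y2 = y + dy, x2 = x + dx;
                if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
                    continue;
                int w = z2 + nz * (y2 + ny * x2);
                if (mask[w] && labels[w] == 0) {
                    labels[w] = next_label;
                    stack.push_back(w);
                }
            }
        }
    }
    return labels;
}

// Persistence-based local-maximum detection inside a mask.
// Voxels are flooded in decreasing intensity (ties broken by lexicographic
// (z,y,x) position). A voxel with no already-flooded 26-neighbour founds a
// component and is recorded as a peak (one representative per plateau).
// When two components meet at level v the peak of the lower-peaked component
// receives prominence = peak_value - v; surviving roots get +Inf.
// [[Rcpp::export(name = ".cpp_persistence_peaks")]]
List cpp_persistence_peaks(NumericVector values, IntegerVector dims,
                           LogicalVector mask) {
    int nz = dims[0], ny = dims[1], nx = dims[2];
    int n = nz * ny * nx;
    std::vector<int> order;
    order.reserve(n);
    for (int i = 0; i < n; ++i) if (mask[i]) order.push_back(i);
    std::sort(order.begin(), order.end(), [&](int a, int b) {
        if (values[a] != values[b]) return values[a] > values[b];
        int za, ya, xa, zb, yb, xb;
        idx_to_zyx(a, nz, ny, za, ya, xa);
        idx_to_zyx(b, nz, ny, zb, yb, xb);
        return lex_key(za, ya, xa, ny, nx) < lex_key(zb, yb, xb, ny, nx);
    });

    UF uf(n);
    std::vector<char> processed(n, 0);
    std::vector<int> comp_peak(n, -1);        // root -> founding peak index
    std::vector<int> peaks;
    std::vector<double> prominence;           // parallel to peaks
    std::vector<int> peak_slot(n, -1);        // voxel -> position in peaks

    for (size_t k = 0; k < order.size(); ++k) {
        int v = order[k];
        int z, y, x; idx_to_zyx(v, nz, ny, z, y, x);
        int best_root = -1;
        for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
            if (dz == 0 && dy == 0 && dx == 0) continue;
            int z2 = z + dz, y2 = y + dy, x2 = x + dx;
            if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
                continue;
            int w = z2 + nz * (y2 + ny * x2);
            if (!processed[w]) continue;
            int root = uf.find(w);
            if (best_root == -1) { best_root = root; continue; }
            if (root == best_root) continue;
            // merge: component whose peak is lower dies here
            int pa = comp_peak[best_root], pb = comp_peak[root];
            bool a_wins;
            if (values[pa] != values[pb]) a_wins = values[pa] > values[pb];
            else {
                int za, ya, xa2, zb, yb, xb2;
                idx_to_zyx(pa, nz, ny, za, ya, xa2);
                idx_to_zyx(pb, nz, ny, zb, yb, xb2);
                a_wins = lex_key(za, ya, xa2, ny, nx) < lex_key(zb, yb, xb2, ny, nx);
            }
            int dead_peak = a_wins ? pb : pa;
            prominence[peak_slot[dead_peak]] = values[dead_peak] - values[v];
            uf.parent[uf.find(a_wins ? root : best_root)] =
                uf.find(a_wins ? best_root : root);
            int surv = uf.find(best_root);
            comp_peak[surv] = a_wins ? pa : pb;
            best_root = surv;
        }
        if (best_root == -1) {
            // no higher processed neighbour: v founds a component (local max)
            comp_peak[uf.find(v)] = v;
            peak_slot[v] = (int)peaks.size();
            peaks.push_back(v);
            prominence.push_back(R_PosInf);
        } else {
            uf.parent[uf.find(v)] = uf.find(best_root);
            int root = uf.find(best_root);
            // comp_peak stays
            comp_peak[root] = comp_peak[root];
        }
        processed[v] = 1;
    }

    IntegerVector out_peaks(peaks.size());
    NumericVector out_prom(peaks.size());
    for (size_t i = 0; i < peaks.size(); ++i) {
        out_peaks[i] = peaks[i] + 1;  // 1-based for R
        out_prom[i] = prominence[i];
    }
    return List::create(_["peak"] = out_peaks, _["prominence"] = out_prom);
}

// Multi-source Dijkstra over a voxel domain with anisotropy-weighted
// 26-neighbour steps (edge length = Euclidean distance between voxel
// centres in micrometres). Equal distances resolve to the lower seed label.
// [[Rcpp::export(name = ".cpp_geodesic_assign")]]
IntegerVector cpp_geodesic_assign(LogicalVector domain, IntegerVector dims,
                                  IntegerVector seeds, NumericVector voxel_size) {
    int nz = dims[0], ny = dims[1], nx = dims[2];
    int n = nz * ny * nx;
    double sz = voxel_size[0], sy = voxel_size[1], sx = voxel_size[2];
    IntegerVector labels(n, 0);
    std::vector<double> dist(n, R_PosInf);

    typedef std::tuple<double, int, int> Node;  // (dist, label, voxel)
    std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
    for (int s = 0; s < seeds.size(); ++s) {
        int v = seeds[s] - 1;
        if (v < 0 || v >= n || !domain[v]) continue;
        pq.push(Node(0.0, s + 1, v));
    }
    while (!pq.empty()) {
        Node nd = pq.top(); pq.pop();
        double d = std::get<0>(nd);
        int lab = std::get<1>(nd), v = std::get<2>(nd);
        if (labels[v] != 0) continue;
        labels[v] = lab;
        dist[v] = d;
        int z, y, x; idx_to_zyx(v, nz, ny, z, y, x);
        for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
            if (dz == 0 && dy == 0 && dx == 0) continue;
            int z2 = z + dz, y2 = y + dy, x2 = x + dx;
            if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
                continue;
            int w = z2 + nz * (y2 + ny * x2);
            if (!domain[w] || labels[w] != 0) continue;
            double step = std::sqrt(dz * dz * sz * sz + dy * dy * sy * sy +
                                    dx * dx * sx * sx);
            if (d + step < dist[w]) {
                dist[w] = d + step;
                pq.push(Node(d + step, lab, w));
            }
        }
    }
    return labels;
}
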