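#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

static inline void get_dims(const IntegerVector &labels, int &nx, int &ny, int &nz) {
    IntegerVector d = labels.attr("dim");
    if (d.size() != 3) stop("expected a 3D array");
    nx = d[0]; ny = d[1]; nz = d[2];
}

// Connected components of the nonzero mask. connectivity: 6 or 26.
// Returns an integer array of component labels 1..k (0 = background),
// numbered in order of first (column-major) encounter.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector labels, int connectivity) {
    int nx, ny, nz;
    get_dims(labels, nx, ny, nz);
    if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    IntegerVector out(n, 0);
    out.attr("dim") = labels.attr("dim");

    std::vector<int> dx, dy, dz;
    for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
                if (a == 0 && b == 0 && c == 0) continue;
                int man = std::abs(a) + std::abs(b) + std::abs(c);
                if (connectivity == 6 && man != 1) continue;
                dx.push_back(a); dy.push_back(b); dz.push_back(c);
            }
    const int noff = (int)dx.size();

    int comp = 0;
    std::vector<R_xlen_t> stack;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (labels[s] == 0 || out[s] != 0) continue;
        ++comp;
        stack.clear();
        stack.push_back(s);
        out[s] = comp;
        while (!stack.empty()) {
            R_xlen_t v = stack.back(); stack.pop_back();
            int k = (int)(v / ((R_xlen_t)nx * ny));
            int rem = (int)(v - (R_xlen_t)k * nx * ny);
            int j = rem / nx, i = rem % nx;
            for (int o = 0; o < noff; ++o) {
                int ii = i + dx[o], jj = j + dy[o], kk = k + dz[o];
                if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
                R_xlen_t w = (R_xlen_t)ii + (R_xlen_t)jj * nx + (R_xlen_t)kk * nx * ny;
                if (labels[w] != 0 && out[w] == 0) {
                    out[w] = comp;
                    stack.push_back(w);
                }
            }
        }
    }
    return out;
}

// All 6-adjacent voxel pairs whose labels differ and are both nonzero.
// Returns 1-based flat indices and the labels on each side.
// [[Rcpp::export]]
List cpp_interface_pairs(IntegerVector labels) {
    int nx, ny, nz;
    get_dims(labels, nx, ny, nz);
    std::vector<double> ia, ib;
    std::vector<int> la, lb;
    const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i) {
                R_xlen_t v = i + (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny;
                int lv = labels[v];
                if (lv == 0) continue;
                if (i + 1 < nx) {
                    int lw = labels[v + sx];
                    if (lw != 0 && lw != lv) { ia.push_back((double)(v + 1)); ib.push_back((double)(v + sx + 1)); la.push_back(lv); lb.push_back(lw); }
                }
                if (j + 1 < ny) {
                    int lw = labels[v + sy];
                    if (lw != 0 && lw != lv) { ia.push_back((double)(v + 1)); ib.push_back((double)(v + sy + 1)); la.push_back(lv); lb.push_back(lw); }
                }
                if (k + 1 < nz) {
                    int lw = labels[v + sz];
                    if (lw != 0 && lw != lv) { ia.push_back((double)(v + 1)); ib.push_back((double)(v + sz + 1)); la.push_back(lv); lb.push_back(lw); }
                }
            }
    return List::create(_["a"] = wrap(ia), _["b"] = wrap(ib),
                        _["label_a"] = wrap(la), _["label_b"] = wrap(lb));
}

// Outer-boundary mask: nonzero voxels with at least one 6-neighbor that is
// background or outside the grid.
// [[Rcpp::export]]
LogicalVector cpp_boundary_mask(IntegerVector labels) {
    int nx, ny, nz;
    get_dims(labels, nx, ny, nz);
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    LogicalVector out(n, false);
    out.attr("dim") = labels.attr("dim");
    const int dx[6] = {1,-1,0,0,0,0}, dy[6] = {0,0,1,-1,0,0}, dz[6] = {0,0,0,0,1,-1};
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i) {
                R_xlen_t v = i + (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny;
                if (labels[v] == 0) continue;
                for (int o = 0; o < 6; ++o) {
                    int ii = i + dx[o], jj = j + dy[o], kk = k + dz[o];
                    if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz ||
                        labels[(R_xlen_t)ii + (R_xlen_t)jj * nx + (R_xlen_t)kk * nx * ny] == 0) {
                        out[v] = true;
                        break;
                    }
                }
            }
    return out;
}

// ---- uniform-grid nearest neighbour ----

struct CellGrid {
    double minx, miny, minz, cell;
    int ncx, ncy, ncz;
    std::unordered_map<int64_t, std::vector<int>> cells;
    int64_t key(int cx, int cy, int cz) const {
        return (int64_t)cx + (int64_t)cy * ncx + (int64_t)cz * ncx * (int64_t)ncy;
    }
};

static void build_grid(const NumericMatrix &pts, double cell, CellGrid &g) {
    const int n = pts.nrow();
    if (n == 0) stop("empty point set");
    g.cell = cell;
    g.minx = pts(0,0); g.miny = pts(0,1); g.minz = pts(0,2);
    double maxx = g.minx, maxy = g.miny, maxz = g.minz;
    for (int i = 1; i < n; ++i) {
        g.minx = std::min(g.minx, pts(i,0)); maxx = std::max(maxx, pts(i,0));
        g.miny = std::min(g.miny, pts(i,1)); maxy = std::max(maxy, pts(i,1));
        g.minz = std::min(g.minz, pts(i,2)); maxz = std::max(maxz, pts(i,2));
    }
    g.ncx = std::max(1, (int)std::floor((maxx - g.minx) / cell) + 1);
    g.ncy = std::max(1, (int)std::floor((maxy - g.miny) / cell) + 1);
    g.ncz = std::max(1, (int)std::floor((maxz - g.minz) / cell) + 1);
    g.cells.reserve(n * 2);
    for (int i = 0; i < n; ++i) {
        int cx = std::min(g.ncx - 1, (int)std::floor((pts(i,0) - g.minx) / cell));
        int cy = std::min(g.ncy - 1, (int)std::floor((pts(i,1) - g.miny) / cell));
        int cz = std::min(g.ncz - 1, (int)std::floor((pts(i,2) - g.minz) / cell));
        g.cells[g.key(cx, cy, cz)].push_back(i);
    }
}

// Nearest target point for each query point. cell: grid cell edge in the same
// units as the coordinates (choose ~ mean point spacing).
// [[Rcpp::export]]
List cpp_nn(NumericMatrix target, NumericMatrix query, double cell) {
    CellGrid g;
    build_grid(target, cell, g);
    const int m = query.nrow();
    IntegerVector idx(m);
    NumericVector dist(m);
    int rmax = std::max(g.ncx, std::max(g.ncy, g.ncz));
    for (int q = 0; q < m; ++q) {
        double px = query(q,0), py = query(q,1), pz = query(q,2);
        int cx = (int)std::floor((px - g.minx) / g.cell);
        int cy = (int)std::floor((py - g.miny) / g.cell);
        int cz = (int)std::floor((pz - g.minz) / g.cell);
        double best = R_PosInf;
        int besti = -1;
        // how far outside the grid the query cell sits (rings below this are empty)
        int r0 = 0;
        r0 = std::max(r0, -cx); r0 = std::max(r0, cx - (g.ncx - 1));
        r0 = std::max(r0, -cy); r0 = std::max(r0, cy - (g.ncy - 1));
        r0 = std::max(r0, -cz); r0 = std::max(r0, cz - (g.ncz - 1));
        for (int r = r0; r <= rmax + r0; ++r) {
            if (besti >= 0 && best <= (double)(r - 1) * g.cell) break;
            for (int a = cx - r; a <= cx + r; ++a) {
                if (a < 0 || a >= g.ncx) continue;
                for (int b = cy - r; b <= cy + r; ++b) {
                    if (b < 0 || b >= g.ncy) continue;
                    for (int c = cz - r; c <= cz + r; ++c) {
                        if (c < 0 || c >= g.ncz) continue;
                        if (std::max(std::abs(a - cx), std::max(std::abs(b - cy), std::abs(c - cz))) != r) continue;
                        auto it = g.cells.find(g.key(a, b, c));
                        if (it == g.cells.end()) continue;
                        for (int t : it->second) {
                            double dxx = target(t,0) - px, dyy = target(t,1) - py, dzz = target(t,2) - pz;
                            double d = std::sqrt(dxx*dxx + dyy*dyy + dzz*dzz);
                            if (d < best) { best = d; besti = t; }
                        }
                    }
                }
            }
        }
        idx[q] = besti + 1;
        dist[q] = best;
    }
    return List::create(_["index"] = idx, _["distance"] = dist);
}

// Indices (1-based, sorted, unique) of pts lying within `radius` of at least
// one center.
// [[Rcpp::export]]
IntegerVector cpp_radius_union(NumericMatrix pts, NumericMatrix centers, double radius) {
    CellGrid g;
    build_grid(pts, std::max(radius, 1e-6), g);
    std::vector<char> hit(pts.nrow(), 0);
    const double r2 = radius * radius;
    for (int q = 0; q < centers.nrow(); ++q) {
        double px = centers(q,0), py = centers(q,1), pz = centers(q,2);
        int cx = (int)std::floor((px - g.minx) / g.cell);
        int cy = (int)std::floor((py - g.miny) / g.cell);
        int cz = (int)std::floor((pz - g.minz) / g.cell);
        for (int a = cx - 1; a <= cx + 1; ++a) {
            if (a < 0 || a >= g.ncx) continue;
            for (int b = cy - 1; b <= cy + 1; ++b) {
                if (b < 0 || b >= g.ncy) continue;
                for (int c = cz - 1; c <= cz + 1; ++c) {
                    if (c < 0 || c >= g.ncz) continue;
                    auto it = g.cells.find(g.key(a, b, c));
                    if (it == g.cells.end()) continue;
                    for (int t : it->second) {
                        if (hit[t]) continue;
                        double dxx = pts(t,0) - px, dyy = pts(t,1) - py, dzz = pts(t,2) - pz;
                        if (dxx*dxx + dyy*dyy + dzz*dzz <= r2) hit[t] = 1;
                    }
                }
            }
        }
    }
    std::vector<int> out;
    for (int i = 0; i < (int)hit.size(); ++i) if (hit[i]) out.push_back(i + 1);
    return wrap(out);
}

// Watertight triangulated boundary surface of the nonzero mask.
// Vertices are voxel-corner positions in 0-based corner-grid units
// (corner a sits at origin + (a - 0.5) * spacing along each axis);
// faces are 1-based triangles wound so normals point outwards.
// [[Rcpp::export]]
List cpp_boundary_faces(IntegerVector labels) {
    int nx, ny, nz;
    get_dims(labels, nx, ny, nz);
    std::unordered_map<int64_t, int> vmap;
    std::vector<double> vx, vy, vz;
    std::vector<int> f1, f2, f3;
    const int64_t CX = nx + 1, CY = ny + 1;

    auto vid = [&](int a, int b, int c) -> int {
        int64_t key = (int64_t)a + (int64_t)b * CX + (int64_t)c * CX * CY;
        auto it = vmap.find(key);
        if (it != vmap.end()) return it->second;
        int id = (int)vx.size();
        vmap[key] = id;
        vx.push_back((double)a); vy.push_back((double)b); vz.push_back((double)c);
        return id;
    };
    auto quad = [&](int q00[3], int q10[3], int q11[3], int q01[3]) {
        int a = vid(q00[0], q00[1], q00[2]);
        int b = vid(q10[0], q10[1], q10[2]);
        int c = vid(q11[0], q11[1], q11[2]);
        int d = vid(q01[0], q01[1], q01[2]);
        f1.push_back(a + 1); f2.push_back(b + 1); f3.push_back(c + 1);
        f1.push_back(a + 1); f2.push_back(c + 1); f3.push_back(d + 1);
    };

    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i) {
                R_xlen_t v = i + (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny;
                if (labels[v] == 0) continue;
                // +x / -x faces: u axis = y, v axis = z (y x z = +x)
                if (i + 1 >= nx || labels[v + 1] == 0) {
                    int q00[3] = {i+1, j,   k}, q10[3] = {i+1, j+1, k},
                        q11[3] = {i+1, j+1, k+1}, q01[3] = {i+1, j, k+1};
                    quad(q00, q10, q11, q01);
                }
                if (i == 0 || labels[v - 1] == 0) {
                    int q00[3] = {i, j, k}, q10[3] = {i, j+1, k},
                        q11[3] = {i, j+1, k+1}, q01[3] = {i, j, k+1};
                    quad(q00, q01, q11, q10);
                }
                // +y / -y faces: u axis = z, v axis = x (z x x = +y)
                if (j + 1 >= ny || labels[v + nx] == 0) {
                    int q00[3] = {i, j+1, k}, q10[3] = {i, j+1, k+1},
                        q11[3] = {i+1, j+1, k+1}, q01[3] = {i+1, j+1, k};
                    quad(q00, q10, q11, q01);
                }
                if (j == 0 || labels[v - nx] == 0) {
                    int q00[3] = {i, j, k}, q10[3] = {i, j, k+1},
                        q11[3] = {i+1, j, k+1}, q01[3] = {i+1, j, k};
                    quad(q00, q01, q11, q10);
                }
                // +z / -z faces: u axis = x, v axis = y (x x y = +z)
                R_xlen_t sz = (R_xlen_t)nx * ny;
                if (k + 1 >= nz || labels[v + sz] == 0) {
                    int q00[3] = {i, j, k+1}, q10[3] = {i+1, j, k+1},
                        q11[3] = {i+1, j+1, k+1}, q01[3] = {i, j+1, k+1};
                    quad(q00, q10, q11, q01);
                }
                if (k == 0 || labels[v - sz] == 0) {
                    int q00[3] = {i, j, k}, q10[3] = {i+1, j, k},
                        q11[3] = {i+1, j+1, k}, q01[3] = {i, j+1, k};
                    quad(q00, q01, q11, q10);
                }
            }

    int nv = (int)vx.size();
    NumericMatrix verts(nv, 3);
    for (int i = 0; i < nv; ++i) { verts(i,0) = vx[i]; verts(i,1) = vy[i]; verts(i,2) = vz[i]; }
    int nf = (int)f1.size();
    IntegerMatrix faces(nf, 3);
    for (int i = 0; i < nf; ++i) { faces(i,0) = f1[i]; faces(i,1) = f2[i]; faces(i,2) = f3[i]; }
    return List::create(_["vertices"] = verts, _["faces"] = faces);
}
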