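#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Surface extraction by marching tetrahedra on the Kuhn (6-tetrahedra)
// decomposition of each grid cube. Every cube face carries the same diagonal
// in adjacent cubes, so the triangulation of space is conforming and the
// extracted iso-surface is closed and watertight by construction (no
// marching-cubes face ambiguities). Vertices are placed on tetrahedron edges
// by linear interpolation of the field at iso level.

// cube corner offsets in (s, r, c) index order
static const int CORNER[8][3] = {
    {0,0,0},{0,0,1},{0,1,1},{0,1,0},{1,0,0},{1,0,1},{1,1,1},{1,1,0}};

// six monotone edge paths 0 -> 6 (Kuhn simplices)
static const int TET[6][4] = {
    {0,1,2,6},{0,1,5,6},{0,3,2,6},{0,3,7,6},{0,4,5,6},{0,4,7,6}};

// [[Rcpp::export]]
List mt_mesh_cpp(NumericVector field, NumericVector spacing, double iso) {
    IntegerVector dims = field.attr("dim");
    if (dims.size() != 3) stop("field must be a 3D array");
    const int ns = dims[0], nr = dims[1], nc = dims[2];
    const double sps = spacing[0], spr = spacing[1], spc = spacing[2];
    const double *f = REAL(field);
    const int64_t nvox = (int64_t)ns * nr * nc;

    std::vector<double> vx, vy, vz;          // vertex coords (slice,row,col) mm
    std::vector<int> fa, fb, fc;             // 0-based face indices
    std::unordered_map<uint64_t, int> vmap;  // edge (lin_a,lin_b) -> vertex id
    vmap.reserve(1 << 16);

    auto lin = [&](int s, int r, int c) -> int64_t {
        return (int64_t)s + (int64_t)ns * ((int64_t)r + (int64_t)nr * c);
    };
    auto coord = [&](int64_t l, int *s, int *r, int *c) {
        *s = (int)(l % ns); int64_t t = l / ns; *r = (int)(t % nr); *c = (int)(t / nr);
    };
    // interpolated vertex on edge between voxels a and b (linear indices)
    auto vert_id = [&](int64_t a, int64_t b) -> int {
        if (a > b) std::swap(a, b);
        uint64_t key = (uint64_t)a * (uint64_t)nvox + (uint64_t)b;
        auto it = vmap.find(key);
        if (it != vmap.end()) return it->second;
        int sa, ra, ca, sb, rb, cb;
        coord(a, &sa, &ra, &ca); coord(b, &sb, &rb, &cb);
        double va = f[a], vb = f[b];
        double t = (iso - va) / (vb - va);
        if (t < 1e-6) t = 1e-6;            // keep triangles non-degenerate
        if (t > 1.0 - 1e-6) t = 1.0 - 1e-6;
        int id = (int)vx.size();
        vx.push_back((sa + t * (sb - sa)) * sps);
        vy.push_back((ra + t * (rb - ra)) * spr);
        vz.push_back((ca + t * (cb - ca)) * spc);
        vmap.emplace(key, id);
        return id;
    };
    // emit one triangle, oriented so its normal points away from the inside
    auto emit = [&](int i0, int i1, int i2, double rs, double rr, double rc) {
        double ax = vx[i0], ay = vy[i0], az = vz[i0];
        double ux = vx[i1]-ax, uy = vy[i1]-ay, uz = vz[i1]-az;
        double wx = vx[i2]-ax, wy = vy[i2]-ay, wz = vz[i2]-az;
        double nx = uy*wz - uz*wy, ny = uz*wx - ux*wz, nz = ux*wy - uy*wx;
        double cx = (vx[i0]+vx[i1]+vx[i2])/3.0, cy = (vy[i0]+vy[i1]+vy[i2])/3.0,
               cz = (vz[i0]+vz[i1]+vz[i2])/3.0;
        // rs,rr,rc is an inside corner (physical units)
        if (nx*(rs-cx) + ny*(rr-cy) + nz*(rc-cz) > 0) std::swap(i1, i2);
        fa.push_back(i0); fb.push_back(i1); fc.push_back(i2);
    };

    int64_t cpos[8]; bool cin[8];
    for (int c = 0; c + 1 < nc; ++c)
      for (int r = 0; r + 1 < nr; ++r)
        for (int s = 0; s + 1 < ns; ++s) {
            int n_in = 0;
            for (int i = 0; i < 8; ++i) {
                cpos[i] = lin(s + CORNER[i][0], r + CORNER[i][1], c + CORNER[i][2]);
                cin[i] = f[cpos[i]] > iso;
                n_in += cin[i];
            }
            if (n_in == 0 || n_in == 8) continue;
            for (int t = 0; t < 6; ++t) {
                int ins[4], out[4], ni = 0, no = 0;
                for (int i = 0; i < 4; ++i) {
                    int ci = TET[t][i];
                    if (cin[ci]) ins[ni++] = ci; else out[no++] = ci;
                }
                if (ni == 0 || ni == 4) continue;
                int sref, rref, cref;
                coord(cpos[ins[0]], &sref, &rref, &cref);
                double rs = sref * sps, rr = rref * spr, rc = cref * spc;
                if (ni == 1) {
                    emit(vert_id(cpos[ins[0]], cpos[out[0]]),
                         vert_id(cpos[ins[0]], cpos[out[1]]),
                         vert_id(cpos[ins[0]], cpos[out[2]]), rs, rr, rc);
                } else if (ni == 3) {
                    emit(vert_id(cpos[ins[0]], cpos[out[0]]),
                         vert_id(cpos[ins[1]], cpos[out[0]]),
                         vert_id(cpos[ins[2]], cpos[out[0]]), rs, rr, rc);
                } else {
                    int q0 = vert_id(cpos[ins[0]], cpos[out[0]]);
                    int q1 = vert_id(cpos[ins[0]], cpos[out[1]]);
                    int q2 = vert_id(cpos[ins[1]], cpos[out[1]]);
                    int q3 = vert_id(cpos[ins[1]], cpos[out[0]]);
                    emit(q0, q1, q2, rs, rr, rc);
                    emit(q0, q2, q3, rs, rr, rc);
                }
            }
        }

    const int nv = (int)vx.size(), nf = (int)fa.size();
    NumericMatrix V(nv, 3);
    for (int i = 0; i < nv; ++i) { V(i,0) = vx[i]; V(i,1) = vy[i]; V(i,2) = vz[i]; }
    IntegerMatrix Fm(nf, 3);
    for (int i = 0; i < nf; ++i) { Fm(i,0) = fa[i]+1; Fm(i,1) = fb[i]+1; Fm(i,2) = fc[i]+1; }
    return List::create(_["vertices"] = V, _["faces"] = Fm);
}

// Taubin lambda|mu smoothing with the uniform umbrella operator; shrinkage of
// the positive (lambda) step is compensated by the negative (mu) step, so
// enclosed volume is approximately preserved.
// [[Rcpp::export]]
NumericMatrix taubin_smooth_cpp(NumericMatrix V, IntegerMatrix Fm,
                                int iterations, double lambda, double mu) {
    const int nv = V.nrow(), nf = Fm.nrow();
    // vertex adjacency from face edges
    std::vector<std::vector<int>> adj(nv);
    for (int i = 0; i < nf; ++i) {
        int a = Fm(i,0)-1, b = Fm(i,1)-1, c = Fm(i,2)-1;
        adj[a].push_back(b); adj[a].push_back(c);
        adj[b].push_back(a); adj[b].push_back(c);
        adj[c].push_back(a); adj[c].push_back(b);
    }
    for (int i = 0; i < nv; ++i) {
        std::sort(adj[i].begin(), adj[i].end());
        adj[i].erase(std::unique(adj[i].begin(), adj[i].end()), adj[i].end());
    }
    std::vector<double> cur(3 * nv), nxt(3 * nv);
    for (int i = 0; i < nv; ++i)
        for (int d = 0; d < 3; ++d) cur[3*i+d] = V(i,d);
    auto step = [&](double w) {
        for (int i = 0; i < nv; ++i) {
            const std::vector<int> &nb = adj[i];
            if (nb.empty()) {
                for (int d = 0; d < 3; ++d) nxt[3*i+d] = cur[3*i+d];
                continue;
            }
            double m[3] = {0,0,0};
            for (int j : nb) for (int d = 0; d < 3; ++d) m[d] += cur[3*j+d];
            for (int d = 0; d < 3; ++d) {
                double avg = m[d] / nb.size();
                nxt[3*i+d] = cur[3*i+d] + w * (avg - cur[3*i+d]);
            }
        }
        cur.swap(nxt);
    };
    for (int it = 0; it < iterations; ++it) { step(lambda); step(-mu); }
    NumericMatrix out(nv, 3);
    for (int i = 0; i < nv; ++i)
        for (int d = 0; d < 3; ++d) out(i,d) = cur[3*i+d];
    return out;
}

// Separable Gaussian smoothing of a 3D array, sigma in voxel units per axis,
// zero (background) boundary condition, kernel truncated at `radius` voxels.
// [[Rcpp::export]]
NumericVector gaussian_smooth3d_cpp(NumericVector vol, NumericVector sigma,
                                    int radius) {
    IntegerVector dims = vol.attr("dim");
    const int ns = dims[0], nr = dims[1], nc = dims[2];
    const int64_t n = (int64_t)ns * nr * nc;
    std::vector<double> a(vol.begin(), vol.end()), b(n);
    const int64_t stride[3] = {1, (int64_t)ns, (int64_t)ns * nr};
    const int len[3] = {ns, nr, nc};

    for (int ax = 0; ax < 3; ++ax) {
        double sg = sigma[ax];
        if (sg <= 0) continue;
        std::vector<double> w(2 * radius + 1);
        double tot = 0;
        for (int k = -radius; k <= radius; ++k) {
            w[k + radius] = std::exp(-0.5 * k * k / (sg * sg));
            tot += w[k + radius];
        }
        for (double &x : w) x /= tot;
        const int64_t st = stride[ax];
        const int L = len[ax];
        // iterate over all lines along axis `ax`
        int o1 = (ax == 0) ? 1 : 0;                 // remaining two axes
        int o2 = (ax == 2) ? 1 : 2;
        for (int j2 = 0; j2 < len[o2]; ++j2)
            for (int j1 = 0; j1 < len[o1]; ++j1) {
                int64_t base = stride[o1] * j1 + stride[o2] * j2;
                for (int i = 0; i < L; ++i) {
                    double acc = 0;
                    int k0 = std::max(-radius, -i), k1 = std::min(radius, L - 1 - i);
                    for (int k = k0; k <= k1; ++k)
                        acc += w[k + radius] * a[base + (int64_t)(i + k) * st];
                    b[base + (int64_t)i * st] = acc;
                }
            }
        a.swap(b);
    }
    NumericVector out(a.begin(), a.end());
    out.attr("dim") = dims;
    return out;
}

// Exact maximum pairwise Euclidean distance of a point cloud (2 or 3
// columns). A KD-tree dual-traversal branch-and-bound: node pairs whose
// bounding-box upper bound cannot beat the current best are pruned, leaf
// pairs are checked exhaustively, so the result is exact. The initial lower
// bound comes from iterated farthest-point sweeps plus extreme points over
// a direction grid.
namespace maxdist {

struct Node {
    int lo, hi;          // point index range [lo, hi)
    int left, right;     // children (-1 for leaf)
    double bmin[3], bmax[3];
};

struct Tree {
    const double *X;     // n x d, row-major
    int d;
    std::vector<int> idx;
    std::vector<Node> nodes;

    double coord(int i, int k) const { return X[(size_t)idx[i] * d + k]; }

    int build(int lo, int hi) {
        int id = (int)nodes.size();
        nodes.push_back(Node());
        Node &nd = nodes.back();
        nd.lo = lo; nd.hi = hi; nd.left = nd.right = -1;
        for (int k = 0; k < d; ++k) {
            nd.bmin[k] = R_PosInf; nd.bmax[k] = R_NegInf;
        }
        for (int i = lo; i < hi; ++i)
            for (int k = 0; k < d; ++k) {
                double v = coord(i, k);
                if (v < nd.bmin[k]) nd.bmin[k] = v;
                if (v > nd.bmax[k]) nd.bmax[k] = v;
            }
        if (hi - lo <= 32) return id;
        int ax = 0; double w = -1;
        for (int k = 0; k < d; ++k) {
            double t = nd.bmax[k] - nd.bmin[k];
            if (t > w) { w = t; ax = k; }
        }
        int mid = (lo + hi) / 2;
        const double *Xp = X; int dd = d;
        std::nth_element(idx.begin() + lo, idx.begin() + mid,
                         idx.begin() + hi, [Xp, dd, ax](int a, int b) {
                             return Xp[(size_t)a * dd + ax] <
                                    Xp[(size_t)b * dd + ax];
                         });
        int l = build(lo, mid), r = build(mid, hi);
        nodes[id].left = l; nodes[id].right = r;
        return id;
    }
};

static double box_ub(const Node &a, const Node &b, int d) {
    double s = 0;
    for (int k = 0; k < d; ++k) {
        double t = std::max(b.bmax[k] - a.bmin[k], a.bmax[k] - b.bmin[k]);
        if (t < 0) t = 0;
        s += t * t;
    }
    return s;
}

static void descend(Tree &T, int ia, int ib, double &best) {
    const Node &a = T.nodes[ia], &b = T.nodes[ib];
    if (box_ub(a, b, T.d) <= best) return;
    bool leaf_a = a.left < 0, leaf_b = b.left < 0;
    if (leaf_a && leaf_b) {
        for (int i = a.lo; i < a.hi; ++i) {
            int j0 = (ia == ib) ? i + 1 : b.lo;
            for (int j = j0; j < b.hi; ++j) {
                double s = 0;
                for (int k = 0; k < T.d; ++k) {
                    double t = T.coord(i, k) - T.coord(j, k);
                    s += t * t;
                }
                if (s > best) best = s;
            }
        }
        return;
    }
    if (ia == ib) {
        descend(T, a.left, a.left, best);
        descend(T, a.right, a.right, best);
        descend(T, a.left, a.right, best);
        return;
    }
    // split the node with the larger box extent
    double ea = 0, eb = 0;
    for (int k = 0; k < T.d; ++k) {
        ea += (a.bmax[k] - a.bmin[k]) * (a.bmax[k] - a.bmin[k]);
        eb += (b.bmax[k] - b.bmin[k]) * (b.bmax[k] - b.bmin[k]);
    }
    if (leaf_b || (!leaf_a && ea >= eb)) {
        int l = a.left, r = a.right;
        double ul = box_ub(T.nodes[l], b, T.d), ur = box_ub(T.nodes[r], b, T.d);
        if (ul >= ur) { descend(T, l, ib, best); descend(T, r, ib, best); }
        else { descend(T, r, ib, best); descend(T, l, ib, best); }
    } else {
        int l = b.left, r = b.right;
        double ul = box_ub(a, T.nodes[l], T.d), ur = box_ub(a, T.nodes[r], T.d);
        if (ul >= ur) { descend(T, ia, l, best); descend(T, ia, r, best); }
        else { descend(T, ia, r, best); descend(T, ia, l, best); }
    }
}

}  // namespace maxdist

// [[Rcpp::export]]
double max_pairwise_dist_cpp(NumericMatrix P) {
    const int n = P.nrow(), d = P.ncol();
    if (n < 2) return 0.0;
    // row-major copy for cache-friendly traversal
    std::vector<double> X((size_t)n * d);
    for (int i = 0; i < n; ++i)
        for (int k = 0; k < d; ++k) X[(size_t)i * d + k] = P(i, k);
    auto dist2 = [&](int i, int j) {
        double s = 0;
        for (int k = 0; k < d; ++k) {
            double t = X[(size_t)i * d + k] - X[(size_t)j * d + k];
            s += t * t;
        }
        return s;
    };
    // lower bound: iterated farthest point from a few starts
    double best = 0;
    int start = 0;
    for (int rep = 0; rep < 6; ++rep) {
        int far = start; double fd = -1;
        for (int i = 0; i < n; ++i) {
            double t = dist2(start, i);
            if (t > fd) { fd = t; far = i; }
        }
        if (fd > best) best = fd;
        start = far;
    }
    // tighten with extreme points over a direction grid (diameter endpoints
    // are extreme in the direction joining them)
    {
        const int M = (d == 3) ? 96 : 48;
        std::vector<int> cand;
        cand.reserve(2 * M);
        for (int m_i = 0; m_i < M; ++m_i) {
            double u[3] = {0, 0, 0};
            if (d == 3) {
                double z = 1.0 - 2.0 * (m_i + 0.5) / M;
                double r = std::sqrt(std::max(0.0, 1.0 - z * z));
                double ph = 2.39996322972865332 * m_i;  // golden angle
                u[0] = z; u[1] = r * std::cos(ph); u[2] = r * std::sin(ph);
            } else {
                double ph = M_PI * m_i / M;
                u[0] = std::cos(ph); u[1] = std::sin(ph);
            }
            int imax = 0, imin = 0;
            double vmax = R_NegInf, vmin = R_PosInf;
            for (int i = 0; i < n; ++i) {
                double t = 0;
                for (int k = 0; k < d; ++k) t += X[(size_t)i * d + k] * u[k];
                if (t > vmax) { vmax = t; imax = i; }
                if (t < vmin) { vmin = t; imin = i; }
            }
            cand.push_back(imax); cand.push_back(imin);
        }
        std::sort(cand.begin(), cand.end());
        cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
        for (size_t a = 0; a < cand.size(); ++a)
            for (size_t b = a + 1; b < cand.size(); ++b) {
                double t = dist2(cand[a], cand[b]);
                if (t > best) best = t;
            }
    }
    maxdist::Tree T;
    T.X = X.data(); T.d = d;
    T.idx.resize(n);
    for (int i = 0; i < n; ++i) T.idx[i] = i;
    T.nodes.reserve(2 * (n / 16 + 2));
    int root = T.build(0, n);
    maxdist::descend(T, root, root, best);
    return std::sqrt(best);
}

// watertight test: every directed edge occurs exactly once and its reverse
// exactly once (closed, consistently oriented 2-manifold)
// [[Rcpp::export]]
bool watertight_cpp(IntegerMatrix Fm, int nv) {
    const int nf = Fm.nrow();
    const uint64_t N = (uint64_t)nv + 1;
    std::vector<uint64_t> fwd, rev;
    fwd.reserve((size_t)nf * 3); rev.reserve((size_t)nf * 3);
    for (int i = 0; i < nf; ++i) {
        uint64_t a = Fm(i,0), b = Fm(i,1), c = Fm(i,2);
        if (a == b || b == c || a == c) return false;
        fwd.push_back(a * N + b); fwd.push_back(b * N + c); fwd.push_back(c * N + a);
        rev.push_back(b * N + a); rev.push_back(c * N + b); rev.push_back(a * N + c);
    }
    std::sort(fwd.begin(), fwd.end());
    for (size_t i = 1; i < fwd.size(); ++i)
        if (fwd[i] == fwd[i-1]) return false;   // duplicated directed edge
    std::sort(rev.begin(), rev.end());
    return fwd == rev;                          // every edge paired both ways
}
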