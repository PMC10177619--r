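#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Sublevel-set cubical persistence of a 2D grayscale image (V-construction:
// pixels are vertices, an edge/square takes the max of its vertices).
// H0 by elder-rule union-find over edges; H1 by Z/2 column reduction of the
// square boundary matrix. Ties broken by (value, dim, row-major anchor,
// horizontal-before-vertical) so output is deterministic.

namespace {

struct DSU {
  std::vector<int> parent;
  explicit DSU(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
};

// sort key for an edge: (value, anchor row-major index, orientation)
struct EdgeRec {
  int value;
  int anchor;   // r * W + c of the top/left endpoint
  int orient;   // 0 = horizontal, 1 = vertical
  int u, v;     // endpoint vertex ids
  bool operator<(const EdgeRec& o) const {
    if (value != o.value) return value < o.value;
    if (anchor != o.anchor) return anchor < o.anchor;
    return orient < o.orient;
  }
};

struct SquareRec {
  int value;
  int anchor;            // r * W + c of the top-left pixel
  int e[4];              // boundary edge positions (filled after edge sort)
  bool operator<(const SquareRec& o) const {
    if (value != o.value) return value < o.value;
    return anchor < o.anchor;
  }
};

}  // namespace

// [[Rcpp::export]]
DataFrame cubical_persistence_cpp(IntegerMatrix img, bool dim0, bool dim1) {
  const int H = img.nrow(), W = img.ncol(), V = H * W;

  std::vector<int> pix(V);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) pix[r * W + c] = img(r, c);

  // enumerate edges: horizontal (r,c)-(r,c+1), vertical (r,c)-(r+1,c)
  std::vector<EdgeRec> edges;
  edges.reserve(static_cast<size_t>(H) * (W - 1) + static_cast<size_t>(H - 1) * W);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      int id = r * W + c;
      if (c + 1 < W) {
        EdgeRec e{std::max(pix[id], pix[id + 1]), id, 0, id, id + 1};
        edges.push_back(e);
      }
      if (r + 1 < H) {
        EdgeRec e{std::max(pix[id], pix[id + W]), id, 1, id, id + W};
        edges.push_back(e);
      }
    }
  std::sort(edges.begin(), edges.end());
  const int E = static_cast<int>(edges.size());

  std::vector<int> out_dim;
  std::vector<double> out_birth, out_death;

  // ---- H0: elder rule ------------------------------------------------
  // vertex seniority rank: (value, row-major id)
  std::vector<int> vrank(V);
  {
    std::vector<int> ord(V);
    for (int i = 0; i < V; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      if (pix[a] != pix[b]) return pix[a] < pix[b];
      return a < b;
    });
    for (int i = 0; i < V; ++i) vrank[ord[i]] = i;
  }
  DSU dsu(V);
  // per-root: seniority rank of the component's oldest vertex
  std::vector<int> comp_rank(V);
  for (int i = 0; i < V; ++i) comp_rank[i] = vrank[i];

  // rank -> vertex value lookup (birth of a component = value of its oldest
  // vertex, identified by its seniority rank)
  std::vector<int> rank2val(V);
  for (int i = 0; i < V; ++i) rank2val[vrank[i]] = pix[i];

  for (int i = 0; i < E; ++i) {
    int ra = dsu.find(edges[i].u), rb = dsu.find(edges[i].v);
    if (ra == rb) continue;
    // younger component (larger seniority rank of oldest vertex) dies
    int elder = ra, young = rb;
    if (comp_rank[ra] > comp_rank[rb]) { elder = rb; young = ra; }
    if (dim0) {
      double b = rank2val[comp_rank[young]];
      double d = edges[i].value;
      if (d > b) {  // drop zero-persistence pairs
        out_dim.push_back(0);
        out_birth.push_back(b);
        out_death.push_back(d);
      }
    }
    dsu.parent[young] = elder;
    comp_rank[elder] = std::min(comp_rank[elder], comp_rank[young]);
  }

  if (dim0) {
    // essential classes: one per surviving component
    std::vector<char> seen(V, 0);
    for (int i = 0; i < V; ++i) {
      int r = dsu.find(i);
      if (!seen[r]) {
        seen[r] = 1;
        out_dim.push_back(0);
        out_birth.push_back(static_cast<double>(rank2val[comp_rank[r]]));
        out_death.push_back(R_PosInf);
      }
    }
  }

  // ---- H1: reduce the square boundary matrix over Z/2 ----------------
  if (dim1 && H > 1 && W > 1) {
    // edge (anchor, orient) -> sorted position
    // anchors fit in 32 bits; key = anchor * 2 + orient
    std::vector<int> edge_pos(static_cast<size_t>(V) * 2, -1);
    for (int i = 0; i < E; ++i)
      edge_pos[static_cast<size_t>(edges[i].anchor) * 2 + edges[i].orient] = i;

    std::vector<SquareRec> squares;
    squares.reserve(static_cast<size_t>(H - 1) * (W - 1));
    for (int r = 0; r + 1 < H; ++r)
      for (int c = 0; c + 1 < W; ++c) {
        int id = r * W + c;
        SquareRec s;
        s.anchor = id;
        s.value = std::max(std::max(pix[id], pix[id + 1]),
                           std::max(pix[id + W], pix[id + W + 1]));
        s.e[0] = edge_pos[static_cast<size_t>(id) * 2 + 0];            // top
        s.e[1] = edge_pos[static_cast<size_t>(id + W) * 2 + 0];        // bottom
        s.e[2] = edge_pos[static_cast<size_t>(id) * 2 + 1];            // left
        s.e[3] = edge_pos[static_cast<size_t>(id + 1) * 2 + 1];        // right
        squares.push_back(s);
      }
    std::sort(squares.begin(), squares.end());

    std::vector<int> low_owner(E, -1);                  // pivot edge -> column
    std::vector<std::vector<int>> cols(squares.size());  // reduced columns
    std::vector<int> tmp;
    for (size_t j = 0; j < squares.size(); ++j) {
      std::vector<int> col(squares[j].e, squares[j].e + 4);
      std::sort(col.begin(), col.end());
      while (!col.empty()) {
        int low = col.back();
        int owner = low_owner[low];
        if (owner < 0) {
          low_owner[low] = static_cast<int>(j);
          double b = edges[low].value, d = squares[j].value;
          if (d > b) {
            out_dim.push_back(1);
            out_birth.push_back(b);
            out_death.push_back(d);
          }
          break;
        }
        // col <- col XOR cols[owner] (both sorted)
        const std::vector<int>& oc = cols[owner];
        tmp.clear();
        std::set_symmetric_difference(col.begin(), col.end(), oc.begin(),
                                      oc.end(), std::back_inserter(tmp));
        col.swap(tmp);
      }
      cols[j].swap(col);
    }
    // a full rectangular grid is contractible: every 1-cycle dies, so no
    // essential H1 classes exist here by construction
  }

  return DataFrame::create(Named("dim") = out_dim, Named("birth") = out_birth,
                           Named("death") = out_death);
}
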