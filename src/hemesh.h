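#pragma once
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <limits>

// Shared halfedge representation of an oriented manifold triangle mesh.
// Halfedge h belongs to face h/3 at corner h%3 and runs from the corner
// vertex to the next one in the face's (counterclockwise) winding.
struct HEMesh {
  int nv = 0, nf = 0;
  std::vector<double> X, Y, Z;  // vertex coordinates (nm)
  std::vector<int> F;           // 3*nf vertex indices, 0-based
  std::vector<int> twin;        // per halfedge; -1 on boundary
  std::vector<double> elen;     // per halfedge length
  std::vector<std::vector<int>> vout;  // outgoing halfedges per vertex
  std::vector<char> vbnd;       // vertex touches a boundary edge
  std::vector<double> angsum;   // total incident face angle per vertex

  inline int from(int h) const { return F[3 * (h / 3) + h % 3]; }
  inline int to(int h) const { return F[3 * (h / 3) + (h % 3 + 1) % 3]; }
  inline int nxt(int h) const { return 3 * (h / 3) + (h % 3 + 1) % 3; }
  inline int prv(int h) const { return 3 * (h / 3) + (h % 3 + 2) % 3; }
  inline int apx(int h) const { return F[3 * (h / 3) + (h % 3 + 2) % 3]; }
};

void build_hemesh(const Rcpp::NumericMatrix& V, const Rcpp::IntegerMatrix& Fm,
                  HEMesh& M);
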