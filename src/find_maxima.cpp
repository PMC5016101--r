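// Noise-tolerant maxima detection with Find-Maxima semantics.
//
// A candidate plateau (connected set of equal-valued pixels none of which
// has a strictly higher 8-neighbour) with value v is accepted iff the
// connected component of {pixels with value >= v - tolerance} containing it
// holds no pixel with value > v. Accepted plateaus are reported as their
// rounded centroids, sorted by decreasing value.
//
// Acceptance is evaluated for all plateaus in one descending sweep with a
// union-find over progressively activated pixels; an exhaustive per-plateau
// flood gives the same answer and serves as the test oracle.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

static inline int find_root(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// [[Rcpp::export(name = ".fm_core")]]
DataFrame fm_core(NumericMatrix img, double tol) {
  const int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  const double *v = &img(0, 0); // column-major, index i = r + c * nr

  // 8-neighbour offsets as (dr, dc)
  const int ndr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int ndc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  // candidate pixels: no strictly higher 8-neighbour
  std::vector<char> cand(n, 0);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const int i = r + c * nr;
      bool ok = true;
      for (int k = 0; k < 8 && ok; ++k) {
        const int rr = r + ndr[k], cc = c + ndc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (v[rr + cc * nr] > v[i]) ok = false;
      }
      cand[i] = ok;
    }
  }

  // label candidate plateaus (adjacent candidates always share a value)
  std::vector<int> plat(n, -1);
  std::vector<double> pval;
  std::vector<double> psum_r, psum_c;
  std::vector<int> pcount, prep;
  std::vector<int> stack;
  for (int i0 = 0; i0 < n; ++i0) {
    if (!cand[i0] || plat[i0] >= 0) continue;
    const int id = (int)pval.size();
    pval.push_back(v[i0]);
    psum_r.push_back(0.0);
    psum_c.push_back(0.0);
    pcount.push_back(0);
    prep.push_back(i0);
    stack.clear();
    stack.push_back(i0);
    plat[i0] = id;
    while (!stack.empty()) {
      const int i = stack.back();
      stack.pop_back();
      const int r = i % nr, c = i / nr;
      psum_r[id] += r;
      psum_c[id] += c;
      pcount[id] += 1;
      for (int k = 0; k < 8; ++k) {
        const int rr = r + ndr[k], cc = c + ndc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const int j = rr + cc * nr;
        if (cand[j] && plat[j] < 0 && v[j] == v[i]) {
          plat[j] = id;
          stack.push_back(j);
        }
      }
    }
  }
  const int np = (int)pval.size();

  // pixels sorted by decreasing value (ties by index for determinism)
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (v[a] != v[b]) return v[a] > v[b];
    return a < b;
  });
  // plateaus sorted by decreasing value
  std::vector<int> porder(np);
  for (int i = 0; i < np; ++i) porder[i] = i;
  std::sort(porder.begin(), porder.end(), [&](int a, int b) {
    if (pval[a] != pval[b]) return pval[a] > pval[b];
    return prep[a] < prep[b];
  });

  // descending sweep: activate pixels with value >= v_plateau - tol, then
  // test whether the plateau's component contains anything higher
  std::vector<int> parent(n, -1);
  std::vector<double> comp_max(n, 0.0);
  std::vector<char> accepted(np, 0);
  int next_pix = 0;
  for (int q = 0; q < np; ++q) {
    const int id = porder[q];
    const double thr = pval[id] - tol;
    while (next_pix < n && v[order[next_pix]] >= thr) {
      const int i = order[next_pix];
      ++next_pix;
      parent[i] = i;
      comp_max[i] = v[i];
      const int r = i % nr, c = i / nr;
      for (int k = 0; k < 8; ++k) {
        const int rr = r + ndr[k], cc = c + ndc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const int j = rr + cc * nr;
        if (parent[j] < 0) continue;
        const int ri = find_root(parent, i), rj = find_root(parent, j);
        if (ri != rj) {
          parent[rj] = ri;
          comp_max[ri] = std::max(comp_max[ri], comp_max[rj]);
        }
      }
    }
    const int root = find_root(parent, prep[id]);
    accepted[id] = !(comp_max[root] > pval[id]);
  }

  // output accepted plateau centroids, sorted by value desc, row, col
  std::vector<int> keep;
  for (int id = 0; id < np; ++id)
    if (accepted[id]) keep.push_back(id);
  std::vector<int> out_r(keep.size()), out_c(keep.size());
  std::vector<double> out_v(keep.size());
  for (size_t k = 0; k < keep.size(); ++k) {
    const int id = keep[k];
    out_r[k] = (int)std::floor(psum_r[id] / pcount[id] + 0.5) + 1; // 1-based
    out_c[k] = (int)std::floor(psum_c[id] / pcount[id] + 0.5) + 1;
    out_v[k] = pval[id];
  }
  std::vector<int> oo(keep.size());
  for (size_t k = 0; k < oo.size(); ++k) oo[k] = (int)k;
  std::sort(oo.begin(), oo.end(), [&](int a, int b) {
    if (out_v[a] != out_v[b]) return out_v[a] > out_v[b];
    if (out_r[a] != out_r[b]) return out_r[a] < out_r[b];
    return out_c[a] < out_c[b];
  });
  IntegerVector rr((int)oo.size()), cc((int)oo.size());
  NumericVector vv((int)oo.size());
  for (size_t k = 0; k < oo.size(); ++k) {
    rr[k] = out_r[oo[k]];
    cc[k] = out_c[oo[k]];
    vv[k] = out_v[oo[k]];
  }
  return DataFrame::create(_["row"] = rr, _["col"] = cc, _["value"] = vv);
}
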