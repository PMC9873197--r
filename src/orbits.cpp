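#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Per-node graphlet orbit counts (orbits 0-14, graphlets up to 4 nodes) on an
// unweighted undirected simple graph.  Every sorted triple {i<j<k} is visited
// once; it contributes the 3-node orbits directly and spawns the sorted
// quadruples {i<j<k<l} through candidate nodes l>k taken from the union of
// the triple's neighborhoods (or their intersection when the triple spans no
// edge, since the fourth node must then connect all three).  Each connected
// induced 4-set is classified by its edge count and degree sequence; for
// graphlets on at most 4 nodes the within-subset degree identifies the orbit
// uniquely within each isomorphism class.

static inline bool testbit(const std::vector<uint64_t> &bs, int i) {
  return (bs[i >> 6] >> (i & 63)) & 1ull;
}

// [[Rcpp::export]]
IntegerMatrix orbit_counts_cpp(IntegerMatrix adj) {
  const int n = adj.nrow();
  const int words = (n + 63) / 64;
  std::vector<std::vector<uint64_t>> nb(n, std::vector<uint64_t>(words, 0));
  std::vector<int> deg(n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && adj(i, j) != 0) {
        nb[i][j >> 6] |= 1ull << (j & 63);
        ++deg[i];
      }
  IntegerMatrix orb(n, 15);
  // orbit 0: degree
  for (int i = 0; i < n; ++i) orb(i, 0) = deg[i];

  std::vector<uint64_t> cand(words);
  for (int i = 0; i < n - 2; ++i) {
    for (int j = i + 1; j < n - 1; ++j) {
      const bool eij = testbit(nb[i], j);
      for (int k = j + 1; k < n; ++k) {
        const bool eik = testbit(nb[i], k);
        const bool ejk = testbit(nb[j], k);
        const int e3 = eij + eik + ejk;
        // 3-node orbits
        if (e3 == 3) {
          ++orb(i, 3); ++orb(j, 3); ++orb(k, 3);
        } else if (e3 == 2) {
          // middle node (incident to both edges) has orbit 2, ends orbit 1
          if (eij && eik) { ++orb(i, 2); ++orb(j, 1); ++orb(k, 1); }
          else if (eij && ejk) { ++orb(j, 2); ++orb(i, 1); ++orb(k, 1); }
          else { ++orb(k, 2); ++orb(i, 1); ++orb(j, 1); }
        }
        // 4-node orbits via candidates l > k
        if (e3 == 0) {
          for (int w = k >> 6; w < words; ++w)
            cand[w] = nb[i][w] & nb[j][w] & nb[k][w];
        } else {
          for (int w = k >> 6; w < words; ++w)
            cand[w] = nb[i][w] | nb[j][w] | nb[k][w];
        }
        for (int w = k >> 6; w < words; ++w) {
          uint64_t bits = cand[w];
          if (w == (k >> 6)) {
            const int b = k & 63;
            const uint64_t mask = (b == 63) ? ~0ull : ((1ull << (b + 1)) - 1ull);
            bits &= ~mask; // only candidates l > k
          }
          while (bits) {
            const int l = (w << 6) + __builtin_ctzll(bits);
            bits &= bits - 1;
            const bool eil = testbit(nb[i], l);
            const bool ejl = testbit(nb[j], l);
            const bool ekl = testbit(nb[k], l);
            const int e4 = e3 + eil + ejl + ekl;
            if (e4 < 3) continue;
            const int di = eij + eik + eil;
            const int dj = eij + ejk + ejl;
            const int dk = eik + ejk + ekl;
            const int dl = eil + ejl + ekl;
            if (di == 0 || dj == 0 || dk == 0 || dl == 0) continue; // disconnected
            const int node[4] = {i, j, k, l};
            const int d[4] = {di, dj, dk, dl};
            if (e4 == 3) {
              int mx = std::max(std::max(di, dj), std::max(dk, dl));
              if (mx == 3) { // star: center orbit 7, leaves orbit 6
                for (int t = 0; t < 4; ++t) orb(node[t], d[t] == 3 ? 7 : 6) += 1;
              } else {       // path: ends orbit 4, middle orbit 5
                for (int t = 0; t < 4; ++t) orb(node[t], d[t] == 1 ? 4 : 5) += 1;
              }
            } else if (e4 == 4) {
              int mx = std::max(std::max(di, dj), std::max(dk, dl));
              if (mx == 3) { // paw: pendant 9, triangle side 10, apex 11
                for (int t = 0; t < 4; ++t)
                  orb(node[t], d[t] == 1 ? 9 : (d[t] == 2 ? 10 : 11)) += 1;
              } else {       // 4-cycle
                for (int t = 0; t < 4; ++t) orb(node[t], 8) += 1;
              }
            } else if (e4 == 5) { // diamond: degree-2 orbit 12, degree-3 orbit 13
              for (int t = 0; t < 4; ++t) orb(node[t], d[t] == 2 ? 12 : 13) += 1;
            } else {              // K4
              for (int t = 0; t < 4; ++t) orb(node[t], 14) += 1;
            }
          }
        }
      }
    }
  }
  return orb;
}

// Lasso with correlation-matrix input, solved by cyclic coordinate descent
// with warm starts along a decreasing penalty path:
//   min_beta 0.5 beta' S11 beta - s12' beta + lambda ||beta||_1
// where S11 = Sigma[-j, -j] (unit diagonal) and s12 = Sigma[-j, j].
// Returns a (p-1) x nlambda coefficient matrix.

// [[Rcpp::export]]
NumericMatrix lasso_cov_path_cpp(NumericMatrix S11, NumericVector s12,
                                 NumericVector lambdas, double tol = 1e-5,
                                 int max_iter = 200) {
  const int p = s12.size();
  const int nl = lambdas.size();
  NumericMatrix out(p, nl);
  std::vector<double> beta(p, 0.0), grad(p);
  for (int m = 0; m < p; ++m) grad[m] = s12[m];
  for (int li = 0; li < nl; ++li) {
    const double lam = lambdas[li];
    for (int it = 0; it < max_iter; ++it) {
      double maxdiff = 0.0;
      for (int m = 0; m < p; ++m) {
        // grad[m] holds s12[m] - sum_{q != m} S11(m,q) beta[q]
        double z = grad[m];
        double bnew = 0.0;
        if (z > lam) bnew = z - lam;
        else if (z < -lam) bnew = z + lam;
        const double diff = bnew - beta[m];
        if (diff != 0.0) {
          for (int q = 0; q < p; ++q)
            if (q != m) grad[q] -= S11(q, m) * diff;
          beta[m] = bnew;
          if (std::abs(diff) > maxdiff) maxdiff = std::abs(diff);
        }
      }
      if (maxdiff < tol) break;
    }
    for (int m = 0; m < p; ++m) out(m, li) = beta[m];
  }
  return out;
}
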