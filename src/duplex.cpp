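#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Intermolecular duplex dynamic program (no intramolecular structure).
//
// The target x (5'->3') is aligned against the reversed miRNA z (so both
// indices increase along the duplex; the miRNA itself runs 3'->5' across the
// target). Pairs must be non-crossing and monotone in both indices. Energy =
// duplex initiation + nearest-neighbor stack terms for adjacent pairs +
// size-dependent bulge/interior-loop penalties for gapped extensions (no
// stacking bonus across a loop). Gap sizes are capped at max_loop per strand.

static const double INF = std::numeric_limits<double>::infinity();

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'U': return 3;
    default: return -1;  // N and anything else never pairs
  }
}

// Pair types: AU=0, UA=1, GC=2, CG=3, GU=4, UG=5 (target base first), -1 none.
static inline int pair_type(int a, int b) {
  if (a < 0 || b < 0) return -1;
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 1 && b == 2) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

static inline double gap_penalty(int gi, int gk, const NumericVector& bulge,
                                 const NumericVector& interior) {
  if (gi == 0 && gk == 0) return 0.0;  // stack handled by caller
  if (gi == 0 || gk == 0) {
    int g = gi + gk;
    int idx = std::min<int>(g, bulge.size()) - 1;
    return bulge[idx];
  }
  int g = gi + gk;  // total interior loop size (minimum 2)
  int idx = std::min<int>(g - 1, (int)interior.size()) - 1;
  return interior[idx];
}

// [[Rcpp::export(name = ".duplex_dp")]]
List duplex_dp(std::string target, std::string mirna_rev, NumericMatrix stack,
               NumericVector bulge, NumericVector interior, double init,
               int max_loop) {
  const int n = target.size(), m = mirna_rev.size();
  std::vector<int> x(n), z(m);
  for (int i = 0; i < n; ++i) x[i] = base_code(target[i]);
  for (int k = 0; k < m; ++k) z[k] = base_code(mirna_rev[k]);

  // 1-based DP tables
  std::vector<double> E((n + 1) * (m + 1), INF);
  std::vector<int> bpi((n + 1) * (m + 1), 0), bpk((n + 1) * (m + 1), 0);
  std::vector<int> st((n + 1) * (m + 1), 0), np((n + 1) * (m + 1), 0);
  std::vector<int> pt((n + 1) * (m + 1), -1);
  const double eps = 1e-9;
  auto at = [m](int i, int k) { return i * (m + 1) + k; };

  int best_i = 0, best_k = 0;
  double best_e = INF;

  for (int i = 1; i <= n; ++i) {
    for (int k = 1; k <= m; ++k) {
      int p = pair_type(x[i - 1], z[k - 1]);
      pt[at(i, k)] = p;
      if (p < 0) continue;
      // open a new duplex at this pair
      double e = init;
      int bi = 0, bk = 0, s0 = i, n0 = 1;
      // extend from an earlier pair
      int gi_max = std::min(max_loop, i - 1);
      int gk_max = std::min(max_loop, k - 1);
      for (int gi = 0; gi <= gi_max; ++gi) {
        int ip = i - 1 - gi;
        if (ip < 1) break;
        for (int gk = 0; gk <= gk_max; ++gk) {
          int kp = k - 1 - gk;
          if (kp < 1) break;
          double prev = E[at(ip, kp)];
          if (prev == INF) continue;
          double add;
          if (gi == 0 && gk == 0) {
            add = stack(pt[at(ip, kp)], p);
          } else {
            add = gap_penalty(gi, gk, bulge, interior);
          }
          double cand = prev + add;
          int cs = st[at(ip, kp)], cn = np[at(ip, kp)] + 1;
          bool better = cand < e - eps ||
            (cand < e + eps && (cs < s0 || (cs == s0 && cn > n0)));
          if (better) {
            e = cand; bi = ip; bk = kp; s0 = cs; n0 = cn;
          }
        }
      }
      E[at(i, k)] = e;
      bpi[at(i, k)] = bi; bpk[at(i, k)] = bk;
      st[at(i, k)] = s0; np[at(i, k)] = n0;
      bool better = e < best_e - eps ||
        (e < best_e + eps && best_e != INF &&
         (s0 < st[at(best_i, best_k)] ||
          (s0 == st[at(best_i, best_k)] && n0 > np[at(best_i, best_k)])));
      if (best_e == INF ? e < INF : better) {
        best_e = e; best_i = i; best_k = k;
      }
    }
  }

  if (best_e == INF) {
    return List::create(_["found"] = false, _["mfe"] = NA_REAL,
                        _["pairs"] = IntegerMatrix(0, 2));
  }
  // trace back
  std::vector<int> pi, pk;
  int ci = best_i, ck = best_k;
  while (ci != 0) {
    pi.push_back(ci); pk.push_back(ck);
    int ni = bpi[at(ci, ck)], nk = bpk[at(ci, ck)];
    ci = ni; ck = nk;
  }
  int K = pi.size();
  IntegerMatrix pairs(K, 2);
  for (int r = 0; r < K; ++r) {  // report 5'->3' on the target
    pairs(r, 0) = pi[K - 1 - r];
    pairs(r, 1) = pk[K - 1 - r];
  }
  return List::create(_["found"] = true, _["mfe"] = best_e,
                      _["pairs"] = pairs);
}
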