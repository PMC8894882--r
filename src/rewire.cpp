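#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Degree-preserving double-edge swaps on a bipartite edge list.
// Edge ends are 1-based integer ids; patients and diseases live in separate
// id spaces. A proposed swap of edges (A-X, B-Y) to (A-Y, B-X) is rejected
// when A == B, X == Y, or either replacement edge already exists; rejected
// proposals are retried until n_swaps swaps are accepted or max_tries
// proposals have been made. Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
List rewire_edges_cpp(IntegerVector patient, IntegerVector disease,
                      double n_swaps, double max_tries) {
  int m = patient.size();
  std::vector<int> p(patient.begin(), patient.end());
  std::vector<int> d(disease.begin(), disease.end());
  std::unordered_set<long long> edges;
  const long long K = 4000000LL;
  edges.reserve(m * 2);
  for (int i = 0; i < m; ++i) edges.insert((long long)p[i] * K + d[i]);
  double accepted = 0, tries = 0;
  while (accepted < n_swaps && tries < max_tries) {
    tries += 1;
    int i = (int)(unif_rand() * m); if (i == m) i = m - 1;
    int j = (int)(unif_rand() * m); if (j == m) j = m - 1;
    if (i == j) continue;
    if (p[i] == p[j] || d[i] == d[j]) continue;
    long long k1 = (long long)p[i] * K + d[j];
    long long k2 = (long long)p[j] * K + d[i];
    if (edges.count(k1) || edges.count(k2)) continue;
    edges.erase((long long)p[i] * K + d[i]);
    edges.erase((long long)p[j] * K + d[j]);
    int tmp = d[i]; d[i] = d[j]; d[j] = tmp;
    edges.insert(k1);
    edges.insert(k2);
    accepted += 1;
  }
  return List::create(_["patient"] = IntegerVector(p.begin(), p.end()),
                      _["disease"] = IntegerVector(d.begin(), d.end()),
                      _["accepted"] = accepted,
                      _["tries"] = tries);
}
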