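#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Contact-constrained double-edge-swap Markov chain over two edge pools.
// Chemical (directed) swap: (a->b, c->d) => (a->d, c->b), preserving every
// node's in- and out-degree. Electrical (undirected) swap: pick one of the
// two re-pairings of {a,b},{c,d} at random, preserving degrees. Proposals
// creating a self-loop, a duplicate edge, or an edge between neurons that are
// not contact-adjacent are rejected. Uses R's RNG: seed from R for
// reproducibility. Node indices are 0-based.

static inline long long pkey(int a, int b, int V) {
  return (long long)a * V + b;
}

// [[Rcpp::export]]
List rewire_edges_cpp(IntegerMatrix chem, IntegerMatrix elec,
                      LogicalMatrix contact, int attempts) {
  const int V = contact.nrow();
  const int nc = chem.nrow(), ne = elec.nrow();
  std::vector<int> cpre(nc), cpost(nc), ea(ne), eb(ne);
  std::unordered_set<long long> cset, eset;
  for (int i = 0; i < nc; ++i) {
    cpre[i] = chem(i, 0); cpost[i] = chem(i, 1);
    cset.insert(pkey(cpre[i], cpost[i], V));
  }
  for (int i = 0; i < ne; ++i) {
    int a = elec(i, 0), b = elec(i, 1);
    if (a > b) std::swap(a, b);
    ea[i] = a; eb[i] = b;
    eset.insert(pkey(a, b, V));
  }
  int acc_chem = 0, acc_elec = 0;
  const int total = nc + ne;
  if (total == 0) attempts = 0;
  for (int t = 0; t < attempts; ++t) {
    const bool chem_move = (unif_rand() * total) < nc;
    if (chem_move) {
      if (nc < 2) continue;
      int i = (int)(unif_rand() * nc), j = (int)(unif_rand() * nc);
      if (i >= nc) i = nc - 1;
      if (j >= nc) j = nc - 1;
      if (i == j) continue;
      const int a = cpre[i], b = cpost[i], c = cpre[j], d = cpost[j];
      if (a == c || b == d) continue;        // no-op swap
      if (a == d || c == b) continue;        // would create self-loop
      if (!contact(a, d) || !contact(c, b)) continue;
      const long long k1 = pkey(a, d, V), k2 = pkey(c, b, V);
      if (cset.count(k1) || cset.count(k2)) continue;  // duplicate
      cset.erase(pkey(a, b, V)); cset.erase(pkey(c, d, V));
      cset.insert(k1); cset.insert(k2);
      cpost[i] = d; cpost[j] = b;
      ++acc_chem;
    } else {
      if (ne < 2) continue;
      int i = (int)(unif_rand() * ne), j = (int)(unif_rand() * ne);
      if (i >= ne) i = ne - 1;
      if (j >= ne) j = ne - 1;
      if (i == j) continue;
      const int a = ea[i], b = eb[i], c = ea[j], d = eb[j];
      if (a == c || a == d || b == c || b == d) continue;  // need 4 nodes
      int x1, y1, x2, y2;
      if (unif_rand() < 0.5) { x1 = a; y1 = d; x2 = c; y2 = b; }
      else                   { x1 = a; y1 = c; x2 = b; y2 = d; }
      if (x1 > y1) std::swap(x1, y1);
      if (x2 > y2) std::swap(x2, y2);
      if (!contact(x1, y1) || !contact(x2, y2)) continue;
      const long long k1 = pkey(x1, y1, V), k2 = pkey(x2, y2, V);
      if (eset.count(k1) || eset.count(k2)) continue;
      eset.erase(pkey(a, b, V)); eset.erase(pkey(c, d, V));
      eset.insert(k1); eset.insert(k2);
      ea[i] = x1; eb[i] = y1; ea[j] = x2; eb[j] = y2;
      ++acc_elec;
    }
  }
  IntegerMatrix chem_out(nc, 2), elec_out(ne, 2);
  for (int i = 0; i < nc; ++i) { chem_out(i, 0) = cpre[i]; chem_out(i, 1) = cpost[i]; }
  for (int i = 0; i < ne; ++i) { elec_out(i, 0) = ea[i]; elec_out(i, 1) = eb[i]; }
  return List::create(_["chemical"] = chem_out, _["electrical"] = elec_out,
                      _["accepted_chemical"] = acc_chem,
                      _["accepted_electrical"] = acc_elec);
}
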