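#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find over pair-groups with an orientation (flip) bit per node
// relative to its parent. find() returns the root and accumulates the
// parity from the node to the root, with path compression.
static int uf_find(int x, std::vector<int> &par, std::vector<unsigned char> &fl,
                   int &parity) {
  int root = x, p = 0;
  while (par[root] != root) { p ^= fl[root]; root = par[root]; }
  // compress
  int cur = x, cp = p;
  while (par[cur] != root) {
    int nxt = par[cur];
    int nf = fl[cur];
    par[cur] = root;
    fl[cur] = (unsigned char) cp;
    cp ^= nf;
    cur = nxt;
  }
  parity = p;
  return root;
}

// Weighted-permutation contraction heuristic for the minimum multiple
// s-t cut problem. Vertices are pair-groups (one per haplotype block,
// infinite-weight intra-block edges already pre-merged). Each edge e
// joins groups eu[e], ev[e] (1-based) and carries the total weight
// supporting the aligned orientation (w_al = w_aa + w_bb) and the
// crossed one (w_cr = w_ab + w_ba). For each of the M permutations the
// edges are contracted in order; a contraction merges the two current
// groups in the orientation with the larger total inter-group supporting
// weight (ties broken by the supplied uniforms); edges internal to one
// group are skipped. The minimum-cut run wins.
// [[Rcpp::export]]
List karger_contract(int n_groups, IntegerVector eu, IntegerVector ev,
                     NumericVector w_al, NumericVector w_cr,
                     IntegerMatrix perms, NumericMatrix ties) {
  const int E = eu.size();
  const int M = perms.nrow();
  double best_cut = R_PosInf;
  std::vector<int> best_par;
  std::vector<unsigned char> best_fl;

  std::vector<int> par(n_groups);
  std::vector<int> grp_size(n_groups);
  std::vector<unsigned char> fl(n_groups);
  std::vector<std::vector<int> > elist(n_groups);

  for (int m = 0; m < M; ++m) {
    for (int i = 0; i < n_groups; ++i) {
      par[i] = i; grp_size[i] = 1; fl[i] = 0; elist[i].clear();
    }
    for (int e = 0; e < E; ++e) {
      elist[eu[e] - 1].push_back(e);
      elist[ev[e] - 1].push_back(e);
    }
    for (int t = 0; t < E; ++t) {
      int e = perms(m, t) - 1;
      int pu, pv;
      int ru = uf_find(eu[e] - 1, par, fl, pu);
      int rv = uf_find(ev[e] - 1, par, fl, pv);
      if (ru == rv) continue;  // already decided; skip conflicting merge
      int a = ru, b = rv;      // iterate the smaller group's edge list
      if (elist[a].size() < elist[b].size()) std::swap(a, b);
      double s_al = 0.0, s_cr = 0.0;
      std::vector<int> transfer;
      for (size_t k = 0; k < elist[b].size(); ++k) {
        int f = elist[b][k];
        int pf1, pf2;
        int r1 = uf_find(eu[f] - 1, par, fl, pf1);
        int r2 = uf_find(ev[f] - 1, par, fl, pf2);
        if (r1 == r2) continue;               // internal, stale
        int other = (r1 == b) ? r2 : r1;
        if (other == a) {
          int rel = pf1 ^ pf2;                // relative parity across frames
          if (rel == 0) { s_al += w_al[f]; s_cr += w_cr[f]; }
          else          { s_al += w_cr[f]; s_cr += w_al[f]; }
        } else {
          transfer.push_back(f);
        }
      }
      int r;  // orientation of b's frame relative to a's
      if (s_al > s_cr) r = 0;
      else if (s_cr > s_al) r = 1;
      else r = (ties(m, t) < 0.5) ? 0 : 1;
      par[b] = a;
      fl[b] = (unsigned char) r;
      grp_size[a] += grp_size[b];
      for (size_t k = 0; k < transfer.size(); ++k) elist[a].push_back(transfer[k]);
      elist[b].clear();
    }
    // cut weight of this run
    double cut = 0.0;
    for (int e = 0; e < E; ++e) {
      int pu, pv;
      uf_find(eu[e] - 1, par, fl, pu);
      uf_find(ev[e] - 1, par, fl, pv);
      cut += ((pu ^ pv) == 0) ? w_cr[e] : w_al[e];
    }
    if (cut < best_cut) {
      best_cut = cut;
      best_par = par;
      best_fl = fl;
    }
  }

  IntegerVector comp(n_groups), flip(n_groups);
  if (best_par.empty()) {  // no edges or M computed nothing: identity
    for (int i = 0; i < n_groups; ++i) { comp[i] = i + 1; flip[i] = 0; }
    best_cut = 0.0;
  } else {
    for (int i = 0; i < n_groups; ++i) {
      int p;
      int r = uf_find(i, best_par, best_fl, p);
      comp[i] = r + 1;
      flip[i] = p;
    }
  }
  return List::create(_["component"] = comp, _["flip"] = flip,
                      _["cut_weight"] = best_cut);
}
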