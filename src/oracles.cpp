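// Exhaustive search oracles for rearrangement analysis, used to validate the
// closed-form DCJ distance and the heuristic genome median on small inputs.
//
// Genomes are passed as lists of signed integer vectors (one per chromosome)
// over blocks 1..N. Internally a genome is its extremity partner array:
// extremities are tail = 2b-1, head = 2b (0-indexed: 2b-2, 2b-1);
// partner[e] = adjacent extremity, or -1 for a telomere. This encoding is
// orientation- and chromosome-order-invariant and represents circular
// intermediates, which DCJ sorting may create.

#include <Rcpp.h>
#include <unordered_map>
#include <queue>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

typedef std::vector<int> Partner;

static int ext_left(int x)  { return x > 0 ? 2 * x - 2 : 2 * (-x) - 1; }
static int ext_right(int x) { return x > 0 ? 2 * x - 1 : 2 * (-x) - 2; }

static Partner genome_to_partner(const List& genome, int n_blocks) {
  Partner p(2 * n_blocks, -1);
  for (int c = 0; c < genome.size(); ++c) {
    IntegerVector v = genome[c];
    for (int k = 0; k + 1 < v.size(); ++k) {
      int a = ext_right(v[k]), b = ext_left(v[k + 1]);
      p[a] = b; p[b] = a;
    }
  }
  return p;
}

static std::string encode(const Partner& p) {
  std::string s(p.size(), 0);
  for (size_t i = 0; i < p.size(); ++i) s[i] = (char)(p[i] + 1);
  return s;
}

// DCJ distance: components of the two-partner union over extremities;
// a component is a cycle when every vertex carries both edges, otherwise a
// path, odd when its vertex count is odd. d = N - cycles - odd_paths / 2.
static int dcj_formula(const Partner& a, const Partner& b) {
  int n2 = (int)a.size();
  std::vector<char> seen(n2, 0);
  int cycles = 0, odd = 0;
  // paths first: start from vertices missing an edge
  for (int s = 0; s < n2; ++s) {
    if (seen[s] || (a[s] != -1 && b[s] != -1)) continue;
    seen[s] = 1;
    if (a[s] == -1 && b[s] == -1) { odd++; continue; }  // one-vertex path
    int use_a = (a[s] != -1) ? 1 : 0;
    int cur = s, nv = 1;
    while (true) {
      int nxt = use_a ? a[cur] : b[cur];
      if (nxt == -1) break;
      cur = nxt; seen[cur] = 1; nv++;
      use_a = 1 - use_a;
    }
    if (nv % 2 == 1) odd++;
  }
  // remaining vertices lie on cycles
  for (int s = 0; s < n2; ++s) {
    if (seen[s]) continue;
    cycles++;
    int cur = s, use_a = 1;
    while (!seen[cur]) {
      seen[cur] = 1;
      cur = use_a ? a[cur] : b[cur];
      use_a = 1 - use_a;
    }
  }
  return n2 / 2 - cycles - odd / 2;
}

// [[Rcpp::export(name = ".dcj_formula_cpp")]]
int dcj_formula_cpp(List a, List b, int n_blocks) {
  Partner pa = genome_to_partner(a, n_blocks);
  Partner pb = genome_to_partner(b, n_blocks);
  return dcj_formula(pa, pb);
}

// total DCJ distance from one candidate genome to a set of genomes
// [[Rcpp::export(name = ".dcj_total_cpp")]]
int dcj_total_cpp(List cand, List genomes, int n_blocks) {
  Partner pc = genome_to_partner(cand, n_blocks);
  int tot = 0;
  for (int g = 0; g < genomes.size(); ++g)
    tot += dcj_formula(pc, genome_to_partner(genomes[g], n_blocks));
  return tot;
}

static void neighbors(const Partner& p, std::vector<Partner>& out) {
  out.clear();
  int n2 = (int)p.size();
  std::vector<std::pair<int,int> > adj;
  std::vector<int> tel;
  for (int e = 0; e < n2; ++e) {
    if (p[e] == -1) tel.push_back(e);
    else if (e < p[e]) adj.push_back(std::make_pair(e, p[e]));
  }
  Partner q;
  // two adjacencies -> two rewirings
  for (size_t i = 0; i < adj.size(); ++i)
    for (size_t j = i + 1; j < adj.size(); ++j) {
      int pq[2] = { adj[i].first, adj[i].second };
      int rs[2] = { adj[j].first, adj[j].second };
      // {p,r},{q,s}
      q = p;
      q[pq[0]] = rs[0]; q[rs[0]] = pq[0];
      q[pq[1]] = rs[1]; q[rs[1]] = pq[1];
      out.push_back(q);
      // {p,s},{q,r}
      q = p;
      q[pq[0]] = rs[1]; q[rs[1]] = pq[0];
      q[pq[1]] = rs[0]; q[rs[0]] = pq[1];
      out.push_back(q);
    }
  // adjacency + telomere
  for (size_t i = 0; i < adj.size(); ++i)
    for (size_t t = 0; t < tel.size(); ++t) {
      int pp = adj[i].first, qq = adj[i].second, r = tel[t];
      q = p; q[pp] = r; q[r] = pp; q[qq] = -1; out.push_back(q);
      q = p; q[qq] = r; q[r] = qq; q[pp] = -1; out.push_back(q);
    }
  // two telomeres -> join
  for (size_t i = 0; i < tel.size(); ++i)
    for (size_t j = i + 1; j < tel.size(); ++j) {
      q = p; q[tel[i]] = tel[j]; q[tel[j]] = tel[i]; out.push_back(q);
    }
  // split one adjacency
  for (size_t i = 0; i < adj.size(); ++i) {
    q = p; q[adj[i].first] = -1; q[adj[i].second] = -1; out.push_back(q);
  }
}

// Breadth-first search over DCJ moves from genome `a`, reporting the minimum
// number of operations to reach each genome in `bs`.
// [[Rcpp::export(name = ".dcj_bfs_cpp")]]
IntegerVector dcj_bfs_cpp(List a, List bs, int n_blocks, int max_states) {
  Partner start = genome_to_partner(a, n_blocks);
  std::unordered_map<std::string, int> dist;
  std::vector<std::string> targets;
  IntegerVector res(bs.size(), -1);
  for (int i = 0; i < bs.size(); ++i)
    targets.push_back(encode(genome_to_partner(bs[i], n_blocks)));
  int remaining = (int)targets.size();
  std::queue<Partner> q;
  dist[encode(start)] = 0;
  q.push(start);
  for (int i = 0; i < (int)targets.size(); ++i)
    if (targets[i] == encode(start)) { res[i] = 0; remaining--; }
  std::vector<Partner> nb;
  while (!q.empty() && remaining > 0) {
    Partner cur = q.front(); q.pop();
    int d = dist[encode(cur)];
    neighbors(cur, nb);
    for (size_t k = 0; k < nb.size(); ++k) {
      std::string key = encode(nb[k]);
      if (dist.count(key)) continue;
      if ((int)dist.size() >= max_states)
        stop("state budget exceeded in DCJ BFS");
      dist[key] = d + 1;
      for (int i = 0; i < (int)targets.size(); ++i)
        if (res[i] == -1 && targets[i] == key) { res[i] = d + 1; remaining--; }
      q.push(nb[k]);
    }
  }
  return res;
}

// Exhaustive genome-median search: enumerate every linear multichromosomal
// arrangement of blocks 1..n (signed permutation + chromosome cuts) and
// return the minimum total DCJ distance to the input genomes.
// [[Rcpp::export(name = ".median_brute_force_cpp")]]
List median_brute_force_cpp(List genomes, int n_blocks) {
  std::vector<Partner> inputs;
  for (int i = 0; i < genomes.size(); ++i)
    inputs.push_back(genome_to_partner(genomes[i], n_blocks));
  std::vector<int> perm(n_blocks);
  for (int i = 0; i < n_blocks; ++i) perm[i] = i + 1;
  int best = INT_MAX;
  std::vector<int> best_signed;
  unsigned best_cuts = 0;
  std::sort(perm.begin(), perm.end());
  do {
    for (unsigned signs = 0; signs < (1u << n_blocks); ++signs) {
      std::vector<int> sp(n_blocks);
      for (int i = 0; i < n_blocks; ++i)
        sp[i] = (signs >> i) & 1 ? -perm[i] : perm[i];
      for (unsigned cuts = 0; cuts < (1u << (n_blocks - 1)); ++cuts) {
        // build partner array directly from the cut pattern
        Partner cand(2 * n_blocks, -1);
        for (int k = 0; k + 1 < n_blocks; ++k) {
          if ((cuts >> k) & 1) continue; // chromosome boundary after k
          int x = ext_right(sp[k]), y = ext_left(sp[k + 1]);
          cand[x] = y; cand[y] = x;
        }
        int tot = 0;
        for (size_t g = 0; g < inputs.size() && tot < best; ++g)
          tot += dcj_formula(cand, inputs[g]);
        if (tot < best) {
          best = tot;
          best_signed = sp;
          best_cuts = cuts;
        }
      }
    }
  } while (std::next_permutation(perm.begin(), perm.end()));
  // decode one optimal arrangement into chromosomes
  List chroms;
  std::vector<int> cur;
  for (int k = 0; k < n_blocks; ++k) {
    cur.push_back(best_signed[k]);
    bool cut = (k == n_blocks - 1) || ((best_cuts >> k) & 1);
    if (cut) {
      chroms.push_back(IntegerVector(cur.begin(), cur.end()));
      cur.clear();
    }
  }
  return List::create(Named("total") = best, Named("genome") = chroms);
}
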