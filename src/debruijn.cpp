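// Minimal de Bruijn assembler: k-mer counting (reads + reverse
// complements), abundance filtering, unitig compaction, simple-bubble
// counting and popping, contig emission.
//
// k-mers are packed 2 bits/base into 64-bit words, so k <= 31.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <string>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int b2(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}
static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline char cmpl(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
  }
  return 'N';
}
static std::string rcseq(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = cmpl(c);
  return r;
}

typedef std::unordered_map<uint64_t, uint32_t> KmerMap;

static void count_seq(const std::string& s, int k, uint64_t mask, KmerMap& m) {
  uint64_t key = 0;
  int run = 0;
  for (size_t p = 0; p < s.size(); ++p) {
    int b = b2(s[p]);
    if (b < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)b) & mask;
    if (++run >= k) m[key]++;
  }
}

static inline uint64_t rc_kmer(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3 - (x & 3));
    x >>= 2;
  }
  return r;
}

struct Graph {
  int k;
  uint64_t mask, himask;
  KmerMap kmers;  // surviving kmers -> count

  bool has(uint64_t x) const { return kmers.find(x) != kmers.end(); }
  int outdeg(uint64_t x, uint64_t succ[4]) const {
    int n = 0;
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t y = ((x << 2) | b) & mask;
      if (has(y)) succ[n++] = y;
    }
    return n;
  }
  int indeg(uint64_t x, uint64_t pred[4]) const {
    int n = 0;
    uint64_t core = x >> 2;
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t y = core | (b << (2 * (k - 1)));
      if (has(y)) pred[n++] = y;
    }
    return n;
  }
};

struct Unitig {
  std::vector<uint64_t> kmers;
  std::string seq;
  double cov;
  uint64_t first() const { return kmers.front(); }
  uint64_t last() const { return kmers.back(); }
};

static std::string kmer2str(uint64_t x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = BASES[x & 3]; x >>= 2; }
  return s;
}

static void build_unitigs(const Graph& g, std::vector<Unitig>& uts) {
  uts.clear();
  std::unordered_set<uint64_t> visited;
  uint64_t tmp[4];

  auto is_start = [&](uint64_t x) {
    uint64_t pred[4];
    int in = g.indeg(x, pred);
    if (in != 1) return true;
    uint64_t succ[4];
    return g.outdeg(pred[0], succ) != 1;
  };

  std::vector<uint64_t> starts;
  starts.reserve(1024);
  for (const auto& kv : g.kmers)
    if (is_start(kv.first)) starts.push_back(kv.first);
  // deterministic order
  std::sort(starts.begin(), starts.end());

  for (uint64_t s : starts) {
    if (visited.count(s)) continue;
    Unitig u;
    uint64_t cur = s;
    while (true) {
      u.kmers.push_back(cur);
      visited.insert(cur);
      uint64_t succ[4];
      if (g.outdeg(cur, succ) != 1) break;
      uint64_t nxt = succ[0];
      uint64_t pred[4];
      if (g.indeg(nxt, pred) != 1) break;
      if (visited.count(nxt)) break;
      cur = nxt;
    }
    uts.push_back(std::move(u));
  }
  // isolated cycles: every kmer has in=out=1
  std::vector<uint64_t> rest;
  for (const auto& kv : g.kmers)
    if (!visited.count(kv.first)) rest.push_back(kv.first);
  std::sort(rest.begin(), rest.end());
  for (uint64_t s : rest) {
    if (visited.count(s)) continue;
    Unitig u;
    uint64_t cur = s;
    while (!visited.count(cur)) {
      u.kmers.push_back(cur);
      visited.insert(cur);
      uint64_t succ[4];
      if (g.outdeg(cur, succ) != 1) break;
      cur = succ[0];
    }
    uts.push_back(std::move(u));
  }
  (void)tmp;

  for (auto& u : uts) {
    u.seq = kmer2str(u.kmers[0], g.k);
    for (size_t i = 1; i < u.kmers.size(); ++i)
      u.seq.push_back(BASES[u.kmers[i] & 3]);
    double c = 0;
    for (uint64_t x : u.kmers) c += g.kmers.at(x);
    u.cov = c / (double)u.kmers.size();
  }
}

struct Bubble { int s, u1, u2, t; };

// unitig-level adjacency + simple-bubble scan
static std::vector<Bubble> find_bubbles(const Graph& g,
                                        const std::vector<Unitig>& uts) {
  std::unordered_map<uint64_t, int> first2ut;
  for (int i = 0; i < (int)uts.size(); ++i) first2ut[uts[i].first()] = i;

  const int n = (int)uts.size();
  std::vector<std::vector<int>> succ(n);
  std::vector<int> indeg(n, 0);
  for (int i = 0; i < n; ++i) {
    uint64_t last = uts[i].last();
    uint64_t nxt[4];
    int m = g.outdeg(last, nxt);
    for (int t = 0; t < m; ++t) {
      auto it = first2ut.find(nxt[t]);
      if (it != first2ut.end()) {
        succ[i].push_back(it->second);
        indeg[it->second]++;
      }
    }
    std::sort(succ[i].begin(), succ[i].end());
    succ[i].erase(std::unique(succ[i].begin(), succ[i].end()), succ[i].end());
  }

  std::vector<Bubble> bubbles;
  for (int s = 0; s < n; ++s) {
    if (succ[s].size() != 2) continue;
    int u1 = succ[s][0], u2 = succ[s][1];
    if (u1 == s || u2 == s || u1 == u2) continue;
    if (indeg[u1] != 1 || indeg[u2] != 1) continue;
    if (succ[u1].size() != 1 || succ[u2].size() != 1) continue;
    int t1 = succ[u1][0], t2 = succ[u2][0];
    if (t1 != t2) continue;
    if (t1 == u1 || t1 == u2 || t1 == s) continue;
    bubbles.push_back({s, u1, u2, t1});
  }
  return bubbles;
}

static std::string canon(const std::string& s) {
  std::string r = rcseq(s);
  return (r < s) ? r : s;
}

// [[Rcpp::export]]
List cpp_debruijn(CharacterVector reads, int k, int min_count,
                  bool pop_bubbles, int max_rounds = 50) {
  Graph g;
  g.k = k;
  g.mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;

  for (int i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    count_seq(s, k, g.mask, g.kmers);
    count_seq(rcseq(s), k, g.mask, g.kmers);
  }
  for (auto it = g.kmers.begin(); it != g.kmers.end();) {
    if ((int)it->second < min_count) it = g.kmers.erase(it);
    else ++it;
  }

  std::vector<Unitig> uts;
  build_unitigs(g, uts);
  int n_bubbles0 = (int)find_bubbles(g, uts).size() / 2;

  if (pop_bubbles) {
    for (int round = 0; round < max_rounds; ++round) {
      std::vector<Bubble> bb = find_bubbles(g, uts);
      if (bb.empty()) break;
      std::unordered_set<uint64_t> kill;
      for (const auto& b : bb) {
        const Unitig &a = uts[b.u1], &c = uts[b.u2];
        int loser;
        if (a.cov != c.cov) loser = (a.cov < c.cov) ? b.u1 : b.u2;
        else loser = (canon(a.seq) <= canon(c.seq)) ? b.u2 : b.u1;
        for (uint64_t x : uts[loser].kmers) kill.insert(x);
      }
      if (kill.empty()) break;
      for (uint64_t x : kill) g.kmers.erase(x);
      build_unitigs(g, uts);
    }
  }

  // contigs: unitigs >= 2k, canonical-deduplicated, deterministic order
  std::vector<std::pair<std::string, double>> contigs;
  std::unordered_set<std::string> seen;
  for (const auto& u : uts) {
    if ((int)u.seq.size() < 2 * k) continue;
    std::string cs = canon(u.seq);
    if (seen.count(cs)) continue;
    seen.insert(cs);
    contigs.push_back({cs, u.cov});
  }
  std::sort(contigs.begin(), contigs.end(),
            [](const std::pair<std::string, double>& a,
               const std::pair<std::string, double>& b) {
              if (a.first.size() != b.first.size())
                return a.first.size() > b.first.size();
              return a.first < b.first;
            });

  CharacterVector seqs(contigs.size());
  NumericVector covs(contigs.size());
  for (size_t i = 0; i < contigs.size(); ++i) {
    seqs[i] = contigs[i].first;
    covs[i] = contigs[i].second;
  }
  return List::create(Named("contigs") = seqs, Named("coverage") = covs,
                      Named("n_bubbles") = n_bubbles0,
                      Named("n_kmers") = (int)g.kmers.size());
}

// [[Rcpp::export]]
int cpp_count_bubbles(CharacterVector reads, int k, int min_count) {
  List res = cpp_debruijn(reads, k, min_count, false);
  return as<int>(res["n_bubbles"]);
}
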