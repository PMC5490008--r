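// Seed-and-extend local aligner with banded affine-gap Smith-Waterman,
// used as the package's read recruiter and fragment-ANI engine, plus a
// CIGAR-driven pileup accumulator.
//
// Gap cost convention: a gap of length L costs gap_open + (L-1)*gap_extend
// (gap_open already includes the first gapped column).

#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <string>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static inline char compbase(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
  }
  return 'N';
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = compbase(c);
  return r;
}

struct Aln {
  bool valid = false;
  int score = 0;
  int qstart = 0, qend = -1, sstart = 0, send = -1;  // 0-based inclusive
  int matches = 0, mismatches = 0, gapcols = 0, gapopens = 0, alen = 0;
  std::string cigar;
};

static const int NEG_INF = -1000000000;

// Banded local alignment of q against s restricted to diagonals
// j - i in [dlo, dhi] (i query index, j subject index, 0-based).
static Aln banded_sw(const std::string& q, const std::string& s,
                     int dlo, int dhi,
                     int match, int mismatch, int go, int ge) {
  const int qlen = (int)q.size(), slen = (int)s.size();
  if (dlo < -(qlen - 1)) dlo = -(qlen - 1);
  if (dhi > slen - 1) dhi = slen - 1;
  Aln out;
  if (dlo > dhi || qlen == 0 || slen == 0) return out;
  const int W = dhi - dlo + 1;

  std::vector<int> Hprev(W, 0), Hcur(W, 0), Fprev(W, NEG_INF), Fcur(W, NEG_INF);
  std::vector<int> Ecur(W, NEG_INF);
  // traceback: bits 0-1 H source (0 stop, 1 diag, 2 E, 3 F);
  // bit 2 E extends; bit 3 F extends
  std::vector<uint8_t> tb((size_t)qlen * W, 0);

  int best = 0, bi = -1, bj = -1;

  for (int i = 0; i < qlen; ++i) {
    std::fill(Hcur.begin(), Hcur.end(), NEG_INF);
    std::fill(Fcur.begin(), Fcur.end(), NEG_INF);
    std::fill(Ecur.begin(), Ecur.end(), NEG_INF);
    int jlo = std::max(0, i + dlo), jhi = std::min(slen - 1, i + dhi);
    const int qb = base2bits(q[i]);
    for (int j = jlo; j <= jhi; ++j) {
      const int b = j - i - dlo;
      uint8_t t = 0;
      // E: gap consuming subject (cigar D); same row, j-1 -> b-1
      int e = NEG_INF;
      if (b - 1 >= 0) {
        int fromH = (Hcur[b - 1] > NEG_INF / 2) ? Hcur[b - 1] + go : NEG_INF;
        int fromE = (Ecur[b - 1] > NEG_INF / 2) ? Ecur[b - 1] + ge : NEG_INF;
        if (fromE > fromH) { e = fromE; t |= 4; } else e = fromH;
      }
      Ecur[b] = e;
      // F: gap consuming query (cigar I); row i-1, same j -> b+1
      int f = NEG_INF;
      if (i > 0 && b + 1 < W) {
        int fromH = (Hprev[b + 1] > NEG_INF / 2) ? Hprev[b + 1] + go : NEG_INF;
        int fromF = (Fprev[b + 1] > NEG_INF / 2) ? Fprev[b + 1] + ge : NEG_INF;
        if (fromF > fromH) { f = fromF; t |= 8; } else f = fromH;
      }
      Fcur[b] = f;
      // H
      int diagH = 0;
      if (i > 0 && j > 0) diagH = (Hprev[b] > NEG_INF / 2) ? Hprev[b] : 0;
      const int sb = base2bits(s[j]);
      const int sub = (qb >= 0 && sb >= 0 && qb == sb) ? match : mismatch;
      int h = 0;     // local restart
      int dir = 0;
      int dscore = diagH + sub;
      if (dscore > h) { h = dscore; dir = 1; }
      if (e > h) { h = e; dir = 2; }
      if (f > h) { h = f; dir = 3; }
      Hcur[b] = h;
      t |= (uint8_t)dir;
      tb[(size_t)i * W + b] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }

  if (best <= 0 || bi < 0) return out;

  // traceback
  std::string rc;  // reversed cigar ops, one char per column
  int i = bi, j = bj;
  int minqi = bi + 1, maxqi = -1, minsj = bj + 1, maxsj = -1;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (i >= 0 && j >= 0) {
    int b = j - i - dlo;
    if (b < 0 || b >= W) break;
    uint8_t t = tb[(size_t)i * W + b];
    if (state == 0) {
      int dir = t & 3;
      if (dir == 0) break;
      if (dir == 1) {
        rc.push_back('M');
        const int qb = base2bits(q[i]), sb = base2bits(s[j]);
        if (qb >= 0 && sb >= 0 && qb == sb) out.matches++; else out.mismatches++;
        minqi = std::min(minqi, i); maxqi = std::max(maxqi, i);
        minsj = std::min(minsj, j); maxsj = std::max(maxsj, j);
        --i; --j;
      } else if (dir == 2) state = 1;
      else state = 2;
    } else if (state == 1) {  // E: consumes subject, cigar D
      rc.push_back('D');
      out.gapcols++;
      minsj = std::min(minsj, j); maxsj = std::max(maxsj, j);
      bool ext = (t & 4) != 0;
      --j;
      if (!ext) { out.gapopens++; state = 0; }
    } else {  // F: consumes query, cigar I
      rc.push_back('I');
      out.gapcols++;
      minqi = std::min(minqi, i); maxqi = std::max(maxqi, i);
      bool ext = (t & 8) != 0;
      --i;
      if (!ext) { out.gapopens++; state = 0; }
    }
  }
  if (maxqi < 0 || maxsj < 0) return out;

  // run-length encode reversed cigar
  std::string cig;
  int n = (int)rc.size();
  int k = n - 1;
  while (k >= 0) {
    char op = rc[k];
    int run = 0;
    while (k >= 0 && rc[k] == op) { ++run; --k; }
    cig += std::to_string(run);
    cig.push_back(op);
  }

  out.valid = true;
  out.score = best;
  out.qstart = minqi; out.qend = maxqi;
  out.sstart = minsj; out.send = maxsj;
  out.alen = out.matches + out.mismatches + out.gapcols;
  out.cigar = cig;
  return out;
}

// k-mer seed index over subjects
struct SeedIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> map;
};

static void index_subjects(const std::vector<std::string>& subjects, int k,
                           SeedIndex& idx) {
  idx.k = k;
  for (int si = 0; si < (int)subjects.size(); ++si) {
    const std::string& s = subjects[si];
    if ((int)s.size() < k) continue;
    uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int run = 0;
    for (int p = 0; p < (int)s.size(); ++p) {
      int b = base2bits(s[p]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k) idx.map[key].push_back({si, p - k + 1});
    }
  }
}

// best alignment of one oriented query against one subject, seeded
static Aln align_seeded(const std::string& qs, const std::string& subj,
                        const std::vector<int>& diags, int band_pad,
                        int match, int mismatch, int go, int ge) {
  Aln best;
  if (diags.empty()) return best;
  std::vector<int> d(diags);
  std::sort(d.begin(), d.end());
  // cluster diagonals, keep up to 8 clusters with most seeds
  struct Cl { int lo, hi, n; };
  std::vector<Cl> cls;
  int lo = d[0], hi = d[0], cnt = 1;
  for (size_t t = 1; t < d.size(); ++t) {
    if (d[t] - hi <= band_pad) { hi = d[t]; ++cnt; }
    else { cls.push_back({lo, hi, cnt}); lo = hi = d[t]; cnt = 1; }
  }
  cls.push_back({lo, hi, cnt});
  if (cls.size() > 8) {
    std::sort(cls.begin(), cls.end(),
              [](const Cl& a, const Cl& b) { return a.n > b.n; });
    cls.resize(8);
  }
  for (const auto& c : cls) {
    Aln a = banded_sw(qs, subj, c.lo - band_pad, c.hi + band_pad,
                      match, mismatch, go, ge);
    if (a.valid && a.score > best.score) best = a;
  }
  return best;
}

// [[Rcpp::export]]
DataFrame cpp_align_batch(CharacterVector queries, CharacterVector subjects,
                          int match, int mismatch, int gap_open,
                          int gap_extend, int min_score, int min_len,
                          int seed_k, int band_pad, bool full_dp) {
  const int nq = queries.size(), ns = subjects.size();
  std::vector<std::string> subj(ns);
  for (int i = 0; i < ns; ++i) subj[i] = as<std::string>(subjects[i]);

  SeedIndex idx;
  if (!full_dp) index_subjects(subj, seed_k, idx);

  std::vector<int> r_qidx, r_sidx, r_qs, r_qe, r_ss, r_se, r_alen, r_mat,
      r_mis, r_gap, r_gopen, r_score;
  std::vector<std::string> r_strand, r_cigar;

  for (int qi = 0; qi < nq; ++qi) {
    const std::string qfwd = as<std::string>(queries[qi]);
    const int qlen = (int)qfwd.size();
    if (qlen == 0) continue;
    for (int st = 0; st < 2; ++st) {
      const std::string qs = (st == 0) ? qfwd : revcomp(qfwd);
      for (int si = 0; si < ns; ++si) {
        Aln a;
        if (full_dp) {
          a = banded_sw(qs, subj[si], -(qlen - 1), (int)subj[si].size() - 1,
                        match, mismatch, gap_open, gap_extend);
        } else {
          // collect seed diagonals for this subject
          std::vector<int> diags;
          uint64_t key = 0,
                   mask = (idx.k < 32) ? ((1ULL << (2 * idx.k)) - 1) : ~0ULL;
          int run = 0;
          for (int p = 0; p < qlen; ++p) {
            int b = base2bits(qs[p]);
            if (b < 0) { run = 0; key = 0; continue; }
            key = ((key << 2) | (uint64_t)b) & mask;
            if (++run >= idx.k) {
              auto it = idx.map.find(key);
              if (it != idx.map.end()) {
                for (const auto& hp : it->second)
                  if (hp.first == si) diags.push_back(hp.second - (p - idx.k + 1));
              }
            }
          }
          a = align_seeded(qs, subj[si], diags, band_pad, match, mismatch,
                           gap_open, gap_extend);
        }
        if (!a.valid || a.score < min_score || a.alen < min_len) continue;
        int q1, q2;
        if (st == 0) { q1 = a.qstart; q2 = a.qend; }
        else { q1 = qlen - 1 - a.qend; q2 = qlen - 1 - a.qstart; }
        r_qidx.push_back(qi + 1);
        r_sidx.push_back(si + 1);
        r_strand.push_back(st == 0 ? "+" : "-");
        r_qs.push_back(q1 + 1);
        r_qe.push_back(q2 + 1);
        r_ss.push_back(a.sstart + 1);
        r_se.push_back(a.send + 1);
        r_alen.push_back(a.alen);
        r_mat.push_back(a.matches);
        r_mis.push_back(a.mismatches);
        r_gap.push_back(a.gapcols);
        r_gopen.push_back(a.gapopens);
        r_score.push_back(a.score);
        r_cigar.push_back(a.cigar);
      }
    }
  }

  return DataFrame::create(
      Named("qidx") = r_qidx, Named("sidx") = r_sidx,
      Named("strand") = r_strand, Named("qstart") = r_qs,
      Named("qend") = r_qe, Named("sstart") = r_ss, Named("send") = r_se,
      Named("length") = r_alen, Named("matches") = r_mat,
      Named("mismatch") = r_mis, Named("gapcols") = r_gap,
      Named("gapopen") = r_gopen, Named("score") = r_score,
      Named("cigar") = r_cigar, Named("stringsAsFactors") = false);
}

// Accumulate allele counts per reference position from CIGAR alignments.
// read_seqs are in original orientation; strand "-" alignments are given
// coordinates on the original read; the CIGAR refers to the reverse
// complement, so the read is flipped here before walking.
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(int ref_len, CharacterVector read_seqs,
                         IntegerVector qstart, IntegerVector qend,
                         IntegerVector sstart, CharacterVector strand,
                         CharacterVector cigar) {
  IntegerMatrix counts(4, ref_len);
  const int n = read_seqs.size();
  for (int h = 0; h < n; ++h) {
    std::string seq = as<std::string>(read_seqs[h]);
    const int L = (int)seq.size();
    bool minus = (as<std::string>(strand[h]) == "-");
    int q = qstart[h] - 1;  // 0-based on aligned orientation
    if (minus) {
      seq = revcomp(seq);
      q = L - qend[h];  // = L - 1 - (qend-1)
    }
    int s = sstart[h] - 1;
    const std::string cig = as<std::string>(cigar[h]);
    size_t p = 0;
    while (p < cig.size()) {
      int num = 0;
      while (p < cig.size() && isdigit(cig[p])) num = num * 10 + (cig[p++] - '0');
      char op = cig[p++];
      if (op == 'M') {
        for (int t = 0; t < num; ++t) {
          if (s >= 0 && s < ref_len && q >= 0 && q < L) {
            int b = base2bits(seq[q]);
            if (b >= 0) counts(b, s)++;
          }
          ++q; ++s;
        }
      } else if (op == 'I') {
        q += num;
      } else if (op == 'D') {
        s += num;
      }
    }
  }
  return counts;
}
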