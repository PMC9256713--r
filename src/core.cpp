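#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// 2-bit base codes; 4 = N / other (never seeds, always mismatches)
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }

typedef std::unordered_map<uint64_t, std::vector<uint32_t> > KmerIndex;

// roll k-mers of s, call f(kmer, pos) for every N-free window
template <typename F>
static void for_each_kmer(const std::string& s, int k, F f) {
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t kmer = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0;  // length of current N-free run
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c > 3) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)c) & mask;
    if (++valid >= k) f(kmer, i - k + 1);
  }
}

// count mismatches between read and genome at offset; N on either side
// counts as a mismatch; early abandon past `cap`
static int count_mm(const std::string& g, size_t off, const std::string& r,
                    int cap) {
  int mm = 0;
  const size_t n = r.size();
  for (size_t i = 0; i < n; ++i) {
    char a = g[off + i], b = r[i];
    int ca = base_code(a), cb = base_code(b);
    if (ca != cb || ca > 3) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

// Map reads against a set of references by exact k-mer seeding and ungapped
// full-length extension. Returns every best-tier hit for every read.
// Columns: read (1-based index), ref (1-based ref index), pos (0-based),
// strand (+/-), mismatches, n_best (number of equal-best placements).
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector ref_seqs, CharacterVector reads,
                        int k, double max_mismatch_frac) {
  const int nref = ref_seqs.size();
  if (nref == 0) stop("empty reference index");
  // concatenate references, remember offsets
  std::string genome;
  std::vector<size_t> ref_off(nref), ref_len(nref);
  for (int i = 0; i < nref; ++i) {
    std::string s = as<std::string>(ref_seqs[i]);
    ref_off[i] = genome.size();
    ref_len[i] = s.size();
    genome += s;
  }
  KmerIndex idx;
  for_each_kmer(genome, k, [&](uint64_t km, int pos) {
    // drop windows that straddle two references
    int ri = (int)(std::upper_bound(ref_off.begin(), ref_off.end(),
                                    (size_t)pos) - ref_off.begin()) - 1;
    if ((size_t)pos + k <= ref_off[ri] + ref_len[ri]) idx[km].push_back(pos);
  });

  std::vector<int> o_read, o_ref, o_pos, o_mm, o_nbest;
  std::vector<std::string> o_strand;

  const int nreads = reads.size();
  for (int r = 0; r < nreads; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    const int len = (int)fwd.size();
    if (len < k) continue;
    std::string rev = revcomp(fwd);
    const int cap0 = (int)std::floor(max_mismatch_frac * len);

    int best = cap0 + 1;
    std::vector<std::pair<size_t, int> > hits;  // (global pos, strand 0/1)
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& rd = (strand == 0) ? fwd : rev;
      // three seed offsets: start, middle, end
      int offs[3] = {0, (len - k) / 2, len - k};
      std::vector<size_t> cand;
      for (int s = 0; s < 3; ++s) {
        int off = offs[s];
        if (s > 0 && off == offs[s - 1]) continue;
        uint64_t km = 0; bool ok = true;
        for (int i = 0; i < k; ++i) {
          int c = base_code(rd[off + i]);
          if (c > 3) { ok = false; break; }
          km = (km << 2) | (uint64_t)c;
        }
        if (!ok) continue;
        auto it = idx.find(km);
        if (it == idx.end()) continue;
        for (uint32_t p : it->second)
          if ((int64_t)p - off >= 0) cand.push_back((size_t)p - off);
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (size_t gpos : cand) {
        int ri = (int)(std::upper_bound(ref_off.begin(), ref_off.end(), gpos)
                       - ref_off.begin()) - 1;
        if (gpos + len > ref_off[ri] + ref_len[ri]) continue;
        int mm = count_mm(genome, gpos, rd, best);
        if (mm < best) {
          best = mm; hits.clear();
          hits.push_back(std::make_pair(gpos, strand));
        } else if (mm == best && best <= cap0) {
          hits.push_back(std::make_pair(gpos, strand));
        }
      }
    }
    if (best > cap0 || hits.empty()) continue;
    for (auto& h : hits) {
      int ri = (int)(std::upper_bound(ref_off.begin(), ref_off.end(), h.first)
                     - ref_off.begin()) - 1;
      o_read.push_back(r + 1);
      o_ref.push_back(ri + 1);
      o_pos.push_back((int)(h.first - ref_off[ri]));
      o_strand.push_back(h.second == 0 ? "+" : "-");
      o_mm.push_back(best);
      o_nbest.push_back((int)hits.size());
    }
  }
  return DataFrame::create(_["read"] = o_read, _["ref"] = o_ref,
                           _["pos"] = o_pos, _["strand"] = o_strand,
                           _["mismatches"] = o_mm, _["n_best"] = o_nbest,
                           _["stringsAsFactors"] = false);
}

// All exact shared w-mers between query and subject (forward strands).
// Returns 0-based positions; hit count capped to keep pathological repeats
// bounded.
// [[Rcpp::export]]
DataFrame cpp_seed_hits(std::string query, std::string subject, int w,
                        int max_hits = 2000000) {
  KmerIndex idx;
  for_each_kmer(subject, w, [&](uint64_t km, int pos) {
    idx[km].push_back(pos);
  });
  std::vector<int> qpos, spos;
  bool truncated = false;
  for_each_kmer(query, w, [&](uint64_t km, int pos) {
    if (truncated) return;
    auto it = idx.find(km);
    if (it == idx.end()) return;
    for (uint32_t p : it->second) {
      if ((int)qpos.size() >= max_hits) { truncated = true; return; }
      qpos.push_back(pos); spos.push_back((int)p);
    }
  });
  if (truncated) warning("seed hit list truncated at max_hits");
  return DataFrame::create(_["qpos"] = qpos, _["spos"] = spos);
}

// Per-position match indicator of `query` laid on `subject` at a fixed
// diagonal: query[i] is compared to subject[i + offset]. Out-of-bounds or
// N positions are 0 (mismatch), NA-free.
// [[Rcpp::export]]
IntegerVector cpp_diag_matches(std::string query, std::string subject,
                               int offset) {
  const int nq = (int)query.size(), ns = (int)subject.size();
  IntegerVector out(nq);
  for (int i = 0; i < nq; ++i) {
    int j = i + offset;
    if (j < 0 || j >= ns) { out[i] = 0; continue; }
    int a = base_code(query[i]), b = base_code(subject[j]);
    out[i] = (a <= 3 && a == b) ? 1 : 0;
  }
  return out;
}

// best suffix(a)-prefix(b) overlap: longest L >= min_ov with
// mismatches <= floor((1-min_id)*L). Returns L (0 if none) and mismatches.
static std::pair<int, int> best_overlap(const std::string& a,
                                        const std::string& b, int min_ov,
                                        double min_id) {
  const int la = (int)a.size(), lb = (int)b.size();
  for (int L = std::min(la, lb); L >= min_ov; --L) {
    int cap = (int)std::floor((1.0 - min_id) * L);
    int mm = 0; bool ok = true;
    const char* pa = a.data() + (la - L);
    for (int i = 0; i < L; ++i) {
      int ca = base_code(pa[i]), cb = base_code(b[i]);
      if (ca != cb || ca > 3) {
        if (++mm > cap) { ok = false; break; }
      }
    }
    if (ok) return std::make_pair(L, mm);
  }
  return std::make_pair(0, 0);
}

struct Merge { int i, j, ov; bool rc_j; std::string merged; };

// Greedy overlap-layout assembly: repeatedly apply the merge with the
// longest admissible suffix-prefix overlap (second sequence tried in both
// orientations); ties broken by lexicographically smallest merged sequence
// so the result is deterministic. Exact duplicate inputs are collapsed
// first. Returns contigs sorted longest-first.
// [[Rcpp::export]]
CharacterVector cpp_assemble_greedy(CharacterVector reads, int min_ov,
                                    double min_id) {
  std::vector<std::string> seqs;
  for (int i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    if (s.empty()) continue;
    std::string r = revcomp(s);
    std::string canon = std::min(s, r);
    bool dup = false;
    for (auto& t : seqs)
      if (t == s || revcomp(t) == s) { dup = true; break; }
    (void)canon;
    if (!dup) seqs.push_back(s);
  }
  const int MAXN = (int)seqs.size();
  if (MAXN == 0) return CharacterVector(0);

  // ov[i][j][o]: best overlap of suffix(i) with prefix(j in orientation o)
  std::vector<std::vector<std::array<int, 2> > > ov(
      MAXN, std::vector<std::array<int, 2> >(MAXN, {{-1, -1}}));
  std::vector<bool> alive(MAXN, true);

  auto compute = [&](int i, int j) {
    for (int o = 0; o < 2; ++o) {
      std::string bj = (o == 0) ? seqs[j] : revcomp(seqs[j]);
      ov[i][j][o] = best_overlap(seqs[i], bj, min_ov, min_id).first;
    }
  };
  for (int i = 0; i < MAXN; ++i)
    for (int j = 0; j < MAXN; ++j)
      if (i != j) compute(i, j);

  while (true) {
    int best_len = 0;
    Merge best;
    for (int i = 0; i < MAXN; ++i) {
      if (!alive[i]) continue;
      for (int j = 0; j < MAXN; ++j) {
        if (i == j || !alive[j]) continue;
        for (int o = 0; o < 2; ++o) {
          int L = ov[i][j][o];
          if (L < min_ov || L < best_len) continue;
          std::string bj = (o == 0) ? seqs[j] : revcomp(seqs[j]);
          std::string merged = seqs[i] + bj.substr(L);
          if (L > best_len ||
              (L == best_len && merged < best.merged)) {
            best_len = L;
            best = Merge{i, j, L, o == 1, merged};
          }
        }
      }
    }
    if (best_len < min_ov) break;
    seqs[best.i] = best.merged;
    alive[best.j] = false;
    for (int j = 0; j < MAXN; ++j)
      if (alive[j] && j != best.i) { compute(best.i, j); compute(j, best.i); }
  }

  std::vector<std::string> out;
  for (int i = 0; i < MAXN; ++i)
    if (alive[i]) out.push_back(seqs[i]);
  std::sort(out.begin(), out.end(), [](const std::string& a,
                                       const std::string& b) {
    return a.size() != b.size() ? a.size() > b.size() : a < b;
  });
  return wrap(out);
}
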