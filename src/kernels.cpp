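// Low-level kernels: exact k-mer counting, anchor-chain alignment,
// paired-read simulation, seed-and-extend read mapping, pileup events.
// All coordinates are 0-based half-open; all RNG is std::mt19937_64
// seeded explicitly from R so results are reproducible bit for bit.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <random>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int b2i(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char I2B[4] = {'A', 'C', 'G', 'T'};

static inline char compl_base(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  default: return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) c = compl_base(c);
  return r;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    out[i] = revcomp_str(s);
  }
  out.names() = seqs.names();
  return out;
}

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Open-addressing counter for canonical k-mer codes (linear probing).
struct KTable {
  std::vector<uint64_t> keys;
  std::vector<uint32_t> vals;
  uint64_t mask;
  size_t n;

  explicit KTable(size_t cap_hint) : n(0) {
    size_t sz = 1024;
    while (sz < cap_hint * 2) sz <<= 1;
    keys.assign(sz, 0);
    vals.assign(sz, 0);
    mask = sz - 1;
  }
  void grow() {
    std::vector<uint64_t> ok;
    std::vector<uint32_t> ov;
    ok.swap(keys); ov.swap(vals);
    keys.assign(ok.size() * 2, 0);
    vals.assign(ov.size() * 2, 0);
    mask = keys.size() - 1;
    for (size_t i = 0; i < ok.size(); ++i) {
      if (ok[i]) {
        uint64_t h = splitmix64(ok[i]) & mask;
        while (keys[h]) h = (h + 1) & mask;
        keys[h] = ok[i];
        vals[h] = ov[i];
      }
    }
  }
  void add(uint64_t code) {
    if (n * 5 > keys.size() * 3) grow();
    uint64_t key = code + 1;  // 0 is the empty slot sentinel
    uint64_t h = splitmix64(key) & mask;
    for (;;) {
      if (keys[h] == 0) { keys[h] = key; vals[h] = 1; ++n; return; }
      if (keys[h] == key) { ++vals[h]; return; }
      h = (h + 1) & mask;
    }
  }
};

// Iterate canonical k-mer codes of a sequence, calling f(pos, code).
template <typename F>
static void for_canonical_kmers(const char* s, size_t len, int k, F f) {
  if ((int)len < k) return;
  const uint64_t kmask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fc = 0, rc = 0;
  int run = 0;
  for (size_t i = 0; i < len; ++i) {
    int b = b2i(s[i]);
    if (b < 0) { run = 0; fc = 0; rc = 0; continue; }
    fc = ((fc << 2) | (uint64_t)b) & kmask;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++run >= k) f(i + 1 - k, fc < rc ? fc : rc);
  }
}

// [[Rcpp::export]]
List kmer_count_cpp(CharacterVector seqs, int k, double cap_hint = 0) {
  if (k < 2 || k > 26)
    stop("k must be between 2 and 26 for exact canonical counting");
  double total_bases = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) total_bases += LENGTH(STRING_ELT(seqs, i));
  // start small and let the table grow: distinct k-mers are far fewer than
  // total instances for deep read sets
  size_t hint = cap_hint > 0 ? (size_t)cap_hint : std::min((double)8e6, total_bases / 8 + 1024);
  KTable tab(hint);
  double total = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    SEXP el = STRING_ELT(seqs, i);
    for_canonical_kmers(CHAR(el), LENGTH(el), k, [&](size_t, uint64_t code) {
      tab.add(code);
      total += 1;
    });
  }
  NumericVector code(tab.n);
  IntegerVector count(tab.n);
  size_t j = 0;
  for (size_t i = 0; i < tab.keys.size(); ++i) {
    if (tab.keys[i]) {
      code[j] = (double)(tab.keys[i] - 1);
      count[j] = (int)tab.vals[i];
      ++j;
    }
  }
  return List::create(_["code"] = code, _["count"] = count, _["total"] = total);
}

// Canonical k-mer code at every start position (NA where a window has non-ACGT).
// [[Rcpp::export]]
List kmer_codes_cpp(CharacterVector seqs, int k) {
  if (k < 2 || k > 26) stop("k must be between 2 and 26");
  List out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    SEXP el = STRING_ELT(seqs, i);
    int len = LENGTH(el);
    int nwin = len - k + 1;
    if (nwin < 1) { out[i] = NumericVector(0); continue; }
    NumericVector v(nwin, NA_REAL);
    for_canonical_kmers(CHAR(el), len, k, [&](size_t pos, uint64_t code) {
      v[pos] = (double)code;
    });
    out[i] = v;
  }
  out.names() = seqs.names();
  return out;
}

// [[Rcpp::export]]
NumericVector kmer_encode_cpp(CharacterVector kmers) {
  NumericVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    SEXP el = STRING_ELT(kmers, i);
    int k = LENGTH(el);
    if (k < 2 || k > 26) { out[i] = NA_REAL; continue; }
    const char* s = CHAR(el);
    uint64_t fc = 0, rc = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int b = b2i(s[j]);
      if (b < 0) { ok = false; break; }
      fc = (fc << 2) | (uint64_t)b;
      rc = rc | ((uint64_t)(3 - b) << (2 * j));
    }
    out[i] = ok ? (double)std::min(fc, rc) : NA_REAL;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector kmer_decode_cpp(NumericVector codes, int k) {
  CharacterVector out(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    if (NumericVector::is_na(codes[i])) { out[i] = NA_STRING; continue; }
    uint64_t c = (uint64_t)codes[i];
    std::string s(k, 'A');
    for (int j = k - 1; j >= 0; --j) { s[j] = I2B[c & 3]; c >>= 2; }
    out[i] = s;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Seed index: sorted (key, tid, tpos) over forward k-mers of target sequences.

struct SeedEntry {
  uint64_t key;
  int32_t tid;
  int32_t tpos;
};

static void build_seed_index(const std::vector<std::string>& tseqs, int k,
                             std::vector<SeedEntry>& idx) {
  const uint64_t kmask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  size_t total = 0;
  for (const auto& s : tseqs) total += s.size();
  idx.reserve(total);
  for (size_t t = 0; t < tseqs.size(); ++t) {
    const std::string& s = tseqs[t];
    uint64_t fc = 0;
    int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = b2i(s[i]);
      if (b < 0) { run = 0; fc = 0; continue; }
      fc = ((fc << 2) | (uint64_t)b) & kmask;
      if (++run >= k)
        idx.push_back({fc, (int32_t)t, (int32_t)(i + 1 - k)});
    }
  }
  std::sort(idx.begin(), idx.end(), [](const SeedEntry& a, const SeedEntry& b) {
    if (a.key != b.key) return a.key < b.key;
    if (a.tid != b.tid) return a.tid < b.tid;
    return a.tpos < b.tpos;
  });
}

static inline std::pair<size_t, size_t> seed_range(const std::vector<SeedEntry>& idx,
                                                   uint64_t key) {
  SeedEntry probe{key, 0, 0};
  auto lo = std::lower_bound(idx.begin(), idx.end(), probe,
                             [](const SeedEntry& a, const SeedEntry& b) { return a.key < b.key; });
  auto hi = lo;
  while (hi != idx.end() && hi->key == key) ++hi;
  return {(size_t)(lo - idx.begin()), (size_t)(hi - idx.begin())};
}

// ---------------------------------------------------------------------------
// Anchor-chain aligner: exact shared k-mers between query and target chained
// on a common (anti)diagonal. Substitution-only alignments (no indels), which
// matches what the bundled simulator produces; chains are broken at anchor
// gaps > max_gap.

struct Anchor {
  int32_t qid, tid;
  int8_t strand;  // 0 = '+', 1 = '-'
  int64_t diag;
  int32_t qpos, tpos;
};

// [[Rcpp::export]]
DataFrame anchor_chain_cpp(CharacterVector qseqs, CharacterVector tseqs, int k,
                           int max_gap, int max_hits, bool self_mode) {
  if (k < 8 || k > 31) stop("anchor k must be in [8, 31]");
  std::vector<std::string> ts(tseqs.size());
  for (R_xlen_t i = 0; i < tseqs.size(); ++i) ts[i] = as<std::string>(tseqs[i]);
  std::vector<SeedEntry> idx;
  build_seed_index(ts, k, idx);

  const uint64_t kmask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::vector<Anchor> anchors;
  for (R_xlen_t q = 0; q < qseqs.size(); ++q) {
    SEXP el = STRING_ELT(qseqs, q);
    const char* s = CHAR(el);
    int len = LENGTH(el);
    uint64_t fc = 0, rc = 0;
    int run = 0;
    for (int i = 0; i < len; ++i) {
      int b = b2i(s[i]);
      if (b < 0) { run = 0; fc = 0; rc = 0; continue; }
      fc = ((fc << 2) | (uint64_t)b) & kmask;
      rc = (rc >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
      if (++run < k) continue;
      int qpos = i + 1 - k;
      for (int strand = 0; strand < 2; ++strand) {
        uint64_t key = strand == 0 ? fc : rc;
        auto r = seed_range(idx, key);
        if (r.second - r.first == 0 || (int)(r.second - r.first) > max_hits) continue;
        for (size_t j = r.first; j < r.second; ++j) {
          const SeedEntry& e = idx[j];
          if (self_mode && e.tid == (int32_t)q) continue;
          int64_t diag = strand == 0 ? (int64_t)qpos - e.tpos : (int64_t)qpos + e.tpos;
          anchors.push_back({(int32_t)q, e.tid, (int8_t)strand, diag, (int32_t)qpos, e.tpos});
        }
      }
    }
  }

  std::sort(anchors.begin(), anchors.end(), [](const Anchor& a, const Anchor& b) {
    if (a.qid != b.qid) return a.qid < b.qid;
    if (a.tid != b.tid) return a.tid < b.tid;
    if (a.strand != b.strand) return a.strand < b.strand;
    if (a.diag != b.diag) return a.diag < b.diag;
    return a.qpos < b.qpos;
  });

  std::vector<int> o_qid, o_tid, o_qs, o_qe, o_ts, o_te, o_n, o_cov;
  std::vector<std::string> o_strand;
  size_t i = 0, n = anchors.size();
  while (i < n) {
    size_t j = i + 1;
    int cov = k;
    while (j < n) {
      const Anchor &a = anchors[j - 1], &b = anchors[j];
      if (b.qid != a.qid || b.tid != a.tid || b.strand != a.strand ||
          b.diag != a.diag || b.qpos - a.qpos > max_gap)
        break;
      cov += std::min(k, b.qpos - a.qpos);
      ++j;
    }
    const Anchor &first = anchors[i], &last = anchors[j - 1];
    o_qid.push_back(first.qid + 1);
    o_tid.push_back(first.tid + 1);
    o_strand.push_back(first.strand == 0 ? "+" : "-");
    o_qs.push_back(first.qpos);
    o_qe.push_back(last.qpos + k);
    if (first.strand == 0) {
      o_ts.push_back(first.tpos);
      o_te.push_back(last.tpos + k);
    } else {
      o_ts.push_back(last.tpos);
      o_te.push_back(first.tpos + k);
    }
    o_n.push_back((int)(j - i));
    o_cov.push_back(cov);
    i = j;
  }

  return DataFrame::create(
      _["qid"] = o_qid, _["tid"] = o_tid, _["strand"] = o_strand,
      _["qstart"] = o_qs, _["qend"] = o_qe, _["tstart"] = o_ts, _["tend"] = o_te,
      _["n_anchors"] = o_n, _["anchor_cov"] = o_cov,
      _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Paired-read simulator. Fragments sampled length-weighted across haplotype
// scaffolds, insert ~ Normal(mean, sd) truncated at [2*read_len, scaffold],
// i.i.d. substitution errors at err_rate (geometric skip sampling).

// [[Rcpp::export]]
List simulate_reads_cpp(CharacterVector seqs, int n_pairs, int read_len,
                        double ins_mean, double ins_sd, double err_rate,
                        double rng_seed) {
  std::vector<std::string> ss(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) ss[i] = as<std::string>(seqs[i]);
  std::vector<double> cum(ss.size());
  double total = 0;
  for (size_t i = 0; i < ss.size(); ++i) { total += (double)ss[i].size(); cum[i] = total; }
  if (total <= 0) stop("empty sequence set");

  std::mt19937_64 rng((uint64_t)rng_seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::normal_distribution<double> norm(ins_mean, ins_sd);

  CharacterVector seq1(n_pairs), seq2(n_pairs);
  IntegerVector origin(n_pairs), pos(n_pairs), insert(n_pairs);

  const double log1me = err_rate > 0 ? std::log1p(-err_rate) : 0.0;
  std::string frag1, frag2;
  for (int p = 0; p < n_pairs; ++p) {
    int sidx = -1, ins = 0;
    for (int attempt = 0; attempt < 200; ++attempt) {
      double u = unif(rng) * total;
      sidx = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
      if (sidx >= (int)ss.size()) sidx = (int)ss.size() - 1;
      ins = (int)std::lround(norm(rng));
      if (ins < 2 * read_len) ins = 2 * read_len;
      if ((int)ss[sidx].size() >= ins) break;
      sidx = -1;
    }
    if (sidx < 0) stop("no scaffold long enough for the insert size");
    const std::string& s = ss[sidx];
    int maxstart = (int)s.size() - ins;
    int st = maxstart > 0 ? (int)(unif(rng) * (maxstart + 1)) : 0;
    if (st > maxstart) st = maxstart;
    frag1 = s.substr(st, read_len);
    frag2 = revcomp_str(s.substr(st + ins - read_len, read_len));
    if (err_rate > 0) {
      for (std::string* m : {&frag1, &frag2}) {
        double i = std::floor(std::log(1.0 - unif(rng)) / log1me);
        while (i < (double)m->size()) {
          int cur = b2i((*m)[(size_t)i]);
          if (cur >= 0) {
            int nb = (cur + 1 + (int)(unif(rng) * 3.0)) & 3;
            (*m)[(size_t)i] = I2B[nb];
          }
          i += 1.0 + std::floor(std::log(1.0 - unif(rng)) / log1me);
        }
      }
    }
    seq1[p] = frag1;
    seq2[p] = frag2;
    origin[p] = sidx + 1;
    pos[p] = st;
    insert[p] = ins;
  }
  return List::create(_["seq1"] = seq1, _["seq2"] = seq2, _["origin"] = origin,
                      _["pos"] = pos, _["insert"] = insert);
}

// ---------------------------------------------------------------------------
// Seed-and-extend mapper: exact seed_len-mer anchors, full-length Hamming
// extension (substitution-only reads), minimum-mismatch placement, equal-best
// ties broken uniformly at random under the supplied seed.

struct Cand {
  int32_t tid, start;
  int8_t strand;
  bool operator<(const Cand& o) const {
    if (tid != o.tid) return tid < o.tid;
    if (start != o.start) return start < o.start;
    return strand < o.strand;
  }
  bool operator==(const Cand& o) const {
    return tid == o.tid && start == o.start && strand == o.strand;
  }
};

// [[Rcpp::export]]
List map_reads_cpp(CharacterVector reads, CharacterVector tseqs, int seed_len,
                   int n_seeds, double max_mm_frac, double rng_seed,
                   int max_hits = 64) {
  if (seed_len < 11 || seed_len > 31) stop("seed_len must be in [11, 31]");
  std::vector<std::string> ts(tseqs.size());
  for (R_xlen_t i = 0; i < tseqs.size(); ++i) ts[i] = as<std::string>(tseqs[i]);
  std::vector<SeedEntry> idx;
  build_seed_index(ts, seed_len, idx);

  std::mt19937_64 rng((uint64_t)rng_seed);
  R_xlen_t n = reads.size();
  IntegerVector o_tid(n), o_start(n), o_nm(n), o_nties(n);
  CharacterVector o_strand(n);

  std::vector<Cand> cands, ties;
  std::string rc;
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP el = STRING_ELT(reads, i);
    const char* fwd = CHAR(el);
    int rl = LENGTH(el);
    o_tid[i] = NA_INTEGER;
    o_start[i] = NA_INTEGER;
    o_nm[i] = NA_INTEGER;
    o_nties[i] = NA_INTEGER;
    o_strand[i] = NA_STRING;
    if (rl < seed_len) continue;
    int max_mm = (int)std::floor(max_mm_frac * rl);
    rc.assign(fwd, fwd + rl);
    rc = revcomp_str(rc);

    cands.clear();
    int span = rl - seed_len;
    int step = n_seeds > 1 ? std::max(1, span / (n_seeds - 1)) : std::max(1, span + 1);
    for (int strand = 0; strand < 2; ++strand) {
      const char* rp = strand == 0 ? fwd : rc.c_str();
      for (int off = 0; off <= span; off += step) {
        uint64_t key = 0;
        bool ok = true;
        for (int j = 0; j < seed_len; ++j) {
          int b = b2i(rp[off + j]);
          if (b < 0) { ok = false; break; }
          key = (key << 2) | (uint64_t)b;
        }
        if (!ok) continue;
        auto r = seed_range(idx, key);
        if (r.second - r.first == 0 || (int)(r.second - r.first) > max_hits) continue;
        for (size_t e = r.first; e < r.second; ++e) {
          int32_t start = idx[e].tpos - off;
          if (start < 0 || start + rl > (int)ts[idx[e].tid].size()) continue;
          cands.push_back({idx[e].tid, start, (int8_t)strand});
        }
        if (off == span) break;
      }
    }
    if (cands.empty()) continue;
    std::sort(cands.begin(), cands.end());
    cands.erase(std::unique(cands.begin(), cands.end()), cands.end());

    int best = max_mm + 1;
    ties.clear();
    for (const Cand& c : cands) {
      const char* rp = c.strand == 0 ? fwd : rc.c_str();
      const char* tp = ts[c.tid].c_str() + c.start;
      int mm = 0;
      for (int j = 0; j < rl; ++j) {
        mm += (rp[j] != tp[j]);
        if (mm > best) break;
      }
      if (mm < best) { best = mm; ties.clear(); ties.push_back(c); }
      else if (mm == best) ties.push_back(c);
    }
    if (best > max_mm || ties.empty()) continue;
    const Cand& pick = ties.size() == 1
        ? ties[0]
        : ties[(size_t)(std::uniform_real_distribution<double>(0, 1)(rng) * ties.size()) % ties.size()];
    o_tid[i] = pick.tid + 1;
    o_start[i] = pick.start;
    o_nm[i] = best;
    o_nties[i] = (int)ties.size();
    o_strand[i] = pick.strand == 0 ? "+" : "-";
  }
  return List::create(_["tid"] = o_tid, _["start"] = o_start,
                      _["strand"] = o_strand, _["nm"] = o_nm,
                      _["n_ties"] = o_nties);
}

// ---------------------------------------------------------------------------
// Pileup mismatch events: positions where an aligned read base differs from
// the target base. Reads are oriented per the mapped strand.

// [[Rcpp::export]]
List mismatch_events_cpp(CharacterVector reads, IntegerVector tid,
                         IntegerVector start, CharacterVector strand,
                         CharacterVector tseqs) {
  std::vector<std::string> ts(tseqs.size());
  for (R_xlen_t i = 0; i < tseqs.size(); ++i) ts[i] = as<std::string>(tseqs[i]);
  std::vector<int> e_tid, e_pos, e_base;
  std::string rc;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    if (tid[i] == NA_INTEGER) continue;
    SEXP el = STRING_ELT(reads, i);
    const char* rp = CHAR(el);
    int rl = LENGTH(el);
    bool minus = strand[i] != NA_STRING && as<std::string>(strand[i]) == "-";
    if (minus) {
      rc.assign(rp, rp + rl);
      rc = revcomp_str(rc);
      rp = rc.c_str();
    }
    const std::string& t = ts[tid[i] - 1];
    int st = start[i];
    if (st < 0 || st + rl > (int)t.size()) continue;
    for (int j = 0; j < rl; ++j) {
      if (rp[j] != t[st + j]) {
        int b = b2i(rp[j]);
        if (b >= 0) {
          e_tid.push_back(tid[i]);
          e_pos.push_back(st + j);
          e_base.push_back(b);
        }
      }
    }
  }
  return List::create(_["tid"] = wrap(e_tid), _["pos"] = wrap(e_pos),
                      _["base"] = wrap(e_base));
}
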