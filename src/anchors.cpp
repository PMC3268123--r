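// Seed-and-extend engines for exact maximal matches and near-exact query
// mapping. Coordinates are 0-based half-open throughout; case-insensitive
// matching with N treated as ambiguous (never matches anything, itself
// included).
#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static inline int base2(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // N or anything else: ambiguous
  }
}

static inline bool base_eq(char x, char y) {
  const int a = base2(x);
  return a >= 0 && a == base2(y);
}

static std::string revcomp_str(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (auto& c : out) {
    switch (c) {
      case 'A': c = 'T'; break; case 'a': c = 't'; break;
      case 'C': c = 'G'; break; case 'c': c = 'g'; break;
      case 'G': c = 'C'; break; case 'g': c = 'c'; break;
      case 'T': c = 'A'; break; case 't': c = 'a'; break;
      default: break;
    }
  }
  return out;
}

// Packed k-mer index: sorted (kmer, payload) pairs, binary-searched at
// query time. k must be <= 31 so the k-mer fits in 62 bits.
struct KmerIndex {
  int k;
  std::vector<std::pair<uint64_t, uint64_t>> entries;

  void build(const std::string& s, int k_, uint64_t payload_base) {
    k = k_;
    const size_t n = s.size();
    if (n < (size_t)k) return;
    uint64_t kmer = 0;
    const uint64_t mask = (1ULL << (2 * k)) - 1;
    int valid = 0;
    for (size_t i = 0; i < n; ++i) {
      const int b = base2(s[i]);
      if (b < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)b) & mask;
      ++valid;
      if (valid >= k)
        entries.emplace_back(kmer, payload_base + (uint64_t)(i - k + 1));
    }
  }

  void finish() { std::sort(entries.begin(), entries.end()); }

  std::pair<size_t, size_t> lookup(uint64_t kmer) const {
    auto lo = std::lower_bound(
        entries.begin(), entries.end(), std::make_pair(kmer, (uint64_t)0));
    auto hi = std::upper_bound(
        entries.begin(), entries.end(), std::make_pair(kmer, ~(uint64_t)0));
    return {(size_t)(lo - entries.begin()), (size_t)(hi - entries.begin())};
  }
};

static bool encode_kmer(const std::string& s, size_t p, int k, uint64_t* out) {
  uint64_t kmer = 0;
  for (int j = 0; j < k; ++j) {
    const int b = base2(s[p + j]);
    if (b < 0) return false;
    kmer = (kmer << 2) | (uint64_t)b;
  }
  *out = kmer;
  return true;
}

// All maximal exact matches of length >= min_len between the query (either
// strand) and each target. The query is indexed once - forward and reverse
// complement merged into one table, strand carried in the payload - and
// every target is scanned at stride min_len - k + 1, which provably visits
// every match of length >= min_len; a per-(strand,diagonal) high-water
// mark avoids re-extending inside an already reported match.
//
// Returns 0-based starts: q_start in forward-query coordinates for strand
// "+" and reverse-complement-query coordinates for strand "-" (the caller
// converts), t_start in target coordinates.
// [[Rcpp::export]]
DataFrame cpp_anchor_scan(std::string query, CharacterVector targets,
                          int min_len, bool both_strands = true) {
  if (query.empty()) stop("empty sequence");
  if (min_len < 20) stop("min_len must be >= 20");
  const int k = std::min(31, min_len);
  const int stride = min_len - k + 1;
  const uint64_t STRAND_BIT = 1ULL << 40;
  const uint64_t POS_MASK = STRAND_BIT - 1;

  std::string rq = both_strands ? revcomp_str(query) : std::string();
  KmerIndex index;
  index.build(query, k, 0);
  if (both_strands) index.build(rq, k, STRAND_BIT);
  index.finish();

  std::vector<int> out_t, out_q, out_s, out_len;
  std::vector<std::string> out_strand;

  for (int ti = 0; ti < targets.size(); ++ti) {
    const std::string t = as<std::string>(targets[ti]);
    if (t.empty()) stop("empty sequence");
    if (t.size() < (size_t)k || index.entries.empty()) continue;
    std::unordered_map<int64_t, int64_t> covered[2];
    const size_t last = t.size() - (size_t)k;
    for (size_t p = 0; p <= last; p += (size_t)stride) {
      uint64_t kmer;
      if (!encode_kmer(t, p, k, &kmer)) continue;
      auto range = index.lookup(kmer);
      for (size_t e = range.first; e < range.second; ++e) {
        const uint64_t payload = index.entries[e].second;
        const int strand = (payload & STRAND_BIT) ? 1 : 0;
        const std::string& q = strand ? rq : query;
        const int64_t ip = (int64_t)(payload & POS_MASK);
        const int64_t sp = (int64_t)p;
        const int64_t diag = sp - ip;
        auto it = covered[strand].find(diag);
        if (it != covered[strand].end() && sp < it->second) continue;
        int64_t left = 0;
        while (sp - left - 1 >= 0 && ip - left - 1 >= 0 &&
               base_eq(t[sp - left - 1], q[ip - left - 1]))
          ++left;
        int64_t right = 0;
        while (sp + k + right < (int64_t)t.size() &&
               ip + k + right < (int64_t)q.size() &&
               base_eq(t[sp + k + right], q[ip + k + right]))
          ++right;
        const int64_t len = k + left + right;
        const int64_t ss = sp - left, is = ip - left;
        covered[strand][diag] = ss + len;
        if (len >= min_len) {
          out_t.push_back(ti + 1);
          out_q.push_back((int)is);
          out_s.push_back((int)ss);
          out_len.push_back((int)len);
          out_strand.push_back(strand ? "-" : "+");
        }
      }
    }
  }
  return DataFrame::create(Named("target") = out_t,
                           Named("q_start") = out_q,
                           Named("t_start") = out_s,
                           Named("length") = out_len,
                           Named("strand") = out_strand,
                           Named("stringsAsFactors") = false);
}

// Map each query (and its reverse complement) against a set of subject
// sequences by seeding (k-mer, stride <= 25) and ungapped full-length
// verification, allowing up to max_mm_per_100 mismatches per 100 bp of
// query. Returns one row per (query, subject, diagonal, strand) hit whose
// mismatch count is within budget and whose full query length fits inside
// the subject. Starts are 0-based; strand "-" means the reverse complement
// of the query matches the subject's forward strand there.
// [[Rcpp::export]]
DataFrame cpp_map_queries(CharacterVector subjects, CharacterVector queries,
                          int k, double max_mm_per_100) {
  if (k < 8 || k > 31) stop("k must be in [8, 31]");
  std::vector<std::string> subj(subjects.size());
  for (int i = 0; i < subjects.size(); ++i)
    subj[i] = as<std::string>(subjects[i]);

  KmerIndex index;
  index.k = k;
  for (size_t i = 0; i < subj.size(); ++i)
    index.build(subj[i], k, ((uint64_t)i) << 40);
  index.finish();
  const uint64_t POS_MASK = (1ULL << 40) - 1;

  std::vector<int> out_q, out_s, out_start, out_mm, out_len;
  std::vector<std::string> out_strand;

  for (int qi = 0; qi < queries.size(); ++qi) {
    const std::string fwd = as<std::string>(queries[qi]);
    const int64_t L = (int64_t)fwd.size();
    if (L < k) continue;
    const int max_mm =
        (int)std::floor(max_mm_per_100 * (double)L / 100.0 + 1e-9);
    const std::string rev = revcomp_str(fwd);
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& q = strand == 0 ? fwd : rev;
      std::unordered_set<uint64_t> seen;
      const int64_t last = L - k;
      const int64_t stride = std::min<int64_t>(25, std::max<int64_t>(1, last));
      for (int64_t p = 0; ; p += stride) {
        if (p > last) break;
        uint64_t kmer;
        if (encode_kmer(q, (size_t)p, k, &kmer)) {
          auto range = index.lookup(kmer);
          for (size_t e = range.first; e < range.second; ++e) {
            const uint64_t payload = index.entries[e].second;
            const int si = (int)(payload >> 40);
            const int64_t spos = (int64_t)(payload & POS_MASK);
            const int64_t sstart = spos - p;
            if (sstart < 0 || sstart + L > (int64_t)subj[si].size()) continue;
            const uint64_t key = (((uint64_t)si) << 40) | (uint64_t)sstart;
            if (!seen.insert(key).second) continue;
            int mm = 0;
            for (int64_t j = 0; j < L && mm <= max_mm; ++j)
              if (!base_eq(q[j], subj[si][sstart + j])) ++mm;
            if (mm <= max_mm) {
              out_q.push_back(qi + 1);
              out_s.push_back(si + 1);
              out_start.push_back((int)sstart);
              out_mm.push_back(mm);
              out_len.push_back((int)L);
              out_strand.push_back(strand == 0 ? "+" : "-");
            }
          }
        }
        if (p == last) break;
        if (p + stride > last) { p = last - stride; }
      }
    }
  }
  return DataFrame::create(Named("query") = out_q, Named("subject") = out_s,
                           Named("start") = out_start,
                           Named("strand") = out_strand,
                           Named("mismatches") = out_mm,
                           Named("length") = out_len,
                           Named("stringsAsFactors") = false);
}

// Exact occurrences of a short pattern in each subject, both strands,
// case-insensitive, by direct scan (no index; meant for primer-sized
// patterns). N never matches.
// [[Rcpp::export]]
DataFrame cpp_find_exact(CharacterVector subjects, std::string pattern) {
  const int64_t m = (int64_t)pattern.size();
  if (m == 0) stop("empty pattern");
  const std::string rc = revcomp_str(pattern);
  std::vector<int> out_s, out_start;
  std::vector<std::string> out_strand;
  for (int si = 0; si < subjects.size(); ++si) {
    const std::string s = as<std::string>(subjects[si]);
    const int64_t n = (int64_t)s.size();
    for (int64_t i = 0; i + m <= n; ++i) {
      bool okf = true, okr = true;
      for (int64_t j = 0; j < m && (okf || okr); ++j) {
        const char c = s[i + j];
        if (okf && !base_eq(c, pattern[j])) okf = false;
        if (okr && !base_eq(c, rc[j])) okr = false;
      }
      if (okf) {
        out_s.push_back(si + 1); out_start.push_back((int)i);
        out_strand.push_back("+");
      }
      if (okr && rc != pattern) {
        out_s.push_back(si + 1); out_start.push_back((int)i);
        out_strand.push_back("-");
      }
    }
  }
  return DataFrame::create(Named("subject") = out_s,
                           Named("start") = out_start,
                           Named("strand") = out_strand,
                           Named("stringsAsFactors") = false);
}

// Case-preserving reverse complement; errors on non-nucleotide characters.
// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) {
  std::string out(s.rbegin(), s.rend());
  for (auto& c : out) {
    switch (c) {
      case 'A': c = 'T'; break; case 'a': c = 't'; break;
      case 'C': c = 'G'; break; case 'c': c = 'g'; break;
      case 'G': c = 'C'; break; case 'g': c = 'c'; break;
      case 'T': c = 'A'; break; case 't': c = 'a'; break;
      case 'N': case 'n': break;
      default:
        stop("non-nucleotide character in sequence: '%c'", c);
    }
  }
  return out;
}

// Count of masked characters (lowercase or N/n) in s[start, end), 0-based
// half-open.
// [[Rcpp::export]]
double cpp_masked_count(std::string s, int start, int end) {
  int64_t n = 0;
  for (int i = start; i < end; ++i) {
    const char c = s[i];
    if ((c >= 'a' && c <= 'z') || c == 'N') ++n;
  }
  return (double)n;
}
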