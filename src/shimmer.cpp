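#include <Rcpp.h>
#include <cstdint>
#include <deque>
using namespace Rcpp;

// 64-bit finalizer (splitmix64-style avalanche) applied on top of an FNV-1a
// pass over the canonical strand form.  The top 53 bits are returned as a
// double so hash values survive R's numeric type exactly.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline char compBase(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 0;
  }
}

static inline bool validBase(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// Canonical (strand-symmetric) hash of s[i, i+k).  strand = 1 when the
// reverse complement is the lexicographically smaller form; palindromes
// report strand 0.  Caller guarantees all k bases are in {A,C,G,T}.
static inline double kmerHashAt(const char *s, R_xlen_t i, int k, int *strand) {
  int cmp = 0;
  for (int j = 0; j < k; ++j) {
    char f = s[i + j];
    char r = compBase(s[i + k - 1 - j]);
    if (f != r) { cmp = (f < r) ? -1 : 1; break; }
  }
  int st = (cmp > 0) ? 1 : 0;
  uint64_t h = 0xCBF29CE484222325ULL;
  if (st == 0) {
    for (int j = 0; j < k; ++j) {
      h ^= (uint64_t)(unsigned char)s[i + j];
      h *= 0x100000001B3ULL;
    }
  } else {
    for (int j = 0; j < k; ++j) {
      h ^= (uint64_t)(unsigned char)compBase(s[i + k - 1 - j]);
      h *= 0x100000001B3ULL;
    }
  }
  if (strand) *strand = st;
  return (double)(mix64(h) >> 11);
}

// [[Rcpp::export(name = ".kmer_hash_cpp")]]
List kmer_hash_cpp(CharacterVector kmers) {
  R_xlen_t n = kmers.size();
  NumericVector hash(n);
  IntegerVector strand(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(kmers, i));
    int k = (int)LENGTH(STRING_ELT(kmers, i));
    if (k < 1) stop("zero-length k-mer");
    for (int j = 0; j < k; ++j) {
      if (!validBase(s[j]))
        stop("invalid alphabet: k-mer may contain only A, C, G, T (got '%c')", s[j]);
    }
    int st;
    hash[i] = kmerHashAt(s, 0, k, &st);
    strand[i] = st;
  }
  return List::create(_["hash"] = hash, _["strand"] = strand);
}

// Level-0 symmetric minimizers: in every window of w consecutive valid
// k-mers keep the k-mer of minimal hash (leftmost on ties); runs broken by
// non-ACGT bases are scanned independently; consecutive duplicate picks are
// collapsed.  Positions are 0-based.
// [[Rcpp::export(name = ".minimizer_scan_cpp")]]
List minimizer_scan_cpp(std::string seq, int w, int k) {
  if (w < 1 || k < 1) stop("w and k must be >= 1");
  R_xlen_t n = (R_xlen_t)seq.size();
  std::vector<double> outHash;
  std::vector<int> outPos, outStrand;
  if (n >= k) {
    const char *s = seq.c_str();
    R_xlen_t nk = n - k + 1;                 // number of k-mer start positions
    // valid[i]: k-mer starting at i has no non-ACGT base
    // prefix counts of invalid bases
    std::vector<R_xlen_t> bad(n + 1, 0);
    for (R_xlen_t i = 0; i < n; ++i) bad[i + 1] = bad[i] + (validBase(s[i]) ? 0 : 1);
    R_xlen_t i = 0;
    while (i < nk) {
      if (bad[i + k] - bad[i] > 0) { ++i; continue; }
      // maximal run of valid k-mer starts beginning at i
      R_xlen_t j = i;
      while (j < nk && bad[j + k] - bad[j] == 0) ++j;   // run = [i, j)
      R_xlen_t runLen = j - i;
      if (runLen >= (R_xlen_t)w) {
        std::vector<double> h(runLen);
        std::vector<int> st(runLen);
        for (R_xlen_t p = 0; p < runLen; ++p) h[p] = kmerHashAt(s, i + p, k, &st[p]);
        std::deque<R_xlen_t> dq;  // indices into run, hashes nondecreasing
        R_xlen_t lastEmitted = -1;
        for (R_xlen_t p = 0; p < runLen; ++p) {
          while (!dq.empty() && h[dq.back()] > h[p]) dq.pop_back();
          dq.push_back(p);
          if (dq.front() <= p - w) dq.pop_front();
          if (p >= (R_xlen_t)w - 1) {
            R_xlen_t sel = dq.front();
            if (sel != lastEmitted) {
              outPos.push_back((int)(i + sel));
              outHash.push_back(h[sel]);
              outStrand.push_back(st[sel]);
              lastEmitted = sel;
            }
          }
        }
      }
      i = j;
    }
  }
  return List::create(_["pos"] = wrap(outPos),
                      _["hash"] = wrap(outHash),
                      _["strand"] = wrap(outStrand));
}

// Sliding window-minimum over an arbitrary hash vector (the hierarchical
// reduction step).  Returns 0-based indices of the selected elements,
// leftmost on ties, consecutive duplicates collapsed.
// [[Rcpp::export(name = ".window_min_idx_cpp")]]
IntegerVector window_min_idx_cpp(NumericVector hash, int w) {
  if (w < 1) stop("window must be >= 1");
  R_xlen_t n = hash.size();
  std::vector<int> out;
  std::deque<R_xlen_t> dq;
  R_xlen_t lastEmitted = -1;
  for (R_xlen_t p = 0; p < n; ++p) {
    while (!dq.empty() && hash[dq.back()] > hash[p]) dq.pop_back();
    dq.push_back(p);
    if (dq.front() <= p - w) dq.pop_front();
    if (p >= (R_xlen_t)w - 1) {
      R_xlen_t sel = dq.front();
      if (sel != lastEmitted) { out.push_back((int)sel); lastEmitted = sel; }
    }
  }
  return wrap(out);
}

// Strand-symmetric minimum-span thinning: while any adjacent pair of kept
// anchors sits closer than min_span, remove the anchor of largest hash
// among those involved in a violation (ties by larger position).  Hashes
// and gap structure are mirror images under reverse complement, so the
// surviving multiset is strand-invariant.  Returns 0-based indices kept.
// [[Rcpp::export(name = ".min_span_thin_cpp")]]
IntegerVector min_span_thin_cpp(IntegerVector pos, NumericVector hash,
                                int min_span) {
  int n = pos.size();
  std::vector<int> prev(n), next(n);
  std::vector<bool> alive(n, true);
  for (int i = 0; i < n; ++i) { prev[i] = i - 1; next[i] = i + 1; }
  while (true) {
    int worst = -1;
    for (int i = 0; i < n; ++i) {
      if (!alive[i]) continue;
      int j = next[i];
      bool inViol = false;
      if (j < n && pos[j] - pos[i] < min_span) inViol = true;
      int p = prev[i];
      if (p >= 0 && pos[i] - pos[p] < min_span) inViol = true;
      if (!inViol) continue;
      if (worst < 0 || hash[i] > hash[worst] ||
          (hash[i] == hash[worst] && pos[i] > pos[worst])) worst = i;
    }
    if (worst < 0) break;
    alive[worst] = false;
    int p = prev[worst], q = next[worst];
    if (p >= 0) next[p] = q;
    if (q < n) prev[q] = p;
  }
  std::vector<int> keep;
  for (int i = 0; i < n; ++i) if (alive[i]) keep.push_back(i);
  return wrap(keep);
}

// Sparse-chaining dynamic program over one (target, orientation) group.
// Anchors must be pre-sorted by (q_begin, t_begin).  Maximizes chain
// cardinality with per-step gap <= max_gap, ties toward the smaller total
// gap.  Returns 1-based predecessor indices (0 = none), chain lengths and
// accumulated gaps; the caller backtracks.
// [[Rcpp::export(name = ".chain_dp_cpp")]]
List chain_dp_cpp(IntegerVector q_begin, IntegerVector q_end,
                  IntegerVector t_begin, IntegerVector t_end,
                  bool same_strand, double max_gap) {
  int n = q_begin.size();
  IntegerVector len(n, 1), pred(n, 0);
  NumericVector gap(n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < i; ++j) {
      if (!(q_begin[j] < q_begin[i])) continue;
      bool okt = same_strand ? (t_begin[j] < t_begin[i])
                             : (t_begin[j] > t_begin[i]);
      if (!okt) continue;
      double gq = q_begin[i] - q_end[j];
      double gt = same_strand ? (double)t_begin[i] - t_end[j]
                              : (double)t_begin[j] - t_end[i];
      if ((gq > max_gap) || (gt > max_gap)) continue;
      double g = gap[j] + (gq > 0 ? gq : 0) + (gt > 0 ? gt : 0);
      if (len[j] + 1 > len[i] || (len[j] + 1 == len[i] && g < gap[i])) {
        len[i] = len[j] + 1;
        gap[i] = g;
        pred[i] = j + 1;
      }
    }
  }
  return List::create(_["len"] = len, _["gap"] = gap, _["pred"] = pred);
}
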