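// Core numeric kernels for the gapped k-mer SVM and deltaSVM scoring.
//
// Sequence encoding: A=0, C=1, G=2, T=3, anything else -1.  An l-mer is a
// base-4 integer with the 5' base most significant, so numeric order on
// codes equals lexicographic order on strings.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static std::vector<int8_t> encode(const std::string &s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (int8_t) base_code(s[i]);
  return v;
}

static inline long long nchoosek(int n, int k) {
  if (k < 0 || k > n) return 0;
  long long r = 1;
  for (int i = 1; i <= k; ++i) r = r * (n - k + i) / i;
  return r;
}

// contribution of an l-mer pair with m mismatches: C(l-m, k) when
// l-m >= k and m <= d, else 0
static std::vector<long long> contrib_lut(int l, int k, int d) {
  std::vector<long long> lut(l + 1, 0);
  for (int m = 0; m <= l; ++m)
    if (l - m >= k && m <= d) lut[m] = nchoosek(l - m, k);
  return lut;
}

// [[Rcpp::export]]
double cpp_pair_contribution(int m, int l, int k) {
  if (l - m >= k) return (double) nchoosek(l - m, k);
  return 0.0;
}

// ---- l-mer code utilities ---------------------------------------------

// codes of all sliding l-mers; NA where the window contains a non-ACGT base
// [[Rcpp::export]]
IntegerVector cpp_lmer_codes(std::string seq, int l) {
  int n = (int) seq.size();
  int nw = n - l + 1;
  if (nw < 1) return IntegerVector(0);
  IntegerVector out(nw);
  uint32_t code = 0, mask = (l == 16) ? 0xFFFFFFFFu : ((1u << (2 * l)) - 1u);
  int bad = -1;  // last index with invalid base
  for (int i = 0; i < n; ++i) {
    int b = base_code(seq[i]);
    if (b < 0) { bad = i; b = 0; }
    code = ((code << 2) | (uint32_t) b) & mask;
    int w = i - l + 1;
    if (w >= 0) out[w] = (bad >= w) ? NA_INTEGER : (int) code;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_codes_to_kmers(IntegerVector codes, int l) {
  int n = codes.size();
  CharacterVector out(n);
  std::string buf(l, 'A');
  for (int i = 0; i < n; ++i) {
    if (codes[i] == NA_INTEGER) { out[i] = NA_STRING; continue; }
    uint32_t c = (uint32_t) codes[i];
    for (int j = l - 1; j >= 0; --j) { buf[j] = BASES[c & 3u]; c >>= 2; }
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_kmers_to_codes(CharacterVector kmers, int l) {
  int n = kmers.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int) s.size() != l) stop("k-mer %d has length %d, expected %d", i + 1, (int) s.size(), l);
    uint32_t code = 0; bool ok = true;
    for (int j = 0; j < l; ++j) {
      int b = base_code(s[j]);
      if (b < 0) { ok = false; break; }
      code = (code << 2) | (uint32_t) b;
    }
    out[i] = ok ? (int) code : NA_INTEGER;
  }
  return out;
}

static inline uint32_t revcomp_code(uint32_t c, int l) {
  uint32_t r = 0;
  for (int j = 0; j < l; ++j) { r = (r << 2) | (3u - (c & 3u)); c >>= 2; }
  return r;
}

// [[Rcpp::export]]
IntegerVector cpp_revcomp_codes(IntegerVector codes, int l) {
  IntegerVector out(codes.size());
  for (int i = 0; i < codes.size(); ++i)
    out[i] = (codes[i] == NA_INTEGER) ? NA_INTEGER : (int) revcomp_code((uint32_t) codes[i], l);
  return out;
}

static inline int hamming_codes(uint32_t a, uint32_t b) {
  uint64_t x = (uint64_t) (a ^ b);
  x = (x | (x >> 1)) & 0x5555555555555555ULL;
#if defined(__GNUC__) || defined(__clang__)
  return (int) __builtin_popcountll(x);
#else
  int n = 0; while (x) { n += (int) (x & 1); x >>= 1; } return n;
#endif
}

// ---- pairwise raw kernel (diagonal-band method; supports truncation) ---

// forward-strand raw kernel between two encoded sequences
static double raw_forward(const std::vector<int8_t> &a, const std::vector<int8_t> &b,
                          int l, const std::vector<long long> &lut) {
  int na = (int) a.size(), nb = (int) b.size();
  long long total = 0;
  for (int t = -(nb - 1); t <= na - 1; ++t) {
    int i0 = std::max(0, t);
    int j0 = i0 - t;
    int len = std::min(na - i0, nb - j0);
    if (len < l) continue;
    int run = 0;
    const int8_t *pa = a.data() + i0, *pb = b.data() + j0;
    for (int p = 0; p < len; ++p) {
      run += (pa[p] >= 0 && pa[p] == pb[p]);
      if (p >= l) run -= (pa[p - l] >= 0 && pa[p - l] == pb[p - l]);
      if (p >= l - 1) total += lut[l - run];
    }
  }
  return (double) total;
}

static std::vector<int8_t> revcomp_enc(const std::vector<int8_t> &a) {
  std::vector<int8_t> r(a.size());
  for (size_t i = 0; i < a.size(); ++i) {
    int8_t b = a[a.size() - 1 - i];
    r[i] = (b < 0) ? b : (int8_t) (3 - b);
  }
  return r;
}

// [[Rcpp::export]]
double cpp_gkm_kernel_pair(std::string x, std::string y, int l, int k, int d,
                           bool both_strands) {
  if ((int) x.size() < l || (int) y.size() < l)
    stop("sequences must be at least l = %d bases long", l);
  std::vector<long long> lut = contrib_lut(l, k, d);
  std::vector<int8_t> a = encode(x), b = encode(y);
  double v = raw_forward(a, b, l, lut);
  if (both_strands) v += raw_forward(a, revcomp_enc(b), l, lut);
  return v;
}

// raw self kernels for a vector of sequences
// [[Rcpp::export]]
NumericVector cpp_gkm_self(CharacterVector seqs, int l, int k, int d,
                           bool both_strands) {
  int n = seqs.size();
  NumericVector out(n);
  std::vector<long long> lut = contrib_lut(l, k, d);
  for (int i = 0; i < n; ++i) {
    std::vector<int8_t> a = encode(as<std::string>(seqs[i]));
    if ((int) a.size() < l) stop("sequence %d shorter than l", i + 1);
    double v = raw_forward(a, a, l, lut);
    if (both_strands) v += raw_forward(a, revcomp_enc(a), l, lut);
    out[i] = v;
  }
  return out;
}

// ---- pattern machinery (untruncated kernel = gapped k-mer dot product) -

// enumerate all k-subsets of {0..l-1} in lexicographic order, flattened
static std::vector<int> all_patterns(int l, int k) {
  std::vector<int> pats;
  std::vector<int> idx(k);
  for (int i = 0; i < k; ++i) idx[i] = i;
  while (true) {
    for (int i = 0; i < k; ++i) pats.push_back(idx[i]);
    int i = k - 1;
    while (i >= 0 && idx[i] == l - k + i) --i;
    if (i < 0) break;
    ++idx[i];
    for (int j = i + 1; j < k; ++j) idx[j] = idx[j - 1] + 1;
  }
  return pats;
}

// projection of an l-mer code onto the k positions of one pattern
static inline uint32_t project(uint32_t code, const int *pos, int l, int k) {
  uint32_t p = 0;
  for (int j = 0; j < k; ++j)
    p = (p << 2) | ((code >> (2 * (l - 1 - pos[j]))) & 3u);
  return p;
}

// collect valid l-mer codes of a sequence (forward plus, optionally, the
// reverse-complement strand) into bag; records owner index for each code
static void bag_codes(const std::string &s, int l, bool both_strands, int owner,
                      std::vector<uint32_t> &codes, std::vector<uint32_t> &owners) {
  std::vector<int8_t> a = encode(s);
  int n = (int) a.size();
  if (n < l) stop("sequence shorter than l");
  uint32_t code = 0, mask = (l == 16) ? 0xFFFFFFFFu : ((1u << (2 * l)) - 1u);
  int bad = -1;
  for (int i = 0; i < n; ++i) {
    int b = a[i];
    if (b < 0) { bad = i; b = 0; }
    code = ((code << 2) | (uint32_t) b) & mask;
    int w = i - l + 1;
    if (w >= 0 && bad < w) {
      codes.push_back(code);
      owners.push_back((uint32_t) owner);
      if (both_strands) {
        codes.push_back(revcomp_code(code, l));
        owners.push_back((uint32_t) owner);
      }
    }
  }
}

// Raw (untruncated) gkm Gram matrix over a set of sequences.  Entry (i,j)
// is the inner product of gapped k-mer count vectors; with both_strands
// the counts of each sequence and its reverse complement are summed and
// the resulting double-counting divided out, which equals
// K_f(x,y) + K_f(x, revcomp(y)).
// [[Rcpp::export]]
NumericMatrix cpp_gkm_gram(CharacterVector seqs, int l, int k, bool both_strands) {
  int n = seqs.size();
  std::vector<uint32_t> codes, owners;
  codes.reserve(1 << 16); owners.reserve(1 << 16);
  for (int i = 0; i < n; ++i)
    bag_codes(as<std::string>(seqs[i]), l, both_strands, i, codes, owners);
  size_t M = codes.size();

  std::vector<int> pats = all_patterns(l, k);
  int npat = (int) (pats.size() / k);
  size_t nbuck = (size_t) 1 << (2 * k);

  NumericMatrix G(n, n);
  double *g = REAL(G);

  std::vector<uint32_t> proj(M), cnt(nbuck + 1), sorted_owner(M);
  std::vector<uint32_t> run_owner; std::vector<double> run_cnt;
  run_owner.reserve(n); run_cnt.reserve(n);

  for (int P = 0; P < npat; ++P) {
    const int *pos = pats.data() + (size_t) P * k;
    for (size_t m = 0; m < M; ++m) proj[m] = project(codes[m], pos, l, k);
    std::fill(cnt.begin(), cnt.end(), 0u);
    for (size_t m = 0; m < M; ++m) ++cnt[proj[m] + 1];
    for (size_t b = 1; b <= nbuck; ++b) cnt[b] += cnt[b - 1];
    std::vector<uint32_t> fill(cnt.begin(), cnt.end() - 1);
    for (size_t m = 0; m < M; ++m) sorted_owner[fill[proj[m]]++] = owners[m];
    for (size_t b = 0; b < nbuck; ++b) {
      uint32_t s = cnt[b], e = cnt[b + 1];
      if (e - s < 1) continue;
      // entries are owner-sorted within a bucket (stable counting sort
      // over an owner-major input); compress to (owner, count)
      run_owner.clear(); run_cnt.clear();
      uint32_t cur = sorted_owner[s]; double c = 0;
      for (uint32_t m = s; m < e; ++m) {
        if (sorted_owner[m] != cur) {
          run_owner.push_back(cur); run_cnt.push_back(c);
          cur = sorted_owner[m]; c = 0;
        }
        c += 1.0;
      }
      run_owner.push_back(cur); run_cnt.push_back(c);
      size_t nr = run_owner.size();
      for (size_t a = 0; a < nr; ++a) {
        double ca = run_cnt[a];
        size_t col = (size_t) run_owner[a] * n;
        for (size_t bb = a; bb < nr; ++bb)
          g[col + run_owner[bb]] += ca * run_cnt[bb];
      }
    }
  }
  // mirror lower triangle to upper, halve for double-stranded counting
  double scale = both_strands ? 0.5 : 1.0;
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double v = g[(size_t) i * n + j] * scale;
      g[(size_t) i * n + j] = v;
      g[(size_t) j * n + i] = v;
    }
  return G;
}

// ---- support-vector score tables --------------------------------------

// Per-pattern lookup tables for fast decision-value computation:
// table[P][w] = sum over support sequences i and their l-mers v (both
// strands when both_strands) with projection w under pattern P of coef_i.
// Scoring a query's forward l-mers against the tables then yields
// sum_i coef_i * raw(s, sv_i) for the untruncated kernel.
// [[Rcpp::export]]
NumericVector cpp_build_score_table(CharacterVector seqs, NumericVector coefs,
                                    int l, int k, bool both_strands) {
  int n = seqs.size();
  if (coefs.size() != n) stop("coefs length must match seqs");
  std::vector<int> pats = all_patterns(l, k);
  int npat = (int) (pats.size() / k);
  size_t nbuck = (size_t) 1 << (2 * k);
  NumericVector table((R_xlen_t) npat * nbuck);
  double *T = REAL(table);
  std::vector<uint32_t> codes, owners;
  for (int i = 0; i < n; ++i)
    bag_codes(as<std::string>(seqs[i]), l, both_strands, i, codes, owners);
  size_t M = codes.size();
  for (int P = 0; P < npat; ++P) {
    const int *pos = pats.data() + (size_t) P * k;
    double *tp = T + (size_t) P * nbuck;
    for (size_t m = 0; m < M; ++m)
      tp[project(codes[m], pos, l, k)] += coefs[owners[m]];
  }
  table.attr("npat") = npat;
  return table;
}

// raw weighted score sum_i coef_i * raw(s, sv_i) for each query sequence
// [[Rcpp::export]]
NumericVector cpp_score_with_table(NumericVector table, CharacterVector seqs,
                                   int l, int k) {
  std::vector<int> pats = all_patterns(l, k);
  int npat = (int) (pats.size() / k);
  size_t nbuck = (size_t) 1 << (2 * k);
  const double *T = REAL(table);
  int n = seqs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::vector<uint32_t> codes, owners;
    bag_codes(as<std::string>(seqs[i]), l, false, 0, codes, owners);
    double s = 0;
    for (int P = 0; P < npat; ++P) {
      const int *pos = pats.data() + (size_t) P * k;
      const double *tp = T + (size_t) P * nbuck;
      for (size_t m = 0; m < codes.size(); ++m)
        s += tp[project(codes[m], pos, l, k)];
    }
    out[i] = s;
  }
  return out;
}

// normalized decision-value contribution for every l-mer u:
//   w(u) = (sum_i coef_i * raw(u, sv_i)) / sqrt(raw(u, u))
// where raw(u,u) = C(l,k) (+ C(l - h, k) for h = hamming(u, revcomp(u))
// when both_strands).  Output indexed by l-mer code (0 .. 4^l - 1).
// [[Rcpp::export]]
NumericVector cpp_weight_table(NumericVector table, int l, int k,
                               bool both_strands) {
  std::vector<int> pats = all_patterns(l, k);
  int npat = (int) (pats.size() / k);
  size_t nbuck = (size_t) 1 << (2 * k);
  const double *T = REAL(table);
  size_t N = (size_t) 1 << (2 * l);
  NumericVector out((R_xlen_t) N);
  double *o = REAL(out);
  std::vector<long long> lut = contrib_lut(l, k, l - k);
  double base_self = (double) nchoosek(l, k);
  for (size_t u = 0; u < N; ++u) {
    double s = 0;
    for (int P = 0; P < npat; ++P)
      s += T[(size_t) P * nbuck + project((uint32_t) u, pats.data() + (size_t) P * k, l, k)];
    double self = base_self;
    if (both_strands)
      self += (double) lut[hamming_codes((uint32_t) u, revcomp_code((uint32_t) u, l))];
    o[u] = s / std::sqrt(self);
  }
  return out;
}

// ---- deltaSVM saturation mutagenesis -----------------------------------

// VIP score for every position x alternate base of seq, summing
// weight(window_alt) - weight(window_ref) over the <= l windows covering
// the position.  Returns 4 x L matrix; the reference base's row holds 0,
// positions whose base is not ACGT hold NA in all rows.
// [[Rcpp::export]]
NumericMatrix cpp_saturation(std::string seq, NumericVector weights, int l) {
  int L = (int) seq.size();
  std::vector<int8_t> a = encode(seq);
  IntegerVector codes = cpp_lmer_codes(seq, l);
  int nw = codes.size();
  NumericMatrix vip(4, L);
  std::fill(vip.begin(), vip.end(), 0.0);
  const double *W = REAL(weights);
  for (int p = 0; p < L; ++p) {
    if (a[p] < 0) {
      for (int b = 0; b < 4; ++b) vip(b, p) = NA_REAL;
      continue;
    }
    int w0 = std::max(0, p - l + 1), w1 = std::min(p, nw - 1);
    for (int b = 0; b < 4; ++b) {
      if (b == a[p]) continue;
      double s = 0; bool any = false;
      for (int w = w0; w <= w1; ++w) {
        if (codes[w] == NA_INTEGER) continue;
        any = true;
        uint32_t ref = (uint32_t) codes[w];
        int shift = 2 * (l - 1 - (p - w));
        uint32_t alt = (ref & ~(3u << shift)) | ((uint32_t) b << shift);
        s += W[alt] - W[ref];
      }
      vip(b, p) = any ? s : NA_REAL;
    }
  }
  return vip;
}

// ---- PWM scanning ------------------------------------------------------

// Scan sequences with a log-odds matrix (4 x w, rows A,C,G,T), both
// strands; report hits with score >= threshold.  Offsets are 0-based.
// [[Rcpp::export]]
DataFrame cpp_pwm_scan(CharacterVector seqs, NumericMatrix pwm, double threshold) {
  int w = pwm.ncol();
  std::vector<int> hit_seq; std::vector<int> hit_off;
  std::vector<int> hit_strand; std::vector<double> hit_score;
  for (int i = 0; i < seqs.size(); ++i) {
    std::vector<int8_t> a = encode(as<std::string>(seqs[i]));
    int n = (int) a.size();
    for (int off = 0; off + w <= n; ++off) {
      bool ok = true; double sf = 0, sr = 0;
      for (int j = 0; j < w; ++j) {
        int8_t b = a[off + j];
        if (b < 0) { ok = false; break; }
        sf += pwm(b, j);
        sr += pwm(3 - a[off + w - 1 - j], j);
      }
      if (!ok) continue;
      if (sf >= threshold) {
        hit_seq.push_back(i + 1); hit_off.push_back(off);
        hit_strand.push_back(0); hit_score.push_back(sf);
      }
      if (sr >= threshold) {
        hit_seq.push_back(i + 1); hit_off.push_back(off);
        hit_strand.push_back(1); hit_score.push_back(sr);
      }
    }
  }
  int nh = (int) hit_seq.size();
  CharacterVector strand(nh);
  for (int i = 0; i < nh; ++i) strand[i] = hit_strand[i] ? "-" : "+";
  return DataFrame::create(_["seq_index"] = hit_seq, _["offset"] = hit_off,
                           _["strand"] = strand, _["score"] = hit_score,
                           _["stringsAsFactors"] = false);
}
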