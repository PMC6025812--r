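#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
#include <limits>

// Global (Needleman-Wunsch) alignment with linear gap penalty, computed in a
// diagonal band that is widened until the banded optimum provably equals the
// unrestricted optimum.  Any path that leaves a band of half-width b uses at
// least |n-m| + 2(b+1) gap characters, so its score is bounded by
//   min(n,m)*match - gap_pen*(|n-m| + 2(b+1));
// once the banded score reaches that bound the band is certified exact.  The
// starting band is seeded from the gapless mismatch count, whose score
// L - 2k is always achievable, so high-identity pairs finish in one pass.
// 'N' is a wildcard: it scores as a match against any base and counts as a
// match when identities are computed.

namespace {

const int MATCH = 1;
const int MISMATCH = -1;
const int GAP = -2; // per gap character
const int NEG_INF = std::numeric_limits<int>::min() / 4;

inline bool base_match(char a, char b) {
  return a == b || a == 'N' || b == 'N';
}

// reusable DP buffers (single-threaded R session)
static std::vector<int> S_buf;
static std::vector<signed char> T_buf;

struct BandSpec {
  int lo_off, hi_off, W;
};

// One banded DP pass filling S_buf/T_buf; returns the corner score or
// NEG_INF if the corner is outside the band.
int nw_banded_pass(const std::string& a, const std::string& b, int band,
                   BandSpec& bs) {
  const int n = (int)a.size(), m = (int)b.size();
  bs.lo_off = band + std::max(0, n - m); // allowed j - i >= -lo_off
  bs.hi_off = band + std::max(0, m - n); // allowed j - i <= hi_off
  bs.W = bs.lo_off + bs.hi_off + 1;
  const int lo_off = bs.lo_off, hi_off = bs.hi_off, W = bs.W;
  const size_t need = (size_t)(n + 1) * W;
  if (S_buf.size() < need) { S_buf.resize(need); T_buf.resize(need); }
  std::fill(S_buf.begin(), S_buf.begin() + need, NEG_INF);

  // row 0: leading gaps in a
  {
    const size_t base = (size_t)0 * W + lo_off;
    S_buf[base] = 0;
    T_buf[base] = 0;
    for (int j = 1; j <= std::min(m, hi_off); ++j) {
      S_buf[base + j] = GAP * j;
      T_buf[base + j] = 3;
    }
  }
  for (int i = 1; i <= n; ++i) {
    const int jlo = std::max(0, i - lo_off), jhi = std::min(m, i + hi_off);
    const size_t row = (size_t)i * W - i + lo_off;      // + j indexes cell
    const size_t prev = (size_t)(i - 1) * W - (i - 1) + lo_off;
    const char ai = a[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      int best = NEG_INF;
      signed char tb = 0;
      if (j >= 1) {
        const int d = S_buf[prev + j - 1];
        if (d > NEG_INF) {
          const int sc = d + (base_match(ai, b[j - 1]) ? MATCH : MISMATCH);
          if (sc > best) { best = sc; tb = 1; }
        }
      }
      if (j - (i - 1) <= hi_off) { // up neighbour in band: gap in b
        const int u = S_buf[prev + j];
        if (u > NEG_INF && u + GAP > best) { best = u + GAP; tb = 2; }
      }
      if (j >= 1 && j - 1 - i >= -lo_off) { // left neighbour: gap in a
        const int l = S_buf[row + j - 1];
        if (l > NEG_INF && l + GAP > best) { best = l + GAP; tb = 3; }
      }
      S_buf[row + j] = best;
      T_buf[row + j] = tb;
    }
  }
  const int off = m - n;
  if (off < -bs.lo_off || off > bs.hi_off) return NEG_INF;
  return S_buf[(size_t)n * W + (off + lo_off)];
}

// Run passes with growing band until the exactness certificate holds.
int nw_exact(const std::string& a, const std::string& b, BandSpec& bs) {
  const int n = (int)a.size(), m = (int)b.size();
  const int full = std::max(n, m);
  const int diff = std::abs(n - m);
  const int minlen = std::min(n, m);
  int k = diff;
  for (int i = 0; i < minlen; ++i)
    if (!base_match(a[i], b[i])) ++k;
  int band = std::min(full, std::max(8, k / 2 + 4));
  while (true) {
    const int score = nw_banded_pass(a, b, band, bs);
    if (score > NEG_INF) {
      const int out_bound = minlen * MATCH + GAP * (diff + 2 * (band + 1));
      if (score >= out_bound || band >= full) return score;
    }
    if (band >= full) return score;
    band = std::min(full, band * 2);
  }
}

struct AlnStats {
  int matches;        // matching columns (N wildcard)
  int cols;           // columns between first and last both-non-gap column
  int score;
};

// Traceback without building strings: counts matches and the columns
// between the first and last both-non-gap column (terminal gap trimming).
AlnStats traceback_stats(const std::string& a, const std::string& b,
                         const BandSpec& bs, int score) {
  const int n = (int)a.size(), m = (int)b.size();
  const int W = bs.W, lo_off = bs.lo_off;
  int i = n, j = m;
  int matches = 0, cols = 0, trail = 0, gap_run = 0;
  bool seen_pair = false; // a both-non-gap column seen (from the 3' side)
  while (i > 0 || j > 0) {
    const signed char t = T_buf[(size_t)i * W + (j - i + lo_off)];
    ++cols;
    if (t == 1) {
      if (!seen_pair) { seen_pair = true; }
      gap_run = 0;
      if (base_match(a[i - 1], b[j - 1])) ++matches;
      --i; --j;
    } else {
      if (!seen_pair) ++trail; // trailing gap run (traceback starts at 3')
      else ++gap_run;          // candidate leading run if it reaches the 5' end
      if (t == 2) --i; else --j;
    }
  }
  const int lead = seen_pair ? gap_run : 0;
  AlnStats st;
  st.matches = matches;
  st.cols = seen_pair ? (cols - lead - trail) : 0;
  st.score = score;
  return st;
}

double identity_pair(const std::string& a, const std::string& b) {
  if (a.empty() || b.empty()) return 0.0;
  BandSpec bs;
  const int score = nw_exact(a, b, bs);
  AlnStats st = traceback_stats(a, b, bs, score);
  if (st.cols <= 0) return 0.0;
  return (double)st.matches / (double)st.cols;
}

} // namespace

// [[Rcpp::export(name = ".nw_align_cpp")]]
Rcpp::List nw_align_cpp(std::string a, std::string b) {
  if (a.empty() || b.empty()) {
    return Rcpp::List::create(
        Rcpp::Named("a") = a.empty() ? std::string(b.size(), '-') : a,
        Rcpp::Named("b") = b.empty() ? std::string(a.size(), '-') : b,
        Rcpp::Named("score") = GAP * (int)(a.size() + b.size()));
  }
  BandSpec bs;
  const int score = nw_exact(a, b, bs);
  std::string ra, rb;
  ra.reserve(a.size() + b.size());
  rb.reserve(a.size() + b.size());
  int i = (int)a.size(), j = (int)b.size();
  while (i > 0 || j > 0) {
    const signed char t = T_buf[(size_t)i * bs.W + (j - i + bs.lo_off)];
    if (t == 1) { ra.push_back(a[--i]); rb.push_back(b[--j]); }
    else if (t == 2) { ra.push_back(a[--i]); rb.push_back('-'); }
    else { ra.push_back('-'); rb.push_back(b[--j]); }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return Rcpp::List::create(Rcpp::Named("a") = ra, Rcpp::Named("b") = rb,
                            Rcpp::Named("score") = score);
}

// [[Rcpp::export(name = ".nw_identity_cpp")]]
double nw_identity_cpp(std::string a, std::string b) {
  return identity_pair(a, b);
}

// [[Rcpp::export(name = ".nw_identity_many_cpp")]]
Rcpp::NumericVector nw_identity_many_cpp(std::string query,
                                         Rcpp::CharacterVector refs) {
  const int k = refs.size();
  Rcpp::NumericVector out(k);
  for (int i = 0; i < k; ++i) {
    out[i] = identity_pair(query, Rcpp::as<std::string>(refs[i]));
  }
  return out;
}

// --- word-count prefilter -------------------------------------------------
// For identity thresholds near 1 a candidate pair must share almost all of
// its 8-mers: an alignment with d non-match columns (substitutions + gap
// characters) destroys at most 8 of the shorter sequence's 8-mers per
// column, and trimmed identity >= t forces d <= minlen*(1-t)/t interior
// differences.  With slack for the length difference and terminal gap
// staircases, a pair sharing fewer 8-mers than
//   (minlen - 7) - 8*(floor(minlen*(1-t)/t) + diff + 10)
// provably falls below t, so the DP can be skipped and 0 returned (such a
// ref can never be a join candidate).  Sequences containing N or '-' skip
// the prefilter because N is a wildcard the word count cannot see.

bool kmer_codes(const std::string& s, std::vector<int>& out) {
  const int w = 8;
  const int n = (int)s.size();
  out.clear();
  if (n < w) return false;
  out.reserve(n - w + 1);
  int code = 0, valid = 0;
  for (int i = 0; i < n; ++i) {
    int v;
    switch (s[i]) {
      case 'A': v = 0; break;
      case 'C': v = 1; break;
      case 'G': v = 2; break;
      case 'T': v = 3; break;
      default: out.clear(); return false; // N or gap: skip the prefilter
    }
    code = ((code << 2) | v) & 0xFFFF;
    if (++valid >= w) out.push_back(code);
  }
  std::sort(out.begin(), out.end());
  return true;
}

int shared_kmers(const std::vector<int>& a, const std::vector<int>& b) {
  int shared = 0;
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) ++i;
    else if (b[j] < a[i]) ++j;
    else { ++shared; ++i; ++j; }
  }
  return shared;
}

// [[Rcpp::export(name = ".nw_identity_filtered_cpp")]]
Rcpp::NumericVector nw_identity_filtered_cpp(std::string query,
                                             Rcpp::CharacterVector refs,
                                             double threshold) {
  const int k = refs.size();
  Rcpp::NumericVector out(k);
  std::vector<int> qk, rk;
  const bool q_ok = threshold > 0.9 && kmer_codes(query, qk);
  for (int i = 0; i < k; ++i) {
    std::string r = Rcpp::as<std::string>(refs[i]);
    if (q_ok && kmer_codes(r, rk)) {
      const int minlen = (int)std::min(query.size(), r.size());
      const int diff = (int)std::abs((long)query.size() - (long)r.size());
      const int d_max = (int)(minlen * (1.0 - threshold) / threshold) + diff + 4;
      const int required = (minlen - 7) - 8 * d_max;
      if (required > 0 && shared_kmers(qk, rk) < required) {
        out[i] = 0.0; // provably below threshold
        continue;
      }
    }
    out[i] = identity_pair(query, r);
  }
  return out;
}

// Whole greedy scan in one call: records arrive pre-sorted (size desc,
// ties lexicographic); each joins the best-identity centroid reaching the
// threshold (identity ties keep the earliest-founded centroid) or founds a
// new one.  Returns, per record, the 1-based index of the centroid's
// founding record, or the record's own index if it founds.  Centroid k-mer
// profiles are cached across the scan.
// [[Rcpp::export(name = ".greedy_assign_cpp")]]
Rcpp::IntegerVector greedy_assign_cpp(Rcpp::CharacterVector seqs,
                                      double threshold) {
  const int n = seqs.size();
  Rcpp::IntegerVector assign(n);
  std::vector<std::string> cen_seq;
  std::vector<int> cen_rec;                 // founding record index (1-based)
  std::vector<std::vector<int>> cen_kmer;   // empty vector = not indexable
  std::vector<int> qk;
  for (int i = 0; i < n; ++i) {
    std::string s = Rcpp::as<std::string>(seqs[i]);
    const bool q_ok = threshold > 0.9 && kmer_codes(s, qk);
    double best_id = -1.0;
    int best = -1;
    for (size_t c = 0; c < cen_seq.size(); ++c) {
      const std::string& r = cen_seq[c];
      if (q_ok && !cen_kmer[c].empty()) {
        const int minlen = (int)std::min(s.size(), r.size());
        const int diff = (int)std::abs((long)s.size() - (long)r.size());
        const int d_max = (int)(minlen * (1.0 - threshold) / threshold) + diff + 4;
        const int required = (minlen - 7) - 8 * d_max;
        if (required > 0 && shared_kmers(qk, cen_kmer[c]) < required) continue;
      }
      const double id = identity_pair(s, r);
      if (id >= threshold && id > best_id) {
        best_id = id;
        best = (int)c;
      }
    }
    if (best >= 0) {
      assign[i] = cen_rec[best];
    } else {
      assign[i] = i + 1;
      cen_rec.push_back(i + 1);
      cen_kmer.emplace_back();
      kmer_codes(s, cen_kmer.back());
      cen_seq.push_back(std::move(s));
    }
  }
  return assign;
}

// Per-position match profile of 'a' against 'b' under the global alignment:
// profile[i] = 1 iff a's i-th base is aligned to a matching (or N) base of b.
// [[Rcpp::export(name = ".match_profile_cpp")]]
Rcpp::IntegerVector match_profile_cpp(std::string a, std::string b) {
  Rcpp::IntegerVector prof((int)a.size());
  if (a.empty() || b.empty()) return prof;
  BandSpec bs;
  nw_exact(a, b, bs);
  int i = (int)a.size(), j = (int)b.size();
  while (i > 0 || j > 0) {
    const signed char t = T_buf[(size_t)i * bs.W + (j - i + bs.lo_off)];
    if (t == 1) {
      prof[i - 1] = base_match(a[i - 1], b[j - 1]) ? 1 : 0;
      --i; --j;
    } else if (t == 2) {
      prof[i - 1] = 0;
      --i;
    } else {
      --j;
    }
  }
  return prof;
}

// Scan candidate 3'(a)/5'(b) overlaps of length >= min_overlap; mismatches
// count positions where both bases are non-N and differ.  Best = lowest
// mismatch fraction, ties broken toward the longest overlap.
// [[Rcpp::export(name = ".overlap_scan_cpp")]]
Rcpp::List overlap_scan_cpp(std::string a, std::string b, int min_overlap) {
  const int n = (int)a.size(), m = (int)b.size();
  const int omax = std::min(n, m);
  int best_o = 0;
  double best_frac = 2.0;
  for (int o = min_overlap; o <= omax; ++o) {
    int mism = 0;
    for (int k = 0; k < o; ++k) {
      char ca = a[n - o + k], cb = b[k];
      if (ca != 'N' && cb != 'N' && ca != cb) ++mism;
    }
    double frac = (double)mism / (double)o;
    if (frac < best_frac || (frac == best_frac && o > best_o)) {
      best_frac = frac;
      best_o = o;
    }
  }
  return Rcpp::List::create(Rcpp::Named("overlap") = best_o,
                            Rcpp::Named("mismatch_frac") =
                                best_o ? best_frac : NA_REAL);
}
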