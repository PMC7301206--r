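#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Suffix array construction by induced sorting (SA-IS), linear in the text
// length.  The text is an integer sequence over 0..K-1 whose last symbol is
// a unique 0 terminator.

static void get_buckets(const std::vector<int>& s, std::vector<int>& bkt,
                        int K, bool end) {
  std::fill(bkt.begin(), bkt.end(), 0);
  for (size_t i = 0; i < s.size(); ++i) bkt[s[i]]++;
  int sum = 0;
  for (int c = 0; c < K; ++c) {
    sum += bkt[c];
    bkt[c] = end ? sum : sum - bkt[c];
  }
}

static void induce_l(const std::vector<int>& s, std::vector<int>& sa,
                     std::vector<int>& bkt, const std::vector<bool>& t,
                     int K) {
  get_buckets(s, bkt, K, false);
  const int n = (int)s.size();
  for (int i = 0; i < n; ++i) {
    int j = sa[i] - 1;
    if (sa[i] > 0 && !t[j]) sa[bkt[s[j]]++] = j;
  }
}

static void induce_s(const std::vector<int>& s, std::vector<int>& sa,
                     std::vector<int>& bkt, const std::vector<bool>& t,
                     int K) {
  get_buckets(s, bkt, K, true);
  const int n = (int)s.size();
  for (int i = n - 1; i >= 0; --i) {
    int j = sa[i] - 1;
    if (sa[i] > 0 && t[j]) sa[--bkt[s[j]]] = j;
  }
}

static void sais(const std::vector<int>& s, std::vector<int>& sa, int K) {
  const int n = (int)s.size();
  std::vector<bool> t(n);
  t[n - 1] = true;  // the terminator is S-type
  for (int i = n - 2; i >= 0; --i)
    t[i] = (s[i] < s[i + 1]) || (s[i] == s[i + 1] && t[i + 1]);
  auto is_lms = [&](int i) { return i > 0 && t[i] && !t[i - 1]; };

  std::vector<int> bkt(K);
  std::fill(sa.begin(), sa.end(), -1);
  get_buckets(s, bkt, K, true);
  for (int i = 1; i < n; ++i)
    if (is_lms(i)) sa[--bkt[s[i]]] = i;
  induce_l(s, sa, bkt, t, K);
  induce_s(s, sa, bkt, t, K);

  // Compact the (now sorted) LMS substrings into the front of sa.
  int n1 = 0;
  for (int i = 0; i < n; ++i)
    if (is_lms(sa[i])) sa[n1++] = sa[i];
  std::fill(sa.begin() + n1, sa.end(), -1);

  // Name LMS substrings by rank; equal substrings share a name.
  int name = 0, prev = -1;
  for (int i = 0; i < n1; ++i) {
    int pos = sa[i];
    bool diff = false;
    if (prev < 0) {
      diff = true;
    } else {
      for (int d = 0;; ++d) {
        if (s[pos + d] != s[prev + d] || t[pos + d] != t[prev + d]) {
          diff = true;
          break;
        }
        if (d > 0 && (is_lms(pos + d) || is_lms(prev + d))) break;
      }
    }
    if (diff) {
      ++name;
      prev = pos;
    }
    sa[n1 + pos / 2] = name - 1;
  }

  std::vector<int> s1;
  s1.reserve(n1);
  for (int i = n1; i < n; ++i)
    if (sa[i] >= 0) s1.push_back(sa[i]);

  std::vector<int> sa1(n1);
  if (name < n1) {
    sais(s1, sa1, name);
  } else {
    for (int i = 0; i < n1; ++i) sa1[s1[i]] = i;
  }

  std::vector<int> lms;
  lms.reserve(n1);
  for (int i = 1; i < n; ++i)
    if (is_lms(i)) lms.push_back(i);

  std::fill(sa.begin(), sa.end(), -1);
  get_buckets(s, bkt, K, true);
  for (int i = n1 - 1; i >= 0; --i) {
    int j = lms[sa1[i]];
    sa[--bkt[s[j]]] = j;
  }
  induce_l(s, sa, bkt, t, K);
  induce_s(s, sa, bkt, t, K);
}

// Build the suffix array of an integer text.  `codes` must end with a
// unique 0 terminator and contain values in 0..alphabet_size-1.
// Returns the 0-based suffix array of the full text (terminator included).
// [[Rcpp::export(name = ".sais_build")]]
IntegerVector sais_build(IntegerVector codes, int alphabet_size) {
  const int n = codes.size();
  if (n == 0) stop("empty text");
  if (codes[n - 1] != 0) stop("text must end with the 0 terminator");
  std::vector<int> s(codes.begin(), codes.end());
  for (int i = 0; i < n - 1; ++i)
    if (s[i] <= 0 || s[i] >= alphabet_size)
      stop("text symbol out of range");
  std::vector<int> sa(n);
  if (n == 1) {
    sa[0] = 0;
  } else {
    sais(s, sa, alphabet_size);
  }
  return IntegerVector(sa.begin(), sa.end());
}

// Bounded-Hamming-distance search by descent over suffix-array intervals.
//
// At depth k the interval [lo, hi) holds every suffix whose first k symbols
// spell the path chosen so far; within it, symbol k is non-decreasing, so
// each child interval is found with two binary searches (O(log n) each).
// Every child symbol that keeps the mismatch budget non-negative is
// explored: a symbol equal to pattern[k] costs 0, any other text symbol
// (including the 'N' code, which never equals a pattern symbol) costs 1,
// and sentinel/terminator symbols (codes < min base code) are never
// descended into, so no reported match spans a segment boundary.  Each
// matching text window is reached by exactly one path, whose accumulated
// cost is its true (minimal) Hamming distance.
//
// [[Rcpp::export(name = ".sa_search")]]
List sa_search(IntegerVector codes, IntegerVector sa, IntegerVector pattern,
               int max_mm, IntegerVector child_codes) {
  const int n = codes.size();
  const int w = pattern.size();
  if (w < 1) stop("empty pattern");
  if (max_mm < 0) stop("negative mismatch budget");

  std::vector<int> pos_out;
  std::vector<int> mm_out;

  struct Frame {
    int lo, hi, depth, mm;
  };
  std::vector<Frame> stack;
  stack.push_back({0, n, 0, 0});

  while (!stack.empty()) {
    Frame f = stack.back();
    stack.pop_back();
    if (f.depth == w) {
      for (int i = f.lo; i < f.hi; ++i) {
        pos_out.push_back(sa[i]);
        mm_out.push_back(f.mm);
      }
      continue;
    }
    const int k = f.depth;
    for (int ci = 0; ci < child_codes.size(); ++ci) {
      const int c = child_codes[ci];
      const int cost = (c == pattern[k]) ? 0 : 1;
      if (f.mm + cost > max_mm) continue;
      // lower bound: first i in [lo, hi) with codes[sa[i]+k] >= c
      int lo = f.lo, hi = f.hi;
      while (lo < hi) {
        int mid = lo + (hi - lo) / 2;
        if (codes[sa[mid] + k] < c) lo = mid + 1; else hi = mid;
      }
      const int lo2 = lo;
      // upper bound: first i with codes[sa[i]+k] > c
      hi = f.hi;
      while (lo < hi) {
        int mid = lo + (hi - lo) / 2;
        if (codes[sa[mid] + k] <= c) lo = mid + 1; else hi = mid;
      }
      if (lo2 < lo)
        stack.push_back({lo2, lo, k + 1, f.mm + cost});
    }
  }

  return List::create(_["pos"] = IntegerVector(pos_out.begin(), pos_out.end()),
                      _["mm"] = IntegerVector(mm_out.begin(), mm_out.end()));
}
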