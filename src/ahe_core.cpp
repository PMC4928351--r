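#include <Rcpp.h>
using namespace Rcpp;

// Match counting treats any pair of identical A/C/G/T characters as a match;
// N (or any other character) never matches anything, including itself.
static inline bool base_match(char a, char b) {
  if (a != b) return false;
  return a == 'A' || a == 'C' || a == 'G' || a == 'T';
}

//' Per-overlap match counts between a read suffix and a mate prefix.
//'
//' For overlap degree o (1..min(n1,n2)) counts matching bases between the
//' last o bases of `r1` and the first o bases of `r2rc` (the mate already
//' reverse-complemented into r1's orientation).
//'
//' @param r1,r2rc upper-case DNA strings.
//' @return integer vector m where m[o] = matches at overlap o.
//' @keywords internal
// [[Rcpp::export]]
IntegerVector overlap_match_counts(std::string r1, std::string r2rc) {
  int n1 = r1.size(), n2 = r2rc.size();
  int omax = std::min(n1, n2);
  IntegerVector out(omax);
  for (int o = 1; o <= omax; ++o) {
    int m = 0;
    const char* a = r1.data() + (n1 - o);
    for (int i = 0; i < o; ++i)
      if (base_match(a[i], r2rc[i])) ++m;
    out[o - 1] = m;
  }
  return out;
}

//' Best gap-free placement of a read against a reference.
//'
//' Considers every gap-free offset of the read against the reference and, for
//' each, the maximum number of matches within any `window` consecutive
//' aligned bases (the whole overlap when shorter than `window`). Returns the
//' best score and its offset; ties go to the smallest offset. Offset d means
//' read base i (1-based) pairs with reference base d + i, so d = 0 aligns the
//' read start with the reference start and negative d hangs off the left end.
//'
//' @return integer vector c(best_window_matches, best_offset).
//' @keywords internal
// [[Rcpp::export]]
IntegerVector best_gapfree_placement(std::string read, std::string ref,
                                     int window = 100) {
  int lr = read.size(), lf = ref.size();
  int best = -1, best_d = 0;
  std::vector<int> ps; // prefix sums of the match indicator
  for (int d = -(lr - 1); d <= lf - 1; ++d) {
    int i0 = std::max(0, -d);          // first read index (0-based) aligned
    int i1 = std::min(lr, lf - d);     // one past last aligned read index
    int len = i1 - i0;
    if (len <= 0) continue;
    ps.assign(len + 1, 0);
    for (int i = 0; i < len; ++i) {
      int ri = i0 + i;
      ps[i + 1] = ps[i] + (base_match(read[ri], ref[ri + d]) ? 1 : 0);
    }
    int w = std::min(window, len), sc = 0;
    for (int s = 0; s + w <= len; ++s)
      sc = std::max(sc, ps[s + w] - ps[s]);
    if (sc > best) { best = sc; best_d = d; }
  }
  IntegerVector out(2);
  out[0] = best; out[1] = best_d;
  return out;
}

//' Scan a read with a library of spaced k-mers.
//'
//' Each library entry is the k sampled characters of a spaced k-mer (a
//' string of length k); `pattern` gives the 0-based offsets of the sampled
//' positions within the window (span = max(pattern) + 1). For every read
//' start position and every k-mer the number of positional matches is
//' counted; hits with at least `min_hits` matches are reported.
//'
//' @return integer matrix with columns kmer (1-based index into `kmers`),
//'   start (1-based read position of the window) and matches.
//' @keywords internal
// [[Rcpp::export]]
IntegerMatrix spaced_kmer_scan(std::string read, CharacterVector kmers,
                               IntegerVector pattern, int min_hits = 17) {
  int k = pattern.size();
  int span = 0;
  for (int j = 0; j < k; ++j) span = std::max(span, pattern[j] + 1);
  int lr = read.size();
  std::vector<int> hit_k, hit_s, hit_m;
  int max_miss = k - min_hits;
  for (int ki = 0; ki < kmers.size(); ++ki) {
    const char* km = CHAR(STRING_ELT(kmers, ki));
    for (int s = 0; s + span <= lr; ++s) {
      int miss = 0;
      for (int j = 0; j < k; ++j) {
        if (!base_match(read[s + pattern[j]], km[j])) {
          if (++miss > max_miss) break;
        }
      }
      if (miss <= max_miss) {
        hit_k.push_back(ki + 1);
        hit_s.push_back(s + 1);
        hit_m.push_back(k - miss);
      }
    }
  }
  IntegerMatrix out(hit_k.size(), 3);
  for (size_t i = 0; i < hit_k.size(); ++i) {
    out(i, 0) = hit_k[i]; out(i, 1) = hit_s[i]; out(i, 2) = hit_m[i];
  }
  colnames(out) = CharacterVector::create("kmer", "start", "matches");
  return out;
}
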