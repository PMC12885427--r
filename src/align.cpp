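#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <string>
using namespace Rcpp;

// Bases compare as equal only when identical and not 'N': an N never counts
// as a match anywhere in the package.
static inline bool base_match(char a, char b) {
  return a == b && a != 'N' && a != 'n';
}

// ---------------------------------------------------------------------------
// Semi-global (pattern-global, text-local) approximate matching, full DP.
// Minimises edit distance; ties broken by leftmost start, then shortest span.
// Returns IntegerVector(start, end, edits) 0-based half-open, or empty if the
// minimum exceeds max_edits.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_approx_match(std::string pattern, std::string text,
                               int max_edits) {
  const int m = (int)pattern.size(), n = (int)text.size();
  if (m == 0 || n == 0) return IntegerVector(0);
  // dp rows over pattern, columns over text; row 0 free start
  std::vector<int> prevD(n + 1), curD(n + 1), prevS(n + 1), curS(n + 1);
  for (int j = 0; j <= n; ++j) { prevD[j] = 0; prevS[j] = j; }
  for (int i = 1; i <= m; ++i) {
    curD[0] = i; curS[0] = 0;
    const char pc = pattern[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int sub = prevD[j - 1] + (base_match(pc, text[j - 1]) ? 0 : 1);
      const int del = prevD[j] + 1;   // consume pattern char
      const int ins = curD[j - 1] + 1; // consume text char
      int d = sub, s = prevS[j - 1];
      if (del < d || (del == d && prevS[j] < s)) { d = del; s = prevS[j]; }
      if (ins < d || (ins == d && curS[j - 1] < s)) { d = ins; s = curS[j - 1]; }
      curD[j] = d; curS[j] = s;
    }
    std::swap(prevD, curD); std::swap(prevS, curS);
  }
  int bd = prevD[0], bs = prevS[0], be = 0;
  for (int j = 1; j <= n; ++j) {
    if (prevD[j] < bd ||
        (prevD[j] == bd && (prevS[j] < bs || (prevS[j] == bs && j < be)))) {
      bd = prevD[j]; bs = prevS[j]; be = j;
    }
  }
  if (bd > max_edits) return IntegerVector(0);
  return IntegerVector::create(bs, be, bd);
}

// Vectorised over texts; row of -1s where no hit within max_edits.
// [[Rcpp::export]]
IntegerMatrix cpp_approx_match_batch(std::string pattern, CharacterVector texts,
                                     int max_edits) {
  IntegerMatrix out(texts.size(), 3);
  for (R_xlen_t k = 0; k < texts.size(); ++k) {
    if (texts[k] == NA_STRING) { out(k, 0) = out(k, 1) = out(k, 2) = -1; continue; }
    IntegerVector h = cpp_approx_match(pattern, as<std::string>(texts[k]), max_edits);
    if (h.size() == 3) { out(k, 0) = h[0]; out(k, 1) = h[1]; out(k, 2) = h[2]; }
    else { out(k, 0) = out(k, 1) = out(k, 2) = -1; }
  }
  colnames(out) = CharacterVector::create("start", "end", "edits");
  return out;
}

// ---------------------------------------------------------------------------
// Blocked Myers bit-parallel semi-global matcher (edits + end position only).
// Used on long V-gene patterns where the full DP would dominate runtime.
// ---------------------------------------------------------------------------

#define MYERS_MAX_BLOCKS 16  // patterns up to 1024 residues

struct MyersPattern {
  int m, b;                       // pattern length, number of 64-bit blocks
  std::vector<uint64_t> peq;      // 256 * b occurrence masks, [char][block]
  MyersPattern(const std::string &p) {
    m = (int)p.size();
    b = (m + 63) / 64;
    if (b > MYERS_MAX_BLOCKS) stop("pattern longer than 1024 residues");
    peq.assign((size_t)256 * b, 0);
    for (int i = 0; i < m; ++i) {
      unsigned char c = (unsigned char)p[i];
      if (c == 'N' || c == 'n') continue;
      peq[(size_t)c * b + i / 64] |= (uint64_t)1 << (i % 64);
    }
  }
};

// best (min-edit, leftmost-end) semi-global occurrence; returns {edits, end}
static void myers_search(const MyersPattern &P, const char *text, int n,
                         int &best_edits, int &best_end) {
  const int b = P.b, m = P.m;
  const int top = (m - 1) % 64;
  uint64_t VP[MYERS_MAX_BLOCKS], VN[MYERS_MAX_BLOCKS];
  for (int v = 0; v < b; ++v) { VP[v] = ~(uint64_t)0; VN[v] = 0; }
  int score = m;
  best_edits = m + n + 1; best_end = -1;
  for (int j = 0; j < n; ++j) {
    const uint64_t *eq = &P.peq[(size_t)(unsigned char)text[j] * b];
    uint64_t addc = 0, hpc = 0, hnc = 0;  // carries: addition, HP shift, HN shift
    for (int v = 0; v < b; ++v) {
      const uint64_t X = eq[v] | VN[v];
      const uint64_t XV = X & VP[v];
      unsigned __int128 sum = (unsigned __int128)XV + VP[v] + addc;
      addc = (uint64_t)(sum >> 64);
      const uint64_t D0 = ((uint64_t)sum ^ VP[v]) | X;
      const uint64_t HN = VP[v] & D0;
      const uint64_t HP = VN[v] | ~(D0 | VP[v]);
      if (v == b - 1) {
        score += (int)((HP >> top) & 1);
        score -= (int)((HN >> top) & 1);
      }
      const uint64_t X2 = (HP << 1) | hpc;
      const uint64_t HN2 = (HN << 1) | hnc;
      hpc = HP >> 63; hnc = HN >> 63;
      VN[v] = X2 & D0;
      VP[v] = HN2 | ~(X2 | D0);
    }
    if (score < best_edits) { best_edits = score; best_end = j + 1; }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_myers_batch(std::string pattern, CharacterVector texts) {
  MyersPattern P(pattern);
  IntegerMatrix out(texts.size(), 2);
  for (R_xlen_t k = 0; k < texts.size(); ++k) {
    const char *t = CHAR(STRING_ELT(texts, k));
    int e, pos; myers_search(P, t, (int)strlen(t), e, pos);
    out(k, 0) = e; out(k, 1) = pos;
  }
  colnames(out) = CharacterVector::create("edits", "end");
  return out;
}

// Recover the start of a semi-global hit ending at `end` (0-based half-open)
// by a reverse pass; returns {start, edits}.
// [[Rcpp::export]]
IntegerVector cpp_myers_start(std::string pattern, std::string text, int end) {
  std::string rp(pattern.rbegin(), pattern.rend());
  std::string rt = text.substr(0, (size_t)end);
  std::reverse(rt.begin(), rt.end());
  MyersPattern P(rp);
  int e, pos; myers_search(P, rt.data(), (int)rt.size(), e, pos);
  if (pos < 0) return IntegerVector(0);
  return IntegerVector::create(end - pos, e);
}

// Batch start recovery for one pattern over many (text, end) hits.
// [[Rcpp::export]]
IntegerVector cpp_myers_start_batch(std::string pattern,
                                    CharacterVector texts,
                                    IntegerVector ends) {
  std::string rp(pattern.rbegin(), pattern.rend());
  MyersPattern P(rp);
  IntegerVector starts(texts.size());
  for (R_xlen_t k = 0; k < texts.size(); ++k) {
    std::string rt = as<std::string>(texts[k]).substr(0, (size_t)ends[k]);
    std::reverse(rt.begin(), rt.end());
    int e, pos; myers_search(P, rt.data(), (int)rt.size(), e, pos);
    starts[k] = pos < 0 ? 0 : ends[k] - pos;
  }
  return starts;
}

// Fast semi-global anchor search for short patterns: forward Myers pass for
// the minimal-edit (leftmost) end, reverse pass for the matching start.
// Returns (start, end, edits) rows, -1s where min edits > max_edits.
// [[Rcpp::export]]
IntegerMatrix cpp_anchor_batch(std::string pattern, CharacterVector texts,
                               int max_edits) {
  MyersPattern P(pattern);
  std::string rp(pattern.rbegin(), pattern.rend());
  MyersPattern PR(rp);
  IntegerMatrix out(texts.size(), 3);
  for (R_xlen_t k = 0; k < texts.size(); ++k) {
    out(k, 0) = out(k, 1) = out(k, 2) = -1;
    if (texts[k] == NA_STRING) continue;
    const char *t = CHAR(STRING_ELT(texts, k));
    const int n = (int)strlen(t);
    if (n == 0) continue;
    int e, pos; myers_search(P, t, n, e, pos);
    if (e > max_edits || pos < 0) continue;
    std::string rt(t, t + pos);
    std::reverse(rt.begin(), rt.end());
    int e2, pos2; myers_search(PR, rt.data(), (int)rt.size(), e2, pos2);
    out(k, 0) = pos2 < 0 ? 0 : pos - pos2;
    out(k, 1) = pos;
    out(k, 2) = e;
  }
  colnames(out) = CharacterVector::create("start", "end", "edits");
  return out;
}

// ---------------------------------------------------------------------------
// Reverse complement (N-preserving)
// ---------------------------------------------------------------------------

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp(c);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}

// ---------------------------------------------------------------------------
// Overlap-based read-pair merging. r2 is given on the sequencing (reverse)
// strand and is reverse-complemented internally. Candidate overlaps o in
// [min_overlap, min(max_overlap, len1, len2)] are scored by mismatch count
// between the tail of r1 and the head of revcomp(r2); the overlap minimising
// mismatch density wins, ties going to the longer overlap. Mismatches within
// the chosen overlap are resolved by the higher-Phred base.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector r1, CharacterVector q1,
                     CharacterVector r2, CharacterVector q2,
                     int min_overlap, int max_overlap,
                     double max_mismatch_density) {
  const R_xlen_t n = r1.size();
  CharacterVector mseq(n), mqual(n), status(n);
  IntegerVector ovl(n), mm(n);
  for (R_xlen_t k = 0; k < n; ++k) {
    std::string s1 = as<std::string>(r1[k]);
    std::string s2 = revcomp(as<std::string>(r2[k]));
    std::string a1 = as<std::string>(q1[k]);
    std::string a2 = as<std::string>(q2[k]);
    std::reverse(a2.begin(), a2.end());
    const int L1 = (int)s1.size(), L2 = (int)s2.size();
    if (L1 == 0 || L2 == 0) stop("empty read in pair %d", (int)(k + 1));
    const int omax = std::min(max_overlap, std::min(L1, L2));
    if (omax < min_overlap) {
      status[k] = "too_short"; mseq[k] = NA_STRING; mqual[k] = NA_STRING;
      ovl[k] = 0; mm[k] = 0; continue;
    }
    int best_o = -1, best_mm = 0;
    double best_d = 1e9;
    for (int o = min_overlap; o <= omax; ++o) {
      const int budget = (int)(max_mismatch_density * o);
      const char *t1 = s1.data() + (L1 - o);
      const char *t2 = s2.data();
      int cnt = 0;
      for (int i = 0; i < o; ++i) {
        if (!base_match(t1[i], t2[i]) && ++cnt > budget) break;
      }
      const double d = (double)cnt / o;
      if (d < best_d || (d == best_d && o > best_o)) {
        best_d = d; best_o = o; best_mm = cnt;
      }
    }
    if (best_o < 0 || best_d > max_mismatch_density) {
      status[k] = "no_overlap"; mseq[k] = NA_STRING; mqual[k] = NA_STRING;
      ovl[k] = 0; mm[k] = 0; continue;
    }
    // assemble: r1 head + resolved overlap + r2 tail
    std::string ms = s1.substr(0, L1 - best_o);
    std::string mq = a1.substr(0, L1 - best_o);
    for (int i = 0; i < best_o; ++i) {
      const char c1 = s1[L1 - best_o + i], c2 = s2[i];
      const char p1 = a1[L1 - best_o + i], p2 = a2[i];
      if (base_match(c1, c2)) { ms += c1; mq += std::max(p1, p2); }
      else if (p2 > p1)       { ms += c2; mq += p2; }
      else                    { ms += c1; mq += p1; }
    }
    ms += s2.substr(best_o); mq += a2.substr(best_o);
    status[k] = "merged"; mseq[k] = ms; mqual[k] = mq;
    ovl[k] = best_o; mm[k] = best_mm;
  }
  return List::create(_["merged_seq"] = mseq, _["merged_qual"] = mqual,
                      _["overlap_len"] = ovl, _["mismatches"] = mm,
                      _["status"] = status);
}

// ---------------------------------------------------------------------------
// 3' adapter trimming: best occurrence of the adapter (full, or a prefix of
// at least min_match bases reaching the read's 3' end) at mismatch fraction
// <= error_rate. Best = lowest mismatch fraction, ties to the longer match
// (leftmost start). Returns trimmed lengths.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_trim_adapter(CharacterVector seqs, std::string adapter,
                               int min_match, double error_rate) {
  const int alen = (int)adapter.size();
  IntegerVector keep(seqs.size());
  for (R_xlen_t k = 0; k < seqs.size(); ++k) {
    const std::string s = as<std::string>(seqs[k]);
    const int L = (int)s.size();
    int best_start = L;
    double best_d = 1e9;
    for (int st = 0; st <= L - min_match; ++st) {
      const int ov = std::min(alen, L - st);
      if (ov < min_match) break;
      // a full internal occurrence must be the whole adapter; a partial
      // occurrence must run to the read end (3' read-through geometry)
      const int budget = (int)(error_rate * ov);
      int cnt = 0;
      for (int i = 0; i < ov; ++i) {
        if (!base_match(s[st + i], adapter[i]) && ++cnt > budget) break;
      }
      if (cnt > budget) continue;
      const double d = (double)cnt / ov;
      if (d < best_d || (d == best_d && st < best_start)) {
        best_d = d; best_start = st;
      }
    }
    keep[k] = best_start;
  }
  return keep;
}

// ---------------------------------------------------------------------------
// Global-alignment identity between two residue strings: identical aligned
// positions (= longest common subsequence under match-1/mismatch-0/gap-0
// scoring) divided by the shorter length.
// ---------------------------------------------------------------------------

static int lcs_len(const std::string &a, const std::string &b) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      cur[j] = (a[i - 1] == b[j - 1]) ? prev[j - 1] + 1
                                      : std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
double cpp_identity(std::string a, std::string b) {
  if (a.empty() || b.empty()) stop("sequences must be non-empty");
  const int mn = std::min(a.size(), b.size());
  return (double)lcs_len(a, b) / mn;
}

// ---------------------------------------------------------------------------
// Greedy incremental clustering over sequences already sorted by decreasing
// abundance: each sequence joins the first existing cluster whose
// representative (founder) passes identity >= identity_thr and
// min(len)/max(len) >= length_thr, else founds a new cluster.
// Returns 1-based cluster ids in input order.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double identity_thr,
                                 double length_thr) {
  const R_xlen_t n = seqs.size();
  IntegerVector cl(n);
  std::vector<std::string> reps;
  for (R_xlen_t k = 0; k < n; ++k) {
    const std::string s = as<std::string>(seqs[k]);
    int hit = -1;
    for (size_t r = 0; r < reps.size(); ++r) {
      const double la = (double)s.size(), lb = (double)reps[r].size();
      const double lr = std::min(la, lb) / std::max(la, lb);
      if (lr < length_thr) continue;
      const int mn = (int)std::min(s.size(), reps[r].size());
      if ((double)lcs_len(s, reps[r]) / mn >= identity_thr) { hit = (int)r; break; }
    }
    if (hit < 0) { reps.push_back(s); hit = (int)reps.size() - 1; }
    cl[k] = hit + 1;
  }
  return cl;
}

// ---------------------------------------------------------------------------
// Per-base substitution errors for the read simulator. Uses R's RNG so that
// set.seed() governs reproducibility.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
CharacterVector cpp_mutate_seqs(CharacterVector seqs, double rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  RNGScope scope;
  CharacterVector out(seqs.size());
  for (R_xlen_t k = 0; k < seqs.size(); ++k) {
    std::string s = as<std::string>(seqs[k]);
    for (size_t i = 0; i < s.size(); ++i) {
      if (unif_rand() < rate) {
        char c = s[i], nb = c;
        while (nb == c) nb = bases[(int)(unif_rand() * 4) & 3];
        s[i] = nb;
      }
    }
    out[k] = s;
  }
  return out;
}
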