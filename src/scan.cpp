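#include <Rcpp.h>
#include <cstring>
#include <vector>

using namespace Rcpp;

// Anchored-start approximate matching of a short read against a long
// subject sequence.
//
// A placement at 0-based subject position s is an alignment in which the
// first read base is aligned (match or substitution) to subject[s]; the
// remainder of the read is aligned against the subject suffix with free end
// (gaps are internal only).  dist(s) is the minimal edit cost of such an
// alignment.  All s with dist(s) <= max_edits are collected; a placement is
// then suppressed when a strictly better placement lies within max_edits
// positions on the same strand (it is a shifted shadow of that alignment,
// not an independent occurrence).
//
// The DP is banded at |i - j| <= max_edits (any cell outside the band costs
// more than the budget) and a row whose band minimum exceeds the remaining
// budget abandons the start position early.

static int anchored_dist(const char *read, int m, const char *subj, int L,
                         int s, int max_edits) {
  int c0 = (read[0] == subj[s]) ? 0 : 1;
  if (c0 > max_edits) return max_edits + 1;
  if (m == 1) return c0;
  // prefix edit distance of read[1..m) vs subj[s+1 ..), free end in subject
  const char *a = read + 1;
  int  n = m - 1;               // read bases left
  const char *b = subj + s + 1;
  int  nb = L - s - 1;          // subject bases available
  int  budget = max_edits - c0;
  int  w = 2 * max_edits + 1;   // band width (in j - i + max_edits)
  std::vector<int> prev(w), cur(w);
  const int INF = 1000000;
  // row i = 0: E[0][j] = j (internal subject gaps after the anchor)
  for (int k = 0; k < w; ++k) {
    int j = k - max_edits;      // j index at row 0
    prev[k] = (j >= 0 && j <= nb) ? j : INF;
  }
  int best_final = INF;
  for (int i = 1; i <= n; ++i) {
    int rowmin = INF;
    for (int k = 0; k < w; ++k) {
      int j = i + k - max_edits;
      int val = INF;
      if (j >= 0 && j <= nb) {
        if (j > 0) {
          char bj = b[j - 1];
          int diag = prev[k];   // E[i-1][j-1]
          if (diag < INF) {
            int c = diag + ((a[i - 1] == bj) ? 0 : 1);
            if (c < val) val = c;
          }
          // deletion in read (consume subject): E[i][j-1] + 1
          if (k > 0 && cur[k - 1] < INF && cur[k - 1] + 1 < val)
            val = cur[k - 1] + 1;
        }
        // insertion in read (consume read): E[i-1][j] + 1
        if (k + 1 < w && prev[k + 1] < INF && prev[k + 1] + 1 < val)
          val = prev[k + 1] + 1;
      }
      cur[k] = val;
      if (val < rowmin) rowmin = val;
    }
    if (rowmin > budget) return max_edits + 1;  // early abandon
    prev.swap(cur);
  }
  for (int k = 0; k < w; ++k)
    if (prev[k] < best_final) best_final = prev[k];
  if (best_final > budget) return max_edits + 1;
  return c0 + best_final;
}

static void scan_impl(const std::string &read, const std::string &subject,
                      int max_edits, std::vector<int> &pos,
                      std::vector<int> &ed) {
  pos.clear(); ed.clear();
  int m = (int)read.size(), L = (int)subject.size();
  if (m == 0 || L == 0) return;
  const char *r = read.c_str(), *s = subject.c_str();
  if (max_edits == 0) {
    int last = L - m;
    for (int i = 0; i <= last; ++i)
      if (std::memcmp(r, s + i, m) == 0) { pos.push_back(i); ed.push_back(0); }
    return;
  }
  int last = L - (m - max_edits);
  if (last > L - 1) last = L - 1;
  for (int i = 0; i <= last; ++i) {
    int d = anchored_dist(r, m, s, L, i, max_edits);
    if (d <= max_edits) { pos.push_back(i); ed.push_back(d); }
  }
  // shadow suppression: drop s when a strictly better placement sits
  // within max_edits positions
  std::vector<bool> keep(pos.size(), true);
  for (size_t u = 0; u < pos.size(); ++u) {
    for (size_t v = 0; v < pos.size(); ++v) {
      if (u == v) continue;
      if (ed[v] < ed[u] && std::abs(pos[v] - pos[u]) <= max_edits) {
        keep[u] = false; break;
      }
    }
  }
  std::vector<int> p2, e2;
  for (size_t u = 0; u < pos.size(); ++u)
    if (keep[u]) { p2.push_back(pos[u]); e2.push_back(ed[u]); }
  pos.swap(p2); ed.swap(e2);
}

// [[Rcpp::export]]
IntegerMatrix cpp_scan_anchored(std::string read, std::string subject,
                                int max_edits) {
  std::vector<int> pos, ed;
  scan_impl(read, subject, max_edits, pos, ed);
  IntegerMatrix out((int)pos.size(), 2);
  for (size_t u = 0; u < pos.size(); ++u) {
    out(u, 0) = pos[u];
    out(u, 1) = ed[u];
  }
  colnames(out) = CharacterVector::create("pos", "edits");
  return out;
}

// Map a set of reads against a panel of consensus sequences with iterative
// deepening (most reads resolve at the exact level) and family-level
// best-hit assignment.  Returns flat parallel vectors.
// [[Rcpp::export]]
List cpp_map_panel(CharacterVector seqs, CharacterVector fams,
                   CharacterVector rc_fams, int max_edits, bool best_only) {
  int nseq = seqs.size(), nfam = fams.size();
  std::vector<std::string> F(nfam), RC(nfam);
  std::vector<int> Ls(nfam);
  for (int f = 0; f < nfam; ++f) {
    F[f] = as<std::string>(fams[f]);
    RC[f] = as<std::string>(rc_fams[f]);
    Ls[f] = (int)F[f].size();
  }
  std::vector<int> o_read, o_fam, o_strand, o_fp, o_ed;
  std::vector<int> pos, ed;
  for (int q = 0; q < nseq; ++q) {
    std::string s = as<std::string>(seqs[q]);
    // per-read hit buffers
    std::vector<int> h_fam, h_strand, h_fp, h_ed;
    for (int d = best_only ? 0 : max_edits; d <= max_edits; ++d) {
      h_fam.clear(); h_strand.clear(); h_fp.clear(); h_ed.clear();
      for (int f = 0; f < nfam; ++f) {
        scan_impl(s, F[f], d, pos, ed);
        for (size_t u = 0; u < pos.size(); ++u) {
          h_fam.push_back(f); h_strand.push_back(0);
          h_fp.push_back(pos[u]); h_ed.push_back(ed[u]);
        }
        scan_impl(s, RC[f], d, pos, ed);
        for (size_t u = 0; u < pos.size(); ++u) {
          h_fam.push_back(f); h_strand.push_back(1);
          h_fp.push_back(Ls[f] - 1 - pos[u]); h_ed.push_back(ed[u]);
        }
      }
      if (!h_fam.empty() && (best_only || d == max_edits)) break;
    }
    if (h_fam.empty()) continue;
    int dmin = max_edits + 1;
    for (size_t u = 0; u < h_ed.size(); ++u)
      if (h_ed[u] < dmin) dmin = h_ed[u];
    std::vector<bool> fam_best(nfam, false);
    for (size_t u = 0; u < h_ed.size(); ++u)
      if (h_ed[u] == dmin) fam_best[h_fam[u]] = true;
    for (size_t u = 0; u < h_ed.size(); ++u) {
      if (!fam_best[h_fam[u]]) continue;
      if (best_only && h_ed[u] != dmin) continue;
      o_read.push_back(q + 1); o_fam.push_back(h_fam[u] + 1);
      o_strand.push_back(h_strand[u]); o_fp.push_back(h_fp[u]);
      o_ed.push_back(h_ed[u]);
    }
  }
  return List::create(_["read"] = wrap(o_read), _["family"] = wrap(o_fam),
                      _["strand"] = wrap(o_strand),
                      _["five_prime"] = wrap(o_fp),
                      _["edits"] = wrap(o_ed));
}

// Exact occurrence count of each read in a subject (used for genome
// multiplicity bookkeeping in tests; the main genome mapper goes through
// Biostrings).
// [[Rcpp::export]]
IntegerVector cpp_count_exact(CharacterVector reads, std::string subject) {
  int n = reads.size();
  IntegerVector out(n);
  const char *s = subject.c_str();
  int L = (int)subject.size();
  for (int q = 0; q < n; ++q) {
    std::string r = as<std::string>(reads[q]);
    int m = (int)r.size(), cnt = 0;
    for (int i = 0; i + m <= L; ++i)
      if (std::memcmp(r.c_str(), s + i, m) == 0) ++cnt;
    out[q] = cnt;
  }
  return out;
}
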