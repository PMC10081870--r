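#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Alphabet convention shared with the R side: letters coded 1..4 = A,C,G,T.
// A di-PWM for a motif of length m is a 16 x (m-1) matrix P whose rows are the
// dinucleotides in lexicographic order (AA, AC, ..., TT): row index of
// dinucleotide (a,b) with a,b in 0..3 is 4*a + b (0-based).
// LAM and LBM are 4 x m matrices with zero boundary columns (m and 1).

namespace {

struct EnumState {
  const NumericMatrix& P;
  const NumericMatrix& lam;
  const NumericMatrix& lbm;
  int a;        // first matrix column of the enumerated block (1-based)
  int h;        // word length to emit (h = b - a + 2)
  double t;
  double cap;
  double base;  // lbm(first_letter, a): best prefix contribution
  std::vector<char> letters;           // current prefix, 0..3
  std::vector<std::string>& words;
  std::vector<double>& scores;
  std::vector<double>& index;          // base-4 value of the word (lex rank)
  long long nodes;
  bool truncated;

  EnumState(const NumericMatrix& P_, const NumericMatrix& lam_,
            const NumericMatrix& lbm_, int a_, int h_, double t_, double cap_,
            std::vector<std::string>& w_, std::vector<double>& s_,
            std::vector<double>& i_)
      : P(P_), lam(lam_), lbm(lbm_), a(a_), h(h_), t(t_), cap(cap_), base(0.0),
        words(w_), scores(s_), index(i_), nodes(0), truncated(false) {}
};

const char LETTER[4] = {'A', 'C', 'G', 'T'};

// Depth-first extension. `len` letters are fixed; partial covers matrix
// columns a .. a+len-2. The last letter sits at motif position a+len-1, so the
// pruning bound is base + partial + lam(last, a+len-1): an upper bound on the
// best full-length word through this prefix, and realizable by some word.
void enum_dfs(EnumState& st, int len, double partial) {
  if (st.truncated) return;
  int last = st.letters[len - 1];
  int pos = st.a + len - 1;                      // motif position, 1-based
  double bound = st.base + partial + st.lam(last, pos - 1);
  if (bound < st.t) return;
  st.nodes++;
  if (len == st.h) {
    if ((double)st.words.size() >= st.cap) {
      st.truncated = true;
      return;
    }
    std::string w(st.h, 'A');
    double idx = 0.0;
    for (int i = 0; i < st.h; ++i) {
      w[i] = LETTER[(int)st.letters[i]];
      idx = idx * 4.0 + st.letters[i];
    }
    st.words.push_back(w);
    st.scores.push_back(bound);  // at len == h, lam is the true best suffix
    st.index.push_back(idx);
    return;
  }
  for (int b = 0; b < 4; ++b) {
    st.letters[len] = (char)b;
    double step = st.P(4 * last + b, pos - 1);   // column `pos` (1-based)
    enum_dfs(st, len + 1, partial + step);
  }
}

}  // namespace

// Branch-and-bound enumeration of words over matrix columns a..b (1-based).
// With a = 1, b = m-1 this is the full enumeration (FE): the zero boundary
// columns of LBM/LAM make the emitted score the exact word score. With a
// proper core it is the core enumeration (CE): the emitted score is the best
// score of any full-length word containing the core word at offset a-1.
// Words come out in lexicographic order.
// [[Rcpp::export]]
List cpp_enumerate(NumericMatrix P, NumericMatrix lam, NumericMatrix lbm,
                   int a, int b, double t, double cap) {
  int h = b - a + 2;
  std::vector<std::string> words;
  std::vector<double> scores, index;
  EnumState st(P, lam, lbm, a, h, t, cap, words, scores, index);
  st.letters.assign(h, 0);
  for (int l0 = 0; l0 < 4 && !st.truncated; ++l0) {
    st.letters[0] = (char)l0;
    st.base = lbm(l0, a - 1);
    enum_dfs(st, 1, 0.0);
  }
  return List::create(_["word"] = wrap(words), _["score"] = wrap(scores),
                      _["index"] = wrap(index),
                      _["nodes"] = (double)st.nodes,
                      _["truncated"] = st.truncated);
}

// Lookahead-pruned window scan over an integer-coded sequence (1..4 = ACGT,
// 0 = ambiguity code). Per window, column scores accumulate left to right and
// the window is abandoned as soon as partial + lam(letter, pos) drops below t.
// Windows reached at an ambiguity code before being pruned are handed back for
// best-disambiguation scoring; windows pruned earlier cannot reach t under any
// disambiguation because the bound majorizes every completion.
// [[Rcpp::export]]
List cpp_scan_os(IntegerVector seq, NumericMatrix P, NumericMatrix lam,
                 int m, double t) {
  int n = seq.size();
  std::vector<int> starts, amb_starts;
  std::vector<double> scores;
  for (int s = 0; s + m <= n; ++s) {
    double partial = 0.0;
    int prev = 0;
    for (int l = 1; l <= m; ++l) {
      int c = seq[s + l - 1];
      if (c == 0) {
        amb_starts.push_back(s + 1);
        break;
      }
      if (l > 1) partial += P(4 * (prev - 1) + (c - 1), l - 2);
      if (partial + lam(c - 1, l - 1) < t) break;
      if (l == m) {
        starts.push_back(s + 1);
        scores.push_back(partial);
      }
      prev = c;
    }
  }
  return List::create(_["start"] = wrap(starts), _["score"] = wrap(scores),
                      _["amb_start"] = wrap(amb_starts));
}

// Exact scores of all length-m windows of an ACGT-coded sequence (0 entries
// poison their windows with -Inf). Used by the full rescoring path.
// [[Rcpp::export]]
NumericVector cpp_score_windows(IntegerVector seq, NumericMatrix P, int m) {
  int n = seq.size();
  int nw = n - m + 1;
  if (nw < 0) nw = 0;
  NumericVector out(nw);
  for (int s = 0; s < nw; ++s) {
    double sc = 0.0;
    bool ok = true;
    for (int j = 0; j + 1 < m; ++j) {
      int a = seq[s + j], b = seq[s + j + 1];
      if (a == 0 || b == 0) { ok = false; break; }
      sc += P(4 * (a - 1) + (b - 1), j);
    }
    out[s] = ok ? sc : R_NegInf;
  }
  return out;
}
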