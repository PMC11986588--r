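#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap Smith-Waterman. Scores: match > 0, mismatch < 0; a gap of
// length L costs gap_open + L * gap_extend (both supplied as negative
// scores). 'N' (or any non-ACGT byte) always scores as a mismatch.
// Coordinates returned are 0-based half-open on query and subject.
// Tie-breaking: among equal-scoring cells the end with the smallest
// subject index, then the smallest query index wins; traceback prefers
// diagonal over a gap in the subject over a gap in the query.

static inline int subst(char a, char b, int match, int mismatch) {
  bool okA = (a == 'A' || a == 'C' || a == 'G' || a == 'T');
  bool okB = (b == 'A' || b == 'C' || b == 'G' || b == 'T');
  if (!okA || !okB) return mismatch;
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export]]
List sw_align_cpp(std::string query, std::string subject,
                  int match, int mismatch, int gap_open, int gap_extend,
                  bool traceback = true) {
  const int m = (int)query.size(), n = (int)subject.size();
  if (m == 0 || n == 0) {
    return List::create(_["score"] = 0,
                        _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0,
                        _["n_columns"] = 0, _["n_matches"] = 0);
  }
  // state matrices over (i = query pos 1..m, j = subject pos 1..n)
  // H best ending in (i,j); E gap in query (consumes subject); F gap in
  // subject (consumes query). Rolling columns over j.
  const int NEG = -1000000000;
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0);
  std::vector<int> Eprev(m + 1, NEG), Ecur(m + 1, NEG);
  // traceback pointers: 2 bits per state would do; use one byte per cell
  // packing H-origin (0 stop,1 diag,2 F,3 E) | F-open<<2 | E-open<<3.
  std::vector<unsigned char> tb;
  if (traceback) tb.assign((size_t)(m + 1) * (n + 1), 0);
  int best = 0, bi = 0, bj = 0;

  for (int j = 1; j <= n; ++j) {
    Hcur[0] = 0; Ecur[0] = NEG;
    int F = NEG;
    char sj = subject[j - 1];
    for (int i = 1; i <= m; ++i) {
      unsigned char ptr = 0;
      // E: gap in query, coming from column j-1
      int e_open = Hprev[i] + gap_open + gap_extend;
      int e_ext  = Eprev[i] + gap_extend;
      int E = (e_open >= e_ext) ? e_open : e_ext;
      if (e_open < e_ext) ptr |= 8;  // E extended
      // F: gap in subject, within column
      int f_open = Hcur[i - 1] + gap_open + gap_extend;
      int f_ext  = F + gap_extend;
      F = (f_open >= f_ext) ? f_open : f_ext;
      if (f_open < f_ext) ptr |= 4;  // F extended
      int diag = Hprev[i - 1] + subst(query[i - 1], sj, match, mismatch);
      int h = 0; unsigned char org = 0;
      if (diag > h) { h = diag; org = 1; }
      if (F > h)    { h = F;    org = 2; }
      if (E > h)    { h = E;    org = 3; }
      Hcur[i] = h; Ecur[i] = E;
      if (traceback) { tb[(size_t)j * (m + 1) + i] = (unsigned char)(ptr | org); }
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur);
  }

  int q_end = bi, s_end = bj, q_start = bi, s_start = bj;
  int ncol = 0, nmatch = 0;
  if (traceback && best > 0) {
    int i = bi, j = bj; int state = 0; // 0 = in H
    while (i > 0 && j > 0) {
      unsigned char c = tb[(size_t)j * (m + 1) + i];
      if (state == 0) {
        int org = c & 3;
        if (org == 0) break;                 // local start
        if (org == 1) {                      // diagonal
          ++ncol;
          if (subst(query[i - 1], subject[j - 1], 1, -1) == 1) ++nmatch;
          --i; --j;
        } else if (org == 2) state = 2;      // enter F (gap in subject)
        else state = 3;                      // enter E (gap in query)
      } else if (state == 2) {               // F: consumes query base
        ++ncol; --i;
        if (!(c & 4)) state = 0;             // was an opening step
        // note: the open/extend flag belongs to the cell we just left
      } else {                               // E: consumes subject base
        ++ncol; --j;
        if (!(c & 8)) state = 0;
      }
    }
    q_start = i; s_start = j;
  } else if (best == 0) {
    q_start = q_end = 0; s_start = s_end = 0;
  }
  return List::create(_["score"] = best,
                      _["q_start"] = q_start, _["q_end"] = q_end,
                      _["s_start"] = s_start, _["s_end"] = s_end,
                      _["n_columns"] = ncol, _["n_matches"] = nmatch);
}

// Batch score-only scan used by the capture scanner: aligns query (a TE)
// against each subject and returns the raw scores.
// [[Rcpp::export]]
IntegerVector sw_score_batch_cpp(std::string query, CharacterVector subjects,
                                 int match, int mismatch,
                                 int gap_open, int gap_extend) {
  const int m = (int)query.size();
  IntegerVector out(subjects.size());
  const int NEG = -1000000000;
  std::vector<int> Hprev(m + 1), Hcur(m + 1), Eprev(m + 1), Ecur(m + 1);
  for (R_xlen_t k = 0; k < subjects.size(); ++k) {
    std::string subject = as<std::string>(subjects[k]);
    const int n = (int)subject.size();
    int best = 0;
    std::fill(Hprev.begin(), Hprev.end(), 0);
    std::fill(Eprev.begin(), Eprev.end(), NEG);
    for (int j = 1; j <= n; ++j) {
      Hcur[0] = 0; Ecur[0] = NEG;
      int F = NEG;
      char sj = subject[j - 1];
      for (int i = 1; i <= m; ++i) {
        int e_open = Hprev[i] + gap_open + gap_extend;
        int e_ext  = Eprev[i] + gap_extend;
        int E = (e_open >= e_ext) ? e_open : e_ext;
        int f_open = Hcur[i - 1] + gap_open + gap_extend;
        int f_ext  = F + gap_extend;
        F = (f_open >= f_ext) ? f_open : f_ext;
        int diag = Hprev[i - 1] + subst(query[i - 1], sj, match, mismatch);
        int h = 0;
        if (diag > h) h = diag;
        if (F > h) h = F;
        if (E > h) h = E;
        Hcur[i] = h; Ecur[i] = E;
        if (h > best) best = h;
      }
      std::swap(Hprev, Hcur); std::swap(Eprev, Ecur);
    }
    out[k] = best;
  }
  return out;
}
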