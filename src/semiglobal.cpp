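#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

// Exact semiglobal alignment: the full query must align; end gaps on the
// subject are free, so query coverage is 100% by construction. Scoring is
// linear (match / mismatch / per-base gap). Ambiguity codes (anything
// outside A/C/G/T) mismatch everything, including themselves.
//
// Tie-breaking among optimal-score alignments: fewer gap columns first,
// then leftmost subject start. Implemented as lexicographic dynamic
// programming over (score, -gap_columns, -subject_start).

struct Cell {
  int score;
  int gaps;   // gap columns on the path
  int start;  // 1-based subject start of the aligned region
};

static inline bool better(int sc, int gp, int st, const Cell &c) {
  if (sc != c.score) return sc > c.score;
  if (gp != c.gaps) return gp < c.gaps;
  return st < c.start;
}

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// [[Rcpp::export(name = ".semiglobal_align_cpp")]]
List semiglobal_align_cpp(std::string query, std::string subject,
                          int match, int mismatch, int gap) {
  const int m = (int) query.size();
  const int n = (int) subject.size();
  if (m == 0 || n == 0) stop("sequences must be non-empty");

  std::vector<Cell> dp((size_t)(m + 1) * (n + 1));
  std::vector<unsigned char> move((size_t)(m + 1) * (n + 1), 0);
  // moves: 0 = origin, 1 = diagonal, 2 = up (query char vs gap),
  //        3 = left (subject char vs gap)
  auto at = [n](int i, int j) { return (size_t) i * (n + 1) + j; };

  for (int j = 0; j <= n; ++j) {
    dp[at(0, j)] = {0, 0, j + 1};  // free leading subject bases
  }
  for (int i = 1; i <= m; ++i) {
    dp[at(i, 0)] = {i * gap, i, 1};
    move[at(i, 0)] = 2;
  }

  for (int i = 1; i <= m; ++i) {
    const char qc = query[i - 1];
    for (int j = 1; j <= n; ++j) {
      const char sc = subject[j - 1];
      const int sub = (qc == sc && is_acgt(qc)) ? match : mismatch;
      const Cell &d = dp[at(i - 1, j - 1)];
      Cell best = {d.score + sub, d.gaps, d.start};
      unsigned char mv = 1;
      const Cell &u = dp[at(i - 1, j)];
      if (better(u.score + gap, u.gaps + 1, u.start, best)) {
        best = {u.score + gap, u.gaps + 1, u.start};
        mv = 2;
      }
      const Cell &l = dp[at(i, j - 1)];
      if (better(l.score + gap, l.gaps + 1, l.start, best)) {
        best = {l.score + gap, l.gaps + 1, l.start};
        mv = 3;
      }
      dp[at(i, j)] = best;
      move[at(i, j)] = mv;
    }
  }

  // free trailing subject bases: best cell in the last row
  int jbest = 0;
  Cell cbest = dp[at(m, 0)];
  for (int j = 1; j <= n; ++j) {
    const Cell &c = dp[at(m, j)];
    if (better(c.score, c.gaps, c.start, cbest)) {
      cbest = c;
      jbest = j;
    }
  }

  // traceback
  std::string aq, as;
  int identities = 0, columns = 0, gaps = 0;
  int i = m, j = jbest;
  while (i > 0 || (j > 0 && move[at(i, j)] != 0)) {
    unsigned char mv = move[at(i, j)];
    if (i == 0) break;  // row 0 cells are origins (leading free gap)
    if (mv == 1) {
      aq.push_back(query[i - 1]);
      as.push_back(subject[j - 1]);
      if (query[i - 1] == subject[j - 1] && is_acgt(query[i - 1])) ++identities;
      --i; --j;
    } else if (mv == 2) {
      aq.push_back(query[i - 1]);
      as.push_back('-');
      ++gaps;
      --i;
    } else {
      aq.push_back('-');
      as.push_back(subject[j - 1]);
      ++gaps;
      --j;
    }
    ++columns;
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(as.begin(), as.end());

  const int sub_start = cbest.start;
  const int sub_end = jbest;  // 0 when the whole subject is skipped

  return List::create(
    _["score"] = cbest.score,
    _["identities"] = identities,
    _["alignment_columns"] = columns,
    _["gap_columns"] = gaps,
    _["pident"] = 100.0 * identities / columns,
    _["qcovs"] = 100.0,
    _["subject_start"] = sub_start,
    _["subject_end"] = sub_end,
    _["aligned_query"] = aq,
    _["aligned_subject"] = as
  );
}
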