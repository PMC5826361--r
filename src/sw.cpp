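#include <Rcpp.h>
#include <climits>
#include <vector>
using namespace Rcpp;

// Gotoh local alignment with affine gaps. Gap of length g costs
// open + g * ext (the BLAST "11,1" convention: a length-1 gap costs 12).
// Residues are 0-based indices into the substitution matrix; a negative
// index means "unknown letter" and scores min_sub against everything.

static const int NEG = INT_MIN / 4;

static inline int sub_score(const IntegerMatrix &S, int ai, int bi,
                            int min_sub) {
  if (ai < 0 || bi < 0) return min_sub;
  return S(ai, bi);
}

// [[Rcpp::export]]
int sw_score_c(IntegerVector a, IntegerVector b, IntegerMatrix S,
               int gap_open, int gap_ext, int min_sub) {
  const int m = a.size(), n = b.size();
  const int go = gap_open + gap_ext;
  std::vector<int> H(n + 1, 0), F(n + 1, NEG);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int Hdiag = 0;    // H[i-1][j-1]
    int Hleft = 0;    // H[i][j-1]
    int E = NEG;      // E[i][j-1]
    for (int j = 1; j <= n; ++j) {
      const int Hup = H[j];                    // H[i-1][j]
      E = std::max(Hleft - go, E - gap_ext);   // gap in query (consumes b)
      F[j] = std::max(Hup - go, F[j] - gap_ext); // gap in subject (consumes a)
      int h = Hdiag + sub_score(S, a[i - 1], b[j - 1], min_sub);
      if (E > h) h = E;
      if (F[j] > h) h = F[j];
      if (h < 0) h = 0;
      Hdiag = Hup;
      H[j] = h;
      Hleft = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Full DP with traceback. Tie-break during traceback: diagonal first, then
// gap-in-query (consumes subject), then gap-in-subject.
// [[Rcpp::export]]
List sw_align_c(IntegerVector a, IntegerVector b, IntegerMatrix S,
                int gap_open, int gap_ext, int min_sub) {
  const int m = a.size(), n = b.size();
  const int go = gap_open + gap_ext;
  const size_t W = n + 1;
  std::vector<int> H((m + 1) * W, 0), E((m + 1) * W, NEG),
      F((m + 1) * W, NEG);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const size_t ij = i * W + j;
      E[ij] = std::max(H[ij - 1] - go, E[ij - 1] - gap_ext);
      F[ij] = std::max(H[ij - W] - go, F[ij - W] - gap_ext);
      int h = H[ij - W - 1] + sub_score(S, a[i - 1], b[j - 1], min_sub);
      if (E[ij] > h) h = E[ij];
      if (F[ij] > h) h = F[ij];
      if (h < 0) h = 0;
      H[ij] = h;
      if (h > best) { best = h; bi = i; bj = j; } // strict: earliest (i,j) wins
    }
  }
  int i = bi, j = bj, matches = 0, alen = 0;
  if (best > 0) {
    int state = 0; // 0 = H, 1 = E (gap in query), 2 = F (gap in subject)
    while (i > 0 && j > 0) {
      const size_t ij = i * W + j;
      if (state == 0) {
        if (H[ij] == 0) break;
        const int s = sub_score(S, a[i - 1], b[j - 1], min_sub);
        if (H[ij] == H[ij - W - 1] + s) {
          if (a[i - 1] >= 0 && a[i - 1] == b[j - 1]) ++matches;
          ++alen; --i; --j;
        } else if (H[ij] == E[ij]) {
          state = 1;
        } else {
          state = 2;
        }
      } else if (state == 1) {
        ++alen;
        if (E[ij] == H[ij - 1] - go) state = 0;
        --j;
      } else {
        ++alen;
        if (F[ij] == H[ij - W] - go) state = 0;
        --i;
      }
    }
  }
  return List::create(_["score"] = best,
                      _["q_start"] = (best > 0) ? i : 0,
                      _["q_end"] = (best > 0) ? bi : 0,
                      _["s_start"] = (best > 0) ? j : 0,
                      _["s_end"] = (best > 0) ? bj : 0,
                      _["align_len"] = alen, _["matches"] = matches);
}
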