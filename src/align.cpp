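#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP), local (Smith-Waterman)
// or global (Needleman-Wunsch), over integer-encoded residues.
//
// Scores are integers pre-scaled by 2 so half-unit gap-extension penalties stay
// exact. Each DP cell packs (score2 << 20) + matches into one 64-bit value;
// both components are additive along an alignment path and matches < 2^20, so
// maximising the packed value maximises score first and, among score-optimal
// paths, the number of identical residue pairs. Remaining ties are broken by
// the smallest end coordinates and a fixed M > X > Y state preference, which
// selects the smallest start coordinates among surviving candidates.
//
// States: M = a[i] ~ b[j]; X = a[i] ~ gap; Y = gap ~ b[j].
// A gap of length L costs gap_open + L * gap_extend.

static const int64_t NEG = INT64_MIN / 4;
static const int64_t PACK = 1 << 20;

static inline int64_t unpack_score2(int64_t v) {
  int64_t matches = ((v % PACK) + PACK) % PACK;
  return (v - matches) / PACK;
}

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(IntegerVector a, IntegerVector b, IntegerMatrix sub2,
                    int gap_open2, int gap_extend2, bool local) {
  const int n = a.size(), m = b.size();
  const int64_t OPEN = (int64_t)(gap_open2 + gap_extend2) * PACK; // first gap column
  const int64_t EXT  = (int64_t)gap_extend2 * PACK;               // each further column

  const size_t W = (size_t)m + 1;
  std::vector<int64_t> M((size_t)(n + 1) * W, NEG);
  std::vector<int64_t> X((size_t)(n + 1) * W, NEG);
  std::vector<int64_t> Y((size_t)(n + 1) * W, NEG);

  M[0] = 0;
  if (!local) {
    for (int i = 1; i <= n; ++i) X[(size_t)i * W] = -((int64_t)gap_open2 * PACK + (int64_t)i * EXT);
    for (int j = 1; j <= m; ++j) Y[(size_t)j]     = -((int64_t)gap_open2 * PACK + (int64_t)j * EXT);
  }

  int64_t best = NEG;
  int best_i = n, best_j = m, best_state = 0; // 0=M 1=X 2=Y

  // NEG is INT64_MIN/4: subtracting gap penalties cannot overflow and keeps
  // unreachable states far below any reachable score, so the inner loop needs
  // no reachability guards.
  const int nres = sub2.nrow();
  std::vector<int64_t> subrow(nres);
  for (int i = 1; i <= n; ++i) {
    int64_t *Mr = &M[(size_t)i * W], *Mp = &M[(size_t)(i - 1) * W];
    int64_t *Xr = &X[(size_t)i * W], *Xp = &X[(size_t)(i - 1) * W];
    int64_t *Yr = &Y[(size_t)i * W], *Yp = &Y[(size_t)(i - 1) * W];
    const int ai = a[i - 1];
    for (int t = 0; t < nres; ++t)
      subrow[t] = (int64_t)sub2(ai, t) * PACK + (ai == t ? 1 : 0);
    for (int j = 1; j <= m; ++j) {
      int64_t base = Mp[j - 1];
      if (Xp[j - 1] > base) base = Xp[j - 1];
      if (Yp[j - 1] > base) base = Yp[j - 1];
      if (local && base < 0) base = 0; // fresh local start
      const int64_t mv = base + subrow[b[j - 1]];
      Mr[j] = mv;

      int64_t x = Xp[j] - EXT;
      if (Mp[j] - OPEN > x) x = Mp[j] - OPEN;
      if (Yp[j] - OPEN > x) x = Yp[j] - OPEN;
      Xr[j] = x;

      int64_t y = Yr[j - 1] - EXT;
      if (Mr[j - 1] - OPEN > y) y = Mr[j - 1] - OPEN;
      if (Xr[j - 1] - OPEN > y) y = Xr[j - 1] - OPEN;
      Yr[j] = y;

      if (local && mv > best) { best = mv; best_i = i; best_j = j; }
    }
  }

  if (!local) {
    const size_t e = (size_t)n * W + m;
    best = M[e]; best_state = 0;
    if (X[e] > best) { best = X[e]; best_state = 1; }
    if (Y[e] > best) { best = Y[e]; best_state = 2; }
  }

  const int64_t score2 = (best == NEG) ? 0 : unpack_score2(best);
  if (local && (best == NEG || score2 <= 0)) {
    return List::create(_["hit"] = false, _["score2"] = 0.0, _["matches"] = 0,
                        _["columns"] = 0, _["q_start"] = 0, _["q_end"] = 0,
                        _["t_start"] = 0, _["t_end"] = 0);
  }

  // Traceback (directions recomputed from the stored matrices).
  int i = best_i, j = best_j, state = best_state;
  int matches = 0, columns = 0;
  const int q_end = local ? best_i : n, t_end = local ? best_j : m;
  int q_start = 1, t_start = 1;

  while (!(i == 0 && j == 0)) {
    const size_t r = (size_t)i * W;
    const size_t p = (i > 0) ? (size_t)(i - 1) * W : 0;
    if (state == 0) { // M consumed a[i], b[j]
      const int64_t subv = (int64_t)sub2(a[i - 1], b[j - 1]) * PACK +
                           (a[i - 1] == b[j - 1] ? 1 : 0);
      const int64_t need = M[r + j] - subv;
      ++columns;
      if (a[i - 1] == b[j - 1]) ++matches;
      if (local && need == 0 &&
          M[p + j - 1] < 0 && X[p + j - 1] < 0 && Y[p + j - 1] < 0) {
        q_start = i; t_start = j; // fresh local start at this column
        break;
      }
      if      (M[p + j - 1] == need) state = 0;
      else if (X[p + j - 1] == need) state = 1;
      else if (Y[p + j - 1] == need) state = 2;
      else stop("alignment traceback failure (M state)");
      --i; --j;
    } else if (state == 1) { // X consumed a[i] against a gap
      const int64_t need_open = X[r + j] + OPEN, need_ext = X[r + j] + EXT;
      ++columns;
      if      (M[p + j] == need_open) state = 0;
      else if (X[p + j] == need_ext)  state = 1;
      else if (Y[p + j] == need_open) state = 2;
      else stop("alignment traceback failure (X state)");
      --i;
    } else { // Y consumed b[j] against a gap
      const int64_t need_open = Y[r + j] + OPEN, need_ext = Y[r + j] + EXT;
      ++columns;
      if      (M[r + j - 1] == need_open) state = 0;
      else if (Y[r + j - 1] == need_ext)  state = 2;
      else if (X[r + j - 1] == need_open) state = 1;
      else stop("alignment traceback failure (Y state)");
      --j;
    }
  }
  if (!local) { q_start = 1; t_start = 1; }

  return List::create(_["hit"] = true, _["score2"] = (double)score2,
                      _["matches"] = matches, _["columns"] = columns,
                      _["q_start"] = q_start, _["q_end"] = q_end,
                      _["t_start"] = t_start, _["t_end"] = t_end);
}
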