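#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with nucleotide-specific affine gap
// penalties: the cost of a gap depends on the base being skipped (the ref
// base for gaps in the read, the read base for gaps in the ref).  A
// negative open/extend value bans gaps over that base.  This is the scoring
// system that makes U-indel-edited reads alignable: T gaps are free (or
// cheap) while A/C/G gaps stay expensive or are disallowed.

static const int NEG = INT_MIN / 4;

static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

// [[Rcpp::export]]
List sw_core(std::string read, std::string ref,
             int match, int mismatch,
             IntegerVector gap_open, IntegerVector gap_extend,
             int band, int band_diag) {
  const int n = (int) read.size();
  const int m = (int) ref.size();
  std::vector<int> rd(n), rf(m);
  for (int i = 0; i < n; ++i) rd[i] = base_idx(read[i]);
  for (int j = 0; j < m; ++j) rf[j] = base_idx(ref[j]);

  // flat (n+1) x (m+1) matrices
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  std::vector<int> M((n + 1) * (m + 1), NEG);
  std::vector<int> X((n + 1) * (m + 1), NEG);  // gap in read (ref consumed)
  std::vector<int> Y((n + 1) * (m + 1), NEG);  // gap in ref (read consumed)
  // traceback: 0 none/stop, 1 from M, 2 from X, 3 from Y
  std::vector<signed char> tM((n + 1) * (m + 1), 0);
  std::vector<signed char> tX((n + 1) * (m + 1), 0);
  std::vector<signed char> tY((n + 1) * (m + 1), 0);

  for (int j = 0; j <= m; ++j) M[at(0, j)] = 0;
  for (int i = 0; i <= n; ++i) M[at(i, 0)] = 0;

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int jlo = 1, jhi = m;
    if (band >= 0) {  // restrict to |(j - i) - band_diag| <= band
      jlo = std::max(1, i + band_diag - band);
      jhi = std::min(m, i + band_diag + band);
      if (jlo > jhi) continue;
    }
    for (int j = jlo; j <= jhi; ++j) {
      // M: consume one read + one ref char
      int sub = (rd[i - 1] == rf[j - 1]) ? match : -mismatch;
      int d0 = M[at(i - 1, j - 1)];
      int d1 = X[at(i - 1, j - 1)];
      int d2 = Y[at(i - 1, j - 1)];
      int bestd = 0; signed char src = 0;       // local: fresh start allowed
      if (d0 >= bestd) { bestd = d0; src = 1; }
      if (d1 > bestd) { bestd = d1; src = 2; }
      if (d2 > bestd) { bestd = d2; src = 3; }
      int mv = (bestd <= NEG / 2) ? NEG : bestd + sub;
      M[at(i, j)] = mv;
      tM[at(i, j)] = src;
      if (mv > best) { best = mv; bi = i; bj = j; }

      // X: gap in read, skipping ref base j-1
      int b = rf[j - 1];
      if (b >= 0 && gap_open[b] >= 0) {
        int open_cost = gap_open[b] + gap_extend[b];
        int ext_cost = gap_extend[b];
        int fromM = M[at(i, j - 1)];
        int fromX = X[at(i, j - 1)];
        int v1 = (fromM <= NEG / 2) ? NEG : fromM - open_cost;
        int v2 = (fromX <= NEG / 2) ? NEG : fromX - ext_cost;
        if (v1 >= v2) { X[at(i, j)] = v1; tX[at(i, j)] = 1; }
        else { X[at(i, j)] = v2; tX[at(i, j)] = 2; }
      }

      // Y: gap in ref, consuming read base i-1
      int c = rd[i - 1];
      if (c >= 0 && gap_open[c] >= 0) {
        int open_cost = gap_open[c] + gap_extend[c];
        int ext_cost = gap_extend[c];
        int fromM = M[at(i - 1, j)];
        int fromY = Y[at(i - 1, j)];
        int v1 = (fromM <= NEG / 2) ? NEG : fromM - open_cost;
        int v2 = (fromY <= NEG / 2) ? NEG : fromY - ext_cost;
        if (v1 >= v2) { Y[at(i, j)] = v1; tY[at(i, j)] = 1; }
        else { Y[at(i, j)] = v2; tY[at(i, j)] = 3; }
      }
    }
  }

  // traceback from the best M cell
  std::string ops;
  int i = bi, j = bj;
  int state = 1;
  while (i > 0 || j > 0) {
    if (state == 1) {
      if (i == 0 || j == 0) break;
      signed char src = tM[at(i, j)];
      ops.push_back('M');
      --i; --j;
      if (src == 0) break;        // local start
      state = src;
    } else if (state == 2) {
      signed char src = tX[at(i, j)];
      ops.push_back('D');
      --j;
      state = src;
    } else {
      signed char src = tY[at(i, j)];
      ops.push_back('I');
      --i;
      state = src;
    }
  }
  std::reverse(ops.begin(), ops.end());
  int read_start = i, ref_start = j;  // 0-based, alignment covers [start, end)

  // canonicalise: shift gaps leftmost across equal characters (T runs)
  // 'M' at p followed by 'I' at p+1 swaps when the read chars are equal;
  // 'M' followed by 'D' swaps when the ref chars are equal.
  bool changed = true;
  while (changed) {
    changed = false;
    int rp = read_start, fp = ref_start;  // positions before column k
    std::vector<int> rpos(ops.size()), fpos(ops.size());
    for (size_t k = 0; k < ops.size(); ++k) {
      rpos[k] = rp; fpos[k] = fp;
      if (ops[k] != 'D') ++rp;
      if (ops[k] != 'I') ++fp;
    }
    for (size_t k = 0; k + 1 < ops.size(); ++k) {
      if (ops[k] == 'M' && ops[k + 1] == 'I' &&
          read[rpos[k]] == read[rpos[k + 1]]) {
        std::swap(ops[k], ops[k + 1]);
        changed = true;
      } else if (ops[k] == 'M' && ops[k + 1] == 'D' &&
                 ref[fpos[k]] == ref[fpos[k + 1]]) {
        std::swap(ops[k], ops[k + 1]);
        changed = true;
      }
    }
  }

  // tally
  int matches = 0, mismatches = 0;
  int rp = read_start, fp = ref_start;
  for (size_t k = 0; k < ops.size(); ++k) {
    if (ops[k] == 'M') {
      if (read[rp] == ref[fp]) ++matches; else ++mismatches;
      ++rp; ++fp;
    } else if (ops[k] == 'D') {
      ++fp;
    } else {
      ++rp;
    }
  }

  return List::create(
    _["score"] = best,
    _["ops"] = ops,
    _["read_start"] = read_start, _["read_end"] = rp,
    _["ref_start"] = ref_start, _["ref_end"] = fp,
    _["matches"] = matches, _["mismatches"] = mismatches);
}
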