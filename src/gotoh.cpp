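#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh) of a read against a reference,
// with run-length traceback. Maximizes score; a gap of length L costs
// gap_open + (L - 1) * gap_extend (both supplied as negative numbers).
//
// States: M = read/ref base aligned; D = gap in read (reference base
// deleted); I = gap in reference (read base inserted).
//
// free_ref_tail = true leaves a trailing reference suffix unpenalized and
// un-traced: the read must be consumed in full, but alignment may end at any
// reference column (model for a sequencing read truncated before the end of
// the amplicon). Ties are broken deterministically: end cell prefers the
// largest reference column; end/backtrace state preference is M, then D,
// then I, except that an open gap prefers to extend.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".gotoh_align_cpp")]]
List gotoh_align_cpp(std::string read, std::string ref,
                     double match, double mismatch,
                     double gap_open, double gap_extend,
                     bool free_ref_tail) {
  const int n = (int) read.size();
  const int m = (int) ref.size();
  const int W = m + 1;

  std::vector<double> M((n + 1) * W, NEG_INF);
  std::vector<double> D((n + 1) * W, NEG_INF);
  std::vector<double> I((n + 1) * W, NEG_INF);
  // predecessor state for traceback: 0 = M, 1 = D, 2 = I, -1 none
  std::vector<signed char> pm((n + 1) * W, -1);
  std::vector<signed char> pd((n + 1) * W, -1);
  std::vector<signed char> pi((n + 1) * W, -1);

  M[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    D[j] = gap_open + (j - 1) * gap_extend;
    pd[j] = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    I[i * W] = gap_open + (i - 1) * gap_extend;
    pi[i * W] = (i == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    const char rb = read[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j;
      const int diag = (i - 1) * W + (j - 1);
      const int up = (i - 1) * W + j;
      const int left = i * W + (j - 1);

      // M: preference M > D > I on ties
      double s = (rb == ref[j - 1]) ? match : mismatch;
      double best = M[diag]; signed char who = 0;
      if (D[diag] > best) { best = D[diag]; who = 1; }
      if (I[diag] > best) { best = I[diag]; who = 2; }
      if (best > NEG_INF / 2) { M[idx] = best + s; pm[idx] = who; }

      // D (consumes ref): extend preferred on ties, then M, then I
      double bd = D[left] + gap_extend; signed char wd = 1;
      double altm = M[left] + gap_open;
      double alti = I[left] + gap_open;
      if (altm > bd) { bd = altm; wd = 0; }
      if (alti > bd) { bd = alti; wd = 2; }
      if (bd > NEG_INF / 2) { D[idx] = bd; pd[idx] = wd; }

      // I (consumes read): extend preferred on ties, then M, then D
      double bi = I[up] + gap_extend; signed char wi = 2;
      double iam = M[up] + gap_open;
      double iad = D[up] + gap_open;
      if (iam > bi) { bi = iam; wi = 0; }
      if (iad > bi) { bi = iad; wi = 1; }
      if (bi > NEG_INF / 2) { I[idx] = bi; pi[idx] = wi; }
    }
  }

  // choose end cell
  int end_j = m;
  double best_score = NEG_INF;
  signed char end_state = 0;
  if (free_ref_tail) {
    for (int j = m; j >= 0; --j) {  // prefer largest j on ties
      const int idx = n * W + j;
      double cell = M[idx]; signed char st = 0;
      if (D[idx] > cell) { cell = D[idx]; st = 1; }
      if (I[idx] > cell) { cell = I[idx]; st = 2; }
      if (cell > best_score) { best_score = cell; end_j = j; end_state = st; }
    }
  } else {
    const int idx = n * W + m;
    best_score = M[idx]; end_state = 0;
    if (D[idx] > best_score) { best_score = D[idx]; end_state = 1; }
    if (I[idx] > best_score) { best_score = I[idx]; end_state = 2; }
  }

  // traceback from (n, end_j)
  std::string path;  // reversed op chars
  int i = n, j = end_j;
  signed char st = end_state;
  int matches = 0, mismatches = 0;
  while (i > 0 || j > 0) {
    if (st == 0) {
      if (i == 0 && j == 0) break;
      signed char prev = pm[i * W + j];
      if (read[i - 1] == ref[j - 1]) { path.push_back('M'); ++matches; }
      else { path.push_back('X'); ++mismatches; }
      --i; --j; st = prev;
    } else if (st == 1) {
      signed char prev = pd[i * W + j];
      path.push_back('D');
      --j; st = prev;
    } else {
      signed char prev = pi[i * W + j];
      path.push_back('I');
      --i; st = prev;
    }
    if (i == 0 && j == 0) break;
  }
  std::reverse(path.begin(), path.end());

  // run-length encode, tracking 0-based start coordinates
  std::vector<std::string> op;
  std::vector<int> len, ref_start, read_start;
  int ri = 0, rj = 0;  // read, ref consumed
  size_t k = 0;
  while (k < path.size()) {
    char c = path[k];
    size_t k2 = k;
    while (k2 < path.size() && path[k2] == c) ++k2;
    int L = (int)(k2 - k);
    op.push_back(std::string(1, c));
    len.push_back(L);
    ref_start.push_back(rj);
    read_start.push_back(ri);
    if (c == 'M' || c == 'X') { ri += L; rj += L; }
    else if (c == 'D') { rj += L; }
    else { ri += L; }
    k = k2;
  }

  return List::create(
    _["score"] = best_score,
    _["op"] = op,
    _["len"] = len,
    _["ref_start"] = ref_start,
    _["read_start"] = read_start,
    _["matches"] = matches,
    _["mismatches"] = mismatches,
    _["ref_aligned_end"] = end_j);
}
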