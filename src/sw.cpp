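// Smith-Waterman local alignment with affine gaps (Gotoh recursion).
//
// Two entry points:
//   sw_score_all_cpp  -- score-only sweep of every query against every
//                        subject (used to shortlist translated-search hits
//                        before the costlier traceback pass)
//   sw_align_cpp      -- single-pair alignment with full traceback
//
// Gap convention: a gap of length L costs gap_open + L * gap_extend, i.e.
// the first gapped residue is charged open + extend (BLAST convention).

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

namespace {

struct Lut {
  int tab[256];
  explicit Lut(const std::string &alphabet) {
    for (int i = 0; i < 256; ++i) tab[i] = -1;
    for (size_t i = 0; i < alphabet.size(); ++i)
      tab[static_cast<unsigned char>(alphabet[i])] = static_cast<int>(i);
  }
  int operator[](char c) const { return tab[static_cast<unsigned char>(c)]; }
};

std::vector<int> encode(const std::string &s, const Lut &lut,
                        const char *what) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int code = lut[s[i]];
    if (code < 0)
      stop("illegal character '%s' at position %d in %s",
           std::string(1, s[i]).c_str(), static_cast<int>(i + 1), what);
    v[i] = code;
  }
  return v;
}

const int NEG_INF = -(1 << 28);

// flat row-major copy of the substitution matrix for fast inner-loop access
std::vector<int> flatten(const IntegerMatrix &mat) {
  const int k = mat.nrow();
  std::vector<int> flat(k * k);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) flat[i * k + j] = mat(i, j);
  return flat;
}

// score-only Gotoh, two rolling rows
int sw_score(const std::vector<int> &a, const std::vector<int> &b,
             const std::vector<int> &flat, int k, int go, int ge) {
  const int n = static_cast<int>(a.size());
  const int m = static_cast<int>(b.size());
  if (n == 0 || m == 0) return 0;
  std::vector<int> Hprev(m + 1, 0), H(m + 1, 0), Fcol(m + 1, NEG_INF);
  int best = 0;
  const int open_cost = go + ge;
  for (int i = 1; i <= n; ++i) {
    int E = NEG_INF;
    H[0] = 0;
    const int *row = flat.data() + a[i - 1] * k;
    const int *hp = Hprev.data();
    int *h_ = H.data();
    int *f_ = Fcol.data();
    for (int j = 1; j <= m; ++j) {
      E = std::max(h_[j - 1] - open_cost, E - ge);
      int f = std::max(hp[j] - open_cost, f_[j] - ge);
      f_[j] = f;
      int h = hp[j - 1] + row[b[j - 1]];
      h = std::max(h, E);
      h = std::max(h, f);
      h = std::max(h, 0);
      h_[j] = h;
      if (h > best) best = h;
    }
    std::swap(H, Hprev);
  }
  return best;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix sw_score_all_cpp(CharacterVector queries,
                               CharacterVector subjects, IntegerMatrix mat,
                               std::string alphabet, int gap_open,
                               int gap_extend) {
  if (mat.nrow() != mat.ncol() ||
      mat.nrow() != static_cast<int>(alphabet.size()))
    stop("substitution matrix dimensions must match the alphabet length");
  Lut lut(alphabet);
  std::vector<int> flat = flatten(mat);
  const int k = mat.nrow();
  const int nq = queries.size(), ns = subjects.size();
  std::vector<std::vector<int>> subj(ns);
  for (int j = 0; j < ns; ++j)
    subj[j] = encode(as<std::string>(subjects[j]), lut, "subject");
  NumericMatrix out(nq, ns);
  for (int i = 0; i < nq; ++i) {
    std::vector<int> q = encode(as<std::string>(queries[i]), lut, "query");
    for (int j = 0; j < ns; ++j)
      out(i, j) = sw_score(q, subj[j], flat, k, gap_open, gap_extend);
    if (i % 64 == 0) checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b, IntegerMatrix mat,
                  std::string alphabet, int gap_open, int gap_extend) {
  if (mat.nrow() != mat.ncol() ||
      mat.nrow() != static_cast<int>(alphabet.size()))
    stop("substitution matrix dimensions must match the alphabet length");
  Lut lut(alphabet);
  std::vector<int> flat = flatten(mat);
  const int kk = mat.nrow();
  std::vector<int> av = encode(a, lut, "sequence a");
  std::vector<int> bv = encode(b, lut, "sequence b");
  const int n = static_cast<int>(av.size());
  const int m = static_cast<int>(bv.size());
  const int open_cost = gap_open + gap_extend;

  // full H/E/F matrices; sequences at this stage are short (<= a few kb)
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG_INF),
      F((n + 1) * (m + 1), NEG_INF);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int e = std::max(H[idx(i, j - 1)] - open_cost, E[idx(i, j - 1)] - gap_extend);
      int f = std::max(H[idx(i - 1, j)] - open_cost, F[idx(i - 1, j)] - gap_extend);
      int h = H[idx(i - 1, j - 1)] + flat[av[i - 1] * kk + bv[j - 1]];
      h = std::max(std::max(h, e), std::max(f, 0));
      E[idx(i, j)] = e;
      F[idx(i, j)] = f;
      H[idx(i, j)] = h;
      if (h > best) { // first maximum in row-major order is kept on ties
        best = h;
        bi = i;
        bj = j;
      }
    }
  }

  std::string a_aln, b_aln;
  int i = bi, j = bj, matches = 0, gap_opens = 0, mismatches = 0;
  int a_end = bi, b_end = bj;
  // traceback preference on ties: diagonal, then gap in b (up), then gap in a
  enum State { MAIN, INE, INF } state = MAIN;
  while (i > 0 && j > 0) {
    int h = H[idx(i, j)];
    if (state == MAIN) {
      if (h == 0) break;
      int diag = H[idx(i - 1, j - 1)] + flat[av[i - 1] * kk + bv[j - 1]];
      if (h == diag) {
        a_aln.push_back(a[i - 1]);
        b_aln.push_back(b[j - 1]);
        if (av[i - 1] == bv[j - 1]) ++matches; else ++mismatches;
        --i; --j;
        continue;
      }
      if (h == F[idx(i, j)]) state = INF;
      else if (h == E[idx(i, j)]) state = INE;
      else stop("traceback inconsistency"); // LCOV_EXCL_LINE
    } else if (state == INF) { // gap in b, consume a
      a_aln.push_back(a[i - 1]);
      b_aln.push_back('-');
      bool opened = (F[idx(i, j)] == H[idx(i - 1, j)] - open_cost);
      --i;
      if (opened) { // prefer closing the gap on ties
        ++gap_opens;
        state = MAIN;
      }
    } else { // INE: gap in a, consume b
      a_aln.push_back('-');
      b_aln.push_back(b[j - 1]);
      bool opened = (E[idx(i, j)] == H[idx(i, j - 1)] - open_cost);
      --j;
      if (opened) {
        ++gap_opens;
        state = MAIN;
      }
    }
  }
  int a_start = i + 1, b_start = j + 1;
  std::reverse(a_aln.begin(), a_aln.end());
  std::reverse(b_aln.begin(), b_aln.end());
  int columns = static_cast<int>(a_aln.size());
  int a_nongap = 0, b_nongap = 0;
  for (char c : a_aln) if (c != '-') ++a_nongap;
  for (char c : b_aln) if (c != '-') ++b_nongap;
  if (best == 0) { // empty local alignment
    a_start = a_end = b_start = b_end = 0;
    a_aln.clear(); b_aln.clear();
    columns = matches = mismatches = a_nongap = b_nongap = gap_opens = 0;
  }
  return List::create(
      _["score"] = best, _["a_start"] = a_start, _["a_end"] = a_end,
      _["b_start"] = b_start, _["b_end"] = b_end, _["a_aln"] = a_aln,
      _["b_aln"] = b_aln, _["columns"] = columns, _["matches"] = matches,
      _["mismatches"] = mismatches, _["gap_opens"] = gap_opens,
      _["a_nongap"] = a_nongap, _["b_nongap"] = b_nongap);
}
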