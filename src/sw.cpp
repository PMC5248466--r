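#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman with Gotoh's recurrences),
// score only. A gap of length L is charged gap_open + L * gap_extend
// (the first gap residue pays both the opening and the extension term).

static std::vector<int> encode(const std::string &s,
                               const std::vector<int> &lut) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int code = lut[(unsigned char)s[i]];
    if (code < 0) stop("residue '%c' not in the scoring alphabet", s[i]);
    v[i] = code;
  }
  return v;
}

static int sw_score_pair(const std::vector<int> &a, const std::vector<int> &b,
                         const std::vector<int> &sub, int na,
                         int open1, int ext) {
  const int m = (int)a.size(), n = (int)b.size();
  const int NEG = INT_MIN / 4;
  std::vector<int> H(n + 1, 0), F(n + 1, NEG);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int Hdiag = 0;  // H[i-1][j-1]
    int Hleft = 0;  // H[i][j-1]
    int E = NEG;    // gap in subject row direction: E[i][j]
    const int *srow = &sub[(size_t)a[i - 1] * na];
    for (int j = 1; j <= n; ++j) {
      const int Hup = H[j];  // H[i-1][j]
      E = std::max(Hleft - open1, E - ext);
      F[j] = std::max(Hup - open1, F[j] - ext);
      int h = Hdiag + srow[b[j - 1]];
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

// [[Rcpp::export]]
IntegerMatrix sw_score_matrix_cpp(CharacterVector queries,
                                  CharacterVector subjects,
                                  IntegerMatrix submat,
                                  CharacterVector alphabet,
                                  int gap_open, int gap_extend) {
  const int na = alphabet.size();
  std::vector<int> lut(256, -1);
  for (int i = 0; i < na; ++i) {
    std::string s = as<std::string>(alphabet[i]);
    if (s.size() != 1) stop("alphabet entries must be single characters");
    lut[(unsigned char)s[0]] = i;
  }
  std::vector<int> sub((size_t)na * na);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < na; ++j) sub[(size_t)i * na + j] = submat(i, j);

  const int nq = queries.size(), ns = subjects.size();
  std::vector<std::vector<int> > qenc(nq), senc(ns);
  for (int i = 0; i < nq; ++i) qenc[i] = encode(as<std::string>(queries[i]), lut);
  for (int j = 0; j < ns; ++j) senc[j] = encode(as<std::string>(subjects[j]), lut);

  const int open1 = gap_open + gap_extend;
  IntegerMatrix out(nq, ns);
  for (int j = 0; j < ns; ++j) {
    for (int i = 0; i < nq; ++i) {
      out(i, j) = sw_score_pair(qenc[i], senc[j], sub, na, open1, gap_extend);
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Full alignment with deterministic traceback for one pair. Tie-breaking in
// traceback: prefer diagonal, then gap-in-subject (query residue unpaired),
// then gap-in-query. Returns score, identities, alignment length and the
// 1-based spans, plus the aligned (gapped) strings.
// [[Rcpp::export]]
List sw_align_pairs_cpp(CharacterVector queries, CharacterVector subjects,
                        IntegerMatrix submat, CharacterVector alphabet,
                        int gap_open, int gap_extend, bool aligned_strings) {
  if (queries.size() != subjects.size())
    stop("queries and subjects must pair up");
  const int na = alphabet.size();
  std::vector<int> lut(256, -1);
  std::vector<char> rev(na);
  for (int i = 0; i < na; ++i) {
    std::string s = as<std::string>(alphabet[i]);
    lut[(unsigned char)s[0]] = i;
    rev[i] = s[0];
  }
  std::vector<int> sub((size_t)na * na);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < na; ++j) sub[(size_t)i * na + j] = submat(i, j);
  const int open1 = gap_open + gap_extend, NEG = INT_MIN / 4;
  const int npair = queries.size();

  IntegerVector score(npair), ident(npair), alen(npair),
      qs(npair), qe(npair), ss(npair), se(npair);
  CharacterVector qa(npair), sa(npair);

  for (int p = 0; p < npair; ++p) {
    std::string A = as<std::string>(queries[p]);
    std::string B = as<std::string>(subjects[p]);
    std::vector<int> a = encode(A, lut), b = encode(B, lut);
    const int m = (int)a.size(), n = (int)b.size();
    std::vector<int> H((size_t)(m + 1) * (n + 1), 0),
        E((size_t)(m + 1) * (n + 1), NEG),
        F((size_t)(m + 1) * (n + 1), NEG);
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= m; ++i) {
      const int *srow = &sub[(size_t)a[i - 1] * na];
      for (int j = 1; j <= n; ++j) {
        const size_t c = (size_t)i * (n + 1) + j;
        const size_t up = c - (n + 1), left = c - 1, diag = up - 1;
        E[c] = std::max(H[left] - open1, E[left] - gap_extend);
        F[c] = std::max(H[up] - open1, F[up] - gap_extend);
        int h = H[diag] + srow[b[j - 1]];
        if (F[c] > h) h = F[c];
        if (E[c] > h) h = E[c];
        if (h < 0) h = 0;
        H[c] = h;
        // first maximal cell in row-major order wins
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }
    score[p] = best;
    if (best <= 0) {
      ident[p] = 0; alen[p] = 0; qs[p] = NA_INTEGER; qe[p] = NA_INTEGER;
      ss[p] = NA_INTEGER; se[p] = NA_INTEGER;
      qa[p] = ""; sa[p] = "";
      continue;
    }
    // traceback from (bi, bj) in state H until a zero cell
    int i = bi, j = bj, nid = 0, len = 0;
    std::string ga, gb;
    char state = 'H';
    while (true) {
      const size_t c = (size_t)i * (n + 1) + j;
      if (state == 'H') {
        if (H[c] == 0) break;
        const size_t diag = c - (n + 1) - 1;
        int d = H[diag] + sub[(size_t)a[i - 1] * na + b[j - 1]];
        if (H[c] == d) {                      // prefer diagonal
          if (aligned_strings) { ga += A[i - 1]; gb += B[j - 1]; }
          if (a[i - 1] == b[j - 1]) ++nid;
          ++len; --i; --j;
        } else if (H[c] == F[c]) {            // then gap in subject
          state = 'F';
        } else if (H[c] == E[c]) {            // then gap in query
          state = 'E';
        } else stop("traceback inconsistency");
      } else if (state == 'F') {
        const size_t up = c - (n + 1);
        if (aligned_strings) { ga += A[i - 1]; gb += '-'; }
        ++len;
        if (F[c] == H[up] - open1) state = 'H';  // gap opened here
        --i;
      } else {  // E
        if (aligned_strings) { ga += '-'; gb += B[j - 1]; }
        ++len;
        if (E[c] == H[c - 1] - open1) state = 'H';
        --j;
      }
    }
    ident[p] = nid; alen[p] = len;
    qs[p] = i + 1; qe[p] = bi; ss[p] = j + 1; se[p] = bj;
    if (aligned_strings) {
      std::reverse(ga.begin(), ga.end());
      std::reverse(gb.begin(), gb.end());
      qa[p] = ga; sa[p] = gb;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["score"] = score, _["identities"] = ident,
                      _["aln_length"] = alen, _["query_start"] = qs,
                      _["query_end"] = qe, _["subject_start"] = ss,
                      _["subject_end"] = se, _["query_aligned"] = qa,
                      _["subject_aligned"] = sa);
}
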