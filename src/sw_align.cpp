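#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman with affine gaps (Gotoh). A gap of length g costs
// gap_open + g * gap_extend, matching the BLASTP -gapopen/-gapextend
// convention. Traceback ties prefer diagonal, then gap-in-subject
// (query residue vs gap), then gap-in-query; only the score is unique
// across co-optimal alignments.

#ifdef __GNUC__
#define RESTRICT __restrict__
#else
#define RESTRICT
#endif

namespace {

const int NEG_INF = INT_MIN / 4;

struct AlnOut {
  int score, qs, qe, ss, se, nid, ncols;
};

struct Workspace {
  std::vector<int> H, E;
  std::vector<unsigned char> tb;  // bits 0-1: H source (0 stop, 1 diag,
                                  // 2 gap-in-subject, 3 gap-in-query);
                                  // bit 2: E extends E; bit 3: F extends F
};

bool align_pair(const std::vector<int>& q, const std::vector<int>& s,
                const int* sm, int nalpha, int go, int ge,
                Workspace& w, AlnOut& out) {
  const int m = static_cast<int>(q.size());
  const int n = static_cast<int>(s.size());
  const int gap1 = go + ge;

  w.H.assign(n + 1, 0);
  w.E.assign(n + 1, NEG_INF);
  w.tb.assign(static_cast<size_t>(m + 1) * (n + 1), 0);

  int best = 0, bi = 0, bj = 0;
  int* RESTRICT H = w.H.data();
  int* RESTRICT Ev = w.E.data();
  const int* RESTRICT sp = s.data();
  for (int i = 1; i <= m; ++i) {
    int Hdiag = 0;  // H[i-1][j-1]
    int Hleft = 0;  // H[i][j-1]
    int F = NEG_INF;
    const int* RESTRICT srow = sm + static_cast<size_t>(q[i - 1]) * nalpha;
    unsigned char* RESTRICT tbrow = &w.tb[static_cast<size_t>(i) * (n + 1)];
    for (int j = 1; j <= n; ++j) {
      // E: column with a gap in the subject (consumes a query residue);
      // F: column with a gap in the query. Ties prefer opening over
      // extending within E/F, and diag > E > F > stop for the H source.
      const int hup = H[j];  // still holds H[i-1][j]
      const int e_open = hup - gap1;
      const int e_ext = Ev[j] - ge;
      const bool e_x = e_ext > e_open;
      const int E = e_x ? e_ext : e_open;
      Ev[j] = E;
      const int f_open = Hleft - gap1;
      const int f_ext = F - ge;
      const bool f_x = f_ext > f_open;
      F = f_x ? f_ext : f_open;
      const int diag = Hdiag + srow[sp[j - 1]];

      int h = 0, src = 0;
      if (F > 0) { h = F; src = 3; }
      if (E >= h && E > 0) { h = E; src = 2; }
      if (diag >= h && diag > 0) { h = diag; src = 1; }

      Hdiag = hup;
      H[j] = h;
      Hleft = h;
      tbrow[j] = static_cast<unsigned char>(src | (e_x ? 4 : 0) |
                                            (f_x ? 8 : 0));
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (best <= 0) return false;

  int i = bi, j = bj, nid = 0, ncols = 0;
  int state = 0;  // 0 = H, 1 = E (gap in subject), 2 = F (gap in query)
  while (true) {
    unsigned char t = w.tb[static_cast<size_t>(i) * (n + 1) + j];
    if (state == 0) {
      int src = t & 3;
      if (src == 0) break;
      if (src == 1) {
        ++ncols;
        if (q[i - 1] == s[j - 1]) ++nid;
        --i; --j;
      } else if (src == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      ++ncols;
      state = (t & 4) ? 1 : 0;
      --i;
    } else {
      ++ncols;
      state = (t & 8) ? 2 : 0;
      --j;
    }
  }

  out.score = best;
  out.qs = i + 1; out.qe = bi;
  out.ss = j + 1; out.se = bj;
  out.nid = nid; out.ncols = ncols;
  return true;
}

std::vector<std::vector<int> > encode_all(const CharacterVector& seqs,
                                          const CharacterVector& alphabet) {
  int lut[256];
  for (int c = 0; c < 256; ++c) lut[c] = -1;
  for (int a = 0; a < alphabet.size(); ++a) {
    std::string ch = as<std::string>(alphabet[a]);
    if (ch.size() == 1) lut[static_cast<unsigned char>(ch[0])] = a;
  }
  std::vector<std::vector<int> > enc(seqs.size());
  for (int k = 0; k < seqs.size(); ++k) {
    std::string s = as<std::string>(seqs[k]);
    enc[k].resize(s.size());
    for (size_t p = 0; p < s.size(); ++p) {
      int code = lut[static_cast<unsigned char>(s[p])];
      if (code < 0)
        stop("residue '%s' at position %d of sequence %d is not in the scoring alphabet",
             std::string(1, s[p]).c_str(), static_cast<int>(p + 1), k + 1);
      enc[k][p] = code;
    }
  }
  return enc;
}

}  // namespace

// [[Rcpp::export]]
List sw_align_sets_cpp(CharacterVector qseqs, CharacterVector sseqs,
                       IntegerMatrix submat, CharacterVector alphabet,
                       int gap_open, int gap_extend) {
  if (submat.nrow() != submat.ncol() || submat.nrow() != alphabet.size())
    stop("substitution matrix must be square over the alphabet");
  const int nalpha = submat.nrow();
  std::vector<int> sm(static_cast<size_t>(nalpha) * nalpha);
  for (int i = 0; i < nalpha; ++i)
    for (int j = 0; j < nalpha; ++j)
      sm[static_cast<size_t>(i) * nalpha + j] = submat(i, j);

  std::vector<std::vector<int> > qenc = encode_all(qseqs, alphabet);
  std::vector<std::vector<int> > senc = encode_all(sseqs, alphabet);

  std::vector<int> vqi, vsj, vscore, vqs, vqe, vss, vse, vnid, vncols;
  size_t cap = qenc.size() * senc.size();
  vqi.reserve(cap); vsj.reserve(cap); vscore.reserve(cap);

  Workspace w;
  AlnOut out;
  for (size_t qi = 0; qi < qenc.size(); ++qi) {
    for (size_t sj = 0; sj < senc.size(); ++sj) {
      if (align_pair(qenc[qi], senc[sj], sm.data(), nalpha,
                     gap_open, gap_extend, w, out)) {
        vqi.push_back(static_cast<int>(qi) + 1);
        vsj.push_back(static_cast<int>(sj) + 1);
        vscore.push_back(out.score);
        vqs.push_back(out.qs); vqe.push_back(out.qe);
        vss.push_back(out.ss); vse.push_back(out.se);
        vnid.push_back(out.nid); vncols.push_back(out.ncols);
      }
    }
    if (qi % 32 == 31) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["query_idx"] = wrap(vqi), _["subject_idx"] = wrap(vsj),
      _["score"] = wrap(vscore),
      _["query_start"] = wrap(vqs), _["query_end"] = wrap(vqe),
      _["subject_start"] = wrap(vss), _["subject_end"] = wrap(vse),
      _["n_identical"] = wrap(vnid), _["n_columns"] = wrap(vncols));
}
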