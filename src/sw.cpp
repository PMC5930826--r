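// Smith-Waterman local alignment with affine gaps (Gotoh), plus a k-mer
// inverted-index candidate-pair generator. Both are throughput kernels for the
// all-vs-all proteome searches; single-pair R wrappers live in R/align.R.
#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>

using namespace Rcpp;

// Map residue characters onto rows of the substitution matrix. Characters not
// present in the matrix alphabet map to -1 and are rejected upstream.
static std::vector<int> build_lut(const CharacterVector& alphabet) {
  std::vector<int> lut(256, -1);
  for (int i = 0; i < alphabet.size(); ++i) {
    std::string a = as<std::string>(alphabet[i]);
    if (a.size() != 1) stop("alphabet entries must be single characters");
    lut[(unsigned char)a[0]] = i;
  }
  return lut;
}

static void encode_seq(const std::string& s, const std::vector<int>& lut,
                       std::vector<int>& out) {
  out.resize(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int code = lut[(unsigned char)s[i]];
    if (code < 0) stop("residue '%s' not covered by the scoring alphabet",
                       std::string(1, s[i]).c_str());
    out[i] = code;
  }
}

// One alignment. Affine gap model: a gap of length L costs open + L * extend,
// i.e. the first gapped position is charged open + extend. The best-scoring
// cell is the first one reached in row-major order (deterministic tie-break:
// smallest query end, then smallest subject end); traceback prefers
// diagonal over up (gap in subject) over left (gap in query).
struct AlnResult {
  int score, qstart, qend, sstart, send, aln_len, identities;
};

static AlnResult sw_one(const std::vector<int>& q, const std::vector<int>& s,
                        const IntegerMatrix& sub, int open_first, int extend,
                        std::vector<int>& H, std::vector<int>& F,
                        std::vector<int>& G) {
  const int m = (int)q.size(), n = (int)s.size();
  const int W = n + 1;
  const int NEG = INT_MIN / 4;
  // only the first row/column need initialization; interior cells are
  // written before they are read
  size_t need = (size_t)(m + 1) * W;
  if (H.size() < need) { H.resize(need); F.resize(need); G.resize(need); }
  for (int j = 0; j <= n; ++j) { H[j] = 0; F[j] = NEG; G[j] = NEG; }
  for (int i = 1; i <= m; ++i) {
    size_t row0 = (size_t)i * W;
    H[row0] = 0; F[row0] = NEG; G[row0] = NEG;
  }

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const int* subrow = &sub(q[i - 1], 0);
    const int nr = sub.nrow();
    size_t row = (size_t)i * W, prow = (size_t)(i - 1) * W;
    for (int j = 1; j <= n; ++j) {
      int f = std::max(H[prow + j] - open_first, F[prow + j] - extend);
      int g = std::max(H[row + j - 1] - open_first, G[row + j - 1] - extend);
      int d = H[prow + j - 1] + subrow[(size_t)s[j - 1] * nr];
      int h = d;
      if (f > h) h = f;
      if (g > h) h = g;
      if (h < 0) h = 0;
      F[row + j] = f;
      G[row + j] = g;
      H[row + j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  AlnResult r;
  r.score = best;
  if (best == 0) {  // empty-alignment sentinel
    r.qstart = r.qend = r.sstart = r.send = 0;
    r.aln_len = r.identities = 0;
    return r;
  }

  int i = bi, j = bj, aln = 0, ident = 0;
  int state = 0;  // 0 = H, 1 = F (up), 2 = G (left)
  while (true) {
    size_t row = (size_t)i * W, prow = (size_t)(i - 1) * W;
    if (state == 0) {
      int h = H[row + j];
      if (h == 0) break;
      int d = H[prow + j - 1] + sub(q[i - 1], s[j - 1]);
      if (h == d) {
        ++aln;
        if (q[i - 1] == s[j - 1]) ++ident;
        --i; --j;
      } else if (h == F[row + j]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {  // gap in subject, consume query residue
      ++aln;
      bool opened = (F[row + j] == H[prow + j] - open_first);
      --i;
      state = opened ? 0 : 1;
    } else {  // gap in query, consume subject residue
      ++aln;
      bool opened = (G[row + j] == H[row + j - 1] - open_first);
      --j;
      state = opened ? 0 : 2;
    }
  }
  // 0-based half-open spans
  r.qstart = i; r.qend = bi;
  r.sstart = j; r.send = bj;
  r.aln_len = aln;
  r.identities = ident;
  return r;
}

// [[Rcpp::export]]
NumericMatrix sw_batch_cpp(CharacterVector seqs, IntegerMatrix pairs,
                           IntegerMatrix sub, CharacterVector alphabet,
                           int open_first, int extend) {
  if (sub.nrow() != sub.ncol() || sub.nrow() != alphabet.size())
    stop("substitution matrix and alphabet sizes disagree");
  std::vector<int> lut = build_lut(alphabet);

  const int nseq = seqs.size();
  std::vector<std::vector<int>> enc(nseq);
  for (int i = 0; i < nseq; ++i)
    encode_seq(as<std::string>(seqs[i]), lut, enc[i]);

  const int np = pairs.nrow();
  NumericMatrix out(np, 7);
  colnames(out) = CharacterVector::create("score", "qstart", "qend", "sstart",
                                          "send", "aln_len", "identities");
  std::vector<int> H, F, G;
  for (int p = 0; p < np; ++p) {
    int qi = pairs(p, 0) - 1, si = pairs(p, 1) - 1;
    if (qi < 0 || qi >= nseq || si < 0 || si >= nseq)
      stop("pair index out of range");
    AlnResult r = sw_one(enc[qi], enc[si], sub, open_first, extend, H, F, G);
    out(p, 0) = r.score;
    out(p, 1) = r.qstart; out(p, 2) = r.qend;
    out(p, 3) = r.sstart; out(p, 4) = r.send;
    out(p, 5) = r.aln_len; out(p, 6) = r.identities;
    if (p % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// All unordered cross-genome sequence pairs sharing at least one exact k-mer.
// Letters are packed 5 bits each (A-Z), so k <= 12 fits in 64 bits.
// [[Rcpp::export]]
IntegerMatrix kmer_candidate_pairs_cpp(CharacterVector seqs,
                                       IntegerVector genome, int k) {
  if (k < 2 || k > 12) stop("k must be in [2, 12]");
  const int nseq = seqs.size();
  if (genome.size() != nseq) stop("genome vector length mismatch");

  std::unordered_map<uint64_t, std::vector<int>> index;
  index.reserve((size_t)nseq * 64);
  std::unordered_set<uint64_t> seen_local;
  for (int i = 0; i < nseq; ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() < k) continue;
    seen_local.clear();
    uint64_t key = 0;
    const uint64_t mask = (k * 5 >= 64) ? ~0ULL : ((1ULL << (k * 5)) - 1);
    for (size_t p = 0; p < s.size(); ++p) {
      unsigned char c = s[p];
      if (c < 'A' || c > 'Z') stop("sequences must be upper-case A-Z");
      key = ((key << 5) | (uint64_t)(c - 'A')) & mask;
      if ((int)p >= k - 1 && seen_local.insert(key).second)
        index[key].push_back(i);
    }
  }

  std::unordered_set<uint64_t> pairset;
  for (const auto& kv : index) {
    const std::vector<int>& v = kv.second;
    if (v.size() < 2) continue;
    for (size_t a = 0; a + 1 < v.size(); ++a)
      for (size_t b = a + 1; b < v.size(); ++b) {
        if (genome[v[a]] == genome[v[b]]) continue;
        pairset.insert((uint64_t)v[a] * (uint64_t)nseq + (uint64_t)v[b]);
      }
  }

  IntegerMatrix out((int)pairset.size(), 2);
  int r = 0;
  for (uint64_t code : pairset) {
    out(r, 0) = (int)(code / nseq) + 1;
    out(r, 1) = (int)(code % nseq) + 1;
    ++r;
  }
  return out;
}
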