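#include <Rcpp.h>
#include <climits>
#include <cstdint>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh) over the amino-acid alphabet.
// Gap of length L costs open + L * ext (BLAST / Biostrings convention).

struct Aln {
  int score = 0;
  int qs = 0, qe = -1, ss = 0, se = -1;   // 0-based inclusive ends
  int nid = 0, ncols = 0, nmis = 0, ngapopen = 0;
  std::vector<int> qa, sa;                // matched-column residue positions (0-based)
};

static inline int lidx(char c) { return c - 'A'; }

static const int NEG = INT_MIN / 4;

static Aln gotoh_local(const std::string& a, const std::string& b,
                       const int* S, int open, int ext,
                       bool traceback) {
  const int m = (int)a.size(), n = (int)b.size();
  Aln res;
  if (m == 0 || n == 0) return res;
  const int GO = open + ext;
  std::vector<int> Mp(n + 1, 0), Mc(n + 1, 0);
  std::vector<int> Xp(n + 1, NEG), Xc(n + 1, NEG);
  std::vector<int> Yp(n + 1, NEG), Yc(n + 1, NEG);
  std::vector<uint8_t> tbM, tbX, tbY;
  const size_t W = (size_t)n + 1;
  if (traceback) {
    tbM.assign((size_t)(m + 1) * W, 0);
    tbX.assign((size_t)(m + 1) * W, 0);
    tbY.assign((size_t)(m + 1) * W, 0);
  }
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; i++) {
    Mc[0] = 0; Xc[0] = NEG; Yc[0] = NEG;
    const int ai = lidx(a[i - 1]);
    for (int j = 1; j <= n; j++) {
      const int s = S[ai * 26 + lidx(b[j - 1])];
      // M: align a[i-1] with b[j-1]
      int pre = 0; uint8_t tM = 0;
      if (Mp[j - 1] > pre) { pre = Mp[j - 1]; tM = 1; }
      if (Xp[j - 1] > pre) { pre = Xp[j - 1]; tM = 2; }
      if (Yp[j - 1] > pre) { pre = Yp[j - 1]; tM = 3; }
      const int vM = pre + s;
      Mc[j] = vM;
      // X: gap in a, consume b[j-1]
      const int xM = Mc[j - 1] - GO, xX = Xc[j - 1] - ext;
      uint8_t tX = 0; int vX;
      if (xM >= xX) { vX = xM; tX = 0; } else { vX = xX; tX = 1; }
      Xc[j] = vX;
      // Y: gap in b, consume a[i-1]
      const int yM = Mp[j] - GO, yY = Yp[j] - ext;
      uint8_t tY = 0; int vY;
      if (yM >= yY) { vY = yM; tY = 0; } else { vY = yY; tY = 1; }
      Yc[j] = vY;
      if (traceback) {
        const size_t o = (size_t)i * W + j;
        tbM[o] = tM; tbX[o] = tX; tbY[o] = tY;
      }
      if (vM > best) { best = vM; bi = i; bj = j; }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  res.score = best;
  if (best <= 0 || !traceback) return res;
  // Traceback from (bi, bj) in state M.
  int i = bi, j = bj; uint8_t st = 1;  // 1=M, 2=X, 3=Y
  res.qe = bi - 1; res.se = bj - 1;
  while (true) {
    const size_t o = (size_t)i * W + j;
    if (st == 1) {
      res.ncols++;
      res.qa.push_back(i - 1); res.sa.push_back(j - 1);
      if (a[i - 1] == b[j - 1]) res.nid++; else res.nmis++;
      const uint8_t t = tbM[o];
      i--; j--;
      if (t == 0) break;
      st = t;
    } else if (st == 2) {
      res.ncols++;
      const uint8_t t = tbX[o];
      j--;
      if (t == 0) { res.ngapopen++; st = 1; }
    } else {
      res.ncols++;
      const uint8_t t = tbY[o];
      i--;
      if (t == 0) { res.ngapopen++; st = 1; }
    }
  }
  res.qs = i; res.ss = j;
  std::reverse(res.qa.begin(), res.qa.end());
  std::reverse(res.sa.begin(), res.sa.end());
  return res;
}

static std::vector<int> flat26(const IntegerMatrix& S) {
  std::vector<int> v(26 * 26);
  for (int i = 0; i < 26; i++)
    for (int j = 0; j < 26; j++) v[i * 26 + j] = S(i, j);
  return v;
}

// [[Rcpp::export]]
List cpp_local_align(std::string a, std::string b, IntegerMatrix S,
                     int open, int ext) {
  std::vector<int> sv = flat26(S);
  Aln r = gotoh_local(a, b, sv.data(), open, ext, true);
  return List::create(
    _["score"] = r.score, _["qstart"] = r.qs + 1, _["qend"] = r.qe + 1,
    _["sstart"] = r.ss + 1, _["send"] = r.se + 1, _["nid"] = r.nid,
    _["ncols"] = r.ncols, _["mismatch"] = r.nmis, _["gapopen"] = r.ngapopen,
    _["q_aligned"] = wrap(r.qa), _["s_aligned"] = wrap(r.sa));
}

// [[Rcpp::export]]
int cpp_local_score(std::string a, std::string b, IntegerMatrix S,
                    int open, int ext) {
  std::vector<int> sv = flat26(S);
  return gotoh_local(a, b, sv.data(), open, ext, false).score;
}

static void kmer_set(const std::string& s, int k, std::vector<uint32_t>& out) {
  out.clear();
  const int n = (int)s.size();
  if (n < k) return;
  for (int i = 0; i + k <= n; i++) {
    uint32_t v = 0;
    for (int j = 0; j < k; j++) v = v * 26u + (uint32_t)lidx(s[i + j]);
    out.push_back(v);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
}

static int shared_count(const std::vector<uint32_t>& x,
                        const std::vector<uint32_t>& y) {
  size_t i = 0, j = 0; int c = 0;
  while (i < x.size() && j < y.size()) {
    if (x[i] < y[j]) i++;
    else if (x[i] > y[j]) j++;
    else { c++; i++; j++; }
  }
  return c;
}

// All-vs-all hit table over a pooled, id-sorted protein set. Each unordered
// pair is aligned once; pairs sharing no k-mer are skipped when both
// sequences are long enough for the word filter to be safe.
// [[Rcpp::export]]
DataFrame cpp_hit_table(CharacterVector ids, CharacterVector seqs,
                        IntegerMatrix S, int open, int ext,
                        double lambda, double logK, double evalue_max,
                        int kmer, int prefilter_minlen) {
  const int N = ids.size();
  std::vector<int> sv = flat26(S);
  std::vector<std::string> sq(N);
  for (int i = 0; i < N; i++) sq[i] = as<std::string>(seqs[i]);
  std::vector<std::vector<uint32_t>> km(N);
  for (int i = 0; i < N; i++)
    if ((int)sq[i].size() >= prefilter_minlen) kmer_set(sq[i], kmer, km[i]);
  std::vector<int> qi, si;
  std::vector<double> pident, evalue, bits, qcov;
  std::vector<int> alen, mism, gapo, qs, qe, ss, se, raw;
  const double ln2 = std::log(2.0);
  for (int i = 0; i < N; i++) {
    const int mlen = (int)sq[i].size();
    for (int j = i + 1; j < N; j++) {
      const int nlen = (int)sq[j].size();
      if (mlen >= prefilter_minlen && nlen >= prefilter_minlen &&
          shared_count(km[i], km[j]) < 1)
        continue;
      Aln r = gotoh_local(sq[i], sq[j], sv.data(), open, ext, true);
      if (r.score <= 0) continue;
      const double bit = (lambda * r.score - logK) / ln2;
      const double E = (double)mlen * (double)nlen * std::pow(2.0, -bit);
      if (E > evalue_max) continue;
      qi.push_back(i); si.push_back(j);
      pident.push_back(r.ncols > 0 ? 100.0 * r.nid / r.ncols : 0.0);
      alen.push_back(r.ncols); mism.push_back(r.nmis); gapo.push_back(r.ngapopen);
      qs.push_back(r.qs + 1); qe.push_back(r.qe + 1);
      ss.push_back(r.ss + 1); se.push_back(r.se + 1);
      evalue.push_back(E); bits.push_back(bit); raw.push_back(r.score);
      qcov.push_back(mlen > 0 ? (double)(r.qe - r.qs + 1) / mlen : 0.0);
    }
    Rcpp::checkUserInterrupt();
  }
  const int H = (int)qi.size();
  CharacterVector qid(H), sid(H);
  for (int h = 0; h < H; h++) { qid[h] = ids[qi[h]]; sid[h] = ids[si[h]]; }
  return DataFrame::create(
    _["qseqid"] = qid, _["sseqid"] = sid, _["pident"] = wrap(pident),
    _["length"] = wrap(alen), _["mismatch"] = wrap(mism),
    _["gapopen"] = wrap(gapo), _["qstart"] = wrap(qs), _["qend"] = wrap(qe),
    _["sstart"] = wrap(ss), _["send"] = wrap(se), _["evalue"] = wrap(evalue),
    _["bitscore"] = wrap(bits), _["raw"] = wrap(raw),
    _["query_coverage"] = wrap(qcov), _["stringsAsFactors"] = false);
}

// Align one query protein against many subjects, keeping every positive hit.
// [[Rcpp::export]]
DataFrame cpp_query_hits(std::string query, CharacterVector ids,
                         CharacterVector seqs, IntegerMatrix S, int open,
                         int ext, double lambda, double logK,
                         double evalue_max, int kmer, int prefilter_minlen) {
  const int N = ids.size();
  std::vector<int> sv = flat26(S);
  std::vector<uint32_t> kq;
  const bool filt = (int)query.size() >= prefilter_minlen;
  if (filt) kmer_set(query, kmer, kq);
  std::vector<int> si;
  std::vector<double> pident, evalue, bits, qcov;
  std::vector<int> raw, qs, qe, ss, se, alen;
  const double ln2 = std::log(2.0);
  for (int j = 0; j < N; j++) {
    std::string sj = as<std::string>(seqs[j]);
    if (filt && (int)sj.size() >= prefilter_minlen) {
      std::vector<uint32_t> kj;
      kmer_set(sj, kmer, kj);
      if (shared_count(kq, kj) < 1) continue;
    }
    Aln r = gotoh_local(query, sj, sv.data(), open, ext, true);
    if (r.score <= 0) continue;
    const double bit = (lambda * r.score - logK) / ln2;
    const double E = (double)query.size() * (double)sj.size() * std::pow(2.0, -bit);
    if (E > evalue_max) continue;
    si.push_back(j);
    pident.push_back(r.ncols > 0 ? 100.0 * r.nid / r.ncols : 0.0);
    alen.push_back(r.ncols); raw.push_back(r.score);
    qs.push_back(r.qs + 1); qe.push_back(r.qe + 1);
    ss.push_back(r.ss + 1); se.push_back(r.se + 1);
    evalue.push_back(E); bits.push_back(bit);
    qcov.push_back((double)(r.qe - r.qs + 1) / (double)query.size());
  }
  const int H = (int)si.size();
  CharacterVector sid(H);
  for (int h = 0; h < H; h++) sid[h] = ids[si[h]];
  return DataFrame::create(
    _["sseqid"] = sid, _["pident"] = wrap(pident), _["length"] = wrap(alen),
    _["qstart"] = wrap(qs), _["qend"] = wrap(qe), _["sstart"] = wrap(ss),
    _["send"] = wrap(se), _["evalue"] = wrap(evalue),
    _["bitscore"] = wrap(bits), _["raw"] = wrap(raw),
    _["query_coverage"] = wrap(qcov), _["stringsAsFactors"] = false);
}
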