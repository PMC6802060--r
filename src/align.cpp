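#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_map>
using namespace Rcpp;

static const int NEG = -1000000000;

// ---------------------------------------------------------------------------
// Affine-gap local alignment of two integer-encoded protein sequences.
// Encoding must index into the substitution matrix S. Gap of length k costs
// gap_open + k * gap_ext.
// [[Rcpp::export]]
List cpp_sw_aa(IntegerVector a, IntegerVector b, IntegerMatrix S,
               int gap_open, int gap_ext) {
  int m = a.size(), n = b.size();
  std::vector<int> M((m + 1) * (n + 1), 0), E((m + 1) * (n + 1), NEG),
      F((m + 1) * (n + 1), NEG);
  std::vector<unsigned char> tr((m + 1) * (n + 1), 0);  // 0 stop,1 diag,2 up(gap in b),3 left(gap in a)
  auto idx = [n](int i, int j) { return i * (n + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int e = std::max(M[idx(i, j - 1)] - gap_open - gap_ext,
                       E[idx(i, j - 1)] == NEG ? NEG : E[idx(i, j - 1)] - gap_ext);
      int f = std::max(M[idx(i - 1, j)] - gap_open - gap_ext,
                       F[idx(i - 1, j)] == NEG ? NEG : F[idx(i - 1, j)] - gap_ext);
      E[idx(i, j)] = e;
      F[idx(i, j)] = f;
      int s = S(a[i - 1], b[j - 1]);
      int diag = M[idx(i - 1, j - 1)] + s;
      int v = 0;
      unsigned char t = 0;
      if (diag > v) { v = diag; t = 1; }
      if (f > v) { v = f; t = 2; }
      if (e > v) { v = e; t = 3; }
      M[idx(i, j)] = v;
      tr[idx(i, j)] = t;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  std::vector<int> col_i, col_j, col_m;
  int i = bi, j = bj;
  while (i > 0 && j > 0 && M[idx(i, j)] > 0) {
    unsigned char t = tr[idx(i, j)];
    if (t == 0) break;
    if (t == 1) {
      col_i.push_back(i);
      col_j.push_back(j);
      col_m.push_back(a[i - 1] == b[j - 1] ? 1 : 0);
      --i; --j;
    } else if (t == 2) {
      // gap in b: walk up through F until it came from M
      while (i > 0 && F[idx(i, j)] != M[idx(i - 1, j)] - gap_open - gap_ext &&
             F[idx(i, j)] != NEG)
        --i;
      --i;
    } else {
      while (j > 0 && E[idx(i, j)] != M[idx(i, j - 1)] - gap_open - gap_ext &&
             E[idx(i, j)] != NEG)
        --j;
      --j;
    }
  }
  // columns are in reverse order; trim terminal mismatch runs so the reported
  // extent reflects the homologous core rather than score-neutral tail creep
  int lo = 0, hi = (int)col_m.size() - 1;
  while (lo <= hi && col_m[hi] == 0) --hi;  // alignment start side
  while (lo <= hi && col_m[lo] == 0) ++lo;  // alignment end side
  int matches = 0, aligned = 0;
  int ai = 0, aj = 0, ae = 0, be = 0;
  if (lo <= hi) {
    for (int k = lo; k <= hi; ++k) {
      ++aligned;
      matches += col_m[k];
    }
    ai = col_i[hi]; aj = col_j[hi];  // smallest (start) coordinates
    ae = col_i[lo]; be = col_j[lo];  // largest (end) coordinates
  }
  return List::create(_["score"] = best, _["a_start"] = ai, _["a_end"] = ae,
                      _["b_start"] = aj, _["b_end"] = be,
                      _["matches"] = matches, _["aligned"] = aligned);
}

// ---------------------------------------------------------------------------
// Affine-gap local nucleotide alignment with full column trace (needed to
// measure identity within a genomic sub-window of the alignment).
// [[Rcpp::export]]
List cpp_sw_nt(std::string a, std::string b, int match, int mismatch,
               int gap_open, int gap_ext) {
  int m = a.size(), n = b.size();
  std::vector<int> M((m + 1) * (n + 1), 0), E((m + 1) * (n + 1), NEG),
      F((m + 1) * (n + 1), NEG);
  std::vector<unsigned char> tr((m + 1) * (n + 1), 0);
  auto idx = [n](int i, int j) { return i * (n + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int e = std::max(M[idx(i, j - 1)] - gap_open - gap_ext,
                       E[idx(i, j - 1)] == NEG ? NEG : E[idx(i, j - 1)] - gap_ext);
      int f = std::max(M[idx(i - 1, j)] - gap_open - gap_ext,
                       F[idx(i - 1, j)] == NEG ? NEG : F[idx(i - 1, j)] - gap_ext);
      E[idx(i, j)] = e;
      F[idx(i, j)] = f;
      int s = (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? match : mismatch;
      if (a[i - 1] == 'N' || b[j - 1] == 'N') s = 0;
      int diag = M[idx(i - 1, j - 1)] + s;
      int v = 0;
      unsigned char t = 0;
      if (diag > v) { v = diag; t = 1; }
      if (f > v) { v = f; t = 2; }
      if (e > v) { v = e; t = 3; }
      M[idx(i, j)] = v;
      tr[idx(i, j)] = t;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  std::vector<int> apos, bpos, mflag;
  int i = bi, j = bj;
  while (i > 0 && j > 0 && M[idx(i, j)] > 0) {
    unsigned char t = tr[idx(i, j)];
    if (t == 0) break;
    if (t == 1) {
      apos.push_back(i);
      bpos.push_back(j);
      mflag.push_back(a[i - 1] == b[j - 1] && a[i - 1] != 'N' ? 1 : 0);
      --i; --j;
    } else if (t == 2) {
      while (i > 0 && F[idx(i, j)] != M[idx(i - 1, j)] - gap_open - gap_ext &&
             F[idx(i, j)] != NEG)
        --i;
      --i;
    } else {
      while (j > 0 && E[idx(i, j)] != M[idx(i, j - 1)] - gap_open - gap_ext &&
             E[idx(i, j)] != NEG)
        --j;
      --j;
    }
  }
  std::reverse(apos.begin(), apos.end());
  std::reverse(bpos.begin(), bpos.end());
  std::reverse(mflag.begin(), mflag.end());
  return List::create(_["score"] = best,
                      _["a_pos"] = wrap(apos), _["b_pos"] = wrap(bpos),
                      _["match"] = wrap(mflag));
}

// ---------------------------------------------------------------------------
// Splice- and frameshift-aware local alignment of a protein against genomic
// DNA. States: codon match (scored by S through the codon translation),
// frameshift (residue consumes 1, 2, 4 or 5 bases; fixed penalty), residue /
// codon skip (linear gap penalty), and intron (entered after GT, left before
// AG, between codons only, fixed penalty, length >= min_intron).
//
// prot: 0-based indices into S; codon_aa: length-64 map (16*b1+4*b2+b3, bases
// A0 C1 G2 T3) to S indices; ncodon_index: S index used for codons containing
// N (scores 0 by construction of S in the R wrapper).

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
List cpp_spliced_align(IntegerVector prot, std::string dna, IntegerMatrix S,
                       IntegerVector codon_aa, int ncodon_index,
                       int stop_index, int fs_pen, int intron_pen,
                       int gap_pen, int min_intron) {
  int m = prot.size(), n = dna.size();
  if ((double)(m + 1) * (n + 1) > 3e8)
    stop("spliced alignment problem too large (%d aa x %d bp)", m, n);
  // per-codon-end aa index: aa_at[j] for codon ending at 1-based j (j>=3)
  std::vector<int> aa_at(n + 1, -1);
  for (int j = 3; j <= n; ++j) {
    int b1 = base_idx(dna[j - 3]), b2 = base_idx(dna[j - 2]),
        b3 = base_idx(dna[j - 1]);
    aa_at[j] = (b1 < 0 || b2 < 0 || b3 < 0) ? ncodon_index
                                            : codon_aa[16 * b1 + 4 * b2 + b3];
  }
  std::vector<int> Hprev(n + 1, NEG), Hcur(n + 1, NEG), Mcur(n + 1, NEG);
  std::vector<int> dbprev(n + 1, NEG), dbcur(n + 1, NEG);
  std::vector<int> daprev(n + 1, -1), dacur(n + 1, -1);
  // trace matrices: M ops and H ops
  // M op: 0 none, 1 start, 2 diag, 3 fs(c=1), 4 fs(2), 5 fs(4), 6 fs(5), 7 intron
  // H op: 0 none, 1 =M, 2 res-skip (from H[i-1][j]), 3 codon-skip (from H[i][j-3])
  std::vector<unsigned char> trM((size_t)(m + 1) * (n + 1), 0),
      trH((size_t)(m + 1) * (n + 1), 0);
  std::unordered_map<long long, int> donor_of;  // (i,j) of intron M-op -> donor pos
  auto idx = [n](int i, int j) { return (size_t)i * (n + 1) + j; };
  auto donor_ok = [&](int j) {  // dna pos j (1-based, consumed up to j); intron starts at j+1
    return j + 2 <= n && dna[j] == 'G' && dna[j + 1] == 'T';
  };
  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    std::fill(Mcur.begin(), Mcur.end(), NEG);
    std::fill(Hcur.begin(), Hcur.end(), NEG);
    std::fill(dbcur.begin(), dbcur.end(), NEG);
    std::fill(dacur.begin(), dacur.end(), -1);
    int p = prot[i - 1];
    for (int j = 3; j <= n; ++j) {
      int s = S(p, aa_at[j]);
      int v = s;  // fresh local start
      unsigned char op = 1;
      int dpos = -1;
      if (Hprev[j - 3] != NEG && Hprev[j - 3] + s > v) {
        v = Hprev[j - 3] + s; op = 2;
      }
      static const int clens[4] = {1, 2, 4, 5};
      static const unsigned char fops[4] = {3, 4, 5, 6};
      for (int k = 0; k < 4; ++k) {
        int jp = j - clens[k];
        if (jp >= 3 && Hprev[jp] != NEG && Hprev[jp] + s + fs_pen > v) {
          v = Hprev[jp] + s + fs_pen; op = fops[k];
        }
      }
      int cut = j - 3 - min_intron;
      if (cut >= 3 && j >= 5 && dna[j - 5] == 'A' && dna[j - 4] == 'G' &&
          dbprev[cut] != NEG && dbprev[cut] + intron_pen + s > v) {
        v = dbprev[cut] + intron_pen + s;
        op = 7;
        dpos = daprev[cut];
      }
      Mcur[j] = v;
      trM[idx(i, j)] = op;
      if (op == 7) donor_of[(long long)i * (n + 1) + j] = dpos;
      if (v > best) { best = v; bi = i; bj = j; }
      // H row
      int hv = v;
      unsigned char hop = 1;
      if (Hprev[j] != NEG && Hprev[j] + gap_pen > hv) { hv = Hprev[j] + gap_pen; hop = 2; }
      if (j >= 6 && Hcur[j - 3] != NEG && Hcur[j - 3] + gap_pen > hv) {
        hv = Hcur[j - 3] + gap_pen; hop = 3;
      }
      Hcur[j] = hv;
      trH[idx(i, j)] = hop;
      // donor prefix max for this row
      dbcur[j] = dbcur[j - 1];
      dacur[j] = dacur[j - 1];
      if (donor_ok(j) && hv != NEG && hv > dbcur[j]) { dbcur[j] = hv; dacur[j] = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(dbprev, dbcur);
    std::swap(daprev, dacur);
  }
  if (bi < 0 || best <= 0) {
    return List::create(_["score"] = 0, _["aligned"] = 0);
  }
  // traceback
  std::vector<int> res_i, res_j;           // aligned residues (codon-ending)
  std::vector<int> res_fs, res_stop, res_m;
  std::vector<int> intron_start, intron_end;  // 1-based inclusive dna coords
  std::vector<int> intron_prot;               // protein position before intron
  int i = bi, j = bj;
  bool inM = true;
  while (i > 0 && j >= 3) {
    if (inM) {
      unsigned char op = trM[idx(i, j)];
      if (op == 0) break;
      res_i.push_back(i);
      res_j.push_back(j);
      res_fs.push_back(op >= 3 && op <= 6 ? 1 : 0);
      res_stop.push_back(aa_at[j] == stop_index ? 1 : 0);
      res_m.push_back(prot[i - 1] == aa_at[j] ? 1 : 0);
      if (op == 1) break;  // local start
      int jp;
      if (op == 2) jp = j - 3;
      else if (op == 3) jp = j - 1;
      else if (op == 4) jp = j - 2;
      else if (op == 5) jp = j - 4;
      else if (op == 6) jp = j - 5;
      else {  // intron
        int d = donor_of[(long long)i * (n + 1) + j];
        intron_start.push_back(d + 1);
        intron_end.push_back(j - 3);
        intron_prot.push_back(i - 1);
        jp = d;
      }
      --i;
      j = jp;
      inM = false;
    } else {
      unsigned char hop = trH[idx(i, j)];
      if (hop == 0) break;
      if (hop == 1) { inM = true; }
      else if (hop == 2) { --i; }
      else { j -= 3; }
    }
  }
  std::reverse(res_i.begin(), res_i.end());
  std::reverse(res_j.begin(), res_j.end());
  std::reverse(res_fs.begin(), res_fs.end());
  std::reverse(res_stop.begin(), res_stop.end());
  std::reverse(res_m.begin(), res_m.end());
  std::reverse(intron_start.begin(), intron_start.end());
  std::reverse(intron_end.begin(), intron_end.end());
  std::reverse(intron_prot.begin(), intron_prot.end());
  int aligned = res_i.size();
  int matches = 0;
  for (int k = 0; k < aligned; ++k) matches += res_m[k];
  StringVector codons(aligned);
  for (int k = 0; k < aligned; ++k)
    codons[k] = dna.substr(res_j[k] - 3, 3);
  return List::create(
      _["score"] = best, _["aligned"] = aligned, _["matches"] = matches,
      _["prot_start"] = res_i.front(), _["prot_end"] = res_i.back(),
      _["dna_start"] = res_j.front() - 2, _["dna_end"] = res_j.back(),
      _["res_prot"] = wrap(res_i), _["res_dna_end"] = wrap(res_j),
      _["res_fs"] = wrap(res_fs), _["res_stop"] = wrap(res_stop),
      _["res_match"] = wrap(res_m), _["codons"] = codons,
      _["intron_start"] = wrap(intron_start),
      _["intron_end"] = wrap(intron_end),
      _["intron_prot"] = wrap(intron_prot),
      _["n_intron"] = (int)intron_start.size());
}
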