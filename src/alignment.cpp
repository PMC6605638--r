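// Alignment kernels: affine-gap Smith-Waterman (single and multi-hit),
// position-specific profile scan, and the spliced protein-to-genome DP
// (intron-aware, frameshift- and stop-tolerant gene model prediction).
//
// Conventions shared with the R layer:
//   * gap_open / gap_extend are NEGATIVE; a gap of length L scores
//     gap_open + (L-1)*gap_extend.
//   * all coordinates returned are 1-based inclusive.
#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cctype>
using namespace Rcpp;

static const double NEG_INF = -1e30;

// 256-entry residue -> matrix row lookup; unknown residues map to 'X'
// (or -1 if the alphabet has no X), lowercase folds to uppercase.
static std::vector<int> make_lut(const std::string& alphabet) {
  std::vector<int> lut(256, -2);
  for (size_t k = 0; k < alphabet.size(); ++k)
    lut[(unsigned char)alphabet[k]] = (int)k;
  int xi = lut[(unsigned char)'X'];
  if (xi == -2) xi = -1;
  for (int c = 0; c < 256; ++c) if (lut[c] == -2) lut[c] = xi;
  for (int c = 'a'; c <= 'z'; ++c) lut[c] = lut[toupper(c)];
  return lut;
}

// standard genetic code, codon index = 16*b1 + 4*b2 + b3 with A=0,C=1,G=2,T=3
static const char CODON_TABLE[65] =
  "KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLLEDEDAAAAGGGGVVVV*Y*YSSSS*CWCLFLF";

static inline int base_idx(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char translate3(char a, char b, char c) {
  int i1 = base_idx(a), i2 = base_idx(b), i3 = base_idx(c);
  if (i1 < 0 || i2 < 0 || i3 < 0) return 'X';
  return CODON_TABLE[16 * i1 + 4 * i2 + i3];
}

// ---------------------------------------------------------------------------
// Smith-Waterman, affine gaps. multihit=FALSE returns the single best local
// alignment; multihit=TRUE returns all alignments with score >= min_score
// whose subject footprints do not overlap a better hit (greedy, score-ordered).
// ---------------------------------------------------------------------------

struct SWHit {
  double score;
  int q_start, q_end, s_start, s_end, matches, aln_len;
};

// [[Rcpp::export]]
DataFrame cpp_sw_align(std::string query, std::string subject,
                       NumericMatrix submat, std::string alphabet,
                       double gap_open, double gap_extend,
                       bool multihit, double min_score, int max_hits) {
  const int m = (int)query.size(), n = (int)subject.size();
  std::vector<double> sc, qs, qe, ss, se, mt, al;
  if (m == 0 || n == 0) {
    return DataFrame::create(_["raw_score"] = sc, _["q_start"] = qs,
                             _["q_end"] = qe, _["s_start"] = ss,
                             _["s_end"] = se, _["matches"] = mt,
                             _["aln_len"] = al);
  }
  std::vector<int> lut = make_lut(alphabet);
  const int na = (int)alphabet.size();
  std::vector<double> flat((size_t)na * na);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < na; ++j) flat[(size_t)i * na + j] = submat(i, j);
  std::vector<int> Q(m + 1), S(n + 1);
  for (int i = 1; i <= m; ++i) Q[i] = lut[(unsigned char)query[i - 1]];
  for (int j = 1; j <= n; ++j) S[j] = lut[(unsigned char)subject[j - 1]];

  const size_t W = (size_t)n + 1;
  std::vector<float> H((size_t)(m + 1) * W, 0.0f);
  std::vector<unsigned char> ptrH((size_t)(m + 1) * W, 0),
      ptrE((size_t)(m + 1) * W, 0), ptrF((size_t)(m + 1) * W, 0);
  std::vector<double> Erow(W, NEG_INF), Frow(W, NEG_INF);
  std::vector<double> Hprev(W, 0.0), Hcur(W, 0.0);

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0.0;
    double Fdiag; // F is column-wise; track per column
    for (int j = 1; j <= n; ++j) {
      // E: gap in query (consumes subject)
      double e_open = Hcur[j - 1] + gap_open;
      double e_ext = (j > 1 ? Erow[j - 1] + gap_extend : NEG_INF);
      double E;
      if (e_open >= e_ext) { E = e_open; ptrE[(size_t)i * W + j] = 1; }
      else { E = e_ext; ptrE[(size_t)i * W + j] = 2; }
      Erow[j] = E;
      // F: gap in subject (consumes query); Frow[j] currently holds F[i-1][j]
      double f_open = Hprev[j] + gap_open;
      double f_ext = Frow[j] + gap_extend;
      if (f_open >= f_ext) { Fdiag = f_open; ptrF[(size_t)i * W + j] = 1; }
      else { Fdiag = f_ext; ptrF[(size_t)i * W + j] = 2; }
      Frow[j] = Fdiag;
      double diag = Hprev[j - 1] +
        ((Q[i] >= 0 && S[j] >= 0) ? flat[(size_t)Q[i] * na + S[j]] : -4.0);
      double h = 0.0; unsigned char p = 0;
      if (diag > h) { h = diag; p = 1; }
      if (E > h) { h = E; p = 2; }
      if (Fdiag > h) { h = Fdiag; p = 3; }
      Hcur[j] = h;
      H[(size_t)i * W + j] = (float)h;
      ptrH[(size_t)i * W + j] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::fill(Erow.begin(), Erow.end(), NEG_INF);
  }

  // candidate end cells
  std::vector<std::pair<double, std::pair<int, int> > > cand;
  if (multihit) {
    for (int i = 1; i <= m; ++i)
      for (int j = 1; j <= n; ++j) {
        double h = H[(size_t)i * W + j];
        if (h >= min_score) cand.push_back({h, {i, j}});
      }
    std::sort(cand.begin(), cand.end(),
              [](const std::pair<double, std::pair<int, int> >& a,
                 const std::pair<double, std::pair<int, int> >& b) {
                if (a.first != b.first) return a.first > b.first;
                if (a.second.second != b.second.second)
                  return a.second.second < b.second.second;
                return a.second.first < b.second.first;
              });
  } else if (best > 0.0) {
    cand.push_back({best, {bi, bj}});
  }

  std::vector<char> used(n + 1, 0);
  int kept = 0;
  for (size_t c = 0; c < cand.size(); ++c) {
    if (max_hits > 0 && kept >= max_hits) break;
    int i = cand[c].second.first, j = cand[c].second.second;
    if (used[j]) continue;
    // traceback
    int qi = i, sj = j, matches = 0, alen = 0;
    bool clash = false;
    int q_hi = i, s_hi = j;
    while (qi > 0 && sj > 0) {
      unsigned char p = ptrH[(size_t)qi * W + sj];
      if (p == 0) break;
      if (p == 1) {
        if (used[sj]) { clash = true; break; }
        if (query[qi - 1] == subject[sj - 1]) ++matches;
        ++alen; --qi; --sj;
      } else if (p == 2) {
        while (true) {
          if (used[sj]) { clash = true; break; }
          unsigned char pe = ptrE[(size_t)qi * W + sj];
          ++alen; --sj;
          if (pe == 1) break;
        }
        if (clash) break;
      } else { // p == 3
        while (true) {
          unsigned char pf = ptrF[(size_t)qi * W + sj];
          ++alen; --qi;
          if (pf == 1) break;
        }
      }
    }
    if (clash) continue;
    int q_lo = qi + 1, s_lo = sj + 1;
    if (multihit) for (int t = s_lo; t <= s_hi; ++t) used[t] = 1;
    sc.push_back(cand[c].first); qs.push_back(q_lo); qe.push_back(q_hi);
    ss.push_back(s_lo); se.push_back(s_hi);
    mt.push_back(matches); al.push_back(alen);
    ++kept;
  }
  return DataFrame::create(_["raw_score"] = sc, _["q_start"] = qs,
                           _["q_end"] = qe, _["s_start"] = ss,
                           _["s_end"] = se, _["matches"] = mt,
                           _["aln_len"] = al);
}

// ---------------------------------------------------------------------------
// Local alignment of a position-specific scoring profile (rows = profile
// columns, cols = amino acids in aa_order) against a protein sequence.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_profile_scan(NumericMatrix prof, std::string seq, std::string aa_order,
                      double gap_open, double gap_extend, double unknown_score) {
  const int m = prof.nrow(), n = (int)seq.size();
  if (m == 0 || n == 0) return List::create(_["score"] = 0.0);
  std::vector<int> lut(256, -1);
  for (size_t k = 0; k < aa_order.size(); ++k)
    lut[(unsigned char)aa_order[k]] = (int)k;
  for (int c = 'a'; c <= 'z'; ++c) lut[c] = lut[toupper(c)];
  std::vector<int> S(n + 1);
  for (int j = 1; j <= n; ++j) S[j] = lut[(unsigned char)seq[j - 1]];

  const size_t W = (size_t)n + 1;
  std::vector<unsigned char> ptrH((size_t)(m + 1) * W, 0),
      ptrE((size_t)(m + 1) * W, 0), ptrF((size_t)(m + 1) * W, 0);
  std::vector<double> Erow(W, NEG_INF), Frow(W, NEG_INF), Hprev(W, 0.0),
      Hcur(W, 0.0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0.0;
    for (int j = 1; j <= n; ++j) {
      double e_open = Hcur[j - 1] + gap_open;
      double e_ext = (j > 1 ? Erow[j - 1] + gap_extend : NEG_INF);
      double E;
      if (e_open >= e_ext) { E = e_open; ptrE[(size_t)i * W + j] = 1; }
      else { E = e_ext; ptrE[(size_t)i * W + j] = 2; }
      Erow[j] = E;
      double f_open = Hprev[j] + gap_open;
      double f_ext = Frow[j] + gap_extend;
      double F;
      if (f_open >= f_ext) { F = f_open; ptrF[(size_t)i * W + j] = 1; }
      else { F = f_ext; ptrF[(size_t)i * W + j] = 2; }
      Frow[j] = F;
      double s = (S[j] >= 0) ? prof(i - 1, S[j]) : unknown_score;
      double diag = Hprev[j - 1] + s;
      double h = 0.0; unsigned char p = 0;
      if (diag > h) { h = diag; p = 1; }
      if (E > h) { h = E; p = 2; }
      if (F > h) { h = F; p = 3; }
      Hcur[j] = h; ptrH[(size_t)i * W + j] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::fill(Erow.begin(), Erow.end(), NEG_INF);
  }
  if (best <= 0.0) return List::create(_["score"] = 0.0);
  int qi = bi, sj = bj;
  while (qi > 0 && sj > 0) {
    unsigned char p = ptrH[(size_t)qi * W + sj];
    if (p == 0) break;
    if (p == 1) { --qi; --sj; }
    else if (p == 2) {
      while (true) { unsigned char pe = ptrE[(size_t)qi * W + sj]; --sj; if (pe == 1) break; }
    } else {
      while (true) { unsigned char pf = ptrF[(size_t)qi * W + sj]; --qi; if (pf == 1) break; }
    }
  }
  return List::create(_["score"] = best, _["p_start"] = qi + 1,
                      _["p_end"] = bi, _["s_start"] = sj + 1,
                      _["s_end"] = bj);
}

// ---------------------------------------------------------------------------
// Spliced protein-to-genome alignment (forward strand of `dna` only; the R
// wrapper handles the reverse strand). Local DP over (protein residue i,
// genomic position j) where state M[i][j] means residue i is aligned to a
// codon ending at j. Moves:
//   * adjacent codon (3 nt), substitution score from submat; in-frame stop
//     codons score stop_penalty and are recorded as internal_stop lesions;
//   * 4 nt or 2 nt "codons" (single-base insertion/deletion), scored with
//     frameshift_penalty, recorded as frameshift lesions;
//   * protein-residue deletion (Dp) and genomic codon insertion (Dc),
//     affine-gapped;
//   * intron jump between codons over a GT..AG pair >= min_intron nt,
//     penalised by intron_penalty.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_spliced_align(std::string protein, std::string dna,
                       NumericMatrix submat, std::string alphabet,
                       double gap_open, double gap_extend,
                       double intron_penalty, int min_intron,
                       double frameshift_penalty, double stop_penalty) {
  const int m = (int)protein.size(), n = (int)dna.size();
  if (m < 1 || n < 3) return List::create(_["score"] = NEG_INF);
  std::vector<int> lut = make_lut(alphabet);
  const int na = (int)alphabet.size();
  std::vector<double> flat((size_t)na * na);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < na; ++j) flat[(size_t)i * na + j] = submat(i, j);
  std::vector<int> P(m + 1);
  for (int i = 1; i <= m; ++i) P[i] = lut[(unsigned char)protein[i - 1]];
  std::vector<char> aaend(n + 1, 0);
  std::vector<int> aaidx(n + 1, -1);
  for (int j = 3; j <= n; ++j) {
    aaend[j] = translate3(dna[j - 3], dna[j - 2], dna[j - 1]);
    aaidx[j] = lut[(unsigned char)aaend[j]];
  }
  // isGT[a]: dna[a..a+1] == "GT" (1-based); isAGend[b]: dna[b-1..b] == "AG"
  std::vector<char> isGT(n + 2, 0), isAGend(n + 2, 0);
  for (int a = 1; a <= n - 1; ++a)
    isGT[a] = (dna[a - 1] == 'G' && dna[a] == 'T');
  for (int b = 2; b <= n; ++b)
    isAGend[b] = (dna[b - 2] == 'A' && dna[b - 1] == 'G');

  const size_t W = (size_t)n + 1;
  std::vector<float> M((size_t)(m + 1) * W);
  std::fill(M.begin(), M.end(), (float)NEG_INF);
  std::vector<unsigned char> ptrM((size_t)(m + 1) * W, 0),
      ptrDp((size_t)(m + 1) * W, 0), ptrDc((size_t)(m + 1) * W, 0);
  std::vector<double> DpPrev(W, NEG_INF), DpCur(W, NEG_INF),
      DcPrev(W, NEG_INF), DcCur(W, NEG_INF), donor(W, NEG_INF);

  double best = NEG_INF; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    // donor[t] = max over exon ends e <= t with GT at e+1 of M[i-1][e]
    double run = NEG_INF;
    for (int t = 0; t <= n; ++t) {
      if (t >= 3 && t + 1 <= n - 1 && isGT[t + 1]) {
        double v = M[(size_t)(i - 1) * W + t];
        if (v > run) run = v;
      }
      donor[t] = run;
    }
    // Dp row: delete protein residue i (no DNA consumed)
    for (int k = 0; k <= n; ++k) {
      double d_open = (double)M[(size_t)(i - 1) * W + k] + gap_open;
      double d_ext = DpPrev[k] + gap_extend;
      if (d_open >= d_ext) { DpCur[k] = d_open; ptrDp[(size_t)i * W + k] = 1; }
      else { DpCur[k] = d_ext; ptrDp[(size_t)i * W + k] = 2; }
    }
    std::fill(DcCur.begin(), DcCur.end(), NEG_INF);
    for (int j = 3; j <= n; ++j) {
      const int s = j - 2; // codon start
      double prev = 0.0; unsigned char code = 1; // fresh local start
      if (j - 3 >= 3) {
        double v = M[(size_t)(i - 1) * W + (j - 3)];
        if (v > prev) { prev = v; code = 2; }
        v = DpPrev[j - 3];
        if (v > prev) { prev = v; code = 3; }
        v = DcPrev[j - 3];
        if (v > prev) { prev = v; code = 4; }
      }
      if (j - 4 >= 3) {
        double v = M[(size_t)(i - 1) * W + (j - 4)] + frameshift_penalty;
        if (v > prev) { prev = v; code = 5; }
      }
      if (s - 1 >= 2 && isAGend[s - 1]) {
        int t = s - 1 - min_intron;
        if (t >= 3) {
          double v = donor[t] + intron_penalty;
          if (v > prev) { prev = v; code = 6; }
        }
      }
      double sub = (aaend[j] == '*')
        ? stop_penalty
        : ((P[i] >= 0 && aaidx[j] >= 0) ? flat[(size_t)P[i] * na + aaidx[j]]
                                        : -4.0);
      double mval = sub + prev; unsigned char mcode = code;
      if (j - 2 >= 3) {
        double fs2 = (double)M[(size_t)(i - 1) * W + (j - 2)] + frameshift_penalty;
        if (fs2 > mval) { mval = fs2; mcode = 7; }
      }
      M[(size_t)i * W + j] = (float)mval;
      ptrM[(size_t)i * W + j] = mcode;
      if (mval > best) { best = mval; bi = i; bj = j; }
      // Dc: skip a genomic codon (insertion in the gene relative to template)
      double extra = (aaend[j] == '*') ? stop_penalty : 0.0;
      double c_open = (double)M[(size_t)i * W + (j - 3)] + gap_open;
      double c_ext = DcCur[j - 3] + gap_extend;
      double dc;
      if (c_open >= c_ext) { dc = c_open; ptrDc[(size_t)i * W + j] = 1; }
      else { dc = c_ext; ptrDc[(size_t)i * W + j] = 2; }
      DcCur[j] = dc + extra;
    }
    std::swap(DpPrev, DpCur);
    std::swap(DcPrev, DcCur);
  }
  if (best <= 0.0) return List::create(_["score"] = NEG_INF);

  // traceback
  int i = bi, j = bj;
  char state = 'M';
  std::vector<std::pair<int, int> > chunks; // consumed nt intervals (reversed)
  std::string emit;                          // emitted residues (reversed)
  int n_stop = 0, n_fs = 0, n_intron = 0;
  int p_start = bi;
  bool done = false;
  while (!done) {
    if (state == 'M') {
      unsigned char code = ptrM[(size_t)i * W + j];
      if (code == 7) {
        chunks.push_back({j - 1, j}); emit.push_back('X'); ++n_fs;
        --i; j -= 2; p_start = i + 1;
        continue;
      }
      if (code == 5) { chunks.push_back({j - 3, j}); ++n_fs; }
      else chunks.push_back({j - 2, j});
      char aa = aaend[j];
      emit.push_back(aa);
      if (aa == '*') ++n_stop;
      p_start = i;
      switch (code) {
        case 1: done = true; break;
        case 2: --i; j -= 3; break;
        case 3: state = 'P'; --i; j -= 3; break;
        case 4: state = 'C'; --i; j -= 3; break;
        case 5: --i; j -= 4; break;
        case 6: {
          int s = j - 2, t = s - 1 - min_intron;
          double dbest = NEG_INF; int earg = -1;
          for (int e = 3; e <= t; ++e) {
            if (e + 1 <= n - 1 && isGT[e + 1]) {
              double v = M[(size_t)(i - 1) * W + e];
              if (v >= dbest) { dbest = v; earg = e; }
            }
          }
          ++n_intron;
          --i; j = earg;
          break;
        }
        default: done = true; break;
      }
    } else if (state == 'P') {
      unsigned char code = ptrDp[(size_t)i * W + j];
      if (code == 1) { state = 'M'; --i; }
      else { --i; }
    } else { // 'C'
      chunks.push_back({j - 2, j});
      char aa = aaend[j];
      emit.push_back(aa);
      if (aa == '*') ++n_stop;
      unsigned char code = ptrDc[(size_t)i * W + j];
      j -= 3;
      if (code == 1) state = 'M';
    }
  }
  std::reverse(chunks.begin(), chunks.end());
  std::reverse(emit.begin(), emit.end());
  // merge contiguous chunks into exons
  std::vector<int> ex_s, ex_e;
  for (size_t c = 0; c < chunks.size(); ++c) {
    if (!ex_s.empty() && chunks[c].first == ex_e.back() + 1)
      ex_e.back() = chunks[c].second;
    else { ex_s.push_back(chunks[c].first); ex_e.push_back(chunks[c].second); }
  }
  std::string cds;
  for (size_t c = 0; c < chunks.size(); ++c)
    cds.append(dna, chunks[c].first - 1, chunks[c].second - chunks[c].first + 1);
  IntegerMatrix exons((int)ex_s.size(), 2);
  for (size_t c = 0; c < ex_s.size(); ++c) {
    exons(c, 0) = ex_s[c]; exons(c, 1) = ex_e[c];
  }
  return List::create(_["score"] = best, _["p_start"] = p_start,
                      _["p_end"] = bi, _["exons"] = exons,
                      _["cds"] = cds, _["protein"] = emit,
                      _["n_stop"] = n_stop, _["n_fs"] = n_fs,
                      _["n_intron"] = n_intron);
}
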