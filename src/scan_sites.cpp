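// Seed-weighted Smith-Waterman scan of a miRNA against a DNA scan region,
// with affine gaps, greedy extraction of non-overlapping sites and a
// simplified nearest-neighbor stack energy for each extracted duplex.
//
// Conventions (mirrored exactly by the pure-R oracle in the test suite):
//  - the miRNA (RNA, 5'->3') is reversed, so alignment columns pair the
//    miRNA 3'->5' against the region 5'->3' (antiparallel duplex);
//  - pair classes: Watson-Crick A-T / U-A / G-C / C-G; wobble G-T / U-G
//    (region read as its RNA transcript);
//  - column scores match/wobble/mismatch are multiplied by the seed weight
//    when the column consumes a miRNA base whose position from the 5' end
//    lies in [seed_lo, seed_hi]; gap penalties are unweighted;
//  - H ties prefer diagonal > gap-in-region (E) > gap-in-miRNA (F) > stop;
//    E/F ties prefer gap-open over gap-extend; the best cell maximizes H,
//    ties broken by smaller region index then smaller miRNA index;
//  - extraction: take the best local alignment; if its score is <= the
//    score threshold, stop; otherwise record it (whether or not it passes
//    the energy threshold), mask its region span, and repeat;
//  - energy: over alignment columns, every two adjacent paired columns with
//    no intervening gap/mismatch column form a stack: both pairs GC-type
//    -3.3, both AU-type -1.1, one of each -2.1, any wobble -1.0 kcal/mol.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static inline int pair_class(char m, char r) {
  if ((m == 'A' && r == 'T') || (m == 'U' && r == 'A') ||
      (m == 'G' && r == 'C') || (m == 'C' && r == 'G')) return 1;  // WC
  if ((m == 'G' && r == 'T') || (m == 'U' && r == 'G')) return 2;  // wobble
  return 0;
}

static inline int pair_type(char m, char r) {
  int c = pair_class(m, r);
  if (c == 2) return 3;                                  // wobble
  if (c == 1) return (m == 'G' || m == 'C') ? 1 : 2;     // GC : AU
  return 0;
}

// [[Rcpp::export(name = ".scan_sites_cpp")]]
DataFrame scan_sites_cpp(std::string region, std::string mirna,
                         double match = 5.0, double wobble = 2.0,
                         double mismatch = -3.0, double gap_open = -8.0,
                         double gap_extend = -2.0, int seed_lo = 2,
                         int seed_hi = 8, double seed_mult = 2.0,
                         double score_min = 140.0, int max_sites = 1000) {
  const int L = region.size();
  const int M = mirna.size();
  std::string q(mirna.rbegin(), mirna.rend());  // miRNA 3'->5'
  std::vector<double> w(M + 1, 1.0);
  for (int j = 1; j <= M; ++j) {
    int orig = M - j + 1;  // position from miRNA 5' end
    if (orig >= seed_lo && orig <= seed_hi) w[j] = seed_mult;
  }
  const double NEG = -1e18;
  std::vector<bool> masked(L + 1, false);

  // substitution table: region base index (A,C,G,T) x reversed-miRNA pos
  auto base_idx = [](char c) {
    switch (c) { case 'A': return 0; case 'C': return 1;
                 case 'G': return 2; case 'T': return 3; default: return -1; }
  };
  std::vector<int> ridx(L);
  for (int i = 0; i < L; ++i) ridx[i] = base_idx(region[i]);
  std::vector<double> sub(4 * (M + 1));
  for (int j = 1; j <= M; ++j) {
    const char bases[4] = {'A', 'C', 'G', 'T'};
    for (int b = 0; b < 4; ++b) {
      int pc = pair_class(q[j - 1], bases[b]);
      sub[b * (M + 1) + j] =
          (pc == 1 ? match : (pc == 2 ? wobble : mismatch)) * w[j];
    }
  }

  // fast score-only pass with rolling rows; almost every scanned pair has
  // no above-threshold site, so the pointer matrices below are rarely built
  auto best_score = [&]() {
    std::vector<double> Hrow(M + 1, 0.0), Hprev(M + 1, 0.0),
        Frow(M + 1, NEG), Fprev(M + 1, NEG);
    double best = 0.0;
    for (int i = 1; i <= L; ++i) {
      if (masked[i]) {
        std::fill(Hprev.begin(), Hprev.end(), 0.0);
        std::fill(Fprev.begin(), Fprev.end(), NEG);
        continue;
      }
      const double *srow = &sub[ridx[i - 1] * (M + 1)];
      double e = NEG;
      Hrow[0] = 0.0; Frow[0] = NEG;
      for (int j = 1; j <= M; ++j) {
        e = std::max(Hrow[j - 1] + gap_open, e + gap_extend);
        double f = std::max(Hprev[j] + gap_open, Fprev[j] + gap_extend);
        double h = Hprev[j - 1] + srow[j];
        if (e > h) h = e;
        if (f > h) h = f;
        if (h < 0) h = 0;
        Hrow[j] = h; Frow[j] = f;
        if (h > best) best = h;
      }
      std::swap(Hrow, Hprev);
      std::swap(Frow, Fprev);
    }
    return best;
  };

  std::vector<double> H, E, F;
  // pointers: pH 0 stop, 1 diag, 2 from E, 3 from F; pE/pF 1 open, 2 extend
  std::vector<signed char> pH, pE, pF;
  std::vector<int> out_start, out_end;
  std::vector<double> out_score, out_energy;
  std::vector<std::string> out_amir, out_apair, out_areg;

  for (int iter = 0; iter < max_sites; ++iter) {
    if (best_score() <= score_min) break;
    if (H.empty()) {
      H.resize((L + 1) * (M + 1)); E.resize((L + 1) * (M + 1));
      F.resize((L + 1) * (M + 1));
      pH.resize((L + 1) * (M + 1)); pE.resize((L + 1) * (M + 1));
      pF.resize((L + 1) * (M + 1));
    }
    // full DP over the current mask
    for (int j = 0; j <= M; ++j) { H[j] = 0; E[j] = NEG; F[j] = NEG; }
    for (int i = 1; i <= L; ++i) {
      double *Hi = &H[i * (M + 1)], *Hp = &H[(i - 1) * (M + 1)];
      double *Ei = &E[i * (M + 1)];
      double *Fi = &F[i * (M + 1)], *Fp = &F[(i - 1) * (M + 1)];
      signed char *pHi = &pH[i * (M + 1)], *pEi = &pE[i * (M + 1)],
                  *pFi = &pF[i * (M + 1)];
      Hi[0] = 0; Ei[0] = NEG; Fi[0] = NEG; pHi[0] = 0;
      if (masked[i]) {
        for (int j = 1; j <= M; ++j) {
          Hi[j] = 0; Ei[j] = NEG; Fi[j] = NEG;
          pHi[j] = 0; pEi[j] = 0; pFi[j] = 0;
        }
        continue;
      }
      for (int j = 1; j <= M; ++j) {
        int pc = pair_class(q[j - 1], region[i - 1]);
        double s = (pc == 1 ? match : (pc == 2 ? wobble : mismatch)) * w[j];
        // E: column consumes miRNA base j, gap in region
        double e_open = Hi[j - 1] + gap_open, e_ext = Ei[j - 1] + gap_extend;
        Ei[j] = std::max(e_open, e_ext);
        pEi[j] = (e_open >= e_ext) ? 1 : 2;
        // F: column consumes region base i, gap in miRNA
        double f_open = Hp[j] + gap_open, f_ext = Fp[j] + gap_extend;
        Fi[j] = std::max(f_open, f_ext);
        pFi[j] = (f_open >= f_ext) ? 1 : 2;
        double diag = Hp[j - 1] + s;
        double best = 0; signed char ptr = 0;
        if (diag >= best) { best = diag; ptr = 1; }
        if (Ei[j] > best) { best = Ei[j]; ptr = 2; }
        if (Fi[j] > best) { best = Fi[j]; ptr = 3; }
        Hi[j] = best; pHi[j] = ptr;
      }
    }
    // argmax, ties -> smaller i then smaller j
    double best = score_min; int bi = -1, bj = -1;
    for (int i = 1; i <= L; ++i)
      for (int j = 1; j <= M; ++j)
        if (H[i * (M + 1) + j] > best) {
          best = H[i * (M + 1) + j]; bi = i; bj = j;
        }
    if (bi < 0) break;  // no alignment exceeds the score threshold

    // traceback
    std::string amir, apair, areg;
    int i = bi, j = bj, state = 0;  // 0 in H, 2 in E, 3 in F
    int end_i = bi;
    while (true) {
      if (state == 0) {
        signed char ptr = pH[i * (M + 1) + j];
        if (ptr == 0) break;
        if (ptr == 1) {
          int pt = pair_class(q[j - 1], region[i - 1]);
          amir.push_back(q[j - 1]);
          apair.push_back(pt == 1 ? '|' : (pt == 2 ? ':' : ' '));
          areg.push_back(region[i - 1]);
          --i; --j;
        } else state = ptr;
      } else if (state == 2) {
        signed char ptr = pE[i * (M + 1) + j];
        amir.push_back(q[j - 1]); apair.push_back(' '); areg.push_back('-');
        --j;
        if (ptr == 1) state = 0;
      } else {
        signed char ptr = pF[i * (M + 1) + j];
        amir.push_back('-'); apair.push_back(' ');
        areg.push_back(region[i - 1]);
        --i;
        if (ptr == 1) state = 0;
      }
    }
    int start_i = i;  // 0-based region start of the site
    std::reverse(amir.begin(), amir.end());
    std::reverse(apair.begin(), apair.end());
    std::reverse(areg.begin(), areg.end());

    // stack energy over adjacent paired columns
    double energy = 0.0;
    int prev_type = 0;
    for (size_t k = 0; k < amir.size(); ++k) {
      int t = (amir[k] == '-' || areg[k] == '-')
                  ? 0 : pair_type(amir[k], areg[k]);
      if (t > 0 && prev_type > 0) {
        if (t == 3 || prev_type == 3) energy += -1.0;
        else if (t == 1 && prev_type == 1) energy += -3.3;
        else if (t == 2 && prev_type == 2) energy += -1.1;
        else energy += -2.1;
      }
      prev_type = t;
    }

    out_start.push_back(start_i);
    out_end.push_back(end_i);
    out_score.push_back(best);
    out_energy.push_back(energy);
    out_amir.push_back(amir);
    out_apair.push_back(apair);
    out_areg.push_back(areg);
    for (int k = start_i + 1; k <= end_i; ++k) masked[k] = true;
  }

  return DataFrame::create(
      _["target_start"] = out_start, _["target_end"] = out_end,
      _["align_score"] = out_score, _["energy"] = out_energy,
      _["align_mirna"] = out_amir, _["align_pairs"] = out_apair,
      _["align_region"] = out_areg, _["stringsAsFactors"] = false);
}
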