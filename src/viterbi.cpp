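#include <Rcpp.h>
using namespace Rcpp;

// Local profile-HMM Viterbi in bit space.
//
// lm: L x 20 match log-odds (bits); li: L x 20 insert log-odds (row k =
// insert state I_k; I_L is never used); lt: L x 7 log2 transition
// probabilities for nodes 1..L, columns (MM, MI, MD, IM, II, DM, DD);
// x: 0-based residue indices.
//
// A local path enters the model at any match state (free entry), walks
// M/I/D transitions, and exits from any match state (free exit). The score
// of a path is the sum of emission log-odds plus transition log2
// probabilities; delete states emit nothing. Returned coordinates are the
// 1-based first and last residues consumed by the best path.
// [[Rcpp::export(name = ".viterbi_local")]]
List viterbi_local(NumericMatrix lm, NumericMatrix li, NumericMatrix lt,
                   IntegerVector x) {
  const int L = lm.nrow();
  const int n = x.size();
  const double NEG = R_NegInf;

  std::vector<double> VMp(L + 1, NEG), VIp(L + 1, NEG), VDp(L + 1, NEG);
  std::vector<double> VM(L + 1, NEG), VI(L + 1, NEG), VD(L + 1, NEG);
  std::vector<int> SMp(L + 1, 0), SIp(L + 1, 0), SDp(L + 1, 0);
  std::vector<int> SM(L + 1, 0), SI(L + 1, 0), SD(L + 1, 0);

  double best = NEG;
  int best_start = 0, best_end = 0;

  for (int i = 1; i <= n; ++i) {
    const int xi = x[i - 1];
    for (int k = 1; k <= L; ++k) {
      // match state: fresh local entry, or extension from node k-1
      double b = 0.0;  // fresh start at residue i
      int s = i;
      if (k > 1) {
        const double fm = VMp[k - 1] + lt(k - 2, 0);
        const double fi = VIp[k - 1] + lt(k - 2, 3);
        const double fd = VDp[k - 1] + lt(k - 2, 5);
        if (fm > b) { b = fm; s = SMp[k - 1]; }
        if (fi > b) { b = fi; s = SIp[k - 1]; }
        if (fd > b) { b = fd; s = SDp[k - 1]; }
      }
      VM[k] = lm(k - 1, xi) + b;
      SM[k] = s;

      // insert state I_k (k < L only)
      if (k < L) {
        const double gm = VMp[k] + lt(k - 1, 1);
        const double gi = VIp[k] + lt(k - 1, 4);
        if (gm >= gi) { VI[k] = li(k - 1, xi) + gm; SI[k] = SMp[k]; }
        else          { VI[k] = li(k - 1, xi) + gi; SI[k] = SIp[k]; }
      } else {
        VI[k] = NEG;
      }
    }
    // delete pass (same residue count, runs along k)
    VD[1] = NEG;
    for (int k = 2; k <= L; ++k) {
      const double hm = VM[k - 1] + lt(k - 2, 2);
      const double hd = VD[k - 1] + lt(k - 2, 6);
      if (hm >= hd) { VD[k] = hm; SD[k] = SM[k - 1]; }
      else          { VD[k] = hd; SD[k] = SD[k - 1]; }
    }
    for (int k = 1; k <= L; ++k) {
      if (VM[k] > best) { best = VM[k]; best_start = SM[k]; best_end = i; }
    }
    std::swap(VM, VMp); std::swap(VI, VIp); std::swap(VD, VDp);
    std::swap(SM, SMp); std::swap(SI, SIp); std::swap(SD, SDp);
  }

  return List::create(_["bit_score"] = best,
                      _["ali_start"] = best_start,
                      _["ali_end"] = best_end);
}
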