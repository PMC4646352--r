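#include <Rcpp.h>
using namespace Rcpp;

// Local (entry/exit at any match state) profile-HMM Viterbi in bit units.
//
// emis: K x 21 matrix of match-state log2-odds; column 21 (index 20) is the
//       "unknown residue" column, fixed at 0 by the caller.
// Insert states emit at background (log-odds 0). Transitions are log2
// probabilities of the inter-column moves; vectors have length K-1 and entry
// k (0-based) covers the gap between match columns k+1 and k+2:
//   tmm: M_k -> M_{k+1}   tmi: M_k -> I_k     tmd: M_k -> D_{k+1}
//   tim: I_k -> M_{k+1}   tii: I_k -> I_k
//   tdm: D_k -> M_{k+1}   tdd: D_k -> D_{k+1}
// Entry into any M and exit from any M are free (score 0), as in local
// domain-search scoring.

// [[Rcpp::export]]
List viterbi_cpp(IntegerVector seq, NumericMatrix emis,
                 NumericVector tmm, NumericVector tmi, NumericVector tmd,
                 NumericVector tim, NumericVector tii,
                 NumericVector tdm, NumericVector tdd) {
  const int L = seq.size(), K = emis.nrow();
  const double NEG = -1e300;

  // scores at (i, k): i residues consumed, state at column k (1-based k)
  std::vector<double> M((L + 1) * (K + 1), NEG), I((L + 1) * (K + 1), NEG),
      D((L + 1) * (K + 1), NEG);
  // pointers: M: 0=entry,1=fromM,2=fromI,3=fromD; I: 1=fromM,2=fromI;
  //           D: 1=fromM,3=fromD
  std::vector<unsigned char> pM((L + 1) * (K + 1), 0),
      pI((L + 1) * (K + 1), 0), pD((L + 1) * (K + 1), 0);

  double best = NEG; int bi = -1, bk = -1;
  for (int i = 1; i <= L; ++i) {
    const int a = seq[i - 1];
    for (int k = 1; k <= K; ++k) {
      const size_t idx = (size_t)i * (K + 1) + k;
      const size_t prev = (size_t)(i - 1) * (K + 1) + (k - 1); // (i-1, k-1)
      // match
      double e = emis(k - 1, a);
      double sc = 0.0; unsigned char p = 0; // free entry
      if (k > 1) {
        double fm = M[prev] + tmm[k - 2];
        double fi = I[prev] + tim[k - 2];
        double fd = D[prev] + tdm[k - 2];
        if (fm > sc) { sc = fm; p = 1; }
        if (fi > sc) { sc = fi; p = 2; }
        if (fd > sc) { sc = fd; p = 3; }
      }
      M[idx] = e + sc; pM[idx] = p;
      if (M[idx] > best) { best = M[idx]; bi = i; bk = k; }
      // insert I_k exists for k < K; consumes residue i at background
      if (k < K) {
        const size_t up = (size_t)(i - 1) * (K + 1) + k;
        double fm = M[up] + tmi[k - 1];
        double fi = I[up] + tii[k - 1];
        if (fm >= fi) { I[idx] = fm; pI[idx] = 1; } else { I[idx] = fi; pI[idx] = 2; }
      }
      // delete D_k (no residue consumed), reachable for k >= 2
      if (k >= 2) {
        const size_t left = (size_t)i * (K + 1) + (k - 1);
        double fm = M[left] + tmd[k - 2];
        double fd = D[left] + tdd[k - 2];
        if (fm >= fd) { D[idx] = fm; pD[idx] = 1; } else { D[idx] = fd; pD[idx] = 3; }
      }
    }
  }

  int env_start = -1, env_end = -1, nM = 0, nI = 0, nD = 0;
  int k_start = -1, k_end = bk;
  if (bi >= 1) {
    env_end = bi; // 1-based inclusive end -> half-open end
    int i = bi, k = bk; char st = 'M';
    while (true) {
      size_t idx = (size_t)i * (K + 1) + k;
      if (st == 'M') {
        ++nM;
        unsigned char p = pM[idx];
        if (p == 0) { env_start = i; k_start = k; break; }
        --i; --k;
        st = (p == 1) ? 'M' : (p == 2) ? 'I' : 'D';
      } else if (st == 'I') {
        ++nI;
        unsigned char p = pI[idx];
        --i;
        st = (p == 1) ? 'M' : 'I';
      } else {
        ++nD;
        unsigned char p = pD[idx];
        --k;
        st = (p == 1) ? 'M' : 'D';
      }
    }
  }

  return List::create(
    _["score_bits"] = (bi >= 1) ? best : R_NegInf,
    _["env_start"] = (bi >= 1) ? env_start - 1 : NA_INTEGER, // 0-based half-open
    _["env_end"] = (bi >= 1) ? env_end : NA_INTEGER,
    _["first_match_state"] = k_start, _["last_match_state"] = k_end,
    _["n_match"] = nM, _["n_insert"] = nI, _["n_delete"] = nD);
}
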