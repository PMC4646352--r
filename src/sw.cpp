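#include <Rcpp.h>
using namespace Rcpp;

// Gotoh three-matrix Smith-Waterman with affine gaps.
// Sequences arrive as 0-based integer codes into the 20x20 substitution
// matrix. Opening a gap costs gap_open + gap_extend for its first position
// (BLAST dialect), each additional position gap_extend.
//
// Traceback tie-breaking: diagonal, then gap-in-subject (query residue
// against a gap), then gap-in-query.

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector s, IntegerMatrix sub,
                  int gap_open, int gap_extend) {
  const int n = q.size(), m = s.size();
  const int open_cost = gap_open + gap_extend;
  const int NEG = INT_MIN / 4;

  // score matrices, (n+1) x (m+1), row-major
  std::vector<int> H((n + 1) * (m + 1), 0);
  std::vector<int> X((n + 1) * (m + 1), NEG); // gap in subject (consumes query)
  std::vector<int> Y((n + 1) * (m + 1), NEG); // gap in query  (consumes subject)
  // traceback: for H, 0=stop(local start),1=diag,2=fromX,3=fromY
  std::vector<unsigned char> ptrH((n + 1) * (m + 1), 0);
  // for X/Y: 0 = opened from H, 1 = extended
  std::vector<unsigned char> ptrX((n + 1) * (m + 1), 0);
  std::vector<unsigned char> ptrY((n + 1) * (m + 1), 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int qi = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      const size_t idx = (size_t)i * (m + 1) + j;
      const size_t up = idx - (m + 1), left = idx - 1, diag = up - 1;

      int xo = H[up] - open_cost, xe = X[up] - gap_extend;
      if (xo >= xe) { X[idx] = xo; ptrX[idx] = 0; } else { X[idx] = xe; ptrX[idx] = 1; }

      int yo = H[left] - open_cost, ye = Y[left] - gap_extend;
      if (yo >= ye) { Y[idx] = yo; ptrY[idx] = 0; } else { Y[idx] = ye; ptrY[idx] = 1; }

      int d = H[diag] + sub(qi, s[j - 1]);
      // preference order on ties: diagonal, gap-in-subject, gap-in-query, stop
      int h = d; unsigned char p = 1;
      if (X[idx] > h) { h = X[idx]; p = 2; }
      if (Y[idx] > h) { h = Y[idx]; p = 3; }
      if (h <= 0) { h = 0; p = 0; }
      H[idx] = h; ptrH[idx] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  int qstart = 0, qend = 0, sstart = 0, send = 0;
  int n_ident = 0, n_cols = 0;
  if (best > 0) {
    int i = bi, j = bj; char state = 'H';
    qend = bi; send = bj;
    while (true) {
      size_t idx = (size_t)i * (m + 1) + j;
      if (state == 'H') {
        unsigned char p = ptrH[idx];
        if (p == 0) break;
        if (p == 1) {
          ++n_cols;
          if (q[i - 1] == s[j - 1]) ++n_ident;
          --i; --j;
          if (H[(size_t)i * (m + 1) + j] == 0 && ptrH[(size_t)i * (m + 1) + j] == 0) {
            // continue loop; stop handled by p==0 next round
          }
        } else if (p == 2) state = 'X';
        else state = 'Y';
      } else if (state == 'X') {
        ++n_cols;
        unsigned char p = ptrX[idx];
        --i;
        state = (p == 0) ? 'H' : 'X';
      } else { // Y
        ++n_cols;
        unsigned char p = ptrY[idx];
        --j;
        state = (p == 0) ? 'H' : 'Y';
      }
      if (i == 0 || j == 0) {
        if (state != 'H') { /* gap runs cannot start the local path */ }
        break;
      }
    }
    qstart = i; sstart = j; // 0-based starts after full traceback
  }

  return List::create(
    _["score"] = best,
    _["qstart"] = qstart, _["qend"] = qend,   // 0-based half-open on query
    _["sstart"] = sstart, _["send"] = send,   // 0-based half-open on subject
    _["n_identical"] = n_ident,
    _["n_columns"] = n_cols);
}

// Plain score-only variant used for bulk all-vs-all scans (no traceback).
// [[Rcpp::export]]
int sw_score_cpp(IntegerVector q, IntegerVector s, IntegerMatrix sub,
                 int gap_open, int gap_extend) {
  const int n = q.size(), m = s.size();
  const int open_cost = gap_open + gap_extend;
  const int NEG = INT_MIN / 4;
  std::vector<int> Hrow(m + 1, 0), Xrow(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    const int qi = q[i - 1];
    int Hdiag = 0, Y = NEG, Hleft = 0;
    for (int j = 1; j <= m; ++j) {
      int X = std::max(Hrow[j] - open_cost, Xrow[j] - gap_extend);
      Y = std::max(Hleft - open_cost, Y - gap_extend);
      int h = std::max(std::max(Hdiag + sub(qi, s[j - 1]), std::max(X, Y)), 0);
      Hdiag = Hrow[j];
      Hrow[j] = h; Xrow[j] = X; Hleft = h;
      if (h > best) best = h;
    }
  }
  return best;
}
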